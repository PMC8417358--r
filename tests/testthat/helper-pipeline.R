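# memoised pipeline run on the small shared simulation (reused by the
# pipeline and acceptance tests to stay within the suite's time budget)
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sm <- small_sim()
      outdir <- file.path(tempdir(), "panrescue_small_out")
      res <- run_pipeline(sm$sim$ref, sm$sim$panel_vcf, sm$sim$sam, outdir,
                          config = pipeline_config(seed = 1L))
      cache <<- list(sm = sm, res = res, outdir = outdir)
    }
    cache
  }
})

# match calls against truth records: same locus (un-normalized anchor
# coordinates), equivalent type (a duplication is an insertion of its
# segment), and svlen within tolerance
score_recovery <- function(truth, calls, pos_tol = 60L, len_tol = 5L) {
  type_match <- function(a, b) (a == "DEL") == (b == "DEL")
  hit_gt <- character(nrow(truth))
  hits <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tv <- truth[i, ]
    j <- which(calls$contig == tv$contig &
                 abs(calls$pos - tv$pos) <= pos_tol &
                 type_match(calls$svtype, tv$svtype) &
                 abs(calls$svlen - tv$svlen) <= len_tol)
    if (length(j)) {
      hits[i] <- TRUE
      hit_gt[i] <- calls$gt[j[1]]
    }
  }
  list(hits = hits, gt = hit_gt,
       recall = mean(hits),
       gt_concordance = if (any(hits))
         mean(hit_gt[hits] == truth$gt[hits]) else NA_real_)
}
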