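# Pipeline orchestration: build-ref -> index -> extract -> realign/pair ->
# cluster -> assemble/infer -> VCF, with per-stage accounting and one
# pipeline-level RNG seed recorded in the report.

#' Pipeline configuration
#'
#' @param flank anchor flank length (default 250).
#' @param k index/seed k-mer length (default 22).
#' @param max_occ seed uniqueness threshold (default 4).
#' @param top_chains chains extended per read (default 12).
#' @param pair_bonus proper-pair bonus K (default 50).
#' @param isize_fallback `c(mean, sd)` used when too few proper pairs.
#' @param depth_min minimum breakpoint depth for a call; `NULL` means
#'   `max(3, 0.1 * mean depth)`: evidence depth among
#'   extracted signal reads runs well below raw coverage at the thinnest
#'   breakpoint class (heterozygous duplications).
#' @param word assembler word length (default 25).
#' @param min_support minimum reads agreeing per extension base (default 2).
#' @param min_reads minimum reads per contig (default 3).
#' @param max_mm maximum mismatches in read-to-contig realignment
#'   (default 3).
#' @param mapq_margin median score gain at or below which a MAPQ-0 cluster
#'   is uncertain (default 5).
#' @param min_svlen minimum reported SV length (default 50).
#' @param seed pipeline RNG seed (default 1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(flank = 250L, k = 22L, max_occ = 4L,
                            top_chains = 12L, pair_bonus = 50,
                            isize_fallback = c(400, 50), depth_min = NULL,
                            word = 25L, min_support = 2L, min_reads = 3L,
                            max_mm = 3L, mapq_margin = 5, min_svlen = 50L,
                            seed = 1L) {
  stopifnot(flank >= 50L, k >= 8L, k <= 31L, max_occ >= 1L,
            top_chains >= 1L, pair_bonus >= 0, word >= 8L,
            min_support >= 1L, min_reads >= 1L, min_svlen >= 1L)
  structure(list(flank = as.integer(flank), k = as.integer(k),
                 max_occ = as.integer(max_occ),
                 top_chains = as.integer(top_chains),
                 pair_bonus = pair_bonus, isize_fallback = isize_fallback,
                 depth_min = depth_min, word = as.integer(word),
                 min_support = as.integer(min_support),
                 min_reads = as.integer(min_reads),
                 max_mm = as.integer(max_mm), mapq_margin = mapq_margin,
                 min_svlen = as.integer(min_svlen), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full SV-rescue pipeline
#'
#' @param ref_fasta reference genome FASTA.
#' @param known_vcf VCF of known SVs (the panel).
#' @param alignments SAM or BAM of original short-read alignments.
#' @param outdir output directory; intermediate files are preserved there.
#' @param config a `pipeline_config`.
#' @return a list of class `panrescue_result`: `calls` (data frame),
#'   `vcf` (path), `report` (per-stage counts), `svref`.
#' @export
run_pipeline <- function(ref_fasta, known_vcf, alignments, outdir,
                         config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  genome <- read_genome(ref_fasta)
  svs <- parse_sv_vcf(known_vcf, genome)
  if (nrow(svs) == 0L) stop("no usable SV records")
  svref <- build_sv_reference(svs, genome, flank = config$flank)
  write_sv_reference(svref, file.path(outdir, "svref"))
  report$anchors <- nrow(svref$anchors)

  index <- build_index(svref, k = config$k)
  params <- realign_params(max_occ = config$max_occ,
                           top_chains = config$top_chains,
                           pair_bonus = config$pair_bonus,
                           seed = config$seed)

  orig <- read_alignments(alignments)
  sig_fq <- file.path(outdir, "signals.fq")
  ext <- extract_signal_reads(orig, sig_fq)
  report$pairs_total <- ext$total
  report$pairs_extracted <- ext$emitted

  mapped <- !is.na(orig$pos)
  model <- suppressWarnings(estimate_isize(
    orig$isize[mapped & flag_bit(orig$flag, 0x2) & flag_bit(orig$flag, 0x40)],
    fallback = config$isize_fallback))
  mean_depth <- sum(vapply(orig$cigar[mapped],
                           function(c) cigar_stats(c)$n_m, numeric(1))) /
    sum(nchar(genome))
  report$mean_depth <- round(mean_depth, 2)
  depth_min <- if (is.null(config$depth_min)) max(3, 0.1 * mean_depth)
               else config$depth_min

  pairs <- read_signal_fastq(sig_fq)
  kept <- list()
  for (pr in pairs) {
    r1 <- pr[[1]]; r2 <- pr[[2]]
    alns1 <- if (nchar(r1$seq) >= config$k)
      realign_read(r1$seq, index, svref, params) else list()
    alns2 <- if (nchar(r2$seq) >= config$k)
      realign_read(r2$seq, index, svref, params) else list()
    cand1 <- pair_candidates(alns1, r1$orig)
    cand2 <- pair_candidates(alns2, r2$orig)
    ps <- score_pairings(cand1, cand2, svref, model, K = config$pair_bonus)
    if (is.null(ps) || !filter_original_best(ps, cand1, cand2)) next
    mk_end <- function(sig, cand) {
      if (is.null(cand) || cand$source != "pansvr") {
        list(mate = sig$mate, seq = sig$seq, qual = sig$qual,
             aln = NULL, orig = sig$orig)
      } else {
        list(mate = sig$mate, seq = sig$seq, qual = sig$qual,
             aln = cand$aln, orig = sig$orig)
      }
    }
    kept[[length(kept) + 1L]] <- list(
      name = r1$name, proper = ps$proper,
      ends = list(mk_end(r1, ps$c1), mk_end(r2, ps$c2)))
  }
  report$pairs_kept <- length(kept)
  emit_sam(kept, svref, file.path(outdir, "realigned.sam"))

  reads <- list()
  for (pr in kept) {
    for (e in pr$ends) {
      if (is.null(e$aln)) next
      a <- e$aln
      reads[[length(reads) + 1L]] <- list(
        name = paste0(pr$name, "/", e$mate), seq = e$seq, qual = e$qual,
        anchor_id = a$anchor_id, anc_start = a$anc_start,
        anc_end = a$anc_end, strand = a$strand, score = a$score,
        mm = a$mm, cigar = a$cigar, orig = e$orig)
    }
  }
  report$reads_realigned <- length(reads)

  clusters <- cluster_reads(reads, svref, k = config$k, seed = config$seed)
  report$clusters <- length(clusters)

  all_calls <- list()
  n_contigs <- 0L
  for (cl in clusters) {
    anchor <- svref$anchors[svref$anchors$anchor_id == cl$anchor_id, ]
    rds <- depth_filter(cl$reads, mean_depth)
    if (!mapq_filter(rds, margin = config$mapq_margin)) next
    if (length(rds) < config$min_reads) next
    oriented <- vapply(rds, function(r)
      if (r$strand == "-") revcomp(r$seq) else r$seq, character(1))
    starts <- vapply(rds, `[[`, numeric(1), "anc_start")
    # long SV regions are assembled per 500 bp block
    block_of <- if (anchor$svlen > 500L) starts %/% 500L else rep(0L, length(rds))
    calns <- list()
    support <- 0L
    for (b in unique(block_of)) {
      sel <- block_of == b
      contigs <- assemble(oriented[sel], word = config$word,
                          min_support = config$min_support,
                          min_reads = config$min_reads,
                          hints = starts[sel])
      for (ct in contigs) {
        n_contigs <- n_contigs + 1L
        ra <- realign_reads_to_contig(oriented[sel][ct$members], ct$seq,
                                      ct$joins, max_mm = config$max_mm)
        ct$depth <- ra$depth
        mem_global <- which(sel)[ct$members]
        cands <- starts[mem_global] - ct$joins
        # every kept read descends from a pair that strictly improved on
        # the original aligner (pair filter), so the improvement
        # requirement holds by construction here
        caln <- align_consensus(ct, cands, improved = TRUE, anchor, params)
        if (is.null(caln)) next
        calns[[length(calns) + 1L]] <- caln
        support <- support + sum(ra$included)
      }
    }
    if (length(calns)) {
      calls <- infer_svs(calns, anchor, depth_min,
                         min_svlen = config$min_svlen, n_support = support)
      if (nrow(calls)) all_calls[[length(all_calls) + 1L]] <- calls
    }
  }
  report$contigs <- n_contigs

  calls <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(contig = character(0), pos = integer(0), svtype = character(0),
               svlen = integer(0), alt_seq = character(0),
               alt_depth = integer(0), n_support = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(calls)) {
    calls$gt <- NA_character_
    for (i in seq_len(nrow(calls))) {
      rd <- ref_support_depth(orig, calls$contig[i], calls$pos[i])
      calls$gt[i] <- genotype_call(calls$alt_depth[i], rd)
    }
    calls <- calls[!is.na(calls$gt), , drop = FALSE]
    calls <- dedup_calls(calls)
  } else {
    calls$gt <- character(0)
  }
  report$calls <- nrow(calls)

  vcf_path <- file.path(outdir, "calls.vcf")
  write_calls_vcf(calls, genome, vcf_path)
  writeLines(paste(names(report), unlist(report), sep = "\t"),
             file.path(outdir, "report.tsv"))
  structure(list(calls = calls, vcf = vcf_path, report = report,
                 svref = svref), class = "panrescue_result")
}

#' @export
print.panrescue_result <- function(x, ...) {
  cat("panrescue pipeline result\n")
  for (nm in names(x$report)) cat(sprintf("  %-16s %s\n", nm, x$report[[nm]]))
  invisible(x)
}

# confident reference-allele depth at a breakpoint: full-length matched
# primary records spanning pos +/- margin
ref_support_depth <- function(orig, contig, pos, margin = 10L) {
  mapped <- !is.na(orig$pos) & orig$rname == contig
  full_m <- grepl("^[0-9]+M$", orig$cigar)
  span <- integer(nrow(orig))
  cand <- which(mapped & full_m)
  if (!length(cand)) return(0L)
  lens <- as.integer(sub("M$", "", orig$cigar[cand]))
  hit <- orig$pos[cand] <= pos - margin &
    orig$pos[cand] + lens - 1L >= pos + margin
  # count physical reads once
  length(unique(paste(orig$qname[cand][hit],
                      bitwAnd(orig$flag[cand][hit], 0xC0))))
}

# collapse duplicate calls of the same type within 50 bp, keeping the
# best-supported one
dedup_calls <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  calls <- calls[order(calls$contig, calls$svtype, calls$pos,
                       -calls$alt_depth), , drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    same <- prev[calls$contig[prev] == calls$contig[i] &
                   calls$svtype[prev] == calls$svtype[i] &
                   abs(calls$pos[prev] - calls$pos[i]) <= 50L]
    if (length(same)) keep[i] <- FALSE
  }
  calls[keep, , drop = FALSE]
}
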