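mk_cluster_read <- function(name, seq, anc_start, score = 100,
                            mapq = 60L, orig_score = 80) {
  list(name = name, seq = seq, qual = strrep("I", nchar(seq)),
       anchor_id = 0L, anc_start = anc_start,
       anc_end = anc_start + nchar(seq), strand = "+", score = score,
       mm = 0L, cigar = paste0(nchar(seq), "M"),
       orig = list(contig = "chr1", pos = anc_start + 1L, strand = "+",
                   score = orig_score, cigar = "100M", mapq = mapq,
                   isize = 400L, mm = 0L))
}

tile_reads <- function(hap, read_len = 60L, step = 7L, prefix = "t") {
  starts <- seq(1L, nchar(hap) - read_len + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    mk_cluster_read(paste0(prefix, i),
                    substr(hap, starts[i], starts[i] + read_len - 1L),
                    anc_start = starts[i] - 1L)
  })
}

test_that("depth filter trims over-covered 64 bp blocks by lowest score", {
  # 50x coverage of one block, mean depth 30 -> trimmed to <= 45
  reads <- lapply(1:50, function(i)
    mk_cluster_read(sprintf("r%02d", i), strrep("A", 64L), 0L, score = i))
  kept <- depth_filter(reads, mean_depth = 30)
  expect_length(kept, 45L)
  # the lowest scores were removed
  expect_true(all(vapply(kept, `[[`, numeric(1), "score") > 5))
  # depth 40 <= 45: untouched
  reads40 <- reads[1:40]
  expect_length(depth_filter(reads40, 30), 40L)
  # equal scores: removal order by read name (determinism)
  reads_eq <- lapply(1:50, function(i)
    mk_cluster_read(sprintf("r%02d", i), strrep("A", 64L), 0L, score = 7))
  kept_eq <- depth_filter(reads_eq, 30)
  expect_equal(vapply(kept_eq, `[[`, character(1), "name"),
               sprintf("r%02d", 6:50))
})

test_that("MAPQ filter discards only low-MAPQ clusters without score gain", {
  mk <- function(mapq, gain) {
    mk_cluster_read("x", strrep("A", 50L), 0L, score = 100 + gain,
                    mapq = mapq, orig_score = 100)
  }
  # 90% MAPQ 0, no gain: discard
  rds <- c(replicate(9, mk(0L, 0), simplify = FALSE),
           replicate(1, mk(60L, 0), simplify = FALSE))
  expect_false(mapq_filter(rds))
  # 90% MAPQ 0 but median gain +40: keep
  rds2 <- c(replicate(9, mk(0L, 40), simplify = FALSE),
            replicate(1, mk(60L, 40), simplify = FALSE))
  expect_true(mapq_filter(rds2))
  # 50% MAPQ 0: keep regardless
  rds3 <- c(replicate(5, mk(0L, 0), simplify = FALSE),
            replicate(5, mk(60L, 0), simplify = FALSE))
  expect_true(mapq_filter(rds3))
})

test_that("error-free tiling reads reassemble the haplotype exactly", {
  hap <- panrescue:::with_seed(41, panrescue:::random_dna(300))
  reads <- tile_reads(hap)
  seqs <- vapply(reads, `[[`, character(1), "seq")
  contigs <- assemble(seqs, word = 25L, min_len = 60L)
  expect_length(contigs, 1L)
  # the contig is the haplotype minus tips supported by fewer than two
  # reads (extension needs min_support agreeing reads)
  expect_true(grepl(contigs[[1]]$seq, hap, fixed = TRUE))
  expect_gte(nchar(contigs[[1]]$seq), 280L)
  # depth from mismatch-only realignment equals the interval-stab pileup
  ct <- contigs[[1]]
  ra <- realign_reads_to_contig(seqs[ct$members], ct$seq, ct$joins)
  expect_true(all(ra$included))
  clen <- nchar(ct$seq)
  pile <- integer(clen)
  for (j in ct$joins) {
    lo <- max(0L, j); hi <- min(clen, j + 60L)
    if (hi > lo) pile[(lo + 1L):hi] <- pile[(lo + 1L):hi] + 1L
  }
  expect_equal(ra$depth, pile)
  # depth conservation: sum equals read bases within the contig (reads
  # overhanging the contig ends are clipped)
  overlap <- vapply(ct$joins, function(j)
    min(clen, j + 60L) - max(0L, j), numeric(1))
  expect_equal(sum(ra$depth), sum(overlap))
})

test_that("1 percent read errors leave the consensus within 1 mismatch per 300 bp", {
  hap <- panrescue:::with_seed(43, panrescue:::random_dna(300))
  set.seed(44)
  reads <- tile_reads(hap, step = 4L)
  seqs <- vapply(reads, function(r) {
    s <- r$seq
    hit <- which(runif(nchar(s)) < 0.01)
    for (h in hit) {
      substr(s, h, h) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, h, h)), 1)
    }
    s
  }, character(1))
  contigs <- assemble(seqs, word = 25L, min_len = 200L)
  expect_gte(length(contigs), 1L)
  ct <- contigs[[which.max(vapply(contigs, function(c) nchar(c$seq), numeric(1)))]]
  pa <- Biostrings::pairwiseAlignment(ct$seq, hap, type = "global-local")
  mm <- Biostrings::nmismatch(pa)
  expect_lte(mm, 1L)
})

test_that("too few reads produce no contig; far-off reads are excluded from depth", {
  expect_length(assemble(c("ACGTACGTACGTACGTACGTACGTACGTAC",
                           "ACGTACGTACGTACGTACGTACGTACGTAC"),
                         word = 25L, min_reads = 3L), 0L)
  # a read with 5 mismatches at its join is excluded from depth
  contig <- panrescue:::with_seed(45, panrescue:::random_dna(100))
  bad <- contig
  for (i in c(10L, 20L, 30L, 40L, 50L)) {
    substr(bad, i, i) <- setdiff(c("A", "C", "G", "T"), substr(bad, i, i))[1]
  }
  ra <- realign_reads_to_contig(c(contig, bad), contig, c(0L, 0L), max_mm = 3L)
  expect_equal(ra$included, c(TRUE, FALSE))
  expect_true(all(ra$depth == 1L))
  # empty read set: zero depth
  ra0 <- realign_reads_to_contig(character(0), contig, integer(0))
  expect_equal(ra0$depth, integer(nchar(contig)))
})

test_that("consensus alignment records variants and applies the filters", {
  fx <- fixture_ins_svref()
  anchor <- fx$svref$anchors[1, ]
  params <- realign_params()
  window_seq <- substr(anchor$seq, 151L, 450L)  # spans the insert junction
  ct <- list(seq = window_seq, depth = rep(10L, 300L))
  # identity: zero variants, full depth projection
  caln <- align_consensus(ct, cand_starts = 150L, improved = TRUE,
                          anchor = anchor, params = params)
  expect_equal(nrow(caln$variants), 0L)
  expect_equal(caln$anc_start, 150L)
  expect_equal(unname(caln$depth_on_anchor[as.character(200L)]), 10L)
  # a 60 bp insertion relative to the anchor is recovered as one I variant
  novel <- panrescue:::with_seed(46, panrescue:::random_dna(60))
  ct2 <- list(seq = paste0(substr(window_seq, 1L, 100L), novel,
                           substr(window_seq, 101L, 300L)),
              depth = rep(10L, 360L))
  caln2 <- align_consensus(ct2, 150L, TRUE, anchor, params)
  iv <- caln2$variants[caln2$variants$type == "I", ]
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$len, 60L)
  expect_equal(iv$anc_pos, 250L)
  expect_equal(iv$seq, novel)
  # filters: no improved read, or all candidates out of range -> dropped
  expect_null(align_consensus(ct, 150L, improved = FALSE, anchor, params))
  expect_null(align_consensus(ct, anchor$len + 10L, TRUE, anchor, params))
})

test_that("inference calls the anchor SV with depths and corrects the allele", {
  fx <- fixture_ins_svref()           # 100 bp insertion at 2500
  anchor <- fx$svref$anchors[1, ]
  params <- realign_params()
  # donor allele differs from the panel allele by a 2 bp substitution
  donor_allele <- anchor$alt_seq
  substr(donor_allele, 40L, 41L) <- "TT"
  donor_window <- paste0(substr(anchor$seq, 101L, 250L), donor_allele,
                         substr(anchor$seq, 351L, 500L))
  ct <- list(seq = donor_window, depth = rep(12L, nchar(donor_window)))
  caln <- align_consensus(ct, 100L, TRUE, anchor, params)
  calls <- infer_svs(list(caln), anchor, depth_min = 3, n_support = 12L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$svtype, "INS")
  expect_equal(calls$svlen, 100L)
  expect_equal(calls$alt_seq, donor_allele)   # donor allele, not panel's
  # breakpoint depth below threshold: no call
  ct_low <- list(seq = donor_window, depth = rep(1L, nchar(donor_window)))
  caln_low <- align_consensus(ct_low, 100L, TRUE, anchor, params)
  expect_equal(nrow(infer_svs(list(caln_low), anchor, depth_min = 3)), 0L)
  # a call shorter than min_svlen is dropped
  short_anchor <- anchor
  short_anchor$svlen <- 30L
  short_anchor$ins_end <- short_anchor$ins_start + 30L
  expect_equal(nrow(infer_svs(list(caln), short_anchor, depth_min = 3)), 0L)
})

test_that("genotyping thresholds map allele fractions to GT", {
  expect_equal(genotype_call(19, 1), "1/1")    # 0.95
  expect_equal(genotype_call(10, 10), "0/1")   # 0.50
  expect_true(is.na(genotype_call(1, 9)))      # 0.10: noise
  expect_equal(genotype_call(0, 0), "./.")
})

test_that("VCF output is left-normalized with consistent alleles", {
  g <- c(chr1 = "GGTATATATATACCCC")
  # deletion of "TA" at pos 10 (1-based padding): left-normalizes into the
  # TA run
  calls <- data.frame(contig = "chr1", pos = 10L, svtype = "DEL",
                      svlen = 2L, alt_seq = "", gt = "0/1",
                      n_support = 5L, alt_depth = 5L,
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, g, path)
  body <- readLines(path)
  rec <- strsplit(body[!grepl("^#", body)], "\t")[[1]]
  expect_equal(as.integer(rec[2]), 2L)          # shifted to the run start
  expect_equal(substr(g[[1]], 2L, 2L), substr(rec[4], 1L, 1L))
  expect_equal(nchar(rec[4]) - nchar(rec[5]), 2L)
  expect_true(grepl("SVTYPE=DEL;SVLEN=-2", rec[8]))
  # the VCF parses with vcfR
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), 1L)
})
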