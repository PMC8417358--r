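test_that("the chain gap penalty matches its closed form", {
  # zero diagonal offset costs exactly the constant
  expect_equal(chain_gap_penalty(140, 100, 50, 10), 3)
  expect_equal(chain_gap_penalty(140, 100, 42, 10), 0.125 * 8 + 3)
  # the absolute value keeps the penalty non-negative either way
  expect_equal(chain_gap_penalty(110, 100, 60, 10), chain_gap_penalty(150, 100, 20, 10))
})

test_that("chaining recurrence reproduces the hand-evaluated cases", {
  # single block: base case f = L
  ch <- sdp_chain(blocks_df(100, 10, 20))
  expect_equal(ch[[1]]$score, 20)
  # co-linear pair on the same diagonal: f = 20 + 20 - 3
  ch <- sdp_chain(blocks_df(c(100, 140), c(10, 50), c(20, 20)))
  expect_equal(ch[[1]]$score, 37)
  # diagonal offset 8: theta = 4
  ch <- sdp_chain(blocks_df(c(100, 140), c(10, 42), c(20, 20)))
  expect_equal(ch[[1]]$score, 36)
  # read-overlap trims the second block's contribution to 15
  ch <- sdp_chain(blocks_df(c(100, 115), c(10, 25), c(20, 20)))
  expect_equal(ch[[1]]$score, 32)
})

test_that("chaining equals exhaustive enumeration on random instances", {
  set.seed(123)
  for (trial in 1:300) {
    n <- sample(2:9, 1)
    df <- blocks_df(ref = sort(sample(1:300, n)),
                    read = sample(1:120, n),
                    len = sample(15:40, n, replace = TRUE))
    ch <- sdp_chain(df, top_n = 1L)
    expect_equal(ch[[1]]$score, brute_chain_best(df),
                 info = sprintf("trial %d", trial))
  }
})

test_that("adding a co-linear non-overlapping block never lowers the best score", {
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(2:6, 1)
    df <- blocks_df(ref = sort(sample(1:200, n)), read = sort(sample(1:100, n)),
                    len = sample(15:30, n, replace = TRUE))
    base <- sdp_chain(df, top_n = 1L)[[1]]$score
    extra <- blocks_df(max(df$ref + df$len) + 10L,
                       max(df$read + df$len) + 10L, 20L)
    grown <- sdp_chain(rbind(df, extra), top_n = 1L)[[1]]$score
    expect_gte(grown, base)
  }
})

test_that("seed selection keeps unique k-mers and always the read ends", {
  # reference with a long (AC) tract: interior repeat k-mers are skipped
  g <- c(chr1 = paste0(panrescue:::with_seed(2, panrescue:::random_dna(600)),
                       strrep("AC", 120),
                       panrescue:::with_seed(3, panrescue:::random_dna(600))))
  sv <- sv_records("d", "chr1", 700L, "DEL", 60L)
  svref <- build_sv_reference(sv, g, flank = 250L)
  idx <- build_index(svref, k = 22L)
  # a pure-repeat read: only its two end k-mers seed
  read <- strrep("AC", 40)
  seeds <- select_seeds(read, idx, max_occ = 4L)
  per_strand <- split(seeds$read_off, seeds$strand)
  for (offs in per_strand) {
    expect_setequal(offs, c(0L, nchar(read) - 22L))
  }
  # a read from unique sequence seeds at every position, occurrence = 1
  read2 <- substr(svref$anchors$seq[1], 31L, 130L)
  seeds2 <- select_seeds(read2, idx, max_occ = 4L)
  fwd <- seeds2[seeds2$strand == "+", ]
  expect_equal(fwd$read_off, 0:(100 - 22))
  expect_true(all(fwd$count == 1L))
})

test_that("unitig merging produces one block per co-linear run and caps positions", {
  fx <- fixture_ins_svref(n = 3000L)
  idx <- build_index(fx$svref, k = 22L)
  read <- substr(fx$svref$anchors$seq[1], 101L, 180L)  # 80 bp unique region
  seeds <- select_seeds(read, idx, max_occ = 4L)
  blocks <- merge_in_unitig(seeds[seeds$strand == "+", ], idx)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$len, 80L)          # k + (runs - 1)
  expect_equal(blocks[[1]]$read_off, 0L)
  expect_equal(blocks[[1]]$gpos, 100L)
  # two runs split by a read gap give two blocks
  gap_read <- paste0(substr(fx$svref$anchors$seq[1], 101L, 140L),
                     substr(fx$svref$anchors$seq[1], 201L, 240L))
  seeds_g <- select_seeds(gap_read, idx, max_occ = 4L)
  blocks_g <- merge_in_unitig(seeds_g[seeds_g$strand == "+", ], idx)
  expect_length(blocks_g, 2L)
})

test_that("a block occurring 1500 times keeps exactly 1000 random positions", {
  unit <- panrescue:::with_seed(99, panrescue:::random_dna(30))
  g <- c(chr1 = paste0(strrep(unit, 1500),
                       panrescue:::with_seed(98, panrescue:::random_dna(300))))
  sv <- sv_records("d", "chr1", nchar(g[[1]]) - 200L, "DEL", 60L)
  # anchor = whole repeat region: flank large enough to cover it
  svref <- build_sv_reference(sv, g, flank = nchar(g[[1]]))
  idx <- build_index(svref, k = 22L)
  read <- strrep(unit, 2)
  seeds <- select_seeds(read, idx, max_occ = 4L)
  blocks <- merge_in_unitig(seeds, idx, max_positions = 1000L, seed = 1L)
  counts <- vapply(blocks, function(b) length(b$gpos), integer(1))
  expect_true(any(counts == 1000L))
  # deterministic under the seed
  blocks2 <- merge_in_unitig(seeds, idx, max_positions = 1000L, seed = 1L)
  expect_equal(lapply(blocks, `[[`, "gpos"), lapply(blocks2, `[[`, "gpos"))
})

test_that("extension yields full-length alignments across SV junctions", {
  fx <- fixture_ins_svref()
  idx <- build_index(fx$svref)
  p <- realign_params()
  anc <- fx$svref$anchors$seq[1]
  # identity: 150M, score 150 * match
  read <- substr(anc, 201L, 350L)   # crosses the insert junction at 250
  a <- realign_read(read, idx, fx$svref, p)[[1]]
  expect_equal(a$cigar, "150M")
  expect_equal(a$score, 150)
  expect_equal(a$anc_start, 200L)
  expect_equal(a$mm, 0L)
  # one SNP: 149 * match - mismatch
  r2 <- read
  old <- substr(r2, 75L, 75L)
  substr(r2, 75L, 75L) <- if (old == "A") "C" else "A"
  a2 <- realign_read(r2, idx, fx$svref, p)[[1]]
  expect_equal(a2$score, 149 - 4)
  expect_equal(a2$mm, 1L)
  # extension score is invariant under reverse-complementing the read
  a3 <- realign_read(revcomp(read), idx, fx$svref, p)[[1]]
  expect_equal(a3$score, a$score)
  expect_equal(a3$strand, "-")
  expect_equal(a3$anc_start, a$anc_start)
})

test_that("anchor-simulated reads with errors realign to the anchor", {
  fx <- fixture_ins_svref(n = 8000L, pos = 4000L)
  idx <- build_index(fx$svref)
  p <- realign_params()
  anc <- fx$svref$anchors$seq[1]
  set.seed(31)
  ok <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    s <- sample.int(nchar(anc) - 150L, 1L)
    read <- substr(anc, s, s + 149L)
    nerr <- rbinom(1, 150, 0.02)
    if (nerr > 0) {
      at <- sample.int(150, nerr)
      for (j in at) {
        substr(read, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(read, j, j)), 1)
      }
    }
    if (sample(c(TRUE, FALSE), 1)) read <- revcomp(read)
    alns <- realign_read(read, idx, fx$svref, p)
    if (length(alns) && abs(alns[[1]]$anc_start - (s - 1L)) <= 5L) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
})
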