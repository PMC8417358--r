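test_that("insert-size model is robust and degenerate cases handled", {
  set.seed(5)
  x <- rnorm(1e4, 400, 50)
  m <- estimate_isize(x)
  expect_lt(abs(m$mean - 400), 5)
  expect_lt(abs(m$sd - 50), 5)
  expect_equal(m$hi - m$mean, 1.5 * m$sd)
  # identical values: degenerate interval of +/- 1 bp
  m2 <- estimate_isize(rep(300, 500))
  expect_equal(m2$mean, 300)
  expect_equal(c(m2$lo, m2$hi), c(299, 301))
  # too few observations: fallback with warning
  expect_warning(m3 <- estimate_isize(rep(300, 10), fallback = c(420, 60)),
                 "falling back")
  expect_equal(m3$mean, 420)
})

test_that("dual coordinates offer the SV-adjusted value downstream only", {
  sv_del <- data.frame(contig = "chr1", pos = 1000L, end = 1500L,
                       svtype = "DEL", svlen = 500L)
  # upstream of the deletion: single unchanged candidate
  expect_equal(dual_coordinates(900L, sv_del), 900L)
  # 100 bp downstream of the 500 bp deletion: {x, x - 500}
  expect_equal(dual_coordinates(1600L, sv_del), c(1600L, 1100L))
  sv_ins <- data.frame(contig = "chr1", pos = 1000L, end = 1000L,
                       svtype = "INS", svlen = 200L)
  expect_equal(dual_coordinates(1100L, sv_ins), c(1100L, 1300L))
  # different contig: unchanged
  expect_equal(dual_coordinates(1600L, sv_del, contig = "chr2"), 1600L)
})

test_that("pair scoring reproduces the worked examples", {
  svref <- toy_svref()
  model <- structure(list(mean = 400, sd = 50, lo = 325, hi = 475),
                     class = "isize_model")
  # proper single results with K = 50: S = 100 + 100 + 50
  c1 <- list(mk_pan(100, start = 100L, strand = "+"))
  c2 <- list(mk_pan(100, start = 300L, strand = "-", read_len = 150L))
  ps <- score_pairings(c1, c2, svref, model, K = 50)
  expect_equal(ps$S, 250)
  expect_true(ps$proper)
  # same but improper (same strand): S = 200
  c2i <- list(mk_pan(100, start = 300L, strand = "+"))
  psi <- score_pairings(c1, c2i, svref, model, K = 50)
  expect_equal(psi$S, 200)
  expect_false(psi$proper)
  # r1 {100, 90}, r2 {80}: only (90, 80) proper -> max(180, 220) = 220
  c1m <- list(mk_pan(100, start = 100L, strand = "+"),
              mk_pan(90, start = 120L, strand = "+"))
  c2m <- list(mk_pan(80, start = 470L, strand = "-", read_len = 30L))
  # make only the second r1 candidate proper: isize from 120 to 500 = 380
  # and from 100 to 500 = 400; both in window -> tweak window
  model2 <- structure(list(mean = 400, sd = 50, lo = 370, hi = 390),
                      class = "isize_model")
  ps2 <- score_pairings(c1m, c2m, svref, model2, K = 50)
  expect_equal(ps2$S, 220)
  expect_equal(c(ps2$p, ps2$q), c(2, 1))
})

test_that("pair scoring equals brute force on random candidate lists", {
  svref <- toy_svref()
  model <- structure(list(mean = 400, sd = 50, lo = 325, hi = 475),
                     class = "isize_model")
  set.seed(77)
  for (trial in 1:300) {
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    if (n1 + n2 == 0) next
    rand_cand <- function() {
      if (runif(1) < 0.75) {
        mk_pan(round(runif(1, 50, 150)), anchor_id = 0L,
               start = sample(0:500, 1),
               strand = sample(c("+", "-"), 1))
      } else {
        mk_orig(round(runif(1, 50, 150)), pos = sample(1000:3000, 1),
                strand = sample(c("+", "-"), 1),
                isize = sample(c(0L, 380L, 900L), 1))
      }
    }
    c1 <- replicate(n1, rand_cand(), simplify = FALSE)
    c2 <- replicate(n2, rand_cand(), simplify = FALSE)
    K <- sample(c(0, 50), 1)
    ps <- score_pairings(c1, c2, svref, model, K = K)
    expect_equal(ps$S, brute_pair_best(c1, c2, svref, model, K),
                 info = sprintf("trial %d", trial))
  }
})

test_that("the bonus never changes the result when no pairing is proper", {
  svref <- toy_svref()
  model <- structure(list(mean = 400, sd = 50, lo = 325, hi = 475),
                     class = "isize_model")
  c1 <- list(mk_pan(100, strand = "+"), mk_pan(80, strand = "+"))
  c2 <- list(mk_pan(90, strand = "+"))  # same strand: never proper
  s0 <- score_pairings(c1, c2, svref, model, K = 0)
  s50 <- score_pairings(c1, c2, svref, model, K = 50)
  expect_equal(s0$S, s50$S)
  expect_equal(c(s0$p, s0$q), c(s50$p, s50$q))
})

test_that("pairs are kept only on strict improvement over the original pair", {
  svref <- toy_svref()
  model <- structure(list(mean = 400, sd = 50, lo = 325, hi = 475),
                     class = "isize_model")
  # anchor pair 250 vs original 240: keep
  c1 <- list(mk_pan(100, start = 100L, strand = "+"),
             mk_orig(120, isize = 900L))
  c2 <- list(mk_pan(100, start = 300L, strand = "-"),
             mk_orig(120, strand = "-", isize = 900L, pos = 1900L))
  ps <- score_pairings(c1, c2, svref, model, K = 50)
  expect_equal(ps$S, 250)
  expect_equal(ps$S_orig, 240)
  expect_true(filter_original_best(ps, c1, c2))
  # tie with the original: unmapped
  c1t <- list(mk_pan(100, start = 100L, strand = "+"),
              mk_orig(125, isize = 900L))
  c2t <- list(mk_pan(100, start = 300L, strand = "-"),
              mk_orig(125, strand = "-", isize = 900L, pos = 1900L))
  pst <- score_pairings(c1t, c2t, svref, model, K = 50)
  expect_equal(pst$S, pst$S_orig)
  expect_false(filter_original_best(pst, c1t, c2t))
  # original strictly better: unmapped
  c1b <- list(mk_pan(80, start = 100L, strand = "+"),
              mk_orig(150, isize = 900L))
  c2b <- list(mk_pan(80, start = 300L, strand = "-"),
              mk_orig(150, strand = "-", isize = 900L, pos = 1900L))
  psb <- score_pairings(c1b, c2b, svref, model, K = 50)
  expect_false(filter_original_best(psb, c1b, c2b))
})

test_that("emitted SAM is coordinate-sorted with referential za tags", {
  svref <- toy_svref()
  mk_endrec <- function(mate, aln) {
    list(mate = mate, seq = strrep("A", 20L), qual = strrep("I", 20L),
         aln = aln, orig = NULL)
  }
  a1 <- list(anchor_id = 0L, anc_start = 40L, anc_end = 60L, strand = "+",
             cigar = "20M", score = 20, mm = 0L, read_len = 20L,
             source = "pansvr")
  a2 <- list(anchor_id = 0L, anc_start = 10L, anc_end = 30L, strand = "-",
             cigar = "20M", score = 20, mm = 0L, read_len = 20L,
             source = "pansvr")
  pairs <- list(list(name = "p1", proper = TRUE,
                     ends = list(mk_endrec(1L, a1), mk_endrec(2L, a2))))
  path <- tempfile(fileext = ".sam")
  emit_sam(pairs, svref, path)
  lines <- readLines(path)
  body <- lines[!grepl("^@", lines)]
  expect_length(body, 2L)
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 4L))
  expect_equal(pos, sort(pos))
  expect_true(all(grepl("za:i:0", body)))
  # the SAM parses with Rsamtools
  parsed <- read_alignments(path)
  expect_equal(nrow(parsed), 2L)
  expect_equal(sort(parsed$pos), c(11L, 41L))
})
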