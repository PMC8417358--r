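test_that("explicit and symbolic VCF records normalize to the same SV", {
  g <- c(chr1 = paste0(strrep("A", 7), "GGGG", strrep("T", 1200)))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1211>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    # explicit DEL: REF=AGGGG ALT=A at POS=7 deletes GGGG (bases 8-11)
    "chr1\t7\tdel_x\tAGGGG\tA\t.\tPASS\t.",
    # the same event, symbolic
    "chr1\t7\tdel_s\t<DEL>\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=11",
    # explicit INS
    "chr1\t4\tins_x\tA\tAGG\t.\tPASS\t.",
    # symbolic DUP of bases 8-11
    "chr1\t7\tdup_s\t<DUP>\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=11",
    # unsupported and off-contig records are skipped
    "chr1\t5\tbnd\tA\t<INV>\t.\tPASS\tSVTYPE=INV",
    "chrX\t5\toff\tA\tAGGTT\t.\tPASS\t."
  ), vcf)
  # vcfR insists the ALT of a symbolic record sits in the ALT column
  lines <- readLines(vcf)
  lines <- sub("<DEL>\t<DEL>", "N\t<DEL>", lines)
  lines <- sub("<DUP>\t<DUP>", "N\t<DUP>", lines)
  writeLines(lines, vcf)

  svs <- suppressWarnings(parse_sv_vcf(vcf, g))
  expect_equal(nrow(svs), 4L)
  dx <- svs[svs$id == "del_x", ]
  ds <- svs[svs$id == "del_s", ]
  expect_equal(dx$pos, 7L); expect_equal(dx$end, 11L); expect_equal(dx$svlen, 4L)
  expect_equal(ds[, c("pos", "end", "svlen", "svtype")],
               dx[, c("pos", "end", "svlen", "svtype")],
               ignore_attr = TRUE)
  ix <- svs[svs$id == "ins_x", ]
  expect_equal(ix$svtype, "INS"); expect_equal(ix$alt_seq, "GG")
  du <- svs[svs$id == "dup_s", ]
  expect_equal(du$svtype, "DUP")
  expect_equal(du$alt_seq, "GGGG")
  expect_equal(du$pos, 11L)  # insertion of the copy after the segment
})

test_that("deletion anchors concatenate the flanks and drop the deleted bases", {
  g <- toy_genome()
  sv <- sv_records("d1", "chr1", 8L, "DEL", 4L)
  a <- build_deletion_anchor(g, sv, flank = 4L)
  expect_equal(a$seq, "CCCCTTTT")
  # truncation at contig boundaries keeps the anchor
  a2 <- build_deletion_anchor(g, sv, flank = 250L)
  expect_equal(a2$seq, "AAAACCCCTTTT")
  expect_equal(a2$upstream_len, 8L)
  expect_equal(a2$downstream_len, 4L)
  expect_false(grepl("GGGG", a2$seq))
  # far from ends, the default flank gives 2 * 250
  big <- fixture_genome(3000L)
  svb <- sv_records("d2", "chr1", 1500L, "DEL", 100L)
  ab <- build_deletion_anchor(big, svb)
  expect_equal(nchar(ab$seq), 500L)
})

test_that("insertion anchors embed the allele exactly once at the insert span", {
  g <- c(chr1 = "AAAATTTT")
  sv <- sv_records("i1", "chr1", 4L, "INS", 2L, "GG")
  a <- build_insertion_anchor(g, sv, flank = 4L)
  expect_equal(a$seq, "AAAAGGTTTT")
  expect_equal(c(a$ins_start, a$ins_end), c(4L, 6L))
  # the repetitive 103 bp allele yields a 603 bp anchor at default flank
  allele <- unname(as.character(Biostrings::readDNAStringSet(
    system.file("extdata", "repetitive_insertion_103bp.fa",
                package = "panrescue"))))
  expect_equal(nchar(allele), 103L)
  big <- fixture_genome(3000L)
  svr <- sv_records("i103", "chr1", 1500L, "INS", 103L, allele)
  ar <- build_insertion_anchor(big, svr)
  expect_equal(nchar(ar$seq), 603L)
  # a DUP materializes as an INS of the duplicated segment
  seg <- substr(big[[1]], 1401L, 1500L)
  svd <- sv_records("dup", "chr1", 1500L, "DUP", 100L, seg)
  svi <- sv_records("ins", "chr1", 1500L, "INS", 100L, seg)
  expect_equal(build_insertion_anchor(big, svd)$seq,
               build_insertion_anchor(big, svi)$seq)
  expect_error(build_insertion_anchor(big,
    data.frame(id = "bad", contig = "chr1", pos = 10L, end = 10L,
               svtype = "INS", svlen = 1L, alt_seq = "")), "empty")
})

rbind_svs_test <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("sv_records", "data.frame")
  df
}

test_that("the SV reference orders anchors, offsets partition, duplicates collapse", {
  big <- fixture_genome(6000L)
  svs <- rbind_svs_test(
    sv_records("b", "chr1", 4000L, "INS", 103L,
               panrescue:::with_seed(1, panrescue:::random_dna(103))),
    sv_records("a", "chr1", 1500L, "DEL", 100L),
    sv_records("a_dup", "chr1", 1500L, "DEL", 100L))  # duplicate record
  svref <- build_sv_reference(svs, big)
  expect_equal(nrow(svref$anchors), 2L)          # dedup kept the first
  expect_equal(svref$anchors$sv_id, c("a", "b")) # ordered by position
  expect_equal(svref$offsets, c(0L, 500L))
  expect_equal(svref$total_len, 500L + 603L)
  expect_error(build_sv_reference(panrescue:::empty_svs(), big),
               "no usable SV records")
})

test_that("lift-over is a bijection on flanks and flags shifted/inserted bases", {
  g <- toy_genome()
  sv <- sv_records("d1", "chr1", 8L, "DEL", 4L)
  svref <- build_sv_reference(sv, g, flank = 4L)
  # offset 0 -> the C at 1-based genome position 5
  lf <- lift_to_genome(svref, 0L, 0L)
  expect_equal(lf$gpos, 5L)
  expect_identical(substr(g[[1]], lf$gpos, lf$gpos), "C")
  expect_false(lf$shifted)
  # downstream flank base is shifted
  lf2 <- lift_to_genome(svref, 0L, 7L)
  expect_true(lf2$shifted)
  expect_equal(lf2$gpos, 16L)
  expect_error(lift_to_genome(svref, 0L, 99L), "out of range")

  # INS: offsets inside the insert span map to the breakpoint, flagged
  fx <- fixture_ins_svref()
  lfi <- lift_to_genome(fx$svref, 0L, 250L + 10L)
  expect_true(lfi$inserted)
  expect_equal(lfi$gpos, 2500L)

  # round trip on every flank base of random anchors
  for (seed in 1:3) {
    fx <- fixture_ins_svref(seed = seed, pos = 2000L + 17L * seed)
    a <- fx$svref$anchors
    flank_offsets <- c(seq_len(a$upstream_len) - 1L,
                       a$ins_end + seq_len(a$downstream_len) - 1L)
    lf <- lift_to_genome(fx$svref, 0L, flank_offsets)
    back <- lift_from_genome(fx$svref, 0L, lf$gpos)
    expect_equal(back, flank_offsets)
  }
})

test_that("anchor length law holds for generated anchors", {
  sm <- small_sim()
  genome <- sm$sim$genome
  svref <- build_sv_reference(sm$sim$panel, genome)
  a <- svref$anchors
  ins_len <- a$ins_end - a$ins_start
  expect_equal(a$len, a$upstream_len + ins_len + a$downstream_len)
  expect_equal(ins_len[a$svtype == "DEL"],
               rep(0L, sum(a$svtype == "DEL")))
  # insertion anchors contain the allele exactly at the insert span
  for (i in which(a$svtype != "DEL")) {
    expect_equal(substr(a$seq[i], a$ins_start[i] + 1L, a$ins_end[i]),
                 a$alt_seq[i])
  }
})

test_that("serialization round-trips offsets and sequences exactly", {
  fx <- fixture_ins_svref()
  dir <- tempfile()
  write_sv_reference(fx$svref, dir)
  back <- read_sv_reference(dir)
  expect_equal(back$offsets, fx$svref$offsets)
  expect_equal(back$anchors$seq, fx$svref$anchors$seq)
  expect_equal(back$anchors$upstream_len, fx$svref$anchors$upstream_len)
  expect_equal(back$total_len, fx$svref$total_len)
})
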