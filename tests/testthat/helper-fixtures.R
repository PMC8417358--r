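# shared fixtures, all generated in code

toy_genome <- function() c(chr1 = "AAAACCCCGGGGTTTT")

# deterministic random genome with one contig
fixture_genome <- function(n = 5000L, seed = 42L, gc = 0.5) {
  g <- panrescue:::with_seed(seed, panrescue:::random_dna(n, gc))
  c(chr1 = g)
}

# an SV reference with one insertion anchor in a random genome
fixture_ins_svref <- function(n = 5000L, pos = 2500L, ins_len = 100L,
                              seed = 42L, flank = 250L) {
  g <- fixture_genome(n, seed)
  ins <- panrescue:::with_seed(seed + 1L, panrescue:::random_dna(ins_len))
  sv <- sv_records("ins1", "chr1", pos, "INS", ins_len, ins)
  list(genome = g, sv = sv, svref = build_sv_reference(sv, g, flank = flank))
}

# write a small SAM file from a record data frame
write_fixture_sam <- function(recs, genome, path = tempfile(fileext = ".sam")) {
  write_sam(recs, genome, path)
  path
}

# one SAM-like record row
sam_rec <- function(qname, flag, rname = "chr1", pos = 100L, mapq = 60L,
                    cigar = "10M", rnext = "=", pnext = 200L, tlen = 110L,
                    seq = strrep("A", 10L), qual = strrep("I", 10L),
                    NM = 0L, AS = NULL) {
  if (is.null(AS)) AS <- nchar(seq) - 5L * NM
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, qual = qual, NM = NM, AS = AS,
             stringsAsFactors = FALSE)
}

# the small shared simulation used by several integration tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_len = 50000L, sv_count = 6L,
                        sv_len_range = c(60L, 400L), seed = 7L)
      dir <- file.path(tempdir(), "panrescue_small_sim")
      cache <<- list(cfg = cfg, sim = simulate_dataset(cfg, dir))
    }
    cache
  }
})
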