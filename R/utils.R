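#' @keywords internal
"_PACKAGE"

# -- sequence helpers ---------------------------------------------------------

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    rawToChar(rev(charToRaw(chartr("ACGTacgtNn", "TGCAtgcaNn", s))))
  }, character(1), USE.NAMES = FALSE)
}

# all k-mers of a string, in order; returns character(0) if too short
kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig (upper case).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  # FASTA headers may carry descriptions; keep the first word as contig name
  names(g) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  g
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# -- CIGAR helpers ------------------------------------------------------------

# parse a CIGAR string into list(op = character, len = integer)
cigar_parse <- function(cig) {
  if (is.na(cig) || cig == "*" || !nzchar(cig)) {
    return(list(op = character(0), len = integer(0)))
  }
  len <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[MIDNSHP=X]", cig))[[1]]
  stopifnot(length(op) == length(len))
  list(op = op, len = len)
}

cigar_build <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return("*")
  # merge adjacent identical ops
  r <- rle(op)
  out_op <- r$values
  out_len <- integer(length(out_op))
  idx <- 1L
  for (i in seq_along(out_op)) {
    out_len[i] <- sum(len[idx:(idx + r$lengths[i] - 1L)])
    idx <- idx + r$lengths[i]
  }
  paste0(out_len, out_op, collapse = "")
}

# summary stats of a CIGAR: bases per op class
cigar_stats <- function(cig) {
  p <- cigar_parse(cig)
  s <- function(ops) sum(p$len[p$op %in% ops])
  list(
    n_m = s(c("M", "=", "X")),   # read bases aligned to reference
    n_i = s("I"),                # inserted read bases
    n_d = s(c("D", "N")),        # deleted reference bases
    n_clip = s(c("S", "H")),
    ref_span = s(c("M", "=", "X", "D", "N")),
    n_gaps = sum(p$op %in% c("I", "D"))
  )
}

# number of indel events and their total length (for NM -> mismatch conversion)
cigar_indel_bases <- function(cig) {
  p <- cigar_parse(cig)
  sum(p$len[p$op %in% c("I", "D")])
}

# CIGAR from a pair of gapped alignment strings (pattern = read, subject = ref)
cigar_from_gapped <- function(pat, sub) {
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  stopifnot(length(pc) == length(sc))
  op <- ifelse(pc == "-", "D", ifelse(sc == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

# -- deterministic RNG scoping ------------------------------------------------

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

# derive a stream-specific 32-bit sub-seed from a pipeline seed
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + stream * 40503) %% 2147483647
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
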