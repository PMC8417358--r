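# Extraction of potential SV-spanning read pairs from an alignment file.
#
# A read pair is "perfectly aligned" when both ends are mapped full-length
# (CIGAR contains only M/=/X), carry at most one mismatch each and the
# proper-pair flag is set. Such pairs carry no SV signal and are rejected;
# every other pair is extracted, with the original-alignment metadata
# serialized into the FASTQ comment so later stages can compare old and new
# alignments.

#' Read alignment records from a SAM or BAM file
#'
#' SAM input is converted to BAM internally via Rsamtools. Secondary,
#' supplementary, duplicate and QC-fail records are dropped; only primary
#' records of physical reads are returned.
#'
#' @param path a SAM or BAM file.
#' @return a data frame with one row per primary record: qname, flag, rname,
#'   pos (1-based, NA if unmapped), mapq, cigar, isize, seq, qual, NM, AS.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize",
             "seq", "qual"),
    tag = c("NM", "AS"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  df <- data.frame(
    qname = res$qname, flag = res$flag,
    rname = as.character(res$rname), pos = res$pos, mapq = res$mapq,
    cigar = res$cigar, isize = res$isize,
    seq = as.character(res$seq), qual = as.character(res$qual),
    NM = if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM,
    AS = if (is.null(res$tag$AS)) NA_integer_ else res$tag$AS,
    stringsAsFactors = FALSE
  )
  drop <- bitwAnd(df$flag, 0x100) > 0 | bitwAnd(df$flag, 0x800) > 0 |
    bitwAnd(df$flag, 0x400) > 0 | bitwAnd(df$flag, 0x200) > 0
  df[!drop, , drop = FALSE]
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

# mismatch count of a record: NM minus indel bases when NM present
record_mismatches <- function(rec) {
  if (is.na(rec$cigar) || rec$cigar == "*") return(NA_integer_)
  if (!is.na(rec$NM)) {
    return(max(0L, rec$NM - cigar_indel_bases(rec$cigar)))
  }
  NA_integer_
}

# comparable alignment score of an original record under the extension
# scoring scheme: matches - 4*mismatches - (6 + len) per gap
record_score <- function(rec, use_as = TRUE) {
  if (is.na(rec$pos)) return(NA_real_)
  if (use_as && !is.na(rec$AS)) return(as.numeric(rec$AS))
  st <- cigar_stats(rec$cigar)
  mm <- record_mismatches(rec)
  if (is.na(mm)) mm <- 0L
  p <- cigar_parse(rec$cigar)
  gap_cost <- sum(ifelse(p$op %in% c("I", "D"), 6 + p$len, 0))
  (st$n_m - mm) - 4 * mm - gap_cost
}

#' Test whether a read pair is perfectly aligned
#'
#' @param rec1,rec2 one-row data frames (rows of [read_alignments()] output)
#'   for the two mates.
#' @return `TRUE` iff both ends are mapped full-length (CIGAR only M/=/X),
#'   have at most one mismatch each and the pair is flagged proper.
#' @export
is_perfect_pair <- function(rec1, rec2) {
  ok_end <- function(r) {
    if (is.na(r$pos) || is.na(r$cigar) || r$cigar == "*") return(FALSE)
    p <- cigar_parse(r$cigar)
    if (any(!p$op %in% c("M", "=", "X"))) return(FALSE)
    mm <- record_mismatches(r)
    !is.na(mm) && mm <= 1L
  }
  ok_end(rec1) && ok_end(rec2) &&
    flag_bit(rec1$flag, 0x2) && flag_bit(rec2$flag, 0x2)
}

orig_comment <- function(rec) {
  if (is.null(rec) || is.na(rec$pos)) return("zp:*")
  mm <- record_mismatches(rec)
  sprintf("zp:%s:%d:%s zs:%g zc:%s zq:%d zi:%d zn:%d",
          rec$rname, rec$pos, if (flag_bit(rec$flag, 0x10)) "-" else "+",
          record_score(rec), rec$cigar, rec$mapq,
          ifelse(is.na(rec$isize), 0L, rec$isize),
          ifelse(is.na(mm), 0L, mm))
}

#' Extract SV-signature read pairs to FASTQ
#'
#' Pairs primary records by name, rejects perfectly aligned pairs and writes
#' the remaining pairs to a FASTQ file, two records per pair, with the
#' original-alignment metadata in the comment field
#' (`zp:contig:pos:strand zs:score zc:CIGAR zq:MAPQ zi:ISIZE zn:mismatches`,
#' or `zp:*` when no original alignment exists). Reverse-strand records are
#' reverse-complemented back to sequencer orientation. Orphan records (mate
#' never seen) are emitted with the mate marked unavailable; pairs with both
#' ends unmapped are emitted (long novel insertion signatures).
#'
#' @param alignments a SAM/BAM path or a data frame from [read_alignments()].
#' @param out_fastq output FASTQ path.
#' @return invisibly, a list with counts: total pairs, rejected (perfect),
#'   emitted, orphans.
#' @export
extract_signal_reads <- function(alignments, out_fastq) {
  df <- if (is.character(alignments)) read_alignments(alignments) else alignments
  lines <- character(0)
  n_total <- 0L; n_perfect <- 0L; n_emit <- 0L; n_orphan <- 0L

  by_name <- split(seq_len(nrow(df)), df$qname)
  # preserve input encounter order of pairs
  ord <- order(vapply(by_name, min, numeric(1)))
  by_name <- by_name[ord]

  con <- file(out_fastq, "w")
  on.exit(close(con))
  for (idx in by_name) {
    rows <- df[idx, , drop = FALSE]
    r1 <- rows[flag_bit(rows$flag, 0x40), , drop = FALSE]
    r2 <- rows[flag_bit(rows$flag, 0x80), , drop = FALSE]
    r1 <- if (nrow(r1)) r1[1, ] else NULL
    r2 <- if (nrow(r2)) r2[1, ] else NULL
    n_total <- n_total + 1L
    if (!is.null(r1) && !is.null(r2) && is_perfect_pair(r1, r2)) {
      n_perfect <- n_perfect + 1L
      next
    }
    if (is.null(r1) || is.null(r2)) n_orphan <- n_orphan + 1L
    n_emit <- n_emit + 1L
    name <- if (!is.null(r1)) r1$qname else r2$qname
    writeLines(fastq_block(name, 1L, r1, r2), con)
    writeLines(fastq_block(name, 2L, r2, r1), con)
  }
  invisible(list(total = n_total, rejected = n_perfect,
                 emitted = n_emit, orphans = n_orphan))
}

fastq_block <- function(name, mate, rec, mate_rec) {
  if (is.null(rec)) {
    # mate unavailable: emit a placeholder so pairs stay together
    return(c(sprintf("@%s/%d zp:*", name, mate), "N", "+", "!"))
  }
  seq <- rec$seq; qual <- rec$qual
  if (!is.na(rec$pos) && flag_bit(rec$flag, 0x10)) {
    seq <- revcomp(seq)
    qual <- rawToChar(rev(charToRaw(qual)))
  }
  c(sprintf("@%s/%d %s", name, mate, orig_comment(rec)), seq, "+", qual)
}

#' Parse a signal FASTQ back into paired records
#'
#' Inverse of [extract_signal_reads()]'s serialization: reads the FASTQ and
#' reconstructs, per pair, the sequences and original-alignment metadata.
#'
#' @param path FASTQ written by [extract_signal_reads()].
#' @return a list of pairs; each pair is a list of two `signal_read` lists
#'   with fields `name`, `mate`, `seq`, `qual`, `orig` (NULL if unavailable,
#'   else list(contig, pos, strand, score, cigar, mapq, isize, mm)).
#' @export
read_signal_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  n <- length(lines) %/% 4L
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- lines[4L * (i - 1L) + 1L]
    seq <- lines[4L * (i - 1L) + 2L]
    qual <- lines[4L * (i - 1L) + 4L]
    parts <- strsplit(sub("^@", "", hdr), " ")[[1]]
    nm <- strsplit(parts[1], "/")[[1]]
    orig <- parse_orig_comment(parts[-1])
    reads[[i]] <- list(name = nm[1], mate = as.integer(nm[2]),
                       seq = seq, qual = qual, orig = orig)
  }
  stopifnot(n %% 2L == 0L)
  lapply(seq_len(n %/% 2L), function(j) reads[(2L * j - 1L):(2L * j)])
}

parse_orig_comment <- function(fields) {
  kv <- list()
  for (f in fields) {
    key <- substr(f, 1, 2)
    val <- substr(f, 4, nchar(f))
    kv[[key]] <- val
  }
  if (is.null(kv$zp) || kv$zp == "*") return(NULL)
  zp <- strsplit(kv$zp, ":")[[1]]
  list(contig = zp[1], pos = as.integer(zp[2]), strand = zp[3],
       score = as.numeric(kv$zs), cigar = kv$zc,
       mapq = as.integer(kv$zq), isize = as.integer(kv$zi),
       mm = as.integer(kv$zn))
}
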