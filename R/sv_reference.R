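# SV records and the anchor ("SV reference") construction.
#
# Internal coordinates are 0-based half-open; VCF input/output is 1-based.
# An SV record follows the VCF convention: `pos` is the 1-based position of
# the base immediately before the event (the padding base), `end` the last
# affected reference base for deletions (end - pos = svlen) and equal to
# `pos` for insertions/duplications.

#' Construct a table of structural variant records
#'
#' @param id character, record identifiers.
#' @param contig character, contig names.
#' @param pos integer, 1-based position of the base before the first breakpoint.
#' @param svtype character, one of "DEL", "INS", "DUP".
#' @param svlen integer, number of affected bases (>= 1).
#' @param alt_seq character, inserted/duplicated sequence ("" for DEL).
#' @param end integer, 1-based second breakpoint; defaults to `pos + svlen`
#'   for deletions and `pos` otherwise.
#' @return a `data.frame` with class `sv_records`.
#' @export
sv_records <- function(id, contig, pos, svtype, svlen, alt_seq = "", end = NULL) {
  n <- length(pos)
  svtype <- toupper(svtype)
  if (is.null(end)) end <- ifelse(svtype == "DEL", pos + svlen, pos)
  df <- data.frame(
    id = as.character(id), contig = as.character(contig),
    pos = as.integer(pos), end = as.integer(end),
    svtype = svtype, svlen = as.integer(svlen),
    alt_seq = toupper(rep_len(as.character(alt_seq), n)),
    stringsAsFactors = FALSE
  )
  bad <- df$svlen < 1L |
    !(df$svtype %in% c("DEL", "INS", "DUP")) |
    (df$svtype == "DEL" & df$end - df$pos != df$svlen) |
    (df$svtype != "DEL" & nchar(df$alt_seq) != df$svlen)
  if (any(bad)) {
    stop("invalid SV record(s): ", paste(df$id[bad], collapse = ", "))
  }
  class(df) <- c("sv_records", "data.frame")
  df
}

#' Parse a VCF of known structural variants
#'
#' Reads a VCF (explicit REF/ALT alleles or symbolic `<DEL>`, `<INS>`,
#' `<DUP>` with `SVLEN`/`END` INFO keys) and normalizes each usable record
#' to an SV record. Duplications are materialized as insertions of the
#' duplicated reference segment at the end of the duplicated interval.
#' Unsupported types (BND, INV, ...) and records on contigs absent from the
#' reference are skipped with a warning count.
#'
#' @param vcf_path path to the VCF file.
#' @param genome named character vector of contig sequences
#'   (see [read_genome()]).
#' @return an `sv_records` data frame (possibly empty).
#' @export
parse_sv_vcf <- function(vcf_path, genome) {
  v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_svs())
  info <- if ("INFO" %in% colnames(v@fix)) v@fix[, "INFO"] else rep(NA, nrow(fix))

  out <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    rec <- normalize_vcf_record(
      contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      id = if (is.na(fix$ID[i]) || fix$ID[i] == ".") paste0("sv", i) else fix$ID[i],
      ref = toupper(fix$REF[i]), alt = toupper(fix$ALT[i]),
      info = info[i], genome = genome
    )
    if (is.null(rec)) n_skipped <- n_skipped + 1L else out[[i]] <- rec
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d unusable VCF record(s)", n_skipped))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_svs())
  do.call(rbind_svs, out)
}

empty_svs <- function() {
  sv_records(character(0), character(0), integer(0), character(0),
             integer(0), character(0))
}

rbind_svs <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("sv_records", "data.frame")
  df
}

info_field <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

normalize_vcf_record <- function(contig, pos, id, ref, alt, info, genome) {
  if (!contig %in% names(genome)) {
    warning(sprintf("record %s: contig %s not in reference; skipped", id, contig))
    return(NULL)
  }
  if (grepl("^<", alt)) {
    type <- toupper(info_field(info, "SVTYPE"))
    if (is.na(type)) type <- gsub("[<>]", "", strsplit(alt, ":")[[1]][1])
    type <- sub(":.*", "", type)
    if (!type %in% c("DEL", "INS", "DUP")) return(NULL)
    svlen <- abs(as.integer(info_field(info, "SVLEN")))
    endv <- as.integer(info_field(info, "END"))
    if (type == "DEL") {
      if (is.na(svlen)) {
        if (is.na(endv)) return(NULL)
        svlen <- endv - pos
      }
      if (is.na(svlen) || svlen < 1L) return(NULL)
      return(sv_records(id, contig, pos, "DEL", svlen))
    }
    if (type == "DUP") {
      if (is.na(endv)) {
        if (is.na(svlen)) return(NULL)
        endv <- pos + svlen
      }
      seg <- substr(genome[[contig]], pos + 1L, endv)
      if (!nzchar(seg)) return(NULL)
      # a tandem duplication is an insertion of the duplicated segment
      # immediately after it
      return(sv_records(id, contig, endv, "DUP", nchar(seg), seg))
    }
    # symbolic <INS> carries no sequence anywhere -> unusable as an anchor
    seq <- info_field(info, "SEQ")
    if (is.na(seq)) {
      warning(sprintf("record %s: symbolic <INS> without sequence; skipped", id))
      return(NULL)
    }
    return(sv_records(id, contig, pos, "INS", nchar(seq), toupper(seq)))
  }
  # explicit alleles, VCF padding-base convention
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) return(NULL)
  if (nchar(ref) > nchar(alt)) {
    if (substr(ref, 1L, nchar(alt)) != alt) return(NULL)
    svlen <- nchar(ref) - nchar(alt)
    return(sv_records(id, contig, pos + nchar(alt) - 1L, "DEL", svlen))
  }
  if (nchar(alt) > nchar(ref)) {
    if (substr(alt, 1L, nchar(ref)) != ref) return(NULL)
    ins <- substr(alt, nchar(ref) + 1L, nchar(alt))
    return(sv_records(id, contig, pos + nchar(ref) - 1L, "INS", nchar(ins), ins))
  }
  NULL # SNV or balanced substitution: not an SV
}

# -- anchors ------------------------------------------------------------------

#' Build the anchor sequence of a deletion
#'
#' The anchor is the reference flank ending at the first breakpoint
#' concatenated directly with the flank starting after the second breakpoint,
#' truncated at contig boundaries. The deleted interval itself is absent.
#'
#' @param genome named character vector of contig sequences.
#' @param sv one-row `sv_records` with `svtype == "DEL"`.
#' @param flank flank length in bp (default 250).
#' @return a list with `seq`, `upstream_len`, `downstream_len`,
#'   `ins_start`, `ins_end` (insert span, empty for deletions).
#' @export
build_deletion_anchor <- function(genome, sv, flank = 250L) {
  stopifnot(sv$svtype == "DEL")
  ctg <- genome[[sv$contig]]
  n <- nchar(ctg)
  if (sv$pos < 0L || sv$end > n) stop("deletion breakpoints outside contig ", sv$contig)
  up_start <- max(0L, sv$pos - flank)              # 0-based
  dn_end <- min(n, sv$end + flank)
  up <- substr(ctg, up_start + 1L, sv$pos)
  dn <- substr(ctg, sv$end + 1L, dn_end)
  list(seq = paste0(up, dn),
       upstream_len = nchar(up), downstream_len = nchar(dn),
       ins_start = nchar(up), ins_end = nchar(up))
}

#' Build the anchor sequence of an insertion or duplication
#'
#' Concatenates the upstream reference flank, the inserted (or duplicated)
#' allele and the downstream flank; the insert span marks the allele within
#' the anchor.
#'
#' @inheritParams build_deletion_anchor
#' @param sv one-row `sv_records` with `svtype` INS or DUP and nonempty
#'   `alt_seq`.
#' @export
build_insertion_anchor <- function(genome, sv, flank = 250L) {
  stopifnot(sv$svtype %in% c("INS", "DUP"))
  if (!nzchar(sv$alt_seq)) stop("insertion record ", sv$id, " has empty allele")
  ctg <- genome[[sv$contig]]
  n <- nchar(ctg)
  if (sv$pos < 0L || sv$pos > n) stop("insertion breakpoint outside contig ", sv$contig)
  up_start <- max(0L, sv$pos - flank)
  dn_end <- min(n, sv$pos + flank)
  up <- substr(ctg, up_start + 1L, sv$pos)
  dn <- substr(ctg, sv$pos + 1L, dn_end)
  list(seq = paste0(up, sv$alt_seq, dn),
       upstream_len = nchar(up), downstream_len = nchar(dn),
       ins_start = nchar(up), ins_end = nchar(up) + nchar(sv$alt_seq))
}

#' Build the SV-anchor reference
#'
#' Generates one anchor per usable SV record, ordered by (contig, pos), and
#' concatenates them into the realignment target. Identical duplicate records
#' (same type, contig, pos and length) are collapsed, keeping the first.
#' Anchors shorter than `min_len` are kept but flagged.
#'
#' @param svs an `sv_records` data frame.
#' @param genome named character vector of contig sequences.
#' @param flank flank length in bp (default 250).
#' @param min_len anchors shorter than this are flagged `short` (default 150).
#' @return an object of class `sv_reference`: a list with `anchors` (data
#'   frame of per-anchor metadata and sequence), `offsets` (0-based start of
#'   each anchor in the concatenation) and `total_len`.
#' @export
build_sv_reference <- function(svs, genome, flank = 250L, min_len = 150L) {
  if (is.null(svs) || nrow(svs) == 0L) stop("no usable SV records")
  key <- paste(svs$svtype, svs$contig, svs$pos, svs$svlen)
  svs <- svs[!duplicated(key), , drop = FALSE]
  svs <- svs[order(svs$contig, svs$pos, svs$svtype), , drop = FALSE]
  rows <- vector("list", nrow(svs))
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    a <- if (sv$svtype == "DEL") build_deletion_anchor(genome, sv, flank)
         else build_insertion_anchor(genome, sv, flank)
    rows[[i]] <- data.frame(
      anchor_id = i - 1L, sv_id = sv$id, contig = sv$contig,
      svtype = sv$svtype, pos = sv$pos, end = sv$end, svlen = sv$svlen,
      alt_seq = sv$alt_seq,
      upstream_len = a$upstream_len, downstream_len = a$downstream_len,
      ins_start = a$ins_start, ins_end = a$ins_end,
      len = nchar(a$seq), short = nchar(a$seq) < min_len,
      seq = a$seq, stringsAsFactors = FALSE
    )
  }
  anchors <- do.call(rbind, rows)
  offsets <- c(0L, cumsum(anchors$len))[seq_len(nrow(anchors))]
  structure(list(anchors = anchors, offsets = as.integer(offsets),
                 total_len = sum(anchors$len), flank = as.integer(flank)),
            class = "sv_reference")
}

#' @export
print.sv_reference <- function(x, ...) {
  cat(sprintf("sv_reference: %d anchors, %d bp total (flank %d)\n",
              nrow(x$anchors), x$total_len, x$flank))
  print(table(x$anchors$svtype))
  invisible(x)
}

#' Lift an anchor coordinate to the genome
#'
#' Maps a 0-based offset within an anchor back to its source genome
#' coordinate. Flank offsets map to unique genome positions; offsets inside
#' an insertion's insert span map to the insertion breakpoint with
#' `inserted = TRUE`. `shifted` marks coordinates downstream of the SV
#' allele, whose original-reference coordinate differs from the donor
#' coordinate by `svlen`.
#'
#' @param svref an `sv_reference`.
#' @param anchor_id integer anchor index (0-based).
#' @param offset integer vector of 0-based offsets within the anchor.
#' @return data frame with columns `contig`, `gpos` (1-based genome
#'   position), `shifted`, `inserted`.
#' @export
lift_to_genome <- function(svref, anchor_id, offset) {
  a <- svref$anchors[svref$anchors$anchor_id == anchor_id, ]
  if (nrow(a) != 1L) stop("unknown anchor_id ", anchor_id)
  if (any(offset < 0L | offset >= a$len)) stop("offset out of range for anchor ", anchor_id)
  up <- a$upstream_len
  ins_len <- a$ins_end - a$ins_start
  gpos <- integer(length(offset))
  shifted <- logical(length(offset))
  inserted <- logical(length(offset))
  for (j in seq_along(offset)) {
    o <- offset[j]
    if (o < up) {                      # upstream flank
      gpos[j] <- a$pos - up + o + 1L
    } else if (o < up + ins_len) {     # inside the inserted allele
      gpos[j] <- a$pos
      inserted[j] <- TRUE
      shifted[j] <- TRUE
    } else {                           # downstream flank
      base_after <- if (a$svtype == "DEL") a$end else a$pos
      gpos[j] <- base_after + (o - up - ins_len) + 1L
      shifted[j] <- TRUE
    }
  }
  data.frame(contig = a$contig, gpos = gpos, shifted = shifted,
             inserted = inserted, stringsAsFactors = FALSE)
}

#' Inverse lift: genome position to anchor offset
#'
#' Restricted to flank bases (the lift-over is a bijection there).
#'
#' @param svref an `sv_reference`.
#' @param anchor_id integer anchor index.
#' @param gpos 1-based genome position.
#' @return 0-based anchor offset, or `NA` if the position is not covered by
#'   the anchor's flanks.
#' @export
lift_from_genome <- function(svref, anchor_id, gpos) {
  a <- svref$anchors[svref$anchors$anchor_id == anchor_id, ]
  if (nrow(a) != 1L) stop("unknown anchor_id ", anchor_id)
  up <- a$upstream_len
  ins_len <- a$ins_end - a$ins_start
  vapply(gpos, function(g) {
    up_first <- a$pos - up + 1L
    if (g >= up_first && g <= a$pos) return(as.integer(g - up_first))
    base_after <- if (a$svtype == "DEL") a$end else a$pos
    if (g > base_after && g <= base_after + a$downstream_len) {
      return(as.integer(up + ins_len + (g - base_after - 1L)))
    }
    NA_integer_
  }, integer(1))
}

# map a global concatenation position to (anchor_id, offset)
global_to_anchor <- function(svref, gpos0) {
  idx <- findInterval(gpos0, svref$offsets)
  data.frame(anchor_id = svref$anchors$anchor_id[idx],
             offset = gpos0 - svref$offsets[idx])
}

# -- serialization ------------------------------------------------------------

#' Write an SV reference to disk
#'
#' Writes `anchors.fa` (one FASTA record per anchor, named by anchor id) and
#' a tab-separated sidecar `anchors.tsv` carrying the per-anchor lift-over
#' metadata, from which the reference can be rebuilt exactly.
#'
#' @param svref an `sv_reference`.
#' @param dir output directory (created if needed).
#' @export
write_sv_reference <- function(svref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- svref$anchors$seq
  names(seqs) <- paste0("anchor", svref$anchors$anchor_id)
  write_fasta(seqs, file.path(dir, "anchors.fa"))
  meta <- svref$anchors[, setdiff(colnames(svref$anchors), "seq")]
  meta$flank <- svref$flank
  utils::write.table(meta, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an SV reference written by [write_sv_reference()]
#'
#' @param dir directory containing `anchors.fa` and `anchors.tsv`.
#' @return an `sv_reference`.
#' @export
read_sv_reference <- function(dir) {
  seqs <- read_genome(file.path(dir, "anchors.fa"))
  meta <- utils::read.table(file.path(dir, "anchors.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  meta$alt_seq[is.na(meta$alt_seq)] <- ""
  flank <- meta$flank[1]
  meta$flank <- NULL
  meta$seq <- unname(seqs[paste0("anchor", meta$anchor_id)])
  stopifnot(!anyNA(meta$seq), nchar(meta$seq) == meta$len)
  offsets <- c(0L, cumsum(meta$len))[seq_len(nrow(meta))]
  structure(list(anchors = meta, offsets = as.integer(offsets),
                 total_len = sum(meta$len), flank = as.integer(flank)),
            class = "sv_reference")
}
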