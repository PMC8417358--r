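# Mate pairing: combine single-end candidate alignments (anchor
# realignments plus the original alignments) into the best-scoring pair.
# The pair score is the sum of the two end scores plus a bonus K when the
# ends pair properly (opposite orientations, insert size within
# mean +/- 1.5 sd). Pairs whose best combination is achieved by the
# original aligner (including score ties) are recorded as unmapped: only
# genuinely improved pairs provide anchor evidence.

#' Estimate an insert-size model from proper pairs
#'
#' Robust location/scale (median and scaled MAD) over absolute insert
#' sizes. With fewer than `min_pairs` observations the configured fallback
#' is used with a warning.
#'
#' @param isizes numeric vector of template lengths from proper pairs
#'   (signs ignored, zeros dropped).
#' @param min_pairs minimum observations (default 100).
#' @param fallback `c(mean, sd)` used when too few observations.
#' @param sd_factor half-width of the acceptance interval in sds
#'   (default 1.5).
#' @return list of class `isize_model`: `mean`, `sd`, `lo`, `hi`.
#' @export
estimate_isize <- function(isizes, min_pairs = 100L,
                           fallback = c(400, 50), sd_factor = 1.5) {
  x <- abs(isizes[!is.na(isizes) & isizes != 0])
  if (length(x) < min_pairs) {
    warning(sprintf("only %d proper pairs; falling back to configured insert model",
                    length(x)))
    m <- fallback[1]; s <- fallback[2]
  } else {
    m <- stats::median(x)
    s <- stats::mad(x, center = m)
  }
  if (s <= 0) s <- 1 / sd_factor  # degenerate: accept +/- 1 bp
  structure(list(mean = m, sd = s,
                 lo = m - sd_factor * s, hi = m + sd_factor * s),
            class = "isize_model")
}

#' Dual genome coordinates of an original alignment near a known SV
#'
#' A coordinate downstream of an SV breakpoint has two interpretations: the
#' original-reference value, and the value adjusted by the SV length (its
#' coordinate on the allele that carries the SV). Both are offered to pair
#' scoring.
#'
#' @param orig_pos 1-based original-reference position.
#' @param sv one anchor row of an `sv_reference` (fields `contig`, `pos`,
#'   `end`, `svtype`, `svlen`).
#' @param contig contig of the original alignment.
#' @return integer vector of one or two candidate coordinates.
#' @export
dual_coordinates <- function(orig_pos, sv, contig = sv$contig) {
  if (!identical(contig, sv$contig)) return(orig_pos)
  bp <- if (sv$svtype == "DEL") sv$end else sv$pos
  if (orig_pos > bp) {
    adj <- if (sv$svtype == "DEL") orig_pos - sv$svlen else orig_pos + sv$svlen
    return(c(orig_pos, adj))
  }
  orig_pos
}

# candidate list for one end: anchor realignments plus the original record
pair_candidates <- function(alns, orig) {
  cands <- lapply(alns, function(a)
    list(score = a$score, source = "pansvr", aln = a))
  if (!is.null(orig) && !is.na(orig$pos)) {
    cands[[length(cands) + 1L]] <-
      list(score = orig$score, source = "orig", orig = orig)
  }
  cands
}

# is a candidate combination a proper pair?
combo_proper <- function(c1, c2, svref, model) {
  in_win <- function(d) !is.na(d) && abs(d) >= model$lo && abs(d) <= model$hi
  if (c1$source == "pansvr" && c2$source == "pansvr") {
    a1 <- c1$aln; a2 <- c2$aln
    if (a1$anchor_id != a2$anchor_id || a1$strand == a2$strand) return(FALSE)
    fwd <- if (a1$strand == "+") a1 else a2
    rev <- if (a1$strand == "+") a2 else a1
    if (fwd$anc_start > rev$anc_start) return(FALSE)  # FR orientation
    return(in_win(rev$anc_end - fwd$anc_start))
  }
  if (c1$source == "orig" && c2$source == "orig") {
    o1 <- c1$orig; o2 <- c2$orig
    if (!identical(o1$contig, o2$contig) || identical(o1$strand, o2$strand))
      return(FALSE)
    d <- abs(o2$pos - o1$pos) + 1L
    return(in_win(if (!is.na(o1$isize) && o1$isize != 0) o1$isize else d))
  }
  # mixed: one end realigned to an anchor, the mate kept original
  pv <- if (c1$source == "pansvr") c1 else c2
  og <- if (c1$source == "pansvr") c2 else c1
  a <- pv$aln
  arow <- svref$anchors[svref$anchors$anchor_id == a$anchor_id, ]
  if (!identical(og$orig$contig, arow$contig)) return(FALSE)
  if (identical(a$strand, og$orig$strand)) return(FALSE)
  lift <- lift_to_genome(svref, a$anchor_id, a$anc_start)
  g1 <- lift$gpos
  for (g2 in dual_coordinates(og$orig$pos, arow, og$orig$contig)) {
    span <- abs(g2 - g1) + a$read_len
    if (in_win(span)) return(TRUE)
  }
  FALSE
}

#' Score all pairings of two candidate lists
#'
#' Exhaustive maximum over all combinations (p, q) of
#' `s(p) + s(q) + (K if proper else 0)`. Ties are broken toward
#' combinations using anchor realignments for more ends, then toward the
#' lowest anchor id and leftmost position.
#'
#' @param cand1,cand2 candidate lists from [pair_candidates()]; either may
#'   be empty (that end is then unpaired and contributes nothing).
#' @param svref the `sv_reference`.
#' @param model an `isize_model`.
#' @param K proper-pair bonus (default 50).
#' @return `NULL` if both lists are empty, else a list of class
#'   `pair_score`: `S`, `p`, `q` (indices, 0 when an end has no candidate),
#'   `proper`, `bonus`, `c1`, `c2` (the chosen candidates or NULL), and
#'   `argmax` (matrix of all tied index pairs).
#' @export
score_pairings <- function(cand1, cand2, svref, model, K = 50) {
  n1 <- length(cand1); n2 <- length(cand2)
  if (n1 == 0L && n2 == 0L) return(NULL)
  best <- NULL
  consider <- function(p, q) {
    s1 <- if (p > 0L) cand1[[p]]$score else 0
    s2 <- if (q > 0L) cand2[[q]]$score else 0
    proper <- p > 0L && q > 0L &&
      combo_proper(cand1[[p]], cand2[[q]], svref, model)
    S <- s1 + s2 + if (proper) K else 0
    list(S = S, p = p, q = q, proper = proper)
  }
  combos <- list()
  if (n1 > 0L && n2 > 0L) {
    for (p in seq_len(n1)) for (q in seq_len(n2)) {
      combos[[length(combos) + 1L]] <- consider(p, q)
    }
  } else if (n1 > 0L) {
    for (p in seq_len(n1)) combos[[length(combos) + 1L]] <- consider(p, 0L)
  } else {
    for (q in seq_len(n2)) combos[[length(combos) + 1L]] <- consider(0L, q)
  }
  S_all <- vapply(combos, `[[`, numeric(1), "S")
  S_max <- max(S_all)
  tied <- combos[S_all >= S_max - 1e-9]
  # preference among ties: more anchor ends, then lowest anchor id/position
  pref <- vapply(tied, function(cb) {
    src <- c(if (cb$p > 0L) cand1[[cb$p]]$source else "none",
             if (cb$q > 0L) cand2[[cb$q]]$source else "none")
    n_pan <- sum(src == "pansvr")
    aid <- min(c(
      if (cb$p > 0L && src[1] == "pansvr") cand1[[cb$p]]$aln$anchor_id else Inf,
      if (cb$q > 0L && src[2] == "pansvr") cand2[[cb$q]]$aln$anchor_id else Inf))
    pos <- min(c(
      if (cb$p > 0L && src[1] == "pansvr") cand1[[cb$p]]$aln$anc_start else Inf,
      if (cb$q > 0L && src[2] == "pansvr") cand2[[cb$q]]$aln$anc_start else Inf))
    c(-n_pan, aid, pos)
  }, numeric(3))
  ord <- order(pref[1, ], pref[2, ], pref[3, ])
  chosen <- tied[[ord[1]]]
  argmax <- t(vapply(tied, function(cb) c(cb$p, cb$q), numeric(2)))
  # score of the original aligner's own result for this pair: original
  # alignments where they exist, unmapped (0) otherwise
  io1 <- which(vapply(cand1, `[[`, character(1), "source") == "orig")
  io2 <- which(vapply(cand2, `[[`, character(1), "source") == "orig")
  S_orig <- 0
  if (length(io1)) S_orig <- S_orig + cand1[[io1[1]]]$score
  if (length(io2)) S_orig <- S_orig + cand2[[io2[1]]]$score
  if (length(io1) && length(io2) &&
      combo_proper(cand1[[io1[1]]], cand2[[io2[1]]], svref, model)) {
    S_orig <- S_orig + K
  }
  if (!length(io1) && !length(io2)) S_orig <- -Inf
  structure(list(
    S = S_max, p = chosen$p, q = chosen$q, proper = chosen$proper,
    bonus = if (chosen$proper) K else 0, S_orig = S_orig,
    c1 = if (chosen$p > 0L) cand1[[chosen$p]] else NULL,
    c2 = if (chosen$q > 0L) cand2[[chosen$q]] else NULL,
    argmax = argmax), class = "pair_score")
}

#' Decide whether a scored pair is kept or recorded unmapped
#'
#' The pair is kept only when its best combination strictly beats the
#' original aligner's own pair result and uses an anchor realignment for at
#' least one end; a score tie with the original pair is recorded unmapped
#' (no evidence gained).
#'
#' @param ps a `pair_score` from [score_pairings()].
#' @param cand1,cand2 the candidate lists that produced it.
#' @return `TRUE` (keep) or `FALSE` (unmapped).
#' @export
filter_original_best <- function(ps, cand1, cand2) {
  if (is.null(ps)) return(FALSE)
  chosen_pan <-
    (!is.null(ps$c1) && ps$c1$source == "pansvr") ||
    (!is.null(ps$c2) && ps$c2$source == "pansvr")
  chosen_pan && ps$S > ps$S_orig + 1e-9
}

# -- SAM output ---------------------------------------------------------------

#' Write kept pairs as SAM against the SV reference
#'
#' One record per anchor-realigned end, sorted by (anchor, position). The
#' `za` integer tag carries the anchor id; `AS`/`NM` the realignment score
#' and mismatches; `zo` the original-alignment metadata string.
#'
#' @param pairs list of kept pairs; each element is a list with `name`,
#'   `ends` (list of up to two per-end lists: `mate`, `seq`, `qual`, `aln`,
#'   `orig`), and `proper`.
#' @param svref the `sv_reference`.
#' @param path output SAM path.
#' @export
emit_sam <- function(pairs, svref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:anchor%d\tLN:%d",
                   svref$anchors$anchor_id, svref$anchors$len))
  recs <- list()
  for (pr in pairs) {
    ends <- pr$ends
    for (i in seq_along(ends)) {
      e <- ends[[i]]
      if (is.null(e$aln)) next
      a <- e$aln
      mate <- if (length(ends) == 2L) ends[[if (i == 1L) 2L else 1L]] else NULL
      flag <- 0x1 + (if (e$mate == 1L) 0x40 else 0x80) +
        (if (a$strand == "-") 0x10 else 0) +
        (if (isTRUE(pr$proper)) 0x2 else 0) +
        (if (!is.null(mate) && !is.null(mate$aln) && mate$aln$strand == "-") 0x20 else 0) +
        (if (is.null(mate) || is.null(mate$aln)) 0x8 else 0)
      seq <- if (a$strand == "-") revcomp(e$seq) else e$seq
      qual <- if (a$strand == "-") rawToChar(rev(charToRaw(e$qual))) else e$qual
      rnext <- "*"; pnext <- 0L; tlen <- 0L
      if (!is.null(mate) && !is.null(mate$aln)) {
        rnext <- if (mate$aln$anchor_id == a$anchor_id) "="
                 else sprintf("anchor%d", mate$aln$anchor_id)
        pnext <- mate$aln$anc_start + 1L
        if (rnext == "=") {
          lo <- min(a$anc_start, mate$aln$anc_start)
          hi <- max(a$anc_end, mate$aln$anc_end)
          tlen <- (hi - lo) * (if (a$anc_start <= mate$aln$anc_start) 1L else -1L)
        }
      }
      orig_tag <- gsub("\t", " ", orig_meta_string(e$orig))
      recs[[length(recs) + 1L]] <- list(
        anchor_id = a$anchor_id, pos = a$anc_start + 1L,
        line = paste(pr$name, flag, sprintf("anchor%d", a$anchor_id),
                     a$anc_start + 1L, 60L, a$cigar, rnext, pnext, tlen,
                     seq, qual,
                     sprintf("za:i:%d", a$anchor_id),
                     sprintf("AS:i:%d", round(a$score)),
                     sprintf("NM:i:%d", a$mm),
                     sprintf("zo:Z:%s", orig_tag),
                     sep = "\t"))
    }
  }
  if (length(recs)) {
    ord <- order(vapply(recs, `[[`, numeric(1), "anchor_id"),
                 vapply(recs, `[[`, numeric(1), "pos"))
    recs <- recs[ord]
  }
  writeLines(c(hdr, vapply(recs, `[[`, character(1), "line")), path)
  invisible(path)
}

orig_meta_string <- function(orig) {
  if (is.null(orig)) return("*")
  sprintf("%s:%d:%s:%g:%s:%d:%d:%d", orig$contig, orig$pos, orig$strand,
          orig$score, orig$cigar, orig$mapq, orig$isize, orig$mm)
}
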