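# Cluster assembly and SV inference: depth/MAPQ filtering of cluster
# reads, greedy word-overlap assembly into consensus contigs with join
# positions, mismatch-only realignment of reads to the contig for per-base
# depth, NW alignment of the consensus against the anchor, and inference
# of genotyped SV calls from breakpoint depths and consensus variants.

#' Filter excess-depth reads within 64 bp blocks
#'
#' The anchor region is partitioned into fixed blocks; within any block
#' whose mean read depth exceeds `factor` times the genome-wide mean,
#' lowest-score reads overlapping the block are discarded until the block
#' depth drops to the threshold. Score ties are broken by read name.
#'
#' @param reads list of cluster reads (fields `anc_start`, `anc_end`,
#'   `score`, `name`).
#' @param mean_depth genome-wide mean read depth.
#' @param block_size block width in bp (default 64).
#' @param factor depth multiple above which reads are removed (default 1.5).
#' @return the retained reads (same structure, possibly fewer).
#' @export
depth_filter <- function(reads, mean_depth, block_size = 64L, factor = 1.5) {
  if (!length(reads)) return(reads)
  limit <- factor * mean_depth
  alive <- rep(TRUE, length(reads))
  st <- vapply(reads, `[[`, numeric(1), "anc_start")
  en <- vapply(reads, `[[`, numeric(1), "anc_end")
  sc <- vapply(reads, `[[`, numeric(1), "score")
  nm <- vapply(reads, `[[`, character(1), "name")
  lo <- min(st); hi <- max(en)
  blocks <- seq(block_size * (lo %/% block_size), hi, by = block_size)
  for (b in blocks) {
    b_end <- b + block_size
    repeat {
      ov <- alive & st < b_end & en > b
      if (!any(ov)) break
      cover <- pmin(en[ov], b_end) - pmax(st[ov], b)
      depth <- sum(cover) / block_size
      if (depth <= limit) break
      cand <- which(ov)
      drop <- cand[order(sc[cand], nm[cand])][1]  # lowest score first
      alive[drop] <- FALSE
    }
  }
  reads[alive]
}

#' Discard uncertain clusters by original mapping quality
#'
#' A cluster is uncertain when over 80 percent of its reads had original
#' MAPQ 0 and the realignment barely improved their scores (median score
#' gain at most `margin`).
#'
#' @param reads cluster reads (fields `score` and `orig`).
#' @param margin maximum median score gain still counted as "no
#'   improvement" (default 5).
#' @param mapq_frac MAPQ-0 fraction threshold (default 0.8).
#' @return `TRUE` to keep the cluster, `FALSE` to discard it.
#' @export
mapq_filter <- function(reads, margin = 5, mapq_frac = 0.8) {
  if (!length(reads)) return(FALSE)
  mapq <- vapply(reads, function(r)
    if (is.null(r$orig)) 0L else r$orig$mapq, integer(1))
  gain <- vapply(reads, function(r) {
    os <- if (is.null(r$orig)) -Inf else r$orig$score
    r$score - os
  }, numeric(1))
  frac0 <- mean(mapq == 0L)
  !(frac0 > mapq_frac && stats::median(gain) <= margin)
}

#' Assemble reads into consensus contigs by greedy word extension
#'
#' Picks the most frequent unused word as the seed contig and extends both
#' directions by the majority base among reads overlapping the contig end,
#' recruiting reads by exact occurrence of the contig's terminal word and
#' recording each read's join position. Extension requires at least
#' `min_support` agreeing reads; contigs supported by fewer than
#' `min_reads` reads or shorter than `min_len` are discarded.
#'
#' @param seqs character vector of read sequences, oriented to the anchor.
#' @param word seed/recruitment word length (default 25).
#' @param min_support minimum reads agreeing on each extension base
#'   (default 2).
#' @param min_reads minimum reads per contig (default 3).
#' @param min_len minimum contig length (default: the read length).
#' @param hints optional per-read anchor start positions; when given, a
#'   read may only join the contig at a position consistent with its hint
#'   (within `hint_tol`), which disambiguates joins between identical
#'   copies of duplicated sequence.
#' @param hint_tol tolerance in bp for hint consistency (default 60).
#' @return list of contigs: `list(seq, members, joins, depth)` where
#'   `joins[i]` is the 0-based contig position where read `members[i]`
#'   joins and `depth` the per-base support from mismatch-only
#'   realignment.
#' @export
assemble <- function(seqs, word = 25L, min_support = 2L, min_reads = 3L,
                     min_len = NULL, hints = NULL, hint_tol = 60L) {
  if (is.null(min_len)) min_len <- if (length(seqs)) max(nchar(seqs)) else 0L
  if (length(seqs) < min_reads) return(list())
  used <- rep(FALSE, length(seqs))
  contigs <- list()
  word_lists <- lapply(seqs, kmerize, k = word)
  repeat {
    avail <- which(!used)
    if (length(avail) < min_reads) break
    tab <- sort(table(unlist(word_lists[avail])), decreasing = TRUE)
    tab <- tab[tab >= min_support]
    if (!length(tab)) break
    # deterministic seed choice: highest count, then lexicographic
    top <- tab[tab == tab[1]]
    seed_word <- sort(names(top))[1]
    res <- grow_contig(seed_word, seqs, word_lists, used, word, min_support,
                       hints, hint_tol)
    used[res$members] <- TRUE
    if (!length(res$members)) used[res$seed_reads] <- TRUE  # avoid loops
    if (length(res$members) >= min_reads && nchar(res$seq) >= min_len) {
      contigs[[length(contigs) + 1L]] <- res
    }
  }
  contigs
}

# extend a seed word into a contig; returns seq, members, joins
grow_contig <- function(seed_word, seqs, word_lists, used, word, min_support,
                        hints = NULL, hint_tol = 60L) {
  members <- integer(0)
  joins <- integer(0)       # read start position in contig coordinates
  contig <- seed_word
  origin <- 0L              # contig coordinate of the first base
  anchor_off <- NA_real_    # estimated anchor position of contig coord 0

  recruit <- function(w, w_contig_pos) {
    for (i in seq_along(seqs)) {
      if (used[i] || i %in% members) next
      off <- regexpr(w, seqs[i], fixed = TRUE)[1]
      if (off < 0L) next
      j <- w_contig_pos - (off - 1L)
      if (!is.null(hints)) {
        if (is.na(anchor_off)) {
          anchor_off <<- hints[i] - j
        } else if (abs(hints[i] - (anchor_off + j)) > hint_tol) {
          next  # joins at a position inconsistent with its realignment
        }
      }
      members <<- c(members, i)
      joins <<- c(joins, j)
    }
  }
  recruit(seed_word, origin)
  seed_reads <- members
  if (!length(members)) return(list(seq = contig, members = members,
                                    joins = joins, depth = integer(0),
                                    seed_reads = seed_reads))
  step <- function(right) {
    # returns TRUE if the contig was extended by one base
    clen <- nchar(contig)
    votes <- character(0)
    for (j in seq_along(members)) {
      s <- seqs[members[j]]
      rel <- if (right) origin + clen - joins[j]       # 0-based offset in read
             else origin - 1L - joins[j]
      if (rel >= 0L && rel < nchar(s)) {
        votes <- c(votes, substr(s, rel + 1L, rel + 1L))
      }
    }
    if (!length(votes)) return(FALSE)
    tv <- sort(table(votes), decreasing = TRUE)
    if (tv[1] < min_support) return(FALSE)
    base <- sort(names(tv[tv == tv[1]]))[1]
    if (right) contig <<- paste0(contig, base)
    else { contig <<- paste0(base, contig); origin <<- origin - 1L }
    TRUE
  }
  extend_dir <- function(right) {
    repeat {
      if (!step(right)) break
      clen <- nchar(contig)
      if (right && clen >= word) {
        recruit(substr(contig, clen - word + 1L, clen), origin + clen - word)
      } else if (!right && clen >= word) {
        recruit(substr(contig, 1L, word), origin)
      }
    }
  }
  extend_dir(TRUE)
  extend_dir(FALSE)
  joins <- joins - origin   # shift to 0-based contig coordinates
  list(seq = contig, members = members, joins = joins, depth = integer(0),
       seed_reads = seed_reads)
}

#' Realign reads to a contig (mismatches only) and compute depth
#'
#' Each read is placed at its recorded join position and scored by Hamming
#' distance over the overlapping part; reads exceeding `max_mm` mismatches
#' are excluded from depth.
#'
#' @param seqs read sequences (anchor orientation).
#' @param contig contig sequence.
#' @param joins 0-based contig positions where each read joins.
#' @param max_mm maximum mismatches (default 3).
#' @return list with `depth` (integer vector, one per contig base) and
#'   `included` (logical per read).
#' @export
realign_reads_to_contig <- function(seqs, contig, joins, max_mm = 3L) {
  clen <- nchar(contig)
  depth <- integer(clen)
  included <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    j <- joins[i]
    c_lo <- max(0L, j)
    c_hi <- min(clen, j + nchar(s))
    if (c_hi <= c_lo) next
    r_lo <- c_lo - j
    sub_r <- substr(s, r_lo + 1L, r_lo + (c_hi - c_lo))
    sub_c <- substr(contig, c_lo + 1L, c_hi)
    mm <- sum(charToRaw(sub_r) != charToRaw(sub_c))
    if (mm > max_mm) next
    included[i] <- TRUE
    depth[(c_lo + 1L):c_hi] <- depth[(c_lo + 1L):c_hi] + 1L
  }
  list(depth = depth, included = included)
}

#' Align a consensus contig to its anchor and record variants
#'
#' Candidate anchor positions come from the supporting reads' realignment
#' positions (deduplicated within 50 bp). The contig is discarded when all
#' candidates fall outside the anchor, or when no supporting read improved
#' on its original alignment score. The best surviving candidate window is
#' aligned globally (NW over the window, contig fully aligned) and
#' consensus-vs-anchor mismatches and indels are recorded in anchor
#' coordinates, together with the projected per-position depth.
#'
#' @param contig a contig from [assemble()] with `depth` filled in.
#' @param cand_starts candidate 0-based anchor start positions of the
#'   contig.
#' @param improved logical: does any supporting read beat its original
#'   alignment score?
#' @param anchor one anchor row of an `sv_reference`.
#' @param params a `realign_params`.
#' @param pad window padding around the candidate (default 100).
#' @return `NULL` if filtered, else a list: `anc_start`, `anc_end`
#'   (0-based half-open), `variants` (data frame: `anc_pos`, `type` in
#'   M/I/D, `len`, `seq`), `depth_on_anchor` (named integer, per anchor
#'   offset), `score`, `pattern`, `subject` (gapped strings).
#' @export
align_consensus <- function(contig, cand_starts, improved, anchor, params,
                            pad = 100L) {
  if (!isTRUE(improved)) return(NULL)
  cl <- nchar(contig$seq)
  cand_starts <- sort(unique(cand_starts))
  cand_starts <- cand_starts[cand_starts > -cl & cand_starts < anchor$len]
  if (!length(cand_starts)) return(NULL)
  keep <- c(TRUE, diff(cand_starts) > 50L)   # dedupe within 50 bp
  cand_starts <- cand_starts[keep]
  best <- NULL
  for (cs in cand_starts) {
    ws <- max(0L, cs - pad)
    we <- min(anchor$len, cs + cl + pad)
    window <- substr(anchor$seq, ws + 1L, we)
    pa <- Biostrings::pairwiseAlignment(
      pattern = contig$seq, subject = window, type = "global-local",
      substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_ext)
    if (is.null(best) || Biostrings::score(pa) > best$score) {
      best <- list(pa = pa, ws = ws, score = Biostrings::score(pa))
    }
  }
  pa <- best$pa; ws <- best$ws
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  anc_start <- ws + Biostrings::start(Biostrings::subject(pa)) - 1L
  # walk the gapped alignment: collect variants and project depth
  variants <- list()
  apos <- anc_start           # 0-based anchor position of next subject base
  cpos <- 0L                  # 0-based contig position of next pattern base
  depth_on_anchor <- integer(0)
  dn <- character(0)
  i <- 1L
  n <- length(pat)
  while (i <= n) {
    if (pat[i] != "-" && sub[i] != "-") {
      if (pat[i] != sub[i]) {
        variants[[length(variants) + 1L]] <- data.frame(
          anc_pos = apos, type = "M", len = 1L, seq = pat[i],
          stringsAsFactors = FALSE)
      }
      depth_on_anchor <- c(depth_on_anchor, contig$depth[cpos + 1L])
      dn <- c(dn, as.character(apos))
      apos <- apos + 1L; cpos <- cpos + 1L; i <- i + 1L
    } else if (sub[i] == "-") {       # insertion in consensus vs anchor
      j <- i
      while (j <= n && sub[j] == "-") j <- j + 1L
      ins_seq <- paste(pat[i:(j - 1L)], collapse = "")
      variants[[length(variants) + 1L]] <- data.frame(
        anc_pos = apos, type = "I", len = j - i, seq = ins_seq,
        stringsAsFactors = FALSE)
      cpos <- cpos + (j - i); i <- j
    } else {                          # deletion in consensus vs anchor
      j <- i
      while (j <= n && pat[j] == "-") j <- j + 1L
      variants[[length(variants) + 1L]] <- data.frame(
        anc_pos = apos, type = "D", len = j - i, seq = "",
        stringsAsFactors = FALSE)
      apos <- apos + (j - i); i <- j
    }
  }
  names(depth_on_anchor) <- dn
  vdf <- if (length(variants)) do.call(rbind, variants)
         else data.frame(anc_pos = integer(0), type = character(0),
                         len = integer(0), seq = character(0),
                         stringsAsFactors = FALSE)
  list(anc_start = anc_start, anc_end = apos, variants = vdf,
       depth_on_anchor = depth_on_anchor, score = best$score,
       pattern = paste(pat, collapse = ""), subject = paste(sub, collapse = ""))
}

# depth lookup helper (0 when position not covered)
depth_at <- function(caln, anc_pos) {
  v <- caln$depth_on_anchor[as.character(anc_pos)]
  ifelse(is.na(v), 0L, as.integer(v))
}

# extract the consensus bases aligned to anchor interval [lo, hi)
consensus_segment <- function(caln, lo, hi) {
  pat <- strsplit(caln$pattern, "")[[1]]
  sub <- strsplit(caln$subject, "")[[1]]
  apos <- caln$anc_start
  out <- character(0)
  for (i in seq_along(pat)) {
    if (sub[i] != "-") {
      if (apos >= lo && apos < hi && pat[i] != "-") out <- c(out, pat[i])
      apos <- apos + 1L
    } else if (pat[i] != "-") {
      # insertion: attach to the current anchor position if inside [lo, hi)
      if (apos > lo && apos < hi) out <- c(out, pat[i])
    }
  }
  paste(out, collapse = "")
}

#' Infer SV calls from consensus-to-anchor alignments
#'
#' The anchor's own SV is called when the consensus covers both breakpoints
#' with depth at least `depth_min`; for insertions the minimum depth over
#' the inserted allele must also reach `depth_min`, and the reported
#' inserted sequence is read off the consensus (so substitutions and small
#' indels of the donor allele relative to the panel allele are carried
#' into the call). Additional indel variants of at least `min_svlen` bp
#' found elsewhere in the alignment are emitted as extra calls. Calls
#' shorter than `min_svlen` are dropped.
#'
#' @param calns list of consensus alignments (from [align_consensus()])
#'   for one anchor.
#' @param anchor the anchor row.
#' @param depth_min minimum breakpoint depth.
#' @param min_svlen minimum SV length reported (default 50).
#' @param n_support supporting read count to annotate.
#' @return data frame of candidate calls: `contig`, `pos` (1-based), `svtype`,
#'   `svlen`, `alt_seq`, `alt_depth`, `n_support`.
#' @export
infer_svs <- function(calns, anchor, depth_min, min_svlen = 50L,
                      n_support = NA_integer_) {
  calls <- list()
  calns <- calns[!vapply(calns, is.null, logical(1))]
  if (length(calns)) {
    # pool depth and variants over all consensus alignments of this
    # anchor: long alleles are assembled per 500 bp block and covered by
    # several contigs whose read sets are disjoint, so summing gives the
    # total read support per position
    pooled_depth <- function(anc_pos) {
      vapply(anc_pos, function(p)
        sum(vapply(calns, depth_at, integer(1), anc_pos = p)),
        integer(1))
    }
    variants <- do.call(rbind, lapply(calns, `[[`, "variants"))
    variants <- variants[!duplicated(variants[, c("anc_pos", "type", "len",
                                                  "seq")]), , drop = FALSE]
    up <- anchor$upstream_len
    # breakpoint depth is taken as the best depth within a small window:
    # panel breakpoints are jittered relative to the donor's, so the NW
    # alignment may place compensating indels right at the junction
    win <- 20L
    bp_depth <- function(lo, hi) {
      max(pooled_depth(max(0L, lo):min(anchor$len - 1L, hi)))
    }
    if (anchor$svtype == "DEL") {
      # junction between upstream and downstream flank at offset `up`
      d_l <- bp_depth(up - 1L - win, up - 1L)
      d_r <- bp_depth(up, up + win)
      if (d_l >= depth_min && d_r >= depth_min) {
        # adjust the length by net indels observed near the junction
        # (call-sized variants are separate events, not adjustments)
        near <- variants[abs(variants$anc_pos - up) <= 50L &
                           variants$type %in% c("I", "D") &
                           variants$len < min_svlen, , drop = FALSE]
        net <- sum(near$len[near$type == "D"]) - sum(near$len[near$type == "I"])
        svlen <- anchor$svlen + net
        if (svlen >= min_svlen) {
          calls[[length(calls) + 1L]] <- data.frame(
            contig = anchor$contig, pos = anchor$pos, svtype = "DEL",
            svlen = svlen, alt_seq = "", alt_depth = min(d_l, d_r),
            n_support = n_support, stringsAsFactors = FALSE)
        }
      }
    } else {
      # the allele is known (it sits in the anchor), so only the two
      # breakpoints need depth; interior depth is required of novel
      # insertions, whose sequence has no anchor support
      is0 <- anchor$ins_start; ie0 <- anchor$ins_end
      d_l <- bp_depth(is0 - 1L - win, is0 - 1L)
      d_r <- bp_depth(ie0, ie0 + win)
      if (d_l >= depth_min && d_r >= depth_min) {
        # the called length is the panel length adjusted by the net indel
        # difference around the allele: a jittered panel breakpoint shows
        # up as a compensating I/D rotation that must not change svlen
        zone <- variants[variants$anc_pos >= is0 - 50L &
                           variants$anc_pos <= ie0 + 50L &
                           variants$type %in% c("I", "D") &
                           variants$len < min_svlen, , drop = FALSE]
        net <- sum(zone$len[zone$type == "I"]) - sum(zone$len[zone$type == "D"])
        svlen <- anchor$svlen + net
        # allele content: read off a fully covering contig if there is
        # one, else correct the panel allele with the pooled variants;
        # reconcile its length to svlen (rotation leaves up to the jitter
        # amount of edge content uncertain)
        full <- which(vapply(calns, function(ca)
          ca$anc_start <= is0 - 1L && ca$anc_end >= ie0 + 1L, logical(1)))
        allele <- if (length(full)) {
          consensus_segment(calns[[full[1]]], is0, ie0)
        } else {
          correct_allele(anchor, variants)
        }
        if (nchar(allele) > svlen) {
          allele <- substr(allele, 1L, svlen)
        } else if (nchar(allele) < svlen) {
          allele <- paste0(allele, substr(anchor$alt_seq,
                                          anchor$svlen - (svlen - nchar(allele)) + 1L,
                                          anchor$svlen))
        }
        if (svlen >= min_svlen) {
          calls[[length(calls) + 1L]] <- data.frame(
            contig = anchor$contig, pos = anchor$pos, svtype = "INS",
            svlen = svlen, alt_seq = allele,
            alt_depth = min(d_l, d_r),
            n_support = n_support, stringsAsFactors = FALSE)
        }
      }
    }
    # extra large indels seen in the consensus outside the allele itself
    ins_zone <- function(p) p >= anchor$ins_start - 50L & p <= anchor$ins_end + 50L
    if (anchor$svtype == "DEL") ins_zone <- function(p) abs(p - up) <= 50L
    extra <- variants[variants$len >= min_svlen &
                        variants$type %in% c("I", "D") &
                        !ins_zone(variants$anc_pos), , drop = FALSE]
    if (nrow(extra)) {
      for (r in seq_len(nrow(extra))) {
        lf <- lift_anchor_pos_safe(anchor, extra$anc_pos[r])
        if (is.na(lf)) next
        d_l <- pooled_depth(extra$anc_pos[r] - 1L)
        d_r <- pooled_depth(
          extra$anc_pos[r] + if (extra$type[r] == "D") extra$len[r] else 0L)
        if (d_l < depth_min || d_r < depth_min) next
        calls[[length(calls) + 1L]] <- data.frame(
          contig = anchor$contig, pos = lf,
          svtype = if (extra$type[r] == "I") "INS" else "DEL",
          svlen = extra$len[r], alt_seq = extra$seq[r],
          alt_depth = min(d_l, d_r), n_support = n_support,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      svtype = character(0), svlen = integer(0),
                      alt_seq = character(0), alt_depth = integer(0),
                      n_support = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

# apply consensus-vs-anchor variants inside the insert span to the panel
# allele: substitutions replace bases, deletions remove them, insertions
# strictly inside the span add bases
correct_allele <- function(anchor, variants) {
  lo <- anchor$ins_start; hi <- anchor$ins_end
  n <- hi - lo
  bases <- strsplit(substr(anchor$seq, lo + 1L, hi), "")[[1]]
  ins_before <- rep("", n + 1L)
  del <- rep(FALSE, n)
  if (nrow(variants)) {
    for (r in seq_len(nrow(variants))) {
      v <- variants[r, ]
      rel <- v$anc_pos - lo
      if (v$type == "M" && rel >= 0L && rel < n) {
        bases[rel + 1L] <- v$seq
      } else if (v$type == "D" && rel < n && rel + v$len > 0L) {
        span <- max(0L, rel):(min(n, rel + v$len) - 1L)
        del[span + 1L] <- TRUE
      } else if (v$type == "I" && rel > 0L && rel < n) {
        ins_before[rel + 1L] <- v$seq
      }
    }
  }
  out <- character(0)
  for (i in seq_len(n)) {
    if (nzchar(ins_before[i])) out <- c(out, ins_before[i])
    if (!del[i]) out <- c(out, bases[i])
  }
  paste(out, collapse = "")
}

# genome position of an anchor offset, NA for offsets inside the allele
lift_anchor_pos_safe <- function(anchor, off) {
  up <- anchor$upstream_len
  ins_len <- anchor$ins_end - anchor$ins_start
  if (off < up) return(anchor$pos - up + off + 1L)
  if (off < up + ins_len) return(anchor$pos)
  base_after <- if (anchor$svtype == "DEL") anchor$end else anchor$pos
  p <- base_after + (off - up - ins_len) + 1L
  if (off - up - ins_len >= anchor$downstream_len) return(NA_integer_)
  p
}

#' Genotype a call from allele-fraction thresholds
#'
#' @param alt_depth consensus depth supporting the SV allele.
#' @param ref_depth depth of confident reference-allele reads at the
#'   breakpoint (from the original alignments).
#' @return "1/1" (fraction >= 0.8), "0/1" (in 0.2..0.8), `NA` (below 0.2:
#'   dropped as noise), or "./." when total depth is zero.
#' @export
genotype_call <- function(alt_depth, ref_depth) {
  tot <- alt_depth + ref_depth
  if (tot == 0) return("./.")
  f <- alt_depth / tot
  if (f >= 0.8) return("1/1")
  if (f >= 0.2) return("0/1")
  NA_character_
}

# -- VCF output ---------------------------------------------------------------

# left-normalize an indel call against the genome
left_normalize <- function(genome, contig, pos, svtype, svlen, alt_seq) {
  ctg <- genome[[contig]]
  if (svtype == "DEL") {
    del <- substr(ctg, pos + 1L, pos + svlen)
    while (pos > 1L && substr(ctg, pos, pos) == substr(del, svlen, svlen)) {
      del <- paste0(substr(ctg, pos, pos), substr(del, 1L, svlen - 1L))
      pos <- pos - 1L
    }
    return(list(pos = pos, alt_seq = ""))
  }
  s <- alt_seq
  n <- nchar(s)
  while (pos > 1L && substr(ctg, pos, pos) == substr(s, n, n)) {
    s <- paste0(substr(ctg, pos, pos), substr(s, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, alt_seq = s)
}

#' Write SV calls as VCF 4.2
#'
#' Explicit padded alleles, left-normalized against the reference; INFO
#' keys SVTYPE, SVLEN, END and RE (supporting reads), single sample with
#' GT.
#'
#' @param calls data frame with `contig`, `pos`, `svtype`, `svlen`,
#'   `alt_seq`, `gt`, `n_support`.
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @param sample sample name (default "SAMPLE").
#' @export
write_calls_vcf <- function(calls, genome, path, sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panrescue",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    calls <- calls[order(calls$contig, calls$pos, calls$svtype), , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      nr <- left_normalize(genome, cl$contig, cl$pos, cl$svtype, cl$svlen,
                           cl$alt_seq)
      ctg <- genome[[cl$contig]]
      pad <- substr(ctg, nr$pos, nr$pos)
      if (cl$svtype == "DEL") {
        ref <- paste0(pad, substr(ctg, nr$pos + 1L, nr$pos + cl$svlen))
        alt <- pad
        endp <- nr$pos + cl$svlen
        svlen <- -cl$svlen
      } else {
        ref <- pad
        alt <- paste0(pad, nr$alt_seq)
        endp <- nr$pos
        svlen <- cl$svlen
      }
      body <- c(body, paste(
        cl$contig, nr$pos, sprintf("panrescue_%d", i), ref, alt, ".", "PASS",
        sprintf("SVTYPE=%s;SVLEN=%d;END=%d;RE=%d",
                cl$svtype, svlen, endp, cl$n_support),
        "GT", cl$gt, sep = "\t"))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
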