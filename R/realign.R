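# Single-end realignment of signal reads against the SV-anchor reference:
# unique-seed selection, unitig merging into match blocks, sparse dynamic
# programming chaining, and DP extension of the top chains.

#' Realignment parameter set
#'
#' @param max_occ k-mers occurring at most this often in the SV reference
#'   are "unique" seeds; more frequent k-mers seed only at read ends
#'   (default 4).
#' @param top_chains number of top-scoring seed chains extended per read
#'   (default 12).
#' @param match,mismatch,gap_open,gap_ext extension scoring scheme
#'   (positive penalties; a length-L gap costs `gap_open + L * gap_ext`).
#' @param max_block_positions a match block mapping to more reference
#'   positions than this has that many positions randomly retained
#'   (default 1000).
#' @param max_chain_seeds per anchor and strand, at most this many expanded
#'   seeds enter the chaining DP, longest blocks first (default 200).
#' @param pair_bonus proper-pair score bonus K (default 50).
#' @param isize_sd_factor proper-pair insert-size window half-width in
#'   standard deviations (default 1.5).
#' @param seed pipeline RNG seed (used for position capping and tie
#'   assignment).
#' @return a list of class `realign_params`.
#' @export
realign_params <- function(max_occ = 4L, top_chains = 12L,
                           match = 1, mismatch = 4, gap_open = 6, gap_ext = 1,
                           max_block_positions = 1000L, max_chain_seeds = 200L,
                           pair_bonus = 50, isize_sd_factor = 1.5,
                           seed = 1L) {
  stopifnot(max_occ >= 1L, top_chains >= 1L, match > 0, mismatch >= 0,
            gap_open >= 0, gap_ext >= 0, max_block_positions >= 1L)
  p <- list(max_occ = as.integer(max_occ), top_chains = as.integer(top_chains),
            match = match, mismatch = mismatch,
            gap_open = gap_open, gap_ext = gap_ext,
            max_block_positions = as.integer(max_block_positions),
            max_chain_seeds = as.integer(max_chain_seeds),
            pair_bonus = pair_bonus, isize_sd_factor = isize_sd_factor,
            seed = as.integer(seed))
  p$submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = -mismatch, baseOnly = FALSE)
  class(p) <- "realign_params"
  p
}

#' Select seed k-mers of a read
#'
#' Every k-mer of the read (both orientations) with at most `max_occ`
#' occurrences in the SV reference becomes a seed; the first and last k-mer
#' of the read additionally seed regardless of occurrence count, so reads
#' lying entirely in repeat tracts still anchor at their ends.
#'
#' @param read read sequence (sequencer orientation).
#' @param index a `dbg_index`.
#' @param max_occ uniqueness threshold.
#' @return data frame of seeds: `read_off` (0-based, in the oriented read),
#'   `strand`, `kmer`, `count`, `unitig_id`, `unitig_offset`.
#' @export
select_seeds <- function(read, index, max_occ = 4L) {
  k <- index$k
  if (nchar(read) < k) {
    return(data.frame(read_off = integer(0), strand = character(0),
                      kmer = character(0), count = integer(0),
                      unitig_id = integer(0), unitig_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  one_strand <- function(seq, strand) {
    kms <- kmerize(seq, k)
    n <- length(kms)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      hit <- lookup(index, kms[i])
      if (hit$count == 0L) next
      if (hit$count > max_occ && i != 1L && i != n) next  # repeat, not an end
      rows[[i]] <- data.frame(read_off = i - 1L, strand = strand,
                              kmer = kms[i], count = hit$count,
                              unitig_id = hit$unitig_id,
                              unitig_offset = hit$unitig_offset,
                              stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  out <- rbind(one_strand(read, "+"), one_strand(revcomp(read), "-"))
  if (is.null(out)) {
    out <- data.frame(read_off = integer(0), strand = character(0),
                      kmer = character(0), count = integer(0),
                      unitig_id = integer(0), unitig_offset = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Merge co-linear seeds within unitigs into match blocks
#'
#' Runs of seeds consecutive in both read and unitig coordinates merge into
#' one block spanning their union; the block is then mapped to SV-reference
#' positions (all occurrence positions of its first k-mer at which the full
#' block matches). Blocks with more than `max_positions` mapping positions
#' have that many positions randomly retained under the pipeline seed.
#'
#' @param seeds data frame from [select_seeds()].
#' @param index a `dbg_index`.
#' @param max_positions cap on per-block positions (default 1000).
#' @param seed RNG seed for the cap sampling.
#' @return list of blocks: each `list(read_off, len, strand, gpos)` with
#'   `gpos` the sorted 0-based global positions of the block.
#' @export
merge_in_unitig <- function(seeds, index, max_positions = 1000L, seed = 1L) {
  if (nrow(seeds) == 0L) return(list())
  k <- index$k
  blocks <- list()
  for (str in unique(seeds$strand)) {
    s <- seeds[seeds$strand == str, , drop = FALSE]
    s <- s[order(s$read_off), , drop = FALSE]
    run_start <- 1L
    flush <- function(from, to) {
      first <- s[from, ]
      len <- k + (s$read_off[to] - s$read_off[from])
      gpos <- index$kmer_pos[[first$kmer]]
      # keep positions where the whole block lies inside one anchor and
      # matches it (unitig occurrences can truncate at anchor ends)
      aidx <- findInterval(gpos, index$anchor_offsets)
      off <- gpos - index$anchor_offsets[aidx]
      ok <- off + len <= index$anchor_lens[aidx]
      if (len > k && any(ok)) {
        # the block's sequence, reconstructed from its consecutive seed k-mers
        blk_seq <- paste0(first$kmer,
                          paste(substr(s$kmer[(from + 1L):to], k, k),
                                collapse = ""))
        ok[ok] <- vapply(which(ok), function(j) {
          substr(index$anchor_seqs[aidx[j]], off[j] + 1L, off[j] + len) == blk_seq
        }, logical(1))
      }
      gpos <- gpos[ok]
      if (!length(gpos)) return(NULL)
      if (length(gpos) > max_positions) {
        gpos <- sort(with_seed(derive_seed(seed, 7L),
                               sample(gpos, max_positions)))
      }
      list(read_off = first$read_off, len = len, strand = str, gpos = gpos)
    }
    n <- nrow(s)
    for (i in seq_len(n)) {
      is_last <- i == n
      breaks <- if (is_last) TRUE else {
        !(s$read_off[i + 1L] == s$read_off[i] + 1L &&
          identical(s$unitig_id[i + 1L], s$unitig_id[i]) &&
          !is.na(s$unitig_id[i]) &&
          s$unitig_offset[i + 1L] == s$unitig_offset[i] + 1L)
      }
      if (breaks) {
        b <- flush(run_start, i)
        if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
        run_start <- i + 1L
      }
    }
  }
  blocks
}

#' Gap penalty between two chained match blocks
#'
#' The penalty grows with the absolute difference of the two blocks'
#' alignment diagonals (reference offset minus read offset) plus a constant:
#' `0.125 * |(ref_p - ref_q) - (read_p - read_q)| + 3`.
#'
#' @param ref_p,ref_q reference positions of the later and earlier block.
#' @param read_p,read_q read positions of the later and earlier block.
#' @return the penalty (score units).
#' @export
chain_gap_penalty <- function(ref_p, ref_q, read_p, read_q) {
  0.125 * abs((ref_p - ref_q) - (read_p - read_q)) + 3
}

#' Chain match blocks by sparse dynamic programming
#'
#' Within each (anchor, strand) group, computes for every block the best
#' chain score `f(p) = max(L(p), max_q f(q) + L(p|q) - theta(p, q))` where
#' `L(p|q)` is the part of block p's read span not overlapping block q and
#' `theta` is [chain_gap_penalty()]. Transitions require strictly increasing
#' reference and read coordinates and are disallowed when the penalty
#' exceeds the gain (`theta > L(p|q)`), which splits distant-diagonal chains.
#'
#' @param seeds data frame with columns `ref` (0-based global reference
#'   position), `read` (0-based read offset), `len`, `anchor_id`, `strand`.
#' @param top_n maximum number of chains returned.
#' @return list of chains ranked by score (ties: lowest anchor, leftmost
#'   position); each chain is `list(score, anchor_id, strand, seeds)` with
#'   `seeds` the member rows in reference order.
#' @export
sdp_chain <- function(seeds, top_n = 12L) {
  if (is.null(seeds) || nrow(seeds) == 0L) return(list())
  chains <- list()
  for (grp in split(seeds, paste(seeds$anchor_id, seeds$strand))) {
    g <- grp[order(grp$ref, grp$read), , drop = FALSE]
    n <- nrow(g)
    f <- g$len
    pred <- integer(n)
    for (p in seq_len(n)) {
      if (p == 1L) next
      q <- seq_len(p - 1L)
      l_pq <- pmin(g$len[p], g$read[p] + g$len[p] - (g$read[q] + g$len[q]))
      theta <- chain_gap_penalty(g$ref[p], g$ref[q], g$read[p], g$read[q])
      valid <- g$ref[q] < g$ref[p] & g$read[q] < g$read[p] &
        l_pq > 0 & theta <= l_pq
      if (!any(valid)) next
      gain <- ifelse(valid, f[q] + l_pq - theta, -Inf)
      best <- which.max(gain)
      if (gain[best] > f[p]) {
        f[p] <- gain[best]
        pred[p] <- best
      }
    }
    used <- logical(n)
    for (p in order(-f, g$ref)) {
      if (used[p]) next
      path <- integer(0)
      q <- p
      while (q != 0L && !used[q]) {
        path <- c(q, path)
        used[q] <- TRUE
        q <- pred[q]
      }
      chains[[length(chains) + 1L]] <- list(
        score = f[p], anchor_id = g$anchor_id[1], strand = g$strand[1],
        seeds = g[path, , drop = FALSE])
    }
  }
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, `[[`, numeric(1), "anchor_id"),
               vapply(chains, function(c) c$seeds$ref[1], numeric(1)))
  chains[ord[seq_len(min(top_n, length(chains)))]]
}

# expand blocks to per-position chaining seeds, bounded per anchor/strand
expand_blocks <- function(blocks, index, max_chain_seeds = 200L) {
  if (!length(blocks)) {
    return(data.frame(ref = integer(0), read = integer(0), len = integer(0),
                      anchor_id = integer(0), strand = character(0)))
  }
  rows <- lapply(blocks, function(b) {
    aidx <- findInterval(b$gpos, index$anchor_offsets)
    data.frame(ref = b$gpos, read = b$read_off, len = b$len,
               anchor_id = index$anchor_ids[aidx], strand = b$strand,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # bound the DP size: keep the longest blocks' positions per anchor/strand
  keep <- unlist(lapply(split(seq_len(nrow(df)),
                              paste(df$anchor_id, df$strand)), function(ix) {
    if (length(ix) <= max_chain_seeds) return(ix)
    ix[order(-df$len[ix], df$ref[ix])][seq_len(max_chain_seeds)]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Extend a seed chain into a full-length alignment
#'
#' The chain fixes the anchor and the diagonal band; the read is then
#' aligned full-length (global in the read, local in the anchor) against
#' the anchor window spanning the chain, with the configured scoring
#' scheme. Alignments are therefore never clipped: an anchor that absorbs
#' the SV yields a contiguous full-length alignment across the junction.
#'
#' @param read read sequence, oriented to the chain's strand.
#' @param chain one chain from [sdp_chain()].
#' @param svref the `sv_reference`.
#' @param params a `realign_params`.
#' @return a `list(anchor_id, anc_start, anc_end, strand, cigar, score, mm,
#'   read_len, source = "pansvr")` with 0-based half-open anchor interval,
#'   or NULL if the chain lies outside its anchor.
#' @export
extend_chain <- function(read, chain, svref, params) {
  a <- svref$anchors[svref$anchors$anchor_id == chain$anchor_id, ]
  if (nrow(a) != 1L) return(NULL)
  aoff <- svref$offsets[match(chain$anchor_id, svref$anchors$anchor_id)]
  s <- chain$seeds
  anc_lo <- min(s$ref) - aoff - s$read[which.min(s$ref)]
  anc_hi <- max(s$ref + s$len) - aoff + (nchar(read) - max(s$read + s$len))
  pad <- 30L
  ws <- max(0L, anc_lo - pad)
  we <- min(a$len, anc_hi + pad)
  if (we - ws < 1L || anc_lo > a$len || anc_hi < 0L) return(NULL)
  window <- substr(a$seq, ws + 1L, we)
  pa <- Biostrings::pairwiseAlignment(
    pattern = read, subject = window, type = "global-local",
    substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_ext)
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  cig <- cigar_from_gapped(pat, sub)
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  mm <- sum(pc != "-" & sc != "-" & pc != sc)
  anc_start <- ws + Biostrings::start(Biostrings::subject(pa)) - 1L
  anc_end <- ws + Biostrings::end(Biostrings::subject(pa))
  list(anchor_id = a$anchor_id, anc_start = anc_start, anc_end = anc_end,
       strand = chain$strand, cigar = cig, score = Biostrings::score(pa),
       mm = mm, read_len = nchar(read), source = "pansvr")
}

#' Realign one read against the SV reference
#'
#' Runs the full single-end path: seed selection on both strands, unitig
#' merging, SDP chaining, and extension of the top chains.
#'
#' @param read read sequence in sequencer orientation.
#' @param index a `dbg_index`.
#' @param svref the `sv_reference` the index was built from.
#' @param params a `realign_params`.
#' @return list of candidate alignments sorted by decreasing score (ties:
#'   lowest anchor, leftmost position); empty if the read cannot be seeded.
#' @export
realign_read <- function(read, index, svref, params = realign_params()) {
  read <- toupper(read)
  seeds <- select_seeds(read, index, params$max_occ)
  if (nrow(seeds) == 0L) return(list())
  blocks <- merge_in_unitig(seeds, index, params$max_block_positions,
                            params$seed)
  sdf <- expand_blocks(blocks, index, params$max_chain_seeds)
  chains <- sdp_chain(sdf, top_n = params$top_chains)
  if (!length(chains)) return(list())
  rc <- revcomp(read)
  alns <- lapply(chains, function(ch) {
    extend_chain(if (ch$strand == "+") read else rc, ch, svref, params)
  })
  alns <- alns[!vapply(alns, is.null, logical(1))]
  if (!length(alns)) return(list())
  key <- vapply(alns, function(x)
    paste(x$anchor_id, x$anc_start, x$strand), character(1))
  alns <- alns[!duplicated(key)]
  ord <- order(-vapply(alns, `[[`, numeric(1), "score"),
               vapply(alns, `[[`, numeric(1), "anchor_id"),
               vapply(alns, `[[`, numeric(1), "anc_start"))
  alns[ord]
}
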