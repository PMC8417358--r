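# In-memory de Bruijn graph index over the SV-anchor reference.
#
# The graph has (k-1)-mers as nodes and the distinct k-mers of the anchor
# concatenation as edges. Unitigs are maximal non-branching edge paths.
# Each k-mer belongs to exactly one unitig at one offset, and every
# occurrence position of every k-mer in the reference is retrievable.
# K-mers never span anchor boundaries, and any k-mer containing an
# ambiguous base (N) is not indexed, which breaks unitigs at Ns.

#' Build the k-mer / unitig index of an SV reference
#'
#' @param svref an `sv_reference` (see [build_sv_reference()]).
#' @param k k-mer length, 8..31 (default 22).
#' @return an object of class `dbg_index` with elements `k`, `unitigs`
#'   (character vector), `kmer_unitig` (environment: k-mer ->
#'   c(unitig_id, offset), 0-based), `kmer_pos` (environment: k-mer ->
#'   sorted 0-based global positions in the anchor concatenation),
#'   `anchor_offsets`, `anchor_seqs`.
#' @export
build_index <- function(svref, k = 22L) {
  k <- as.integer(k)
  if (k < 8L || k > 31L) stop("k must be between 8 and 31")
  anchors <- svref$anchors
  usable <- anchors$len >= k
  if (!all(usable)) {
    warning(sprintf("%d anchor(s) shorter than k = %d skipped from the index",
                    sum(!usable), k))
  }
  all_kmers <- character(0)
  all_pos <- integer(0)
  for (i in which(usable)) {
    km <- kmerize(anchors$seq[i], k)
    pos <- svref$offsets[i] + seq_along(km) - 1L
    keep <- !grepl("N", km, fixed = TRUE)
    all_kmers <- c(all_kmers, km[keep])
    all_pos <- c(all_pos, pos[keep])
  }
  if (!length(all_kmers)) stop("no indexable k-mers (all anchors too short?)")
  kmer_pos_list <- split(all_pos, all_kmers)
  kmer_pos_list <- lapply(kmer_pos_list, sort)
  kmer_pos <- list2env(kmer_pos_list, hash = TRUE,
                       size = max(29L, length(kmer_pos_list)))

  ut <- build_unitigs(names(kmer_pos_list), k)

  structure(list(k = k, unitigs = ut$unitigs, kmer_unitig = ut$kmer_unitig,
                 kmer_pos = kmer_pos,
                 anchor_offsets = svref$offsets,
                 anchor_ids = svref$anchors$anchor_id,
                 anchor_lens = svref$anchors$len,
                 anchor_seqs = svref$anchors$seq),
            class = "dbg_index")
}

# unitigs = maximal non-branching edge paths over distinct k-mers
build_unitigs <- function(kmers, k) {
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  out_edges <- split(kmers, pref)          # node -> outgoing edge k-mers
  out_deg <- lengths(out_edges)
  in_deg <- table(suf)
  deg_in <- function(node) { v <- in_deg[node]; ifelse(is.na(v), 0L, as.integer(v)) }
  deg_out <- function(node) { v <- out_deg[node]; ifelse(is.na(v), 0L, as.integer(v)) }

  visited <- new.env(hash = TRUE, size = max(29L, length(kmers)))
  kmer_unitig <- new.env(hash = TRUE, size = max(29L, length(kmers)))
  unitigs <- character(0)

  walk_from <- function(e) {
    # extend a unitig forward from edge e; e assumed unvisited
    path <- e
    assign(e, TRUE, envir = visited)
    repeat {
      node <- substr(path[length(path)], 2L, k)
      if (deg_out(node) != 1L || deg_in(node) != 1L) break
      nxt <- out_edges[[node]][1]
      if (!is.null(visited[[nxt]])) break   # cycle closed
      path <- c(path, nxt)
      assign(nxt, TRUE, envir = visited)
    }
    uid <- length(unitigs)                   # 0-based id
    useq <- paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
    unitigs[[length(unitigs) + 1L]] <<- useq
    for (j in seq_along(path)) {
      assign(path[j], c(uid, j - 1L), envir = kmer_unitig)
    }
  }

  # starts: edges whose source node is branching (or a tip)
  is_start <- !(deg_in(pref) == 1L & deg_out(pref) == 1L)
  for (e in kmers[is_start]) if (is.null(visited[[e]])) walk_from(e)
  # leftover edges belong to pure cycles; break each at an arbitrary edge
  for (e in kmers) if (is.null(visited[[e]])) walk_from(e)

  list(unitigs = unitigs, kmer_unitig = kmer_unitig)
}

#' @export
print.dbg_index <- function(x, ...) {
  cat(sprintf("dbg_index: k = %d, %d distinct k-mers, %d unitigs\n",
              x$k, length(ls(x$kmer_pos)), length(x$unitigs)))
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index a `dbg_index`.
#' @param kmer a string of length `index$k`.
#' @return a list with `count`, `gpos` (sorted 0-based global positions in
#'   the anchor concatenation), `unitig_id` and `unitig_offset` (0-based),
#'   or a zero-count result if the k-mer is absent or contains N.
#' @export
lookup <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("k-mer length must equal index k")
  empty <- list(count = 0L, gpos = integer(0),
                unitig_id = NA_integer_, unitig_offset = NA_integer_)
  if (grepl("N", kmer, fixed = TRUE)) return(empty)
  pos <- index$kmer_pos[[kmer]]
  if (is.null(pos)) return(empty)
  u <- index$kmer_unitig[[kmer]]
  list(count = length(pos), gpos = pos,
       unitig_id = as.integer(u[1]), unitig_offset = as.integer(u[2]))
}
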