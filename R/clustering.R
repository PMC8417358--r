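# Read clustering: nearby known SVs are grouped greedily, only the two
# best-supported SVs of a group are retained, and reads assigned to the
# dropped members are redistributed by shared k-mer counting.

#' Group nearby SVs
#'
#' Greedy left-to-right expansion per contig: an SV joins the current group
#' when its upstream breakpoint is within `max_gap` bp of the group's
#' downstream border, and the group extends until no nearby SV can join.
#' Groups never overlap.
#'
#' @param svs a data frame with columns `contig`, `pos`, `end` (anchor
#'   table of an `sv_reference` works directly).
#' @param max_gap grouping distance in bp (default 50).
#' @return integer vector of group ids (0-based), parallel to rows of
#'   `svs`.
#' @export
group_nearby_svs <- function(svs, max_gap = 50L) {
  gid <- integer(nrow(svs))
  if (nrow(svs) == 0L) return(gid)
  ord <- order(svs$contig, svs$pos, svs$end)
  cur <- -1L
  border <- -Inf
  ctg <- ""
  for (i in ord) {
    if (!identical(svs$contig[i], ctg) || svs$pos[i] > border + max_gap) {
      cur <- cur + 1L
      ctg <- svs$contig[i]
      border <- svs$end[i]
    } else {
      border <- max(border, svs$end[i])
    }
    gid[i] <- cur
  }
  gid
}

#' Retain the two best-supported SVs of a group
#'
#' @param members integer vector of anchor ids in the group.
#' @param counts named numeric vector of supporting-read counts (names are
#'   anchor ids as characters; missing means zero).
#' @return integer vector of one or two retained anchor ids (count-maximal;
#'   ties broken by lower anchor id), or an empty vector if the group has
#'   no reads at all.
#' @export
select_top2 <- function(members, counts) {
  cnt <- counts[as.character(members)]
  cnt[is.na(cnt)] <- 0
  if (sum(cnt) == 0) return(integer(0))
  ord <- order(-cnt, members)
  members[ord][seq_len(min(2L, length(members)))]
}

# distinct k-mer set of a sequence (both orientations of the read are the
# caller's concern; anchors are single-stranded)
kmer_set <- function(seq, k) unique(kmerize(seq, k))

#' Reassign a read between two retained SVs by k-mer counting
#'
#' Counts the read's distinct k-mers present in each anchor sequence (the
#' read is considered in both orientations; the better orientation per
#' anchor counts) and assigns the read to the anchor sharing more k-mers.
#' Ties are resolved by a seeded uniform choice.
#'
#' @param read_seq read sequence.
#' @param seq_a,seq_b the two anchor sequences.
#' @param k k-mer length.
#' @param seed RNG seed for tie resolution.
#' @return 1 if assigned to the first anchor, 2 if to the second.
#' @export
reassign_read <- function(read_seq, seq_a, seq_b, k, seed = 1L) {
  shared <- function(anchor_seq) {
    aset <- kmer_set(anchor_seq, k)
    fwd <- sum(kmer_set(read_seq, k) %in% aset)
    rev <- sum(kmer_set(revcomp(read_seq), k) %in% aset)
    max(fwd, rev)
  }
  na <- shared(seq_a)
  nb <- shared(seq_b)
  if (na > nb) return(1L)
  if (nb > na) return(2L)
  with_seed(seed, sample(c(1L, 2L), 1L))
}

#' Cluster realigned reads by anchor with top-2 retention
#'
#' Takes the kept pairs (each end carrying an anchor realignment), counts
#' per-anchor support, groups nearby SVs, keeps the two count-maximal SVs
#' per group and reassigns the remaining reads by shared k-mers.
#'
#' @param reads list of per-read entries: `list(name, seq, qual, anchor_id,
#'   anc_start, anc_end, strand, score, mm, cigar, orig)` (one entry per
#'   realigned end).
#' @param svref the `sv_reference`.
#' @param k k-mer length for reassignment (default: 22).
#' @param seed RNG seed shared with the pipeline.
#' @return list of clusters, one per retained anchor with at least one
#'   read: `list(anchor_id, reads)`; reads keep their original fields with
#'   `anchor_id` rewritten to the cluster's anchor.
#' @export
cluster_reads <- function(reads, svref, k = 22L, seed = 1L) {
  if (!length(reads)) return(list())
  aid <- vapply(reads, `[[`, numeric(1), "anchor_id")
  counts <- table(aid)
  anchors <- svref$anchors
  gid <- group_nearby_svs(anchors)
  retained_by_group <- lapply(split(anchors$anchor_id, gid), select_top2,
                              counts = counts)
  retained <- unlist(retained_by_group, use.names = FALSE)
  group_of <- stats::setNames(gid, anchors$anchor_id)

  assign_to <- integer(length(reads))
  for (i in seq_along(reads)) {
    a <- aid[i]
    g <- group_of[[as.character(a)]]
    ret <- retained_by_group[[as.character(g)]]
    if (length(ret) == 0L) { assign_to[i] <- NA_integer_; next }
    if (a %in% ret) { assign_to[i] <- a; next }
    if (length(ret) == 1L) { assign_to[i] <- ret[1]; next }
    sa <- anchors$seq[anchors$anchor_id == ret[1]]
    sb <- anchors$seq[anchors$anchor_id == ret[2]]
    pick <- reassign_read(reads[[i]]$seq, sa, sb, k,
                          seed = derive_seed(seed, 11L + i))
    assign_to[i] <- ret[pick]
  }
  keep <- !is.na(assign_to)
  out <- list()
  for (a in sort(unique(assign_to[keep]))) {
    members <- which(keep & assign_to == a)
    rds <- lapply(reads[members], function(r) { r$anchor_id <- a; r })
    out[[length(out) + 1L]] <- list(anchor_id = a, reads = rds)
  }
  out
}
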