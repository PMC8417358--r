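# exhaustive chain enumeration oracle: best score over all ordered subsets
# of blocks under the same transition rules as the DP
brute_chain_best <- function(df) {
  df <- df[order(df$ref, df$read), , drop = FALSE]
  n <- nrow(df)
  best <- -Inf
  # depth-first over chains extending each start block
  extend <- function(last, score) {
    best <<- max(best, score)
    if (last == n) return()
    for (p in (last + 1L):n) {
      if (df$ref[p] <= df$ref[last] || df$read[p] <= df$read[last]) next
      l_pq <- min(df$len[p], df$read[p] + df$len[p] -
                    (df$read[last] + df$len[last]))
      theta <- chain_gap_penalty(df$ref[p], df$ref[last],
                                 df$read[p], df$read[last])
      if (l_pq <= 0 || theta > l_pq) next
      extend(p, score + l_pq - theta)
    }
  }
  for (s in seq_len(n)) extend(s, df$len[s])
  best
}

blocks_df <- function(ref, read, len, anchor_id = 0L, strand = "+") {
  data.frame(ref = ref, read = read, len = len, anchor_id = anchor_id,
             strand = strand, stringsAsFactors = FALSE)
}


# brute-force pairing oracle
brute_pair_best <- function(cand1, cand2, svref, model, K) {
  best <- -Inf
  n1 <- length(cand1); n2 <- length(cand2)
  if (n1 && n2) {
    for (p in seq_len(n1)) for (q in seq_len(n2)) {
      s <- cand1[[p]]$score + cand2[[q]]$score +
        if (panrescue:::combo_proper(cand1[[p]], cand2[[q]], svref, model)) K else 0
      best <- max(best, s)
    }
  } else if (n1) {
    best <- max(vapply(cand1, `[[`, numeric(1), "score"))
  } else if (n2) {
    best <- max(vapply(cand2, `[[`, numeric(1), "score"))
  }
  best
}

mk_pan <- function(score, anchor_id = 0L, start = 100L, strand = "+",
                   read_len = 150L) {
  list(score = score, source = "pansvr",
       aln = list(anchor_id = anchor_id, anc_start = start,
                  anc_end = start + read_len, strand = strand,
                  read_len = read_len))
}
mk_orig <- function(score, pos = 1000L, strand = "+", isize = 400L) {
  list(score = score, source = "orig",
       orig = list(contig = "chr1", pos = pos, strand = strand,
                   score = score, mapq = 60L, isize = isize, mm = 0L,
                   cigar = "150M"))
}

toy_svref <- function() {
  fx <- fixture_ins_svref()
  fx$svref
}

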