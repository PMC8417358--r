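# Deterministic simulator: random genome with tandem-repeat tracts, donor
# genome with implanted SVs, divergent known-SV panels (jitter, allele
# divergence, leave-out), paired-end reads with substitution errors, and
# companion original-style alignments that show the clipping/discordant
# signatures a real aligner produces at SV breakpoints. The companion
# alignments are produced by projecting each read's known donor interval
# through the implant map and soft-clipping across breakpoints; the
# projector is intentionally simple and exists to generate realistic
# original-alignment metadata, not to be a general-purpose aligner.

#' Simulation configuration
#'
#' @param genome_len reference length in bp (default 200000).
#' @param gc GC fraction (default 0.5).
#' @param repeats data frame of tandem-repeat tract specs (`unit`,
#'   `copies`, `count`); default: three tracts of (AC) x 50.
#' @param contig contig name (default "chr1").
#' @param sv_count number of implanted SVs (default 20).
#' @param sv_len_range SV length range in bp (default c(60, 1000)).
#' @param sv_types types cycled over the implants.
#' @param min_sv_gap minimum separation between implants (default 1000).
#' @param read_len read length (default 150).
#' @param insert_mean,insert_sd insert-size distribution (default 400, 50).
#' @param depth mean sequencing depth (default 30).
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param jitter maximum breakpoint shift of panel records in bp
#'   (default 10).
#' @param divergence per-base substitution rate applied to panel insertion
#'   alleles (default 0.02).
#' @param leave_out fraction of truth records removed from the panel
#'   (default 0).
#' @param seed mandatory RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 200000L, gc = 0.5,
                       repeats = data.frame(unit = "AC", copies = 50L,
                                            count = 3L,
                                            stringsAsFactors = FALSE),
                       contig = "chr1",
                       sv_count = 20L, sv_len_range = c(60L, 1000L),
                       sv_types = c("DEL", "INS", "DUP"),
                       min_sv_gap = 1000L,
                       read_len = 150L, insert_mean = 400, insert_sd = 50,
                       depth = 30, error_rate = 0.001,
                       jitter = 10L, divergence = 0.02, leave_out = 0,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(gc >= 0, gc <= 1, error_rate >= 0, error_rate <= 1,
            divergence >= 0, divergence <= 1, leave_out >= 0, leave_out <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the configured GC fraction, with the configured
#' tandem-repeat tracts spliced in at random positions. Deterministic
#' under the seed.
#'
#' @param cfg a `sim_config`.
#' @return named character vector of one contig.
#' @export
simulate_genome <- function(cfg) {
  g <- with_seed(derive_seed(cfg$seed, 1L), {
    base <- random_dna(cfg$genome_len, cfg$gc)
    tracts <- character(0)
    if (!is.null(cfg$repeats) && nrow(cfg$repeats)) {
      for (i in seq_len(nrow(cfg$repeats))) {
        tracts <- c(tracts, rep(strrep(cfg$repeats$unit[i],
                                       cfg$repeats$copies[i]),
                                cfg$repeats$count[i]))
      }
    }
    for (tr in tracts) {
      at <- sample.int(nchar(base) - 1L, 1L)
      base <- paste0(substr(base, 1L, at), tr,
                     substr(base, at + 1L, nchar(base)))
    }
    base
  })
  stats::setNames(g, cfg$contig)
}

#' Implant SVs into a genome
#'
#' Places non-overlapping SVs separated by at least `min_sv_gap` bp (and
#' 2 kb from the contig ends), assigns each a genotype (homozygous or
#' heterozygous, equal probability) and applies them to produce the two
#' donor haplotypes: the first carries every SV, the second only the
#' homozygous ones. Returns the truth records (with `gt`) plus the
#' reference-to-haplotype segment maps used for read projection.
#'
#' @param genome named character vector (one contig).
#' @param cfg a `sim_config`.
#' @return list: `haps` (two haplotype sequences), `maps` (their segment
#'   maps: data frames `type` M/I, `ref_start`, `donor_start`, `len`,
#'   0-based), `truth` (`sv_records` with a `gt` column). `donor`/`map`
#'   alias the first haplotype.
#' @export
implant_svs <- function(genome, cfg) {
  ctg <- genome[[1]]
  n <- nchar(ctg)
  res <- with_seed(derive_seed(cfg$seed, 2L), {
    types <- rep_len(cfg$sv_types, cfg$sv_count)
    lens <- sample(seq(cfg$sv_len_range[1], cfg$sv_len_range[2]),
                   cfg$sv_count, replace = TRUE)
    # place left to right with the required gap
    margin <- 2000L
    slots <- numeric(0)
    cursor <- margin
    budget <- n - margin
    for (i in seq_len(cfg$sv_count)) {
      span <- lens[i] + cfg$min_sv_gap
      if (cursor + span > budget) stop("genome too short for requested SVs")
      at <- cursor + sample.int(max(1L, (budget - cursor) %/%
                                      (cfg$sv_count - i + 1L) - span), 1L)
      slots <- c(slots, at)
      cursor <- at + span
    }
    alt <- character(cfg$sv_count)
    for (i in seq_len(cfg$sv_count)) {
      alt[i] <- switch(types[i],
        DEL = "",
        INS = random_dna(lens[i], cfg$gc),
        DUP = substr(ctg, slots[i] - lens[i] + 1L, slots[i]))
    }
    gt <- sample(c("1/1", "0/1"), cfg$sv_count, replace = TRUE)
    list(types = types, lens = lens, slots = as.integer(slots), alt = alt,
         gt = gt)
  })
  truth <- sv_records(id = sprintf("truth%02d", seq_len(cfg$sv_count)),
                      contig = names(genome)[1], pos = res$slots,
                      svtype = res$types, svlen = res$lens,
                      alt_seq = res$alt)
  truth$gt <- res$gt
  truth <- truth[order(truth$pos), , drop = FALSE]
  truth$id <- sprintf("truth%02d", seq_len(nrow(truth)))

  hapA <- apply_svs(ctg, truth)
  hapB <- apply_svs(ctg, truth[truth$gt == "1/1", , drop = FALSE])
  list(haps = list(hapA$seq, hapB$seq), maps = list(hapA$map, hapB$map),
       truth = truth, donor = hapA$seq, map = hapA$map)
}

# apply a set of SVs to a contig; returns the altered sequence and the
# ref<->altered segment map
apply_svs <- function(ctg, svs) {
  n <- nchar(ctg)
  map <- list()
  parts <- character(0)
  r <- 0L; d <- 0L
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    m_len <- sv$pos - r
    if (m_len > 0L) {
      map[[length(map) + 1L]] <- data.frame(type = "M", ref_start = r,
                                            donor_start = d, len = m_len)
      parts <- c(parts, substr(ctg, r + 1L, r + m_len))
      r <- r + m_len; d <- d + m_len
    }
    if (sv$svtype == "DEL") {
      r <- r + sv$svlen
    } else {
      map[[length(map) + 1L]] <- data.frame(type = "I", ref_start = r,
                                            donor_start = d, len = sv$svlen)
      parts <- c(parts, sv$alt_seq)
      d <- d + sv$svlen
    }
  }
  if (r < n) {
    map[[length(map) + 1L]] <- data.frame(type = "M", ref_start = r,
                                          donor_start = d, len = n - r)
    parts <- c(parts, substr(ctg, r + 1L, n))
  }
  list(seq = paste(parts, collapse = ""), map = do.call(rbind, map))
}

#' Derive a divergent known-SV panel from the truth set
#'
#' Breakpoints are shifted by up to `jitter` bp, insertion/duplication
#' alleles mutated at the `divergence` substitution rate, and a
#' `leave_out` fraction of records removed — emulating a population panel
#' that is close to, but not identical with, the donor's own variants.
#'
#' @param truth `sv_records` truth set.
#' @param cfg a `sim_config` (fields `jitter`, `divergence`, `leave_out`,
#'   `seed`).
#' @return list: `panel` (`sv_records`), `left_out` (ids removed).
#' @export
make_known_panel <- function(truth, cfg) {
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- nrow(truth)
    n_out <- round(cfg$leave_out * n)
    out_idx <- if (n_out > 0L) sort(sample.int(n, n_out)) else integer(0)
    keep <- setdiff(seq_len(n), out_idx)
    if (!length(keep)) {
      return(list(panel = empty_svs(), left_out = truth$id[out_idx]))
    }
    rows <- lapply(keep, function(i) {
      sv <- truth[i, ]
      delta <- if (cfg$jitter > 0L)
        sample(seq(-cfg$jitter, cfg$jitter), 1L) else 0L
      pos <- max(1L, sv$pos + delta)
      alt <- sv$alt_seq
      if (nzchar(alt) && cfg$divergence > 0) {
        b <- strsplit(alt, "")[[1]]
        hit <- which(stats::runif(length(b)) < cfg$divergence)
        for (h in hit) b[h] <- sample(setdiff(c("A", "C", "G", "T"), b[h]), 1L)
        alt <- paste(b, collapse = "")
      }
      sv_records(id = paste0("panel_", sv$id), contig = sv$contig, pos = pos,
                 svtype = sv$svtype, svlen = sv$svlen, alt_seq = alt)
    })
    list(panel = do.call(rbind_svs, rows), left_out = truth$id[out_idx])
  })
}

#' Write SV records as an explicit-allele VCF
#'
#' @param svs `sv_records`.
#' @param genome named character vector.
#' @param path output path.
#' @export
write_svs_vcf <- function(svs, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(svs)) {
    svs <- svs[order(svs$contig, svs$pos), , drop = FALSE]
    for (i in seq_len(nrow(svs))) {
      sv <- svs[i, ]
      ctg <- genome[[sv$contig]]
      pad <- substr(ctg, sv$pos, sv$pos)
      if (sv$svtype == "DEL") {
        ref <- paste0(pad, substr(ctg, sv$pos + 1L, sv$pos + sv$svlen))
        alt <- pad
        info <- sprintf("SVTYPE=DEL;SVLEN=%d;END=%d", -sv$svlen, sv$end)
      } else {
        ref <- pad
        alt <- paste0(pad, sv$alt_seq)
        info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", sv$svtype, sv$svlen,
                        sv$end)
      }
      body <- c(body, paste(sv$contig, sv$pos, sv$id, ref, alt, ".", "PASS",
                            info, sep = "\t"))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# project a donor interval [s, e) (0-based) through the implant map:
# returns NULL if no reference-mapped piece, else list(pos (1-based),
# cigar, m_read_lo, m_read_hi) where [m_read_lo, m_read_hi) is the
# reference-aligned part of the read (forward orientation)
project_interval <- function(s, e, map) {
  ov <- map[map$donor_start < e & map$donor_start + map$len > s &
              map$type == "M", , drop = FALSE]
  if (!nrow(ov)) return(NULL)
  ds <- pmax(s, ov$donor_start)
  de <- pmin(e, ov$donor_start + ov$len)
  lens <- de - ds
  j <- which.max(lens)   # longest reference-mapped piece wins; rest clipped
  ref_start <- ov$ref_start[j] + (ds[j] - ov$donor_start[j])
  lo <- ds[j] - s
  hi <- de[j] - s
  cig <- cigar_build(c("S", "M", "S"), c(lo, hi - lo, (e - s) - hi))
  list(pos = ref_start + 1L, cigar = cig, m_read_lo = lo, m_read_hi = hi)
}

#' Simulate paired-end reads and companion original-style alignments
#'
#' Fragments are drawn with Normal insert sizes, both ends sequenced with
#' substitution errors, and each end projected onto the original reference
#' through the implant map: reads crossing implanted breakpoints come out
#' soft-clipped, reads inside novel insertions unmapped — the signature
#' classes the extractor consumes. Reads whose aligned span lies inside a
#' simulated tandem-repeat tract get MAPQ 0.
#'
#' @param haps one haplotype sequence (character) or a list of two; pairs
#'   are drawn from the haplotypes with equal probability.
#' @param maps the matching implant map(s) from [implant_svs()].
#' @param cfg a `sim_config`.
#' @param genome named character vector (for contig name and MAPQ-0
#'   tracts).
#' @return data frame of SAM-like records (two rows per pair): qname,
#'   flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual, NM, AS.
#' @export
simulate_reads <- function(haps, maps, cfg, genome) {
  if (is.character(haps)) haps <- list(haps)
  if (is.data.frame(maps)) maps <- list(maps)
  rl <- cfg$read_len
  mean_len <- mean(vapply(haps, nchar, numeric(1)))
  n_pairs <- round(cfg$depth * mean_len / (2 * rl))
  contig <- names(genome)[1]
  tracts <- repeat_tracts(genome[[1]], cfg)

  with_seed(derive_seed(cfg$seed, 4L), {
    hap_of <- sample.int(length(haps), n_pairs, replace = TRUE)
    # inserts truncated at +/- 3 sd so concordant pairs are always flagged
    # proper by the 3 sd orientation/isize rule below
    ins <- pmax(rl + 20L, pmin(round(cfg$insert_mean + 3 * cfg$insert_sd),
                               pmax(round(cfg$insert_mean - 3 * cfg$insert_sd),
                                    round(stats::rnorm(n_pairs, cfg$insert_mean,
                                                       cfg$insert_sd)))))
    frag_s <- vapply(seq_len(n_pairs), function(i) {
      dl <- nchar(haps[[hap_of[i]]])
      ins[i] <<- min(ins[i], dl)
      sample.int(dl - ins[i] + 1L, 1L) - 1L
    }, numeric(1))
    frag_strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    qual <- strrep("I", rl)
    recs <- vector("list", 2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      donor <- haps[[hap_of[i]]]
      map <- maps[[hap_of[i]]]
      s <- frag_s[i]; e <- s + ins[i]
      left_seq <- substr(donor, s + 1L, s + rl)
      right_seq <- substr(donor, e - rl + 1L, e)
      # apply sequencing errors in forward (reference) orientation
      err_l <- which(stats::runif(rl) < cfg$error_rate)
      err_r <- which(stats::runif(rl) < cfg$error_rate)
      left_seq <- mutate_at(left_seq, err_l)
      right_seq <- mutate_at(right_seq, err_r)
      pl <- project_interval(s, s + rl, map)
      pr <- project_interval(e - rl, e, map)
      nm_l <- proj_nm(pl, err_l)
      nm_r <- proj_nm(pr, err_r)
      # mate roles: on a "+" fragment R1 is the left (forward) end
      if (frag_strand[i] == "+") {
        ends <- list(list(p = pl, seq = left_seq, nm = nm_l, strand = "+"),
                     list(p = pr, seq = right_seq, nm = nm_r, strand = "-"))
      } else {
        ends <- list(list(p = pr, seq = right_seq, nm = nm_r, strand = "-"),
                     list(p = pl, seq = left_seq, nm = nm_l, strand = "+"))
      }
      name <- sprintf("r%06d", i)
      proper <- !is.null(pl) && !is.null(pr) && {
        span <- (pr$pos + rl) - pl$pos
        abs(span - cfg$insert_mean) <= 3 * cfg$insert_sd + 1
      }
      for (m in 1:2) {
        en <- ends[[m]]
        other <- ends[[if (m == 1L) 2L else 1L]]
        mapped <- !is.null(en$p)
        mate_mapped <- !is.null(other$p)
        flag <- 0x1 + (if (m == 1L) 0x40 else 0x80) +
          (if (!mapped) 0x4 else 0) + (if (!mate_mapped) 0x8 else 0) +
          (if (mapped && en$strand == "-") 0x10 else 0) +
          (if (mate_mapped && other$strand == "-") 0x20 else 0) +
          (if (proper && mapped && mate_mapped) 0x2 else 0)
        tlen <- 0L
        if (mapped && mate_mapped) {
          lo <- min(pl$pos, pr$pos); hi <- max(pl$pos + rl, pr$pos + rl)
          tlen <- (hi - lo) * (if (en$strand == "+") 1L else -1L)
        }
        mapq <- if (!mapped) 0L
                else if (in_tract(en$p$pos, en$p$pos + rl, tracts)) 0L
                else 60L
        st <- cigar_stats(if (mapped) en$p$cigar else "*")
        as_score <- if (mapped) (st$n_m - en$nm) - 4L * en$nm else NA_integer_
        recs[[2L * (i - 1L) + m]] <- data.frame(
          qname = name, flag = flag,
          rname = if (mapped) contig else "*",
          pos = if (mapped) en$p$pos else 0L,
          mapq = mapq, cigar = if (mapped) en$p$cigar else "*",
          rnext = if (mate_mapped) (if (mapped) "=" else contig) else "*",
          pnext = if (mate_mapped) other$p$pos else 0L,
          tlen = tlen, seq = en$seq, qual = qual,
          NM = if (mapped) en$nm else NA_integer_,
          AS = if (mapped) as_score else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  })
}

mutate_at <- function(seq, pos) {
  if (!length(pos)) return(seq)
  b <- strsplit(seq, "")[[1]]
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

proj_nm <- function(p, err) {
  if (is.null(p)) return(NA_integer_)
  sum(err > p$m_read_lo & err <= p$m_read_hi)
}

# locate the simulated repeat tracts in the finished genome
repeat_tracts <- function(ctg, cfg) {
  if (is.null(cfg$repeats) || !nrow(cfg$repeats)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- list()
  for (i in seq_len(nrow(cfg$repeats))) {
    tr <- strrep(cfg$repeats$unit[i], cfg$repeats$copies[i])
    at <- gregexpr(tr, ctg, fixed = TRUE)[[1]]
    if (at[1] > 0L) {
      out[[length(out) + 1L]] <- data.frame(start = as.integer(at),
                                            end = as.integer(at) + nchar(tr))
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

in_tract <- function(lo, hi, tracts) {
  any(tracts$start <= lo & tracts$end >= hi)
}

#' Write SAM-like records to a SAM file
#'
#' @param recs data frame from [simulate_reads()].
#' @param genome named character vector (for the header).
#' @param path output SAM path.
#' @export
write_sam <- function(recs, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                   recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
                   recs$cigar, recs$rnext, recs$pnext, recs$tlen,
                   recs$seq, recs$qual,
                   ifelse(is.na(recs$NM), "",
                          sprintf("\tNM:i:%d\tAS:i:%d", recs$NM, recs$AS)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Generate a full simulated dataset on disk
#'
#' Writes `ref.fa`, `donor.fa`, `truth.vcf`, `panel.vcf` and `reads.sam`
#' into `dir`; byte-identical across runs with the same configuration.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory.
#' @return list with the file paths plus `truth`, `panel`, `left_out`.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(cfg)
  imp <- implant_svs(genome, cfg)
  pan <- make_known_panel(imp$truth, cfg)
  reads <- simulate_reads(imp$haps, imp$maps, cfg, genome)
  paths <- list(ref = file.path(dir, "ref.fa"),
                donor = file.path(dir, "donor.fa"),
                truth_vcf = file.path(dir, "truth.vcf"),
                panel_vcf = file.path(dir, "panel.vcf"),
                sam = file.path(dir, "reads.sam"))
  write_fasta(genome, paths$ref)
  write_fasta(stats::setNames(unlist(imp$haps),
                              paste0(names(genome)[1], "_hap", 1:2)),
              paths$donor)
  write_svs_vcf(imp$truth, genome, paths$truth_vcf)
  write_svs_vcf(pan$panel, genome, paths$panel_vcf)
  write_sam(reads, genome, paths$sam)
  c(paths, list(truth = imp$truth, panel = pan$panel,
                left_out = pan$left_out, genome = genome,
                donor = imp$donor, map = imp$map))
}
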