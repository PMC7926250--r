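# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (PAM-anchored enumeration, GRanges
# arithmetic, profiled fitting) so agreement is evidence, not tautology.

# Reverse complement (local copy, string-based).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  gg_x <- endsWith(x, "GG"); gg_rc <- endsWith(rc, "GG")
  out <- pmin(x, rc)
  out[gg_x & !gg_rc] <- x[gg_x & !gg_rc]
  out[!gg_x & gg_rc] <- rc[!gg_x & gg_rc]
  out
}

# Position-by-position substring scan: every interval whose k-mer ends in GG
# in either orientation contributes one count to its canonical id.
oracle_kmer_counts <- function(genome, k = c(22L, 23L)) {
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    for (kk in k) {
      if (n < kk) next
      starts <- seq_len(n - kk + 1L)
      words <- substring(s, starts, starts + kk - 1L)
      hit <- (endsWith(words, "GG") | startsWith(words, "CC")) &
        !grepl("N", words, fixed = TRUE)
      if (!any(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts[hit] - 1L,
        sequence = oracle_canonical(words[hit]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), chrom = character(),
                      count = integer()))
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(start ~ sequence + chrom, data = df, FUN = length)
  names(agg)[3] <- "count"
  agg[order(agg$sequence, agg$chrom), ]
}

# Occurrence positions (0-based starts) of canonical id `sq` on one
# chromosome, by full scan.
oracle_occurrences <- function(seqchar, sq) {
  kk <- nchar(sq)
  n <- nchar(seqchar)
  if (n < kk) return(integer())
  starts <- seq_len(n - kk + 1L)
  words <- substring(seqchar, starts, starts + kk - 1L)
  starts[oracle_canonical(words) == sq &
           (endsWith(words, "GG") | startsWith(words, "CC")) &
           !grepl("N", words, fixed = TRUE)] - 1L
}

# Exhaustive focal-region search: every (i, j) occurrence window, span and
# inequality checked directly; maximal qualifying windows retained.
oracle_focal_regions <- function(occ, total_off, k, max_span = 1e6,
                                 min_spec = 20) {
  fc <- length(occ)
  cand <- list()
  for (i in seq_len(fc)) {
    for (j in i:fc) {
      if ((occ[j] + k - occ[i]) >= max_span) break
      nR <- fc - (j - i + 1L)
      spec <- (fc - nR) / (1 + total_off + nR)
      if (spec >= min_spec) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j, nR = nR)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      n_outside = integer()))
  }
  m <- do.call(rbind, cand)
  # maximality: no other qualifying window strictly contains it AND
  # it cannot be extended (any extension breaks span); equivalently keep
  # windows not nested in another candidate window
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, "i"] <= m[r, "i"] & m[, "j"] >= m[r, "j"] &
           (m[, "i"] < m[r, "i"] | m[, "j"] > m[r, "j"]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  out <- data.frame(start = occ[m[, "i"]], end = occ[m[, "j"]] + k,
                    n_outside = m[, "nR"])
  out[order(out$start), , drop = FALSE]
}

# Random genome helper (character vector of chromosomes).
random_genome <- function(chrom_lens, seed) {
  set.seed(seed)
  vapply(chrom_lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base boolean bitmap oracle for interval set operations on one
# chromosome of length L. Intervals are 0-based half-open tibbles.
bitmap_of <- function(intervals, L) {
  v <- rep(FALSE, L)
  for (r in seq_len(nrow(intervals))) {
    s <- max(intervals$start[r], 0L) + 1L
    e <- min(intervals$end[r], L)
    if (e >= s) v[s:e] <- TRUE
  }
  v
}

intervals_of <- function(bitmap) {
  r <- rle(bitmap)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Naive per-base pileup for coverage tracks (single chromosome).
oracle_pileup <- function(fragments, L, scale) {
  v <- numeric(L)
  for (r in seq_len(nrow(fragments))) {
    v[(fragments$start[r] + 1):fragments$end[r]] <-
      v[(fragments$start[r] + 1):fragments$end[r]] + 1
  }
  v * scale
}

# Naive metagene resampler for one feature: returns the bin-mean vector the
# same way a hand calculation would (positions gathered per bin, then mean).
oracle_feature_profile <- function(sig, start, end, strand, flank, bin,
                                   body_bins) {
  L <- end - start
  val <- function(p0) {
    ifelse(p0 >= 0 & p0 < length(sig), sig[p0 + 1], NA_real_)
  }
  up <- sapply(seq_len(flank / bin), function(j) {
    s <- start - (flank / bin - j + 1) * bin
    mean(val(s:(s + bin - 1)))
  })
  body <- sapply(seq_len(body_bins), function(j) {
    lo <- floor((j - 1) * L / body_bins); hi <- floor(j * L / body_bins) - 1
    mean(val((start + lo):(start + hi)))
  })
  down <- sapply(seq_len(flank / bin), function(j) {
    s <- end + (j - 1) * bin
    mean(val(s:(s + bin - 1)))
  })
  prof <- c(up, body, down)
  if (strand == "-") rev(prof) else prof
}
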