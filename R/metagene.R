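#' Metagene profile with scale-regions semantics
#'
#' Averages a per-base signal over a set of stranded features: each feature
#' body is rescaled to `body_bins` bins, while the upstream and downstream
#' flanks are taken in fixed-width bins (500 bp by default, 30 kb flanks).
#' Minus-strand features are orientation-flipped so that "upstream" is
#' always the 5' side. Flank bins that fall off the chromosome contribute
#' nothing (NA, excluded from the mean).
#'
#' Body bin `j` of a feature of length `L` covers bases
#' `(floor((j-1) * L / B), floor(j * L / B)]` (0-based within the body), so
#' the bins partition the body exactly.
#'
#' @param signal Named list of per-base numeric vectors, one per chromosome
#'   (position i of the vector is base i-1 in 0-based coordinates).
#' @param features Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `strand` (`"+"`/`"-"`).
#' @param flank Flank width in bp (default 30000).
#' @param bin Flank bin width in bp (default 500).
#' @param body_bins Number of bins the body is rescaled to (default 60).
#' @return Tibble with `segment` (`upstream`/`body`/`downstream`), `bin`
#'   (1-based within segment), `position` (bp relative to TSS for flanks,
#'   fraction for body), `mean_signal`, `n` (features contributing).
#' @export
metagene_profile <- function(signal, features, flank = 30000, bin = 500,
                             body_bins = 60) {
  check_cols(features, c("chrom", "start", "end", "strand"), "features")
  if (flank %% bin != 0) abort_field("metagene_profile: flank must be a multiple of bin")
  n_flank <- flank %/% bin
  n_tot <- 2 * n_flank + body_bins

  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    L <- f$end - f$start
    if (L < 1) {
      warning(sprintf("feature %d shorter than one base; skipped", i))
      next
    }
    sig <- signal[[f$chrom]]
    if (is.null(sig)) abort_field("metagene_profile: no signal for chromosome '%s'", f$chrom)

    base_at <- function(pos0) {
      # pos0: 0-based positions; values outside the chromosome are NA
      out <- rep(NA_real_, length(pos0))
      ok <- pos0 >= 0 & pos0 < length(sig)
      out[ok] <- sig[pos0[ok] + 1]
      out
    }

    # Body bins (exact partition).
    bnd <- floor(seq_len(body_bins) * L / body_bins)
    lo <- c(0, bnd[-body_bins])
    body <- vapply(seq_len(body_bins), function(j) {
      mean(base_at(seq.int(f$start + lo[j], f$start + bnd[j] - 1)))
    }, numeric(1))

    # Flanks in fixed bins.
    up <- vapply(seq_len(n_flank), function(j) {
      s <- f$start - (n_flank - j + 1) * bin
      mean(base_at(seq.int(s, s + bin - 1)))
    }, numeric(1))
    down <- vapply(seq_len(n_flank), function(j) {
      s <- f$end + (j - 1) * bin
      mean(base_at(seq.int(s, s + bin - 1)))
    }, numeric(1))

    prof <- c(up, body, down)
    if (f$strand == "-") prof <- rev(prof)
    rows[[i]] <- prof
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) abort_field("metagene_profile: no usable features")
  mat <- do.call(rbind, rows)

  pos <- c(seq(-flank, -bin, by = bin),
           (seq_len(body_bins) - 0.5) / body_bins,
           seq(0, flank - bin, by = bin))
  tibble::tibble(
    segment = rep(c("upstream", "body", "downstream"),
                  times = c(n_flank, body_bins, n_flank)),
    bin = c(seq_len(n_flank), seq_len(body_bins), seq_len(n_flank)),
    position = pos,
    mean_signal = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat))
  )
}

#' Simple LOESS smoother of ED50 against genomic distance
#'
#' Convenience wrapper used to inspect the spatial gradient of accumulation
#' timing along the chromosome (ED50 as a function of distance to the Xist
#' locus).
#'
#' @param distance,ed50 Numeric vectors.
#' @param span LOESS span.
#' @return Tibble with `distance` and `smoothed` ED50, sorted by distance.
#' @export
loess_ed50 <- function(distance, ed50, span = 0.75) {
  fit <- stats::loess(ed50 ~ distance, span = span,
                      family = "symmetric")
  ord <- order(distance)
  tibble::tibble(distance = distance[ord], smoothed = fit$fitted[ord])
}
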