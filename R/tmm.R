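#' Trimmed mean of M-values normalization factors
#'
#' Direct transcription of the TMM method (Robinson & Oshlack 2010) applied
#' to B6 counts over autosomal consensus peaks. For each sample against the
#' reference sample, per-peak `M` (log2 count ratio after library-size
#' scaling) and `A` (mean log2 abundance) values are computed over peaks
#' with non-zero counts in both samples; `M` is trimmed two-sided by 30%
#' and `A` by 5%, and the factor is `2 ^ (precision-weighted mean of the
#' retained M)`, with weights the inverse binomial variances
#' `(N - n) / (N n)` summed over the two samples. Factors are reported
#' relative to the reference sample (reference factor is exactly 1); no
#' geometric-mean rescaling across samples is applied.
#'
#' @param peak_counts Matrix (peaks x samples) or tibble in long form with
#'   columns `peak`, `sample_id`, `count`.
#' @param reference_sample Column/sample name of the reference; default the
#'   first sample.
#' @param logratio_trim,sum_trim Trim fractions for M and A (defaults 0.3
#'   and 0.05, the published defaults).
#' @return Tibble with `sample_id`, `tmm_factor`, `library_size`.
#' @export
tmm_factors <- function(peak_counts, reference_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  if (inherits(peak_counts, "data.frame")) {
    check_cols(peak_counts, c("peak", "sample_id", "count"), "peak_counts")
    mat <- peak_counts |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                         values_fill = 0L) |>
      tibble::column_to_rownames("peak") |>
      as.matrix()
  } else {
    mat <- as.matrix(peak_counts)
  }
  if (ncol(mat) < 2) abort_field("tmm_factors: need >= 2 samples")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("sample_", seq_len(ncol(mat)))
  lib <- colSums(mat)
  if (any(lib <= 0)) {
    abort_field("tmm_factors: sample(s) %s have zero total counts",
                paste(colnames(mat)[lib <= 0], collapse = ", "))
  }
  reference_sample <- reference_sample %||% colnames(mat)[1]
  if (!reference_sample %in% colnames(mat)) {
    abort_field("tmm_factors: reference sample '%s' not found", reference_sample)
  }
  ref <- mat[, reference_sample]
  factors <- vapply(colnames(mat), function(s) {
    if (s == reference_sample) return(1)
    tmm_pair(mat[, s], ref, sample_name = s,
             logratio_trim = logratio_trim, sum_trim = sum_trim)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(mat), tmm_factor = unname(factors),
                 library_size = unname(lib))
}

# One observed-vs-reference TMM factor, the published formulas verbatim.
tmm_pair <- function(obs, ref, sample_name = "?", logratio_trim = 0.3,
                     sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  nO <- sum(obs); nR <- sum(ref)
  both <- obs > 0 & ref > 0
  if (!any(both)) {
    abort_field("tmm_factors: sample '%s' shares no non-zero peaks with the reference",
                sample_name)
  }
  obs <- obs[both]; ref <- ref[both]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Build normalized accumulation tracks
#'
#' Converts windowed B6 counts into per-window accumulation tracks: each
#' sample's counts are scaled by `1e7 / library_size / tmm_factor`,
#' replicates sharing (mark, timepoint) are averaged, the `t = 0` value is
#' subtracted from every timepoint (so the track is exactly 0 at t = 0),
#' and a variant rescaled by the chromosome-wide mean accumulation at the
#' final timepoint is added (the "fraction of the 24-h level" view).
#'
#' @param counts An `allelic_counts` tibble (see [count_windows()]).
#' @param factors Tibble `sample_id`, `tmm_factor`, `library_size` from
#'   [tmm_factors()]; `library_size` may be overridden to the full
#'   library total.
#' @param samples Sample sheet: `sample_id`, `mark`, `timepoint`,
#'   `replicate`.
#' @param allele Which allele's counts to track (default `"B6"`).
#' @param rescale_chrom Chromosome over which the final-timepoint mean for
#'   the rescaled variant is taken (default: all windows present).
#' @param collapse_replicates If TRUE (default) replicates sharing
#'   (mark, timepoint) are averaged after normalization — the display
#'   track. With FALSE each replicate keeps its own row, with the
#'   replicate-mean t0 subtracted as the common baseline — the form used
#'   for curve fitting, where replicate observations enter jointly.
#' @return Tibble of class `accumulation_tracks`: `window`, `chrom`,
#'   `start`, `end`, `mark` (+ `replicate` when not collapsed),
#'   `timepoint`, `signal`, `signal_t0sub`, `signal_rescaled`.
#' @export
normalize_tracks <- function(counts, factors, samples, allele = "B6",
                             rescale_chrom = NULL,
                             collapse_replicates = TRUE) {
  check_cols(samples, c("sample_id", "mark", "timepoint", "replicate"),
             "samples")
  check_cols(factors, c("sample_id", "tmm_factor", "library_size"), "factors")
  missing <- setdiff(unique(counts$sample_id), factors$sample_id)
  if (length(missing) > 0) {
    abort_field("normalize_tracks: no normalization factor for sample(s) %s",
                paste(missing, collapse = ", "))
  }
  has_t0 <- samples |>
    dplyr::group_by(.data$mark) |>
    dplyr::summarise(ok = any(.data$timepoint == 0), .groups = "drop")
  if (any(!has_t0$ok)) {
    abort_field("normalize_tracks: mark(s) %s have no t = 0 sample",
                paste(has_t0$mark[!has_t0$ok], collapse = ", "))
  }

  scaled <- counts |>
    dplyr::filter(.data$allele == !!allele) |>
    dplyr::inner_join(factors, by = "sample_id") |>
    dplyr::inner_join(samples, by = "sample_id") |>
    dplyr::mutate(norm = .data$count * 1e7 /
                    (.data$library_size * .data$tmm_factor))
  if (collapse_replicates) {
    norm <- scaled |>
      dplyr::group_by(.data$window, .data$chrom, .data$start, .data$end,
                      .data$mark, .data$timepoint) |>
      dplyr::summarise(signal = mean(.data$norm), .groups = "drop")
    grp <- c("window", "mark")
  } else {
    norm <- scaled |>
      dplyr::select("window", "chrom", "start", "end", "mark",
                    "replicate", "timepoint", signal = "norm")
    # replicate-level rows share one baseline: the replicate-mean t0.
    # Subtracting each replicate's own noisy t0 would give every replicate
    # a different random offset and inflate the joint-fit noise.
    grp <- c("window", "mark")
  }

  t_last <- max(norm$timepoint)
  out <- norm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(signal_t0sub = .data$signal -
                    mean(.data$signal[.data$timepoint == 0])) |>
    dplyr::ungroup()
  ref_windows <- if (is.null(rescale_chrom)) rep(TRUE, nrow(out)) else
    out$chrom == rescale_chrom
  denom <- mean(out$signal_t0sub[out$timepoint == t_last & ref_windows])
  out$signal_rescaled <- if (is.finite(denom) && denom != 0)
    out$signal_t0sub / denom else NA_real_
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$mark,
                        .data$timepoint)
  class(out) <- c("accumulation_tracks", class(out))
  out
}
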