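#' Segment the Xist domain in one frame
#'
#' Otsu threshold over the frame (assumed a max projection of the nuclear
#' region), keep the largest connected component if it reaches `min_area`
#' pixels and its mean intensity exceeds `min_contrast` times the
#' outside-mask mean. An empty mask (no domain yet) is a valid result;
#' all-zero or constant frames yield an empty mask.
#'
#' @param frame Numeric matrix (Y x X intensities).
#' @param min_area Minimum component area in pixels (default 10).
#' @param min_contrast Minimum in-mask / out-of-mask mean-intensity ratio
#'   for the component to count as a domain (default 1.2); guards against
#'   thresholding pure noise before the domain appears.
#' @return Logical matrix of the same dimension.
#' @export
segment_domain <- function(frame, min_area = 10, min_contrast = 1.2) {
  empty <- matrix(FALSE, nrow(frame), ncol(frame))
  rng <- range(frame)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(empty)
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0) return(empty)
  biggest <- which.max(sizes)
  comp <- matrix(as.integer(lab) == biggest, nrow(frame), ncol(frame))
  if (sizes[biggest] < min_area) return(empty)
  bg <- mean(frame[!comp])
  if (!is.finite(bg) || bg <= 0 || mean(frame[comp]) / bg < min_contrast) {
    return(empty)
  }
  comp
}

#' Per-cell mintbody enrichment trace
#'
#' Segments the Xist channel frame by frame, measures the mean mintbody
#' intensity inside the domain, and normalizes by a whole-nucleus
#' background estimate sampled every `bg_every` frames and linearly
#' interpolated to all frames. The onset frame is the first frame with a
#' detected domain.
#'
#' @param xist,mintbody Numeric arrays `(frames, Y, X)`; same dimensions.
#' @param frame_interval Minutes between frames (default 15).
#' @param bg_every Background sampling stride in frames (default 10).
#' @param ... Passed to [segment_domain()].
#' @return Tibble of class `cell_trace`: `frame`, `time_min`,
#'   `domain_area`, `domain_mean`, `background`, `ratio` (NA where no
#'   domain), with attributes `onset_frame` (NA when no domain ever
#'   detected) and `frame_interval`.
#' @export
enrichment_trace <- function(xist, mintbody, frame_interval = 15,
                             bg_every = 10, ...) {
  if (!identical(dim(xist), dim(mintbody))) {
    abort_field("enrichment_trace: channel dimensions differ")
  }
  n <- dim(xist)[1]
  area <- integer(n); dmean <- rep(NA_real_, n)
  nuc_mean <- numeric(n)
  for (f in seq_len(n)) {
    mask <- segment_domain(xist[f, , ], ...)
    area[f] <- sum(mask)
    mb <- mintbody[f, , ]
    nuc_mean[f] <- mean(mb)
    if (area[f] > 0) dmean[f] <- mean(mb[mask])
  }
  samp <- seq.int(1L, n, by = bg_every)
  bg <- stats::approx(samp, nuc_mean[samp], xout = seq_len(n),
                      rule = 2)$y
  onset <- which(area > 0)[1]
  out <- tibble::tibble(
    frame = seq_len(n),
    time_min = (seq_len(n) - 1) * frame_interval,
    domain_area = area,
    domain_mean = dmean,
    background = bg,
    ratio = dmean / bg
  )
  attr(out, "onset_frame") <- if (is.na(onset)) NA_integer_ else onset
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("cell_trace", class(out))
  out
}

#' Aggregate single-cell traces aligned to Xist onset
#'
#' Re-indexes each trace to time since its own Xist onset, then reports the
#' per-timepoint mean enrichment ratio, 25th/75th percentiles and cell
#' count. Traces without a detected onset are excluded.
#'
#' @param traces List of `cell_trace` objects (see [enrichment_trace()]).
#' @param min_cells Minimum number of cells with a defined onset
#'   (default 30).
#' @return Tibble of class `aggregate_trace`: `time_since_onset` (min),
#'   `mean_ratio`, `q25`, `q75`, `n`; attribute `cells` holds the
#'   cell-level long table used for the per-timepoint tests.
#' @export
aggregate_traces <- function(traces, min_cells = 30) {
  keep <- !vapply(traces, function(tr) is.na(attr(tr, "onset_frame")),
                  logical(1))
  traces <- traces[keep]
  if (length(traces) < min_cells) {
    abort_field("aggregate_traces: %d cells with detected onset (need >= %d)",
                length(traces), min_cells)
  }
  cells <- purrr::imap_dfr(traces, function(tr, i) {
    onset <- attr(tr, "onset_frame")
    iv <- attr(tr, "frame_interval")
    tr |>
      dplyr::mutate(cell = i,
                    time_since_onset = (.data$frame - onset) * iv) |>
      dplyr::filter(.data$time_since_onset >= 0, !is.na(.data$ratio)) |>
      dplyr::select("cell", "time_since_onset", "ratio")
  })
  agg <- cells |>
    dplyr::group_by(.data$time_since_onset) |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio),
      q25 = unname(stats::quantile(.data$ratio, 0.25)),
      q75 = unname(stats::quantile(.data$ratio, 0.75)),
      n = dplyr::n(),
      .groups = "drop"
    )
  attr(agg, "cells") <- cells
  class(agg) <- c("aggregate_trace", class(agg))
  agg
}

#' Detect the histone-mark enrichment onset delay
#'
#' Per timepoint since Xist onset, a one-sample t-test of the cell-level
#' enrichment ratios against 1.0 (one-sided, enrichment), with
#' Benjamini-Hochberg adjustment across timepoints. The reported onset is
#' the first timepoint whose adjusted p-value is below `alpha` and whose
#' successor also passes (run-of-2 rule against isolated flukes).
#'
#' @param aggregate An `aggregate_trace` (cell-level data in its `cells`
#'   attribute) or the cell-level tibble itself (`cell`,
#'   `time_since_onset`, `ratio`).
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum cells per timepoint for a test (default 3).
#' @return List with `onset_min` (minutes since Xist onset; `NA` if none)
#'   and `tests` (per-timepoint tibble with `p_value`, `p_adj`).
#' @export
detect_onset_delay <- function(aggregate, alpha = 0.05, min_n = 3) {
  cells <- attr(aggregate, "cells") %||% aggregate
  check_cols(cells, c("time_since_onset", "ratio"), "aggregate")
  tests <- cells |>
    dplyr::group_by(.data$time_since_onset) |>
    dplyr::summarise(
      n = sum(is.finite(.data$ratio)),
      p_value = if (sum(is.finite(.data$ratio)) >= min_n &&
                    stats::sd(.data$ratio, na.rm = TRUE) > 0)
        stats::t.test(.data$ratio, mu = 1,
                      alternative = "greater")$p.value else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_since_onset)
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  sig <- !is.na(tests$p_adj) & tests$p_adj < alpha
  onset <- NA_real_
  run <- which(sig & dplyr::lead(sig, default = FALSE))
  if (length(run) > 0) onset <- tests$time_since_onset[run[1]]
  list(onset_min = onset, tests = tests)
}

#' Per-timepoint divergence between two marks' enrichment traces
#'
#' Unpaired (Welch) t-test between the two marks' cell-level ratios at each
#' shared timepoint, BH-adjusted; reports the first timepoint of sustained
#' (run-of-2) divergence. Timepoints with fewer than 3 cells in either
#' group are tested but flagged `low_power`.
#'
#' @param agg_a,agg_b `aggregate_trace` objects on the same onset-aligned
#'   time grid.
#' @param alpha Significance level (default 0.05).
#' @return List with `divergence_min` (`NA` if none) and `tests` tibble
#'   (`time_since_onset`, `n_a`, `n_b`, `p_value`, `p_adj`, `low_power`).
#' @export
compare_mark_traces <- function(agg_a, agg_b, alpha = 0.05) {
  ca <- attr(agg_a, "cells"); cb <- attr(agg_b, "cells")
  if (is.null(ca) || is.null(cb)) {
    abort_field("compare_mark_traces: inputs must be aggregate_trace objects")
  }
  grid <- intersect(unique(ca$time_since_onset), unique(cb$time_since_onset))
  if (!setequal(unique(ca$time_since_onset), unique(cb$time_since_onset))) {
    abort_field("compare_mark_traces: the two aggregates are not on the same time grid")
  }
  grid <- sort(grid)
  tests <- purrr::map_dfr(grid, function(t0) {
    xa <- ca$ratio[ca$time_since_onset == t0]
    xb <- cb$ratio[cb$time_since_onset == t0]
    p <- if (length(xa) >= 2 && length(xb) >= 2 &&
             (stats::sd(xa) > 0 || stats::sd(xb) > 0))
      stats::t.test(xa, xb)$p.value else NA_real_
    tibble::tibble(time_since_onset = t0, n_a = length(xa),
                   n_b = length(xb), p_value = p,
                   low_power = length(xa) < 3 || length(xb) < 3)
  })
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  sig <- !is.na(tests$p_adj) & tests$p_adj < alpha
  run <- which(sig & dplyr::lead(sig, default = FALSE))
  list(divergence_min = if (length(run) > 0) tests$time_since_onset[run[1]]
       else NA_real_,
       tests = tests)
}

#' Write / read a movie as multi-page TIFF
#'
#' Thin adapters over the tiff package; intensities are scaled to `[0, 1]`
#' by `max_intensity` on write and rescaled on read.
#'
#' @param movie Numeric array `(frames, Y, X)`.
#' @param path TIFF path.
#' @param max_intensity Intensity corresponding to 1.0 in the file.
#' @return `read_movie_tiff` returns the array; `write_movie_tiff` the path
#'   invisibly.
#' @export
write_movie_tiff <- function(movie, path, max_intensity = 4096) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_field("write_movie_tiff requires the tiff package")
  }
  pages <- lapply(seq_len(dim(movie)[1]), function(f) {
    pmin(pmax(movie[f, , ] / max_intensity, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, max_intensity = 4096) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_field("read_movie_tiff requires the tiff package")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * max_intensity
  arr
}
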