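#' Plot accumulation tracks
#'
#' Mean normalized B6 accumulation per timepoint with the interquartile
#' range across windows, per mark.
#'
#' @param tracks An `accumulation_tracks` tibble from [normalize_tracks()].
#' @param variant Which column to show (`"signal_t0sub"` by default).
#' @return A ggplot.
#' @export
plot_accumulation <- function(tracks, variant = "signal_t0sub") {
  df <- tracks |>
    dplyr::group_by(.data$mark, .data$timepoint) |>
    dplyr::summarise(mid = stats::median(.data[[variant]]),
                     lo = stats::quantile(.data[[variant]], 0.25),
                     hi = stats::quantile(.data[[variant]], 0.75),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$mid,
                                   colour = .data$mark,
                                   fill = .data$mark)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DOX induction (h)", y = "B6 accumulation vs t0",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ll4_fit <- function(object, timepoints = NULL, ...) {
  tmax <- if (is.null(timepoints)) 24 else max(timepoints)
  grid <- tibble::tibble(t = seq(0, tmax, length.out = 200))
  grid$y <- ll4(grid$t, object$b, object$c, object$d, object$e)
  ggplot2::ggplot(grid, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$e, linetype = 2) +
    ggplot2::labs(x = "DOX induction (h)", y = "fitted accumulation",
                  subtitle = sprintf("ED50 = %.2f h", object$e)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aggregate_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_since_onset,
                                       .data$mean_ratio)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "time since Xist onset (min)",
                  y = "mintbody enrichment ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  profile$xi <- seq_len(nrow(profile))
  ggplot2::ggplot(profile, ggplot2::aes(.data$xi, .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = range(profile$xi[profile$segment == "body"]) + c(-0.5, 0.5),
      linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "bin (upstream | body | downstream)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}
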