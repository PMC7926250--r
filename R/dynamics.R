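#' Four-parameter log-logistic curve
#'
#' Evaluates `f(t) = c + (d - c) / (1 + exp(b * (log(t) - log(e))))`, the
#' LL.4 dose-response form with dose = hours of Xist induction. `b` is the
#' slope (negative for an increasing accumulation curve), `c` and `d` the
#' lower and upper asymptotes, and `e` the inflection dose: `f(e) = (c+d)/2`,
#' so `e` is the ED50 in hours. At `t = 0` the limit is used: `c` for
#' `b < 0`, `d` for `b > 0`, `(c+d)/2` for `b = 0`.
#'
#' @param t Hours (non-negative numeric vector).
#' @param b,c,d,e Curve parameters; `e > 0`.
#' @return Numeric vector of curve values.
#' @export
ll4 <- function(t, b, c, d, e) {
  if (e <= 0) abort_field("ll4: inflection dose e must be > 0")
  out <- c + (d - c) / (1 + exp(b * (log(pmax(t, .Machine$double.xmin)) - log(e))))
  if (any(t == 0)) {
    lim <- if (b < 0) c else if (b > 0) d else (c + d) / 2
    out[t == 0] <- lim
  }
  out
}

# Logistic transition g in [0,1]: f = c + (d-c)*g.
ll4_g <- function(t, b, e) {
  g <- 1 / (1 + exp(b * (log(pmax(t, .Machine$double.xmin)) - log(e))))
  if (any(t == 0)) g[t == 0] <- if (b < 0) 0 else if (b > 0) 1 else 0.5
  g
}

# Profiled SSE: for fixed (b, log e) the model is linear in (c, d).
ll4_profile_sse <- function(par, t, y) {
  g <- ll4_g(t, par[1], exp(par[2]))
  X <- cbind(1 - g, g)
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit the four-parameter log-logistic accumulation model
#'
#' Nonlinear least squares of the LL.4 model to one window's accumulation
#' values. The fit is profiled: for fixed slope `b` and inflection `e` the
#' model is linear in the asymptotes `(c, d)`, so a coarse grid plus
#' L-BFGS-B over `(b, log e)` with an exact inner linear solve locates the
#' optimum basin, followed by a full Levenberg-Marquardt polish
#' ([minpack.lm::nls.lm()]). Repeated timepoints (replicate observations)
#' are fitted jointly. Non-convergence is a valid outcome and is flagged,
#' not raised.
#'
#' @param timepoints Hours, same length as `values`; `t = 0` allowed.
#' @param values Normalized accumulation values.
#' @param e_max Upper bound for `e`; default 10 x max timepoint.
#' @param b_max Bound on `|b|`.
#' @return An object of class `ll4_fit`: list with `b`, `c`, `d`, `e`,
#'   `residual_sum` (sum of squared residuals), `converged`, `ed50` (= `e`),
#'   `ic35`, `n`.
#' @export
fit_ll4 <- function(timepoints, values, e_max = 10 * max(timepoints), b_max = 50) {
  if (length(timepoints) != length(values)) {
    abort_field("fit_ll4: timepoints and values differ in length")
  }
  keep <- is.finite(timepoints) & is.finite(values)
  t <- as.numeric(timepoints[keep]); y <- as.numeric(values[keep])
  if (length(t) < 4) abort_field("fit_ll4: need at least 4 finite (t, y) pairs")
  if (any(t < 0)) abort_field("fit_ll4: timepoints must be >= 0")

  if (stats::sd(y) == 0) {
    # Flat input: c = d, e unidentifiable.
    return(new_ll4_fit(b = 0, c = y[1], d = y[1], e = NA_real_,
                       residual_sum = 0, converged = FALSE, n = length(y)))
  }

  grid_b <- c(-8, -4, -2, -1, -0.5, 0.5, 1, 2, 4, 8)
  tpos <- sort(unique(t[t > 0]))
  grid_e <- unique(pmin(c(tpos, exp((log(min(tpos)) + log(max(tpos))) / 2),
                          2 * max(tpos)), e_max))
  best <- NULL
  for (b0 in grid_b) {
    for (e0 in grid_e) {
      s <- ll4_profile_sse(c(b0, log(e0)), t, y)
      if (is.null(best) || s < best$s) best <- list(b = b0, le = log(e0), s = s)
    }
  }
  opt <- stats::optim(c(best$b, best$le), ll4_profile_sse, t = t, y = y,
                      method = "L-BFGS-B",
                      lower = c(-b_max, log(1e-3)), upper = c(b_max, log(e_max)))
  g <- ll4_g(t, opt$par[1], exp(opt$par[2]))
  cd <- stats::.lm.fit(cbind(1 - g, g), y)$coefficients
  p0 <- c(opt$par[1], cd[1], cd[2], exp(opt$par[2]))

  fit <- try(minpack.lm::nls.lm(
    par = p0,
    lower = c(-b_max, -Inf, -Inf, 1e-3),
    upper = c(b_max, Inf, Inf, e_max),
    fn = function(p, t, y) y - ll4(t, p[1], p[2], p[3], p[4]),
    t = t, y = y,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)

  if (inherits(fit, "try-error") || !fit$info %in% 1:4 ||
      !all(is.finite(fit$par))) {
    # Fall back on the profiled optimum; flag as non-converged only if even
    # that is degenerate.
    conv <- all(is.finite(p0)) && opt$convergence == 0
    return(ll4_identifiability_guard(new_ll4_fit(
      b = p0[1], c = p0[2], d = p0[3], e = p0[4],
      residual_sum = ll4_profile_sse(opt$par, t, y),
      converged = conv, n = length(y)), y))
  }
  p <- fit$par
  out <- new_ll4_fit(b = p[1], c = p[2], d = p[3], e = p[4],
                     residual_sum = fit$deviance, converged = TRUE,
                     n = length(y))
  ll4_identifiability_guard(out, y)
}

# A window with no real response within the time course must not yield a
# spurious inflection dose. Two guards flag such fits non-converged (so
# capping treats the window as late-accumulating): (1) the fitted response
# range must clear twice the residual RMSE, and (2) the LL.4 model must
# beat the constant-mean model in an F-test (3 extra parameters) at 0.05.
ll4_identifiability_guard <- function(fit, y, k = 2, alpha = 0.05) {
  if (fit$residual_sum == 0) return(fit)
  rmse <- sqrt(fit$residual_sum / max(fit$n - 4, 1))
  if (is.finite(rmse) && rmse > 0 && abs(fit$d - fit$c) < k * rmse) {
    fit$converged <- FALSE
    return(fit)
  }
  if (fit$n > 4) {
    sse0 <- sum((y - mean(y))^2)
    fstat <- ((sse0 - fit$residual_sum) / 3) /
      (fit$residual_sum / (fit$n - 4))
    p <- stats::pf(fstat, 3, fit$n - 4, lower.tail = FALSE)
    if (!is.na(p) && p > alpha) fit$converged <- FALSE
  }
  fit
}

new_ll4_fit <- function(b, c, d, e, residual_sum, converged, n) {
  # (b, c, d, e) and (-b, d, c, e) define the same curve; canonicalize so
  # c is always the lower asymptote (b < 0 then means increasing)
  if (is.finite(c) && is.finite(d) && c > d) {
    tmp <- c; c <- d; d <- tmp; b <- -b
  }
  structure(
    list(b = unname(b), c = unname(c), d = unname(d), e = unname(e),
         residual_sum = unname(residual_sum), converged = converged,
         ed50 = unname(e), ic35 = ll4_ic35(b, e), n = n),
    class = "ll4_fit"
  )
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat("LL.4 fit: b =", signif(x$b, 4), " c =", signif(x$c, 4),
      " d =", signif(x$d, 4), " e (ED50) =", signif(x$e, 4), "h\n")
  cat("  residual sum =", signif(x$residual_sum, 4),
      " converged =", x$converged, "\n")
  invisible(x)
}

# Dose at which the curve has traversed 35% of its response range from the
# starting level: t = e * ((1-p)/p)^(1/b) for an increasing curve (b < 0),
# t = e * (p/(1-p))^(1/b) for a decreasing one; below ED50 in both cases.
ll4_ic35 <- function(b, e, p = 0.35) {
  if (!is.finite(b) || !is.finite(e) || b == 0) return(NA_real_)
  if (b < 0) e * ((1 - p) / p)^(1 / b) else e * (p / (1 - p))^(1 / b)
}

#' Fit accumulation curves for a table of windows
#'
#' Maps [fit_ll4()] over windows of a long accumulation table and returns a
#' tidy fit table (one row per window per mark).
#'
#' @param tracks Tibble with columns `window`, `timepoint`, `value` and
#'   optionally `mark` (and `replicate`; replicates are fitted jointly).
#' @inheritParams fit_ll4
#' @return Tibble of class `ll4_fits` with columns `window`, `mark` (if
#'   present), `b`, `c`, `d`, `e`, `residual_sum`, `converged`, `ed50`,
#'   `ic35`, `n`.
#' @export
fit_accumulation <- function(tracks, e_max = NULL, b_max = 50) {
  check_cols(tracks, c("window", "timepoint", "value"), "tracks")
  grp <- intersect(c("window", "mark"), names(tracks))
  e_max <- e_max %||% (10 * max(tracks$timepoint))
  out <- tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_ll4(df$timepoint, df$value, e_max = e_max, b_max = b_max)
      tibble::as_tibble(unclass(f))
    }) |>
    dplyr::ungroup()
  class(out) <- c("ll4_fits", class(out))
  out
}

#' Retain fits with low residuals
#'
#' Computes mean and SD of the residual sums over converged fits and keeps
#' fits strictly below `mean + 1.5 * SD`. When all converged residual sums
#' are identical (SD = 0) the strict test would reject everything, so by
#' documented special case all converged fits are retained. Non-converged
#' fits are never retained.
#'
#' @param fits A `ll4_fits` tibble from [fit_accumulation()].
#' @param k Multiplier on the SD (default 1.5).
#' @return `fits` with a logical `retained` column.
#' @export
filter_fits <- function(fits, k = 1.5) {
  check_cols(fits, c("residual_sum", "converged"), "fits")
  conv <- fits$converged & is.finite(fits$residual_sum)
  if (sum(conv) < 2) abort_field("filter_fits: need >= 2 converged fits")
  rs <- fits$residual_sum[conv]
  s <- stats::sd(rs)
  thr <- mean(rs) + k * s
  fits$retained <- conv & (if (s == 0) TRUE else fits$residual_sum < thr)
  fits
}

#' Cap ED50 values at the late-accumulation bound
#'
#' Windows whose fit did not converge, was rejected by the residual filter,
#' or produced `e` above `cap` hours are treated as late-accumulating and
#' assigned exactly `cap` (24 h by default); all others keep their fitted
#' inflection dose. Idempotent.
#'
#' @param fits A `ll4_fits` tibble, after [filter_fits()] (a missing
#'   `retained` column is treated as all-retained).
#' @param cap Hours; default 24.
#' @return `fits` with an `ed50_capped` column in `(0, cap]`.
#' @export
cap_ed50 <- function(fits, cap = 24) {
  check_cols(fits, c("e", "converged"), "fits")
  retained <- if ("retained" %in% names(fits)) fits$retained else fits$converged
  late <- !fits$converged | !retained | !is.finite(fits$e) | fits$e > cap
  fits$ed50_capped <- ifelse(late, cap, fits$e)
  fits
}

#' Compare accumulation timing of two marks
#'
#' Paired two-sided Wilcoxon signed-rank test on per-window ED50 values of
#' two marks over shared windows. Only windows with ED50 strictly below
#' `cap` for both marks enter the comparison. With all differences zero the
#' p-value is 1 by definition (no signed ranks).
#'
#' @param ed50_a,ed50_b Named or positionally paired ED50 vectors (hours),
#'   same length.
#' @param cap Exclusion bound (default 24 h).
#' @param min_pairs Minimum usable pairs (default 10).
#' @return Object of class `mark_comparison`: list with `n`, `statistic`,
#'   `p_value`, `median_diff` (a - b), and the paired vectors.
#' @export
compare_marks <- function(ed50_a, ed50_b, cap = 24, min_pairs = 10) {
  if (length(ed50_a) != length(ed50_b)) {
    abort_field("compare_marks: ED50 vectors differ in length")
  }
  keep <- is.finite(ed50_a) & is.finite(ed50_b) & ed50_a < cap & ed50_b < cap
  a <- ed50_a[keep]; b <- ed50_b[keep]
  if (length(a) < min_pairs) {
    abort_field("compare_marks: only %d shared windows with ED50 < %s h (need >= %d)",
                length(a), format(cap), min_pairs)
  }
  d <- a - b
  if (all(d == 0)) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               alternative = "two.sided"))
  }
  structure(
    list(n = length(a), statistic = unname(res$statistic),
         p_value = res$p.value, median_diff = stats::median(d),
         ed50_a = a, ed50_b = b),
    class = "mark_comparison"
  )
}

#' @export
print.mark_comparison <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank on", x$n, "windows\n")
  cat("  median ED50 difference (a - b):", signif(x$median_diff, 4), "h\n")
  cat("  V =", x$statistic, ", p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Cluster genes into silencing-kinetics classes by IC35
#'
#' One-dimensional k-means (k = 3, 50 restarts under a fixed seed) on IC35
#' values; clusters are labelled early/intermediate/late by ascending
#' cluster centre so labels are deterministic.
#'
#' @param ic35 Numeric vector of IC35 values (hours), named by gene or
#'   accompanied by `ids`.
#' @param ids Optional gene identifiers.
#' @param seed RNG seed for the k-means restarts.
#' @return Tibble with `gene`, `ic35`, `class` (factor early < intermediate
#'   < late).
#' @export
ic35_classes <- function(ic35, ids = names(ic35), seed = 1L) {
  keep <- is.finite(ic35)
  x <- ic35[keep]
  if (length(unique(x)) < 3) {
    abort_field("ic35_classes: need >= 3 distinct finite IC35 values")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = 3, nstart = 50)
  ord <- order(km$centers)
  lab <- factor(c("early", "intermediate", "late")[match(km$cluster, ord)],
                levels = c("early", "intermediate", "late"))
  ids <- ids %||% as.character(seq_along(ic35))
  tibble::tibble(gene = ids[keep], ic35 = x, class = lab)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-category correlation of 24-h accumulation between two marks
#'
#' Pearson correlation of log accumulation values per feature category
#' (e.g., initially-active gene bodies, silent gene bodies, intergenic
#' windows). Non-positive values cannot be logged and are dropped, with the
#' drop count reported.
#'
#' @param df Tibble with columns `acc_a`, `acc_b` and `category`.
#' @param min_pairs Minimum positive pairs per category (default 10).
#' @return Tibble with one row per category: `category`, `n`, `n_dropped`,
#'   `rho`, `p_value`.
#' @export
category_correlation <- function(df, min_pairs = 10) {
  check_cols(df, c("acc_a", "acc_b", "category"), "df")
  df |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(g, key) {
      pos <- g$acc_a > 0 & g$acc_b > 0 & is.finite(g$acc_a) & is.finite(g$acc_b)
      n_drop <- sum(!pos)
      if (sum(pos) < min_pairs) {
        abort_field("category_correlation: category '%s' has %d positive pairs (need >= %d)",
                    as.character(key[[1]]), sum(pos), min_pairs)
      }
      ct <- stats::cor.test(log(g$acc_a[pos]), log(g$acc_b[pos]),
                            method = "pearson")
      tibble::tibble(n = sum(pos), n_dropped = n_drop,
                     rho = unname(ct$estimate), p_value = ct$p.value)
    }) |>
    dplyr::ungroup()
}
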