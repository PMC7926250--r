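#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LL.4 fit
#'
#' @param x An `ll4_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.ll4_fit <- function(x, ...) {
  tibble::tibble(term = c("b", "c", "d", "e"),
                 estimate = c(x$b, x$c, x$d, x$e))
}

#' @rdname tidy.ll4_fit
#' @export
glance.ll4_fit <- function(x, ...) {
  tibble::tibble(residual_sum = x$residual_sum, converged = x$converged,
                 ed50 = x$ed50, ic35 = x$ic35, n = x$n)
}

#' Tidy a mark comparison
#'
#' @param x A `mark_comparison` from [compare_marks()].
#' @param ... Unused.
#' @export
tidy.mark_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 median_diff = x$median_diff, n = x$n)
}

#' @rdname tidy.mark_comparison
#' @export
glance.mark_comparison <- function(x, ...) tidy.mark_comparison(x)
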