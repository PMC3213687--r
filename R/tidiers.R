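#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a per-set logistic enrichment fit
#'
#' @param x An `afe_logit` object from [fit_set_regression()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`,
#'   `significance`): `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.afe_logit <- function(x, ...) {
  est <- c(x$intercept, x$slope)
  se <- c(x$se_intercept, x$se_slope)
  stat <- est / se
  tibble(
    term = c("intercept", "significance"),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = if (x$separated) rep(NA_real_, 2) else 2 * pnorm(-abs(stat))
  )
}

#' One-row model summary of a per-set logistic enrichment fit
#'
#' @inheritParams tidy.afe_logit
#' @return A one-row tibble: `slope`, `wald_p`, `odds_ratio`, `direction`,
#'   `separated`, `converged`, `n`, `n_members`.
#' @exportS3Method generics::glance
glance.afe_logit <- function(x, ...) {
  tibble(
    slope = x$slope, wald_p = x$wald_p, odds_ratio = x$odds_ratio,
    direction = x$direction, separated = x$separated,
    converged = x$converged, n = x$n, n_members = x$n_members
  )
}
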