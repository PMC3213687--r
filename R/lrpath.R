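#' Per-gene differential-expression p-values (pooled-variance t-test)
#'
#' Two-sample two-sided Student t-test with pooled variance for every gene of
#' a two-class dataset; the inputs of the regression-based enrichment branch.
#'
#' @param dataset An [expression_dataset()].
#' @return A tibble with columns `gene`, `t`, `p_value`. Genes with zero
#'   pooled variance get `p_value = 1` (no evidence either way) with a
#'   warning.
#' @export
gene_pvalues <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  is_a <- dataset$phenotype == dataset$classes[1]
  a <- dataset$exprs[, is_a, drop = FALSE]
  b <- dataset$exprs[, !is_a, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2 || nb < 2) abort("Each phenotype class needs at least two samples.")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2)
  ssb <- rowSums((b - mb)^2)
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " gene(s) with zero pooled variance; p set to 1."))
    tstat[degenerate] <- 0
    p[degenerate] <- 1
  }
  tibble(gene = rownames(dataset$exprs), t = unname(tstat), p_value = unname(p))
}

#' Transform p-values to (frequency-adjusted) significance scores
#'
#' The regression branch models set membership against
#' \eqn{s_i = -\log(p_i)} (natural log; p-values floored at 1e-300 to keep
#' \eqn{s} finite). Appearance-frequency adjustment raises \eqn{s} to the
#' per-gene power `exponent_lrpath`, which is below 1 for promiscuous genes
#' (demoting their significance, since \eqn{s > 1} for any p < 1/e) and above
#' 1 for pathway-specific genes.
#'
#' @param pvals A tibble with columns `gene` and `p_value` (see
#'   [gene_pvalues()]), or one that already carries a significance column
#'   `s`.
#' @param exponents Named numeric vector of per-gene regression exponents;
#'   missing genes (and `NULL`) get the neutral exponent 1.
#' @return The input with columns `s` (raw \eqn{-\log p}) and `s_adj`
#'   (adjusted significance) appended.
#' @export
adjust_significance <- function(pvals, exponents = NULL) {
  out <- as_tibble(pvals)
  if (!"s" %in% names(out)) {
    if (!"p_value" %in% names(out)) abort("Need a `p_value` (or `s`) column.")
    if (any(out$p_value > 1 | out$p_value < 0)) abort("p-values must lie in [0, 1].")
    out$s <- -log(pmax(out$p_value, 1e-300))
  }
  if (any(out$s < 0)) abort("Significance scores must be non-negative.")
  w <- exponent_lookup(exponents, out$gene)
  out$s_adj <- out$s^w
  out
}

#' Logistic-regression enrichment fit for one gene set
#'
#' Fits \eqn{\mathrm{logit}\,\Pr(member_i) = \alpha + \beta s_i} by maximum
#' likelihood (IRLS, tolerance 1e-8, at most 50 iterations). A positive slope
#' means membership odds grow with differential-expression significance, i.e.
#' the set is enriched. The odds ratio is reported over the inter-decile span
#' of `s`: \eqn{OR = \exp(\beta \Delta)} with \eqn{\Delta = q_{90}(s) -
#' q_{10}(s)}, so `OR > 1` exactly when `slope > 0`.
#'
#' @param s Numeric vector of per-gene significance scores.
#' @param membership 0/1 (or logical) vector: is each gene in the set?
#' @param min_size Minimum number of members (default 10).
#' @return An object of class `afe_logit`: a list with `slope`, `intercept`,
#'   `wald_p`, `odds_ratio`, `direction` (`"enriched"`/`"depleted"`),
#'   `separated` (logical; when `TRUE` the likelihood has no finite maximum
#'   and `wald_p` is `NA`), `n`, `n_members`, and the standard errors.
#'   Use [generics::tidy()] / [generics::glance()] to extract tidy summaries.
#' @examples
#' fit <- fit_set_regression(c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
#'                           c(0, 0, 0, 0, 0, 1, 0, 1, 1, 0, 1, 1),
#'                           min_size = 2)
#' generics::tidy(fit)
#' @export
fit_set_regression <- function(s, membership, min_size = 10) {
  membership <- as.integer(membership)
  if (length(membership) != length(s)) abort("`s` and `membership` lengths differ.")
  if (!all(membership %in% c(0L, 1L))) abort("`membership` must be 0/1.")
  n1 <- sum(membership)
  if (n1 == 0 || n1 == length(membership)) {
    abort("Membership must include both members and non-members.")
  }
  if (n1 < min_size) {
    abort(paste0("Set has ", n1, " members; minimum is ", min_size, "."))
  }
  fit <- suppressWarnings(
    glm(membership ~ s, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 50))
  )
  beta <- unname(coef(fit)[2])
  alpha <- unname(coef(fit)[1])
  se <- sqrt(diag(vcov(fit)))
  # under (quasi-)complete separation the ML slope diverges and its Wald SE
  # explodes much faster than the estimate; a huge SE-to-estimate ratio is
  # the practical signature
  separated <- !fit$converged || se[2] > 10 * (abs(beta) + 2)
  wald_p <- if (separated) NA_real_ else 2 * pnorm(-abs(beta / se[2]))
  delta <- unname(diff(quantile(s, c(0.1, 0.9))))
  structure(
    list(
      slope = beta, intercept = alpha, se_slope = unname(se[2]),
      se_intercept = unname(se[1]), wald_p = wald_p,
      odds_ratio = exp(beta * delta), delta = delta,
      direction = if (beta > 0) "enriched" else "depleted",
      separated = separated, converged = fit$converged,
      n = length(s), n_members = n1
    ),
    class = "afe_logit"
  )
}

#' @export
print.afe_logit <- function(x, ...) {
  cat("<afe_logit> slope = ", format(x$slope, digits = 4),
      ", Wald p = ", format(x$wald_p, digits = 4),
      ", OR(inter-decile) = ", format(x$odds_ratio, digits = 4),
      if (x$separated) "  [separated]", "\n", sep = "")
  invisible(x)
}

#' Run the frequency-weighted LRpath pipeline
#'
#' Computes per-gene t-test p-values (or takes them as given), transforms
#' them to \eqn{-\log p}, applies the appearance-frequency adjustment, and
#' fits one membership-vs-significance logistic regression per gene set.
#'
#' @param x An [expression_dataset()] (t-tests are computed internally) or a
#'   data frame with columns `gene`, `p_value`.
#' @inheritParams run_gsea
#' @return A tibble with columns `set`, `size`, `slope`, `wald_p`,
#'   `odds_ratio`, `direction`, `separated`, sorted by `wald_p`, with class
#'   `afe_lrpath`. Per-set failures (e.g. a set covering the whole universe)
#'   are recorded in the `error` column without aborting the run.
#' @examples
#' pv <- tibble::tibble(gene = paste0("g", 1:40),
#'                      p_value = seq(0.001, 0.9, length.out = 40))
#' coll <- gene_set_tbl(tibble::tibble(
#'   set = rep(c("up", "bg"), each = 12),
#'   gene = paste0("g", c(1:12, 29:40))
#' ))
#' run_lrpath(pv, coll)
#' @export
run_lrpath <- function(x, collection, weights = c("none", "af", "rf", "iw"),
                       freq = NULL, weight_seed = NULL, min_size = 10,
                       n_pathways = NULL, cap = 2) {
  weights <- match.arg(weights)
  pvals <- if (inherits(x, "expression_dataset")) gene_pvalues(x) else as_tibble(x)
  if (anyDuplicated(pvals$gene)) abort("Duplicate gene identifiers in p-value table.")
  collection <- restrict_collection(collection, pvals$gene, min_size = min_size)
  ftab <- resolve_weights(weights, collection, freq = freq, seed = weight_seed,
                          n_pathways = n_pathways, cap = cap)
  exponents <- NULL
  if (!is.null(ftab)) {
    exponents <- stats::setNames(ftab$exponent_lrpath, ftab$gene)
  }
  adj <- adjust_significance(pvals, exponents)
  member_idx <- membership_index(collection, adj$gene)
  rows <- purrr::imap(member_idx, function(idx, nm) {
    membership <- integer(nrow(adj))
    membership[idx] <- 1L
    fit <- tryCatch(fit_set_regression(adj$s_adj, membership, min_size = min_size),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(set = nm, size = length(idx), slope = NA_real_, wald_p = NA_real_,
             odds_ratio = NA_real_, direction = NA_character_,
             separated = NA, error = conditionMessage(fit))
    } else {
      tibble(set = nm, size = length(idx), slope = fit$slope,
             wald_p = fit$wald_p, odds_ratio = fit$odds_ratio,
             direction = fit$direction, separated = fit$separated,
             error = NA_character_)
    }
  })
  res <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$wald_p)
  if (all(is.na(res$error))) res$error <- NULL
  attr(res, "weights") <- weights
  class(res) <- c("afe_lrpath", class(res))
  res
}
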