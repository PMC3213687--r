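# Independent oracle: direct maximisation of the Bernoulli log-likelihood
# over (alpha, beta) with optim, no IRLS involved.
logit_loglik_mle <- function(s, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * s
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))$par
}

test_that("pooled-variance t-tests match the t-distribution oracle", {
  m <- rbind(
    same = c(1, 2, 3, 1, 2, 3),
    diff = c(1, 2, 3, 4, 3, 4, 5, 6)[1:6]
  )
  # build an 8-sample dataset for the documented 4v4 case
  m2 <- rbind(diff = c(1, 2, 3, 4, 3, 4, 5, 6),
              same = c(1, 2, 3, 1, 1, 2, 3, 1))
  colnames(m2) <- paste0("s", 1:8)
  ds <- expression_dataset(m2, rep(c("A", "B"), each = 4))
  pv <- gene_pvalues(ds)
  expect_equal(pv$t[pv$gene == "diff"], -2.1909, tolerance = 1e-4)
  expect_equal(pv$p_value[pv$gene == "diff"],
               2 * pt(-abs(-2 / sqrt(5 / 6)), df = 6), tolerance = 1e-12)
  expect_equal(pv$p_value[pv$gene == "diff"], 0.0710, tolerance = 1e-3)

  # identical groups -> t = 0, p = 1
  m3 <- rbind(eq = c(1, 2, 3, 1, 2, 3))
  colnames(m3) <- paste0("s", 1:6)
  pv3 <- gene_pvalues(expression_dataset(m3, rep(c("A", "B"), each = 3)))
  expect_equal(pv3$t, 0)
  expect_equal(pv3$p_value, 1)

  # constant gene -> p = 1 with a warning
  m4 <- rbind(const = c(5, 5, 5, 5), varying = c(1, 2, 3, 4))
  colnames(m4) <- paste0("s", 1:4)
  expect_warning(
    pv4 <- gene_pvalues(expression_dataset(m4, c("A", "A", "B", "B"))),
    "zero pooled variance"
  )
  expect_equal(pv4$p_value[pv4$gene == "const"], 1)
})

test_that("significance adjustment is s^w with the documented fixed points", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        p_value = exp(-c(4, 4, 4, 0)))
  out <- adjust_significance(tab, exponents = c(a = 1, b = 1.5, c = 0.8))
  expect_equal(out$s, c(4, 4, 4, 0), tolerance = 1e-12)
  expect_equal(out$s_adj[1], 4)                       # w = 1 identity
  expect_equal(out$s_adj[2], 8, tolerance = 1e-12)    # 4^1.5
  expect_equal(out$s_adj[3], exp(0.8 * log(4)), tolerance = 1e-12)
  expect_equal(out$s_adj[3], 3.0314, tolerance = 1e-4)
  expect_equal(out$s_adj[4], 0)                       # s = 0 fixed
  # s = 1 fixed under any exponent
  one <- adjust_significance(tibble::tibble(gene = "x", p_value = exp(-1)),
                             exponents = c(x = 1.7))
  expect_equal(one$s_adj, 1, tolerance = 1e-12)
  # p = 0 floored, s stays finite
  z <- adjust_significance(tibble::tibble(gene = "x", p_value = 0))
  expect_true(is.finite(z$s))
})

test_that("adjustment preserves ranking among genes sharing an exponent", {
  set.seed(31)
  tab <- tibble::tibble(gene = sprintf("g%02d", 1:50),
                        p_value = runif(50, 1e-8, 1))
  w <- stats::setNames(rep(c(0.6, 1.4), 25), tab$gene)
  out <- adjust_significance(tab, w)
  for (grp in c(0.6, 1.4)) {
    sub <- out[w[out$gene] == grp, ]
    expect_equal(order(sub$s), order(sub$s_adj))
  }
})

test_that("set regression matches the likelihood oracle and flags separation", {
  # symmetric design: member fraction 1/2 at both levels -> alpha = beta = 0
  fit0 <- fit_set_regression(c(1, 1, 2, 2), c(0, 1, 0, 1), min_size = 2)
  expect_equal(fit0$slope, 0, tolerance = 1e-8)
  expect_equal(fit0$intercept, 0, tolerance = 1e-8)

  # perfect separation
  fit_sep <- fit_set_regression(c(1, 1, 2, 2), c(0, 0, 1, 1), min_size = 2)
  expect_true(fit_sep$separated)
  expect_true(is.na(fit_sep$wald_p))

  # quasi-complete separation (solving the score equations pushes a fitted
  # probability to 1) is flagged too
  fit_q <- fit_set_regression(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 1, 1, 1),
                              min_size = 2)
  expect_true(fit_q$separated)

  # finite MLE matches optim-based maximisation to 1e-6
  s <- c(0, 0.5, 1, 1, 2, 2, 3, 0.2, 2.5, 1.5)
  y <- c(0, 0, 0, 1, 1, 0, 1, 0, 1, 0)
  fit <- fit_set_regression(s, y, min_size = 2)
  oracle <- logit_loglik_mle(s, y)
  expect_false(fit$separated)
  expect_gt(fit$slope, 0)
  expect_equal(fit$slope, oracle[2], tolerance = 1e-6)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)

  # random small instances against the oracle
  set.seed(77)
  for (i in 1:25) {
    n <- 40
    s <- round(runif(n, 0, 4), 3)
    y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.6 * s))
    if (sum(y) < 3 || sum(y) > n - 3) next
    fit <- fit_set_regression(s, y, min_size = 2)
    if (fit$separated) next
    oracle <- logit_loglik_mle(s, y)
    expect_equal(fit$slope, oracle[2], tolerance = 1e-4)
  }

  expect_error(fit_set_regression(c(1, 2), c(1, 1), min_size = 1), "both members")
  expect_error(fit_set_regression(c(1, 2, 3), c(0, 1, 1), min_size = 10), "minimum")
})

test_that("odds ratio direction matches the slope sign", {
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    s <- runif(n, 0, 5)
    beta <- runif(1, -1, 1)
    y <- stats::rbinom(n, 1, stats::plogis(-0.5 + beta * s))
    if (sum(y) < 5 || sum(y) > n - 5) next
    fit <- fit_set_regression(s, y, min_size = 2)
    if (fit$separated) next
    expect_equal(fit$odds_ratio > 1, fit$slope > 0)
    expect_equal(fit$direction == "enriched", fit$slope > 0)
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_set_regression(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 1, 1, 1),
                            min_size = 2)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("intercept", "significance"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- generics::glance(fit)
  expect_equal(gl$wald_p, fit$wald_p)
  expect_equal(gl$n, 6L)
})

test_that("run_lrpath is neutral without weights, detects planted sets, isolates errors", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:300)
  # planted: members of 'hit' get stochastically smaller p-values
  pv <- tibble::tibble(
    gene = genes,
    p_value = runif(300, 0.001, 1)
  )
  hit_genes <- genes[1:30]
  pv$p_value[pv$gene %in% hit_genes] <- rbeta(30, 0.4, 3) * 0.5 + 1e-6
  coll <- gene_set_tbl(dplyr::bind_rows(
    tibble::tibble(set = "hit", gene = hit_genes),
    tibble::tibble(set = "bg1", gene = genes[101:130]),
    tibble::tibble(set = "bg2", gene = genes[131:160]),
    tibble::tibble(set = "all", gene = genes)
  ))
  res <- run_lrpath(pv, coll)
  expect_s3_class(res, "afe_lrpath")
  # the whole-universe set fails alone, others are unaffected
  expect_true(!is.na(res$error[res$set == "all"]))
  expect_true(all(is.na(res$error[res$set != "all"])))
  hit_p <- res$wald_p[res$set == "hit"]
  expect_gt(res$slope[res$set == "hit"], 0)
  expect_lt(hit_p, median(res$wald_p[res$set %in% c("bg1", "bg2")]))

  # mode "none" equals adjusting with exponents identically 1
  ones <- frequency_table(coll)
  ones$exponent_lrpath <- 1
  ones$exponent_gsea <- 1
  forced <- run_lrpath(pv, coll, weights = "af", freq = ones)
  strip <- function(x) as.data.frame(lapply(x, unname))
  expect_identical(strip(res), strip(forced))
})

test_that("Wald p-values are near-uniform when membership is independent of significance", {
  set.seed(99)
  n <- 2000
  s <- -log(runif(n))
  ps <- replicate(300, {
    y <- integer(n)
    y[sample.int(n, 60)] <- 1L
    fit_set_regression(s, y)$wald_p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(abs(mean(ps < 0.5) - 0.5), 3 * sqrt(0.25 / 300))
})
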