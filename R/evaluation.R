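#' Cross-dataset concordance of per-set enrichment scores
#'
#' Pearson correlation between two result tables over the sets present in
#' both (intersection by set name). For the running-sum branch the score is
#' the NES; for the regression branch the conventional score is the signed
#' log significance, `sign(slope) * -log10(wald_p)`.
#'
#' @param res_a,res_b Result tibbles (from [run_gsea()] or [run_lrpath()],
#'   or any table with a `set` column and the score field).
#' @param score Which score to correlate: `"nes"` (default) or
#'   `"signed_logp"`.
#' @return A one-row tibble: `pearson_r`, `n_common_sets`, `n_dropped`
#'   (sets present in only one table). Zero variance in either score vector
#'   yields `NA` with a warning.
#' @examples
#' a <- tibble::tibble(set = c("s1", "s2", "s3"), nes = c(1, 2, 3))
#' b <- tibble::tibble(set = c("s1", "s2", "s3"), nes = c(1, 3, 2))
#' score_concordance(a, b)  # r = 0.5
#' @export
score_concordance <- function(res_a, res_b, score = c("nes", "signed_logp")) {
  score <- match.arg(score)
  xa <- concordance_score(res_a, score)
  xb <- concordance_score(res_b, score)
  merged <- dplyr::inner_join(xa, xb, by = "set", suffix = c("_a", "_b"))
  merged <- merged[stats::complete.cases(merged), ]
  n_dropped <- length(union(xa$set, xb$set)) - nrow(merged)
  if (nrow(merged) < 3) {
    abort(paste0("Only ", nrow(merged), " sets are common to both tables; need >= 3."))
  }
  r <- if (sd(merged$value_a) == 0 || sd(merged$value_b) == 0) {
    warn("Zero variance in a score vector; correlation undefined.")
    NA_real_
  } else {
    cor(merged$value_a, merged$value_b)
  }
  tibble(pearson_r = r, n_common_sets = nrow(merged), n_dropped = n_dropped)
}

concordance_score <- function(res, score) {
  if (score == "nes") {
    if (!"nes" %in% names(res)) abort("Result table lacks an `nes` column.")
    tibble(set = res$set, value = res$nes)
  } else {
    if (!all(c("slope", "wald_p") %in% names(res))) {
      abort("Result table lacks `slope`/`wald_p` columns.")
    }
    tibble(set = res$set,
           value = sign(res$slope) * -log10(pmax(res$wald_p, 1e-300)))
  }
}

#' Overlap of the top-k set lists of two result tables
#'
#' Replicates the "number of overlapping pathways for increasing list
#' length" comparison: each table is filtered (running-sum branch:
#' `fdr_q <= fdr_cutoff`; regression branch: `odds_ratio > 1`), ranked by the
#' branch's ranking metric (NES descending / Wald p ascending), and the size
#' of the intersection of the two top-k lists is reported for k = 1..k_max.
#'
#' @inheritParams score_concordance
#' @param k_max Largest list length to evaluate.
#' @param branch `"gsea"` or `"lrpath"`; picks the filter and ranking metric.
#' @param fdr_cutoff FDR filter for the gsea branch (default 0.05).
#' @return A tibble with columns `k`, `overlap` (non-decreasing, bounded by
#'   `k`). If the filter empties either list the curve is all zeros, with a
#'   warning.
#' @export
top_overlap <- function(res_a, res_b, k_max = 20, branch = c("gsea", "lrpath"),
                        fdr_cutoff = 0.05) {
  branch <- match.arg(branch)
  top_list <- function(res) {
    if (branch == "gsea") {
      res <- res[!is.na(res$fdr_q) & res$fdr_q <= fdr_cutoff, ]
      res$set[order(-res$nes)]
    } else {
      res <- res[!is.na(res$odds_ratio) & res$odds_ratio > 1 & !is.na(res$wald_p), ]
      res$set[order(res$wald_p)]
    }
  }
  la <- top_list(res_a)
  lb <- top_list(res_b)
  if (length(la) == 0 || length(lb) == 0) {
    warn("The filter removed every set from one of the lists; overlap curve is zero.")
  }
  tibble(
    k = seq_len(k_max),
    overlap = vapply(seq_len(k_max), function(k) {
      length(intersect(head(la, k), head(lb, k)))
    }, integer(1))
  )
}

#' Summarise a control experiment over repeated frequency draws
#'
#' Runs a user-supplied pipeline once per seeded control draw (random
#' frequency or inverse weight), collects the per-draw concordance, and
#' reports its mean and standard error of the mean over the draws.
#'
#' @param runner A function taking a single integer draw seed and returning a
#'   scalar correlation (or `NA` on failure).
#' @param n_draws Number of control draws (default 10).
#' @param seed Master seed; draw `d` uses seed `seed + d`.
#' @return A one-row tibble: `mean_r`, `sem` (`sd/sqrt(n)`), `n_draws`
#'   (successful), `n_failed`.
#' @export
control_replicates <- function(runner, n_draws = 10, seed = 1) {
  if (n_draws < 2) abort("`n_draws` must be at least 2.")
  rs <- vapply(seq_len(n_draws), function(d) {
    out <- tryCatch(runner(seed + d), error = function(e) NA_real_)
    if (length(out) != 1) NA_real_ else as.numeric(out)
  }, numeric(1))
  ok <- !is.na(rs)
  if (sum(!ok) > 0) {
    warn(paste0(sum(!ok), " of ", n_draws, " control draws failed and were excluded."))
  }
  if (sum(ok) < 2) abort("Fewer than 2 control draws succeeded.")
  rs <- rs[ok]
  tibble(mean_r = mean(rs), sem = sd(rs) / sqrt(length(rs)),
         n_draws = length(rs), n_failed = sum(!ok))
}
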