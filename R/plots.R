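#' Plot the running-sum profile of one gene set
#'
#' Shows \eqn{P_{hit} - P_{miss}} along the ranked gene list with member
#' positions marked in the rug; the horizontal line marks the enrichment
#' score (the signed maximum deviation from zero).
#'
#' @param es_result The list returned by [enrichment_score()].
#' @return A ggplot object.
#' @export
plot_running_sum <- function(es_result) {
  profile <- es_result$profile
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = es_result$es, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = profile[profile$is_member, ],
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in gene list", y = expression(P[hit] - P[miss]),
                  title = sprintf("ES = %.3f (%d members)",
                                  es_result$es, es_result$n_members)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-afenrich
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot enrichment result tables
#'
#' `autoplot()` on a [run_gsea()] result draws NES per set, coloured by
#' whether the permutation FDR clears `fdr_cutoff`; on a [run_lrpath()]
#' result it draws the signed log Wald significance per set, coloured by
#' direction.
#'
#' @param object An `afe_gsea` or `afe_lrpath` result tibble.
#' @param fdr_cutoff FDR threshold used for colouring (gsea branch).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-afenrich
NULL

#' @rdname autoplot-afenrich
#' @exportS3Method ggplot2::autoplot
autoplot.afe_gsea <- function(object, fdr_cutoff = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- !is.na(df$fdr_q) & df$fdr_q <= fdr_cutoff
  df$set <- factor(df$set, levels = df$set[order(df$nes)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = sprintf("FDR q <= %.2g", fdr_cutoff)
    ) +
    ggplot2::labs(x = "normalised enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-afenrich
#' @exportS3Method ggplot2::autoplot
autoplot.afe_lrpath <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$wald_p), ]
  df$signed_logp <- sign(df$slope) * -log10(pmax(df$wald_p, 1e-300))
  df$set <- factor(df$set, levels = df$set[order(df$signed_logp)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_logp, y = .data$set,
                                   colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(sign(beta) %.% -log[10](p[Wald])), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a top-list overlap curve
#'
#' @param overlap A tibble from [top_overlap()] (columns `k`, `overlap`), or
#'   a named list of such tibbles to compare methods.
#' @return A ggplot object.
#' @export
plot_overlap_curve <- function(overlap) {
  if (is.data.frame(overlap)) overlap <- list(result = overlap)
  df <- dplyr::bind_rows(overlap, .id = "method")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$overlap,
                                   colour = .data$method)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::labs(x = "length of ranked list (k)",
                  y = "overlapping sets in both top-k lists") +
    ggplot2::theme_minimal()
}
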