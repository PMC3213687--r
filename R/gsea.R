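#' Rank genes by signal-to-noise ratio
#'
#' The per-gene ranking statistic for a two-class design is
#' \eqn{r_j = (\mu_A - \mu_B) / (\sigma_A + \sigma_B)} with sample standard
#' deviations (n-1 denominator). Each class standard deviation is floored at
#' `0.2 |mu|` of its class (at 0.2 when the class mean is zero), the usual
#' stabilisation against near-constant genes.
#'
#' @param dataset An [expression_dataset()].
#' @return A tibble with columns `gene`, `score`, sorted by `score`
#'   descending; ties are broken by gene identifier so the ranking is
#'   deterministic.
#' @export
signal_to_noise <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sc <- s2n_scores(dataset$exprs, dataset$phenotype == dataset$classes[1])
  genes <- rownames(dataset$exprs)
  ord <- order(-sc, genes)
  tibble(gene = genes[ord], score = unname(sc[ord]))
}

# Vectorised signal-to-noise over a logical class-A indicator; returns scores
# in the matrix row order.
s2n_scores <- function(exprs, is_a) {
  a <- exprs[, is_a, drop = FALSE]
  b <- exprs[, !is_a, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2 || nb < 2) abort("Each phenotype class needs at least two samples.")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  sa <- sqrt(pmax(rowSums((a - ma)^2), 0) / (na - 1))
  sb <- sqrt(pmax(rowSums((b - mb)^2), 0) / (nb - 1))
  sa <- pmax(sa, ifelse(ma == 0, 0.2, 0.2 * abs(ma)))
  sb <- pmax(sb, ifelse(mb == 0, 0.2, 0.2 * abs(mb)))
  (ma - mb) / (sa + sb)
}

# Enrichment score from sorted member positions.
#
# `sort_pos`: strictly increasing ranks (1-based) of the set members in the
# ranked list; `w`: the corresponding weights |r|^p in the same order; `n`:
# total genes. The running sum increases by w/N_R at each member and falls by
# 1/(N - N_H) per non-member, so its extrema lie at member positions (upper)
# and just before member positions (lower). ES is the extremum of largest
# absolute value; exact ties go to the earlier rank position.
es_from_positions <- function(sort_pos, w, n) {
  nh <- length(sort_pos)
  if (nh == 0) abort("No set member is present in the ranked list.")
  if (nh == n) abort("A set covering every ranked gene has no complement.")
  nr <- sum(w)
  if (nr == 0) abort("All member scores are zero (N_R = 0); ES undefined.")
  cumw <- cumsum(w)
  miss <- (sort_pos - seq_len(nh)) / (n - nh)
  dev_hit <- cumw / nr - miss
  dev_pre <- c(0, cumw[-nh]) / nr - miss
  cand <- c(dev_hit, dev_pre)
  ranks <- c(sort_pos, sort_pos - 1L)
  amax <- max(abs(cand))
  if (amax == 0) return(0)
  # magnitude ties (within float noise of an exact tie) go to the earlier rank
  sel <- which(abs(cand) >= amax - 1e-9)
  cand[sel[which.min(ranks[sel])]]
}

#' Frequency-weighted enrichment score for one gene set
#'
#' Walks the ranked gene list accumulating \eqn{P_{hit}} (members, in steps of
#' \eqn{|r_j|^{p_j} / N_R} with \eqn{N_R = \sum_{members} |r_j|^{p_j}}) and
#' \eqn{P_{miss}} (non-members, in steps of \eqn{1/(N - N_H)}). The
#' enrichment score is the signed maximum deviation from zero of
#' \eqn{P_{hit} - P_{miss}}. With all exponents 1 this is the classic
#' correlation-weighted statistic; with all exponents 0 it reduces to the
#' unweighted Kolmogorov-Smirnov statistic; appearance-frequency exponents
#' shrink the steps of promiscuous genes (since \eqn{|r_j| \le 1} and
#' \eqn{p_j > 1}) and enlarge those of pathway-specific genes.
#'
#' @param ranked A ranked list from [signal_to_noise()] (tibble with `gene`,
#'   `score`, sorted descending).
#' @param members Character vector of member gene identifiers; members absent
#'   from the ranked list are ignored.
#' @param exponents Named numeric vector of per-gene exponents; genes without
#'   an entry (and `NULL`) get the neutral exponent 1.
#' @return A list with elements `es` (the enrichment score), `n_members`
#'   (members used) and `profile`, a tibble (`rank`, `gene`, `is_member`,
#'   `running`) of the full running sum, which ends at 0.
#' @export
enrichment_score <- function(ranked, members, exponents = NULL) {
  genes <- ranked$gene
  n <- length(genes)
  pos <- which(genes %in% members)
  if (length(pos) == 0) abort("No set member is present in the ranked list.")
  p <- exponent_lookup(exponents, genes[pos])
  w <- abs(ranked$score[pos])^p
  es <- es_from_positions(pos, w, n)
  steps <- rep(-1 / (n - length(pos)), n)
  steps[pos] <- w / sum(w)
  profile <- tibble(
    rank = seq_len(n),
    gene = genes,
    is_member = seq_len(n) %in% pos,
    running = cumsum(steps)
  )
  list(es = es, n_members = length(pos), profile = profile)
}

exponent_lookup <- function(exponents, genes) {
  if (is.null(exponents)) return(rep(1, length(genes)))
  if (is.null(names(exponents))) {
    if (length(exponents) == 1) return(rep(exponents, length(genes)))
    stopifnot(length(exponents) == length(genes))
    return(exponents)
  }
  p <- exponents[genes]
  p[is.na(p)] <- 1
  unname(p)
}

# Compute ES for every set of a (pre-restricted) collection given raw scores
# in dataset gene order. `member_idx` is a list of integer indices into
# `genes` per set.
es_all_sets <- function(scores, genes, member_idx, p_vec) {
  n <- length(scores)
  ord <- order(-scores, genes)
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  absr <- abs(scores)
  vapply(member_idx, function(idx) {
    pos <- rnk[idx]
    o <- order(pos)
    es_from_positions(pos[o], (absr[idx][o])^(p_vec[idx][o]), n)
  }, numeric(1))
}

#' Phenotype-permutation null distribution of enrichment scores
#'
#' For each permutation the phenotype labels are shuffled (class sizes
#' preserved), genes are re-ranked by signal-to-noise, and every set's
#' enrichment score is recomputed with the same per-gene exponents as the
#' observed analysis.
#'
#' @inheritParams enrichment_score
#' @param dataset An [expression_dataset()].
#' @param collection A `gene_set_tbl`, already restricted to the dataset's
#'   genes (see [restrict_collection()]).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed making the permutations reproducible.
#' @param perm_matrix Optional integer matrix (`n_perm` rows, one column per
#'   sample) of explicit sample permutations, overriding the seeded draws.
#' @return A numeric matrix of null enrichment scores, `n_perm` rows, one
#'   named column per set.
#' @export
permutation_null <- function(dataset, collection, exponents = NULL,
                             n_perm = 1000, seed = NULL, perm_matrix = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(perm_matrix)) {
    if (n_perm < 1) abort("`n_perm` must be at least 1.")
    ns <- ncol(dataset$exprs)
    perm_matrix <- with_seed(seed, t(replicate(n_perm, sample.int(ns))))
  }
  genes <- rownames(dataset$exprs)
  p_vec <- exponent_lookup(exponents, genes)
  member_idx <- membership_index(collection, genes)
  is_a <- dataset$phenotype == dataset$classes[1]
  null_es <- matrix(NA_real_, nrow(perm_matrix), length(member_idx),
                    dimnames = list(NULL, names(member_idx)))
  for (b in seq_len(nrow(perm_matrix))) {
    sc <- s2n_scores(dataset$exprs, is_a[perm_matrix[b, ]])
    null_es[b, ] <- es_all_sets(sc, genes, member_idx, p_vec)
  }
  null_es
}

membership_index <- function(collection, genes) {
  sets <- split(collection$gene, factor(collection$set, levels = unique(collection$set)))
  lapply(sets, function(g) which(genes %in% g))
}

#' Normalise enrichment scores and attach permutation FDR q-values
#'
#' NES is the enrichment score divided by the mean same-sign null score of
#' its set, making scores comparable across set sizes. The nominal p-value is
#' the fraction of same-sign null scores at least as extreme as the observed
#' one (reported as 0 when no null score reaches it). The FDR q-value follows
#' the sign-stratified permutation scheme of Subramanian et al.: the fraction
#' of all same-sign null NES values at least as extreme, divided by the
#' fraction of observed same-sign NES values at least as extreme, clipped to
#' [0, 1] and made monotone within each sign.
#'
#' @param observed_es Named numeric vector of observed enrichment scores.
#' @param null_es Null score matrix from [permutation_null()] (columns match
#'   `observed_es` names).
#' @return A tibble with columns `set`, `es`, `nes`, `nominal_p`, `fdr_q`.
#'   Sets with no same-sign null scores get `NA` NES and are excluded from
#'   the q computation.
#' @export
normalize_and_fdr <- function(observed_es, null_es) {
  sets <- names(observed_es)
  stopifnot(!is.null(sets), all(sets %in% colnames(null_es)))
  null_es <- null_es[, sets, drop = FALSE]
  pos_mean <- apply(null_es, 2, function(x) mean(x[x > 0]))
  neg_mean <- apply(null_es, 2, function(x) mean(abs(x[x < 0])))
  is_pos <- observed_es >= 0
  nes <- ifelse(is_pos, observed_es / pos_mean, observed_es / neg_mean)
  nominal_p <- vapply(seq_along(observed_es), function(j) {
    x <- null_es[, j]
    if (is_pos[j]) {
      same <- x[x > 0]
      if (length(same) == 0) return(NA_real_)
      mean(same >= observed_es[j])
    } else {
      same <- abs(x[x < 0])
      if (length(same) == 0) return(NA_real_)
      mean(same >= abs(observed_es[j]))
    }
  }, numeric(1))

  # null NES matrix, same sign-stratified normalisation
  null_nes <- null_es
  for (j in seq_len(ncol(null_es))) {
    x <- null_es[, j]
    y <- numeric(length(x))
    y[x > 0] <- x[x > 0] / pos_mean[j]
    y[x < 0] <- x[x < 0] / neg_mean[j]
    null_nes[, j] <- y
  }
  all_null <- as.vector(null_nes)
  fdr_q <- rep(NA_real_, length(nes))
  for (sign_pos in c(TRUE, FALSE)) {
    obs_side <- if (sign_pos) nes[!is.na(nes) & nes >= 0] else -nes[!is.na(nes) & nes < 0]
    null_side <- if (sign_pos) all_null[all_null >= 0] else -all_null[all_null < 0]
    idx <- which(!is.na(nes) & (if (sign_pos) nes >= 0 else nes < 0))
    if (length(idx) == 0 || length(null_side) == 0) next
    vals <- abs(nes[idx])
    raw <- vapply(vals, function(v) {
      num <- mean(null_side >= v)
      den <- mean(obs_side >= v)
      min(1, num / den)
    }, numeric(1))
    # q-value monotonisation: q_i = min FDR over cutoffs that include set i
    o <- order(-vals)
    q_sorted <- raw[o]
    q_sorted <- rev(cummin(rev(q_sorted)))
    raw[o] <- q_sorted
    fdr_q[idx] <- raw
  }
  tibble(set = sets, es = unname(observed_es), nes = unname(nes),
         nominal_p = nominal_p, fdr_q = fdr_q)
}

#' Run the frequency-weighted GSEA pipeline
#'
#' Ranks genes by signal-to-noise, computes every set's frequency-weighted
#' enrichment score, builds a phenotype-permutation null, and reports NES,
#' nominal p and permutation FDR q per set.
#'
#' @inheritParams permutation_null
#' @param weights Weighting mode: `"none"` (classic exponent 1 for every
#'   gene), `"af"` (appearance-frequency exponents), `"rf"` (random-frequency
#'   control) or `"iw"` (inverse-weight control). The control modes require
#'   `weight_seed`.
#' @param freq Optional precomputed frequency table (from
#'   [frequency_table()] or a control transform); by default it is computed
#'   from `collection`.
#' @param weight_seed Seed for the `rf`/`iw` control draws.
#' @param min_size Minimum number of set members present in the dataset
#'   (default 10); smaller sets are dropped.
#' @param n_pathways Overrides the collection size used in the IDF
#'   computation (e.g. 195 for the full KEGG PATHWAY collection).
#' @param cap Exponent clip bound, see [add_exponents()].
#' @return A tibble with columns `set`, `size`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`, sorted by `nes` descending, with class `afe_gsea`.
#' @examples
#' sim <- simulate_collection(sim_config(n_genes = 300, n_sets = 8), seed = 1)
#' pair <- simulate_dataset_pair(sim$collection, sim_config(n_genes = 300, n_sets = 8),
#'                               seed_a = 1, seed_b = 2)
#' run_gsea(pair$dataset_a, sim$collection, weights = "af", n_perm = 25, seed = 7)
#' @export
run_gsea <- function(dataset, collection, weights = c("none", "af", "rf", "iw"),
                     freq = NULL, n_perm = 1000, seed = NULL,
                     weight_seed = NULL, min_size = 10, n_pathways = NULL,
                     cap = 2) {
  weights <- match.arg(weights)
  genes <- rownames(dataset$exprs)
  collection <- restrict_collection(collection, genes, min_size = min_size)
  ftab <- resolve_weights(weights, collection, freq = freq, seed = weight_seed,
                          n_pathways = n_pathways, cap = cap)
  exponents <- NULL
  if (!is.null(ftab)) {
    exponents <- stats::setNames(ftab$exponent_gsea, ftab$gene)
  }
  p_vec <- exponent_lookup(exponents, genes)
  member_idx <- membership_index(collection, genes)
  sc <- s2n_scores(dataset$exprs, dataset$phenotype == dataset$classes[1])
  observed <- es_all_sets(sc, genes, member_idx, p_vec)
  null_es <- permutation_null(dataset, collection, exponents = exponents,
                              n_perm = n_perm, seed = seed)
  res <- normalize_and_fdr(observed, null_es)
  res$size <- lengths(member_idx)[res$set]
  res <- dplyr::select(res, "set", "size", "es", "nes", "nominal_p", "fdr_q") |>
    dplyr::arrange(dplyr::desc(.data$nes))
  attr(res, "weights") <- weights
  attr(res, "n_perm") <- n_perm
  class(res) <- c("afe_gsea", class(res))
  res
}
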