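#' Add inverse document frequency (IDF) to a frequency table
#'
#' IDF treats each pathway as a document and each gene as a term:
#' \eqn{idf_i = \log(n_{pathways} / f_i)}. A gene found in every pathway has
#' IDF 0; the rarer the gene, the larger its IDF.
#'
#' @param freq A tibble with columns `gene`, `f` (see
#'   [appearance_frequency()]).
#' @param n_pathways Number of sets in the source collection. Defaults to the
#'   `n_pathways` attribute of `freq`; override (e.g. to 195, the size of the
#'   KEGG PATHWAY collection this weighting was designed around) to decouple
#'   the IDF scale from the loaded collection.
#' @param log_base Base of the logarithm (default natural log). The derived
#'   exponents are ratios of logs and hence base-invariant; only the reported
#'   `idf` column changes with the base.
#' @return `freq` with an `idf` column and attributes `n_pathways`,
#'   `mean_idf` (arithmetic mean of `idf` over the genes in the table).
#' @export
add_idf <- function(freq, n_pathways = NULL, log_base = exp(1)) {
  n_pathways <- n_pathways %||% attr(freq, "n_pathways")
  if (is.null(n_pathways) || n_pathways < 1) {
    abort("`n_pathways` must be a positive integer.")
  }
  if (nrow(freq) == 0) abort("Empty frequency table.")
  if (any(freq$f < 1)) abort("Appearance frequencies must be >= 1.")
  if (any(freq$f > n_pathways)) {
    abort(paste0(
      "Appearance frequency exceeds the number of pathways (",
      max(freq$f), " > ", n_pathways, ")."
    ))
  }
  out <- dplyr::mutate(freq, idf = log(n_pathways / .data$f, base = log_base))
  attr(out, "n_pathways") <- n_pathways
  attr(out, "mean_idf") <- mean(out$idf)
  out
}

#' Add the per-gene weighting exponents to a frequency table
#'
#' The mean IDF over all genes is the calibration point: a gene whose IDF
#' equals the mean gets exponent exactly 1 (neutral). For the running-sum
#' branch the exponent is `mean_idf / idf`, increasing in appearance
#' frequency and capped at `cap` -- frequent genes have \eqn{|r|^p} shrunk
#' because \eqn{|r| \le 1}. For the regression branch the reciprocal form
#' `idf / mean_idf` is used (clipped to `[1/cap, cap]`), decreasing in
#' frequency, because the \eqn{-\log(P)} values it exponentiates exceed 1 and
#' the weighting must still demote frequent genes.
#'
#' @param freq A frequency table with `idf` filled (see [add_idf()]).
#' @param cap Upper clip bound for both exponents (default 2); the lower
#'   bound is `1/cap`.
#' @return `freq` with columns `exponent_gsea`, `exponent_lrpath`.
#' @export
add_exponents <- function(freq, cap = 2) {
  if (!"idf" %in% names(freq)) abort("Run add_idf() first: `idf` column missing.")
  mean_idf <- attr(freq, "mean_idf") %||% mean(freq$idf)
  if (mean_idf <= 0) {
    abort("mean IDF is not positive (every gene is in every set); exponents undefined.")
  }
  if (cap <= 1) abort("`cap` must exceed 1.")
  out <- dplyr::mutate(
    freq,
    exponent_gsea = ifelse(.data$idf == 0, cap, pmin(mean_idf / .data$idf, cap)),
    exponent_lrpath = pmin(pmax(.data$idf / mean_idf, 1 / cap), cap)
  )
  attr(out, "mean_idf") <- mean_idf
  attr(out, "cap") <- cap
  out
}

#' Build the complete appearance-frequency table for a collection
#'
#' Convenience pipeline: [appearance_frequency()] |> [add_idf()] |>
#' [add_exponents()].
#'
#' @inheritParams add_idf
#' @inheritParams add_exponents
#' @param collection A `gene_set_tbl`.
#' @return A tibble with columns `gene`, `f`, `idf`, `exponent_gsea`,
#'   `exponent_lrpath` and attributes `n_pathways`, `mean_idf`.
#' @examples
#' coll <- gene_set_tbl(tibble::tibble(
#'   set = rep(c("A", "B"), c(3, 2)),
#'   gene = c("g1", "g2", "g3", "g2", "g4")
#' ))
#' frequency_table(coll)
#' @export
frequency_table <- function(collection, n_pathways = NULL, log_base = exp(1),
                            cap = 2) {
  appearance_frequency(collection) |>
    add_idf(n_pathways = n_pathways, log_base = log_base) |>
    add_exponents(cap = cap)
}

# Recompute idf/exponents after a control transform changed f.
refresh_frequency <- function(freq, n_pathways, log_base = exp(1), cap = 2) {
  freq |>
    dplyr::select("gene", "f") |>
    add_idf(n_pathways = n_pathways, log_base = log_base) |>
    add_exponents(cap = cap)
}

#' Random-frequency (RF) negative control
#'
#' Reassigns the observed appearance frequencies to genes by a seeded uniform
#' permutation, so the marginal frequency distribution is preserved exactly
#' while the gene-to-frequency link is destroyed. IDF and exponents are
#' recomputed from the permuted frequencies.
#'
#' @param freq A frequency table (at minimum columns `gene`, `f`).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @inheritParams add_idf
#' @inheritParams add_exponents
#' @return A frequency table of the same shape with permuted `f`.
#' @export
random_frequency <- function(freq, seed, n_pathways = NULL, log_base = exp(1),
                             cap = 2) {
  if (nrow(freq) == 0) abort("Empty frequency table.")
  n_pathways <- n_pathways %||% attr(freq, "n_pathways")
  out <- freq
  out$f <- with_seed(seed, freq$f[sample.int(length(freq$f))])
  refresh_frequency(out, n_pathways = n_pathways, log_base = log_base, cap = cap)
}

#' Inverse-weight (IW) negative control
#'
#' Maps each frequency to an "inverse" frequency so that pathway-specific
#' genes are treated as promiscuous and vice versa, while roughly preserving
#' the overall frequency distribution: `f = 1` becomes a seeded uniform draw
#' from 20..30, `f > 20` becomes 1, and intermediate frequencies are mapped by
#' the antitone linear rule `21 - f`. Output frequencies are truncated at
#' `n_pathways` so the IDF stays non-negative for small collections.
#'
#' @inheritParams random_frequency
#' @return A frequency table with the inverted `f`.
#' @export
inverse_frequency <- function(freq, seed, n_pathways = NULL, log_base = exp(1),
                              cap = 2) {
  if (nrow(freq) == 0) abort("Empty frequency table.")
  n_pathways <- n_pathways %||% attr(freq, "n_pathways")
  f <- freq$f
  inv <- ifelse(f > 20, 1L, 21L - as.integer(f))
  ones <- which(f == 1)
  if (length(ones) > 0) {
    inv[ones] <- with_seed(seed, sample(20:30, length(ones), replace = TRUE))
  }
  inv <- pmin(inv, n_pathways %||% max(inv))
  out <- freq
  out$f <- as.integer(inv)
  refresh_frequency(out, n_pathways = n_pathways, log_base = log_base, cap = cap)
}

#' Write / read a frequency table as TSV
#'
#' Columns: `gene`, `f`, `idf`, `exponent_gsea`, `exponent_lrpath`.
#'
#' @param freq A frequency table.
#' @param path File path.
#' @return `write_frequency_tsv()` returns `path` invisibly;
#'   `read_frequency_tsv()` returns the tibble.
#' @export
write_frequency_tsv <- function(freq, path) {
  readr::write_tsv(as_tibble(freq), path)
  invisible(path)
}

#' @rdname write_frequency_tsv
#' @export
read_frequency_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

# Exponent lookup: named vector of exponents for `genes`, defaulting to 1
# (neutral) for genes with no frequency record.
exponent_vector <- function(freq, genes, which = c("exponent_gsea", "exponent_lrpath")) {
  which <- match.arg(which)
  w <- rep(1, length(genes))
  names(w) <- genes
  if (!is.null(freq)) {
    hit <- match(genes, freq$gene)
    ok <- !is.na(hit)
    w[ok] <- freq[[which]][hit[ok]]
  }
  w
}

# Resolve a weighting mode to a frequency table (or NULL for mode "none").
resolve_weights <- function(mode = c("none", "af", "rf", "iw"), collection,
                            freq = NULL, seed = NULL, n_pathways = NULL,
                            cap = 2) {
  mode <- match.arg(mode)
  if (mode == "none") return(NULL)
  base <- freq %||% frequency_table(collection, n_pathways = n_pathways, cap = cap)
  if (mode == "af") return(base)
  if (is.null(seed)) {
    abort(paste0("Weighting mode '", mode, "' requires a `seed`."))
  }
  np <- n_pathways %||% attr(base, "n_pathways")
  switch(mode,
    rf = random_frequency(base, seed = seed, n_pathways = np, cap = cap),
    iw = inverse_frequency(base, seed = seed, n_pathways = np, cap = cap)
  )
}
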