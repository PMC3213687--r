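#' Configuration for the synthetic enrichment benchmark
#'
#' Bundles the parameters of the synthetic gene-set collection and of the
#' paired two-class expression datasets. The defaults emulate the structure
#' this weighting scheme targets: a heavy-tailed appearance-frequency
#' distribution in which about half of the genes belong to exactly one set
#' (truncated geometric with success probability 0.5), a small group of
#' promiscuous hub genes shared by many sets, a handful of truly enriched
#' sets whose specific genes shift in both datasets, and decoy sets whose
#' only signal comes from dataset-specific hub activation.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_sets Number of gene sets (default 40).
#' @param geom_prob Success probability of the truncated geometric frequency
#'   law for ordinary genes (default 0.5, putting about half of the genes at
#'   frequency 1).
#' @param n_per_class Samples per phenotype class (default 30, the median
#'   scale of the two-class microarray cohorts this benchmark emulates).
#' @param delta Standardised between-class mean shift of differentially
#'   expressed genes, in units of `noise_sd` (default 1).
#' @param noise_sd Standard deviation of the Gaussian expression noise,
#'   common to both classes (default 1).
#' @param n_true_sets Number of truly enriched sets (default 6). The signal
#'   genes of true set k shift by `delta * true_set_effects[k]`.
#' @param true_set_effects Per-true-set effect multipliers (default all 1:
#'   every planted pathway carries the same standardised effect; pass a
#'   declining sequence to emulate graded pathway strengths).
#' @param n_decoy_sets Number of hub-driven decoy sets (default 6).
#' @param n_hubs Number of hub genes (default 30). Each hub joins
#'   `hub_true_sets` of the true sets and `hub_decoy_sets` of the decoy sets
#'   (chosen at random, so every true/decoy set has the same expected hub
#'   count but a different hub composition), with the rest of its memberships
#'   spread evenly over the remaining sets up to a total frequency drawn
#'   uniformly from `hub_frequency`.
#' @param hub_frequency Integer range of hub appearance frequencies
#'   (default 12..20, truncated at `n_sets`).
#' @param hub_true_sets,hub_decoy_sets Number of true / decoy sets each hub
#'   joins (defaults 2 and 2).
#' @param hub_prob Per-dataset probability that a hub gene is differentially
#'   expressed (default 0.3); activation is drawn independently per dataset,
#'   which is what makes the hub-driven enrichment dataset-specific.
#' @param hub_effect Effect multiplier for activated hubs (default 1): an
#'   activated hub shifts by `delta * hub_effect`, i.e. it responds like any
#'   other differentially expressed gene; what distinguishes the two cohorts
#'   is *which* hubs respond, not how strongly.
#' @param signal_max_f Members of true sets with appearance frequency at most
#'   this value (and which are not hubs) carry the shared differential signal
#'   (default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_sets = 40, geom_prob = 0.5,
                       n_per_class = 30, delta = 1, noise_sd = 1,
                       n_true_sets = 6, n_decoy_sets = 6,
                       true_set_effects = rep(1, n_true_sets),
                       n_hubs = 30, hub_frequency = c(12, 20),
                       hub_true_sets = 2, hub_decoy_sets = 2, hub_prob = 0.3,
                       hub_effect = 1, signal_max_f = 2) {
  cfg <- list(
    n_genes = n_genes, n_sets = n_sets, geom_prob = geom_prob,
    n_per_class = n_per_class, delta = delta, noise_sd = noise_sd,
    n_true_sets = n_true_sets, n_decoy_sets = n_decoy_sets,
    true_set_effects = true_set_effects, n_hubs = n_hubs,
    hub_frequency = hub_frequency, hub_true_sets = hub_true_sets,
    hub_decoy_sets = hub_decoy_sets, hub_prob = hub_prob,
    hub_effect = hub_effect, signal_max_f = signal_max_f
  )
  if (length(true_set_effects) != n_true_sets || any(true_set_effects < 0)) {
    abort("`true_set_effects` needs one non-negative multiplier per true set.")
  }
  counts <- c(n_genes, n_sets, n_per_class)
  if (any(counts < 1)) abort("All counts must be positive.")
  if (delta < 0) abort("`delta` must be non-negative.")
  if (geom_prob <= 0 || geom_prob > 1) abort("`geom_prob` must lie in (0, 1].")
  if (n_hubs > 0) {
    if (hub_true_sets > n_true_sets || hub_decoy_sets > n_decoy_sets) {
      abort("Hubs cannot join more true/decoy sets than exist.")
    }
    if (hub_true_sets + hub_decoy_sets > min(hub_frequency)) {
      abort("Hub frequency range is too small for the forced memberships.")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene-set collection with realistic frequency structure
#'
#' Each ordinary gene draws a target appearance frequency from a geometric
#' distribution truncated to `[1, n_sets]` and is assigned to that many
#' distinct sets uniformly at random, so the realised membership counts equal
#' the drawn frequencies exactly. Each hub gene joins a random subset of the
#' true and decoy sets (fixed counts, see [sim_config()]) and its remaining
#' memberships are spread over the other sets by least-loaded balanced
#' allocation, so sets differ in *which* hubs they contain much more than in
#' *how many* -- the composition difference is what makes hub-driven decoy
#' enrichment dataset-specific once each dataset activates its own random
#' subset of hubs. Any set left empty is refilled with a forced assignment
#' (and a message); with the default configuration this never triggers.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the collection is deterministic given the seed.
#' @return A list of class `sim_collection`: `collection` (a
#'   `gene_set_tbl`), `freq_truth` (tibble `gene`, `f` of realised
#'   frequencies), `truth_sets` (tibble `set`, `is_true`, `is_decoy`),
#'   `hub_genes`, `signal_genes` (tibble `gene`, `effect`: the
#'   true-set-specific low-frequency genes and their shift multipliers).
#' @export
simulate_collection <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  expected_memberships <- cfg$n_genes / cfg$geom_prob
  if (expected_memberships < 2 * cfg$n_sets) {
    abort("Infeasible configuration: expected memberships cannot populate the sets.")
  }
  if (cfg$n_hubs >= cfg$n_genes) abort("`n_hubs` must be smaller than `n_genes`.")
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  set_ids <- sprintf("S%03d", seq_len(cfg$n_sets))
  true_sets <- set_ids[seq_len(cfg$n_true_sets)]
  decoy_sets <- set_ids[cfg$n_true_sets + seq_len(cfg$n_decoy_sets)]
  hub_genes <- if (cfg$n_hubs > 0) gene_ids[seq_len(cfg$n_hubs)] else character(0)
  ordinary <- setdiff(gene_ids, hub_genes)

  memb <- with_seed(seed, {
    f_ord <- pmin(1L + rgeom(length(ordinary), cfg$geom_prob), cfg$n_sets)
    ord_rows <- purrr::map2(ordinary, f_ord, function(g, f) {
      tibble(set = set_ids[sample.int(cfg$n_sets, f)], gene = g)
    })
    other_sets <- setdiff(set_ids, c(true_sets, decoy_sets))
    load <- stats::setNames(numeric(length(other_sets)), other_sets)
    hub_rows <- purrr::map(hub_genes, function(g) {
      f <- sample(seq(cfg$hub_frequency[1], min(cfg$hub_frequency[2], cfg$n_sets)), 1)
      forced <- c(sample(true_sets, cfg$hub_true_sets),
                  sample(decoy_sets, cfg$hub_decoy_sets))
      n_extra <- min(max(0, f - length(forced)), length(other_sets))
      # least-loaded allocation keeps per-set hub counts nearly equal
      extra <- names(sort(load + stats::runif(length(load))))[seq_len(n_extra)]
      load[extra] <<- load[extra] + 1
      tibble(set = c(forced, extra), gene = g)
    })
    dplyr::bind_rows(ord_rows, hub_rows)
  })
  # refill any empty set with a forced extra membership
  empty <- setdiff(set_ids, unique(memb$set))
  if (length(empty) > 0) {
    inform(paste0(length(empty), " empty set(s) refilled by forced assignment."))
    fill <- with_seed(seed + 10007L, tibble(
      set = empty, gene = sample(ordinary, length(empty))
    ))
    memb <- dplyr::bind_rows(memb, fill)
    memb <- dplyr::distinct(memb, .data$set, .data$gene)
  }
  memb$set <- factor(memb$set, levels = set_ids)
  memb <- dplyr::arrange(memb, .data$set, .data$gene)
  memb$set <- as.character(memb$set)
  memb$description <- "synthetic"
  collection <- gene_set_tbl(memb)

  freq_truth <- appearance_frequency(collection)
  effects <- tibble(set = true_sets, effect = as.numeric(cfg$true_set_effects))
  candidates <- collection |>
    dplyr::filter(.data$set %in% true_sets, !.data$gene %in% hub_genes) |>
    dplyr::inner_join(freq_truth, by = "gene") |>
    dplyr::filter(.data$f <= cfg$signal_max_f) |>
    dplyr::inner_join(effects, by = "set")
  signal_genes <- if (nrow(candidates) == 0) {
    tibble(gene = character(0), effect = numeric(0))
  } else {
    candidates |>
      dplyr::summarise(effect = max(.data$effect), .by = "gene") |>
      dplyr::arrange(.data$gene)
  }
  structure(
    list(
      collection = collection,
      freq_truth = dplyr::select(freq_truth, "gene", "f"),
      truth_sets = tibble(set = set_ids, is_true = set_ids %in% true_sets,
                          is_decoy = set_ids %in% decoy_sets),
      hub_genes = hub_genes,
      signal_genes = signal_genes,
      config = cfg
    ),
    class = "sim_collection"
  )
}

#' Simulate a pair of two-class datasets sharing true signal but not hub noise
#'
#' Both datasets carry the same differential signal (`delta` shift of the
#' true sets' specific genes between classes), emulating two independent
#' studies of the same biology. Each dataset additionally activates its own
#' random subset of hub genes, creating dataset-specific decoy enrichment of
#' every set those hubs touch -- the false-positive mechanism that
#' appearance-frequency weighting is designed to suppress.
#'
#' @param sim A `sim_collection` from [simulate_collection()].
#' @param seed_a,seed_b Seeds for the two datasets' noise and hub draws.
#' @param config Optional [sim_config()] overriding `sim$config`.
#' @return A list: `dataset_a`, `dataset_b` ([expression_dataset()] objects),
#'   `truth` (list with `signal_genes`, `active_hubs_a`, `active_hubs_b`,
#'   `truth_sets`).
#' @export
simulate_dataset_pair <- function(sim, seed_a = 1, seed_b = 2, config = NULL) {
  stopifnot(inherits(sim, "sim_collection"))
  cfg <- config %||% sim$config
  if (cfg$delta == 0 && nrow(sim$signal_genes) > 0) {
    warn("`delta` is 0 with non-empty true sets: this is a null simulation.")
  }
  genes <- sort(unique(sim$collection$gene))
  one <- function(seed, tag) {
    with_seed(seed, {
      n <- 2 * cfg$n_per_class
      m <- matrix(rnorm(length(genes) * n, 0, cfg$noise_sd), length(genes), n,
                  dimnames = list(genes, paste0(tag, "_s", seq_len(n))))
      cls <- rep(c("A", "B"), each = cfg$n_per_class)
      sig <- match(sim$signal_genes$gene, genes)
      shift <- cfg$delta * cfg$noise_sd * sim$signal_genes$effect
      m[sig, cls == "B"] <- m[sig, cls == "B"] + shift
      active <- sim$hub_genes[stats::runif(length(sim$hub_genes)) < cfg$hub_prob]
      m[genes %in% active, cls == "B"] <-
        m[genes %in% active, cls == "B"] + cfg$delta * cfg$hub_effect * cfg$noise_sd
      list(dataset = expression_dataset(m, cls), active_hubs = active)
    })
  }
  a <- one(seed_a, "A")
  b <- one(seed_b, "B")
  list(
    dataset_a = a$dataset, dataset_b = b$dataset,
    truth = list(signal_genes = sim$signal_genes,
                 active_hubs_a = a$active_hubs, active_hubs_b = b$active_hubs,
                 truth_sets = sim$truth_sets)
  )
}

#' Write a simulated benchmark to disk
#'
#' Emits the GMT collection, GCT/CLS files for both datasets, and two truth
#' TSVs (`truth_sets.tsv`: set, is_true, is_decoy; `truth_genes.tsv`: gene,
#' f, is_hub, is_signal).
#'
#' @param sim A `sim_collection`.
#' @param pair A dataset pair from [simulate_dataset_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(sim$collection, file.path(dir, "collection.gmt"))
  write_gct(pair$dataset_a, file.path(dir, "dataset_a.gct"))
  write_gct(pair$dataset_b, file.path(dir, "dataset_b.gct"))
  write_cls(pair$dataset_a$phenotype, file.path(dir, "dataset_a.cls"))
  write_cls(pair$dataset_b$phenotype, file.path(dir, "dataset_b.cls"))
  readr::write_tsv(sim$truth_sets, file.path(dir, "truth_sets.tsv"))
  genes <- sim$freq_truth
  genes$is_hub <- genes$gene %in% sim$hub_genes
  genes$is_signal <- genes$gene %in% sim$signal_genes$gene
  readr::write_tsv(genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
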