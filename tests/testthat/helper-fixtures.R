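# Shared fixture builders (everything is generated in code; no binary files).

toy_collection <- function() {
  gene_set_tbl(tibble::tibble(
    set = rep(c("A", "B"), c(2, 2)),
    gene = c("g1", "g2", "g2", "g3")
  ))
}

# Small deterministic two-class dataset with one planted up-shifted block.
toy_dataset <- function(n_genes = 60, n_per_class = 5, shift_genes = character(0),
                        delta = 2, seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes, 2 * n_per_class,
              dimnames = list(genes, paste0("s", seq_len(2 * n_per_class))))
  cls <- rep(c("A", "B"), each = n_per_class)
  m[genes %in% shift_genes, cls == "B"] <-
    m[genes %in% shift_genes, cls == "B"] + delta
  expression_dataset(m, cls)
}

# Independent brute-force enrichment score: explicit walk down the ranked
# list, tracking the extremum, first occurrence winning ties within a sign,
# earlier rank winning an exact cross-sign magnitude tie. Written before and
# independently of the package's position-based computation.
brute_force_es <- function(scores, is_member, exponents) {
  n <- length(scores)
  nh <- sum(is_member)
  nr <- sum(abs(scores[is_member])^exponents[is_member])
  running <- 0
  best_pos <- 0
  best_pos_rank <- Inf
  best_neg <- 0
  best_neg_rank <- Inf
  for (i in seq_len(n)) {
    if (is_member[i]) {
      running <- running + abs(scores[i])^exponents[i] / nr
    } else {
      running <- running - 1 / (n - nh)
    }
    if (running > best_pos) {
      best_pos <- running
      best_pos_rank <- i
    }
    if (running < best_neg) {
      best_neg <- running
      best_neg_rank <- i
    }
  }
  # compare magnitudes with a small epsilon: sequential accumulation can
  # break an exact rational tie by one ulp
  if (abs(best_pos) - abs(best_neg) > 1e-9) return(best_pos)
  if (abs(best_neg) - abs(best_pos) > 1e-9) return(best_neg)
  if (best_pos_rank <= best_neg_rank) best_pos else best_neg
}

# Random small ES instance: ranked scores (descending, distinct), a random
# member subset, random exponents.
random_es_instance <- function(n_max = 20, exp_range = c(0.5, 2)) {
  n <- sample(3:n_max, 1)
  scores <- sort(round(runif(n, -1, 1), 6), decreasing = TRUE)
  nh <- sample(seq_len(n - 1), 1)
  members <- sort(sample.int(n, nh))
  exponents <- runif(n, exp_range[1], exp_range[2])
  list(n = n, scores = scores, members = members, exponents = exponents)
}
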