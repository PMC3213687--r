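#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated gene-set format used by GSEA and MSigDB: one set
#' per line, fields `name`, `description`, then one gene identifier per field.
#' The collection is returned in long ("tidy") form, one row per
#' (set, gene) membership, preserving file order.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description`, `gene` and class
#'   `gene_set_tbl`. Duplicate genes within a line are dropped with a warning.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("A\tfirst\tg1\tg2", "B\tsecond\tg2"), gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("GMT file is empty: ", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3)
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed GMT line ", bad[1], " in ", path,
      ": expected at least 3 tab-separated fields (name, description, gene), got ",
      n_fields[bad[1]]
    ))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    dup <- names_[duplicated(names_)][1]
    abort(paste0("Duplicate set name in GMT file: '", dup, "'"))
  }
  rows <- purrr::map2(fields, seq_along(fields), function(f, i) {
    genes <- f[-c(1, 2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(paste0(
        "Set '", f[[1]], "' (line ", i, ") lists duplicate genes; de-duplicated."
      ))
      genes <- unique(genes)
    }
    tibble(set = f[[1]], description = f[[2]], gene = genes)
  })
  new_gene_set_tbl(dplyr::bind_rows(rows))
}

#' Construct a gene-set collection from a long tibble
#'
#' @param x A data frame with columns `set`, `gene` and optionally
#'   `description` (one row per membership).
#' @return A validated `gene_set_tbl` tibble.
#' @export
gene_set_tbl <- function(x) {
  x <- as_tibble(x)
  if (!all(c("set", "gene") %in% names(x))) {
    abort("A gene-set collection needs columns `set` and `gene`.")
  }
  if (!"description" %in% names(x)) {
    x$description <- ""
  }
  x <- dplyr::select(x, "set", "description", "gene")
  if (anyDuplicated(x[c("set", "gene")])) {
    abort("Duplicate (set, gene) memberships in collection.")
  }
  if (nrow(x) == 0) {
    abort("A gene-set collection must contain at least one membership.")
  }
  new_gene_set_tbl(x)
}

new_gene_set_tbl <- function(x) {
  class(x) <- c("gene_set_tbl", class(x))
  x
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_tbl` (or any tibble with `set`,
#'   `description`, `gene` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(all(c("set", "gene") %in% names(collection)))
  if (!"description" %in% names(collection)) collection$description <- ""
  split_idx <- split(seq_len(nrow(collection)),
                     factor(collection$set, levels = unique(collection$set)))
  lines <- vapply(split_idx, function(i) {
    paste(c(collection$set[i[1]], collection$description[i[1]],
            collection$gene[i]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a gene universe and a minimum set size
#'
#' Sets are intersected with `universe`; sets with fewer surviving genes than
#' `min_size` are dropped with a message.
#'
#' @param collection A `gene_set_tbl`.
#' @param universe Character vector of gene identifiers to keep.
#' @param min_size Minimum surviving set size (default 10).
#' @return The filtered collection.
#' @export
restrict_collection <- function(collection, universe, min_size = 10) {
  out <- dplyr::filter(collection, .data$gene %in% universe)
  sizes <- dplyr::count(out, .data$set)
  drop <- sizes$set[sizes$n < min_size]
  lost <- setdiff(unique(collection$set), sizes$set)
  drop <- union(drop, lost)
  if (length(drop) > 0) {
    inform(paste0(
      length(drop), " set(s) dropped (fewer than ", min_size,
      " genes in the dataset): ", paste(head(drop, 5), collapse = ", "),
      if (length(drop) > 5) ", ..." else ""
    ))
    out <- dplyr::filter(out, !.data$set %in% drop)
  }
  if (nrow(out) == 0) abort("No gene set survives the size filter.")
  new_gene_set_tbl(as_tibble(out))
}

#' Per-gene appearance frequency across a collection
#'
#' The appearance frequency \eqn{f_i} of gene \eqn{i} is the number of
#' distinct sets that contain it -- the "document frequency" of the
#' pathway-as-document analogy. Genes absent from every set do not appear in
#' the table.
#'
#' @param collection A `gene_set_tbl`.
#' @return A tibble with columns `gene`, `f`, sorted by gene; carries
#'   attribute `n_pathways` (number of sets in the collection).
#' @examples
#' coll <- gene_set_tbl(tibble::tibble(
#'   set = c("A", "A", "B", "B"), gene = c("g1", "g2", "g2", "g3")
#' ))
#' appearance_frequency(coll)
#' @export
appearance_frequency <- function(collection) {
  if (nrow(collection) == 0) abort("Empty collection.")
  out <- collection |>
    dplyr::distinct(.data$set, .data$gene) |>
    dplyr::count(.data$gene, name = "f") |>
    dplyr::arrange(.data$gene)
  attr(out, "n_pathways") <- length(unique(collection$set))
  out
}
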