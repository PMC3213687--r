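#' Construct a two-class expression dataset
#'
#' Bundles a genes-by-samples expression matrix with a two-class phenotype
#' vector. All downstream ranking and testing assumes exactly two phenotype
#' classes with at least two samples each.
#'
#' @param exprs Numeric matrix, genes in rows (unique rownames), samples in
#'   columns. No missing values are allowed; imputation is out of scope.
#' @param phenotype Character or factor of length `ncol(exprs)` with exactly
#'   two levels, in sample (column) order.
#' @return An object of class `expression_dataset`: a list with elements
#'   `exprs`, `phenotype` (factor), `classes` (the two level names, in order
#'   of first appearance).
#' @export
expression_dataset <- function(exprs, phenotype) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs))) abort("`exprs` needs gene identifiers as rownames.")
  if (anyDuplicated(rownames(exprs))) abort("Duplicate gene identifiers in `exprs`.")
  if (anyNA(exprs)) abort("Expression matrix contains missing values.")
  if (length(phenotype) != ncol(exprs)) {
    abort(paste0(
      "Phenotype length (", length(phenotype),
      ") does not match the number of samples (", ncol(exprs), ")."
    ))
  }
  classes <- unique(as.character(phenotype))
  if (length(classes) != 2) {
    abort(paste0("Exactly two phenotype classes required, got ", length(classes), "."))
  }
  phenotype <- factor(as.character(phenotype), levels = classes)
  if (any(table(phenotype) < 2)) {
    abort("Each phenotype class needs at least two samples.")
  }
  structure(
    list(exprs = exprs, phenotype = phenotype, classes = classes),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$phenotype)
  cat("<expression_dataset> ", nrow(x$exprs), " genes x ", ncol(x$exprs),
      " samples (", x$classes[1], ": ", tab[1], ", ", x$classes[2], ": ",
      tab[2], ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$exprs)

#' Read an expression matrix from a GCT file
#'
#' GCT (v1.2) layout: line 1 `#1.2`, line 2 `<n_genes>\t<n_samples>`, line 3
#' the header (`Name`, `Description`, sample names), then one row per gene.
#'
#' @param path Path to a GCT file.
#' @return A numeric matrix (genes x samples) with gene rownames; the
#'   `Description` column is kept as attribute `description`.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort(paste0("GCT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    abort("Not a GCT v1.2 file: first line must be '#1.2'.")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (length(dims) < 2 || anyNA(dims)) abort("GCT dimensions line is malformed.")
  body <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(body) != dims[1]) {
    abort(paste0("GCT declares ", dims[1], " genes but has ", nrow(body), " rows."))
  }
  if (ncol(body) - 2 != dims[2]) {
    abort(paste0("GCT declares ", dims[2], " samples but has ", ncol(body) - 2,
                 " sample columns."))
  }
  if (anyDuplicated(body[[1]])) abort("Duplicate gene Name in GCT file.")
  m <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- body[[1]]
  attr(m, "description") <- body[[2]]
  m
}

#' Write an expression matrix to a GCT file
#'
#' @param exprs Numeric matrix with gene rownames (or an
#'   `expression_dataset`, whose matrix part is written).
#' @param path Output path.
#' @param description Optional per-gene description column (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gct <- function(exprs, path, description = NULL) {
  if (inherits(exprs, "expression_dataset")) exprs <- exprs$exprs
  description <- description %||% rep("na", nrow(exprs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(exprs), ncol(exprs), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(exprs)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(exprs), description,
                format(exprs, trim = TRUE, digits = 17))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read two-class phenotype labels from a categorical CLS file
#'
#' Layout: line 1 `<n_samples> <n_classes> 1`, line 2 `# <name1> <name2>`,
#' line 3 the per-sample labels (either the class names or 0/1 codes, which
#' are mapped to the declared names in order).
#'
#' @param path Path to a CLS file.
#' @return Character vector of per-sample class labels.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) abort(paste0("CLS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("CLS file needs three lines (counts, names, labels).")
  counts <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  if (length(counts) < 2 || anyNA(counts[1:2])) {
    abort("CLS counts line is malformed; numeric (continuous) CLS is not supported.")
  }
  n_samples <- counts[1]
  n_classes <- counts[2]
  if (n_classes != 2) {
    abort(paste0("Two-class design required; CLS declares ", n_classes, " classes."))
  }
  name_fields <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (name_fields[1] != "#") abort("CLS class-name line must start with '#'.")
  class_names <- name_fields[-1]
  if (length(class_names) != 2) abort("CLS must declare exactly two class names.")
  labels <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  if (length(labels) != n_samples) {
    abort(paste0("CLS declares ", n_samples, " samples but lists ",
                 length(labels), " labels."))
  }
  if (all(labels %in% c("0", "1"))) {
    labels <- class_names[as.integer(labels) + 1]
  }
  if (!all(labels %in% class_names)) {
    abort("CLS labels include values outside the declared class names.")
  }
  labels
}

#' Write two-class phenotype labels to a categorical CLS file
#'
#' @param phenotype Character/factor vector of per-sample labels (two classes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(phenotype, path) {
  phenotype <- as.character(phenotype)
  classes <- unique(phenotype)
  if (length(classes) != 2) abort("Exactly two classes required.")
  writeLines(c(
    paste(length(phenotype), 2, 1),
    paste("#", classes[1], classes[2]),
    paste(phenotype, collapse = " ")
  ), path)
  invisible(path)
}

#' Read a GCT + CLS pair into an expression dataset
#'
#' @param gct Path to the GCT expression file.
#' @param cls Path to the CLS phenotype file.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(gct, cls) {
  m <- read_gct(gct)
  labels <- read_cls(cls)
  expression_dataset(m, labels)
}
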