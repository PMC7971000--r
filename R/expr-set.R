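#' Expression set: a gene x sample matrix with sample metadata
#'
#' Lightweight container pairing a non-negative numeric matrix (TPM or
#' calibrated ratio units) with a sample-metadata table. Row names are gene
#' ids; columns are samples described one-per-row in `samples`.
#'
#' @param values numeric matrix, genes x samples, non-negative, unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param samples data.frame with one row per column of `values`; must
#'   contain columns `sample`, `species`, `sex` (one of "male", "female",
#'   "monoecious"), `tissue`, `replicate`.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `samples`.
#' @export
expr_set <- function(values, samples) {
  values <- as.matrix(values)
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    stop("expression matrix must have unique gene ids as rownames")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "species", "sex", "tissue", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample metadata rows (", nrow(samples),
         ") do not match matrix columns (", ncol(values), ")")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!identical(colnames(values), as.character(samples$sample))) {
    stop("matrix colnames do not match samples$sample")
  }
  bad_sex <- setdiff(unique(samples$sex), c("male", "female", "monoecious"))
  if (length(bad_sex) > 0) {
    stop("unknown sex levels: ", paste(bad_sex, collapse = ", "))
  }
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("  sex:    ", paste(unique(x$samples$sex), collapse = ", "), "\n")
  cat("  tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Subset an expression set by genes and/or samples
#'
#' @param x an `expr_set`.
#' @param genes character vector of gene ids (or logical/integer index).
#' @param samples_keep character vector of sample ids (or index).
#' @return A new `expr_set`.
#' @export
subset_expr <- function(x, genes = NULL, samples_keep = NULL) {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  s <- x$samples
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples_keep)) {
    if (is.character(samples_keep)) {
      idx <- match(samples_keep, colnames(v))
      if (anyNA(idx)) stop("unknown sample ids")
    } else {
      idx <- samples_keep
    }
    v <- v[, idx, drop = FALSE]
    s <- s[idx, , drop = FALSE]
  }
  expr_set(v, s)
}
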