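#' Gene-by-sample expression container
#'
#' Light container used across the package: a gene x sample matrix (dense
#' `matrix` or sparse [Matrix::dgCMatrix-class]) carrying a layer tag naming
#' the transformation that produced it, plus per-sample metadata.
#'
#' The `counts` layer is raw (integer) counts; `TPM` is length-normalised
#' expression summing to 1e6 per sample; `log2TPM` is thresholded log2 TPM;
#' `lognorm` is depth-normalised natural-log expression; `scaled` holds
#' covariate-regressed z-scores.
#'
#' @param values gene x sample numeric matrix with row and column names.
#' @param layer one of `"counts"`, `"TPM"`, `"log2TPM"`, `"lognorm"`,
#'   `"scaled"`.
#' @param sample_meta optional `data.frame`, one row per sample (matched by
#'   row name or order). Columns `total` and `n_genes` are (re)computed from
#'   the matrix when `layer == "counts"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, layer = c("counts", "TPM", "log2TPM",
                                                "lognorm", "scaled"),
                              sample_meta = NULL) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in expression matrix")
  if (layer %in% c("counts", "TPM") && min_value(values) < 0)
    stop(sprintf("negative values are not allowed in the %s layer", layer))
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(row.names = colnames(values))
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != ncol(values))
      stop("sample_meta must have one row per sample")
    rownames(sample_meta) <- colnames(values)
  }
  if (layer == "counts") {
    sample_meta$total <- as.numeric(Matrix::colSums(values))
    sample_meta$n_genes <- as.integer(Matrix::colSums(values > 0))
  }
  structure(list(values = values, layer = layer, sample_meta = sample_meta),
            class = "ExpressionMatrix")
}

min_value <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    xs <- methods::as(x, "CsparseMatrix")@x
    if (length(xs) == 0) 0 else min(0, min(xs))
  } else min(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [layer: %s, %s]\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  if (ncol(x$sample_meta) > 0)
    cat("sample_meta:", paste(colnames(x$sample_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x an `ExpressionMatrix`.
#' @param i gene index (names, logical or integer).
#' @param j sample index.
#' @param ... unused.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  meta <- x$sample_meta[colnames(v), , drop = FALSE]
  structure(list(values = v, layer = x$layer, sample_meta = meta),
            class = "ExpressionMatrix")
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
em_values <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$values
}

#' @rdname expression_matrix
#' @export
em_layer <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$layer
}

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

assert_layer <- function(x, layers) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$layer %in% layers)
    stop(sprintf("expected layer %s, got '%s'",
                 paste(sQuote(layers), collapse = " or "), x$layer))
  invisible(x)
}

as_dense <- function(v) {
  if (methods::is(v, "sparseMatrix")) as.matrix(v) else v
}
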