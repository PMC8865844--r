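#' Transcripts-per-million from raw counts
#'
#' Length-normalised rates `count/length` are rescaled per sample to sum to
#' one million.
#'
#' @param counts an `ExpressionMatrix` on the `counts` layer.
#' @param gene_lengths numeric vector of transcript lengths in bp, named by
#'   gene or in matrix row order; all > 0.
#' @return an `ExpressionMatrix` on the `TPM` layer.
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  assert_layer(counts, "counts")
  v <- as_dense(counts$values)
  if (!is.null(names(gene_lengths))) {
    miss <- setdiff(rownames(v), names(gene_lengths))
    if (length(miss))
      stop("gene lengths missing for: ", paste(utils::head(miss, 5),
                                               collapse = ", "))
    gene_lengths <- gene_lengths[rownames(v)]
  }
  stopifnot(length(gene_lengths) == nrow(v), all(gene_lengths > 0))
  rate <- v / gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(v)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, `/`) * 1e6
  expression_matrix(tpm, "TPM", counts$sample_meta)
}

#' Thresholded log2 TPM
#'
#' Values with TPM > 1 become `log2(TPM)`; values <= 1 are set to 0, so the
#' transform maps the noise floor to zero and is continuous at TPM = 1.
#'
#' @param tpm an `ExpressionMatrix` on the `TPM` layer.
#' @return an `ExpressionMatrix` on the `log2TPM` layer.
#' @export
log2_tpm_threshold <- function(tpm) {
  assert_layer(tpm, "TPM")
  v <- as_dense(tpm$values)
  out <- ifelse(v > 1, log2(pmax(v, 1)), 0)
  dimnames(out) <- dimnames(v)
  expression_matrix(out, "log2TPM", tpm$sample_meta)
}

#' Depth log-normalisation of UMI counts
#'
#' `x -> ln(1 + scale_factor * x / column_total)`, the standard single-cell
#' normalisation with a fixed pseudo-depth.
#'
#' @param counts an `ExpressionMatrix` on the `counts` layer with nonzero
#'   column totals.
#' @param scale_factor pseudo-depth (default 10,000).
#' @return an `ExpressionMatrix` on the `lognorm` layer (sparse in, sparse
#'   out).
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  assert_layer(counts, "counts")
  v <- counts$values
  tot <- as.numeric(Matrix::colSums(v))
  if (any(tot == 0))
    stop("zero-total column(s): ",
         paste(colnames(v)[tot == 0], collapse = ", "))
  if (methods::is(v, "sparseMatrix")) {
    v <- methods::as(v, "CsparseMatrix")
    out <- v %*% Matrix::Diagonal(ncol(v), scale_factor / tot)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(v)
  } else {
    out <- log1p(sweep(v, 2, tot / scale_factor, `/`))
  }
  expression_matrix(out, "lognorm", counts$sample_meta)
}

#' Remove samples outside per-specimen depth bounds
#'
#' Depth filters differ by platform and specimen (e.g. minimum grid read
#' coverage, UMI floors for nuclei, a UMI window for amoebae), so the rule
#' is a per-specimen table of inclusive `(min, max)` bounds on the total
#' counts of each sample.
#'
#' @param matrix an `ExpressionMatrix` whose `sample_meta` carries `total`
#'   (and `specimen` when per-specimen rules are used).
#' @param rule either `c(min, max)` applied to all samples, or a data.frame
#'   with columns `specimen`, `min`, `max`.
#' @return the filtered `ExpressionMatrix`; the number of removed samples is
#'   reported per specimen via `message()`.
#' @export
filter_samples_by_depth <- function(matrix, rule) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  tot <- matrix$sample_meta$total
  if (is.null(tot)) tot <- as.numeric(Matrix::colSums(matrix$values))
  if (is.data.frame(rule)) {
    stopifnot(all(c("specimen", "min", "max") %in% names(rule)))
    spec <- matrix$sample_meta$specimen
    if (is.null(spec)) stop("per-specimen rule but no specimen metadata")
    unknown <- setdiff(rule$specimen, unique(spec))
    if (length(unknown))
      stop("rule references unknown specimen(s): ",
           paste(unknown, collapse = ", "))
    keep <- rep(TRUE, length(tot))
    for (k in seq_len(nrow(rule))) {
      in_spec <- spec == rule$specimen[k]
      keep[in_spec] <- tot[in_spec] >= rule$min[k] & tot[in_spec] <= rule$max[k]
    }
  } else {
    stopifnot(is.numeric(rule), length(rule) == 2)
    keep <- tot >= rule[1] & tot <= rule[2]
  }
  message(sprintf("filter_samples_by_depth: removed %d of %d samples",
                  sum(!keep), length(keep)))
  matrix[, keep]
}

#' Keep only annotated transcripts
#'
#' A transcript is retained when its annotation row has a nonempty UniProt
#' id or a nonempty description; transcripts absent from the annotation are
#' treated as unannotated and counted in the message.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param annotation data.frame with columns `transcript_id`, `uniprot_id`,
#'   `description`.
#' @return the filtered `ExpressionMatrix`, original gene order preserved.
#' @export
filter_annotated_genes <- function(matrix, annotation) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            all(c("transcript_id", "uniprot_id", "description") %in%
                  names(annotation)))
  nonempty <- function(x) !is.na(x) & trimws(as.character(x)) != ""
  ok_ids <- annotation$transcript_id[nonempty(annotation$uniprot_id) |
                                       nonempty(annotation$description)]
  genes <- gene_ids(matrix)
  keep <- genes %in% ok_ids
  n_absent <- sum(!genes %in% annotation$transcript_id)
  message(sprintf(
    "filter_annotated_genes: kept %d of %d transcripts (%d absent from annotation)",
    sum(keep), length(keep), n_absent))
  matrix[keep, ]
}

#' Covariate-regression scaling
#'
#' Per gene, ordinary-least-squares residuals against per-sample covariates
#' (detected-gene and total-count regression by default, with intercept),
#' z-scored across samples and clipped. Constant genes scale to a row of
#' zeros.
#'
#' @param matrix an `ExpressionMatrix` on the `lognorm` or `log2TPM` layer.
#' @param covariates character vector of `sample_meta` columns to regress
#'   out (default `c("n_genes", "total")`).
#' @param clip symmetric clipping bound of the z-scores (default 10).
#' @return an `ExpressionMatrix` on the `scaled` layer (dense).
#' @export
scale_with_regression <- function(matrix, covariates = c("n_genes", "total"),
                                  clip = 10) {
  assert_layer(matrix, c("lognorm", "log2TPM"))
  miss <- setdiff(covariates, colnames(matrix$sample_meta))
  if (length(miss))
    stop("covariates missing from sample_meta: ", paste(miss, collapse = ", "))
  v <- as_dense(matrix$values)
  X <- cbind(intercept = 1,
             as.matrix(matrix$sample_meta[, covariates, drop = FALSE]))
  # drop constant covariates (would make X singular)
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                            function(z) stats::sd(z) > 0))
  X <- X[, keep_col, drop = FALSE]
  qr_x <- qr(X)
  resid <- t(qr.resid(qr_x, t(v)))
  s <- apply(resid, 1, stats::sd)
  # genes fully absorbed by the covariates (or constant) scale to zeros;
  # the tolerance is relative to the gene's original spread
  s0 <- apply(v, 1, stats::sd)
  absorbed <- !is.finite(s) | s <= 1e-8 * s0 | s0 == 0
  resid[absorbed, ] <- 0
  s[absorbed] <- Inf
  out <- resid / s
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  dimnames(out) <- dimnames(v)
  expression_matrix(out, "scaled", matrix$sample_meta)
}
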