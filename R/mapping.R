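#' Pseudobulk profiles per cluster
#'
#' Arithmetic mean of each gene's normalised expression across the samples
#' of every cluster.
#'
#' @param matrix an `ExpressionMatrix` on the `lognorm` (or `log2TPM`)
#'   layer.
#' @param clusters a `ClusterAssignment` or labels (named by sample or in
#'   column order); every sample must be labelled.
#' @param source tag recorded on the result (`"nuclei"` or `"spatial"`).
#' @return list of class `PseudobulkMatrix`: `means` (gene x cluster),
#'   `n_samples` per cluster, `source`.
#' @export
pseudobulk <- function(matrix, clusters, source = "nuclei") {
  assert_layer(matrix, c("lognorm", "log2TPM"))
  v <- matrix$values
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
  else clusters
  if (!is.null(names(cl))) cl <- cl[colnames(v)]
  stopifnot(length(cl) == ncol(v))
  if (anyNA(cl)) stop("every sample must be clustered")
  labs <- sort(unique(cl))
  n_samples <- integer(0)
  means <- sapply(labs, function(lab) {
    idx <- which(cl == lab)
    if (length(idx) == 0) stop("empty cluster: ", lab)
    n_samples[as.character(lab)] <<- length(idx)
    as.numeric(Matrix::rowMeans(v[, idx, drop = FALSE]))
  })
  rownames(means) <- rownames(v)
  colnames(means) <- as.character(labs)
  structure(list(means = means, n_samples = n_samples, source = source),
            class = "PseudobulkMatrix")
}

#' @export
print.PseudobulkMatrix <- function(x, ...) {
  cat(sprintf("PseudobulkMatrix (%s): %d genes x %d clusters\n",
              x$source, nrow(x$means), ncol(x$means)))
  invisible(x)
}

scale_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Project nuclei clusters onto spatial clusters by pseudobulk correlation
#'
#' Restricts both pseudobulk matrices to the union of the top `top_n`
#' marker genes per spatial cluster, computes Spearman correlation between
#' every (nuclei cluster, spatial cluster) pair, then z-scales the matrix
#' first by column and then by row and clips to [-1, 1]. Nuclei clusters
#' are hierarchically clustered (Ward on 1 - Pearson of the scaled rows).
#'
#' @param nuclei_pb,spatial_pb [pseudobulk()] results.
#' @param spatial_markers a `MarkerTable` from the spatial dataset.
#' @param top_n markers per spatial cluster (default 50); fewer available
#'   markers are used with a warning.
#' @return list of class `CorrelationMap`: `raw`, `scaled` (nuclei x
#'   spatial), `marker_genes`, `dendrogram` (hclust of nuclei clusters, NULL
#'   for < 3 clusters).
#' @export
map_clusters <- function(nuclei_pb, spatial_pb, spatial_markers, top_n = 50) {
  stopifnot(inherits(nuclei_pb, "PseudobulkMatrix"),
            inherits(spatial_pb, "PseudobulkMatrix"))
  genes_common <- intersect(rownames(nuclei_pb$means),
                            rownames(spatial_pb$means))
  sel <- character(0)
  for (lab in unique(spatial_markers$cluster)) {
    mk <- spatial_markers[spatial_markers$cluster == lab, ]
    mk <- mk[order(mk$p_adj, mk$p), ]
    avail <- mk$gene[mk$gene %in% genes_common]
    if (length(avail) < top_n)
      warning(sprintf("cluster %s: only %d of %d markers available",
                      lab, length(avail), top_n))
    sel <- union(sel, utils::head(avail, top_n))
  }
  if (length(sel) < 3) stop("fewer than 3 usable marker genes")
  a <- nuclei_pb$means[sel, , drop = FALSE]
  b <- spatial_pb$means[sel, , drop = FALSE]
  degen_a <- apply(a, 2, stats::sd) == 0
  degen_b <- apply(b, 2, stats::sd) == 0
  raw <- suppressWarnings(stats::cor(a, b, method = "spearman"))
  raw[degen_a, ] <- NA
  raw[, degen_b] <- NA
  scaled <- apply(raw, 2, scale_vec)                   # by column
  scaled <- t(apply(scaled, 1, scale_vec))             # then by row
  dimnames(scaled) <- dimnames(raw)
  scaled[scaled > 1] <- 1
  scaled[scaled < -1] <- -1
  dendro <- NULL
  if (nrow(scaled) >= 3 && all(apply(scaled, 1, stats::sd) > 0))
    dendro <- stats::hclust(stats::as.dist(1 - stats::cor(t(scaled))),
                            method = "ward.D2")
  structure(list(raw = raw, scaled = scaled, marker_genes = sel,
                 dendrogram = dendro),
            class = "CorrelationMap")
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat(sprintf("CorrelationMap: %d nuclei clusters x %d spatial clusters (%d markers)\n",
              nrow(x$raw), ncol(x$raw), length(x$marker_genes)))
  invisible(x)
}

#' Correlate one nuclei-cluster pseudobulk against individual grids
#'
#' Spearman correlation between the chosen nuclei cluster's pseudobulk and
#' every grid's expression over the marker genes. Raw correlations are
#' returned per grid; interpreted as fan or network scores depending on the
#' cluster chosen.
#'
#' @param nuclei_pb a [pseudobulk()] result.
#' @param cluster_id column of `nuclei_pb` to use.
#' @param grid_matrix an `ExpressionMatrix` of grids on a continuous layer.
#' @param marker_genes genes to correlate over (present in both inputs).
#' @return named numeric vector of per-grid Spearman r (NA for grids with
#'   zero variance over the markers, flagged with a warning).
#' @export
grid_scores <- function(nuclei_pb, cluster_id, grid_matrix, marker_genes) {
  stopifnot(inherits(nuclei_pb, "PseudobulkMatrix"),
            inherits(grid_matrix, "ExpressionMatrix"))
  cluster_id <- as.character(cluster_id)
  stopifnot(cluster_id %in% colnames(nuclei_pb$means))
  miss <- setdiff(marker_genes,
                  intersect(rownames(nuclei_pb$means), gene_ids(grid_matrix)))
  if (length(miss))
    stop("marker genes absent from an input: ", paste(miss, collapse = ", "))
  ref <- nuclei_pb$means[marker_genes, cluster_id]
  g <- as_dense(grid_matrix$values)[marker_genes, , drop = FALSE]
  degen <- apply(g, 2, stats::sd) == 0
  if (any(degen))
    warning("grids with zero variance over markers: ",
            paste(colnames(g)[degen], collapse = ", "))
  out <- suppressWarnings(
    as.numeric(stats::cor(ref, g, method = "spearman")))
  out[degen] <- NA
  stats::setNames(out, colnames(g))
}
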