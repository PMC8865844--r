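#' Diffusion-map embedding
#'
#' Gaussian kernel on pairwise Euclidean distances with either a global
#' bandwidth or a local one (distance to the k-th neighbour), density
#' normalisation (anisotropic, alpha = 1) to remove sampling-density
#' effects, and the top nontrivial right eigenvectors of the normalised
#' transition operator. Components carry a deterministic sign (largest
#' |entry| positive) and are invariant to rigid motions of the feature
#' space.
#'
#' @param features samples x dims numeric matrix.
#' @param n_comps number of nontrivial components (default 2).
#' @param kernel_sigma positive bandwidth, or `"local"` (default).
#' @param k neighbour index for the local bandwidth (default
#'   `max(5, ceiling(sqrt(n)))`).
#' @return list with `components` (samples x n_comps), `eigenvalues`.
#' @export
diffusion_map <- function(features, n_comps = 2, kernel_sigma = "local",
                          k = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < n_comps + 1)
    stop("need at least n_comps + 1 samples")
  if (is.null(rownames(features)))
    rownames(features) <- paste0("s", seq_len(n))
  d <- as.matrix(stats::dist(features))
  if (identical(kernel_sigma, "local")) {
    if (is.null(k)) k <- max(5, ceiling(sqrt(n)))
    k <- min(k, n - 1)
    sig <- apply(d, 1, function(row) sort(row)[k + 1])  # row includes self 0
    sig[sig == 0] <- min(sig[sig > 0], 1)
    denom <- outer(sig^2, sig^2, `+`)
  } else {
    stopifnot(is.numeric(kernel_sigma), kernel_sigma > 0)
    denom <- 2 * kernel_sigma^2
  }
  K <- exp(-d^2 / denom)
  # connectivity of the kernel graph
  adj <- K > 1e-12
  diag(adj) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (comp$no > 1)
    stop(sprintf("kernel graph is disconnected (%d components of sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")))
  q <- rowSums(K)
  W <- K / outer(q, q)
  Dw <- rowSums(W)
  A <- W / sqrt(outer(Dw, Dw))
  eig <- eigen(A, symmetric = TRUE)
  # right eigenvectors of the row-normalised operator
  psi <- eig$vectors / sqrt(Dw)
  comps <- psi[, 2:(n_comps + 1), drop = FALSE]
  comps <- apply(comps, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  rownames(comps) <- rownames(features)
  colnames(comps) <- paste0("DC", seq_len(n_comps))
  list(components = comps, eigenvalues = eig$values[2:(n_comps + 1)])
}

#' Block-wise ranking along the first diffusion component
#'
#' Samples are ranked block-by-block following `group_sequence` (the
#' manually ordered groups, e.g. by embedding location); within each block
#' they are sorted by the first diffusion component, whose global direction
#' is chosen so the block medians increase along the sequence. Orderings
#' are defined up to global reversal.
#'
#' @param components matrix from [diffusion_map()] (or a numeric vector of
#'   first-component values, named by sample).
#' @param group_of_sample group label per sample (named by sample or in
#'   component order).
#' @param group_sequence ordered list of group labels; each element may be
#'   a vector of labels forming one block. Must cover all groups; empty
#'   blocks are skipped with a warning.
#' @return list of class `Ordering`: `rank` (named, 0..n-1),
#'   `component_values`, `group_sequence`.
#' @export
order_by_groups <- function(components, group_of_sample, group_sequence) {
  dc1 <- if (is.matrix(components)) components[, 1] else components
  ids <- names(dc1)
  if (is.null(ids)) ids <- paste0("s", seq_along(dc1))
  names(dc1) <- ids
  grp <- group_of_sample
  if (!is.null(names(grp))) grp <- grp[ids]
  stopifnot(length(grp) == length(dc1))
  if (anyNA(grp)) stop("every sample must be grouped")
  if (!is.list(group_sequence)) group_sequence <- as.list(group_sequence)
  seq_labs <- unlist(group_sequence)
  not_cov <- setdiff(unique(as.character(grp)), as.character(seq_labs))
  if (length(not_cov))
    stop("group_sequence does not cover group(s): ",
         paste(not_cov, collapse = ", "))
  blocks <- lapply(group_sequence, function(labels)
    ids[as.character(grp) %in% as.character(labels)])
  empty <- lengths(blocks) == 0
  if (any(empty)) {
    warning(sprintf("skipping %d empty group(s) in the sequence", sum(empty)))
    blocks <- blocks[!empty]
  }
  direction <- 1
  if (length(blocks) > 1) {
    med <- vapply(blocks, function(b) stats::median(dc1[b]), numeric(1))
    rho <- suppressWarnings(stats::cor(med, seq_along(med),
                                       method = "spearman"))
    if (is.finite(rho) && rho < 0) direction <- -1
  }
  ordered_ids <- unlist(lapply(blocks, function(b)
    b[order(direction * dc1[b])]))
  rank <- stats::setNames(seq_along(ordered_ids) - 1L, ordered_ids)[ids]
  structure(list(rank = rank, component_values = dc1,
                 group_sequence = group_sequence),
            class = "Ordering")
}

#' @export
print.Ordering <- function(x, ...) {
  cat(sprintf("Ordering: %d samples over %d blocks\n",
              length(x$rank), length(x$group_sequence)))
  invisible(x)
}

#' Smoothed expression trends along an ordering
#'
#' Locally weighted regression (LOESS) of each gene's expression on the
#' pseudotime rank, evaluated on the rank grid. The default smoothing
#' window mirrors a bandwidth of ~10 rank units scaled to a fraction:
#' `span = max(0.3, 10/n)`.
#'
#' @param matrix an `ExpressionMatrix` containing the ordered samples.
#' @param ordering an [order_by_groups()] result.
#' @param genes genes to smooth (must be present).
#' @param span LOESS span in (0, 1]; `NULL` uses the default above.
#' @return list with `ranks` (sorted) and `curves` (gene x rank matrix).
#' @export
expression_trends <- function(matrix, ordering, genes, span = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(ordering, "Ordering"))
  miss <- setdiff(genes, gene_ids(matrix))
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  ids <- intersect(names(ordering$rank), sample_ids(matrix))
  n <- length(ids)
  if (n < 10) stop("need at least 10 ordered samples")
  if (is.null(span)) span <- max(0.3, 10 / n)
  if (span * n < 3) stop("span yields smoothing windows of fewer than 3 points")
  rk <- sort(ordering$rank[ids])
  v <- as_dense(matrix$values)[genes, names(rk), drop = FALSE]
  curves <- t(vapply(genes, function(g) {
    fit <- stats::loess(v[g, ] ~ rk, span = span, degree = 2,
                        family = "gaussian")
    stats::predict(fit, newdata = data.frame(rk = as.numeric(rk)))
  }, numeric(n)))
  colnames(curves) <- names(rk)
  list(ranks = rk, curves = curves, span = span)
}

#' Pseudospatial ordering of grids along the mitotic wave
#'
#' Applies the same diffusion + block-ranking machinery to spatial grids:
#' a diffusion map over the grids' expression of phase-marker genes, with
#' blocks given by the grid clusters ordered by their mean G2/M-marker
#' expression.
#'
#' @param grid_matrix an `ExpressionMatrix` of grids (continuous layer).
#' @param grid_clusters a `ClusterAssignment` or label vector over grids.
#' @param marker_genes phase-marker genes used as diffusion features.
#' @param g2m_genes genes whose mean orders the blocks (default
#'   `marker_genes`).
#' @param n_comps diffusion components (default 2).
#' @return an `Ordering` over grids.
#' @export
pseudospatial_order <- function(grid_matrix, grid_clusters, marker_genes,
                                g2m_genes = marker_genes, n_comps = 2) {
  stopifnot(inherits(grid_matrix, "ExpressionMatrix"))
  v <- as_dense(grid_matrix$values)
  miss <- setdiff(union(marker_genes, g2m_genes), rownames(v))
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  cl <- if (inherits(grid_clusters, "ClusterAssignment")) grid_clusters$cluster
  else grid_clusters
  if (!is.null(names(cl))) cl <- cl[colnames(v)]
  stopifnot(length(cl) == ncol(v))
  dm <- diffusion_map(t(v[marker_genes, , drop = FALSE]), n_comps = n_comps)
  g2m <- colMeans(v[g2m_genes, , drop = FALSE])
  block_means <- tapply(g2m, cl, mean)
  seq_blocks <- as.list(names(sort(block_means)))
  order_by_groups(dm$components, stats::setNames(as.character(cl),
                                                 colnames(v)), seq_blocks)
}
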