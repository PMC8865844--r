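#' Principal components of a scaled expression matrix
#'
#' PCA over samples (genes as features) with a deterministic sign
#' convention: the loading of largest magnitude on every component is made
#' positive, so repeated runs agree exactly.
#'
#' @param matrix an `ExpressionMatrix` on the `scaled` layer, or a plain
#'   samples x features numeric matrix.
#' @param n_pcs number of components, at most `min(genes, samples)`.
#' @return list with `scores` (samples x PCs), `loadings`
#'   (features x PCs), `sdev` and `var_explained` (fractions).
#' @export
run_pca <- function(matrix, n_pcs = 10) {
  if (inherits(matrix, "ExpressionMatrix")) {
    assert_layer(matrix, "scaled")
    x <- t(as_dense(matrix$values))
  } else {
    x <- as.matrix(matrix)
  }
  if (n_pcs > min(dim(x)))
    stop(sprintf("n_pcs = %d exceeds min(samples, features) = %d",
                 n_pcs, min(dim(x))))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  var_all <- pc$sdev^2
  list(scores = scores, loadings = loadings, sdev = pc$sdev[seq_len(k)],
       var_explained = var_all[seq_len(k)] / sum(var_all))
}

snn_graph <- function(scores, k_neighbors, prune = 1 / 15) {
  n <- nrow(scores)
  stopifnot(k_neighbors < n)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  # include self in the neighbour set (standard SNN construction)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  edges <- list(); wts <- numeric(0)
  for (i in seq_len(n)) {
    cand <- unique(c(nn[i, ], which(apply(nn, 1, function(r) i %in% r))))
    cand <- cand[cand > i]
    for (j in cand) {
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      if (jac >= prune) {
        edges[[length(edges) + 1]] <- c(i, j)
        wts <- c(wts, jac)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  igraph::E(g)$weight <- wts
  g
}

#' Graph-based (Louvain) clustering of samples
#'
#' Builds a shared-nearest-neighbour graph (Jaccard weights over the
#' k-nearest-neighbour sets, weak links pruned) and runs Louvain modularity
#' community detection at the given resolution. A fixed seed makes the
#' partition reproducible. Labels are contiguous integers from 0, ordered by
#' decreasing cluster size.
#'
#' @param scores samples x dims numeric matrix (e.g. PC scores).
#' @param k_neighbors neighbours for the SNN graph (< n samples).
#' @param resolution Louvain resolution; smaller merges clusters.
#' @param seed RNG seed for the community search.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return list of class `ClusterAssignment`: `cluster` (named integer
#'   vector), `method`, `parameters`.
#' @export
cluster_graph <- function(scores, k_neighbors = 20, resolution = 1,
                          seed = 0, prune = 1 / 15) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("s", seq_len(nrow(scores)))
  if (max(stats::dist(scores)) == 0)
    stop("degenerate input: all samples identical")
  g <- snn_graph(scores, k_neighbors, prune)
  comm <- with_seed_local(seed,
                          igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  relab <- stats::setNames(seq_along(sizes) - 1L,
                           names(sort(sizes, decreasing = TRUE)))
  cl <- relab[as.character(memb)]
  structure(list(cluster = stats::setNames(as.integer(cl), rownames(scores)),
                 method = "graph",
                 parameters = list(k_neighbors = k_neighbors,
                                   resolution = resolution, seed = seed)),
            class = "ClusterAssignment")
}

#' Hierarchical (Ward) clustering on correlation distances
#'
#' Distance `1 - Pearson(i, j)` between samples, Ward linkage
#' (`hclust` `ward.D2`). The tree is cut either at a user `k` or at the
#' largest gap in merge heights.
#'
#' @param x an `ExpressionMatrix` (samples = columns) or a samples x
#'   features numeric matrix.
#' @param k number of clusters; `NULL` picks the largest merge-height gap.
#' @return list of class `ClusterAssignment` with `cluster` (0-based,
#'   decreasing size), `method`, `parameters` and the `hclust` tree.
#' @export
cluster_hierarchical <- function(x, k = NULL) {
  if (inherits(x, "ExpressionMatrix")) {
    m <- t(as_dense(x$values))   # samples x genes
  } else {
    m <- as.matrix(x)
  }
  stopifnot(nrow(m) >= 2)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s), correlation undefined: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "ward.D2")
  if (is.null(k)) {
    h <- hc$height
    k <- if (length(h) >= 2) {
      gaps <- diff(h)
      nrow(m) - which.max(gaps)   # cut below the largest gap
    } else 2
    k <- max(2, min(k, nrow(m)))
  }
  memb <- stats::cutree(hc, k = k)
  sizes <- table(memb)
  relab <- stats::setNames(seq_along(sizes) - 1L,
                           names(sort(sizes, decreasing = TRUE)))
  cl <- relab[as.character(memb)]
  structure(list(cluster = stats::setNames(as.integer(cl), rownames(m)),
                 method = "hierarchical",
                 parameters = list(k = k, linkage = "ward.D2",
                                   distance = "1 - Pearson"),
                 tree = hc),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment (%s): %d samples in %d clusters\n",
              x$method, length(x$cluster), length(unique(x$cluster))))
  print(table(cluster = x$cluster))
  invisible(x)
}
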