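#' Sampling-grid layout
#'
#' Regular layout of square sampling grids: each grid has a (row, col)
#' index, a centre in um, and an inclusion flag (grids without clear overlap
#' with the organism are excluded by the user).
#'
#' @param rc data.frame with columns `row` and `col` (1-based, unique
#'   pairs), optionally `grid_id` and `included`.
#' @param pitch edge length of one grid (um).
#' @return data.frame of class `GridLayout` with columns `grid_id`, `row`,
#'   `col`, `x_center_um`, `y_center_um`, `included`; `pitch` is stored as
#'   an attribute.
#' @export
grid_layout <- function(rc, pitch) {
  stopifnot(pitch > 0, all(c("row", "col") %in% names(rc)))
  if (anyDuplicated(rc[, c("row", "col")]))
    stop("duplicated (row, col) in grid layout")
  out <- data.frame(
    grid_id = if ("grid_id" %in% names(rc)) as.character(rc$grid_id)
    else sprintf("r%02dc%02d", rc$row, rc$col),
    row = as.integer(rc$row), col = as.integer(rc$col))
  if (anyDuplicated(out$grid_id)) stop("duplicated grid_id")
  out$x_center_um <- (out$col - 0.5) * pitch
  out$y_center_um <- (out$row - 0.5) * pitch
  out$included <- if ("included" %in% names(rc)) as.logical(rc$included)
  else TRUE
  attr(out, "pitch") <- pitch
  class(out) <- c("GridLayout", "data.frame")
  out
}

#' Differential expression of a grid region against the rest
#'
#' Two-group marker test (region vs all other included grids), e.g. the
#' 4 x 4 block of grids covering a food source. Thin wrapper over
#' [rank_markers()] with the induced two-cluster labelling.
#'
#' @param matrix an `ExpressionMatrix` on `lognorm` or `log2TPM`.
#' @param layout a [grid_layout()] covering the matrix samples.
#' @param region_grids character vector of grid ids forming the region;
#'   must be a nonempty proper subset of the samples.
#' @param ... passed to [rank_markers()].
#' @return the `MarkerTable` rows for the region group, with a `region`
#'   attribute listing the grids.
#' @export
region_de <- function(matrix, layout, region_grids, ...) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  ids <- sample_ids(matrix)
  if (length(region_grids) == 0) stop("region_grids is empty")
  miss <- setdiff(region_grids, ids)
  if (length(miss))
    stop("region grids absent from matrix: ", paste(miss, collapse = ", "))
  if (length(region_grids) >= length(ids))
    stop("region must be a proper subset of the grids")
  lab <- ifelse(ids %in% region_grids, "region", "rest")
  mk <- rank_markers(matrix, stats::setNames(lab, ids), ...)
  res <- mk[mk$cluster == "region", , drop = FALSE]
  attr(res, "region") <- region_grids
  res
}

#' Per-grid fan scores across specimens
#'
#' Scores every grid of every specimen against a set of growth-front marker
#' genes with [module_score()], extracts the `top_n` highest-scoring grids
#' per specimen, and pools those grids (genes common to all specimens) for
#' joint analysis.
#'
#' @param matrices named list of per-specimen `ExpressionMatrix` objects on
#'   a continuous layer.
#' @param fan_marker_genes marker gene ids; a specimen missing more than
#'   half of them is an error.
#' @param top_n grids to extract per specimen (default 10).
#' @param seed control-draw seed for the module scores.
#' @return list with `scores` (per specimen, named numeric), `top_grids`
#'   (per specimen) and `pooled` (ExpressionMatrix of the pooled top grids).
#' @export
fan_score_specimens <- function(matrices, fan_marker_genes, top_n = 10,
                                seed = 0) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("SM", seq_along(matrices))
  scores <- list(); top_grids <- list()
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    present <- intersect(fan_marker_genes, gene_ids(m))
    if (length(present) < length(fan_marker_genes) / 2)
      stop(sprintf("specimen %s is missing more than half the marker genes",
                   nm))
    sc <- module_score(m, present, seed = seed)
    scores[[nm]] <- sc
    top_grids[[nm]] <- names(sort(sc, decreasing = TRUE))[
      seq_len(min(top_n, length(sc)))]
  }
  common <- Reduce(intersect, lapply(matrices, gene_ids))
  pooled_vals <- do.call(cbind, lapply(names(matrices), function(nm) {
    v <- as_dense(matrices[[nm]]$values)[common, top_grids[[nm]], drop = FALSE]
    colnames(v) <- paste(nm, top_grids[[nm]], sep = ":")
    v
  }))
  pooled <- expression_matrix(pooled_vals, matrices[[1]]$layer)
  list(scores = scores, top_grids = top_grids, pooled = pooled)
}

#' Pairwise distance versus transcriptome correlation
#'
#' Tests whether nearby grids are transcriptionally more similar: (1) the
#' `n_hvg` most variable genes of the scaled layer are selected; (2) each
#' gene's scaled values are shifted by its |minimum| so all values are
#' nonnegative (a documented no-op for Pearson, kept for fidelity with the
#' original procedure); (3) Pearson correlation between all grid pairs
#' (diagonal excluded); (4) Euclidean distance between grid centres; (5)
#' ordinary least squares of correlation on distance with a two-sided slope
#' t-test.
#'
#' @param matrix an `ExpressionMatrix` on the `scaled` layer.
#' @param layout a [grid_layout()]; only `included` grids present in the
#'   matrix are used (>= 3 required).
#' @param n_hvg number of top-variance genes (default 200); fewer available
#'   genes are used with a warning.
#' @return list of class `DistanceCorrelationResult`: `pairs` data.frame
#'   (`grid_i`, `grid_j`, `distance_um`, `r`), `slope`, `intercept`,
#'   `slope_p`, `n_pairs`.
#' @export
distance_correlation <- function(matrix, layout, n_hvg = 200) {
  assert_layer(matrix, "scaled")
  stopifnot(inherits(layout, "GridLayout"))
  ids <- intersect(sample_ids(matrix), layout$grid_id[layout$included])
  if (length(ids) < 3) stop("need at least 3 included grids")
  v <- as_dense(matrix$values)[, ids, drop = FALSE]
  if (nrow(v) < n_hvg) {
    warning(sprintf("only %d genes available (< n_hvg = %d); using all",
                    nrow(v), n_hvg))
    n_hvg <- nrow(v)
  }
  vars <- apply(v, 1, stats::var)
  hv <- order(vars, decreasing = TRUE)[seq_len(n_hvg)]
  m <- v[hv, , drop = FALSE]
  m <- m + abs(apply(m, 1, min))   # per-gene positive shift
  r <- stats::cor(m)
  xy <- layout[match(ids, layout$grid_id), c("x_center_um", "y_center_um")]
  d <- as.matrix(stats::dist(xy))
  ut <- upper.tri(r)
  pairs <- data.frame(
    grid_i = rep(ids, times = length(ids))[as.vector(ut)],
    grid_j = rep(ids, each = length(ids))[as.vector(ut)],
    distance_um = d[ut], r = r[ut])
  fit <- stats::lm(r ~ distance_um, data = pairs)
  cf <- summary(fit)$coefficients
  # pairs sharing a grid are dependent, so the naive OLS interval is
  # anticonservative; slope_ci is a leave-one-grid-out jackknife interval
  slope_of <- function(px) {
    stats::cov(px$distance_um, px$r) / stats::var(px$distance_um)
  }
  loo <- vapply(ids, function(g)
    slope_of(pairs[pairs$grid_i != g & pairs$grid_j != g, ]), numeric(1))
  G <- length(ids)
  se_jack <- sqrt((G - 1) / G * sum((loo - mean(loo))^2))
  tq <- stats::qt(0.975, G - 1)
  slope <- cf["distance_um", "Estimate"]
  structure(list(pairs = pairs, slope = slope,
                 intercept = cf["(Intercept)", "Estimate"],
                 slope_p = cf["distance_um", "Pr(>|t|)"],
                 slope_ci = c(slope - tq * se_jack, slope + tq * se_jack),
                 n_pairs = nrow(pairs)),
            class = "DistanceCorrelationResult")
}

#' @export
print.DistanceCorrelationResult <- function(x, ...) {
  cat(sprintf("DistanceCorrelationResult: %d pairs, slope %.3g (p = %.3g)\n",
              x$n_pairs, x$slope, x$slope_p))
  invisible(x)
}
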