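# Two-sided Wilcoxon rank-sum p-values for many genes at once.
# values: genes x samples; in_group: logical over samples.
# Small balanced groups take an exact permutation path (tie-safe subset
# enumeration); larger groups use the normal approximation with tie and
# continuity correction.
wilcox_rows <- function(values, in_group, exact_max_subsets = 20000) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  N <- n1 + n2
  ranks <- t(apply(values, 1, rank))
  rsum <- rowSums(ranks[, in_group, drop = FALSE])
  mu_r <- n1 * (N + 1) / 2
  use_exact <- n1 <= 10 && n2 <= 10 && choose(N, n1) <= exact_max_subsets
  if (use_exact) {
    subsets <- utils::combn(N, n1)
    p <- numeric(nrow(values))
    chunk <- 200
    for (s in seq(1, nrow(values), by = chunk)) {
      rows <- s:min(s + chunk - 1, nrow(values))
      perm <- matrix(0, length(rows), ncol(subsets))
      for (k in seq_len(ncol(subsets)))
        perm[, k] <- rowSums(ranks[rows, subsets[, k], drop = FALSE])
      dev_obs <- abs(rsum[rows] - mu_r)
      p[rows] <- rowMeans(abs(perm - mu_r) >= dev_obs - 1e-9)
    }
  } else {
    ties_term <- apply(ranks, 1, function(r) {
      t <- table(r)
      sum(t^3 - t)
    })
    sigma2 <- n1 * n2 / 12 * ((N + 1) - ties_term / (N * (N - 1)))
    z_raw <- rsum - mu_r
    cc <- pmin(abs(z_raw), 0.5) * sign(z_raw)   # continuity correction
    z <- ifelse(sigma2 > 0, (z_raw - cc) / sqrt(sigma2), 0)
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  stat <- rsum - n1 * (n1 + 1) / 2   # Mann-Whitney U of the in-group
  list(statistic = stat, p = p)
}

log_mean_exp <- function(x, layer) {
  if (layer == "log2TPM") log(mean(2^x - 1) + 1) else log(mean(expm1(x)) + 1)
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, tests each gene with a two-sided Wilcoxon rank-sum
#' test of the cluster's samples against all others. Genes are pre-filtered
#' on detection fraction and log fold-change; p-values are Bonferroni
#' adjusted over all genes in the matrix (the conventional conservative
#' default), with Benjamini-Hochberg as an option.
#'
#' @param matrix an `ExpressionMatrix` on the `lognorm` or `log2TPM` layer.
#' @param clusters a `ClusterAssignment` or a vector of labels (named by
#'   sample or in column order).
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param logfc_min minimum |avg_log_fc| (natural-log scale, default 0.25).
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @return a `MarkerTable` data.frame with columns `gene`, `cluster`,
#'   `statistic`, `p`, `p_adj`, `avg_log_fc`, `pct_in`, `pct_out`, ordered
#'   by increasing p within cluster.
#' @export
rank_markers <- function(matrix, clusters, min_pct = 0.1, logfc_min = 0.25,
                         p_adjust = c("bonferroni", "BH")) {
  assert_layer(matrix, c("lognorm", "log2TPM"))
  p_adjust <- match.arg(p_adjust)
  v <- as_dense(matrix$values)
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
  else clusters
  if (!is.null(names(cl))) cl <- cl[colnames(v)]
  stopifnot(length(cl) == ncol(v))
  labs <- sort(unique(cl))
  if (length(labs) < 2) stop("need at least 2 clusters")
  out <- list()
  for (lab in labs) {
    in_g <- cl == lab
    if (sum(in_g) == 1)
      warning(sprintf("cluster %s has a single sample", lab))
    pct_in <- rowMeans(v[, in_g, drop = FALSE] > 0)
    pct_out <- rowMeans(v[, !in_g, drop = FALSE] > 0)
    lfc <- apply(v[, in_g, drop = FALSE], 1, log_mean_exp, matrix$layer) -
      apply(v[, !in_g, drop = FALSE], 1, log_mean_exp, matrix$layer)
    test <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= logfc_min
    if (!any(test)) next
    wt <- wilcox_rows(v[test, , drop = FALSE], in_g)
    p_adj <- switch(p_adjust,
                    bonferroni = pmin(1, wt$p * nrow(v)),
                    BH = stats::p.adjust(wt$p, "BH"))
    tab <- data.frame(gene = rownames(v)[test], cluster = lab,
                      statistic = wt$statistic, p = wt$p, p_adj = p_adj,
                      avg_log_fc = lfc[test], pct_in = pct_in[test],
                      pct_out = pct_out[test], row.names = NULL)
    out[[as.character(lab)]] <- tab[order(tab$p, -tab$avg_log_fc), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("MarkerTable", "data.frame")
  res
}

#' Expression-matched module score of a gene set
#'
#' Mean expression of the set minus the mean of a control set drawn from
#' expression-matched bins: genes are binned by average expression across
#' samples, and for each set gene `n_ctrl` control genes are sampled (with
#' the seeded RNG) from its bin. Scores are invariant to adding a constant
#' to all values.
#'
#' @param matrix an `ExpressionMatrix` (any continuous layer).
#' @param gene_set character vector of gene ids, all present in the matrix.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return named numeric vector of per-sample scores.
#' @export
module_score <- function(matrix, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (length(gene_set) == 0) stop("gene_set is empty")
  miss <- setdiff(gene_set, gene_ids(matrix))
  if (length(miss))
    stop("genes absent from matrix: ", paste(miss, collapse = ", "))
  v <- as_dense(matrix$values)
  avg <- rowMeans(v)
  n_bins <- min(n_bins, nrow(v))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(v)
  ctrl <- with_seed_local(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
  })
  colMeans(v[gene_set, , drop = FALSE]) - colMeans(v[ctrl, , drop = FALSE])
}

#' Detected-gene sets and their overlap across datasets
#'
#' A gene counts as detected in a dataset when its total expression exceeds
#' the `quantile_cutoff` quantile of the nonzero gene totals, removing
#' sparsely expressed genes before comparing repertoires. Overlaps are
#' reported as Venn-region counts for two or three datasets.
#'
#' @param matrices named list of `ExpressionMatrix` objects (>= 2) sharing
#'   a gene universe.
#' @param quantile_cutoff quantile of nonzero totals (default 0.10); 0 keeps
#'   every gene with nonzero total.
#' @return list with `detected` (list of gene-id vectors) and `venn`
#'   (named counts of exclusive regions).
#' @export
detected_gene_overlap <- function(matrices, quantile_cutoff = 0.10) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("set", seq_along(matrices))
  detected <- lapply(matrices, function(m) {
    stopifnot(inherits(m, "ExpressionMatrix"))
    tot <- as.numeric(Matrix::rowSums(m$values))
    names(tot) <- gene_ids(m)
    nz <- tot[tot > 0]
    if (length(nz) == 0) return(character(0))
    cut <- if (quantile_cutoff == 0) 0
    else stats::quantile(nz, quantile_cutoff, names = FALSE)
    names(nz)[nz > cut]
  })
  universes <- lapply(matrices, gene_ids)
  shared <- Reduce(intersect, universes)
  if (length(shared) == 0) stop("disjoint gene universes")
  sets <- names(detected)
  venn <- c()
  for (k in seq_along(sets)) {
    combos <- utils::combn(sets, k, simplify = FALSE)
    for (cmb in combos) {
      inside <- Reduce(intersect, detected[cmb])
      outside <- unlist(detected[setdiff(sets, cmb)], use.names = FALSE)
      venn[paste(cmb, collapse = "&")] <- length(setdiff(inside, outside))
    }
  }
  list(detected = detected, venn = venn)
}

#' Display-contrast limits from nonzero expression quantiles
#'
#' The (10th, 90th) percentiles of the nonzero values (linear-interpolation
#' quantiles), the contrast window used for feature plots.
#'
#' @param values numeric vector with at least one nonzero entry.
#' @param probs the two quantiles (default `c(0.1, 0.9)`).
#' @return `c(lo, hi)`.
#' @export
feature_contrast_limits <- function(values, probs = c(0.1, 0.9)) {
  nz <- values[values != 0]
  if (length(nz) == 0) stop("all values are zero; contrast undefined")
  stats::quantile(nz, probs, names = FALSE, type = 7)
}
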