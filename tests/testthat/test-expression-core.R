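counts_em <- function(m) expression_matrix(m, "counts")

test_that("TPM: closed forms, column sums, and a two-pass oracle", {
  m <- matrix(c(10, 10, 40, 40), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tpm <- tpm_from_counts(counts_em(m), c(a = 100, b = 100))
  expect_equal(unname(em_values(tpm)[, 1]), c(5e5, 5e5))

  tpm2 <- tpm_from_counts(counts_em(m), c(a = 200, b = 100))
  expect_equal(unname(em_values(tpm2)["a", 1] / em_values(tpm2)["b", 1]), 0.5)
  expect_equal(unname(colSums(em_values(tpm2))), c(1e6, 1e6))

  set.seed(2)
  big <- matrix(rpois(500, 20), 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  len <- runif(50, 200, 5000)
  names(len) <- rownames(big)
  got <- em_values(tpm_from_counts(counts_em(big), len))
  # independent two-pass computation
  want <- big
  for (j in 1:10) {
    rate <- numeric(50)
    for (i in 1:50) rate[i] <- big[i, j] / len[i]
    for (i in 1:50) want[i, j] <- rate[i] / sum(rate) * 1e6
  }
  expect_lt(max(abs(got - want) / pmax(want, 1e-9)), 1e-6)

  zero <- big; zero[, 3] <- 0
  expect_error(tpm_from_counts(counts_em(zero), len), "s3")
})

test_that("log2 TPM thresholding", {
  m <- matrix(c(8, 0.5, 1, 1024), 4, 1,
              dimnames = list(letters[1:4], "s"))
  em <- expression_matrix(m, "TPM")
  out <- em_values(log2_tpm_threshold(em))
  expect_equal(unname(out[, 1]), c(3, 0, 0, 10))
  expect_error(log2_tpm_threshold(counts_em(matrix(1, 1, 1))), "layer")
})

test_that("log-normalisation closed form, zeros, monotonicity, sparse parity", {
  m <- matrix(c(100, 9900, 0, 50, 100, 9850), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ln <- lognormalize(counts_em(m))
  expect_equal(unname(em_values(ln)["a", 1]), log(101), tolerance = 1e-12)
  expect_equal(unname(em_values(ln)["c", 1]), 0)
  v <- em_values(ln)
  expect_true(all(diff(v[order(m[, 2]), 2]) >= 0))

  sp <- lognormalize(counts_em(Matrix::Matrix(m, sparse = TRUE)))
  expect_equal(as.matrix(em_values(sp)), em_values(ln), tolerance = 1e-12)

  bad <- m; bad[, 2] <- 0
  expect_error(lognormalize(counts_em(bad)), "zero-total")
})

test_that("depth filters implement the per-specimen bounds", {
  m <- matrix(c(150000, 250000, 90000, 120000), nrow = 1)
  colnames(m) <- paste0("g", 1:4)
  rownames(m) <- "gene1"
  em <- expression_matrix(m, "counts",
                          data.frame(specimen = c("SM1", "SM1", "SM2", "SM2")))
  rule <- data.frame(specimen = c("SM1", "SM2"),
                     min = c(2e5, 1e5), max = c(Inf, Inf))
  kept <- suppressMessages(filter_samples_by_depth(em, rule))
  expect_identical(colnames(em_values(kept)), c("g2", "g4"))

  # UMI ceiling: a nucleus with 3,500 total under max = 3,000 is removed
  nm <- matrix(c(2900, 3500), nrow = 1,
               dimnames = list("g", c("n1", "n2")))
  nem <- expression_matrix(nm, "counts")
  kept2 <- suppressMessages(filter_samples_by_depth(nem, c(0, 3000)))
  expect_identical(colnames(em_values(kept2)), "n1")

  # amoeba window 6,000-25,000
  am <- matrix(c(5000, 7000, 26000), nrow = 1,
               dimnames = list("g", c("c1", "c2", "c3")))
  kept3 <- suppressMessages(
    filter_samples_by_depth(expression_matrix(am, "counts"), c(6000, 25000)))
  expect_identical(colnames(em_values(kept3)), "c2")

  expect_error(suppressMessages(filter_samples_by_depth(
    em, data.frame(specimen = "SM9", min = 0, max = 1))), "unknown specimen")
})

test_that("annotation filter keeps UniProt or described transcripts", {
  m <- matrix(1, 10, 2, dimnames = list(paste0("t", 1:10), c("s1", "s2")))
  ann <- data.frame(
    transcript_id = paste0("t", 1:8),
    uniprot_id = c("P1", "", "P3", "", "", "P6", "", ""),
    description = c("", "", "x", "desc", "", "", "", NA))
  out <- suppressMessages(filter_annotated_genes(counts_em(m), ann))
  expect_identical(rownames(em_values(out)), c("t1", "t3", "t4", "t6"))
})

test_that("regression scaling: absorption, z-score limit, and oracle", {
  set.seed(3)
  n <- 30
  meta <- data.frame(total = runif(n, 1e3, 1e4), n_genes = runif(n, 50, 500))
  # gene 1 perfectly linear in total
  v <- rbind(0.002 * meta$total + 1, matrix(rnorm(99 * n), 99, n))
  dimnames(v) <- list(paste0("g", 1:100), paste0("s", 1:n))
  em <- expression_matrix(v, "lognorm", meta)
  sc <- scale_with_regression(em)
  expect_lt(max(abs(em_values(sc)["g1", ])), 1e-8)

  # constant covariates reduce to a plain z-score
  meta2 <- data.frame(total = rep(5, n), n_genes = rep(7, n))
  em2 <- expression_matrix(v, "lognorm", meta2)
  sc2 <- scale_with_regression(em2)
  zs <- t(scale(t(v)))
  expect_equal(unname(em_values(sc2)[2, ]), unname(zs[2, ]),
               tolerance = 1e-10)

  # normal-equations oracle for the residuals
  X <- cbind(1, meta$total, meta$n_genes)
  beta <- solve(t(X) %*% X, t(X) %*% t(v))
  res_oracle <- t(v) - X %*% beta
  for (g in c(5, 50, 100)) {
    r <- res_oracle[, g]
    expect_equal(unname(em_values(sc)[g, ]), unname(r / sd(r)),
                 tolerance = 1e-8)
    # residuals orthogonal to covariates
    expect_lt(abs(sum(r / sqrt(sum(r^2)) * meta$total /
                        sqrt(sum(meta$total^2)))), 1e-6)
  }

  # constant gene scales to zeros
  v3 <- v; v3[4, ] <- 2
  sc3 <- scale_with_regression(expression_matrix(v3, "lognorm", meta))
  expect_true(all(em_values(sc3)[4, ] == 0))
})

test_that("PCA: exact line, determinism, two-cluster separation", {
  set.seed(4)
  t_par <- rnorm(40)
  line <- outer(t_par, c(1, 2, 3, -1, 0.5)) +
    matrix(rnorm(200, sd = 1e-5), 40, 5)
  pc <- run_pca(line, n_pcs = 3)
  expect_gte(pc$var_explained[1], 0.999)

  pc2 <- run_pca(line, n_pcs = 3)
  expect_identical(pc$scores, pc2$scores)

  blob <- rbind(matrix(rnorm(100, 0), 20, 5), matrix(rnorm(100, 4), 20, 5))
  pcb <- run_pca(blob, n_pcs = 2)
  expect_equal(auc_of(pcb$scores[, 1], rep(c(FALSE, TRUE), each = 20)), 1)

  expect_error(run_pca(blob, n_pcs = 99), "n_pcs")
})

test_that("graph clustering separates blobs and degenerates sensibly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(160, 0), 80, 2), matrix(rnorm(160, 6), 80, 2))
  rownames(X) <- paste0("s", 1:160)
  cl <- cluster_graph(X, k_neighbors = 15, resolution = 0.1, seed = 1)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_equal(adjusted_rand(cl$cluster, rep(1:2, each = 80)), 1)

  # resolution -> 0 collapses a connected cloud to one cluster
  Y <- matrix(rnorm(300), 150, 2, dimnames = list(paste0("y", 1:150), NULL))
  cl0 <- cluster_graph(Y, k_neighbors = 15, resolution = 1e-4, seed = 1)
  expect_identical(length(unique(cl0$cluster)), 1L)

  # duplicated dataset gets the identical partition on both copies
  X2 <- rbind(X, X + matrix(rnorm(320, sd = 1e-9), 160, 2))
  rownames(X2) <- paste0("s", 1:320)
  cl2 <- cluster_graph(X2, k_neighbors = 15, resolution = 0.1, seed = 1)
  expect_equal(adjusted_rand(cl2$cluster[1:160], cl2$cluster[161:320]), 1)

  expect_error(cluster_graph(matrix(1, 10, 2), k_neighbors = 3),
               "degenerate")
})

test_that("hierarchical clustering on correlation distances", {
  set.seed(6)
  base <- matrix(rnorm(40), 20, 2)
  m <- cbind(a = base[, 1], b = base[, 1], c = -base[, 1], d = base[, 2])
  hc <- cluster_hierarchical(t(m), k = 2)
  d <- 1 - cor(m)
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_identical(hc$tree$merge[1, ], c(-1L, -2L))  # identical pair first

  # 3-block structure recovered exactly at k = 3
  centers <- matrix(rnorm(3 * 30, sd = 3), 3, 30)
  samp <- do.call(cbind, lapply(1:3, function(b)
    matrix(centers[b, ], 30, 8) + matrix(rnorm(240, sd = 0.3), 30, 8)))
  colnames(samp) <- paste0("s", 1:24)
  hc3 <- cluster_hierarchical(t(samp), k = 3)
  expect_equal(adjusted_rand(hc3$cluster, rep(1:3, each = 8)), 1)

  # order invariance
  perm <- sample(24)
  hcp <- cluster_hierarchical(t(samp)[perm, ], k = 3)
  expect_equal(adjusted_rand(hcp$cluster[colnames(samp)],
                             hc3$cluster[colnames(samp)]), 1)

  const <- t(cbind(samp, konst = rep(2, 30)))
  expect_error(cluster_hierarchical(const), "konst")
})

test_that("detected-gene overlap with quantile cutoff", {
  mk <- function(tot, ids = paste0("g", seq_along(tot))) {
    m <- matrix(tot, ncol = 1, dimnames = list(ids, "s1"))
    expression_matrix(cbind(m, m, deparse.level = 0)[, 1, drop = FALSE] * 1,
                      "counts")
  }
  a <- mk(c(1:100))
  b <- mk(c(1:100))
  ov <- detected_gene_overlap(list(x = a, y = b))
  expect_identical(ov$detected$x, ov$detected$y)
  expect_identical(unname(ov$venn["x&y"]), length(ov$detected$x))
  expect_identical(unname(ov$venn["x"]), 0L)
  # {1..100}: the 10% quantile removes exactly the bottom 10 genes
  expect_identical(length(ov$detected$x), 90L)
  expect_identical(ov$detected$x, paste0("g", 11:100))

  ov0 <- detected_gene_overlap(list(x = a, y = b), quantile_cutoff = 0)
  expect_identical(length(ov0$detected$x), 100L)

  dis <- mk(1:5, ids = paste0("h", 1:5))
  expect_error(detected_gene_overlap(list(a, dis)), "disjoint")
})

test_that("feature contrast limits use nonzero linear-interpolation quantiles", {
  expect_equal(feature_contrast_limits(c(0, 0, 1:10)), c(1.9, 9.1))
  expect_equal(feature_contrast_limits(rep(3, 5)), c(3, 3))
  expect_equal(feature_contrast_limits(c(0, 0, 5)), c(5, 5))
  expect_error(feature_contrast_limits(c(0, 0)), "zero")
})
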