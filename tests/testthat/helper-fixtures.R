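# small, fast configurations used across tests
tiny_cfg <- function(seed = 1, ...) {
  args <- list(domain_size = c(300, 300), n_genes = 600,
               n_markers_per_program = 20, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# lognormalized grid dataset with truth, shared by several files
grid_fixture <- function(seed = 1, ...) {
  g <- simulate_spatial_grids(tiny_cfg(seed, ...))
  g$lognorm <- lognormalize(g$counts)
  g
}

# adjusted Rand index (independent of any package code)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  e1 <- sum_comb(rowSums(tab))
  e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  mx <- (e1 + e2) / 2
  (idx - expected) / (mx - expected)
}

# area under the ROC curve for scores separating a binary truth
auc_of <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
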