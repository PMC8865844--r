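# Independent oracles used by the module and acceptance suites. These stay
# deliberately naive: exhaustive scans, permutation enumeration, explicit
# loops -- never the package's own code path.

# exhaustive maximisation of the between-class variance over histogram cuts
otsu_oracle <- function(x, n_bins = 64) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  h <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  best <- -Inf; best_cut <- NA
  for (tcut in 1:(n_bins - 1)) {
    w0 <- sum(h[1:tcut]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:tcut] * mids[1:tcut]) / w0
    mu1 <- sum(h[(tcut + 1):n_bins] * mids[(tcut + 1):n_bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_cut <- tcut }
  }
  edges[best_cut + 1]
}

# best one-to-one matching by enumerating all permutations (tiny n):
# maximise matches within the radius, then minimise total matched distance
match_oracle <- function(px, py, tx, ty, radius) {
  np <- length(px); nt <- length(tx)
  d <- sqrt(outer(px, tx, `-`)^2 + outer(py, ty, `-`)^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- c(tp = -1, cost = Inf)
  k <- min(np, nt)
  for (pr in perms(seq_len(max(np, nt)))) {
    sel <- pr[seq_len(k)]
    if (np <= nt) { pi_ <- seq_len(np); ti_ <- sel[seq_len(np)] }
    else { pi_ <- sel; ti_ <- seq_len(nt) }
    ok <- d[cbind(pi_, ti_)] <= radius
    tp <- sum(ok); cost <- sum(d[cbind(pi_, ti_)][ok])
    if (tp > best["tp"] || (tp == best["tp"] && cost < best["cost"]))
      best <- c(tp = tp, cost = cost)
  }
  best
}

# exact two-sided permutation p for the rank-sum test, recomputing ranks
# from the raw values for every relabelling
wilcox_perm_oracle <- function(x_in, x_out) {
  vals <- c(x_in, x_out)
  n1 <- length(x_in)
  N <- length(vals)
  mu <- n1 * (N + 1) / 2
  obs <- sum(rank(vals)[seq_len(n1)])
  combos <- utils::combn(N, n1)
  stats <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# optimal-assignment cost via scipy (pre-installed python), written to/from
# temp CSVs; independent LSAP solver for the matching oracle at n = 50
scipy_assignment_cost <- function(cost) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  write.table(cost, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from scipy.optimize import linear_sum_assignment\n",
    "c = np.loadtxt(%s, delimiter=',')\n",
    "r, k = linear_sum_assignment(c)\n",
    "open(%s, 'w').write(repr(float(c[r, k].sum())) + chr(10))\n"),
    deparse(fin), deparse(fout))
  sfile <- tempfile(fileext = ".py")
  writeLines(script, sfile)
  res <- system2("python", sfile, stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("scipy oracle failed: ", paste(res, collapse = "\n"))
  as.numeric(readLines(fout))
}
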