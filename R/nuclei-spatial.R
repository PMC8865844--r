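#' Per-object shape statistics from a label mask
#'
#' Computes, for every labelled object, the area (pixel count times pixel
#' area), the eccentricity derived from the second central moments of its
#' pixel coordinates, and the equivalent-circle diameter `2 sqrt(area/pi)`.
#'
#' @param mask integer label matrix (0 = background), rows = y.
#' @param pixel_size um per pixel (> 0).
#' @return data.frame with columns `label`, `area_um2`, `eccentricity`,
#'   `diameter_um`, `x_um`, `y_um` (centroid, pixel-centre convention).
#'   Empty mask gives an empty table.
#' @export
shape_stats <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  idx <- which(mask > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      eccentricity = numeric(0), diameter_um = numeric(0),
                      x_um = numeric(0), y_um = numeric(0)))
  lab <- as.integer(mask[idx])
  rc <- arrayInd(idx, dim(mask))
  ys <- rc[, 1] - 0.5
  xs <- rc[, 2] - 0.5
  f <- factor(lab)
  n <- as.vector(table(f))
  sx <- rowsum(xs, f)[, 1]; sy <- rowsum(ys, f)[, 1]
  cx <- sx / n; cy <- sy / n
  dx <- xs - cx[f]; dy <- ys - cy[f]
  # central moments; 1/12 adds the variance of a unit pixel itself so a
  # one-pixel object has a defined (circular) shape
  m20 <- rowsum(dx^2, f)[, 1] / n + 1 / 12
  m02 <- rowsum(dy^2, f)[, 1] / n + 1 / 12
  m11 <- rowsum(dx * dy, f)[, 1] / n
  tr <- m20 + m02
  det_ <- m20 * m02 - m11^2
  disc <- sqrt(pmax(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ecc <- sqrt(pmax(0, 1 - l2 / l1))
  area <- n * pixel_size^2
  data.frame(label = as.integer(levels(f)),
             area_um2 = area,
             eccentricity = ecc,
             diameter_um = 2 * sqrt(area / pi),
             x_um = cx * pixel_size,
             y_um = cy * pixel_size,
             row.names = NULL)
}

nn_brute <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

nn_grid <- function(x, y) {
  n <- length(x)
  ex <- max(x) - min(x); ey <- max(y) - min(y)
  # cell edge ~ mean spacing; guard degenerate (collinear/coincident) spreads
  s <- max(sqrt(ex * ey / n), (ex + ey) / (2 * n))
  if (!is.finite(s) || s <= 0) s <- 1
  cx <- floor((x - min(x)) / s)
  cy <- floor((y - min(y)) / s)
  cell_of <- split(seq_len(n), paste(cx, cy))
  out <- numeric(n)
  max_ring <- max(cx) - min(cx) + max(cy) - min(cy) + 2
  for (i in seq_len(n)) {
    best <- Inf
    k <- 0
    while (k <= max_ring) {
      # ring of cells at Chebyshev distance k; any point beyond ring k-1
      # is at least (k-1)*s away, so stop once that bound exceeds best
      if (k > 0 && (k - 1) * s >= best) break
      cand <- integer(0)
      if (k == 0) {
        cand <- cell_of[[paste(cx[i], cy[i])]]
      } else {
        for (dx in -k:k) {
          dys <- if (abs(dx) == k) -k:k else c(-k, k)
          for (dy in dys) {
            idx <- cell_of[[paste(cx[i] + dx, cy[i] + dy)]]
            if (!is.null(idx)) cand <- c(cand, idx)
          }
        }
      }
      cand <- cand[cand != i]
      if (length(cand)) {
        d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
        best <- min(best, sqrt(min(d2)))
      }
      k <- k + 1
    }
    out[i] <- best
  }
  out
}

#' Nearest-neighbour distances between nuclei
#'
#' Distance of every point to its closest other point, with summary
#' statistics. The default bucketed spatial search returns results identical
#' to the O(n^2) scan (`method = "brute"`), which is retained as the
#' reference path.
#'
#' @param pattern a [point_pattern()] with at least two points.
#' @param r optional radius (um); the fraction of points with a neighbour
#'   within `r` is reported.
#' @param method `"grid"` (bucketed search) or `"brute"` (O(n^2) scan).
#' @return list with `distances` (per point, pattern order), `mean`, `max`,
#'   and `frac_within_r` (NA when `r` is missing).
#' @export
nearest_neighbor_distances <- function(pattern, r = NULL,
                                       method = c("grid", "brute")) {
  stopifnot(inherits(pattern, "PointPattern"))
  method <- match.arg(method)
  pts <- pattern$points
  if (nrow(pts) < 2)
    stop("nearest-neighbour distances are undefined for fewer than 2 points")
  d <- if (method == "brute") nn_brute(pts$x, pts$y) else nn_grid(pts$x, pts$y)
  list(distances = as.numeric(d), mean = mean(d), max = max(d),
       frac_within_r = if (is.null(r)) NA_real_ else mean(d <= r))
}

#' Gaussian kernel density (intensity) map of a point pattern
#'
#' Isotropic Gaussian KDE evaluated on a regular grid of `cell_size` um
#' cells covering the pattern's domain, scaled as an intensity (nuclei per
#' um^2) so that the map integrates to the point count. No boundary
#' correction is applied.
#'
#' @param pattern a [point_pattern()] with at least one point.
#' @param bandwidth kernel sd in um, or `"auto"` for Scott's rule
#'   `mean(sd_x, sd_y) * n^(-1/6)`.
#' @param cell_size evaluation-cell edge in um (> 0).
#' @return A `DensityMap`: list with `values` (rows = y, bottom row first),
#'   `cell_size`, `bandwidth`, `origin`.
#' @export
kde_density_map <- function(pattern, bandwidth = "auto", cell_size = 10) {
  stopifnot(inherits(pattern, "PointPattern"))
  if (cell_size <= 0) stop("cell_size must be > 0")
  pts <- pattern$points
  n <- nrow(pts)
  if (n < 1) stop("KDE needs at least one point")
  if (identical(bandwidth, "auto")) {
    s <- mean(c(stats::sd(pts$x), stats::sd(pts$y)))
    if (!is.finite(s) || s <= 0)
      stop("cannot auto-select a bandwidth (degenerate pattern); give one")
    bandwidth <- s * n^(-1 / 6)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  d <- pattern$domain
  nc <- max(1L, ceiling((d[2] - d[1]) / cell_size))
  nr <- max(1L, ceiling((d[4] - d[3]) / cell_size))
  gx <- d[1] + (seq_len(nc) - 0.5) * cell_size
  gy <- d[3] + (seq_len(nr) - 0.5) * cell_size
  # separable kernel: map = Gy %*% t(Gx), each column a 1-D Gaussian profile
  k1 <- function(grid, p) exp(-outer(grid, p, `-`)^2 / (2 * bandwidth^2)) /
    (sqrt(2 * pi) * bandwidth)
  vals <- k1(gy, pts$y) %*% t(k1(gx, pts$x))
  structure(list(values = vals, cell_size = cell_size, bandwidth = bandwidth,
                 origin = c(d[1], d[3])),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap: %d x %d cells of %g um, bandwidth %g um\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$bandwidth))
  invisible(x)
}

#' Otsu threshold of a numeric vector
#'
#' Histogram threshold maximising the between-class variance
#' `w0 w1 (mu0 - mu1)^2` over all bin cuts, the classic unsupervised split
#' of a bimodal distribution.
#'
#' @param x numeric values.
#' @param n_bins number of histogram bins (default 64).
#' @return the threshold (upper edge of the last lower-class bin).
#' @export
otsu_threshold <- function(x, n_bins = 64) {
  stopifnot(length(x) >= 2)
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate profile, no split")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  s0 <- cumsum(h * mids)
  mu0 <- s0 / w0
  mu1 <- (sum(h * mids) - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  cut <- which.max(bcv[-n_bins])
  edges[cut + 1]
}

#' Split a density map into fan and network bands along y
#'
#' Averages the density map across x to obtain a 1-D profile along y, then
#' finds the unbiased Otsu cut of that profile and labels every y-bin
#' `"fan"` (above threshold: the dense growth front) or `"network"`.
#'
#' @param map a `DensityMap` with at least 2 rows.
#' @param n_bins histogram bins for the Otsu cut.
#' @return list of class `RegionSplit` with `threshold`, `bin_labels`,
#'   `profile`, `boundary_row` (first row of the fan band under the best
#'   step fit) and `boundary_y` in um.
#' @export
fan_network_split <- function(map, n_bins = 64) {
  stopifnot(inherits(map, "DensityMap"), nrow(map$values) >= 2)
  profile <- rowMeans(map$values)
  thr <- otsu_threshold(profile, n_bins)
  lab <- ifelse(profile > thr, "fan", "network")
  if (length(unique(lab)) < 2) stop("degenerate profile, no split")
  # best step position: minimise mislabels against 'network below, fan above'
  nb <- length(lab)
  fan_below <- c(0, cumsum(lab == "fan"))            # fans among rows < b
  net_from <- rev(c(0, cumsum(rev(lab == "network")))) # networks among rows >= b
  mis <- fan_below + net_from
  b <- which.min(mis)
  structure(list(threshold = thr, bin_labels = lab, profile = profile,
                 boundary_row = b,
                 boundary_y = map$origin[2] + (b - 1) * map$cell_size),
            class = "RegionSplit")
}

#' Welch two-sample t-test of region densities
#'
#' Independent two-sided t-test with unequal variances comparing fan and
#' network density samples. Degenerate inputs (zero variance in both groups)
#' return p = 1 for equal means and p = 0 otherwise.
#'
#' @param fan_values,network_values numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `mean_fan`, `mean_network`.
#' @export
density_ttest <- function(fan_values, network_values) {
  stopifnot(length(fan_values) >= 2, length(network_values) >= 2)
  if (stats::sd(fan_values) == 0 && stats::sd(network_values) == 0) {
    eq <- isTRUE(all.equal(mean(fan_values), mean(network_values)))
    return(list(t = if (eq) 0 else sign(mean(fan_values) -
                                          mean(network_values)) * Inf,
                p = if (eq) 1 else 0,
                mean_fan = mean(fan_values),
                mean_network = mean(network_values)))
  }
  ht <- stats::t.test(fan_values, network_values, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_fan = mean(fan_values), mean_network = mean(network_values))
}

# Jonker-Volgenant shortest augmenting path solver for the square linear
# assignment problem; returns, for each row, its assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free_j <- which(!used[-1])
      cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
      upd <- cur < minv[free_j + 1]
      minv[free_j[upd] + 1] <- cur[upd]
      way[free_j[upd] + 1] <- j0
      jbest <- free_j[which.min(minv[free_j + 1])]
      delta <- minv[jbest + 1]
      usedj <- which(used)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[-usedj] <- minv[-usedj] - delta
      j0 <- jbest
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_of_row <- integer(n)
  assign_of_row[p[-1]] <- seq_len(n)
  assign_of_row
}

#' Score detected nuclei against ground truth
#'
#' One-to-one matching between predicted and true points minimising the
#' total matched distance subject to a radius cap (optimal assignment; pairs
#' farther than `match_radius` cannot match). TP = matched pairs,
#' FP = unmatched predictions, FN = unmatched truth;
#' precision = TP/(TP+FP), accuracy = TP/(TP+FP+FN).
#'
#' @param predicted,truth [point_pattern()] objects.
#' @param match_radius maximum matching distance (um, > 0); defaults to the
#'   mean true diameter when available.
#' @return list of class `DetectionEval` with `tp`, `fp`, `fn`, `precision`,
#'   `accuracy`, `match_radius` and the `matching` data.frame
#'   (predicted id, truth id, distance).
#' @export
evaluate_detection <- function(predicted, truth, match_radius = NULL) {
  stopifnot(inherits(predicted, "PointPattern"), inherits(truth, "PointPattern"))
  if (is.null(match_radius)) {
    if (!"diameter" %in% names(truth$points))
      stop("no match_radius given and truth has no diameters")
    match_radius <- mean(truth$points$diameter)
  }
  stopifnot(match_radius > 0)
  np <- nrow(predicted$points)
  nt <- nrow(truth$points)
  matching <- data.frame(predicted_id = integer(0), truth_id = integer(0),
                         distance = numeric(0))
  if (np > 0 && nt > 0) {
    dx <- outer(predicted$points$x, truth$points$x, `-`)
    dy <- outer(predicted$points$y, truth$points$y, `-`)
    d <- sqrt(dx^2 + dy^2)
    N <- max(np, nt)
    penalty <- N * match_radius + 1
    cost <- matrix(penalty, N, N)
    cost[seq_len(np), seq_len(nt)] <- ifelse(d <= match_radius, d, penalty)
    asg <- solve_assignment(cost)
    for (i in seq_len(np)) {
      j <- asg[i]
      if (j <= nt && d[i, j] <= match_radius)
        matching <- rbind(matching,
                          data.frame(predicted_id = predicted$points$id[i],
                                     truth_id = truth$points$id[j],
                                     distance = d[i, j]))
    }
  }
  tp <- nrow(matching)
  fp <- np - tp
  fn <- nt - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 accuracy = if (tp + fp + fn > 0) tp / (tp + fp + fn)
                 else NA_real_,
                 match_radius = match_radius, matching = matching),
            class = "DetectionEval")
}

#' @export
print.DetectionEval <- function(x, ...) {
  cat(sprintf("DetectionEval: tp %d fp %d fn %d | precision %.3f accuracy %.3f (radius %g um)\n",
              x$tp, x$fp, x$fn, x$precision, x$accuracy, x$match_radius))
  invisible(x)
}

union_find_label <- function(fg, nr, nc) {
  # two-pass 8-connectivity labelling with union-find over foreground pixels
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!fg[rr, cc]) next
    neigh <- integer(0)
    if (rr > 1 && fg[rr - 1, cc]) neigh <- c(neigh, lab[rr - 1, cc])
    if (cc > 1) {
      if (fg[rr, cc - 1]) neigh <- c(neigh, lab[rr, cc - 1])
      if (rr > 1 && fg[rr - 1, cc - 1]) neigh <- c(neigh, lab[rr - 1, cc - 1])
      if (rr < nr && fg[rr + 1, cc - 1]) neigh <- c(neigh, lab[rr + 1, cc - 1])
    }
    if (length(neigh) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[rr, cc] <- nxt
    } else {
      roots <- vapply(neigh, find, integer(1))
      r0 <- min(roots)
      for (r1 in roots) parent[find(r1)] <- r0
      lab[rr, cc] <- r0
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    idx <- which(lab > 0)
    lab[idx] <- relab[lab[idx]]
  }
  lab
}

#' Threshold-based blob detection of nuclei in an image
#'
#' Simple stand-in detector: foreground pixels exceed the image mean plus
#' `threshold_sd` standard deviations; 8-connected components of at least
#' `min_area_px` pixels are objects, reported with their intensity-weighted
#' centroids in physical units.
#'
#' @param image 2-D numeric matrix (rows = y, bottom row first).
#' @param threshold_sd threshold in sd units above the image mean.
#' @param min_area_px minimum component area in pixels.
#' @param pixel_size um per pixel.
#' @param origin `(x, y)` of the image's lower-left corner in um.
#' @return list with `mask` (integer labels) and `pattern`
#'   (a [point_pattern()] of centroids).
#' @export
blob_segment <- function(image, threshold_sd = 2, min_area_px = 4,
                         pixel_size = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(image))
  thr <- mean(image) + threshold_sd * stats::sd(image)
  fg <- image > thr
  nr <- nrow(image); nc <- ncol(image)
  if (!any(fg)) {
    return(list(mask = matrix(0L, nr, nc),
                pattern = point_pattern(numeric(0), numeric(0),
                                        domain = c(origin[1],
                                                   origin[1] + nc * pixel_size,
                                                   origin[2],
                                                   origin[2] + nr * pixel_size))))
  }
  lab <- union_find_label(fg, nr, nc)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) {
    return(list(mask = matrix(0L, nr, nc),
                pattern = point_pattern(numeric(0), numeric(0),
                                        domain = c(origin[1],
                                                   origin[1] + nc * pixel_size,
                                                   origin[2],
                                                   origin[2] + nr * pixel_size))))
  }
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  idx <- which(lab > 0)
  lab[idx] <- relab[lab[idx]]
  idx <- which(lab > 0)
  rc <- arrayInd(idx, dim(lab))
  w <- image[idx]
  f <- factor(lab[idx])
  wsum <- rowsum(w, f)[, 1]
  cx <- rowsum(w * (rc[, 2] - 0.5), f)[, 1] / wsum
  cy <- rowsum(w * (rc[, 1] - 0.5), f)[, 1] / wsum
  pat <- point_pattern(origin[1] + cx * pixel_size,
                       origin[2] + cy * pixel_size,
                       domain = c(origin[1], origin[1] + nc * pixel_size,
                                  origin[2], origin[2] + nr * pixel_size))
  list(mask = lab, pattern = pat)
}
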