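#' Configuration of the synthetic plasmodium world
#'
#' Bundles every knob of the generators. Defaults encode the emulated
#' biology: a growth-front (fan) band occupying `fan_fraction` of the y-axis
#' with twice the nuclei intensity of the vein network, nuclei of mean
#' diameter 5.65 um, shallow single-nucleus libraries averaging 591 UMIs,
#' deep amoeba libraries averaging 14,525 UMIs, SmartSeq2-like grid libraries
#' (~200k reads), 4 mm sampling grids, and a mitotic wave travelling along
#' grid columns.
#'
#' @param domain_size `c(width, height)` of the imaged domain (um).
#' @param fan_fraction fraction of the y-extent assigned to the fan band,
#'   in (0, 1). The fan is the top band (y large).
#' @param lambda_fan,lambda_network nuclei intensities (nuclei per um^2).
#' @param hardcore_radius minimum centre-to-centre spacing (um), >= 0.
#' @param diameter_mean,diameter_cv log-normal nucleus diameter mean (um)
#'   and coefficient of variation.
#' @param n_grids `c(rows, cols)` of the sampling grid.
#' @param grid_pitch edge length of one sampling grid (um).
#' @param n_genes number of simulated transcripts.
#' @param n_markers_per_program planted marker genes per program
#'   (fan, network, oat, wave).
#' @param program_log2fc log2 fold-change of planted markers in their home
#'   region; also sets the peak-to-trough ratio of wave genes.
#' @param wave_speed phase advance of the mitotic wave per grid column
#'   (radians).
#' @param libsize_grid,libsize_nucleus,libsize_amoeba mean sequencing depths.
#' @param nb_dispersion negative-binomial size parameter for grid counts
#'   (variance = mu + mu^2/size); `Inf` gives Poisson counts.
#' @param seed integer seed; identical config + seed reproduces outputs
#'   bit-for-bit.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(domain_size = c(1000, 1000),
                       fan_fraction = 0.4,
                       lambda_fan = 0.01,
                       lambda_network = 0.005,
                       hardcore_radius = 3,
                       diameter_mean = 5.65,
                       diameter_cv = 0.15,
                       n_grids = c(10, 12),
                       grid_pitch = 4000,
                       n_genes = 1500,
                       n_markers_per_program = 40,
                       program_log2fc = 2,
                       wave_speed = pi / 12,
                       libsize_grid = 2e5,
                       libsize_nucleus = 591,
                       libsize_amoeba = 14525,
                       nb_dispersion = 2,
                       seed = 1L) {
  stopifnot(length(domain_size) == 2, all(domain_size > 0),
            length(n_grids) == 2, all(n_grids >= 1), grid_pitch > 0,
            n_genes >= 4, n_markers_per_program >= 1,
            4 * n_markers_per_program <= n_genes,
            program_log2fc >= 0, diameter_mean > 0, diameter_cv >= 0)
  if (!(lambda_fan > 0) || !(lambda_network > 0))
    stop("lambda_fan and lambda_network must be > 0")
  if (hardcore_radius < 0) stop("hardcore_radius must be >= 0")
  if (!(fan_fraction > 0 && fan_fraction < 1))
    stop("fan_fraction must lie strictly between 0 and 1")
  if (any(c(libsize_grid, libsize_nucleus, libsize_amoeba) <= 0))
    stop("all library sizes must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0 (Inf for Poisson)")
  cfg <- list(domain_size = as.numeric(domain_size),
              fan_fraction = fan_fraction,
              lambda_fan = lambda_fan, lambda_network = lambda_network,
              hardcore_radius = hardcore_radius,
              diameter_mean = diameter_mean, diameter_cv = diameter_cv,
              n_grids = as.integer(n_grids), grid_pitch = grid_pitch,
              n_genes = as.integer(n_genes),
              n_markers_per_program = as.integer(n_markers_per_program),
              program_log2fc = program_log2fc, wave_speed = wave_speed,
              libsize_grid = libsize_grid, libsize_nucleus = libsize_nucleus,
              libsize_amoeba = libsize_amoeba, nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# wave multiplier exp(a * cos(phase - peak)); a chosen so the peak-to-trough
# ratio equals 2^program_log2fc
wave_amplitude_from <- function(cfg) log(2) * cfg$program_log2fc / 2

matern_proposal_intensity <- function(lambda, r) {
  if (r == 0) return(lambda)
  occ <- lambda * pi * r^2
  if (occ >= 1)
    stop(sprintf(paste0("requested intensity %.4g exceeds the hard-core ",
                        "packing bound %.4g for radius %g um"),
                 lambda, 1 / (pi * r^2), r))
  -log(1 - occ) / (pi * r^2)
}

# Matern II dependent thinning: keep a proposal iff no other proposal within
# r carries a smaller mark. Chunked vectorised distance scan (memory-bounded).
matern_thin <- function(x, y, marks, r, chunk = 512L) {
  n <- length(x)
  if (n == 0 || r == 0) return(rep(TRUE, n))
  keep <- logical(n)
  r2 <- r^2
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[idx], x, `-`)^2 + outer(y[idx], y, `-`)^2
    within <- d2 < r2
    within[cbind(seq_along(idx), idx)] <- FALSE
    mm <- matrix(marks, nrow = length(idx), ncol = n, byrow = TRUE)
    mm[!within] <- Inf
    keep[idx] <- marks[idx] < apply(mm, 1, min)
  }
  keep
}

#' Simulate a hard-core inhomogeneous nuclei point pattern
#'
#' Nuclei centres follow a Matern II hard-core process with intensity
#' `lambda_fan` in the fan band (top `fan_fraction` of the y-axis) and
#' `lambda_network` below it. The proposal intensity is inverted analytically
#' so the realised intensity matches the requested one; intensities beyond
#' the packing bound `1/(pi r^2)` raise an error. Diameters are log-normal
#' with the configured mean and CV.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `pattern` ([point_pattern()]) and `truth`
#'   (region label per point, the true fan boundary y, and the generative
#'   parameters).
#' @export
simulate_nuclei_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  W <- cfg$domain_size[1]; H <- cfg$domain_size[2]
  y_boundary <- (1 - cfg$fan_fraction) * H
  r <- cfg$hardcore_radius
  lp_fan <- matern_proposal_intensity(cfg$lambda_fan, r)
  lp_net <- matern_proposal_intensity(cfg$lambda_network, r)
  n_net <- stats::rpois(1, lp_net * W * y_boundary)
  n_fan <- stats::rpois(1, lp_fan * W * (H - y_boundary))
  x <- c(stats::runif(n_net, 0, W), stats::runif(n_fan, 0, W))
  y <- c(stats::runif(n_net, 0, y_boundary),
         stats::runif(n_fan, y_boundary, H))
  marks <- stats::runif(n_net + n_fan)
  keep <- matern_thin(x, y, marks, r)
  x <- x[keep]; y <- y[keep]
  sdlog <- sqrt(log(1 + cfg$diameter_cv^2))
  meanlog <- log(cfg$diameter_mean) - sdlog^2 / 2
  diam <- stats::rlnorm(length(x), meanlog, sdlog)
  pat <- point_pattern(x, y, domain = c(0, W, 0, H), diameter = diam)
  region <- ifelse(y >= y_boundary, "fan", "network")
  truth <- synthetic_truth(
    region_of_point = stats::setNames(region, pat$points$id),
    params = list(lambda_fan = cfg$lambda_fan,
                  lambda_network = cfg$lambda_network,
                  y_boundary = y_boundary, hardcore_radius = r,
                  note = "distributional stand-in; no generative model exists for the real organism"))
  list(pattern = pat, truth = truth)
}

#' Render a point pattern into a synthetic fluorescence image
#'
#' Stand-in for a deconvolved, maximum-projected micrograph: every nucleus
#' becomes an isotropic Gaussian spot whose sd combines its physical radius
#' and the optical blur, plus additive Gaussian background noise. A label
#' mask carries ground-truth object ids (nearest nucleus within its radius).
#'
#' @param pattern a [point_pattern()]; points must lie inside its domain.
#' @param pixel_size um per pixel (> 0).
#' @param psf_sigma optical blur sd (um).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @return list with `image` (rows = y, bottom row first) and `mask`
#'   (integer label matrix, 0 = background), plus `pixel_size`.
#' @export
render_nuclei_image <- function(pattern, pixel_size = 1, psf_sigma = 1,
                                noise_sd = 0) {
  stopifnot(inherits(pattern, "PointPattern"), pixel_size > 0, psf_sigma >= 0)
  d <- pattern$domain
  nc <- max(1L, ceiling((d[2] - d[1]) / pixel_size))
  nr <- max(1L, ceiling((d[4] - d[3]) / pixel_size))
  px <- d[1] + (seq_len(nc) - 0.5) * pixel_size
  py <- d[3] + (seq_len(nr) - 0.5) * pixel_size
  img <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  pts <- pattern$points
  diam <- if ("diameter" %in% names(pts)) pts$diameter else
    rep(4 * pixel_size, nrow(pts))
  best_d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pts))) {
    sd_i <- sqrt(psf_sigma^2 + (diam[i] / 4)^2)
    gx <- exp(-((px - pts$x[i])^2) / (2 * sd_i^2))
    gy <- exp(-((py - pts$y[i])^2) / (2 * sd_i^2))
    img <- img + outer(gy, gx)
    # label: pixels within the nucleus radius, nearest centre wins
    rad <- diam[i] / 2
    jx <- which(abs(px - pts$x[i]) <= rad)
    jy <- which(abs(py - pts$y[i]) <= rad)
    if (length(jx) && length(jy)) {
      d2 <- outer((py[jy] - pts$y[i])^2, (px[jx] - pts$x[i])^2, `+`)
      upd <- d2 <= rad^2 & d2 < best_d2[jy, jx, drop = FALSE]
      if (any(upd)) {
        sub_m <- mask[jy, jx, drop = FALSE]
        sub_b <- best_d2[jy, jx, drop = FALSE]
        sub_m[upd] <- i
        sub_b[upd] <- d2[upd]
        mask[jy, jx] <- sub_m
        best_d2[jy, jx] <- sub_b
      }
    }
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  list(image = img, mask = mask, pixel_size = pixel_size)
}

#' Ground-truth bundle for synthetic data
#'
#' @param ... named truth fields (`region_of_grid`, `phase_of_grid`,
#'   `program_genes`, `cluster_of_nucleus`, `region_of_point`,
#'   `phase_of_cell`, `params`).
#' @return list of class `SyntheticTruth`.
#' @export
synthetic_truth <- function(...) {
  truth <- list(...)
  if (!is.null(truth$program_genes)) {
    gs <- truth$program_genes
    if (length(gs) > 1) {
      all_g <- unlist(gs, use.names = FALSE)
      if (anyDuplicated(all_g)) stop("program gene sets must be disjoint")
    }
  }
  class(truth) <- "SyntheticTruth"
  truth
}

make_gene_programs <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  m <- cfg$n_markers_per_program
  list(genes = genes,
       program_genes = list(fan = genes[1:m],
                            network = genes[(m + 1):(2 * m)],
                            oat = genes[(2 * m + 1):(3 * m)],
                            wave = genes[(3 * m + 1):(4 * m)]))
}

#' Simulate a gridded spatial transcriptome with planted programs
#'
#' Grids tile a `rows x cols` layout at `grid_pitch` spacing. Expected
#' expression per grid is baseline abundance times a region fold-change
#' (fan / network / oat programs, the oat program in a 4 x 4 food-contact
#' block) times a strictly positive cyclic wave factor
#' `exp(a cos(phase - peak))` for wave genes, with phase advancing by
#' `wave_speed` per column. Counts are negative binomial with mean summing
#' to `libsize_grid` per grid (`nb_dispersion = Inf` gives Poisson).
#'
#' @param cfg a [sim_config()].
#' @param specimen specimen label stored in sample metadata.
#' @param wave_amplitude override of the wave factor amplitude `a`
#'   (default derived from `program_log2fc`; 0 disables the wave).
#' @return list with `counts` (ExpressionMatrix), `layout` (a
#'   [grid_layout()] data.frame) and `truth`.
#' @export
simulate_spatial_grids <- function(cfg, specimen = "SM1",
                                   wave_amplitude = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)
  rows <- cfg$n_grids[1]; cols <- cfg$n_grids[2]
  gp <- make_gene_programs(cfg)
  layout <- grid_layout(expand.grid(row = seq_len(rows), col = seq_len(cols)),
                        pitch = cfg$grid_pitch)
  height <- rows * cfg$grid_pitch
  region <- ifelse(layout$y_center_um >= (1 - cfg$fan_fraction) * height,
                   "fan", "network")
  oat <- layout$row <= 4 & layout$col <= 4 & region == "network"
  region[oat] <- "oat"
  phase <- ((layout$col - 1) * cfg$wave_speed) %% (2 * pi)
  a <- if (is.null(wave_amplitude)) wave_amplitude_from(cfg) else wave_amplitude
  base <- stats::rlnorm(cfg$n_genes, 0, 1)
  names(base) <- gp$genes
  fc <- 2^cfg$program_log2fc
  peaks <- stats::runif(cfg$n_markers_per_program, 0, 2 * pi)
  n_grid <- nrow(layout)
  counts <- matrix(0L, cfg$n_genes, n_grid,
                   dimnames = list(gp$genes, layout$grid_id))
  for (j in seq_len(n_grid)) {
    mu <- base
    mu[gp$program_genes[[region[j]]]] <-
      mu[gp$program_genes[[region[j]]]] * fc
    if (a > 0)
      mu[gp$program_genes$wave] <-
        mu[gp$program_genes$wave] * exp(a * cos(phase[j] - peaks))
    mu <- mu / sum(mu) * cfg$libsize_grid
    counts[, j] <- if (is.infinite(cfg$nb_dispersion))
      stats::rpois(cfg$n_genes, mu)
    else
      stats::rnbinom(cfg$n_genes, mu = mu, size = cfg$nb_dispersion)
  }
  meta <- data.frame(specimen = specimen, x = layout$x_center_um,
                     y = layout$y_center_um, row.names = layout$grid_id)
  em <- expression_matrix(counts, "counts", meta)
  truth <- synthetic_truth(
    region_of_grid = stats::setNames(region, layout$grid_id),
    phase_of_grid = stats::setNames(phase, layout$grid_id),
    program_genes = gp$program_genes,
    params = list(wave_amplitude = a, wave_peaks = peaks,
                  program_log2fc = cfg$program_log2fc,
                  note = "distributional stand-in; no generative model exists for the real organism"))
  list(counts = em, layout = layout, truth = truth)
}

draw_multinomial_counts <- function(profiles, group, depth_mean, genes) {
  n <- length(group)
  depth <- stats::rpois(n, depth_mean)
  trip_i <- vector("list", n); trip_x <- vector("list", n)
  for (j in seq_len(n)) {
    cj <- stats::rmultinom(1, depth[j], profiles[, group[j]])[, 1]
    nz <- which(cj > 0)
    trip_i[[j]] <- nz
    trip_x[[j]] <- cj[nz]
  }
  lens <- lengths(trip_i)
  Matrix::sparseMatrix(i = unlist(trip_i),
                       j = rep.int(seq_len(n), lens),
                       x = unlist(trip_x),
                       dims = c(length(genes), n),
                       dimnames = list(genes, paste0("n", seq_len(n))))
}

#' Simulate shallow single-nucleus UMI counts
#'
#' Every nucleus is assigned a program: either a region program
#' (fan / network) or, when `n_phase_bins > 0`, a mitotic-wave phase bin.
#' The UMI vector is multinomial at depth ~ Poisson(`libsize_nucleus`) from
#' the program's relative-expression profile, emulating libraries of a few
#' hundred UMIs. Column sums equal the drawn library sizes by construction.
#'
#' @param cfg a [sim_config()].
#' @param n_nuclei number of nuclei.
#' @param programs region programs to use when `n_phase_bins == 0`; pass a
#'   single program for a null (structureless) dataset.
#' @param n_phase_bins if > 0, nuclei are spread over this many wave-phase
#'   bins instead of region programs.
#' @return list with `counts` (sparse ExpressionMatrix) and `truth`
#'   (`cluster_of_nucleus`, `phase_of_nucleus`, `program_genes`).
#' @export
simulate_nuclei_counts <- function(cfg, n_nuclei = 1000,
                                   programs = c("fan", "network"),
                                   n_phase_bins = 0) {
  stopifnot(inherits(cfg, "SimulationConfig"), n_nuclei >= 1)
  set.seed(cfg$seed + 2L)
  gp <- make_gene_programs(cfg)
  base <- stats::rlnorm(cfg$n_genes, 0, 1)
  names(base) <- gp$genes
  fc <- 2^cfg$program_log2fc
  a <- wave_amplitude_from(cfg)
  peaks <- stats::runif(cfg$n_markers_per_program, 0, 2 * pi)
  if (n_phase_bins > 0) {
    centers <- 2 * pi * (seq_len(n_phase_bins) - 1) / n_phase_bins
    prog_names <- sprintf("phase_%d", seq_len(n_phase_bins))
    profiles <- sapply(centers, function(ph) {
      mu <- base
      mu[gp$program_genes$wave] <- mu[gp$program_genes$wave] *
        exp(a * cos(ph - peaks))
      mu / sum(mu)
    })
    colnames(profiles) <- prog_names
    phase_of <- stats::setNames(centers, prog_names)
  } else {
    stopifnot(all(programs %in% names(gp$program_genes)))
    prog_names <- programs
    profiles <- sapply(programs, function(p) {
      mu <- base
      mu[gp$program_genes[[p]]] <- mu[gp$program_genes[[p]]] * fc
      mu / sum(mu)
    })
    colnames(profiles) <- prog_names
    phase_of <- stats::setNames(rep(NA_real_, length(prog_names)), prog_names)
  }
  group <- sample(prog_names, n_nuclei, replace = TRUE)
  counts <- draw_multinomial_counts(profiles, group, cfg$libsize_nucleus,
                                    gp$genes)
  em <- expression_matrix(counts, "counts")
  truth <- synthetic_truth(
    cluster_of_nucleus = stats::setNames(group, colnames(counts)),
    phase_of_nucleus = stats::setNames(phase_of[group], colnames(counts)),
    program_genes = gp$program_genes,
    params = list(wave_amplitude = a, wave_peaks = peaks,
                  note = "distributional stand-in; no generative model exists for the real organism"))
  list(counts = em, truth = truth)
}

#' Simulate deep single-cell amoeba UMI counts
#'
#' As [simulate_nuclei_counts()] but with a continuous cell-cycle phase per
#' cell (uniform on [0, 2pi)) modulating the wave genes, and libraries
#' averaging `libsize_amoeba` UMIs (the mRNA-rich cytoplasm sampled in whole
#' cells). `cyclic = FALSE` removes the phase programs (null model).
#'
#' @param cfg a [sim_config()].
#' @param n_cells number of cells.
#' @param cyclic whether the cyclic phase program modulates expression.
#' @return list with `counts` (sparse ExpressionMatrix) and `truth`
#'   (`phase_of_cell`, `program_genes`).
#' @export
simulate_amoeba_counts <- function(cfg, n_cells = 400, cyclic = TRUE) {
  stopifnot(inherits(cfg, "SimulationConfig"), n_cells >= 1)
  set.seed(cfg$seed + 3L)
  gp <- make_gene_programs(cfg)
  base <- stats::rlnorm(cfg$n_genes, 0, 1)
  names(base) <- gp$genes
  a <- wave_amplitude_from(cfg)
  peaks <- stats::runif(cfg$n_markers_per_program, 0, 2 * pi)
  phase <- stats::runif(n_cells, 0, 2 * pi)
  depth <- stats::rpois(n_cells, cfg$libsize_amoeba)
  trip_i <- vector("list", n_cells); trip_x <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    mu <- base
    if (cyclic)
      mu[gp$program_genes$wave] <- mu[gp$program_genes$wave] *
        exp(a * cos(phase[j] - peaks))
    cj <- stats::rmultinom(1, depth[j], mu / sum(mu))[, 1]
    nz <- which(cj > 0)
    trip_i[[j]] <- nz
    trip_x[[j]] <- cj[nz]
  }
  counts <- Matrix::sparseMatrix(i = unlist(trip_i),
                                 j = rep.int(seq_len(n_cells),
                                             lengths(trip_i)),
                                 x = unlist(trip_x),
                                 dims = c(cfg$n_genes, n_cells),
                                 dimnames = list(gp$genes,
                                                 paste0("c", seq_len(n_cells))))
  em <- expression_matrix(counts, "counts")
  truth <- synthetic_truth(
    phase_of_cell = stats::setNames(phase, colnames(counts)),
    program_genes = gp$program_genes,
    params = list(wave_amplitude = if (cyclic) a else 0, wave_peaks = peaks,
                  cyclic = cyclic,
                  note = "distributional stand-in; no generative model exists for the real organism"))
  list(counts = em, truth = truth)
}
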