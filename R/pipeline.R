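#' Pipeline run configuration
#'
#' Flat, fully serialisable configuration for [run_pipeline()]. Unknown
#' keys are rejected so a config always round-trips through the manifest.
#'
#' @param seed integer seed forwarded to the simulation config.
#' @param outdir output directory of the run.
#' @param stages ordered subset of
#'   `c("simulate", "density", "grids", "markers", "map", "wave")`.
#' @param sim named list of [sim_config()] overrides.
#' @param density list: `cell_size` (um) for the KDE map.
#' @param markers list: `min_pct`, `logfc_min` for [rank_markers()].
#' @param map list: `top_n` markers, `n_nuclei` simulated nuclei.
#' @param wave list: `n_phase_bins`, `n_nuclei`.
#' @return validated list of class `RunConfig`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("plasmap_run_"),
                       stages = c("simulate", "density", "grids", "markers",
                                  "map", "wave"),
                       sim = list(), density = list(cell_size = 25),
                       markers = list(min_pct = 0.1, logfc_min = 0.25),
                       map = list(top_n = 50, n_nuclei = 600),
                       wave = list(n_phase_bins = 8, n_nuclei = 400)) {
  all_stages <- c("simulate", "density", "grids", "markers", "map", "wave")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
  }
  check_keys(sim, names(formals(sim_config)), "sim")
  check_keys(density, "cell_size", "density")
  check_keys(markers, c("min_pct", "logfc_min"), "markers")
  check_keys(map, c("top_n", "n_nuclei"), "map")
  check_keys(wave, c("n_phase_bins", "n_nuclei"), "wave")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 stages = stages, sim = sim, density = density,
                 markers = markers, map = map, wave = wave),
            class = "RunConfig")
}

run_stage <- function(name, manifest, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s (partial outputs preserved)",
                 name, conditionMessage(e)), call. = FALSE))
  manifest$stages[[name]] <- list(elapsed_s = proc.time()[["elapsed"]] - t0)
  manifest$res[[name]] <- res
  manifest
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order -- simulate (point pattern, grid
#' transcriptome, nuclei counts), density (KDE + fan/network split +
#' density t-test), grids (normalise, scale, PCA, cluster), markers
#' (Wilcoxon cluster markers), map (nuclei clustering, pseudobulk,
#' correlation projection), wave (phase-binned nuclei, diffusion ordering)
#' -- writing every artefact plus a JSON manifest (package version, seed,
#' config hash, per-stage timings). Identical config + seed reproduces an
#' identical manifest up to timings.
#'
#' @param config a [run_config()].
#' @return (invisibly) the run directory; the manifest is
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_file)
  # the hash identifies the parameters, not where the run landed
  hashable <- unclass(config)
  hashable$outdir <- NULL
  hash_file <- tempfile()
  writeLines(jsonlite::toJSON(hashable, auto_unbox = TRUE, digits = NA),
             hash_file)
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  man <- list(package = "plasmap",
              version = as.character(utils::packageVersion("plasmap")),
              seed = config$seed,
              config_hash = unname(tools::md5sum(hash_file)),
              stages = list(), res = list())
  st <- config$stages
  sim <- NULL; grids <- NULL; nuc <- NULL

  if ("simulate" %in% st) man <- run_stage("simulate", man, function() {
    simp <- simulate_nuclei_pattern(cfg)
    write_point_csv(simp$pattern, file.path(out, "nuclei_points.csv"))
    write_truth_json(simp$truth, file.path(out, "nuclei_truth.json"))
    g <- simulate_spatial_grids(cfg)
    write_grid_table(g$counts, g$layout, file.path(out, "grid_counts.tsv"),
                     file.path(out, "grid_coords.csv"))
    write_truth_json(g$truth, file.path(out, "grid_truth.json"))
    nc <- simulate_nuclei_counts(cfg, n_nuclei = config$map$n_nuclei)
    write_mtx(nc$counts, out, prefix = "nuclei_")
    list(pattern = simp, grids = g, nuclei = nc)
  })
  sim <- man$res$simulate
  if ("density" %in% st) man <- run_stage("density", man, function() {
    if (is.null(sim)) stop("density stage needs the simulate stage")
    map <- kde_density_map(sim$pattern$pattern,
                           cell_size = config$density$cell_size)
    split <- fan_network_split(map)
    fan_rows <- which(split$bin_labels == "fan")
    tt <- density_ttest(as.vector(map$values[fan_rows, ]),
                        as.vector(map$values[-fan_rows, ]))
    res <- list(boundary_y = split$boundary_y, threshold = split$threshold,
                t = tt$t, p = tt$p,
                mean_fan = tt$mean_fan, mean_network = tt$mean_network)
    jsonlite::write_json(res, file.path(out, "density_split.json"),
                         auto_unbox = TRUE, digits = NA)
    list(map = map, split = split, ttest = tt)
  })
  if ("grids" %in% st) man <- run_stage("grids", man, function() {
    if (is.null(sim)) stop("grids stage needs the simulate stage")
    ln <- lognormalize(sim$grids$counts)
    sc <- scale_with_regression(ln)
    pc <- run_pca(sc, n_pcs = min(10, ncol(sc$values) - 1))
    hc <- cluster_hierarchical(sc, k = 3)
    utils::write.table(
      data.frame(grid_id = names(hc$cluster), cluster = hc$cluster),
      file.path(out, "grid_clusters.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    list(lognorm = ln, scaled = sc, pca = pc, clusters = hc)
  })
  grids <- man$res$grids
  if ("markers" %in% st) man <- run_stage("markers", man, function() {
    if (is.null(grids)) stop("markers stage needs the grids stage")
    mk <- rank_markers(grids$lognorm, grids$clusters,
                       min_pct = config$markers$min_pct,
                       logfc_min = config$markers$logfc_min)
    write_marker_tsv(mk, file.path(out, "grid_markers.tsv"))
    mk
  })
  if ("map" %in% st) man <- run_stage("map", man, function() {
    if (is.null(sim) || is.null(grids) || is.null(man$res$markers))
      stop("map stage needs simulate, grids and markers stages")
    nln <- lognormalize(sim$nuclei$counts)
    npc <- run_pca(scale_with_regression(nln),
                   n_pcs = min(10, ncol(nln$values) - 1))
    ncl <- cluster_graph(npc$scores, k_neighbors = 15, resolution = 0.5,
                         seed = config$seed)
    npb <- pseudobulk(nln, ncl, source = "nuclei")
    spb <- pseudobulk(grids$lognorm, grids$clusters, source = "spatial")
    cm <- map_clusters(npb, spb, man$res$markers, top_n = config$map$top_n)
    utils::write.table(cm$raw, file.path(out, "map_raw.tsv"), sep = "\t",
                       quote = FALSE)
    utils::write.table(cm$scaled, file.path(out, "map_scaled.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(cm$dendrogram))
      write_newick(cm$dendrogram, file.path(out, "map_dendrogram.nwk"))
    cm
  })
  if ("wave" %in% st) man <- run_stage("wave", man, function() {
    wnuc <- simulate_nuclei_counts(cfg, n_nuclei = config$wave$n_nuclei,
                                   n_phase_bins = config$wave$n_phase_bins)
    wln <- lognormalize(wnuc$counts)
    wave_genes <- wnuc$truth$program_genes$wave
    dm <- diffusion_map(t(as_dense(wln$values)[wave_genes, ]))
    ord <- order_by_groups(dm$components,
                           wnuc$truth$cluster_of_nucleus,
                           as.list(sprintf("phase_%d",
                                           seq_len(config$wave$n_phase_bins))))
    utils::write.csv(
      data.frame(sample_id = names(ord$rank), rank = ord$rank,
                 component = ord$component_values[names(ord$rank)]),
      file.path(out, "wave_ordering.csv"), row.names = FALSE, quote = FALSE)
    list(ordering = ord, truth = wnuc$truth)
  })
  manifest <- man[c("package", "version", "seed", "config_hash")]
  manifest$stages <- man$stages
  manifest$outputs <- sort(setdiff(list.files(out), "manifest.json"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
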