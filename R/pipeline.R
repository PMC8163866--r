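# Pipeline orchestration: phantom -> virtual scan -> pre-processing ->
# k-means -> background rejection for each modality, plus the full
# cross-modality run driven by one YAML run configuration.

#' Truth tissue mask of a phantom at a scan resolution
#'
#' @param phantom A [tissue_phantom()].
#' @param resolution_um Scan pixel pitch (phantom pitch must divide it).
#' @param field_mm Scan extent; `NULL` = full phantom.
#' @return Logical matrix, `TRUE` on tissue.
#' @export
phantom_tissue_mask <- function(phantom, resolution_um, field_mm = NULL) {
  scan_labels(phantom, resolution_um, field_mm) > 0L
}

#' MIR arm of the workflow
#'
#' Simulates the four-laser scan, runs the fixed pre-processing chain,
#' stacks the per-laser images into features, clusters with k-means and
#' rejects background clusters against a tissue mask (phantom truth by
#' default, Otsu on mean absorbance otherwise).
#'
#' @param phantom A [tissue_phantom()].
#' @param k Cluster count.
#' @param scanner A [scanner_config()].
#' @param seed Seed for both the scan and the clustering.
#' @param preprocess Named list of [preprocess_mir()] arguments.
#' @param restarts k-means restarts (default 5).
#' @param mask_source `"truth"` or `"otsu"`.
#' @param majority Background-rejection majority (default 0.5).
#' @param cluster_within_mask Restrict clustering itself to the tissue mask
#'   (used for nearly-binary tissues whose coarse partition would otherwise
#'   be slide-vs-tissue); default FALSE: cluster first, reject second.
#' @return List: `scan`, `images` (processed), `features`, `map`
#'   (a `label_map` after rejection), `tissue_mask`.
#' @export
run_mir_pipeline <- function(phantom, k, scanner = scanner_config(), seed = 1,
                             preprocess = list(), restarts = 5L,
                             mask_source = c("truth", "otsu"), majority = 0.5,
                             cluster_within_mask = FALSE) {
  mask_source <- match.arg(mask_source)
  scan <- simulate_mir_scan(phantom, scanner, seed = seed)
  prep <- do.call(preprocess_mir, c(list(scan), preprocess))
  feats <- stack_features(prep$images)
  tissue <- if (mask_source == "truth")
    phantom_tissue_mask(phantom, scanner$spatial_resolution_um, scanner$field_mm)
  else {
    mean_a <- Reduce(`+`, lapply(prep$images, image_values)) / length(prep$images)
    otsu_mask(mean_a)
  }
  map <- kmeans_segment(feats, k, seed = seed, restarts = restarts,
                        mask = if (cluster_within_mask) tissue else NULL)
  map <- reject_background_clusters(map, tissue, majority = majority)
  list(scan = scan, images = prep$images, manifest = prep$manifest,
       features = feats, map = map, tissue_mask = tissue)
}

#' FT-IR arm of the workflow
#'
#' Simulates the hyperspectral cube, smooths/vector-normalizes/restricts it,
#' clusters the per-pixel spectra and rejects background clusters.
#'
#' @param phantom A [tissue_phantom()].
#' @param k Cluster count.
#' @param ftir An [ftir_config()].
#' @param seed Seed for the scan and the clustering.
#' @param smooth_window,ranges [preprocess_cube()] parameters.
#' @param restarts k-means restarts.
#' @param majority Background-rejection majority.
#' @param cluster_within_mask As in [run_mir_pipeline()].
#' @return List: `cube` (raw), `processed`, `features`, `map`, `tissue_mask`.
#' @export
run_ftir_pipeline <- function(phantom, k, ftir = ftir_config(), seed = 1,
                              smooth_window = 5L,
                              ranges = list(c(750, 1500), c(2500, 4000)),
                              restarts = 5L, majority = 0.5,
                              cluster_within_mask = FALSE) {
  cube <- simulate_ftir(phantom, ftir, seed = seed)
  proc <- preprocess_cube(cube, smooth_window = smooth_window, ranges = ranges)
  feats <- stack_features(proc)
  tissue <- phantom_tissue_mask(phantom, ftir$pixel_pitch_um, ftir$field_mm)
  map <- kmeans_segment(feats, k, seed = seed, restarts = restarts,
                        mask = if (cluster_within_mask) tissue else NULL)
  map <- reject_background_clusters(map, tissue, majority = majority)
  list(cube = cube, processed = proc, features = feats, map = map,
       tissue_mask = tissue)
}

#' Kept cluster best matching a truth mask
#'
#' Scores every kept cluster of a label map by Dice against a ground-truth
#' mask and returns the best.
#'
#' @param map A `label_map`.
#' @param truth_mask Logical matrix on the same grid.
#' @return List `cluster_id`, `dice`, `mask`.
#' @export
best_matching_cluster <- function(map, truth_mask) {
  ids <- sort(unique(as.vector(map$labels)))
  ids <- ids[ids >= 0L]
  if (length(ids) == 0L) stopf("no kept clusters")
  dices <- vapply(ids, function(id)
    dice_coefficient(map$labels == id, truth_mask), numeric(1L))
  best <- which.max(dices)
  list(cluster_id = ids[best], dice = dices[best],
       mask = map$labels == ids[best])
}

# Nearest-neighbour resampling of an integer label raster onto a new pitch.
resample_labels <- function(labels, src_pitch_um, dst_pitch_um) {
  if (src_pitch_um == dst_pitch_um) return(labels)
  ext_r <- nrow(labels) * src_pitch_um
  ext_c <- ncol(labels) * src_pitch_um
  n_r <- max(1L, floor(ext_r / dst_pitch_um + 1e-9))
  n_c <- max(1L, floor(ext_c / dst_pitch_um + 1e-9))
  ri <- pmin(pmax(round(((seq_len(n_r) - 0.5) * dst_pitch_um) / src_pitch_um + 0.5), 1L),
             nrow(labels))
  ci <- pmin(pmax(round(((seq_len(n_c) - 0.5) * dst_pitch_um) / src_pitch_um + 0.5), 1L),
             ncol(labels))
  labels[ri, ci, drop = FALSE]
}

#' Default run configuration
#'
#' The documented defaults for every section of a pipeline run
#' configuration; [read_run_config()] starts from these and overlays the
#' user's YAML.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    phantom = list(type = "brain", field_mm = c(5, 5), pixel_pitch_um = 20,
                   seed = 1, water_fraction = 0,
                   nodule_diameter_mm = 3, margin_irregularity = 0.3,
                   margin_width_mm = 0),
    scanner = list(spatial_resolution_um = 20, oversampling = 10,
                   mirror_velocity_mps = 5.3, noise_sd = 0.02,
                   slide_reflectance = 1),
    ftir = list(enabled = TRUE, pixel_pitch_um = 20, wavenumber_max = 4000,
                wavenumber_min = 750, spectral_spacing = 8,
                accumulations = 2, noise_sd = 0.02),
    preprocess = list(floor = 0, low_percentile = 10, gain = 1,
                      tv_strength = 4, adapt_window = 7, tv_iterations = 60,
                      p_low = 1, p_high = 99, smooth_window = 5,
                      align_shifts = FALSE),
    segment = list(k = 4, seed = 1, restarts = 5, majority = 0.5,
                   mask = "truth", cluster_within_mask = FALSE),
    compare = list(wavenumbers = c(2790, 2926, 3350), roi = NULL,
                   mir_time_s = 3, ftir_time_s = 675))
}

#' Read and validate a run configuration
#'
#' One YAML document with sections `phantom`, `scanner`, `ftir`,
#' `preprocess`, `segment`, `compare`; every key has a documented default
#' (see [default_run_config()]); unknown sections or keys are rejected.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stopf("unknown config section(s): %s", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badk))
      stopf("unknown key(s) in section `%s`: %s", sec, paste(badk, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

build_phantom_from_config <- function(pc) {
  switch(pc$type,
    brain = make_brain_phantom(unlist(pc$field_mm), pc$pixel_pitch_um,
                               water_fraction = pc$water_fraction,
                               seed = pc$seed),
    liver = make_liver_phantom(unlist(pc$field_mm), pc$pixel_pitch_um,
                               nodule_diameter_mm = pc$nodule_diameter_mm,
                               margin_irregularity = pc$margin_irregularity,
                               margin_width_mm = pc$margin_width_mm,
                               water_fraction = pc$water_fraction,
                               seed = pc$seed),
    stopf("unknown phantom type `%s` (brain or liver)", pc$type))
}

#' Run the full two-modality workflow from one configuration
#'
#' Generates the phantom, simulates and segments both modalities, computes
#' the per-wavenumber similarity report, the segmentation concordance and
#' the throughput report, and (optionally) writes every artefact plus a
#' re-run manifest under `out_dir`.
#'
#' @param config Configuration list from [read_run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List: `phantom`, `mir`, `ftir`, `similarity`, `concordance`,
#'   `throughput`, `timings_s`.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL) {
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  phantom <- build_phantom_from_config(config$phantom)
  t_all$phantom <- tic() - t0

  pp <- config$preprocess
  mir_pre <- pp[setdiff(names(pp), "smooth_window")]
  sc <- config$scanner
  scanner <- scanner_config(spatial_resolution_um = sc$spatial_resolution_um,
                            oversampling = sc$oversampling,
                            mirror_velocity_mps = sc$mirror_velocity_mps,
                            noise_sd = sc$noise_sd,
                            slide_reflectance = sc$slide_reflectance)
  sg <- config$segment
  t0 <- tic()
  mir <- run_mir_pipeline(phantom, k = sg$k, scanner = scanner,
                          seed = sg$seed, preprocess = mir_pre,
                          restarts = sg$restarts, mask_source = sg$mask,
                          majority = sg$majority,
                          cluster_within_mask = isTRUE(sg$cluster_within_mask))
  t_all$mir <- tic() - t0

  ftir_res <- NULL; similarity <- NULL; concordance <- NULL; throughput <- NULL
  if (isTRUE(config$ftir$enabled)) {
    fc <- config$ftir
    fcfg <- ftir_config(wavenumber_max = fc$wavenumber_max,
                        wavenumber_min = fc$wavenumber_min,
                        spectral_spacing = fc$spectral_spacing,
                        pixel_pitch_um = fc$pixel_pitch_um,
                        accumulations = fc$accumulations,
                        noise_sd = fc$noise_sd)
    t0 <- tic()
    ftir_res <- run_ftir_pipeline(phantom, k = sg$k, ftir = fcfg,
                                  seed = sg$seed,
                                  smooth_window = pp$smooth_window,
                                  restarts = sg$restarts,
                                  majority = sg$majority,
                                  cluster_within_mask = isTRUE(sg$cluster_within_mask))
    t_all$ftir <- tic() - t0

    t0 <- tic()
    similarity <- channel_similarity(mir$images, ftir_res$cube,
                                     wavenumbers = unlist(config$compare$wavenumbers),
                                     roi = config$compare$roi)
    fmap <- ftir_res$map
    fmap$labels <- resample_labels(fmap$labels, fcfg$pixel_pitch_um,
                                   scanner$spatial_resolution_um)
    d_m <- dim(mir$map$labels); d_f <- dim(fmap$labels)
    n_r <- min(d_m[1L], d_f[1L]); n_c <- min(d_m[2L], d_f[2L])
    mmap <- mir$map
    mmap$labels <- mmap$labels[seq_len(n_r), seq_len(n_c)]
    fmap$labels <- fmap$labels[seq_len(n_r), seq_len(n_c)]
    concordance <- label_concordance(mmap, fmap)
    throughput <- throughput_report(
      field_mm = if (is.null(scanner$field_mm))
        dim(phantom$labels) * phantom$pixel_pitch_um / 1e3 else scanner$field_mm,
      mir_config = scanner, mir_time_s = config$compare$mir_time_s,
      ftir_cfg = fcfg, ftir_time_s = config$compare$ftir_time_s)
    t_all$compare <- tic() - t0
  }

  out <- list(phantom = phantom, mir = mir, ftir = ftir_res,
              similarity = similarity, concordance = concordance,
              throughput = throughput, timings_s = t_all)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_phantom(result$phantom, file.path(out_dir, "phantom"))
  write_mir_scan(result$mir$scan, file.path(out_dir, "mir_scan"))
  write_label_map(result$mir$map, file.path(out_dir, "mir_labels"))
  if (!is.null(result$ftir)) {
    write_cube(result$ftir$cube, file.path(out_dir, "ftir_cube.bsq"))
    write_label_map(result$ftir$map, file.path(out_dir, "ftir_labels"))
  }
  if (!is.null(result$similarity)) {
    utils::write.csv(result$similarity$table,
                     file.path(out_dir, "similarity.csv"), row.names = FALSE)
  }
  if (!is.null(result$throughput)) {
    tr <- result$throughput
    utils::write.csv(data.frame(
      modality = c("mir", "ftir"),
      pixels = c(tr$mir$pixels, tr$ftir$pixels),
      channels = c(tr$mir$channels, tr$ftir$channels),
      values_total = c(tr$mir$values_total, tr$ftir$values_total),
      scan_time_s = c(tr$mir$scan_time_s, tr$ftir$scan_time_s)),
      file.path(out_dir, "throughput.csv"), row.names = FALSE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("mirscan")),
                   config = config, timings_s = result$timings_s)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
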