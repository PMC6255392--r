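#' Default pipeline configuration
#'
#' A desk-scale end-to-end run: a small synthetic tissue block, the standard
#' 5 x 5 um / 140 nm disector geometry, the deformation cascade at its
#' typical magnitudes (2.2% per-axis embedding dilation, 1.4% X dilation,
#' 17.9% Y shrinkage, 1.5% thinner sections), log-normal size statistics and
#' the jackknife percent-symmetric estimate.
#'
#' @param seed global RNG seed.
#' @return Nested list understood by [run_pipeline()]; serialises losslessly
#'   to YAML.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    tissue = list(box_dims = c(16, 16, 5.6),
                  density_asym = 5.6e8, density_sym = 1.4e8,
                  feret_scale = 200, size_log_sigma = 0.8,
                  cleft_range_asym = c(30, 50), cleft_range_sym = c(20, 40),
                  mito_count = 20, mito_diameter_range = c(300, 800)),
    deformation = list(Re = 1.022^3, RX = 1.014, RY = 0.821, RZ = 0.985),
    grid = list(frame_size = 5, section_spacing = 70, lookup_offset = 2,
                ref_step = 6, guard_xy = 0.5, guard_z = 4),
    masks = list(render = FALSE, pixel_size = 40, max_px = 512),
    output = list(dir = "synstereo-run")
  )
}

#' Read / write a pipeline configuration
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  config <- modifyList(default_config(), config)
  tis <- config$tissue
  if (any(unlist(tis[c("density_asym", "density_sym")]) < 0))
    stop_input("densities must be non-negative")
  if (any(unlist(tis$box_dims) <= 0)) stop_input("box dimensions must be positive")
  config
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> section -> calibrate -> count -> sizes -> stats,
#' writing every intermediate artifact (CSV tables, JSON estimates,
#' optionally TIFF masks) plus a manifest recording inputs, seeds and the
#' package version, into `out_dir`. Outputs are bit-identical for identical
#' config + seed.
#'
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `output$dir`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package = "synstereo",
                   version = as.character(utils::packageVersion("synstereo")),
                   seed = seed, stages = list())
  stage <- function(name, files) {
    manifest$stages[[name]] <<- list(files = files)
  }

  # 1. simulate ground-truth tissue
  spec <- do.call(tissue_spec, c(config$tissue, list(seed = seed)))
  tissue <- generate_tissue(spec)
  f_truth <- file.path(out_dir, "ground_truth.csv")
  write_ground_truth(tissue, f_truth)
  stage("simulate", f_truth)

  # 2. deform + section
  factors <- do.call(deformation_factors, config$deformation)
  deformed <- apply_forward_deformation(tissue, factors)
  thickness <- config$grid$section_spacing * factors$RZ
  stack <- section_tissue(deformed, thickness = thickness)
  f_fp <- file.path(out_dir, "footprints.csv")
  write.csv(stack$footprints, f_fp, row.names = FALSE)
  files <- f_fp
  if (isTRUE(config$masks$render)) {
    f_tif <- file.path(out_dir, "masks.tif")
    write_mask_stack(render_masks(stack, config$masks$pixel_size,
                                  config$masks$max_px), f_tif)
    files <- c(files, f_tif)
  }
  stage("section", files)

  # 3. calibrate the deformation cascade from synthetic measurements
  emb <- synthetic_landmarks(factors$Re^(1 / 3), seed = seed)
  cutp <- rbind(cbind(synthetic_landmarks(factors$RX, seed = seed), axis = "X"),
                cbind(synthetic_landmarks(factors$RY, seed = seed), axis = "Y"))
  cyl <- section_cylinders(deformed$mitochondria, thickness)
  fac_est <- estimate_deformation(emb, cutp, cyl,
                                  nominal = config$grid$section_spacing)
  f_fac <- file.path(out_dir, "deformation_factors.json")
  write_json_file(unclass(fac_est), f_fac)
  stage("calibrate", f_fac)

  # 4. disector counting + density
  grid_spec <- do.call(disector_grid_spec, config$grid)
  pairs <- build_disector_grid(stack, grid_spec, seed = seed)
  counts <- count_disectors(stack, pairs)
  f_cnt <- file.path(out_dir, "disector_counts.csv")
  write_disector_counts(counts, f_cnt)
  est <- estimate_density(counts, section_spacing = fac_est$t_bar,
                          factors = fac_est)
  f_den <- file.path(out_dir, "density_estimate.json")
  write_json_file(unclass(est), f_den)
  stage("count", c(f_cnt, f_den))

  # 5. synapse sizes (log-normal summaries per type, on ground truth volumes)
  sizes <- lapply(split(tissue$synapses$volume_nm3, tissue$synapses$type),
                  lognormal_stats)
  f_sz <- file.path(out_dir, "size_stats.json")
  write_json_file(lapply(sizes, unclass), f_sz)
  stage("sizes", f_sz)

  # 6. group statistics: jackknife percent symmetric
  jk <- percent_symmetric_jackknife(counts$q_sym, counts$q_total)
  f_jk <- file.path(out_dir, "percent_symmetric.json")
  write_json_file(unclass(jk), f_jk)
  stage("stats", f_jk)

  f_man <- file.path(out_dir, "manifest.json")
  write_json_file(manifest, f_man)
  invisible(list(tissue = tissue, stack = stack, factors_estimated = fac_est,
                 counts = counts, density = est, sizes = sizes, jackknife = jk,
                 manifest = manifest, out_dir = out_dir))
}
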