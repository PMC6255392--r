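#' Simulate one complete disector experiment
#'
#' Runs the full chain on synthetic tissue with known ground truth:
#' generate -> (optionally) deform -> section -> build grid -> count ->
#' estimate density (calibrated back to the wet state) -> jackknife percent
#' symmetric. When `factors` is supplied the tissue is forward-deformed and
#' the calibration factors are re-estimated from synthetic measurements
#' (noiseless landmark pairs plus the sectioned mitochondrial cylinders), so
#' the whole calibration path is exercised, not just the arithmetic.
#'
#' @param spec a [tissue_spec()]; its densities are the ground truth.
#' @param grid a [disector_grid_spec()].
#' @param factors optional [deformation_factors()] to apply forward.
#' @param seed RNG seed for tissue generation and grid sampling.
#' @param n_landmarks landmark pairs per calibration stage.
#' @return List: `estimate` ([estimate_density()]), `jackknife`
#'   ([percent_symmetric_jackknife()] or `NULL` if impossible), `counts`,
#'   `factors_estimated`, `truth` (list with wet-state `density_asym`,
#'   `density_sym`, `density_total`, `fraction_sym`), `n_objects`.
#' @export
simulate_disector_experiment <- function(spec, grid = disector_grid_spec(),
                                         factors = NULL, seed = NULL,
                                         n_landmarks = 3) {
  spec$seed <- seed %||% spec$seed
  tissue <- generate_tissue(spec)
  thickness <- grid$section_spacing
  fac_est <- NULL
  if (!is.null(factors)) {
    tissue <- apply_forward_deformation(tissue, factors)
    # sections are cut so that the measured thickness reflects RZ
    thickness <- grid$section_spacing * factors$RZ
    fac_est <- estimate_deformation(
      embedding_pairs = synthetic_landmarks(factors$Re^(1 / 3), n_landmarks, seed),
      cutting_pairs = rbind(
        cbind(synthetic_landmarks(factors$RX, n_landmarks, seed), axis = "X"),
        cbind(synthetic_landmarks(factors$RY, n_landmarks, seed), axis = "Y")),
      cylinders = section_cylinders(tissue$mitochondria, thickness),
      nominal = grid$section_spacing)
  }
  stack <- section_tissue(tissue, thickness = thickness)
  pairs <- build_disector_grid(stack, grid, seed = seed)
  counts <- count_disectors(stack, pairs)
  # the analyst works with the *measured* thickness; its error cancels in
  # the calibrated product (raw ~ 1/t_bar, Rcum ~ t_bar)
  est <- estimate_density(counts,
                          section_spacing = if (is.null(fac_est)) thickness
                                            else fac_est$t_bar,
                          factors = fac_est %||% 1)
  jk <- NULL
  if (sum(counts$q_total) > 0 && nrow(counts) >= 2 &&
      all(sum(counts$q_total) - counts$q_total > 0)) {
    jk <- percent_symmetric_jackknife(counts$q_sym, counts$q_total)
  }
  list(estimate = est, jackknife = jk, counts = counts,
       factors_estimated = fac_est,
       truth = list(density_asym = spec$density_asym,
                    density_sym = spec$density_sym,
                    density_total = spec$density_asym + spec$density_sym,
                    fraction_sym = spec$density_sym /
                      (spec$density_asym + spec$density_sym)),
       n_objects = nrow(tissue$synapses))
}

# noiseless landmark pairs at a given per-axis ratio
synthetic_landmarks <- function(ratio, n = 3, seed = NULL) {
  d0 <- with_seed(seed, runif(n, 40, 120))
  data.frame(distance_from = d0, distance_to = d0 * ratio)
}

#' Density-recovery experiment over seeds
#'
#' Repeats [simulate_disector_experiment()] over a set of seeds and reports
#' the per-seed relative errors of the estimated total density against the
#' generator's true rate, plus their mean absolute value and mean (signed)
#' value.
#'
#' @param spec,grid,factors passed to [simulate_disector_experiment()].
#' @param seeds integer vector of seeds.
#' @return List: `rel_error` (per seed, as fractions), `mean_abs_pct`,
#'   `mean_signed_pct`, `n_disectors`, `n_objects` (per-seed).
#' @export
density_recovery_experiment <- function(spec, grid = disector_grid_spec(),
                                        factors = NULL, seeds = 1:20) {
  res <- lapply(seeds, function(s)
    simulate_disector_experiment(spec, grid, factors = factors, seed = s))
  truth <- spec$density_asym + spec$density_sym
  est <- vapply(res, function(r) r$estimate$density_total, numeric(1))
  rel <- (est - truth) / truth
  list(rel_error = rel,
       mean_abs_pct = mean(abs(rel)) * 100,
       mean_signed_pct = mean(rel) * 100,
       n_disectors = vapply(res, function(r) r$estimate$n_disectors, numeric(1)),
       n_objects = vapply(res, function(r) r$n_objects, numeric(1)))
}
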