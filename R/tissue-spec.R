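#' Specify a synthetic tissue volume
#'
#' A `tissue_spec` describes the ground-truth conditions of a synthetic
#' HVC-like tissue block: synapse number densities per type, log-normal
#' physical-size distributions, synaptic cleft thickness ranges, target mean
#' Feret diameter, and the mitochondrial cylinders used for section-thickness
#' calibration. Defaults emulate the conditions reported for songbird HVC:
#' total synapse density of 7e8/mm^3 (within the 5--8e8/mm^3 range) with a 20%
#' symmetric (inhibitory) fraction, mean Feret diameters around 200 nm,
#' symmetric cleft thicknesses of 20--40 nm and somewhat wider asymmetric
#' clefts.
#'
#' Synapses are modelled as oriented disks (diameter = Feret diameter,
#' thickness = cleft); the disk captures the geometry of flat synapses that
#' can slip between consecutive cutting planes. Physical volumes are drawn
#' log-normally per type; when `size_log_mu` is not given it is derived from
#' `feret_scale` so that the population mean Feret diameter equals
#' `feret_scale`: for volume V ~ logN(mu, sigma^2) and cleft c uniform on
#' (a, b), D = sqrt(4V / (pi c)) has mean
#' (2/sqrt(pi)) E(c^-1/2) exp(mu/2 + sigma^2/8).
#'
#' @param box_dims physical extents of the tissue box in micrometres (x, y, z).
#' @param density_asym,density_sym number densities per mm^3 of asymmetric
#'   (excitatory) and symmetric (inhibitory) synapses. Either may be zero;
#'   negative values are rejected.
#' @param size_log_sigma standard deviation of log physical volume (log nm^3),
#'   shared by both types.
#' @param size_log_mu optional named vector `c(asym = , sym = )` of log-volume
#'   means (log nm^3); derived from `feret_scale` when `NULL`.
#' @param cleft_range_asym,cleft_range_sym cleft thickness intervals in nm;
#'   must lie within (0, 100) nm.
#' @param feret_scale target population mean Feret diameter in nm.
#' @param mito_count number of mitochondrial calibration cylinders.
#' @param mito_diameter_range cylinder diameter interval in nm.
#' @param seed RNG seed; identical seeds yield identical tissue.
#' @return An object of class `tissue_spec`.
#' @seealso [generate_tissue()]
#' @export
tissue_spec <- function(box_dims = c(20, 20, 7),
                        density_asym = 5.6e8,
                        density_sym = 1.4e8,
                        size_log_sigma = 0.8,
                        size_log_mu = NULL,
                        cleft_range_asym = c(30, 50),
                        cleft_range_sym = c(20, 40),
                        feret_scale = 200,
                        mito_count = 20,
                        mito_diameter_range = c(300, 800),
                        seed = NULL) {
  if (length(box_dims) != 3) stop_input("`box_dims` must have length 3")
  check_positive(box_dims, "box_dims")
  check_positive(density_asym, "density_asym", strict = FALSE)
  check_positive(density_sym, "density_sym", strict = FALSE)
  check_positive(size_log_sigma, "size_log_sigma", strict = FALSE)
  check_positive(feret_scale, "feret_scale")
  check_positive(mito_count, "mito_count", strict = FALSE)
  check_positive(mito_diameter_range, "mito_diameter_range")
  for (rng in list(asym = cleft_range_asym, sym = cleft_range_sym)) {
    if (length(rng) != 2 || any(rng <= 0) || any(rng >= 100) || rng[1] > rng[2])
      stop_input("cleft ranges must be ordered intervals within (0, 100) nm")
  }
  if (is.null(size_log_mu)) {
    size_log_mu <- c(
      asym = derive_size_log_mu(feret_scale, size_log_sigma, cleft_range_asym),
      sym  = derive_size_log_mu(feret_scale, size_log_sigma, cleft_range_sym)
    )
  } else {
    if (is.null(names(size_log_mu)))
      size_log_mu <- setNames(rep_len(size_log_mu, 2), c("asym", "sym"))
    if (!all(c("asym", "sym") %in% names(size_log_mu)))
      stop_input("`size_log_mu` must be named with 'asym' and 'sym'")
  }
  structure(list(
    box_dims = as.numeric(box_dims),
    density_asym = density_asym, density_sym = density_sym,
    size_log_mu = size_log_mu[c("asym", "sym")],
    size_log_sigma = size_log_sigma,
    cleft_range_asym = as.numeric(cleft_range_asym),
    cleft_range_sym = as.numeric(cleft_range_sym),
    feret_scale = feret_scale,
    mito_count = mito_count,
    mito_diameter_range = as.numeric(mito_diameter_range),
    seed = seed
  ), class = "tissue_spec")
}

# E[1/sqrt(c)] for c ~ U(a, b)
mean_inv_sqrt_unif <- function(rng) {
  if (rng[2] == rng[1]) return(1 / sqrt(rng[1]))
  2 * (sqrt(rng[2]) - sqrt(rng[1])) / (rng[2] - rng[1])
}

derive_size_log_mu <- function(feret_scale, sigma, cleft_range) {
  k <- 2 / sqrt(pi) * mean_inv_sqrt_unif(cleft_range)
  2 * (log(feret_scale) - log(k)) - sigma^2 / 4
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat("Synthetic tissue specification\n")
  cat(sprintf("  box: %.1f x %.1f x %.1f um (%.0f um^3)\n",
              x$box_dims[1], x$box_dims[2], x$box_dims[3], prod(x$box_dims)))
  cat(sprintf("  densities: asym %.3g/mm^3, sym %.3g/mm^3 (%.1f%% symmetric)\n",
              x$density_asym, x$density_sym,
              100 * x$density_sym / max(x$density_asym + x$density_sym, 1)))
  cat(sprintf("  log-volume mu (asym, sym): %.3f, %.3f; sigma %.2f\n",
              x$size_log_mu[["asym"]], x$size_log_mu[["sym"]], x$size_log_sigma))
  cat(sprintf("  target mean Feret: %.0f nm; clefts asym [%g, %g] nm, sym [%g, %g] nm\n",
              x$feret_scale, x$cleft_range_asym[1], x$cleft_range_asym[2],
              x$cleft_range_sym[1], x$cleft_range_sym[2]))
  cat(sprintf("  mitochondria: %d cylinders, diameters [%g, %g] nm\n",
              x$mito_count, x$mito_diameter_range[1], x$mito_diameter_range[2]))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
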