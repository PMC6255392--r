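#' Generate synthetic tissue with known ground truth
#'
#' Places synapses of each type as independent homogeneous Poisson point
#' processes at the densities requested in the spec, draws per-type log-normal
#' physical volumes, uniform cleft thicknesses and orientations uniform on the
#' sphere, and derives each synapse's Feret diameter from its volume and cleft
#' under the oriented-disk proxy (V = pi/4 D^2 c). Mitochondria are generated
#' as cylinders with in-plane (longitudinal) axes for section-thickness
#' calibration.
#'
#' @param spec a [tissue_spec()].
#' @return An object of class `synth_tissue`: a list with `synapses` (one row
#'   per object: `id`, `type`, `x_um`, `y_um`, `z_um`, `volume_nm3`,
#'   `feret_nm`, `cleft_nm`, `nx`, `ny`, `nz`), `mitochondria` (`id`,
#'   `x_um`, `y_um`, `z_um`, `diameter_nm`, `phi`), and the `spec`.
#' @examples
#' tis <- generate_tissue(tissue_spec(box_dims = c(5, 5, 2), seed = 1))
#' nrow(tis$synapses)
#' @export
generate_tissue <- function(spec) {
  if (!inherits(spec, "tissue_spec")) stop_input("`spec` must be a tissue_spec")
  with_seed(spec$seed, {
    vol_mm3 <- prod(spec$box_dims) * 1e-9          # um^3 -> mm^3
    n_asym <- rpois(1, spec$density_asym * vol_mm3)
    n_sym  <- rpois(1, spec$density_sym * vol_mm3)
    syn <- rbind(
      draw_synapses(n_asym, "asym", spec),
      draw_synapses(n_sym, "sym", spec)
    )
    if (nrow(syn)) syn$id <- seq_len(nrow(syn))
    mito <- draw_mitochondria(spec)
    structure(list(synapses = syn, mitochondria = mito, spec = spec),
              class = "synth_tissue")
  })
}

draw_synapses <- function(n, type, spec) {
  if (n == 0) {
    return(data.frame(id = integer(), type = character(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      volume_nm3 = numeric(), feret_nm = numeric(),
                      cleft_nm = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric()))
  }
  rng_cleft <- spec[[paste0("cleft_range_", type)]]
  vol <- rlnorm(n, spec$size_log_mu[[type]], spec$size_log_sigma)
  cleft <- runif(n, rng_cleft[1], rng_cleft[2])
  feret <- sqrt(4 * vol / (pi * cleft))
  nrm <- runif_sphere(n)
  data.frame(
    id = rep(NA_integer_, n), type = type,
    x_um = runif(n, 0, spec$box_dims[1]),
    y_um = runif(n, 0, spec$box_dims[2]),
    z_um = runif(n, 0, spec$box_dims[3]),
    volume_nm3 = vol, feret_nm = feret, cleft_nm = cleft,
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3]
  )
}

# uniform unit vectors on S^2
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  a <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(a), r * sin(a), z)
}

draw_mitochondria <- function(spec) {
  n <- spec$mito_count
  if (n == 0) {
    return(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), diameter_nm = numeric(), phi = numeric()))
  }
  data.frame(
    id = seq_len(n),
    x_um = runif(n, 0, spec$box_dims[1]),
    y_um = runif(n, 0, spec$box_dims[2]),
    z_um = runif(n, 0, spec$box_dims[3]),
    diameter_nm = runif(n, spec$mito_diameter_range[1], spec$mito_diameter_range[2]),
    phi = runif(n, 0, 2 * pi)   # in-plane azimuth of the longitudinal axis
  )
}

#' @export
print.synth_tissue <- function(x, ...) {
  cat(sprintf("Synthetic tissue: %d synapses (%d asym, %d sym), %d mitochondria\n",
              nrow(x$synapses), sum(x$synapses$type == "asym"),
              sum(x$synapses$type == "sym"), nrow(x$mitochondria)))
  cat(sprintf("  box %.1f x %.1f x %.1f um\n", x$spec$box_dims[1],
              x$spec$box_dims[2], x$spec$box_dims[3]))
  invisible(x)
}

#' Write / read ground-truth object tables
#'
#' One row per object with unit-bearing column names; plain CSV.
#'
#' @param tissue a `synth_tissue` or a synapse data frame.
#' @param path file path.
#' @return `read_ground_truth` returns the synapse data frame.
#' @export
write_ground_truth <- function(tissue, path) {
  syn <- if (inherits(tissue, "synth_tissue")) tissue$synapses else tissue
  write.csv(syn, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
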