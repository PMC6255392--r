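#' Cut tissue into serial sections
#'
#' Computes each object's extent along the cutting axis from the oriented-disk
#' proxy (diameter = Feret, thickness = cleft, orientation = disk normal):
#' with u = |n_z|, the z-extent is `feret * sqrt(1 - u^2) + cleft * u` (nm).
#' Footprints are then assigned to sections under one of two conventions:
#'
#' * `"slab"` (default): sections are contiguous slabs
#'   `[k t, (k+1) t)` and an object leaves a footprint in every slab its
#'   z-interval intersects. This is the physical ssSEM picture (the whole
#'   section thickness is projected into the image) and the convention used
#'   for disector counting.
#' * `"plane"`: an object leaves a footprint in section k only if its
#'   z-interval crosses the cutting plane `z = k t`. A thin, flat object lying
#'   entirely between two consecutive planes leaves no footprint; this is the
#'   geometry behind the missed-synapse model (see [miss_probability()]).
#'
#' @param objects a `synth_tissue` or synapse data frame ([generate_tissue()]).
#' @param thickness section thickness / cutting-plane spacing in nm.
#' @param convention footprint convention, `"slab"` or `"plane"`.
#' @param n_sections number of sections; defaults to covering the tissue box
#'   (or the objects' z-range).
#' @param pixel_size optional pixel size in nm, recorded for mask rendering.
#' @return An object of class `section_stack`: list with `footprints`
#'   (`section` 0-based, `id`, `type`, `x_um`, `y_um`, `r_um` in-plane profile
#'   radius), `objects` (input rows plus `z_extent_nm`, `z0_um`, `z1_um`),
#'   `thickness_nm`, `n_sections`, `convention`, `field_dims_um`.
#' @examples
#' tis <- generate_tissue(tissue_spec(box_dims = c(5, 5, 2), seed = 1))
#' stk <- section_tissue(tis, thickness = 70)
#' stk$n_sections
#' @export
section_tissue <- function(objects, thickness = 70,
                           convention = c("slab", "plane"),
                           n_sections = NULL, pixel_size = NULL) {
  convention <- match.arg(convention)
  check_positive(thickness, "thickness")
  field <- NULL
  if (inherits(objects, "synth_tissue")) {
    field <- objects$spec$box_dims
    syn <- objects$synapses
  } else syn <- as.data.frame(objects)
  t_um <- thickness / 1000
  if (nrow(syn)) {
    u <- pmin(1, abs(syn$nz))
    ext_nm <- syn$feret_nm * sqrt(pmax(0, 1 - u^2)) + syn$cleft_nm * u
    syn$z_extent_nm <- ext_nm
    syn$z0_um <- syn$z_um - ext_nm / 2000
    syn$z1_um <- syn$z_um + ext_nm / 2000
  } else {
    syn$z_extent_nm <- numeric(0); syn$z0_um <- numeric(0); syn$z1_um <- numeric(0)
  }
  if (is.null(n_sections)) {
    zmax <- if (!is.null(field)) field[3] else if (nrow(syn)) max(syn$z1_um) else t_um
    n_sections <- max(1L, ceiling(zmax / t_um - .eps))
  }
  fp <- footprint_table(syn, t_um, n_sections, convention)
  structure(list(footprints = fp, objects = syn, thickness_nm = thickness,
                 n_sections = as.integer(n_sections), convention = convention,
                 pixel_size_nm = pixel_size,
                 field_dims_um = field,
                 deformation = attr(objects, "deformation")),
            class = "section_stack")
}

footprint_table <- function(syn, t_um, n_sections, convention) {
  empty <- data.frame(section = integer(), id = integer(), type = character(),
                      x_um = numeric(), y_um = numeric(), r_um = numeric())
  if (!nrow(syn)) return(empty)
  if (convention == "slab") {
    k0 <- floor(syn$z0_um / t_um)
    k1 <- floor(syn$z1_um / t_um)
  } else {
    k0 <- ceiling(syn$z0_um / t_um)
    k1 <- floor(syn$z1_um / t_um)
  }
  k0 <- pmax(k0, 0L)
  k1 <- pmin(k1, n_sections - 1L)
  nsec <- pmax(0L, k1 - k0 + 1L)
  if (sum(nsec) == 0) return(empty)
  idx <- rep.int(seq_len(nrow(syn)), nsec)
  sec <- unlist(lapply(seq_len(nrow(syn)),
                       function(i) if (nsec[i] > 0) seq.int(k0[i], k1[i]) else integer(0)),
                use.names = FALSE)
  data.frame(section = as.integer(sec), id = syn$id[idx],
             type = syn$type[idx], x_um = syn$x_um[idx], y_um = syn$y_um[idx],
             r_um = syn$feret_nm[idx] / 2000)
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("Section stack: %d sections of %g nm (%s convention), %d footprints from %d objects\n",
              x$n_sections, x$thickness_nm, x$convention,
              nrow(x$footprints), nrow(x$objects)))
  invisible(x)
}

#' Section the calibration cylinders
#'
#' Measures, for each longitudinally cut mitochondrial cylinder, its diameter
#' and the number of section thicknesses it spans: a cylinder whose z-extent
#' (its diameter, since the axis lies in-plane) runs from its first to its
#' last appearance spans `s = k_last - k_first` section boundaries. Cylinders
#' that cross no boundary (possible when diameter < thickness) are dropped, as
#' they carry no thickness information.
#'
#' @param mitochondria mitochondria data frame from [generate_tissue()].
#' @param thickness true section thickness in nm.
#' @return Data frame with `diameter_nm` and `sections_spanned`, ready for
#'   [estimate_section_thickness()].
#' @export
section_cylinders <- function(mitochondria, thickness = 70) {
  check_positive(thickness, "thickness")
  m <- as.data.frame(mitochondria)
  if (!nrow(m)) return(data.frame(diameter_nm = numeric(), sections_spanned = integer()))
  t_um <- thickness / 1000
  z0 <- m$z_um - m$diameter_nm / 2000
  z1 <- m$z_um + m$diameter_nm / 2000
  s <- floor(z1 / t_um) - floor(z0 / t_um)
  keep <- s >= 1
  data.frame(diameter_nm = m$diameter_nm[keep],
             sections_spanned = as.integer(s[keep]))
}
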