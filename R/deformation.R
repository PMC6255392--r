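#' Tissue deformation factors
#'
#' Bundles the deformation cascade mapping ultrathin-section measurements back
#' to the wet-tissue state: the isotropic 3D embedding factor `Re`, the
#' anisotropic cutting factors `RX` (perpendicular to the cutting direction)
#' and `RY` (parallel to it), the mean section thickness `t_bar` with its
#' ratio `RZ = t_bar / nominal`, and the cumulative volumetric factor
#' `Rcum = Re * RX * RY * RZ`.
#'
#' @param Re dimensionless 3D embedding volume factor (> 0).
#' @param RX,RY,RZ dimensionless per-axis cutting factors (> 0).
#' @param t_bar mean section thickness in nm (optional bookkeeping).
#' @return An object of class `deformation_factors`.
#' @examples
#' deformation_factors(Re = 1.022^3, RX = 1.014, RY = 0.821, RZ = 0.985)
#' @export
deformation_factors <- function(Re = 1, RX = 1, RY = 1, RZ = 1, t_bar = NA_real_) {
  for (nm in c("Re", "RX", "RY", "RZ")) check_positive(get(nm), nm)
  structure(list(Re = Re, RX = RX, RY = RY, RZ = RZ, t_bar = t_bar,
                 Rcum = Re * RX * RY * RZ),
            class = "deformation_factors")
}

#' @export
print.deformation_factors <- function(x, ...) {
  cat(sprintf("Deformation factors: Re=%.4f RX=%.4f RY=%.4f RZ=%.4f -> Rcum=%.4f\n",
              x$Re, x$RX, x$RY, x$RZ, x$Rcum))
  if (is.finite(x$t_bar)) cat(sprintf("  mean section thickness %.2f nm\n", x$t_bar))
  invisible(x)
}

#' Cumulative volumetric deformation
#'
#' `Rcum = Re * RX * RY * RZ`: the overall change in tissue volume from the
#' wet state to the ultrathin-section state.
#'
#' @param factors a [deformation_factors()] object, or a list with elements
#'   `Re`, `RX`, `RY`, `RZ`.
#' @return The dimensionless product.
#' @export
cumulative_deformation <- function(factors) {
  need <- c("Re", "RX", "RY", "RZ")
  if (!all(need %in% names(factors)))
    stop_input("`factors` must contain Re, RX, RY and RZ")
  vals <- vapply(need, function(nm) factors[[nm]], numeric(1))
  check_positive(vals, "deformation factors")
  prod(vals)
}

#' Estimate the embedding deformation factor
#'
#' The 3D embedding factor is the cube of the mean landmark-distance ratio
#' between embedded and wet sections: `Re = (mean(S_embedded / S_wet))^3`.
#' The per-pair mean-of-ratios convention matches the per-landmark formula;
#' at least three landmark pairs per sample are customary.
#'
#' @param pairs data frame with columns `distance_from` (wet, um) and
#'   `distance_to` (embedded, um); one row per landmark pair.
#' @return `Re`, dimensionless.
#' @examples
#' estimate_embedding_factor(data.frame(distance_from = c(100, 80, 60),
#'                                      distance_to = 1.022 * c(100, 80, 60)))
#' @export
estimate_embedding_factor <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1) stop_input("need at least one landmark pair")
  check_positive(pairs$distance_from, "distance_from")
  check_positive(pairs$distance_to, "distance_to")
  if (nrow(pairs) < 3)
    warning("fewer than 3 landmark pairs; estimate may be unstable")
  mean(pairs$distance_to / pairs$distance_from)^3
}

#' Estimate the anisotropic cutting deformation factors
#'
#' Ultramicrotomy deforms the section anisotropically; the per-axis factors
#' are mean landmark-distance ratios between ultrathin and embedded sections,
#' estimated separately along the axis perpendicular to the cutting direction
#' (X) and parallel to it (Y).
#'
#' @param pairs data frame with columns `axis` (`"X"` or `"Y"`),
#'   `distance_from` (embedded, um) and `distance_to` (ultrathin, um).
#' @return Named numeric `c(RX = , RY = )`.
#' @export
estimate_cutting_factors <- function(pairs) {
  pairs <- as.data.frame(pairs)
  check_positive(pairs$distance_from, "distance_from")
  check_positive(pairs$distance_to, "distance_to")
  ax <- toupper(as.character(pairs$axis))
  if (!all(c("X", "Y") %in% ax))
    stop_input("`pairs` must contain landmark pairs for both axes X and Y")
  ratio <- pairs$distance_to / pairs$distance_from
  c(RX = mean(ratio[ax == "X"]), RY = mean(ratio[ax == "Y"]))
}

#' Estimate mean section thickness from cylindrical objects
#'
#' The cylindrical-diameters method: for each longitudinally cut cylindrical
#' object (typically a mitochondrion) with measured diameter `d_i` that spans
#' `s_i` section thicknesses (the number of section boundaries between its
#' first and last appearance), the mean section thickness is
#' `t_bar = mean(d_i / s_i)` and `RZ = t_bar / nominal`.
#'
#' @param cyls data frame with columns `diameter_nm` and `sections_spanned`.
#' @param nominal nominal (microtome advancement) thickness in nm, default 70.
#' @return List with `t_bar` (nm) and `RZ`.
#' @examples
#' estimate_section_thickness(data.frame(diameter_nm = c(138, 69),
#'                                       sections_spanned = c(2, 1)))
#' @export
estimate_section_thickness <- function(cyls, nominal = 70) {
  cyls <- as.data.frame(cyls)
  if (nrow(cyls) < 1) stop_input("need at least one cylinder")
  check_positive(nominal, "nominal")
  check_positive(cyls$diameter_nm, "diameter_nm")
  s <- cyls$sections_spanned
  if (any(s < 1) || any(s != round(s)))
    stop_input("`sections_spanned` must be positive integers")
  t_bar <- mean(cyls$diameter_nm / s)
  list(t_bar = t_bar, RZ = t_bar / nominal)
}

#' Calibrate a density estimate to the wet-tissue state
#'
#' Object counts are conserved across deformation while volumes scale by
#' `Rcum` (ultrathin volume = wet volume x Rcum), so the wet-state density is
#' the ultrathin-state density multiplied by `Rcum`.
#'
#' @param raw_density density measured at the ultrathin-section scale
#'   (any count-per-volume unit).
#' @param factors a [deformation_factors()] object or a single `Rcum` value.
#' @return Calibrated density, same units as `raw_density`.
#' @export
calibrate_density <- function(raw_density, factors) {
  check_positive(raw_density, "raw_density", strict = FALSE)
  rcum <- if (inherits(factors, "deformation_factors")) factors$Rcum
          else if (is.numeric(factors) && length(factors) == 1) factors
          else cumulative_deformation(factors)
  check_positive(rcum, "Rcum")
  raw_density * rcum
}

# per-axis scale factors of the forward deformation
deformation_scales <- function(factors) {
  e <- factors$Re^(1 / 3)
  c(sx = e * factors$RX, sy = e * factors$RY, sz = e * factors$RZ)
}

#' Apply or invert the forward deformation cascade
#'
#' Deforms ground-truth objects from the wet state into the ultrathin-section
#' state: coordinates scale per axis by the embedding factor `Re^(1/3)` times
#' the axis-specific cutting factor, volumes scale by the exact product
#' `Rcum`, the disk proxy's Feret diameter by the in-plane geometric mean
#' `sqrt(sx sy)` and its cleft thickness by `sz`. Orientations are kept. The
#' operation is exactly invertible.
#'
#' @param objects a `synth_tissue` or a synapse data frame (see
#'   [generate_tissue()]).
#' @param factors a [deformation_factors()] object.
#' @return Object of the same shape with deformed geometry; the applied
#'   factors are attached as attribute `"deformation"`.
#' @export
apply_forward_deformation <- function(objects, factors) {
  if (!inherits(factors, "deformation_factors"))
    stop_input("`factors` must be a deformation_factors object")
  transform_tissue(objects, deformation_scales(factors), factors)
}

#' @rdname apply_forward_deformation
#' @export
invert_deformation <- function(objects, factors) {
  if (!inherits(factors, "deformation_factors"))
    stop_input("`factors` must be a deformation_factors object")
  transform_tissue(objects, 1 / deformation_scales(factors), NULL)
}

transform_tissue <- function(objects, s, record) {
  if (inherits(objects, "synth_tissue")) {
    objects$synapses <- transform_tissue(objects$synapses, s, NULL)
    m <- objects$mitochondria
    if (nrow(m)) {
      m$x_um <- m$x_um * s[["sx"]]; m$y_um <- m$y_um * s[["sy"]]
      m$z_um <- m$z_um * s[["sz"]]
      m$diameter_nm <- m$diameter_nm * sqrt(s[["sx"]] * s[["sy"]])
      objects$mitochondria <- m
    }
    objects$spec$box_dims <- objects$spec$box_dims * s
    attr(objects, "deformation") <- record
    return(objects)
  }
  df <- as.data.frame(objects)
  df$x_um <- df$x_um * s[["sx"]]
  df$y_um <- df$y_um * s[["sy"]]
  df$z_um <- df$z_um * s[["sz"]]
  df$volume_nm3 <- df$volume_nm3 * prod(s)
  df$feret_nm <- df$feret_nm * sqrt(s[["sx"]] * s[["sy"]])
  df$cleft_nm <- df$cleft_nm * s[["sz"]]
  attr(df, "deformation") <- record
  df
}

#' Read calibration measurement tables
#'
#' Landmark pairs: CSV with columns `stage_from`, `stage_to`, `axis`
#' (`iso`/`X`/`Y`), `distance_from`, `distance_to` (um). Cylinders: CSV with
#' `diameter_nm`, `sections_spanned`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_landmark_pairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("distance_from", "distance_to")
  if (!all(need %in% names(df)))
    stop_input("landmark CSV needs columns distance_from, distance_to")
  df
}

#' @rdname read_landmark_pairs
#' @export
read_cylinders <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("diameter_nm", "sections_spanned") %in% names(df)))
    stop_input("cylinder CSV needs columns diameter_nm, sections_spanned")
  df
}

#' Estimate the full deformation cascade from measurement tables
#'
#' Convenience wrapper: embedding landmarks (wet -> embedded), cutting
#' landmarks (embedded -> ultrathin, axis-labelled) and cylinder measurements
#' are combined into a single [deformation_factors()] object.
#'
#' @param embedding_pairs,cutting_pairs landmark data frames
#'   (see [read_landmark_pairs()]).
#' @param cylinders cylinder data frame (see [read_cylinders()]).
#' @param nominal nominal section thickness in nm.
#' @return A [deformation_factors()] object.
#' @export
estimate_deformation <- function(embedding_pairs, cutting_pairs, cylinders,
                                 nominal = 70) {
  Re <- estimate_embedding_factor(embedding_pairs)
  rxy <- estimate_cutting_factors(cutting_pairs)
  th <- estimate_section_thickness(cylinders, nominal)
  deformation_factors(Re = Re, RX = rxy[["RX"]], RY = rxy[["RY"]],
                      RZ = th$RZ, t_bar = th$t_bar)
}
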