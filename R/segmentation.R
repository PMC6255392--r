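#' Label 26-connected components in a binary voxel stack
#'
#' Breadth-first labelling of foreground voxels under 26-connectivity (face,
#' edge and corner neighbours), the convention used for 3D synapse
#' segmentations.
#'
#' @param mask 3D logical/numeric array (rows x cols x sections); non-zero
#'   voxels are foreground.
#' @return Integer array of the same dimensions: 0 = background, 1..k =
#'   component labels.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { d <- c(d, 1L); dim(mask) <- d }
  if (length(d) != 3) stop_input("`mask` must be a 2D or 3D array")
  fg <- which(mask != 0)
  labels <- array(0L, dim = d)
  if (!length(fg)) return(labels)
  # 26-neighbourhood offsets in (i, j, k)
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  coord <- arrayInd(fg, d)
  in_fg <- array(FALSE, dim = d); in_fg[fg] <- TRUE
  lab <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      ni <- ijk[1] + nb[, 1]; nj <- ijk[2] + nb[, 2]; nk <- ijk[3] + nb[, 3]
      ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      lin <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
      lin <- lin[in_fg[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Extract segmented objects from a labelled (or binary) stack
#'
#' Turns a mask stack into an object table: one row per 26-connected
#' component, with voxel counts, centroids and calibrated physical volume
#' (voxel count x pixel_size^2 x thickness, optionally divided by `Rcum`
#' to reach the wet state).
#'
#' @param mask binary or pre-labelled integer 3D array.
#' @param pixel_size pixel edge length in nm.
#' @param thickness section thickness in nm.
#' @param factors optional [deformation_factors()]; when given, physical
#'   volumes are calibrated to the wet state (image volume / Rcum).
#' @param labelled set `TRUE` when `mask` is already a label array.
#' @return Object of class `segmented_objects`: data frame (`id`, `n_voxels`,
#'   `cx`, `cy`, `cz` in voxel units, `volume_nm3`, `touches_margin`) with the
#'   voxel index sets in attribute `"voxels"`.
#' @export
segment_objects <- function(mask, pixel_size = 5, thickness = 10,
                            factors = NULL, labelled = FALSE) {
  check_positive(pixel_size, "pixel_size")
  check_positive(thickness, "thickness")
  labels <- if (labelled) mask else label_components(mask)
  d <- dim(labels)
  fg <- which(labels != 0L)
  voxel_nm3 <- pixel_size^2 * thickness
  if (!is.null(factors)) voxel_nm3 <- voxel_nm3 / cumulative_deformation(factors)
  if (!length(fg)) {
    out <- data.frame(id = integer(), n_voxels = integer(), cx = numeric(),
                      cy = numeric(), cz = numeric(), volume_nm3 = numeric(),
                      touches_margin = logical())
    attr(out, "voxels") <- list()
    class(out) <- c("segmented_objects", "data.frame")
    return(out)
  }
  lab <- labels[fg]
  coord <- arrayInd(fg, d)
  ids <- sort(unique(lab))
  vox <- split(fg, lab)[as.character(ids)]
  byid <- split(seq_along(fg), lab)[as.character(ids)]
  margin <- coord[, 1] == 1 | coord[, 1] == d[1] |
            coord[, 2] == 1 | coord[, 2] == d[2]
  out <- data.frame(
    id = ids,
    n_voxels = vapply(byid, length, integer(1)),
    cx = vapply(byid, function(ii) mean(coord[ii, 1]), numeric(1)),
    cy = vapply(byid, function(ii) mean(coord[ii, 2]), numeric(1)),
    cz = vapply(byid, function(ii) mean(coord[ii, 3]), numeric(1)),
    touches_margin = vapply(byid, function(ii) any(margin[ii]), logical(1))
  )
  out$volume_nm3 <- out$n_voxels * voxel_nm3
  rownames(out) <- NULL
  attr(out, "voxels") <- vox
  attr(out, "dim") <- NULL
  attr(out, "stack_dim") <- d
  attr(out, "voxel_nm3") <- voxel_nm3
  class(out) <- c("segmented_objects", "data.frame")
  out
}

#' Filter segmented objects by size and margin contact
#'
#' Removes components with fewer than `min_voxels` interconnected voxels
#' (too small to be synapses; the standard cut is 1000 voxels) and partial
#' segmentations that touch the image margin (or a supplied margin mask).
#' The removal report backs the QC contract that no more than a few percent
#' of synapses may be lost at this stage.
#'
#' @param objects a [segment_objects()] table.
#' @param min_voxels minimum voxel count to keep (default 1000).
#' @param drop_margin drop objects touching the in-plane stack margin.
#' @param margin_mask optional logical array marking margin voxels (e.g. the
#'   value-255 alignment margins); objects overlapping it are dropped.
#' @return Filtered `segmented_objects` with a `report` attribute:
#'   `n_input`, `n_kept`, `n_small`, `n_margin`.
#' @export
filter_objects <- function(objects, min_voxels = 1000, drop_margin = TRUE,
                           margin_mask = NULL) {
  vox <- attr(objects, "voxels")
  small <- objects$n_voxels < min_voxels
  marg <- if (drop_margin) objects$touches_margin else rep(FALSE, nrow(objects))
  if (!is.null(margin_mask)) {
    hit <- vapply(vox, function(v) any(margin_mask[v]), logical(1))
    marg <- marg | hit
  }
  keep <- !small & !marg
  out <- objects[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "voxels") <- vox[keep]
  attr(out, "stack_dim") <- attr(objects, "stack_dim")
  attr(out, "voxel_nm3") <- attr(objects, "voxel_nm3")
  attr(out, "report") <- list(n_input = nrow(objects), n_kept = sum(keep),
                              n_small = sum(small), n_margin = sum(marg & !small))
  class(out) <- c("segmented_objects", "data.frame")
  out
}

#' Rule-based correction of falsely split or merged components
#'
#' Falsely split synapses appear as same-type components separated by a
#' sub-resolution gap: components whose minimal voxel-to-voxel distance is
#' below `merge_gap` voxels are merged. Components whose voxel count exceeds
#' `flag_factor` times the median are flagged as candidate false merges in
#' the report (they are not split automatically).
#'
#' @param objects a [segment_objects()] table.
#' @param merge_gap merge components closer than this many voxel edge
#'   lengths (default 2).
#' @param types optional per-object type labels; only identical types merge.
#' @param flag_factor size multiple of the median above which a component is
#'   flagged as a candidate false merge.
#' @return Corrected `segmented_objects`; report attribute lists `merged`
#'   (pairs merged) and `flagged_ids`.
#' @export
correct_components <- function(objects, merge_gap = 2, types = NULL,
                               flag_factor = 10) {
  n <- nrow(objects)
  vox <- attr(objects, "voxels")
  d <- attr(objects, "stack_dim")
  if (is.null(types)) types <- rep("obj", n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merged_pairs <- list()
  if (n > 1) {
    coords <- lapply(vox, function(v) arrayInd(v, d))
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (types[i] != types[j]) next
      # bounding-box prefilter before the exact pairwise distance
      bi <- apply(coords[[i]], 2, range); bj <- apply(coords[[j]], 2, range)
      gap <- pmax(bj[1, ] - bi[2, ], bi[1, ] - bj[2, ], 0)
      if (sqrt(sum(gap^2)) >= merge_gap) next
      dmin <- min_pair_dist(coords[[i]], coords[[j]])
      if (dmin < merge_gap) {
        parent[find(j)] <- find(i)
        merged_pairs[[length(merged_pairs) + 1]] <- c(objects$id[i], objects$id[j])
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  vox_new <- lapply(groups, function(ii) sort(unlist(vox[ii], use.names = FALSE)))
  voxel_nm3 <- attr(objects, "voxel_nm3") %||% 1
  out <- data.frame(
    id = unname(vapply(groups, function(ii) as.integer(objects$id[ii[1]]), integer(1))),
    n_voxels = vapply(vox_new, length, integer(1))
  )
  out$volume_nm3 <- out$n_voxels * voxel_nm3
  cen <- t(vapply(vox_new, function(v) colMeans(arrayInd(v, d)), numeric(3)))
  out$cx <- cen[, 1]; out$cy <- cen[, 2]; out$cz <- cen[, 3]
  out$touches_margin <- vapply(groups, function(ii) any(objects$touches_margin[ii]),
                               logical(1))
  med <- median(out$n_voxels)
  flagged <- out$id[out$n_voxels > flag_factor * med]
  rownames(out) <- NULL
  attr(out, "voxels") <- vox_new
  attr(out, "stack_dim") <- d
  attr(out, "voxel_nm3") <- voxel_nm3
  attr(out, "report") <- list(merged = merged_pairs, flagged_ids = flagged)
  class(out) <- c("segmented_objects", "data.frame")
  out
}

min_pair_dist <- function(a, b) {
  # exact minimum Euclidean distance between two voxel coordinate sets
  best <- Inf
  for (r in seq_len(nrow(a))) {
    dd <- sqrt((b[, 1] - a[r, 1])^2 + (b[, 2] - a[r, 2])^2 + (b[, 3] - a[r, 3])^2)
    best <- min(best, min(dd))
  }
  best
}

#' Per-object morphometry table
#'
#' Combines voxel counts, calibrated volumes and minimum-bounding-sphere
#' Feret diameters into the standard per-object CSV layout.
#'
#' @param objects a [segment_objects()] table.
#' @param pixel_size pixel edge length in nm.
#' @param thickness section thickness in nm.
#' @param types optional per-object type labels.
#' @return Data frame `id`, `type`, `n_voxels`, `volume_nm3`, `feret_nm`.
#' @export
object_morphometry <- function(objects, pixel_size = 5, thickness = 10,
                               types = NULL) {
  vox <- attr(objects, "voxels")
  d <- attr(objects, "stack_dim")
  feret <- vapply(vox, function(v) {
    xyz <- arrayInd(v, d)
    pts <- cbind(xyz[, 1] * pixel_size, xyz[, 2] * pixel_size,
                 xyz[, 3] * thickness)
    feret_diameter(pts)
  }, numeric(1))
  data.frame(id = objects$id,
             type = if (is.null(types)) "obj" else types,
             n_voxels = objects$n_voxels,
             volume_nm3 = objects$volume_nm3,
             feret_nm = unname(feret))
}
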