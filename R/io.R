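#' Write and read binary mask stacks as multipage TIFF
#'
#' Masks follow the exported-segmentation convention: 8-bit multipage TIFF,
#' pixel value 1 = synapse, 0 = background. Alignment margins may carry the
#' value 255 (white); [read_mask_stack()] rejects such stacks unless
#' `margin_value` is given, in which case margin pixels are separated out so
#' they are excluded from object detection.
#'
#' @param mask 3D array (rows x cols x sections) of values 0/1 (and
#'   optionally 255 for margins).
#' @param path TIFF file path.
#' @return `write_mask_stack` returns `path` invisibly; `read_mask_stack`
#'   returns a list with `mask` (logical array of synapse voxels), `margin`
#'   (logical array of margin voxels, all-`FALSE` when absent) and `values`
#'   (the raw integer array).
#' @export
write_mask_stack <- function(mask, path) {
  d <- dim(mask)
  if (length(d) == 2) { d <- c(d, 1L); dim(mask) <- d }
  if (length(d) != 3) stop_input("`mask` must be a 2D or 3D array")
  vals <- as.integer(round(as.numeric(mask)))
  if (!all(vals %in% c(0L, 1L, 255L)))
    stop_input("mask values must be 0, 1 or 255")
  dim(vals) <- d
  pages <- lapply(seq_len(d[3]), function(k) vals[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_stack
#' @param margin_value margin pixel value to accept and separate (usually
#'   255); `NULL` rejects any non-binary stack.
#' @export
read_mask_stack <- function(path, margin_value = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop_input("empty TIFF stack")
  vals <- vapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]     # tolerate grey-stored-as-RGB
    as.integer(round(pg * 255))
  }, matrix(0L, nrow(pages[[1]]), ncol(pages[[1]])))
  ok <- sort(unique(as.integer(vals)))
  allowed <- c(0L, 1L, if (!is.null(margin_value)) as.integer(margin_value))
  if (!all(ok %in% allowed)) {
    stop_input(sprintf(
      "non-binary pixel values (%s); pass `margin_value` to accept margins",
      paste(utils::head(setdiff(ok, c(0L, 1L)), 5), collapse = ", ")))
  }
  list(mask = vals == 1L,
       margin = if (is.null(margin_value)) array(FALSE, dim(vals))
                else vals == as.integer(margin_value),
       values = vals)
}

#' Render a section stack to binary masks
#'
#' Rasterises the circular profile footprints of a [section_tissue()] stack
#' at the given pixel size. Rendering is intentionally small-scale (the
#' object-level footprints remain the primary representation); the image is
#' capped at `max_px` pixels per side.
#'
#' @param stack a [section_tissue()] stack.
#' @param pixel_size pixel edge length in nm.
#' @param max_px maximum image edge length in pixels (default 512).
#' @return 3D 0/1 array (rows = y, cols = x, pages = sections).
#' @export
render_masks <- function(stack, pixel_size = 40, max_px = 512) {
  check_positive(pixel_size, "pixel_size")
  field <- stack$field_dims_um
  if (is.null(field)) {
    fp <- stack$footprints
    field <- c(max(fp$x_um + fp$r_um), max(fp$y_um + fp$r_um))
  }
  px_um <- pixel_size / 1000
  nxp <- min(max_px, ceiling(field[1] / px_um))
  nyp <- min(max_px, ceiling(field[2] / px_um))
  out <- array(0L, dim = c(nyp, nxp, stack$n_sections))
  xc <- (seq_len(nxp) - 0.5) * px_um
  yc <- (seq_len(nyp) - 0.5) * px_um
  fp <- stack$footprints
  for (r in seq_len(nrow(fp))) {
    ix <- which(abs(xc - fp$x_um[r]) <= fp$r_um[r])
    iy <- which(abs(yc - fp$y_um[r]) <= fp$r_um[r])
    if (!length(ix) || !length(iy)) next
    sub <- outer((yc[iy] - fp$y_um[r])^2, (xc[ix] - fp$x_um[r])^2, `+`) <= fp$r_um[r]^2
    k <- fp$section[r] + 1L
    if (k >= 1 && k <= stack$n_sections) {
      tile <- matrix(out[iy, ix, k], length(iy), length(ix))
      tile[sub] <- 1L
      out[iy, ix, k] <- tile
    }
  }
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
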