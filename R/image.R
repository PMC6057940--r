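#' Calibrated SHG image
#'
#' Container for a single-channel grayscale microscopy image with a physical
#' pixel size. All downstream statistics (coverage, GLCM texture, orientation)
#' operate on this type or on a bare numeric matrix.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities
#'   (rows = image rows, 0-based row/col convention for geometry).
#' @param pixel_size_um Physical pixel size in micrometres per pixel
#'   (isotropic; anisotropic sampling is not supported).
#' @param bit_depth_source Integer bit depth of the source data (8 or 16);
#'   informational.
#' @param name Image identifier used in outputs and error messages.
#' @return An object of class `shg_image`.
#' @export
shg_image <- function(pixels, pixel_size_um, bit_depth_source = 16L,
                      name = "image") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    fq_stop("bad_input", "pixels must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || any(pixels < 0))
    fq_stop("bad_input", "intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    fq_stop("bad_pixel_size", "pixel_size_um must be a positive scalar")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 bit_depth_source = as.integer(bit_depth_source),
                 name = as.character(name)),
            class = "shg_image")
}

#' @export
print.shg_image <- function(x, ...) {
  cat(sprintf("<shg_image> %s: %d x %d px, %.4g um/px (%.3g x %.3g um), range [%.4g, %.4g]\n",
              x$name, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um, ncol(x$pixels) * x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.shg_image <- function(x) dim(x$pixels)

#' Ordered z-stack of SHG images
#'
#' @param slices List of [shg_image] objects with identical shapes and pixel
#'   sizes, ordered by acquisition depth.
#' @param depth_step_um Axial distance between consecutive slices (um).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, depth_step_um = 1) {
  if (!is.list(slices) || length(slices) == 0L)
    fq_stop("bad_input", "slices must be a non-empty list of shg_image")
  if (!all(vapply(slices, inherits, logical(1), "shg_image")))
    fq_stop("bad_input", "all slices must be shg_image objects")
  d <- dim(slices[[1L]]$pixels)
  px <- slices[[1L]]$pixel_size_um
  same <- vapply(slices, function(s)
    identical(dim(s$pixels), d) && isTRUE(all.equal(s$pixel_size_um, px)),
    logical(1))
  if (!all(same))
    fq_stop("bad_input", "all slices must share shape and pixel size")
  if (depth_step_um <= 0) fq_stop("bad_input", "depth_step_um must be > 0")
  structure(list(slices = slices, depth_step_um = depth_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1L]]$pixels)
  cat(sprintf("<image_stack> %d slices of %d x %d px, depth step %.4g um\n",
              length(x$slices), d[1], d[2], x$depth_step_um))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' Region-of-interest mask
#'
#' Boolean mask annotating an image of the same shape, e.g. a stromal
#' compartment or the tumor-stromal interface band.
#'
#' @param pixels Logical matrix.
#' @param label Text label recorded in outputs, e.g. `"stroma"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label = "roi") {
  if (!is.matrix(pixels)) fq_stop("bad_input", "mask pixels must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      fq_stop("bad_input", "mask pixels must be logical or 0/1")
    pixels <- pixels > 0
  }
  structure(list(pixels = pixels, label = as.character(label)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d x %d px, %d true (%.2f%%)\n",
              x$label, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

# Resolve an optional ROI argument against an image shape; returns a logical
# matrix covering the whole image when roi is NULL.
resolve_roi <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  m <- if (inherits(roi, "roi_mask")) roi$pixels else roi
  if (!is.matrix(m)) fq_stop("bad_input", "roi must be a matrix or roi_mask")
  if (!is.logical(m)) m <- m > 0
  if (!identical(dim(m), as.integer(dims)))
    fq_stop("shape_mismatch", "roi shape does not match image shape")
  m
}
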