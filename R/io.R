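#' Read a calibrated grayscale TIFF
#'
#' Reads an 8- or 16-bit single- or multi-page grayscale TIFF losslessly
#' (integer digital numbers are preserved). The physical pixel size must be
#' supplied explicitly: TIFF resolution tags are unreliable across
#' acquisition software, so a configured value always wins; tags are used
#' only when `pixel_size_um` is `NULL` and the file carries a resolution in
#' pixels per centimetre or inch.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in um/px (recommended). `NULL` falls back
#'   to TIFF tags and errors if they are absent or anisotropic.
#' @param channel Optional channel index for multi-channel pages.
#' @param depth_step_um Axial spacing used when the file has multiple pages.
#' @return An [shg_image] for single-page files, an [image_stack] otherwise.
#' @export
read_image <- function(path, pixel_size_um = NULL, channel = NULL,
                       depth_step_um = 1) {
  if (!file.exists(path))
    fq_stop("unreadable_file", sprintf("cannot read '%s': no such file", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e)
                      fq_stop("unreadable_file",
                              sprintf("cannot read '%s': %s", path,
                                      conditionMessage(e))))
  if (is.null(pixel_size_um)) {
    info <- attributes(pages[[1L]])
    xr <- info$x.resolution; yr <- info$y.resolution
    unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
    if (is.null(xr) || is.null(yr) || xr <= 0)
      fq_stop("missing_pixel_size",
              "pixel size not supplied and no usable TIFF resolution tags")
    if (!isTRUE(all.equal(xr, yr)))
      fq_stop("anisotropic_pixels",
              "anisotropic pixel sizes are not supported")
    per_um <- switch(unit, inch = xr / 25400, cm = xr / 10000,
                     fq_stop("missing_pixel_size",
                             "TIFF resolution unit not recognized"))
    pixel_size_um <- 1 / per_um
  }
  take_channel <- function(a) {
    a <- array(as.double(a), dim = dim(a))   # drop TIFF tag attributes
    if (length(dim(a)) == 3L) {
      nc <- dim(a)[3L]
      ch <- if (is.null(channel)) 1L else as.integer(channel)
      if (ch < 1L || ch > nc)
        fq_stop("bad_channel",
                sprintf("channel %d out of range (1..%d)", ch, nc))
      a[, , ch]
    } else {
      if (!is.null(channel) && channel != 1L)
        fq_stop("bad_channel", "single-channel image: channel must be 1")
      a
    }
  }
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  nm <- basename(path)
  imgs <- lapply(seq_along(pages), function(i)
    shg_image(take_channel(pages[[i]]), pixel_size_um, as.integer(bits),
              name = if (length(pages) > 1L) sprintf("%s[%d]", nm, i) else nm))
  if (length(imgs) == 1L) imgs[[1L]] else image_stack(imgs, depth_step_um)
}

#' Write a grayscale image to TIFF
#'
#' Writes integer digital numbers losslessly at the requested bit depth.
#' Intensities are divided by `max_value` (default: full scale of the bit
#' depth) and clipped to \[0, 1\] before encoding, so images whose pixels are
#' integers in range round-trip exactly through [read_image()].
#'
#' @param img An [shg_image], [roi_mask], [image_stack], or matrix.
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16.
#' @param max_value Intensity mapped to full scale; defaults to `2^bits - 1`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 16L, max_value = NULL) {
  if (!bits %in% c(8L, 16L)) fq_stop("bad_input", "bits must be 8 or 16")
  if (is.null(max_value)) max_value <- 2^bits - 1
  enc <- function(m) {
    m <- m / max_value
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  }
  if (inherits(img, "image_stack")) {
    tiff::writeTIFF(lapply(img$slices, function(s) enc(s$pixels)), path,
                    bits.per.sample = as.integer(bits))
  } else {
    m <- as_pixel_matrix(img)
    if (is.logical(m)) m <- m * max_value
    tiff::writeTIFF(enc(m), path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Read a binary ROI mask from TIFF or PNG
#'
#' Nonzero pixels become `TRUE`.
#'
#' @param path Path to a TIFF or PNG file.
#' @param label Label attached to the mask.
#' @return A [roi_mask].
#' @export
read_roi_mask <- function(path, label = "roi") {
  if (!file.exists(path))
    fq_stop("unreadable_file", sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else
    tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  roi_mask(m > 0, label = label)
}

#' Normalize image intensities
#'
#' @param img An [shg_image].
#' @param method `"none"` (identity; the coverage threshold is defined on the
#'   raw scale), `"max"` (divide by the maximum), or `"percentile"` (divide
#'   by the `p`-th percentile then clip to \[0, 1\]; the recommended
#'   preparation before orientation/GLCM analysis).
#' @param p Percentile in (0, 100\] used by `method = "percentile"`.
#' @return An [shg_image] with intensities in \[0, 1\] (unless `"none"`).
#' @export
normalize_intensity <- function(img, method = c("none", "max", "percentile"),
                                p = 99.9) {
  method <- match.arg(method)
  px <- as_pixel_matrix(img)
  out <- img
  if (method == "none") return(img)
  if (method == "max") {
    m <- max(px)
    if (m <= 0) {
      warning("all-zero image: max normalization left it unchanged")
      return(img)
    }
    out$pixels <- px / m
  } else {
    if (p <= 0 || p > 100) fq_stop("bad_input", "p must be in (0, 100]")
    q <- stats::quantile(px, p / 100, names = FALSE)
    if (q <= 0) {
      warning("non-positive percentile value: normalization left image unchanged")
      return(img)
    }
    v <- px / q
    v[v > 1] <- 1
    out$pixels <- v
  }
  out
}

#' Tumor-stromal interface band
#'
#' Returns the band of pixels outside a compartment mask whose Euclidean
#' distance (center-to-center, in physical units) to the nearest compartment
#' pixel is at most `distance_um`. With a cancer-associated-fibroblast (CAF)
#' compartment mask and the default 200 um this reproduces the convention of
#' scoring cells "within a distance of 200 um" of the tumor-stromal
#' interface.
#'
#' @param compartment_mask A [roi_mask] (or logical matrix) with both `TRUE`
#'   and `FALSE` pixels.
#' @param distance_um Band depth in micrometres (default 200).
#' @param pixel_size_um Pixel size in um/px.
#' @return A [roi_mask] labelled `"interface_band"`.
#' @export
interface_band <- function(compartment_mask, distance_um = 200,
                           pixel_size_um) {
  m <- if (inherits(compartment_mask, "roi_mask")) compartment_mask$pixels
       else compartment_mask
  if (!is.matrix(m)) fq_stop("bad_input", "compartment_mask must be a matrix")
  if (!is.logical(m)) m <- m > 0
  if (all(m) || !any(m))
    fq_stop("no_interface",
            "compartment mask must contain both classes; no interface exists")
  if (pixel_size_um <= 0) fq_stop("bad_pixel_size", "pixel_size_um must be > 0")
  if (distance_um < 0) fq_stop("bad_input", "distance_um must be >= 0")
  # distance, for every non-compartment pixel, to the nearest compartment
  # pixel: Euclidean distance map of the complement
  d <- EBImage::distmap(EBImage::Image(!m), metric = "euclidean")
  d <- EBImage::imageData(d)
  band <- !m & (d * pixel_size_um <= distance_um) & d > 0
  roi_mask(band, label = "interface_band")
}
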