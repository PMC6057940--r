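#' Binarize an image at a global threshold
#'
#' Converts an intensity image to a binary mask using a single threshold: a
#' pixel is positive iff its intensity is strictly greater than `threshold`.
#' The threshold is meant to be one value applied across all images of a
#' study (see [pooled_otsu_threshold()] for a reproducible automatic choice).
#'
#' @param img An [shg_image] or numeric matrix.
#' @param threshold Finite numeric threshold on the raw intensity scale.
#' @return A [roi_mask] labelled `"shg_positive"`.
#' @export
binarize <- function(img, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    fq_stop("bad_input", "threshold must be a finite scalar")
  px <- as_pixel_matrix(img)
  roi_mask(px > threshold, label = "shg_positive")
}

#' Percent area covered by signal
#'
#' Counts positive pixels of a binary mask within an optional ROI and reports
#' the percentage of ROI area covered.
#'
#' @param mask A [roi_mask] or logical matrix (the binarized signal).
#' @param roi Optional [roi_mask] restricting the computation.
#' @param threshold_used Threshold echoed into the result (provenance).
#' @return An object of class `coverage_result` with `coverage_percent`,
#'   `n_roi_pixels`, `n_covered`, `threshold_used`.
#' @export
coverage_fraction <- function(mask, roi = NULL, threshold_used = NA_real_) {
  m <- if (inherits(mask, "roi_mask")) mask$pixels else mask
  if (!is.matrix(m)) fq_stop("bad_input", "mask must be a matrix or roi_mask")
  if (!is.logical(m)) m <- m > 0
  r <- resolve_roi(roi, dim(m))
  n <- sum(r)
  if (n == 0L) fq_stop("empty_roi", "ROI contains no pixels")
  covered <- sum(m & r)
  structure(list(coverage_percent = 100 * covered / n,
                 n_roi_pixels = n, n_covered = covered,
                 threshold_used = threshold_used,
                 by_depth = NULL, peak_coverage_percent = NULL),
            class = "coverage_result")
}

#' Coverage of an image at a threshold
#'
#' Convenience wrapper: [binarize()] then [coverage_fraction()].
#'
#' @inheritParams binarize
#' @inheritParams coverage_fraction
#' @return A `coverage_result`.
#' @export
coverage <- function(img, threshold, roi = NULL) {
  coverage_fraction(binarize(img, threshold), roi, threshold_used = threshold)
}

#' Coverage by imaging depth
#'
#' Applies the global threshold to every slice of a z-stack and reports the
#' per-depth coverage profile together with its peak value, the depth-resolved
#' collagen abundance readout.
#'
#' @param stack An [image_stack].
#' @param threshold Global threshold applied to all slices.
#' @param roi Optional [roi_mask] shared by all slices.
#' @return A `coverage_result` whose `by_depth` is a data frame of
#'   `(depth_um, coverage_percent)` and whose `peak_coverage_percent` is the
#'   maximum over depth; scalar fields describe the peak slice.
#' @export
coverage_by_depth <- function(stack, threshold, roi = NULL) {
  if (!inherits(stack, "image_stack"))
    fq_stop("bad_input", "stack must be an image_stack")
  if (length(stack$slices) == 0L) fq_stop("bad_input", "empty stack")
  per <- lapply(stack$slices, function(s) coverage(s, threshold, roi))
  cov <- vapply(per, function(x) x$coverage_percent, numeric(1))
  depth <- (seq_along(per) - 1L) * stack$depth_step_um
  k <- which.max(cov)
  out <- per[[k]]
  out$by_depth <- data.frame(depth_um = depth, coverage_percent = cov)
  out$peak_coverage_percent <- cov[k]
  out
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %.3f%% (%d / %d px, threshold %s)\n",
              x$coverage_percent, x$n_covered, x$n_roi_pixels,
              format(x$threshold_used)))
  if (!is.null(x$by_depth))
    cat(sprintf("  depth profile: %d slices, peak %.3f%% at %.4g um\n",
                nrow(x$by_depth), x$peak_coverage_percent,
                x$by_depth$depth_um[which.max(x$by_depth$coverage_percent)]))
  invisible(x)
}

#' Plot a coverage depth profile
#'
#' @param x A `coverage_result` from [coverage_by_depth()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coverage_result <- function(x, ...) {
  if (is.null(x$by_depth))
    fq_stop("bad_input", "no depth profile in this coverage_result")
  graphics::plot(x$by_depth$depth_um, x$by_depth$coverage_percent,
                 type = "b", xlab = "depth (um)", ylab = "coverage (%)", ...)
  invisible(x)
}

#' Pooled-histogram Otsu threshold
#'
#' Computes a single Otsu threshold from the pooled intensity histogram of a
#' set of images, to be applied globally across the study. This is a
#' reproducible stand-in for a manually chosen study-wide threshold.
#'
#' @param imgs A list of [shg_image] objects (or matrices), or a single one.
#' @param n_bins Number of histogram bins pooled over the joint range.
#' @return The threshold (numeric scalar) on the raw intensity scale.
#' @export
pooled_otsu_threshold <- function(imgs, n_bins = 256L) {
  if (inherits(imgs, "shg_image") || is.matrix(imgs)) imgs <- list(imgs)
  vals <- lapply(imgs, as_pixel_matrix)
  lo <- min(vapply(vals, min, numeric(1)))
  hi <- max(vapply(vals, max, numeric(1)))
  if (hi <= lo) fq_stop("degenerate_texture", "pooled intensity range is empty")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- Reduce(`+`, lapply(vals, function(v)
    tabulate(pmin(findInterval(v, edges, all.inside = TRUE), n_bins), n_bins)))
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  edges[k + 1L]
}
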