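#' GLCM configuration
#'
#' Parameters for the gray-level co-occurrence matrix (GLCM) correlation
#' decay analysis. Defaults follow common GLCM practice (the choice is fully
#' exposed): 64 gray levels, offsets 1..64 px, the four principal angles
#' averaged, symmetric accumulation.
#'
#' @param n_gray_levels Number of quantization levels (>= 2).
#' @param distances_px Strictly ascending positive integer offsets.
#' @param angles_deg Subset of `c(0, 45, 90, 135)`.
#' @param symmetric Accumulate pairs in both directions.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_gray_levels = 64L, distances_px = 1:64,
                        angles_deg = c(0, 45, 90, 135), symmetric = TRUE) {
  if (n_gray_levels < 2L) fq_stop("bad_input", "n_gray_levels must be >= 2")
  if (length(distances_px) == 0L || any(distances_px < 1) ||
      any(diff(distances_px) <= 0))
    fq_stop("bad_input", "distances_px must be non-empty, positive, ascending")
  if (!all(angles_deg %in% c(0, 45, 90, 135)) || length(angles_deg) == 0L)
    fq_stop("bad_input", "angles_deg must be drawn from {0, 45, 90, 135}")
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 distances_px = as.integer(distances_px),
                 angles_deg = angles_deg, symmetric = isTRUE(symmetric)),
            class = "glcm_config")
}

#' Quantize intensities to discrete gray levels
#'
#' Uniformly bins the intensity range observed inside the ROI into
#' `n_gray_levels` levels `0 .. n-1`. A constant image maps to level 0.
#' Per-image quantization over the ROI makes the correlation feature
#' invariant to affine intensity maps, limiting per-image gain differences.
#'
#' @param img An [shg_image] or matrix.
#' @param n_gray_levels Number of levels (>= 2).
#' @param roi Optional [roi_mask]; range computed over ROI pixels only.
#' @return Integer matrix of levels in `0 .. n_gray_levels - 1`.
#' @export
quantize <- function(img, n_gray_levels, roi = NULL) {
  if (n_gray_levels < 2L) fq_stop("bad_input", "n_gray_levels must be >= 2")
  px <- as_pixel_matrix(img)
  r <- resolve_roi(roi, dim(px))
  v <- px[r]
  mn <- min(v); mx <- max(v)
  if (mx <= mn) return(matrix(0L, nrow(px), ncol(px)))
  lev <- floor((px - mn) / (mx - mn) * n_gray_levels)
  lev[lev < 0] <- 0
  lev[lev > n_gray_levels - 1] <- n_gray_levels - 1
  storage.mode(lev) <- "integer"
  lev
}

# angle (deg) -> (drow, dcol) offset at Chebyshev step d.
# Convention: 0 deg = +col, 90 deg = -row (angles CCW with rows growing down).
glcm_offset <- function(distance_px, angle_deg) {
  d <- as.integer(distance_px)
  switch(as.character(angle_deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         fq_stop("bad_input", "angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Normalized joint histogram of level pairs `(p, p + offset)` where the
#' offset is `distance_px` steps along `angle_deg` (0 deg = +col,
#' 90 deg = -row; diagonal offsets step `distance_px` in both axes). Pairs
#' are restricted to `roi` (both endpoints inside). With `symmetric = TRUE`
#' each pair is also counted in the reverse direction, making P exactly
#' symmetric.
#'
#' @param levels Integer level matrix from [quantize()].
#' @param distance_px Positive integer offset length.
#' @param angle_deg One of 0, 45, 90, 135.
#' @param symmetric Accumulate both directions.
#' @param n_gray_levels Number of levels (defaults to `max(levels) + 1`).
#' @param roi Optional [roi_mask].
#' @return An `n x n` matrix with non-negative entries summing to 1.
#' @export
glcm <- function(levels, distance_px, angle_deg, symmetric = TRUE,
                 n_gray_levels = NULL, roi = NULL) {
  if (!is.matrix(levels)) fq_stop("bad_input", "levels must be a matrix")
  if (distance_px < 1) fq_stop("bad_input", "distance_px must be >= 1")
  n <- if (is.null(n_gray_levels)) max(levels) + 1L else
    as.integer(n_gray_levels)
  off <- glcm_offset(distance_px, angle_deg)
  nr <- nrow(levels); nc <- ncol(levels)
  r <- resolve_roi(roi, dim(levels))
  r_lo <- max(1L, 1L - off[1L]); r_hi <- min(nr, nr - off[1L])
  c_lo <- max(1L, 1L - off[2L]); c_hi <- min(nc, nc - off[2L])
  if (r_hi < r_lo || c_hi < c_lo)
    fq_stop("no_pairs", "offset exceeds image extent: no pixel pairs")
  r1 <- seq.int(r_lo, r_hi)
  c1 <- seq.int(c_lo, c_hi)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + off[1L], c1 + off[2L], drop = FALSE]
  ok <- r[r1, c1, drop = FALSE] & r[r1 + off[1L], c1 + off[2L], drop = FALSE]
  if (!any(ok)) fq_stop("no_pairs", "no pixel pairs inside ROI for this offset")
  idx <- a[ok] * n + b[ok] + 1L
  counts <- tabulate(idx, nbins = n * n)
  P <- matrix(counts, n, n, byrow = TRUE)  # row = first level i, col = j
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' Haralick correlation of a GLCM
#'
#' `corr = sum_ij (i - mu_i)(j - mu_j) P[i, j] / (sd_i * sd_j)` with marginal
#' means and standard deviations of P. Defined only for non-degenerate
#' textures (marginal variance > 0).
#'
#' @param P Normalized GLCM from [glcm()].
#' @return Correlation in \[-1, 1\].
#' @export
glcm_correlation <- function(P) {
  n <- nrow(P)
  i <- seq_len(n) - 1
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj)
  var_i <- sum((i - mu_i)^2 * pi_); var_j <- sum((i - mu_j)^2 * pj)
  if (var_i <= 0 || var_j <= 0)
    fq_stop("degenerate_texture",
            "constant texture: GLCM correlation is undefined")
  cov_ij <- sum(outer(i - mu_i, i - mu_j) * P)
  cov_ij / sqrt(var_i * var_j)
}

#' GLCM correlation decay curve
#'
#' Computes the angle-averaged Haralick correlation at each configured offset
#' distance. Slower decay of this curve indicates a more organized,
#' longer-range-correlated fiber network; faster decay a more disordered one.
#' Two scalar summaries are reported: the area under the correlation curve
#' (trapezoidal, normalized by the distance span) and the half-decay
#' distance (first offset at which the correlation falls to half its value
#' at the smallest offset, linearly interpolated; `Inf` if never reached).
#'
#' @param img An [shg_image] or matrix.
#' @param config A [glcm_config()].
#' @param roi Optional [roi_mask].
#' @return An object of class `glcm_decay` with `distances_px`,
#'   `correlation`, `auc`, `half_decay_distance_px`, `config`.
#' @export
correlation_decay <- function(img, config = glcm_config(), roi = NULL) {
  lev <- quantize(img, config$n_gray_levels, roi)
  nm <- if (inherits(img, "shg_image")) img$name else "image"
  corr <- vapply(config$distances_px, function(d) {
    vals <- vapply(config$angles_deg, function(a) {
      P <- glcm(lev, d, a, config$symmetric, config$n_gray_levels, roi)
      tryCatch(glcm_correlation(P), fq_degenerate_texture = function(e)
        fq_stop("degenerate_texture",
                sprintf("%s: %s", nm, conditionMessage(e))))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  ds <- as.numeric(config$distances_px)
  auc <- if (length(ds) == 1L) corr[1L] else {
    span <- ds[length(ds)] - ds[1L]
    sum(diff(ds) * (corr[-1L] + corr[-length(corr)]) / 2) / span
  }
  half <- corr[1L] / 2
  hd <- Inf
  below <- which(corr <= half)
  if (length(below) > 0L) {
    k <- below[1L]
    if (k == 1L) hd <- ds[1L]
    else {
      # linear interpolation between the bracketing offsets
      hd <- ds[k - 1L] + (ds[k] - ds[k - 1L]) *
        (corr[k - 1L] - half) / (corr[k - 1L] - corr[k])
    }
  }
  structure(list(distances_px = ds, correlation = corr, auc = auc,
                 half_decay_distance_px = hd, config = config, image = nm),
            class = "glcm_decay")
}

#' @export
print.glcm_decay <- function(x, ...) {
  cat(sprintf(paste0("<glcm_decay> %s: %d offsets (%g..%g px), corr[1] = %.3f, ",
                     "auc = %.3f, half-decay = %s px\n"),
              x$image, length(x$distances_px), min(x$distances_px),
              max(x$distances_px), x$correlation[1L], x$auc,
              format(round(x$half_decay_distance_px, 2))))
  invisible(x)
}

#' Plot a GLCM correlation decay curve
#'
#' @param x A `glcm_decay`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glcm_decay <- function(x, ...) {
  graphics::plot(x$distances_px, x$correlation, type = "l",
                 xlab = "offset distance (px)", ylab = "GLCM correlation",
                 ylim = range(c(0, x$correlation)), ...)
  graphics::abline(h = x$correlation[1L] / 2, lty = 3)
  invisible(x)
}
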