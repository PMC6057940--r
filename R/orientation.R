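# Cubic B-spline machinery -----------------------------------------------

# In-place recursive prefilter along columns of each row-vectorized matrix
# dimension: converts samples to cubic B-spline interpolation coefficients.
# Mirror (reflect-101) boundary conditions; exact inversion of the [1 4 1]/6
# interpolation kernel up to the stated tolerance.
bspline_prefilter_dim <- function(S, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(bspline_prefilter_dim(t(S), "col")))
  z <- sqrt(3) - 2                      # pole of the cubic B-spline
  N <- ncol(S)
  if (N < 2L) return(S)
  S <- S * 6                            # gain (1 - z)(1 - 1/z) = 6
  C <- S
  # causal init: truncated mirror-extended sum, horizon at |z|^K < 1e-14
  K <- min(as.integer(ceiling(log(1e-14) / log(abs(z)))), 2L * N - 2L)
  ext <- c(seq_len(N), seq.int(N - 1L, 2L))  # one mirror period
  per <- length(ext)
  init_idx <- ext[((seq_len(K + 1L) - 1L) %% per) + 1L]
  zp <- z^(0:K)
  C[, 1L] <- S[, init_idx, drop = FALSE] %*% zp
  for (k in 2:N) C[, k] <- S[, k] + z * C[, k - 1L]
  # anti-causal
  D <- C
  D[, N] <- (z / (z * z - 1)) * (C[, N] + z * C[, N - 1L])
  for (k in seq.int(N - 1L, 1L)) D[, k] <- z * (D[, k + 1L] - C[, k])
  D
}

# Full 2-D prefilter.
bspline_prefilter <- function(m) {
  bspline_prefilter_dim(bspline_prefilter_dim(m, "col"), "row")
}

# Interpolation kernel values at integer offsets: B(0) = 4/6, B(+-1) = 1/6;
# derivative kernel B'(+-1) = -+ 1/2, B'(0) = 0.
bspline_val_kernel <- c(1, 4, 1) / 6
bspline_der_kernel <- c(0.5, 0, -0.5)  # f'(i) = (c[i+1] - c[i-1]) / 2

#' Cubic B-spline image gradient
#'
#' Represents the image in a cubic B-spline basis (recursive prefilter with
#' mirror boundaries) and evaluates the continuous spatial derivatives
#' analytically at pixel centers. Exact for polynomial images up to degree 3
#' at pixels away from the boundary layer.
#'
#' @param img An [shg_image] or numeric matrix, at least 4 x 4.
#' @return List with `fx` (derivative along +col) and `fy` (derivative along
#'   +row, i.e. downward in image coordinates).
#' @export
bspline_gradient <- function(img) {
  m <- as_pixel_matrix(img)
  if (nrow(m) < 4L || ncol(m) < 4L)
    fq_stop("image_too_small", "image must be at least 4 x 4")
  C <- bspline_prefilter(m)
  # fx: derivative along columns, interpolation along rows
  fx <- conv_mirror(conv_mirror(C, rev(bspline_der_kernel), "col"),
                    bspline_val_kernel, "row")
  fy <- conv_mirror(conv_mirror(C, rev(bspline_der_kernel), "row"),
                    bspline_val_kernel, "col")
  list(fx = fx, fy = fy)
}

# Evaluate the spline (given 2-D coefficients) at arbitrary continuous
# (row, col) positions (0-based pixel centers). Used by rotate_image.
bspline_eval <- function(C, r, c) {
  nr <- nrow(C); nc <- ncol(C)
  b3 <- function(t) {
    at <- abs(t)
    ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
           ifelse(at < 2, (2 - at)^3 / 6, 0))
  }
  fold <- function(i, n) {
    # reflect-101 fold of 0-based index into 0..n-1
    period <- 2L * (n - 1L)
    i <- abs(i) %% period
    ifelse(i > (n - 1L), period - i, i)
  }
  r0 <- floor(r); c0 <- floor(c)
  out <- numeric(length(r))
  for (dr in -1:2) for (dc in -1:2) {
    ri <- fold(r0 + dr, nr); ci <- fold(c0 + dc, nc)
    w <- b3(r - (r0 + dr)) * b3(c - (c0 + dc))
    out <- out + w * C[cbind(ri + 1, ci + 1)]
  }
  out
}

#' Rotate an image with bicubic (B-spline) interpolation
#'
#' Rotates counter-clockwise (in the package's angle convention: toward
#' decreasing rows) about the image center.
#'
#' @param img An [shg_image] or matrix.
#' @param angle_deg Rotation angle, degrees CCW.
#' @return Object of the same kind as the input.
#' @export
rotate_image <- function(img, angle_deg) {
  m <- as_pixel_matrix(img)
  C <- bspline_prefilter(m)
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  phi <- angle_deg * pi / 180
  g <- expand.grid(r = seq_len(nr) - 1, c = seq_len(nc) - 1)
  # output pixel (r, c): source = inverse rotation. With x = col, y = -row,
  # CCW by -phi maps (x, y) -> (x cos + y sin, -x sin + y cos).
  x <- g$c - cc; y <- -(g$r - cr)
  xs <- x * cos(phi) + y * sin(phi)
  ys <- -x * sin(phi) + y * cos(phi)
  src_r <- cr - ys; src_c <- cc + xs
  vals <- bspline_eval(C, src_r, src_c)
  out <- matrix(vals, nr, nc)
  out[out < 0] <- 0
  if (inherits(img, "shg_image")) {
    img$pixels <- out
    img$name <- sprintf("%s_rot%g", img$name, angle_deg)
    img
  } else out
}

# Structure tensor --------------------------------------------------------

#' Structure tensor fields
#'
#' Gaussian-windowed outer products of the image gradient. The inputs are
#' interpreted in mathematical coordinates (x = +col, y = up); pass
#' `fy = -gradient$fy` when the gradient was computed in image (row-down)
#' coordinates — the [analyze_orientation()] wrapper does this for you.
#'
#' @param fx,fy Gradient component matrices.
#' @param window_sigma_px Gaussian window s.d. in pixels (> 0).
#' @return List with `Jxx`, `Jxy`, `Jyy` (same shape as inputs).
#' @export
structure_tensor <- function(fx, fy, window_sigma_px = 2) {
  if (!identical(dim(fx), dim(fy)))
    fq_stop("shape_mismatch", "fx and fy must have the same shape")
  if (!is.numeric(window_sigma_px) || window_sigma_px <= 0)
    fq_stop("bad_input", "window_sigma_px must be > 0")
  list(Jxx = gaussian_smooth(fx * fx, window_sigma_px),
       Jxy = gaussian_smooth(fx * fy, window_sigma_px),
       Jyy = gaussian_smooth(fy * fy, window_sigma_px))
}

#' Per-pixel orientation and coherency from structure tensor fields
#'
#' The local dominant gradient orientation is
#' `0.5 * atan2(2 Jxy, Jxx - Jyy)`; the structure (fiber) orientation is
#' perpendicular to it and reported in degrees CCW from the +col axis, in the
#' axial range (-90, 90]. Coherency is the normalized eigenvalue contrast
#' `sqrt((Jxx - Jyy)^2 + 4 Jxy^2) / (Jxx + Jyy)`, 0 for isotropic texture
#' and 1 for a rank-one tensor. Pixels are gated by tensor energy (trace) and
#' coherency, implementing the masking of isotropic pixels; pixels within
#' `border_margin_px` of the frame are excluded to suppress boundary
#' artifacts of the windowed average.
#'
#' @param tensor List with `Jxx`, `Jxy`, `Jyy` from [structure_tensor()].
#' @param energy_gate Percentile (0-100) of ROI energies below which pixels
#'   are masked.
#' @param coherency_gate Minimum coherency for a pixel to be valid.
#' @param border_margin_px Border exclusion margin in pixels.
#' @param roi Optional [roi_mask] for the energy percentile and validity.
#' @return Object of class `orientation_field` with `theta_deg`, `coherency`,
#'   `energy`, `valid_mask`.
#' @export
orientation_field <- function(tensor, energy_gate = 25, coherency_gate = 0.2,
                              border_margin_px = 0L, roi = NULL) {
  Jxx <- tensor$Jxx; Jxy <- tensor$Jxy; Jyy <- tensor$Jyy
  energy <- Jxx + Jyy
  theta_g <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  theta <- axial_wrap(theta_g + 90)
  coh <- matrix(0, nrow(Jxx), ncol(Jxx))
  pos <- energy > 0
  coh[pos] <- sqrt((Jxx[pos] - Jyy[pos])^2 + 4 * Jxy[pos]^2) / energy[pos]
  coh[coh > 1] <- 1
  r <- resolve_roi(roi, dim(Jxx))
  egate <- stats::quantile(energy[r], energy_gate / 100, names = FALSE)
  valid <- r & pos & (energy >= egate) & (coh >= coherency_gate)
  if (border_margin_px > 0L) {
    b <- as.integer(border_margin_px)
    nr <- nrow(valid); nc <- ncol(valid)
    if (2L * b >= nr || 2L * b >= nc) valid[] <- FALSE
    else {
      valid[c(seq_len(b), seq.int(nr - b + 1L, nr)), ] <- FALSE
      valid[, c(seq_len(b), seq.int(nc - b + 1L, nc))] <- FALSE
    }
  }
  structure(list(theta_deg = theta, coherency = coh, energy = energy,
                 valid_mask = valid), class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d px, %d valid (%.1f%%), median coherency %.3f\n",
              nrow(x$theta_deg), ncol(x$theta_deg), sum(x$valid_mask),
              100 * mean(x$valid_mask),
              stats::median(x$coherency[x$valid_mask])))
  invisible(x)
}

#' Axial orientation histogram, peak alignment and alignment frequency
#'
#' Histograms the valid orientations into uniform bins over (-90, 90],
#' optionally weighting each pixel by its coherency. The peak alignment is
#' the center of the maximal bin (ties broken toward the smaller angle); the
#' alignment frequency is the total histogram mass in bins whose centers lie
#' within `delta_deg` of the peak under axial (mod 180) distance.
#'
#' @param field An [orientation_field()].
#' @param roi Optional [roi_mask] intersected with the valid mask.
#' @param bin_width_deg Bin width; must divide 180 evenly.
#' @param delta_deg Alignment half-window in degrees, in (0, 90).
#' @param weighting `"coherency"` (default) or `"none"`.
#' @return Object of class `orientation_histogram` with `bin_centers_deg`,
#'   `frequency` (sums to 1), `peak_angle_deg`, `alignment_frequency`,
#'   `delta_deg`, `n_valid_pixels`.
#' @export
orientation_histogram <- function(field, roi = NULL, bin_width_deg = 1,
                                  delta_deg = 10,
                                  weighting = c("coherency", "none")) {
  weighting <- match.arg(weighting)
  if (delta_deg <= 0 || delta_deg >= 90)
    fq_stop("bad_input", "delta_deg must lie in (0, 90)")
  nb <- 180 / bin_width_deg
  if (abs(nb - round(nb)) > 1e-9)
    fq_stop("bad_input", "bin_width_deg must divide 180 evenly")
  nb <- as.integer(round(nb))
  r <- resolve_roi(roi, dim(field$theta_deg))
  sel <- field$valid_mask & r
  if (!any(sel)) fq_stop("no_oriented_signal", "no oriented signal in ROI")
  th <- field$theta_deg[sel]
  w <- if (weighting == "coherency") field$coherency[sel] else
    rep(1, length(th))
  # bin k covers (-90 + (k-1)*bw, -90 + k*bw]; theta in (-90, 90]
  bw <- 180 / nb
  k <- as.integer(ceiling((th + 90) / bw))
  k[k < 1L] <- 1L; k[k > nb] <- nb
  agg <- rowsum(w, k)
  freq <- numeric(nb)
  freq[as.integer(rownames(agg))] <- agg[, 1L]
  freq <- freq / sum(freq)
  centers <- -90 + (seq_len(nb) - 0.5) * bw
  peak <- centers[which.max(freq)]   # which.max -> first max = smaller angle
  # bins whose centers lie in the half-open axial window (peak - d, peak + d]
  # (total width 2 * delta, so a uniform distribution gives 2 * delta / 180)
  sdiff <- ((centers - peak + 90) %% 180) - 90
  aligned <- sdiff > -delta_deg & sdiff <= delta_deg
  structure(list(bin_centers_deg = centers, bin_width_deg = bw,
                 frequency = freq, peak_angle_deg = peak,
                 alignment_frequency = sum(freq[aligned]),
                 delta_deg = delta_deg, weighting = weighting,
                 n_valid_pixels = sum(sel)),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf(paste0("<orientation_histogram> peak %.4g deg, alignment ",
                     "frequency %.3f (delta %.3g deg, %s-weighted, %d px)\n"),
              x$peak_angle_deg, x$alignment_frequency, x$delta_deg,
              x$weighting, x$n_valid_pixels))
  invisible(x)
}

#' Plot an axial orientation histogram
#'
#' @param x An `orientation_histogram`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.orientation_histogram <- function(x, ...) {
  graphics::plot(x$bin_centers_deg, x$frequency, type = "h",
                 xlab = "orientation (deg)", ylab = "frequency", ...)
  graphics::abline(v = x$peak_angle_deg, col = 2, lty = 2)
  invisible(x)
}

#' Full orientation analysis of an image
#'
#' Convenience pipeline: cubic B-spline gradient, structure tensor (in
#' mathematical coordinates), orientation field with energy/coherency gates
#' and a `3 * window_sigma_px` border exclusion, then the axial histogram.
#'
#' @param img An [shg_image] or matrix.
#' @param roi Optional [roi_mask].
#' @param window_sigma_px Structure-tensor window s.d. in px.
#' @param bin_width_deg,delta_deg,weighting Passed to
#'   [orientation_histogram()].
#' @param energy_gate,coherency_gate Passed to [orientation_field()].
#' @return List with `field` and `histogram`.
#' @export
analyze_orientation <- function(img, roi = NULL, window_sigma_px = 2,
                                bin_width_deg = 1, delta_deg = 10,
                                weighting = "coherency", energy_gate = 25,
                                coherency_gate = 0.2) {
  g <- bspline_gradient(img)
  tens <- structure_tensor(g$fx, -g$fy, window_sigma_px)
  fld <- orientation_field(tens, energy_gate, coherency_gate,
                           border_margin_px = ceiling(3 * window_sigma_px),
                           roi = roi)
  hist <- orientation_histogram(fld, roi, bin_width_deg, delta_deg, weighting)
  list(field = fld, histogram = hist)
}

#' Pool orientation histograms across fields of view
#'
#' Averages the binned frequencies of several [orientation_histogram()]
#' objects (weighted by their valid pixel counts) and recomputes the peak
#' alignment and alignment frequency on the pooled histogram. This mirrors
#' the common acquisition design of imaging several separate areas per
#' sample and reporting one orientation readout per sample.
#'
#' @param histograms A list of `orientation_histogram` objects sharing bin
#'   layout and `delta_deg`.
#' @param weight_by_pixels Weight each field by its number of valid pixels
#'   (otherwise plain average).
#' @return An `orientation_histogram` for the pooled sample.
#' @export
pool_orientation_histograms <- function(histograms, weight_by_pixels = TRUE) {
  if (length(histograms) == 0L) fq_stop("bad_input", "no histograms to pool")
  h1 <- histograms[[1L]]
  same <- vapply(histograms, function(h)
    identical(h$bin_centers_deg, h1$bin_centers_deg) &&
      isTRUE(all.equal(h$delta_deg, h1$delta_deg)), logical(1))
  if (!all(same))
    fq_stop("bad_input", "histograms must share bin layout and delta_deg")
  w <- if (weight_by_pixels)
    vapply(histograms, function(h) as.numeric(h$n_valid_pixels), numeric(1))
  else rep(1, length(histograms))
  w <- w / sum(w)
  freq <- Reduce(`+`, Map(function(h, wi) h$frequency * wi, histograms, w))
  freq <- freq / sum(freq)
  centers <- h1$bin_centers_deg
  peak <- centers[which.max(freq)]
  sdiff <- ((centers - peak + 90) %% 180) - 90
  aligned <- sdiff > -h1$delta_deg & sdiff <= h1$delta_deg
  structure(list(bin_centers_deg = centers, bin_width_deg = h1$bin_width_deg,
                 frequency = freq, peak_angle_deg = peak,
                 alignment_frequency = sum(freq[aligned]),
                 delta_deg = h1$delta_deg, weighting = h1$weighting,
                 n_valid_pixels = sum(vapply(histograms, function(h)
                   h$n_valid_pixels, numeric(1)))),
            class = "orientation_histogram")
}

#' Compare two axial orientation distributions
#'
#' Mann-Whitney U test across distributions: both samples are expressed as
#' absolute axial deviations from the peak of their pooled histogram, and the
#' deviations are compared with a two-sided, continuity-corrected
#' Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param samples_a,samples_b Numeric vectors of axial angles in degrees.
#' @param bin_width_deg Bin width used to locate the pooled peak.
#' @return List with `statistic` (U), `p_value`, `joint_peak_deg`.
#' @export
compare_orientation_distributions <- function(samples_a, samples_b,
                                              bin_width_deg = 1) {
  if (length(samples_a) == 0L || length(samples_b) == 0L)
    fq_stop("bad_input", "both samples must be non-empty")
  pooled <- axial_wrap(c(samples_a, samples_b))
  nb <- as.integer(180 / bin_width_deg)
  k <- pmin(pmax(as.integer(ceiling((pooled + 90) / bin_width_deg)), 1L), nb)
  freq <- tabulate(k, nb)
  peak <- -90 + (which.max(freq) - 0.5) * bin_width_deg
  da <- axial_dist(axial_wrap(samples_a), peak)
  db <- axial_dist(axial_wrap(samples_b), peak)
  wt <- stats::wilcox.test(da, db, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       joint_peak_deg = peak)
}
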