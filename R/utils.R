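# Internal utilities shared across modules.

# Condition helper: all package errors carry a subclass "fq_<what>" so callers
# and tests can trap them precisely.
fq_stop <- function(what, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("fq_", what), "fq_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# Wrap angles (degrees) into the axial range (-90, 90].
axial_wrap <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[a <= -90] <- a[a <= -90] + 180
  a
}

# Axial distance between angles in degrees: |a - b| taken mod 180, folded to
# [0, 90].
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Deterministic substream seed. One documented global seed drives the run;
# substreams are split by a small integer id (fiber index, slice index, noise
# stage). Kept strictly below 2^31 - 1.
fq_mix_seed <- function(seed, id) {
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(id) + 1) * 16807
  as.integer(s %% 2147483646) + 1L
}

# Mirror (reflect-101) index vector for padding a length-n axis by r samples.
mirror_index <- function(n, r) {
  if (n < 2) return(rep(1L, n + 2L * r))
  idx <- c(seq.int(r + 1L, 2L), seq_len(n), seq.int(n - 1L, n - r))
  # for r >= n the reflected runs above can go out of range; fold explicitly
  if (r >= n) {
    period <- 2L * (n - 1L)
    raw <- c(seq.int(-r, -1L), seq.int(0L, n - 1L), seq.int(n, n - 1L + r))
    folded <- abs(raw) %% period
    folded[folded > (n - 1L)] <- period - folded[folded > (n - 1L)]
    idx <- folded + 1L
  }
  idx
}

# Separable 1-D convolution of a matrix along rows or columns with mirror
# boundaries. `kernel` must have odd length and is applied centered.
conv_mirror <- function(m, kernel, along = c("col", "row")) {
  along <- match.arg(along)
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  if (along == "row") return(t(conv_mirror(t(m), kernel, "col")))
  n <- ncol(m)
  idx <- mirror_index(n, r)
  pad <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), n)
  for (t in seq_len(k)) {
    out <- out + kernel[t] * pad[, seq.int(t, t + n - 1L), drop = FALSE]
  }
  out
}

# Gaussian kernel (normalized) with radius ceiling(3.5 * sigma).
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with mirror boundaries.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  conv_mirror(conv_mirror(m, k, "col"), k, "row")
}

# Pixel matrix extraction: accepts shg_image, roi_mask, or bare matrix.
as_pixel_matrix <- function(x) {
  if (inherits(x, "shg_image") || inherits(x, "roi_mask")) return(x$pixels)
  if (is.matrix(x)) return(x)
  fq_stop("bad_input", "expected an shg_image, roi_mask, or matrix")
}
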