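# Shared fixtures: small phantoms and brute-force oracles built in code.

quick_spec <- function(..., seed = 1L) {
  args <- list(height_px = 128L, width_px = 128L, pixel_size_um = 1.25,
               n_fibers = 60L, peak_angle_deg = 30, kappa = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(fiber_scene_spec, args)
}

# Brute-force GLCM by explicit double loop over all pixel pairs.
brute_glcm <- function(lev, d, ang, symmetric, n) {
  off <- switch(as.character(ang),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  P <- matrix(0, n, n)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nrow(lev) && c2 >= 1 && c2 <= ncol(lev)) {
      P[lev[r, c] + 1, lev[r2, c2] + 1] <- P[lev[r, c] + 1, lev[r2, c2] + 1] + 1
      if (symmetric)
        P[lev[r2, c2] + 1, lev[r, c] + 1] <- P[lev[r2, c2] + 1, lev[r, c] + 1] + 1
    }
  }
  P / sum(P)
}

# Brute-force interface band by all-pairs distances.
brute_band <- function(m, dist, px) {
  tr <- which(m, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (m[r, c]) next
    dmin <- sqrt(min((tr[, 1] - r)^2 + (tr[, 2] - c)^2)) * px
    out[r, c] <- dmin <= dist && dmin > 0
  }
  out
}

# One pooled-areas orientation measurement: three separate fields per sample,
# mirroring multi-area acquisition; returns the pooled histogram.
pooled_sample_histogram <- function(kappa, peak_angle_deg, seed,
                                    n_areas = 3L, n_fibers = 300L,
                                    px = 256L) {
  hs <- lapply(seq_len(n_areas), function(j) {
    sp <- fiber_scene_spec(height_px = px, width_px = px,
                          pixel_size_um = 1.25, n_fibers = n_fibers,
                          peak_angle_deg = peak_angle_deg, kappa = kappa,
                          seed = seed * 100L + j)
    sc <- if (kappa == 0) generate_isotropic_texture(sp) else
      generate_fiber_scene(sp)
    analyze_orientation(sc$image)$histogram
  })
  pool_orientation_histograms(hs)
}

axial_dist <- fibrilquant:::axial_dist

# Build a small synthetic study on disk: two groups of phantom TIFFs.
make_study <- function(dir, n_per_group = 3L, px = 128L, seed0 = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n_per_group)) {
    spA <- fiber_scene_spec(height_px = px, width_px = px,
                            pixel_size_um = 1.25, n_fibers = 60L,
                            peak_angle_deg = 0, kappa = 100,
                            seed = seed0 + i)
    pA <- file.path(dir, sprintf("aligned_%d.tif", i))
    write_scene(generate_fiber_scene(spA), pA)
    pI <- file.path(dir, sprintf("isotropic_%d.tif", i))
    write_scene(generate_isotropic_texture(spA), pI)
    rows[[length(rows) + 1L]] <- data.frame(path = pA, group = "aligned")
    rows[[length(rows) + 1L]] <- data.frame(path = pI, group = "isotropic")
  }
  do.call(rbind, rows)
}

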