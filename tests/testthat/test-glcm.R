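test_that("quantization maps ranges and ramps as documented", {
  expect_true(all(quantize(matrix(5, 4, 4), 8) == 0L))
  m <- matrix(seq(0, 1, length.out = 16), 4, 4)
  q <- quantize(m, 2)
  expect_identical(q, matrix(as.integer(m >= 0.5), 4, 4))
  ramp <- matrix(0:3, 1, 4)
  expect_identical(quantize(ramp, 4), matrix(0:3, 1, 4))
})

test_that("glcm equals brute-force pair enumeration on small images", {
  set.seed(42)
  for (rep in 1:3) {
    lev <- matrix(sample(0:5, 14 * 11, TRUE), 14, 11)
    for (ang in c(0, 45, 90, 135)) for (d in 1:3) for (sym in c(TRUE, FALSE)) {
      expect_equal(glcm(lev, d, ang, sym, 6),
                   brute_glcm(lev, d, ang, sym, 6), tolerance = 1e-12)
    }
  }
})

test_that("glcm normalization and symmetry invariants hold", {
  set.seed(17)
  lev <- matrix(sample(0:7, 20 * 20, TRUE), 20, 20)
  for (ang in c(0, 45, 90, 135)) {
    P <- glcm(lev, 2, ang, symmetric = TRUE, 8)
    expect_equal(sum(P), 1)
    expect_identical(P, t(P))
    expect_true(all(P >= 0))
  }
})

test_that("the 1x4 alternating strip gives the textbook symmetric GLCM", {
  P <- glcm(matrix(c(0L, 1L, 0L, 1L), 1, 4), 1, 0, TRUE, 2)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("analytic correlation cases: checkerboard, stripes, constant", {
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(glcm_correlation(glcm(cb, 1, 0, TRUE, 2)), -1)
  stripes <- matrix(rep(c(0L, 1L), length.out = 8)[col(matrix(0, 8, 8))], 8, 8)
  expect_equal(glcm_correlation(glcm(stripes, 2, 0, TRUE, 2)), 1)
  const <- glcm(matrix(0L, 5, 5), 1, 0, TRUE, 2)
  expect_error(glcm_correlation(const), class = "fq_degenerate_texture")
})

test_that("correlation stays within [-1, 1] on random textures", {
  set.seed(23)
  for (rep in 1:5) {
    lev <- matrix(sample(0:15, 30 * 30, TRUE), 30, 30)
    r <- glcm_correlation(glcm(lev, sample(1:4, 1), 45, TRUE, 16))
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("oversized offsets raise a no-pairs error", {
  expect_error(glcm(matrix(0:3, 1, 4), 4, 0, TRUE, 4), class = "fq_no_pairs")
})

test_that("a single-distance decay reports that correlation as its auc", {
  sc <- generate_fiber_scene(quick_spec(seed = 3L))
  dec <- correlation_decay(sc$image, glcm_config(distances_px = 1))
  expect_length(dec$correlation, 1L)
  expect_identical(dec$auc, dec$correlation[1L])
})

test_that("white noise decorrelates at every offset", {
  sp <- fiber_scene_spec(height_px = 256L, width_px = 256L,
                         pixel_size_um = 1.25, n_fibers = 0L,
                         background_level = 0.5, psf_sigma_um = 0,
                         noise_gaussian_sd = 0.1, noise_poisson_scale = 0,
                         seed = 19L)
  sc <- generate_fiber_scene(sp)
  dec <- correlation_decay(sc$image, glcm_config(distances_px = 1:8))
  expect_true(all(abs(dec$correlation) < 0.1))
})

test_that("degenerate images propagate a named error from the decay", {
  img <- shg_image(matrix(3, 16, 16), 1, name = "flat_img")
  expect_error(correlation_decay(img, glcm_config(distances_px = 1:2)),
               "flat_img", class = "fq_degenerate_texture")
})

test_that("an aligned phantom decays slower than its isotropic mate", {
  cfg <- glcm_config(distances_px = 1:24, angles_deg = 0)
  sp <- fiber_scene_spec(height_px = 256L, width_px = 256L,
                         pixel_size_um = 1.25, n_fibers = 160L,
                         peak_angle_deg = 0, kappa = 100, seed = 2L)
  al <- correlation_decay(normalize_intensity(
    generate_fiber_scene(sp)$image, "percentile"), cfg)
  iso <- correlation_decay(normalize_intensity(
    generate_isotropic_texture(sp)$image, "percentile"), cfg)
  expect_gt(al$auc, iso$auc)
  expect_gt(al$half_decay_distance_px, iso$half_decay_distance_px)
})
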