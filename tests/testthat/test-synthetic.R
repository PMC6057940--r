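test_that("empty scene is background plus noise with zero coverage", {
  sp <- quick_spec(n_fibers = 0L, background_level = 0.1,
                   noise_gaussian_sd = 0.02, noise_poisson_scale = 0)
  sc <- generate_fiber_scene(sp)
  expect_identical(sc$true_coverage_fraction, 0)
  expect_false(any(sc$truth_mask$pixels))
  expect_lt(abs(mean(sc$image$pixels) - 0.1), 0.01)
  expect_equal(nrow(sc$fiber_segments), 0L)
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- quick_spec(seed = 7L)
  a <- generate_fiber_scene(sp)
  b <- generate_fiber_scene(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth_mask$pixels, b$truth_mask$pixels)
  expect_identical(a$fiber_segments, b$fiber_segments)
})

test_that("extreme concentration pins every fiber to the peak angle", {
  sp <- quick_spec(kappa = 1e6, peak_angle_deg = 30, n_fibers = 50L,
                   wiggle = 0)
  sc <- generate_fiber_scene(sp)
  expect_true(all(axial_dist(sc$fiber_segments$angle_deg, 30) < 0.5))
  # circular variance of doubled angles shrinks to ~0
  th2 <- sc$fiber_segments$angle_deg * 2 * pi / 180
  R <- sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  expect_lt(1 - R, 1e-4)
})

test_that("ground-truth angles stay in the axial range", {
  for (s in 1:3) {
    sc <- generate_fiber_scene(quick_spec(kappa = 0.5, seed = s))
    a <- sc$fiber_segments$angle_deg
    expect_true(all(a > -90 & a <= 90))
  }
})

test_that("coverage is monotone in fiber count under a shared seed stream", {
  sp40 <- quick_spec(n_fibers = 40L, seed = 3L)
  sp80 <- quick_spec(n_fibers = 80L, seed = 3L)
  a <- generate_fiber_scene(sp40)
  b <- generate_fiber_scene(sp80)
  expect_gte(b$true_coverage_fraction, a$true_coverage_fraction)
  # the first 40 fibers are identical, so footprints are nested
  expect_true(all(b$truth_mask$pixels[a$truth_mask$pixels]))
})

test_that("isotropic generator produces uniform axial angles", {
  sp <- quick_spec(height_px = 256L, width_px = 256L, n_fibers = 600L,
                   seed = 11L)
  sc <- generate_isotropic_texture(sp)
  # one draw per fiber: segments within a fiber share a single angle draw
  first <- sc$fiber_segments[!duplicated(sc$fiber_segments$fiber), ]
  bins <- cut(first$angle_deg, breaks = seq(-90, 90, by = 10),
              include.lowest = TRUE)
  ct <- chisq.test(table(bins))
  expect_gt(ct$p.value, 0.01)
  # alignment fraction near the uniform expectation 2 * delta / 180
  expect_lt(abs(sc$true_alignment_fraction - 20 / 180), 0.03)
})

test_that("von Mises axial sampler is seeded and concentrates with kappa", {
  set.seed(5); a <- rvonmises_axial(200, 15, 4)
  set.seed(5); b <- rvonmises_axial(200, 15, 4)
  expect_identical(a, b)
  spread <- function(k) {
    set.seed(1)
    x <- rvonmises_axial(2000, 0, k)
    1 - sqrt(mean(cos(2 * x * pi / 180))^2 + mean(sin(2 * x * pi / 180))^2)
  }
  expect_true(spread(2) > spread(8) && spread(8) > spread(32))
  expect_error(rvonmises_axial(10, 0, -1), class = "fq_invalid_spec")
})

test_that("invalid scene specs are rejected", {
  expect_error(fiber_scene_spec(height_px = 0), class = "fq_invalid_spec")
  expect_error(fiber_scene_spec(pixel_size_um = -1), class = "fq_invalid_spec")
  expect_error(fiber_scene_spec(kappa = -2), class = "fq_invalid_spec")
  expect_error(fiber_scene_spec(fiber_width_um = 0), class = "fq_invalid_spec")
})

test_that("stack slices order coverage by the density profile", {
  sp <- quick_spec(n_fibers = 60L, seed = 2L)
  st <- generate_stack(sp, 3L, c(0, 1, 0.5))
  cov <- st$truth$true_coverage_fraction
  expect_true(cov[2] > cov[3] && cov[3] > cov[1])
  expect_identical(cov[1], 0)
})

test_that("single-slice stack reproduces the plain scene", {
  sp <- quick_spec(seed = 9L)
  st <- generate_stack(sp, 1L, 1)
  sc <- generate_fiber_scene(sp)
  expect_identical(st$stack$slices[[1L]]$pixels, sc$image$pixels)
  expect_identical(st$truth$true_coverage_fraction, sc$true_coverage_fraction)
})

test_that("stack rejects mismatched density profiles", {
  expect_error(generate_stack(quick_spec(), 3L, c(0, 1)),
               class = "fq_invalid_spec")
  expect_error(generate_stack(quick_spec(), 2L, c(0, 2)),
               class = "fq_invalid_spec")
})

test_that("scenes round-trip through TIFF plus JSON sidecar", {
  sc <- generate_fiber_scene(quick_spec(seed = 4L))
  path <- file.path(tempdir(), "scene.tif")
  write_scene(sc, path)
  img <- read_image(path, pixel_size_um = sc$spec$pixel_size_um)
  expect_s3_class(img, "shg_image")
  expect_identical(dim(img$pixels), dim(sc$image$pixels))
  truth <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(truth$true_coverage_fraction, sc$true_coverage_fraction)
  expect_equal(truth$spec$seed, 4L)
  unlink(c(path, paste0(path, ".json")))
})
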