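test_that("B-spline gradient is exact on low-order polynomials", {
  n <- 48L
  cc <- matrix(rep(0:(n - 1), each = n), n) / n     # scaled coordinates
  rr <- matrix(rep(0:(n - 1), times = n), n) / n
  interior <- 17:(n - 16)
  # linear ramp: exact everywhere in the interior
  g <- bspline_gradient(3 * cc * n)                 # img(r, c) = 3c
  expect_lt(max(abs(g$fx[interior, interior] - 3)), 1e-6)
  expect_lt(max(abs(g$fy[interior, interior])), 1e-6)
  # constant image: zero gradient
  g0 <- bspline_gradient(matrix(2, 16, 16))
  expect_lt(max(abs(g0$fx)), 1e-9)
  expect_lt(max(abs(g0$fy)), 1e-9)
  # full cubic in both axes
  img <- cc^3 - 2 * cc^2 + 0.5 * cc + rr^3 + rr * cc
  g3 <- bspline_gradient(img)
  fx_true <- (3 * cc^2 - 4 * cc + 0.5 + rr) / n
  fy_true <- (3 * rr^2 + cc) / n
  expect_lt(max(abs((g3$fx - fx_true)[interior, interior])), 1e-6)
  expect_lt(max(abs((g3$fy - fy_true)[interior, interior])), 1e-6)
  expect_error(bspline_gradient(matrix(0, 3, 3)), class = "fq_image_too_small")
})

test_that("structure tensor averages gradient outer products", {
  one <- matrix(1, 20, 20); zero <- matrix(0, 20, 20)
  tens <- structure_tensor(one, zero, 2)
  expect_equal(tens$Jxx, one, tolerance = 1e-12)
  expect_equal(tens$Jxy, zero, tolerance = 1e-12)
  expect_equal(tens$Jyy, zero, tolerance = 1e-12)
  t0 <- structure_tensor(zero, zero, 2)
  expect_true(all(t0$Jxx == 0) && all(t0$Jyy == 0))
  expect_error(structure_tensor(one, zero, 0), class = "fq_bad_input")
  # vertical stripes: gradient purely along +col
  n <- 64L
  img <- matrix(sin(2 * pi * rep(0:(n - 1), each = n) / 8), n)
  g <- bspline_gradient(img)
  tv <- structure_tensor(g$fx, -g$fy, 2)
  interior <- 17:(n - 16)
  expect_gt(mean(tv$Jxx[interior, interior]),
            100 * mean(tv$Jyy[interior, interior]))
  expect_lt(max(abs(tv$Jxy[interior, interior])),
            0.01 * mean(tv$Jxx[interior, interior]))
})

test_that("stripe patterns recover the expected structure orientation", {
  n <- 64L
  vert <- matrix(sin(2 * pi * rep(0:(n - 1), each = n) / 8), n)   # varies by col
  horiz <- matrix(sin(2 * pi * rep(0:(n - 1), times = n) / 8), n) # varies by row
  peak_of <- function(img) {
    h <- analyze_orientation(img, coherency_gate = 0.5)$histogram
    h$peak_angle_deg
  }
  expect_lt(axial_dist(peak_of(vert), 90), 1)
  expect_lt(axial_dist(peak_of(horiz), 0), 1)
})

test_that("coherency is bounded and white noise stays incoherent", {
  set.seed(3)
  img <- matrix(runif(256 * 256), 256)
  g <- bspline_gradient(img)
  tens <- structure_tensor(g$fx, -g$fy, 2)
  fld <- orientation_field(tens, energy_gate = 25, coherency_gate = 0,
                           border_margin_px = 6L)
  expect_true(all(fld$coherency >= 0 & fld$coherency <= 1))
  expect_lt(median(fld$coherency[fld$valid_mask]), 0.3)
  h <- orientation_histogram(fld, bin_width_deg = 10, delta_deg = 10,
                             weighting = "none")
  expect_lt(max(h$frequency), 3 / length(h$frequency))
})

test_that("histogram mass is conserved and degenerate fields peak correctly", {
  n <- 32L
  fld <- structure(list(theta_deg = matrix(30, n, n),
                        coherency = matrix(0.9, n, n),
                        energy = matrix(1, n, n),
                        valid_mask = matrix(TRUE, n, n)),
                   class = "orientation_field")
  h <- orientation_histogram(fld, bin_width_deg = 1, delta_deg = 10)
  expect_equal(sum(h$frequency), 1)
  expect_lte(abs(h$peak_angle_deg - 30), 0.5)
  expect_equal(h$alignment_frequency, 1)
  # uniform orientations: alignment frequency near 2 * delta / 180
  set.seed(8)
  fldu <- structure(list(theta_deg = matrix(rvonmises_axial(512^2, 0, 0), 512),
                         coherency = matrix(1, 512, 512),
                         energy = matrix(1, 512, 512),
                         valid_mask = matrix(TRUE, 512, 512)),
                    class = "orientation_field")
  hu <- orientation_histogram(fldu, bin_width_deg = 1, delta_deg = 10,
                              weighting = "none")
  expect_lt(abs(hu$alignment_frequency - 20 / 180), 0.03)
  # empty selection errors
  fld$valid_mask[] <- FALSE
  expect_error(orientation_histogram(fld), class = "fq_no_oriented_signal")
})

test_that("phantom peak and alignment frequency are recovered", {
  h <- pooled_sample_histogram(kappa = 8, peak_angle_deg = 40, seed = 21L,
                               n_fibers = 250L)
  expect_lt(axial_dist(h$peak_angle_deg, 40), 2)
  # alignment frequency against generator truth for the same fields
  truths <- vapply(1:3, function(j) {
    sp <- fiber_scene_spec(height_px = 256L, width_px = 256L,
                           pixel_size_um = 1.25, n_fibers = 250L,
                           peak_angle_deg = 40, kappa = 8,
                           seed = 21L * 100L + j)
    generate_fiber_scene(sp)$true_alignment_fraction
  }, numeric(1))
  expect_gt(h$alignment_frequency, mean(truths) - 0.05)
})

test_that("pooling histograms preserves layout and total mass", {
  h <- pooled_sample_histogram(kappa = 4, peak_angle_deg = 0, seed = 2L,
                               n_areas = 2L, n_fibers = 80L, px = 128L)
  expect_equal(sum(h$frequency), 1)
  single <- pooled_sample_histogram(kappa = 4, peak_angle_deg = 0, seed = 3L,
                                    n_areas = 1L, n_fibers = 80L, px = 128L)
  same <- pool_orientation_histograms(list(single, single))
  expect_equal(same$frequency, single$frequency)
  expect_equal(same$peak_angle_deg, single$peak_angle_deg)
})

test_that("orientation distribution comparison is calibrated", {
  set.seed(5)
  s <- rvonmises_axial(500, 30, 5)
  expect_gt(compare_orientation_distributions(s, s)$p_value, 0.99)
  set.seed(9)
  a <- rvonmises_axial(1000, 0, 0)
  b <- rvonmises_axial(1000, 0, 20)
  expect_lt(compare_orientation_distributions(a, b)$p_value, 0.001)
  expect_error(compare_orientation_distributions(numeric(0), b),
               class = "fq_bad_input")
})
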