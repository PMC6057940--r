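test_that("single-dose fit matches the closed form and the cloglog GLM", {
  d <- dilution_experiment(100, 10, 5)
  fit <- fit_single_hit(d)
  closed <- -log(1 - 5 / 10) / 100
  expect_lt(abs(fit$frequency - closed) / closed, 1e-6)
  gl <- glm(cbind(responded, tested - responded) ~ 1 + offset(log(dose)),
            family = binomial("cloglog"), data = d)
  expect_lt(abs(fit$frequency - exp(coef(gl))) / fit$frequency, 1e-6)
  expect_equal(fit$one_in, 144)
  expect_identical(fit$boundary_flag, "none")
})

test_that("dose rescaling rescales the frequency exactly", {
  base <- dilution_experiment(c(10, 50, 250, 1250), rep(24, 4),
                              c(2, 4, 10, 22))
  f1 <- fit_single_hit(base)
  for (cfac in c(3, 0.1)) {
    f2 <- fit_single_hit(dilution_experiment(base$dose * cfac, base$tested,
                                             base$responded))
    expect_lt(abs(f1$frequency / cfac - f2$frequency) /
                (f1$frequency / cfac), 1e-9)
  }
})

test_that("boundary assays are flagged with one-sided likelihood bounds", {
  neg <- dilution_experiment(c(10, 100), c(6, 6), c(0, 0))
  fn <- fit_single_hit(neg)
  expect_identical(fn$boundary_flag, "all_negative")
  expect_identical(fn$frequency, 0)
  # closed form: sum(n_d * d) * f_upper = -log(0.05)
  expect_lt(abs(fn$ci95_high - (-log(0.05) / sum(neg$tested * neg$dose))) /
              fn$ci95_high, 1e-6)
  pos <- dilution_experiment(c(10, 100), c(6, 6), c(6, 6))
  fp <- fit_single_hit(pos)
  expect_identical(fp$boundary_flag, "all_positive")
  expect_true(is.infinite(fp$frequency))
  expect_true(is.finite(fp$ci95_low) && fp$ci95_low > 0)
})

test_that("profile interval brackets the MLE and narrows with more animals", {
  doses <- c(10, 50, 250, 1250)
  small <- fit_single_hit(simulate_dilution(1 / 435, doses, 12, seed = 4))
  big <- fit_single_hit(simulate_dilution(1 / 435, doses, 96, seed = 4))
  for (f in list(small, big)) {
    expect_lte(f$ci95_low, f$frequency)
    expect_gte(f$ci95_high, f$frequency)
  }
  width <- function(f) log(f$ci95_high) - log(f$ci95_low)
  expect_lt(width(big), width(small))
})

test_that("identical groups give a null likelihood-ratio comparison", {
  a <- dilution_experiment(c(10, 50, 250), rep(12, 3), c(1, 4, 9), "a")
  cmp <- compare_frequencies(a, a)
  expect_lt(cmp$statistic, 1e-8)
  expect_gt(cmp$p_value, 0.999)
})

test_that("double-boundary comparisons are rejected with guidance", {
  neg <- dilution_experiment(10, 5, 0)
  pos <- dilution_experiment(10, 5, 5)
  expect_error(compare_frequencies(neg, pos), class = "fq_double_boundary")
})

test_that("simulation saturates and reproduces under a fixed seed", {
  sat <- simulate_dilution(1, c(100, 1000), 10, seed = 2)
  expect_true(all(sat$responded == sat$tested))
  rare <- simulate_dilution(1e-9, c(10, 100), 10, seed = 2)
  expect_true(all(rare$responded == 0))
  expect_identical(simulate_dilution(1 / 300, c(10, 100), 24, seed = 7),
                   simulate_dilution(1 / 300, c(10, 100), 24, seed = 7))
})

test_that("model methods expose coefficients, intervals and predictions", {
  d <- simulate_dilution(1 / 435, c(10, 50, 250, 1250), 24, seed = 11)
  fit <- fit_single_hit(d)
  expect_named(coef(fit), "frequency")
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci95_low, fit$ci95_high))
  p <- predict(fit, newdata = c(0.0001, 1e9))
  expect_lt(p[1], 1e-6)
  expect_gt(p[2], 1 - 1e-6)
  expect_equal(as.numeric(logLik(fit)), fit$log_likelihood)
  expect_output(print(fit), "1 in")
})

test_that("dilution tables round-trip through delimited text", {
  path <- file.path(tempdir(), "lda.csv")
  writeLines(c("dose,tested,responded,group",
               "10,24,2,ctrl", "50,24,6,ctrl",
               "10,24,5,hh", "50,24,12,hh"), path)
  tabs <- read_dilution_table(path)
  expect_named(tabs, c("ctrl", "hh"))
  expect_equal(tabs$hh$responded, c(5L, 12L))
  expect_error(read_dilution_table(file.path(tempdir(), "missing.csv")),
               class = "fq_unreadable_file")
  unlink(path)
})

test_that("invalid dose-response tables are rejected", {
  expect_error(dilution_experiment(numeric(0), integer(0), integer(0)),
               class = "fq_bad_input")
  expect_error(dilution_experiment(-5, 10, 2), class = "fq_bad_input")
  expect_error(dilution_experiment(10, 5, 6), class = "fq_bad_input")
})
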