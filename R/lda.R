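#' Limiting-dilution experiment table
#'
#' A dose-response table from a limiting-dilution transplantation assay:
#' graded cell doses, number of recipients tested, number responding (tumor
#' takes).
#'
#' @param dose Positive numeric vector, cells per transplant.
#' @param tested Positive integer vector, recipients per dose.
#' @param responded Non-negative integer vector, takes per dose
#'   (`responded <= tested`).
#' @param group_label Text label for the experimental group.
#' @return An object of class `dilution_experiment` (a data frame).
#' @export
dilution_experiment <- function(dose, tested, responded,
                                group_label = "group") {
  if (length(dose) == 0L) fq_stop("bad_input", "at least one dose is required")
  if (length(tested) != length(dose) || length(responded) != length(dose))
    fq_stop("bad_input", "dose, tested, responded must have equal length")
  if (any(!is.finite(dose)) || any(dose <= 0))
    fq_stop("bad_input", "doses must be positive")
  if (any(tested < 1) || any(responded < 0) || any(responded > tested))
    fq_stop("bad_input", "need 0 <= responded <= tested, tested >= 1")
  structure(data.frame(dose = as.numeric(dose), tested = as.integer(tested),
                       responded = as.integer(responded)),
            group_label = as.character(group_label),
            class = c("dilution_experiment", "data.frame"))
}

#' Read a dilution-assay table from delimited text
#'
#' Expects a header with columns `dose`, `tested`, `responded` and an
#' optional `group` column; returns one [dilution_experiment()] per group.
#'
#' @param path File path (comma-, tab-, or semicolon-delimited; autodetected
#'   from the header line).
#' @return A named list of `dilution_experiment` objects.
#' @export
read_dilution_table <- function(path) {
  if (!file.exists(path))
    fq_stop("unreadable_file", sprintf("cannot read '%s'", path))
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("dose", "tested", "responded")
  if (!all(need %in% names(df)))
    fq_stop("bad_input", "table must have columns dose, tested, responded")
  if (!"group" %in% names(df)) df$group <- "group"
  out <- lapply(split(df, df$group), function(g)
    dilution_experiment(g$dose, g$tested, g$responded, g$group[1L]))
  out
}

# Binomial log-likelihood of the single-hit model at frequency f:
# P(response | dose d) = 1 - exp(-f d). Parameterized in log f.
single_hit_loglik <- function(logf, dose, tested, responded) {
  fd <- exp(logf) * dose
  # log(1 - exp(-fd)) computed stably
  lp <- ifelse(fd > 1e-8, log1p(-exp(-fd)), log(fd) + log1p(-fd / 2))
  sum(responded * lp - (tested - responded) * fd)
}

single_hit_score <- function(logf, dose, tested, responded) {
  f <- exp(logf)
  fd <- f * dose
  em <- exp(-fd)
  sum(responded * fd * em / (1 - em) - (tested - responded) * fd)
}

#' Fit the single-hit Poisson limiting-dilution model
#'
#' Estimates the active (tumor-initiating) cell frequency `f` from a
#' limiting-dilution assay under the single-hit Poisson model
#' `P(response | dose d) = 1 - exp(-f d)` — equivalently a binomial GLM with
#' complementary log-log link and offset `log d`. The likelihood is maximized
#' in `log f` by a bracketed root of the score (the log-likelihood is concave
#' in `log f`); the 95% confidence interval comes from the profile
#' likelihood, with a Wald fallback. Assays in which no animal responded, or
#' every animal responded, are boundary cases: the frequency estimate sits at
#' the boundary and a one-sided 95% likelihood bound is reported, flagged in
#' `boundary_flag`.
#'
#' @param exp_data A [dilution_experiment()] or a data frame with columns
#'   `dose`, `tested`, `responded`.
#' @param conf_level Confidence level for the profile interval.
#' @return An object of class `single_hit_fit` with components `frequency`,
#'   `ci95_low`, `ci95_high`, `one_in` (`round(1 / frequency)`),
#'   `log_likelihood`, `boundary_flag` (`"none"`, `"all_negative"`,
#'   `"all_positive"`), `data`, `group_label`. Methods: `print`, `summary`,
#'   `coef`, `confint`, `logLik`, `predict`.
#' @examples
#' fit <- fit_single_hit(dilution_experiment(
#'   dose = c(10, 50, 250, 1250), tested = rep(24, 4),
#'   responded = c(1, 3, 11, 22)))
#' fit
#' @export
fit_single_hit <- function(exp_data, conf_level = 0.95) {
  if (!inherits(exp_data, "dilution_experiment"))
    exp_data <- dilution_experiment(exp_data$dose, exp_data$tested,
                                    exp_data$responded)
  d <- exp_data$dose; n <- exp_data$tested; x <- exp_data$responded
  glabel <- attr(exp_data, "group_label")
  ll <- function(lf) single_hit_loglik(lf, d, n, x)
  drop2 <- stats::qchisq(conf_level, 1) / 2
  drop1 <- -log(1 - conf_level)      # one-sided likelihood bound
  lo_lim <- log(.Machine$double.xmin) / 2
  if (all(x == 0L)) {
    # likelihood maximized as f -> 0; sup log-lik = 0
    upper <- stats::uniroot(function(lf) ll(lf) + drop1,
                            lower = -60, upper = 60, tol = 1e-12)$root
    est <- list(frequency = 0, ci95_low = 0, ci95_high = exp(upper),
                log_likelihood = 0, boundary_flag = "all_negative")
  } else if (all(x == n)) {
    # likelihood maximized as f -> Inf; sup log-lik = 0
    lower <- stats::uniroot(function(lf) ll(lf) + drop1,
                            lower = -60, upper = 60, tol = 1e-12)$root
    est <- list(frequency = Inf, ci95_low = exp(lower), ci95_high = Inf,
                log_likelihood = 0, boundary_flag = "all_positive")
  } else {
    # bracket the score root
    lo <- -5; hi <- 5
    while (single_hit_score(lo, d, n, x) < 0 && lo > lo_lim) lo <- lo - 5
    while (single_hit_score(hi, d, n, x) > 0 && hi < 60) hi <- hi + 5
    lf_hat <- stats::uniroot(single_hit_score, c(lo, hi), dose = d,
                             tested = n, responded = x, tol = 1e-13)$root
    ll_max <- ll(lf_hat)
    bound <- function(side) {
      f_ <- function(lf) ll(lf) - (ll_max - drop2)
      step <- 1
      a <- lf_hat; b <- lf_hat + side * step
      while (f_(b) > 0 && abs(b) < 80) b <- b + side * step
      if (f_(b) > 0) return(NA_real_)   # no root; fall back to Wald later
      stats::uniroot(f_, sort(c(a, b)), tol = 1e-11)$root
    }
    lo_b <- bound(-1); hi_b <- bound(+1)
    if (is.na(lo_b) || is.na(hi_b)) {
      # Wald fallback in log f from the numerical observed information
      h <- 1e-4
      info <- -(ll(lf_hat + h) - 2 * ll_max + ll(lf_hat - h)) / h^2
      se <- if (info > 0) 1 / sqrt(info) else NA_real_
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      if (is.na(lo_b)) lo_b <- lf_hat - z * se
      if (is.na(hi_b)) hi_b <- lf_hat + z * se
    }
    est <- list(frequency = exp(lf_hat), ci95_low = exp(lo_b),
                ci95_high = exp(hi_b), log_likelihood = ll_max,
                boundary_flag = "none")
  }
  est$one_in <- if (is.finite(est$frequency) && est$frequency > 0)
    round(1 / est$frequency) else NA_real_
  est$conf_level <- conf_level
  est$data <- exp_data
  est$group_label <- glabel
  class(est) <- "single_hit_fit"
  est
}

#' @export
print.single_hit_fit <- function(x, ...) {
  cat(sprintf("Single-hit limiting-dilution fit (%s)\n", x$group_label))
  if (x$boundary_flag == "none") {
    cat(sprintf("  frequency: %.4g  (1 in %d)\n", x$frequency, x$one_in))
    cat(sprintf("  %g%% CI: %.4g .. %.4g  (1 in %d .. 1 in %d)\n",
                100 * x$conf_level, x$ci95_low, x$ci95_high,
                round(1 / x$ci95_high), round(1 / x$ci95_low)))
  } else {
    cat(sprintf("  boundary assay (%s): frequency %s, one-sided %g%% bound [%.4g, %.4g]\n",
                x$boundary_flag, format(x$frequency), 100 * x$conf_level,
                x$ci95_low, x$ci95_high))
  }
  invisible(x)
}

#' @export
summary.single_hit_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood: %.4f on %d dose groups (%d animals)\n",
              object$log_likelihood, nrow(object$data),
              sum(object$data$tested)))
  invisible(object)
}

#' @export
coef.single_hit_fit <- function(object, ...) {
  c(frequency = object$frequency)
}

#' @export
confint.single_hit_fit <- function(object, parm = "frequency", level = 0.95,
                                   ...) {
  if (!isTRUE(all.equal(level, object$conf_level)))
    object <- fit_single_hit(object$data, conf_level = level)
  m <- matrix(c(object$ci95_low, object$ci95_high), 1, 2,
              dimnames = list("frequency",
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
logLik.single_hit_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 1L, class = "logLik")
}

#' @export
predict.single_hit_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  1 - exp(-object$frequency * d)
}

#' Likelihood-ratio comparison of two limiting-dilution assays
#'
#' Tests equality of the active-cell frequency between two groups: twice the
#' gain in log-likelihood of group-specific frequencies over a shared
#' frequency, referred to chi-square with 1 degree of freedom.
#'
#' @param a,b [dilution_experiment()] objects (or data frames).
#' @return List with `statistic`, `df`, `p_value`, `fit_a`, `fit_b`,
#'   `fit_pooled`.
#' @export
compare_frequencies <- function(a, b) {
  fa <- fit_single_hit(a); fb <- fit_single_hit(b)
  if (fa$boundary_flag != "none" && fb$boundary_flag != "none")
    fq_stop("double_boundary",
            paste("both groups are boundary assays (all-negative or",
                  "all-positive); the frequency ratio is not identifiable.",
                  "Add informative doses."))
  pooled <- dilution_experiment(c(fa$data$dose, fb$data$dose),
                                c(fa$data$tested, fb$data$tested),
                                c(fa$data$responded, fb$data$responded),
                                "pooled")
  fp <- fit_single_hit(pooled)
  stat <- max(0, 2 * (fa$log_likelihood + fb$log_likelihood -
                        fp$log_likelihood))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       fit_a = fa, fit_b = fb, fit_pooled = fp)
}

#' Simulate a limiting-dilution assay
#'
#' Draws takes per dose as `Binomial(n, 1 - exp(-f d))`.
#'
#' @param f_true True active-cell frequency (> 0).
#' @param doses Vector of cell doses.
#' @param n_per_dose Recipients per dose.
#' @param seed Integer seed.
#' @param group_label Label for the simulated experiment.
#' @return A [dilution_experiment()].
#' @export
simulate_dilution <- function(f_true, doses, n_per_dose, seed = 1L,
                              group_label = "simulated") {
  if (f_true <= 0) fq_stop("bad_input", "f_true must be > 0")
  set.seed(seed)
  p <- 1 - exp(-f_true * doses)
  x <- stats::rbinom(length(doses), n_per_dose, p)
  dilution_experiment(doses, rep(n_per_dose, length(doses)), x, group_label)
}
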