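#' Compare a metric between groups
#'
#' Runs one of the standard tests used on image-derived metrics: equal-
#' variance two-sided t test for scalar per-image metrics, Mann-Whitney U for
#' distribution-level comparisons, Kruskal-Wallis for three or more groups,
#' or Fisher's exact test for penetrance counts.
#'
#' @param values_by_group A named list of numeric vectors (one per group),
#'   or, for `test = "fisher_exact"`, a 2 x 2 count matrix.
#' @param test One of `"t_equal_var"`, `"mann_whitney"`, `"kruskal_wallis"`,
#'   `"fisher_exact"`.
#' @param metric Name of the metric (provenance; echoed into outputs).
#' @return An object of class `group_comparison` with the group means and
#'   standard errors, the test name, statistic and two-sided p value.
#' @export
compare_groups <- function(values_by_group,
                           test = c("t_equal_var", "mann_whitney",
                                    "kruskal_wallis", "fisher_exact"),
                           metric = "metric") {
  test <- match.arg(test)
  if (test == "fisher_exact") {
    if (!is.matrix(values_by_group))
      fq_stop("bad_input", "fisher_exact requires a count matrix")
    ft <- stats::fisher.test(values_by_group)
    res <- list(metric = metric, test = test, statistic = NA_real_,
                p_value = ft$p.value, groups = NULL)
    class(res) <- "group_comparison"
    return(res)
  }
  g <- values_by_group
  if (!is.list(g) || length(g) < 2L)
    fq_stop("bad_input", "need at least two groups")
  if (is.null(names(g))) names(g) <- paste0("group", seq_along(g))
  if (test %in% c("t_equal_var") && any(vapply(g, length, integer(1)) < 2L))
    fq_stop("bad_input", "variance-based tests need n >= 2 per group")
  summ <- data.frame(
    group = names(g),
    n = vapply(g, length, integer(1)),
    mean = vapply(g, mean, numeric(1)),
    sem = vapply(g, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    row.names = NULL)
  out <- switch(test,
    t_equal_var = {
      if (length(g) != 2L) fq_stop("bad_input", "t test needs exactly 2 groups")
      ht <- stats::t.test(g[[1L]], g[[2L]], var.equal = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    mann_whitney = {
      if (length(g) != 2L)
        fq_stop("bad_input", "Mann-Whitney needs exactly 2 groups")
      ht <- stats::wilcox.test(g[[1L]], g[[2L]], exact = FALSE,
                               correct = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    kruskal_wallis = {
      ht <- stats::kruskal.test(g)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  res <- list(metric = metric, test = test, statistic = out$statistic,
              p_value = out$p_value, groups = summ)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s: statistic %s, p = %.4g\n",
              x$metric, x$test, format(x$statistic, digits = 4), x$p_value))
  if (!is.null(x$groups)) {
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("  %s: mean %.4g +- %.4g s.e.m. (n = %d)\n",
                  x$groups$group[i], x$groups$mean[i], x$groups$sem[i],
                  x$groups$n[i]))
  }
  invisible(x)
}

#' Study configuration
#'
#' Assembles the configuration for a batch run: an image manifest, the
#' study-wide coverage threshold (or pooled-Otsu policy), GLCM and
#' orientation parameters, and a seed.
#'
#' @param images Data frame with columns `path`, `group`, and optionally
#'   `roi_path` (`NA` for none) and `pixel_size_um`.
#' @param pixel_size_um Default pixel size for images without their own.
#' @param threshold Study-wide coverage threshold, or `"otsu-pooled"` to
#'   compute a pooled-histogram Otsu threshold across all images.
#' @param glcm A [glcm_config()].
#' @param window_sigma_px,bin_width_deg,delta_deg,weighting,energy_gate,coherency_gate
#'   Orientation parameters (see [analyze_orientation()]).
#' @param seed Integer seed recorded and used for any stochastic step.
#' @return An object of class `study_config`.
#' @export
study_config <- function(images, pixel_size_um = 0.625,
                         threshold = "otsu-pooled",
                         glcm = glcm_config(distances_px = 1:32),
                         window_sigma_px = 2, bin_width_deg = 1,
                         delta_deg = 10, weighting = "coherency",
                         energy_gate = 25, coherency_gate = 0.2,
                         seed = 1L) {
  if (!is.data.frame(images) || nrow(images) == 0L ||
      !all(c("path", "group") %in% names(images)))
    fq_stop("bad_input", "images must be a data frame with path and group")
  if (!"roi_path" %in% names(images)) images$roi_path <- NA_character_
  if (!"pixel_size_um" %in% names(images))
    images$pixel_size_um <- pixel_size_um
  structure(list(images = images, threshold = threshold, glcm = glcm,
                 window_sigma_px = window_sigma_px,
                 bin_width_deg = bin_width_deg, delta_deg = delta_deg,
                 weighting = weighting, energy_gate = energy_gate,
                 coherency_gate = coherency_gate, seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with fields mirroring [study_config()]; `images` is
#'   a list of `{path, group, roi_path, pixel_size_um}` records.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  imgs <- do.call(rbind, lapply(y$images, function(e)
    data.frame(path = e$path, group = e$group,
               roi_path = if (is.null(e$roi_path)) NA_character_ else e$roi_path,
               pixel_size_um = if (is.null(e$pixel_size_um))
                 y$pixel_size_um else e$pixel_size_um)))
  gc_args <- y$glcm
  gcfg <- if (is.null(gc_args)) glcm_config(distances_px = 1:32) else
    do.call(glcm_config, gc_args)
  study_config(
    images = imgs,
    pixel_size_um = if (is.null(y$pixel_size_um)) 0.625 else y$pixel_size_um,
    threshold = if (is.null(y$threshold)) "otsu-pooled" else y$threshold,
    glcm = gcfg,
    window_sigma_px = if (is.null(y$window_sigma_px)) 2 else y$window_sigma_px,
    bin_width_deg = if (is.null(y$bin_width_deg)) 1 else y$bin_width_deg,
    delta_deg = if (is.null(y$delta_deg)) 10 else y$delta_deg,
    weighting = if (is.null(y$weighting)) "coherency" else y$weighting,
    energy_gate = if (is.null(y$energy_gate)) 25 else y$energy_gate,
    coherency_gate = if (is.null(y$coherency_gate)) 0.2 else y$coherency_gate,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

# stable hash of the configuration (md5 of its canonical YAML rendering)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(unclass(config), function(x)
    if (is.data.frame(x)) as.list(x) else if (inherits(x, "glcm_config"))
      unclass(x) else x)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full image study
#'
#' For every image in the manifest: coverage at the study-wide threshold,
#' GLCM correlation-decay summaries, and orientation summaries, all
#' restricted to the image's ROI when one is given. Scalar per-image metrics
#' are then compared between groups with the equal-variance t test (two
#' groups; Kruskal-Wallis for more). Per-image failures are logged and
#' skipped, not silent. Outputs are deterministic given config + seed and are
#' written as UTF-8 CSV with a JSON run manifest embedding the config hash
#' and package version.
#'
#' @param config A [study_config()] or path to a YAML file.
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @return An object of class `study_result` with `metrics` (per-image data
#'   frame), `comparisons` (data frame, empty when only one group),
#'   `threshold`, `failures` (character vector), `config_hash`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  if (!inherits(config, "study_config"))
    fq_stop("bad_input", "config must be a study_config or YAML path")
  set.seed(config$seed)
  man <- config$images
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  note("run_study: %d images, %d groups, seed %d", nrow(man),
       length(unique(man$group)), config$seed)
  imgs <- vector("list", nrow(man))
  rois <- vector("list", nrow(man))
  failures <- character(0)
  for (i in seq_len(nrow(man))) {
    imgs[[i]] <- tryCatch(
      read_image(man$path[i], pixel_size_um = man$pixel_size_um[i]),
      error = function(e) e)
    if (inherits(imgs[[i]], "error")) next
    if (!is.na(man$roi_path[i]))
      rois[[i]] <- tryCatch(read_roi_mask(man$roi_path[i]),
                            error = function(e) e)
  }
  # study-wide threshold, possibly pooled Otsu over all readable images
  readable <- !vapply(imgs, inherits, logical(1), "error")
  thr <- config$threshold
  if (identical(thr, "otsu-pooled")) {
    thr <- pooled_otsu_threshold(imgs[readable])
    note("pooled Otsu threshold across %d images: %.6g", sum(readable), thr)
  } else thr <- as.numeric(thr)
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      img <- imgs[[i]]
      if (inherits(img, "error")) stop(conditionMessage(img))
      if (inherits(img, "image_stack")) img <- img$slices[[1L]]
      roi <- rois[[i]]
      if (inherits(roi, "error")) stop(conditionMessage(roi))
      cov <- coverage(img, thr, roi)
      nimg <- normalize_intensity(img, "percentile", p = 99.9)
      dec <- correlation_decay(nimg, config$glcm, roi)
      ori <- analyze_orientation(nimg, roi,
                                 window_sigma_px = config$window_sigma_px,
                                 bin_width_deg = config$bin_width_deg,
                                 delta_deg = config$delta_deg,
                                 weighting = config$weighting,
                                 energy_gate = config$energy_gate,
                                 coherency_gate = config$coherency_gate)
      data.frame(
        image = basename(man$path[i]), group = man$group[i],
        roi = if (is.null(roi)) "full_frame" else roi$label,
        threshold = thr,
        coverage_percent = cov$coverage_percent,
        glcm_auc = dec$auc,
        glcm_half_decay_px = dec$half_decay_distance_px,
        peak_angle_deg = ori$histogram$peak_angle_deg,
        alignment_frequency = ori$histogram$alignment_frequency,
        n_valid_pixels = ori$histogram$n_valid_pixels)
    }, error = function(e) {
      note("FAILED %s: %s", man$path[i], conditionMessage(e))
      failures <<- c(failures, man$path[i])
      NULL
    })
    rows[[i]] <- res
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  # group comparisons on scalar metrics
  comparisons <- NULL
  groups <- unique(metrics$group)
  scalar_metrics <- c("coverage_percent", "glcm_auc", "glcm_half_decay_px",
                      "alignment_frequency")
  if (length(groups) >= 2L) {
    test <- if (length(groups) == 2L) "t_equal_var" else "kruskal_wallis"
    cmp <- lapply(scalar_metrics, function(mname) {
      vals <- split(metrics[[mname]], metrics$group)
      vals <- lapply(vals, function(v) v[is.finite(v)])
      if (any(vapply(vals, length, integer(1)) < 2L)) return(NULL)
      gc_ <- compare_groups(vals, test, metric = mname)
      data.frame(metric = mname, test = gc_$test, statistic = gc_$statistic,
                 p_value = gc_$p_value)
    })
    comparisons <- do.call(rbind, cmp[!vapply(cmp, is.null, logical(1))])
  } else {
    note("single group: comparisons table left empty")
  }
  if (is.null(comparisons))
    comparisons <- data.frame(metric = character(0), test = character(0),
                              statistic = numeric(0), p_value = numeric(0))
  chash <- config_hash(config)
  result <- structure(list(metrics = metrics, comparisons = comparisons,
                           threshold = thr, failures = failures,
                           config = config, config_hash = chash,
                           log = log_lines),
                      class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "fibrilquant",
      version = as.character(utils::packageVersion("fibrilquant")),
      config_hash = chash, seed = config$seed, threshold = thr,
      n_images = nrow(man), n_failed = length(failures),
      parameters = list(
        glcm = unclass(config$glcm),
        window_sigma_px = config$window_sigma_px,
        bin_width_deg = config$bin_width_deg, delta_deg = config$delta_deg,
        weighting = config$weighting, energy_gate = config$energy_gate,
        coherency_gate = config$coherency_gate))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d images, threshold %.6g, %d failures, config %s\n",
              nrow(x$metrics), x$threshold, length(x$failures),
              substr(x$config_hash, 1, 8)))
  if (nrow(x$comparisons) > 0) {
    cat("  comparisons:\n")
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("    %s (%s): p = %.4g\n", x$comparisons$metric[i],
                  x$comparisons$test[i], x$comparisons$p_value[i]))
  }
  invisible(x)
}
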