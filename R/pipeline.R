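# File-based pipeline stages: simulate measurement sets or images, extract
# particles from images, fit/select mixture models, and compare conditions.
# Every stage is a pure function of (inputs, config, seed); each run writes
# its resolved configuration beside its outputs so results are reproducible.

#' Read and write measurement CSV files
#'
#' The measurement interchange format is a comma-separated UTF-8 file with a
#' header and columns `value`, `unit`, `condition` (plus an optional integer
#' `component` truth column from the simulator).
#'
#' @param path CSV file path.
#' @param data Measurement tibble.
#' @return `read_measurements()` returns a tibble; `write_measurements()`
#'   returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    vlp_abort(paste0("Measurement file not found: ", path), class = "io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"value" %in% names(df)) {
    vlp_abort(paste0("No `value` column in ", path), class = "io_error")
  }
  measurement_values(df)  # validates units and finiteness
  as_tibble(df)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(data, path) {
  if (!is.data.frame(data) || !"value" %in% names(data)) {
    vlp_abort("`data` must contain a `value` column.")
  }
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

write_run_config <- function(dir, config) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Pipeline stage: simulate measurements or images
#'
#' With `image = FALSE` draws a measurement set from a preset or explicit
#' component spec and writes `measurements.csv` (including the latent
#' component truth). With `image = TRUE` renders `n_images` synthetic AFM
#' topographs with `particles_per_image` particles each, writing a PNG and a
#' JSON truth sidecar per image.
#'
#' @param out_dir Output directory (created if missing).
#' @param preset Preset name (see [gmm_presets()]); ignored when `spec` given.
#' @param spec Explicit component spec (`weight`/`mean`/`sigma` data frame).
#' @param n Number of particles to draw (measurement mode).
#' @param seed Integer seed; outputs are byte-identical under the same seed.
#' @param condition Condition label; defaults to the preset name.
#' @param image Simulate images instead of measurements?
#' @param n_images,particles_per_image,size,calibration,noise_sd Image-mode
#'   parameters (see [simulate_particle_truth()]).
#' @return Invisibly, a character vector of the files written.
#' @export
run_simulate <- function(out_dir, preset = NULL, spec = NULL, n = 100,
                         seed = 1, condition = NULL, image = FALSE,
                         n_images = 3, particles_per_image = 5,
                         size = 256, calibration = 115, noise_sd = 6) {
  if (is.null(spec)) {
    if (is.null(preset)) vlp_abort("Provide `preset` or `spec`.")
    spec <- gmm_preset(preset)
  } else {
    spec <- validate_spec(spec, allow_zero_sigma = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  files <- character(0)
  if (!image) {
    n <- check_count(n, "n")
    cond <- condition %||% preset %||% "simulated"
    meas <- sample_mixture(spec, n = n, seed = seed, condition = cond)
    f <- file.path(out_dir, "measurements.csv")
    write_measurements(meas, f)
    files <- f
  } else {
    for (i in seq_len(n_images)) {
      tr <- simulate_particle_truth(particles_per_image, size = size,
                                    calibration = calibration,
                                    noise_sd = noise_sd, seed = seed + i)
      img <- make_afm_image(tr, seed = seed + 1000L + i)
      fimg <- file.path(out_dir, sprintf("image_%02d.png", i))
      write_afm_image(img, fimg)
      ftr <- file.path(out_dir, sprintf("image_%02d_truth.json", i))
      jsonlite::write_json(
        c(list(particles = as_tibble(tr)),
          attributes(tr)[c("size", "calibration", "noise_sd", "background", "shape")]),
        ftr, auto_unbox = TRUE, digits = NA)
      files <- c(files, fimg, ftr)
    }
  }
  write_run_config(out_dir, list(
    stage = "simulate", preset = preset, spec = as_tibble(spec), n = n,
    seed = seed, image = image,
    n_images = if (image) n_images else NULL,
    particles_per_image = if (image) particles_per_image else NULL,
    size = if (image) size else NULL, calibration = if (image) calibration else NULL,
    noise_sd = if (image) noise_sd else NULL))
  invisible(files)
}

#' Pipeline stage: extract particle measurements from images
#'
#' Runs [extract_particles()] on each image and concatenates the retained
#' records into `particles.csv`; excluded regions are written to
#' `excluded.csv` with their rejection reasons.
#'
#' @param images Character vector of image paths.
#' @param calibration Pixels per 200 nm (required).
#' @param out_dir Output directory.
#' @param ... Passed on to [extract_particles()].
#' @return Invisibly, the path of `particles.csv`.
#' @export
run_extract <- function(images, calibration, out_dir, ...) {
  if (missing(calibration)) vlp_abort("`calibration` is required.")
  if (length(images) < 1L) vlp_abort("At least one image is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- purrr::map(images, function(p) {
    kept <- extract_particles(p, calibration = calibration, ...)
    excl <- attr(kept, "excluded")
    kept$image <- p; if (nrow(excl)) excl$image <- p
    list(kept = kept, excluded = excl, level = attr(kept, "level"))
  })
  kept <- purrr::map_dfr(res, "kept")
  excluded <- purrr::map_dfr(res, "excluded")
  if (nrow(kept) == 0L) warn("No particles were retained from any image.")
  f <- file.path(out_dir, "particles.csv")
  utils::write.csv(kept, f, row.names = FALSE)
  utils::write.csv(excluded, file.path(out_dir, "excluded.csv"), row.names = FALSE)
  write_run_config(out_dir, list(
    stage = "extract", images = images, calibration = calibration,
    levels_chosen = purrr::map_dbl(res, "level")))
  invisible(f)
}

#' Pipeline stage: fit or select a mixture model
#'
#' Fits a fixed `k` (when given) or selects the component count over
#' `k_range`, then writes the model (`model.json`), the QQ diagnostic pairs
#' (`qq.csv`), the component confidence intervals (`intervals.csv`) and the
#' per-k selection report (`selection.json`).
#'
#' @param measurements Path to a measurement CSV, or a measurement tibble.
#' @param out_dir Output directory.
#' @param k Fixed component count (optional).
#' @param k_range Candidate counts when `k` is not given.
#' @param seed Integer seed.
#' @param gain_threshold,linearity_threshold Selection thresholds
#'   (see [select_gmm()]).
#' @param ... Passed on to [fit_gmm()].
#' @return Invisibly, the fitted `vlp_gmm` object.
#' @export
run_fit <- function(measurements, out_dir, k = NULL, k_range = 1:5, seed = 1,
                    gain_threshold = 2, linearity_threshold = 0.005, ...) {
  data <- if (is.character(measurements)) read_measurements(measurements) else measurements
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(k)) {
    sel <- select_gmm(data, k_range = k_range, gain_threshold = gain_threshold,
                      linearity_threshold = linearity_threshold, seed = seed, ...)
    fit <- sel$model
    jsonlite::write_json(
      list(k_selected = sel$k, gain_threshold = sel$gain_threshold,
           linearity_threshold = sel$linearity_threshold, seed = seed,
           report = sel$report),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  } else {
    fit <- fit_gmm(data, k = k, seed = seed, ...)
  }
  qq <- qq_diagnostic(data, fit)
  jsonlite::write_json(
    list(k = fit$k, components = fit$components, log_likelihood = fit$loglik,
         n_iterations = fit$n_iter, converged = fit$converged, n = fit$n,
         unit = fit$unit, condition = fit$condition, seed = seed,
         tolerance = fit$tol,
         qq = list(slope = qq$slope, intercept = qq$intercept,
                   r_squared = qq$r_squared)),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(qq$points, file.path(out_dir, "qq.csv"), row.names = FALSE)
  utils::write.csv(component_ci(fit), file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)
  write_run_config(out_dir, list(
    stage = "fit", k = k, k_range = k_range, seed = seed,
    gain_threshold = gain_threshold, linearity_threshold = linearity_threshold))
  invisible(fit)
}

#' Pipeline stage: compare conditions by chi-squared test
#'
#' Pools measurement sets from two or more conditions, selects (or fits) a
#' mixture per condition, hard-assigns every particle, and compares the
#' resulting count table with Pearson's chi-squared test. Writes
#' `counts.csv` and `chisq.json`.
#'
#' @param measurements Character vector of measurement CSV paths, or a single
#'   tibble with a `condition` column spanning two or more conditions.
#' @param out_dir Output directory.
#' @param k_range Candidate component counts per condition.
#' @param seed Integer seed.
#' @param ... Passed on to [select_gmm()].
#' @return Invisibly, a tibble with `statistic`, `df`, `p_value`.
#' @export
run_compare <- function(measurements, out_dir, k_range = 1:4, seed = 1, ...) {
  data <- if (is.character(measurements)) {
    purrr::map_dfr(measurements, read_measurements)
  } else {
    measurements
  }
  if (!"condition" %in% names(data)) vlp_abort("`condition` column is required.")
  conds <- unique(data$condition)
  if (length(conds) < 2L) vlp_abort("At least two conditions are required.")
  if (any(!table(data$condition) >= 2L)) vlp_abort("Every condition needs data.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  models <- lapply(setNames(conds, conds), function(cond) {
    select_gmm(data[data$condition == cond, ], k_range = k_range,
               seed = seed, ...)$model
  })
  tab <- count_table(data, models)
  res <- chi_squared_compare(tab)
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "counts.csv"))
  jsonlite::write_json(
    list(statistic = res$statistic, df = res$df, p_value = res$p_value,
         conditions = conds, k_per_condition =
           purrr::map_int(models, function(m) m$k), seed = seed),
    file.path(out_dir, "chisq.json"), auto_unbox = TRUE, digits = NA)
  write_run_config(out_dir, list(stage = "compare", k_range = k_range, seed = seed))
  invisible(res)
}
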