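# Published mixture parameters for thermally aged HPV-11 VLP collections.
# Each preset is one fitted row of the reported area/width tables: mixing
# fraction, component mean and component sigma, plus the total particle
# count behind the fit. Units: nm^2 for areas, nm for widths.
.vlp_presets <- local({
  p <- function(unit, n_total, weight, mean, sigma) {
    list(unit = unit, n_total = n_total,
         spec = tibble::tibble(weight = weight, mean = mean, sigma = sigma))
  }
  list(
    # single-pass imaging, per-particle area (nm^2)
    area_2h = p("area_nm2", 36L, c(0.15, 0.85), c(1184, 1566), c(103, 120)),
    area_3h = p("area_nm2", 33L, c(0.12, 0.60, 0.28), c(1331, 1585, 1993),
                c(27, 69, 185)),
    area_4h = p("area_nm2", 23L, c(0.41, 0.20, 0.30, 0.09),
                c(1107, 1351, 1639, 2011), c(85, 35, 71, 59)),
    area_ensemble3 = p("area_nm2", 92L, c(0.66, 0.27, 0.07),
                       c(1450, 1613, 2093), c(241, 56, 128)),
    area_ensemble4 = p("area_nm2", 92L, c(0.07, 0.59, 0.25, 0.09),
                       c(1054, 1479, 1617, 2045), c(48, 194, 54, 150)),
    # single-pass imaging, per-particle width (nm)
    width_singlepass_2h = p("width_nm", 54L, c(0.10, 0.46, 0.44),
                            c(73.6, 80.3, 81.4), c(0.83, 6.22, 3.28)),
    width_singlepass_3h = p("width_nm", 33L, 1.00, 74.1, 8.47),
    width_singlepass_4h = p("width_nm", 42L, c(0.50, 0.43, 0.07),
                            c(60.8, 71.2, 81.0), c(3.24, 3.92, 0.70)),
    width_singlepass_ensemble = p("width_nm", 129L, c(0.23, 0.77),
                                  c(61.8, 78.0), c(3.60, 6.25)),
    # double-pass imaging, per-particle width (nm)
    width_doublepass_0h = p("width_nm", 19L, c(0.62, 0.38),
                            c(98.1, 112.7), c(5.11, 2.81)),
    width_doublepass_1h = p("width_nm", 25L, c(0.62, 0.38),
                            c(98.5, 113.3), c(7.05, 8.27)),
    width_doublepass_2h = p("width_nm", 23L, c(0.33, 0.67),
                            c(109.9, 123.0), c(10.8, 8.98)),
    width_doublepass_3h = p("width_nm", 31L, 1.00, 106.2, 7.08),
    width_doublepass_ensemble = p("width_nm", 98L, c(0.23, 0.46, 0.22, 0.09),
                                  c(96.8, 106.3, 114.8, 129.6),
                                  c(5.6, 6.9, 5.5, 5.6))
  )
})

#' Published VLP mixture presets
#'
#' Component specifications (mixing fraction, mean, standard deviation) of
#' the fitted Gaussian mixture models reported for thermally aged HPV type 11
#' virus-like particles, by measurement type (particle area in nm\eqn{^2} or
#' lateral width in nm), AFM pass count, and aging time. These presets are
#' the ground truth used by [sample_mixture()] to emulate the unpublished
#' raw measurements.
#'
#' @param name Preset identifier; one of the names listed by `gmm_presets()`.
#'
#' @return `gmm_preset()` returns a tibble with columns `weight`, `mean` and
#'   `sigma` (one row per mixture component, weights summing to 1) and
#'   attributes `unit` (`"area_nm2"` or `"width_nm"`), `n_total` (number of
#'   particles behind the published fit) and `preset` (the name).
#'   `gmm_presets()` returns a tibble summarising all available presets.
#'
#' @examples
#' gmm_presets()
#' gmm_preset("area_2h")
#' @export
gmm_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.vlp_presets)) {
    vlp_abort(
      paste0("Unknown preset ", if (is.character(name)) paste0("'", name, "' "),
             "- valid presets are: ", toString(names(.vlp_presets)), "."),
      class = "lookup_error"
    )
  }
  p <- .vlp_presets[[name]]
  spec <- p$spec
  attr(spec, "unit") <- p$unit
  attr(spec, "n_total") <- p$n_total
  attr(spec, "preset") <- name
  spec
}

#' @rdname gmm_preset
#' @export
gmm_presets <- function() {
  purrr::map_dfr(names(.vlp_presets), function(nm) {
    p <- .vlp_presets[[nm]]
    tibble(
      preset = nm, unit = p$unit, n_total = p$n_total,
      k = nrow(p$spec),
      weights = paste(format(p$spec$weight, trim = TRUE), collapse = "/"),
      means = paste(format(p$spec$mean, trim = TRUE), collapse = "/")
    )
  })
}

# validate a component specification (weights/means/sigmas data frame)
validate_spec <- function(spec, allow_zero_sigma = FALSE) {
  if (!is.data.frame(spec) ||
      !all(c("weight", "mean", "sigma") %in% names(spec))) {
    vlp_abort("`spec` must be a data frame with columns weight, mean, sigma.")
  }
  spec <- as_tibble(spec[, c("weight", "mean", "sigma")])
  if (nrow(spec) < 1L) vlp_abort("`spec` must contain at least one component.")
  if (any(!is.finite(spec$weight)) || any(spec$weight <= 0) || any(spec$weight > 1)) {
    vlp_abort("Component weights must lie in (0, 1].")
  }
  if (abs(sum(spec$weight) - 1) > 1e-9) {
    vlp_abort("Component weights must sum to 1 (tolerance 1e-9).")
  }
  if (any(!is.finite(spec$mean))) vlp_abort("Component means must be finite.")
  if (any(!is.finite(spec$sigma)) ||
      any(spec$sigma < 0) ||
      (!allow_zero_sigma && any(spec$sigma <= 0))) {
    vlp_abort(if (allow_zero_sigma) "Component sigmas must be >= 0." else
      "Component sigmas must be > 0.")
  }
  spec
}
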