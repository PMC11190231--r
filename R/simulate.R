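#' Draw per-particle measurements from a Gaussian mixture
#'
#' Samples `n` scalar particle measurements from a mixture of normal
#' components, recording for every draw which component generated it. This
#' is the measurement-level simulator: with a preset from [gmm_preset()] it
#' emulates the particle area / width collections behind the published fits,
#' with known ground truth.
#'
#' @param spec Data frame of mixture components with columns `weight`,
#'   `mean`, `sigma` (e.g. from [gmm_preset()]). Weights must sum to 1.
#'   A zero `sigma` is tolerated here (and flagged) so degenerate fixtures
#'   can be built; model fitting itself rejects zero sigmas.
#' @param n Number of particles to draw.
#' @param seed Integer seed; the same `(spec, n, seed)` always yields the
#'   same sample. `NULL` uses the current RNG state.
#' @param unit Measurement unit label, `"area_nm2"` or `"width_nm"`. Defaults
#'   to the spec's `unit` attribute when present.
#' @param condition Free-text condition label (e.g. aging time) stored with
#'   every row.
#'
#' @return A tibble with one row per particle: `value`, `unit`, `condition`
#'   and `component` (1-based index of the generating component, the latent
#'   class label). The generating spec and seed are kept as attributes
#'   `spec` and `seed`.
#'
#' @examples
#' x <- sample_mixture(gmm_preset("area_2h"), n = 50, seed = 1)
#' table(x$component)
#' @export
sample_mixture <- function(spec, n, seed = NULL, unit = NULL, condition = NA_character_) {
  spec <- validate_spec(spec, allow_zero_sigma = TRUE)
  n <- check_count(n, "n")
  unit <- unit %||% attr(spec, "unit") %||% NA_character_
  if (any(spec$sigma == 0)) {
    warn("`spec` contains zero-variance components; draws from them are constant.")
  }
  k <- nrow(spec)
  out <- with_seed_if(seed, {
    z <- sample.int(k, n, replace = TRUE, prob = spec$weight)
    tibble(
      value = rnorm(n, spec$mean[z], spec$sigma[z]),
      unit = unit,
      condition = condition,
      component = z
    )
  })
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Lay out synthetic particles for an AFM-like image
#'
#' Places `n` round particles uniformly at random inside an image, rejecting
#' positions that would overlap an existing particle or clip the border, and
#' returns the ground-truth layout consumed by [make_afm_image()].
#'
#' @param n Number of particles.
#' @param size Image size in pixels, `c(rows, cols)` or a single number.
#' @param radius_px Range (length-2) or fixed value of particle half-maximum
#'   radii, in pixels. The default range corresponds to the reported VLP
#'   area scale (roughly 1000--2000 nm\eqn{^2}) at the default calibration.
#' @param calibration Pixels per 200 nm; warned about outside the reported
#'   103--125 range.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise, in 8-bit intensity units.
#' @param amplitude Peak particle intensity above background.
#' @param background Background intensity level.
#' @param min_sep Centre-separation multiplier: two particles must be at
#'   least `min_sep` times their radius sum (plus a fixed 6 px guard for the
#'   edge rings) apart.
#' @param seed Integer seed for reproducible layouts.
#'
#' @return A tibble of class `vlp_image_truth`: columns `x`, `y` (centre,
#'   pixels), `radius_px`, `amplitude`, `overlapping`; attributes
#'   `size`, `calibration`, `noise_sd`, `background` and `shape` (the dome
#'   shape exponent used when rendering).
#'
#' @examples
#' tr <- simulate_particle_truth(5, size = 256, seed = 1)
#' img <- make_afm_image(tr, seed = 1)
#' @export
simulate_particle_truth <- function(n, size = c(256L, 256L),
                                    radius_px = c(11, 15),
                                    calibration = 115,
                                    noise_sd = 6,
                                    amplitude = 160,
                                    background = 20,
                                    min_sep = 1.6,
                                    seed = NULL) {
  n <- check_count(n, "n", min = 0L)
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  check_calibration(calibration)
  if (length(radius_px) == 1L) radius_px <- rep(radius_px, 2L)
  if (any(radius_px <= 0)) vlp_abort("`radius_px` must be positive.")
  out <- with_seed_if(seed, {
    xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
    tries <- 0L
    while (length(xs) < n && tries < 5000L) {
      tries <- tries + 1L
      r <- runif(1, radius_px[1], radius_px[2])
      margin <- r + 6   # keep the dome and its edge ring off the border
      x <- runif(1, 1 + margin, size[2] - margin)
      y <- runif(1, 1 + margin, size[1] - margin)
      if (length(xs) == 0 ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep * (rs + r) + 6)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      }
    }
    if (length(xs) < n) {
      vlp_abort("Could not place all particles without overlap; reduce `n` or radii.")
    }
    tibble(x = xs, y = ys, radius_px = rs, amplitude = amplitude,
           overlapping = FALSE)
  })
  new_image_truth(out, size = size, calibration = calibration,
                  noise_sd = noise_sd, background = background)
}

#' Construct an image ground-truth object from explicit particle positions
#'
#' @param particles Data frame with columns `x`, `y`, `radius_px` and
#'   optionally `amplitude`.
#' @inheritParams simulate_particle_truth
#' @param shape Dome shape exponent of the rendered intensity profile (see
#'   [make_afm_image()]).
#' @return A `vlp_image_truth` tibble; see [simulate_particle_truth()].
#' @export
afm_image_truth <- function(particles, size = c(256L, 256L), calibration = 115,
                            noise_sd = 6, background = 20, amplitude = 160,
                            shape = 8) {
  if (!is.data.frame(particles) || !all(c("x", "y", "radius_px") %in% names(particles))) {
    vlp_abort("`particles` must have columns x, y, radius_px.")
  }
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  check_calibration(calibration)
  p <- as_tibble(particles)
  if (nrow(p) > 0 && any(p$radius_px <= 0)) vlp_abort("Particle radii must be > 0.")
  if (nrow(p) > 0 &&
      (any(p$x < 1) || any(p$x > size[2]) || any(p$y < 1) || any(p$y > size[1]))) {
    vlp_abort("Particle centres must lie inside the image bounds.")
  }
  if (!"amplitude" %in% names(p)) p$amplitude <- amplitude
  # flag overlap: centres closer than the sum of radii
  p$overlapping <- FALSE
  if (nrow(p) > 1) {
    d <- as.matrix(stats::dist(cbind(p$x, p$y)))
    rsum <- outer(p$radius_px, p$radius_px, "+")
    diag(d) <- Inf
    p$overlapping <- apply(d < rsum, 1, any)
    if (any(p$overlapping)) {
      warn("Some particles overlap; they are flagged in the returned truth.")
    }
  }
  new_image_truth(p, size = size, calibration = calibration,
                  noise_sd = noise_sd, background = background, shape = shape)
}

new_image_truth <- function(p, size, calibration, noise_sd, background, shape = 8) {
  if (noise_sd < 0) vlp_abort("`noise_sd` must be >= 0.")
  structure(
    p,
    size = size, calibration = calibration, noise_sd = noise_sd,
    background = background, shape = shape,
    class = c("vlp_image_truth", class(p))
  )
}

#' Render a synthetic AFM topograph from a particle layout
#'
#' Draws each particle as a radially symmetric flat-topped dome (a
#' generalized-Gaussian intensity profile, emulating how a compressed VLP
#' appears under an AFM tip), adds Gaussian intensity noise, and quantizes
#' to 8-bit grayscale. The profile of a particle with half-maximum radius
#' \eqn{R} and shape exponent \eqn{p} is
#' \eqn{I(r) = A \exp(-\ln 2 \, (r/R)^p)}, so the intensity falls to half
#' its peak exactly at \eqn{r = R}; the analytic reference area of the
#' particle is \eqn{\pi R^2}.
#'
#' @param truth A `vlp_image_truth` layout from [simulate_particle_truth()]
#'   or [afm_image_truth()].
#' @param size Image size in pixels; defaults to the truth's `size` attribute.
#' @param seed Integer seed controlling the noise field.
#'
#' @return An integer-valued numeric matrix in \[0, 255\] (rows = image rows).
#' @export
make_afm_image <- function(truth, size = NULL, seed = NULL) {
  if (!inherits(truth, "vlp_image_truth")) {
    vlp_abort("`truth` must be a vlp_image_truth object.")
  }
  size <- size %||% attr(truth, "size")
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 1L)) vlp_abort("`size` must be positive.")
  nr <- size[1]; nc <- size[2]
  if (nrow(truth) > 0 &&
      (any(truth$x < 1) || any(truth$x > nc) || any(truth$y < 1) || any(truth$y > nr))) {
    vlp_abort("Particles do not fit within the image bounds.")
  }
  bg <- attr(truth, "background")
  p <- attr(truth, "shape")
  img <- matrix(bg, nr, nc)
  if (nrow(truth) > 0) {
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), nc), nr, nc)
    for (i in seq_len(nrow(truth))) {
      r <- sqrt((xs - truth$x[i])^2 + (ys - truth$y[i])^2)
      img <- img + truth$amplitude[i] * exp(-log(2) * (r / truth$radius_px[i])^p)
    }
  }
  nsd <- attr(truth, "noise_sd")
  if (nsd > 0) {
    img <- img + with_seed_if(seed, matrix(rnorm(nr * nc, 0, nsd), nr, nc))
  }
  pmin(pmax(round(img), 0), 255)
}

#' Analytic reference areas and widths of a particle layout
#'
#' @param truth A `vlp_image_truth` layout.
#' @return The input tibble with reference columns appended: `area_px_true`
#'   (\eqn{\pi R^2}), `width_px_true` (\eqn{2R}), and their nanometre
#'   conversions under the layout's calibration.
#' @export
truth_measurements <- function(truth) {
  if (!inherits(truth, "vlp_image_truth")) {
    vlp_abort("`truth` must be a vlp_image_truth object.")
  }
  npp <- 200 / attr(truth, "calibration")
  dplyr::mutate(
    as_tibble(truth),
    area_px_true = pi * .data$radius_px^2,
    width_px_true = 2 * .data$radius_px,
    area_nm2_true = .data$area_px_true * npp^2,
    width_nm_true = .data$width_px_true * npp
  )
}
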