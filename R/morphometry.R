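# Image-processing chain turning an AFM topograph into per-particle area and
# width measurements: bandpass smoothing, Sobel edge magnitude, thresholding
# of the edge map, connected-component labeling with hole filling, and
# calibrated measurement. A particle is a closed edge contour: its interior
# is recovered by filling the hole of the thresholded edge ring, and the
# contour's finite thickness is split evenly between particle and
# surroundings when measuring (half the ring belongs to the particle).

#' Fourier bandpass filter
#'
#' Attenuates structures smaller than `filter_small_px` and larger than
#' `filter_large_px` with smooth Gaussian transfer functions in the
#' frequency domain (defaults 3 and 40 px, the defaults of ImageJ's
#' FFT bandpass filter). The mean intensity (DC component) is preserved, so
#' a constant image passes through unchanged; the result is clipped back to
#' the 8-bit intensity range.
#'
#' @param img Grayscale intensity matrix.
#' @param filter_small_px,filter_large_px Structure-size band, in pixels;
#'   `0 < filter_small_px < filter_large_px` required.
#' @return Filtered intensity matrix on the 0--255 scale.
#' @export
fft_bandpass <- function(img, filter_small_px = 3, filter_large_px = 40) {
  if (!is.matrix(img)) vlp_abort("`img` must be a matrix.")
  if (!is.finite(filter_small_px) || !is.finite(filter_large_px) ||
      filter_small_px <= 0 || filter_small_px >= filter_large_px) {
    vlp_abort("Need 0 < filter_small_px < filter_large_px.")
  }
  nr <- nrow(img); nc <- ncol(img)
  fy <- c(0:(nr %/% 2), -rev(seq_len(nr - nr %/% 2 - 1))) / nr
  fx <- c(0:(nc %/% 2), -rev(seq_len(nc - nc %/% 2 - 1))) / nc
  f2 <- outer(fy^2, fx^2, "+")      # squared spatial frequency (cycles/px)^2
  H <- exp(-2 * f2 * filter_small_px^2) * (1 - exp(-2 * f2 * filter_large_px^2))
  m <- mean(img)
  out <- Re(stats::fft(stats::fft(img - m) * H, inverse = TRUE)) / (nr * nc) + m
  pmin(pmax(out, 0), 255)
}

#' Sobel edge magnitude
#'
#' Per-pixel gradient magnitude \eqn{\sqrt{G_x^2 + G_y^2}} from the 3x3
#' Sobel kernels, the behaviour of ImageJ's "Find Edges"
#' routine. Borders are handled by edge replication.
#'
#' @param img Grayscale intensity matrix.
#' @return Matrix of gradient magnitudes (same size as `img`).
#' @export
find_edges <- function(img) {
  if (!is.matrix(img)) vlp_abort("`img` must be a matrix.")
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1) -
        sh(-1,  1) - 2 * sh(0,  1) - sh(1,  1)
  gy <- sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1) -
        sh( 1, -1) - 2 * sh( 1, 0) - sh( 1, 1)
  sqrt(gx^2 + gy^2)
}

#' Threshold an image into a binary mask
#'
#' @param img Grayscale or edge-magnitude matrix.
#' @param level Threshold, in intensity units inside \[0, 255\]; pixels with
#'   intensity `>= level` become foreground. Edge maps of AFM VLP images are
#'   typically thresholded between 10 and 45 units.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
apply_threshold <- function(img, level) {
  if (!is.matrix(img)) vlp_abort("`img` must be a matrix.")
  if (length(level) != 1L || !is.finite(level) || level < 0 || level > 255) {
    vlp_abort("`level` must lie in [0, 255].")
  }
  img >= level
}

# connected-component labels of a logical mask (raster-scan ordering);
# 8- or 4-connectivity, via an igraph union of pixel adjacencies
label_mask <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    ok <- r + o[1] >= 1L & r + o[1] <= nr & cc + o[2] <= nc
    nb <- idx[ok] + o[1] + o[2] * nr
    keep <- id[nb] > 0L
    from <- c(from, id[idx[ok]][keep])
    to <- c(to, id[nb][keep])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  mem <- igraph::components(g)$membership
  mem <- match(mem, unique(mem))   # deterministic raster-scan label order
  lab[idx] <- mem
  lab
}

#' Label connected particles in a binary mask
#'
#' Connected components under 8-connectivity. Holes (background regions not
#' reachable from the image border, 4-connected) are filled into their
#' enclosing region first, so a closed edge contour becomes one solid
#' particle; regions that enclosed a hole are marked `boundary_closed`.
#' Regions touching the image border are flagged so they can be excluded
#' from statistics while remaining available for audit.
#'
#' @param mask Logical matrix (e.g. from [apply_threshold()]).
#' @param fill_holes Fill enclosed background into regions first?
#' @param connectivity Foreground connectivity, 8 (default) or 4.
#' @return An object of class `vlp_labels`: list with `labels` (integer
#'   matrix, 0 = background), `holes` (logical matrix of filled pixels) and
#'   `regions`, a tibble with per-region `label`, `area_px_raw` (filled
#'   pixel count), `hole_px`, `perimeter_px`, `circularity`,
#'   `boundary_closed`, `touches_border` and bounding-box columns.
#' @export
label_particles <- function(mask, fill_holes = TRUE, connectivity = 8) {
  if (!is.matrix(mask)) vlp_abort("`mask` must be a matrix.")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) vlp_abort("`mask` must be binary.")
    mask <- mask > 0
  }
  if (!connectivity %in% c(4, 8)) vlp_abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)

  holes <- matrix(FALSE, nr, nc)
  if (fill_holes && any(!mask)) {
    bg <- label_mask(!mask, connectivity = 4)
    outside <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
    holes <- bg > 0L & !matrix(bg %in% outside, nr, nc)
  }
  filled <- mask | holes
  lab <- label_mask(filled, connectivity = connectivity)
  n <- max(lab)

  if (n == 0L) {
    regions <- tibble(label = integer(), area_px_raw = integer(),
                      hole_px = integer(), perimeter_px = integer(),
                      circularity = numeric(), boundary_closed = logical(),
                      touches_border = logical(), row_min = integer(),
                      row_max = integer(), col_min = integer(),
                      col_max = integer(), x = numeric(), y = numeric())
    return(structure(list(labels = lab, holes = holes, regions = regions),
                     class = "vlp_labels"))
  }

  # 4-neighbour boundary pixels, for a perimeter-based circularity estimate
  padl <- rbind(0L, cbind(0L, lab, 0L), 0L)
  core <- padl[2:(nr + 1), 2:(nc + 1)]
  on_boundary <- core > 0L &
    (padl[seq_len(nr), 2:(nc + 1)] != core |
     padl[3:(nr + 2), 2:(nc + 1)] != core |
     padl[2:(nr + 1), seq_len(nc)] != core |
     padl[2:(nr + 1), 3:(nc + 2)] != core)

  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(l, n)
  hole_px <- tabulate(l[holes[idx]], n)
  perim <- tabulate(l[on_boundary[idx]], n)
  row_min <- vapply(split(r, l), min, integer(1))
  row_max <- vapply(split(r, l), max, integer(1))
  col_min <- vapply(split(cc, l), min, integer(1))
  col_max <- vapply(split(cc, l), max, integer(1))

  regions <- tibble(
    label = seq_len(n),
    area_px_raw = area,
    hole_px = hole_px,
    perimeter_px = perim,
    circularity = 4 * pi * area / pmax(perim, 1)^2,
    boundary_closed = hole_px > 0L,
    touches_border = row_min == 1L | row_max == nr | col_min == 1L | col_max == nc,
    row_min = unname(row_min), row_max = unname(row_max),
    col_min = unname(col_min), col_max = unname(col_max),
    x = unname(vapply(split(cc, l), function(v) mean(v), numeric(1))),
    y = unname(vapply(split(r, l), function(v) mean(v), numeric(1)))
  )
  structure(list(labels = lab, holes = holes, regions = regions),
            class = "vlp_labels")
}

#' @export
print.vlp_labels <- function(x, ...) {
  cat(sprintf("Labeled mask: %d region%s on a %d x %d image\n",
              nrow(x$regions), if (nrow(x$regions) == 1) "" else "s",
              nrow(x$labels), ncol(x$labels)))
  print(x$regions, ...)
  invisible(x)
}

#' Measure labeled particles in calibrated units
#'
#' For every labeled region: `area_px` is the enclosed area and `width_px`
#' the widest lateral extent along the image x axis. For regions that arose
#' from a closed edge contour (`boundary_closed`), the contour's thickness
#' is split evenly between particle and background
#' (`edge_correction = TRUE`): the area is the hole plus half the ring, and
#' the width is reduced by the mean ring thickness. Raw filled pixel counts
#' are retained in `area_px_raw` / `width_px_raw`. Pixel measurements are
#' converted to nanometres with `area_nm2 = area_px * (200 / calibration)^2`
#' and `width_nm = width_px * (200 / calibration)`.
#'
#' @param labels A `vlp_labels` object from [label_particles()].
#' @param calibration Pixels per 200 nm.
#' @param edge_correction Split the closed contour's thickness evenly
#'   between particle and surroundings?
#' @return A tibble with one row per region: `label`, `area_px`, `area_nm2`,
#'   `width_px`, `width_nm`, `circularity`, `boundary_closed`,
#'   `touches_border`, plus the raw pixel columns.
#' @export
measure_particles <- function(labels, calibration, edge_correction = TRUE) {
  if (!inherits(labels, "vlp_labels")) {
    vlp_abort("`labels` must come from label_particles().")
  }
  npp <- nm_per_px(calibration)
  reg <- labels$regions
  if (nrow(reg) == 0L) {
    return(tibble(label = integer(), area_px = numeric(), area_nm2 = numeric(),
                  width_px = numeric(), width_nm = numeric(),
                  circularity = numeric(), boundary_closed = logical(),
                  touches_border = logical(), area_px_raw = integer(),
                  width_px_raw = integer(), x = numeric(), y = numeric()))
  }
  width_raw <- reg$col_max - reg$col_min + 1L
  area <- as.numeric(reg$area_px_raw)
  width <- as.numeric(width_raw)
  if (edge_correction) {
    closed <- reg$boundary_closed
    ring <- reg$area_px_raw - reg$hole_px
    area[closed] <- reg$hole_px[closed] + ring[closed] / 2
    # ring thickness from the outer/inner equivalent-disk radii
    r_out <- sqrt(reg$area_px_raw / pi)
    r_in <- sqrt(reg$hole_px / pi)
    width[closed] <- pmax(width_raw[closed] - (r_out - r_in)[closed], 1)
  }
  tibble(
    label = reg$label,
    area_px = area,
    area_nm2 = area * npp^2,
    width_px = width,
    width_nm = width * npp,
    circularity = reg$circularity,
    boundary_closed = reg$boundary_closed,
    touches_border = reg$touches_border,
    area_px_raw = reg$area_px_raw,
    width_px_raw = width_raw,
    x = reg$x,
    y = reg$y
  )
}

#' Automatic threshold selection for an edge map
#'
#' Automates the manual balancing act behind choosing an edge-map threshold
#' in the 10--45 range: for each candidate level, the edge map is thresholded, labeled and
#' filtered to plausible particles (closed contour, not touching the border,
#' area inside `area_range_px`, circularity at least `min_circularity`), and
#' the level retaining the most particles wins. Ties are broken toward the
#' lowest level, which closes the largest number of faint contours.
#'
#' @param img Edge-magnitude matrix (see [find_edges()]).
#' @param levels Candidate threshold levels.
#' @param area_range_px Plausible particle area window, in pixels (applied to
#'   the edge-corrected area).
#' @param min_circularity Minimum circularity of the filled region.
#' @return A list of class `vlp_sweep`: `level` (chosen), `counts` (tibble of
#'   `level`, `n_particles`), `mask` (the winning binary mask).
#' @export
threshold_sweep <- function(img, levels = seq(10, 45, by = 5),
                            area_range_px = c(150, 1500),
                            min_circularity = 0.5) {
  if (!is.matrix(img)) vlp_abort("`img` must be a matrix.")
  if (length(levels) < 1L) vlp_abort("`levels` must be non-empty.")
  levels <- sort(unique(levels))
  counts <- integer(length(levels))
  for (i in seq_along(levels)) {
    lp <- label_particles(apply_threshold(img, levels[i]))
    meas <- measure_particles(lp, calibration = 115)  # counts are calibration-free
    keep <- meas$boundary_closed & !meas$touches_border &
      meas$area_px >= area_range_px[1] & meas$area_px <= area_range_px[2] &
      meas$circularity >= min_circularity
    counts[i] <- sum(keep)
  }
  if (all(counts == 0L)) {
    warn("No particles found at any threshold level.")
  }
  best <- levels[which.max(counts)]   # which.max takes the first (lowest) tie
  structure(
    list(level = best,
         counts = tibble(level = levels, n_particles = counts),
         mask = apply_threshold(img, best)),
    class = "vlp_sweep"
  )
}

#' @export
print.vlp_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep: level %g chosen\n", x$level))
  print(x$counts, ...)
  invisible(x)
}

#' Extract particle measurements from an AFM image
#'
#' The full morphometry chain: grayscale conversion, Fourier bandpass
#' smoothing, Sobel edge magnitude, automatic (or fixed) thresholding of the
#' edge map, connected-component labeling with hole filling, and calibrated
#' measurement. Regions failing the particle filters (open contour, border
#' contact, implausible size or shape) are excluded from the result but
#' returned in the `excluded` attribute for audit.
#'
#' @param image Grayscale matrix, RGB array, or path to an image file.
#' @param calibration Pixels per 200 nm.
#' @param filter_small_px,filter_large_px Bandpass band (see [fft_bandpass()]).
#' @param levels Candidate threshold levels for [threshold_sweep()].
#' @param level Optional fixed threshold level overriding the sweep.
#' @param size_range_nm2 Plausible particle area window, in nm\eqn{^2}.
#' @param min_circularity Minimum circularity of the filled region.
#' @param unit,condition Labels attached to the returned measurements.
#' @return A tibble of retained particle records (see [measure_particles()]),
#'   with attributes `level` (threshold used) and `excluded` (tibble of
#'   rejected regions with a `reason` column).
#' @examples
#' tr <- simulate_particle_truth(3, size = 200, seed = 7)
#' img <- make_afm_image(tr, seed = 7)
#' nrow(extract_particles(img, calibration = 115))
#' @export
extract_particles <- function(image, calibration,
                              filter_small_px = 3, filter_large_px = 40,
                              levels = seq(10, 45, by = 5), level = NULL,
                              size_range_nm2 = c(450, 4500),
                              min_circularity = 0.5,
                              unit = "area_nm2", condition = NA_character_) {
  img <- if (is.character(image)) read_afm_image(image) else to_grayscale(image)
  npp <- nm_per_px(calibration)
  area_range_px <- size_range_nm2 / npp^2
  edges <- find_edges(fft_bandpass(img, filter_small_px, filter_large_px))
  if (is.null(level)) {
    sweep <- threshold_sweep(edges, levels = levels,
                             area_range_px = area_range_px,
                             min_circularity = min_circularity)
    level <- sweep$level
    mask <- sweep$mask
  } else {
    mask <- apply_threshold(edges, level)
  }
  meas <- measure_particles(label_particles(mask), calibration = calibration)
  reason <- dplyr::case_when(
    !meas$boundary_closed ~ "open_contour",
    meas$touches_border ~ "touches_border",
    meas$area_px < area_range_px[1] ~ "too_small",
    meas$area_px > area_range_px[2] ~ "too_large",
    meas$circularity < min_circularity ~ "low_circularity",
    TRUE ~ NA_character_
  )
  kept <- meas[is.na(reason), , drop = FALSE]
  kept$unit <- unit
  kept$condition <- condition
  excluded <- meas[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  attr(kept, "level") <- level
  attr(kept, "excluded") <- excluded
  kept
}
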