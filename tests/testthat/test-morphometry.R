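# image-processing chain: conversion, bandpass, edges, thresholding,
# labeling and calibrated measurement

test_that("grayscale conversion is idempotent and luminance-weighted", {
  g <- matrix(runif(100, 0, 255), 10, 10)
  expect_identical(to_grayscale(g), g)

  white <- array(1, dim = c(4, 4, 3))
  expect_equal(to_grayscale(white), matrix(255, 4, 4), tolerance = 1e-12)

  rgb <- array(0, dim = c(2, 2, 3))
  rgb[, , 1] <- 0.2; rgb[, , 2] <- 0.5; rgb[, , 3] <- 0.9
  lum <- (0.299 * 0.2 + 0.587 * 0.5 + 0.114 * 0.9) * 255
  expect_equal(to_grayscale(rgb), matrix(lum, 2, 2), tolerance = 1e-10)
})

test_that("image files round-trip through PNG", {
  img <- matrix(seq(0, 255, length.out = 64), 8, 8)
  path <- withr::local_tempfile(fileext = ".png")
  write_afm_image(img, path)
  back <- read_afm_image(path)
  expect_equal(back, img, tolerance = 1)  # 8-bit quantization
  expect_error(read_afm_image("no/such/file.png"), "no/such",
               class = "vlpmix_io_error")
})

test_that("the bandpass filter preserves constants and attenuates noise and ramps", {
  flat <- matrix(120, 32, 32)
  expect_equal(fft_bandpass(flat), flat, tolerance = 1e-9)

  set.seed(5)
  noise <- matrix(rnorm(256 * 256, 128, 10), 256, 256)
  filtered <- fft_bandpass(noise, 3, 40)
  expect_lt(var(as.vector(filtered)), var(as.vector(noise)))

  ramp <- matrix(rep(seq(40, 215, length.out = 256), each = 256), 256, 256)
  framp <- fft_bandpass(ramp, 3, 40)
  centre <- 33:224  # ignore wrap-around edge effects of the periodic transform
  expect_lt(diff(range(framp[centre, centre])), diff(range(ramp[centre, centre])))

  expect_error(fft_bandpass(flat, 40, 3), class = "vlpmix_validation_error")
  expect_error(fft_bandpass(flat, 3, 3), class = "vlpmix_validation_error")
})

test_that("the edge detector is the 3x3 Sobel gradient magnitude", {
  expect_true(all(find_edges(matrix(7, 16, 16)) == 0))

  # vertical step of height h: interior response is 4h on the flanking columns
  step <- function(h) cbind(matrix(0, 8, 4), matrix(h, 8, 4))
  e1 <- find_edges(step(10))
  expect_equal(max(e1), 40)
  expect_true(all(which(e1[4, ] > 0) %in% c(4, 5)))
  # magnitude proportional to step height
  expect_equal(max(find_edges(step(20))), 2 * max(e1))

  # mirroring the image mirrors the edge map
  img <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(find_edges(img[, 8:1]), find_edges(img)[, 8:1], tolerance = 1e-10)
})

test_that("thresholding validates its level and covers super-level sets", {
  img <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_true(all(apply_threshold(img, 0)))
  expect_error(apply_threshold(img, 256), class = "vlpmix_validation_error")
  expect_error(apply_threshold(img, -1), class = "vlpmix_validation_error")

  # analytic super-level set of the dome profile: I(r) = A 2^{-(r/R)^p}
  tr <- afm_image_truth(tibble::tibble(x = 41, y = 41, radius_px = 12),
                        size = 81, noise_sd = 0, background = 0, amplitude = 200)
  mask <- apply_threshold(make_afm_image(tr), 45)
  r45 <- 12 * (log(200 / 45) / log(2))^(1 / 8)
  expect_lt(abs(sum(mask) - pi * r45^2) / (pi * r45^2), 0.05)
})

test_that("labeling uses 8-connectivity and flags border contact", {
  # two disjoint disks
  m <- matrix(FALSE, 40, 40)
  xs <- matrix(rep(1:40, each = 40), 40, 40); ys <- t(xs)
  m[(xs - 10)^2 + (ys - 10)^2 <= 25] <- TRUE
  m[(xs - 30)^2 + (ys - 30)^2 <= 25] <- TRUE
  expect_identical(nrow(label_particles(m)$regions), 2L)

  # checkerboard: diagonal neighbours connect under 8- but not 4-connectivity
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  expect_identical(max(label_particles(cb, fill_holes = FALSE)$labels), 1L)
  expect_identical(max(label_particles(cb, fill_holes = FALSE,
                                       connectivity = 4)$labels), 18L)

  # a disk clipped by the border is detected but flagged
  mb <- matrix(FALSE, 30, 30)
  xs <- matrix(rep(1:30, each = 30), 30, 30); ys <- t(xs)
  mb[(xs - 2)^2 + (ys - 15)^2 <= 36] <- TRUE
  reg <- label_particles(mb)$regions
  expect_identical(nrow(reg), 1L)
  expect_true(reg$touches_border)
})

test_that("closed contours are filled and marked boundary_closed", {
  ring <- matrix(FALSE, 20, 20)
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  lp <- label_particles(ring)
  expect_identical(nrow(lp$regions), 1L)
  expect_true(lp$regions$boundary_closed)
  expect_identical(lp$regions$area_px_raw, 11L * 11L)  # outline plus interior
  expect_identical(lp$regions$hole_px, 9L * 9L)

  open_arc <- ring; open_arc[5, 8:12] <- FALSE
  lp2 <- label_particles(open_arc)
  expect_false(any(lp2$regions$boundary_closed))
})

test_that("measurements convert pixels to nanometres by the calibration law", {
  # rasterized disk of radius 10
  m <- matrix(FALSE, 41, 41)
  xs <- matrix(rep(1:41, each = 41), 41, 41); ys <- t(xs)
  m[(xs - 21)^2 + (ys - 21)^2 <= 100] <- TRUE
  rec <- measure_particles(label_particles(m), calibration = 103)
  expect_lt(abs(rec$width_px - 20) , 1.5)                       # diameter within ~1 px
  expect_lt(abs(rec$area_px - pi * 100) / (pi * 100), 0.05)
  expect_equal(rec$area_nm2, rec$area_px * (200 / 103)^2, tolerance = 1e-12)
  expect_equal(rec$width_nm, rec$width_px * (200 / 103), tolerance = 1e-12)

  # a single pixel at 125 px / 200 nm
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  rec1 <- measure_particles(label_particles(one), calibration = 125)
  expect_equal(rec1$width_nm, 1.6)
  expect_equal(rec1$area_nm2, 2.56)

  # areas scale with the square of the pixel pitch
  a103 <- measure_particles(label_particles(m), calibration = 103)$area_nm2
  a125 <- measure_particles(label_particles(m), calibration = 125)$area_nm2
  expect_equal(a103 / a125, (125 / 103)^2, tolerance = 1e-12)

  expect_identical(nrow(measure_particles(label_particles(matrix(FALSE, 4, 4)),
                                          calibration = 115)), 0L)
})

test_that("calibration is validated and warns outside the reported range", {
  expect_error(nm_per_px(0), class = "vlpmix_validation_error")
  expect_warning(nm_per_px(90), "outside")
  expect_equal(nm_per_px(115) * 115 / 200, 1, tolerance = 1e-12)  # round trip
})

test_that("the threshold sweep prefers the lowest level among ties", {
  tr <- afm_image_truth(tibble::tibble(x = 33, y = 33, radius_px = 12),
                        size = 65, noise_sd = 0, background = 20, amplitude = 170)
  edges <- find_edges(fft_bandpass(make_afm_image(tr)))
  sw <- threshold_sweep(edges, levels = seq(10, 45, by = 5),
                        area_range_px = c(100, 1500))
  expect_true(all(sw$counts$n_particles == 1L))
  expect_identical(sw$level, 10)

  expect_warning(sw0 <- threshold_sweep(matrix(0, 32, 32)), "No particles")
  expect_true(all(sw0$counts$n_particles == 0L))
})

test_that("the sweep separates blobs that merge at permissive thresholds", {
  # two blobs close enough that faint outer contours fuse at low levels
  tr <- afm_image_truth(tibble::tibble(x = c(28, 55), y = c(41, 41),
                                       radius_px = c(10, 10)),
                        size = 81, noise_sd = 0, background = 20, amplitude = 170)
  edges <- find_edges(fft_bandpass(make_afm_image(tr)))
  low <- measure_particles(label_particles(apply_threshold(edges, 2)),
                           calibration = 115)
  expect_lt(sum(low$boundary_closed & low$area_px <= 600), 2L)  # merged or bridged
  sw <- threshold_sweep(edges, levels = seq(5, 45, by = 5),
                        area_range_px = c(100, 600))
  kept <- measure_particles(label_particles(sw$mask), calibration = 115)
  kept <- kept[kept$boundary_closed & !kept$touches_border &
                 kept$area_px <= 600, ]
  expect_identical(nrow(kept), 2L)
})

test_that("the full chain is invariant to particle translation", {
  base <- tibble::tibble(x = c(60, 140), y = c(70, 150), radius_px = c(12, 13))
  shifted <- dplyr::mutate(base, x = x + 9, y = y - 7)
  rec <- function(p) {
    tr <- afm_image_truth(p, size = 220, noise_sd = 0, background = 20,
                          amplitude = 170)
    out <- extract_particles(make_afm_image(tr), calibration = 115)
    out[order(out$area_px), c("area_px", "width_px")]
  }
  a <- rec(base); b <- rec(shifted)
  expect_equal(a$area_px, b$area_px, tolerance = 0.02)
  expect_equal(a$width_px, b$width_px, tolerance = 0.05)
})

test_that("extract_particles recovers counts and logs exclusions", {
  tr <- simulate_particle_truth(4, size = 220, seed = 51)
  img <- make_afm_image(tr, seed = 51)
  rec <- extract_particles(img, calibration = 115)
  expect_identical(nrow(rec), 4L)
  expect_true(all(rec$width_px >= rec$area_px / nrow(img)))  # trivial geometry bound
  excl <- attr(rec, "excluded")
  expect_true(is.data.frame(excl))
  expect_true(all(excl$reason %in% c("open_contour", "touches_border",
                                     "too_small", "too_large", "low_circularity")))
})
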