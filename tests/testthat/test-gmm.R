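# the EM core: densities, likelihood, E/M steps, and full fits

test_that("gaussian_pdf matches the closed form", {
  expect_equal(gaussian_pdf(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-7)
  # peak value is 1/(sigma sqrt(2 pi)) for any mean
  for (s in c(0.5, 3, 120)) {
    expect_equal(gaussian_pdf(17, 17, s), 1 / (s * sqrt(2 * pi)), tolerance = 1e-12)
  }
  expect_error(gaussian_pdf(0, 0, 0), class = "vlpmix_validation_error")
  expect_error(gaussian_pdf(0, 0, -2), class = "vlpmix_validation_error")
})

test_that("densities integrate to one (quadrature oracle)", {
  q1 <- integrate(function(x) gaussian_pdf(x, 2, 3), 2 - 24, 2 + 24)
  expect_lt(abs(q1$value - 1), 1e-6)
  m <- tibble::tibble(weight = c(0.3, 0.7), mean = c(0, 50), sigma = c(1, 10))
  q2 <- integrate(function(x) mixture_pdf(x, m), -60, 160)
  expect_lt(abs(q2$value - 1), 1e-6)
})

test_that("mixture_pdf reduces to gaussian_pdf at K = 1 and obeys symmetry", {
  m1 <- tibble::tibble(weight = 1, mean = 3, sigma = 2)
  xs <- seq(-5, 11, by = 0.5)
  expect_equal(mixture_pdf(xs, m1), gaussian_pdf(xs, 3, 2), tolerance = 1e-12)
  # equal-weight symmetric pair evaluated at the midpoint
  d <- 6
  m2 <- tibble::tibble(weight = c(0.5, 0.5), mean = c(-d / 2, d / 2), sigma = c(1.5, 1.5))
  expect_equal(mixture_pdf(0, m2), gaussian_pdf(d / 2, 0, 1.5), tolerance = 1e-12)
  bad <- tibble::tibble(weight = c(0.6, 0.6), mean = c(0, 1), sigma = c(1, 1))
  expect_error(mixture_pdf(0, bad), class = "vlpmix_validation_error")
})

test_that("log-likelihood matches a term-by-term hand computation", {
  m1 <- tibble::tibble(weight = 1, mean = 5, sigma = 1)
  expect_equal(mixture_loglik(5, m1), log(1 / sqrt(2 * pi)), tolerance = 1e-12)

  x <- c(1.2, -0.7, 3.5, 4.1, 0.0)
  m <- tibble::tibble(weight = c(0.3, 0.7), mean = c(0, 3), sigma = c(1, 2))
  # spreadsheet-style oracle: explicit exponentials, no shared code
  by_hand <- sum(log(
    0.3 * exp(-(x - 0)^2 / 2) / sqrt(2 * pi) +
    0.7 * exp(-(x - 3)^2 / (2 * 4)) / (2 * sqrt(2 * pi))
  ))
  expect_equal(mixture_loglik(x, m), by_hand, tolerance = 1e-10)
  # additivity over observations
  expect_equal(mixture_loglik(c(x, x), m), 2 * mixture_loglik(x, m), tolerance = 1e-10)
})

test_that("log-space evaluation survives extreme observations", {
  m <- tibble::tibble(weight = c(0.5, 0.5), mean = c(0, 10), sigma = c(1, 1))
  ll <- mixture_loglik(1e4, m)   # density underflows to 0 in linear space
  expect_true(is.finite(ll))
  g <- e_step(1e4, m)
  expect_equal(rowSums(g), 1, tolerance = 1e-12)
})

test_that("e_step produces the closed-form responsibilities", {
  m1 <- tibble::tibble(weight = 1, mean = 2, sigma = 1)
  expect_equal(as.vector(e_step(c(1, 2, 3), m1)), c(1, 1, 1))

  m2 <- tibble::tibble(weight = c(0.5, 0.5), mean = c(-1, 1), sigma = c(2, 2))
  expect_equal(as.vector(e_step(0, m2)), c(0.5, 0.5), tolerance = 1e-12)

  m3 <- tibble::tibble(weight = c(0.5, 0.5), mean = c(0, 10), sigma = c(1, 1))
  g <- e_step(0, m3)
  expect_equal(g[1, 1], 1 / (1 + exp(-50)), tolerance = 1e-12)

  # rows always sum to one
  x <- rnorm(50, 5, 4)
  expect_equal(rowSums(e_step(x, m3)), rep(1, 50), tolerance = 1e-12)
})

test_that("m_step reduces to weighted moments and renormalizes exactly", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  # all mass on one component: sample mean and biased variance
  p1 <- m_step(x, matrix(1, length(x), 1))
  expect_equal(p1$mean, mean(x))
  expect_equal(p1$sigma^2, mean((x - mean(x))^2))
  expect_equal(p1$weight, 1)

  # 0/1 partition: per-group moments and group-size weights
  gamma <- cbind(as.numeric(x < 5), as.numeric(x >= 5))
  p2 <- m_step(x, gamma)
  lo <- x[x < 5]; hi <- x[x >= 5]
  expect_equal(p2$mean, c(mean(lo), mean(hi)))
  expect_equal(p2$sigma^2, c(mean((lo - mean(lo))^2), mean((hi - mean(hi))^2)))
  expect_equal(p2$weight, c(length(lo), length(hi)) / length(x))
  expect_identical(sum(p2$weight), 1)

  # an empty column is a component collapse
  expect_error(m_step(x, cbind(1, 0 * x)), class = "vlpmix_collapse_error")
})

test_that("quantile initialization places means at midpoint quantiles", {
  x <- c(1, 2, 3, 4)
  init <- gmm_init(x, 2)
  expect_equal(init$mean, quantile(x, c(0.25, 0.75), names = FALSE))
  expect_equal(init$weight, c(0.5, 0.5))
  expect_equal(init$sigma, rep(sd(x), 2))
  expect_equal(gmm_init(x, 1)$mean, median(x))
  r1 <- gmm_init(x, 2, strategy = "random", seed = 4)
  r2 <- gmm_init(x, 2, strategy = "random", seed = 4)
  expect_identical(r1, r2)
  expect_error(gmm_init(c(1, 2), 3), class = "vlpmix_validation_error")
})

test_that("a one-component fit is the closed-form Gaussian MLE", {
  x <- sample_mixture(gmm_preset("width_singlepass_3h"), 200, seed = 3)$value
  fit <- fit_gmm(x, 1, seed = 1)
  expect_equal(fit$components$mean, mean(x), tolerance = 1e-9)
  expect_equal(fit$components$sigma, sqrt(mean((x - mean(x))^2)), tolerance = 1e-9)
  expect_equal(fit$components$weight, 1)
  expect_true(fit$converged)
})

test_that("EM recovers well-separated generating parameters", {
  d <- sample_mixture(well_separated_spec(), 5000, seed = 21)
  fit <- fit_gmm(d$value, 2, seed = 21)
  expect_true(all(abs(fit$components$mean - c(0, 10)) <= 0.1))
  expect_true(all(abs(fit$components$sigma - 1) <= 0.1))
  # with a 10-sigma separation the weight estimate must match the realized
  # label fractions almost exactly; sampling noise of the labels is separate
  frac <- tabulate(d$component, 2) / nrow(d)
  expect_true(all(abs(fit$components$weight - frac) <= 0.005))
  expect_true(all(abs(fit$components$weight - c(0.4, 0.6)) <= 3.5 * sqrt(0.4 * 0.6 / 5000)))
})

test_that("fits are deterministic, mean-sorted and initialization-order free", {
  x <- sample_mixture(well_separated_spec(), 400, seed = 5)$value
  f1 <- fit_gmm(x, 2, seed = 9)
  f2 <- fit_gmm(x, 2, seed = 9)
  expect_identical(f1$components, f2$components)
  expect_false(is.unsorted(f1$components$mean))
  # a different initialization route lands on the same mean-sorted model
  f3 <- fit_gmm(x, 2, init = "random", seed = 2)
  expect_equal(f1$components, f3$components, tolerance = 1e-4)
})

test_that("the log-likelihood trace is non-decreasing for every fit", {
  specs <- list(gmm_preset("width_singlepass_3h"), gmm_preset("area_2h"),
                gmm_preset("area_3h"), gmm_preset("area_ensemble4"))
  for (seed in 1:8) {
    k <- (seed - 1) %% 4 + 1
    x <- sample_mixture(specs[[k]], 250, seed = seed)
    fit <- fit_gmm(x, k, seed = seed)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("EM matches or beats a brute-force grid search on tiny data", {
  set.seed(31)
  x <- c(rnorm(3, 0, 0.5), rnorm(3, 6, 0.8))
  fit <- fit_gmm(x, 2, seed = 31)
  expect_gte(fit$loglik, grid_search_loglik(x) - 1e-6)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  # overlapping components: our restarted EM must reach at least the
  # likelihood of the reference fitter
  x <- sample_mixture(gmm_preset("area_2h"), 500, seed = 13)$value
  fit <- fit_gmm(x, 2, seed = 13)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_gte(fit$loglik, mc$loglik - 1e-3)

  # well-separated components: both fitters land on the same optimum
  y <- sample_mixture(well_separated_spec(), 500, seed = 14)$value
  fy <- fit_gmm(y, 2, seed = 14)
  my <- mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fy$loglik, my$loglik, tolerance = 1e-6)
  expect_equal(sort(fy$components$mean), sort(as.vector(my$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(sort(fy$components$weight), sort(as.vector(my$parameters$pro)),
               tolerance = 1e-3)
})

test_that("degenerate fitting requests are rejected", {
  expect_error(fit_gmm(c(1, 2), 3, seed = 1), class = "vlpmix_validation_error")
  expect_error(fit_gmm(rep(4, 10), 1, seed = 1), class = "vlpmix_validation_error")
  expect_error(fit_gmm(tibble::tibble(value = c(1, 2), unit = c("area_nm2", "width_nm")), 1),
               class = "vlpmix_validation_error")
})
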