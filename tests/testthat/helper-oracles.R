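# Independent oracles used to freeze expected values; these deliberately do
# not share code paths with the package implementation.

# brute-force log-likelihood maximization for a 2-component mixture on a tiny
# dataset: component means on data quantiles, sigmas and weights on grids
grid_search_loglik <- function(x) {
  mu_grid <- unique(quantile(x, seq(0.05, 0.95, by = 0.1), names = FALSE))
  rng <- diff(range(x))
  sigma_grid <- rng * c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1)
  w_grid <- seq(0.1, 0.9, by = 0.1)
  ll <- function(w, m1, m2, s1, s2) {
    sum(log(w * exp(-(x - m1)^2 / (2 * s1^2)) / (s1 * sqrt(2 * pi)) +
            (1 - w) * exp(-(x - m2)^2 / (2 * s2^2)) / (s2 * sqrt(2 * pi))))
  }
  best <- -Inf
  for (m1 in mu_grid) for (m2 in mu_grid) {
    if (m2 < m1) next
    for (s1 in sigma_grid) for (s2 in sigma_grid) for (w in w_grid) {
      v <- ll(w, m1, m2, s1, s2)
      if (v > best) best <- v
    }
  }
  best
}

# a small two-component fixture with clearly separated modes
well_separated_spec <- function() {
  tibble::tibble(weight = c(0.4, 0.6), mean = c(0, 10), sigma = c(1, 1))
}
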