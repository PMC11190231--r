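# Univariate Gaussian mixture fitting by Expectation-Maximization.
#
# The mixture density is p(x) = sum_k w_k G(x | mu_k, sigma_k) with
# sum_k w_k = 1; a K-component model has 3K - 1 free parameters. Fitting
# maximizes the log-likelihood l(theta) = sum_i log sum_k w_k G(x_i | ...)
# by alternating posterior-membership estimation (E-step) with closed-form
# parameter updates (M-step). All density arithmetic is done in log space
# with log-sum-exp normalization so that nm^2-scale measurements cannot
# underflow.

#' Gaussian probability density
#'
#' Density of a single normal component,
#' \eqn{G(x \mid \mu, \sigma) = \frac{1}{\sigma\sqrt{2\pi}}
#' e^{-(x-\mu)^2 / 2\sigma^2}}.
#'
#' @param x Numeric vector of evaluation points.
#' @param mean,sigma Component mean and standard deviation (`sigma > 0`).
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @examples
#' gaussian_pdf(0, 0, 1)  # 1 / sqrt(2 * pi)
#' @export
gaussian_pdf <- function(x, mean, sigma, log = FALSE) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    vlp_abort("`sigma` must be > 0.")
  }
  dnorm(x, mean, sigma, log = log)
}

# normalize a mixture model argument into a weight/mean/sigma tibble
as_mixture <- function(model) {
  if (inherits(model, "vlp_gmm")) model <- model$components
  validate_spec(model)
}

# N x K matrix of log(w_k) + log G(x_i | mu_k, sigma_k)
log_component_matrix <- function(x, m) {
  vapply(
    seq_len(nrow(m)),
    function(k) log(m$weight[k]) + dnorm(x, m$mean[k], m$sigma[k], log = TRUE),
    numeric(length(x))
  )
}

#' Mixture probability density
#'
#' Weighted sum of Gaussian component densities,
#' \eqn{p(x) = \sum_k w_k G(x \mid \mu_k, \sigma_k)}.
#'
#' @param x Numeric vector of evaluation points.
#' @param model A fitted [fit_gmm()] object or a data frame with columns
#'   `weight`, `mean`, `sigma` (weights summing to 1).
#' @return Numeric vector of densities.
#' @export
mixture_pdf <- function(x, model) {
  m <- as_mixture(model)
  ld <- log_component_matrix(x, m)
  dim(ld) <- c(length(x), nrow(m))
  exp(row_logsumexp(ld))
}

#' Mixture log-likelihood
#'
#' \eqn{\ell(\theta) = \sum_i \log \sum_k w_k G(x_i \mid \mu_k, \sigma_k)},
#' computed with an underflow-safe log-sum-exp.
#'
#' @param data Measurement data frame (column `value`) or numeric vector.
#' @param model Mixture model (see [mixture_pdf()]).
#' @return A single number; additive over observations.
#' @export
mixture_loglik <- function(data, model) {
  x <- measurement_values(data)
  m <- as_mixture(model)
  ld <- log_component_matrix(x, m)
  dim(ld) <- c(length(x), nrow(m))
  sum(row_logsumexp(ld))
}

#' E-step: posterior component responsibilities
#'
#' For each observation, the posterior probability that it was generated by
#' each mixture component:
#' \eqn{\gamma_{ik} = w_k G(x_i \mid \mu_k, \sigma_k) /
#' \sum_j w_j G(x_i \mid \mu_j, \sigma_j)}. Rows sum to 1; normalization is
#' done in log space so extreme observations never divide by zero.
#'
#' @inheritParams mixture_loglik
#' @return An N x K numeric matrix of responsibilities.
#' @export
e_step <- function(data, model) {
  x <- measurement_values(data)
  m <- as_mixture(model)
  ld <- log_component_matrix(x, m)
  dim(ld) <- c(length(x), nrow(m))
  exp(ld - row_logsumexp(ld))
}

#' M-step: maximum-likelihood parameter updates
#'
#' Given responsibilities, computes the weighted-moment updates
#' \eqn{\hat\mu_k = \sum_i \gamma_{ik} x_i / \sum_i \gamma_{ik}},
#' \eqn{\hat\sigma_k^2 = \sum_i \gamma_{ik} (x_i - \hat\mu_k)^2 /
#' \sum_i \gamma_{ik}} (using the freshly updated mean), and
#' \eqn{\hat w_k = \sum_i \gamma_{ik} / N}. The returned weights sum to 1
#' exactly by construction.
#'
#' @inheritParams mixture_loglik
#' @param gamma N x K responsibility matrix with rows summing to 1.
#' @return A tibble with columns `weight`, `mean`, `sigma` (one row per
#'   component, in the column order of `gamma`).
#' @export
m_step <- function(data, gamma) {
  x <- measurement_values(data)
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != length(x)) {
    vlp_abort("`gamma` must have one row per observation.")
  }
  if (any(abs(rowSums(gamma) - 1) > 1e-6)) {
    vlp_abort("Responsibility rows must sum to 1.")
  }
  nk <- colSums(gamma)
  if (any(nk < 1e-12)) {
    vlp_abort(
      sprintf("Component %s collapsed (no responsibility mass).",
              toString(which(nk < 1e-12))),
      class = "collapse_error"
    )
  }
  mu <- colSums(gamma * x) / nk
  sigma2 <- vapply(seq_along(nk),
                   function(k) sum(gamma[, k] * (x - mu[k])^2) / nk[k],
                   numeric(1))
  w <- nk / length(x)
  w <- w / sum(w)  # exact unit sum despite floating error
  tibble(weight = w, mean = mu, sigma = sqrt(sigma2))
}

#' Starting values for the EM algorithm
#'
#' The `"quantile"` strategy places component means at the
#' \eqn{(j - 0.5)/K} data quantiles, all sigmas at the pooled standard
#' deviation, and uniform weights. The `"random"` strategy perturbs the
#' quantile means with Gaussian noise of half the pooled sd.
#'
#' @inheritParams mixture_loglik
#' @param k Number of components (`N >= k` required).
#' @param strategy `"quantile"` or `"random"`.
#' @param seed Integer seed (used by `"random"` only).
#' @return A tibble with columns `weight`, `mean`, `sigma`.
#' @export
gmm_init <- function(data, k, strategy = c("quantile", "random"), seed = NULL) {
  x <- measurement_values(data)
  k <- check_count(k, "k")
  strategy <- match.arg(strategy)
  if (length(x) < k) vlp_abort("Need at least as many observations as components.")
  mu <- quantile(x, (seq_len(k) - 0.5) / k, names = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- max(abs(x), 1)  # degenerate spread
  if (strategy == "random") {
    mu <- with_seed_if(seed, sort(mu + rnorm(k, 0, s / 2)))
  }
  tibble(weight = rep(1 / k, k), mean = mu, sigma = rep(s, k))
}

# one full EM run from a given start; returns NULL on component collapse
run_em <- function(x, start, max_iter, tol, sigma_floor) {
  k <- nrow(start)
  w <- start$weight; mu <- start$mean; s <- pmax(start$sigma, sigma_floor)
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  ld <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) ld[, j] <- log(w[j]) + dnorm(x, mu[j], s[j], log = TRUE)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    gamma <- exp(ld - lse)
    nk <- colSums(gamma)
    if (any(nk < 1e-12)) return(NULL)
    mu <- colSums(gamma * x) / nk
    for (j in seq_len(k)) s[j] <- sqrt(sum(gamma[, j] * (x - mu[j])^2) / nk[j])
    s <- pmax(s, sigma_floor)
    w <- nk / n
  }
  list(weight = w, mean = mu, sigma = s, loglik = trace[length(trace)],
       trace = trace, n_iter = it, converged = converged)
}

#' Fit a univariate Gaussian mixture by Expectation-Maximization
#'
#' Alternates [e_step()] and [m_step()] from a [gmm_init()] start until the
#' log-likelihood of successive iterations agrees within `tol` (the
#' "6 decimal places" reading gives the default `1e-6`) or `max_iter`
#' iterations (default cap 1000) are reached. To avoid poor local optima,
#' `restarts` additional randomly perturbed starts are run for a short burn-in
#' and the most promising start is then run to full convergence. Component
#' sigmas are floored at `1e-6` times the data range, preventing the
#' degenerate likelihood singularity of mixtures. Components are reported
#' sorted by ascending mean, so fits are invariant to initialization order.
#'
#' @param data Measurement data frame (column `value`, optional `unit` and
#'   `condition`) or numeric vector. `length(data) >= k` required.
#' @param k Number of mixture components.
#' @param init Initialization strategy passed to [gmm_init()] for the first
#'   start; the remaining `restarts` starts are always random perturbations.
#' @param restarts Number of additional random starts (default 10).
#' @param seed Integer seed making the whole fit deterministic.
#' @param max_iter Iteration cap per start.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param burn_iter Burn-in iterations used to rank candidate starts.
#' @param keep_data Store the data inside the fit (needed by [qq_diagnostic()]
#'   and [autoplot()] defaults)?
#'
#' @return An object of class `vlp_gmm`: a list with `components` (tibble of
#'   `weight`, `mean`, `sigma`, mean-sorted), `k`, `n`, `loglik`, `n_iter`,
#'   `converged`, `trace` (log-likelihood per iteration of the winning run),
#'   `unit`, `condition`, `seed`, `tol` and (optionally) `data`. Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#'
#' @examples
#' x <- sample_mixture(gmm_preset("area_2h"), 200, seed = 1)
#' fit <- fit_gmm(x, k = 2, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
fit_gmm <- function(data, k, init = c("quantile", "random"), restarts = 10,
                    seed = NULL, max_iter = 1000, tol = 1e-6,
                    burn_iter = 50, keep_data = TRUE) {
  x <- measurement_values(data)
  k <- check_count(k, "k")
  init <- match.arg(init)
  max_iter <- check_count(max_iter, "max_iter")
  restarts <- check_count(restarts, "restarts", min = 0L)
  if (length(x) < k) {
    vlp_abort("Need at least as many observations as mixture components.")
  }
  rng <- diff(range(x))
  if (rng == 0) vlp_abort("Measurements are constant; a mixture cannot be fit.")
  sigma_floor <- 1e-6 * rng

  fit <- with_seed_if(seed, {
    starts <- c(
      list(gmm_init(x, k, strategy = init)),
      lapply(seq_len(restarts), function(i) gmm_init(x, k, strategy = "random"))
    )
    burns <- lapply(starts, function(st) {
      run_em(x, st, max_iter = min(burn_iter, max_iter), tol = tol,
             sigma_floor = sigma_floor)
    })
    lls <- vapply(burns, function(b) if (is.null(b)) -Inf else b$loglik, numeric(1))
    if (all(!is.finite(lls))) {
      vlp_abort(
        sprintf("All %d EM starts collapsed a component; cannot fit k = %d.",
                length(starts), k),
        class = "collapse_error"
      )
    }
    best <- burns[[which.max(lls)]]
    run_em(x, tibble(weight = best$weight, mean = best$mean, sigma = best$sigma),
           max_iter = max_iter, tol = tol, sigma_floor = sigma_floor)
  })
  if (is.null(fit)) {
    vlp_abort("EM collapsed a component during the final run.",
              class = "collapse_error")
  }

  o <- order(fit$mean)
  structure(
    list(
      components = tibble(weight = fit$weight[o], mean = fit$mean[o],
                          sigma = fit$sigma[o]),
      k = k,
      n = length(x),
      loglik = fit$loglik,
      n_iter = fit$n_iter,
      converged = fit$converged,
      trace = fit$trace,
      unit = measurement_unit(data),
      condition = measurement_condition(data),
      seed = seed,
      tol = tol,
      data = if (keep_data) x else NULL
    ),
    class = "vlp_gmm"
  )
}

#' @export
print.vlp_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture model: %d component%s, n = %d%s\n",
              x$k, if (x$k > 1) "s" else "", x$n,
              if (!is.na(x$unit)) paste0(" (", x$unit, ")") else ""))
  cat(sprintf("log-likelihood %.4f after %d iteration%s (%s)\n",
              x$loglik, x$n_iter, if (x$n_iter > 1) "s" else "",
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$components, ...)
  invisible(x)
}
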