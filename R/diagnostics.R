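# Model assessment and inference: mixture quantile-quantile diagnostics,
# sequential choice of the number of components, Student-t confidence
# intervals for component means, hard assignment and chi-squared comparison
# of modeled populations.

#' Mixture cumulative distribution function
#'
#' \eqn{F(x) = \sum_k w_k \Phi((x - \mu_k)/\sigma_k)}; monotone
#' non-decreasing with limits 0 and 1.
#'
#' @inheritParams mixture_pdf
#' @return Numeric vector of probabilities.
#' @export
mixture_cdf <- function(x, model) {
  m <- as_mixture(model)
  v <- vapply(seq_len(nrow(m)),
              function(k) m$weight[k] * pnorm(x, m$mean[k], m$sigma[k]),
              numeric(length(x)))
  dim(v) <- c(length(x), nrow(m))
  rowSums(v)
}

#' Mixture quantile function
#'
#' Inverse of [mixture_cdf()], computed by bracketed bisection: the bracket
#' starts at the component means plus/minus 10 sigmas, expands until it
#' encloses the root, and is halved until its width falls below
#' \eqn{10^{-9}} times the model scale.
#'
#' @param p Probabilities, all strictly inside (0, 1).
#' @inheritParams mixture_pdf
#' @return Numeric vector of quantiles, same length as `p`.
#' @export
mixture_quantile <- function(p, model) {
  m <- as_mixture(model)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    vlp_abort("`p` must lie strictly inside (0, 1).")
  }
  lo <- rep(min(m$mean - 10 * m$sigma), length(p))
  hi <- rep(max(m$mean + 10 * m$sigma), length(p))
  scale <- max(abs(lo[1]), abs(hi[1]), 1)
  span <- hi - lo
  # expand the bracket until it encloses every requested probability
  while (any(bad <- mixture_cdf(lo, m) > p)) {
    lo[bad] <- lo[bad] - span[bad]; span[bad] <- 2 * span[bad]
  }
  while (any(bad <- mixture_cdf(hi, m) < p)) {
    hi[bad] <- hi[bad] + span[bad]; span[bad] <- 2 * span[bad]
  }
  while (max(hi - lo) > 1e-9 * scale) {
    mid <- (lo + hi) / 2
    below <- mixture_cdf(mid, m) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Mixture quantile-quantile diagnostic
#'
#' Orders the observed measurements, pairs the i-th order statistic with the
#' model quantile at the midpoint plotting position \eqn{(i - 0.5)/N}, and
#' regresses observed on theoretical quantiles by least squares. For a
#' correctly specified model the points concentrate on the identity line
#' (slope 1, intercept 0), so the regression's coefficient of determination
#' measures the linearity of the plot and hence the goodness of fit.
#'
#' @inheritParams mixture_loglik
#' @return An object of class `vlp_qq`: list with `points` (tibble `p`,
#'   `theoretical`, `observed`), `slope`, `intercept`, `r_squared` and `n`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' x <- sample_mixture(gmm_preset("area_2h"), 100, seed = 1)
#' fit <- fit_gmm(x, 2, seed = 1)
#' glance(qq_diagnostic(x, fit))
#' @export
qq_diagnostic <- function(data, model) {
  x <- measurement_values(data)
  if (length(x) < 3L) vlp_abort("At least 3 observations are required.")
  if (diff(range(x)) == 0) {
    vlp_abort("Measurements are constant; the QQ regression is undefined.")
  }
  m <- as_mixture(model)
  n <- length(x)
  pp <- (seq_len(n) - 0.5) / n
  obs <- sort(x)
  theo <- mixture_quantile(pp, m)
  fit <- lm(obs ~ theo)
  structure(
    list(
      points = tibble(p = pp, theoretical = theo, observed = obs),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      # R^2 of a simple regression is the squared correlation; avoids the
      # "essentially perfect fit" warning of summary.lm on exact data
      r_squared = stats::cor(obs, theo)^2,
      n = n
    ),
    class = "vlp_qq"
  )
}

#' @export
print.vlp_qq <- function(x, ...) {
  cat(sprintf(
    "Mixture QQ diagnostic: n = %d, slope %.4f, intercept %.4f, R^2 %.5f\n",
    x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Select the number of mixture components
#'
#' Fits every `k` in `k_range` in ascending order and walks the sequence,
#' accepting a larger model only while it still pays for itself: `k + 1` is
#' accepted over the last accepted `k` when the log-likelihood gain is at
#' least `gain_threshold` per added component *and* the QQ coefficient of
#' determination improves by at least `linearity_threshold` per added
#' component. The walk stops at the first rejected step; the last accepted
#' fit is returned together with a per-`k` report. `force_k` overrides the
#' automatic choice (recorded in the report), mirroring a judgment call in
#' favour of a visually better fit.
#'
#' @inheritParams fit_gmm
#' @param k_range Candidate component counts, e.g. `1:5`.
#' @param gain_threshold Minimum log-likelihood improvement per added
#'   component.
#' @param linearity_threshold Minimum QQ \eqn{R^2} improvement per added
#'   component.
#' @param force_k Optional component count that overrides the selection.
#' @param ... Passed on to [fit_gmm()].
#'
#' @return An object of class `vlp_gmm_selection`: list with `model` (the
#'   selected `vlp_gmm`), `k` (selected count), `report` (tibble with one
#'   row per candidate: `k`, `loglik`, `qq_r_squared`, `loglik_gain`,
#'   `r_squared_gain`, `accepted`, `forced`), `gain_threshold`,
#'   `linearity_threshold` and `seed`. Supports [tidy()] and [autoplot()].
#' @examples
#' x <- sample_mixture(gmm_preset("area_2h"), 300, seed = 2)
#' sel <- select_gmm(x, k_range = 1:3, seed = 2)
#' sel$k
#' @export
select_gmm <- function(data, k_range = 1:5, gain_threshold = 2,
                       linearity_threshold = 0.005, seed = NULL,
                       force_k = NULL, ...) {
  x <- measurement_values(data)
  k_range <- sort(unique(vapply(k_range, check_count, integer(1), name = "k_range")))
  if (max(k_range) > length(x) / 2) {
    vlp_abort("`k_range` must not exceed half the number of observations.")
  }
  if (!is.null(force_k)) {
    force_k <- check_count(force_k, "force_k")
    if (!force_k %in% k_range) vlp_abort("`force_k` must be one of `k_range`.")
  }

  fits <- vector("list", length(k_range))
  r2 <- ll <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- tryCatch(
      fit_gmm(data, k_range[i], seed = seed, ...),
      vlpmix_collapse_error = function(e) NULL
    )
    if (!is.null(fits[[i]])) {
      ll[i] <- fits[[i]]$loglik
      r2[i] <- qq_diagnostic(x, fits[[i]])$r_squared
    }
  }
  if (all(vapply(fits, is.null, logical(1)))) {
    vlp_abort("No candidate model could be fit.", class = "collapse_error")
  }

  accepted <- rep(FALSE, length(k_range))
  cur <- which(!vapply(fits, is.null, logical(1)))[1]
  accepted[cur] <- TRUE
  i <- cur + 1L
  while (i <= length(k_range)) {
    if (is.null(fits[[i]])) break
    dk <- k_range[i] - k_range[cur]
    if (ll[i] - ll[cur] >= gain_threshold * dk &&
        r2[i] - r2[cur] >= linearity_threshold * dk) {
      accepted[i] <- TRUE
      cur <- i
      i <- i + 1L
    } else {
      break
    }
  }
  chosen <- if (is.null(force_k)) cur else match(force_k, k_range)
  if (is.null(fits[[chosen]])) {
    vlp_abort("The forced model could not be fit.", class = "collapse_error")
  }

  report <- tibble(
    k = k_range,
    loglik = ll,
    qq_r_squared = r2,
    loglik_gain = c(NA_real_, diff(ll)),
    r_squared_gain = c(NA_real_, diff(r2)),
    accepted = accepted,
    forced = !is.null(force_k) & k_range == (force_k %||% -1L)
  )
  structure(
    list(model = fits[[chosen]], k = k_range[chosen], report = report,
         gain_threshold = gain_threshold,
         linearity_threshold = linearity_threshold, seed = seed),
    class = "vlp_gmm_selection"
  )
}

#' @export
print.vlp_gmm_selection <- function(x, ...) {
  cat(sprintf("Mixture model selection: k = %d chosen%s\n", x$k,
              if (any(x$report$forced)) " (forced)" else ""))
  print(x$report, ...)
  invisible(x)
}

# round-half-up, the convention reproducing the published per-component n
round_half_up <- function(x) floor(x + 0.5)

#' Confidence intervals for component means
#'
#' The half-width of the interval for each component mean is
#' \eqn{\pm t \sigma_k / \sqrt{n}}, where \eqn{t} is the two-sided Student t
#' quantile for \eqn{n - 1} degrees of freedom and \eqn{n} is the effective
#' per-component count, estimated as the total number of observations
#' divided by the number of components (rounded half up).
#'
#' @param model Mixture model (fit or `weight`/`mean`/`sigma` data frame).
#' @param n Total number of observations behind the fit; defaults to the
#'   fit's own sample size.
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with one row per component: `component`, `mean`, `sigma`,
#'   `n_eff`, `df`, `t_value`, `half_width`, `lower`, `upper`, `confidence`.
#' @examples
#' component_ci(gmm_preset("area_2h"), n = 36)
#' @export
component_ci <- function(model, n = NULL, confidence = 0.95) {
  m <- as_mixture(model)
  n <- n %||% (if (inherits(model, "vlp_gmm")) model$n else NULL)
  if (is.null(n)) vlp_abort("`n` (total observation count) is required.")
  n <- check_count(n, "n", min = 2L)
  if (length(confidence) != 1L || confidence <= 0 || confidence >= 1) {
    vlp_abort("`confidence` must lie in (0, 1).")
  }
  k <- nrow(m)
  if (n < 2L * k) vlp_abort("Need at least 2 observations per component.")
  n_eff <- round_half_up(n / k)
  if (n_eff < 2L) vlp_abort("Effective per-component count must be >= 2.")
  t_val <- qt(1 - (1 - confidence) / 2, df = n_eff - 1)
  hw <- t_val * m$sigma / sqrt(n_eff)
  tibble(
    component = seq_len(k),
    mean = m$mean, sigma = m$sigma,
    n_eff = n_eff, df = n_eff - 1L, t_value = t_val,
    half_width = hw, lower = m$mean - hw, upper = m$mean + hw,
    confidence = confidence
  )
}

#' Hard assignment of observations to mixture components
#'
#' Assigns every observation to the component with the largest posterior
#' responsibility; exact ties go to the smaller-mean component.
#'
#' @inheritParams mixture_loglik
#' @return The measurements as a tibble with an integer `component` column
#'   (components indexed in ascending-mean order).
#' @export
hard_assign <- function(data, model) {
  x <- measurement_values(data)
  m <- as_mixture(model)
  o <- order(m$mean)
  gamma <- e_step(x, m[o, ])
  comp <- max.col(gamma, ties.method = "first")
  out <- if (is.data.frame(data)) as_tibble(data) else tibble(value = x)
  out$component <- comp
  out
}

#' Contingency table of component membership by condition
#'
#' Builds the count table compared by [chi_squared_compare()]: one row per
#' condition, one column per mixture component, entries the hard-assigned
#' particle counts. Either a single shared model or one model per condition
#' (a named list) may be supplied; with per-condition models, components are
#' mapped to shared columns by their ascending-mean rank.
#'
#' @param data Measurement data frame with `value` and `condition` columns.
#' @param models A single mixture model, or a named list of models keyed by
#'   condition.
#' @return An integer matrix (conditions x components) with row sums equal to
#'   the per-condition sample sizes.
#' @export
count_table <- function(data, models) {
  if (!is.data.frame(data) || !all(c("value", "condition") %in% names(data))) {
    vlp_abort("`data` must contain `value` and `condition` columns.")
  }
  conds <- unique(data$condition)
  if (length(conds) < 2L) vlp_abort("At least two conditions are required.")
  per_cond <- !inherits(models, "vlp_gmm") && !is.data.frame(models) && is.list(models)
  if (per_cond && !all(conds %in% names(models))) {
    vlp_abort("`models` must be named after every condition.")
  }
  kmax <- if (per_cond) {
    max(vapply(models, function(m) nrow(as_mixture(m)), integer(1)))
  } else {
    nrow(as_mixture(models))
  }
  tab <- matrix(0L, nrow = length(conds), ncol = kmax,
                dimnames = list(as.character(conds), paste0("component_", seq_len(kmax))))
  for (cond in conds) {
    sub <- data[data$condition == cond, , drop = FALSE]
    mod <- if (per_cond) models[[as.character(cond)]] else models
    asg <- hard_assign(sub$value, mod)$component
    cnt <- tabulate(asg, nbins = kmax)
    tab[as.character(cond), ] <- cnt
  }
  tab
}

#' Pearson chi-squared comparison of count tables
#'
#' Tests whether the component-membership composition differs between
#' conditions: \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from
#' the row/column margins and \eqn{(r-1)(c-1)} degrees of freedom (no
#' continuity correction).
#'
#' @param table Matrix or data frame of non-negative counts (conditions x
#'   components).
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @examples
#' chi_squared_compare(rbind(c(10, 20), c(20, 10)))
#' @export
chi_squared_compare <- function(table) {
  tab <- as.matrix(table)
  if (any(!is.finite(tab)) || any(tab < 0)) {
    vlp_abort("Counts must be non-negative and finite.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    vlp_abort("Every row and column of the count table must have a positive margin.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = as.integer(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Descriptive statistics of a measurement set
#'
#' Arithmetic mean, sample (n-1) standard deviation and count, per condition
#' when a `condition` column is present.
#'
#' @inheritParams mixture_loglik
#' @return A tibble with columns `condition` (if grouped), `n`, `mean`, `sd`
#'   and `degenerate` (`TRUE` when all values in a group are identical).
#' @export
describe_measurements <- function(data) {
  x <- measurement_values(data)
  grouped <- is.data.frame(data) && "condition" %in% names(data)
  one <- function(v, cond = NULL) {
    if (length(v) < 2L) {
      vlp_abort("At least 2 observations are required for a standard deviation.")
    }
    out <- tibble(n = length(v), mean = mean(v), sd = sd(v),
                  degenerate = diff(range(v)) == 0)
    if (!is.null(cond)) out <- dplyr::bind_cols(tibble(condition = cond), out)
    out
  }
  if (grouped) {
    purrr::map_dfr(split(data$value, data$condition),
                   ~ one(.x), .id = "condition")
  } else {
    one(x)
  }
}
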