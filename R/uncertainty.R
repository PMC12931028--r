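# Parametric Monte-Carlo variance machinery: draw model parameters from
# their asymptotic multivariate normal (on the transformed scale, so
# positive parameters stay positive), draw random-effect values from the
# normal approximation to their posteriors, re-evaluate the estimand under
# each draw, and summarize with an empirical SE and percentile (or normal)
# confidence intervals. Plus the median-hazard-ratio summary.

#' Draw model parameters from their asymptotic distribution
#'
#' `B` multivariate-normal draws on the transformed scale (log shape, log
#' scale, beta, log variances) using the fitted covariance matrix,
#' back-transformed to the natural scale. Deterministic given `seed`;
#' drawn positive parameters are strictly positive by construction.
#'
#' @param fit A [fit_hiersurv()] result with a valid covariance matrix.
#' @param B Number of draws (>= 2).
#' @param seed Integer seed.
#' @return Object of class `param_draws`: list with the draw matrix
#'   (`B` x n_par, transformed scale) and metadata; index with
#'   [params_from_draw()].
#' @export
draw_parameters <- function(fit, B, seed) {
  if (is.null(fit$vcov)) {
    abort("Parameter covariance unavailable; cannot draw parameters.",
          class = "mlsurvstd_config_error")
  }
  if (B < 2) abort("`B` must be at least 2.",
                   class = "mlsurvstd_config_error")
  mu <- fit$estimate_trans
  draws <- withr::with_seed(seed, MASS::mvrnorm(B, mu = mu,
                                                Sigma = fit$vcov))
  if (B == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(mu)
  structure(list(draws = draws, B = B, seed = seed,
                 covariates = fit$covariates, fixed = fit$fixed),
            class = "param_draws")
}

#' Materialize one parameter draw as a `model_params`
#'
#' @param pd A [draw_parameters()] object.
#' @param b Draw index in `1:B`.
#' @return A [model_params()] on the natural scale.
#' @export
params_from_draw <- function(pd, b) {
  v <- pd$draws[b, ]
  covs <- pd$covariates
  beta <- if (length(covs) > 0) setNames(v[paste0("beta_", covs)], covs)
    else numeric(0)
  vs <- if (is.na(pd$fixed$surgeon)) exp(v[["log_var_surgeon"]]) else
    pd$fixed$surgeon
  vc <- if (is.na(pd$fixed$center)) exp(v[["log_var_center"]]) else
    pd$fixed$center
  model_params(exp(v[["log_shape"]]), exp(v[["log_scale"]]), beta, vs, vc)
}

#' Draw random-effect values from their posterior normal approximation
#'
#' Independent draws per cluster from `N(EB mean, posterior SD^2)`,
#' independently across clusters and levels. Deterministic given `seed`.
#'
#' @param eb An `eb_predictions` tibble (with SDs).
#' @param B Number of draws.
#' @param seed Integer seed.
#' @return List of class `ranef_draws` with matrices `surgeon` and
#'   `center` (`B` rows, one column per cluster).
#' @export
draw_random_effects <- function(eb, B, seed) {
  if (anyNA(eb$sd)) {
    abort("EB predictions lack SDs; cannot draw random effects.",
          class = "mlsurvstd_config_error")
  }
  draw_level <- function(lev) {
    sub <- eb[eb$level == lev, , drop = FALSE]
    m <- matrix(rnorm(B * nrow(sub), mean = rep(sub$estimate, each = B),
                      sd = rep(sub$sd, each = B)), nrow = B)
    colnames(m) <- sub$cluster
    m
  }
  withr::with_seed(seed, {
    structure(list(surgeon = draw_level("surgeon"),
                   center = draw_level("center"), B = B, seed = seed),
              class = "ranef_draws")
  })
}

#' Monte-Carlo confidence interval for a standardized estimand
#'
#' Implements the parametric simulation procedure: draw model parameters
#' and posterior random-effect values, re-evaluate the estimand for each
#' draw, and summarize. The reported point estimate is the plug-in value
#' (not the mean of draws); the SE is the square root of the empirical
#' variance across the `B` repetitions (1/B denominator); the default CI
#' is the empirical 2.5th/97.5th percentile, the alternative the normal
#' interval `point +/- 1.96 SE`. Non-finite draws are excluded with a
#' warning; more than 5% exclusions is an error.
#'
#' @param psi Pure function `psi(params, effects)` returning a numeric
#'   scalar or vector; `params` is a [model_params()], `effects` a list
#'   with named vectors `surgeon` and `center`.
#' @param fit A [fit_hiersurv()] result with a valid covariance.
#' @param eb Optional `eb_predictions`; when `NULL` (estimands fixing all
#'   effects at zero) the random-effect draw step is vacuous.
#' @param B Number of repetitions (default 1000, with the percentile
#'   method).
#' @param seed Integer seed driving both draw streams.
#' @param method `"percentile"` or `"normal"`.
#' @return Tibble with one row per component of `psi`: `point`, `se`,
#'   `lower`, `upper`; the draw matrix is in attribute `draws`.
#' @export
mc_interval <- function(psi, fit, eb = NULL, B = 1000, seed = 20240101,
                        method = c("percentile", "normal")) {
  method <- match.arg(method)
  pd <- draw_parameters(fit, B, seed)
  re <- if (!is.null(eb)) draw_random_effects(eb, B, seed + 1L)
  point_effects <- eb_effects(eb)
  point <- psi(fit$params, point_effects)
  draws <- matrix(NA_real_, B, length(point))
  for (b in seq_len(B)) {
    eff_b <- if (is.null(re)) point_effects else {
      list(surgeon = re$surgeon[b, ], center = re$center[b, ])
    }
    val <- tryCatch(psi(params_from_draw(pd, b), eff_b),
                    error = function(e) rep(NA_real_, length(point)))
    draws[b, ] <- val
  }
  ok <- rowSums(!is.finite(draws)) == 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (n_bad > 0.05 * B) {
      abort(sprintf("%d of %d Monte-Carlo draws were non-finite.", n_bad, B),
            class = "mlsurvstd_numeric_error")
    }
    warn(sprintf("Excluded %d non-finite Monte-Carlo draw(s).", n_bad))
    draws <- draws[ok, , drop = FALSE]
  }
  mu <- colMeans(draws)
  se <- sqrt(colMeans(sweep(draws, 2, mu)^2))
  if (method == "percentile") {
    qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    lower <- point - 1.96 * se
    upper <- point + 1.96 * se
  }
  structure(tibble(point = point, se = se, lower = lower, upper = upper),
            draws = draws, B = B, n_excluded = n_bad, method = method,
            class = c("mc_interval", class(tibble())))
}

#' Median hazard ratio of a random intercept
#'
#' The median of the hazard ratio comparing the higher-risk to the
#' lower-risk member of randomly drawn cluster pairs whose log-hazard
#' offsets are iid `N(0, sigma2)`:
#' `exp(sqrt(2 * sigma2) * qnorm(0.75))`.
#'
#' @param sigma2 Random-intercept variance(s), >= 0.
#' @return Median hazard ratio(s), always >= 1.
#' @examples
#' median_hazard_ratio(0.019)
#' @export
median_hazard_ratio <- function(sigma2) {
  if (any(sigma2 < 0)) {
    abort("Variance must be non-negative.",
          class = "mlsurvstd_config_error")
  }
  exp(sqrt(2 * sigma2) * qnorm(0.75))
}
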