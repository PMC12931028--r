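# Shared fixtures: small datasets, fabricated fitted models, and
# brute-force oracles used across the suite.

toy_one_cluster <- function() {
  as_survdata(data.frame(
    time = c(1.2, 0.7, 2.5, 0.4, 1.8), event = c(1, 0, 1, 1, 0),
    surgeon = "s1", center = "A", x1 = c(0.5, -1, 0.2, 0.9, -0.3)))
}

toy_params <- function(var_surgeon = 0.15, var_center = 0.2) {
  model_params(1.3, 0.4, c(x1 = 0.5), var_surgeon, var_center)
}

# Fabricated converged fit object so posterior / standardization /
# uncertainty code can be exercised at known parameter values.
fake_fit <- function(params, covariates = names(params$beta),
                     vcov = NULL) {
  est <- c(log_shape = log(params$shape), log_scale = log(params$scale))
  if (length(params$beta) > 0) {
    b <- params$beta
    names(b) <- paste0("beta_", covariates)
    est <- c(est, b)
  }
  est <- c(est, log_var_surgeon = log(max(params$var_surgeon, 1e-12)),
           log_var_center = log(max(params$var_center, 1e-12)))
  structure(list(
    params = params, covariates = covariates,
    estimate_trans = est,
    vcov = vcov %||% (diag(length(est)) * 0),
    transform = tibble::tibble(
      term = names(est),
      transform = ifelse(startsWith(names(est), "log_"), "log", "identity")),
    fixed = list(surgeon = NA, center = NA),
    loglik = NA_real_, nodes = 15,
    convergence = list(converged = TRUE, optim_code = 0, vcov_ok = TRUE)
  ), class = "hiersurv_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_sim_config <- function(K = 5, J = 2, I = 20, var_surgeon = 0.05,
                             var_center = 0.1, censor_rate = 0.02) {
  sim_config(K = K, surgeons_per_center = J, patients_per_surgeon = I,
             shape = 1.2, scale = 0.1, beta = c(x1 = 0.5),
             var_surgeon = var_surgeon, var_center = var_center,
             covariates = list(x1 = list(type = "normal", mean = 0, sd = 1)),
             censor_horizon = 20, censor_rate = censor_rate)
}

# Dense-grid log of the joint integral over (alpha, gamma) for a
# one-surgeon center: independent arithmetic on the raw records.
grid_cluster_loglik <- function(data, params, lim = 4, m = 1501) {
  gr <- seq(-lim, lim, length.out = m)
  h <- gr[2] - gr[1]
  X <- as.matrix(data[, names(params$beta), drop = FALSE])
  Z <- outer(gr, gr, "+")   # alpha rows, gamma columns
  lp <- matrix(0, m, m)
  for (i in seq_len(nrow(data))) {
    xb <- if (length(params$beta)) sum(X[i, ] * params$beta) else 0
    lp <- lp + data$event[i] *
      (log(params$shape) + log(params$scale) +
         (params$shape - 1) * log(data$time[i]) + xb + Z) -
      params$scale * data$time[i]^params$shape * exp(xb + Z)
  }
  lp <- lp + dnorm(gr, 0, sqrt(params$var_surgeon), log = TRUE) +
    rep(dnorm(gr, 0, sqrt(params$var_center), log = TRUE), each = m)
  mx <- max(lp)
  list(logint = mx + log(sum(exp(lp - mx)) * h * h), grid = gr, lp = lp)
}
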