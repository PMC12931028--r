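# Empirical-Bayes posterior predictions of the random intercepts, with
# model parameters fixed at their maximum-likelihood estimates.
#
# For a center with J surgeons the joint posterior of (gamma, alpha_1..J)
# is (J+1)-dimensional, but the surgeons are conditionally independent
# given gamma, so every posterior quantity reduces to nested 1-D
# quadratures: an outer adaptive Gauss-Hermite pass over gamma and, at
# each outer node, inner adaptive passes over one alpha at a time.

#' Unnormalized joint log posterior of one center's random effects
#'
#' Returns `sum_ij log f_ij(alpha_j, gamma) + sum_j log phi(alpha_j;
#' var_surgeon) + log phi(gamma; var_center)` at the fitted parameters. The
#' normalizing constant (the center's marginal likelihood) is deliberately
#' omitted; exponentiate and normalize over a grid to recover the proper
#' posterior density.
#'
#' @param fit A converged [fit_hiersurv()] result.
#' @param data The `survdata` the model was fitted to.
#' @param center Center label.
#' @param gamma Scalar center effect.
#' @param alphas Numeric vector of surgeon effects, one per surgeon of the
#'   center, ordered by sorted surgeon label.
#' @return Scalar unnormalized log posterior density.
#' @export
log_posterior_density <- function(fit, data, center, gamma, alphas) {
  sub <- data[data$center == center, , drop = FALSE]
  ss <- build_suffstats(sub, fit$covariates)
  if (length(alphas) != ss$S) {
    abort(sprintf("`alphas` has length %d but center '%s' has %d surgeons.",
                  length(alphas), center, ss$S),
          class = "mlsurvstd_config_error")
  }
  p <- fit$params
  st <- surgeon_stats(ss, p$shape, p$scale, p$beta)
  ll <- sum(st$A + st$D * (alphas + gamma) -
              safe_exp(alphas + gamma) * st$H)
  prior_a <- if (p$var_surgeon > 0) {
    sum(dnorm(alphas, 0, sqrt(p$var_surgeon), log = TRUE))
  } else if (all(alphas == 0)) 0 else -Inf
  prior_g <- if (p$var_center > 0) {
    dnorm(gamma, 0, sqrt(p$var_center), log = TRUE)
  } else if (gamma == 0) 0 else -Inf
  ll + prior_a + prior_g
}

# Posterior moments for one center: outer adaptive GH over gamma with
# normalized weights; inner adaptive moments of each alpha per outer node.
center_posterior_moments <- function(ss, params, nodes = 25) {
  st <- surgeon_stats(ss, params$shape, params$scale, params$beta)
  var_s <- params$var_surgeon; var_c <- params$var_center
  gh <- gh_rule(nodes)
  if (var_c == 0) {
    inn <- inner_logG(st$A, st$D, st$H, rep(0, ss$S), var_s, gh,
                      moments = TRUE)
    return(list(
      gamma_mean = rep(0, ss$K), gamma_sd = rep(0, ss$K),
      alpha_mean = inn$m1,
      alpha_sd = sqrt(pmax(inn$m2 - inn$m1^2, 0))))
  }
  om <- center_outer_mode(st, ss, var_s, var_c, gh)
  x <- gh$x; w <- gh$w; Q <- length(x)
  gnodes <- om$mode + outer(om$tau, sqrt(2) * x)      # K x Q
  gam_s <- gnodes[ss$s_center, , drop = FALSE]
  inn <- inner_logG(rep(st$A, Q), rep(st$D, Q), rep(st$H, Q),
                    as.vector(gam_s), var_s, gh, moments = TRUE)
  logG <- matrix(inn$logG, ss$S, Q)
  csum <- rowsum(logG, ss$s_center)                   # K x Q
  M <- csum + dnorm(gnodes, 0, sqrt(var_c), log = TRUE) +
    matrix(log(w) + x^2, ss$K, Q, byrow = TRUE)
  Wmat <- exp(M - do.call(pmax, as.data.frame(M)))
  Wmat <- Wmat / rowSums(Wmat)                        # normalized K x Q
  g1 <- rowSums(Wmat * gnodes)
  g2 <- rowSums(Wmat * gnodes^2)
  Ws <- Wmat[ss$s_center, , drop = FALSE]             # S x Q
  m1 <- matrix(inn$m1, ss$S, Q)
  m2 <- matrix(inn$m2, ss$S, Q)
  a1 <- rowSums(Ws * m1)
  a2 <- rowSums(Ws * m2)
  list(gamma_mean = g1, gamma_sd = sqrt(pmax(g2 - g1^2, 0)),
       alpha_mean = a1, alpha_sd = sqrt(pmax(a2 - a1^2, 0)))
}

# Joint posterior mode for one center (profile over gamma; alphas by the
# inner Newton at the optimum) and curvature-based SDs from the arrowhead
# precision matrix.
center_posterior_mode <- function(ss, params) {
  st <- surgeon_stats(ss, params$shape, params$scale, params$beta)
  var_s <- params$var_surgeon; var_c <- params$var_center

  alpha_hat <- function(gam_s) {
    if (var_s == 0) return(rep(0, length(gam_s)))
    a <- rep(0, length(gam_s))
    for (it in 1:30) {
      eg <- safe_exp(a + gam_s)
      f <- st$D - st$H * eg - a / var_s
      fp <- -st$H * eg - 1 / var_s
      step <- pmax(pmin(f / fp, 2), -2)
      a <- a - step
      if (max(abs(step)) < 1e-12) break
    }
    a
  }
  profile_lp <- function(g) {
    gam_s <- g[ss$s_center]
    a <- alpha_hat(gam_s)
    pa <- if (var_s > 0) dnorm(a, 0, sqrt(var_s), log = TRUE) else 0
    contrib <- st$A + st$D * (a + gam_s) - safe_exp(a + gam_s) * st$H + pa
    dnorm(g, 0, sqrt(var_c), log = TRUE) +
      as.vector(rowsum(contrib, ss$s_center))
  }

  if (var_c == 0) {
    g <- rep(0, ss$K)
  } else {
    h <- 1e-5
    g <- rep(0, ss$K)
    for (it in 1:40) {
      d1 <- (profile_lp(g + h) - profile_lp(g - h)) / (2 * h)
      d2 <- pmin((profile_lp(g + h) - 2 * profile_lp(g) +
                    profile_lp(g - h)) / h^2, -1e-8)
      step <- pmax(pmin(d1 / (-d2), 1), -1)
      g <- g + step
      if (max(abs(step)) < 1e-10) break
    }
  }
  a <- alpha_hat(g[ss$s_center])

  # Arrowhead negative Hessian: B_j = exp(alpha_j + gamma) * H_j.
  B <- st$H * safe_exp(a + g[ss$s_center])
  P_aa <- B + if (var_s > 0) 1 / var_s else Inf
  sumB <- as.vector(rowsum(B, ss$s_center))
  sumB2 <- as.vector(rowsum(B^2 / P_aa, ss$s_center))
  if (var_c > 0) {
    P_gg <- sumB + 1 / var_c
    var_g <- 1 / (P_gg - sumB2)
    var_a <- 1 / P_aa + (B / P_aa)^2 * var_g[ss$s_center]
  } else {
    var_g <- rep(0, ss$K)
    var_a <- 1 / P_aa
  }
  if (var_s == 0) var_a <- rep(0, ss$S)
  list(gamma_mode = g, gamma_sd = sqrt(pmax(var_g, 0)),
       alpha_mode = a, alpha_sd = sqrt(pmax(var_a, 0)))
}

check_converged <- function(fit) {
  if (!isTRUE(fit$convergence$converged)) {
    abort("Model fit did not converge; refusing posterior predictions.",
          class = "mlsurvstd_convergence_error")
  }
}

#' Empirical-Bayes predictions for every surgeon and center
#'
#' Applies the posterior mean (default, minimizing posterior mean-squared
#' error) or posterior mode to each cluster at both hierarchical levels.
#' Posterior SDs accompany means; mode SDs come from the inverse curvature
#' at the joint mode. Clusters are ranked within level by prediction
#' (rank 1 = smallest effect = lowest hazard = best performance), ties
#' broken by lexicographic cluster id.
#'
#' @param fit A converged [fit_hiersurv()] result.
#' @param data The fitted `survdata`.
#' @param method `"mean"` or `"mode"`.
#' @param nodes Quadrature nodes for posterior means (default 25).
#' @return A tibble of class `eb_predictions`: `level`, `cluster`, `center`,
#'   `estimate`, `sd`, `rank`, `method`, with attributes `var_surgeon`,
#'   `var_center`, `best`, `worst`.
#' @export
predict_ranef <- function(fit, data, method = c("mean", "mode"),
                          nodes = 25) {
  method <- match.arg(method)
  check_converged(fit)
  params <- fit$params
  rows <- list()
  for (cen in sort(unique(data$center))) {
    sub <- data[data$center == cen, , drop = FALSE]
    ss <- build_suffstats(sub, fit$covariates)
    pm <- if (method == "mean") {
      m <- center_posterior_moments(ss, params, nodes)
      list(g = m$gamma_mean, gs = m$gamma_sd, a = m$alpha_mean,
           as = m$alpha_sd)
    } else {
      m <- center_posterior_mode(ss, params)
      list(g = m$gamma_mode, gs = m$gamma_sd, a = m$alpha_mode,
           as = m$alpha_sd)
    }
    rows[[cen]] <- dplyr::bind_rows(
      tibble(level = "center", cluster = cen, center = cen,
             estimate = pm$g, sd = pm$gs),
      tibble(level = "surgeon", cluster = ss$surgeon_labels, center = cen,
             estimate = pm$a, sd = pm$as)
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out |>
    dplyr::group_by(.data$level) |>
    dplyr::arrange(.data$estimate, .data$cluster, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$level == "center"), .data$cluster)
  out$method <- method
  best <- out |> dplyr::filter(.data$rank == 1)
  worst <- out |>
    dplyr::group_by(.data$level) |>
    dplyr::filter(.data$rank == max(.data$rank)) |>
    dplyr::ungroup()
  structure(out, var_surgeon = params$var_surgeon,
            var_center = params$var_center,
            best = setNames(best$cluster, best$level),
            worst = setNames(worst$cluster, worst$level),
            class = c("eb_predictions", class(tibble())))
}

#' Empirical-Bayes posterior mean of a single cluster effect
#'
#' Posterior mean and SD of one surgeon- or center-level random intercept
#' by nested adaptive Gauss-Hermite quadrature. A cluster absent from the
#' data (no subjects) has posterior equal to the prior: mean 0, SD equal
#' to the prior SD.
#'
#' @inheritParams predict_ranef
#' @param cluster Cluster label.
#' @param level `"surgeon"` or `"center"`.
#' @return One-row tibble: `level`, `cluster`, `estimate`, `sd`.
#' @export
eb_mean <- function(fit, data, cluster, level = c("surgeon", "center"),
                    nodes = 25) {
  level <- match.arg(level)
  check_converged(fit)
  eb_one(fit, data, cluster, level, nodes, mode = FALSE)
}

#' Empirical-Bayes posterior mode of a single cluster effect
#'
#' Joint posterior mode of the center's random effects, found by profiling
#' the center effect (the surgeon effects are conditionally independent
#' given the center effect); the SD comes from the inverse curvature of the
#' joint log posterior at the mode.
#'
#' @inheritParams eb_mean
#' @return One-row tibble: `level`, `cluster`, `estimate`, `sd`.
#' @export
eb_mode <- function(fit, data, cluster, level = c("surgeon", "center"),
                    nodes = 25) {
  level <- match.arg(level)
  check_converged(fit)
  eb_one(fit, data, cluster, level, nodes, mode = TRUE)
}

eb_one <- function(fit, data, cluster, level, nodes, mode) {
  params <- fit$params
  present <- if (level == "center") cluster %in% data$center else
    cluster %in% data$surgeon
  if (!present) {
    prior_var <- if (level == "center") params$var_center else
      params$var_surgeon
    return(tibble(level = level, cluster = cluster, estimate = 0,
                  sd = sqrt(prior_var)))
  }
  cen <- if (level == "center") cluster else
    data$center[match(cluster, data$surgeon)]
  sub <- data[data$center == cen, , drop = FALSE]
  ss <- build_suffstats(sub, fit$covariates)
  if (mode) {
    m <- center_posterior_mode(ss, params)
    est <- if (level == "center") m$gamma_mode[1] else
      m$alpha_mode[match(cluster, ss$surgeon_labels)]
    sdv <- if (level == "center") m$gamma_sd[1] else
      m$alpha_sd[match(cluster, ss$surgeon_labels)]
  } else {
    m <- center_posterior_moments(ss, params, nodes)
    est <- if (level == "center") m$gamma_mean[1] else
      m$alpha_mean[match(cluster, ss$surgeon_labels)]
    sdv <- if (level == "center") m$gamma_sd[1] else
      m$alpha_sd[match(cluster, ss$surgeon_labels)]
  }
  if (!is.finite(est) || !is.finite(sdv)) {
    abort(sprintf("Non-finite posterior quadrature for cluster '%s'.",
                  cluster), class = "mlsurvstd_numeric_error")
  }
  tibble(level = level, cluster = cluster, estimate = est, sd = sdv)
}
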