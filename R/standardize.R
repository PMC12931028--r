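# Directly standardized survival probabilities: model-based conditional
# survival curves averaged over a fixed reference case-mix (by default the
# whole study population), with the random effects either fixed at their
# empirical-Bayes predictions (or at 0 for the theoretical average cluster)
# or marginalized over their estimated Gaussian prior.

#' Fully conditional survival probability
#'
#' `S0(t)^(exp(x beta + alpha + gamma))` with baseline survival
#' `S0(t) = exp(-scale * t^shape)`.
#'
#' @param params A [model_params()].
#' @param x Covariate vector (or matrix, one row per subject).
#' @param alpha,gamma Random intercepts to condition on.
#' @param times Vector of evaluation times (>= 0).
#' @return If `x` is a vector, a vector over `times`; if a matrix, a
#'   `nrow(x)` by `length(times)` matrix.
#' @export
conditional_survival <- function(params, x = NULL, alpha = 0, gamma = 0,
                                 times) {
  if (any(times < 0)) abort("`times` must be non-negative.")
  base <- params$scale * times^params$shape
  if (is.matrix(x)) {
    eta <- linear_predictor(x, params$beta, nrow(x)) + alpha + gamma
    exp(-outer(exp(eta), base))
  } else {
    n <- 1L
    eta <- linear_predictor(x, params$beta, n) + alpha + gamma
    exp(-base * exp(eta))
  }
}

# --- estimand descriptors -------------------------------------------------

# A descriptor captures everything needed to (re-)evaluate a standardized
# curve for given parameters and random-effect values; the Monte-Carlo CI
# machinery re-evaluates the same descriptor under each draw.
std_descriptor <- function(type, surgeon = NULL, center = NULL,
                           level = NULL, cluster = NULL, nodes = 30) {
  list(type = type, surgeon = surgeon, center = center,
       level = level, cluster = cluster, nodes = nodes)
}

effect_value <- function(effects, level, id) {
  if (is.null(id) || identical(id, "average")) return(0)
  v <- effects[[level]][[id]]
  if (is.null(v) || is.na(v)) {
    abort(sprintf("No %s-level prediction available for cluster '%s'.",
                  level, id), class = "mlsurvstd_config_error")
  }
  v
}

# Core evaluator: standardized survival curve over `times` for a covariate
# matrix Xpop under a descriptor, parameters and effect values.
eval_estimand <- function(desc, params, effects, Xpop, times) {
  base <- params$scale * times^params$shape
  xb <- linear_predictor(Xpop, params$beta, nrow(Xpop))
  if (desc$type == "fixed") {
    off <- effect_value(effects, "surgeon", desc$surgeon) +
      effect_value(effects, "center", desc$center)
    return(colMeans(exp(-outer(exp(xb + off), base))))
  }
  # marginal: fix one level, integrate the other over its prior
  fixed_level <- desc$level
  other_var <- if (fixed_level == "center") params$var_surgeon else
    params$var_center
  off <- effect_value(effects, fixed_level, desc$cluster)
  if (other_var == 0) {
    return(colMeans(exp(-outer(exp(xb + off), base))))
  }
  gh <- gh_rule(desc$nodes)
  acc <- matrix(0, 1, length(times))
  for (r in seq_along(gh$x)) {
    u <- sqrt(2 * other_var) * gh$x[r]
    acc <- acc + (gh$w[r] / sqrt(pi)) *
      colMeans(exp(-outer(exp(xb + off + u), base)))
  }
  val <- as.vector(acc)
  if (any(!is.finite(val))) {
    abort("Non-finite quadrature in marginal standardization.",
          class = "mlsurvstd_numeric_error")
  }
  val
}

resolve_population <- function(data, population, covariates) {
  if (is.null(population)) {
    X <- as.matrix(data[, covariates, drop = FALSE])
  } else if (is.numeric(population)) {
    X <- as.matrix(data[population, covariates, drop = FALSE])
  } else if (is.data.frame(population)) {
    X <- as.matrix(population[, covariates, drop = FALSE])
  } else {
    abort("`population` must be NULL, row indices, or a data frame.")
  }
  if (nrow(X) == 0) {
    abort("Empty standardization population.",
          class = "mlsurvstd_config_error")
  }
  storage.mode(X) <- "double"
  X
}

default_times <- function(data, length_out = 100) {
  seq(0, unname(quantile(data$time, 0.99)), length.out = length_out)
}

eb_effects <- function(eb) {
  if (is.null(eb)) return(list(surgeon = numeric(0), center = numeric(0)))
  list(
    surgeon = setNames(eb$estimate[eb$level == "surgeon"],
                       eb$cluster[eb$level == "surgeon"]),
    center = setNames(eb$estimate[eb$level == "center"],
                      eb$cluster[eb$level == "center"])
  )
}

resolve_cluster_id <- function(id, eb, level) {
  if (is.null(id) || !id %in% c("best", "worst")) return(id)
  sel <- attr(eb, id)
  if (!is.null(sel) && level %in% names(sel)) return(unname(sel[[level]]))
  sub <- if (!is.null(eb)) eb[eb$level == level, , drop = FALSE]
  if (is.null(sub) || nrow(sub) == 0) {
    abort(sprintf("Cannot resolve '%s' %s without EB predictions.",
                  id, level), class = "mlsurvstd_config_error")
  }
  ord <- order(sub$estimate, sub$cluster)
  if (id == "best") sub$cluster[ord[1]] else sub$cluster[ord[length(ord)]]
}

finish_std <- function(est, times, desc, Xpop, data, ci_tab = NULL) {
  stopifnot(all(diff(times) >= 0))
  out <- tibble(time = times, estimate = est)
  if (!is.null(ci_tab)) {
    out$se <- ci_tab$se; out$lower <- ci_tab$lower; out$upper <- ci_tab$upper
  }
  # Extrapolation guard: share of the standardization population coming
  # from clusters other than the fixed one(s).
  frac_ext <- NA_real_
  if (!is.null(data)) {
    own <- rep(TRUE, nrow(data))
    if (!is.null(desc$center) && !identical(desc$center, "average")) {
      own <- own & data$center == desc$center
    }
    if (!is.null(desc$cluster) && identical(desc$level, "center")) {
      own <- data$center == desc$cluster
    }
    if (!is.null(desc$surgeon) && !identical(desc$surgeon, "average")) {
      own <- own & data$surgeon == desc$surgeon
    }
    if (!is.null(desc$cluster) && identical(desc$level, "surgeon")) {
      own <- data$surgeon == desc$cluster
    }
    frac_ext <- 1 - mean(own)
  }
  structure(out, estimand = desc, population_hash = rlang::hash(Xpop),
            n_population = nrow(Xpop), frac_external = frac_ext,
            class = c("std_surv", class(tibble())))
}

#' Standardized survival fixing surgeon and center effects
#'
#' Averages the fully conditional survival over a reference population:
#' `(1/m) sum_i S0(t)^(exp(X_i beta + alpha + gamma))`, plugging in the
#' empirical-Bayes predictions of the named surgeon and center. The
#' keyword `"average"` fixes the corresponding effect at 0 (the theoretical
#' average cluster); `"best"`/`"worst"` resolve through the EB ranking.
#'
#' @param fit A converged [fit_hiersurv()] result.
#' @param data The fitted `survdata` (source of the default population and
#'   time grid).
#' @param eb [predict_ranef()] output; required unless both effects are
#'   `"average"`.
#' @param surgeon,center Cluster labels, or `"average"`, `"best"`,
#'   `"worst"`.
#' @param times Evaluation grid; default 100 points from 0 to the 99th
#'   percentile of observed follow-up.
#' @param population Standardization population: `NULL` (all subjects), a
#'   vector of row indices, or a data frame with the covariate columns.
#' @param ci Optional list `list(B =, seed =, method =)` requesting
#'   Monte-Carlo confidence bands via [mc_interval()].
#' @return A `std_surv` tibble (`time`, `estimate`, and `se`/`lower`/
#'   `upper` when `ci` is given) with estimand metadata in attributes,
#'   including `frac_external`, the share of the population drawn from
#'   other clusters (extrapolation guard).
#' @export
standardize_fixed <- function(fit, data, eb = NULL, surgeon = "average",
                              center = "average", times = NULL,
                              population = NULL, ci = NULL) {
  check_converged(fit)
  surgeon <- resolve_cluster_id(surgeon, eb, "surgeon")
  center <- resolve_cluster_id(center, eb, "center")
  times <- times %||% default_times(data)
  Xpop <- resolve_population(data, population, fit$covariates)
  desc <- std_descriptor("fixed", surgeon = surgeon, center = center)
  effects <- eb_effects(eb)
  est <- eval_estimand(desc, fit$params, effects, Xpop, times)
  ci_tab <- if (!is.null(ci)) std_ci(desc, fit, eb, Xpop, times, ci)
  finish_std(est, times, desc, Xpop, data, ci_tab)
}

#' Standardized survival fixing one level and marginalizing the other
#'
#' Fixes the empirical-Bayes prediction of one hierarchical unit and
#' integrates the other level's random intercept over its estimated prior
#' `N(0, sigma^2)` with (non-adaptive) Gauss-Hermite quadrature — the prior
#' is exactly Gaussian, so adaptivity is unnecessary. With `level =
#' "center"` this is the survival if the whole population were treated at
#' that center, marginally over surgeons; `level = "surgeon"` swaps roles.
#'
#' @inheritParams standardize_fixed
#' @param level `"center"` or `"surgeon"`: the level held fixed.
#' @param cluster Label of the fixed cluster (or `"average"`, `"best"`,
#'   `"worst"`).
#' @param nodes Gauss-Hermite nodes for the prior integral (default 30).
#' @return A `std_surv` tibble; see [standardize_fixed()].
#' @export
standardize_marginal <- function(fit, data, eb = NULL,
                                 level = c("center", "surgeon"),
                                 cluster = "average", times = NULL,
                                 population = NULL, nodes = 30, ci = NULL) {
  level <- match.arg(level)
  check_converged(fit)
  cluster <- resolve_cluster_id(cluster, eb, level)
  times <- times %||% default_times(data)
  Xpop <- resolve_population(data, population, fit$covariates)
  desc <- std_descriptor("marginal", level = level, cluster = cluster,
                         nodes = nodes)
  effects <- eb_effects(eb)
  est <- eval_estimand(desc, fit$params, effects, Xpop, times)
  ci_tab <- if (!is.null(ci)) std_ci(desc, fit, eb, Xpop, times, ci)
  finish_std(est, times, desc, Xpop, data, ci_tab)
}

# Monte-Carlo confidence band for a descriptor.
std_ci <- function(desc, fit, eb, Xpop, times, ci) {
  ci <- modifyList(list(B = 1000, seed = 20240101, method = "percentile"),
                   as.list(ci))
  psi <- function(params, effects) {
    eval_estimand(desc, params, effects, Xpop, times)
  }
  mc_interval(psi, fit, eb, B = ci$B, seed = ci$seed, method = ci$method)
}

#' Contrast two standardized survival curves
#'
#' Pointwise difference `a - b` of two standardized estimates sharing the
#' same time grid and the same standardization population (both enforced,
#' so the comparison is over a common case-mix). Covers contrasts between
#' any pair of (surgeon, center) combinations, within-center surgeon
#' comparisons, and marginal center or surgeon comparisons, depending on
#' how `a` and `b` were built.
#'
#' @param a,b `std_surv` tibbles (minuend and subtrahend).
#' @param fit,data,eb Needed only when `ci` is requested (the contrast is
#'   re-evaluated under each parameter/effect draw).
#' @param ci Optional `list(B =, seed =, method =)`.
#' @return A `std_contrast` tibble (`time`, `estimate`, optional bands)
#'   with both estimand descriptors in attributes.
#' @export
contrast_standardized <- function(a, b, fit = NULL, data = NULL, eb = NULL,
                                  ci = NULL) {
  if (!isTRUE(all.equal(a$time, b$time))) {
    abort("Time grids differ; contrasts need a shared grid.",
          class = "mlsurvstd_config_error")
  }
  if (!identical(attr(a, "population_hash"), attr(b, "population_hash"))) {
    abort("Standardization populations differ; refusing the contrast.",
          class = "mlsurvstd_config_error")
  }
  out <- tibble(time = a$time, estimate = a$estimate - b$estimate)
  if (!is.null(ci)) {
    if (is.null(fit)) {
      abort("`fit` (and `eb` if clusters are involved) are required for CIs.")
    }
    ci <- modifyList(list(B = 1000, seed = 20240101, method = "percentile"),
                     as.list(ci))
    da <- attr(a, "estimand"); db <- attr(b, "estimand")
    Xpop <- resolve_population(data, NULL, fit$covariates)
    if (!identical(rlang::hash(Xpop), attr(a, "population_hash"))) {
      abort("`data` does not reproduce the population the curves used.")
    }
    psi <- function(params, effects) {
      eval_estimand(da, params, effects, Xpop, a$time) -
        eval_estimand(db, params, effects, Xpop, a$time)
    }
    tab <- mc_interval(psi, fit, eb, B = ci$B, seed = ci$seed,
                       method = ci$method)
    out$se <- tab$se; out$lower <- tab$lower; out$upper <- tab$upper
  }
  structure(out, minuend = attr(a, "estimand"),
            subtrahend = attr(b, "estimand"),
            population_hash = attr(a, "population_hash"),
            class = c("std_contrast", class(tibble())))
}

#' Standardized survival at one time for every cluster of a level
#'
#' Convenience wrapper producing the per-cluster estimates (and optional
#' CI bands) that feed [rank_clusters()].
#'
#' @inheritParams standardize_fixed
#' @param time Single evaluation time.
#' @param level `"center"` or `"surgeon"`.
#' @param type `"marginal"` (fix the cluster, integrate the other level;
#'   default) or `"fixed"` (other level's effect set to 0).
#' @return Tibble `cluster`, `estimate` (+ `lower`, `upper` with `ci`).
#' @export
standardize_all_clusters <- function(fit, data, eb, time,
                                     level = c("center", "surgeon"),
                                     type = c("marginal", "fixed"),
                                     population = NULL, ci = NULL) {
  level <- match.arg(level)
  type <- match.arg(type)
  clusters <- sort(unique(eb$cluster[eb$level == level]))
  rows <- purrr::map(clusters, function(cl) {
    est <- if (type == "marginal") {
      standardize_marginal(fit, data, eb, level = level, cluster = cl,
                           times = time, population = population, ci = ci)
    } else if (level == "center") {
      standardize_fixed(fit, data, eb, surgeon = "average", center = cl,
                        times = time, population = population, ci = ci)
    } else {
      standardize_fixed(fit, data, eb, surgeon = cl, center = "average",
                        times = time, population = population, ci = ci)
    }
    out <- tibble(cluster = cl, estimate = est$estimate[1])
    if (!is.null(ci)) {
      out$lower <- est$lower[1]; out$upper <- est$upper[1]
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Rank and categorize clusters against a reference survival
#'
#' Orders clusters by their standardized survival at a reference time and
#' categorizes them against a reference value (typically the theoretical
#' average cluster): `medium` risk if the cluster's CI covers the
#' reference, `low` risk if the CI lies entirely above it (better
#' survival), `high` risk if entirely below. Without CI bands all clusters
#' are `uncategorized` unless the tercile policy is explicitly requested
#' (top/middle/bottom thirds by point estimate). The policy applied is
#' recorded in the output attributes.
#'
#' @param estimates Tibble with `cluster` and `estimate` (survival at the
#'   reference time), e.g. from [standardize_all_clusters()].
#' @param reference Scalar reference survival, or a `std_surv` evaluated at
#'   the same single time.
#' @param bands Optional tibble `cluster`, `lower`, `upper` (or already
#'   columns of `estimates`).
#' @param policy `"ci"` (default) or `"tercile"`.
#' @return A `cluster_ranking` tibble: `cluster`, `estimate`, `lower`,
#'   `upper`, `rank` (1 = highest survival), `category`.
#' @export
rank_clusters <- function(estimates, reference, bands = NULL,
                          policy = c("ci", "tercile")) {
  policy <- match.arg(policy)
  ref <- if (inherits(reference, "std_surv")) reference$estimate[1] else
    as.numeric(reference)
  est <- as_tibble(estimates)
  if (!is.null(bands)) {
    est <- dplyr::left_join(est, bands[, c("cluster", "lower", "upper")],
                            by = "cluster")
  }
  if (!all(c("lower", "upper") %in% names(est))) {
    est$lower <- NA_real_; est$upper <- NA_real_
  }
  est <- est |>
    dplyr::arrange(dplyr::desc(.data$estimate), .data$cluster) |>
    dplyr::mutate(rank = dplyr::row_number())
  n <- nrow(est)
  category <- if (policy == "ci") {
    if (anyNA(est$lower) || anyNA(est$upper)) {
      rep("uncategorized", n)
    } else {
      dplyr::case_when(
        est$lower > ref ~ "low",
        est$upper < ref ~ "high",
        TRUE ~ "medium"
      )
    }
  } else {
    cut_pts <- ceiling(c(n / 3, 2 * n / 3))
    ifelse(est$rank <= cut_pts[1], "low",
           ifelse(est$rank <= cut_pts[2], "medium", "high"))
  }
  est$category <- category
  structure(est, reference = ref, policy = policy,
            class = c("cluster_ranking", class(tibble())))
}
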