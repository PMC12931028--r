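# Marginal likelihood of the three-level Weibull proportional-hazards model
# with nested Gaussian random intercepts, computed by nested adaptive
# Gauss-Hermite quadrature.
#
# Conditional on the random effects, a subject's log-likelihood contribution
# is d * log h(t) - H(t) with h(t) = shape * scale * t^(shape-1) *
# exp(X beta + alpha + gamma) and H(t) = scale * t^shape * exp(.). Summed
# over the subjects of one surgeon this collapses to
#   A_j + D_j * (alpha + gamma) - exp(alpha + gamma) * H_j,
# where A_j collects the terms free of the random effects, D_j is the
# surgeon's event count and H_j the sum of scale * t^shape * exp(X beta).
# The whole marginal likelihood therefore depends on the data only through
# per-surgeon scalars, which keeps both quadrature levels one-dimensional
# and cheap.

#' Model parameters of the three-level Weibull PH model
#'
#' @param shape,scale Weibull baseline parameters (> 0); the baseline
#'   cumulative hazard is `scale * t^shape`.
#' @param beta Named numeric vector of fixed-effect coefficients (log-hazard
#'   ratios), one per covariate; may be empty.
#' @param var_surgeon,var_center Random-intercept variances (>= 0).
#' @return A list of class `model_params`.
#' @export
model_params <- function(shape, scale, beta = numeric(0),
                         var_surgeon = 0, var_center = 0) {
  if (shape <= 0 || scale <= 0) {
    abort("`shape` and `scale` must be positive.",
          class = "mlsurvstd_config_error")
  }
  if (var_surgeon < 0 || var_center < 0) {
    abort("Variances must be non-negative.",
          class = "mlsurvstd_config_error")
  }
  structure(list(shape = shape, scale = scale, beta = beta,
                 var_surgeon = var_surgeon, var_center = var_center),
            class = "model_params")
}

#' Conditional subject log-likelihood
#'
#' Log-likelihood contribution of one subject given the random effects:
#' `d * log h(t) - H(t)`, the log of f(t)^d * S(t)^(1-d).
#'
#' @param params A [model_params()].
#' @param time,event Follow-up time(s) and event indicator(s).
#' @param x Covariate vector (or matrix with one row per subject).
#' @param alpha,gamma Surgeon- and center-level random intercepts.
#' @return Numeric vector of log-likelihood contributions.
#' @export
subject_loglik <- function(params, time, event, x = NULL,
                           alpha = 0, gamma = 0) {
  p <- params$shape; lam <- params$scale
  if (any(time == 0 & event == 1 & p < 1)) {
    abort("Event at time 0 with shape < 1: log-hazard undefined.",
          class = "mlsurvstd_domain_error")
  }
  xb <- linear_predictor(x, params$beta, length(time))
  eta <- xb + alpha + gamma
  cumhaz <- lam * time^p * exp(eta)
  event * (log(p) + log(lam) + (p - 1) * log(time) + eta) - cumhaz
}

linear_predictor <- function(x, beta, n) {
  if (length(beta) == 0 || is.null(x)) return(rep(0, n))
  if (is.matrix(x)) as.vector(x %*% beta) else rep(sum(x * beta), n)
}

# Sufficient-statistic container ------------------------------------------

# Index structure shared by the likelihood, posterior and standardization
# code. Surgeons are re-indexed 1..S (globally unique after nesting
# validation), centers 1..K.
build_suffstats <- function(data, covariates = survdata_covariates(data)) {
  sfac <- factor(data$surgeon)
  S <- nlevels(sfac)
  srow <- as.integer(sfac)
  cen_of_s <- data$center[match(levels(sfac), data$surgeon)]
  cfac <- factor(cen_of_s)
  K <- nlevels(cfac)
  s_center <- as.integer(cfac)
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  d <- as.numeric(data$event)
  t <- as.numeric(data$time)
  # Per-surgeon event counts and event-weighted sums used in A_j.
  D <- as.vector(rowsum(d, srow, reorder = TRUE))
  SLT <- as.vector(rowsum(d * log(pmax(t, .Machine$double.xmin)), srow))
  XtE <- if (ncol(X) > 0) rowsum(X * d, srow) else
    matrix(0, nrow = S, ncol = 0)
  list(t = t, d = d, X = X, srow = srow, s_center = s_center,
       S = S, K = K, n = length(t), P = ncol(X),
       D = D, SLT = SLT, XtE = XtE,
       surgeon_labels = levels(sfac), center_labels = levels(cfac),
       center_of_surgeon = cen_of_s, covariates = covariates)
}

# Per-surgeon (A_j, H_j) at given baseline/fixed-effect parameters.
surgeon_stats <- function(ss, shape, scale, beta) {
  xb <- if (ss$P > 0) as.vector(ss$X %*% beta) else numeric(ss$n)
  w <- scale * ss$t^shape * exp(xb)
  H <- as.vector(rowsum(w, ss$srow))
  A <- ss$D * (log(shape) + log(scale)) + (shape - 1) * ss$SLT +
    if (ss$P > 0) as.vector(ss$XtE %*% beta) else 0
  list(A = A, D = ss$D, H = H)
}

# Inner (surgeon-level) adaptive GH integral ------------------------------

# log G_j(gamma) = log Int phi(a; var_s) exp(A + D(a+gamma) - e^(a+gamma) H) da
# for vectors of surgeon statistics and gamma values of equal length.
# The integrand mode solves D - H e^(a+gamma) - a/var_s = 0 (concave),
# found by damped Newton; quadrature nodes are recentered and rescaled
# there. Optionally returns normalized posterior moments of alpha.
inner_logG <- function(A, D, H, gamma, var_s, gh, moments = FALSE) {
  m <- length(gamma)
  if (var_s == 0) {
    lg <- A + D * gamma - safe_exp(gamma) * H
    if (moments) return(list(logG = lg, m1 = rep(0, m), m2 = rep(0, m)))
    return(lg)
  }
  a <- rep(0, m)
  for (it in 1:14) {
    eg <- safe_exp(a + gamma)
    f <- D - H * eg - a / var_s
    fp <- -H * eg - 1 / var_s
    step <- pmax(pmin(f / fp, 2), -2)
    a <- a - step
    if (max(abs(step)) < 1e-12) break
  }
  curv <- H * safe_exp(a + gamma) + 1 / var_s
  tau <- 1 / sqrt(curv)
  x <- gh$x; w <- gh$w; R <- length(x)
  anodes <- a + outer(tau, sqrt(2) * x)           # m x R
  ll <- A + D * (anodes + gamma) - safe_exp(anodes + gamma) * H
  lw <- matrix(log(w) + x^2, m, R, byrow = TRUE)
  M <- lw + ll + dnorm(anodes, 0, sqrt(var_s), log = TRUE)
  mx <- do.call(pmax, as.data.frame(M))
  u <- exp(M - mx)
  s0 <- rowSums(u)
  logG <- log(sqrt(2) * tau) + mx + log(s0)
  if (!moments) return(logG)
  list(logG = logG,
       m1 = rowSums(u * anodes) / s0,
       m2 = rowSums(u * anodes^2) / s0)
}

# Outer (center-level) integrand: for a K-vector g of center effects,
# log phi(g; var_c) + sum over the center's surgeons of log G_j(g).
center_outer_obj <- function(g, st, ss, var_s, var_c, gh) {
  gam_s <- g[ss$s_center]
  lg <- inner_logG(st$A, st$D, st$H, gam_s, var_s, gh)
  dnorm(g, 0, sqrt(var_c), log = TRUE) +
    as.vector(rowsum(lg, ss$s_center))
}

# Mode and curvature of the outer integrand, vectorized over centers
# (damped Newton on numerically differentiated objective).
center_outer_mode <- function(st, ss, var_s, var_c, gh) {
  h <- 1e-4
  g <- rep(0, ss$K)
  d2 <- rep(-1 / var_c, ss$K)
  for (it in 1:30) {
    f0 <- center_outer_obj(g, st, ss, var_s, var_c, gh)
    f1 <- center_outer_obj(g + h, st, ss, var_s, var_c, gh)
    f2 <- center_outer_obj(g - h, st, ss, var_s, var_c, gh)
    d1 <- (f1 - f2) / (2 * h)
    d2 <- pmin((f1 - 2 * f0 + f2) / h^2, -1e-8)
    step <- pmax(pmin(d1 / (-d2), 1.5), -1.5)
    g <- g + step
    if (max(abs(step)) < 1e-10) break
  }
  list(mode = g, tau = 1 / sqrt(-d2))
}

# Per-center marginal log-likelihood vector (length K).
center_loglik_vec <- function(ss, params, nodes = 15) {
  st <- surgeon_stats(ss, params$shape, params$scale, params$beta)
  var_s <- params$var_surgeon; var_c <- params$var_center
  gh <- gh_rule(nodes)
  if (var_c == 0) {
    lg <- inner_logG(st$A, st$D, st$H, rep(0, ss$S), var_s, gh)
    return(as.vector(rowsum(lg, ss$s_center)))
  }
  om <- center_outer_mode(st, ss, var_s, var_c, gh)
  x <- gh$x; w <- gh$w; Q <- length(x)
  gnodes <- om$mode + outer(om$tau, sqrt(2) * x)   # K x Q
  gam_s <- gnodes[ss$s_center, , drop = FALSE]     # S x Q
  lg <- inner_logG(rep(st$A, Q), rep(st$D, Q), rep(st$H, Q),
                   as.vector(gam_s), var_s, gh)
  csum <- rowsum(matrix(lg, ss$S, Q), ss$s_center) # K x Q
  M <- csum + dnorm(gnodes, 0, sqrt(var_c), log = TRUE) +
    matrix(log(w) + x^2, ss$K, Q, byrow = TRUE)
  log(sqrt(2) * om$tau) + lse_rows(M)
}

#' Marginal log-likelihood contribution of one center
#'
#' Computes `log L_k = log Int phi(g; var_center) prod_j [Int phi(a;
#' var_surgeon) prod_i f_i(a, g) da] dg` for a single center by nested
#' adaptive Gauss-Hermite quadrature (inner integrals recentered at the
#' conditional mode of the surgeon effect, outer at the mode of the center
#' effect), with log-sum-exp accumulation. A zero variance collapses the
#' corresponding integral to a point mass at 0.
#'
#' @param params A [model_params()].
#' @param data A `survdata` tibble (may contain several centers).
#' @param center Center label; defaults to the only center in `data`.
#' @param nodes Quadrature nodes per dimension (>= 3).
#' @return The center's marginal log-likelihood (scalar).
#' @export
cluster_loglik <- function(params, data, center = NULL, nodes = 15) {
  if (nodes < 3) {
    abort("`nodes` must be at least 3.", class = "mlsurvstd_config_error")
  }
  if (is.null(center)) {
    center <- unique(data$center)
    if (length(center) > 1) {
      abort("`data` has several centers; name one via `center`.")
    }
  }
  sub <- data[data$center == center, , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("Unknown center '%s'.", center))
  ss <- build_suffstats(sub, survdata_covariates(data))
  sum(center_loglik_vec(ss, params, nodes))
}

# Full-data marginal log-likelihood.
marginal_loglik <- function(ss, params, nodes = 15) {
  sum(center_loglik_vec(ss, params, nodes))
}
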