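# Maximum-likelihood estimation of the three-level Weibull PH model.
# Positive parameters are optimized on the log scale (log shape, log scale,
# log variances); the parameter covariance matrix is reported on that
# transformed scale, with the transform map recorded, so that downstream
# multivariate-normal parameter draws respect positivity.

#' Fit the three-level Weibull proportional-hazards mixed model
#'
#' Maximizes the marginal likelihood (summed [cluster_loglik()] over
#' centers) over (log shape, log scale, beta, log var_surgeon,
#' log var_center) with BFGS. Starting values for the baseline and fixed
#' effects come from a single-level Weibull fit ([survival::survreg()]);
#' variances start at 0.05 unless fixed. The parameter covariance matrix is
#' the inverse of a central-finite-difference Hessian at the optimum.
#'
#' @param data A `survdata` tibble (see [as_survdata()]).
#' @param covariates Covariate columns to adjust for; defaults to the
#'   dataset's covariate attribute.
#' @param nodes Gauss-Hermite nodes per integral (default 15).
#' @param fix_var Optional named numeric, e.g. `c(surgeon = 0)` or
#'   `c(surgeon = 0, center = 0)`, fixing a variance component instead of
#'   estimating it (a zero collapses that integral to a point mass).
#' @param start Optional `model_params` with starting values.
#' @param control Passed to [stats::optim()] (BFGS); sensible defaults are
#'   merged in.
#' @return An object of class `hiersurv_fit`: `params` ([model_params()] at
#'   the optimum), `loglik`, `vcov` (transformed scale), `transform`
#'   (tibble mapping coordinates to transforms), `convergence` (list with
#'   `converged`, `optim_code`, `counts`, `vcov_ok`), and data summary
#'   fields (`n`, `K`, `S`, `covariates`).
#' @export
fit_hiersurv <- function(data, covariates = NULL, nodes = 15,
                         fix_var = NULL, start = NULL, control = list()) {
  covariates <- covariates %||% survdata_covariates(data)
  if (sum(data$event) < 1) {
    abort("Need at least one event to fit the model.",
          class = "mlsurvstd_parse_error")
  }
  ss <- build_suffstats(data, covariates)

  fixed <- list(
    surgeon = if ("surgeon" %in% names(fix_var)) fix_var[["surgeon"]] else NA,
    center = if ("center" %in% names(fix_var)) fix_var[["center"]] else NA
  )

  start <- start %||% starting_values(data, covariates)
  par0 <- c(log(start$shape), log(start$scale), start$beta)
  names(par0) <- c("log_shape", "log_scale",
                   if (length(covariates)) paste0("beta_", covariates))
  if (is.na(fixed$surgeon)) {
    par0 <- c(par0, log_var_surgeon = log(max(start$var_surgeon, 0.05)))
  }
  if (is.na(fixed$center)) {
    par0 <- c(par0, log_var_center = log(max(start$var_center, 0.05)))
  }

  unpack <- function(par) {
    nb <- length(covariates)
    beta <- if (nb > 0) setNames(par[2 + seq_len(nb)], covariates) else
      numeric(0)
    i <- 2 + nb
    vs <- if (is.na(fixed$surgeon)) exp(par[[i <- i + 1]]) else fixed$surgeon
    vc <- if (is.na(fixed$center)) exp(par[[i + 1]]) else fixed$center
    model_params(exp(par[[1]]), exp(par[[2]]), beta, vs, vc)
  }

  negll <- function(par) {
    val <- tryCatch(-marginal_loglik(ss, unpack(par), nodes),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }

  ctrl <- modifyList(list(maxit = 400, reltol = 1e-12,
                          ndeps = rep(1e-5, length(par0))), control)
  opt <- optim(par0, negll, method = "BFGS", control = ctrl)

  hess <- fd_hessian(negll, opt$par)
  vcov <- tryCatch({
    v <- solve(hess)
    if (any(diag(v) < 0)) NULL else (v + t(v)) / 2
  }, error = function(e) NULL)
  if (is.null(vcov)) {
    warn("Singular or indefinite Hessian: parameter covariance unavailable.")
  }

  params <- unpack(opt$par)
  transform <- tibble(
    term = names(opt$par),
    transform = ifelse(startsWith(names(opt$par), "log_"), "log", "identity")
  )
  structure(list(
    params = params,
    loglik = -opt$value,
    estimate_trans = opt$par,
    vcov = vcov,
    transform = transform,
    fixed = fixed,
    nodes = nodes,
    convergence = list(converged = opt$convergence == 0 && !is.null(vcov),
                       optim_code = opt$convergence,
                       counts = opt$counts,
                       vcov_ok = !is.null(vcov)),
    n = ss$n, K = ss$K, S = ss$S,
    covariates = covariates
  ), class = "hiersurv_fit")
}

# Single-level Weibull PH starting values via survreg (AFT -> PH mapping:
# shape = 1/scale_aft, scale = exp(-intercept/scale_aft), beta = -b/scale_aft).
starting_values <- function(data, covariates) {
  res <- tryCatch({
    fml <- if (length(covariates) > 0) {
      stats::reformulate(covariates,
                         response = quote(survival::Surv(time, event)))
    } else {
      survival::Surv(time, event) ~ 1
    }
    sr <- survival::survreg(fml, data = as.data.frame(data),
                            dist = "weibull")
    p <- 1 / sr$scale
    b <- coef(sr)
    model_params(shape = p, scale = exp(-b[[1]] * p),
                 beta = if (length(covariates)) -b[-1] * p else numeric(0),
                 var_surgeon = 0.05, var_center = 0.05)
  }, error = function(e) NULL)
  res %||% model_params(shape = 1, scale = sum(data$event) / sum(data$time),
                        beta = setNames(rep(0, length(covariates)),
                                        covariates),
                        var_surgeon = 0.05, var_center = 0.05)
}

# Central finite-difference Hessian with per-coordinate step
# h_i = max(1e-4, 1e-4 * |x_i|).
fd_hessian <- function(f, x) {
  p <- length(x)
  h <- pmax(1e-4, 1e-4 * abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

#' @export
print.hiersurv_fit <- function(x, ...) {
  cat("Three-level Weibull PH mixed model\n")
  cat(sprintf("  n = %d subjects, %d surgeons, %d centers\n",
              x$n, x$S, x$K))
  cat(sprintf("  log-likelihood: %.4f   converged: %s\n",
              x$loglik, x$convergence$converged))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fitted three-level survival model
#'
#' @param x A `hiersurv_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (natural scale), `std.error`
#'   (delta method from the transformed-scale covariance; `NA` when the
#'   covariance is unavailable or the term was fixed).
#' @method tidy hiersurv_fit
#' @export
tidy.hiersurv_fit <- function(x, ...) {
  est_t <- x$estimate_trans
  se_t <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else
    rep(NA_real_, length(est_t))
  is_log <- x$transform$transform == "log"
  natural <- ifelse(is_log, exp(est_t), est_t)
  se_nat <- ifelse(is_log, natural * se_t, se_t)
  term <- sub("^log_", "", x$transform$term)
  term <- sub("^beta_", "", term)
  out <- tibble(term = term, estimate = unname(natural),
                std.error = unname(se_nat))
  for (lev in c("surgeon", "center")) {
    if (!is.na(x$fixed[[lev]])) {
      out <- dplyr::bind_rows(out, tibble(
        term = paste0("var_", lev), estimate = x$fixed[[lev]],
        std.error = NA_real_))
    }
  }
  out
}

#' Glance at a fitted three-level survival model
#'
#' @param x A `hiersurv_fit`.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `AIC`, `nobs`, `n_surgeons`,
#'   `n_centers`, `converged`.
#' @method glance hiersurv_fit
#' @export
glance.hiersurv_fit <- function(x, ...) {
  npar <- length(x$estimate_trans)
  tibble(logLik = x$loglik, AIC = 2 * npar - 2 * x$loglik, nobs = x$n,
         n_surgeons = x$S, n_centers = x$K,
         converged = x$convergence$converged)
}

#' Serialize a fitted model to JSON
#'
#' The JSON carries everything downstream stages consume: natural-scale
#' parameters, the transformed-scale estimates, transform map, covariance
#' matrix, log-likelihood, convergence information and covariate names.
#'
#' @param fit A `hiersurv_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    params = list(shape = fit$params$shape, scale = fit$params$scale,
                  beta = as.list(fit$params$beta),
                  var_surgeon = fit$params$var_surgeon,
                  var_center = fit$params$var_center),
    estimate_trans = as.list(fit$estimate_trans),
    transform = fit$transform,
    vcov = fit$vcov,
    loglik = fit$loglik,
    fixed = fit$fixed,
    nodes = fit$nodes,
    convergence = fit$convergence[c("converged", "optim_code", "vcov_ok")],
    n = fit$n, K = fit$K, S = fit$S,
    covariates = fit$covariates
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return A `hiersurv_fit`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$params$beta) %||% numeric(0)
  fit <- list(
    params = model_params(obj$params$shape, obj$params$scale, beta,
                          obj$params$var_surgeon, obj$params$var_center),
    loglik = obj$loglik,
    estimate_trans = unlist(obj$estimate_trans),
    vcov = if (!is.null(obj$vcov)) as.matrix(obj$vcov) else NULL,
    transform = as_tibble(obj$transform),
    fixed = list(surgeon = obj$fixed$surgeon %||% NA,
                 center = obj$fixed$center %||% NA),
    nodes = obj$nodes,
    convergence = c(obj$convergence,
                    list(counts = NULL)),
    n = obj$n, K = obj$K, S = obj$S,
    covariates = obj$covariates %||% character(0)
  )
  structure(fit, class = "hiersurv_fit")
}
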