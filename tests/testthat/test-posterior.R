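test_that("the unnormalized posterior normalizes to the cluster likelihood", {
  d <- toy_one_cluster()
  p <- toy_params()
  fit <- fake_fit(p)
  gr <- seq(-4, 4, length.out = 161)
  h <- gr[2] - gr[1]
  lp <- outer(gr, gr, Vectorize(function(a, g)
    log_posterior_density(fit, d, "A", g, a)))
  mx <- max(lp)
  logint <- mx + log(sum(exp(lp - mx)) * h * h)
  # integral of the unnormalized posterior = cluster marginal likelihood
  expect_lt(abs(exp(logint - cluster_loglik(p, d)) - 1), 1e-6)
})

test_that("posterior density input validation and tail behaviour", {
  d <- toy_one_cluster()
  fit <- fake_fit(toy_params())
  expect_error(log_posterior_density(fit, d, "A", 0, c(0, 0)),
               class = "mlsurvstd_config_error")
  # Gaussian prior dominates in the tails: decreasing in |gamma|
  v <- vapply(c(3, 5, 8), function(g)
    log_posterior_density(fit, d, "A", g, 0), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("EB means and SDs match dense 2-D grid integration", {
  d <- toy_one_cluster()
  p <- toy_params()
  fit <- fake_fit(p)
  gor <- grid_cluster_loglik(d, p, lim = 4, m = 1501)
  w <- exp(gor$lp - max(gor$lp))
  w <- w / sum(w)
  gr <- gor$grid
  ma <- sum(rowSums(w) * gr)
  sa <- sqrt(sum(rowSums(w) * gr^2) - ma^2)
  mg <- sum(colSums(w) * gr)
  sg <- sqrt(sum(colSums(w) * gr^2) - mg^2)
  ea <- eb_mean(fit, d, "s1", "surgeon")
  eg <- eb_mean(fit, d, "A", "center")
  expect_lt(abs(ea$estimate - ma), 1e-4)
  expect_lt(abs(ea$sd - sa), 1e-4)
  expect_lt(abs(eg$estimate - mg), 1e-4)
  expect_lt(abs(eg$sd - sg), 1e-4)
})

test_that("EB means match self-normalized importance sampling", {
  d <- toy_one_cluster()
  p <- toy_params()
  fit <- fake_fit(p)
  X <- as.matrix(d[, "x1", drop = FALSE])
  B <- 200000
  withr::with_seed(31, {
    a <- rnorm(B, 0, sqrt(p$var_surgeon))
    g <- rnorm(B, 0, sqrt(p$var_center))
  })
  lw <- rep(0, B)
  for (i in seq_len(nrow(d))) {   # vectorized over draws, per subject
    lw <- lw + subject_loglik(p, rep(d$time[i], B), rep(d$event[i], B),
                              matrix(X[i, ], B, 1, byrow = TRUE), a, g)
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  est_is <- sum(w * a)
  # block-wise SE of the IS estimate
  blocks <- split(seq_len(B), rep(1:20, length.out = B))
  bl <- vapply(blocks, function(ix) sum(w[ix] * a[ix]) / sum(w[ix]),
               numeric(1))
  se <- sd(bl) / sqrt(20)
  ea <- eb_mean(fit, d, "s1", "surgeon")
  expect_lt(abs(ea$estimate - est_is), 3 * se)
})

test_that("a cluster without data keeps its prior", {
  d <- toy_one_cluster()
  fit <- fake_fit(toy_params())
  em <- eb_mean(fit, d, "ghost", "surgeon")
  expect_equal(em$estimate, 0)
  expect_equal(em$sd, sqrt(0.15))
  mm <- eb_mode(fit, d, "ghost", "center")
  expect_equal(mm$estimate, 0)
})

test_that("posterior uncertainty shrinks below the prior with data", {
  d <- toy_one_cluster()
  fit <- fake_fit(toy_params())
  ea <- eb_mean(fit, d, "s1", "surgeon")
  eg <- eb_mean(fit, d, "A", "center")
  expect_lt(ea$sd, sqrt(0.15))
  expect_lt(eg$sd, sqrt(0.2))
})

test_that("mean and mode converge as the cluster grows", {
  # surgeon variance 0 so the center offset is the identified quantity
  # (with both levels free only the sum alpha + gamma is identified and
  # the center-effect posterior SD floors at the prior partition)
  p <- model_params(1.3, 0.4, c(x1 = 0.5), var_surgeon = 0,
                    var_center = 0.1)
  fit <- fake_fit(p)
  make_cluster <- function(I, seed) {
    cfg <- sim_config(K = 1, surgeons_per_center = 1,
                      patients_per_surgeon = I, shape = p$shape,
                      scale = p$scale, beta = p$beta,
                      var_surgeon = 0, var_center = 0,
                      covariates = list(x1 = list(type = "normal",
                                                  mean = 0, sd = 1)),
                      censor_horizon = 30, censor_rate = 0)
    simulate_survdata(cfg, seed = seed)
  }
  d_small <- make_cluster(10, 41)
  d_big <- make_cluster(1000, 41)
  sd_small <- eb_mean(fit, d_small, "c01", "center")$sd
  sd_big <- eb_mean(fit, d_big, "c01", "center")$sd
  expect_lt(sd_big, sd_small)
  expect_lt(sd_big, 0.05)
  eb <- eb_mean(fit, d_big, "c01", "center")
  # posterior concentrates at the fixed-effect MLE of the offset
  X <- as.matrix(d_big[, "x1", drop = FALSE])
  mle <- log(sum(d_big$event) /
               sum(p$scale * d_big$time^p$shape * exp(0.5 * d_big$x1)))
  expect_lt(abs(eb$estimate - mle), 0.05)
  mb <- eb_mode(fit, d_big, "c01", "center")
  expect_lt(abs(mb$estimate - eb$estimate), 0.02 * eb$sd + 1e-6)
})

test_that("shrinkage increases for smaller clusters with identical data", {
  base <- data.frame(time = c(0.3, 0.5, 0.8, 1.1, 0.6),
                     event = c(1, 1, 1, 0, 1), x1 = c(0.2, -0.4, 0.1, 0.7,
                                                      -0.2))
  big <- base[rep(1:5, 10), ]   # 50 subjects, same per-subject data
  df <- rbind(cbind(base, surgeon = "small", center = "A"),
              cbind(big, surgeon = "large", center = "B"))
  d <- as_survdata(df, covariates = "x1")
  fit <- fake_fit(toy_params(var_surgeon = 0.1, var_center = 1e-8))
  es <- eb_mean(fit, d, "small", "surgeon")
  el <- eb_mean(fit, d, "large", "surgeon")
  expect_lt(abs(es$estimate), abs(el$estimate))
  expect_gt(abs(el$estimate), 0.01)  # informative data moves the prediction
})

test_that("predict_ranef returns coherent rankings at both levels", {
  d <- simulate_survdata(small_sim_config(K = 6, J = 2, I = 15), seed = 37)
  fit <- fit_hiersurv(d)
  eb <- predict_ranef(fit, d)
  expect_equal(sum(eb$level == "center"), 6)
  expect_equal(sum(eb$level == "surgeon"), 12)
  expect_true(all(eb$sd >= 0))
  # ranks are a permutation within level, ordered by estimate
  for (lev in c("center", "surgeon")) {
    sub <- eb[eb$level == lev, ]
    expect_setequal(sub$rank, seq_len(nrow(sub)))
    expect_equal(sub$cluster[order(sub$rank)],
                 sub$cluster[order(sub$estimate, sub$cluster)])
  }
  # best/worst bookkeeping matches the ranks
  expect_equal(unname(attr(eb, "best")[["center"]]),
               eb$cluster[eb$level == "center" & eb$rank == 1])
  # ranking is invariant to relabeling
  d2 <- d
  d2$center <- paste0("x", d2$center)
  d2$surgeon <- paste0("x", d2$surgeon)
  d2 <- as_survdata(as.data.frame(d2), covariates = "x1")
  eb2 <- predict_ranef(fit, d2)
  expect_equal(paste0("x", eb$cluster[order(eb$level, eb$rank)]),
               eb2$cluster[order(eb2$level, eb2$rank)])
})

test_that("null data produce predictions consistent with zero effects", {
  d <- simulate_survdata(small_sim_config(K = 8, J = 2, I = 20,
                                          var_surgeon = 0, var_center = 0),
                         seed = 43)
  fit <- fake_fit(model_params(1.2, 0.1, c(x1 = 0.5), 0.01, 0.01))
  eb <- predict_ranef(fit, d)
  expect_true(all(abs(eb$estimate) < 3 * eb$sd + 1e-8))
  # center-level EB means average out near zero
  cen <- eb[eb$level == "center", ]
  expect_lt(abs(mean(cen$estimate)), 3 * mean(cen$sd))
})

test_that("modes agree with means on near-quadratic posteriors", {
  # large balanced cluster: posterior ~ Gaussian, mode ~ mean
  d <- simulate_survdata(small_sim_config(K = 1, J = 3, I = 200,
                                          var_surgeon = 0.05,
                                          var_center = 0.05), seed = 47)
  fit <- fake_fit(model_params(1.2, 0.1, c(x1 = 0.5), 0.05, 0.05))
  em <- predict_ranef(fit, d, method = "mean")
  eo <- predict_ranef(fit, d, method = "mode")
  expect_equal(em$cluster, eo$cluster)
  expect_true(all(abs(em$estimate - eo$estimate) <
                    0.02 * em$sd + 1e-6))
})
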