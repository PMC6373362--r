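test_that("linear-Gaussian inversion matches the conjugate closed form", {
  set.seed(11)
  for (rep in 1:5) {
    inst <- lg_instance(p = 4, n = 20, s2 = 0.4)
    prior <- list(mean = inst$m0, cov = inst$S0)
    g <- function(th) drop(inst$X %*% th)
    # noise precision fixed at its true value (zero-variance hyperprior)
    fit <- vl_fit(inst$y, g, prior,
                  hyper = list(mean = log(1 / inst$s2), var = 0),
                  control = list(tol = 1e-8, max_iter = 200))
    oracle <- lg_posterior(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
    expect_equal(unname(fit$mean), oracle$mean, tolerance = 1e-6)
    expect_equal(unname(fit$cov), oracle$cov, tolerance = 1e-6)
    # at the optimum the free energy equals the analytic log evidence
    lev <- lg_log_evidence(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
    expect_equal(fit$free_energy, lev, tolerance = 1e-6)
  }
})

test_that("free energy decomposes with zero complexity at the prior", {
  set.seed(3)
  inst <- lg_instance(p = 3, n = 10)
  g <- function(th) drop(inst$X %*% th)
  prior <- list(mean = inst$m0, cov = inst$S0)
  fe <- sipeb:::vl_free_energy(inst$y, g, prior, q_mean = inst$m0,
                               q_cov = inst$S0,
                               lambda = log(1 / inst$s2))
  expect_equal(fe$complexity, 0, tolerance = 1e-8)
  expect_equal(fe$F, fe$accuracy - fe$complexity)

  # complexity is a KL divergence: non-negative for any q
  for (rep in 1:10) {
    qm <- inst$m0 + rnorm(3, 0, 0.5)
    qc <- diag(runif(3, 0.05, 1.5))
    fe2 <- sipeb:::vl_free_energy(inst$y, g, prior, qm, qc,
                                  lambda = log(1 / inst$s2))
    expect_gte(fe2$complexity, 0)
    expect_equal(fe2$F, fe2$accuracy - fe2$complexity)
  }

  expect_error(sipeb:::vl_free_energy(inst$y, g, prior, inst$m0,
                                      diag(c(1, -1, 1)),
                                      lambda = log(1 / inst$s2)),
               "positive definite")
})

test_that("widening the prior on an unsupported parameter cannot raise the evidence", {
  set.seed(21)
  n <- 30
  X <- cbind(rnorm(n), 0) # second parameter has no data support
  y <- drop(X %*% c(0.8, 0)) + rnorm(n, 0, 0.5)
  ev <- vapply(c(0.1, 0.5, 2, 8), function(v) {
    lg_log_evidence(y, X, c(0, 0), diag(c(0.5, v)), 0.25)
  }, numeric(1))
  # occam: flat in the unused direction (exactly, for an orthogonal design)
  expect_true(all(diff(ev) <= 1e-8))
  # and the fitted F shows the same flatness
  f <- vapply(c(0.1, 2), function(v) {
    vl_fit(y, function(th) drop(X %*% th),
           list(mean = c(0, 0), cov = diag(c(0.5, v))),
           hyper = list(mean = log(4), var = 0),
           control = list(tol = 1e-8))$free_energy
  }, numeric(1))
  expect_equal(f[1], f[2], tolerance = 1e-5)
})

test_that("DCM self-consistency: noiseless data from the prior mean stays at the prior mean", {
  spec <- tiny_spec(2, n_volumes = 32)
  prior <- dcm_priors(spec)
  params0 <- sipeb:::theta_to_params(prior$mean, spec)
  sim <- simulate_bold(params0, spec, noise_sd = 0)
  fit <- dcm_fit(sim, spec, prior, control = list(max_iter = 16))
  expect_lt(max(abs(fit$mean - prior$mean)), 0.05)
  expect_true(all(diff(fit$F_trace) >= 0))
})

test_that("posterior credible intervals cover true couplings near unit SNR", {
  # parameter recovery on a 3-node chain, 20 repetitions
  spec <- tiny_spec(3, n_volumes = 48)
  a_true <- matrix(0, 3, 3)
  a_true[2, 1] <- 0.5
  a_true[3, 2] <- 0.4
  cm <- matrix(c(1, 0, 0), 3, 1)
  p <- dcm_params(spec, a = a_true, c = cm)
  clean <- simulate_bold(p, spec)
  snr_sd <- mean(apply(clean$y, 2, sd)) # noise at the signal scale: SNR ~ 1
  prior <- dcm_priors(spec)
  covered <- total <- 0
  for (rep in 1:20) {
    sim <- simulate_bold(p, spec, noise_sd = snr_sd, seed = 1000 + rep)
    fit <- dcm_fit(sim, spec, prior, control = list(max_iter = 32))
    for (lab in c("A(2,1)", "A(3,2)")) {
      k <- match(lab, names(fit$mean))
      ci <- fit$mean[k] + c(-1, 1) * qnorm(0.95) * sqrt(fit$cov[k, k])
      truth <- if (lab == "A(2,1)") 0.5 else 0.4
      covered <- covered + (truth >= ci[1] && truth <= ci[2])
      total <- total + 1
    }
  }
  # 90% intervals should cover in the large majority of cases
  expect_gte(covered / total, 0.7)
})

test_that("shrinking the prior variance pulls the posterior coupling toward zero", {
  spec <- tiny_spec(2, n_volumes = 48)
  a <- matrix(0, 2, 2)
  a[2, 1] <- 0.6
  p <- dcm_params(spec, a = a, c = matrix(c(1, 0), 2, 1))
  sim <- simulate_bold(p, spec, noise_sd = 0.5, seed = 77)
  est <- vapply(c(0.5, 0.3, 0.1, 0.02), function(v) {
    fit <- dcm_fit(sim, spec, dcm_priors(spec, sigma_a = v))
    fit$mean[["A(2,1)"]]
  }, numeric(1))
  expect_true(all(diff(abs(est)) <= 1e-6)) # monotone shrinkage
  expect_gt(abs(est[1]), abs(est[4]))
})

test_that("drift confounds are projected out of data and model alike", {
  spec <- tiny_spec(2, n_volumes = 48)
  a <- matrix(0, 2, 2); a[2, 1] <- 0.5
  p <- dcm_params(spec, a = a, c = matrix(c(1, 0), 2, 1))
  sim <- simulate_bold(p, spec, noise_sd = 0.4, seed = 31)
  fit0 <- dcm_fit(sim, spec)

  # add a strong linear drift and declare it as a confound
  drift <- scale(seq_len(spec$n_volumes))
  drifted <- sim
  drifted$y <- sim$y + drift %*% t(c(3, -2))
  drifted$confound_basis <- cbind(1, drift)
  fitc <- dcm_fit(drifted, spec)
  expect_lt(abs(fitc$mean[["A(2,1)"]] - fit0$mean[["A(2,1)"]]), 0.1)

  # without the confound declaration the drift corrupts the fit badly
  plain <- sim
  plain$y <- drifted$y
  fitp <- dcm_fit(plain, spec)
  expect_gt(sd(residuals(fitp)), sd(residuals(fitc)))
})
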