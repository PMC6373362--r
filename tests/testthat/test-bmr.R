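test_that("reducing to the identical prior changes nothing", {
  set.seed(5)
  inst <- lg_instance()
  post <- lg_posterior(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
  full <- fake_posterior(post$mean, post$cov, inst$m0, inst$S0)
  red <- bmr_reduce(full, list(mean = full$prior$mean, cov = inst$S0))
  expect_equal(red$delta_F, 0, tolerance = 1e-9)
  expect_equal(unname(red$mean), post$mean, tolerance = 1e-9)
  expect_equal(red$cov, post$cov, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("one-dimensional reduction matches the conjugate evidence ratio", {
  # y ~ N(theta, s2), theta ~ N(0, v): evidence is N(y; 0, v + s2)
  y <- 1.3; s2 <- 0.5; v_full <- 1.0; v_red <- 0.2
  post_var <- 1 / (1 / v_full + 1 / s2)
  post_mean <- post_var * y / s2
  full <- fake_posterior(post_mean, post_var, 0, v_full)
  red <- bmr_reduce(full, list(mean = 0, cov = matrix(v_red)))
  oracle <- dnorm(y, 0, sqrt(v_red + s2), log = TRUE) -
    dnorm(y, 0, sqrt(v_full + s2), log = TRUE)
  expect_equal(red$delta_F, oracle, tolerance = 1e-10)
  # and the reduced posterior matches direct conjugate updating
  expect_equal(unname(red$mean), (1 / (1 / v_red + 1 / s2)) * y / s2,
               tolerance = 1e-8)
})

test_that("analytic reduction equals direct evidence ratios on random linear-Gaussian problems", {
  set.seed(42)
  worst <- 0
  for (rep in 1:120) {
    p <- sample(2:8, 1)
    inst <- lg_instance(p = p, n = p + sample(3:10, 1), s2 = runif(1, 0.2, 1))
    post <- lg_posterior(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
    full <- fake_posterior(post$mean, post$cov, inst$m0, inst$S0)
    # random perturbation of the prior (means and variances)
    m0R <- inst$m0 + rnorm(p, 0, 0.3)
    S0R <- diag(diag(inst$S0) * runif(p, 0.3, 1.2), p)
    red <- bmr_reduce(full, list(mean = m0R, cov = S0R))
    oracle <- lg_log_evidence(inst$y, inst$X, m0R, S0R, inst$s2) -
      lg_log_evidence(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
    worst <- max(worst, abs(red$delta_F - oracle))
    # reduced posterior agrees with re-estimation under the reduced prior
    reref <- lg_posterior(inst$y, inst$X, m0R, S0R, inst$s2)
    expect_equal(unname(red$mean), reref$mean, tolerance = 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("pinning a truly absent parameter is rewarded; log evidences chain additively", {
  set.seed(8)
  inst <- lg_instance(p = 3, n = 40, s2 = 0.3)
  # make the third parameter truly zero and regenerate data
  theta <- inst$theta; theta[3] <- 0
  inst$y <- drop(inst$X %*% theta) + rnorm(40, 0, sqrt(inst$s2))
  post <- lg_posterior(inst$y, inst$X, inst$m0 * 0, inst$S0, inst$s2)
  full <- fake_posterior(post$mean, post$cov, inst$m0 * 0, inst$S0)
  pinned <- diag(inst$S0)
  pinned[3] <- 0 # exact switch-off
  red <- bmr_reduce(full, list(mean = rep(0, 3), cov = diag(pinned, 3)))
  expect_gt(red$delta_F, 0)
  expect_lt(abs(red$mean[3]), 1e-6)

  # chaining: A->B then B->C sums to A->C (shared full posterior)
  SB <- diag(c(0.8, 0.5, 0.4) * diag(inst$S0), 3)
  SC <- diag(c(0.5, 0.3, 0.2) * diag(inst$S0), 3)
  dAB <- bmr_reduce(full, list(mean = rep(0, 3), cov = SB))$delta_F
  fullB <- fake_posterior(post$mean, post$cov, rep(0, 3), inst$S0)
  dAC <- bmr_reduce(fullB, list(mean = rep(0, 3), cov = SC))$delta_F
  # additivity of log evidence ratios: dF(A->C) = dF(A->B) + dF(B->C)
  postB <- lg_posterior(inst$y, inst$X, rep(0, 3), SB, inst$s2)
  fullB2 <- fake_posterior(postB$mean, postB$cov, rep(0, 3), SB)
  dBC <- bmr_reduce(fullB2, list(mean = rep(0, 3), cov = SC))$delta_F
  expect_equal(dAB + dBC, dAC, tolerance = 1e-8)
})

test_that("an over-relaxed reduced prior is rejected with a diagnostic", {
  full <- fake_posterior(c(0.2, 0.1), diag(c(1, 1)), c(0, 0),
                         diag(c(0.1, 0.1)))
  expect_error(bmr_reduce(full, list(mean = c(0, 0), cov = diag(c(100, 100)))),
               "not positive definite")
})

test_that("batch scoring is permutation-equivariant and failure-tolerant", {
  set.seed(13)
  inst <- lg_instance(p = 3, n = 20)
  post <- lg_posterior(inst$y, inst$X, inst$m0, inst$S0, inst$s2)
  full <- fake_posterior(post$mean, post$cov, inst$m0, inst$S0)
  priors <- list(
    list(mean = inst$m0, cov = inst$S0), # identity entry
    list(mean = rep(0, 3), cov = 0.5 * inst$S0),
    list(mean = rep(0, 3), cov = 0.25 * inst$S0)
  )
  dF <- score_model_set(full, priors)
  expect_equal(dF[1], 0, tolerance = 1e-9)
  perm <- c(3, 1, 2)
  expect_equal(score_model_set(full, priors[perm]), dF[perm],
               tolerance = 1e-12, ignore_attr = TRUE)
  # a failing model is flagged, not fatal: an (approximate) posterior wider
  # than its prior cannot absorb a much wider reduced prior
  full_wide <- fake_posterior(rep(0.1, 3), diag(1, 3), rep(0, 3),
                              diag(0.5, 3))
  priors_w <- list(list(mean = rep(0, 3), cov = diag(0.5, 3)),
                   list(mean = rep(0, 3), cov = diag(0.25, 3)),
                   list(mean = rep(0, 3), cov = diag(1e4, 3)))
  dF2 <- score_model_set(full_wide, priors_w)
  expect_true(is.na(dF2[3]))
  expect_equal(dF2[1], 0, tolerance = 1e-9)
  expect_false(anyNA(dF2[1:2]))
  expect_match(attr(dF2, "errors")[3], "positive definite")
})

test_that("softmax converts log evidences to calibrated probabilities", {
  expect_equal(softmax_prob(c(4, 4)), c(0.5, 0.5))
  # a log Bayes factor of 3 is ~95% for the winner
  expect_equal(softmax_prob(c(0, 3))[2], 0.9526, tolerance = 1e-4)
  # the reported group-level margin corresponds to probability ~ 1
  expect_equal(softmax_prob(c(0, 15.52))[2], 1, tolerance = 1e-6)
  # invariance to additive constants; always a simplex element
  set.seed(2)
  for (rep in 1:20) {
    f <- rnorm(sample(2:12, 1), sd = 5)
    pr <- softmax_prob(f)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
    expect_equal(softmax_prob(f + 123.4), pr, tolerance = 1e-12)
  }
  expect_error(softmax_prob(numeric(0)), "empty")
})
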