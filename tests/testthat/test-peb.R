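# A-parameter table for hand-built posteriors (2 extrinsic connections)
toy_table <- function() {
  data.frame(type = 0L, i = c(2, 1), j = c(1, 2),
             label = c("A(2,1)", "A(1,2)"))
}

toy_fit <- function(mean, var, F = 0, prior_var = 0.5) {
  tab <- toy_table()
  fake_posterior(setNames(mean, tab$label), diag(var, 2),
                 rep(0, 2), diag(prior_var, 2), F = F, table = tab)
}

test_that("identical subjects pool to the common posterior mean", {
  fits <- replicate(4, toy_fit(c(0.4, -0.2), c(0.05, 0.05)),
                    simplify = FALSE)
  # a broad second-level prior removes shrinkage from the comparison
  tab <- toy_table()
  prior <- sipeb:::new_prior(setNames(rep(0, 2), paste0(tab$label, ":x1")),
                             diag(100, 2), tab)
  pm <- peb_fit(fits, prior = prior)
  # symmetry: the group mean is the common prior-removed subject mean
  # (removing the first-level shrinkage inflates 0.4 to 0.4*Pi/(Pi-P0))
  mt <- (0.4 / 0.05) / (1 / 0.05 - 1 / 0.5)
  expect_equal(unname(coef(pm)), c(mt, -mt / 2), tolerance = 0.01)
})

test_that("pooling is precision-weighted", {
  # subject 1 is 100x more precise on both connections
  f1 <- toy_fit(c(0.5, 0.5), c(0.001, 0.001))
  f2 <- toy_fit(c(-0.5, -0.5), c(0.1, 0.1))
  pm <- peb_fit(list(f1, f2))
  # closed-form weighted average oracle (data precisions after removing the
  # shared prior, inflated by the estimated random effects)
  g <- pm$gamma$mean
  w1 <- 1 / (1 / (1 / 0.001 - 1 / 0.5) + exp(-g) * pm$Q[1, 1])
  w2 <- 1 / (1 / (1 / 0.1 - 1 / 0.5) + exp(-g) * pm$Q[1, 1])
  m1 <- (0.5 / 0.001) / (1 / 0.001 - 1 / 0.5)   # prior-removed subject means
  m2 <- (-0.5 / 0.1) / (1 / 0.1 - 1 / 0.5)
  oracle <- (w1 * m1 + w2 * m2) / (w1 + w2 + 1 / 0.5)
  expect_equal(unname(coef(pm)[1]), oracle, tolerance = 1e-6)
  # the precise subject pulls the group mean to its own sign, despite the
  # equally-sized opposite estimate (dominance is bounded by the random
  # effects, which floor every subject's marginal variance)
  expect_gt(unname(coef(pm)[1]), 0.1)
})

test_that("label mismatches and rank-deficient designs are hard errors", {
  f1 <- toy_fit(c(0.1, 0.1), c(0.1, 0.1))
  f2 <- f1
  names(f2$mean) <- c("A(3,1)", "A(1,2)")
  expect_error(peb_fit(list(f1, f2)), "labelling")
  expect_error(peb_fit(list(f1, toy_fit(c(0, 0), c(0.1, 0.1))),
                       design = matrix(c(1, 1, 2, 2), 2, 2)),
               "rank deficient")
  expect_error(peb_fit(list(f1)), "at least 2")
})

test_that("group posterior recovers a known group mean and random-effects scale", {
  set.seed(31)
  S <- 12
  true_group <- c(0.5, -0.3)
  true_re_sd <- 0.18
  obs_var <- 0.03
  reps <- lapply(1:3, function(r) {
    fits <- lapply(1:S, function(i) {
      th <- true_group + rnorm(2, 0, true_re_sd)
      # conjugate single-observation posterior per connection
      post_var <- 1 / (1 / 0.5 + 1 / obs_var)
      obs <- th + rnorm(2, 0, sqrt(obs_var))
      toy_fit(post_var * obs / obs_var, post_var)
    })
    peb_fit(fits)
  })
  for (pm in reps) {
    sds <- sqrt(diag(pm$beta_cov))
    # truth within 3 posterior sds
    expect_true(all(abs(coef(pm) - true_group) < 3 * sds + 0.05))
    # estimated between-subject variance within a factor ~2 of truth
    re_var <- mean(diag(pm$random_cov))
    expect_gt(re_var, true_re_sd^2 / 3)
    expect_lt(re_var, true_re_sd^2 * 3)
  }
})

test_that("the group free energy is internally consistent and penalises useless predictors", {
  set.seed(17)
  fits <- lapply(1:6, function(i)
    toy_fit(rnorm(2, 0.3, 0.1), c(0.05, 0.08)))
  pm <- peb_fit(fits)
  # recomputation from sufficient statistics reproduces the stored F
  fe <- group_free_energy(pm)
  expect_equal(fe$F, pm$free_energy, tolerance = 1e-6)
  expect_equal(fe$accuracy - fe$complexity, fe$F)
  expect_gte(fe$complexity, 0)

  # re-evaluating with the group posterior as second-level prior: the beta
  # complexity all but vanishes and the bound improves
  post_prior <- list(mean = pm$beta_mean, cov = pm$beta_cov,
                     labels = names(pm$beta_mean))
  fe2 <- group_free_energy(pm, prior = post_prior)
  expect_lt(fe2$complexity, fe$complexity)
  expect_gt(fe2$F, fe$F)

  # the KL term itself is exactly zero when q equals the prior
  expect_equal(sipeb:::gauss_kl(pm$beta_mean, pm$beta_cov, pm$beta_mean,
                                sipeb:::chol_inv(pm$beta_cov),
                                sipeb:::logdet(pm$beta_cov)),
               0, tolerance = 1e-8)
})

test_that("a nuisance covariate column does not inflate the group evidence", {
  set.seed(23)
  fits <- lapply(1:8, function(i) toy_fit(rnorm(2, 0.3, 0.1), c(0.05, 0.05)))
  pm1 <- peb_fit(fits)
  X2 <- cbind(1, scale(rnorm(8))) # random, irrelevant covariate
  pm2 <- peb_fit(fits, design = X2)
  expect_lte(pm2$free_energy, pm1$free_energy + 0.5)
})

test_that("empirical priors shrink subject-to-subject dispersion", {
  set.seed(41)
  fits <- lapply(1:10, function(i)
    toy_fit(rnorm(2, 0.4, 0.35), c(0.2, 0.2)))
  pm <- peb_fit(fits)
  refined <- peb_subject_posteriors(pm)
  spread_first <- apply(sapply(fits, function(f) f$mean), 1, sd)
  spread_refined <- apply(sapply(refined, function(f) f$mean), 1, sd)
  expect_true(all(spread_refined < spread_first))
})
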