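test_that("the sigmoid mapping evaluates and orders as expected", {
  h <- mapping_hyperparams(alpha = 0, delta = 0, sigma_max = 0.4)
  expect_equal(sigmoid_prior_variance(c(0, 0.3, 1), h), rep(0.2, 3))

  h2 <- mapping_hyperparams(alpha = 0.5, delta = 8, sigma_max = 0.5)
  expect_equal(sigmoid_prior_variance(1, h2), 0.5 / (1 + exp(-7.5)))
  expect_equal(sigmoid_prior_variance(1, h2), 0.5, tolerance = 1e-3)

  # strictly increasing in phi whenever delta > 0
  phis <- seq(0, 1, by = 0.1)
  v <- sigmoid_prior_variance(phis, h2)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < h2$sigma_max))

  expect_error(mapping_hyperparams(0, -1, 0.5), "delta")
  expect_error(mapping_hyperparams(0, 1, 0), "sigma_max")
})

test_that("the default lattice enumerates 405 mappings including 45 flat controls", {
  g <- mapping_grid()
  expect_equal(nrow(g), 405)
  expect_equal(length(unique(g$alpha)), 9)
  expect_equal(length(unique(g$delta)), 9)
  expect_equal(length(unique(g$sigma_max)), 5)
  expect_equal(sum(g$delta == 0), 45)
  expect_error(mapping_grid(alpha = numeric(0)), "empty")
})

test_that("informed priors rewrite extrinsic variances and pin forbidden pairs", {
  spec <- dcm_spec(3, tr = 4, n_volumes = 8)
  base <- dcm_priors(spec, sigma_a = 0.25)
  phi <- matrix(0, 3, 3)
  phi[1, 2] <- phi[2, 1] <- 1
  phi[1, 3] <- phi[3, 1] <- 0.5
  conn <- group_connectome(list(phi))

  # a flat mapping at sigma_max = 2 x base variance and alpha = 0 reproduces
  # the base prior on extrinsic entries
  flat <- build_informed_prior(conn, mapping_hyperparams(0, 0, 0.5), base)
  ext <- grepl("^A\\((\\d+),(\\d+)\\)$", base$labels) &
    !grepl("^A\\((\\d+),\\1\\)$", base$labels)
  expect_equal(diag(flat$cov)[ext], diag(base$cov)[ext], tolerance = 1e-12)
  # everything else untouched
  expect_equal(diag(flat$cov)[!ext], diag(base$cov)[!ext])

  # all-zero phi: uniform variance sigma_max / (1 + e^alpha)
  conn0 <- suppressWarnings(group_connectome(list(matrix(0, 3, 3))))
  h <- mapping_hyperparams(1, 8, 0.5)
  inf0 <- build_informed_prior(conn0, h, base)
  expect_equal(unique(round(diag(inf0$cov)[ext], 12)),
               round(0.5 / (1 + exp(1)), 12))

  # informed variances always lie strictly inside (0, sigma_max)
  set.seed(1)
  connr <- make_connectome(3, density = 1, seed = 2)
  for (rep in 1:10) {
    hr <- mapping_hyperparams(runif(1, -2, 2), runif(1, 0, 16),
                              runif(1, 0.1, 0.5))
    vr <- diag(build_informed_prior(connr, hr, base)$cov)[ext]
    expect_true(all(vr > 0 & vr < hr$sigma_max))
  }
})

test_that("masked pairs of the 12-node template are exactly pinned", {
  tpl <- bm_network_template()
  set.seed(4)
  M <- matrix(rexp(144), 12, 12, dimnames = list(tpl$labels, tpl$labels))
  conn <- group_connectome(list(symmetrize_counts(streamline_counts(M))),
                           forbidden_mask = tpl$forbidden_mask)
  spec <- dcm_spec(12, tr = 4, n_volumes = 8,
                   region_labels = tpl$labels)
  base <- dcm_priors(spec)
  inf <- build_informed_prior(conn, mapping_hyperparams(0.5, 8, 0.5), base)
  qr_ <- sipeb:::parse_A_label(base$labels)
  ext <- !is.na(qr_[, 1]) & qr_[, 1] != qr_[, 2]
  pinned <- diag(inf$cov) == 0
  expected <- ext & conn$forbidden_mask[qr_[, , drop = FALSE]]
  expected[is.na(expected)] <- FALSE
  expect_equal(sum(pinned), 10) # 5 undirected pairs = 10 directed entries
  expect_equal(unname(which(pinned)), which(expected))
})

test_that("grid search scores 405 models deterministically and flags the null margin", {
  set.seed(19)
  # hand-built group-level situation: 6 'subjects' with heterogeneous truth
  tab <- data.frame(type = 0L, i = c(2, 1, 3, 1, 3, 2),
                    j = c(1, 2, 1, 3, 2, 3),
                    label = c("A(2,1)", "A(1,2)", "A(3,1)", "A(1,3)",
                              "A(3,2)", "A(2,3)"))
  conn <- make_connectome(3, density = 1, seed = 3)
  h_true <- mapping_hyperparams(0.5, 8, 0.5)
  vtrue <- sigmoid_prior_variance(conn$phi[cbind(tab$i, tab$j)], h_true)
  beta <- rnorm(6, 0, sqrt(vtrue))
  fits <- lapply(1:6, function(i) {
    obs <- beta + rnorm(6, 0, 0.1)
    post_var <- 1 / (1 / 0.5 + 1 / 0.01)
    fake_posterior(setNames(post_var * (obs / 0.01), tab$label),
                   diag(post_var, 6), rep(0, 6), diag(0.5, 6), table = tab)
  })
  pm <- peb_fit(fits)
  gr <- sipeb_search(pm, conn)
  expect_equal(nrow(gr$models), 405)
  expect_equal(sum(gr$models$is_null), 45)
  expect_equal(sum(gr$models$post_prob), 1, tolerance = 1e-10)
  expect_equal(gr$best_relative_log_evidence, max(gr$models$delta_F))
  expect_true(gr$best_index %in% gr$ties)
  expect_equal(gr$informed_vs_null,
               max(gr$models$delta_F[!gr$models$is_null]) -
                 max(gr$models$delta_F[gr$models$is_null]))

  # pure function of its inputs: a second call is bit-identical
  gr2 <- sipeb_search(pm, conn)
  expect_identical(gr$models$delta_F, gr2$models$delta_F)

  pmats <- probability_matrices(gr)
  expect_length(pmats, 5)
  expect_equal(sum(vapply(pmats, sum, numeric(1))), 1, tolerance = 1e-10)
})

test_that("subject-level mapping application has the expected sign behaviour", {
  spec <- tiny_spec(2, n_volumes = 48)
  base <- dcm_priors(spec, sigma_a = 0.25)
  phi <- matrix(0, 2, 2)
  phi[1, 2] <- phi[2, 1] <- 1
  conn <- group_connectome(list(phi))

  a <- matrix(0, 2, 2)
  a[2, 1] <- 0.6
  a[1, 2] <- 0.4
  p <- dcm_params(spec, a = a, c = matrix(c(1, 0), 2, 1))
  sim <- simulate_bold(p, spec, noise_sd = 0.4, seed = 12)
  fit <- dcm_fit(sim, spec, base)

  # a mapping that reproduces the subject's own prior leaves the evidence
  # unchanged (flat sigmoid at twice the base variance)
  same <- apply_mapping_to_subject(fit, conn,
                                   mapping_hyperparams(0, 0, 0.5))
  # zero up to the conditioning of the estimated posterior covariance
  expect_equal(same$delta_F, 0, tolerance = 0.01)

  # aggressive shrinkage of strongly coupled data is penalised
  shrunk <- apply_mapping_to_subject(fit, conn,
                                     mapping_hyperparams(2, 0, 0.002))
  expect_lt(shrunk$delta_F, 0)
})
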