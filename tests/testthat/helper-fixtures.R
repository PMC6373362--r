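# Shared fixtures and independent oracles. Everything is generated in code;
# expensive cohort studies are memoised so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small DCM spec with a boxcar input driving region 1
tiny_spec <- function(n_regions = 2, n_volumes = 48, tr = 4,
                      microtime_bins = 16L) {
  total <- tr * n_volumes
  dcm_spec(n_regions, onsets = list(seq(24, total - 24, by = 48)),
           durations = list(24), tr = tr, n_volumes = n_volumes,
           microtime_bins = microtime_bins)
}

# random linear-Gaussian instance: y = X theta + e, e ~ N(0, s2 I),
# theta ~ N(m0, S0) with diagonal S0
lg_instance <- function(p = 4, n = 12, s2 = 0.5) {
  X <- matrix(rnorm(n * p), n, p)
  m0 <- rnorm(p, 0, 0.3)
  v0 <- runif(p, 0.1, 2)
  theta <- rnorm(p, m0, sqrt(v0))
  y <- drop(X %*% theta) + rnorm(n, 0, sqrt(s2))
  list(X = X, y = y, m0 = m0, S0 = diag(v0, p), s2 = s2, theta = theta)
}

# closed-form log evidence of a linear-Gaussian model (oracle)
lg_log_evidence <- function(y, X, m0, S0, s2) {
  C <- X %*% S0 %*% t(X) + diag(s2, length(y))
  R <- chol(C)
  d <- backsolve(R, y - drop(X %*% m0), transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(d^2)
}

# closed-form posterior of the same model (oracle)
lg_posterior <- function(y, X, m0, S0, s2) {
  P <- solve(S0) + crossprod(X) / s2
  C <- solve(P)
  m <- drop(C %*% (solve(S0, m0) + crossprod(X, y) / s2))
  list(mean = m, cov = C)
}

# posterior-like object accepted by peb_fit / bmr_reduce
fake_posterior <- function(mean, cov, prior_mean, prior_cov, F = 0,
                           table = NULL) {
  labels <- names(mean) %||% paste0("A(", seq_along(mean), ",0)")
  names(mean) <- labels
  prior <- list(mean = setNames(prior_mean, labels),
                cov = as.matrix(prior_cov), labels = labels, table = table)
  list(mean = mean, cov = as.matrix(cov), free_energy = F, prior = prior)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one recovery repetition: cohort -> inversions -> PEB -> grid search (and
# the per-subject application of the true mapping). The reduced volume count
# keeps a repetition around a minute.
recovery_run <- function(seed, true_mapping = mapping_hyperparams(0.5, 8, 0.5),
                         n_volumes = 48) {
  co <- suppressMessages(make_cohort(cohort_spec(
    seed = seed, n_volumes = n_volumes, true_mapping = true_mapping)))
  fits <- fit_cohort(co)
  pm <- peb_fit(fits)
  gr <- sipeb_search(pm, co$truth$connectome)
  sub_dF <- vapply(fits, function(f)
    apply_mapping_to_subject(f, co$truth$connectome,
                             mapping_hyperparams(0.5, 8, 0.5))$delta_F,
    numeric(1))
  list(grid = gr, subject_dF = sub_dF, truth = co$truth)
}

recovery_study <- function(seeds, null_gen = FALSE) {
  key <- paste0("recovery_", if (null_gen) "null_" else "true_",
                paste(seeds, collapse = "-"))
  cached(key, lapply(seeds, function(s) {
    recovery_run(seed = s,
                 true_mapping = if (null_gen) mapping_hyperparams(0, 0, 0.5)
                 else mapping_hyperparams(0.5, 8, 0.5))
  }))
}
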