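# Synthetic fixtures and cohorts: structural matrices, group and subject
# effective connectivity drawn under a known sigmoid mapping, and simulated
# BOLD — everything needed to exercise the full pipeline with known ground
# truth. All randomness flows from a single cohort seed through named
# sub-streams, so e.g. changing only the noise level leaves the structural
# fixtures and connectivity ground truth bit-identical.

#' Generate a random structural connectome
#'
#' Symmetric non-negative matrix with a given fraction of nonzero pairs.
#' Nonzero strengths are drawn from an exponential distribution (streamline
#' counts are heavy-tailed: many weak connections, few strong ones) and the
#' matrix is max-scaled so the strongest connection equals 1.
#'
#' @param n_regions number of nodes.
#' @param density fraction of region pairs with a nonzero connection, in
#'   (0, 1].
#' @param seed integer seed (mandatory; output is deterministic given it).
#' @param labels optional node names.
#' @param forbidden_mask optional logical matrix of pairs excluded a priori.
#' @return a \code{connectome} object.
#' @export
make_connectome <- function(n_regions, density = 0.8, seed, labels = NULL,
                            forbidden_mask = NULL) {
  if (density <= 0 || density > 1) stopf("density must be in (0, 1]")
  set.seed(seed)
  N <- n_regions
  M <- matrix(0, N, N)
  ut <- which(upper.tri(M))
  on <- runif(length(ut)) < density
  M[ut[on]] <- rexp(sum(on))
  M <- M + t(M)
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  group_connectome(list(M), forbidden_mask = forbidden_mask)
}

#' Draw a group-mean connectivity matrix under a sigmoid mapping
#'
#' Each allowed extrinsic entry is drawn from a zero-mean Gaussian whose
#' variance is the sigmoid of the corresponding structural strength; when
#' \code{delta > 0}, squared couplings therefore regress positively on
#' \eqn{\varphi}. Forbidden pairs and the diagonal are 0.
#'
#' @param connectome a \code{connectome}.
#' @param h a [mapping_hyperparams()] object (the true mapping).
#' @param seed integer seed.
#' @return N x N numeric matrix (diagonal zero).
#' @export
sample_group_A <- function(connectome, h, seed) {
  set.seed(seed)
  N <- nrow(connectome$phi)
  A <- matrix(0, N, N)
  allowed <- !connectome$forbidden_mask & !diag(TRUE, N)
  sds <- sqrt(sigmoid_prior_variance(connectome$phi[allowed], h))
  A[allowed] <- rnorm(sum(allowed), 0, sds)
  dimnames(A) <- dimnames(connectome$phi)
  A
}

# largest real part of the effective connectivity spectrum (self entries at
# their log-scale value, here 0 -> -0.5 Hz)
spectral_abscissa <- function(A) {
  Aeff <- A
  diag(Aeff) <- -0.5 * exp(diag(A) * 0) # ground-truth self-scaling is 0
  max(Re(eigen(Aeff, only.values = TRUE)$values))
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the emulated study design: 12 subjects, TR = 4 s, 114
#' volumes per session, driving input to region 1 in alternating stimulation
#' blocks after a 24 s baseline, and a true mapping with alpha = 0.5,
#' delta = 8, sigma_max = 0.5. The between-subject standard deviation
#' defaults to \code{sqrt(0.5/16)} (random-effects variance 1/16 of the
#' maximal prior variance) and the observation noise to 0.5 percent signal,
#' putting the simulated data near unit signal-to-noise.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_regions number of regions.
#' @param true_mapping a [mapping_hyperparams()] object; \code{delta = 0}
#'   generates structure-independent connectivity.
#' @param between_subject_sd sd of the between-subject random effects on
#'   allowed extrinsic connections (Hz).
#' @param noise_sd observation noise sd (percent signal).
#' @param tr,n_volumes,microtime_bins acquisition timing.
#' @param seed mandatory integer master seed.
#' @param density connectome density passed to [make_connectome()].
#' @param forbidden_mask optional exclusion mask for the connectome.
#' @param c_value driving-input strength into region 1.
#' @param region_labels optional node names.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 12, n_regions = 5,
                        true_mapping = mapping_hyperparams(0.5, 8, 0.5),
                        between_subject_sd = sqrt(0.5 / 16),
                        noise_sd = 0.5, tr = 4, n_volumes = 114,
                        microtime_bins = 16L, seed, density = 0.8,
                        forbidden_mask = NULL, c_value = 1,
                        region_labels = NULL) {
  if (missing(seed)) stopf("a cohort seed is mandatory")
  if (n_subjects < 2) stopf("need at least 2 subjects")
  stopifnot(between_subject_sd >= 0, noise_sd >= 0)
  structure(list(n_subjects = n_subjects, n_regions = n_regions,
                 true_mapping = true_mapping,
                 between_subject_sd = between_subject_sd,
                 noise_sd = noise_sd, tr = tr, n_volumes = n_volumes,
                 microtime_bins = as.integer(microtime_bins),
                 seed = as.integer(seed), density = density,
                 forbidden_mask = forbidden_mask, c_value = c_value,
                 region_labels = region_labels),
            class = "cohort_spec")
}

# default block design: 24 s baseline, then 24 s-on / 24 s-off stimulation
# (short sessions fall back to a single mid-session block)
cohort_onsets <- function(tr, n_volumes) {
  total <- tr * n_volumes
  on <- seq(24, by = 48, length.out = max(1, (total - 24) %/% 48))
  on <- on[on < total - 8]
  if (!length(on)) on <- total / 4
  list(onsets = list(on), durations = list(24))
}

#' Generate a synthetic cohort
#'
#' Draws the structural connectome, the group connectivity under the true
#' mapping, per-subject connectivity (group mean plus i.i.d. Gaussian random
#' effects on allowed extrinsic entries) and simulates each subject's BOLD.
#' Draws producing an unstable neuronal system are rejected and redrawn from
#' an incremented sub-seed (with a message); ground truth is returned
#' alongside the data.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class \code{cohort}: \code{datasets} (list of
#'   [bold_dataset()]), \code{spec} (the shared [dcm_spec()]), and
#'   \code{truth} (connectome, mapping, group and subject A matrices,
#'   seeds).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  conn <- make_connectome(spec$n_regions, spec$density,
                          seed = subseed(spec$seed, 1),
                          labels = spec$region_labels,
                          forbidden_mask = spec$forbidden_mask)
  timing <- cohort_onsets(spec$tr, spec$n_volumes)
  N <- spec$n_regions
  c_mask <- matrix(FALSE, N, 1)
  c_mask[1, 1] <- TRUE
  dspec <- dcm_spec(N, c_mask = c_mask, onsets = timing$onsets,
                    durations = timing$durations, tr = spec$tr,
                    n_volumes = spec$n_volumes,
                    microtime_bins = spec$microtime_bins,
                    region_labels = conn$region_labels)

  # group-mean connectivity: reject draws with an unstable spectrum
  k <- 0
  repeat {
    A2 <- sample_group_A(conn, spec$true_mapping, subseed(spec$seed, 2) + k)
    if (spectral_abscissa(A2) < -0.05) break
    k <- k + 1
    if (k > 200) stopf("could not find a stable group connectivity draw")
    if (k == 1) message("unstable group draw rejected; resampling")
  }

  allowed <- !conn$forbidden_mask & !diag(TRUE, N)
  cmat <- matrix(0, N, 1)
  cmat[1, 1] <- spec$c_value
  datasets <- vector("list", spec$n_subjects)
  subject_A <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    att <- 0
    repeat {
      set.seed(subseed(spec$seed, 100 + i) + att * 7919)
      Ai <- A2
      Ai[allowed] <- Ai[allowed] +
        rnorm(sum(allowed), 0, spec$between_subject_sd)
      if (spectral_abscissa(Ai) < -0.05) break
      att <- att + 1
      if (att > 200) stopf("subject %d: no stable connectivity draw", i)
      if (att == 1) message(sprintf(
        "subject %d: unstable draw rejected; resampling", i))
    }
    params <- dcm_params(dspec, a = Ai, c = cmat)
    datasets[[i]] <- simulate_bold(params, dspec,
                                   noise_sd = spec$noise_sd,
                                   seed = subseed(spec$seed, 500 + i))
    subject_A[[i]] <- Ai
  }
  structure(list(datasets = datasets, spec = dspec,
                 truth = list(connectome = conn,
                              mapping = spec$true_mapping,
                              group_A = A2, subject_A = subject_A,
                              seed = spec$seed,
                              between_subject_sd = spec$between_subject_sd,
                              noise_sd = spec$noise_sd),
                 cohort_spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cs <- x$cohort_spec
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d regions, TR %gs x %d volumes\n",
    cs$n_subjects, cs$n_regions, cs$tr, cs$n_volumes))
  cat(sprintf("  true mapping: alpha = %g, delta = %g, sigma_max = %g; RE sd %.3f; noise sd %.2f\n",
              cs$true_mapping$alpha, cs$true_mapping$delta,
              cs$true_mapping$sigma_max, cs$between_subject_sd, cs$noise_sd))
  invisible(x)
}

#' Invert every subject of a cohort
#'
#' Convenience wrapper running [dcm_fit()] on each dataset with a shared
#' specification and prior.
#'
#' @param cohort a [make_cohort()] result (or a list of [bold_dataset()]
#'   objects plus an explicit \code{spec}).
#' @param prior first-level prior (default [dcm_priors()] of the spec).
#' @param control passed to [dcm_fit()].
#' @return list of \code{dcmfit} objects.
#' @export
fit_cohort <- function(cohort, prior = NULL, control = list()) {
  spec <- cohort$spec
  prior <- prior %||% dcm_priors(spec)
  lapply(cohort$datasets, function(d) dcm_fit(d, spec, prior,
                                              control = control))
}
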