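# Bayesian model reduction: analytic evidence and posterior of a model that
# differs from an estimated ("full") model only in its priors. The Gaussian
# integral of the Savage-Dickey generalisation gives, with precisions
# Pq (posterior), P0 (full prior), P0R (reduced prior):
#   PqR = Pq + P0R - P0
#   dF  = 0.5 [ logdet Pq + logdet P0R - logdet P0 - logdet PqR ]
#       + 0.5 [ h' PqR^{-1} h - mq'Pq mq - m0R'P0R m0R + m0'P0 m0 ],
#   h   = Pq mq + P0R m0R - P0 m0.
# Pinned parameters (zero prior variance) are handled in precision space with
# a large-but-finite cap, matching "switched off entirely" semantics without
# special-casing exact zeros.

PIN_PRECISION_CAP <- 1e8

#' Strong-evidence threshold on the log Bayes factor
#'
#' A log Bayes factor of about 3 corresponds to roughly 95\% posterior
#' probability for one of two models; reporting code uses this as the
#' threshold for "strong evidence".
#'
#' @return the numeric threshold (3).
#' @export
strong_evidence_threshold <- function() 3

# covariance (possibly with exact-zero pinned diagonal entries) -> precision
cov_to_precision <- function(S) {
  S <- as.matrix(S)
  z <- diag(S) <= 1e-12
  if (any(z)) {
    S[z, ] <- 0
    S[, z] <- 0
    diag(S)[z] <- 1 / PIN_PRECISION_CAP
  }
  chol_inv(S)
}

bmr_core <- function(mq, Cq, m0, S0, m0R, S0R) {
  Pq <- cov_to_precision(Cq)
  P0 <- cov_to_precision(S0)
  P0R <- cov_to_precision(S0R)
  PqR <- sym_part(Pq + P0R - P0)
  R <- tryCatch(chol(PqR), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(PqR, symmetric = TRUE)
    worst <- which.max(abs(ev$vectors[, which.min(ev$values)]))
    stopf(paste0("implied reduced-posterior precision is not positive ",
                 "definite (worst parameter: %s); the reduced prior relaxes ",
                 "the full prior too far"),
          names(mq)[worst] %||% worst)
  }
  h <- drop(Pq %*% mq + P0R %*% m0R - P0 %*% m0)
  CqR <- chol2inv(R)
  mqR <- drop(CqR %*% h)
  ld <- function(P) 2 * sum(log(diag(chol(sym_part(P)))))
  dF <- 0.5 * (ld(Pq) + ld(P0R) - ld(P0) - 2 * sum(log(diag(R)))) +
    0.5 * (drop(crossprod(h, mqR)) - drop(crossprod(mq, Pq %*% mq)) -
             drop(crossprod(m0R, P0R %*% m0R)) +
             drop(crossprod(m0, P0 %*% m0)))
  names(mqR) <- names(mq)
  dimnames(CqR) <- dimnames(as.matrix(Cq))
  list(delta_F = dF, mean = mqR, cov = sym_part(CqR))
}

#' Reduce a fitted model under new priors (Bayesian model reduction)
#'
#' Computes, without re-inversion, the log evidence of a model identical to
#' the full one except for its priors, together with the reduced posterior.
#' The computation is a non-iterative Gaussian integral of the posterior and
#' the prior ratio.
#'
#' @param full a fitted object carrying a Gaussian posterior: a
#'   [dcm_fit()] result, a [peb_fit()] result, or a list with \code{mean},
#'   \code{cov} and \code{prior}.
#' @param reduced_prior prior of the reduced model (list with \code{mean},
#'   \code{cov}), over the same parameters as the full prior. Zero variance
#'   pins a parameter at its prior mean.
#' @param full_prior optionally override the prior stored in \code{full}.
#' @return an object of class \code{reduced_model}: \code{delta_F} (log
#'   evidence of reduced minus full), \code{mean}, \code{cov},
#'   \code{reduced_prior}.
#' @export
bmr_reduce <- function(full, reduced_prior, full_prior = NULL) {
  UseMethod("bmr_reduce")
}

#' @export
bmr_reduce.default <- function(full, reduced_prior, full_prior = NULL) {
  fp <- full_prior %||% full$prior
  if (is.null(fp)) stopf("no full prior available")
  if (!is.null(reduced_prior$labels) && !is.null(fp$labels) &&
      !identical(reduced_prior$labels, fp$labels))
    stopf("full and reduced priors are over different parameter labellings")
  out <- bmr_core(full$mean, full$cov, fp$mean, fp$cov,
                  reduced_prior$mean, reduced_prior$cov)
  out$reduced_prior <- reduced_prior
  class(out) <- "reduced_model"
  out
}

#' @export
bmr_reduce.peb <- function(full, reduced_prior, full_prior = NULL) {
  fp <- full_prior %||% full$prior
  out <- bmr_core(full$beta_mean, full$beta_cov, fp$mean, fp$cov,
                  reduced_prior$mean, reduced_prior$cov)
  out$reduced_prior <- reduced_prior
  class(out) <- "reduced_model"
  out
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf("Reduced model: delta-F = %.3f (%s the full model)\n",
              x$delta_F,
              if (x$delta_F > 0) "favoured over" else "disfavoured against"))
  invisible(x)
}

#' Score a set of reduced models
#'
#' Applies [bmr_reduce()] to each prior in a list; a failure for one model is
#' recorded (as \code{NA} with the message in the \code{errors} attribute)
#' rather than aborting the batch. Pure function of the full posterior/prior
#' and the reduced priors.
#'
#' @param full as in [bmr_reduce()].
#' @param reduced_priors list of priors.
#' @return numeric vector of log-evidence differences (reduced minus full),
#'   in input order.
#' @export
score_model_set <- function(full, reduced_priors) {
  if (length(reduced_priors) < 1) stopf("need at least one reduced prior")
  msgs <- character(length(reduced_priors))
  out <- vapply(seq_along(reduced_priors), function(k) {
    tryCatch(bmr_reduce(full, reduced_priors[[k]])$delta_F,
             error = function(e) {
               msgs[k] <<- conditionMessage(e)
               NA_real_
             })
  }, numeric(1))
  if (any(nzchar(msgs))) attr(out, "errors") <- msgs
  out
}

#' Convert log evidences to posterior model probabilities
#'
#' Softmax over free energies: invariant to adding a constant, always a valid
#' probability simplex element.
#'
#' @param free_energies finite numeric vector (NA treated as minus infinity).
#' @return probability vector summing to 1.
#' @export
softmax_prob <- function(free_energies) {
  if (length(free_energies) == 0) stopf("empty evidence vector")
  f <- as.numeric(free_energies)
  f[is.na(f)] <- -Inf
  if (all(!is.finite(f))) stopf("no finite evidence values")
  e <- exp(f - max(f))
  e / sum(e)
}
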