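# Second-level Parametric Empirical Bayes over subjects' extrinsic
# connectivity. Each subject's first-level posterior is consumed as Gaussian
# sufficient statistics (mean, covariance) — the time series are never
# revisited. Removing the first-level prior from each posterior leaves the
# subject's data likelihood for the selected parameters (precision Pt_i,
# centre mt_i); the hierarchy
#   mt_i ~ N(X_i beta, Pt_i^{-1} + exp(-gamma) Q),  beta ~ N(mu0, S0)
# is then a linear-Gaussian model whose evidence is analytic given the
# between-subject log-precision gamma, which is optimised by 1-D search with
# a Laplace correction.

#' Fit a second-level PEB model of group effective connectivity
#'
#' Pools subject-level DCM posteriors in a Bayesian GLM with parametric
#' random effects on connectivity. Each subject contributes proportionally to
#' their first-level posterior precision, so subjects with inefficient
#' estimates carry less weight. Only the extrinsic (between-region) A
#' parameters enter the second level; all other parameters remain first-level
#' nuisance.
#'
#' @param fits list (length >= 2) of [dcm_fit()] results, or of lists with
#'   \code{mean}, \code{cov}, \code{free_energy} and \code{prior} over a
#'   shared labelling.
#' @param design S x K between-subject design matrix; default a single ones
#'   column (the group mean). Must have full column rank.
#' @param prior second-level prior over the group parameters; default
#'   zero-mean with the first-level prior variances (per design column).
#' @param re_scale prior expectation of the between-subject variance as a
#'   fraction of the first-level prior variance (default 1/16).
#' @param hyper Gaussian hyperprior on the random-effects log-precision.
#' @param select labels of the parameters carried to the second level;
#'   default all extrinsic A parameters.
#' @return an object of class \code{peb}: group posterior
#'   (\code{beta_mean}, \code{beta_cov}), random-effects log-precision
#'   posterior (\code{gamma}), \code{free_energy} with decomposition,
#'   second-level \code{prior}, per-subject sufficient statistics, and the
#'   random-effects base covariance \code{Q}.
#' @export
peb_fit <- function(fits, design = NULL, prior = NULL, re_scale = 1 / 16,
                    hyper = list(mean = 0, var = 1 / 16), select = NULL) {
  S <- length(fits)
  if (S < 2) stopf("PEB needs at least 2 subjects")
  labels <- names(fits[[1]]$mean)
  for (i in seq_len(S)) {
    if (!identical(names(fits[[i]]$mean), labels))
      stopf("subject %d has a different parameter labelling", i)
  }
  tab <- fits[[1]]$prior$table
  if (is.null(select)) {
    if (is.null(tab)) stopf("cannot identify extrinsic parameters: no table")
    select <- tab$label[tab$type == 0L & tab$i != tab$j]
  }
  sel <- match(select, labels)
  if (anyNA(sel)) stopf("selected labels missing from subject posteriors")
  p <- length(sel)

  X <- design %||% matrix(1, S, 1)
  X <- as.matrix(X)
  if (nrow(X) != S) stopf("design has %d rows for %d subjects", nrow(X), S)
  K <- ncol(X)
  if (qr(X)$rank < K) stopf("design matrix is rank deficient")

  # subject sufficient statistics: everything the evidence needs is kept in
  # precision space, so a posterior barely tighter than its prior (singular
  # prior-removed precision) stays numerically benign
  subj <- vector("list", S)
  for (i in seq_len(S)) {
    fi <- fits[[i]]
    Ci <- sym_part(as.matrix(fi$cov)[sel, sel, drop = FALSE])
    mi <- fi$mean[sel]
    S0i <- sym_part(as.matrix(fi$prior$cov)[sel, sel, drop = FALSE])
    m0i <- fi$prior$mean[sel]
    Pi <- chol_inv(Ci)
    P0 <- chol_inv(S0i)
    subj[[i]] <- list(
      Pi = Pi, P0 = P0,
      a = drop(Pi %*% mi - P0 %*% m0i),
      quad0 = drop(crossprod(mi, Pi %*% mi)) -
        drop(crossprod(m0i, P0 %*% m0i)),
      ldPi = logdet(Pi), ldP0 = logdet(P0),
      Pt = sym_part(Pi - P0),
      F1 = fi$free_energy %||% 0)
  }

  # second-level prior (group-mean block gets the first-level variances)
  S0sel <- sym_part(as.matrix(fits[[1]]$prior$cov)[sel, sel, drop = FALSE])
  if (is.null(prior)) {
    beta_labels <- as.vector(outer(labels[sel], seq_len(K),
                                   function(l, k) sprintf("%s:x%d", l, k)))
    cov_b <- kronecker(diag(K), S0sel)
    dimnames(cov_b) <- list(beta_labels, beta_labels)
    ptab <- tab[match(labels[sel], tab$label), , drop = FALSE]
    ptab <- ptab[rep(seq_len(p), K), , drop = FALSE]
    ptab$label <- beta_labels
    prior <- new_prior(setNames(rep(0, p * K), beta_labels), cov_b, ptab)
  }
  Q <- S0sel * re_scale

  Fg <- function(gm) peb_evidence(subj, X, prior, Q, gm)
  obj <- function(gm) Fg(gm)$F + dnorm(gm, hyper$mean, sqrt(hyper$var),
                                       log = TRUE)
  opt <- optimize(obj, interval = c(-8, 8), maximum = TRUE, tol = 1e-4)
  gm <- opt$maximum
  h <- 1e-3
  curv <- -(obj(gm + h) - 2 * obj(gm) + obj(gm - h)) / h^2
  Cg <- if (is.finite(curv) && curv > 0) 1 / curv else hyper$var
  klg <- 0.5 * (Cg / hyper$var + (gm - hyper$mean)^2 / hyper$var - 1 +
                  log(hyper$var / Cg))
  est <- Fg(gm)
  structure(list(beta_mean = est$mB, beta_cov = est$CB,
                 design = X, prior = prior,
                 gamma = list(mean = gm, cov = Cg),
                 free_energy = est$F - klg,
                 accuracy = est$accuracy,
                 complexity = est$complexity + klg,
                 random_cov = exp(-gm) * Q, Q = Q, hyper = hyper,
                 param_labels = labels[sel], subjects = subj,
                 n_subjects = S),
            class = "peb")
}

# evidence of the linear-Gaussian second level for a given gamma. For each
# subject, replacing the first-level prior (precision P0, mean m0) by the
# empirical prior N(X_i beta, Gamma^{-1}) gives a Gaussian integral in theta
# with precision Pc = Pi - P0 + Gamma; collecting terms in beta yields a
# quadratic log-likelihood with curvature S_i = Gamma - Gamma Pc^{-1} Gamma
# and gradient Gamma Pc^{-1} a_i. The marginal over beta is then conjugate.
peb_evidence <- function(subj, X, prior, Q, gm) {
  S <- length(subj)
  p <- nrow(Q)
  K <- ncol(X)
  P_B0 <- cov_to_precision(prior$cov)
  ldSB0 <- -logdet(P_B0)
  Qinv <- chol_inv(Q)
  G <- exp(gm) * Qinv
  ldG <- p * gm + logdet(Qinv)
  PB <- P_B0
  hB <- drop(P_B0 %*% prior$mean)
  const <- 0
  Sl <- vector("list", S)
  for (i in seq_len(S)) {
    si <- subj[[i]]
    Pc <- sym_part(si$Pt + G)
    W <- chol_inv(Pc)
    GW <- G %*% W
    Sl[[i]] <- sym_part(G - GW %*% G)
    bi <- drop(GW %*% si$a)
    const <- const + si$F1 +
      0.5 * (si$ldPi + ldG - si$ldP0 - logdet(Pc)) +
      0.5 * (drop(crossprod(si$a, W %*% si$a)) - si$quad0)
    PB <- PB + kronecker(X[i, ] %o% X[i, ], Sl[[i]])
    hB <- hB + drop(kronecker(X[i, ], bi))
  }
  PB <- sym_part(PB)
  CB <- chol_inv(PB)
  mB <- drop(CB %*% hB)
  logmarg <- const +
    0.5 * (drop(crossprod(hB, mB)) -
             drop(crossprod(prior$mean, P_B0 %*% prior$mean)) -
             logdet(PB) - ldSB0)
  KLB <- gauss_kl(mB, CB, prior$mean, P_B0, ldSB0)
  names(mB) <- prior$labels
  dimnames(CB) <- list(prior$labels, prior$labels)
  list(F = logmarg, accuracy = logmarg + KLB, complexity = KLB, mB = mB,
       CB = sym_part(CB))
}

#' Group-level free-energy decomposition
#'
#' Recomputes (from the stored sufficient statistics) the group free energy
#' of an estimated PEB model as accuracy minus complexity — the quantity the
#' structure-function mapping grid compares.
#'
#' @param model an estimated [peb_fit()] object.
#' @param prior optionally evaluate under a different second-level prior.
#' @return list with \code{F}, \code{accuracy}, \code{complexity}.
#' @export
group_free_energy <- function(model, prior = NULL) {
  if (!inherits(model, "peb")) stopf("not an estimated PEB model")
  prior <- prior %||% model$prior
  est <- peb_evidence(model$subjects, model$design, prior, model$Q,
                      model$gamma$mean)
  klg <- 0.5 * (model$gamma$cov / model$hyper$var +
                  (model$gamma$mean - model$hyper$mean)^2 / model$hyper$var -
                  1 + log(model$hyper$var / model$gamma$cov))
  list(F = est$F - klg, accuracy = est$accuracy,
       complexity = est$complexity + klg)
}

#' Subject posteriors under the empirical (group) prior
#'
#' Re-evaluates each subject's selected parameters using the group posterior
#' as an empirical prior — the shrinkage that pulls inefficient subjects
#' toward the group mean.
#'
#' @param model a [peb_fit()] object.
#' @return list (one per subject) of lists with \code{mean} and \code{cov}.
#' @export
peb_subject_posteriors <- function(model) {
  p <- length(model$param_labels)
  X <- model$design
  lapply(seq_len(model$n_subjects), function(i) {
    Xi <- kronecker(t(X[i, ]), diag(p))
    prior_cov <- sym_part(model$random_cov +
                            Xi %*% model$beta_cov %*% t(Xi))
    prior_mean <- drop(Xi %*% model$beta_mean)
    Pp <- chol_inv(prior_cov)
    si <- model$subjects[[i]]
    Cpost <- chol_inv(Pp + sym_part(si$Pt))
    # si$a is the prior-removed information vector Pt %*% mt
    mpost <- drop(Cpost %*% (Pp %*% prior_mean + si$a))
    list(mean = setNames(mpost, model$param_labels), cov = Cpost)
  })
}

#' @export
print.peb <- function(x, ...) {
  cat(sprintf("PEB model: %d subjects, %d group parameters (design %d x %d)\n",
              x$n_subjects, length(x$beta_mean), nrow(x$design),
              ncol(x$design)))
  cat(sprintf("  group F %.3f = accuracy %.3f - complexity %.3f\n",
              x$free_energy, x$accuracy, x$complexity))
  cat(sprintf("  between-subject log-precision %.2f (sd of RE ~ %.3f)\n",
              x$gamma$mean, sqrt(mean(diag(x$random_cov)))))
  invisible(x)
}

#' @export
coef.peb <- function(object, ...) object$beta_mean

#' @export
summary.peb <- function(object, ...) {
  sds <- sqrt(pmax(diag(object$beta_cov), 0))
  out <- data.frame(label = names(object$beta_mean),
                    estimate = unname(object$beta_mean), sd = sds,
                    prob_nonzero = 1 - 2 * pnorm(-abs(object$beta_mean) / pmax(sds, 1e-12)))
  structure(list(table = out, free_energy = object$free_energy,
                 gamma = object$gamma), class = "summary.peb")
}

#' @export
print.summary.peb <- function(x, ...) {
  cat(sprintf("PEB group posterior (F = %.3f)\n", x$free_energy))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
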