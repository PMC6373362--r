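#' Sigmoid structure-to-prior-variance mapping hyperparameters
#'
#' The mapping from structural connection strength \eqn{\varphi \in [0,1]} to
#' the prior variance of the corresponding effective connection is the
#' logistic function \deqn{\Sigma_y = \Sigma_{y\,max} / (1 + \exp(\alpha -
#' \delta \varphi)),} where \code{sigma_max} is the maximal prior variance,
#' \code{delta} the slope (\code{delta = 0} transmits no structural
#' information — a flat, null mapping) and \code{alpha} the inflection point.
#'
#' @param alpha inflection point.
#' @param delta slope (>= 0).
#' @param sigma_max maximal prior variance (> 0).
#' @return an object of class \code{mapping_hyperparams}.
#' @export
mapping_hyperparams <- function(alpha, delta, sigma_max) {
  if (sigma_max <= 0) stopf("sigma_max must be positive")
  if (delta < 0) stopf("delta must be non-negative")
  structure(list(alpha = alpha, delta = delta, sigma_max = sigma_max),
            class = "mapping_hyperparams")
}

#' @export
print.mapping_hyperparams <- function(x, ...) {
  cat(sprintf("sigmoid mapping: alpha = %g, delta = %g, sigma_max = %g\n",
              x$alpha, x$delta, x$sigma_max))
  invisible(x)
}

#' Prior variance implied by structural connection strength
#'
#' @param phi structural strength(s) in \eqn{[0, 1]} (vectorised).
#' @param h a [mapping_hyperparams()] object.
#' @return prior variance(s); strictly increasing in \code{phi} when
#'   \code{delta > 0}, constant when \code{delta = 0}.
#' @export
sigmoid_prior_variance <- function(phi, h) {
  stopifnot(all(is.finite(phi)))
  h$sigma_max / (1 + exp(h$alpha - h$delta * phi))
}

#' Hyperparameter lattice for the structure-function mapping search
#'
#' The default lattice (alpha from -2 to 2 in steps of 0.5, delta from 0 to
#' 16 in steps of 2, sigma_max from 0.1 to 0.5 in steps of 0.1) enumerates
#' 405 mappings, including the flat (delta = 0) control models.
#'
#' @param alpha,delta,sigma_max ordered value lattices.
#' @return an object of class \code{mapping_grid}: a data frame of all
#'   combinations (alpha varying fastest) with one row per model.
#' @export
mapping_grid <- function(alpha = seq(-2, 2, by = 0.5),
                         delta = seq(0, 16, by = 2),
                         sigma_max = seq(0.1, 0.5, by = 0.1)) {
  if (!length(alpha) || !length(delta) || !length(sigma_max))
    stopf("empty lattice")
  g <- expand.grid(alpha = alpha, delta = delta, sigma_max = sigma_max,
                   KEEP.OUT.ATTRS = FALSE)
  structure(g, class = c("mapping_grid", "data.frame"))
}

# labels like "A(2,1)" or "A(2,1):x1" -> (q, r) or NA
parse_A_label <- function(labels) {
  m <- regmatches(labels, regexec("^A\\((\\d+),(\\d+)\\)(:x1)?$", labels))
  t(vapply(m, function(x) {
    if (length(x) == 0) return(c(NA_integer_, NA_integer_))
    c(as.integer(x[2]), as.integer(x[3]))
  }, integer(2)))
}

#' Build a structurally informed prior
#'
#' Returns a copy of \code{base_prior} in which the variance of every
#' extrinsic connection \eqn{A_{q,r}} is replaced by the sigmoid of the
#' structural strength \eqn{\varphi_{q,r}}. Pairs excluded from structural
#' assessment (the connectome's forbidden mask) are pinned to the prior mean
#' (zero variance); self-connections and all other parameters are untouched.
#' Prior means are never modified — structure only licenses departures from
#' zero, it does not impose them.
#'
#' @param connectome a [group_connectome()] object.
#' @param h a [mapping_hyperparams()] object.
#' @param base_prior the prior to modify (first-level [dcm_priors()] or the
#'   second-level prior of a [peb_fit()]).
#' @return a prior of the same shape as \code{base_prior}.
#' @export
build_informed_prior <- function(connectome, h, base_prior) {
  qr_ <- parse_A_label(base_prior$labels)
  ext <- !is.na(qr_[, 1]) & qr_[, 1] != qr_[, 2]
  if (!any(ext)) stopf("no extrinsic A parameters in the prior")
  N <- nrow(connectome$phi)
  if (max(qr_[ext, ], na.rm = TRUE) > N)
    stopf("prior refers to region %d but the connectome has %d regions",
          max(qr_[ext, ], na.rm = TRUE), N)
  if (!is.null(base_prior$region_labels) &&
      !identical(base_prior$region_labels, connectome$region_labels))
    stopf("connectome region labels do not match the prior")
  prior <- base_prior
  for (k in which(ext)) {
    q <- qr_[k, 1]; r <- qr_[k, 2]
    v <- if (connectome$forbidden_mask[q, r]) 0
    else sigmoid_prior_variance(connectome$phi[q, r], h)
    prior$cov[k, ] <- 0
    prior$cov[, k] <- 0
    prior$cov[k, k] <- v
  }
  prior
}

#' Search the structure-function mapping space
#'
#' Builds one structurally informed second-level prior per lattice point and
#' scores every mapping against the full (structurally uninformed) PEB model
#' by Bayesian model reduction. Flat mappings (\code{delta = 0}) form the
#' null set against which the added value of structure is judged: the search
#' reports whether any informed model exceeds the best flat model by at least
#' the strong-evidence threshold.
#'
#' @param peb_model an estimated [peb_fit()] object.
#' @param connectome a [group_connectome()] object.
#' @param grid a [mapping_grid()]; default the full 405-model lattice.
#' @param base_prior second-level prior defining the full model (default the
#'   one stored in \code{peb_model}).
#' @param threshold strong-evidence threshold on the log Bayes factor.
#' @return an object of class \code{sipeb_grid}: \code{models} (data frame
#'   with hyperparameters, \code{delta_F} relative to the full model and
#'   softmax posterior probability), \code{best} (first-by-lattice-order
#'   maximiser), \code{ties} (indices within \code{threshold} of the
#'   maximum), \code{best_relative_log_evidence},
#'   \code{informed_vs_null} (best informed minus best flat model), and
#'   \code{structural_priors_favoured}.
#' @export
sipeb_search <- function(peb_model, connectome, grid = mapping_grid(),
                         base_prior = NULL,
                         threshold = strong_evidence_threshold()) {
  stopifnot(inherits(peb_model, "peb"))
  base_prior <- base_prior %||% peb_model$prior
  priors <- lapply(seq_len(nrow(grid)), function(k) {
    build_informed_prior(connectome,
                         mapping_hyperparams(grid$alpha[k], grid$delta[k],
                                             grid$sigma_max[k]),
                         base_prior)
  })
  dF <- score_model_set(peb_model, priors)
  prob <- softmax_prob(dF)
  models <- data.frame(model = seq_len(nrow(grid)), grid,
                       delta_F = as.numeric(dF), post_prob = prob,
                       is_null = grid$delta == 0,
                       ok = !is.na(dF))
  errs <- attr(dF, "errors")
  if (!is.null(errs)) models$error <- errs
  best_idx <- which.max(ifelse(is.na(dF), -Inf, dF))
  ties <- which(dF >= dF[best_idx] - threshold)
  best_null <- suppressWarnings(max(dF[models$is_null], na.rm = TRUE))
  best_informed <- suppressWarnings(max(dF[!models$is_null], na.rm = TRUE))
  informed_vs_null <- best_informed - best_null
  structure(list(
    models = models,
    best = mapping_hyperparams(grid$alpha[best_idx], grid$delta[best_idx],
                               grid$sigma_max[best_idx]),
    best_index = best_idx,
    ties = ties,
    best_relative_log_evidence = dF[best_idx],
    best_null_log_evidence = best_null,
    informed_vs_null = informed_vs_null,
    structural_priors_favoured = !models$is_null[best_idx] &&
      informed_vs_null >= threshold,
    threshold = threshold,
    connectome = connectome
  ), class = "sipeb_grid")
}

#' @export
print.sipeb_grid <- function(x, ...) {
  cat(sprintf("Structure-function mapping search: %d models (%d flat controls)\n",
              nrow(x$models), sum(x$models$is_null)))
  b <- x$best
  cat(sprintf("  best: alpha = %g, delta = %g, sigma_max = %g (dF = %.2f vs full, p = %.3f)\n",
              b$alpha, b$delta, b$sigma_max, x$best_relative_log_evidence,
              x$models$post_prob[x$best_index]))
  cat(sprintf("  best informed vs best flat control: dF = %.2f -> structural priors %s\n",
              x$informed_vs_null,
              if (x$structural_priors_favoured) "favoured (strong evidence)"
              else "not decisively favoured"))
  if (length(x$ties) > 1)
    cat(sprintf("  note: %d models within %g of the maximum\n",
                length(x$ties), x$threshold))
  invisible(x)
}

#' @export
summary.sipeb_grid <- function(object, ...) {
  m <- object$models
  agg <- stats::aggregate(post_prob ~ sigma_max, data = m, FUN = sum)
  structure(list(by_sigma = agg, best = object$best,
                 informed_vs_null = object$informed_vs_null,
                 favoured = object$structural_priors_favoured),
            class = "summary.sipeb_grid")
}

#' @export
print.summary.sipeb_grid <- function(x, ...) {
  cat("Posterior probability mass by sigma_max level:\n")
  print(x$by_sigma, row.names = FALSE, digits = 3)
  cat(sprintf("Best mapping: alpha = %g, delta = %g, sigma_max = %g; informed vs null dF = %.2f\n",
              x$best$alpha, x$best$delta, x$best$sigma_max,
              x$informed_vs_null))
  invisible(x)
}

#' Heatmaps of posterior model probability over the mapping lattice
#'
#' One alpha-by-delta panel per \code{sigma_max} level.
#'
#' @param x a \code{sipeb_grid}.
#' @param ... unused.
#' @export
plot.sipeb_grid <- function(x, ...) {
  m <- x$models
  sig <- sort(unique(m$sigma_max))
  old <- graphics::par(mfrow = c(1, length(sig)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  al <- sort(unique(m$alpha))
  de <- sort(unique(m$delta))
  for (s in sig) {
    z <- matrix(NA, length(de), length(al))
    sub <- m[m$sigma_max == s, ]
    for (k in seq_len(nrow(sub)))
      z[match(sub$delta[k], de), match(sub$alpha[k], al)] <- sub$post_prob[k]
    graphics::image(de, al, z, xlab = "delta", ylab = "alpha",
                    main = sprintf("sigma_max = %g", s),
                    col = grDevices::hcl.colors(64, "viridis"),
                    zlim = c(0, max(m$post_prob)))
  }
  invisible(x)
}

#' Posterior-probability matrices per sigma_max level
#'
#' Heatmap-ready alpha-by-delta matrices of posterior model probability.
#'
#' @param x a \code{sipeb_grid}.
#' @return named list of matrices (rows alpha, columns delta), one per
#'   sigma_max level.
#' @export
probability_matrices <- function(x) {
  m <- x$models
  al <- sort(unique(m$alpha))
  de <- sort(unique(m$delta))
  out <- list()
  for (s in sort(unique(m$sigma_max))) {
    z <- matrix(NA_real_, length(al), length(de),
                dimnames = list(paste0("alpha=", al), paste0("delta=", de)))
    sub <- m[m$sigma_max == s, ]
    for (k in seq_len(nrow(sub)))
      z[match(sub$alpha[k], al), match(sub$delta[k], de)] <- sub$post_prob[k]
    out[[sprintf("sigma_max=%g", s)]] <- z
  }
  out
}

#' Apply a structure-function mapping to an individual DCM
#'
#' Builds the structurally informed first-level prior implied by the mapping
#' and scores it against the subject's full (structurally naive) model by
#' Bayesian model reduction, returning the per-subject relative log evidence.
#'
#' @param subject_full a [dcm_fit()] result inverted under the full
#'   (uninformed) prior.
#' @param connectome a [group_connectome()] object.
#' @param h a [mapping_hyperparams()] object (typically the group optimum).
#' @param subject_prior optionally override the prior stored in the fit.
#' @return a \code{reduced_model} (see [bmr_reduce()]); its \code{delta_F} is
#'   the informed-minus-uninformed log evidence for this subject.
#' @export
apply_mapping_to_subject <- function(subject_full, connectome, h,
                                     subject_prior = NULL) {
  subject_prior <- subject_prior %||% subject_full$prior
  informed <- build_informed_prior(connectome, h, subject_prior)
  bmr_reduce(subject_full, informed, full_prior = subject_prior)
}
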