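#' Invert a DCM by variational Laplace
#'
#' Subject-level model inversion: ascends the variational free energy (a
#' lower bound on the log model evidence, decomposing as accuracy minus
#' complexity) by regularised Gauss-Newton, returning a Gaussian posterior
#' over all model parameters together with per-region noise log-precisions.
#'
#' @param data a [bold_dataset()].
#' @param spec the matching [dcm_spec()].
#' @param prior a [dcm_priors()] object covering every free parameter.
#' @param hyper Gaussian hyperprior on the per-region noise log-precisions
#'   (one per region).
#' @param control passed to [vl_fit()].
#' @return an object of class \code{dcmfit} (inherits \code{vl_fit}); see
#'   [vl_fit()] for fields. Additionally carries \code{spec} and \code{data}.
#' @seealso [coef.dcmfit()], [simulate.dcmfit()], [bmr_reduce()]
#' @export
dcm_fit <- function(data, spec, prior = dcm_priors(spec),
                    hyper = list(mean = 0, var = 16), control = list()) {
  stopifnot(inherits(data, "bold_dataset"), inherits(spec, "dcm_spec"))
  if (ncol(data$y) != spec$n_regions)
    stopf("data has %d regions; spec expects %d", ncol(data$y), spec$n_regions)
  if (nrow(data$y) != spec$n_volumes)
    stopf("data has %d volumes; spec expects %d", nrow(data$y), spec$n_volumes)
  tab <- param_table(spec)
  if (!identical(prior$labels, tab$label))
    stopf("prior labels do not match the model's parameter table")

  fm <- dcm_model_functions(data, spec, control$fd_step %||% 1e-4)
  fit <- vl_fit(fm$y, fm$g, prior, jacobian = fm$jac, groups = fm$groups,
                group_df = fm$group_df, hyper = hyper, control = control)
  fit$spec <- spec
  fit$data <- data
  fit$region_labels <- spec$region_labels
  class(fit) <- c("dcmfit", class(fit))
  fit
}

# prediction/Jacobian closures (confounds projected out of data and model
# identically); observations stacked region-major
dcm_model_functions <- function(data, spec, fd_step = 1e-4) {
  u <- spec_inputs(spec)
  tab <- param_table(spec)
  N <- spec$n_regions
  T_ <- spec$n_volumes
  dt <- spec$tr / spec$microtime_bins
  X0 <- data$confound_basis
  proj <- NULL
  kdf <- 0
  if (!is.null(X0)) {
    X0 <- as.matrix(X0)
    proj <- diag(T_) - X0 %*% solve(crossprod(X0), t(X0))
    kdf <- qr(X0)$rank
  }
  project <- function(v) {
    if (is.null(proj)) return(v)
    as.numeric(proj %*% matrix(v, T_, length(v) / T_))
  }
  g <- function(th) {
    res <- dcm_predict_cpp(th, tab$type, tab$i, tab$j, N, u,
                           T_, spec$microtime_bins, dt)
    if (!res$ok) return(NULL)
    project(res$y)
  }
  jac <- function(th) {
    free <- attr(th, "free_idx")
    res <- dcm_jacobian_cpp(th, tab$type, tab$i, tab$j, N, u,
                            T_, spec$microtime_bins, dt,
                            free, fd_step)
    if (!res$ok) return(NULL)
    if (is.null(proj)) res$J else apply(res$J, 2, project)
  }
  list(y = project(as.numeric(data$y)), g = g, jac = jac,
       groups = rep(seq_len(N), each = T_),
       group_df = rep(T_ - kdf, N))
}

#' Evaluate the first-level free energy at a given posterior
#'
#' Laplace-form evaluation of the variational free energy (expected
#' log-likelihood under \code{q} minus the KL divergence from the priors)
#' for an arbitrary Gaussian \code{q} — not necessarily the optimum.
#'
#' @param data,spec,prior as in [dcm_fit()].
#' @param q_mean,q_cov the Gaussian posterior to evaluate (full parameter
#'   dimension).
#' @param noise per-region noise model: either a numeric vector of
#'   log-precisions (treated as fixed) or a list with \code{mean} and
#'   \code{cov}, in which case the hyperprior KL is included.
#' @param hyper hyperprior used for the noise KL term.
#' @return list with \code{F}, \code{accuracy}, \code{complexity}.
#' @export
dcm_free_energy <- function(data, spec, prior, q_mean, q_cov, noise,
                            hyper = list(mean = 0, var = 16)) {
  fm <- dcm_model_functions(data, spec)
  free <- which(diag(as.matrix(prior$cov)) > 1e-10)
  jac <- function(th) {
    th2 <- th
    attr(th2, "free_idx") <- free
    fm$jac(th2)
  }
  vl_free_energy(fm$y, fm$g, prior, q_mean, q_cov, noise,
                 groups = fm$groups, group_df = fm$group_df, hyper = hyper,
                 jacobian = jac)
}

#' @export
print.dcmfit <- function(x, ...) {
  cat(sprintf("DCM fit: %d regions, %d parameters (%d free)\n",
              x$spec$n_regions, length(x$mean), length(x$free)))
  cat(sprintf("  free energy %.3f = accuracy %.3f - complexity %.3f\n",
              x$free_energy, x$accuracy, x$complexity))
  cat(sprintf("  %s after %d iterations; noise log-precision %s\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              paste(sprintf("%.2f", x$lambda), collapse = " ")))
  invisible(x)
}

#' Extract connectivity estimates from a DCM fit
#'
#' @param object a \code{dcmfit}.
#' @param type \code{"A"} for the posterior-mean extrinsic/self matrix (self
#'   entries on the log scale as parameterised), \code{"vector"} for the full
#'   named parameter vector.
#' @param ... unused.
#' @return matrix or named vector.
#' @export
coef.dcmfit <- function(object, type = c("A", "vector"), ...) {
  type <- match.arg(type)
  if (type == "vector") return(object$mean)
  tab <- param_table(object$spec)
  N <- object$spec$n_regions
  A <- matrix(0, N, N, dimnames = list(object$region_labels,
                                       object$region_labels))
  sel <- tab$type == 0L
  A[cbind(tab$i[sel], tab$j[sel])] <- object$mean[sel]
  A
}

#' @export
fitted.dcmfit <- function(object, ...) {
  matrix(object$fitted, object$spec$n_volumes, object$spec$n_regions,
         dimnames = list(NULL, object$region_labels))
}

#' @export
residuals.dcmfit <- function(object, ...) {
  matrix(object$residuals, object$spec$n_volumes, object$spec$n_regions,
         dimnames = list(NULL, object$region_labels))
}

#' Simulate BOLD data from a fitted DCM
#'
#' Generates data at the posterior mean (posterior predictive in the plug-in
#' sense), with observation noise at the posterior noise level.
#'
#' @param object a \code{dcmfit}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise include observation noise (default TRUE).
#' @param ... unused.
#' @return a list of [bold_dataset()] objects (length \code{nsim}).
#' @export
simulate.dcmfit <- function(object, nsim = 1, seed = 1, noise = TRUE, ...) {
  params <- theta_to_params(object$mean, object$spec)
  sds <- sqrt(exp(-object$lambda))
  lapply(seq_len(nsim), function(k) {
    sim <- simulate_bold(params, object$spec, noise_sd = 0)
    if (noise) {
      set.seed(subseed(seed, k))
      sim$y <- sim$y + matrix(rnorm(length(sim$y), 0,
                                    rep(sds, each = nrow(sim$y))),
                              nrow(sim$y), ncol(sim$y))
    }
    sim
  })
}

#' @export
summary.dcmfit <- function(object, ...) {
  tab <- param_table(object$spec)
  sds <- sqrt(pmax(diag(object$cov), 0))
  out <- data.frame(label = tab$label, estimate = unname(object$mean),
                    sd = sds,
                    lower90 = unname(object$mean) - qnorm(0.95) * sds,
                    upper90 = unname(object$mean) + qnorm(0.95) * sds)
  structure(list(table = out, free_energy = object$free_energy,
                 accuracy = object$accuracy, complexity = object$complexity,
                 converged = object$converged,
                 n_iterations = object$n_iterations),
            class = "summary.dcmfit")
}

#' @export
print.summary.dcmfit <- function(x, ...) {
  cat(sprintf("DCM posterior (F = %.3f, %s)\n", x$free_energy,
              if (x$converged) "converged" else "not converged"))
  ext <- grepl("^A\\(", x$table$label)
  print(x$table[ext, ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.dcmfit <- function(x, regions = NULL, ...) {
  y <- x$data$y
  f <- fitted(x)
  regions <- regions %||% seq_len(min(4, ncol(y)))
  old <- graphics::par(mfrow = c(length(regions), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  t <- seq_len(nrow(y)) * x$spec$tr
  for (r in regions) {
    graphics::plot(t, y[, r], type = "l", col = "grey50",
                   ylab = x$region_labels[r], xlab = "")
    graphics::lines(t, f[, r], col = "firebrick")
  }
  invisible(x)
}
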