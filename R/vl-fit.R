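# Variational Laplace under a nonlinear Gaussian observation model:
#   y = g(theta) + e,  e ~ N(0, diag over noise groups of exp(-lambda_g) I)
# with Gaussian priors on theta and on the log-precisions lambda. Free energy
# is ascended by Gauss-Newton steps with Levenberg-Marquardt regularisation;
# lambda is updated by Newton steps inside every objective evaluation, so the
# recorded free energy is a function of theta alone and accepted iterations
# are monotone by construction.

#' Fit a nonlinear model by variational Laplace
#'
#' Generic engine behind [dcm_fit()]; exposed because any model with Gaussian
#' priors and additive Gaussian noise can be inverted with it (and because a
#' linear \code{g} admits an exact conjugate solution against which the
#' implementation can be checked).
#'
#' @param y numeric vector of observations (for multi-region data, regions
#'   stacked; see \code{groups}).
#' @param g prediction function: takes the full parameter vector, returns a
#'   vector matching \code{y}, or NULL/non-finite values on failure.
#' @param prior list with \code{mean} and \code{cov} over the full parameter
#'   vector. Zero prior variance pins a parameter at its prior mean.
#' @param jacobian optional function returning the \code{length(y) x n_free}
#'   Jacobian for the free parameters (columns in free-parameter order); by
#'   default central finite differences of \code{g}.
#' @param groups integer vector assigning each observation to a noise group
#'   (one log-precision per group); default a single group.
#' @param group_df effective degrees of freedom per group (defaults to the
#'   group sizes; reduced when confounds have been projected out).
#' @param hyper list with \code{mean} and \code{var} of the Gaussian
#'   hyperprior on each group's log-precision; \code{var = 0} fixes the
#'   log-precisions at \code{mean}.
#' @param control list: \code{max_iter} (64), \code{tol} (0.01),
#'   \code{n_converge} (4), \code{fd_step} (1e-4), \code{lm_init} (1e-3),
#'   \code{lm_max_try} (6).
#' @return an object of class \code{vl_fit}: posterior \code{mean} and
#'   \code{cov} (full dimension; pinned entries have zero variance),
#'   \code{free_energy} with its \code{accuracy}/\code{complexity}
#'   decomposition, noise posterior (\code{lambda}, \code{lambda_cov}),
#'   \code{F_trace}, \code{n_iterations}, \code{converged}, \code{fitted},
#'   \code{residuals} and the \code{prior}.
#' @export
vl_fit <- function(y, g, prior, jacobian = NULL, groups = NULL,
                   group_df = NULL, hyper = list(mean = 0, var = 16),
                   control = list()) {
  ctl <- modifyList(list(max_iter = 64L, tol = 0.01, n_converge = 4L,
                         fd_step = 1e-4, lm_init = 1e-3, lm_max_try = 6L),
                    control)
  y <- as.numeric(y)
  n <- length(y)
  groups <- as.integer(groups %||% rep(1L, n))
  G <- max(groups)
  gidx <- split(seq_len(n), groups)
  df <- as.numeric(group_df %||% lengths(gidx))
  mu0 <- prior$mean
  S0 <- as.matrix(prior$cov)
  p <- length(mu0)
  free <- which(diag(S0) > 1e-10)
  nf <- length(free)
  if (nf == 0) stopf("no free parameters")
  S0f <- sym_part(S0[free, free, drop = FALSE])
  P0f <- chol_inv(S0f)
  ldS0f <- logdet(S0f)
  h_mean <- rep_len(hyper$mean, G)
  h_var <- rep_len(hyper$var, G)
  fixed_lambda <- all(h_var == 0)

  # user jacobians receive the free indices via an attribute on theta
  jac_fun <- if (!is.null(jacobian)) {
    function(th) {
      attr(th, "free_idx") <- free
      jacobian(th)
    }
  } else function(th) {
    J <- matrix(0, n, nf)
    for (k in seq_len(nf)) {
      thp <- th; thp[free[k]] <- thp[free[k]] + ctl$fd_step
      thm <- th; thm[free[k]] <- thm[free[k]] - ctl$fd_step
      gp <- g(thp); gm <- g(thm)
      if (is.null(gp) || is.null(gm)) return(NULL)
      J[, k] <- (gp - gm) / (2 * ctl$fd_step)
    }
    J
  }

  eval_state <- function(th, lam) {
    gv <- g(th)
    if (is.null(gv) || any(!is.finite(gv))) return(list(F = -Inf))
    r <- y - gv
    J <- jac_fun(th)
    if (is.null(J) || any(!is.finite(J))) return(list(F = -Inf))
    H <- NULL; Cf <- NULL; e <- numeric(G); ldH <- NA
    compute <- function(lam) {
      Pi <- exp(lam)[groups]
      H <- sym_part(crossprod(J, J * Pi) + P0f)
      R <- tryCatch(chol(H), error = function(err) NULL)
      if (is.null(R)) {
        H <- H + diag(1e-6 * max(diag(H)), nf)
        R <- chol(H)
      }
      Cf <- chol2inv(R)
      e <- vapply(seq_len(G), function(gg) {
        idx <- gidx[[gg]]
        Jg <- J[idx, , drop = FALSE]
        sum(r[idx]^2) + sum((Jg %*% Cf) * Jg)
      }, numeric(1))
      list(H = H, Cf = Cf, e = e, ldH = 2 * sum(log(diag(R))))
    }
    for (it in 1:8) {
      cs <- compute(lam)
      if (fixed_lambda) break
      gr <- 0.5 * df - 0.5 * exp(lam) * cs$e - (lam - h_mean) / h_var
      he <- -0.5 * exp(lam) * cs$e - 1 / h_var
      dl <- pmin(pmax(-gr / he, -2), 2)
      lam <- lam + dl
      if (max(abs(dl)) < 1e-4) { cs <- compute(lam); break }
    }
    acc <- sum(0.5 * df * lam - 0.5 * exp(lam) * cs$e) -
      0.5 * sum(df) * log(2 * pi)
    d <- th[free] - mu0[free]
    klth <- 0.5 * (sum(cs$Cf * P0f) + drop(crossprod(d, P0f %*% d)) - nf +
                     ldS0f + cs$ldH)
    if (fixed_lambda) {
      kll <- 0; lam_cov <- rep(0, G)
    } else {
      lam_cov <- 1 / (0.5 * exp(lam) * cs$e + 1 / h_var)
      kll <- sum(0.5 * (lam_cov / h_var + (lam - h_mean)^2 / h_var - 1 +
                          log(h_var / lam_cov)))
    }
    list(F = acc - klth - kll, accuracy = acc, complexity = klth + kll,
         r = r, J = J, H = cs$H, Cf = cs$Cf, e = cs$e, lam = lam,
         lam_cov = lam_cov, gv = gv)
  }

  th <- mu0
  st <- eval_state(th, h_mean)
  if (!is.finite(st$F))
    stopf("forward model failed at the prior mean; cannot start inversion")
  nu <- ctl$lm_init
  F_trace <- st$F
  n_small <- 0L
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(ctl$max_iter)) {
    grad <- drop(crossprod(st$J, exp(st$lam)[groups] * st$r)) -
      drop(P0f %*% (th[free] - mu0[free]))
    improved <- FALSE
    dF <- 0
    for (tri in seq_len(ctl$lm_max_try)) {
      Hd <- st$H + diag(nu * mean(diag(st$H)), nf)
      dth <- tryCatch(solve(Hd, grad), error = function(err) NULL)
      if (!is.null(dth) && all(is.finite(dth))) {
        th2 <- th
        th2[free] <- th[free] + dth
        st2 <- eval_state(th2, st$lam)
        if (is.finite(st2$F) && st2$F > st$F) {
          dF <- st2$F - st$F
          st <- st2; th <- th2
          nu <- max(nu / 4, 1e-8)
          improved <- TRUE
          break
        }
      }
      nu <- nu * 8
    }
    F_trace <- c(F_trace, st$F)
    n_small <- if (abs(dF) < ctl$tol) n_small + 1L else 0L
    if (n_small >= ctl$n_converge) { converged <- TRUE; break }
  }

  cov <- matrix(0, p, p, dimnames = list(names(mu0), names(mu0)))
  cov[free, free] <- sym_part(st$Cf)
  structure(list(mean = setNames(th, names(mu0)), cov = cov,
                 free_energy = st$F, accuracy = st$accuracy,
                 complexity = st$complexity,
                 lambda = st$lam, lambda_cov = st$lam_cov,
                 F_trace = F_trace, n_iterations = iter,
                 converged = converged, fitted = st$gv, residuals = st$r,
                 groups = groups, group_df = df, free = free, prior = prior),
            class = "vl_fit")
}

# Free-energy decomposition at a *given* approximate posterior q (no fitting).
# Shared by the exported first-level evaluator and tests.
vl_free_energy <- function(y, g, prior, q_mean, q_cov, lambda, groups = NULL,
                           group_df = NULL, hyper = NULL, jacobian = NULL,
                           fd_step = 1e-4) {
  y <- as.numeric(y)
  n <- length(y)
  groups <- as.integer(groups %||% rep(1L, n))
  G <- max(groups)
  gidx <- split(seq_len(n), groups)
  df <- as.numeric(group_df %||% lengths(gidx))
  mu0 <- prior$mean
  S0 <- as.matrix(prior$cov)
  free <- which(diag(S0) > 1e-10)
  nf <- length(free)
  S0f <- sym_part(S0[free, free, drop = FALSE])
  P0f <- chol_inv(S0f)
  q_cov <- as.matrix(q_cov)
  Cf <- sym_part(q_cov[free, free, drop = FALSE])
  R <- tryCatch(chol(Cf), error = function(err) NULL)
  if (is.null(R)) stopf("posterior covariance is not positive definite")
  gv <- g(q_mean)
  if (is.null(gv) || any(!is.finite(gv))) stopf("prediction failed at q_mean")
  r <- y - gv
  J <- if (is.null(jacobian)) {
    Jm <- matrix(0, n, nf)
    for (k in seq_len(nf)) {
      thp <- q_mean; thp[free[k]] <- thp[free[k]] + fd_step
      thm <- q_mean; thm[free[k]] <- thm[free[k]] - fd_step
      Jm[, k] <- (g(thp) - g(thm)) / (2 * fd_step)
    }
    Jm
  } else jacobian(q_mean)
  lam <- rep_len(if (is.list(lambda)) lambda$mean else lambda, G)
  e <- vapply(seq_len(G), function(gg) {
    idx <- gidx[[gg]]
    Jg <- J[idx, , drop = FALSE]
    sum(r[idx]^2) + sum((Jg %*% Cf) * Jg)
  }, numeric(1))
  acc <- sum(0.5 * df * lam - 0.5 * exp(lam) * e) - 0.5 * sum(df) * log(2 * pi)
  d <- q_mean[free] - mu0[free]
  klth <- 0.5 * (sum(Cf * P0f) + drop(crossprod(d, P0f %*% d)) - nf +
                   logdet(S0f) - 2 * sum(log(diag(R))))
  kll <- 0
  if (is.list(lambda) && !is.null(lambda$cov) && !is.null(hyper)) {
    h_mean <- rep_len(hyper$mean, G)
    h_var <- rep_len(hyper$var, G)
    lv <- rep_len(lambda$cov, G)
    kll <- sum(0.5 * (lv / h_var + (lam - h_mean)^2 / h_var - 1 +
                        log(h_var / lv)))
  }
  list(F = acc - klth - kll, accuracy = acc, complexity = klth + kll)
}

#' @export
print.vl_fit <- function(x, ...) {
  cat(sprintf(
    "Variational Laplace fit: %d parameters (%d free), F = %.3f (%s after %d iterations)\n",
    length(x$mean), length(x$free), x$free_energy,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  cat(sprintf("  accuracy %.3f, complexity %.3f\n", x$accuracy, x$complexity))
  invisible(x)
}
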