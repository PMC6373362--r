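#' Balloon-model constants
#'
#' Fixed haemodynamic constants of the one-state DCM observation model:
#' vasodilatory decay (1/s), flow autoregulation (1/s), mean venous transit
#' time (s), vessel stiffness exponent, resting oxygen extraction fraction and
#' resting venous volume (percent-signal units). Transit time and
#' neurovascular gain are additionally free per region as log-scaling
#' parameters around these values.
#'
#' @return named numeric vector.
#' @export
hdm_constants <- function() {
  c(decay = 0.64, autoregulation = 0.32, transit = 2.0,
    stiffness = 0.32, extraction = 0.4, V0 = 4.0)
}

#' DCM parameter set
#'
#' Assembles neuronal and haemodynamic parameters consistent with a
#' [dcm_spec()]. Entries outside the corresponding masks must be zero; the
#' diagonal of \code{a} is the log-scaling of the self-connection, with the
#' effective self-coupling \eqn{-0.5 \exp(a_{ii})} Hz.
#'
#' @param spec a \code{dcm_spec}.
#' @param a N x N extrinsic/self coupling matrix (Hz; diagonal on log scale).
#' @param b optional list (per input) of N x N modulatory matrices
#'   (self-connections only).
#' @param c optional N x J driving-input matrix.
#' @param transit,gain per-region log-scaling of venous transit time and
#'   neurovascular coupling gain (default 0).
#' @return an object of class \code{dcm_params}.
#' @export
dcm_params <- function(spec, a = NULL, b = NULL, c = NULL,
                       transit = NULL, gain = NULL) {
  N <- spec$n_regions
  J <- ncol(spec$u)
  a <- if (is.null(a)) matrix(0, N, N) else as.matrix(a)
  if (any(a[!spec$a_mask] != 0))
    stopf("nonzero 'a' entry outside a_mask")
  if (is.null(b)) b <- replicate(length(spec$b_masks),
                                 matrix(0, N, N), simplify = FALSE)
  if (is.null(c)) c <- matrix(0, N, max(J, 1))
  c <- as.matrix(c)
  for (j in seq_along(spec$b_masks)) {
    if (any(b[[j]][!spec$b_masks[[j]]] != 0))
      stopf("nonzero 'b' entry outside b_mask for input %d", j)
  }
  if (J > 0 && any(c[, seq_len(J), drop = FALSE][!spec$c_mask[, seq_len(J)]] != 0))
    stopf("nonzero 'c' entry outside c_mask")
  transit <- rep_len(transit %||% 0, N)
  gain <- rep_len(gain %||% 0, N)
  stopifnot(all(is.finite(a)), all(is.finite(c)),
            all(is.finite(transit)), all(is.finite(gain)))
  structure(list(a = a, b = b, c = c, transit = transit, gain = gain),
            class = "dcm_params")
}

# dcm_params -> canonical free-parameter vector (order of param_table)
params_to_theta <- function(params, spec) {
  tab <- param_table(spec)
  th <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    th[k] <- switch(as.character(tab$type[k]),
                    "0" = params$a[tab$i[k], tab$j[k]],
                    "1" = params$b[[tab$j[k]]][tab$i[k], tab$i[k]],
                    "2" = params$c[tab$i[k], tab$j[k]],
                    "3" = params$transit[tab$i[k]],
                    "4" = params$gain[tab$i[k]])
  }
  names(th) <- tab$label
  th
}

theta_to_params <- function(theta, spec) {
  tab <- param_table(spec)
  N <- spec$n_regions
  J <- ncol(spec$u)
  a <- matrix(0, N, N)
  b <- replicate(length(spec$b_masks), matrix(0, N, N), simplify = FALSE)
  cc <- matrix(0, N, max(J, 1))
  transit <- numeric(N); gain <- numeric(N)
  for (k in seq_len(nrow(tab))) {
    v <- theta[k]
    if (tab$type[k] == 0L) a[tab$i[k], tab$j[k]] <- v
    else if (tab$type[k] == 1L) b[[tab$j[k]]][tab$i[k], tab$i[k]] <- v
    else if (tab$type[k] == 2L) cc[tab$i[k], tab$j[k]] <- v
    else if (tab$type[k] == 3L) transit[tab$i[k]] <- v
    else gain[tab$i[k]] <- v
  }
  dcm_params(spec, a = a, b = b, c = cc, transit = transit, gain = gain)
}

# effective connectivity matrix at input u (vector of length J)
effective_A <- function(params, u = NULL) {
  A <- params$a
  N <- nrow(A)
  selfscale <- diag(A)
  if (!is.null(u) && length(params$b) > 0) {
    for (j in seq_along(params$b))
      selfscale <- selfscale + u[j] * diag(params$b[[j]])
  }
  diag(A) <- -0.5 * exp(selfscale)
  A
}

#' Neuronal drift of the bilinear model
#'
#' Evaluates \eqn{\dot z = (A + \sum_j u_j B^{(j)}) z + C u}, with the
#' self-coupling convention \eqn{A_{ii} = -0.5\exp(a_{ii} + \sum_j u_j
#' b^{(j)}_{ii})} ensuring negative self-feedback (stability at small
#' extrinsic weights). The driving term is scaled as \eqn{(C/16)u}, the
#' conventional units choice that makes a unit-variance prior on C
#' commensurate with coupling parameters in Hz and keeps boxcar inputs in a
#' physiological regime.
#'
#' @param z state vector (one element per region).
#' @param u input values at the current time (length J).
#' @param params a [dcm_params()] set.
#' @param spec the matching [dcm_spec()].
#' @return the state derivative (Hz).
#' @export
neuronal_drift <- function(z, u, params, spec) {
  if (length(z) != spec$n_regions) stopf("state has wrong length")
  if (any(!is.finite(z))) stopf("non-finite neuronal state")
  A <- effective_A(params, u)
  dz <- A %*% z
  J <- ncol(spec$u)
  if (J > 0 && length(u) > 0)
    dz <- dz + (params$c[, seq_len(J), drop = FALSE] / 16) %*% u
  drop(dz)
}

#' Haemodynamic state derivatives (balloon/windkessel)
#'
#' One region's haemodynamic dynamics: a vasodilatory signal driven by
#' neuronal activity, inducing blood flow, venous ballooning and
#' deoxyhaemoglobin washout. Flow, volume and dHb are carried as logarithms so
#' positivity is structural.
#'
#' @param neural scalar neuronal activity driving the region.
#' @param h_state numeric length-4 vector \code{(s, log f, log v, log q)}.
#' @param haemo list with \code{transit} and \code{gain} log-scaling scalars.
#' @return derivative of \code{h_state}.
#' @export
haemodynamic_step <- function(neural, h_state, haemo = list(transit = 0, gain = 0)) {
  cst <- hdm_constants()
  tau <- cst[["transit"]] * exp(haemo$transit %||% 0)
  if (tau <= 0 || !is.finite(tau)) stopf("non-physical transit time")
  gn <- exp(haemo$gain %||% 0)
  s <- h_state[1]; f <- exp(h_state[2]); v <- exp(h_state[3]); q <- exp(h_state[4])
  fout <- v^(1 / cst[["stiffness"]])
  Ef <- 1 - (1 - cst[["extraction"]])^(1 / f)
  c(gn * neural - cst[["decay"]] * s - cst[["autoregulation"]] * (f - 1),
    s / f,
    (f - fout) / (tau * v),
    (f * Ef / cst[["extraction"]] - fout * q / v) / (tau * q))
}

# BOLD observation from log haemodynamic states (percent signal)
bold_signal <- function(lv, lq) {
  cst <- hdm_constants()
  E0 <- cst[["extraction"]]
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  v <- exp(lv); q <- exp(lq)
  cst[["V0"]] * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Simulate a BOLD dataset from a DCM
#'
#' Integrates the neuronal and haemodynamic equations on the microtime grid
#' (matrix-exponential propagation of the bilinear neuronal subsystem, RK4 for
#' the haemodynamic states), samples the BOLD observation at each TR, and adds
#' i.i.d. Gaussian observation noise.
#'
#' @param params a [dcm_params()] set.
#' @param spec a [dcm_spec()].
#' @param noise_sd standard deviation of additive observation noise
#'   (percent-signal units).
#' @param seed integer seed; required when \code{noise_sd > 0}. Given the
#'   seed the output is deterministic.
#' @return an object of class \code{bold_dataset} with fields \code{y}
#'   (\code{n_volumes x N}), \code{tr}, \code{n_volumes},
#'   \code{microtime_bins}, \code{u}, \code{region_labels},
#'   \code{confound_basis} (NULL), \code{noise_sd}, \code{seed}.
#' @export
simulate_bold <- function(params, spec, noise_sd = 0, seed = NULL) {
  u <- spec_inputs(spec)
  res <- dcm_simulate_cpp(effective_raw_A(params), bself_matrix(params, spec),
                          params$c, params$transit, params$gain, u,
                          spec$n_volumes, spec$microtime_bins,
                          spec$tr / spec$microtime_bins)
  if (!res$ok)
    stopf("integration diverged in region %d (%s) at t = %.2f s",
          res$bad_region, spec$region_labels[res$bad_region], res$bad_time)
  y <- res$y
  if (noise_sd > 0) {
    if (is.null(seed)) stopf("a seed is required when noise_sd > 0")
    set.seed(seed)
    y <- y + matrix(rnorm(length(y), 0, noise_sd), nrow(y), ncol(y))
  }
  colnames(y) <- spec$region_labels
  bold_dataset(y, spec, noise_sd = noise_sd, seed = seed)
}

# raw A matrix with diagonal carrying the log self-scaling (as C++ expects)
effective_raw_A <- function(params) params$a

bself_matrix <- function(params, spec) {
  N <- spec$n_regions
  J <- ncol(spec$u)
  B <- matrix(0, N, max(J, 1))
  for (j in seq_along(params$b)) B[, j] <- diag(params$b[[j]])
  B
}

#' BOLD dataset container
#'
#' @param y \code{n_volumes x N} numeric matrix of observed BOLD.
#' @param spec the [dcm_spec()] describing timing and inputs.
#' @param confound_basis optional \code{n_volumes x K} drift regressors.
#' @param noise_sd,seed provenance of simulated data (optional).
#' @return an object of class \code{bold_dataset}.
#' @export
bold_dataset <- function(y, spec, confound_basis = NULL, noise_sd = NULL,
                         seed = NULL) {
  y <- as.matrix(y)
  if (nrow(y) != spec$n_volumes)
    stopf("y has %d rows; spec expects %d volumes", nrow(y), spec$n_volumes)
  if (any(!is.finite(y))) stopf("non-finite values in BOLD data")
  structure(list(y = y, tr = spec$tr, n_volumes = spec$n_volumes,
                 microtime_bins = spec$microtime_bins, u = spec$u,
                 region_labels = spec$region_labels,
                 confound_basis = confound_basis,
                 noise_sd = noise_sd, seed = seed),
            class = "bold_dataset")
}

#' Write / read a BOLD dataset (TSV plus JSON sidecar)
#'
#' One column per region; TR, inputs (as the microtime matrix), noise level
#' and seed go to \code{<path>.json}.
#'
#' @param x a \code{bold_dataset}; \code{path} the TSV destination.
#' @return \code{path} (write) or a \code{bold_dataset} (read).
#' @export
write_bold <- function(x, path) {
  write.table(as.data.frame(x$y), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  side <- list(tr = x$tr, n_volumes = x$n_volumes,
               microtime_bins = x$microtime_bins,
               region_labels = x$region_labels,
               u = x$u, noise_sd = x$noise_sd, seed = x$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  y <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  u <- side$u
  u <- if (is.null(u) || length(u) == 0) {
    matrix(0, side$n_volumes * side$microtime_bins, 0)
  } else as.matrix(u)
  spec <- dcm_spec(ncol(y), u = u, tr = side$tr, n_volumes = side$n_volumes,
                   microtime_bins = side$microtime_bins,
                   region_labels = side$region_labels)
  bold_dataset(y, spec, noise_sd = side$noise_sd, seed = side$seed)
}
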