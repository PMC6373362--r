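#' Compile stimulus onsets to the microtime input grid
#'
#' Inputs are represented on a grid of \code{microtime_bins} subdivisions of
#' each repetition time; a bin is 1 while any stimulus epoch covers its start
#' and 0 otherwise.
#'
#' @param onsets,durations lists (one element per input) of numeric vectors in
#'   seconds; scalars are recycled over onsets.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes.
#' @param microtime_bins bins per TR.
#' @return a \code{(n_volumes * microtime_bins) x J} matrix.
#' @export
compile_inputs <- function(onsets, durations, tr, n_volumes,
                           microtime_bins = 16L) {
  if (!is.list(onsets)) onsets <- list(onsets)
  if (!is.list(durations)) durations <- list(durations)
  J <- length(onsets)
  dt <- tr / microtime_bins
  nb <- n_volumes * microtime_bins
  tgrid <- (seq_len(nb) - 1) * dt
  u <- matrix(0, nb, J)
  for (j in seq_len(J)) {
    on <- onsets[[j]]
    du <- rep_len(durations[[j]], length(on))
    for (k in seq_along(on)) {
      u[tgrid >= on[k] & tgrid < on[k] + du[k], j] <- 1
    }
  }
  u
}

#' Specify a dynamic causal model
#'
#' Defines the network structure and acquisition timing of a one-state,
#' bilinear, deterministic DCM for fMRI: which extrinsic connections are
#' allowed (\code{a_mask}), which self-connections are modulated by which
#' inputs (\code{b_masks}; the bilinear term acts on the intrinsic
#' excitability, i.e., the log self-coupling), and which regions receive
#' driving input (\code{c_mask}).
#'
#' @param n_regions number of regions N.
#' @param a_mask N x N logical; allowed extrinsic + self connections. The
#'   diagonal is always treated as present. Default: fully connected.
#' @param b_masks list (one N x N logical per input) of modulated
#'   self-connections; only diagonal entries may be TRUE. Default: none.
#' @param c_mask N x J logical of driving-input targets.
#' @param u microtime input matrix (rows = \code{n_volumes * microtime_bins}),
#'   or NULL to compile from \code{onsets}/\code{durations}.
#' @param onsets,durations per-input stimulus timing (seconds), used when
#'   \code{u} is NULL.
#' @param tr repetition time (s).
#' @param n_volumes number of volumes per session.
#' @param microtime_bins integration bins per TR (>= 2; default 16).
#' @param mean_centre_inputs subtract each input's session mean before it
#'   enters the bilinear and driving terms (the mean-centred-input option).
#' @param region_labels optional node names.
#' @return an object of class \code{dcm_spec}.
#' @export
dcm_spec <- function(n_regions, a_mask = NULL, b_masks = NULL, c_mask = NULL,
                     u = NULL, onsets = NULL, durations = NULL,
                     tr = 4, n_volumes = 114, microtime_bins = 16L,
                     mean_centre_inputs = TRUE, region_labels = NULL) {
  N <- as.integer(n_regions)
  region_labels <- region_labels %||% paste0("R", seq_len(N))
  if (is.null(a_mask)) a_mask <- matrix(TRUE, N, N)
  a_mask <- as.matrix(a_mask)
  if (!identical(dim(a_mask), c(N, N))) stopf("a_mask must be %d x %d", N, N)
  diag(a_mask) <- TRUE
  if (is.null(u)) {
    if (is.null(onsets)) {
      u <- matrix(0, n_volumes * microtime_bins, 0)
    } else {
      u <- compile_inputs(onsets, durations %||% 0, tr, n_volumes,
                          microtime_bins)
    }
  }
  u <- as.matrix(u)
  if (nrow(u) != n_volumes * microtime_bins)
    stopf("input grid has %d rows; expected n_volumes * microtime_bins = %d",
          nrow(u), n_volumes * microtime_bins)
  J <- ncol(u)
  if (is.null(c_mask)) {
    c_mask <- matrix(FALSE, N, max(J, 1))
    if (J > 0) c_mask[1, ] <- TRUE # default: input drives region 1
  }
  c_mask <- as.matrix(c_mask)
  if (J > 0 && !any(c_mask)) stopf("at least one c_mask entry must be TRUE")
  if (is.null(b_masks)) b_masks <- vector("list", 0)
  if (length(b_masks) > 0) {
    if (length(b_masks) != J) stopf("need one b_mask per input")
    for (bm in b_masks) {
      if (any(bm & !diag(TRUE, N)))
        stopf("b_masks may modulate self-connections only")
      if (any(bm & !a_mask))
        stopf("b_masks must be a subset of a_mask")
    }
  }
  structure(list(n_regions = N, a_mask = a_mask, b_masks = b_masks,
                 c_mask = c_mask, u = u, tr = tr,
                 n_volumes = as.integer(n_volumes),
                 microtime_bins = as.integer(microtime_bins),
                 mean_centre_inputs = isTRUE(mean_centre_inputs),
                 region_labels = region_labels),
            class = "dcm_spec")
}

# effective (possibly mean-centred) microtime inputs
spec_inputs <- function(spec) {
  u <- spec$u
  if (ncol(u) > 0 && spec$mean_centre_inputs)
    u <- sweep(u, 2, colMeans(u))
  u
}

# canonical free-parameter table: A (column-major over mask), B (per input,
# self only), C, transit, gain. Types match the C++ codes.
param_table <- function(spec) {
  N <- spec$n_regions
  rows <- list()
  idx <- which(spec$a_mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  rows$A <- data.frame(type = 0L, i = idx[, 1], j = idx[, 2],
                       label = sprintf("A(%d,%d)", idx[, 1], idx[, 2]))
  if (length(spec$b_masks) > 0) {
    bs <- do.call(rbind, lapply(seq_along(spec$b_masks), function(j) {
      d <- which(diag(spec$b_masks[[j]]))
      if (length(d) == 0) return(NULL)
      data.frame(type = 1L, i = d, j = j,
                 label = sprintf("B%d(%d,%d)", j, d, d))
    }))
    rows$B <- bs
  }
  J <- ncol(spec$u)
  if (J > 0) {
    ci <- which(spec$c_mask[, seq_len(J), drop = FALSE], arr.ind = TRUE)
    ci <- ci[order(ci[, 2], ci[, 1]), , drop = FALSE]
    rows$C <- data.frame(type = 2L, i = ci[, 1], j = ci[, 2],
                         label = sprintf("C(%d,%d)", ci[, 1], ci[, 2]))
  }
  rows$transit <- data.frame(type = 3L, i = seq_len(N), j = 1L,
                             label = sprintf("transit(%d)", seq_len(N)))
  rows$gain <- data.frame(type = 4L, i = seq_len(N), j = 1L,
                          label = sprintf("gain(%d)", seq_len(N)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat(sprintf("DCM specification: %d regions, %d input(s), TR = %gs, %d volumes (%d bins/TR)\n",
              x$n_regions, ncol(x$u), x$tr, x$n_volumes, x$microtime_bins))
  cat(sprintf("  extrinsic connections: %d of %d possible; modulatory inputs: %d; driven regions: %s\n",
              sum(x$a_mask) - x$n_regions, x$n_regions * (x$n_regions - 1),
              length(x$b_masks),
              if (ncol(x$u) > 0) paste(which(apply(x$c_mask, 1, any)),
                                       collapse = ",") else "none"))
  invisible(x)
}
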