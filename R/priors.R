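#' Default shrinkage priors for a DCM
#'
#' Every parameter gets an independent zero-mean Gaussian prior. Extrinsic
#' (between-region) couplings get variance \code{sigma_a} (default 0.5, the
#' maximal prior variance used throughout); log self-connections and
#' modulatory terms get 1/64; driving inputs 1; haemodynamic log-scaling
#' parameters 1/64. Values other than \code{sigma_a} are declared package
#' defaults (the framework this implements leaves them to the estimation
#' scheme) and are echoed in the returned object.
#'
#' @param spec a [dcm_spec()].
#' @param sigma_a prior variance of extrinsic connections.
#' @param sigma_self,sigma_b,sigma_c,sigma_transit,sigma_gain remaining
#'   variances.
#' @return an object of class \code{dcm_prior}: list with \code{mean}
#'   (named), \code{cov} (diagonal matrix), \code{labels} and \code{table}
#'   (parameter coordinates).
#' @export
dcm_priors <- function(spec, sigma_a = 0.5, sigma_self = 1 / 64,
                       sigma_b = 1 / 64, sigma_c = 1,
                       sigma_transit = 1 / 64, sigma_gain = 1 / 64) {
  tab <- param_table(spec)
  v <- numeric(nrow(tab))
  ext <- tab$type == 0L & tab$i != tab$j
  v[ext] <- sigma_a
  v[tab$type == 0L & tab$i == tab$j] <- sigma_self
  v[tab$type == 1L] <- sigma_b
  v[tab$type == 2L] <- sigma_c
  v[tab$type == 3L] <- sigma_transit
  v[tab$type == 4L] <- sigma_gain
  new_prior(setNames(rep(0, nrow(tab)), tab$label), diag(v, nrow(tab)), tab,
            defaults = list(sigma_a = sigma_a, sigma_self = sigma_self,
                            sigma_b = sigma_b, sigma_c = sigma_c,
                            sigma_transit = sigma_transit,
                            sigma_gain = sigma_gain))
}

new_prior <- function(mean, cov, table, defaults = NULL) {
  cov <- as.matrix(cov)
  dimnames(cov) <- list(names(mean), names(mean))
  if (max(abs(cov - t(cov))) > 1e-10) stopf("prior covariance not symmetric")
  if (any(diag(cov) < 0)) stopf("negative prior variance")
  structure(list(mean = mean, cov = cov, labels = names(mean),
                 table = table, defaults = defaults),
            class = "dcm_prior")
}

#' Replace prior variances for selected parameters
#'
#' @param prior a \code{dcm_prior}.
#' @param labels parameter labels to modify.
#' @param variances new variances (recycled); a variance of exactly 0 pins
#'   the parameter to its prior mean.
#' @return the modified prior.
#' @export
set_prior_variance <- function(prior, labels, variances) {
  idx <- match(labels, prior$labels)
  if (anyNA(idx))
    stopf("unknown parameter label(s): %s",
          paste(labels[is.na(idx)], collapse = ", "))
  variances <- rep_len(variances, length(idx))
  prior$cov[idx, ] <- 0
  prior$cov[, idx] <- 0
  diag(prior$cov)[idx] <- variances
  prior
}

#' @export
print.dcm_prior <- function(x, ...) {
  cat(sprintf("Gaussian prior over %d parameters\n", length(x$mean)))
  tv <- tapply(diag(x$cov), x$table$type, function(z) paste(
    format(sort(unique(round(z, 6)))), collapse = "/"))
  nm <- c("0" = "A", "1" = "B", "2" = "C", "3" = "transit", "4" = "gain")
  for (t in names(tv)) cat(sprintf("  %s variance: %s\n", nm[[t]], tv[[t]]))
  invisible(x)
}
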