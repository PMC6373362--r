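#' @keywords internal
"_PACKAGE"

#' @useDynLib sipeb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm optimize rnorm runif setNames coef fitted residuals
#'   simulate var sd qnorm pnorm rexp
#' @importFrom utils modifyList read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

sym_part <- function(M) (M + t(M)) / 2

chol_inv <- function(M) chol2inv(chol(sym_part(M)))

logdet <- function(M) {
  2 * sum(log(diag(chol(sym_part(M)))))
}

# log N(x; m, C) for a dense covariance
ldmvnorm <- function(x, m, C) {
  R <- chol(sym_part(C))
  d <- backsolve(R, x - m, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(d^2)
}

# KL( N(m1,C1) || N(m0,C0) ), C0 supplied as precision P0 with its log-det
gauss_kl <- function(m1, C1, m0, P0, logdet_C0) {
  d <- m1 - m0
  0.5 * (sum(C1 * P0) + drop(crossprod(d, P0 %*% d)) - length(m1) +
           logdet_C0 - logdet(C1))
}

# deterministic sub-stream seeds below 2^31
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + k * 10007) %% 2147483629)
}

# FNV-1a hash of a serialised R object, as 8 hex digits (artifact provenance)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
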