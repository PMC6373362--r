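#' Directional streamline-count table
#'
#' Container for the raw output of probabilistic tractography between a set of
#' regions: entry \code{(seed, target)} is the streamline average count from
#' the seed to the target region (the mean, over seed voxels, of the number of
#' streamlines reaching the target). The matrix is directional and generally
#' asymmetric; the diagonal carries no information and is ignored.
#'
#' @param counts square numeric matrix of non-negative streamline averages.
#' @param region_labels character vector of node names; defaults to the
#'   dimnames of \code{counts}.
#' @param subject_id optional identifier.
#' @return an object of class \code{streamline_counts}.
#' @export
streamline_counts <- function(counts, region_labels = NULL, subject_id = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stopf("streamline count matrix must be square (got %d x %d)",
          nrow(counts), ncol(counts))
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("negative or non-finite streamline count at entry (%d, %d)",
          bad[1, 1], bad[1, 2])
  region_labels <- region_labels %||% rownames(counts) %||%
    paste0("R", seq_len(nrow(counts)))
  if (length(region_labels) != nrow(counts))
    stopf("%d region labels supplied for a %d-region matrix",
          length(region_labels), nrow(counts))
  dimnames(counts) <- list(region_labels, region_labels)
  structure(list(counts = counts, region_labels = region_labels,
                 subject_id = subject_id),
            class = "streamline_counts")
}

#' Average the two tractography directions of a streamline-count table
#'
#' Diffusion imaging carries no directional information and streamline counts
#' depend on which region is the seed, so the two directions are averaged:
#' \code{out[i, j] = (counts[i, j] + counts[j, i]) / 2}. The diagonal is set
#' to zero (self entries are undefined).
#'
#' @param counts a [streamline_counts] object or a square non-negative matrix.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
symmetrize_counts <- function(counts) {
  if (!inherits(counts, "streamline_counts")) counts <- streamline_counts(counts)
  M <- (counts$counts + t(counts$counts)) / 2
  diag(M) <- 0
  M
}

#' Group structural connectome
#'
#' Averages per-subject symmetric streamline matrices at the group level,
#' zeroes forbidden pairs and the diagonal, and scales relative to the maximum
#' remaining connection strength so that the strongest group-average
#' connection equals 1. No thresholding is applied: zero and near-zero
#' strengths are retained and simply induce small prior variance downstream.
#'
#' @param subject_matrices a list of symmetric non-negative matrices (one per
#'   subject, identical dimensions and labels), or a single matrix.
#' @param forbidden_mask optional square logical matrix marking region pairs
#'   with no structural assessment; these are pinned to exactly zero.
#' @return an object of class \code{connectome} with elements \code{phi}
#'   (symmetric, in \eqn{[0, 1]}), \code{region_labels}, \code{forbidden_mask}
#'   and \code{scale} (the divisor used for max-scaling).
#' @export
group_connectome <- function(subject_matrices, forbidden_mask = NULL) {
  if (is.matrix(subject_matrices)) subject_matrices <- list(subject_matrices)
  if (length(subject_matrices) < 1) stopf("need at least one subject matrix")
  dims <- vapply(subject_matrices, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[1, 1]))
    stopf("subject matrices differ in shape")
  labels <- rownames(as.matrix(subject_matrices[[1]])) %||%
    paste0("R", seq_len(dims[1, 1]))
  for (m in subject_matrices) {
    lm <- rownames(as.matrix(m))
    if (!is.null(lm) && !identical(lm, labels))
      stopf("region labels differ across subject matrices")
  }
  N <- dims[1, 1]
  phi <- Reduce(`+`, lapply(subject_matrices, as.matrix)) /
    length(subject_matrices)
  phi <- sym_part(phi)
  diag(phi) <- 0
  if (is.null(forbidden_mask)) {
    forbidden_mask <- matrix(FALSE, N, N)
  } else {
    forbidden_mask <- as.matrix(forbidden_mask)
    if (!identical(dim(forbidden_mask), c(N, N)))
      stopf("forbidden_mask shape does not match the connectome")
    forbidden_mask <- forbidden_mask | t(forbidden_mask)
  }
  diag(forbidden_mask) <- FALSE
  phi[forbidden_mask] <- 0
  mx <- max(phi)
  if (mx <= 0) {
    warning("all-zero structural matrix; max-scaling skipped", call. = FALSE)
    mx <- 1
  }
  phi <- phi / mx
  dimnames(phi) <- list(labels, labels)
  dimnames(forbidden_mask) <- list(labels, labels)
  structure(list(phi = phi, region_labels = labels,
                 forbidden_mask = forbidden_mask, scale = mx),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Group structural connectome\n")
  cat(sprintf("  regions: %d (%s%s)\n", length(x$region_labels),
              paste(utils::head(x$region_labels, 4), collapse = ", "),
              if (length(x$region_labels) > 4) ", ..." else ""))
  offdiag <- x$phi[upper.tri(x$phi)]
  cat(sprintf("  phi range: [%.3f, %.3f], nonzero pairs: %d/%d\n",
              min(offdiag), max(offdiag), sum(offdiag > 0), length(offdiag)))
  cat(sprintf("  forbidden pairs: %d, scaling factor: %.4g\n",
              sum(x$forbidden_mask[upper.tri(x$forbidden_mask)]), x$scale))
  invisible(x)
}

#' Read a streamline-count table from CSV/TSV
#'
#' Expects a header row of region labels and a matching first column.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (\code{.tsv} = tab, otherwise comma).
#' @param subject_id optional identifier.
#' @return a [streamline_counts] object.
#' @export
read_streamline_counts <- function(path, subject_id = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  M <- as.matrix(df)
  if (!identical(rownames(M), colnames(M)))
    stopf("row and column labels disagree in %s", path)
  streamline_counts(M, subject_id = subject_id %||% basename(path))
}

#' Write / read a group connectome (CSV plus JSON sidecar)
#'
#' The matrix is written as CSV with labelled rows and columns; labels,
#' forbidden pairs and the scaling factor go to \code{<path>.json}.
#'
#' @param x a \code{connectome}.
#' @param path CSV destination.
#' @return \code{path}, invisibly.
#' @export
write_connectome <- function(x, path) {
  df <- data.frame(region = x$region_labels, x$phi, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  fp <- which(x$forbidden_mask & upper.tri(x$forbidden_mask), arr.ind = TRUE)
  side <- list(
    region_labels = x$region_labels,
    forbidden_pairs = if (nrow(fp) > 0)
      data.frame(from = x$region_labels[fp[, 1]],
                 to = x$region_labels[fp[, 2]]) else list(),
    scale = x$scale
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  labels <- as.character(df[[1]])
  phi <- as.matrix(df[, -1, drop = FALSE])
  dimnames(phi) <- list(labels, labels)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  N <- length(labels)
  forbidden <- matrix(FALSE, N, N, dimnames = list(labels, labels))
  fp <- side$forbidden_pairs
  if (is.data.frame(fp) && nrow(fp) > 0) {
    for (k in seq_len(nrow(fp))) {
      i <- match(fp$from[k], labels); j <- match(fp$to[k], labels)
      forbidden[i, j] <- forbidden[j, i] <- TRUE
    }
  }
  structure(list(phi = phi, region_labels = labels,
                 forbidden_mask = forbidden,
                 scale = side$scale %||% 1),
            class = "connectome")
}

#' Region labels of the 12-node biological-motion network template
#'
#' Labels (only — no claim about real anatomy) mirroring the published
#' 12-region network used as a structural template for the full-scale
#' synthetic fixture, together with the conventional exclusion of
#' cerebellar-occipital pairs from structural assessment. The cerebellar
#' node is labelled per the published coordinate table ("Crus I"), which
#' differs from the running text ("lobule VI") of the source description.
#'
#' @return a list with \code{labels} (length 12) and \code{forbidden_mask}
#'   (12 x 12 logical; the 5 undirected cerebellar-occipital pairs).
#' @export
bm_network_template <- function() {
  labels <- c("L MT", "R MT", "R insula", "L cerebellar Crus I", "R STS",
              "R FFG", "R IFG", "L V6", "L V3", "R V1", "L V1", "R V3")
  occipital <- c("L V6", "L V3", "R V1", "L V1", "R V3")
  forbidden <- matrix(FALSE, 12, 12, dimnames = list(labels, labels))
  cb <- match("L cerebellar Crus I", labels)
  oc <- match(occipital, labels)
  forbidden[cb, oc] <- TRUE
  forbidden[oc, cb] <- TRUE
  list(labels = labels, forbidden_mask = forbidden)
}
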