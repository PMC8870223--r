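#' Counts per million
#'
#' Scales each sample (column) so that it sums to one million.  The log2
#' transform used elsewhere in the pipeline adds a pseudo-count of 0.5 to
#' the raw counts before scaling (see [log2_cpm()]); `compute_cpm` itself is
#' the plain linear normalization.
#'
#' @param counts a [count_matrix()] or plain non-negative matrix.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
compute_cpm <- function(counts) {
  m <- unclass(as.matrix(counts))
  lib <- colSums(m)
  if (any(lib == 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(m)[lib == 0], collapse = ", "))
  sweep(m, 2, lib, "/") * 1e6
}

#' log2 CPM with a 0.5 pseudo-count
#'
#' log2((count + 0.5) / (library size + 1) * 1e6).  The pseudo-count avoids
#' -Inf for zero counts; the +1 on the library size keeps columns comparable.
#'
#' @inheritParams compute_cpm
#' @export
log2_cpm <- function(counts) {
  m <- unclass(as.matrix(counts))
  lib <- colSums(m)
  if (any(lib == 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(m)[lib == 0], collapse = ", "))
  log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = count / (length_kb * mapped_millions), the classic length- and
#' depth-normalized expression unit.
#'
#' @param counts a [count_matrix()] carrying feature lengths, or a plain
#'   matrix with `lengths` supplied.
#' @param lengths feature lengths in bp (taken from the count_matrix when
#'   omitted).
#' @return Numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths = NULL) {
  m <- unclass(as.matrix(counts))
  if (is.null(lengths)) lengths <- feature_lengths(counts)
  if (is.null(lengths))
    stopf("feature lengths are required for RPKM")
  if (length(lengths) != nrow(m))
    stopf("lengths must have one entry per feature")
  bad <- !is.finite(lengths) | lengths <= 0
  if (any(bad))
    stopf("missing or non-positive length for feature(s): %s",
          paste(rownames(m)[bad], collapse = ", "))
  lib <- colSums(m)
  if (any(lib == 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(m)[lib == 0], collapse = ", "))
  sweep(sweep(m, 1, lengths / 1e3, "/"), 2, lib / 1e6, "/")
}

#' Row-wise z-scores
#'
#' Centers and scales each feature across samples: mean 0, sd 1 (sample sd,
#' n-1 denominator).  Constant rows, whose sd is zero, map to all-zero rows.
#' This is the transform used for expression heatmaps.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stopf("z-scores need >= 2 samples per row")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' PCA embedding of samples
#'
#' Centered (not scaled) singular value decomposition of the sample x
#' feature matrix; returns per-sample coordinates on the leading principal
#' components, plus the fraction of variance each explains.
#'
#' @param m numeric matrix, features x samples (e.g. log2 CPM).
#' @param n_components number of components to return.
#' @return A list with `coords` (samples x components), `var_explained`.
#' @export
pca_embed <- function(m, n_components = 2) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stopf("PCA needs >= 2 samples")
  if (n_components > ncol(m))
    stopf("requested %d components for %d samples", n_components, ncol(m))
  p <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- seq_len(min(n_components, ncol(p$x)))
  co <- p$x[, k, drop = FALSE]
  ve <- (p$sdev^2 / sum(p$sdev^2))[k]
  list(coords = co, var_explained = ve)
}
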