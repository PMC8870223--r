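#' Feature-by-sample count matrix with condition labels
#'
#' Light container for gene- or peak-level read counts.  Rows are features
#' (genes or reference peaks), columns are samples; every sample carries a
#' culture-condition label (e.g. \code{MONO}, \code{TSW}, \code{CO}) and
#' features may carry lengths in bp (needed for RPKM).
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param condition character vector of condition labels, one per sample.
#' @param lengths optional numeric vector of feature lengths in bp.
#' @return An object of class \code{count_matrix}: the count matrix with
#'   \code{condition} and \code{lengths} attributes.
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, condition = c("MONO", "MONO", "CO", "CO"))
#' conditions(cm)
#' @export
count_matrix <- function(counts, condition, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs feature and sample names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate feature identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (length(condition) != ncol(counts))
    stopf("need one condition label per sample (%d labels for %d samples)",
          length(condition), ncol(counts))
  if (anyNA(condition)) stopf("every sample needs a condition label")
  if (!is.null(lengths)) {
    if (length(lengths) != nrow(counts))
      stopf("lengths must have one entry per feature")
    if (any(!is.finite(lengths)) || any(lengths <= 0))
      stopf("feature lengths must be positive")
    lengths <- setNames(as.numeric(lengths), rownames(counts))
  }
  structure(counts,
            condition = setNames(as.character(condition), colnames(counts)),
            lengths = lengths,
            class = c("count_matrix", "matrix", "array"))
}

#' @rdname count_matrix
#' @param x a \code{count_matrix}.
#' @export
conditions <- function(x) attr(x, "condition")

#' @rdname count_matrix
#' @export
feature_lengths <- function(x) attr(x, "lengths")

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  tab <- table(conditions(x))
  cat("conditions:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  if (!is.null(feature_lengths(x))) cat("feature lengths: present\n")
  invisible(x)
}

# subset samples, keeping attributes in step
subset_samples <- function(cm, keep) {
  count_matrix(unclass(cm)[, keep, drop = FALSE],
               condition = conditions(cm)[keep],
               lengths = feature_lengths(cm))
}
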