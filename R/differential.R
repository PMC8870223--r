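#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1.  Thin validating wrapper around
#' `p.adjust(method = "BH")` so that malformed p-values fail loudly.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression between two culture conditions
#'
#' Negative-binomial differential testing (edgeR: TMM normalization,
#' tagwise dispersion, exact test) between a baseline and a comparison
#' condition, with the three-way call rule used throughout the pipeline:
#' a gene is called up or down iff FDR < `fdr`, |fold change| > `fc`, and
#' average log2 CPM > `min_log2cpm`.  The average log2 CPM is computed with a
#' 0.5 pseudo-count ([log2_cpm()]) and averaged over the samples of the two
#' conditions under test.
#'
#' @param counts a [count_matrix()] (genes x samples).
#' @param baseline,comparison condition labels; fold changes are
#'   comparison over baseline.
#' @param fdr FDR threshold for the call (default 0.05).
#' @param fc fold-change threshold, linear scale (default 1.5; applied
#'   two-sided as |log2FC| > log2(fc)).
#' @param min_log2cpm expression floor on average log2 CPM (default 0).
#' @return A data.frame with columns `feature`, `log2fc`, `log2cpm`,
#'   `pvalue`, `fdr`, `call` (factor: up/down/unchanged), ordered as the
#'   input features.
#' @export
differential_expression <- function(counts, baseline, comparison,
                                    fdr = 0.05, fc = 1.5, min_log2cpm = 0) {
  cond <- conditions(counts)
  for (lab in c(baseline, comparison))
    if (!lab %in% cond) stopf("condition '%s' not present in the data", lab)
  keep <- cond %in% c(baseline, comparison)
  cm <- subset_samples(counts, which(keep))
  grp <- factor(conditions(cm), levels = c(baseline, comparison))
  if (any(table(grp) < 2))
    stopf("need >= 2 replicates per condition (got %s)",
          paste(table(grp), collapse = " vs "))

  y <- edgeR::DGEList(counts = unclass(cm), group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- suppressWarnings(tryCatch(edgeR::estimateDisp(y), error = function(e) y))
  et <- if (!is.null(y$tagwise.dispersion) || !is.null(y$common.dispersion)) {
    edgeR::exactTest(y, pair = c(baseline, comparison))
  } else {
    # degenerate data (e.g. zero within-group variance): dispersion cannot
    # be estimated; a small fixed value keeps the test defined
    edgeR::exactTest(y, pair = c(baseline, comparison), dispersion = 0.05)
  }
  res <- et$table  # logFC, logCPM, PValue in input feature order

  l2cpm <- rowMeans(log2_cpm(cm))
  q <- bh_fdr(res$PValue)
  call <- rep("unchanged", nrow(res))
  sig <- q < fdr & abs(res$logFC) > log2(fc) & l2cpm > min_log2cpm
  call[sig & res$logFC > 0] <- "up"
  call[sig & res$logFC < 0] <- "down"
  out <- data.frame(feature = rownames(cm),
                    log2fc = res$logFC,
                    log2cpm = l2cpm,
                    pvalue = res$PValue,
                    fdr = q,
                    call = factor(call, levels = c("up", "down", "unchanged")),
                    row.names = NULL, stringsAsFactors = FALSE)
  # TMM-effective library sizes, for consumers re-deriving normalized means
  attr(out, "effective_libsize") <-
    setNames(y$samples$lib.size * y$samples$norm.factors, colnames(cm))
  out
}

#' Differential chromatin accessibility between conditions
#'
#' Same negative-binomial machinery as [differential_expression()] applied
#' to reference-peak read counts, with the stricter thresholds used for
#' accessibility: FDR < 0.01 and |fold change| > 1.5 by default, and no
#' expression floor.
#'
#' @inheritParams differential_expression
#' @export
differential_peaks <- function(counts, baseline, comparison,
                               fdr = 0.01, fc = 1.5) {
  differential_expression(counts, baseline, comparison,
                          fdr = fdr, fc = fc, min_log2cpm = -Inf)
}

#' Posterior fold-change bound (GFOLD-style value)
#'
#' Reliability-aware log2 fold change for designs with few or no
#' replicates.  Each group's normalized read rate gets a Gamma posterior
#' under a Poisson likelihood with the Jeffreys prior (shape 1/2): rate |
#' counts ~ Gamma(sum(counts) + 1/2, sum(libsizes)).  The ratio of two
#' independent Gamma rates is a scaled F variate, so the central credible
#' interval of log2(rateB / rateA) is available in closed form.  The value
#' returned is the interval bound nearest zero: the lower bound when the
#' whole interval is positive, the upper bound when it is negative, and 0
#' when the interval spans zero.  |value| > log2(1.5) = 0.585 is the
#' conventional differential cutoff.
#'
#' @param countsA,countsB integer count vectors (one entry per sample).
#' @param libsizesA,libsizesB library sizes matching each count vector.
#' @param credibility central credible mass (default 0.99).
#' @return Signed numeric scalar (log2 units).
#' @export
gfold_value <- function(countsA, countsB, libsizesA, libsizesB,
                        credibility = 0.99) {
  if (length(countsA) < 1 || length(countsB) < 1)
    stopf("both groups need >= 1 sample")
  if (length(libsizesA) != length(countsA) ||
      length(libsizesB) != length(countsB))
    stopf("library sizes must match counts")
  if (credibility <= 0 || credibility >= 1)
    stopf("credibility must lie in (0, 1)")
  aA <- sum(countsA) + 0.5; rA <- sum(libsizesA)
  aB <- sum(countsB) + 0.5; rB <- sum(libsizesB)
  lo_q <- (1 - credibility) / 2
  # rateB/rateA = (aB/rB)/(aA/rA) * F(2*aB, 2*aA) in distribution
  scale <- (aB / rB) / (aA / rA)
  lo <- log2(scale * qf(lo_q, 2 * aB, 2 * aA))
  hi <- log2(scale * qf(1 - lo_q, 2 * aB, 2 * aA))
  if (lo > 0) lo else if (hi < 0) hi else 0
}

#' @rdname gfold_value
#' @param fc fold-change threshold the cutoff corresponds to.
#' @return `gfold_cutoff` returns the |GFOLD value| cutoff corresponding to
#'   a linear fold change `fc` (log2(1.5) = 0.585 for the default).
#' @export
gfold_cutoff <- function(fc = 1.5) log2(fc)
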