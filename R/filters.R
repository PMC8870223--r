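#' Stromal-signature gene filter
#'
#' Direct coculture samples carry a small stromal-cell contamination, so
#' genes that are hallmarks of the stroma and silent in the tumor cells can
#' masquerade as induced.  A gene is excluded iff (a) it ranks in the top
#' `top_n` of the stromal expression profile (descending; ties at the
#' boundary are all included, so the cut is deterministic and
#' order-independent) and (b) its maximum RPKM across all tumor-cell
#' samples is below `silent_rpkm`.
#'
#' @param mm_rpkm RPKM matrix of the tumor (myeloma) samples, genes x samples.
#' @param stromal_rpkm named numeric vector: stromal expression per gene.
#' @param top_n stromal rank cutoff (default 1000).
#' @param silent_rpkm "silent in tumor" ceiling (default 2).
#' @return Character vector of excluded gene ids.
#' @export
stromal_signature_filter <- function(mm_rpkm, stromal_rpkm,
                                     top_n = 1000, silent_rpkm = 2) {
  if (length(stromal_rpkm) == 0) stopf("stromal expression vector is empty")
  if (is.null(names(stromal_rpkm))) stopf("stromal vector must be named by gene")
  mm_rpkm <- as.matrix(mm_rpkm)
  ord <- sort(stromal_rpkm, decreasing = TRUE)
  if (length(ord) <= top_n) {
    top <- names(ord)
  } else {
    cutoff <- ord[top_n]
    top <- names(ord)[ord >= cutoff]  # ties at the boundary all included
  }
  shared <- intersect(top, rownames(mm_rpkm))
  silent <- shared[apply(mm_rpkm[shared, , drop = FALSE], 1, max) < silent_rpkm]
  sort(silent)
}

#' Promoter-openness gene filter
#'
#' Genes whose promoter chromatin is closed in every culture condition are
#' unlikely to be genuinely expressed by the tumor cells and are excluded.
#' "Open in condition c" means the promoter window overlaps at least one
#' reference peak supported by that condition's samples.  By default a gene
#' is excluded iff its promoter is closed in ALL conditions; setting
#' `require_all_open = TRUE` switches to the stricter reading that excludes
#' any gene not open in every condition.
#'
#' @param open_status logical matrix, genes x conditions: TRUE = promoter
#'   open in that condition.
#' @param conditions condition labels to consider (default: all columns).
#' @param require_all_open if TRUE, exclude genes not open in all
#'   conditions; if FALSE (default), exclude only genes closed in all.
#' @return Character vector of excluded gene ids.
#' @export
promoter_open_filter <- function(open_status, conditions = colnames(open_status),
                                 require_all_open = FALSE) {
  open_status <- as.matrix(open_status)
  missing <- setdiff(conditions, colnames(open_status))
  if (length(missing))
    stopf("no promoter status for condition(s): %s", paste(missing, collapse = ", "))
  m <- open_status[, conditions, drop = FALSE]
  if (anyNA(m)) stopf("promoter status contains NA")
  excl <- if (require_all_open) !apply(m, 1, all) else !apply(m, 1, any)
  sort(rownames(m)[excl])
}

#' Build a rank file from differential-expression results
#'
#' Two-column ranking (gene, fold change) sorted descending by fold change,
#' the preranked input to GSEA.  Genes on the exclusion list (stromal
#' signature, closed promoter) are omitted.  Ties in fold change are broken
#' by gene id so the output is deterministic.
#'
#' @param results data.frame from [differential_expression()].
#' @param exclude character vector of gene ids to drop.
#' @param score column of `results` to rank by (default `log2fc`).
#' @return data.frame with columns `gene`, `score`, sorted descending.
#' @export
make_rnk <- function(results, exclude = character(), score = "log2fc") {
  if (anyDuplicated(results$feature))
    stopf("duplicate gene symbols in results")
  if (!score %in% names(results)) stopf("no column '%s' in results", score)
  keep <- !(results$feature %in% exclude)
  out <- data.frame(gene = results$feature[keep],
                    score = results[[score]][keep],
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
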