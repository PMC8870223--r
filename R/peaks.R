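#' Compile a consensus reference peak set across samples
#'
#' Per-sample peak calls are merged into union intervals (calls that
#' overlap or directly abut are merged), each merged interval gets a
#' support count -- the number of distinct samples contributing at least
#' one overlapping call -- and intervals supported by at least
#' `min_support` samples are retained.  The consensus summit of a retained
#' interval is the median of the contributing calls' summits (lower median
#' on ties), so it always coincides with an observed summit.
#'
#' All coordinates are 1-based closed `GRanges`; file readers and writers
#' handle BED's 0-based half-open convention.
#'
#' @param peak_list list of `GRanges`, one per sample, each with a `summit`
#'   metadata column (absolute position, NA when absent).
#' @param min_support minimum number of supporting samples (default 3).
#' @return `GRanges` of reference peaks with metadata columns `support`
#'   and `summit`, sorted, named `peak_1 ... peak_n`.
#' @export
compile_reference_peaks <- function(peak_list, min_support = 3) {
  if (!is.list(peak_list) && !methods::is(peak_list, "GRangesList"))
    stopf("peak_list must be a list of GRanges")
  if (length(peak_list) < min_support)
    stopf("only %d samples supplied but min_support = %d",
          length(peak_list), min_support)
  all <- unlist(GenomicRanges::GRangesList(lapply(peak_list, function(g) {
    mc <- S4Vectors::mcols(g)
    S4Vectors::mcols(g) <- NULL
    g$summit <- if ("summit" %in% names(mc)) mc$summit else NA_integer_
    g
  })), use.names = FALSE)
  sample_of <- rep(seq_along(peak_list), vapply(peak_list, length, 1L))

  merged <- GenomicRanges::reduce(all)  # merges overlapping and abutting calls
  hits <- GenomicRanges::findOverlaps(merged, all)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  support <- unname(vapply(split(sample_of[sh], factor(qh, seq_along(merged))),
                           function(s) length(unique(s)), 1L))
  keep <- support >= min_support
  ref <- merged[keep]
  support <- support[keep]
  if (length(ref) == 0) {
    ref$support <- integer(0)
    ref$summit <- integer(0)
    return(ref)
  }

  # consensus summit: lower median of contributing summits
  summit <- rep(NA_integer_, length(ref))
  keep_idx <- which(keep)
  by_peak <- split(all$summit[sh], factor(qh, seq_along(merged)))
  for (i in seq_along(keep_idx)) {
    s <- sort(by_peak[[keep_idx[i]]])
    s <- s[!is.na(s)]
    if (length(s)) summit[i] <- s[ceiling(length(s) / 2)]
  }
  ref$support <- support
  ref$summit <- summit
  ref <- GenomicRanges::sort(ref)
  names(ref) <- paste0("peak_", seq_along(ref))
  ref
}

#' Count reads in reference peaks by the midpoint rule
#'
#' A read (fragment interval) is assigned to a peak iff its midpoint falls
#' inside the peak; since reference peaks are disjoint, every read is
#' counted at most once and a read spanning a peak boundary is assigned
#' unambiguously.  The midpoint of a read on \[start, end\] (1-based
#' closed) is `floor((start + end) / 2)`.
#'
#' @param read_list list of `GRanges` (one per sample) of read/fragment
#'   intervals.
#' @param peaks reference `GRanges` from [compile_reference_peaks()].
#' @param condition condition label per sample (same length as
#'   `read_list`).
#' @return A [count_matrix()], peaks x samples.  Reads on chromosomes
#'   absent from the peak set are skipped with a warning.
#' @export
count_reads_in_peaks <- function(read_list, peaks, condition) {
  if (length(condition) != length(read_list))
    stopf("need one condition label per sample")
  sample_names <- names(read_list) %||% paste0("sample_", seq_along(read_list))
  peak_chr <- GenomicRanges::seqnames(peaks)
  counts <- matrix(0L, length(peaks), length(read_list),
                   dimnames = list(names(peaks), sample_names))
  for (j in seq_along(read_list)) {
    r <- read_list[[j]]
    unknown <- !(as.character(GenomicRanges::seqnames(r)) %in%
                   as.character(unique(peak_chr)))
    if (any(unknown)) {
      warnf("sample %s: %d read(s) on chromosomes absent from the peak set; skipped",
            sample_names[j], sum(unknown))
      r <- r[!unknown]
    }
    mid <- floor((GenomicRanges::start(r) + GenomicRanges::end(r)) / 2)
    mids <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(r)),
                                   IRanges::IRanges(mid, width = 1))
    counts[, j] <- GenomicRanges::countOverlaps(peaks, mids)
  }
  count_matrix(counts, condition = condition,
               lengths = GenomicRanges::width(peaks))
}

#' Classify reference peaks as promoter or distal
#'
#' The promoter of a gene is the window TSS +/- `window` bp.  A peak is a
#' promoter peak iff it overlaps any promoter window by >= 1 bp, and
#' distal otherwise, so the two labels partition the peak set.
#'
#' @param peaks reference `GRanges`.
#' @param gene_models data.frame with columns `gene`, `chrom`, `strand`,
#'   `tss` (1-based position), `length`.
#' @param window promoter half-width in bp (default 2500).
#' @return factor of labels (`promoter`/`distal`), one per peak.
#' @export
classify_promoter_distal <- function(peaks, gene_models, window = 2500) {
  prom <- promoter_windows(gene_models, window)
  lab <- ifelse(GenomicRanges::countOverlaps(peaks, prom) > 0,
                "promoter", "distal")
  factor(lab, levels = c("promoter", "distal"))
}

# promoter windows as GRanges (1-based closed [tss - w, tss + w])
promoter_windows <- function(gene_models, window = 2500) {
  check_gene_models(gene_models)
  GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(pmax(1L, gene_models$tss - window),
                     gene_models$tss + window),
    gene = gene_models$gene)
}

check_gene_models <- function(gm) {
  need <- c("gene", "chrom", "strand", "tss")
  miss <- setdiff(need, names(gm))
  if (length(miss)) stopf("gene models lack column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(gm$gene)) stopf("duplicate gene ids in gene models")
  if (any(!gm$strand %in% c("+", "-"))) stopf("gene strand must be + or -")
  if (any(gm$tss < 1)) stopf("TSS outside chromosome bounds")
  invisible(gm)
}

#' Summit-centered windows for motif analysis
#'
#' The 101-bp (default) window summit +/- `half_width`, clipped at
#' chromosome starts (and ends when lengths are known) with a warning.
#'
#' @param peaks reference `GRanges` with a `summit` metadata column.
#' @param half_width half window width in bp (default 50).
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   clip right edges.
#' @return `GRanges` of windows, named as the peaks.
#' @export
summit_windows <- function(peaks, half_width = 50, chrom_lengths = NULL) {
  if (is.null(peaks$summit) || anyNA(peaks$summit))
    stopf("every peak needs a summit for summit windows")
  start <- peaks$summit - half_width
  end <- peaks$summit + half_width
  clipped <- start < 1
  if (!is.null(chrom_lengths)) {
    maxend <- chrom_lengths[as.character(GenomicRanges::seqnames(peaks))]
    clipped <- clipped | end > maxend
    end <- pmin(end, maxend)
  }
  if (any(clipped))
    warnf("%d summit window(s) clipped at chromosome bounds", sum(clipped))
  start <- pmax(1L, start)
  w <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                              IRanges::IRanges(start, end))
  names(w) <- names(peaks)
  w
}
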