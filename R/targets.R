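#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a basal domain around its TSS -- `basal_up` bp upstream
#' and `basal_down` bp downstream, strand-aware -- which is then extended
#' in both directions up to `max_ext` bp, stopping early at the nearest
#' other gene's basal-domain boundary on that side.  Basal domains are
#' never truncated; extended domains of neighboring genes typically
#' overlap in the intergenic space between their basal domains.  A basal
#' domain that overlaps a neighbor's basal domain does not truncate it.
#' Chromosome ends clip both.
#'
#' @param gene_models data.frame with `gene`, `chrom`, `strand`, `tss`.
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   in bp (defaults 5000 / 1000).
#' @param max_ext maximum extension in bp (default 1e6).
#' @param chrom_lengths optional named vector clipping right edges.
#' @return data.frame with one row per gene: `gene`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `ext_start`, `ext_end` (1-based
#'   closed coordinates).
#' @export
assign_regulatory_domains <- function(gene_models, basal_up = 5000,
                                      basal_down = 1000, max_ext = 1e6,
                                      chrom_lengths = NULL) {
  check_gene_models(gene_models)
  gm <- gene_models
  up <- gm$strand == "+"
  basal_start <- ifelse(up, gm$tss - basal_up, gm$tss - basal_down)
  basal_end <- ifelse(up, gm$tss + basal_down, gm$tss + basal_up)
  basal_start <- pmax(1, basal_start)
  out <- data.frame(gene = gm$gene, chrom = gm$chrom, strand = gm$strand,
                    tss = gm$tss,
                    basal_start = basal_start, basal_end = basal_end,
                    ext_start = NA_real_, ext_end = NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(out$chrom)) {
    idx <- which(out$chrom == chr)
    bs <- out$basal_start[idx]; be <- out$basal_end[idx]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else Inf
    for (k in seq_along(idx)) {
      others_end <- be[-k]; others_start <- bs[-k]
      left_wall <- others_end[others_end <= bs[k]]
      left <- max(1, bs[k] - max_ext, if (length(left_wall)) max(left_wall) + 1 else 1)
      right_wall <- others_start[others_start >= be[k]]
      right <- min(len, be[k] + max_ext,
                   if (length(right_wall)) min(right_wall) - 1 else Inf)
      out$ext_start[idx[k]] <- min(left, bs[k])
      out$ext_end[idx[k]] <- max(right, be[k])
    }
    if (is.finite(len)) {
      out$basal_end[idx] <- pmin(out$basal_end[idx], len)
      out$ext_end[idx] <- pmin(out$ext_end[idx], len)
    }
  }
  out
}

#' Assign peaks to target genes
#'
#' A peak targets every gene whose extended regulatory domain it overlaps
#' by at least 1 bp; a peak may therefore have several targets and a gene
#' several peaks.  The association table can be queried from either side.
#'
#' @param peaks `GRanges` of (reference or differential) peaks, named.
#' @param domains data.frame from [assign_regulatory_domains()].
#' @return data.frame with columns `peak`, `gene`.
#' @export
peaks_to_targets <- function(peaks, domains) {
  dg <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$ext_start, domains$ext_end))
  hits <- GenomicRanges::findOverlaps(peaks, dg)
  pk <- names(peaks) %||% as.character(seq_along(peaks))
  data.frame(peak = pk[S4Vectors::queryHits(hits)],
             gene = domains$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Genes linked to multiple peaks gaining accessibility
#'
#' The gene set at the heart of the regulome-transcriptome integration:
#' expressed genes associated with more than two (>= `min_peaks`) distinct
#' peaks that gained accessibility.
#'
#' @param associations data.frame from [peaks_to_targets()].
#' @param increasing_peaks character vector of peak ids called "up" by the
#'   differential-accessibility stage.
#' @param expressed_genes character vector of genes considered expressed.
#' @param min_peaks minimum number of distinct gaining peaks (default 3,
#'   i.e. "> 2").
#' @return Sorted character vector of gene ids.
#' @export
multi_peak_genes <- function(associations, increasing_peaks, expressed_genes,
                             min_peaks = 3) {
  if (length(expressed_genes) == 0) stopf("expressed gene set is empty")
  a <- associations[associations$peak %in% increasing_peaks, , drop = FALSE]
  a <- unique(a)
  n <- table(a$gene)
  genes <- names(n)[n >= min_peaks]
  sort(intersect(genes, expressed_genes))
}
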