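#' Pipeline configuration
#'
#' All stage thresholds in one serializable object.  Defaults are the
#' conventional cutoffs for this workflow: expression calls at FDR < 0.05,
#' |FC| > 1.5 and mean log2 CPM > 0; accessibility calls at FDR < 0.01 and
#' |FC| > 1.5, or |GFOLD value| > log2(1.5) = 0.585; reference peaks need
#' support from three samples; promoters are TSS +/- 2500 bp; motif windows
#' are summit +/- 50 bp; the multi-peak rule needs > 2 gaining peaks; the
#' survival screen splits at the top quartile and calls support at
#' p < 0.05 with HR > 1.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param de_fdr,de_fc,min_log2cpm expression call thresholds.
#' @param peak_fdr,peak_fc accessibility call thresholds.
#' @param gfold_cut GFOLD cutoff (log2 units).
#' @param min_support reference-peak support threshold.
#' @param promoter_window promoter half-width (bp).
#' @param summit_half_width motif window half-width (bp).
#' @param min_peaks multi-peak gene threshold (distinct gaining peaks).
#' @param distal_only count only distal gaining peaks for the multi-peak
#'   rule (default FALSE: any class).
#' @param expressed_rpkm "expressed" floor (mean RPKM in the comparison
#'   condition).
#' @param quartile top-group fraction of the survival split.
#' @param marker_alpha,marker_min_hr per-cohort support thresholds.
#' @param motif_p motif scan p-value threshold.
#' @param gsea_nperm GSEA permutations.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            de_fdr = 0.05, de_fc = 1.5, min_log2cpm = 0,
                            peak_fdr = 0.01, peak_fc = 1.5,
                            gfold_cut = gfold_cutoff(1.5),
                            min_support = 3,
                            promoter_window = 2500,
                            summit_half_width = 50,
                            min_peaks = 3,
                            distal_only = FALSE,
                            expressed_rpkm = 1,
                            quartile = 0.25,
                            marker_alpha = 0.05, marker_min_hr = 1,
                            motif_p = 1e-4,
                            gsea_nperm = 1000) {
  cfg <- as.list(environment())
  for (p in c("de_fdr", "peak_fdr", "marker_alpha"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) stopf("%s must lie in (0, 1)", p)
  if (cfg$de_fc <= 1 || cfg$peak_fc <= 1) stopf("fold-change cutoffs must exceed 1")
  if (cfg$quartile <= 0 || cfg$quartile >= 0.5) stopf("quartile must be in (0, 0.5)")
  if (cfg$min_support < 1 || cfg$min_peaks < 1) stopf("count thresholds must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$conditions <- as.list(x$sim$conditions)
  x$sim$atac_conditions <- as.list(x$sim$atac_conditions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$conditions <- unlist(x$sim$conditions)
  x$sim$atac_conditions <- unlist(x$sim$atac_conditions)
  x$sim <- do.call(sim_config, x$sim)
  do.call(pipeline_config, x)
}

#' Promoter openness by condition
#'
#' A gene's promoter is open in a condition iff its TSS +/- `window`
#' overlaps at least one reference peak that is itself supported by at
#' least one of that condition's peak calls.
#'
#' @param ref reference `GRanges` from [compile_reference_peaks()].
#' @param peak_calls per-sample list of call `GRanges`.
#' @param condition condition label per sample.
#' @param gene_models gene-model data.frame.
#' @param window promoter half-width (bp).
#' @return Logical matrix, genes x conditions.
#' @export
promoter_open_status <- function(ref, peak_calls, condition, gene_models,
                                 window = 2500) {
  prom <- promoter_windows(gene_models, window)
  conds <- unique(condition)
  out <- matrix(FALSE, nrow(gene_models), length(conds),
                dimnames = list(gene_models$gene, conds))
  for (cc in conds) {
    calls <- unlist(GenomicRanges::GRangesList(
      lapply(peak_calls[condition == cc], function(g) {
        S4Vectors::mcols(g) <- NULL; g
      })), use.names = FALSE)
    open_ref <- ref[GenomicRanges::countOverlaps(ref, calls) > 0]
    out[, cc] <- GenomicRanges::countOverlaps(prom, open_ref) > 0
  }
  out
}

# GFOLD value for every row of a count matrix
gfold_values <- function(counts, baseline, comparison, credibility = 0.99) {
  cond <- conditions(counts)
  a <- which(cond == baseline); b <- which(cond == comparison)
  lib <- colSums(unclass(counts))
  vapply(seq_len(nrow(counts)), function(i)
    gfold_value(unclass(counts)[i, a], unclass(counts)[i, b],
                lib[a], lib[b], credibility), 1)
}

#' Run the full coculture analysis on a synthetic study
#'
#' Chains every stage: simulation, differential expression for the three
#' condition contrasts, exclusion filters, rnk + GSEA, reference-peak
#' compilation, read counting, NB and GFOLD differential accessibility,
#' promoter/distal classification, target assignment, multi-peak genes,
#' expression-shift K-S test, call concordance, motif enrichment, and the
#' multi-cohort survival screen, then scores every stage against the
#' generator's truth tables.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory for result files and the run
#'   manifest.
#' @param sim optional pre-generated [simulate_all()] bundle (generated
#'   from `config$sim` when NULL).
#' @return A `stromareg_run` list; see components in the manifest it
#'   writes.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         sim = NULL) {
  t0 <- Sys.time()
  if (is.null(sim)) sim <- simulate_all(config$sim)
  gm <- sim$gene_models
  log_line <- function(fmt, ...) message(sprintf(fmt, ...))

  ## -- expression -------------------------------------------------------
  cm <- sim$expression$counts
  de <- list(
    TSW_vs_MONO = differential_expression(cm, "MONO", "TSW",
      fdr = config$de_fdr, fc = config$de_fc, min_log2cpm = config$min_log2cpm),
    CO_vs_MONO = differential_expression(cm, "MONO", "CO",
      fdr = config$de_fdr, fc = config$de_fc, min_log2cpm = config$min_log2cpm),
    CO_vs_TSW = differential_expression(cm, "TSW", "CO",
      fdr = config$de_fdr, fc = config$de_fc, min_log2cpm = config$min_log2cpm))
  for (nm in names(de))
    log_line("DE %s: %d up, %d down of %d genes", nm,
             sum(de[[nm]]$call == "up"), sum(de[[nm]]$call == "down"), nrow(de[[nm]]))

  rpkm <- compute_rpkm(cm)

  ## -- accessibility ----------------------------------------------------
  acc <- sim$accessibility
  ref <- compile_reference_peaks(acc$peak_calls, config$min_support)
  peak_counts <- suppressWarnings(
    count_reads_in_peaks(acc$reads, ref, acc$condition))
  log_line("reference peaks: %d (support >= %d) from %d samples",
           length(ref), config$min_support, length(acc$peak_calls))
  dp <- differential_peaks(peak_counts, "MONO", "CO",
                           fdr = config$peak_fdr, fc = config$peak_fc)
  gf <- gfold_values(peak_counts, "MONO", "CO")
  dp$gfold <- gf
  dp$gfold_call <- ifelse(gf > config$gfold_cut, "up",
                          ifelse(gf < -config$gfold_cut, "down", "unchanged"))
  peak_class <- classify_promoter_distal(ref, gm, config$promoter_window)
  log_line("differential peaks CO vs MONO: %d up, %d down; %d promoter / %d distal",
           sum(dp$call == "up"), sum(dp$call == "down"),
           sum(peak_class == "promoter"), sum(peak_class == "distal"))

  ## -- filters + rnk + GSEA --------------------------------------------
  open_status <- promoter_open_status(ref, acc$peak_calls, acc$condition,
                                      gm, config$promoter_window)
  # "silent in the tumor cells" is judged on the uncontaminated samples
  # (MONO/TSW); CO samples carry the stromal admixture the filter targets
  pure <- conditions(cm) != "CO"
  stromal_excl <- stromal_signature_filter(rpkm[, pure, drop = FALSE],
                                           sim$expression$stromal_profile)
  promoter_excl <- promoter_open_filter(open_status)
  excl <- union(stromal_excl, promoter_excl)
  log_line("filters: %d stromal-signature, %d closed-promoter, %d excluded total",
           length(stromal_excl), length(promoter_excl), length(excl))
  rnk <- lapply(de, make_rnk, exclude = excl)
  gsea <- gsea_collection(rnk$CO_vs_MONO, sim$gene_sets,
                          n_perm = config$gsea_nperm,
                          seed = derive_seed(config$sim$seed, "gsea"))

  ## -- targets + multi-peak genes --------------------------------------
  domains <- assign_regulatory_domains(
    gm, chrom_lengths = c(chr1 = config$sim$chrom_length))
  assoc <- peaks_to_targets(ref, domains)
  up_peaks <- dp$feature[dp$call == "up"]
  if (config$distal_only)
    up_peaks <- intersect(up_peaks, names(ref)[peak_class == "distal"])
  co_cols <- conditions(cm) == "CO"
  expressed <- rownames(rpkm)[rowMeans(rpkm[, co_cols, drop = FALSE]) >=
                                config$expressed_rpkm]
  mp <- multi_peak_genes(assoc, up_peaks, expressed, config$min_peaks)
  log_line("multi-peak genes (> %d gaining peaks, expressed): %d",
           config$min_peaks - 1, length(mp))

  ## -- expression shift of multi-peak genes ----------------------------
  fc_lookup <- setNames(de$CO_vs_MONO$log2fc, de$CO_vs_MONO$feature)
  ks <- if (length(mp) >= 2)
    ks_shift_test(fc_lookup[mp], fc_lookup[setdiff(names(fc_lookup), mp)])
  else NULL

  ## -- concordance of the two contrasts (filtered gene universe) -------
  keep_genes <- setdiff(de$TSW_vs_MONO$feature, excl)
  callsA <- setNames(as.character(de$TSW_vs_MONO$call), de$TSW_vs_MONO$feature)
  callsB <- setNames(as.character(de$CO_vs_TSW$call), de$CO_vs_TSW$feature)
  conc <- contingency_concordance(callsA[keep_genes], callsB[keep_genes])

  ## -- motif enrichment -------------------------------------------------
  win <- summit_windows(ref, config$summit_half_width,
                        chrom_lengths = c(chr1 = config$sim$chrom_length))
  ref2master <- GenomicRanges::findOverlaps(ref, acc$master, select = "first")
  seq_of <- function(peaks) {
    m <- ref2master[match(peaks, names(ref))]
    s <- sim$sequences$sequences[names(acc$master)[m[!is.na(m)]]]
    s
  }
  nondiff_peaks <- dp$feature[dp$call == "unchanged"]
  fg_seq <- seq_of(up_peaks)
  bg_seq <- seq_of(nondiff_peaks)
  motif_enr <- if (length(fg_seq) && length(bg_seq))
    motif_enrichment(fg_seq, bg_seq, sim$motif, config$motif_p)
  else NULL

  ## -- survival screen --------------------------------------------------
  screen <- survival_screen(sim$cohorts$cohorts,
                            primary = sim$cohorts$primary,
                            alpha = config$marker_alpha,
                            min_hr = config$marker_min_hr,
                            q = config$quartile)
  markers <- unique(screen$gene[screen$marker])
  log_line("survival screen: %d of %d genes called unfavorable markers",
           length(markers), length(unique(screen$gene)))

  ## -- recovery against truth ------------------------------------------
  recovery <- score_recovery(sim, de, dp, mp, markers, domains, config,
                             excluded = excl)

  run <- structure(list(
    config = config, de = de, rnk = rnk, gsea = gsea,
    reference_peaks = ref, peak_counts = peak_counts,
    differential_peaks = dp, peak_class = peak_class,
    open_status = open_status, excluded = list(stromal = stromal_excl,
                                               promoter = promoter_excl),
    domains = domains, associations = assoc,
    multi_peak_genes = mp, ks_shift = ks, concordance = conc,
    motif_enrichment = motif_enr, survival = screen, markers = markers,
    recovery = recovery,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "stromareg_run")
  if (!is.null(outdir)) write_run(run, sim, outdir)
  run
}

# stage-level recovery metrics against the generator's truth tables.
# DE metrics are computed on the filtered analysis (after the stromal and
# closed-promoter exclusions), which is the gene universe the method
# reports on.
score_recovery <- function(sim, de, dp, mp, markers, domains, config,
                           excluded = character()) {
  tg <- sim$expression$truth
  de_co <- de$CO_vs_MONO
  called <- setdiff(de_co$feature[de_co$call != "unchanged"], excluded)
  true_de <- setdiff(tg$gene[tg$planted_log2fc != 0], excluded)
  de_sens <- if (length(true_de)) mean(true_de %in% called) else NA
  de_fdr_emp <- if (length(called)) mean(!(called %in% true_de)) else 0

  master <- sim$accessibility$master
  truth_up_master <- names(master)[master$planted_log2fc > 0]

  # gene-level multi-peak truth: genes whose domains hold > 2 truly gaining
  # peaks (the planted genes by construction, plus any gene whose domain
  # happens to collect enough gaining background peaks)
  assoc_truth <- peaks_to_targets(master, domains)
  truth_mp <- multi_peak_genes(
    assoc_truth, truth_up_master,
    expressed_genes = sim$gene_models$gene, min_peaks = config$min_peaks)
  planted_mp <- sim$accessibility$truth_multipeak_genes
  mp_sens <- if (length(planted_mp)) mean(planted_mp %in% mp) else NA
  mp_prec <- if (length(mp)) mean(mp %in% truth_mp) else NA

  true_markers <- sim$cohorts$truth_markers
  marker_sens <- if (length(true_markers)) mean(true_markers %in% markers) else NA
  null_genes <- setdiff(unique(sim$cohorts$cohorts[[1]] |>
                                 names() |>
                                 setdiff(c("patient", "time", "event"))),
                        true_markers)
  marker_fpr <- if (length(null_genes)) mean(null_genes %in% markers) else NA

  list(de_sensitivity = de_sens, de_empirical_fdr = de_fdr_emp,
       multipeak_sensitivity = mp_sens, multipeak_precision = mp_prec,
       marker_sensitivity = marker_sens, marker_fpr = marker_fpr,
       n_de_called = length(called), n_multipeak = length(mp),
       n_markers = length(markers))
}

write_run <- function(run, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  for (nm in names(run$de))
    .write_tsv(run$de[[nm]], fp(paste0("de_", nm, ".tsv")))
  for (nm in names(run$rnk))
    write_rnk(run$rnk[[nm]], fp(paste0(nm, ".rnk")))
  ref <- run$reference_peaks
  ref$score <- ref$support
  write_narrowpeak(ref, fp("reference_peaks.narrowPeak"))
  write_counts(run$peak_counts, fp("peak_counts.tsv"))
  dpt <- run$differential_peaks
  dpt$class <- as.character(run$peak_class)
  .write_tsv(dpt, fp("differential_peaks.tsv"))
  .write_tsv(run$associations, fp("peak_gene_associations.tsv"))
  writeLines(run$multi_peak_genes, fp("multi_peak_genes.txt"))
  .write_tsv(run$gsea, fp("gsea.tsv"))
  .write_tsv(run$survival, fp("survival_screen.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("stromareg")),
    seed = run$config$sim$seed,
    thresholds = unclass(run$config)[setdiff(names(run$config), "sim")],
    sim = lapply(unclass(run$config$sim), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    stage_counts = list(
      genes = nrow(run$de[[1]]),
      reference_peaks = length(run$reference_peaks),
      de_calls = vapply(run$de, function(d) sum(d$call != "unchanged"), 1),
      diff_peaks = sum(run$differential_peaks$call != "unchanged"),
      multi_peak_genes = length(run$multi_peak_genes),
      markers = length(run$markers)),
    recovery = run$recovery,
    motif_enrichment = run$motif_enrichment[c("fraction_fg", "fraction_bg",
                                              "pvalue")],
    concordance = run$concordance[c("observed", "expected", "ratio", "pvalue")])
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.stromareg_run <- function(x, ...) {
  cat("stromareg pipeline run\n")
  cat(sprintf("  genes: %d, reference peaks: %d\n",
              nrow(x$de[[1]]), length(x$reference_peaks)))
  for (nm in names(x$de))
    cat(sprintf("  DE %s: %d up / %d down\n", nm,
                sum(x$de[[nm]]$call == "up"), sum(x$de[[nm]]$call == "down")))
  cat(sprintf("  diff peaks CO vs MONO: %d up / %d down\n",
              sum(x$differential_peaks$call == "up"),
              sum(x$differential_peaks$call == "down")))
  cat(sprintf("  multi-peak genes: %d; markers: %d\n",
              length(x$multi_peak_genes), length(x$markers)))
  r <- x$recovery
  cat(sprintf("  recovery: DE sens %.2f (emp. FDR %.2f), multipeak %.2f/%.2f, markers %.2f\n",
              r$de_sensitivity, r$de_empirical_fdr,
              r$multipeak_sensitivity, r$multipeak_precision,
              r$marker_sensitivity))
  if (!is.null(x$motif_enrichment))
    cat(sprintf("  motif: fg %.3f vs bg %.3f (p = %.2g)\n",
                x$motif_enrichment$fraction_fg, x$motif_enrichment$fraction_bg,
                x$motif_enrichment$pvalue))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
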