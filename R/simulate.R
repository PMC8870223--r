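#' Configuration for the synthetic coculture experiment
#'
#' Defines the simulated study: a three-condition expression design
#' (monoculture MONO, transwell TSW, direct coculture CO), a two-condition
#' chromatin-accessibility design (MONO vs CO), summit-window sequences
#' with planted motif instances, and five survival cohorts with planted
#' expression-dependent hazards.  All randomness flows from `seed` through
#' named substreams per data type, so regenerating one data type never
#' changes another.
#'
#' @param seed master RNG seed.
#' @param n_genes number of genes on the toy chromosome.
#' @param n_peaks number of master accessible regions.
#' @param conditions named integer vector of RNA replicate counts per
#'   condition (>= 2 each).
#' @param atac_conditions named integer vector of ATAC replicate counts.
#' @param de_fraction fraction of genes with a planted expression effect.
#' @param de_log2fc planted expression effect size (log2; sign randomized
#'   per gene).
#' @param adhesion_fraction fraction of planted genes that receive an
#'   additional same-sign shift in CO only, emulating the adhesion
#'   component that acts on top of soluble factors.
#' @param adhesion_log2fc size of that additional CO-only shift (log2).
#' @param dispersion negative-binomial dispersion of gene counts.
#' @param base_mean median baseline gene count.
#' @param contamination_fraction stromal read fraction mixed into CO
#'   samples; must be < 0.05.
#' @param acc_gain_fraction,acc_loss_fraction fractions of master peaks
#'   gaining/losing accessibility in CO.
#' @param acc_log2fc planted accessibility effect size (log2).
#' @param multipeak_gene_count genes planted with 3 gaining distal peaks
#'   in their exclusive regulatory space.
#' @param motif_plant_rate_fg,motif_plant_rate_bg per-window motif
#'   planting probabilities for gaining vs other windows.
#' @param n_cohorts number of survival cohorts (>= 2; the first is
#'   primary).
#' @param cohort_size patients per cohort.
#' @param censoring_rate fraction of patients censored.
#' @param marker_hr hazard ratio planted on top-quartile carriers of
#'   marker genes (> 0).
#' @param n_marker_genes planted prognostic markers.
#' @param n_survival_genes total genes carried in the cohort tables
#'   (markers plus nulls).
#' @param chrom_length toy chromosome length in bp.
#' @param read_length ATAC read length in bp.
#' @param peak_width master peak width in bp.
#' @param reads_per_peak baseline NB mean reads per peak per sample.
#' @param peak_dispersion NB dispersion of peak counts.
#' @param sample_peak_prob probability a master peak is called in a given
#'   sample (exercises reference compilation).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 400,
                       n_peaks = 1200,
                       conditions = c(MONO = 3, TSW = 3, CO = 3),
                       atac_conditions = c(MONO = 3, TSW = 3, CO = 3),
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       adhesion_fraction = 0.5,
                       adhesion_log2fc = 1,
                       dispersion = 0.1,
                       base_mean = 100,
                       contamination_fraction = 0.03,
                       acc_gain_fraction = 0.08,
                       acc_loss_fraction = 0.05,
                       acc_log2fc = 2,
                       multipeak_gene_count = 10,
                       motif_plant_rate_fg = 0.25,
                       motif_plant_rate_bg = 0.05,
                       n_cohorts = 5,
                       cohort_size = 500,
                       censoring_rate = 0.2,
                       marker_hr = 2,
                       n_marker_genes = 10,
                       n_survival_genes = 40,
                       chrom_length = 1e7,
                       read_length = 50,
                       peak_width = 250,
                       reads_per_peak = 50,
                       peak_dispersion = 0.1,
                       sample_peak_prob = 0.9) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$contamination_fraction >= 0.05 || cfg$contamination_fraction < 0)
    stopf("contamination_fraction must be in [0, 0.05): the stromal carry-over in sorted coculture cells is below 5%%")
  props <- c("de_fraction", "adhesion_fraction", "acc_gain_fraction",
             "acc_loss_fraction", "motif_plant_rate_fg",
             "motif_plant_rate_bg", "censoring_rate", "sample_peak_prob")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must lie in [0, 1]", p)
  if (any(cfg$conditions < 2) || any(cfg$atac_conditions < 2))
    stopf("every condition needs >= 2 replicates")
  if (cfg$marker_hr <= 0) stopf("marker_hr must be positive")
  if (cfg$multipeak_gene_count > cfg$n_genes)
    stopf("multipeak_gene_count exceeds the number of genes")
  if (cfg$n_cohorts < 2) stopf("need >= 2 cohorts (one primary plus validation)")
  if (cfg$n_marker_genes > cfg$n_survival_genes)
    stopf("n_marker_genes exceeds n_survival_genes")
  invisible(cfg)
}

#' Toy genome gene models
#'
#' Places `n_genes` genes on one linear chromosome at random TSSs with a
#' minimum spacing of 15 kb (so basal regulatory domains never overlap
#' and each gene keeps an exclusive distal strip), random strand, and
#' gene lengths uniform in 1-10 kb.
#'
#' @param config a [sim_config()].
#' @return data.frame: `gene`, `chrom`, `strand`, `tss`, `length`.
#' @export
make_gene_models <- function(config) {
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    min_gap <- 15000
    margin <- 60000
    usable <- config$chrom_length - 2 * margin - n * min_gap
    if (usable <= 0) stopf("chromosome too short for %d genes", n)
    slack <- sort(runif(n)) * usable
    tss <- as.integer(round(margin + slack + (seq_len(n) - 1) * min_gap))
    data.frame(gene = sprintf("gene_%03d", seq_len(n)),
               chrom = "chr1",
               strand = sample(c("+", "-"), n, replace = TRUE),
               tss = tss,
               length = as.integer(round(runif(n, 1000, 10000))),
               stringsAsFactors = FALSE)
  })
}

#' Simulate the three-condition expression experiment
#'
#' Negative-binomial gene counts for MONO/TSW/CO replicates.  A
#' `de_fraction` of genes carries a planted log2 effect (random sign) in
#' TSW and CO relative to MONO.  CO samples are a (1-f)/f mixture of the
#' tumor profile with a distinct stromal profile (f =
#' `contamination_fraction`), realized as independent NB draws whose
#' stromal portion is tracked per sample.  A small set of stroma-specific
#' genes is silent in the tumor and highly expressed in the stroma, so
#' the stromal-signature filter has something to find.
#'
#' @param config a [sim_config()].
#' @param gene_models from [make_gene_models()] (generated if NULL).
#' @return list: `counts` ([count_matrix()] with gene lengths),
#'   `truth` (per gene: `planted_log2fc`, `is_stromal_signature`),
#'   `stromal_profile` (stromal RPKM-scale vector), `stromal_share`
#'   (realized stromal read fraction per CO sample).
#' @export
simulate_expression <- function(config, gene_models = NULL) {
  validate_sim_config(config)
  if (is.null(gene_models)) gene_models <- make_gene_models(config)
  with_seed(derive_seed(config$seed, "expression"), {
    n <- config$n_genes
    genes <- gene_models$gene
    f <- config$contamination_fraction

    base <- exp(rnorm(n, log(config$base_mean), 0.5))
    n_stromal <- max(4L, round(0.05 * n))
    stromal_sig <- sort(sample.int(n, n_stromal))
    base[stromal_sig] <- runif(n_stromal, 0.002, 0.01)  # silent in tumor

    n_de <- round(config$de_fraction * n)
    de_idx <- sample(setdiff(seq_len(n), stromal_sig), n_de)
    effect <- numeric(n)
    if (n_de > 0)
      effect[de_idx] <- config$de_log2fc *
        rep_len(c(1, -1), n_de)[sample.int(n_de)]
    # adhesion component: an extra same-sign shift in CO for a fraction of
    # the planted genes (direct contact acts on top of soluble factors)
    adhesion <- numeric(n)
    n_adh <- round(config$adhesion_fraction * n_de)
    if (n_adh > 0) {
      adh_idx <- sample(de_idx, n_adh)
      adhesion[adh_idx] <- sign(effect[adh_idx]) * config$adhesion_log2fc
    }

    mu <- cbind(MONO = base, TSW = base * 2^effect,
                CO = base * 2^(effect + adhesion))

    # stromal profile: permuted tumor-like means, very high at signature genes
    stromal_mu <- exp(rnorm(n, log(config$base_mean), 0.5))
    stromal_mu[stromal_sig] <- exp(rnorm(n_stromal, log(config$base_mean * 40), 0.3))
    stromal_mu <- stromal_mu * sum(mu[, "CO"]) / sum(stromal_mu)

    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    draw <- function(m) {
      if (is.finite(size)) rnbinom(length(m), mu = m, size = size)
      else rpois(length(m), m)
    }
    cols <- list(); cond <- character(); share <- numeric()
    for (cc in names(config$conditions)) {
      for (r in seq_len(config$conditions[[cc]])) {
        if (cc == "CO") {
          mm <- draw((1 - f) * mu[, "CO"])
          st <- draw(f * stromal_mu)
          cols[[length(cols) + 1]] <- mm + st
          share <- c(share, sum(st) / max(1, sum(mm + st)))
        } else {
          cols[[length(cols) + 1]] <- draw(mu[, cc])
        }
        cond <- c(cond, cc)
      }
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(genes,
                             paste0(cond, "_", unlist(lapply(config$conditions, seq_len))))
    truth <- data.frame(gene = genes, planted_log2fc = effect,
                        planted_adhesion_log2fc = adhesion,
                        base_mean = base,
                        is_stromal_signature = seq_len(n) %in% stromal_sig,
                        stringsAsFactors = FALSE)
    stromal_profile <- setNames(
      stromal_mu / (gene_models$length / 1e3) / (sum(stromal_mu) / 1e6), genes)
    list(counts = count_matrix(counts, cond, lengths = gene_models$length),
         truth = truth,
         stromal_profile = stromal_profile,
         stromal_share = share)
  })
}

#' Simulate per-sample peak calls and ATAC read intervals
#'
#' Master accessible regions are placed on the toy chromosome: one
#' promoter peak at most gene TSSs, three planted distal gaining peaks in
#' the exclusive basal-side strip of each chosen multi-peak gene (inside
#' the regulatory domain, outside every +/-2500 bp promoter window), and
#' background peaks elsewhere.  Each sample calls each master peak with
#' probability `sample_peak_prob` (planted and promoter peaks always),
#' with +/-10 bp edge jitter, so consensus compilation is exercised.
#' Reads are `read_length`-bp intervals whose midpoints scatter around
#' the summit; per-peak read counts are NB with the planted log2 effects
#' applied in CO.
#'
#' @param config a [sim_config()].
#' @param gene_models from [make_gene_models()].
#' @param promoterless_genes genes whose TSS gets no promoter peak
#'   (silent genes; default: a random 15\% of non-multipeak genes).
#' @param mp_candidates preferred genes for multi-peak planting (e.g.
#'   the expression-induced genes, so chromatin gains and induction
#'   co-occur as they do in real data); topped up from the remaining
#'   non-silent genes when too few.
#' @return list: `peak_calls` (list of `GRanges` per sample), `reads`
#'   (list of `GRanges` per sample), `condition` (per sample),
#'   `master` (`GRanges` of master peaks with truth columns
#'   `planted_log2fc`, `multipeak_gene`, `kind`), `truth_multipeak_genes`
#'   (character), `domains` (regulatory domains used for planting).
#' @export
simulate_accessibility <- function(config, gene_models,
                                   promoterless_genes = NULL,
                                   mp_candidates = NULL) {
  validate_sim_config(config)
  if (config$multipeak_gene_count > nrow(gene_models))
    stopf("multipeak_gene_count exceeds available genes")
  chrom_lengths <- c(chr1 = config$chrom_length)
  domains <- assign_regulatory_domains(gene_models, chrom_lengths = chrom_lengths)
  with_seed(derive_seed(config$seed, "accessibility"), {
    pw <- config$peak_width
    eligible <- setdiff(gene_models$gene, promoterless_genes)
    if (length(eligible) < config$multipeak_gene_count)
      stopf("multipeak_gene_count exceeds available (non-silent) genes")
    pref <- intersect(mp_candidates %||% character(), eligible)
    k <- config$multipeak_gene_count
    mp_genes <- if (length(pref) >= k) sample(pref, k)
                else c(pref, sample(setdiff(eligible, pref), k - length(pref)))
    mp_genes <- sort(mp_genes)

    # planted distal gaining peaks: exclusive basal-side strip of each gene,
    # upstream of the promoter window (strand-aware), 4 per gene so the
    # multi-peak rule (> 2 gaining) tolerates one missed differential call
    planted <- do.call(rbind, c(list(
      data.frame(start = integer(0), end = integer(0), gene = character(0),
                 stringsAsFactors = FALSE)),
      lapply(mp_genes, function(g) {
        gm <- gene_models[gene_models$gene == g, ]
        off <- c(-4900, -4300, -3700, -3100)  # relative to TSS, + strand
        if (gm$strand == "-") off <- -off - 200
        start <- gm$tss + off
        data.frame(start = start, end = start + 199, gene = g,
                   stringsAsFactors = FALSE)
      })))

    # promoter peaks everywhere except the silent (promoterless) genes
    if (is.null(promoterless_genes))
      promoterless_genes <- sample(setdiff(gene_models$gene, mp_genes),
                                   round(0.15 * nrow(gene_models)))
    prom_genes <- which(!(gene_models$gene %in% promoterless_genes))
    prom <- data.frame(start = gene_models$tss[prom_genes] - round(pw / 2),
                       end = gene_models$tss[prom_genes] + round(pw / 2) - 1,
                       gene = gene_models$gene[prom_genes])

    # background peaks: random, kept >= 500 bp clear of other peaks
    n_bg <- config$n_peaks - nrow(planted) - nrow(prom)
    if (n_bg < 0) stopf("n_peaks too small for planted + promoter peaks")
    occupied <- IRanges::IRanges(c(planted$start, prom$start) - 500,
                                 c(planted$end, prom$end) + 500)
    bg_start <- integer(0)
    cand <- round(runif(n_bg * 3, 1e4, config$chrom_length - 1e4))
    for (s in cand) {
      if (length(bg_start) >= n_bg) break
      iv <- IRanges::IRanges(s - 500, s + pw + 500)
      if (!any(IRanges::overlapsAny(iv, occupied))) {
        bg_start <- c(bg_start, s)
        occupied <- c(occupied, iv)
      }
    }
    bg <- data.frame(start = bg_start, end = bg_start + pw - 1,
                     gene = NA_character_)

    master <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(planted$start, prom$start, bg$start),
                       c(planted$end, prom$end, bg$end)))
    master$kind <- rep(c("planted", "promoter", "background"),
                       c(nrow(planted), nrow(prom), nrow(bg)))
    master$multipeak_gene <- c(planted$gene, rep(NA, nrow(prom)), bg$gene)
    master$summit <- as.integer(floor((GenomicRanges::start(master) +
                                         GenomicRanges::end(master)) / 2))

    n_master <- length(master)
    effect <- numeric(n_master)
    effect[master$kind == "planted"] <- config$acc_log2fc
    bg_idx <- which(master$kind == "background")
    n_gain <- round(config$acc_gain_fraction * n_master) -
      sum(master$kind == "planted")
    n_gain <- max(0, n_gain)
    n_loss <- round(config$acc_loss_fraction * n_master)
    pick <- sample(bg_idx, min(length(bg_idx), n_gain + n_loss))
    effect[pick[seq_len(n_gain)]] <- config$acc_log2fc
    if (n_loss > 0) effect[pick[n_gain + seq_len(n_loss)]] <- -config$acc_log2fc
    master$planted_log2fc <- effect
    names(master) <- sprintf("master_%04d", seq_len(n_master))
    ord <- order(GenomicRanges::start(master))
    master <- master[ord]
    names(master) <- sprintf("master_%04d", seq_len(n_master))

    conds <- rep(names(config$atac_conditions), config$atac_conditions)
    sample_names <- paste0("atac_", conds, "_",
                           unlist(lapply(config$atac_conditions, seq_len)))
    size <- if (config$peak_dispersion > 0) 1 / config$peak_dispersion else Inf
    peak_calls <- list(); reads <- list()
    for (j in seq_along(conds)) {
      present <- runif(n_master) < config$sample_peak_prob
      present[master$kind != "background"] <- TRUE
      jit_s <- round(runif(sum(present), -10, 10))
      jit_e <- round(runif(sum(present), -10, 10))
      pc <- master[present]
      GenomicRanges::start(pc) <- GenomicRanges::start(pc) + jit_s
      GenomicRanges::end(pc) <- GenomicRanges::end(pc) + jit_e
      pc$summit <- pmin(pmax(master$summit[present] +
                               round(runif(sum(present), -5, 5)),
                             GenomicRanges::start(pc)),
                        GenomicRanges::end(pc))
      calls <- pc
      S4Vectors::mcols(calls) <- NULL
      calls$summit <- pc$summit
      names(calls) <- NULL
      peak_calls[[sample_names[j]]] <- calls

      mu <- config$reads_per_peak *
        2^(if (conds[j] == "CO") master$planted_log2fc else 0)
      nr <- if (is.finite(size)) rnbinom(n_master, mu = mu, size = size)
            else rpois(n_master, mu)
      mid <- unlist(lapply(seq_len(n_master), function(k) {
        if (nr[k] == 0) return(integer(0))
        m <- round(rnorm(nr[k], master$summit[k], config$peak_width / 6))
        pmin(pmax(m, GenomicRanges::start(master)[k] + 2),
             GenomicRanges::end(master)[k] - 2)
      }))
      n_noise <- round(0.05 * length(mid))
      mid <- c(mid, round(runif(n_noise, 1e3, config$chrom_length - 1e3)))
      half <- floor(config$read_length / 2)
      rd <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(pmax(1, mid - half),
                         width = config$read_length))
      reads[[sample_names[j]]] <- rd
    }
    list(peak_calls = peak_calls, reads = reads, condition = conds,
         master = master, truth_multipeak_genes = mp_genes,
         domains = domains)
  })
}

#' Simulate summit-window sequences with planted motif instances
#'
#' Each 101-bp (by default) window is filled with i.i.d. background
#' nucleotides; with the foreground (gaining windows) or background
#' planting probability, one motif instance sampled from the PWM is
#' written at a random offset on a random strand.
#'
#' @param window_names character vector of window ids.
#' @param is_fg logical: is each window a foreground (gaining) window?
#' @param motif a [motif_model()].
#' @param config a [sim_config()] (supplies plant rates and seed).
#' @param width window width in bp (default 101).
#' @return list: `sequences` (named character), `truth` (data.frame with
#'   `window`, `is_fg`, `planted`, `offset`, `strand`).
#' @export
simulate_sequences <- function(window_names, is_fg, motif, config,
                               width = 101) {
  validate_sim_config(config)
  if (width < motif$width)
    stopf("window width %d shorter than motif width %d", width, motif$width)
  if (length(is_fg) != length(window_names))
    stopf("is_fg must match window_names")
  with_seed(derive_seed(config$seed, "sequences"), {
    n <- length(window_names)
    bases <- c("A", "C", "G", "T")
    rate <- ifelse(is_fg, config$motif_plant_rate_fg, config$motif_plant_rate_bg)
    planted <- runif(n) < rate
    offset <- ifelse(planted,
                     1L + floor(runif(n) * (width - motif$width + 1)), NA)
    strand <- ifelse(planted, ifelse(runif(n) < 0.5, "+", "-"), NA)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(bases, width, replace = TRUE, prob = motif$background)
      if (planted[i]) {
        inst <- vapply(seq_len(motif$width), function(j)
          sample(bases, 1, prob = motif$probs[, j]), "")
        if (strand[i] == "-")
          inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        s[offset[i]:(offset[i] + motif$width - 1)] <- inst
      }
      paste(s, collapse = "")
    }, "")
    names(seqs) <- window_names
    list(sequences = seqs,
         truth = data.frame(window = window_names, is_fg = is_fg,
                            planted = planted, offset = offset,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' Simulate survival cohorts with planted expression-dependent hazards
#'
#' Per cohort, per patient: one expression value per screened gene
#' (log-normal, i.i.d.), an exponential survival time whose hazard is
#' multiplied by `marker_hr` for every planted marker gene in which the
#' patient sits in the top expression quartile, and independent
#' censoring at the configured rate (a censored patient's time is
#' uniform on (0, event time)).
#'
#' @param config a [sim_config()].
#' @param marker_genes planted marker gene ids (default
#'   `marker_001 ...`); the remaining screened genes are nulls.
#' @return list: `cohorts` (named list of data.frames: `patient`,
#'   `time`, `event`, one column per gene), `primary` (cohort name),
#'   `truth_markers` (character).
#' @export
simulate_cohorts <- function(config, marker_genes = NULL) {
  validate_sim_config(config)
  if (is.null(marker_genes))
    marker_genes <- sprintf("marker_%03d", seq_len(config$n_marker_genes))
  if (length(marker_genes) > config$n_survival_genes)
    stopf("more marker genes than screened genes")
  null_genes <- sprintf("null_%03d",
                        seq_len(config$n_survival_genes - length(marker_genes)))
  genes <- c(marker_genes, null_genes)
  with_seed(derive_seed(config$seed, "cohorts"), {
    h0 <- 0.1
    cohorts <- list()
    for (ci in seq_len(config$n_cohorts)) {
      n <- config$cohort_size
      expr <- matrix(exp(rnorm(n * length(genes))), n, length(genes),
                     dimnames = list(NULL, genes))
      hazard <- rep(h0, n)
      k <- ceiling(0.25 * n)
      for (g in marker_genes) {
        top <- order(-expr[, g])[seq_len(k)]
        hazard[top] <- hazard[top] * config$marker_hr
      }
      t_event <- rexp(n, hazard)
      censored <- runif(n) < config$censoring_rate
      time <- ifelse(censored, runif(n) * t_event, t_event)
      cohorts[[paste0("cohort_", ci)]] <- data.frame(
        patient = sprintf("pt_%d_%04d", ci, seq_len(n)),
        time = round(pmax(time, 1e-4), 6),
        event = as.integer(!censored),
        expr, stringsAsFactors = FALSE)
    }
    list(cohorts = cohorts, primary = "cohort_1",
         truth_markers = marker_genes)
  })
}

#' The bundled synthetic AP-1-like motif
#'
#' A 10-bp ATGACTCATC-consensus position weight matrix (synthetic, built
#' in code; also shipped as `inst/extdata/ap1_synthetic.meme`) standing in
#' for the bZIP-family motifs enriched at stroma-induced distal sites.
#' The matrix is sharp enough (0.95 consensus probability per position)
#' that sampled instances with up to one mismatch still pass the default
#' 1e-4 scan threshold, so planted instances are recoverable.
#'
#' @param pseudo pseudo-count for [motif_model()].
#' @return A [motif_model()].
#' @export
default_motif <- function(pseudo = 0.1) {
  cons <- c("A", "T", "G", "A", "C", "T", "C", "A", "T", "C")
  probs <- sapply(cons, function(b) {
    p <- rep(0.05 / 3, 4)
    p[match(b, c("A", "C", "G", "T"))] <- 0.95
    p
  })
  rownames(probs) <- c("A", "C", "G", "T")
  colnames(probs) <- NULL
  motif_model("AP1_synthetic", probs, pseudo = pseudo)
}

#' Generate the full synthetic study
#'
#' Runs every generator with substreams of one seed and (optionally)
#' writes all external files: counts TSV + sample sheet, per-sample
#' narrowPeak and BED6 reads, gene models, summit-window FASTA, motif
#' MEME file, cohort TSVs, gene-set GMT, and truth tables.
#'
#' @param config a [sim_config()].
#' @param outdir directory to write files into (NULL = in-memory only).
#' @param motif motif to plant (default [default_motif()]).
#' @return list with components `gene_models`, `expression`,
#'   `accessibility`, `sequences`, `cohorts`, `motif`, `config` and, when
#'   written, `files`.
#' @export
simulate_all <- function(config = sim_config(), outdir = NULL,
                         motif = default_motif()) {
  gm <- make_gene_models(config)
  expr <- simulate_expression(config, gm)
  # silent genes (no promoter peak in any condition): the stromal-signature
  # genes plus the lowest-expressed unplanted genes, up to 15% of all genes
  tg <- expr$truth
  silent <- tg$gene[tg$is_stromal_signature]
  pool <- tg[!tg$is_stromal_signature & tg$planted_log2fc == 0, ]
  extra <- round(0.15 * nrow(tg)) - length(silent)
  if (extra > 0)
    silent <- c(silent, pool$gene[order(pool$base_mean)][seq_len(extra)])
  acc <- simulate_accessibility(config, gm, promoterless_genes = silent,
                                mp_candidates = tg$gene[tg$planted_log2fc > 0])
  seqs <- simulate_sequences(names(acc$master),
                             acc$master$planted_log2fc > 0,
                             motif, config)
  coh <- simulate_cohorts(config)
  up <- expr$truth$gene[expr$truth$planted_log2fc > 0]
  dn <- expr$truth$gene[expr$truth$planted_log2fc < 0]
  gene_sets <- list(planted_up = up, planted_down = dn)
  with_seed(derive_seed(config$seed, "gsea"),
            gene_sets$random_set <- sort(sample(gm$gene, 30)))
  out <- list(gene_models = gm, expression = expr, accessibility = acc,
              sequences = seqs, cohorts = coh, motif = motif,
              gene_sets = gene_sets, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outdir, ...)
    write_counts(expr$counts, fp("rna_counts.tsv"))
    write_sample_sheet(expr$counts, fp("rna_samples.tsv"))
    write_gene_models(gm, fp("gene_models.tsv"))
    for (s in names(acc$peak_calls))
      write_narrowpeak(acc$peak_calls[[s]], fp(paste0(s, "_peaks.narrowPeak")))
    for (s in names(acc$reads)) {
      r <- acc$reads[[s]]
      r$name <- paste0("read_", seq_along(r))
      write_bed6(r, fp(paste0(s, "_reads.bed")))
    }
    write_fasta(seqs$sequences, fp("summit_windows.fa"))
    write_meme(setNames(list(motif), motif$name), fp("motif.meme"))
    for (cn in names(coh$cohorts))
      write_cohort(coh$cohorts[[cn]], fp(paste0(cn, ".tsv")))
    write_gmt(gene_sets, fp("gene_sets.gmt"))
    .write_tsv(expr$truth, fp("truth_genes.tsv"))
    .write_tsv(data.frame(peak = names(acc$master),
                          granges_to_bed(acc$master),
                          kind = acc$master$kind,
                          planted_log2fc = acc$master$planted_log2fc,
                          multipeak_gene = acc$master$multipeak_gene),
               fp("truth_peaks.tsv"))
    .write_tsv(seqs$truth, fp("truth_windows.tsv"))
    .write_tsv(data.frame(gene = coh$truth_markers), fp("truth_markers.tsv"))
    out$files <- list.files(outdir, full.names = TRUE)
  }
  out
}
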