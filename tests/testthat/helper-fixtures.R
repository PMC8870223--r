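# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no stored binary data.

# quick GRanges constructor (1-based closed)
gr <- function(start, end, chrom = "chr1", summit = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(summit)) g$summit <- summit
  g
}

# random per-sample peak-call lists on a small coordinate range, for
# comparing interval code against per-base brute force
random_peak_instance <- function(n_samples = 5, max_pos = 400, max_calls = 6) {
  lapply(seq_len(n_samples), function(i) {
    k <- sample.int(max_calls, 1)
    s <- sample.int(max_pos - 20, k, replace = TRUE)
    w <- sample(5:30, k, replace = TRUE)
    g <- gr(s, pmin(s + w, max_pos))
    g$summit <- floor((GenomicRanges::start(g) + GenomicRanges::end(g)) / 2)
    g
  })
}

# brute-force reference compilation: per-base union occupancy -> maximal
# runs -> count distinct samples touching each run -> threshold
bf_reference_peaks <- function(peak_list, min_support, max_pos = 500) {
  cov <- sapply(peak_list, function(g) {
    v <- logical(max_pos)
    for (i in seq_along(g))
      v[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    v
  })
  occ <- rowSums(cov) > 0
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(runs)
  runs$support <- vapply(seq_len(nrow(runs)), function(i)
    sum(apply(cov[runs$start[i]:runs$end[i], , drop = FALSE], 2, any)), 0L)
  runs[runs$support >= min_support, c("start", "end", "support")]
}

# brute-force midpoint read counting: quadratic all-pairs containment scan
bf_count_reads <- function(reads, peaks) {
  mid <- floor((GenomicRanges::start(reads) + GenomicRanges::end(reads)) / 2)
  vapply(seq_along(peaks), function(i)
    sum(as.character(GenomicRanges::seqnames(reads)) ==
          as.character(GenomicRanges::seqnames(peaks))[i] &
        mid >= GenomicRanges::start(peaks)[i] &
        mid <= GenomicRanges::end(peaks)[i]), 0L)
}

# small two-group NB count matrix
nb_counts <- function(n_genes = 50, mu = 100, disp = 0.1, reps = 3,
                      fc_idx = integer(), log2fc = 0,
                      conds = c("MONO", "CO")) {
  mu_mat <- matrix(mu, n_genes, 2)
  mu_mat[fc_idx, 2] <- mu * 2^log2fc
  m <- cbind(
    matrix(rnbinom(n_genes * reps, mu = mu_mat[, 1], size = 1 / disp), n_genes),
    matrix(rnbinom(n_genes * reps, mu = mu_mat[, 2], size = 1 / disp), n_genes))
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * reps)))
  count_matrix(m, rep(conds, each = reps))
}

# tiny survival cohort with optional group hazard ratio
sim_surv <- function(n = 60, hr = 1, cens = 0.2, h0 = 0.1) {
  grp <- rep(c("rest", "top25"), length.out = n)
  t_ev <- rexp(n, h0 * ifelse(grp == "top25", hr, 1))
  censored <- runif(n) < cens
  data.frame(patient = sprintf("p%03d", seq_len(n)),
             time = ifelse(censored, runif(n) * t_ev, t_ev),
             event = as.integer(!censored),
             group = grp)
}
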