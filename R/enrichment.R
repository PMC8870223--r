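#' Preranked gene-set enrichment (classic weighted running sum)
#'
#' Classic GSEA statistic on a preranked list: genes are ordered by score
#' (descending, ties broken by gene id), the running sum gains
#' |score|^weight / sum(|score_hits|^weight) at each set member and loses
#' 1/(N - Nh) elsewhere, and the enrichment score ES is the maximal signed
#' deviation from zero.  Significance is assessed by gene-label
#' permutation: the nominal p is the fraction of same-sign permutation
#' scores at least as extreme as ES, and NES = ES divided by the mean
#' |null ES| of matching sign.  The leading edge is the set members at or
#' before (after, for negative ES) the extremum.
#'
#' @param rnk data.frame with columns `gene`, `score` (a ranking such as
#'   log2 fold changes); need not be pre-sorted.
#' @param geneset character vector of member gene ids.
#' @param weight score-weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list: `es`, `nes`, `pvalue`, `leading_edge`, `n_hits`.
#' @export
gsea_preranked <- function(rnk, geneset, weight = 1, n_perm = 1000, seed = 1) {
  if (anyDuplicated(rnk$gene)) stopf("duplicate genes in ranking")
  if (any(!is.finite(rnk$score))) stopf("ranking scores must be finite")
  ord <- order(-rnk$score, rnk$gene)
  genes <- rnk$gene[ord]
  scores <- rnk$score[ord]
  hit <- genes %in% geneset
  nh <- sum(hit)
  if (nh == 0) stopf("gene set has no overlap with the ranking")
  if (nh == length(genes)) stopf("gene set covers the whole ranking")
  if (n_perm < 100) warnf("n_perm = %d is low; p-values will be coarse", n_perm)

  est <- gsea_es(scores, hit, weight)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(length(genes))
      h[sample.int(length(genes), nh)] <- TRUE
      gsea_es(scores, h, weight)$es
    }, 1)
  })
  same <- null_es[sign(null_es) == sign(est$es)]
  pvalue <- if (length(same) == 0) 1 / (n_perm + 1) else
    (1 + sum(abs(same) >= abs(est$es))) / (1 + length(same))
  nes <- if (length(same) == 0) NA_real_ else est$es / mean(abs(same))
  le <- if (est$es >= 0) genes[seq_len(est$argmax)][hit[seq_len(est$argmax)]]
        else genes[est$argmax:length(genes)][hit[est$argmax:length(genes)]]
  list(es = est$es, nes = nes, pvalue = pvalue,
       leading_edge = le, n_hits = nh, null_es = null_es)
}

# running-sum core: scores sorted descending, hit = logical membership
gsea_es <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores[hit])^weight
  nr <- sum(w)
  inc <- numeric(n)
  inc[hit] <- if (nr > 0) w / nr else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  i <- which.max(abs(run))
  list(es = run[i], argmax = i, running = run)
}

#' GSEA over a collection of gene sets with permutation FDR
#'
#' Runs [gsea_preranked()] for every set in a collection and computes FDR
#' q-values by the sign-matched NES-pooling recipe: the q for a set is the
#' ratio of the pooled-null tail fraction to the observed tail fraction of
#' same-sign NES values, capped at 1.
#'
#' @inheritParams gsea_preranked
#' @param genesets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: `set`, `size`, `es`, `nes`, `pvalue`, `fdr`.
#' @export
gsea_collection <- function(rnk, genesets, weight = 1, n_perm = 1000, seed = 1) {
  res <- lapply(seq_along(genesets), function(i)
    gsea_preranked(rnk, genesets[[i]], weight, n_perm, seed + i))
  es <- vapply(res, `[[`, 1, "es")
  nes <- vapply(res, `[[`, 1, "nes")
  p <- vapply(res, `[[`, 1, "pvalue")
  null_nes <- unlist(lapply(res, function(r) {
    same_pos <- r$null_es[r$null_es > 0]
    same_neg <- r$null_es[r$null_es < 0]
    c(if (length(same_pos)) same_pos / mean(same_pos),
      if (length(same_neg)) -(same_neg / mean(same_neg)))
  }))
  fdr <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= x)
      den <- mean(nes[!is.na(nes) & nes >= 0] >= x)
    } else {
      num <- mean(null_nes[null_nes < 0] <= x)
      den <- mean(nes[!is.na(nes) & nes < 0] <= x)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 1)
  data.frame(set = names(genesets),
             size = vapply(res, `[[`, 1L, "n_hits"),
             es = es, nes = nes, pvalue = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and a
#' gene set drawn from a common universe, with the enrichment ratio
#' observed / expected = hits / (list_size * set_size / universe).
#'
#' @param hits overlap count.
#' @param list_size size of the query list.
#' @param set_size size of the gene set.
#' @param universe size of the gene universe.
#' @return list: `pvalue`, `ratio`, `expected`.
#' @export
hypergeom_enrichment <- function(hits, list_size, set_size, universe) {
  if (hits > min(list_size, set_size) || max(list_size, set_size) > universe ||
      min(hits, list_size, set_size) < 0)
    stopf("inconsistent counts: hits=%d list=%d set=%d universe=%d",
          hits, list_size, set_size, universe)
  if (list_size == 0 || set_size == 0)
    return(list(pvalue = 1, ratio = 0, expected = 0))
  expected <- list_size * set_size / universe
  p <- phyper(hits - 1, set_size, universe - set_size, list_size,
              lower.tail = FALSE)
  list(pvalue = p, ratio = hits / expected, expected = expected)
}

#' @rdname hypergeom_enrichment
#' @param gene_list character vector of query genes.
#' @param genesets named list of gene sets.
#' @param universe_genes character vector defining the universe; sets and
#'   list are intersected with it.
#' @return `hypergeom_enrichment_sets` returns a data.frame with one row
#'   per set (`set`, `hits`, `set_size`, `expected`, `ratio`, `pvalue`,
#'   `fdr`).
#' @export
hypergeom_enrichment_sets <- function(gene_list, genesets, universe_genes) {
  gene_list <- intersect(gene_list, universe_genes)
  rows <- lapply(names(genesets), function(nm) {
    gs <- intersect(genesets[[nm]], universe_genes)
    h <- length(intersect(gene_list, gs))
    r <- hypergeom_enrichment(h, length(gene_list), length(gs),
                              length(universe_genes))
    data.frame(set = nm, hits = h, set_size = length(gs),
               expected = r$expected, ratio = r$ratio, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$pvalue)
  out
}

#' Two-sample Kolmogorov-Smirnov shift test
#'
#' Compares two sets of fold changes (e.g. genes near gaining peaks vs all
#' genes) by the two-sample K-S statistic.  For small problems
#' (n * m <= `exact_limit`) the p-value is exact, computed by enumerating
#' every assignment of the pooled values into groups; beyond that it
#' delegates to `stats::ks.test`, which itself uses the exact D
#' distribution for moderate sample sizes and the asymptotic distribution
#' for large ones.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param exact_limit largest n*m for which the exact permutation null is
#'   enumerated (default 30).
#' @return list: `statistic` (D), `pvalue`, `exact` (logical).
#' @export
ks_shift_test <- function(x, y, exact_limit = 30) {
  if (length(x) < 2 || length(y) < 2) stopf("each group needs n >= 2")
  d_obs <- ks_d(x, y)
  n <- length(x); m <- length(y)
  if (n * m <= exact_limit) {
    pooled <- c(x, y)
    idx <- combn(n + m, n)
    ds <- apply(idx, 2, function(i) ks_d(pooled[i], pooled[-i]))
    p <- mean(ds >= d_obs - 1e-12)
    list(statistic = d_obs, pvalue = p, exact = TRUE)
  } else {
    p <- suppressWarnings(ks.test(x, y)$p.value)
    list(statistic = d_obs, pvalue = p, exact = FALSE)
  }
}

ks_d <- function(x, y) {
  v <- sort(unique(c(x, y)))
  fx <- vapply(v, function(t) mean(x <= t), 1)
  fy <- vapply(v, function(t) mean(y <= t), 1)
  max(abs(fx - fy))
}

#' Concordance of differential calls between two comparisons
#'
#' Given per-gene calls (up/down/unchanged) from two condition
#' comparisons over the same gene universe, counts the genes changing
#' consistently (up in both, or down in both), compares it with the count
#' expected under independence of the two call margins, and reports the
#' observed/expected ratio.  Significance comes from a two-sided Fisher
#' exact test on the 2x2 collapse whose first cell is the consistent
#' genes and whose margins are the changed-gene counts of each
#' comparison.
#'
#' @param callsA,callsB factors/characters in \{up, down, unchanged\},
#'   named by gene or aligned to the same gene order.
#' @return list: `observed`, `expected`, `ratio`, `pvalue`, `table`.
#' @export
contingency_concordance <- function(callsA, callsB) {
  if (!is.null(names(callsA)) && !is.null(names(callsB))) {
    common <- intersect(names(callsA), names(callsB))
    if (length(common) == 0) stopf("call vectors share no genes")
    callsA <- callsA[common]; callsB <- callsB[common]
  } else if (length(callsA) != length(callsB)) {
    stopf("unnamed call vectors must have equal length")
  }
  a <- as.character(callsA); b <- as.character(callsB)
  n <- length(a)
  obs <- sum(a == "up" & b == "up") + sum(a == "down" & b == "down")
  exp_cons <- (sum(a == "up") * sum(b == "up") +
               sum(a == "down") * sum(b == "down")) / n
  a_ch <- sum(a != "unchanged"); b_ch <- sum(b != "unchanged")
  tab <- matrix(c(obs, a_ch - obs, b_ch - obs, n - a_ch - b_ch + obs), 2, 2)
  p <- if (any(tab < 0)) NA_real_ else fisher.test(tab)$p.value
  list(observed = obs, expected = exp_cons,
       ratio = if (exp_cons > 0) obs / exp_cons else NA_real_,
       pvalue = p, table = tab)
}
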