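#' Position weight matrix motif model
#'
#' A motif is a per-position nucleotide probability matrix over A/C/G/T
#' plus background frequencies.  A pseudo-count is added to every cell
#' (then columns renormalized) before forming the log2-odds scoring
#' matrix, so all probabilities are strictly positive.
#'
#' @param name motif name.
#' @param probs 4 x width numeric matrix, rows A, C, G, T; columns sum
#'   to 1.
#' @param background length-4 nucleotide background, sums to 1 (default
#'   uniform).
#' @param pseudo pseudo-count added per cell (default 0.1).
#' @return Object of class `motif_model` with elements `name`, `width`,
#'   `probs`, `background`, `pseudo`, `logodds` (log2).
#' @export
motif_model <- function(name, probs, background = rep(0.25, 4), pseudo = 0.1) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stopf("probability matrix needs 4 rows (A,C,G,T)")
  if (ncol(probs) < 3) stopf("motif width must be >= 3")
  if (any(probs < 0) || any(abs(colSums(probs) - 1) > 1e-4))
    stopf("motif columns must be probability distributions")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-4)
    stopf("background must be 4 frequencies summing to 1")
  if (any(background <= 0)) stopf("background frequencies must be positive")
  rownames(probs) <- c("A", "C", "G", "T")
  padj <- sweep(probs + pseudo, 2, colSums(probs + pseudo), "/")
  lo <- log2(padj / background)
  structure(list(name = name, width = ncol(probs), probs = probs,
                 background = background, pseudo = pseudo, logodds = lo),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s', width %d\n", x$name, x$width))
  cat("consensus:", paste(rownames(x$probs)[apply(x$probs, 2, which.max)],
                          collapse = ""), "\n")
  invisible(x)
}

#' Exact score distribution and p-values for a motif
#'
#' Dynamic program over discretized log-odds scores: the log-odds matrix
#' is rounded onto an integer grid (`resolution` steps across the score
#' range), and the exact distribution of the integer score of a random
#' background sequence of the motif's width is accumulated column by
#' column.  The p-value of a score s is P(score >= s) under that
#' background model.  Scanning uses the same integer grid, so lookup is
#' exact on the grid.
#'
#' @param motif a [motif_model()].
#' @param resolution number of discretization steps across the score
#'   range (default 1000).
#' @return Object of class `motif_score_dist`: `step`, `int_matrix`
#'   (integer scores per cell), `tail` (tail probabilities indexed by
#'   integer score + 1), `max_int`.
#' @export
score_distribution <- function(motif, resolution = 1000) {
  if (resolution < 100) warnf("resolution %d is coarse; p-values will be rough",
                              resolution)
  lo <- motif$logodds
  col_min <- apply(lo, 2, min)
  rng <- sum(apply(lo, 2, max) - col_min)
  step <- if (rng > 0) rng / resolution else 1
  im <- round(sweep(lo, 2, col_min, "-") / step)  # integers >= 0 per cell
  storage.mode(im) <- "integer"
  max_int <- sum(apply(im, 2, max))
  pmf <- numeric(max_int + 1)
  pmf[1] <- 1
  bg <- motif$background
  for (j in seq_len(ncol(im))) {
    new <- numeric(max_int + 1)
    for (b in 1:4) {
      k <- im[b, j]
      nz <- which(pmf > 0)
      new[nz + k] <- new[nz + k] + pmf[nz] * bg[b]
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  structure(list(step = step, col_min = col_min, int_matrix = im,
                 tail = tail, max_int = max_int, motif = motif$name),
            class = "motif_score_dist")
}

# integer score of every offset of an integer-encoded sequence (1..4, NA for N)
.scan_int_scores <- function(s_int, im) {
  w <- ncol(im)
  L <- length(s_int)
  if (L < w) return(integer(0))
  n_off <- L - w + 1
  sc <- integer(n_off)
  ok <- rep(TRUE, n_off)
  for (i in seq_len(w)) {
    idx <- s_int[i:(n_off + i - 1)]
    ok <- ok & !is.na(idx)
    v <- im[cbind(ifelse(is.na(idx), 1L, idx), i)]
    sc <- sc + v
  }
  sc[!ok] <- NA_integer_
  sc
}

.encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  v
}

.revcomp_int <- function(s_int) rev(5L - s_int)  # A<->T, C<->G on 1..4; NA stays NA

#' Scan sequences for motif occurrences
#'
#' Scores every offset of every sequence (both strands by default) against
#' the motif and reports positions whose exact-distribution p-value is at
#' or below the threshold.  Offsets containing N are skipped; sequences
#' shorter than the motif yield no hits.
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`.
#' @param motif a [motif_model()].
#' @param p_threshold report hits with p <= this (default 1e-4).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param dist precomputed [score_distribution()] (computed if NULL).
#' @return data.frame: `sequence`, `offset` (1-based start on the forward
#'   strand), `strand`, `score` (log2 odds), `pvalue`.
#' @export
scan_sequences <- function(sequences, motif, p_threshold = 1e-4,
                           both_strands = TRUE, dist = NULL) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  if (is.null(dist)) dist <- score_distribution(motif)
  im <- dist$int_matrix
  w <- ncol(im)
  shift <- sum(dist$col_min)
  out <- vector("list", length(sequences))
  for (s in seq_along(sequences)) {
    s_int <- .encode_dna(sequences[[s]])
    hits <- list()
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      v <- if (st == "+") s_int else .revcomp_int(s_int)
      sc <- .scan_int_scores(v, im)
      if (!length(sc)) next
      p <- dist$tail[sc + 1L]
      keep <- which(!is.na(sc) & p <= p_threshold)
      if (!length(keep)) next
      off <- if (st == "+") keep else length(s_int) - (keep + w - 1L) + 1L
      hits[[st]] <- data.frame(
        sequence = names(sequences)[s], offset = off, strand = st,
        score = sc[keep] * dist$step + shift, pvalue = p[keep],
        stringsAsFactors = FALSE)
    }
    out[[s]] <- if (length(hits)) do.call(rbind, hits) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Motif enrichment in foreground vs background windows
#'
#' A window "contains" the motif iff it has at least one scan hit at the
#' p-value threshold.  Containment fractions of the foreground (e.g.
#' summit windows of peaks gaining accessibility) and background
#' (windows of non-differential peaks -- the default and recommended
#' control) are compared by a Fisher exact test.
#'
#' @param fg_windows,bg_windows sequence sets (character or DNAStringSet).
#' @inheritParams scan_sequences
#' @return list: `fraction_fg`, `fraction_bg`, `odds_ratio`, `pvalue`,
#'   `n_fg`, `n_bg`.
#' @export
motif_enrichment <- function(fg_windows, bg_windows, motif,
                             p_threshold = 1e-4, both_strands = TRUE) {
  if (length(fg_windows) == 0 || length(bg_windows) == 0)
    stopf("foreground and background window sets must be non-empty")
  dist <- score_distribution(motif)
  contains <- function(seqs) {
    h <- scan_sequences(seqs, motif, p_threshold, both_strands, dist)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
    names(seqs) %in% h$sequence
  }
  fg <- contains(fg_windows); bg <- contains(bg_windows)
  tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), 2, 2)
  ft <- fisher.test(tab)
  list(fraction_fg = mean(fg), fraction_bg = mean(bg),
       odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
       n_fg = length(fg), n_bg = length(bg))
}
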