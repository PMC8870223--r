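# enumeration oracle: score every k-mer, weight by background
enumerate_kmers <- function(w) {
  g <- expand.grid(rep(list(1:4), w))
  as.matrix(g)
}

test_that("motif_model validates its probability structure", {
  p <- matrix(0.25, 4, 5)
  m <- motif_model("flat", p)
  expect_equal(m$width, 5)
  expect_error(motif_model("bad", p[1:3, ]), "4 rows")
  expect_error(motif_model("bad", matrix(0.3, 4, 5)), "probability")
  expect_error(motif_model("short", matrix(0.25, 4, 2)), "width")
  expect_error(motif_model("bg", p, background = c(1, 0, 0, 0)), "positive")
})

test_that("exact score distribution equals exhaustive k-mer enumeration", {
  set.seed(51)
  for (trial in 1:5) {
    w <- sample(3:5, 1)
    probs <- matrix(rgamma(4 * w, 1), 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    m <- motif_model(sprintf("m%d", trial), probs, background = bg)
    d <- score_distribution(m, resolution = 2000)
    kmers <- enumerate_kmers(w)
    int_scores <- apply(kmers, 1, function(k) sum(d$int_matrix[cbind(k, 1:w)]))
    wts <- apply(kmers, 1, function(k) prod(bg[k]))
    # for every observed integer score the DP tail equals the enumerated tail
    for (s in unique(int_scores)) {
      expect_equal(d$tail[s + 1], sum(wts[int_scores >= s]), tolerance = 1e-9)
    }
    # monotone non-increasing tail
    expect_true(all(diff(d$tail) <= 1e-12))
  }
})

test_that("a point-mass motif's best word has p = background mass of one k-mer", {
  probs <- matrix(0.001 / 3, 4, 4)
  probs[cbind(c(1, 3, 2, 4), 1:4)] <- 0.999
  m <- motif_model("point", probs)
  d <- score_distribution(m, resolution = 2000)
  best <- sum(apply(d$int_matrix, 2, max))
  expect_equal(d$tail[best + 1], (1 / 4)^4, tolerance = 1e-9)
})

test_that("discretized p-values converge to continuous enumeration as resolution grows", {
  set.seed(53)
  probs <- matrix(rgamma(4 * 4, 1), 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  m <- motif_model("conv", probs)
  kmers <- enumerate_kmers(4)
  cont <- apply(kmers, 1, function(k) sum(m$logodds[cbind(k, 1:4)]))
  wts <- rep(1 / 256, 256)
  target_word <- kmers[77, ]
  p_cont <- mean(cont >= sum(m$logodds[cbind(target_word, 1:4)]) - 1e-12)
  errs <- vapply(c(200, 2000, 20000), function(res) {
    d <- score_distribution(m, res)
    s <- sum(d$int_matrix[cbind(target_word, 1:4)])
    abs(d$tail[s + 1] - p_cont)
  }, 1)
  expect_lt(errs[3], 1e-3)
  expect_true(errs[3] <= errs[1] + 1e-9)
})

test_that("scanning finds the consensus and respects the threshold", {
  m <- default_motif()
  cons <- paste(rownames(m$probs)[apply(m$probs, 2, which.max)], collapse = "")
  seqs <- c(hit = paste0("ACGT", cons, "ACGTACGT"),
            miss = "ACGTACGTACGTACGTACGTAC")
  hits <- scan_sequences(seqs, m, p_threshold = 1e-4)
  expect_true(any(hits$sequence == "hit" & hits$offset == 5 & hits$strand == "+"))
  expect_false(any(hits$sequence == "miss"))
  # p-threshold 0 silences everything
  expect_equal(nrow(scan_sequences(seqs, m, p_threshold = 0)), 0)
  # sequences shorter than the motif yield no hits, not an error
  expect_equal(nrow(scan_sequences(c(s = "ACGT"), m)), 0)
})

test_that("scan equals a brute-force position scorer on random sequences", {
  set.seed(55)
  m <- default_motif()
  d <- score_distribution(m)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:30)
  hits <- scan_sequences(seqs, m, p_threshold = 0.01, both_strands = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  found <- list()
  for (nm in names(seqs)) {
    ch <- strsplit(seqs[[nm]], "")[[1]]
    for (off in 1:(60 - m$width + 1)) {
      for (st in c("+", "-")) {
        word <- ch[off:(off + m$width - 1)]
        if (st == "-") word <- rev(comp[word])
        ii <- match(word, c("A", "C", "G", "T"))
        s_int <- sum(d$int_matrix[cbind(ii, 1:m$width)])
        if (d$tail[s_int + 1] <= 0.01)
          found[[length(found) + 1]] <- data.frame(sequence = nm, offset = off,
                                                   strand = st)
      }
    }
  }
  found <- do.call(rbind, found)
  got <- hits[order(hits$sequence, hits$offset, hits$strand),
              c("sequence", "offset", "strand")]
  exp <- found[order(found$sequence, found$offset, found$strand), ]
  rownames(got) <- rownames(exp) <- NULL
  expect_equal(got, exp)
})

test_that("both-strand scans are invariant under reverse complementation", {
  set.seed(57)
  m <- default_motif()
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:10)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- vapply(seqs, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "")
  h1 <- scan_sequences(seqs, m, p_threshold = 0.01)
  h2 <- scan_sequences(rc, m, p_threshold = 0.01)
  # same number of hits per sequence, offsets mirrored
  expect_equal(nrow(h1), nrow(h2))
  for (nm in names(seqs)) {
    a <- h1[h1$sequence == nm, ]
    b <- h2[h2$sequence == nm, ]
    expect_setequal(a$offset, 40 - (b$offset + m$width - 1) + 1)
  }
})

test_that("windows with N are skipped at affected offsets only", {
  m <- default_motif()
  cons <- paste(rownames(m$probs)[apply(m$probs, 2, which.max)], collapse = "")
  s <- c(x = paste0("NNNN", cons, "NNNNNN"))
  hits <- scan_sequences(s, m, p_threshold = 1e-4)
  expect_true(any(hits$offset == 5))
  expect_true(all(hits$offset == 5 | hits$strand == "-"))
})

test_that("motif enrichment recovers planted foreground excess", {
  cfg <- sim_config(seed = 59, motif_plant_rate_fg = 0.25,
                    motif_plant_rate_bg = 0.05)
  m <- default_motif()
  sim <- simulate_sequences(paste0("w", 1:600),
                            rep(c(TRUE, FALSE), c(150, 450)), m, cfg)
  fg <- sim$sequences[sim$truth$is_fg]
  bg <- sim$sequences[!sim$truth$is_fg]
  r <- motif_enrichment(fg, bg, m)
  expect_lt(r$pvalue, 0.01)
  expect_gt(r$odds_ratio, 2)
  # identical fg and bg: no enrichment
  r0 <- motif_enrichment(bg[1:100], bg[1:100], m)
  expect_equal(r0$fraction_fg, r0$fraction_bg)
  expect_equal(r0$pvalue, 1)
  expect_error(motif_enrichment(character(0), bg, m), "non-empty")
})

test_that("background-only containment matches the analytic per-window rate", {
  set.seed(61)
  m <- default_motif()
  d <- score_distribution(m)
  # attained p at the 1e-4 threshold
  p_eff <- max(d$tail[d$tail <= 1e-4])
  n_win <- 400; L <- 101
  seqs <- vapply(seq_len(n_win), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), "")
  names(seqs) <- paste0("w", seq_len(n_win))
  hits <- scan_sequences(seqs, m, p_threshold = 1e-4)
  rate <- mean(names(seqs) %in% hits$sequence)
  n_off <- 2 * (L - m$width + 1)
  expected <- 1 - (1 - p_eff)^n_off
  expect_lt(abs(rate - expected), 3 * sqrt(expected / n_win) + 0.01)
})

test_that("the bundled MEME file round-trips and matches the in-code motif", {
  f <- system.file("extdata", "ap1_synthetic.meme", package = "stromareg")
  motifs <- read_meme(f)
  m <- motifs$AP1_synthetic
  expect_equal(m$width, 10)
  expect_equal(m$probs, default_motif()$probs, tolerance = 1e-4)
  tmp <- tempfile(fileext = ".meme")
  write_meme(motifs, tmp)
  back <- read_meme(tmp)
  expect_equal(back$AP1_synthetic$probs, m$probs, tolerance = 1e-5)
})
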