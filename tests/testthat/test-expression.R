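make_cm <- function(m, cond, lengths = NULL) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  count_matrix(m, cond, lengths = lengths)
}

test_that("CPM normalization forces columns to one million", {
  cm <- make_cm(cbind(c(10, 90), c(5, 5)), c("MONO", "CO"))
  cpm <- compute_cpm(cm)
  expect_equal(unname(cpm[, 1]), c(1e5, 9e5))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  one <- make_cm(matrix(10, 1, 1), "MONO")
  expect_equal(unname(compute_cpm(one)[1, 1]), 1e6)
  zero <- make_cm(cbind(c(0, 10)), "MONO")
  expect_equal(unname(compute_cpm(zero)[1, 1]), 0)
  bad <- matrix(c(0, 0, 1, 1), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(compute_cpm(bad), "s1")
})

test_that("RPKM matches the per-entry unit definition", {
  # 1 read on a 1 kb feature in a 1e6-read library -> RPKM 1
  m <- matrix(c(1, 999999), 2, 1,
              dimnames = list(c("a", "b"), "s1"))
  r <- compute_rpkm(m, lengths = c(1000, 5000))
  expect_equal(unname(r["a", 1]), 1.0)
  expect_equal(unname(compute_rpkm(m * 0 + c(0, 10), lengths = c(1000, 500))["a", 1]), 0)
  # random matrix against a direct formula loop
  set.seed(42)
  m <- matrix(rpois(80, 50), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  len <- sample(200:5000, 20)
  r <- compute_rpkm(m, lengths = len)
  for (i in 1:20) for (j in 1:4) {
    expect_equal(r[i, j],
                 m[i, j] / (len[i] / 1e3) / (sum(m[, j]) / 1e6),
                 tolerance = 1e-9)
  }
  expect_error(compute_rpkm(m), "lengths")
})

test_that("BH adjustment follows the step-up rule and is order-invariant", {
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(0.02), 0.02)
  # hand-executed step-up: p_(i) * m / i, cummin from the top
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(1)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression calls obey the three-part rule", {
  set.seed(7)
  cm <- nb_counts(n_genes = 200, mu = 100, disp = 0.05, reps = 3,
                  fc_idx = 1:20, log2fc = 2)
  de <- differential_expression(cm, "MONO", "CO")
  expect_true(all(de$call[1:20] == "up"))
  expect_true(all(de$fdr[de$call != "unchanged"] < 0.05))
  expect_true(all(abs(de$log2fc[de$call != "unchanged"]) > log2(1.5)))
  expect_true(all(de$log2cpm[de$call != "unchanged"] > 0))
  # identical replicate columns in both groups -> all unchanged, log2FC 0
  m <- matrix(rep(c(30, 60, 90, 50), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cm2 <- count_matrix(m, rep(c("MONO", "CO"), each = 3))
  de2 <- differential_expression(cm2, "MONO", "CO")
  expect_true(all(de2$call == "unchanged"))
  expect_equal(de2$log2fc, rep(0, 4), tolerance = 1e-8)
  # replicate and label errors
  cm3 <- make_cm(matrix(10, 4, 3), c("MONO", "MONO", "CO"))
  expect_error(differential_expression(cm3, "MONO", "CO"), "replicates")
  expect_error(differential_expression(cm2, "MONO", "XX"), "XX")
})

test_that("log2FC tracks the direct normalized group-mean ratio for well-measured genes", {
  set.seed(8)
  cm <- nb_counts(n_genes = 300, mu = 200, disp = 0.05, reps = 3,
                  fc_idx = 1:30, log2fc = 1.5)
  de <- differential_expression(cm, "MONO", "CO")
  eff <- attr(de, "effective_libsize")
  cpm <- sweep(unclass(cm), 2, eff, "/") * 1e6
  direct <- log2(rowMeans(cpm[, 4:6]) / rowMeans(cpm[, 1:3]))
  keep <- rowMeans(unclass(cm)) >= 50
  expect_lt(max(abs(de$log2fc[keep] - direct[keep])), 0.1)
})

test_that("stromal-signature filter needs both high stromal rank and tumor silence", {
  mm <- matrix(c(0.3, 50, 0, 0.2), 4, 1,
               dimnames = list(c("gA", "gB", "gC", "gD"), "s1"))
  stromal <- setNames(c(1000, 900, 800, 5), c("gA", "gB", "gC", "gD"))
  excl <- stromal_signature_filter(mm, stromal, top_n = 3)
  expect_true("gA" %in% excl)   # rank 1, silent
  expect_false("gB" %in% excl)  # rank 2 but expressed (RPKM 50)
  expect_true("gC" %in% excl)   # rank 3, silent
  expect_false("gD" %in% excl)  # silent but rank 4 > top_n
  # ties at the boundary are all included
  st2 <- setNames(c(10, 5, 5, 1), c("gA", "gB", "gC", "gD"))
  excl2 <- stromal_signature_filter(mm, st2, top_n = 2)
  expect_true("gC" %in% excl2)
  expect_error(stromal_signature_filter(mm, numeric(0)), "empty")
})

test_that("promoter-openness filter excludes only genes closed everywhere (default reading)", {
  st <- rbind(gA = c(MONO = FALSE, TSW = FALSE, CO = FALSE),
              gB = c(TRUE, TRUE, TRUE),
              gC = c(FALSE, TRUE, FALSE))
  expect_equal(promoter_open_filter(st), "gA")
  # stricter reading: not open in all three
  expect_equal(promoter_open_filter(st, require_all_open = TRUE),
               c("gA", "gC"))
  expect_error(promoter_open_filter(st, conditions = c("MONO", "XX")), "XX")
})

test_that("rnk construction sorts by fold change and honors exclusions", {
  res <- data.frame(feature = c("a", "b", "c"),
                    log2fc = c(2, 0.5, 1))
  rnk <- make_rnk(res)
  expect_equal(rnk$gene, c("a", "c", "b"))
  rnk2 <- make_rnk(res, exclude = "c")
  expect_false("c" %in% rnk2$gene)
  expect_error(make_rnk(data.frame(feature = c("a", "a"), log2fc = 1:2)),
               "duplicate")
  # round-trip through the rnk file format
  f <- tempfile(fileext = ".rnk")
  write_rnk(rnk, f)
  back <- read_rnk(f)
  expect_equal(back$gene, rnk$gene)
  expect_equal(back$score, rnk$score, tolerance = 1e-5)
})

test_that("row z-scores have mean 0, sd 1, and flatten constant rows", {
  z <- zscore_rows(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(3)
  m <- matrix(rnorm(60), 6)
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 6))
})

test_that("PCA embedding separates planted conditions and respects duplicates", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 1, 0))
  co <- pca_embed(m, 2)$coords
  expect_equal(co["a", ], co["b", ])
  # rank-1 matrix: all variance on PC1
  r1 <- outer(1:5, c(1, 2, 3, 4))
  dimnames(r1) <- list(paste0("g", 1:5), paste0("s", 1:4))
  expect_gt(pca_embed(r1, 2)$var_explained[1], 0.999)
  expect_error(pca_embed(m, 5), "components")
  # synthetic three-condition data: MONO separates from TSW/CO
  cfg <- sim_config(seed = 6, n_genes = 200)
  expr <- simulate_expression(cfg)
  emb <- pca_embed(log2_cpm(expr$counts), 2)$coords
  cond <- conditions(expr$counts)
  centroid <- apply(emb, 2, tapply, cond, mean)
  d_between <- sqrt(sum((centroid["MONO", ] -
                           colMeans(centroid[c("TSW", "CO"), ]))^2))
  within <- max(sqrt(rowSums((emb - centroid[cond, ])^2)))
  expect_gt(d_between, within)
})
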