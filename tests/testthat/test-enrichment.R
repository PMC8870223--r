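# independent running-sum evaluation used as the GSEA oracle
oracle_es <- function(scores, hit, weight = 1) {
  n <- length(scores); nh <- sum(hit)
  nr <- sum(abs(scores[hit])^weight)
  run <- 0; best <- 0
  best_i <- 1
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(scores[i])^weight / nr else -1 / (n - nh)
    if (abs(run) > abs(best)) { best <- run; best_i <- i }
  }
  list(es = best, argmax = best_i)
}

test_that("GSEA ES equals an explicit running-sum tabulation on a 10-gene ranking", {
  rnk <- data.frame(gene = letters[1:10],
                    score = c(5, 4, 3, 2.5, 2, 1, 0.5, -1, -2, -4))
  gs <- c("b", "d", "i")
  res <- gsea_preranked(rnk, gs, weight = 1, n_perm = 200, seed = 1)
  oracle <- oracle_es(rnk$score, rnk$gene %in% gs, 1)
  expect_equal(res$es, oracle$es, tolerance = 1e-12)
  # a set formed by the k top-ranked genes maximizes concentration
  topset <- gsea_preranked(rnk, c("a", "b", "c"), n_perm = 200, seed = 1)
  expect_gt(topset$es, 0)
  expect_setequal(topset$leading_edge, c("a", "b", "c"))
})

test_that("unweighted GSEA is antisymmetric under ranking reversal", {
  set.seed(2)
  rnk <- data.frame(gene = paste0("g", 1:40), score = sort(rnorm(40), TRUE))
  gs <- sample(rnk$gene, 8)
  a <- gsea_preranked(rnk, gs, weight = 0, n_perm = 100, seed = 3)
  rev_rnk <- data.frame(gene = rnk$gene, score = -rnk$score)
  b <- gsea_preranked(rev_rnk, gs, weight = 0, n_perm = 100, seed = 3)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("GSEA ES is invariant to positive rescaling of the scores", {
  set.seed(4)
  rnk <- data.frame(gene = paste0("g", 1:30), score = sort(rnorm(30), TRUE))
  gs <- sample(rnk$gene, 6)
  a <- gsea_preranked(rnk, gs, n_perm = 100, seed = 1)
  rnk2 <- data.frame(gene = rnk$gene, score = rnk$score * 7.3)
  b <- gsea_preranked(rnk2, gs, n_perm = 100, seed = 1)
  expect_equal(a$es, b$es, tolerance = 1e-12)
})

test_that("GSEA ES agrees with fgsea's statistic on random cases", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  for (i in 1:10) {
    n <- 50
    rnk <- data.frame(gene = paste0("g", 1:n),
                      score = sort(rnorm(n), decreasing = TRUE))
    gs <- sample(rnk$gene, 10)
    mine <- gsea_preranked(rnk, gs, weight = 1, n_perm = 100, seed = 1)
    stats <- setNames(rnk$score, rnk$gene)
    ref <- fgsea::calcGseaStat(stats, which(rnk$gene %in% gs),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine$es, ref, tolerance = 1e-6)
  }
})

test_that("GSEA nominal p is calibrated under random gene sets", {
  set.seed(8)
  n <- 60
  rnk <- data.frame(gene = paste0("g", 1:n),
                    score = sort(rnorm(n), decreasing = TRUE))
  ps <- vapply(1:150, function(i) {
    gs <- sample(rnk$gene, 8)
    gsea_preranked(rnk, gs, n_perm = 200, seed = 100 + i)$pvalue
  }, 1)
  # roughly uniform: mean near 0.5, no mass pile-up at the low end
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("GSEA over a collection reports permutation FDR and planted signal", {
  cfg <- sim_config(seed = 10, n_genes = 150)
  expr <- simulate_expression(cfg)
  de <- differential_expression(expr$counts, "MONO", "CO")
  rnk <- make_rnk(de)
  up <- expr$truth$gene[expr$truth$planted_log2fc > 0]
  sets <- list(planted_up = up,
               random1 = sort(sample(expr$truth$gene, 20)),
               random2 = sort(sample(expr$truth$gene, 20)))
  res <- gsea_collection(rnk, sets, n_perm = 300, seed = 5)
  expect_equal(res$set, names(sets))
  expect_gt(res$es[1], 0)
  expect_lt(res$pvalue[1], 0.05)
  expect_lt(res$fdr[1], 0.25)
  expect_true(all(sign(res$nes) == sign(res$es)))
})

test_that("hypergeometric enrichment equals direct combinatorics", {
  # universe 10, set 5, list 5, overlap 5 -> p = 1/C(10,5)
  r <- hypergeom_enrichment(5, 5, 5, 10)
  expect_equal(r$pvalue, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(0, 0, 4, 10)$pvalue, 1)
  expect_equal(hypergeom_enrichment(0, 0, 4, 10)$ratio, 0)
  # random configurations vs explicit PMF tail summation
  set.seed(12)
  for (i in 1:50) {
    u <- sample(20:200, 1)
    ss <- sample.int(u %/% 2, 1)
    ls <- sample.int(u %/% 2, 1)
    h <- sample(0:min(ss, ls), 1)
    tail_sum <- sum(vapply(h:min(ss, ls), function(k)
      choose(ss, k) * choose(u - ss, ls - k) / choose(u, ls), 1))
    expect_equal(hypergeom_enrichment(h, ls, ss, u)$pvalue, tail_sum,
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment(6, 5, 5, 10), "inconsistent")
})

test_that("hypergeometric screening over gene sets applies BH", {
  universe <- paste0("g", 1:100)
  lst <- paste0("g", 1:20)
  sets <- list(hit_set = paste0("g", 1:15),
               null_set = paste0("g", 81:100))
  res <- hypergeom_enrichment_sets(lst, sets, universe)
  expect_lt(res$pvalue[1], 1e-6)
  expect_gt(res$ratio[1], 4)
  expect_equal(res$fdr, bh_fdr(res$pvalue))
})

test_that("K-S shift test: D statistic and exact enumeration", {
  x <- c(1, 2, 3); r <- ks_shift_test(x, x)
  expect_equal(r$statistic, 0)
  r2 <- ks_shift_test(c(1, 2), c(3, 4))
  expect_equal(r2$statistic, 1)
  expect_true(r2$exact)
  expect_equal(r2$pvalue, 1 / 3, tolerance = 1e-12)
  expect_error(ks_shift_test(1, c(1, 2)), "n >= 2")
})

test_that("exact K-S p equals full enumeration and tracks the asymptotic p", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    r <- ks_shift_test(x, y, exact_limit = 30)
    # independent enumeration over all C(10,5) assignments
    pooled <- c(x, y)
    idx <- combn(10, 5)
    d_obs <- r$statistic
    ds <- apply(idx, 2, function(s) {
      a <- pooled[s]; b <- pooled[-s]
      v <- sort(unique(pooled))
      max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), 1)))
    })
    expect_equal(r$pvalue, mean(ds >= d_obs - 1e-12), tolerance = 1e-12)
    asym <- ks_shift_test(x, y, exact_limit = 0)
    expect_false(asym$exact)
    expect_lt(abs(asym$pvalue - r$pvalue), 0.02)
  }
})

test_that("concordance ratio matches the margins-product expectation", {
  # 1000 genes, 100 up in A, 150 up in B, 40 consistent up-up, no downs
  a <- rep("unchanged", 1000); b <- rep("unchanged", 1000)
  a[1:100] <- "up"
  b[c(1:40, 201:310)] <- "up"
  r <- contingency_concordance(a, b)
  expect_equal(r$observed, 40)
  expect_equal(r$expected, 100 * 150 / 1000)
  expect_equal(r$ratio, 40 / 15, tolerance = 1e-12)
  expect_lt(r$pvalue, 1e-6)
})

test_that("concordance is ~1 under independence and extreme for identical calls", {
  set.seed(16)
  ratios <- vapply(1:200, function(i) {
    a <- sample(c("up", "down", "unchanged"), 500, TRUE, prob = c(.1, .1, .8))
    b <- sample(c("up", "down", "unchanged"), 500, TRUE, prob = c(.1, .1, .8))
    contingency_concordance(a, b)$ratio
  }, 1)
  expect_lt(abs(mean(ratios) - 1), 0.1)
  a <- c(rep("up", 60), rep("down", 60), rep("unchanged", 380))
  r <- contingency_concordance(a, a)
  expect_gt(r$ratio, 3)
  expect_lt(r$pvalue, 1e-10)
  # named vectors align on the shared gene universe
  a2 <- setNames(a, paste0("g", 1:500))
  expect_error(contingency_concordance(a2, setNames(a, paste0("x", 1:500))),
               "share no genes")
})
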