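test_that("variance fractions recover known orthogonal shares", {
  set.seed(101)
  n <- 2000
  g <- scale(rbinom(n, 2, 0.4))
  e <- scale(rnorm(n))
  y <- as.vector(g + e)   # 50/50 split
  fr <- variance_fractions(y, list(genotype = g))
  expect_equal(unname(fr["genotype"]), 0.5, tolerance = 0.05)
  expect_equal(sum(fr), 1)
  # independent of all predictors: residual fraction near 1
  fr0 <- variance_fractions(rnorm(500), list(genotype = rbinom(500, 2, 0.3)))
  expect_gt(unname(fr0["residual"]), 0.97)
})

test_that("variance fractions equal marginal R2 for orthogonal predictors", {
  set.seed(102)
  n <- 400
  x1 <- rnorm(n); x2 <- residuals(lm(rnorm(n) ~ x1))  # exactly orthogonal to x1
  x1 <- x1 - mean(x1); x2 <- x2 - mean(x2)
  y <- 0.8 * x1 + 0.4 * x2 + rnorm(n)
  fr <- variance_fractions(y, list(a = x1, b = x2))
  r2a <- summary(lm(y ~ x1))$r.squared
  r2b <- summary(lm(y ~ x2))$r.squared
  expect_equal(unname(fr["a"] / fr["b"]), r2a / r2b, tolerance = 0.05)
})

test_that("CCF matches hand computations and is linear in VAF", {
  expect_equal(ccf(0.25, 0.5, 2, 2, 1), 1.0)
  expect_equal(ccf(0.5, 1, 2, 2, 1), 1.0)
  expect_equal(ccf(0.1, 0.5, 2, 2, 1), 0.4)
  v <- c(0.05, 0.1, 0.2)
  expect_equal(ccf(v, 0.8), v * ccf(1e-9, 0.8) / 1e-9, tolerance = 1e-6)
  expect_equal(ccf(1, 0.5, 8, 2, 1), 1.5)   # clamped at 1.5
  expect_warning(out <- ccf(0.2, 0), "purity")
  expect_true(is.na(out))
})

test_that("MATH score matches hand computations and is scale-invariant", {
  expect_equal(math_score(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.2 / 0.6)
  expect_equal(math_score(rep(0.4, 5)), 0)
  x <- runif(50, 0.1, 1)
  expect_equal(math_score(2 * x), math_score(x) / 1)
  # two equal subclone clusters at 0.3 and 0.9: MAD = 0.3, median = 0.6
  cc <- rep(c(0.3, 0.9), 50)
  expect_equal(math_score(cc), 0.3 / 0.6)
  expect_warning(math_score(c(0.1, 0.2)), "fewer than 3")
  expect_equal(math_score(c(0.5, 0.7, 0.9), conventional = TRUE),
               100 * 1.4826 * 0.2 / 0.7)
})

test_that("eGene fraction and QTL ratio are simple set arithmetic", {
  expect_equal(egene_fraction(c("a", "b"), c("a", "b", "c", "d")), 0.5)
  expect_equal(egene_fraction(character(0), "a"), 0)
  expect_equal(egene_fraction(c("a"), c("a")), 1)
  expect_error(egene_fraction("a", character(0)), "empty")
  expect_equal(qtl_ratio(10, 20), 0.5)
  expect_equal(qtl_ratio(0, 5), 0)
  expect_equal(qtl_ratio(623, 10), 62.3)
  expect_warning(qtl_ratio(3, 0), "zero")
})

test_that("Jaccard similarity and min-max scaling behave per definition", {
  s <- similarity_matrix(list(x = c("B", "C"), y = c("B", "C", "D", "E")))
  expect_equal(s$raw["x", "y"], 0.5)
  expect_equal(diag(s$raw), c(x = 1, y = 1))
  s3 <- similarity_matrix(list(a = as.character(1:2),
                               b = as.character(1:4),
                               c = as.character(1:8)))
  off <- sort(s3$raw[upper.tri(s3$raw)])
  sc <- sort(s3$scaled[upper.tri(s3$scaled)])
  expect_equal(sc, (off - min(off)) / (max(off) - min(off)))
  expect_equal(range(sc), c(0, 1))
  # symmetry and order preservation
  expect_equal(s3$raw, t(s3$raw))
  expect_equal(order(s3$raw[upper.tri(s3$raw)]),
               order(s3$scaled[upper.tri(s3$scaled)]))
  # identical sets everywhere: scaled collapses to 0 with a note
  suppressMessages(se <- similarity_matrix(list(a = "g", b = "g", c = "g")))
  expect_true(all(se$scaled[upper.tri(se$scaled)] == 0))
})

test_that("downsampling is seeded, sorted and order-invariant", {
  ids <- sprintf("P%03d", 1:203)
  d1 <- suppressMessages(downsample(ids, 200, seed = 3))
  expect_length(d1, 200)
  expect_false(is.unsorted(d1))
  expect_identical(d1, suppressMessages(downsample(rev(ids), 200, seed = 3)))
  expect_identical(d1, suppressMessages(downsample(ids, 200, seed = 3)))
  # cohorts smaller than n are skipped
  expect_null(suppressMessages(downsample(sprintf("P%03d", 1:143), 200)))
})

test_that("sharing counts identify ubiquitous and private eGenes", {
  sh <- sharing_counts(list(t1 = c("a", "b"), t2 = c("b", "c")))
  expect_equal(sh$counts[["b"]], 2L)
  expect_equal(sh$shared_in_all, "b")
  expect_equal(sort(sh$unique_to_one), c("a", "c"))
  one <- sharing_counts(list(t1 = c("a", "b")))
  expect_true(all(one$counts == 1L))
  dis <- sharing_counts(list(t1 = "a", t2 = "b"))
  expect_length(dis$shared_in_all, 0)
})

test_that("per-sample MATH scores flow from the mutation table", {
  set.seed(104)
  mt <- data.frame(sample = rep(c("s1", "s2"), each = 10),
                   vaf = runif(20, 0.05, 0.45))
  pur <- c(s1 = 0.8, s2 = 0.6)
  ms <- sample_math_scores(mt, pur)
  expect_equal(ms$sample, c("s1", "s2"))
  expect_equal(ms$n_mutations, c(10L, 10L))
  cc1 <- ccf(mt$vaf[1:10], 0.8)
  expect_equal(ms$math[1], math_score(cc1))
})
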