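test_that("genotype filtering applies MAF, missingness and r2 rules", {
  g <- make_genotypes(n = 40, k = 6, maf = 0.3, seed = 2)
  D <- g$dosages
  D[, 1] <- rbinom(40, 2, 0.005)            # rare variant, MAF < 0.01
  D[1, 2] <- NA                             # sparse missingness on variant 2
  D[2, 3:6] <- NA                           # sample 2 missing 4/6 > 2.5%
  v <- g$variants
  v$r2 <- c(0.9, 0.9, 0.2, 0.9, 0.9, 0.9)   # variant 3 fails imputation r2
  g2 <- genotype_matrix(D, v, g$samples)
  suppressMessages(f <- filter_genotypes(g2, maf_min = 0.01,
                                         snp_missing_max = 0.95,
                                         sample_missing_max = 0.025,
                                         r2_min = 0.3))
  expect_false("v001" %in% f$variants$id)
  expect_false("v003" %in% f$variants$id)
  expect_false("S002" %in% f$samples)
  expect_false(anyNA(f$dosages))
  # mean imputation preserves the allele frequency of variant 2
  kept <- setdiff(seq_len(40), 2)
  expect_equal(mean(f$dosages[, "v002"]),
               mean(D[kept, 2], na.rm = TRUE), tolerance = 1e-12)
})

test_that("a per-call quality mask blanks calls before filtering", {
  g <- make_genotypes(n = 40, k = 5, maf = 0.3, seed = 4)
  qm <- matrix(TRUE, 40, 5)
  qm[, 2] <- FALSE                # variant 2 entirely low quality
  qm[3, 3] <- FALSE               # one masked call on variant 3
  f <- suppressMessages(filter_genotypes(g, snp_missing_max = 0.5,
                                         sample_missing_max = 0.5,
                                         quality_mask = qm))
  expect_false("v002" %in% f$variants$id)
  kept <- setdiff(seq_len(40), 3)
  expect_equal(f$dosages[3, "v003"], mean(g$dosages[kept, 3]))
})

test_that("genotype filtering is the identity on clean data and idempotent", {
  g <- make_genotypes(n = 60, k = 10, maf = 0.3, seed = 3)
  f1 <- suppressMessages(filter_genotypes(g))
  expect_equal(f1$dosages, g$dosages)
  f2 <- suppressMessages(filter_genotypes(f1))
  expect_identical(f2$dosages, f1$dosages)
  expect_identical(f2$variants, f1$variants)
})

test_that("genotype PCs separate simulated subpopulations and are sign-stable", {
  set.seed(7)
  n <- 80; k <- 150
  maf1 <- runif(k, 0.05, 0.5)
  shift <- sample(c(-0.25, 0.25), k, replace = TRUE)
  maf2 <- pmin(pmax(maf1 + shift, 0.05), 0.5)
  D <- rbind(
    matrix(rbinom(n / 2 * k, 2, rep(maf1, each = n / 2)), n / 2, k),
    matrix(rbinom(n / 2 * k, 2, rep(maf2, each = n / 2)), n / 2, k))
  v <- data.frame(id = sprintf("v%03d", 1:k), chrom = "chr1",
                  pos = seq_len(k) * 100, ref = "A", alt = "G")
  g <- genotype_matrix(D, v, sprintf("S%03d", 1:n))
  pcs <- genotype_pcs(g, k = 2)
  pop <- rep(1:2, each = n / 2)
  # silhouette of the 2-population split on PC1
  s <- vapply(seq_len(n), function(i) {
    own <- setdiff(which(pop == pop[i]), i)
    a <- mean(abs(pcs[i, 1] - pcs[own, 1]))
    b <- mean(abs(pcs[i, 1] - pcs[pop != pop[i], 1]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(s), 0.8)
  expect_identical(pcs, genotype_pcs(g, k = 2))
})

test_that("size factors are the median-of-ratios estimator", {
  counts <- matrix(c(10, 100, 20, 200, 10, 100), 2, 3)
  sf <- size_factors(counts)
  expect_equal(unname(sf / sf[1]), c(1, 2, 1))
  # doubling one sample doubles its factor relative to the others (the
  # pseudo-reference rescales by 2^(1/n), so equivariance holds on ratios)
  counts2 <- counts
  counts2[, 2] <- counts[, 2] * 2
  sf2 <- size_factors(counts2)
  expect_equal(unname(sf2[2] / sf2[1]), unname(2 * sf[2] / sf[1]))
  expect_equal(unname(sf2[3] / sf2[1]), unname(sf[3] / sf[1]))
  # two samples, B = 2 x A: factor ratio is exactly 2
  two <- matrix(c(10, 50, 20, 100), 2, 2)
  sft <- size_factors(two)
  expect_equal(unname(sft[2] / sft[1]), 2)
  # all-identical samples share one constant factor
  cc <- matrix(rep(c(5, 50, 500), 4), 3, 4)
  expect_equal(length(unique(size_factors(cc))), 1L)
  # failure when no gene is positive everywhere
  bad <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(bad), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(11)
  counts <- matrix(rnbinom(200 * 8, mu = 50, size = 5), 200, 8)
  counts <- sweep(counts, 2, c(1, 2, 0.5, 1, 3, 1, 0.8, 1.5), "*")
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(size_factors(counts)), unname(ref), tolerance = 1e-10)
})

test_that("gene filtering uses inclusive joint thresholds", {
  n <- 10
  counts <- rbind(rep(6L, n), rep(0L, n), c(rep(10L, 1), rep(0L, n - 1)))
  tpm <- rbind(c(rep(0.1, 2), rep(0, n - 2)), rep(0, n),
               c(10, rep(0, n - 1)))
  # gene 1: passes (0.1 TPM and 6 reads) in exactly 20% of samples -> kept
  tpm[1, ] <- c(0.1, 0.1, rep(0.09, n - 2))
  e <- expression_set(counts, tpm, data.frame(
    id = c("a", "b", "c"), chrom = "chr1", start = c(1, 100, 200) * 1e3,
    end = c(1, 100, 200) * 1e3 + 500, strand = "+"))
  f <- suppressMessages(filter_genes(e, 0.1, 6, 0.2))
  expect_identical(rownames(f$counts), "a")
})

test_that("expression outlier flagging catches a constructed outlier", {
  set.seed(5)
  counts <- matrix(rnbinom(300 * 30, mu = 100, size = 10), 300, 30)
  colnames(counts) <- sprintf("S%02d", 1:30)
  e <- make_expression(counts)
  colnames(e$counts) <- colnames(e$tpm) <- colnames(counts)
  e <- normalize_expression(e)
  # homogeneous cohort: no flags at 3 SD on 6 PCs (small binomial slack)
  expect_lte(length(expression_outliers(e)), 1)
  # inject a divergent sample after normalization (bypasses size factors)
  e2 <- e
  e2$normalized[, 7] <- e2$normalized[, 7] * 10
  expect_true("S07" %in% expression_outliers(e2))
  # infinite cutoff flags nothing
  expect_identical(expression_outliers(e, sd_cut = Inf), character(0))
})

test_that("hidden factors recover strong simulated factors", {
  set.seed(13)
  n <- 100; g <- 400; k <- 3
  Fh <- matrix(rnorm(n * k), n, k)
  L <- matrix(rnorm(g * k, 0, 1), g, k)
  expr <- 2^(L %*% t(Fh) + matrix(rnorm(g * n, 0, 0.5), g, n) + 8)
  hf <- hidden_factors(expr, k = 3)
  cc <- cancor(hf, Fh)$cor
  expect_true(all(cc > 0.9))
  expect_error(hidden_factors(expr, k = 0), "positive")
  # orthogonal columns
  xp <- crossprod(scale(hf, center = TRUE, scale = FALSE))
  off <- xp[upper.tri(xp)] / sqrt(diag(xp)[1] * diag(xp)[2])
  expect_lt(max(abs(off)), 1e-8)
})

test_that("inverse normal transform matches its closed form and properties", {
  expect_equal(inverse_normal(c(5, 1, 9)),
               qnorm((c(2, 1, 3) - 3 / 8) / (3 - 3 / 4 + 1)))
  expect_equal(inverse_normal(c(5, 1, 9))[1], 0)
  x <- rnorm(50, 10, 3)
  # invariance to strictly monotone transforms
  expect_equal(inverse_normal(x), inverse_normal(exp(x / 5)))
  # antisymmetry without ties
  expect_equal(inverse_normal(-x), -inverse_normal(x))
  # variance close to 1 at large n
  set.seed(21)
  u <- runif(1001)
  expect_gt(var(inverse_normal(u)), 0.9)
  expect_lt(var(inverse_normal(u)), 1.1)
  expect_error(inverse_normal(rep(1, 5)), "identical")
})
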