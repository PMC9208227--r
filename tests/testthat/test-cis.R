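test_that("cis window selection is inclusive at the 1 Mb boundary", {
  gene <- data.frame(chrom = "chr1", start = 2e6, end = 2.01e6)
  v <- data.frame(id = c("a", "b", "c", "d", "e"),
                  chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                  pos = c(1e6, 1e6 - 1, 2.005e6, 3.01e6, 2e6))
  expect_equal(cis_window(gene, v, 1e6), c(1, 3, 4))  # start-1e6 inclusive
  expect_equal(cis_window(gene, v, 0), 3)             # gene body only
})

test_that("minor-allele-count filter counts rounded hard calls", {
  D <- matrix(0, 200, 3)
  D[1:3, 1] <- 1     # MAC 3 -> removed
  D[1:5, 2] <- 1     # MAC 5 -> kept (boundary)
  expect_equal(mac_filter(D, 5), 2L)   # column 3 all-ref removed too
  expect_equal(mac_filter(D, 0), 1:3)
})

test_that("nominal scan recovers slopes and is null-calibrated", {
  set.seed(31)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  y <- 0.5 * g + rnorm(n)
  y <- (y - mean(y))
  sc <- nominal_scan(y, cbind(g = g))
  expect_equal(sc$slope, 0.5, tolerance = 0.1)
  expect_lt(sc$p, 1e-10)
  # null p-values are uniform
  set.seed(32)
  G <- matrix(rbinom(200 * 400, 2, 0.3), 200, 400)
  pn <- nominal_scan(rnorm(200), G)$p
  expect_gt(ks.test(pn, "punif")$p.value, 0.01)
  expect_error(nominal_scan(rnorm(10), matrix(1, 10, 1)), "zero-variance")
})

test_that("lead variant tie-break is positional then lexicographic", {
  expect_equal(lead_variant(c(0.5, 0.1, 0.1), c(300, 200, 100)), 3)
  expect_equal(lead_variant(c(0.1, 0.1), c(5, 5), c("b", "a")), 2)
})

test_that("permuted minima over independent null variants follow Beta(1, k)", {
  set.seed(41)
  n <- 150; k <- 10
  G <- matrix(rbinom(n * k, 2, 0.4), n, k)
  colnames(G) <- paste0("v", 1:k)
  y <- rnorm(n)
  pp <- permutation_pass(y, G, 10000, 10000, seed = 5)
  expect_gt(pp$beta_shape1, 0.8)
  expect_lt(pp$beta_shape1, 1.2)
  expect_gt(pp$beta_shape2, 8)
  expect_lt(pp$beta_shape2, 13)
  # reproducibility under the seed
  pp2 <- permutation_pass(y, G, 10000, 10000, seed = 5)
  expect_identical(pp[c("adjusted_p", "empirical_p", "beta_shape1")],
                   pp2[c("adjusted_p", "empirical_p", "beta_shape1")])
})

test_that("beta-adjusted p matches the closed form under Beta(1, 10)", {
  expect_equal(pbeta(0.001, 1, 10), 1 - 0.999^10)
  expect_equal(pbeta(0.001, 1, 10), 0.00996, tolerance = 1e-3)
})

test_that("a strong effect gets a finite adjusted p below permutation resolution", {
  set.seed(43)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  y <- sqrt(0.2 / 0.8) / sd(g) * g + rnorm(n)
  G <- cbind(g, matrix(rbinom(n * 20, 2, 0.3), n, 20))
  colnames(G) <- paste0("v", seq_len(ncol(G)))
  pp <- permutation_pass(inverse_normal(y), G, 200, 1000, seed = 3)
  expect_lt(pp$adjusted_p, 1 / 1000)
  expect_gt(pp$adjusted_p, 0)
  expect_equal(pp$empirical_p, 1 / (1 + pp$n_perm))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and handle ties", {
  expect_equal(storey_qvalues(c(0.001, 0.5, 0.9), pi0 = 1),
               c(0.003, 0.75, 0.9))
  q <- storey_qvalues(rep(0.02, 5), pi0 = 1)
  expect_true(all(q == q[1]))
  expect_equal(storey_qvalues(c(0.1, 0.2, 0.3), pi0 = 1),
               p.adjust(c(0.1, 0.2, 0.3), "BH"))
  # uniform p at large m gives pi0 near 1
  set.seed(51)
  p <- runif(5000)
  q <- storey_qvalues(p)
  pi0_hat <- q[which.max(p)] / max(p)
  expect_gt(pi0_hat, 0.9)
  expect_lte(pi0_hat, 1)
  # monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("eGene calling respects the FDR threshold", {
  r <- data.frame(gene_id = c("a", "b", "c"),
                  q_value = c(0.01, 0.2, NA))
  expect_equal(call_egenes(r, 0.05), "a")
  expect_equal(call_egenes(r, 1), c("a", "b"))
  expect_equal(call_egenes(r[0, ], 0.05), character(0))
})

test_that("residualization removes somatic shifts and covariate structure", {
  set.seed(61)
  n <- 300
  covars <- cbind(pc1 = rnorm(n), hf1 = rnorm(n))
  cna <- ifelse(runif(n) < 0.1, 1, 0)
  y <- 2 * cna + 0.5 * covars[, 1] + rnorm(n)
  r <- residualize(inverse_normal(y), covars, cna = cna,
                   mutation = rep(0, n) |> (\(m) {m[1:5] <- 1; m})())
  tt <- t.test(r[cna == 1], r[cna == 0])
  expect_lt(abs(tt$statistic), 3)
  expect_lt(abs(cor(r, covars[, 1])), 0.1)
  # covariates orthogonal to expression: residuals are centered expression
  y2 <- rnorm(n)
  q <- qr(cbind(1, covars))
  r2 <- qr.resid(q, y2)
  expect_equal(rank(residualize(y2, covars)), rank(r2))
  # perfect fit degenerates
  expect_error(residualize(covars[, 1], covars), "degenerate|collinear")
})

test_that("somQTL testing finds injected CNA effects and skips quiet genes", {
  set.seed(71)
  n <- 300
  cna <- matrix(0, 3, n, dimnames = list(c("g1", "g2", "g3"), NULL))
  mut <- matrix(0, 3, n, dimnames = list(c("g1", "g2", "g3"), NULL))
  cna[1, sample(n, 30)] <- 1
  expr <- rbind(inverse_normal(1 * cna[1, ] + rnorm(n)),
                inverse_normal(rnorm(n)),
                inverse_normal(rnorm(n)))
  rownames(expr) <- c("g1", "g2", "g3")
  cna[2, sample(n, 20)] <- -1   # null CNA on g2
  res <- suppressMessages(somqtl_test(expr, cna, mut))
  expect_true(all(res$gene_id %in% c("g1", "g2")))   # g3 has no events
  expect_lt(res$p[res$gene_id == "g1"], 1e-6)
  expect_gt(res$p[res$gene_id == "g2"], 0.001)
})

test_that("allelic fold change matches its closed form and recovers 2-fold alleles", {
  # b0 = 10, b1 = 5 -> aFC = 1; b1 = 0 -> aFC = 0
  d <- rep(0:2, each = 30)
  expect_equal(allelic_fold_change(10 + 5 * d, d), 1, tolerance = 1e-10)
  expect_equal(allelic_fold_change(rep(10, 90), d), 0)
  # multiplicative allele: alt haplotype doubles output
  set.seed(81)
  n <- 500
  h1 <- rbinom(n, 1, 0.4); h2 <- rbinom(n, 1, 0.4)
  expr <- (2^h1 + 2^h2) / 2 * 100 * exp(rnorm(n, 0, 0.05))
  afc <- allelic_fold_change(expr, h1 + h2)
  expect_equal(afc, 1, tolerance = 0.1)
  expect_warning(allelic_fold_change(pmax(100 - 60 * d, 0), d), "undefined")
})
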