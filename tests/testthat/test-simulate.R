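test_that("config validation rejects impossible settings", {
  expect_error(sim_config(effect_r2 = 1), "effect_r2")
  expect_error(sim_config(maf_range = c(0, 0.5)))
  expect_error(sim_config(effect_class_probs = c(shared = 0.5,
                                                 tumor_restricted = 0.2,
                                                 stroma_restricted = 0.2)))
})

test_that("genotype simulation respects shape, bounds and forced frequency", {
  cfg <- sim_config(n_samples = 100, n_genes = 10, n_variants = 1000,
                    gene_spacing = 2e4, cis_window_bp = 2e5,
                    maf_range = c(0.5, 0.5), seed = 4)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$dosages), c(100, 1000))
  expect_true(all(g$dosages >= 0 & g$dosages <= 2))
  af <- colMeans(round(g$dosages)) / 2
  # forced MAF 0.5: binomial tolerance around 0.5 at 2n = 200 draws
  expect_lt(max(abs(af - 0.5)), 4 * sqrt(0.25 / 200))
  expect_gt(mean(abs(af - 0.5) < 2 * sqrt(0.25 / 200)), 0.9)
})

test_that("genotype simulation is deterministic under the seed", {
  cfg <- small_sim_config(seed = 77)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
})

test_that("too-sparse variant tiling fails with a named deficit", {
  cfg <- sim_config(n_samples = 20, n_genes = 20, n_variants = 60,
                    gene_spacing = 1e6, seed = 1)
  expect_error(simulate_genotypes(cfg), "deficit")
})

test_that("cohort simulation honors null and forced-class configurations", {
  co0 <- suppressMessages(simulate_cohort(small_sim_config(cis_effect_frac = 0,
                                                           seed = 5)))
  expect_equal(nrow(co0$truth$effects), 0)
  cot <- suppressMessages(simulate_cohort(small_sim_config(
    effect_class_probs = c(shared = 0, tumor_restricted = 1,
                           stroma_restricted = 0), seed = 6)))
  expect_true(all(cot$truth$effects$class == "tumor_restricted"))
  expect_true(all(cot$truth$effects$gene_id %in% cot$expression$genes$id))
  expect_true(all(cot$truth$effects$variant_id %in% cot$genotypes$variants$id))
})

test_that("cohort simulation is reproducible and invariants hold", {
  cfg <- small_sim_config(seed = 8)
  c1 <- suppressMessages(simulate_cohort(cfg))
  c2 <- suppressMessages(simulate_cohort(cfg))
  expect_identical(c1$expression$counts, c2$expression$counts)
  expect_identical(c1$mutations$vaf, c2$mutations$vaf)
  expect_identical(c1$purity, c2$purity)
  vf <- as.matrix(c1$truth$variance_fractions)
  expect_true(all(vf >= 0 & vf <= 1))
  expect_true(all(rowSums(vf) <= 1 + 1e-8))
  expect_true(all(c1$somatic$cna %in% c(-1, 0, 1)))
  expect_true(all(c1$somatic$mutation %in% c(0, 1)))
  expect_true(all(c1$purity >= 0.1 & c1$purity <= 0.99))
})

test_that("clonal diploid mutations at full purity give VAF near 0.5", {
  cfg <- small_sim_config(subclone_ccf_means = 1.0,
                          purity_params = c(200, 1e-8),
                          purity_bounds = c(0.99, 0.999999), seed = 9)
  co <- suppressMessages(simulate_cohort(cfg))
  # VAF = CCF * purity * m / (purity*CNt + (1-purity)*CNn) ~ 1 * 1 * 1 / 2
  expect_equal(mean(co$mutations$vaf), 0.5, tolerance = 0.03)
})

test_that("generated VAFs round-trip through the CCF formula", {
  co <- suppressMessages(simulate_cohort(small_sim_config(seed = 10)))
  cc <- ccf(co$mutations$vaf, co$purity[co$mutations$sample],
            co$mutations$cn_tumor, co$mutations$cn_normal,
            co$mutations$multiplicity)
  # read-depth binomial noise dominates; the round-trip must be unbiased
  # and tight in RMSE
  err <- cc - co$mutations$ccf_true
  expect_lt(abs(mean(err)), 0.03)
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("latent variance fractions match the truth registry at n >= 500", {
  cfg <- small_sim_config(n_samples = 600, cis_effect_frac = 0.3,
                          effect_r2 = 0.15, seed = 12)
  co <- suppressMessages(simulate_cohort(cfg))
  tr <- co$truth
  # genes with cis effects should carry a genotype fraction near effect_r2
  # effect_r2 targets the observed-expression scale, so the latent genotype
  # fraction sits slightly above it (count noise enters the denominator)
  gf <- tr$variance_fractions[tr$effects$gene_id, "genotype"]
  expect_gt(mean(gf), 0.12)
  expect_lt(mean(gf), 0.21)
  # hidden and residual components were injected at variances 0.3 and 0.7 on
  # a unit non-cis scale; their mean fractions must sit near 0.3/1.1 and
  # 0.7/1.1 once somatic and cis contributions enter the denominator
  hm <- mean(tr$variance_fractions$hidden)
  rm_ <- mean(tr$variance_fractions$residual)
  expect_gt(hm, 0.18); expect_lt(hm, 0.36)
  expect_gt(rm_, 0.5); expect_lt(rm_, 0.75)
})
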