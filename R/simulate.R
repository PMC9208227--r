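# Synthetic multi-omic cohort generator with a ground-truth effect registry.
# Emulates the statistical structure the mapping pipeline assumes: HWE
# dosages with local LD, hidden expression factors, sparse somatic events,
# bounded tumor purity, cis effects that are shared / tumor-restricted /
# stroma-restricted, negative-binomial counts, and subclonal mutation CCFs.

#' Simulation configuration
#'
#' Validated parameter set for the synthetic cohort generator. Defaults
#' describe a mid-sized tumor cohort: 200 samples, 200 genes tiled on one
#' synthetic chromosome, 5,000 variants with a uniform MAF spectrum and
#' first-order local LD, 20% of genes carrying a cis effect explaining 10% of
#' latent expression variance, sparse high-level CNAs and inactivating
#' mutations, Beta(5,2) purity truncated to \[0.1, 0.99\], and three mutation
#' CCF clusters (clonal plus two subclones).
#'
#' @param n_samples,n_genes,n_variants cohort dimensions
#' @param maf_range minor-allele-frequency range, within (0, 0.5\]
#' @param cis_effect_frac fraction of genes given a true cis effect
#' @param effect_r2 target fraction of latent expression variance explained
#'   per true cis effect (must be < 1)
#' @param effect_class_probs named probabilities over `shared`,
#'   `tumor_restricted`, `stroma_restricted` (must sum to 1)
#' @param somatic_amp_rate,somatic_del_rate,somatic_mut_rate per-gene
#'   per-sample event probabilities
#' @param somatic_effect_size standardized latent-expression shift per event
#' @param n_hidden_factors number of hidden expression factors
#' @param purity_params Beta shape parameters of the purity distribution
#' @param purity_bounds truncation bounds for purity
#' @param subclone_ccf_means CCF cluster modes for mutations
#' @param gene_spacing,gene_length gene tiling on the synthetic chromosome (bp)
#' @param cis_window_bp window used for the minimum-variant tiling check
#' @param min_cis_variants required variants per gene window (default 50)
#' @param ld_copy_prob adjacent-variant haplotype copying probability at zero
#'   distance (first-order LD; 0 disables LD)
#' @param ld_decay_bp exponential decay length of the copying probability
#' @param dosage_noise half-width of the uniform dosage noise around hard calls
#' @param nb_dispersion negative-binomial dispersion of the count model
#' @param libsize_sigma log-normal sigma of library-size multipliers
#' @param mutations_per_sample Poisson mean of mutations per sample (min 3)
#' @param seq_depth read depth used to draw observed VAFs
#' @param base_log_mu_range range of per-gene baseline log mean counts
#' @param hidden_var,resid_var latent variance of the hidden-factor and
#'   residual components (their sum sets the non-cis latent variance scale)
#' @param seed RNG seed
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_samples = 200L, n_genes = 200L, n_variants = 5000L,
                       maf_range = c(0.05, 0.5), cis_effect_frac = 0.2,
                       effect_r2 = 0.1,
                       effect_class_probs = c(shared = 0.7,
                                              tumor_restricted = 0.2,
                                              stroma_restricted = 0.1),
                       somatic_amp_rate = 0.02, somatic_del_rate = 0.02,
                       somatic_mut_rate = 0.03, somatic_effect_size = 1,
                       n_hidden_factors = 5L, purity_params = c(5, 2),
                       purity_bounds = c(0.1, 0.99),
                       subclone_ccf_means = c(1.0, 0.6, 0.3),
                       gene_spacing = 1e5, gene_length = 1e4,
                       cis_window_bp = 1e6, min_cis_variants = 50L,
                       ld_copy_prob = 0.9, ld_decay_bp = 1e5,
                       dosage_noise = 0.05, nb_dispersion = 0.1,
                       libsize_sigma = 0.3, mutations_per_sample = 20,
                       seq_depth = 100L,
                       base_log_mu_range = log(c(100, 1000)),
                       hidden_var = 0.3, resid_var = 0.7, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$cis_effect_frac, cfg$somatic_amp_rate, cfg$somatic_del_rate,
             cfg$somatic_mut_rate, cfg$ld_copy_prob)
  stopifnot(n_samples > 0, n_genes > 0, n_variants > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            all(probs >= 0), all(probs <= 1),
            all(c("shared", "tumor_restricted", "stroma_restricted") %in%
                  names(effect_class_probs)),
            all(effect_class_probs >= 0),
            abs(sum(effect_class_probs) - 1) < 1e-8,
            n_hidden_factors >= 0,
            all(purity_params > 0), purity_bounds[1] > 0, purity_bounds[2] < 1,
            all(subclone_ccf_means > 0), all(subclone_ccf_means <= 1),
            nb_dispersion > 0, seq_depth > 0, hidden_var >= 0, resid_var > 0)
  if (effect_r2 >= 1) stop("effect_r2 must be < 1")
  structure(cfg, class = "sim_config")
}

# Deterministic gene tiling on the synthetic chromosome.
sim_gene_annotation <- function(cfg) {
  start <- round(cfg$cis_window_bp) + (seq_len(cfg$n_genes) - 1) * cfg$gene_spacing + 1
  data.frame(id = sprintf("gene%04d", seq_len(cfg$n_genes)),
             chrom = "chr1", start = start,
             end = start + cfg$gene_length - 1, strand = "+",
             stringsAsFactors = FALSE)
}

# Haploid allele sequence with first-order Markov LD along the chromosome.
sim_haplotypes <- function(n, maf, pos, copy_prob, decay_bp) {
  k <- length(maf)
  H <- matrix(0L, n, k)
  H[, 1] <- stats::rbinom(n, 1, maf[1])
  if (k > 1) {
    for (j in 2:k) {
      cp <- copy_prob * exp(-(pos[j] - pos[j - 1]) / decay_bp)
      copy <- stats::rbinom(n, 1, cp) == 1L
      fresh <- stats::rbinom(n, 1, maf[j])
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    }
  }
  H
}

#' Simulate a genotype dosage matrix
#'
#' Variants receive uniform positions on a single synthetic chromosome whose
#' length is set by the gene tiling; per-variant allele frequencies are drawn
#' from `maf_range`; hard-call genotypes are the sum of two haplotypes drawn
#' under Hardy-Weinberg with first-order local LD; dosages add bounded uniform
#' noise, clamped to \[0,2\]. Fails with the per-gene deficit when the variant
#' density leaves any gene with fewer than `min_cis_variants` cis variants.
#'
#' @param cfg a [sim_config()]
#' @return a [genotype_matrix()]
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "genotypes"), {
    genes <- sim_gene_annotation(cfg)
    L <- max(genes$end) + round(cfg$cis_window_bp)
    if (cfg$n_variants > L) stop("n_variants exceeds chromosome length")
    pos <- sort(sample.int(L, cfg$n_variants))
    maf <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
    n_cis <- vapply(seq_len(nrow(genes)), function(i) {
      sum(pos >= genes$start[i] - cfg$cis_window_bp &
            pos <= genes$end[i] + cfg$cis_window_bp)
    }, numeric(1))
    if (any(n_cis < cfg$min_cis_variants)) {
      short <- which(n_cis < cfg$min_cis_variants)
      stop(sprintf(
        "n_variants too small to tile all cis windows: %d gene(s) below %d cis variants (worst: %s with %d, deficit %d)",
        length(short), cfg$min_cis_variants, genes$id[short[1]],
        n_cis[short[1]], cfg$min_cis_variants - n_cis[short[1]]))
    }
    hard <- sim_haplotypes(cfg$n_samples, maf, pos, cfg$ld_copy_prob,
                           cfg$ld_decay_bp) +
      sim_haplotypes(cfg$n_samples, maf, pos, cfg$ld_copy_prob, cfg$ld_decay_bp)
    D <- hard
    if (cfg$dosage_noise > 0) {
      D <- D + matrix(stats::runif(length(hard), -cfg$dosage_noise,
                                   cfg$dosage_noise), nrow(hard))
      D <- pmin(pmax(D, 0), 2)
    }
    variants <- data.frame(id = sprintf("var%05d", seq_len(cfg$n_variants)),
                           chrom = "chr1", pos = pos,
                           ref = "A", alt = "G", maf = maf,
                           stringsAsFactors = FALSE)
    genotype_matrix(D, variants,
                    samples = sprintf("S%04d", seq_len(cfg$n_samples)))
  })
}

# Truncated Beta draw via inverse-CDF (deterministic under the seed).
rbeta_trunc <- function(n, shape, bounds) {
  lo <- stats::pbeta(bounds[1], shape[1], shape[2])
  hi <- stats::pbeta(bounds[2], shape[1], shape[2])
  stats::qbeta(stats::runif(n, lo, hi), shape[1], shape[2])
}

#' Simulate a complete synthetic tumor cohort
#'
#' Generates genotypes, somatic alterations, purity, hidden factors and
#' per-gene latent expression
#' `latent = baseline + hidden factors + somatic shifts + cis term`,
#' where the cis term is `b * dosage` for shared effects, `b * dosage * purity`
#' for tumor-restricted effects and `b * dosage * (1 - purity)` for
#' stroma-restricted effects, with `b` calibrated per gene so the cis term
#' explains approximately `effect_r2` of latent variance. Counts are drawn
#' from a negative-binomial observation model around `exp(latent)` with
#' log-normal library-size multipliers. Mutation CCFs are drawn from the
#' configured subclone clusters and converted to observed VAFs through the
#' sample's purity and local copy number at finite read depth. All injected
#' effects are recorded in the ground-truth registry.
#'
#' @param cfg a [sim_config()]
#' @return object of class `sim_cohort`: list with `genotypes`
#'   ([genotype_matrix()]), `expression` ([expression_set()]), `somatic`
#'   (list of genes x samples matrices `cna`, `mutation`), `purity`, `sex`,
#'   `mutations` (per-mutation data.frame), `truth` (list `effects`,
#'   `variance_fractions`), and `config`
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  geno <- simulate_genotypes(cfg)
  genes <- sim_gene_annotation(cfg)
  n <- cfg$n_samples
  G <- cfg$n_genes
  with_seed(stage_seed(cfg$seed, "cohort"), {
    purity <- rbeta_trunc(n, cfg$purity_params, cfg$purity_bounds)
    names(purity) <- geno$samples
    if (stats::sd(purity) == 0) tq_log("simulate_cohort: degenerate purity (all equal)")
    sex <- stats::rbinom(n, 1, 0.5)
    names(sex) <- geno$samples

    k <- cfg$n_hidden_factors
    Fh <- if (k > 0) matrix(stats::rnorm(n * k), n, k) else NULL
    Lh <- if (k > 0) matrix(stats::rnorm(G * k, 0, sqrt(cfg$hidden_var / k)), G, k) else NULL

    u <- matrix(stats::runif(G * n), G, n)
    amp <- (u < cfg$somatic_amp_rate) * 1L
    del <- (u >= cfg$somatic_amp_rate &
              u < cfg$somatic_amp_rate + cfg$somatic_del_rate) * 1L
    cna <- amp - del
    mut <- matrix(stats::rbinom(G * n, 1, cfg$somatic_mut_rate), G, n)
    dimnames(cna) <- dimnames(mut) <- list(genes$id, geno$samples)

    n_cis <- round(cfg$cis_effect_frac * G)
    cis_genes <- if (n_cis > 0) sort(sample.int(G, n_cis)) else integer(0)
    classes <- if (n_cis > 0) {
      sample(names(cfg$effect_class_probs), n_cis, replace = TRUE,
             prob = cfg$effect_class_probs)
    } else character(0)

    D <- geno$dosages
    base_mu <- stats::runif(G, cfg$base_log_mu_range[1], cfg$base_log_mu_range[2])
    counts <- matrix(0L, G, n, dimnames = list(genes$id, geno$samples))
    libsize <- exp(stats::rnorm(n, 0, cfg$libsize_sigma))
    effects <- data.frame(gene_id = character(0), variant_id = character(0),
                          class = character(0), slope = numeric(0),
                          stringsAsFactors = FALSE)
    vf <- matrix(0, G, 4, dimnames = list(genes$id,
                                          c("genotype", "somatic", "hidden", "residual")))
    cis_lookup <- stats::setNames(rep(NA_integer_, G), genes$id)
    cis_class <- stats::setNames(rep(NA_character_, G), genes$id)
    if (n_cis > 0) {
      cis_lookup[cis_genes] <- 0L
      cis_class[cis_genes] <- classes
    }
    for (g in seq_len(G)) {
      hid <- if (k > 0) as.vector(Fh %*% Lh[g, ]) else rep(0, n)
      shift <- cfg$somatic_effect_size * (cna[g, ] - mut[g, ])
      eps <- stats::rnorm(n, 0, sqrt(cfg$resid_var))
      other <- hid + shift + eps
      cis_term <- rep(0, n)
      if (!is.na(cis_lookup[g])) {
        idx <- cis_window(genes[g, ], geno$variants, cfg$cis_window_bp)
        emp_maf <- pmin(colMeans(D[, idx, drop = FALSE]) / 2,
                        1 - colMeans(D[, idx, drop = FALSE]) / 2)
        cand <- idx[emp_maf >= 0.1]
        if (length(cand) == 0) cand <- idx
        v <- cand[sample.int(length(cand), 1)]
        scale_vec <- switch(cis_class[g],
                            shared = rep(1, n),
                            tumor_restricted = purity,
                            stroma_restricted = 1 - purity)
        x <- D[, v] * scale_vec
        vx <- stats::var(x)
        # calibrate the slope so the cis term explains ~effect_r2 of the
        # observed log-scale expression variance: latent background plus the
        # delta-method count-noise variance (dispersion + 1/mu)
        mu0 <- libsize * exp(base_mu[g] + other)
        v_noise <- cfg$nb_dispersion + mean(1 / pmax(mu0, 1))
        b <- sample(c(-1, 1), 1) *
          sqrt(cfg$effect_r2 / (1 - cfg$effect_r2) *
                 (stats::var(other) + v_noise) / vx)
        cis_term <- b * x
        cis_lookup[g] <- v
        effects <- rbind(effects, data.frame(
          gene_id = genes$id[g], variant_id = geno$variants$id[v],
          class = cis_class[g], slope = b, stringsAsFactors = FALSE))
      }
      latent <- base_mu[g] + other + cis_term
      vtot <- stats::var(latent)
      fr <- c(stats::var(cis_term), stats::var(shift), stats::var(hid),
              stats::var(eps)) / vtot
      # components are generated independently; tiny sampling covariances can
      # push the ratio sum past 1, so cap it there
      vf[g, ] <- fr / max(1, sum(fr))
      mu <- libsize * exp(latent)
      counts[g, ] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    storage.mode(counts) <- "integer"
    gene_len <- genes$end - genes$start + 1
    rate <- counts / gene_len
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6

    mut_rows <- vector("list", n)
    for (j in seq_len(n)) {
      nm <- max(3L, stats::rpois(1, cfg$mutations_per_sample))
      cl <- sample(cfg$subclone_ccf_means, nm, replace = TRUE)
      cc <- pmin(1, pmax(0.02, stats::rnorm(nm, cl, 0.05)))
      vaf_true <- cc * purity[j] * 1 / (purity[j] * 2 + (1 - purity[j]) * 2)
      alt <- stats::rbinom(nm, cfg$seq_depth, vaf_true)
      mut_rows[[j]] <- data.frame(
        sample = geno$samples[j],
        mutation_id = sprintf("%s_m%03d", geno$samples[j], seq_len(nm)),
        vaf = alt / cfg$seq_depth, cn_tumor = 2, cn_normal = 2,
        multiplicity = 1, ccf_true = cc, stringsAsFactors = FALSE)
    }
    mutations <- do.call(rbind, mut_rows)
    rownames(mutations) <- NULL

    expr <- expression_set(counts, tpm, genes)
    structure(list(genotypes = geno, expression = expr,
                   somatic = list(cna = cna, mutation = mut),
                   purity = purity, sex = sex, mutations = mutations,
                   truth = list(effects = effects,
                                variance_fractions = as.data.frame(vf)),
                   config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d genes, %d variants\n",
              x$config$n_samples, x$config$n_genes, x$config$n_variants))
  cat(sprintf("  true cis effects: %d (%s)\n", nrow(x$truth$effects),
              paste(names(table(x$truth$effects$class)),
                    table(x$truth$effects$class), sep = "=", collapse = ", ")))
  cat(sprintf("  purity: median %.2f [%.2f, %.2f]\n",
              stats::median(x$purity), min(x$purity), max(x$purity)))
  invisible(x)
}
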