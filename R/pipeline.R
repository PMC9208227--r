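# End-to-end orchestration: simulate -> genotype QC -> expression QC ->
# cis mapping -> interaction mapping -> cohort summaries, with derived
# per-stage seeds and a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Thresholds default to the mapping model's standard values: MAF 0.01,
#' sample missingness 0.025, 5 genotype PCs, 15 hidden expression factors,
#' gene filter 0.1 TPM / 6 reads / 20% of samples, outlier cut 3 SD on the
#' first 6 expression PCs, cis window 1 Mb, MAC 5, adaptive permutations
#' 1000-10,000, eGene FDR 0.05, ieGene FDR 0.10, tertile alpha 0.05,
#' downsampling size 200.
#'
#' @param maf_min,snp_missing_max,sample_missing_max,r2_min genotype QC
#' @param n_genotype_pcs,n_hidden_factors covariate dimensions
#' @param tpm_min,count_min,frac_min gene expression filter
#' @param outlier_pcs,outlier_sd expression outlier removal
#' @param window,mac_min,n_perm cis scan parameters
#' @param egene_fdr,iegene_fdr,tertile_alpha significance thresholds
#' @param downsample_n downsampling target size
#' @param seed master seed; stage seeds are derived via [stage_seed()]
#' @return named list of class `run_config`
#' @export
run_config <- function(maf_min = 0.01, snp_missing_max = 0.95,
                       sample_missing_max = 0.025, r2_min = 0.3,
                       n_genotype_pcs = 5L, n_hidden_factors = 15L,
                       tpm_min = 0.1, count_min = 6, frac_min = 0.20,
                       outlier_pcs = 6L, outlier_sd = 3,
                       window = 1e6, mac_min = 5L,
                       n_perm = c(1000L, 10000L),
                       egene_fdr = 0.05, iegene_fdr = 0.10,
                       tertile_alpha = 0.05, downsample_n = 200L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(maf_min >= 0, maf_min <= 0.5, n_genotype_pcs > 0,
            n_hidden_factors > 0, length(n_perm) == 2,
            n_perm[1] <= n_perm[2], egene_fdr > 0, egene_fdr <= 1,
            iegene_fdr > 0, iegene_fdr <= 1)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: genotype QC (frequency/missingness filters, ancestry
#' PCs), expression QC (size-factor normalization, gene filtering, PCA
#' outlier removal, inverse-normal transform, hidden factors), somatic-aware
#' cis-eQTL mapping with permutation/beta gene-level inference, genotype x
#' purity interaction mapping with tertile classification, and cohort
#' summaries (per-gene variance fractions for eGenes, per-sample MATH scores,
#' eGene fraction, eQTL/somQTL ratio). Each stage writes a TSV to `out_dir`
#' and the run ends with a JSON manifest recording parameters, derived stage
#' seeds, stage record counts and output checksums. Reruns with the same
#' inputs and seed are byte-identical.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], a cohort directory
#'   path (as written by [write_cohort()]), or a [sim_config()] (the cohort
#'   is then generated and written to `out_dir/input`)
#' @param out_dir output directory
#' @param config a [run_config()]
#' @return (invisibly) list with the fitted objects and summary tables:
#'   `cis`, `interaction`, `somqtl`, `variance`, `math`, `summary`, `manifest`
#' @export
run_pipeline <- function(cohort, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (inherits(cohort, "sim_config")) {
    cohort <- simulate_cohort(cohort)
    write_cohort(cohort, file.path(out_dir, "input"))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  stages <- character(0)
  note <- function(s) {
    stages <<- c(stages, s)
    tq_log("stage complete: %s", s)
  }

  ## -- genotype QC ---------------------------------------------------------
  geno <- filter_genotypes(cohort$genotypes, maf_min = config$maf_min,
                           snp_missing_max = config$snp_missing_max,
                           sample_missing_max = config$sample_missing_max,
                           r2_min = config$r2_min)
  gpcs <- genotype_pcs(geno, k = config$n_genotype_pcs)
  note("qc_genotypes")

  ## -- expression QC -------------------------------------------------------
  e <- cohort$expression
  keep_s <- intersect(colnames(e$counts), geno$samples)
  e <- expression_set(e$counts[, keep_s, drop = FALSE],
                      e$tpm[, keep_s, drop = FALSE], e$genes)
  e <- normalize_expression(e)
  out_s <- expression_outliers(e, n_pcs = config$outlier_pcs,
                               sd_cut = config$outlier_sd)
  if (length(out_s)) {
    tq_log("expression outliers removed: %s", paste(out_s, collapse = ", "))
    keep_s <- setdiff(keep_s, out_s)
    e <- expression_set(cohort$expression$counts[, keep_s, drop = FALSE],
                        cohort$expression$tpm[, keep_s, drop = FALSE],
                        cohort$expression$genes)
    e <- normalize_expression(e)
  }
  e <- filter_genes(e, tpm_min = config$tpm_min, count_min = config$count_min,
                    frac_min = config$frac_min)
  e <- transform_expression(e)
  nhf <- min(config$n_hidden_factors, length(keep_s) - 2L, nrow(e$counts) - 1L)
  hf <- hidden_factors(e, k = nhf)
  samp_idx <- match(keep_s, geno$samples)
  geno_s <- genotype_matrix(geno$dosages[samp_idx, , drop = FALSE],
                            geno$variants, geno$samples[samp_idx])
  covars <- build_covariates(gpcs[samp_idx, , drop = FALSE], hf,
                             sex = cohort$sex[keep_s])
  som <- list(cna = cohort$somatic$cna[rownames(e$counts), keep_s, drop = FALSE],
              mutation = cohort$somatic$mutation[rownames(e$counts), keep_s,
                                                 drop = FALSE])
  write_tsv(covars, file.path(out_dir, "covariates.tsv"), row_label = "sample")
  note("qc_expression")

  ## -- cis mapping ---------------------------------------------------------
  fit <- cis_eqtl(e, geno_s, covariates = covars, somatic = som,
                  window = config$window, mac_min = config$mac_min,
                  n_perm = config$n_perm, fdr = config$egene_fdr,
                  seed = stage_seed(seed, "map_cis"))
  write_tsv(fit$results, file.path(out_dir, "cis_eqtl.tsv"))
  som_res <- somqtl_test(e$transformed, som$cna, som$mutation, covars,
                         fdr = config$egene_fdr)
  write_tsv(som_res, file.path(out_dir, "somqtl.tsv"))
  note("map_cis")

  ## -- interaction mapping -------------------------------------------------
  ifit <- interaction_eqtl(e, geno_s, purity = cohort$purity[keep_s],
                           covariates = covars, somatic = som,
                           window = config$window, mac_min = config$mac_min,
                           n_perm = config$n_perm, fdr = config$iegene_fdr,
                           alpha = config$tertile_alpha,
                           seed = stage_seed(seed, "map_interaction"))
  write_tsv(ifit$results, file.path(out_dir, "interaction_eqtl.tsv"))
  note("map_interaction")

  ## -- summaries -----------------------------------------------------------
  vrows <- lapply(fit$egenes, function(gid) {
    lv <- match(fit$results$lead_variant[fit$results$gene_id == gid],
                geno_s$variants$id)
    groups <- list(genotype = geno_s$dosages[, lv],
                   cna = som$cna[gid, ], mutation = som$mutation[gid, ],
                   hidden_factors = hf,
                   genotype_pcs = gpcs[samp_idx, , drop = FALSE],
                   sex = cohort$sex[keep_s])
    fr <- variance_fractions(e$transformed[gid, ], groups)
    cbind(data.frame(gene_id = gid), as.data.frame(t(fr)))
  })
  variance <- if (length(vrows)) do.call(rbind, vrows) else
    data.frame(gene_id = character(0))
  write_tsv(variance, file.path(out_dir, "variance_fractions.tsv"))
  math <- sample_math_scores(cohort$mutations[cohort$mutations$sample %in% keep_s, ],
                             cohort$purity)
  write_tsv(math, file.path(out_dir, "math_scores.tsv"))
  n_som_sig <- sum(som_res$significant)
  summary_tab <- data.frame(
    n_samples = length(keep_s),
    n_genes_expressed = nrow(e$counts),
    n_egenes = length(fit$egenes),
    egene_fraction = egene_fraction(fit$egenes, rownames(e$counts)),
    n_somqtl = n_som_sig,
    eqtl_somqtl_ratio = if (n_som_sig > 0) qtl_ratio(length(fit$egenes), n_som_sig)
                        else NA_real_,
    n_iegenes = length(ifit$iegenes),
    median_math = stats::median(math$math, na.rm = TRUE))
  write_tsv(summary_tab, file.path(out_dir, "summary.tsv"))
  note("summarize")

  ## -- manifest ------------------------------------------------------------
  outputs <- c("covariates.tsv", "cis_eqtl.tsv", "somqtl.tsv",
               "interaction_eqtl.tsv", "variance_fractions.tsv",
               "math_scores.tsv", "summary.tsv")
  manifest <- list(
    package = "tumorQTL",
    version = as.character(utils::packageVersion("tumorQTL")),
    master_seed = seed,
    stage_seeds = list(map_cis = stage_seed(seed, "map_cis"),
                       map_interaction = stage_seed(seed, "map_interaction")),
    config = unclass(config),
    stages = stages,
    n_samples = length(keep_s),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cis = fit, interaction = ifit, somqtl = som_res,
                 variance = variance, math = math, summary = summary_tab,
                 manifest = manifest))
}
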