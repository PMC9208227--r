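# Two-stage cis-eQTL mapping: covariate/somatic residualization, per-variant
# nominal scan, adaptive permutation pass with beta approximation, Storey
# q-values, eGene calling, somQTL tests, and allelic fold change.

#' Residualize expression on covariates and somatic alterations
#'
#' Stage one of the two-stage regression: ordinary least squares of a gene's
#' transformed expression on an intercept, the covariate table (genotype PCs,
#' hidden factors, sex) and the gene's somatic codes (CNA in {-1,0,+1},
#' inactivating mutation in {0,1}); residuals are then re-normalized with the
#' rank-based inverse normal transform. Constant somatic columns are dropped
#' with a log note.
#'
#' @param y transformed expression vector for one gene
#' @param covars samples x covariates matrix (or NULL)
#' @param cna per-sample CNA code vector for the gene (or NULL)
#' @param mutation per-sample inactivating-mutation indicator (or NULL)
#' @return inverse-normal-transformed residual vector
#' @export
residualize <- function(y, covars = NULL, cna = NULL, mutation = NULL) {
  X <- cbind(intercept = rep(1, length(y)),
             if (!is.null(covars)) as.matrix(covars),
             if (!is.null(cna)) cbind(cna = as.numeric(cna)),
             if (!is.null(mutation)) cbind(mutation = as.numeric(mutation)))
  som_cols <- intersect(colnames(X), c("cna", "mutation"))
  if (length(som_cols)) {
    const <- som_cols[apply(X[, som_cols, drop = FALSE], 2, stats::sd) == 0]
    if (length(const)) {
      tq_log("residualize: dropping constant somatic column(s): %s",
             paste(const, collapse = ", "))
      X <- X[, setdiff(colnames(X), const), drop = FALSE]
    }
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  r <- qr.resid(qr_x, y)
  if (stats::sd(r) < 1e-10 * (stats::sd(y) + 1e-300)) {
    stop("degenerate residuals: expression is fully explained by the covariates")
  }
  inverse_normal(r)
}

#' Select variants in a gene's cis window
#'
#' Variants on the gene's chromosome with position in
#' `[start - window, end + window]`, inclusive at both boundaries.
#'
#' @param gene one-row annotation (list/data.frame with `chrom`,`start`,`end`)
#' @param variants variant data.frame (`chrom`, `pos`)
#' @param window flanking distance in bp (default 1e6)
#' @return integer indices into `variants`
#' @export
cis_window <- function(gene, variants, window = 1e6) {
  stopifnot(window >= 0)
  which(variants$chrom == gene$chrom &
          variants$pos >= gene$start - window &
          variants$pos <= gene$end + window)
}

#' Filter variants by minor allele count
#'
#' Minor allele count is computed on dosages rounded to the nearest hard call.
#'
#' @param dosages samples x variants dosage matrix
#' @param mac_min minimum count of the minor allele (default 5)
#' @return integer indices of retained variants
#' @export
mac_filter <- function(dosages, mac_min = 5L) {
  stopifnot(mac_min >= 0)
  hard <- round(as.matrix(dosages))
  alt <- colSums(hard)
  mac <- pmin(alt, 2 * nrow(hard) - alt)
  which(mac >= mac_min)
}

#' Per-variant nominal association scan
#'
#' Simple linear regression of a residualized, inverse-normal-transformed
#' expression vector on each cis variant's dosage; two-sided t-test on n-2
#' degrees of freedom.
#'
#' @param y residualized INT expression vector
#' @param dosages samples x cis-variants dosage matrix
#' @return data.frame(slope, t, p), one row per variant
#' @export
nominal_scan <- function(y, dosages) {
  D <- as.matrix(dosages)
  n <- length(y)
  stopifnot(nrow(D) == n, ncol(D) >= 1, all(is.finite(y)))
  sds <- apply(D, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance variant in nominal scan (apply mac_filter first)")
  yc <- y - mean(y)
  Dc <- sweep(D, 2, colMeans(D))
  sxx <- colSums(Dc^2)
  sxy <- as.vector(crossprod(Dc, yc))
  syy <- sum(yc^2)
  slope <- sxy / sxx
  r2 <- pmin(sxy^2 / (sxx * syy), 1 - 1e-14)
  tt <- sign(slope) * sqrt(r2 * (n - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  data.frame(slope = slope, t = tt, p = p, row.names = colnames(D))
}

#' Deterministic lead-variant selection
#'
#' Smallest p, ties broken by smaller genomic position, then lexicographic id.
#' @param p nominal p per variant
#' @param pos genomic positions
#' @param id variant ids
#' @return index of the lead variant
#' @export
lead_variant <- function(p, pos, id = as.character(seq_along(p))) {
  order(p, pos, id)[1]
}

#' Adaptive permutation pass for one gene
#'
#' Permutes the phenotype, records the minimum nominal p across cis variants
#' per permutation, stops early once the observed minimum is clearly
#' non-extreme (>= 30 permuted minima at or below it after `n_perm_min`
#' permutations, else continues to `n_perm_max`), fits a Beta distribution to
#' the permuted minima by maximum likelihood, and reports the Beta CDF at the
#' observed minimum as the gene-level adjusted p. The empirical p uses the
#' (1 + exceedances) / (1 + N) estimator.
#'
#' @param y residualized INT expression vector
#' @param dosages samples x cis-variants dosage matrix
#' @param n_perm_min,n_perm_max adaptive permutation bounds
#'   (defaults 1000, 10000)
#' @param seed integer seed for the permutation stream (NULL: current RNG)
#' @return list(empirical_p, beta_shape1, beta_shape2, adjusted_p, n_perm,
#'   nominal_p_lead, lead_index, slope_lead)
#' @export
permutation_pass <- function(y, dosages, n_perm_min = 1000L,
                             n_perm_max = 10000L, seed = NULL) {
  D <- as.matrix(dosages)
  n <- length(y)
  stopifnot(nrow(D) == n, n_perm_min <= n_perm_max)
  Gs <- col_unit(D)
  ys <- y - mean(y)
  ys <- ys / sqrt(sum(ys^2))
  r_obs <- as.vector(crossprod(Gs, ys))
  r2_obs <- r_obs^2
  obs_min_p <- min(r2_to_p(r2_obs, n))
  perm_fun <- function(b) {
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    Yp <- matrix(ys[idx], n, b)
    R2 <- crossprod(Gs, Yp)^2
    mx <- R2[cbind(max.col(t(R2), ties.method = "first"), seq_len(b))]
    r2_to_p(mx, n)
  }
  run <- function() perm_calibrate(obs_min_p, perm_fun, n_perm_min, n_perm_max)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  lead <- which(r2_obs == max(r2_obs))[1]
  res$nominal_p_lead <- obs_min_p
  res$lead_index <- lead
  res
}

#' Storey q-values
#'
#' pi0 is estimated on the lambda grid 0.05..0.95 (step 0.05) with a cubic
#' smoother (`smooth.spline`, df = 3) evaluated at the largest lambda, clipped
#' to (0, 1\]. For small families (m < 100) the smoother is unstable and a
#' fixed lambda = 0.5 estimator is used instead, with a log note. q-values are
#' the pi0-scaled step-up quantities, monotone in p.
#'
#' @param p p-value vector in (0,1\]
#' @param lambda grid for pi0 estimation
#' @param pi0 optional fixed pi0 (overrides estimation; pi0 = 1 gives
#'   Benjamini-Hochberg)
#' @return q-value vector aligned with `p`
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      tq_log("storey_qvalues: m = %d < 100, using fixed lambda = 0.5 pi0 estimator", m)
      pi0 <- mean(p > 0.5) / 0.5
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / r[o])
  pmin(q, 1)
}

#' Call eGenes at a gene-level FDR
#'
#' @param results data.frame with `gene_id` and `q_value`
#' @param fdr q-value threshold (default 0.05)
#' @return character vector of eGene ids
#' @export
call_egenes <- function(results, fdr = 0.05) {
  if (NROW(results) == 0) return(character(0))
  results$gene_id[!is.na(results$q_value) & results$q_value <= fdr]
}

#' Somatic alteration-expression association tests (somQTLs)
#'
#' Per gene, regresses INT expression on the covariates plus the gene's
#' somatic CNA code and inactivating-mutation indicator, and reports the
#' somatic coefficients' t-test p-values. Storey q-values are computed across
#' all tested gene-predictor pairs. Genes whose somatic predictors are all
#' constant are skipped.
#'
#' @param expr_t transformed expression matrix, genes x samples
#' @param cna genes x samples CNA code matrix in {-1,0,+1}
#' @param mutation genes x samples mutation indicator matrix in {0,1}
#' @param covars samples x covariates matrix (or NULL)
#' @param fdr significance threshold on q (default 0.05)
#' @return data.frame(gene_id, predictor, coefficient, p, q, significant)
#' @export
somqtl_test <- function(expr_t, cna, mutation, covars = NULL, fdr = 0.05) {
  genes <- rownames(expr_t)
  base <- cbind(intercept = rep(1, ncol(expr_t)),
                if (!is.null(covars)) as.matrix(covars))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    preds <- list()
    if (stats::sd(cna[i, ]) > 0) preds$cna <- cna[i, ]
    if (stats::sd(mutation[i, ]) > 0) preds$mutation <- mutation[i, ]
    if (length(preds) == 0) next
    X <- cbind(base, do.call(cbind, preds))
    colnames(X) <- c(colnames(base), names(preds))
    cols <- ncol(base) + seq_along(preds)
    tst <- lm_coef_tests(X, expr_t[i, ], cols)
    rows[[i]] <- data.frame(gene_id = genes[i], predictor = names(preds),
                            coefficient = tst$estimate, p = tst$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(gene_id = character(0), predictor = character(0),
                      coefficient = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  rownames(out) <- NULL
  out$q <- storey_qvalues(out$p)
  out$significant <- out$q <= fdr
  out
}

#' Allelic fold change of a cis variant
#'
#' Fits expression on the linear (size-factor-normalized, untransformed) scale
#' as `mu * (1 + d/2 * (2^aFC - 1))`, i.e. aFC = log2((b0 + 2 b1)/b0) from the
#' least-squares fit of expression on dosage. Covariate effects are removed on
#' the log scale beforehand. The estimate is clamped to +/- log2(100); it is
#' undefined (NA, with a warning) when the fitted reference-allele expression
#' b0 or the fitted alternate-homozygote expression b0 + 2 b1 is non-positive.
#'
#' @param expr_linear normalized untransformed expression vector (>= 0)
#' @param dosage variant dosage vector
#' @param covars samples x covariates matrix (or NULL)
#' @return log2 allelic fold change (NA if undefined)
#' @export
allelic_fold_change <- function(expr_linear, dosage, covars = NULL) {
  stopifnot(all(expr_linear >= 0))
  if (stats::sd(dosage) == 0) stop("variant is monomorphic")
  e <- expr_linear
  if (!is.null(covars)) {
    l <- log2(e + 1)
    X <- cbind(1, as.matrix(covars))
    r <- qr.resid(qr(X), l)
    e <- pmax(2^(r + mean(l)) - 1, 0)
  }
  b <- stats::coef(stats::lm.fit(cbind(1, dosage), e))
  b0 <- b[1]
  b2 <- b[1] + 2 * b[2]
  if (b0 <= 0 || b2 <= 0) {
    warning("allelic fold change undefined: non-positive fitted expression")
    return(NA_real_)
  }
  afc <- log2(b2 / b0)
  max(min(afc, log2(100)), -log2(100))
}

#' Map cis-eQTLs across genes
#'
#' The package's main fitting routine. For each gene: residualize transformed
#' expression on covariates and the gene's somatic codes (then re-apply the
#' inverse normal transform), restrict to cis-window variants passing the
#' minor-allele-count filter, scan all variants, and calibrate the minimum
#' nominal p by the adaptive permutation pass with beta approximation.
#' Gene-level adjusted p-values are converted to Storey q-values and eGenes
#' called at `fdr`. When the expression set carries normalized counts, the
#' lead variant's allelic fold change is also estimated.
#'
#' @param expression an [expression_set()] with `transformed` filled
#' @param genotypes a filtered [genotype_matrix()]
#' @param covariates samples x covariates matrix (or NULL)
#' @param somatic list with genes x samples matrices `cna` and `mutation`
#'   (or NULL)
#' @param window cis window in bp (default 1e6)
#' @param mac_min minor-allele-count filter (default 5)
#' @param n_perm length-2 adaptive permutation bounds (default c(1000, 10000))
#' @param fdr eGene q-value threshold (default 0.05)
#' @param seed master seed; per-gene permutation seeds are derived from it
#' @return object of class `cis_eqtl` with elements `results` (per-gene
#'   data.frame), `egenes`, `n_samples`, `params`
#' @export
cis_eqtl <- function(expression, genotypes, covariates = NULL, somatic = NULL,
                     window = 1e6, mac_min = 5L, n_perm = c(1000L, 10000L),
                     fdr = 0.05, seed = 1L) {
  stopifnot(inherits(expression, "expression_set"),
            inherits(genotypes, "genotype_matrix"),
            length(n_perm) == 2, n_perm[1] <= n_perm[2])
  if (is.null(expression$transformed)) stop("transform_expression first")
  expr_t <- expression$transformed
  genes <- expression$genes
  D <- genotypes$dosages
  vinfo <- genotypes$variants
  n <- ncol(expr_t)
  stopifnot(nrow(D) == n)
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    y0 <- expr_t[i, ]
    y <- residualize(y0, covariates,
                     cna = if (!is.null(somatic)) somatic$cna[gid, ],
                     mutation = if (!is.null(somatic)) somatic$mutation[gid, ])
    idx <- cis_window(genes[i, ], vinfo, window)
    if (length(idx)) idx <- idx[mac_filter(D[, idx, drop = FALSE], mac_min)]
    if (length(idx) == 0) {
      res[[i]] <- data.frame(gene_id = gid, n_var = 0L, beta_shape1 = NA_real_,
                             beta_shape2 = NA_real_, true_df = NA_real_,
                             lead_variant = NA_character_, distance = NA_real_,
                             nominal_p = NA_real_, slope = NA_real_,
                             empirical_p = NA_real_, adjusted_p = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    Dg <- D[, idx, drop = FALSE]
    scan <- nominal_scan(y, Dg)
    li <- lead_variant(scan$p, vinfo$pos[idx], vinfo$id[idx])
    pp <- permutation_pass(y, Dg, n_perm[1], n_perm[2],
                           seed = stage_seed(seed, paste0("cis:", gid)))
    res[[i]] <- data.frame(
      gene_id = gid, n_var = length(idx),
      beta_shape1 = pp$beta_shape1, beta_shape2 = pp$beta_shape2,
      true_df = NA_real_,
      lead_variant = vinfo$id[idx][li],
      distance = vinfo$pos[idx][li] - genes$start[i],
      nominal_p = scan$p[li], slope = scan$slope[li],
      empirical_p = pp$empirical_p, adjusted_p = pp$adjusted_p,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  ok <- !is.na(results$adjusted_p)
  results$q_value <- NA_real_
  if (any(ok)) results$q_value[ok] <- storey_qvalues(results$adjusted_p[ok])
  results$afc_log2 <- NA_real_
  if (!is.null(expression$normalized)) {
    for (i in which(ok)) {
      lv <- match(results$lead_variant[i], vinfo$id)
      results$afc_log2[i] <- suppressWarnings(
        allelic_fold_change(expression$normalized[results$gene_id[i], ],
                            D[, lv], covariates))
    }
  }
  structure(list(results = results,
                 egenes = call_egenes(results, fdr),
                 n_samples = n,
                 params = list(window = window, mac_min = mac_min,
                               n_perm = n_perm, fdr = fdr, seed = seed)),
            class = "cis_eqtl")
}
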