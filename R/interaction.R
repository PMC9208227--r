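# Genotype x tumor-purity interaction eQTLs: per-variant scan, gene-level
# permutation calibration, ieGene calling, and purity-tertile classification.

# Build the interaction base design [intercept, covars, somatic, centered
# purity] and its orthonormal basis; shared by scan and permutation pass.
interaction_base <- function(n, purity, covars, cna, mutation) {
  stopifnot(length(purity) == n, all(purity >= 0), all(purity <= 1))
  if (stats::sd(purity) == 0) stop("constant purity: interaction model is unidentifiable")
  pc <- purity - mean(purity)
  X0 <- cbind(intercept = rep(1, n),
              if (!is.null(covars)) as.matrix(covars),
              if (!is.null(cna)) cbind(cna = as.numeric(cna)),
              if (!is.null(mutation)) cbind(mutation = as.numeric(mutation)),
              purity = pc)
  keep <- c(TRUE, apply(X0[, -1, drop = FALSE], 2, stats::sd) > 0)
  X0 <- X0[, keep, drop = FALSE]
  qr_x <- qr(X0)
  if (qr_x$rank < ncol(X0)) {
    bad <- colnames(X0)[qr_x$pivot[(qr_x$rank + 1):ncol(X0)]]
    stop("rank-deficient interaction design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(Q = qr.Q(qr_x), ncol = ncol(X0), pc = pc)
}

# Interaction t-tests for all variants given precomputed residual pieces.
# Solves, per variant, the 2-regressor system (g_r, (g*pc)_r) against y_r.
interaction_fit <- function(y_r, G_r, GP_r, df) {
  a11 <- colSums(G_r^2)
  a22 <- colSums(GP_r^2)
  a12 <- colSums(G_r * GP_r)
  b1 <- as.vector(crossprod(G_r, y_r))
  b2 <- as.vector(crossprod(GP_r, y_r))
  det <- a11 * a22 - a12^2
  bad <- det <= .Machine$double.eps * a11 * a22
  det[bad] <- NA_real_
  beta1 <- (a22 * b1 - a12 * b2) / det
  beta2 <- (a11 * b2 - a12 * b1) / det
  rss <- sum(y_r^2) - (beta1 * b1 + beta2 * b2)
  sigma2 <- pmax(rss, 0) / df
  se2 <- sigma2 * a11 / det
  tt <- beta2 / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  list(coef = beta2, t = tt, p = p)
}

#' Per-variant genotype x purity interaction scan
#'
#' Fits, per cis variant, the model
#' `expression ~ covariates + somatic + genotype + purity + genotype:purity`
#' by OLS with purity centered before forming the product term, and reports
#' the product-term coefficient and its two-sided t-test p-value.
#'
#' @param y transformed expression vector for one gene
#' @param dosages samples x cis-variants dosage matrix
#' @param purity per-sample tumor purity in \[0,1\], non-constant
#' @param covars samples x covariates matrix (or NULL)
#' @param cna,mutation per-sample somatic codes for the gene (or NULL)
#' @return data.frame(interaction_coef, t, p), one row per variant
#' @export
interaction_scan <- function(y, dosages, purity, covars = NULL,
                             cna = NULL, mutation = NULL) {
  D <- as.matrix(dosages)
  n <- length(y)
  stopifnot(nrow(D) == n)
  base <- interaction_base(n, purity, covars, cna, mutation)
  df <- n - base$ncol - 2L
  proj <- function(M) M - base$Q %*% crossprod(base$Q, M)
  y_r <- as.vector(proj(matrix(y)))
  G_r <- proj(D)
  GP_r <- proj(D * base$pc)
  fit <- interaction_fit(y_r, G_r, GP_r, df)
  data.frame(interaction_coef = fit$coef, t = fit$t, p = fit$p,
             row.names = colnames(D))
}

#' Gene-level interaction permutation pass
#'
#' Takes the minimum interaction p across cis variants and calibrates it by
#' jointly permuting the rows of the genotype matrix across samples (the
#' purity-expression-covariate relationship is preserved), with the same
#' adaptive stopping and beta approximation as the cis permutation pass.
#'
#' @inheritParams interaction_scan
#' @param n_perm_min,n_perm_max adaptive permutation bounds
#' @param seed permutation seed (NULL: current RNG stream)
#' @return list(empirical_p, beta_shape1, beta_shape2, adjusted_p, n_perm,
#'   nominal_p_lead, lead_index)
#' @export
interaction_gene_pass <- function(y, dosages, purity, covars = NULL,
                                  cna = NULL, mutation = NULL,
                                  n_perm_min = 1000L, n_perm_max = 10000L,
                                  seed = NULL) {
  D <- as.matrix(dosages)
  n <- length(y)
  k <- ncol(D)
  base <- interaction_base(n, purity, covars, cna, mutation)
  df <- n - base$ncol - 2L
  proj <- function(M) M - base$Q %*% crossprod(base$Q, M)
  y_r <- as.vector(proj(matrix(y)))
  obs_scan <- interaction_scan(y, D, purity, covars, cna, mutation)
  obs_min <- min(obs_scan$p, na.rm = TRUE)
  # permutations are batched: b permuted copies of the genotype block are
  # stacked column-wise so both projections run as single BLAS calls
  # Permuting the rows of the genotype block is equivalent to applying the
  # inverse permutation to the small fixed pieces (Q, purity, residualized
  # expression), so every per-variant statistic reduces to matrix products
  # against the fixed dosage matrix: batches run as a handful of GEMMs
  # without materializing permuted genotype copies.
  cdim <- ncol(base$Q)
  D2 <- D * D
  cd2 <- colSums(D2)
  Qpc <- base$Q * base$pc
  ypc <- y_r * base$pc
  yy <- sum(y_r^2)
  stack_inv <- function(M, inv, bb) {
    # n x (c*bb) matrix whose i-th block is M[inv[, i], ]
    A <- M[as.vector(inv), , drop = FALSE]
    dim(A) <- c(n, bb, ncol(M))
    A <- aperm(A, c(1, 3, 2))
    dim(A) <- c(n, ncol(M) * bb)
    A
  }
  sub_b <- 64L
  perm_fun <- function(b) {
    out <- numeric(0)
    while (length(out) < b) {
      bb <- min(sub_b, b - length(out))
      inv <- vapply(seq_len(bb), function(i) order(sample.int(n)), integer(n))
      U <- crossprod(stack_inv(base$Q, inv, bb), D)   # (c*bb) x k
      V <- crossprod(stack_inv(Qpc, inv, bb), D)
      dim(U) <- dim(V) <- c(cdim, bb, k)
      su <- colSums(U * U)                            # bb x k
      sv <- colSums(V * V)
      suv <- colSums(U * V)
      pc_s <- matrix(base$pc[inv], n, bb)
      pc2_s <- pc_s * pc_s
      a11 <- matrix(cd2, bb, k, byrow = TRUE) - su
      a22 <- crossprod(pc2_s, D2) - sv
      a12 <- crossprod(pc_s, D2) - suv
      b1 <- crossprod(matrix(y_r[inv], n, bb), D)
      b2 <- crossprod(matrix(ypc[inv], n, bb), D)
      det <- a11 * a22 - a12^2
      det[det <= .Machine$double.eps * a11 * a22] <- NA_real_
      beta1 <- (a22 * b1 - a12 * b2) / det
      beta2 <- (a11 * b2 - a12 * b1) / det
      sigma2 <- pmax(yy - (beta1 * b1 + beta2 * b2), 0) / df
      t2 <- beta2^2 * det / (sigma2 * a11)
      tmax <- apply(t2, 1, max, na.rm = TRUE)
      out <- c(out, 2 * stats::pt(-sqrt(tmax), df))
    }
    out
  }
  run <- function() perm_calibrate(obs_min, perm_fun, n_perm_min, n_perm_max)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  res$nominal_p_lead <- obs_min
  res$lead_index <- which(obs_scan$p == obs_min)[1]
  res
}

#' Call interaction eGenes at a gene-level FDR
#'
#' Storey q-values over gene-level adjusted interaction p-values, thresholded
#' at `fdr` (default 0.10, reflecting the lower power of the interaction
#' model).
#'
#' @param results data.frame with `gene_id` and `q_value`
#' @param fdr q-value threshold (default 0.1)
#' @return character vector of ieGene ids
#' @export
call_iegenes <- function(results, fdr = 0.1) {
  if (NROW(results) == 0) return(character(0))
  results$gene_id[!is.na(results$q_value) & results$q_value <= fdr]
}

#' Classify an interaction eQTL by purity tertile
#'
#' Samples are split at the 1/3 and 2/3 purity quantiles (linear-interpolation
#' quantiles; boundary ties go to the lower tertile). Expression (covariates
#' already removed upstream) is regressed on dosage within the low and high
#' tertiles separately. Labels: `low_purity_only` if only the low-tertile
#' slope is significant at `alpha`, `high_purity_only` for the reverse,
#' `opposite_directions` if both are significant with opposite signs,
#' otherwise `unclassified`.
#'
#' @param y covariate-removed expression vector
#' @param dosage lead-variant dosage vector
#' @param purity per-sample purity
#' @param alpha within-tertile significance level (default 0.05)
#' @param min_per_tertile minimum samples per tertile (default 10)
#' @return one-row data.frame(class_label, n_low, n_high, slope_low,
#'   slope_high, p_low, p_high)
#' @export
tertile_classify <- function(y, dosage, purity, alpha = 0.05,
                             min_per_tertile = 10L) {
  qs <- stats::quantile(purity, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  low <- purity <= qs[1]
  high <- purity > qs[2]
  slope_fit <- function(sel) {
    if (sum(sel) < 2 || stats::sd(dosage[sel]) == 0) {
      return(c(slope = NA_real_, p = NA_real_))
    }
    f <- lm_coef_tests(cbind(1, g = dosage[sel]), y[sel], 2)
    c(slope = f$estimate, p = f$p)
  }
  out <- data.frame(class_label = "unclassified",
                    n_low = sum(low), n_high = sum(high),
                    slope_low = NA_real_, slope_high = NA_real_,
                    p_low = NA_real_, p_high = NA_real_,
                    stringsAsFactors = FALSE)
  if (sum(low) < min_per_tertile || sum(high) < min_per_tertile) {
    tq_log("tertile_classify: tertile below %d samples, unclassified", min_per_tertile)
    return(out)
  }
  fl <- slope_fit(low)
  fh <- slope_fit(high)
  out$slope_low <- fl["slope"]; out$p_low <- fl["p"]
  out$slope_high <- fh["slope"]; out$p_high <- fh["p"]
  sl <- !is.na(fl["p"]) && fl["p"] < alpha
  sh <- !is.na(fh["p"]) && fh["p"] < alpha
  out$class_label <-
    if (sl && sh && sign(fl["slope"]) != sign(fh["slope"])) "opposite_directions"
    else if (sl && !sh) "low_purity_only"
    else if (sh && !sl) "high_purity_only"
    else "unclassified"
  out
}

#' Map genotype x purity interaction eQTLs across genes
#'
#' For each gene, scans cis variants for a genotype x purity interaction,
#' calibrates the minimum interaction p by genotype permutation with beta
#' approximation, computes Storey q-values across genes, calls ieGenes at
#' `fdr`, and classifies each ieGene's lead variant by purity tertile.
#'
#' @param expression an [expression_set()] with `transformed` filled
#' @param genotypes a filtered [genotype_matrix()]
#' @param purity per-sample tumor purity in \[0,1\] (named or sample-aligned)
#' @param covariates samples x covariates matrix (or NULL)
#' @param somatic list with genes x samples matrices `cna`, `mutation` (or NULL)
#' @param window cis window in bp (default 1e6)
#' @param mac_min minor-allele-count filter (default 5)
#' @param n_perm adaptive permutation bounds (default c(1000, 10000))
#' @param fdr ieGene q-value threshold (default 0.1)
#' @param alpha within-tertile significance level (default 0.05)
#' @param seed master seed
#' @return object of class `ieqtl` with `results`, `iegenes`, `params`
#' @export
interaction_eqtl <- function(expression, genotypes, purity, covariates = NULL,
                             somatic = NULL, window = 1e6, mac_min = 5L,
                             n_perm = c(1000L, 10000L), fdr = 0.1,
                             alpha = 0.05, seed = 1L) {
  stopifnot(inherits(expression, "expression_set"),
            inherits(genotypes, "genotype_matrix"))
  if (is.null(expression$transformed)) stop("transform_expression first")
  expr_t <- expression$transformed
  genes <- expression$genes
  D <- genotypes$dosages
  vinfo <- genotypes$variants
  n <- ncol(expr_t)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    y <- expr_t[i, ]
    cna_i <- if (!is.null(somatic)) somatic$cna[gid, ]
    mut_i <- if (!is.null(somatic)) somatic$mutation[gid, ]
    idx <- cis_window(genes[i, ], vinfo, window)
    if (length(idx)) idx <- idx[mac_filter(D[, idx, drop = FALSE], mac_min)]
    if (length(idx) == 0) next
    Dg <- D[, idx, drop = FALSE]
    scan <- interaction_scan(y, Dg, purity, covariates, cna_i, mut_i)
    li <- lead_variant(scan$p, vinfo$pos[idx], vinfo$id[idx])
    gp <- interaction_gene_pass(y, Dg, purity, covariates, cna_i, mut_i,
                                n_perm[1], n_perm[2],
                                seed = stage_seed(seed, paste0("ieqtl:", gid)))
    rows[[i]] <- data.frame(
      gene_id = gid, lead_variant = vinfo$id[idx][li],
      lead_index_global = idx[li],
      interaction_coef = scan$interaction_coef[li],
      interaction_p = scan$p[li],
      beta_shape1 = gp$beta_shape1, beta_shape2 = gp$beta_shape2,
      empirical_p = gp$empirical_p, adjusted_p = gp$adjusted_p,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(gene_id = character(0))
    return(structure(list(results = results, iegenes = character(0),
                          params = list()), class = "ieqtl"))
  }
  rownames(results) <- NULL
  results$q_value <- storey_qvalues(results$adjusted_p)
  iegenes <- call_iegenes(results, fdr)
  cls <- data.frame(class_label = rep(NA_character_, nrow(results)),
                    n_low = NA_integer_, n_high = NA_integer_,
                    slope_low = NA_real_, slope_high = NA_real_,
                    p_low = NA_real_, p_high = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in which(results$gene_id %in% iegenes)) {
    gid <- results$gene_id[i]
    gi <- match(gid, genes$id)
    y_adj <- residualize(expr_t[gi, ], covariates,
                         cna = if (!is.null(somatic)) somatic$cna[gid, ],
                         mutation = if (!is.null(somatic)) somatic$mutation[gid, ])
    cl <- tertile_classify(y_adj, D[, results$lead_index_global[i]], purity,
                           alpha = alpha)
    cls[i, ] <- cl
  }
  results <- cbind(results[setdiff(names(results), "lead_index_global")], cls)
  structure(list(results = results, iegenes = iegenes, n_samples = n,
                 params = list(window = window, mac_min = mac_min,
                               n_perm = n_perm, fdr = fdr, alpha = alpha,
                               seed = seed)),
            class = "ieqtl")
}
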