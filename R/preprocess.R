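# Genotype QC, expression normalization/filtering, and covariate estimation.

#' Construct a genotype matrix object
#'
#' Container for imputed genotype dosages with variant metadata. Dosages are
#' expected alternate-allele counts in \[0,2\]; `NA` marks missing calls.
#'
#' @param dosages numeric matrix, samples x variants; values in \[0,2\] or NA
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `r2` (imputation quality)
#' @param samples sample identifiers (defaults to `rownames(dosages)`)
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `samples`
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            nrow(variants) == ncol(dosages),
            length(samples) == nrow(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0,2] (or be NA)")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) stop("variant positions must be strictly increasing within chromosome")
  }
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ",")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Construct an expression set
#'
#' Raw counts and TPM with gene coordinates. `normalized` (post size-factor)
#' and `transformed` (post rank-based inverse-normal) slots are filled by
#' [normalize_expression()] and [transform_expression()].
#'
#' @param counts non-negative integer matrix, genes x samples
#' @param tpm non-negative matrix, genes x samples
#' @param genes data.frame with `id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates)
#' @return object of class `expression_set`
#' @export
expression_set <- function(counts, tpm, genes) {
  counts <- as.matrix(counts)
  tpm <- as.matrix(tpm)
  stopifnot(all(counts >= 0), all(tpm >= 0),
            all(dim(counts) == dim(tpm)),
            is.data.frame(genes),
            all(c("id", "chrom", "start", "end", "strand") %in% names(genes)),
            nrow(genes) == nrow(counts),
            all(genes$start < genes$end))
  rownames(counts) <- rownames(tpm) <- genes$id
  structure(list(counts = counts, tpm = tpm, genes = genes,
                 normalized = NULL, size_factors = NULL, transformed = NULL),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  normalized: %s, transformed: %s\n",
              !is.null(x$normalized), !is.null(x$transformed)))
  invisible(x)
}

#' Filter a genotype matrix on frequency, missingness and imputation quality
#'
#' Removes variants with minor allele frequency below `maf_min`, variants with
#' missingness above `snp_missing_max`, and (when an `r2` column is present)
#' variants with imputation quality below `r2_min`; then removes samples whose
#' residual missingness exceeds `sample_missing_max`; finally mean-imputes any
#' remaining missing dosages per variant. The variant-missingness default is
#' deliberately lax (0.95) and should be tightened (e.g. 0.05) when call-level
#' missingness matters; it is exposed as a parameter for that reason.
#'
#' @param g a [genotype_matrix()]
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param snp_missing_max maximum per-variant missingness (default 0.95)
#' @param sample_missing_max maximum per-sample missingness (default 0.025)
#' @param r2_min minimum imputation r2 (default 0.3; ignored if no `r2` column)
#' @param quality_mask optional samples x variants logical matrix; calls with
#'   `FALSE` (failing an upstream per-call quality score) are set missing
#'   before any filter is applied
#' @return filtered `genotype_matrix` with no missing dosages
#' @export
filter_genotypes <- function(g, maf_min = 0.01, snp_missing_max = 0.95,
                             sample_missing_max = 0.025, r2_min = 0.3,
                             quality_mask = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1, snp_missing_max >= 0,
            snp_missing_max <= 1, sample_missing_max >= 0,
            sample_missing_max <= 1)
  D <- g$dosages
  if (!is.null(quality_mask)) {
    stopifnot(is.logical(quality_mask), all(dim(quality_mask) == dim(D)))
    D[!quality_mask] <- NA_real_
  }
  af <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  miss_v <- colMeans(is.na(D))
  keep_v <- maf >= maf_min & miss_v <= snp_missing_max
  if (!is.null(g$variants$r2)) {
    keep_v <- keep_v & (is.na(g$variants$r2) | g$variants$r2 >= r2_min)
  }
  tq_log("filter_genotypes: %d/%d variants retained (MAF/missingness/r2)",
         sum(keep_v), length(keep_v))
  D <- D[, keep_v, drop = FALSE]
  miss_s <- rowMeans(is.na(D))
  keep_s <- miss_s <= sample_missing_max
  tq_log("filter_genotypes: %d/%d samples retained (missingness)",
         sum(keep_s), length(keep_s))
  D <- D[keep_s, , drop = FALSE]
  if (ncol(D) == 0 || nrow(D) == 0) stop("no variants or samples survive genotype filtering")
  # mean imputation preserves the per-variant allele frequency
  for (j in which(colSums(is.na(D)) > 0)) {
    D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  }
  genotype_matrix(D, g$variants[keep_v, , drop = FALSE], g$samples[keep_s])
}

#' Principal components of a matrix with a fixed sign convention
#'
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive, making repeated calls bit-reproducible.
#' @noRd
pca_scores <- function(X, k, scale. = FALSE, prefix = "PC") {
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (k <= 0) stop("number of components must be positive")
  if (k > min(dim(X)) - 1) stop("k too large for matrix dimensions")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale., rank. = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0(prefix, seq_len(k))
  scores
}

#' Genotype principal components (ancestry covariates)
#'
#' Top-k principal components of the centered, per-variant
#' variance-standardized dosage matrix. Default k = 5.
#'
#' @param g a [genotype_matrix()] with no missing dosages
#' @param k number of components (default 5)
#' @return samples x k score matrix, columns `PC1..PCk`
#' @export
genotype_pcs <- function(g, k = 5L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (k <= 0) stop("k must be positive")
  if (any(is.na(g$dosages))) stop("run filter_genotypes first (missing dosages present)")
  s <- pca_scores(g$dosages, k, scale. = TRUE, prefix = "PC")
  rownames(s) <- g$samples
  s
}

#' Median-of-ratios size factors (geometric-mean method)
#'
#' The DESeq-style estimator: a per-gene geometric mean over samples forms the
#' pseudo-reference; a sample's factor is the median ratio of its counts to
#' the reference, over genes with strictly positive counts in every sample.
#'
#' @param counts genes x samples count matrix
#' @return positive numeric vector of per-sample size factors
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    stop("no gene has strictly positive counts in all samples; ",
         "pseudo-reference fallback is not implemented")
  }
  sf <- apply(counts, 2, function(s) exp(stats::median(log(s[ok]) - loggeo[ok])))
  names(sf) <- colnames(counts)
  sf
}

#' Apply size-factor normalization to an expression set
#'
#' @param e an [expression_set()]
#' @return `e` with `normalized` and `size_factors` filled
#' @export
normalize_expression <- function(e) {
  stopifnot(inherits(e, "expression_set"))
  sf <- size_factors(e$counts)
  e$size_factors <- sf
  e$normalized <- sweep(e$counts, 2, sf, "/")
  e
}

#' Filter lowly-expressed genes
#'
#' A gene is retained iff, jointly, TPM >= `tpm_min` and counts >= `count_min`
#' in at least `frac_min` of samples (inclusive thresholds).
#'
#' @param e an [expression_set()]
#' @param tpm_min TPM threshold (default 0.1)
#' @param count_min read-count threshold (default 6)
#' @param frac_min minimum fraction of samples (default 0.20)
#' @return filtered `expression_set`
#' @export
filter_genes <- function(e, tpm_min = 0.1, count_min = 6, frac_min = 0.20) {
  stopifnot(inherits(e, "expression_set"),
            tpm_min >= 0, count_min >= 0, frac_min >= 0)
  pass <- rowMeans(e$tpm >= tpm_min & e$counts >= count_min) >= frac_min
  tq_log("filter_genes: %d/%d genes retained", sum(pass), length(pass))
  out <- expression_set(e$counts[pass, , drop = FALSE],
                        e$tpm[pass, , drop = FALSE],
                        e$genes[pass, , drop = FALSE])
  if (!is.null(e$normalized)) {
    out$normalized <- e$normalized[pass, , drop = FALSE]
    out$size_factors <- e$size_factors
  }
  if (!is.null(e$transformed)) out$transformed <- e$transformed[pass, , drop = FALSE]
  out
}

#' Flag expression outlier samples by PCA
#'
#' PCA on log2(normalized + 1) expression; a sample is flagged when its score
#' lies more than `sd_cut` standard deviations from the mean on any of the
#' first `n_pcs` components.
#'
#' @param e a normalized [expression_set()]
#' @param n_pcs number of leading components to inspect (default 6)
#' @param sd_cut standard-deviation cutoff (default 3)
#' @return character vector of flagged sample ids (possibly empty)
#' @export
expression_outliers <- function(e, n_pcs = 6L, sd_cut = 3) {
  stopifnot(inherits(e, "expression_set"))
  if (is.null(e$normalized)) stop("normalize_expression first")
  x <- t(log2(e$normalized + 1))
  n_pcs <- min(n_pcs, nrow(x) - 1L)
  s <- pca_scores(x, n_pcs)
  flagged <- rep(FALSE, nrow(x))
  for (j in seq_len(ncol(s))) {
    z <- (s[, j] - mean(s[, j])) / stats::sd(s[, j])
    flagged <- flagged | abs(z) > sd_cut
  }
  colnames(e$normalized)[flagged]
}

#' Hidden expression factors (PEER-style covariates via PCA)
#'
#' Top-k principal components of the per-gene standardized log2 expression
#' matrix, used as hidden covariates absorbing broad technical and biological
#' variation. Default k = 15.
#'
#' @param e a normalized [expression_set()] (or a genes x samples matrix of
#'   normalized expression)
#' @param k number of factors (default 15)
#' @return samples x k score matrix, columns `HF1..HFk`
#' @export
hidden_factors <- function(e, k = 15L) {
  if (inherits(e, "expression_set")) {
    if (is.null(e$normalized)) stop("normalize_expression first")
    m <- e$normalized
  } else {
    m <- as.matrix(e)
  }
  if (k <= 0) stop("k must be positive")
  x <- log2(m + 1)
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  xs <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  pca_scores(t(xs), k, prefix = "HF")
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles via
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset c = 3/8; ties take
#' the average rank.
#'
#' @param x numeric vector, length >= 2, not all equal
#' @param offset rank offset c (default 3/8, Blom)
#' @return transformed vector, mean approximately 0
#' @export
inverse_normal <- function(x, offset = 3 / 8) {
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  if (length(unique(x)) == 1L) stop("degenerate input: all values identical")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Rank-based inverse normal transform of each gene in an expression set
#'
#' @param e a normalized [expression_set()]
#' @return `e` with `transformed` filled (genes x samples)
#' @export
transform_expression <- function(e) {
  stopifnot(inherits(e, "expression_set"))
  if (is.null(e$normalized)) stop("normalize_expression first")
  e$transformed <- t(apply(e$normalized, 1, inverse_normal))
  dimnames(e$transformed) <- dimnames(e$normalized)
  e
}

#' Assemble the per-sample covariate table
#'
#' @param genotype_pcs samples x k PC matrix (or NULL)
#' @param hidden_factors samples x k factor matrix (or NULL)
#' @param sex 0/1 indicator vector (or NULL)
#' @return samples x covariates numeric matrix
#' @export
build_covariates <- function(genotype_pcs = NULL, hidden_factors = NULL,
                             sex = NULL) {
  parts <- list()
  if (!is.null(genotype_pcs)) parts$pcs <- as.matrix(genotype_pcs)
  if (!is.null(hidden_factors)) parts$hf <- as.matrix(hidden_factors)
  if (!is.null(sex)) {
    sx <- matrix(as.numeric(sex), ncol = 1, dimnames = list(NULL, "sex"))
    parts$sex <- sx
  }
  if (length(parts) == 0) return(NULL)
  out <- do.call(cbind, unname(parts))
  if (anyNA(out)) stop("covariate table contains missing values")
  out
}
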