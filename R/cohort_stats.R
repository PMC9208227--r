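# Per-gene variance partitioning, CCF / MATH intratumor-heterogeneity
# scoring, eGene-sharing summaries, downsampling, and eQTL/somQTL ratios.

#' Partition a gene's expression variance across predictor groups
#'
#' Fits the full fixed-effect OLS model containing all predictor groups; the
#' fraction attributed to group G is the semi-partial R^2
#' `(RSS_without_G - RSS_full) / TSS`, floored at 0; the residual fraction is
#' `RSS_full / TSS`. The vector is renormalized to sum to one. For mutually
#' orthogonal groups this equals each group's marginal R^2. Constant
#' predictors are dropped with a log note.
#'
#' @param y expression vector (typically INT-transformed)
#' @param groups named list; each element a vector or samples x p matrix of
#'   predictors for one component (e.g. genotype, cna, mutation,
#'   hidden_factors, genotype_pcs, sex)
#' @return named numeric vector of fractions (groups plus `residual`),
#'   summing to 1
#' @export
variance_fractions <- function(y, groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  n <- length(y)
  mats <- lapply(groups, function(g) {
    m <- as.matrix(g)
    stopifnot(nrow(m) == n)
    m
  })
  for (nm in names(mats)) {
    if (is.null(colnames(mats[[nm]]))) {
      colnames(mats[[nm]]) <- paste0(nm, seq_len(ncol(mats[[nm]])))
    }
    mats[[nm]] <- drop_constant_cols(mats[[nm]], what = nm)
  }
  keep <- vapply(mats, function(m) ncol(m) > 0, logical(1))
  mats <- mats[keep]
  fit_rss <- function(X) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) stop("rank-deficient variance-partition design")
    sum(qr.resid(qr_x, y)^2)
  }
  X_full <- cbind(1, do.call(cbind, unname(mats)))
  rss_full <- fit_rss(X_full)
  tss <- sum((y - mean(y))^2)
  fr <- vapply(names(mats), function(nm) {
    rest <- mats[setdiff(names(mats), nm)]
    X_wo <- if (length(rest)) cbind(1, do.call(cbind, unname(rest)))
            else matrix(1, n, 1)
    max(0, (fit_rss(X_wo) - rss_full) / tss)
  }, numeric(1))
  out <- c(fr, residual = rss_full / tss)
  dropped <- setdiff(names(groups), names(mats))
  if (length(dropped)) {
    out <- c(out, stats::setNames(rep(0, length(dropped)), dropped))
    out <- out[c(names(groups), "residual")]
  }
  out / sum(out)
}

#' Cancer cell fraction of a mutation
#'
#' `CCF = VAF * (purity * CNt + (1 - purity) * CNn) / (purity * multiplicity)`,
#' clamped to \[0, 1.5\]; values above 1 (super-clonal artifacts) are retained
#' up to the clamp. Vectorized with recycling. Zero purity yields NA with a
#' warning.
#'
#' @param vaf variant allele fraction in \[0,1\]
#' @param purity tumor purity in (0,1\]
#' @param cn_tumor local total copy number in the tumor (default 2)
#' @param cn_normal local copy number in normal cells (default 2)
#' @param multiplicity mutation copies per carrying cell (default 1)
#' @return numeric CCF vector
#' @export
ccf <- function(vaf, purity, cn_tumor = 2, cn_normal = 2, multiplicity = 1) {
  stopifnot(all(vaf >= 0), all(vaf <= 1), all(purity >= 0), all(purity <= 1),
            all(multiplicity >= 1))
  out <- vaf * (purity * cn_tumor + (1 - purity) * cn_normal) /
    (purity * multiplicity)
  if (any(purity == 0)) {
    warning("CCF undefined for purity = 0; returning NA")
    out[rep_len(purity == 0, length(out))] <- NA_real_
  }
  pmin(pmax(out, 0), 1.5)
}

#' MATH intratumor-heterogeneity score
#'
#' Median absolute deviation of a patient's mutation CCFs divided by their
#' median (verbatim definition: unscaled MAD, no consistency constant and no
#' x100 factor). Set `conventional = TRUE` for the original
#' `100 * 1.4826 * MAD / median` variant.
#'
#' @param ccfs numeric vector of cancer cell fractions (>= 3 values)
#' @param conventional use the 1.4826 x 100 scaling (default FALSE)
#' @return MATH score (NA with a warning when undefined)
#' @export
math_score <- function(ccfs, conventional = FALSE) {
  ccfs <- ccfs[!is.na(ccfs)]
  if (length(ccfs) < 3) {
    warning("MATH undefined: fewer than 3 mutations")
    return(NA_real_)
  }
  med <- stats::median(ccfs)
  if (med <= 0) {
    warning("MATH undefined: non-positive median CCF")
    return(NA_real_)
  }
  m <- stats::mad(ccfs, constant = 1)
  if (conventional) 100 * 1.4826 * m / med else m / med
}

#' Fraction of expressed genes that are eGenes
#'
#' @param egenes character set of eGene ids (must be a subset of `expressed`)
#' @param expressed character set of expressed gene ids
#' @return proportion |egenes| / |expressed|
#' @export
egene_fraction <- function(egenes, expressed) {
  if (length(expressed) == 0) stop("egene_fraction undefined: empty expressed set")
  stopifnot(all(egenes %in% expressed))
  length(unique(egenes)) / length(unique(expressed))
}

#' Jaccard similarity of eGene sets across cohorts
#'
#' Raw index J(A,B) = |A intersect B| / |A union B|; the scaled index min-max
#' rescales the off-diagonal values to \[0,1\]. When both sets of a pair are
#' empty, J is defined as 0 (flagged). When all off-diagonal values are equal
#' the scaled values are set to 0 with a log note.
#'
#' @param egene_sets named list of character vectors, one per cohort
#' @return list with `raw` and `scaled` symmetric matrices (scaled diagonal NA)
#' @export
similarity_matrix <- function(egene_sets) {
  stopifnot(is.list(egene_sets), length(egene_sets) >= 2,
            !is.null(names(egene_sets)))
  k <- length(egene_sets)
  raw <- matrix(1, k, k, dimnames = list(names(egene_sets), names(egene_sets)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- unique(egene_sets[[i]])
      b <- unique(egene_sets[[j]])
      u <- length(union(a, b))
      if (u == 0) {
        tq_log("similarity_matrix: both eGene sets empty for %s/%s; J set to 0",
               names(egene_sets)[i], names(egene_sets)[j])
        raw[i, j] <- raw[j, i] <- 0
      } else {
        raw[i, j] <- raw[j, i] <- length(intersect(a, b)) / u
      }
    }
  }
  off <- raw[upper.tri(raw)]
  scaled <- matrix(NA_real_, k, k, dimnames = dimnames(raw))
  if (max(off) > min(off)) {
    sc <- (raw - min(off)) / (max(off) - min(off))
    scaled[upper.tri(scaled)] <- sc[upper.tri(sc)]
    scaled[lower.tri(scaled)] <- t(sc)[lower.tri(sc)]
  } else {
    tq_log("similarity_matrix: all off-diagonal similarities equal; scaled values set to 0")
    scaled[upper.tri(scaled) | lower.tri(scaled)] <- 0
  }
  list(raw = raw, scaled = scaled)
}

#' Downsample a cohort to a fixed size
#'
#' Uniform random sample without replacement; the input is sorted before
#' sampling so the draw is invariant to input order, and the output is sorted.
#' Cohorts smaller than `n` are skipped (NULL, with a log note).
#'
#' @param sample_ids character vector of sample ids
#' @param n target size (default 200)
#' @param seed integer seed
#' @return sorted character vector of `n` ids, or NULL if the cohort is too
#'   small
#' @export
downsample <- function(sample_ids, n = 200L, seed = 1L) {
  ids <- sort(unique(sample_ids))
  if (n > length(ids)) {
    tq_log("downsample: cohort of %d smaller than n = %d, skipped", length(ids), n)
    return(NULL)
  }
  sort(with_seed(seed, sample(ids, n)))
}

#' Ratio of eQTL to somQTL associations
#'
#' @param n_egene_assoc number of gene-level eQTL associations
#' @param n_somqtl number of gene-level somQTL associations
#' @return ratio (NA with a warning when the denominator is zero)
#' @export
qtl_ratio <- function(n_egene_assoc, n_somqtl) {
  if (n_somqtl == 0) {
    warning("qtl_ratio undefined: zero somQTL associations")
    return(NA_real_)
  }
  n_egene_assoc / n_somqtl
}

#' Cross-cohort eGene sharing counts
#'
#' @param egene_sets named list of character vectors, one per cohort
#' @return list with `counts` (named integer vector: cohorts per gene),
#'   `shared_in_all` (genes present in every cohort) and `unique_to_one`
#'   (genes present in exactly one cohort)
#' @export
sharing_counts <- function(egene_sets) {
  stopifnot(is.list(egene_sets), length(egene_sets) >= 1)
  tab <- table(unlist(lapply(egene_sets, unique)))
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(counts = counts,
       shared_in_all = names(counts)[counts == length(egene_sets)],
       unique_to_one = names(counts)[counts == 1L])
}

#' Per-sample MATH scores from a mutation table
#'
#' Computes each mutation's CCF from VAF, the sample's purity and local copy
#' number, then the per-sample MATH score.
#'
#' @param mutations data.frame with columns `sample`, `vaf`, and optionally
#'   `cn_tumor`, `cn_normal`, `multiplicity`
#' @param purity named per-sample purity vector
#' @param conventional passed to [math_score()]
#' @return data.frame(sample, n_mutations, math)
#' @export
sample_math_scores <- function(mutations, purity, conventional = FALSE) {
  stopifnot(all(c("sample", "vaf") %in% names(mutations)))
  cn_t <- if (!is.null(mutations$cn_tumor)) mutations$cn_tumor else 2
  cn_n <- if (!is.null(mutations$cn_normal)) mutations$cn_normal else 2
  mult <- if (!is.null(mutations$multiplicity)) mutations$multiplicity else 1
  cc <- ccf(mutations$vaf, purity[mutations$sample], cn_t, cn_n, mult)
  ids <- sort(unique(mutations$sample))
  math <- vapply(ids, function(s) {
    suppressWarnings(math_score(cc[mutations$sample == s],
                                conventional = conventional))
  }, numeric(1))
  data.frame(sample = ids,
             n_mutations = as.integer(table(mutations$sample)[ids]),
             math = math, row.names = NULL, stringsAsFactors = FALSE)
}
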