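# S3 methods for the fitted cis-eQTL and interaction-eQTL objects.

#' @export
print.cis_eqtl <- function(x, ...) {
  cat("Somatic-aware cis-eQTL scan\n")
  cat(sprintf("  genes tested: %d (%d with cis variants)\n",
              nrow(x$results), sum(x$results$n_var > 0)))
  cat(sprintf("  samples: %d, window: %g bp, MAC >= %d, permutations: %d-%d\n",
              x$n_samples, x$params$window, x$params$mac_min,
              x$params$n_perm[1], x$params$n_perm[2]))
  cat(sprintf("  eGenes at q <= %.2g: %d\n", x$params$fdr, length(x$egenes)))
  invisible(x)
}

#' @export
summary.cis_eqtl <- function(object, ...) {
  r <- object$results
  ok <- !is.na(r$adjusted_p)
  out <- list(
    n_genes = nrow(r),
    n_tested = sum(ok),
    n_egenes = length(object$egenes),
    egene_fraction = if (sum(ok)) length(object$egenes) / sum(ok) else NA_real_,
    fdr = object$params$fdr,
    adjusted_p_quantiles = stats::quantile(r$adjusted_p[ok],
                                           c(0, 0.25, 0.5, 0.75, 1)),
    lead = r[ok, ][order(r$adjusted_p[ok]), ][
      seq_len(min(5, sum(ok))),
      c("gene_id", "lead_variant", "nominal_p", "slope", "adjusted_p",
        "q_value", "afc_log2")])
  class(out) <- "summary.cis_eqtl"
  out
}

#' @export
print.summary.cis_eqtl <- function(x, ...) {
  cat(sprintf("cis-eQTL scan: %d/%d genes tested, %d eGenes (%.1f%%) at q <= %.2g\n",
              x$n_tested, x$n_genes, x$n_egenes, 100 * x$egene_fraction, x$fdr))
  cat("top associations:\n")
  print(x$lead, row.names = FALSE, digits = 3)
  invisible(x)
}

#' QQ plot of gene-level adjusted p-values
#'
#' Observed -log10 adjusted p against the uniform expectation; genome-wide
#' inflation or a true-signal excess lifts the upper tail.
#' @param x a `cis_eqtl` object
#' @param ... passed to [plot()]
#' @export
plot.cis_eqtl <- function(x, ...) {
  p <- sort(x$results$adjusted_p[!is.na(x$results$adjusted_p)])
  n <- length(p)
  exp_p <- (seq_len(n) - 0.5) / n
  plot(-log10(exp_p), -log10(p), xlab = "expected -log10(p)",
       ylab = "observed -log10(adjusted p)",
       main = "cis-eQTL gene-level p-values", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
print.ieqtl <- function(x, ...) {
  cat("Genotype x purity interaction eQTL scan\n")
  cat(sprintf("  genes tested: %d\n", nrow(x$results)))
  cat(sprintf("  ieGenes at q <= %.2g: %d\n", x$params$fdr, length(x$iegenes)))
  if (length(x$iegenes)) {
    cls <- table(x$results$class_label[x$results$gene_id %in% x$iegenes])
    cat(sprintf("  classes: %s\n",
                paste(names(cls), cls, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.ieqtl <- function(object, ...) {
  r <- object$results
  out <- list(
    n_genes = nrow(r),
    n_iegenes = length(object$iegenes),
    fdr = object$params$fdr,
    classes = table(r$class_label[r$gene_id %in% object$iegenes]),
    lead = r[order(r$adjusted_p), ][
      seq_len(min(5, nrow(r))),
      c("gene_id", "lead_variant", "interaction_coef", "interaction_p",
        "adjusted_p", "q_value", "class_label")])
  class(out) <- "summary.ieqtl"
  out
}

#' @export
print.summary.ieqtl <- function(x, ...) {
  cat(sprintf("interaction-eQTL scan: %d genes, %d ieGenes at q <= %.2g\n",
              x$n_genes, x$n_iegenes, x$fdr))
  if (length(x$classes)) {
    cat("purity-tertile classes: ")
    cat(paste(names(x$classes), x$classes, sep = "=", collapse = ", "), "\n")
  }
  cat("top interactions:\n")
  print(x$lead, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Purity-stratified association plot for one interaction eQTL
#'
#' Expression against dosage, colored by purity tertile, with per-tertile
#' fitted lines: the visual form of the tertile classification.
#' @param x an `ieqtl` object
#' @param gene gene id to display (default: smallest adjusted p)
#' @param y covariate-removed expression vector for the gene
#' @param dosage lead-variant dosages
#' @param purity per-sample purity
#' @param ... passed to [plot()]
#' @export
plot.ieqtl <- function(x, gene = NULL, y = NULL, dosage = NULL, purity = NULL,
                       ...) {
  if (is.null(y) || is.null(dosage) || is.null(purity)) {
    stop("supply y, dosage and purity vectors for the gene to display")
  }
  qs <- stats::quantile(purity, c(1 / 3, 2 / 3), names = FALSE)
  grp <- 1L + (purity > qs[1]) + (purity > qs[2])
  cols <- c("#2166AC", "grey60", "#B2182B")
  plot(jitter(dosage, 0.3), y, col = cols[grp], pch = 16,
       xlab = "dosage", ylab = "adjusted expression",
       main = if (is.null(gene)) "interaction eQTL" else gene, ...)
  for (g in c(1L, 3L)) {
    sel <- grp == g
    if (sum(sel) > 2 && stats::sd(dosage[sel]) > 0) {
      abline(stats::lm(y[sel] ~ dosage[sel]), col = cols[g], lwd = 2)
    }
  }
  legend("topright", c("low purity", "mid", "high purity"), col = cols,
         pch = 16, bty = "n")
  invisible(x)
}
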