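# Plain-text I/O: TSV matrices, BED-like annotation (0-based half-open on
# disk, 1-based inclusive in memory), and VCF dosage import via vcfR.

write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               row_label),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

read_matrix_tsv <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write gene annotation as BED (0-based, half-open)
#'
#' In-memory gene bounds are 1-based inclusive; on disk the BED convention
#' (`start - 1`, `end`) is used.
#'
#' @param genes data.frame with `id`, `chrom`, `start`, `end`, `strand`
#' @param path output path
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1,
                    end = genes$end, name = genes$id, score = ".",
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read BED-like gene annotation (converted to 1-based inclusive)
#'
#' @param path BED file (chrom, start, end, name, score, strand)
#' @return data.frame with `id`, `chrom`, `start`, `end`, `strand`
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(id = bed[[4]], chrom = bed[[1]], start = bed[[2]] + 1,
             end = bed[[3]], strand = if (ncol(bed) >= 6) bed[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Read a genotype dosage matrix from VCF
#'
#' Extracts the per-sample `DS` (dosage) FORMAT field. Requires the `vcfR`
#' package.
#'
#' @param path VCF file (plain or bgzipped)
#' @return a [genotype_matrix()]
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants, samples = colnames(ds))
}

#' Write a synthetic cohort to a directory of plain-text tables
#'
#' Emits the dosage matrix, variant table, BED gene annotation, count and TPM
#' matrices, somatic CNA/mutation tables, purity, sex, the per-mutation table
#' and the ground-truth registry.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(cohort$genotypes$variants, p("variants.tsv"))
  write_tsv(t(cohort$genotypes$dosages), p("dosages.tsv"), row_label = "variant_id")
  write_gene_bed(cohort$expression$genes, p("genes.bed"))
  write_tsv(cohort$expression$counts, p("counts.tsv"), row_label = "gene_id")
  write_tsv(round(cohort$expression$tpm, 4), p("tpm.tsv"), row_label = "gene_id")
  write_tsv(cohort$somatic$cna, p("somatic_cna.tsv"), row_label = "gene_id")
  write_tsv(cohort$somatic$mutation, p("somatic_mutation.tsv"), row_label = "gene_id")
  write_tsv(data.frame(sample = names(cohort$purity), purity = cohort$purity),
            p("purity.tsv"))
  write_tsv(data.frame(sample = names(cohort$sex), sex = cohort$sex),
            p("sex.tsv"))
  write_tsv(cohort$mutations, p("mutations.tsv"))
  write_tsv(cohort$truth$effects, p("truth_effects.tsv"))
  write_tsv(cohort$truth$variance_fractions, p("truth_variance_fractions.tsv"),
            row_label = "gene_id")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory
#' @return list with the same structure as a `sim_cohort` (without `config`;
#'   `truth` present only if the truth tables exist)
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  variants <- read_tsv(p("variants.tsv"))
  dosages <- t(read_matrix_tsv(p("dosages.tsv")))
  genes <- read_gene_bed(p("genes.bed"))
  counts <- read_matrix_tsv(p("counts.tsv"))
  tpm <- read_matrix_tsv(p("tpm.tsv"))
  pur <- read_tsv(p("purity.tsv"))
  sex <- read_tsv(p("sex.tsv"))
  out <- list(
    genotypes = genotype_matrix(dosages, variants, samples = rownames(dosages)),
    expression = expression_set(counts, tpm, genes),
    somatic = list(cna = read_matrix_tsv(p("somatic_cna.tsv")),
                   mutation = read_matrix_tsv(p("somatic_mutation.tsv"))),
    purity = stats::setNames(pur$purity, pur$sample),
    sex = stats::setNames(sex$sex, sex$sample),
    mutations = read_tsv(p("mutations.tsv")))
  if (file.exists(p("truth_effects.tsv"))) {
    out$truth <- list(
      effects = read_tsv(p("truth_effects.tsv")),
      variance_fractions = read_tsv(p("truth_variance_fractions.tsv")))
  }
  out
}
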