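# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; no data files are read.

# Small genotype matrix with independent variants (no LD), hard calls only.
make_genotypes <- function(n = 100, k = 20, maf = 0.3, seed = 1,
                           chrom = "chr1", pos = NULL) {
  set.seed(seed)
  D <- matrix(rbinom(n * k, 2, maf), n, k)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = k)
  v <- data.frame(id = sprintf("v%03d", seq_len(k)), chrom = chrom, pos = pos,
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(D, v, samples = sprintf("S%03d", seq_len(n)))
}

# Tiny expression set with known counts.
make_expression <- function(counts, chrom = "chr1") {
  g <- nrow(counts)
  genes <- data.frame(id = sprintf("g%03d", seq_len(g)), chrom = chrom,
                      start = seq(1e4, by = 1e5, length.out = g),
                      end = seq(1e4, by = 1e5, length.out = g) + 999,
                      strand = "+", stringsAsFactors = FALSE)
  expression_set(counts, counts / 10, genes)
}

# Fast small simulation config for end-to-end tests; the short cis window
# keeps per-gene variant counts modest.
small_sim_config <- function(...) {
  defaults <- list(n_samples = 120, n_genes = 30, n_variants = 900,
                   gene_spacing = 4e4, cis_window_bp = 2e5,
                   n_hidden_factors = 3)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
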