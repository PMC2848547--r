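# Shared fixture builders. Everything is generated in code; no stored data.

write_lines_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A hand-sized panel/gene pair with known cis relationships.
toy_panel <- function() {
  tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "1", "1", "2"),
    pos = c(1e6, 4e6, 9.5e6, 1e6),
    maf = c(0.10, 0.22, 0.34, 0.47),
    platforms = "affy6",
    function_class = "intronic"
  )
}

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2"),
    chrom = c("1", "2"),
    start = c(4.9e6, 2e6),
    end = c(5.0e6, 2.1e6)
  )
}

# Uniformly random SNP/gene layout for brute-force comparisons.
random_layout <- function(n_snps, n_genes, n_chrom = 3, span = 2e7) {
  tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(n_snps)),
    chrom = as.character(sample(n_chrom, n_snps, replace = TRUE)),
    pos = round(runif(n_snps, 1, span)),
    maf = runif(n_snps, 0, 0.5)
  ) -> snps
  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    chrom = as.character(sample(n_chrom, n_genes, replace = TRUE)),
    start = round(runif(n_genes, 1, span))
  )
  genes$end <- genes$start + round(runif(n_genes, 1e3, 3e6))
  list(snps = snps, genes = genes)
}

# Plain-loop cis/trans call, deliberately independent of the package's
# vectorized join implementation.
brute_cis <- function(snp, gene, window = 4e6) {
  if (snp$chrom != gene$chrom) {
    return("trans")
  }
  d <- if (snp$pos < gene$start) {
    gene$start - snp$pos
  } else if (snp$pos > gene$end) {
    snp$pos - gene$end
  } else {
    0
  }
  if (d <= window) "cis" else "trans"
}

# Same rendering the package uses to key `targets_at`, restated here so the
# tests do not reach into internals.
fmt_threshold_for_test <- function(x) trimws(formatC(x, format = "g", digits = 15))

# Random r2 graph over n nodes as a pair table.
random_r2_graph <- function(n, p_edge = 0.25) {
  ids <- sprintf("s%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  tibble::tibble(
    rsid_a = pairs[keep, 1],
    rsid_b = pairs[keep, 2],
    r2 = runif(sum(keep))
  )
}
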