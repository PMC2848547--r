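#' Founder-only allele frequencies
#'
#' Computes minor allele frequencies from a genotype matrix using founders
#' only. Children's alleles are copies of their parents', so including them
#' would double-count transmitted chromosomes; a founder is a pedigree member
#' with neither parent present in the pedigree.
#'
#' @param genotypes Numeric matrix of minor-allele dosages in \{0, 1, 2\}
#'   (NA for missing), samples in rows (rownames = sample ids), SNPs in
#'   columns (colnames = rsids).
#' @param pedigree Data frame with columns `sample_id`, `father_id`,
#'   `mother_id`; parent ids are `NA` or `""` when absent. Named parents must
#'   themselves appear in the pedigree.
#' @return A tibble with columns `rsid`, `maf` (`min(f, 1 - f)`, always in
#'   \[0, 0.5\]). SNPs with no non-missing founder genotype are excluded and
#'   reported via a message.
#' @examples
#' geno <- rbind(dad = c(rs1 = 2), mom = c(rs1 = 1), kid = c(rs1 = 0))
#' ped <- data.frame(
#'   sample_id = c("dad", "mom", "kid"),
#'   father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mom")
#' )
#' founder_allele_freq(geno, ped) # maf 0.25: child ignored
#' @export
founder_allele_freq <- function(genotypes, pedigree) {
  assert_columns(pedigree, c("sample_id", "father_id", "mother_id"), "pedigree")
  no_parent <- function(x) is.na(x) | x == ""
  named_parents <- with(pedigree, c(
    father_id[!no_parent(father_id)], mother_id[!no_parent(mother_id)]
  ))
  unknown <- setdiff(unique(named_parents), pedigree$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "pedigree: parent(s) not present as samples: %s",
      paste(unknown, collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }
  founders <- pedigree$sample_id[
    no_parent(pedigree$father_id) & no_parent(pedigree$mother_id)
  ]
  missing_rows <- setdiff(rownames(genotypes), pedigree$sample_id)
  if (length(missing_rows) > 0) {
    abort(sprintf(
      "genotypes: sample(s) absent from pedigree: %s",
      paste(head(missing_rows, 3), collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }
  g <- genotypes[rownames(genotypes) %in% founders, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  undefined <- n_obs == 0
  if (any(undefined)) {
    inform(sprintf(
      "founder_allele_freq: %d SNP(s) with no non-missing founder genotypes excluded",
      sum(undefined)
    ))
  }
  tibble::tibble(
    rsid = colnames(genotypes)[!undefined],
    maf = unname(pmin(f[!undefined], 1 - f[!undefined]))
  )
}

#' Assign SNPs to minor-allele-frequency bins
#'
#' Partitions \[0, 0.5\] into `n_bins = 0.5 / width` non-overlapping bins of
#' equal width. Bin `k` (0-based) covers `[k * width, (k + 1) * width)`,
#' except the last bin which is closed at 0.5, so every valid MAF is assigned
#' exactly once.
#'
#' @param snps Data frame with columns `rsid` and `maf` (each in \[0, 0.5\]);
#'   rows with `NA` maf are excluded with a message.
#' @param width Bin width; default 0.05 gives ten bins.
#' @return A `maf_bins` object: list with `width`, `n_bins`, and `assignment`
#'   (tibble `rsid`, `maf`, `bin`).
#' @examples
#' bins <- assign_maf_bins(data.frame(rsid = c("a", "b"), maf = c(0.07, 0.5)))
#' bins$assignment
#' @export
assign_maf_bins <- function(snps, width = 0.05) {
  assert_columns(snps, c("rsid", "maf"), "snps")
  stopifnot(width > 0, width <= 0.5)
  undefined <- is.na(snps$maf)
  if (any(undefined)) {
    inform(sprintf(
      "assign_maf_bins: %d SNP(s) with undefined MAF excluded", sum(undefined)
    ))
    snps <- snps[!undefined, , drop = FALSE]
  }
  if (any(snps$maf < 0 | snps$maf > 0.5)) {
    abort("assign_maf_bins: maf must lie in [0, 0.5]",
      class = "eqtlenrich_validation_error"
    )
  }
  n_bins <- as.integer(ceiling(0.5 / width - 1e-9))
  bin <- pmin(as.integer(floor(snps$maf / width + 1e-12)), n_bins - 1L)
  structure(
    list(
      width = width,
      n_bins = n_bins,
      assignment = tibble::tibble(
        rsid = snps$rsid, maf = snps$maf, bin = bin
      )
    ),
    class = "maf_bins"
  )
}

#' @export
print.maf_bins <- function(x, ...) {
  cat(sprintf(
    "<maf_bins> %d SNPs in %d bins of width %g\n",
    nrow(x$assignment), x$n_bins, x$width
  ))
  print(bin_counts(x))
  invisible(x)
}

#' Per-bin SNP counts of a `maf_bins` object
#'
#' @param bins A `maf_bins` object.
#' @return A tibble with columns `bin` and `n` (bins with zero SNPs omitted).
#' @export
bin_counts <- function(bins) {
  stopifnot(inherits(bins, "maf_bins"))
  dplyr::count(bins$assignment, .data$bin, name = "n")
}

#' Restrict a `maf_bins` object to a subset of SNPs
#'
#' @param bins A `maf_bins` object.
#' @param rsids Character vector of SNPs to keep; rsids absent from the
#'   assignment are dropped with a message.
#' @return A `maf_bins` object over the intersection.
#' @export
subset_bins <- function(bins, rsids) {
  stopifnot(inherits(bins, "maf_bins"))
  keep <- bins$assignment$rsid %in% rsids
  n_missing <- length(setdiff(rsids, bins$assignment$rsid))
  if (n_missing > 0) {
    inform(sprintf(
      "subset_bins: %d rsid(s) have no MAF-bin assignment and were dropped",
      n_missing
    ))
  }
  structure(
    list(
      width = bins$width, n_bins = bins$n_bins,
      assignment = bins$assignment[keep, , drop = FALSE]
    ),
    class = "maf_bins"
  )
}

#' Draw MAF-matched SNP sets without replacement
#'
#' Generates `n_reps` random SNP sets from the pool so that every replicate
#' reproduces the target set's per-bin counts exactly: in each frequency bin
#' the replicate holds as many pool SNPs as the target does, drawn uniformly
#' without replacement within the replicate. Across replicates SNPs may
#' recur; each replicate is an independent fresh draw on its own RNG
#' substream, so replicate `i` is identical for a given `seed` regardless of
#' how many replicates are requested.
#'
#' @param pool_bins,target_bins `maf_bins` objects for the sampling pool and
#'   the target set. Both must use the same bin width.
#' @param n_reps Number of replicate sets.
#' @param seed Integer seed.
#' @return A list of `n_reps` character vectors of rsids.
#' @export
matched_sample <- function(pool_bins, target_bins, n_reps, seed) {
  stopifnot(
    inherits(pool_bins, "maf_bins"), inherits(target_bins, "maf_bins"),
    n_reps >= 1
  )
  if (!isTRUE(all.equal(pool_bins$width, target_bins$width))) {
    abort("matched_sample: pool and target bin widths differ",
      class = "eqtlenrich_validation_error"
    )
  }
  need <- bin_counts(target_bins)
  pool_by_bin <- split(
    pool_bins$assignment$rsid,
    factor(pool_bins$assignment$bin, levels = need$bin)
  )
  have <- vapply(pool_by_bin, length, integer(1))
  short <- which(have < need$n)
  if (length(short) > 0) {
    abort(sprintf(
      "matched_sample: pool bin %d holds %d SNP(s) but target requires %d",
      need$bin[short[1]], have[short[1]], need$n[short[1]]
    ), class = "eqtlenrich_infeasible_error")
  }
  seeds <- substream_seeds(seed, n_reps)
  k <- need$n
  lapply(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    unlist(
      lapply(seq_along(pool_by_bin), function(b) {
        sample_vec(pool_by_bin[[b]], k[b])
      }),
      use.names = FALSE
    )
  })
}
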