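#' Classify SNP-gene pairs as cis or trans
#'
#' A SNP is cis to a gene when it lies on the same chromosome within a fixed
#' window (default 4 Mb) of the gene's boundaries; the distance is zero for a
#' SNP inside the gene, and the window boundary is inclusive. Everything else
#' — farther away, or on another chromosome — is trans.
#'
#' @param snp_chrom,snp_pos Chromosome label and 1-based position of the
#'   SNP(s); vectors are recycled per usual rules.
#' @param gene_chrom,gene_start,gene_end Gene coordinates, 1-based inclusive.
#' @param window Cis window in base pairs (default 4e6).
#' @return Character vector of `"cis"` / `"trans"`.
#' @examples
#' classify_cis_trans("1", 1e6, "1", 4.9e6, 5e6) # "cis": 3.9 Mb away
#' classify_cis_trans("1", 1e6, "2", 4.9e6, 5e6) # "trans": other chromosome
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                               gene_end, window = 4e6) {
  stopifnot(window > 0)
  d <- pmax(gene_start - snp_pos, snp_pos - gene_end, 0)
  ifelse(snp_chrom == gene_chrom & d <= window, "cis", "trans")
}

# All SNP x gene pairs within the cis window, via a per-chromosome join.
# Returns tibble(rsid, gene_id).
cis_pairs <- function(snps, genes, window = 4e6) {
  assert_columns(snps, c("rsid", "chrom", "pos"), "snps")
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  dplyr::inner_join(
    dplyr::select(snps, "rsid", "chrom", "pos"),
    dplyr::select(genes, "gene_id", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(
      pmax(.data$start - .data$pos, .data$pos - .data$end, 0) <= window
    ) |>
    dplyr::select("rsid", "gene_id")
}

#' Count genes in each SNP's cis window
#'
#' @param snps Data frame with `rsid`, `chrom`, `pos`.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window Cis window in base pairs.
#' @return A tibble `rsid`, `n_c` covering every SNP (zero when no gene is
#'   within the window).
#' @export
cis_gene_counts <- function(snps, genes, window = 4e6) {
  counts <- cis_pairs(snps, genes, window) |>
    dplyr::distinct() |>
    dplyr::count(.data$rsid, name = "n_c")
  tibble::tibble(rsid = snps$rsid) |>
    dplyr::left_join(counts, by = "rsid") |>
    dplyr::mutate(n_c = dplyr::coalesce(.data$n_c, 0L))
}

#' Digest an eQTL association table into per-SNP summaries
#'
#' For every panel SNP this computes the quantities the eQTL function score
#' is built from: the smallest cis p-value `p_c` (kept only when below the
#' cis storage truncation), the overall smallest p-value `p_o` (minimum over
#' cis signals below the cis truncation and trans signals below the trans
#' truncation — it can come from either side), the cis Bonferroni denominator
#' `n_c`, and the total number of transcripts `n_o`. Optionally it also
#' counts, per threshold, the distinct transcripts a SNP regulates (used for
#' master-regulator calls).
#'
#' @param associations Data frame with `rsid`, `gene_id`, `p` (one row per
#'   SNP-transcript association).
#' @param genes Gene coordinates (`gene_id`, `chrom`, `start`, `end`); every
#'   `gene_id` in `associations` must resolve here.
#' @param snps SNP panel (`rsid`, `chrom`, `pos`); every association `rsid`
#'   must resolve here.
#' @param n_total Total number of transcripts used in the underlying eQTL
#'   study — the trans Bonferroni denominator (13080 for the LCL exon-array
#'   study these tables usually come from).
#' @param cis_trunc,trans_trunc Storage truncations for cis (default 0.01)
#'   and trans (default 1e-4) signals.
#' @param mr_thresholds P-value thresholds at which to count distinct target
#'   transcripts (default none). Required for [is_master_regulator()].
#' @param window Cis window in base pairs.
#' @param cis_mode `"annotated"` (default): `n_c` counts all genes within the
#'   SNP's cis window, reflecting the number of cis tests performed;
#'   `"observed"`: count only genes with an observed cis association row.
#' @return A tibble with one row per panel SNP: `rsid`, `p_min` (smallest
#'   untruncated association p, `NA` if none), `p_c`, `p_o`, `n_c`, `n_o`,
#'   and `targets_at` (list-column of named integer vectors keyed by
#'   threshold) when `mr_thresholds` is non-empty.
#' @export
summarize_eqtls <- function(associations, genes, snps, n_total = 13080L,
                            cis_trunc = 0.01, trans_trunc = 1e-4,
                            mr_thresholds = NULL, window = 4e6,
                            cis_mode = c("annotated", "observed")) {
  cis_mode <- match.arg(cis_mode)
  assert_columns(associations, c("rsid", "gene_id", "p"), "associations")
  stopifnot(n_total >= 1)
  bad_genes <- setdiff(associations$gene_id, genes$gene_id)
  if (length(bad_genes) > 0) {
    abort(sprintf(
      "summarize_eqtls: unresolvable gene_id(s): %s",
      paste(head(bad_genes, 5), collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }
  bad_snps <- setdiff(associations$rsid, snps$rsid)
  if (length(bad_snps) > 0) {
    abort(sprintf(
      "summarize_eqtls: association rsid(s) absent from panel: %s",
      paste(head(bad_snps, 5), collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }

  assoc <- associations |>
    dplyr::inner_join(
      dplyr::select(snps, "rsid", snp_chrom = "chrom", pos = "pos"),
      by = "rsid"
    ) |>
    dplyr::inner_join(
      dplyr::select(genes, "gene_id",
        gene_chrom = "chrom", start = "start", end = "end"
      ),
      by = "gene_id"
    ) |>
    dplyr::mutate(class = classify_cis_trans(
      .data$snp_chrom, .data$pos, .data$gene_chrom,
      .data$start, .data$end, window
    ))

  per_snp <- assoc |>
    dplyr::mutate(
      p_cis = ifelse(.data$class == "cis", .data$p, Inf),
      p_surv = ifelse(
        (.data$class == "cis" & .data$p < cis_trunc) |
          (.data$class == "trans" & .data$p < trans_trunc),
        .data$p, Inf
      )
    ) |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      p_min = min(.data$p),
      p_c = min(.data$p_cis),
      p_o = min(.data$p_surv),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_c = ifelse(.data$p_c < cis_trunc, .data$p_c, NA_real_),
      p_o = ifelse(is.finite(.data$p_o), .data$p_o, NA_real_)
    )

  if (cis_mode == "annotated") {
    nc <- cis_gene_counts(snps, genes, window)
  } else {
    nc <- assoc |>
      dplyr::filter(.data$class == "cis") |>
      dplyr::distinct(.data$rsid, .data$gene_id) |>
      dplyr::count(.data$rsid, name = "n_c")
    nc <- tibble::tibble(rsid = snps$rsid) |>
      dplyr::left_join(nc, by = "rsid") |>
      dplyr::mutate(n_c = dplyr::coalesce(.data$n_c, 0L))
  }

  out <- tibble::tibble(rsid = snps$rsid) |>
    dplyr::left_join(per_snp, by = "rsid") |>
    dplyr::left_join(nc, by = "rsid") |>
    dplyr::mutate(n_o = as.integer(n_total))

  if (length(mr_thresholds) > 0) {
    keys <- fmt_threshold(mr_thresholds)
    tab <- split(assoc[c("gene_id", "p")], assoc$rsid)
    empty <- setNames(integer(length(keys)), keys)
    out$targets_at <- lapply(out$rsid, function(id) {
      rows <- tab[[id]]
      if (is.null(rows)) {
        return(empty)
      }
      setNames(vapply(
        mr_thresholds,
        function(t) length(unique(rows$gene_id[rows$p < t])),
        integer(1)
      ), keys)
    })
  }
  out
}

#' Compute the eQTL function score
#'
#' A one-dimensional, non-negative summary of a SNP's eQTL evidence built on
#' Bonferroni corrections applied separately to the cis and overall (trans-
#' capable) signals:
#' \deqn{S = \max(0,\; -\log_{10}(\min(1, p_c N_c)),\;
#'               -\log_{10}(\min(1, p_o N_o)))}
#' where \eqn{p_c} is the smallest cis p-value and \eqn{N_c} the number of
#' cis transcripts (the cis tests performed), \eqn{p_o} the overall smallest
#' p-value and \eqn{N_o} the total transcript count. A missing signal
#' contributes zero, and scores are truncated at zero, so `score > 3` means
#' some Bonferroni-corrected p-value is below 1e-3.
#'
#' @param summaries A tibble from [summarize_eqtls()] (columns `rsid`, `p_c`,
#'   `p_o`, `n_c`, `n_o`).
#' @return A tibble `rsid`, `cis_component`, `trans_component`, `score` with
#'   `score = max(0, cis_component, trans_component)`.
#' @export
compute_score <- function(summaries) {
  assert_columns(summaries, c("rsid", "p_c", "p_o", "n_c", "n_o"), "summaries")
  if (any(summaries$n_o <= 0)) {
    abort("compute_score: n_o must be positive",
      class = "eqtlenrich_validation_error"
    )
  }
  cis <- ifelse(
    !is.na(summaries$p_c) & summaries$n_c >= 1,
    -log10(pmin(1, summaries$p_c * summaries$n_c)),
    0
  )
  trans <- ifelse(
    !is.na(summaries$p_o),
    -log10(pmin(1, summaries$p_o * summaries$n_o)),
    0
  )
  tibble::tibble(
    rsid = summaries$rsid,
    cis_component = pmax(cis, 0),
    trans_component = pmax(trans, 0),
    score = pmax(0, cis, trans)
  )
}

#' Is a SNP an eQTL at a threshold?
#'
#' A SNP is called an eQTL when its smallest association p-value is strictly
#' below the threshold.
#'
#' @param summaries A tibble from [summarize_eqtls()].
#' @param threshold P-value threshold in (0, 1\].
#' @return Logical vector aligned with the rows of `summaries`; SNPs with no
#'   associations are `FALSE`.
#' @export
is_eqtl <- function(summaries, threshold) {
  assert_columns(summaries, c("rsid", "p_min"), "summaries")
  stopifnot(threshold > 0, threshold <= 1)
  !is.na(summaries$p_min) & summaries$p_min < threshold
}

#' Is a SNP a master regulator?
#'
#' Master regulators (eQTL hot spots) are SNPs that regulate at least
#' `n_targets` distinct transcripts at the given association p-value
#' threshold.
#'
#' @param summaries A tibble from [summarize_eqtls()] built with
#'   `mr_thresholds` including `threshold`.
#' @param n_targets Minimum number of distinct target transcripts
#'   (inclusive); conventional values are 10, 50, 100, 1000.
#' @param threshold Association p-value threshold (strict `<` per target).
#' @return Logical vector aligned with the rows of `summaries`.
#' @export
is_master_regulator <- function(summaries, n_targets = 10, threshold) {
  assert_columns(summaries, c("rsid", "targets_at"), "summaries")
  stopifnot(n_targets >= 1)
  key <- fmt_threshold(threshold)
  first <- summaries$targets_at[[1]]
  if (!key %in% names(first)) {
    abort(sprintf(
      "is_master_regulator: summaries were not built with mr_threshold %s (have: %s)",
      key, paste(names(first), collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }
  vapply(
    summaries$targets_at, function(x) x[[key]] >= n_targets, logical(1)
  )
}
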