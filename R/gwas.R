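#' Quality-control filter for GWAS summary records
#'
#' Keeps records with less than `max_missing` missing data, MAF at or above
#' `min_maf`, and a non-empty rsid. The filter is idempotent; per-reason
#' exclusion counts are reported and stored in the `"qc_log"` attribute.
#'
#' @param gwas Data frame of GWAS records (`rsid`, `chrom`, `p`, `maf`,
#'   `missing_rate`).
#' @param max_missing Exclusive upper bound on missingness (default 0.05).
#' @param min_maf Inclusive lower bound on MAF (default 0.01).
#' @return The filtered tibble.
#' @export
qc_filter <- function(gwas, max_missing = 0.05, min_maf = 0.01) {
  assert_columns(gwas, c("rsid", "maf", "missing_rate"), "gwas")
  fail_missing <- !(gwas$missing_rate < max_missing)
  fail_maf <- !(gwas$maf >= min_maf)
  fail_rsid <- is.na(gwas$rsid) | gwas$rsid == ""
  keep <- !(fail_missing | fail_maf | fail_rsid)
  log <- c(
    high_missing = sum(fail_missing), low_maf = sum(fail_maf),
    no_rsid = sum(fail_rsid), kept = sum(keep)
  )
  inform(sprintf(
    "qc_filter: kept %d / %d (dropped %d for missingness >= %g, %d for MAF < %g, %d with no rsid)",
    log[["kept"]], nrow(gwas), log[["high_missing"]], max_missing,
    log[["low_maf"]], min_maf, log[["no_rsid"]]
  ))
  out <- tibble::as_tibble(gwas)[keep, , drop = FALSE]
  attr(out, "qc_log") <- log
  out
}

#' Remove all records on one chromosome
#'
#' A sensitivity analysis: strong extended LD (notably around the MHC on
#' chromosome 6) can dominate enrichment signals, so analyses are repeated
#' with that chromosome excluded.
#'
#' @param gwas Data frame with a `chrom` column.
#' @param chrom Chromosome label to drop (default `"6"`).
#' @return The tibble without records on `chrom`.
#' @export
exclude_chromosome <- function(gwas, chrom = "6") {
  assert_columns(gwas, "chrom", "gwas")
  drop <- gwas$chrom == chrom
  inform(sprintf(
    "exclude_chromosome: removed %d record(s) on chromosome %s",
    sum(drop), chrom
  ))
  tibble::as_tibble(gwas)[!drop, , drop = FALSE]
}

#' Proportion of sub-threshold associations within a functional class
#'
#' @param gwas Data frame with `rsid` and `p`.
#' @param classes Data frame with `rsid` and `function_class`.
#' @param cls Function class to query (e.g. `"nonsynonymous"`).
#' @param assoc_threshold Association p-value threshold (strict `<`).
#' @return The proportion of class members with `p < assoc_threshold`, or
#'   `NA` when the class has no members among the GWAS records (0/0 is
#'   undefined, not zero).
#' @export
class_proportion <- function(gwas, classes, cls, assoc_threshold = 0.01) {
  assert_columns(gwas, c("rsid", "p"), "gwas")
  assert_columns(classes, c("rsid", "function_class"), "classes")
  members <- dplyr::inner_join(
    dplyr::select(gwas, "rsid", "p"),
    dplyr::filter(classes, .data$function_class == cls),
    by = "rsid"
  )
  if (nrow(members) == 0) {
    inform(sprintf("class_proportion: no GWAS SNPs in class %s", cls))
    return(NA_real_)
  }
  mean(members$p < assoc_threshold)
}

new_bin_series <- function(series, ordering, bin_size, threshold, n_sims,
                           threshold_kind) {
  structure(
    list(
      series = series, ordering = ordering, bin_size = bin_size,
      threshold = threshold, threshold_kind = threshold_kind,
      n_sims = n_sims,
      last_bin_partial = series$n[nrow(series)] < bin_size
    ),
    class = "bin_series"
  )
}

#' @export
print.bin_series <- function(x, ...) {
  cat(sprintf(
    "<bin_series> %d bins of %d SNPs, ordered %s; counting %s\n",
    nrow(x$series), x$bin_size, x$ordering,
    switch(x$threshold_kind,
      assoc = sprintf("association p < %s", format(x$threshold)),
      score = sprintf("score > %s", format(x$threshold))
    )
  ))
  if (x$last_bin_partial) {
    cat(sprintf("  (final bin partial: %d SNPs)\n", x$series$n[nrow(x$series)]))
  }
  print(x$series, n = 13)
  invisible(x)
}

# Simulated 95% bands for the count of "hits" in a draw of size k without
# replacement. Within each stratum (a MAF bin, or the whole pool), the count
# in such a draw is hypergeometric; strata partition the pool and are drawn
# independently, so per-stratum hypergeometric draws summed over strata have
# exactly the law of the full matched draw.
#   strata: tibble with columns m (hits in stratum), n (stratum size),
#           k (draw size from stratum)
band_counts <- function(strata, n_sims) {
  sims <- rep(0, n_sims)
  for (i in seq_len(nrow(strata))) {
    sims <- sims + rhyper(
      n_sims, strata$m[i], strata$n[i] - strata$m[i], strata$k[i]
    )
  }
  sims
}

bin_band <- function(sims) {
  unname(quantile(sims, c(0.025, 0.975)))
}

# Core of both series: rank SNPs, cut into consecutive bins, count hits per
# bin, attach expectation and simulation bands.
rank_bin_series <- function(df, hit, bin_size, n_sims, seed, ordering,
                            threshold, threshold_kind, maf = NULL,
                            expectation = c("all", "remaining"),
                            maf_width = 0.05) {
  expectation <- match.arg(expectation)
  stopifnot(bin_size >= 1, n_sims >= 1)
  n <- nrow(df)
  total_hits <- sum(hit)
  bin <- (seq_len(n) - 1L) %/% bin_size
  series <- tibble::tibble(bin = bin, hit = hit) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(), count = sum(.data$hit), .groups = "drop"
    )
  series$expectation <- if (expectation == "all") {
    total_hits / n * series$n
  } else {
    (total_hits - series$count) / (n - series$n) * series$n
  }

  set.seed(as.integer(seed))
  if (is.null(maf)) {
    bands <- lapply(series$n, function(k) {
      bin_band(band_counts(
        tibble::tibble(m = total_hits, n = n, k = k), n_sims
      ))
    })
  } else {
    maf_bin <- pmin(
      as.integer(floor(maf / maf_width + 1e-12)),
      as.integer(ceiling(0.5 / maf_width - 1e-9)) - 1L
    )
    pool <- tibble::tibble(maf_bin = maf_bin, hit = hit) |>
      dplyr::group_by(.data$maf_bin) |>
      dplyr::summarise(
        m = sum(.data$hit), n = dplyr::n(), .groups = "drop"
      )
    bands <- lapply(split(maf_bin, bin), function(bins_here) {
      need <- as.data.frame(table(bins_here), stringsAsFactors = FALSE)
      names(need) <- c("maf_bin", "k")
      need$maf_bin <- as.integer(need$maf_bin)
      strata <- dplyr::inner_join(pool, need, by = "maf_bin")
      bin_band(band_counts(strata, n_sims))
    })
  }
  series$band_low <- vapply(bands, `[`, numeric(1), 1)
  series$band_high <- vapply(bands, `[`, numeric(1), 2)
  new_bin_series(series, ordering, bin_size, threshold, n_sims, threshold_kind)
}

#' Score-ordered bin series of GWAS association hits
#'
#' Ranks SNPs by eQTL function score (descending, ties broken by rsid),
#' cuts the ranking into consecutive bins of `bin_size`, and counts per bin
#' the SNPs with association `p < assoc_threshold`. If score carries no
#' information about the trait the counts should hover around the flat
#' expectation (the overall sub-threshold proportion times the bin size);
#' 95% bands come from `n_sims` simulated draws of each bin's size from the
#' full filtered SNP set, matched on MAF to the bin's SNPs (a high-scoring
#' bin is frequency-biased, so the null must be too).
#'
#' @param gwas QC-filtered GWAS records (`rsid`, `p`, and `maf` when
#'   `maf_matched`).
#' @param scores Data frame with `rsid` and the score column; GWAS records
#'   without a score are dropped with a message.
#' @param bin_size SNPs per bin (default 10000).
#' @param assoc_threshold Association p-value threshold (default 0.01,
#'   strict `<`).
#' @param n_sims Simulated draws per bin for the bands (default 100).
#' @param seed Integer seed for the band simulations.
#' @param maf_matched Match simulated draws on MAF (default `TRUE`).
#' @param expectation `"all"` (default): expectation from the sub-threshold
#'   proportion over all ranked SNPs; `"remaining"`: for each bin, from the
#'   SNPs outside that bin.
#' @param score_col Name of the score column in `scores` (default
#'   `"score"`); [cis_trans_split_series()] uses the component columns.
#' @return A `bin_series` object whose `series` tibble has columns `bin`
#'   (0-based), `n`, `count`, `expectation`, `band_low`, `band_high`.
#' @export
score_bin_series <- function(gwas, scores, bin_size = 10000,
                             assoc_threshold = 0.01, n_sims = 100, seed,
                             maf_matched = TRUE,
                             expectation = c("all", "remaining"),
                             score_col = "score") {
  assert_columns(gwas, c("rsid", "p"), "gwas")
  assert_columns(scores, c("rsid", score_col), "scores")
  if (maf_matched) assert_columns(gwas, "maf", "gwas")
  df <- dplyr::inner_join(
    tibble::as_tibble(gwas),
    dplyr::select(scores, "rsid", .score = dplyr::all_of(score_col)),
    by = "rsid"
  )
  n_dropped <- nrow(gwas) - nrow(df)
  if (n_dropped > 0) {
    inform(sprintf(
      "score_bin_series: %d GWAS SNP(s) without a score dropped", n_dropped
    ))
  }
  df <- dplyr::arrange(df, dplyr::desc(.data$.score), .data$rsid)
  rank_bin_series(
    df,
    hit = df$p < assoc_threshold, bin_size = bin_size, n_sims = n_sims,
    seed = seed, ordering = "by_score_desc", threshold = assoc_threshold,
    threshold_kind = "assoc", maf = if (maf_matched) df$maf else NULL,
    expectation = expectation
  )
}

#' Association-ordered bin series of high-scoring SNPs
#'
#' Ranks SNPs by GWAS association p-value (ascending, ties broken by rsid),
#' cuts the ranking into consecutive bins of `bin_size`, and counts per bin
#' the SNPs with eQTL function score strictly greater than
#' `score_threshold`. The expectation is the overall proportion of such
#' scores times the bin size; 95% bands come from `n_sims` random draws of
#' each bin's size from the full score list.
#'
#' @inheritParams score_bin_series
#' @param score_threshold Count SNPs with score strictly above this value
#'   (default 3, i.e. a Bonferroni-corrected p below 1e-3).
#' @return A `bin_series` object.
#' @export
assoc_bin_series <- function(gwas, scores, bin_size = 10000,
                             score_threshold = 3, n_sims = 100, seed,
                             score_col = "score") {
  assert_columns(gwas, c("rsid", "p"), "gwas")
  assert_columns(scores, c("rsid", score_col), "scores")
  df <- dplyr::inner_join(
    tibble::as_tibble(gwas),
    dplyr::select(scores, "rsid", .score = dplyr::all_of(score_col)),
    by = "rsid"
  )
  n_dropped <- nrow(gwas) - nrow(df)
  if (n_dropped > 0) {
    inform(sprintf(
      "assoc_bin_series: %d GWAS SNP(s) without a score dropped", n_dropped
    ))
  }
  df <- dplyr::arrange(df, .data$p, .data$rsid)
  rank_bin_series(
    df,
    hit = df$.score > score_threshold, bin_size = bin_size, n_sims = n_sims,
    seed = seed, ordering = "by_assoc_p_asc", threshold = score_threshold,
    threshold_kind = "score", maf = NULL
  )
}

#' Score-ordered bin series using only the cis or trans score component
#'
#' The eQTL function score blends cis and trans evidence, whose Bonferroni
#' adjustments differ. This reruns [score_bin_series()] ranking on one
#' component alone, to ask which side of the regulation carries an observed
#' enrichment.
#'
#' @inheritParams score_bin_series
#' @param score_records Output of [compute_score()] (needs `cis_component`
#'   and `trans_component`).
#' @param which `"cis"` or `"trans"`.
#' @param ... Passed on to [score_bin_series()].
#' @return A `bin_series` object.
#' @export
cis_trans_split_series <- function(gwas, score_records,
                                   which = c("cis", "trans"), ...) {
  which <- match.arg(which)
  col <- paste0(which, "_component")
  assert_columns(score_records, c("rsid", col), "score_records")
  score_bin_series(gwas, score_records, score_col = col, ...)
}
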