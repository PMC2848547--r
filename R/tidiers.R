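#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [enrichment_test()] or
#'   [master_regulator_enrichment()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic` (what was counted), `observed`,
#'   `null_mean`, `null_q025`, `null_q975`, `empirical_p`.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  q <- unname(quantile(x$null_counts, c(0.025, 0.975)))
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    null_mean = mean(x$null_counts),
    null_q025 = q[1],
    null_q975 = q[2],
    empirical_p = x$empirical_p
  )
}

#' Glance at an enrichment result
#'
#' @inheritParams tidy.enrichment_result
#' @return A one-row tibble of test metadata: `n_target`, `n_reps`,
#'   `eqtl_threshold`, `pool_name`, `empirical_p`.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_target = x$n_target,
    n_reps = x$n_reps,
    eqtl_threshold = x$eqtl_threshold,
    pool_name = x$pool_name,
    empirical_p = x$empirical_p
  )
}

#' Tidy a pruned-enrichment result
#'
#' @param x A `pruned_enrichment` from [pruned_enrichment()].
#' @param ... Unused.
#' @return A tibble with one row per LD-pruned set: `prune`, `n_retained`,
#'   `observed`, `null_mean`, `empirical_p`.
#' @method tidy pruned_enrichment
#' @export
tidy.pruned_enrichment <- function(x, ...) {
  purrr::map_dfr(seq_along(x$per_prune), function(j) {
    r <- x$per_prune[[j]]
    tibble::tibble(
      prune = j, n_retained = r$n_target, observed = r$observed,
      null_mean = mean(r$null_counts), empirical_p = r$empirical_p
    )
  })
}

#' Glance at a pruned-enrichment result
#'
#' @inheritParams tidy.pruned_enrichment
#' @return A one-row tibble: `n_prunes`, `r2_threshold`, `n_reps`,
#'   `median_empirical_p`, `max_empirical_p`.
#' @method glance pruned_enrichment
#' @export
glance.pruned_enrichment <- function(x, ...) {
  p <- vapply(x$per_prune, function(r) r$empirical_p, numeric(1))
  tibble::tibble(
    n_prunes = x$n_prunes,
    r2_threshold = x$r2_threshold,
    n_reps = x$per_prune[[1]]$n_reps,
    median_empirical_p = stats::median(p),
    max_empirical_p = max(p)
  )
}

#' Tidy a bin series
#'
#' @param x A `bin_series` from [score_bin_series()] or
#'   [assoc_bin_series()].
#' @param ... Unused.
#' @return The per-bin tibble: `bin`, `n`, `count`, `expectation`,
#'   `band_low`, `band_high`.
#' @method tidy bin_series
#' @export
tidy.bin_series <- function(x, ...) {
  x$series
}

#' Glance at a bin series
#'
#' @inheritParams tidy.bin_series
#' @return A one-row tibble: `n_bins`, `bin_size`, `ordering`, `threshold`,
#'   `n_sims`, `last_bin_partial`, `total_count`.
#' @method glance bin_series
#' @export
glance.bin_series <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$series),
    bin_size = x$bin_size,
    ordering = x$ordering,
    threshold = x$threshold,
    n_sims = x$n_sims,
    last_bin_partial = x$last_bin_partial,
    total_count = sum(x$series$count)
  )
}
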