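new_enrichment_result <- function(observed, null_counts, n_reps,
                                  eqtl_threshold, n_target, pool_name,
                                  statistic) {
  structure(
    list(
      observed = observed,
      null_counts = null_counts,
      empirical_p = mean(null_counts > observed),
      n_reps = n_reps,
      eqtl_threshold = eqtl_threshold,
      n_target = n_target,
      pool_name = pool_name,
      statistic = statistic
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  p_txt <- if (x$empirical_p == 0) {
    sprintf("< %s", format(1 / x$n_reps))
  } else {
    format(x$empirical_p)
  }
  cat(sprintf(
    "<enrichment_result> %s SNPs among %d targets\n", x$statistic, x$n_target
  ))
  cat(sprintf(
    "  observed %.0f; null mean %.1f (range %.0f-%.0f) over %d MAF-matched replicates\n",
    x$observed, mean(x$null_counts), min(x$null_counts), max(x$null_counts),
    x$n_reps
  ))
  cat(sprintf(
    "  empirical p %s (threshold %s, pool %s)\n",
    p_txt, format(x$eqtl_threshold), x$pool_name
  ))
  invisible(x)
}

# Shared engine: count flagged SNPs in the target and in each MAF-matched
# replicate drawn from the pool.
enrichment_engine <- function(target, pool_bins, flags, eqtl_threshold,
                              n_reps, seed, pool_name, statistic) {
  stopifnot(inherits(pool_bins, "maf_bins"), n_reps >= 1)
  target <- unique(target)
  in_pool <- target %in% pool_bins$assignment$rsid
  if (!all(in_pool)) {
    inform(sprintf(
      "%s: %d target SNP(s) without a MAF-bin assignment excluded",
      statistic, sum(!in_pool)
    ))
    target <- target[in_pool]
  }
  if (length(target) == 0) {
    abort("enrichment: empty target set after MAF filtering",
      class = "eqtlenrich_validation_error"
    )
  }
  target_bins <- subset_bins(pool_bins, target)
  flag_of <- function(ids) {
    f <- flags[match(ids, names(flags))]
    sum(f, na.rm = TRUE)
  }
  observed <- flag_of(target)
  replicates <- matched_sample(pool_bins, target_bins, n_reps, seed)
  null_counts <- vapply(replicates, flag_of, numeric(1))
  new_enrichment_result(
    observed, null_counts, n_reps, eqtl_threshold,
    length(target), pool_name, statistic
  )
}

#' MAF-matched resampling test for eQTL enrichment
#'
#' Tests whether a target SNP set (typically trait-associated catalog SNPs)
#' contains more eQTLs than expected given its minor-allele-frequency
#' distribution. `n_reps` random SNP sets of the same size and per-bin MAF
#' composition are drawn without replacement from the pool of typed SNPs;
#' the empirical p-value is the proportion of replicates whose eQTL count
#' strictly exceeds the observed count, so its granularity is `1 / n_reps`
#' and a reported 0 means "below `1 / n_reps`".
#'
#' @param target Character vector of target rsids (deduplicated; members
#'   without a MAF-bin assignment are excluded with a message).
#' @param pool_bins A [assign_maf_bins()] object over the sampling pool.
#' @param summaries Per-SNP eQTL summaries from [summarize_eqtls()]; pool
#'   SNPs absent from `summaries` count as non-eQTLs.
#' @param eqtl_threshold P-value threshold defining an eQTL (strict `<`).
#' @param n_reps Number of null replicates (default 1000).
#' @param seed Integer seed.
#' @param pool_name Label stored in the result (for reporting only).
#' @return An `enrichment_result` object; see [tidy.enrichment_result()].
#' @export
enrichment_test <- function(target, pool_bins, summaries, eqtl_threshold,
                            n_reps = 1000, seed, pool_name = "pool") {
  flags <- setNames(is_eqtl(summaries, eqtl_threshold), summaries$rsid)
  enrichment_engine(
    target, pool_bins, flags, eqtl_threshold, n_reps, seed,
    pool_name, "eQTL"
  )
}

#' MAF-matched resampling test for master-regulator enrichment
#'
#' Identical to [enrichment_test()] with the eQTL indicator replaced by the
#' master-regulator indicator: a SNP counts when it regulates at least
#' `n_targets` distinct transcripts at the threshold.
#'
#' @inheritParams enrichment_test
#' @inheritParams is_master_regulator
#' @return An `enrichment_result` object.
#' @export
master_regulator_enrichment <- function(target, pool_bins, summaries,
                                        n_targets = 10, eqtl_threshold,
                                        n_reps = 1000, seed,
                                        pool_name = "pool") {
  flags <- setNames(
    is_master_regulator(summaries, n_targets, eqtl_threshold),
    summaries$rsid
  )
  enrichment_engine(
    target, pool_bins, flags, eqtl_threshold, n_reps, seed,
    pool_name, sprintf("master-regulator(>=%d)", n_targets)
  )
}

#' Greedy LD pruning of a SNP set
#'
#' Walks the SNPs in order and keeps each one unless it is in linkage
#' disequilibrium (`r2 > threshold`) with an already-kept SNP. The result is
#' independent (no retained pair exceeds the threshold) and maximal (every
#' dropped SNP is linked to at least one retained SNP). Pairs absent from
#' `r2` are treated as unlinked (r2 = 0).
#'
#' @param rsids Ordered character vector of SNPs to prune.
#' @param r2 Data frame with columns `rsid_a`, `rsid_b`, `r2` (symmetric;
#'   either orientation suffices).
#' @param threshold Retain only pairs with `r2 <=` this value (default 0.3).
#' @param seed If non-`NULL`, randomize the keep-order first (the choice of
#'   which SNP of a correlated set survives is otherwise order-dependent).
#' @return Character vector of retained rsids (in the order walked).
#' @examples
#' r2 <- data.frame(
#'   rsid_a = c("a", "b"), rsid_b = c("b", "c"), r2 = c(0.5, 0.5)
#' )
#' ld_prune(c("a", "b", "c"), r2) # keeps a and c
#' @export
ld_prune <- function(rsids, r2, threshold = 0.3, seed = NULL) {
  assert_columns(r2, c("rsid_a", "rsid_b", "r2"), "r2")
  if (any(r2$r2 < 0 | r2$r2 > 1)) {
    abort("ld_prune: r2 values must lie in [0, 1]",
      class = "eqtlenrich_validation_error"
    )
  }
  rsids <- unique(rsids)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    rsids <- sample(rsids)
  }
  linked <- r2[r2$r2 > threshold &
    r2$rsid_a %in% rsids & r2$rsid_b %in% rsids, , drop = FALSE]
  nbr <- split(
    c(linked$rsid_b, linked$rsid_a),
    c(linked$rsid_a, linked$rsid_b)
  )
  kept <- character(0)
  kept_set <- new.env(parent = emptyenv(), size = length(rsids))
  for (id in rsids) {
    neighbours <- nbr[[id]]
    blocked <- FALSE
    for (nb in neighbours) {
      if (!is.null(kept_set[[nb]])) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) {
      kept <- c(kept, id)
      assign(id, TRUE, envir = kept_set)
    }
  }
  kept
}

#' Enrichment over repeated LD-pruned target sets
#'
#' Correlated catalog SNPs can carry the same signal several times; pruning
#' removes the redundancy, but which SNP of a correlated set survives is
#' arbitrary. This repeats the analysis over `n_prunes` independently
#' randomized prunes, running a MAF-matched enrichment test (with bins
#' recomputed from each pruned set) on every one, so the conclusion can be
#' checked for robustness to the pruning choice.
#'
#' @inheritParams enrichment_test
#' @inheritParams ld_prune
#' @param n_prunes Number of randomized LD-pruned sets (default 100).
#' @param n_reps Null replicates per pruned set (default 100).
#' @param r2_threshold LD pruning threshold (default 0.3).
#' @return A `pruned_enrichment` object: list with `per_prune` (one
#'   `enrichment_result` per pruned set), `n_prunes`, `r2_threshold`.
#' @export
pruned_enrichment <- function(target, pool_bins, summaries, r2,
                              eqtl_threshold, n_prunes = 100, n_reps = 100,
                              seed, r2_threshold = 0.3,
                              pool_name = "pool") {
  stopifnot(n_prunes >= 1)
  seeds <- substream_seeds(seed, 2 * n_prunes)
  per_prune <- lapply(seq_len(n_prunes), function(j) {
    pruned <- ld_prune(target, r2, r2_threshold, seed = seeds[2 * j - 1])
    enrichment_test(
      pruned, pool_bins, summaries, eqtl_threshold, n_reps,
      seed = seeds[2 * j], pool_name = pool_name
    )
  })
  structure(
    list(
      per_prune = per_prune, n_prunes = n_prunes,
      r2_threshold = r2_threshold
    ),
    class = "pruned_enrichment"
  )
}

#' @export
print.pruned_enrichment <- function(x, ...) {
  p <- vapply(x$per_prune, function(r) r$empirical_p, numeric(1))
  n <- vapply(x$per_prune, function(r) r$n_target, numeric(1))
  cat(sprintf(
    "<pruned_enrichment> %d LD-pruned sets (r2 <= %g), %d replicates each\n",
    x$n_prunes, x$r2_threshold, x$per_prune[[1]]$n_reps
  ))
  cat(sprintf(
    "  retained SNPs: median %d; empirical p: median %.3g (range %.3g-%.3g)\n",
    as.integer(stats::median(n)), stats::median(p), min(p), max(p)
  ))
  invisible(x)
}

#' Chi-square comparison of eQTL rates between two SNP subgroups
#'
#' Compares the proportion of eQTLs between two disjoint SNP subgroups
#' (e.g. SNPs from autoimmune-disorder studies versus all other catalog
#' SNPs) with a 1-df Pearson chi-square on the 2x2 table
#' `[[a, n_a - a], [b, n_b - b]]`, without continuity correction.
#'
#' @param a,n_a eQTL count and total for the first subgroup.
#' @param b,n_b eQTL count and total for the second subgroup.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `prop_a`,
#'   `prop_b`. A degenerate table (a zero margin) yields statistic 0 and p 1
#'   with a warning.
#' @examples
#' subgroup_chisq(17, 259, 29, 1339)
#' @export
subgroup_chisq <- function(a, n_a, b, n_b) {
  stopifnot(
    length(a) == 1, length(b) == 1, n_a >= 1, n_b >= 1,
    a >= 0, a <= n_a, b >= 0, b <= n_b
  )
  tab <- matrix(c(a, n_a - a, b, n_b - b), nrow = 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warn("subgroup_chisq: degenerate 2x2 table (zero margin); returning statistic 0, p 1")
    stat <- 0
    p <- 1
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  tibble::tibble(
    statistic = stat, df = 1L, p_value = p,
    prop_a = a / n_a, prop_b = b / n_b
  )
}
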