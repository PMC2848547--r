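# Minimal world where eQTL status is fully controlled: one MAF bin, `flags`
# says which pool SNPs are eQTLs.
flag_world <- function(n_pool, eqtl_idx) {
  pool <- tibble::tibble(
    rsid = sprintf("p%03d", seq_len(n_pool)),
    maf = runif(n_pool, 0.20, 0.249) # a single bin
  )
  summaries <- tibble::tibble(
    rsid = pool$rsid[eqtl_idx],
    p_min = 1e-9
  )
  list(pool = pool, bins = assign_maf_bins(pool), summaries = summaries)
}

test_that("empirical p counts strict exceedances of the observed count", {
  withr::local_seed(51)
  w <- flag_world(8, 1:4)
  res <- enrichment_test(w$pool$rsid[1:4], w$bins, w$summaries,
    eqtl_threshold = 1e-4, n_reps = 50, seed = 3
  )
  expect_equal(res$observed, 4)
  expect_true(all(res$null_counts <= 4))
  expect_equal(res$empirical_p, mean(res$null_counts > res$observed))
  expect_equal(res$empirical_p, 0) # nothing can exceed the maximum
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(tidy(res)$observed, 4)
  expect_equal(glance(res)$n_reps, 50)
})

test_that("null counts follow the exact hypergeometric law on one bin", {
  withr::local_seed(52)
  # pool of 4 with 2 eQTLs, target of size 2: null count ~ Hypergeom(4,2,2)
  w <- flag_world(4, 1:2)
  res <- enrichment_test(w$pool$rsid[1:2], w$bins, w$summaries,
    eqtl_threshold = 1e-4, n_reps = 6000, seed = 9
  )
  counts <- table(factor(res$null_counts, levels = 0:2))
  gof <- chisq.test(counts, p = dhyper(0:2, 2, 2, 2))
  expect_gt(gof$p.value, 0.01)
})

test_that("master-regulator enrichment is predicate substitution", {
  withr::local_seed(53)
  pool <- tibble::tibble(
    rsid = sprintf("p%03d", 1:40), maf = runif(40, 0, 0.5)
  )
  # every flagged SNP is both an eQTL and a 10-target master regulator
  flagged <- sample(pool$rsid, 15)
  summaries <- tibble::tibble(
    rsid = pool$rsid,
    p_min = ifelse(pool$rsid %in% flagged, 1e-9, 0.5),
    targets_at = lapply(pool$rsid, function(id) {
      c("0.0001" = if (id %in% flagged) 12L else 2L)
    })
  )
  bins <- assign_maf_bins(pool)
  target <- sample(pool$rsid, 12)
  a <- enrichment_test(target, bins, summaries, 1e-4, n_reps = 40, seed = 7)
  b <- master_regulator_enrichment(target, bins, summaries,
    n_targets = 10, eqtl_threshold = 1e-4, n_reps = 40, seed = 7
  )
  expect_equal(a$observed, b$observed)
  expect_equal(a$null_counts, b$null_counts)
  expect_equal(a$empirical_p, b$empirical_p)
})

test_that("degenerate master-regulator worlds give zero counts", {
  withr::local_seed(54)
  pool <- tibble::tibble(rsid = sprintf("p%02d", 1:20), maf = runif(20, 0, 0.5))
  summaries <- tibble::tibble(
    rsid = pool$rsid, p_min = 1e-9,
    targets_at = rep(list(c("0.0001" = 1L)), 20)
  )
  res <- master_regulator_enrichment(
    pool$rsid[1:5], assign_maf_bins(pool), summaries,
    n_targets = 10, eqtl_threshold = 1e-4, n_reps = 30, seed = 2
  )
  expect_equal(res$observed, 0)
  expect_true(all(res$null_counts == 0))
  expect_equal(res$empirical_p, 0)
})

test_that("raising the eQTL threshold never decreases the observed count", {
  withr::local_seed(55)
  pool <- tibble::tibble(rsid = sprintf("p%03d", 1:60), maf = runif(60, 0, 0.5))
  summaries <- tibble::tibble(
    rsid = pool$rsid, p_min = 10^-runif(60, 0, 9)
  )
  bins <- assign_maf_bins(pool)
  target <- sample(pool$rsid, 20)
  obs <- vapply(c(1e-8, 1e-6, 1e-4, 1e-2), function(thr) {
    enrichment_test(target, bins, summaries, thr, n_reps = 5, seed = 1)$observed
  }, numeric(1))
  expect_true(all(diff(obs) >= 0))
})

test_that("greedy LD pruning is independent and maximal", {
  r2 <- tibble::tibble(
    rsid_a = c("a", "b", "a"), rsid_b = c("b", "c", "c"),
    r2 = c(0.5, 0.5, 0.1)
  )
  expect_equal(ld_prune(c("a", "b", "c"), r2), c("a", "c"))
  # r2 at/below the threshold keeps both
  pair <- tibble::tibble(rsid_a = "a", rsid_b = "b", r2 = 0.2)
  expect_equal(ld_prune(c("a", "b"), pair), c("a", "b"))
  strong <- tibble::tibble(rsid_a = "a", rsid_b = "b", r2 = 0.9)
  expect_equal(ld_prune(c("a", "b"), strong), "a")
  # missing pairs are unlinked
  expect_equal(ld_prune(c("x", "y"), strong), c("x", "y"))
})

test_that("pruning postconditions hold on random graphs", {
  withr::local_seed(56)
  for (g in 1:200) {
    n <- sample(3:20, 1)
    r2 <- random_r2_graph(n, p_edge = runif(1, 0.05, 0.5))
    ids <- sprintf("s%02d", seq_len(n))
    kept <- ld_prune(ids, r2, threshold = 0.3, seed = g)
    linked <- r2[r2$r2 > 0.3, ]
    edge_key <- paste(linked$rsid_a, linked$rsid_b)
    # independence: no retained pair linked
    if (length(kept) > 1) {
      pairs <- t(utils::combn(sort(kept), 2))
      expect_false(any(paste(pairs[, 1], pairs[, 2]) %in% edge_key))
    }
    # maximality: every dropped SNP is linked to a retained one
    for (d in setdiff(ids, kept)) {
      nbrs <- c(
        linked$rsid_b[linked$rsid_a == d], linked$rsid_a[linked$rsid_b == d]
      )
      expect_true(any(nbrs %in% kept))
    }
  }
})

test_that("pruned enrichment recomputes bins per pruned set", {
  withr::local_seed(57)
  pool <- tibble::tibble(rsid = sprintf("p%03d", 1:80), maf = runif(80, 0, 0.5))
  summaries <- tibble::tibble(rsid = pool$rsid, p_min = 10^-runif(80, 0, 9))
  bins <- assign_maf_bins(pool)
  target <- sample(pool$rsid, 25)
  # unlinked target: pruning is the identity, results differ only by draws
  empty_r2 <- tibble::tibble(
    rsid_a = character(0), rsid_b = character(0), r2 = numeric(0)
  )
  pe <- pruned_enrichment(target, bins, summaries, empty_r2,
    eqtl_threshold = 1e-4, n_prunes = 4, n_reps = 20, seed = 11
  )
  expect_equal(
    unique(vapply(pe$per_prune, function(r) r$n_target, numeric(1))),
    25
  )
  expect_equal(
    unique(vapply(pe$per_prune, function(r) r$observed, numeric(1))),
    sum(summaries$p_min[summaries$rsid %in% target] < 1e-4)
  )
  # n_prunes = 1 is the ld_prune + enrichment_test composition
  r2 <- random_r2_graph(25)
  r2$rsid_a <- target[match(r2$rsid_a, sprintf("s%02d", 1:25))]
  r2$rsid_b <- target[match(r2$rsid_b, sprintf("s%02d", 1:25))]
  pe1 <- pruned_enrichment(target, bins, summaries, r2,
    eqtl_threshold = 1e-4, n_prunes = 1, n_reps = 15, seed = 13
  )
  seeds <- eqtlenrich:::substream_seeds(13, 2)
  pruned <- ld_prune(target, r2, 0.3, seed = seeds[1])
  direct <- enrichment_test(pruned, bins, summaries, 1e-4,
    n_reps = 15, seed = seeds[2]
  )
  expect_equal(pe1$per_prune[[1]]$null_counts, direct$null_counts)
  expect_equal(glance(pe1)$n_prunes, 1)
  expect_equal(nrow(tidy(pe1)), 1)
})

test_that("subgroup chi-square matches the closed form and handles degeneracy", {
  # equal rates: no association
  flat <- subgroup_chisq(10, 100, 20, 200)
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)

  # closed form N(ad - bc)^2 / (r1 r2 c1 c2) on [[20, 80], [10, 90]]
  got <- subgroup_chisq(20, 100, 10, 100)
  a <- 20; b <- 80; c <- 10; d <- 90; n <- 200
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got$statistic, stat, tolerance = 1e-12)
  expect_equal(got$statistic, 3.922, tolerance = 1e-3)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(got$p_value, 0.048, tolerance = 2e-2)

  expect_warning(deg <- subgroup_chisq(0, 10, 0, 10), "degenerate")
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
})
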