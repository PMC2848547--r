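test_that("cis/trans classification follows the 4 Mb inclusive window", {
  # 3.9 Mb upstream of the gene start: cis
  expect_equal(classify_cis_trans("1", 1e6, "1", 4.9e6, 5e6), "cis")
  # other chromosome: trans regardless of position
  expect_equal(classify_cis_trans("1", 1e6, "2", 4.9e6, 5e6), "trans")
  # exactly 4 Mb from the gene start: boundary is inclusive
  expect_equal(classify_cis_trans("1", 9e5, "1", 4.9e6, 5e6), "cis")
  expect_equal(classify_cis_trans("1", 9e5 - 1, "1", 4.9e6, 5e6), "trans")
  # inside the gene: distance zero
  expect_equal(classify_cis_trans("1", 4.95e6, "1", 4.9e6, 5e6), "cis")
})

test_that("cis/trans and summaries match brute-force enumeration", {
  withr::local_seed(31)
  for (world in 1:20) {
    layout <- random_layout(n_snps = 20, n_genes = 15)
    snps <- layout$snps
    genes <- layout$genes
    n_assoc <- sample(10:40, 1)
    assoc <- tibble::tibble(
      rsid = sample(snps$rsid, n_assoc, replace = TRUE),
      gene_id = sample(genes$gene_id, n_assoc, replace = TRUE),
      p = 10^-runif(n_assoc, 0, 9)
    )
    assoc <- dplyr::distinct(assoc, rsid, gene_id, .keep_all = TRUE)
    summ <- summarize_eqtls(assoc, genes, snps, n_total = 100,
      mr_thresholds = c(1e-4, 1e-2)
    )

    for (i in seq_len(nrow(snps))) {
      snp <- snps[i, ]
      rows <- assoc[assoc$rsid == snp$rsid, ]
      cls <- character(nrow(rows))
      for (j in seq_len(nrow(rows))) {
        gene <- genes[genes$gene_id == rows$gene_id[j], ]
        cls[j] <- brute_cis(snp, gene)
        expect_equal(
          classify_cis_trans(
            snp$chrom, snp$pos, gene$chrom, gene$start, gene$end
          ),
          cls[j]
        )
      }
      s <- summ[summ$rsid == snp$rsid, ]
      # n_c: genes whose window contains the SNP, association or not
      n_c <- 0
      for (g in seq_len(nrow(genes))) {
        if (brute_cis(snp, genes[g, ]) == "cis") n_c <- n_c + 1
      }
      expect_equal(s$n_c, n_c)
      # p_min, p_c, p_o by direct scan
      if (nrow(rows) == 0) {
        expect_true(is.na(s$p_min) && is.na(s$p_c) && is.na(s$p_o))
      } else {
        expect_equal(s$p_min, min(rows$p))
        pc <- rows$p[cls == "cis"]
        pc <- pc[pc < 0.01]
        expect_equal(s$p_c, if (length(pc)) min(pc) else NA_real_)
        surv <- c(pc, rows$p[cls == "trans"][rows$p[cls == "trans"] < 1e-4])
        expect_equal(s$p_o, if (length(surv)) min(surv) else NA_real_)
        for (thr in c(1e-4, 1e-2)) {
          expect_equal(
            s$targets_at[[1]][[fmt_threshold_for_test(thr)]],
            length(unique(rows$gene_id[rows$p < thr]))
          )
        }
      }
    }
  }
})

test_that("eQTL summary truncations drop weak signals", {
  snps <- toy_panel()
  genes <- toy_genes()
  # rs4 is cis to G2 (1 Mb away); a trans p of 0.5 survives nothing
  assoc <- tibble::tibble(rsid = "rs1", gene_id = "G2", p = 0.5)
  s <- summarize_eqtls(assoc, genes, snps, n_total = 100)
  row <- s[s$rsid == "rs1", ]
  expect_true(is.na(row$p_c))
  expect_true(is.na(row$p_o))
  expect_equal(row$p_min, 0.5) # untruncated minimum still recorded

  # cis 1e-5 and trans 1e-6: p_o takes the overall minimum
  assoc2 <- tibble::tibble(
    rsid = c("rs1", "rs1"), gene_id = c("G1", "G2"), p = c(1e-5, 1e-6)
  )
  s2 <- summarize_eqtls(assoc2, genes, snps, n_total = 100)
  row2 <- s2[s2$rsid == "rs1", ]
  expect_equal(row2$p_c, 1e-5)
  expect_equal(row2$p_o, 1e-6)

  expect_error(
    summarize_eqtls(
      tibble::tibble(rsid = "rs1", gene_id = "NOPE", p = 0.5),
      genes, snps
    ),
    "NOPE",
    class = "eqtlenrich_validation_error"
  )
})

test_that("the function score equals the Bonferroni formula and truncates at 0", {
  mk <- function(p_c, p_o, n_c, n_o = 13080L) {
    tibble::tibble(
      rsid = "x", p_min = p_o, p_c = p_c, p_o = p_o, n_c = n_c, n_o = n_o
    )
  }
  # no surviving signal
  expect_equal(compute_score(mk(NA, NA, 5))$score, 0)
  # worked case: cis side dominates
  sc <- compute_score(mk(1e-8, 1e-8, 50))
  expect_equal(sc$cis_component, -log10(5e-7), tolerance = 1e-12)
  expect_equal(sc$trans_component, -log10(1.308e-4), tolerance = 1e-12)
  expect_equal(sc$score, 6.301029995663981, tolerance = 1e-10)
  # corrected p of exactly 1 maps to score 0
  expect_equal(compute_score(mk(NA, 1 / 13080, 0))$score, 0)
})

test_that("eQTL and master-regulator calls use strict and inclusive bounds", {
  s <- tibble::tibble(
    rsid = c("a", "b", "c"),
    p_min = c(9.9e-5, 1e-4, NA),
    targets_at = list(
      c("0.0001" = 12L), c("0.0001" = 10L), c("0.0001" = 9L)
    )
  )
  expect_equal(is_eqtl(s, 1e-4), c(TRUE, FALSE, FALSE))
  expect_equal(is_master_regulator(s, 10, 1e-4), c(TRUE, TRUE, FALSE))
  expect_error(
    is_master_regulator(s, 10, 1e-6), "mr_threshold",
    class = "eqtlenrich_validation_error"
  )
})

test_that("score is monotone in its inputs", {
  withr::local_seed(41)
  base <- tibble::tibble(
    rsid = sprintf("s%04d", 1:2000),
    p_c = 10^-runif(2000, 2.1, 12),
    p_o = NA_real_,
    n_c = sample(1:200, 2000, replace = TRUE),
    n_o = 13080L
  )
  base$p_o <- base$p_c * runif(2000, 0.1, 1) # p_o <= p_c
  base$p_min <- base$p_o
  s0 <- compute_score(base)$score

  shrink <- base
  shrink$p_c <- shrink$p_c * runif(2000, 0.01, 1)
  shrink$p_o <- shrink$p_o * runif(2000, 0.01, 1)
  expect_true(all(compute_score(shrink)$score >= s0 - 1e-12))

  grow <- base
  grow$n_c <- grow$n_c + sample(1:100, 2000, replace = TRUE)
  expect_true(all(compute_score(grow)$score <= s0 + 1e-12))

  expect_true(all(s0 >= 0))
  # score > 3 iff some Bonferroni-corrected p < 1e-3
  corrected <- pmin(base$p_c * base$n_c, base$p_o * base$n_o)
  expect_equal(s0 > 3, corrected < 1e-3)
})

test_that("removing association rows never strengthens a summary", {
  withr::local_seed(42)
  layout <- random_layout(n_snps = 15, n_genes = 10)
  assoc <- tibble::tibble(
    rsid = sample(layout$snps$rsid, 60, replace = TRUE),
    gene_id = sample(layout$genes$gene_id, 60, replace = TRUE),
    p = 10^-runif(60, 0, 8)
  ) |> dplyr::distinct(rsid, gene_id, .keep_all = TRUE)
  full <- summarize_eqtls(assoc, layout$genes, layout$snps,
    n_total = 100, mr_thresholds = 1e-2
  )
  less <- summarize_eqtls(assoc[-sample(nrow(assoc), 5), ],
    layout$genes, layout$snps,
    n_total = 100, mr_thresholds = 1e-2
  )
  m <- dplyr::inner_join(full, less, by = "rsid", suffix = c("_f", "_l"))
  expect_true(all(is.na(m$p_min_l) | m$p_min_l >= m$p_min_f))
  expect_true(all(is.na(m$p_c_l) | m$p_c_l >= m$p_c_f))
  expect_true(all(is.na(m$p_o_l) | m$p_o_l >= m$p_o_f))
  t_f <- vapply(m$targets_at_f, `[[`, integer(1), 1)
  t_l <- vapply(m$targets_at_l, `[[`, integer(1), 1)
  expect_true(all(t_l <= t_f))
})
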