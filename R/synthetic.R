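#' Configuration for a synthetic eQTL/GWAS world
#'
#' Bundles and validates every generator parameter. The generator emulates
#' the statistical structure the pipeline is built to detect: a SNP panel
#' whose MAFs follow a Beta law scaled to \[0, 0.5\]; block-constant LD; a
#' planted subset of true cis-eQTLs (a fraction of them multi-target
#' hotspots) whose association p-values follow Beta(a, 1); a trait catalog
#' drawn with selection weight favouring eQTLs (factor `rho`) and common
#' alleles (exponent `maf_bias`, reproducing the common-allele shift of real
#' catalogs); and GWAS p-values whose true signals preferentially land on
#' eQTL SNPs (factor `kappa`). Setting `rho = 1` (or `kappa = 1`) gives the
#' exact null for the corresponding analysis.
#'
#' @param n_snps,n_genes,n_catalog Panel, gene and catalog sizes.
#' @param n_chrom Number of chromosomes the panel is laid out on.
#' @param maf_shape1,maf_shape2 Beta shape parameters; MAF = 0.5 * Beta.
#' @param ld_block_size SNPs per LD block (consecutive within chromosome).
#' @param within_block_r2 Pairwise r2 inside a block (0 between blocks).
#' @param f_cis_eqtl Fraction of SNPs that are true cis-eQTLs.
#' @param eqtl_p_shape Beta(a, 1) shape for true eQTL association p-values
#'   (a < 1 concentrates mass near 0).
#' @param lambda_targets Poisson mean for extra cis targets per true eQTL.
#' @param f_master Fraction of true eQTLs that are multi-target hotspots.
#' @param master_targets Base number of genome-wide targets per hotspot
#'   (actual count is `master_targets + Poisson(master_targets / 2)`).
#' @param rho Catalog selection weight multiplier for true eQTLs (1 = null).
#' @param maf_bias Exponent coupling catalog selection weight to MAF
#'   (0 = no frequency bias).
#' @param kappa GWAS weight multiplier: true trait SNPs are drawn with this
#'   extra weight on true eQTLs (1 = null).
#' @param n_true_trait Number of true trait-associated SNPs in the GWAS.
#' @param gwas_p_shape Beta(b, 1) shape for true trait-SNP p-values.
#' @param frac_blank_rsid Fraction of GWAS records with a blanked rsid
#'   (exercises QC).
#' @param cis_trunc,trans_trunc Storage truncations applied to the emitted
#'   eQTL table (only sub-truncation rows are kept, mirroring the truncated
#'   extracts real databases serve).
#' @param window Cis window in base pairs.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_snps = 5000, n_genes = 300, n_catalog = 300,
                             n_chrom = 22, maf_shape1 = 0.7,
                             maf_shape2 = 1.3, ld_block_size = 5,
                             within_block_r2 = 0.8, f_cis_eqtl = 0.2,
                             eqtl_p_shape = 0.1, lambda_targets = 1,
                             f_master = 0.02, master_targets = 40,
                             rho = 3, maf_bias = 1, kappa = 3,
                             n_true_trait = 100, gwas_p_shape = 0.01,
                             frac_blank_rsid = 0.005, cis_trunc = 0.01,
                             trans_trunc = 1e-4, window = 4e6, seed = 1) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    n_catalog = as.integer(n_catalog), n_chrom = as.integer(n_chrom),
    maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
    ld_block_size = as.integer(ld_block_size),
    within_block_r2 = within_block_r2, f_cis_eqtl = f_cis_eqtl,
    eqtl_p_shape = eqtl_p_shape, lambda_targets = lambda_targets,
    f_master = f_master, master_targets = master_targets,
    rho = rho, maf_bias = maf_bias, kappa = kappa,
    n_true_trait = as.integer(n_true_trait), gwas_p_shape = gwas_p_shape,
    frac_blank_rsid = frac_blank_rsid, cis_trunc = cis_trunc,
    trans_trunc = trans_trunc, window = window, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_snps >= 10, n_genes >= 1, n_catalog >= 1, n_chrom >= 1,
      maf_shape1 > 0, maf_shape2 > 0, ld_block_size >= 1,
      within_block_r2 >= 0, within_block_r2 <= 1,
      f_cis_eqtl >= 0, f_cis_eqtl <= 1, eqtl_p_shape > 0,
      lambda_targets >= 0, f_master >= 0, f_master <= 1,
      master_targets >= 1, rho >= 1, maf_bias >= 0, kappa >= 1,
      n_true_trait >= 0, n_true_trait <= n_snps, gwas_p_shape > 0,
      frac_blank_rsid >= 0, frac_blank_rsid < 1,
      cis_trunc > 0, cis_trunc <= 1, trans_trunc > 0,
      trans_trunc <= cis_trunc, window > 0
    )
  })
  if (cfg$n_catalog > cfg$n_snps) {
    abort("synthetic_config: n_catalog cannot exceed n_snps",
      class = "eqtlenrich_validation_error"
    )
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a complete synthetic world
#'
#' Produces every table the pipeline consumes — SNP panel, gene map, eQTL
#' association extract, pairwise r2 table, trait catalog, GWAS summary — plus
#' a truth record of the planted labels, all as a deterministic function of
#' the configuration (same config and seed give a bit-identical world).
#'
#' @param config A [synthetic_config()] object.
#' @return An `eqtl_world` list with elements `panel`, `genes`, `eqtl`,
#'   `r2`, `catalog`, `gwas`, `truth` (list of `eqtl_rsids`, `master_rsids`,
#'   `trait_rsids`) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  # --- panel: contiguous layout over chromosomes ---
  n <- cfg$n_snps
  rsid <- sprintf("rs%07d", seq_len(n))
  chrom <- as.character(rep_len(
    rep(seq_len(cfg$n_chrom), each = ceiling(n / cfg$n_chrom)), n
  ))
  chrom <- sort(chrom) # contiguous per chromosome, label order irrelevant
  spacing <- sample(2e3:8e4, n, replace = TRUE)
  pos <- stats::ave(spacing, chrom, FUN = cumsum)
  maf <- 0.5 * rbeta(n, cfg$maf_shape1, cfg$maf_shape2)
  platforms <- sample(
    c("affy6", "illumina1M", "affy6;illumina1M"), n,
    replace = TRUE, prob = c(0.25, 0.25, 0.5)
  )
  function_class <- sample(
    FUNCTION_CLASSES, n,
    replace = TRUE,
    prob = c(0.01, 0.01, 0.35, 0.55, 0.05, 0.03)
  )
  panel <- tibble::tibble(
    rsid = rsid, chrom = chrom, pos = as.numeric(pos), maf = maf,
    platforms = platforms, function_class = function_class
  )

  # --- genes: uniform over each chromosome's span ---
  chrom_len <- tapply(panel$pos, panel$chrom, max)
  gene_chrom <- sample(names(chrom_len), cfg$n_genes,
    replace = TRUE, prob = as.numeric(chrom_len)
  )
  gene_start <- floor(runif(cfg$n_genes, 1, chrom_len[gene_chrom]))
  gene_len <- sample(5e3:2e5, cfg$n_genes, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("GENE%05d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, start = gene_start, end = gene_start + gene_len
  )

  # --- planted cis-eQTLs and hotspots ---
  all_cis <- cis_pairs(panel, genes, cfg$window)
  cis_by_snp <- split(all_cis$gene_id, all_cis$rsid)
  eligible <- names(cis_by_snp)
  n_eqtl <- min(round(cfg$f_cis_eqtl * n), length(eligible))
  eqtl_rsids <- if (n_eqtl > 0) sample(eligible, n_eqtl) else character(0)
  planted <- if (n_eqtl > 0) {
    n_avail <- lengths(cis_by_snp[eqtl_rsids])
    n_t <- pmin(1L + rpois(n_eqtl, cfg$lambda_targets), n_avail)
    tibble::tibble(
      rsid = rep(eqtl_rsids, n_t),
      gene_id = unlist(lapply(seq_len(n_eqtl), function(i) {
        sample_vec(cis_by_snp[[eqtl_rsids[i]]], n_t[i])
      }), use.names = FALSE)
    )
  } else {
    tibble::tibble(rsid = character(0), gene_id = character(0))
  }
  planted$p <- rbeta(nrow(planted), cfg$eqtl_p_shape, 1)

  n_master <- round(cfg$f_master * n_eqtl)
  master_rsids <- if (n_master > 0) sample(eqtl_rsids, n_master) else character(0)
  hotspot <- if (n_master > 0) {
    n_t <- cfg$master_targets + rpois(n_master, cfg$master_targets / 2)
    n_t <- pmin(n_t, cfg$n_genes)
    tibble::tibble(
      rsid = rep(master_rsids, n_t),
      gene_id = unlist(lapply(seq_len(n_master), function(i) {
        sample_vec(genes$gene_id, n_t[i])
      }), use.names = FALSE),
      p = rbeta(sum(n_t), cfg$eqtl_p_shape, 1)
    )
  } else {
    tibble::tibble(rsid = character(0), gene_id = character(0), p = numeric(0))
  }

  # --- background noise: uniform p over all pairs, emitted only below the
  #     storage truncations (simulated by thinning, never enumerating) ---
  n_cis_total <- nrow(all_cis)
  m_cis <- rbinom(1, n_cis_total, cfg$cis_trunc)
  noise_cis <- all_cis[sample_vec(seq_len(n_cis_total), m_cis), , drop = FALSE]
  noise_cis$p <- runif(m_cis, 0, cfg$cis_trunc)
  n_trans_total <- as.numeric(n) * cfg$n_genes - n_cis_total
  m_trans <- rbinom(1, n_trans_total, cfg$trans_trunc)
  noise_trans <- tibble::tibble(
    rsid = sample(panel$rsid, m_trans, replace = TRUE),
    gene_id = sample(genes$gene_id, m_trans, replace = TRUE),
    p = runif(m_trans, 0, cfg$trans_trunc)
  )

  eqtl <- dplyr::bind_rows(planted, hotspot, noise_cis, noise_trans) |>
    dplyr::inner_join(
      dplyr::select(panel, "rsid", snp_chrom = "chrom", pos = "pos"),
      by = "rsid"
    ) |>
    dplyr::inner_join(
      dplyr::select(genes, "gene_id",
        gene_chrom = "chrom", start = "start", end = "end"
      ),
      by = "gene_id"
    ) |>
    dplyr::mutate(trunc = ifelse(
      classify_cis_trans(
        .data$snp_chrom, .data$pos, .data$gene_chrom,
        .data$start, .data$end, cfg$window
      ) == "cis", cfg$cis_trunc, cfg$trans_trunc
    )) |>
    dplyr::filter(.data$p < .data$trunc) |>
    dplyr::group_by(.data$rsid, .data$gene_id) |>
    dplyr::summarise(p = min(.data$p), .groups = "drop") |>
    dplyr::arrange(.data$rsid, .data$gene_id)

  # --- block-constant LD ---
  r2 <- block_r2_table(panel, cfg$ld_block_size, cfg$within_block_r2)

  # --- trait catalog: weighted sampling without replacement ---
  is_true_eqtl <- panel$rsid %in% eqtl_rsids
  w <- ifelse(is_true_eqtl, cfg$rho, 1) * panel$maf^cfg$maf_bias
  catalog_rsids <- sample(panel$rsid, cfg$n_catalog, prob = w)
  disease_class <- sample(
    DISEASE_CLASSES, cfg$n_catalog,
    replace = TRUE, prob = c(0.2, 0.15, 0.1, 0.55)
  )
  catalog <- tibble::tibble(
    rsid = catalog_rsids,
    trait = paste0("trait_", sample(50, cfg$n_catalog, replace = TRUE)),
    disease_class = disease_class,
    reported_p = 10^-runif(cfg$n_catalog, 5, 20)
  ) |>
    dplyr::arrange(.data$rsid)

  # --- GWAS summary: true signals preferentially on eQTL SNPs ---
  w_trait <- ifelse(is_true_eqtl, cfg$kappa, 1)
  trait_rsids <- if (cfg$n_true_trait > 0) {
    sample(panel$rsid, cfg$n_true_trait, prob = w_trait)
  } else {
    character(0)
  }
  is_trait <- panel$rsid %in% trait_rsids
  gwas_p <- runif(n)
  gwas_p[is_trait] <- rbeta(sum(is_trait), cfg$gwas_p_shape, 1)
  gwas_p <- pmax(gwas_p, 1e-300) # keep within (0, 1]
  gwas_rsid <- panel$rsid
  blank <- runif(n) < cfg$frac_blank_rsid
  gwas_rsid[blank] <- ""
  gwas <- tibble::tibble(
    rsid = gwas_rsid, chrom = panel$chrom, p = gwas_p, maf = panel$maf,
    missing_rate = rbeta(n, 0.3, 15)
  )

  structure(
    list(
      panel = panel, genes = genes, eqtl = eqtl, r2 = r2,
      catalog = catalog, gwas = gwas,
      truth = list(
        eqtl_rsids = sort(eqtl_rsids),
        master_rsids = sort(master_rsids),
        trait_rsids = sort(trait_rsids)
      ),
      config = cfg
    ),
    class = "eqtl_world"
  )
}

# Pairwise r2 rows for consecutive blocks of `block_size` SNPs within each
# chromosome; between-block pairs are unlinked and omitted.
block_r2_table <- function(panel, block_size, r2_value) {
  if (block_size < 2 || r2_value == 0) {
    return(tibble::tibble(
      rsid_a = character(0), rsid_b = character(0), r2 = numeric(0)
    ))
  }
  idx <- stats::ave(
    seq_len(nrow(panel)), panel$chrom,
    FUN = function(i) (seq_along(i) - 1L) %/% block_size
  )
  members <- tibble::tibble(
    rsid = panel$rsid, block = paste(panel$chrom, idx, sep = ":")
  )
  out <- dplyr::inner_join(
    members, members,
    by = "block", suffix = c("_a", "_b"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$rsid_a < .data$rsid_b) |>
    dplyr::transmute(
      rsid_a = .data$rsid_a, rsid_b = .data$rsid_b, r2 = r2_value
    )
  dplyr::arrange(out, .data$rsid_a, .data$rsid_b)
}

#' @export
print.eqtl_world <- function(x, ...) {
  cat(sprintf(
    "<eqtl_world> %d SNPs, %d genes, %d eQTL rows, %d catalog SNPs (seed %d)\n",
    nrow(x$panel), nrow(x$genes), nrow(x$eqtl), nrow(x$catalog),
    x$config$seed
  ))
  cat(sprintf(
    "  planted: %d true eQTLs (%d hotspots), %d true trait SNPs; rho=%g kappa=%g\n",
    length(x$truth$eqtl_rsids), length(x$truth$master_rsids),
    length(x$truth$trait_rsids), x$config$rho, x$config$kappa
  ))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits every pipeline input dialect: panel TSV, genes BED, eQTL TSV,
#' catalog TSV, GWAS TSV, r2 TSV and a truth JSON. Reading the files back
#' through the `io_formats` readers reproduces the in-memory world; the
#' writers are deterministic, so the same world always produces byte-
#' identical files.
#'
#' @param world An `eqtl_world` from [generate_world()].
#' @param directory Output directory (created if needed).
#' @return Named character vector of the seven file paths, invisibly.
#' @export
world_to_files <- function(world, directory) {
  stopifnot(inherits(world, "eqtl_world"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    panel = file.path(directory, "panel.tsv"),
    genes = file.path(directory, "genes.bed"),
    eqtl = file.path(directory, "eqtl.tsv"),
    catalog = file.path(directory, "catalog.tsv"),
    gwas = file.path(directory, "gwas.tsv"),
    r2 = file.path(directory, "r2.tsv"),
    truth = file.path(directory, "truth.json")
  )
  readr::write_tsv(world$panel, paths[["panel"]], progress = FALSE)
  bed <- dplyr::transmute(world$genes,
    chrom = .data$chrom, start = .data$start - 1, end = .data$end,
    name = .data$gene_id
  )
  readr::write_tsv(bed, paths[["genes"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(world$eqtl, paths[["eqtl"]], progress = FALSE)
  readr::write_tsv(world$catalog, paths[["catalog"]], progress = FALSE)
  readr::write_tsv(world$gwas, paths[["gwas"]], progress = FALSE)
  readr::write_tsv(world$r2, paths[["r2"]], progress = FALSE)
  jsonlite::write_json(
    c(world$truth, list(config = unclass(world$config))),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a synthetic world back from disk
#'
#' Inverse of [world_to_files()], routing each file through its
#' `io_formats` reader.
#'
#' @param directory Directory written by [world_to_files()].
#' @return An `eqtl_world` list (the `config` element is a plain list).
#' @export
world_from_files <- function(directory) {
  truth <- jsonlite::read_json(
    file.path(directory, "truth.json"),
    simplifyVector = TRUE
  )
  structure(
    list(
      panel = read_panel(file.path(directory, "panel.tsv")),
      genes = read_genes(file.path(directory, "genes.bed")),
      eqtl = read_eqtl_table(file.path(directory, "eqtl.tsv")),
      r2 = read_r2_table(file.path(directory, "r2.tsv")),
      catalog = suppressMessages(
        read_catalog(file.path(directory, "catalog.tsv"))
      ),
      gwas = read_gwas_summary(file.path(directory, "gwas.tsv")),
      truth = truth[c("eqtl_rsids", "master_rsids", "trait_rsids")],
      config = truth$config
    ),
    class = "eqtl_world"
  )
}
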