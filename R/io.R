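#' @name io_formats
#' @title Readers and writers for the pipeline's flat-file tables
#'
#' @description
#' Every external table the pipeline touches is a tab-separated UTF-8 file
#' with a header row; lines starting with `#` are skipped. Readers validate
#' each record against its domain invariants and fail with the offending data
#' line number, so downstream modules only ever see clean tibbles. Gene
#' coordinates additionally accept BED (0-based half-open, converted on read
#' to 1-based inclusive).
#'
#' Tables and their columns:
#' \describe{
#'   \item{catalog}{`rsid`, `trait`, `disease_class`
#'     (autoimmune / cancer / neuro_psych / other), `reported_p`}
#'   \item{eqtl}{`rsid`, `gene_id`, `p` — one row per SNP-transcript
#'     association that survived the storage truncations}
#'   \item{gwas}{`rsid` (may be empty), `chrom`, `p`, `maf`, `missing_rate`}
#'   \item{panel}{`rsid`, `chrom`, `pos`, `maf`, `platforms`
#'     (`;`-separated platform names), `function_class`}
#'   \item{genes}{BED (`chrom`, `start`, `end`, `gene_id`) or a 1-based TSV
#'     with columns `gene_id`, `chrom`, `start`, `end`}
#'   \item{r2}{`rsid_a`, `rsid_b`, `r2` — symmetric pairwise linkage
#'     disequilibrium; absent pairs are treated as unlinked}
#' }
NULL

DISEASE_CLASSES <- c("autoimmune", "cancer", "neuro_psych", "other")
FUNCTION_CLASSES <- c(
  "nonsynonymous", "coding-synonymous", "intronic",
  "intergenic", "other", "unknown"
)

read_tsv_strict <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path),
      class = "eqtlenrich_io_error"
    )
  }
  df <- suppressWarnings(readr::read_tsv(path,
    comment = "#", col_types = col_types,
    progress = FALSE, na = character()
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "%s: %d malformed value(s), first at line %d (expected %s)",
      what, nrow(probs), probs$row[1], probs$expected[1]
    ), class = "eqtlenrich_parse_error")
  }
  assert_columns(df, names(col_types$cols), what)
  df
}

# line number of data row i in a headered TSV (1 header line, comments aside)
bad_rows_msg <- function(idx, n_show = 3) {
  lines <- idx + 1L
  shown <- paste(head(lines, n_show), collapse = ", ")
  if (length(lines) > n_show) shown <- paste0(shown, ", ...")
  sprintf("line%s %s", if (length(lines) > 1) "s" else "", shown)
}

validate_p <- function(p, what, allow_one = TRUE) {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: p-values must lie in (0, 1]; violation at %s",
      what, bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  invisible(p)
}

#' Read a trait-associated SNP catalog
#'
#' Reads an NHGRI-catalog-style table of SNPs reproducibly associated with
#' complex traits, keeps entries at or below the inclusion threshold, and
#' collapses duplicate rsids (first occurrence wins) so the catalog is a set
#' of unique SNPs.
#'
#' @param path Path to a TSV with columns `rsid`, `trait`, `disease_class`,
#'   `reported_p`.
#' @param inclusion_threshold Keep entries with `reported_p` at or below this
#'   value (default `1e-5`, the conventional catalog inclusion level).
#' @return A tibble with one row per unique rsid, columns `rsid`, `trait`,
#'   `disease_class`, `reported_p`. The number of collapsed duplicates is
#'   reported as a message and stored in the `"n_collapsed"` attribute.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "rsid\ttrait\tdisease_class\treported_p",
#'   "rs1\tCrohn's disease\tautoimmune\t1e-8",
#'   "rs2\theight\tother\t1e-6"
#' ), path)
#' read_catalog(path)
#' @export
read_catalog <- function(path, inclusion_threshold = 1e-5) {
  df <- read_tsv_strict(
    path,
    readr::cols(
      rsid = readr::col_character(),
      trait = readr::col_character(),
      disease_class = readr::col_character(),
      reported_p = readr::col_double()
    ),
    "catalog"
  )
  if (nrow(df) == 0) {
    return(structure(df, n_collapsed = 0L))
  }
  bad_class <- which(!df$disease_class %in% DISEASE_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf(
      "catalog: unknown disease_class %s at %s (expected one of %s)",
      df$disease_class[bad_class[1]], bad_rows_msg(bad_class),
      paste(DISEASE_CLASSES, collapse = ", ")
    ), class = "eqtlenrich_validation_error")
  }
  validate_p(df$reported_p, "catalog")
  df <- dplyr::filter(df, .data$reported_p <= inclusion_threshold)
  n_before <- nrow(df)
  df <- dplyr::distinct(df, .data$rsid, .keep_all = TRUE)
  n_collapsed <- n_before - nrow(df)
  if (n_collapsed > 0) {
    inform(sprintf("catalog: collapsed %d duplicate rsid(s)", n_collapsed))
  }
  structure(df, n_collapsed = n_collapsed)
}

#' Read a SNP-by-transcript eQTL association table
#'
#' @param path Path to a TSV with columns `rsid`, `gene_id`, `p`.
#' @return A tibble of validated associations (all p in (0, 1]).
#' @export
read_eqtl_table <- function(path) {
  df <- read_tsv_strict(
    path,
    readr::cols(
      rsid = readr::col_character(),
      gene_id = readr::col_character(),
      p = readr::col_double()
    ),
    "eqtl table"
  )
  if (nrow(df) > 0) validate_p(df$p, "eqtl table")
  df
}

#' Read GWAS summary statistics
#'
#' Rows are returned unfiltered; quality control is a separate, explicit step
#' ([qc_filter()]), so records with empty rsids, high missingness or low MAF
#' survive reading.
#'
#' @param path Path to a TSV with columns `rsid`, `chrom`, `p`, `maf`,
#'   `missing_rate`. `rsid` may be the empty string.
#' @return A tibble of validated records.
#' @export
read_gwas_summary <- function(path) {
  df <- read_tsv_strict(
    path,
    readr::cols(
      rsid = readr::col_character(),
      chrom = readr::col_character(),
      p = readr::col_double(),
      maf = readr::col_double(),
      missing_rate = readr::col_double()
    ),
    "gwas summary"
  )
  if (nrow(df) == 0) {
    return(df)
  }
  validate_p(df$p, "gwas summary")
  bad <- which(df$maf < 0 | df$maf > 0.5)
  if (length(bad) > 0) {
    abort(sprintf(
      "gwas summary: maf must lie in [0, 0.5]; violation at %s",
      bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  bad <- which(df$missing_rate < 0 | df$missing_rate > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "gwas summary: missing_rate must lie in [0, 1]; violation at %s",
      bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  df
}

#' Read a SNP panel table
#'
#' @param path Path to a TSV with columns `rsid`, `chrom`, `pos`, `maf`,
#'   `platforms`, `function_class`.
#' @return A tibble of validated panel records; rsids are unique.
#' @export
read_panel <- function(path) {
  df <- read_tsv_strict(
    path,
    readr::cols(
      rsid = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      maf = readr::col_double(),
      platforms = readr::col_character(),
      function_class = readr::col_character()
    ),
    "panel"
  )
  if (nrow(df) == 0) {
    return(df)
  }
  bad <- which(df$maf < 0 | df$maf > 0.5)
  if (length(bad) > 0) {
    abort(sprintf(
      "panel: maf must lie in [0, 0.5]; violation at %s", bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  bad <- which(df$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "panel: pos must be >= 1; violation at %s", bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  bad <- which(!df$function_class %in% FUNCTION_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf(
      "panel: unknown function_class %s at %s",
      df$function_class[bad[1]], bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  if (anyDuplicated(df$rsid)) {
    abort("panel: rsids must be unique", class = "eqtlenrich_validation_error")
  }
  df
}

#' Read gene coordinates
#'
#' Accepts either BED (columns chrom, start, end, name; 0-based half-open,
#' converted on read to 1-based inclusive) or a GFF-lite TSV with header
#' columns `gene_id`, `chrom`, `start`, `end` already 1-based inclusive.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"tsv"`; the default guesses from the file
#'   extension (`.bed` means BED, anything else means TSV).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive, `start <= end`).
#' @export
read_genes <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    df <- readr::read_tsv(path,
      comment = "#", progress = FALSE,
      col_names = c("chrom", "start", "end", "gene_id"),
      col_types = readr::cols(
        chrom = readr::col_character(),
        start = readr::col_double(),
        end = readr::col_double(),
        gene_id = readr::col_character()
      )
    )
    df <- dplyr::transmute(df,
      gene_id = .data$gene_id, chrom = .data$chrom,
      start = .data$start + 1, end = .data$end
    )
  } else {
    df <- read_tsv_strict(
      path,
      readr::cols(
        gene_id = readr::col_character(),
        chrom = readr::col_character(),
        start = readr::col_double(),
        end = readr::col_double()
      ),
      "genes"
    )
  }
  bad <- which(df$start > df$end | df$start < 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "genes: need 1 <= start <= end; violation at %s", bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  df
}

#' Read a pairwise r-squared table
#'
#' @param path Path to a TSV with columns `rsid_a`, `rsid_b`, `r2`.
#' @return A tibble of pairs with `r2` in \[0, 1\].
#' @export
read_r2_table <- function(path) {
  df <- read_tsv_strict(
    path,
    readr::cols(
      rsid_a = readr::col_character(),
      rsid_b = readr::col_character(),
      r2 = readr::col_double()
    ),
    "r2 table"
  )
  bad <- which(df$r2 < 0 | df$r2 > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "r2 table: r2 must lie in [0, 1]; violation at %s", bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  df
}

#' Read a PLINK-style .frq allele frequency table
#'
#' An optional MAF source: whitespace-delimited columns `CHR`, `SNP`, `A1`,
#' `A2`, `MAF`, `NCHROBS` as written by `plink --freq`.
#'
#' @param path Path to the .frq file.
#' @return A tibble with columns `rsid`, `chrom`, `maf`.
#' @export
read_frq <- function(path) {
  df <- readr::read_table(path,
    col_types = readr::cols(
      CHR = readr::col_character(), SNP = readr::col_character(),
      A1 = readr::col_character(), A2 = readr::col_character(),
      MAF = readr::col_double(), NCHROBS = readr::col_double()
    ), progress = FALSE
  )
  assert_columns(df, c("CHR", "SNP", "MAF"), ".frq")
  bad <- which(df$MAF < 0 | df$MAF > 0.5)
  if (length(bad) > 0) {
    abort(sprintf(
      ".frq: MAF must lie in [0, 0.5]; violation at %s", bad_rows_msg(bad)
    ), class = "eqtlenrich_validation_error")
  }
  dplyr::transmute(df, rsid = .data$SNP, chrom = .data$CHR, maf = .data$MAF)
}

#' Write a SNP score table
#'
#' Writes rsid / score / class records as TSV with scores rendered at fixed
#' six decimal places, so a write-read cycle round-trips exactly on the
#' rendered values.
#'
#' @param records A data frame with columns `rsid`, `score` and optionally
#'   `cis_component`, `trans_component`; scores must be finite and >= 0.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(records, path) {
  assert_columns(records, c("rsid", "score"), "score records")
  num_cols <- intersect(
    c("score", "cis_component", "trans_component"), names(records)
  )
  for (col in num_cols) {
    v <- records[[col]]
    if (any(!is.finite(v) | v < 0)) {
      abort(sprintf("score records: %s must be finite and >= 0", col),
        class = "eqtlenrich_validation_error"
      )
    }
  }
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    dplyr::across(dplyr::all_of(num_cols), ~ sprintf("%.6f", .x))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP score table written by [write_score_table()]
#'
#' @param path Path to the score TSV.
#' @return A tibble with `rsid`, `score` and any component columns.
#' @export
read_score_table <- function(path) {
  df <- readr::read_tsv(path,
    comment = "#", progress = FALSE,
    col_types = readr::cols(
      rsid = readr::col_character(),
      .default = readr::col_double()
    )
  )
  assert_columns(df, c("rsid", "score"), "score table")
  df
}
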