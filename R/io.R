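#' Read a cohort variant table
#'
#' Tab-separated layout shared by the scoring and burden modules (a
#' COSMIC-like export): columns `sample`, `gene`, `tumor_site`, `origin`,
#' `hgvs_p`. HGVS protein changes are parsed with [parse_hgvs()]; missense
#' rows gain `protein_pos`, `ref_aa`, `alt_aa`, and every row keeps its
#' `category` so non-missense rows still count toward mutation burden.
#'
#' @param path TSV path.
#' @return Tibble of variant records.
#' @export
read_variants_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    gene = readr::col_character(),
    tumor_site = readr::col_character(),
    origin = readr::col_character(),
    hgvs_p = readr::col_character()
  ))
  parsed <- parse_hgvs(raw$hgvs_p)
  dplyr::bind_cols(
    raw,
    parsed[, c("position", "ref_aa", "alt_aa", "category")]
  ) |>
    dplyr::rename(protein_pos = "position")
}

#' Write a cohort variant table
#'
#' Inverse of [read_variants_tsv()]; extra columns (scores, tiers) are
#' carried along so scored tables round-trip.
#'
#' @param variants Variants tibble (needs `sample`, `gene`, `tumor_site`,
#'   `origin`, `hgvs_p`).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read a gene CDS-length table
#'
#' Mirrors an Ensembl/BioMart "CDS Length" export: TSV with columns `gene`
#' and `cds_length_bp`.
#'
#' @param path TSV path.
#' @return Tibble with `gene`, `cds_length_bp`.
#' @export
read_gene_lengths_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    cds_length_bp = readr::col_integer()
  ))
}

#' Read a gene-age (phylostratum) table
#'
#' TSV with columns `gene` and `phylostratum` (integer 1-19; 1 = origin of
#' life, 19 = primates).
#'
#' @param path TSV path.
#' @return Tibble with `gene`, `phylostratum`.
#' @export
read_ages_tsv <- function(path) {
  ages <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    phylostratum = readr::col_integer()
  ))
  if (any(ages$phylostratum < 1 | ages$phylostratum > 19, na.rm = TRUE))
    stop("phylostrata must lie in 1..19", call. = FALSE)
  ages
}

#' Write a tier report (or any summary tibble) as JSON
#'
#' @param report Data frame, e.g. from [tier_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
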