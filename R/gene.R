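#' Construct a coding gene model
#'
#' Validates a coding sequence (CDS) and records its translation. The CDS
#' must have length divisible by 3, start with ATG, end in a single stop
#' codon, and contain no internal stop.
#'
#' @param symbol Gene symbol (opaque label).
#' @param cds Nucleotide string over ACGT, including the terminal stop codon.
#' @return An object of class `gene_model`: list with `symbol`, `cds`,
#'   `protein` (translation without the stop), `n_codons` (including stop).
#' @examples
#' gene_model("TOY", "ATGGCTTGA")
#' @export
gene_model <- function(symbol, cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("CDS length must be divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", cds))
    stop("CDS may only contain A, C, G, T", call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  if (codons[1] != "ATG")
    stop("CDS must start with ATG", call. = FALSE)
  if (aas[length(aas)] != "*")
    stop("CDS must end with a stop codon", call. = FALSE)
  if (any(aas[-length(aas)] == "*"))
    stop("CDS contains an internal stop codon", call. = FALSE)
  structure(
    list(symbol = symbol, cds = cds,
         protein = paste(aas[-length(aas)], collapse = ""),
         n_codons = length(codons)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$symbol, ": ", nchar(x$cds), " nt CDS, ",
      nchar(x$protein), " aa\n", sep = "")
  invisible(x)
}

#' Read coding sequences from FASTA into gene models
#'
#' One [gene_model()] per record; record ids become gene symbols.
#'
#' @param path CDS FASTA path.
#' @return Named list of `gene_model` objects.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  models <- purrr::map2(ids, as.character(set), gene_model)
  stats::setNames(models, ids)
}

#' Write gene-model CDS to FASTA
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  writeLines(unlist(lapply(genes, function(g) c(paste0(">", g$symbol),
                                                g$cds))), path)
  invisible(path)
}

#' Enumerate every single-nucleotide substitution of a CDS
#'
#' Every CDS nucleotide has 3 alternative bases, giving 9 SNV events per
#' codon; each event is classified by the standard genetic code as
#' `missense`, `synonymous`, or `nonsense` (events creating or destroying a
#' stop codon both fall in the nonsense class, so the three classes
#' partition all `9 * n_codons` events and stop codons yield no missense
#' rows).
#'
#' @param gene A [gene_model()].
#' @return An `action_table`: tibble with one row per SNV event and columns
#'   `gene`, `cds_pos`, `ref_nt`, `alt_nt`, `codon`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `class`. Attribute `class_counts` holds the event
#'   tally. Missense rows gain `s`, `m`, `r`, `ea` after [ea_score()].
#' @examples
#' enumerate_snvs(gene_model("TOY", "ATGTGA"))
#' @export
enumerate_snvs <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  nts <- strsplit(gene$cds, "")[[1]]
  L <- length(nts)
  bases <- c("A", "C", "G", "T")
  # 3 alternatives per position; 9 events per codon
  cds_pos <- rep(seq_len(L), each = 3)
  ref_nt <- nts[cds_pos]
  alt_nt <- unlist(lapply(nts, function(b) setdiff(bases, b)), use.names = FALSE)
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon_start <- (codon_idx - 1L) * 3L
  ref_codon <- paste0(nts[codon_start + 1L], nts[codon_start + 2L],
                      nts[codon_start + 3L])
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_nt
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  class <- dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    ref_aa == "*" | alt_aa == "*" ~ "nonsense",
    .default = "missense"
  )
  tab <- tibble::tibble(
    gene = gene$symbol,
    cds_pos = cds_pos,
    ref_nt = ref_nt,
    alt_nt = alt_nt,
    codon = codon_idx,
    protein_pos = ifelse(ref_aa == "*", NA_integer_, codon_idx),
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    class = class
  )
  counts <- table(factor(tab$class,
                         c("missense", "synonymous", "nonsense")))
  stopifnot(sum(counts) == 9L * gene$n_codons)
  attr(tab, "class_counts") <- c(counts)
  attr(tab, "gene_symbol") <- gene$symbol
  attr(tab, "protein") <- gene$protein
  class(tab) <- c("action_table", class(tibble::tibble()))
  tab
}

#' @export
print.action_table <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat("<action_table> ", attr(x, "gene_symbol"), ": ", nrow(x),
      " SNV events (", paste(names(cc), cc, sep = " ", collapse = ", "),
      ")", if ("ea" %in% names(x)) " [scored]", "\n", sep = "")
  NextMethod()
}
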