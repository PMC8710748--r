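#' Amino-acid alphabet used throughout
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order.
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein multiple alignment
#'
#' Bundles aligned amino-acid rows with the identity of the query (reference)
#' row and the map from alignment columns to 1-based query residue numbers.
#' Columns where the query is gapped carry no query position and are excluded
#' from trace output.
#'
#' @param sequences Named character vector of equal-length aligned rows over
#'   the 20 amino acids plus `"-"` for gaps.
#' @param query Index or name of the query row (default first row). The query
#'   row must contain no ambiguous characters.
#' @return An object of class `aa_msa`: a list with `ids`, `matrix` (rows x
#'   columns character matrix), `query_index`, and `query_pos` (integer vector
#'   over columns, `NA` where the query is gapped).
#' @examples
#' msa <- aa_msa(c(q = "MKV-", h = "MRVA"))
#' msa$query_pos
#' @export
aa_msa <- function(sequences, query = 1L) {
  if (length(sequences) < 1) stop("need at least one sequence", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("all aligned rows must have equal length", call. = FALSE)
  if (is.character(query)) query <- match(query, ids)
  query <- as.integer(query)
  if (is.na(query) || query < 1 || query > length(sequences))
    stop("query row not found", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), c(AA20, "-"))
  if (length(bad))
    stop("unexpected alignment characters: ", paste(bad, collapse = " "),
         call. = FALSE)
  qrow <- mat[query, ]
  query_pos <- rep(NA_integer_, ncol(mat))
  query_pos[qrow != "-"] <- seq_len(sum(qrow != "-"))
  structure(
    list(ids = ids, matrix = mat, query_index = query, query_pos = query_pos),
    class = "aa_msa"
  )
}

#' @export
print.aa_msa <- function(x, ...) {
  cat("<aa_msa> ", length(x$ids), " sequences x ", ncol(x$matrix),
      " columns; query = ", x$ids[x$query_index],
      " (", sum(!is.na(x$query_pos)), " residues)\n", sep = "")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param msa An [aa_msa()] object.
#' @return Integer count.
#' @export
n_sequences <- function(msa) length(msa$ids)

#' Read an aligned protein FASTA
#'
#' @param path Path to a FASTA file of equal-length aligned protein sequences
#'   (gap character `-`).
#' @param query Index or id of the query row (default 1).
#' @return An [aa_msa()] object.
#' @export
read_msa_fasta <- function(path, query = 1L) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  aa_msa(seqs, query = query)
}

#' Write an alignment to FASTA
#'
#' @param msa An [aa_msa()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  rows <- apply(msa$matrix, 1, paste, collapse = "")
  writeLines(paste0(">", msa$ids, "\n", rows), path)
  invisible(path)
}

#' Drop heavily gapped rows from an alignment
#'
#' Emulates selecting homologs with the fewest possible alignment gaps:
#' rows gapped at more than `max_gap_frac` of the query's residue columns are
#' removed. The query row is always kept.
#'
#' @param msa An [aa_msa()] object.
#' @param max_gap_frac Maximum tolerated fraction of gaps over query columns.
#' @return A filtered [aa_msa()] object.
#' @export
filter_gapped_rows <- function(msa, max_gap_frac = 0.5) {
  stopifnot(max_gap_frac >= 0, max_gap_frac <= 1)
  qcols <- which(!is.na(msa$query_pos))
  frac <- rowMeans(msa$matrix[, qcols, drop = FALSE] == "-")
  keep <- frac <= max_gap_frac
  keep[msa$query_index] <- TRUE
  seqs <- apply(msa$matrix[keep, , drop = FALSE], 1, paste, collapse = "")
  aa_msa(seqs, query = msa$ids[msa$query_index])
}

#' Ungapped query sequence of an alignment
#' @param msa An [aa_msa()] object.
#' @return Single protein string.
#' @export
msa_query_protein <- function(msa) {
  paste(msa$matrix[msa$query_index, msa$matrix[msa$query_index, ] != "-"],
        collapse = "")
}
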