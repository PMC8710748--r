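# BLOSUM62 log-odds over the 20 standard amino acids (integer half-bits),
# row/column order = AA20. Inlined as source so the package ships text-only.
BLOSUM62_ROWS <- c(
  "A  4 0 -2 -1 -2 0 -2 -1 -1 -1 -1 -2 -1 -1 -1 1 0 0 -3 -2",
  "C  0 9 -3 -4 -2 -3 -3 -1 -3 -1 -1 -3 -3 -3 -3 -1 -1 -1 -2 -2",
  "D -2 -3 6 2 -3 -1 -1 -3 -1 -4 -3 1 -1 0 -2 0 -1 -3 -4 -3",
  "E -1 -4 2 5 -3 -2 0 -3 1 -3 -2 0 -1 2 0 0 -1 -2 -3 -2",
  "F -2 -2 -3 -3 6 -3 -1 0 -3 0 0 -3 -4 -3 -3 -2 -2 -1 1 3",
  "G  0 -3 -1 -2 -3 6 -2 -4 -2 -4 -3 0 -2 -2 -2 0 -2 -3 -2 -3",
  "H -2 -3 -1 0 -1 -2 8 -3 -1 -3 -2 1 -2 0 0 -1 -2 -3 -2 2",
  "I -1 -1 -3 -3 0 -4 -3 4 -3 2 1 -3 -3 -3 -3 -2 -1 3 -3 -1",
  "K -1 -3 -1 1 -3 -2 -1 -3 5 -2 -1 0 -1 1 2 0 -1 -2 -3 -2",
  "L -1 -1 -4 -3 0 -4 -3 2 -2 4 2 -3 -3 -2 -2 -2 -1 1 -2 -1",
  "M -1 -1 -3 -2 0 -3 -2 1 -1 2 5 -2 -2 0 -1 -1 -1 1 -1 -1",
  "N -2 -3 1 0 -3 0 1 -3 0 -3 -2 6 -2 0 0 1 0 -3 -4 -2",
  "P -1 -3 -1 -1 -4 -2 -2 -3 -1 -3 -2 -2 7 -1 -2 -1 -1 -2 -4 -3",
  "Q -1 -3 0 2 -3 -2 0 -3 1 -2 0 0 -1 5 1 0 -1 -2 -2 -1",
  "R -1 -3 -2 0 -3 -2 0 -3 2 -2 -1 0 -2 1 5 -1 -1 -3 -3 -2",
  "S  1 -1 0 0 -2 0 -1 -2 0 -2 -1 1 -1 0 -1 4 1 -2 -3 -2",
  "T  0 -1 -1 -1 -2 -2 -2 -1 -1 -1 -1 0 -1 -1 -1 1 5 0 -2 -2",
  "V  0 -1 -3 -2 -1 -3 -3 3 -2 1 1 -3 -2 -2 -3 -2 0 4 -3 -1",
  "W -3 -2 -4 -3 1 -2 -2 -3 -3 -2 -1 -4 -4 -2 -3 -3 -2 -3 11 2",
  "Y -2 -2 -3 -2 3 -3 2 -1 -2 -1 -1 -2 -3 -1 -2 -2 -2 -1 2 7"
)

#' The BLOSUM62 amino-acid log-odds matrix
#'
#' Standard symmetric 20x20 integer substitution log-odds table used as the
#' default input to [severity_from_logodds()].
#'
#' @return Integer matrix with `AA20` row and column names.
#' @export
blosum62 <- function() {
  vals <- lapply(strsplit(trimws(BLOSUM62_ROWS), "\\s+"), function(x)
    as.integer(x[-1]))
  m <- do.call(rbind, vals)
  dimnames(m) <- list(AA20, AA20)
  stopifnot(isSymmetric(m))
  m
}

#' Substitution-severity magnitudes from a log-odds matrix
#'
#' Converts an amino-acid log-odds matrix into per-pair substitution
#' magnitudes `m[a, b]` in `[0, 1]` by row-wise min-max normalization over
#' the off-diagonal entries:
#' `m_ab = (max_c B(a,c) - B(a,b)) / (max_c B(a,c) - min_c B(a,c))`
#' (`c != a`). The most-favored substitution from each residue scores 0
#' (most conservative), the least-favored 1 (most radical), and the
#' diagonal is forced to 0. A constant row would be degenerate and maps to
#' 1 for all substitutions, with a warning.
#'
#' @param logodds Symmetric numeric 20x20 matrix with `AA20` dimnames
#'   (default [blosum62()]).
#' @return A `severity_matrix`: numeric 20x20 matrix of magnitudes.
#' @export
severity_from_logodds <- function(logodds = blosum62()) {
  stopifnot(is.matrix(logodds), nrow(logodds) == 20, ncol(logodds) == 20)
  if (!all(AA20 %in% rownames(logodds)) || !all(AA20 %in% colnames(logodds)))
    stop("log-odds matrix must be named by the 20 amino acids", call. = FALSE)
  logodds <- logodds[AA20, AA20]
  if (!isSymmetric(unname(logodds)))
    stop("log-odds matrix must be symmetric", call. = FALSE)
  m <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (a in AA20) {
    row <- logodds[a, setdiff(AA20, a)]
    hi <- max(row); lo <- min(row)
    if (hi == lo) {
      warning("constant log-odds row for ", a,
              "; all substitutions set to magnitude 1", call. = FALSE)
      m[a, setdiff(AA20, a)] <- 1
    } else {
      m[a, setdiff(AA20, a)] <- (hi - row) / (hi - lo)
    }
  }
  structure(m, class = c("severity_matrix", "matrix", "array"))
}
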