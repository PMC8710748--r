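AA3 <- c(Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F",
         Gly = "G", His = "H", Ile = "I", Lys = "K", Leu = "L",
         Met = "M", Asn = "N", Pro = "P", Gln = "Q", Arg = "R",
         Ser = "S", Thr = "T", Val = "V", Trp = "W", Tyr = "Y",
         Ter = "*")

#' Parse HGVS protein-change notation
#'
#' Accepts one-letter (`"L858P"`, `"p.L858P"`) and three-letter
#' (`"p.Trp803Arg"`) missense notation, normalized to one-letter form.
#' Non-missense notations are rejected with a category label so callers
#' can count them without scoring: `synonymous` (`p.L858=` or ref equal to
#' alt), `nonsense` (`*`/`Ter`/`X` alternate), `frameshift` (`fs`),
#' `indel` (`del`/`ins`/`dup`), and `unparsed` for anything else.
#'
#' @param x Character vector of HGVS protein strings.
#' @return Tibble with one row per input: `input`, `position`, `ref_aa`,
#'   `alt_aa`, `category` (`missense` or a rejection label), and `hgvs`
#'   (the normalized `p.<ref><pos><alt>` form for missense rows).
#' @examples
#' parse_hgvs(c("L858P", "p.Trp803Arg", "p.L858=", "p.Q23fs"))
#' @export
parse_hgvs <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  one <- "^(?:p\\.)?([A-Z])(\\d+)([A-Z])$"
  three <- "^(?:p\\.)?([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$"
  syn <- "^(?:p\\.)?(?:[A-Z*]|[A-Z][a-z]{2})(\\d+)=$"
  parse_one <- function(txt) {
    bad <- function(cat) tibble::tibble(
      input = txt, position = NA_integer_, ref_aa = NA_character_,
      alt_aa = NA_character_, category = cat, hgvs = NA_character_)
    if (grepl("fs", txt)) return(bad("frameshift"))
    if (grepl("del|ins|dup", txt)) return(bad("indel"))
    if (grepl(syn, txt)) return(bad("synonymous"))
    ref <- alt <- NA_character_; pos <- NA_integer_
    if (grepl(one, txt)) {
      m <- regmatches(txt, regexec(one, txt))[[1]]
      ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
      if (alt == "X" || ref == "X") return(bad("nonsense"))
      if (!(ref %in% AA20) || !(alt %in% AA20)) return(bad("unparsed"))
    } else if (grepl(three, txt)) {
      m <- regmatches(txt, regexec(three, txt))[[1]]
      if (m[2] == "Ter" || m[4] == "Ter") return(bad("nonsense"))
      if (!(m[2] %in% names(AA3)) || !(m[4] %in% names(AA3)))
        return(bad("unparsed"))
      ref <- AA3[[m[2]]]; pos <- as.integer(m[3]); alt <- AA3[[m[4]]]
    } else if (grepl("\\*", txt)) {
      return(bad("nonsense"))
    } else {
      return(bad("unparsed"))
    }
    if (ref == alt) return(bad("synonymous"))
    tibble::tibble(input = txt, position = pos, ref_aa = ref, alt_aa = alt,
                   category = "missense",
                   hgvs = paste0("p.", ref, pos, alt))
  }
  purrr::list_rbind(lapply(x, parse_one))
}

#' Format a missense protein change as HGVS
#'
#' @param position 1-based residue number.
#' @param ref_aa,alt_aa One-letter amino acids.
#' @return Character vector `p.<ref><pos><alt>`.
#' @export
format_hgvs <- function(position, ref_aa, alt_aa) {
  paste0("p.", ref_aa, position, alt_aa)
}
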