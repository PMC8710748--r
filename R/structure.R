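#' Read Calpha coordinates from a PDB file
#'
#' Reads the ATOM records of a PDB-format file (first model only, Calpha
#' atoms only, one chain) into a per-residue coordinate table. Insertion
#' codes are rejected with an error.
#'
#' @param path PDB file path.
#' @param chain Chain id to keep (default: first chain present).
#' @return A `structure_model`: tibble with `chain`, `resno` (author
#'   residue number), `aa` (one-letter), `x`, `y`, `z` (Angstrom).
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("no Calpha ATOM records found", call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported; renumber the structure",
         call. = FALSE)
  if (anyDuplicated(at$resno))
    stop("duplicate residue numbers in chain ", chain, call. = FALSE)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  out <- tibble::tibble(chain = chain, resno = as.integer(at$resno),
                        aa = aa1, x = at$x, y = at$y, z = at$z)
  class(out) <- c("structure_model", class(out))
  out
}

#' Build a structure model from a coordinate table
#'
#' @param coords Data frame with `resno`, `x`, `y`, `z` (and optionally
#'   `aa`, `chain`).
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(coords) {
  stopifnot(is.data.frame(coords),
            all(c("resno", "x", "y", "z") %in% names(coords)))
  if (anyDuplicated(coords$resno))
    stop("residue numbers must be unique", call. = FALSE)
  out <- tibble::as_tibble(coords)
  if (!"chain" %in% names(out)) out$chain <- "A"
  if (!"aa" %in% names(out)) out$aa <- "A"
  out <- out[, c("chain", "resno", "aa", "x", "y", "z")]
  out$resno <- as.integer(out$resno)
  class(out) <- c("structure_model", class(out))
  out
}

#' Map sequence positions to structure residue numbers
#'
#' Either a constant `offset` (sequence position 1 maps to structure
#' residue `1 + offset`) or an explicit two-column map. The mapping must be
#' injective.
#'
#' @param offset Integer offset (default 0 = identity numbering).
#' @param map Optional data frame with `seq_pos` and `resno` overriding the
#'   offset.
#' @return A `residue_mapping` object (function-like list).
#' @export
residue_mapping <- function(offset = 0L, map = NULL) {
  if (!is.null(map)) {
    stopifnot(is.data.frame(map),
              all(c("seq_pos", "resno") %in% names(map)))
    if (anyDuplicated(map$seq_pos) || anyDuplicated(map$resno))
      stop("residue mapping must be injective", call. = FALSE)
    fun <- function(seq_pos) map$resno[match(seq_pos, map$seq_pos)]
  } else {
    offset <- as.integer(offset)
    fun <- function(seq_pos) as.integer(seq_pos) + offset
  }
  structure(list(to_resno = fun, offset = offset, map = map),
            class = "residue_mapping")
}

#' Annotate structure residues with sequence-level scores
#'
#' Joins per-residue scores (an ET profile, tiered variants, or any table
#' keyed by sequence position) onto structure coordinates through a residue
#' mapping. Positions that map outside the resolved residues are reported
#' as unresolved, never silently dropped.
#'
#' @param scores Data frame with a sequence-position column (`residue` or
#'   `protein_pos` or `seq_pos`) and at least one score column.
#' @param structure A `structure_model`.
#' @param mapping A [residue_mapping()] (default identity).
#' @return List with `annotated` (tibble: structure residue + score
#'   columns) and `unresolved` (tibble of positions not in the structure).
#'   Errors if the intersection is empty.
#' @export
map_scores <- function(scores, structure, mapping = residue_mapping()) {
  stopifnot(is.data.frame(scores), inherits(structure, "structure_model"),
            inherits(mapping, "residue_mapping"))
  pos_col <- intersect(c("residue", "protein_pos", "seq_pos"),
                       names(scores))[1]
  if (is.na(pos_col))
    stop("scores need a residue/protein_pos/seq_pos column", call. = FALSE)
  scores <- tibble::as_tibble(scores)
  scores$resno <- mapping$to_resno(scores[[pos_col]])
  resolved <- scores$resno %in% structure$resno
  if (!any(resolved))
    stop("no scored position maps into the structure (scored positions ",
         min(scores[[pos_col]]), "-", max(scores[[pos_col]]),
         "; structure residues ", min(structure$resno), "-",
         max(structure$resno), ")", call. = FALSE)
  annotated <- dplyr::inner_join(structure, scores, by = "resno")
  list(annotated = annotated,
       unresolved = scores[!resolved, , drop = FALSE])
}

#' Write a PDB file with scores in the temperature-factor column
#'
#' Emits one Calpha atom per residue with the mapped score as its B-factor
#' so structure viewers can color by score. Residues without a score get
#' B-factor 0.
#'
#' @param structure A `structure_model`.
#' @param scores Data frame with sequence positions and a `score` column
#'   (first numeric column used if unnamed).
#' @param path Output PDB path.
#' @param mapping A [residue_mapping()].
#' @return `path`, invisibly.
#' @export
write_pdb_bfactor <- function(structure, scores, path,
                              mapping = residue_mapping()) {
  ann <- map_scores(scores, structure, mapping)$annotated
  score_col <- setdiff(names(ann)[vapply(ann, is.numeric, logical(1))],
                       c("resno", "x", "y", "z"))
  if ("score" %in% names(ann)) score_col <- "score"
  score_col <- score_col[1]
  b <- rep(0, nrow(structure))
  b[match(ann$resno, structure$resno)] <- ann[[score_col]]
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  aa3 <- vapply(structure$aa, function(a)
    bio3d::aa123(a), character(1))
  n <- nrow(structure)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = structure$resno, resid = aa3,
                   chain = structure$chain, elety = rep("CA", n),
                   b = b, o = rep(1, n))
  invisible(path)
}

#' Ordered-region enrichment of flagged sites
#'
#' Treats residues resolved in the coordinate file as the ordered region
#' (a user mask of ordered residue numbers may be given instead) and asks
#' whether flagged sequence positions fall in it more often than chance:
#' the ordered fraction is `|flagged in ordered| / |flagged|` and the
#' p-value is the hypergeometric upper tail of drawing that many ordered
#' positions in `|flagged|` draws from a protein of `protein_length`
#' positions of which `|ordered|` are ordered.
#'
#' @param flagged Integer vector of flagged sequence positions.
#' @param structure A `structure_model` (or `NULL` when `ordered` given).
#' @param protein_length Total protein length L (>= number resolved).
#' @param mapping A [residue_mapping()].
#' @param ordered Optional explicit integer vector of ordered sequence
#'   positions, overriding the structure's resolved set.
#' @return A `colocalization` object (list): `n_flagged`,
#'   `n_flagged_ordered`, `ordered_fraction`, `n_ordered`,
#'   `protein_length`, `p_ordered`. `NULL` fields when no site is flagged.
#' @export
ordered_enrichment <- function(flagged, structure = NULL, protein_length,
                               mapping = residue_mapping(),
                               ordered = NULL) {
  if (is.null(ordered)) {
    stopifnot(inherits(structure, "structure_model"))
    # sequence positions whose mapped residue number is resolved
    ordered <- which(mapping$to_resno(seq_len(protein_length)) %in%
                       structure$resno)
  }
  ordered <- unique(as.integer(ordered))
  if (protein_length < length(ordered))
    stop("protein_length smaller than the ordered set", call. = FALSE)
  flagged <- unique(as.integer(flagged))
  if (length(flagged) == 0) {
    res <- list(n_flagged = 0L, n_flagged_ordered = NA_integer_,
                ordered_fraction = NA_real_, n_ordered = length(ordered),
                protein_length = protein_length, p_ordered = NA_real_)
    class(res) <- "colocalization"
    return(res)
  }
  x <- sum(flagged %in% ordered)
  p <- stats::phyper(x - 1, m = length(ordered),
                     n = protein_length - length(ordered),
                     k = length(flagged), lower.tail = FALSE)
  res <- list(n_flagged = length(flagged), n_flagged_ordered = x,
              ordered_fraction = x / length(flagged),
              n_ordered = length(ordered),
              protein_length = protein_length, p_ordered = p)
  class(res) <- "colocalization"
  res
}

# mean pairwise Euclidean distance between rows of an n x 3 matrix
mean_pairwise_dist <- function(xyz) {
  mean(stats::dist(xyz))
}

#' Spatial clustering of flagged sites on a structure
#'
#' Statistic: mean pairwise Calpha distance among the flagged sites that
#' are resolved in the structure. Null: `P` equal-size random subsets of
#' the resolved residues. `p = (#{null <= observed} + 1) / (P + 1)`; rigid
#' motions of the coordinates leave the result unchanged.
#'
#' @param flagged Integer vector of flagged sequence positions (>= 2 must
#'   be resolved).
#' @param structure A `structure_model`.
#' @param mapping A [residue_mapping()].
#' @param P Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return A `colocalization` object: `n_flagged_resolved`,
#'   `mean_pairwise_dist`, `p_spatial`, `P`, `seed`. `NULL`-style result
#'   (NA statistic and p) when fewer than 2 flagged sites are resolved.
#' @export
spatial_clustering <- function(flagged, structure,
                               mapping = residue_mapping(),
                               P = 10000, seed = 1L) {
  stopifnot(inherits(structure, "structure_model"))
  flagged <- unique(as.integer(flagged))
  resno <- mapping$to_resno(flagged)
  idx <- match(resno, structure$resno)
  idx <- idx[!is.na(idx)]
  res <- list(n_flagged_resolved = length(idx),
              mean_pairwise_dist = NA_real_, p_spatial = NA_real_,
              P = as.integer(P), seed = seed)
  class(res) <- "colocalization"
  if (length(idx) < 2) {
    warning("fewer than 2 flagged sites resolved; no spatial test",
            call. = FALSE)
    return(res)
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  obs <- mean_pairwise_dist(xyz[idx, , drop = FALSE])
  k <- length(idx)
  nres <- nrow(xyz)
  null_le <- withr::with_seed(seed, {
    sum(vapply(seq_len(P), function(i) {
      sub <- sample.int(nres, k)
      mean_pairwise_dist(xyz[sub, , drop = FALSE]) <= obs
    }, logical(1)))
  })
  res$mean_pairwise_dist <- obs
  res$p_spatial <- (null_le + 1) / (P + 1)
  res
}

#' @export
print.colocalization <- function(x, ...) {
  cat("<colocalization>\n")
  if (!is.null(x$p_ordered)) {
    cat("  ordered: ", x$n_flagged_ordered, "/", x$n_flagged,
        " flagged sites in the ordered region (", x$n_ordered, " of ",
        x$protein_length, " positions); hypergeometric p = ",
        format(x$p_ordered, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$p_spatial)) {
    cat("  spatial: mean pairwise Calpha distance ",
        format(x$mean_pairwise_dist, digits = 4), " A over ",
        x$n_flagged_resolved, " resolved sites; permutation p = ",
        format(x$p_spatial, digits = 3), " (P = ", x$P, ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname ordered_enrichment
#' @param x A `colocalization` object.
#' @param ... Unused.
#' @export
tidy.colocalization <- function(x, ...) {
  tibble::as_tibble(x[!vapply(x, is.null, logical(1))])
}
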