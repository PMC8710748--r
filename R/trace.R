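#' Build a phylogenetic tree for trace analysis
#'
#' Constructs a rooted binary guide tree by UPGMA (average-linkage
#' agglomeration) on the fractional-identity distance between aligned rows.
#' Pairwise identity is computed over the columns where both rows are
#' ungapped; a pair with no mutually ungapped column gets distance 1. The
#' result is deterministic for a fixed input.
#'
#' The object also carries the nested partitions the real-valued trace sums
#' over: `partition(n)` is the set of `n` groups obtained by cutting the tree
#' at its `n - 1` deepest internal nodes, for `n = 1 .. N - 1`.
#'
#' @param msa An [aa_msa()] object with at least two sequences.
#' @return An object of class `et_tree`: a list with the `hclust` fit
#'   (`hc`), sequence `ids`, and the distance matrix used (`dist`).
#' @export
build_tree <- function(msa) {
  stopifnot(inherits(msa, "aa_msa"))
  n <- n_sequences(msa)
  if (n < 2) stop("need at least 2 sequences to build a tree", call. = FALSE)
  d <- identity_distance(msa)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hc = hc, ids = msa$ids, dist = d), class = "et_tree")
}

#' Fractional-identity distance matrix of an alignment
#'
#' @param msa An [aa_msa()] object.
#' @return Symmetric numeric matrix of 1 - fractional identity, identities
#'   scored over mutually non-gap columns.
#' @export
identity_distance <- function(msa) {
  m <- msa$matrix
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <-
        if (!any(ok)) 1 else 1 - mean(m[i, ok] == m[j, ok])
    }
  }
  d
}

#' Tree partition at a given level
#'
#' @param tree An `et_tree` from [build_tree()].
#' @param n Number of groups (1 to N - 1).
#' @return Integer vector of group labels named by sequence id.
#' @export
tree_partition <- function(tree, n) {
  stopifnot(inherits(tree, "et_tree"))
  N <- length(tree$ids)
  if (n < 1 || n > N) stop("partition level out of range", call. = FALSE)
  stats::cutree(tree$hc, k = n)
}

#' @export
print.et_tree <- function(x, ...) {
  cat("<et_tree> UPGMA over", length(x$ids), "sequences\n")
  invisible(x)
}

# Shannon entropy (natural log) of the non-gap residues of one column slice.
# All-gap or single-residue slices score 0.
column_entropy <- function(chars) {
  chars <- chars[chars != "-"]
  if (length(chars) < 2) return(0)
  p <- tabulate(factor(chars, levels = AA20), nbins = 20)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}

#' Real-valued evolutionary trace of an alignment
#'
#' For every alignment column carrying a query residue, computes
#' \deqn{\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g \in P(n)} S(g, i)}
#' where \eqn{P(n)} are the nested tree partitions into \eqn{n} groups and
#' \eqn{S(g, i)} is the Shannon entropy (natural log) of the non-gap
#' amino-acid frequencies of column \eqn{i} restricted to group \eqn{g}
#' (zero for an all-gap or single-sequence group). Gaps never enter the
#' frequency counts (the "gap-reducing" behavior). \eqn{\rho} is then turned
#' into a percentile importance score
#' `et_score = 100 * rank(rho) / L` (average rank on ties, `L` scored
#' positions), so low scores mark the evolutionarily most important residues.
#'
#' @param msa An [aa_msa()] object.
#' @param tree Optional `et_tree`; built with [build_tree()] if omitted.
#' @param tier1_max,tier2_max Percentile cutoffs passed to [tier_residues()].
#' @param max_gap_frac If not `NULL`, rows gapped above this fraction are
#'   dropped first via [filter_gapped_rows()] (a supplied `tree` is then
#'   rebuilt on the filtered alignment).
#' @return A `trace_profile`: a tibble with one row per query residue and
#'   columns `residue`, `ref_aa`, `rho`, `et_score`, `tier`.
#' @examples
#' msa <- aa_msa(c(q = "MAV", h = "MAI"))
#' compute_rvet(msa)
#' @export
compute_rvet <- function(msa, tree = NULL, tier1_max = 2, tier2_max = 4,
                         max_gap_frac = NULL) {
  stopifnot(inherits(msa, "aa_msa"))
  if (!is.null(max_gap_frac)) {
    filtered <- filter_gapped_rows(msa, max_gap_frac)
    if (length(filtered$ids) != length(msa$ids)) {
      msa <- filtered
      tree <- NULL
    }
  }
  if (is.null(tree)) tree <- build_tree(msa)
  if (!setequal(tree$ids, msa$ids))
    stop("tree leaves do not match alignment sequence ids", call. = FALSE)
  N <- n_sequences(msa)
  cols <- which(!is.na(msa$query_pos))
  m <- msa$matrix[tree$ids, cols, drop = FALSE]  # align row order to tree ids

  rho <- rep(1, length(cols))
  # distinct clusters appear once per merge; cache entropy sums per cluster
  # and weight by the harmonic factor of the levels where the cluster lives
  memberships <- lapply(seq_len(N - 1), function(n) {
    stats::cutree(tree$hc, k = n)[tree$ids]
  })
  seen <- new.env(parent = emptyenv())
  for (n in seq_len(N - 1)) {
    grp <- memberships[[n]]
    for (g in unique(grp)) {
      rows <- which(grp == g)
      key <- paste(rows, collapse = ",")
      ent <- get0(key, envir = seen)
      if (is.null(ent)) {
        ent <- apply(m[rows, , drop = FALSE], 2, column_entropy)
        assign(key, ent, envir = seen)
      }
      rho <- rho + ent / n
    }
  }

  et <- 100 * rank(rho, ties.method = "average") / length(rho)
  prof <- tibble::tibble(
    residue = msa$query_pos[cols],
    ref_aa = msa$matrix[msa$query_index, cols],
    rho = rho,
    et_score = et
  )
  prof <- tier_residues(prof, tier1_max = tier1_max, tier2_max = tier2_max)
  class(prof) <- c("trace_profile", class(tibble::tibble()))
  prof
}

#' Assign importance tiers to traced residues
#'
#' Labels residues `tier1` (`et_score <= tier1_max`), `tier2`
#' (`tier1_max < et_score <= tier2_max`) or `untiered`. Alternatively,
#' target residue counts derive the cutoffs from the sorted score list:
#' `tier1_n` takes the `tier1_n` lowest-scoring residues as tier 1 (ties at
#' the boundary are all included), and `tier2_n` the next block.
#'
#' @param profile A `trace_profile` tibble (needs an `et_score` column).
#' @param tier1_max,tier2_max Percentile cutoffs, `0 < tier1_max <=
#'   tier2_max <= 100`.
#' @param tier1_n,tier2_n Alternate count mode: numbers of residues wanted in
#'   each tier; overrides the percentile cutoffs when supplied.
#' @return The profile with a `tier` column (factor tier1/tier2/untiered).
#' @export
tier_residues <- function(profile, tier1_max = 2, tier2_max = 4,
                          tier1_n = NULL, tier2_n = NULL) {
  stopifnot(is.data.frame(profile), "et_score" %in% names(profile))
  score <- profile$et_score
  if (!is.null(tier1_n)) {
    stopifnot(tier1_n >= 1, tier1_n <= length(score))
    srt <- sort(score)
    tier1_max <- srt[tier1_n]
    tier2_max <- if (is.null(tier2_n)) tier1_max else {
      stopifnot(tier2_n >= 0, tier1_n + tier2_n <= length(score))
      if (tier2_n == 0) tier1_max else srt[tier1_n + tier2_n]
    }
  }
  if (!(tier1_max > 0 && tier1_max <= tier2_max && tier2_max <= 100))
    stop("tier cutoffs must satisfy 0 < tier1_max <= tier2_max <= 100",
         call. = FALSE)
  tier <- dplyr::case_when(
    score <= tier1_max ~ "tier1",
    score <= tier2_max ~ "tier2",
    .default = "untiered"
  )
  profile$tier <- factor(tier, levels = c("tier1", "tier2", "untiered"))
  attr(profile, "tier_cutoffs") <- c(tier1_max = tier1_max,
                                     tier2_max = tier2_max)
  if (!inherits(profile, "trace_profile"))
    class(profile) <- c("trace_profile", class(profile))
  profile
}

#' Write / read a per-residue trace profile as TSV
#'
#' Columns: `residue`, `ref_aa`, `rho`, `et_score`, `tier`.
#' @param profile A `trace_profile`.
#' @param path File path.
#' @return `path` invisibly, or the profile tibble for the reader.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as.data.frame(profile), path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  prof <- readr::read_tsv(
    path,
    col_types = readr::cols(
      residue = readr::col_integer(),
      ref_aa = readr::col_character(),
      rho = readr::col_double(),
      et_score = readr::col_double(),
      tier = readr::col_character()
    )
  )
  prof$tier <- factor(prof$tier, levels = c("tier1", "tier2", "untiered"))
  class(prof) <- c("trace_profile", class(prof))
  prof
}

#' Plot a trace profile along the sequence
#'
#' @param object A `trace_profile`.
#' @param ... Unused.
#' @return A ggplot: ET percentile per residue, tiered residues highlighted.
#' @export
autoplot.trace_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$residue, y = .data$et_score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$residue, yend = 100),
                          color = "grey80") +
    ggplot2::geom_point(ggplot2::aes(color = .data$tier), size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_manual(
      values = c(tier1 = "#d7301f", tier2 = "#fc8d59", untiered = "grey40")
    ) +
    ggplot2::labs(x = "residue", y = "ET percentile (0 = most important)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
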