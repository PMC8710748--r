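#' Per-residue functional sensitivity from a trace profile
#'
#' `s_i = (100 - et_score_i) / 100`, so the evolutionarily most important
#' residues (ET percentile near 0) approach sensitivity 1.
#'
#' @param profile A `trace_profile` from [compute_rvet()].
#' @return Tibble with `residue` and `s`.
#' @export
compute_sensitivity <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("residue", "et_score") %in% names(profile)))
  tibble::tibble(residue = profile$residue,
                 s = (100 - profile$et_score) / 100)
}

#' Score an action table with evolutionary-action percentiles
#'
#' For each missense SNV event, the raw action is `r = s_i * m_ab`: the
#' site's functional sensitivity times the magnitude of the amino-acid
#' change. EA is the within-gene percentile of `r` over all missense SNV
#' events, `ea = 100 * rank(r) / n` (average rank on ties), so 100 marks
#' the most pathogenic possible changes and the EA distribution is
#' invariant under any strictly increasing transform of `r`.
#'
#' @param table An `action_table` from [enumerate_snvs()].
#' @param profile `trace_profile` covering the gene's protein positions.
#' @param severity A `severity_matrix` (default from [blosum62()]).
#' @param missing_sensitivity `"strict"` errors on a scored position with no
#'   ET score; `"median"` substitutes the median sensitivity (with a
#'   message).
#' @return The `action_table` with columns `s`, `m`, `r`, `ea` filled on
#'   missense rows (`NA` elsewhere).
#' @export
ea_score <- function(table, profile, severity = severity_from_logodds(),
                     missing_sensitivity = c("strict", "median")) {
  stopifnot(inherits(table, "action_table"))
  missing_sensitivity <- match.arg(missing_sensitivity)
  sens <- compute_sensitivity(profile)
  s <- sens$s[match(table$protein_pos, sens$residue)]
  mis <- table$class == "missense"
  if (anyNA(s[mis])) {
    if (missing_sensitivity == "strict")
      stop("positions without an ET score: ",
           paste(utils::head(unique(table$protein_pos[mis & is.na(s)]), 5),
                 collapse = ", "), call. = FALSE)
    message(sum(is.na(s[mis])), " missense events at positions without an ",
            "ET score; using median sensitivity")
    s[mis & is.na(s)] <- stats::median(sens$s)
  }
  m <- rep(NA_real_, nrow(table))
  m[mis] <- severity[cbind(table$ref_aa[mis], table$alt_aa[mis])]
  r <- ifelse(mis, s * m, NA_real_)
  ea <- rep(NA_real_, nrow(table))
  ea[mis] <- 100 * rank(r[mis], ties.method = "average") / sum(mis)
  table$s <- ifelse(mis, s, NA_real_)
  table$m <- m
  table$r <- r
  table$ea <- ea
  table
}

#' Amino-acid-level EA lookup for an action table
#'
#' The EA of a protein change `ref_aa pos alt_aa` is the mean EA over the
#' SNV events that produce it.
#'
#' @param table A scored `action_table`.
#' @return Tibble with `protein_pos`, `ref_aa`, `alt_aa`, `ea`,
#'   `n_events`.
#' @export
aa_level_ea <- function(table) {
  stopifnot(inherits(table, "action_table"), "ea" %in% names(table))
  table |>
    dplyr::filter(.data$class == "missense") |>
    dplyr::summarise(ea = mean(.data$ea), n_events = dplyr::n(),
                     .by = c("protein_pos", "ref_aa", "alt_aa"))
}

#' Attach EA scores to observed variants
#'
#' Each record gains the amino-acid-level EA of its protein change (mean
#' over the SNV events producing it). Records whose reference amino acid
#' does not match the gene model, or that are synonymous, are rejected with
#' a per-record diagnostic in `status`. Substitutions unreachable by any
#' single SNV are scored by their `sensitivity x magnitude` percentile
#' against the same missense background and flagged `multi_nt`.
#'
#' @param variants Data frame with `gene`, `protein_pos`, `ref_aa`,
#'   `alt_aa` (as from [parse_hgvs()] / [read_variants_tsv()]).
#' @param table A scored `action_table` for the gene.
#' @param severity,profile Needed only to score multi-nucleotide changes;
#'   defaults reuse the values embedded in the table (`s` per position,
#'   background `r`).
#' @return The variants tibble with `ea`, `multi_nt`, and `status`
#'   (`scored`, `ref_mismatch`, `synonymous`, `out_of_range`) columns;
#'   attribute `n_rejected` counts the rejected rows.
#' @export
score_variants <- function(variants, table,
                           severity = severity_from_logodds(),
                           profile = NULL) {
  stopifnot(is.data.frame(variants), inherits(table, "action_table"),
            "ea" %in% names(table))
  gene_sym <- attr(table, "gene_symbol")
  protein <- strsplit(attr(table, "protein"), "")[[1]]
  if ("gene" %in% names(variants) &&
      !all(variants$gene %in% gene_sym))
    stop("variant gene symbols do not match the action table (",
         gene_sym, ")", call. = FALSE)

  aa_ea <- aa_level_ea(table)
  mis <- table[table$class == "missense", ]
  bg_r <- mis$r
  s_by_pos <- tapply(mis$s, mis$protein_pos, function(x) x[1])

  out <- tibble::as_tibble(variants)
  n <- nrow(out)
  ea <- rep(NA_real_, n)
  multi_nt <- rep(FALSE, n)
  status <- rep("scored", n)
  for (i in seq_len(n)) {
    pos <- out$protein_pos[i]
    if (is.na(pos) || pos < 1 || pos > length(protein)) {
      status[i] <- "out_of_range"; next
    }
    if (out$ref_aa[i] != protein[pos]) {
      status[i] <- "ref_mismatch"; next
    }
    if (out$ref_aa[i] == out$alt_aa[i]) {
      status[i] <- "synonymous"; next
    }
    hit <- aa_ea$ea[aa_ea$protein_pos == pos &
                      aa_ea$alt_aa == out$alt_aa[i]]
    if (length(hit)) {
      ea[i] <- hit
    } else {
      # not reachable by one nucleotide change: percentile of s*m against
      # the same SNV-event background
      s_i <- s_by_pos[[as.character(pos)]]
      r_i <- s_i * severity[out$ref_aa[i], out$alt_aa[i]]
      ea[i] <- 100 * (sum(bg_r < r_i) + (sum(bg_r == r_i) + 1) / 2) /
        length(bg_r)
      multi_nt[i] <- TRUE
    }
  }
  out$ea <- ea
  out$multi_nt <- multi_nt
  out$status <- status
  attr(out, "n_rejected") <- sum(status != "scored")
  out
}

#' Tier scored variants as severe / mixed / benign
#'
#' `severe`: `ea >= severe_min` (boundary included); `benign`:
#' `ea < benign_max`; `mixed` otherwise. The default 80/30 cutoffs follow
#' the EA80 convention; genes calibrated at EA70 pass `severe_min = 70`.
#'
#' @param variants Scored variants (an `ea` column).
#' @param severe_min,benign_max EA cutoffs, `severe_min > benign_max`.
#' @return Variants with a `tier` factor (`severe`, `mixed`, `benign`;
#'   `NA` for unscored rows).
#' @export
tier_variants <- function(variants, severe_min = 80, benign_max = 30) {
  stopifnot(is.data.frame(variants), "ea" %in% names(variants))
  if (severe_min <= benign_max)
    stop("severe_min must exceed benign_max", call. = FALSE)
  tier <- dplyr::case_when(
    is.na(variants$ea) ~ NA_character_,
    variants$ea >= severe_min ~ "severe",
    variants$ea < benign_max ~ "benign",
    .default = "mixed"
  )
  variants$tier <- factor(tier, levels = c("severe", "mixed", "benign"))
  variants
}

# half-away-from-zero rounding (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize tiers of one gene's variants by origin
#'
#' Per origin: total scored variants, severe count, severe percentage
#' (half-away-from-zero rounding at `digits`), and the number of unique
#' protein positions among the severe set. Unscored rows are excluded.
#'
#' @param variants Tiered variants for one gene (columns `origin`,
#'   `protein_pos`, `tier`; rows with `NA` tier are dropped).
#' @param digits Decimal places for the severe percentage.
#' @return Tibble with `origin`, `n_total`, `n_severe`, `pct_severe`,
#'   `n_unique_severe_residues`. Empty input gives a zero-row summary;
#'   an origin with no variants would simply be absent.
#' @export
tier_report <- function(variants, digits = 0) {
  stopifnot(is.data.frame(variants), "tier" %in% names(variants))
  scored <- dplyr::filter(variants, !is.na(.data$tier))
  if (!"origin" %in% names(scored)) scored$origin <- "all"
  if (nrow(scored) == 0) {
    return(tibble::tibble(origin = character(), n_total = integer(),
                          n_severe = integer(), pct_severe = double(),
                          n_unique_severe_residues = integer()))
  }
  scored |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_severe = sum(.data$tier == "severe"),
      pct_severe = ifelse(dplyr::n() == 0, NA_real_,
                          round_half_up(100 * sum(.data$tier == "severe") /
                                          dplyr::n(), digits)),
      n_unique_severe_residues =
        dplyr::n_distinct(.data$protein_pos[.data$tier == "severe"]),
      .by = "origin"
    )
}

#' Bootstrap test of observed EA against the all-substitution background
#'
#' Draws `B` resamples of size `length(observed)` with replacement from the
#' SNV-event-weighted background EA values (each enumerated missense event
#' counts once, so a change reachable by two SNVs weighs twice), computes
#' the mean of each resample, and reports the two-sided p-value
#' `p = 2 * min(P(mean* >= obs), P(mean* <= obs))` with the small-sample
#' `(count + 1) / (B + 1)` correction, capped at 1.
#'
#' @param observed Numeric vector of observed EA scores (length >= 1).
#' @param background A scored `action_table`, or a numeric vector of
#'   background EA values.
#' @param B Number of bootstrap resamples (default 100,000; below 100 a
#'   warning is issued).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return An `ea_bootstrap` object: list with `statistic` (observed mean),
#'   `background_mean`, `n_observed`, `B`, `p_value`, `seed`.
#' @export
ea_bootstrap <- function(observed, background, B = 1e5, seed = 1L) {
  observed <- observed[!is.na(observed)]
  if (length(observed) == 0) stop("no observed EA values", call. = FALSE)
  if (inherits(background, "action_table")) {
    stopifnot("ea" %in% names(background))
    background <- background$ea[background$class == "missense"]
  }
  background <- background[!is.na(background)]
  if (length(background) == 0) stop("empty background", call. = FALSE)
  B <- as.integer(B)
  if (B < 100) warning("B < 100 gives a very coarse p-value", call. = FALSE)
  obs <- mean(observed)
  k <- length(observed)
  means <- withr::with_seed(seed, {
    draws <- sample.int(length(background), k * B, replace = TRUE)
    colMeans(matrix(background[draws], nrow = k))
  })
  p_hi <- (sum(means >= obs) + 1) / (B + 1)
  p_lo <- (sum(means <= obs) + 1) / (B + 1)
  structure(
    list(statistic = obs, background_mean = mean(background),
         n_observed = k, B = B, p_value = min(1, 2 * min(p_hi, p_lo)),
         seed = seed),
    class = "ea_bootstrap"
  )
}

#' @export
print.ea_bootstrap <- function(x, ...) {
  cat("Bootstrap test of mean EA\n",
      "  observed mean EA: ", format(x$statistic, digits = 4),
      " (n = ", x$n_observed, ")\n",
      "  background mean:  ", format(x$background_mean, digits = 4), "\n",
      "  B = ", x$B, ", two-sided p = ", format(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ea_bootstrap
#' @param x An `ea_bootstrap` object.
#' @param ... Unused.
#' @export
tidy.ea_bootstrap <- function(x, ...) {
  tibble::tibble(statistic = x$statistic,
                 background_mean = x$background_mean,
                 n_observed = x$n_observed, B = x$B,
                 p.value = x$p_value)
}

#' @rdname ea_bootstrap
#' @export
glance.ea_bootstrap <- function(x, ...) tidy.ea_bootstrap(x)

#' EA distribution plot for a scored gene
#'
#' @param object A scored `action_table`.
#' @param ... Unused.
#' @return ggplot histogram of missense EA with the 30/80 tier boundaries.
#' @export
autoplot.action_table <- function(object, ...) {
  stopifnot("ea" %in% names(object))
  dat <- dplyr::filter(object, .data$class == "missense")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ea)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0, fill = "grey60") +
    ggplot2::geom_vline(xintercept = c(30, 80), linetype = 2) +
    ggplot2::labs(x = "EA score", y = "missense SNV events") +
    ggplot2::theme_minimal()
}
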