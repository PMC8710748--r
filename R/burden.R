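#' Assign tumor samples to mutation-load groups
#'
#' Stratifies a cohort by per-sample simple-mutation count: `low` for at
#' most `low_max` mutations, `high` for at least `high_min`, `medium`
#' between. Defaults follow the low <41 / medium 41-700 / high >700
#' convention.
#'
#' @param samples Data frame with a `mutation_count` column.
#' @param low_max Largest count still in the low group (default 40).
#' @param high_min Smallest count already in the high group (default 701).
#' @return `samples` with an `mlg` factor column (`low`, `medium`, `high`).
#' @examples
#' assign_mlg(data.frame(mutation_count = c(40, 41, 700, 701)))
#' @export
assign_mlg <- function(samples, low_max = 40, high_min = 701) {
  stopifnot(is.data.frame(samples), "mutation_count" %in% names(samples),
            low_max < high_min)
  counts <- samples$mutation_count
  if (any(counts < 0 | is.na(counts)))
    stop("mutation counts must be non-negative", call. = FALSE)
  samples$mlg <- factor(
    dplyr::case_when(counts <= low_max ~ "low",
                     counts >= high_min ~ "high",
                     .default = "medium"),
    levels = c("low", "medium", "high")
  )
  tibble::as_tibble(samples)
}

#' Normalized per-gene mutation rate
#'
#' Mutations per 100 bp of coding sequence per 1,000 patients:
#' `rate = count * (100 / cds_length_bp) * (1000 / n_patients)`.
#'
#' @param count Gene mutation count (vectorized).
#' @param cds_length_bp CDS length in base pairs (> 0).
#' @param n_patients Number of patients in the stratum (> 0).
#' @return Numeric rate(s).
#' @examples
#' normalized_rate(50, 1000, 5000)  # 1.0
#' @export
normalized_rate <- function(count, cds_length_bp, n_patients) {
  if (any(cds_length_bp <= 0)) stop("cds_length_bp must be > 0", call. = FALSE)
  if (any(n_patients <= 0)) stop("n_patients must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count * (100 / cds_length_bp) * (1000 / n_patients)
}

#' Rank genes by normalized mutation rate and split into bins
#'
#' Only genes with at least one mutation participate. Genes are ranked in
#' ascending rate order with ties broken by gene symbol (stable), then
#' split into `n_bins` contiguous rank bins whose sizes differ by at most
#' one (bin 1 = least mutated).
#'
#' @param gene_rates Data frame with `gene` and `rate` columns and a
#'   mutation `count` column (rows with `count == 0` are dropped; if no
#'   `count` column is present all rows participate).
#' @param n_bins Number of bins (default 35).
#' @return A `gene_mutability` tibble: input rows plus `rank` and `bin`.
#' @export
rank_and_bin <- function(gene_rates, n_bins = 35) {
  stopifnot(is.data.frame(gene_rates),
            all(c("gene", "rate") %in% names(gene_rates)))
  dat <- tibble::as_tibble(gene_rates)
  if ("count" %in% names(dat)) dat <- dplyr::filter(dat, .data$count > 0)
  n <- nrow(dat)
  if (n < n_bins)
    stop("need at least ", n_bins, " mutated genes to form ", n_bins,
         " bins (have ", n, ")", call. = FALSE)
  dat <- dplyr::arrange(dat, .data$rate, .data$gene)
  dat$rank <- seq_len(n)
  # contiguous rank bins; sizes are floor(n/n_bins) or ceiling(n/n_bins)
  dat$bin <- as.integer(ceiling(dat$rank * n_bins / n))
  class(dat) <- c("gene_mutability", class(dat))
  dat
}

#' Per-bin median gene age and mutation rate
#'
#' Summarizes [rank_and_bin()] output against a phylostratum table: for
#' each bin, the median phylostratum (interpolated for even counts; genes
#' without an age are excluded from the age median only) and the median
#' normalized rate.
#'
#' @param bins A `gene_mutability` tibble.
#' @param ages Data frame with `gene` and `phylostratum` (1 = origin of
#'   life ... 19 = primates).
#' @return Tibble with `bin`, `n_genes`, `n_aged`, `median_phylostratum`,
#'   `median_rate`. A warning is issued if fewer than half the binned genes
#'   have an age; an all-unknown bin gets `NA` median age.
#' @export
bin_age_summary <- function(bins, ages) {
  stopifnot(is.data.frame(bins), all(c("bin", "rate") %in% names(bins)),
            is.data.frame(ages),
            all(c("gene", "phylostratum") %in% names(ages)))
  dat <- dplyr::left_join(bins, ages, by = "gene")
  if (mean(!is.na(dat$phylostratum)) < 0.5)
    warning("fewer than half of binned genes have a known age",
            call. = FALSE)
  dat |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_aged = sum(!is.na(.data$phylostratum)),
      median_phylostratum = if (all(is.na(.data$phylostratum)))
        NA_real_ else stats::median(.data$phylostratum, na.rm = TRUE),
      median_rate = stats::median(.data$rate),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
}

#' Selection index
#'
#' `si = (mut * 100 / tot) / (med / 1000)`: the percentage of a tumor
#' type's samples carrying qualifying (damaging) mutations in a gene,
#' normalized by the type's median per-sample mutation burden in units of
#' 1,000.
#'
#' @param mut Number of samples with qualifying gene mutations.
#' @param tot Total samples of the tumor type (> 0).
#' @param med Median mutation count over all samples of the type (> 0).
#' @return Numeric selection index (vectorized); 0 iff `mut` is 0.
#' @examples
#' selection_index(10, 1000, 100)  # 10
#' @export
selection_index <- function(mut, tot, med) {
  if (any(tot <= 0)) stop("tot must be > 0", call. = FALSE)
  if (any(med <= 0)) stop("med must be > 0", call. = FALSE)
  if (any(mut < 0)) stop("mut must be non-negative", call. = FALSE)
  (mut * 100 / tot) / (med / 1000)
}

#' Scan tumor types for selection on a gene
#'
#' For every tumor site with at least `min_mutated_samples` samples
#' carrying a qualifying mutation (EA at or above `ea_min`) in `gene`,
#' computes the selection index, then flags sites whose index exceeds the
#' cross-site upper 99% confidence bound
#' `mean + t(0.995, k - 1) * sd / sqrt(k)` over the `k` qualifying sites
#' (`ci = "t"`), or a percentile bootstrap bound on the site values
#' (`ci = "bootstrap"`).
#'
#' @param variants Scored variants (`sample`, `gene`, `tumor_site`, `ea`).
#' @param samples Cohort table (`sample`, `tumor_site`, `mutation_count`).
#' @param gene Gene symbol to scan.
#' @param ea_min Minimum EA for a mutation to qualify (default 60).
#' @param min_mutated_samples Minimum qualifying samples per site
#'   (default 3).
#' @param ci Confidence-bound construction, `"t"` (default) or
#'   `"bootstrap"`.
#' @param B Bootstrap resamples when `ci = "bootstrap"`.
#' @param seed Seed for the bootstrap bound.
#' @return A `selection_scan` tibble: one row per qualifying site with
#'   `tumor_site`, `mut`, `tot`, `med`, `si`, `flagged`; attributes
#'   `upper_bound`, `ci_method`, `n_sites`. With fewer than two qualifying
#'   sites the bound is `NA` and nothing is flagged (with a warning).
#' @export
selection_scan <- function(variants, samples, gene, ea_min = 60,
                           min_mutated_samples = 3,
                           ci = c("t", "bootstrap"), B = 2000, seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(is.data.frame(variants),
            all(c("sample", "gene", "ea") %in% names(variants)),
            is.data.frame(samples),
            all(c("sample", "tumor_site", "mutation_count") %in%
                  names(samples)))
  qual <- variants |>
    dplyr::filter(.data$gene == !!gene, !is.na(.data$ea),
                  .data$ea >= ea_min) |>
    dplyr::distinct(.data$sample)
  per_site <- samples |>
    dplyr::summarise(
      tot = dplyr::n(),
      med = stats::median(.data$mutation_count),
      mut = sum(.data$sample %in% qual$sample),
      .by = "tumor_site"
    ) |>
    dplyr::filter(.data$mut >= min_mutated_samples)
  if (nrow(per_site) == 0) {
    warning("no tumor site qualifies for gene ", gene, call. = FALSE)
    out <- tibble::tibble(tumor_site = character(), mut = integer(),
                          tot = integer(), med = double(), si = double(),
                          flagged = logical())
    attr(out, "upper_bound") <- NA_real_
    attr(out, "ci_method") <- ci
    attr(out, "n_sites") <- 0L
    class(out) <- c("selection_scan", class(out))
    return(out)
  }
  per_site$si <- selection_index(per_site$mut, per_site$tot, per_site$med)
  k <- nrow(per_site)
  if (k < 2) {
    warning("fewer than 2 qualifying sites; confidence bound undefined",
            call. = FALSE)
    bound <- NA_real_
    per_site$flagged <- FALSE
  } else if (ci == "t") {
    bound <- mean(per_site$si) +
      stats::qt(0.995, k - 1) * stats::sd(per_site$si) / sqrt(k)
    per_site$flagged <- per_site$si > bound
  } else {
    boot_means <- withr::with_seed(seed, {
      vapply(seq_len(B), function(i)
        mean(sample(per_site$si, k, replace = TRUE)), numeric(1))
    })
    bound <- stats::quantile(boot_means, 0.99, names = FALSE)
    per_site$flagged <- per_site$si > bound
  }
  out <- dplyr::arrange(per_site, dplyr::desc(.data$si))
  out <- out[, c("tumor_site", "mut", "tot", "med", "si", "flagged")]
  attr(out, "upper_bound") <- bound
  attr(out, "ci_method") <- ci
  attr(out, "n_sites") <- k
  attr(out, "gene") <- gene
  class(out) <- c("selection_scan", class(out))
  out
}

#' @rdname selection_scan
#' @param x A `selection_scan` object.
#' @param ... Unused.
#' @export
glance.selection_scan <- function(x, ...) {
  tibble::tibble(
    gene = attr(x, "gene") %||% NA_character_,
    n_sites = attr(x, "n_sites"),
    upper_bound = attr(x, "upper_bound"),
    ci_method = attr(x, "ci_method"),
    n_flagged = sum(x$flagged)
  )
}

#' @rdname selection_scan
#' @export
tidy.selection_scan <- function(x, ...) tibble::as_tibble(x)

#' Plot a selection scan
#'
#' @param object A `selection_scan`.
#' @param ... Unused.
#' @return ggplot of per-site selection index with the cross-site bound.
#' @export
autoplot.selection_scan <- function(object, ...) {
  bound <- attr(object, "upper_bound")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$tumor_site,
                                                  .data$si),
                               y = .data$si, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = bound, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#d7301f")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "selection index", fill = "above bound") +
    ggplot2::theme_minimal()
}

#' Plot gene mutability bins
#'
#' @param object A `gene_mutability` tibble from [rank_and_bin()].
#' @param ... Unused.
#' @return ggplot of normalized rate against rank (log scale), colored by
#'   bin.
#' @export
autoplot.gene_mutability <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$rate,
                                       color = factor(.data$bin))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gene rank", y = "mutations / 100 bp / 1,000 patients") +
    ggplot2::theme_minimal()
}
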