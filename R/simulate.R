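SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all[Biostrings::GENETIC_CODE[all] != "*"]
})

# random rooted binary tree over `tips` labels: recursive random splits,
# exponential branch lengths. Returns edge list (parent, child, length) with
# node 1 = root; leaves carry labels.
random_binary_tree <- function(tips, mean_branch = 0.25) {
  n_nodes <- 0L
  edges <- list()
  labels <- list()
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    n_nodes
  }
  grow <- function(members, parent) {
    node <- new_node()
    if (!is.null(parent)) {
      edges[[length(edges) + 1L]] <<-
        c(parent, node, stats::rexp(1, 1 / mean_branch))
    }
    if (length(members) == 1L) {
      labels[[as.character(node)]] <<- members
      return(node)
    }
    k <- if (length(members) == 2L) 1L else
      sample.int(length(members) - 1L, 1L)
    pick <- sample(seq_along(members), k)
    grow(members[pick], node)
    grow(members[-pick], node)
    node
  }
  root <- grow(sample(tips), NULL)
  list(edges = do.call(rbind, edges), labels = labels, root = root)
}

#' Simulate a protein alignment with planted important sites
#'
#' Evolves sequences down a random binary tree under an equal-exchange
#' substitution process with two site classes: a planted fraction of
#' "important" (slow) columns and the rest fast, with per-branch
#' substitution probability `1 - exp(-rate * length)`. The query row is the
#' root sequence. With `n_clades = 2` the tips are split into two planted
#' clades joined by long stem branches. The output is gapless and
#' deterministic per seed.
#'
#' @param n_sequences Rows in the alignment including the query root
#'   (default 32).
#' @param n_columns Alignment columns (default 200).
#' @param frac_important Fraction of slow (important) columns (default 0.2).
#' @param rate_ratio Fast:slow substitution-rate ratio (default 10; a ratio
#'   of at most 1 leaves no recoverable signal and warns). `Inf` freezes
#'   important columns entirely.
#' @param fast_rate Substitution rate of fast columns per unit branch
#'   length (default 1.2).
#' @param mean_branch Mean branch length (default 0.25).
#' @param n_clades 1 (default) or 2 planted clades.
#' @param clade_sep Stem branch length separating planted clades.
#' @param seed Integer seed (mandatory).
#' @return List with `msa` (an [aa_msa()], query row `"query"` first),
#'   `truth` (list: `important_sites`, `clade` tip assignment, parameters).
#' @export
simulate_msa <- function(n_sequences = 32, n_columns = 200,
                         frac_important = 0.2, rate_ratio = 10,
                         fast_rate = 1.2, mean_branch = 0.25,
                         n_clades = 1, clade_sep = 1.5, seed) {
  stopifnot(n_sequences >= 2, n_columns >= 1, frac_important >= 0,
            frac_important <= 1, n_clades %in% c(1, 2))
  if (rate_ratio <= 1)
    warning("rate_ratio <= 1: planted sites are not slower than background",
            call. = FALSE)
  force(seed)
  withr::with_seed(seed, {
    n_tips <- n_sequences - 1L
    tip_ids <- sprintf("t%02d", seq_len(n_tips))
    n_imp <- round(frac_important * n_columns)
    important <- sort(sample.int(n_columns, n_imp))
    rates <- rep(fast_rate, n_columns)
    rates[important] <- if (is.infinite(rate_ratio)) 0 else
      fast_rate / rate_ratio
    root_seq <- sample(AA20, n_columns, replace = TRUE)

    evolve <- function(seq, branch_len) {
      p <- 1 - exp(-rates * branch_len)
      hit <- which(stats::runif(n_columns) < p)
      for (j in hit) seq[j] <- sample(setdiff(AA20, seq[j]), 1)
      seq
    }

    clade <- NULL
    if (n_clades == 2) {
      half <- floor(n_tips / 2)
      groups <- list(tip_ids[seq_len(half)], tip_ids[-seq_len(half)])
      clade <- stats::setNames(rep(c("A", "B"), c(half, n_tips - half)),
                               tip_ids)
    } else {
      groups <- list(tip_ids)
    }
    seqs <- character(0)
    for (gi in seq_along(groups)) {
      stem <- if (n_clades == 2) clade_sep else 0
      g <- groups[[gi]]
      if (length(g) == 1L) {
        tipseq <- evolve(root_seq, stem + stats::rexp(1, 1 / mean_branch))
        seqs[g] <- paste(tipseq, collapse = "")
        next
      }
      tr <- random_binary_tree(g, mean_branch)
      node_seq <- list()
      node_seq[[as.character(tr$root)]] <- evolve(root_seq, stem)
      ord <- order(tr$edges[, 1])  # parents are created before children
      for (e in ord) {
        par <- as.character(tr$edges[e, 1])
        chl <- as.character(tr$edges[e, 2])
        node_seq[[chl]] <- evolve(node_seq[[par]], tr$edges[e, 3])
      }
      for (nd in names(tr$labels))
        seqs[tr$labels[[nd]]] <- paste(node_seq[[nd]], collapse = "")
    }
    rows <- c(query = paste(root_seq, collapse = ""), seqs[tip_ids])
    list(
      msa = aa_msa(rows, query = "query"),
      truth = list(important_sites = important, clade = clade,
                   rate_ratio = rate_ratio,
                   frac_important = frac_important, seed = seed)
    )
  })
}

#' Simulate a synthetic trace profile
#'
#' A stand-in per-residue ET profile (random percentile permutation) for
#' cohort-scale experiments where running the full trace on every gene is
#' unnecessary: EA scoring only consumes the percentile.
#'
#' @param protein_length Number of residues.
#' @param protein Optional protein string (for `ref_aa`); defaults to `A`s.
#' @param seed Integer seed.
#' @return A `trace_profile` tibble.
#' @export
simulate_profile <- function(protein_length, protein = NULL, seed) {
  withr::with_seed(seed, {
    et <- sample(100 * seq_len(protein_length) / protein_length)
    ref <- if (is.null(protein)) rep("A", protein_length) else
      strsplit(protein, "")[[1]]
    prof <- tibble::tibble(residue = seq_len(protein_length), ref_aa = ref,
                           rho = 1 + et / 100, et_score = et)
    tier_residues(prof)
  })
}

#' Simulate a gene set with planted hot genes
#'
#' Random valid coding sequences (ATG start, sense internal codons, one
#' terminal stop) with lengths drawn log-uniform over `codon_range`, plus
#' per-gene mutability multipliers (1 except for planted hot genes).
#'
#' @param n_genes Number of genes (default 40).
#' @param codon_range Range of coding codon counts drawn log-uniform
#'   (default c(100, 1200)).
#' @param hot_genes Number of planted hot genes (default 3).
#' @param hot_multiplier Rate multiplier for hot genes (default 8).
#' @param seed Integer seed.
#' @return List with `genes` (named list of [gene_model()]), `lengths`
#'   (tibble `gene`, `cds_length_bp`), `multipliers` (named numeric),
#'   `truth` (hot gene names).
#' @export
simulate_gene_set <- function(n_genes = 40, codon_range = c(100, 1200),
                              hot_genes = 3, hot_multiplier = 8, seed) {
  stopifnot(n_genes >= 1, hot_genes <= n_genes)
  withr::with_seed(seed, {
    syms <- sprintf("G%03d", seq_len(n_genes))
    n_codons <- round(exp(stats::runif(n_genes, log(codon_range[1]),
                                       log(codon_range[2]))))
    genes <- purrr::map2(syms, n_codons, function(sym, nc) {
      body <- sample(SENSE_CODONS, nc - 1, replace = TRUE)
      gene_model(sym, paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1)),
                            collapse = ""))
    })
    names(genes) <- syms
    mult <- stats::setNames(rep(1, n_genes), syms)
    hot <- character(0)
    if (hot_genes > 0) {
      hot <- sample(syms, hot_genes)
      mult[hot] <- hot_multiplier
    }
    list(
      genes = genes,
      lengths = tibble::tibble(
        gene = syms,
        cds_length_bp = vapply(genes, function(g) nchar(g$cds), integer(1))
      ),
      multipliers = mult,
      truth = list(hot_genes = hot, seed = seed)
    )
  })
}

#' Score a simulated gene set
#'
#' Enumerates and EA-scores every gene of a [simulate_gene_set()] result
#' using synthetic per-gene trace profiles.
#'
#' @param gene_set Result of [simulate_gene_set()].
#' @param seed Integer seed for the per-gene profiles.
#' @return Named list of scored `action_table`s.
#' @export
score_gene_set <- function(gene_set, seed) {
  sev <- severity_from_logodds()
  out <- purrr::imap(gene_set$genes, function(g, sym) {
    prof <- simulate_profile(nchar(g$protein), g$protein,
                             seed = seed + match(sym, names(gene_set$genes)))
    ea_score(enumerate_snvs(g), prof, sev)
  })
  out
}

#' Simulate a tumor cohort with a planted selection target
#'
#' Per-sample mutation burdens are drawn log-uniform over `burden_range`
#' (spanning four orders of magnitude by default, so all three
#' mutation-load groups are populated). The draw is stratified within each
#' tumor site (systematic quantiles of the log-uniform, randomly permuted):
#' marginally the burden distribution is unchanged, but per-site median
#' burdens are comparable, which is the regime the selection index's
#' median normalization assumes. Mutations land on genes with
#' probability proportional to CDS length times the gene multiplier; within
#' a gene, SNV events are drawn uniformly from the enumerated table --
#' except for the planted selection target (one gene in one tumor site),
#' whose missense events are tilted with probability proportional to
#' `exp(lambda * ea / 100)`. Deterministic per seed.
#'
#' @param scored_tables Named list of scored `action_table`s (e.g. from
#'   [score_gene_set()]).
#' @param lengths Tibble `gene`, `cds_length_bp` for the same genes.
#' @param multipliers Named per-gene rate multipliers (default all 1).
#' @param n_samples Cohort size (default 1560, i.e. 120 samples per site
#'   under the default 13 tumor sites).
#' @param tumor_sites Vector of site labels (default 13 sites).
#' @param burden_range Per-sample mutation count range, sampled log-uniform
#'   (default `c(1, 1e4)`).
#' @param target_gene,target_site Planted selection target (both `NULL`
#'   for no target).
#' @param lambda Exponential EA tilt strength of the target (default 3).
#' @param seed Integer seed.
#' @return List with `samples` (tibble `sample`, `tumor_site`,
#'   `mutation_count`), `variants` (tibble `sample`, `gene`, `tumor_site`,
#'   `origin`, `hgvs_p`, `protein_pos`, `ref_aa`, `alt_aa`, `category`,
#'   `ea`), and `truth`.
#' @export
simulate_cohort <- function(scored_tables, lengths,
                            multipliers = NULL, n_samples = 1560,
                            tumor_sites = sprintf("site%02d", 1:13),
                            burden_range = c(1, 1e4),
                            target_gene = NULL, target_site = NULL,
                            lambda = 3, seed) {
  syms <- names(scored_tables)
  stopifnot(!is.null(syms), all(lengths$gene %in% syms),
            all(syms %in% lengths$gene))
  if (is.null(multipliers)) multipliers <- stats::setNames(rep(1, length(syms)), syms)
  if (!is.null(target_gene) && !target_gene %in% syms)
    stop("target gene ", target_gene, " absent from the gene set",
         call. = FALSE)
  withr::with_seed(seed, {
    samples <- tibble::tibble(
      sample = sprintf("S%04d", seq_len(n_samples)),
      tumor_site = sample(tumor_sites, n_samples, replace = TRUE)
    )
    lo <- log10(burden_range[1]); hi <- log10(burden_range[2])
    samples <- samples |>
      dplyr::mutate(
        mutation_count = {
          n <- dplyr::n()
          q <- (sample.int(n) - stats::runif(n)) / n  # jittered quantiles
          pmax(1L, as.integer(round(10^(lo + q * (hi - lo)))))
        },
        .by = "tumor_site"
      )
    gene_w <- lengths$cds_length_bp * multipliers[lengths$gene]
    gene_syms <- lengths$gene

    total <- sum(samples$mutation_count)
    ev_sample <- rep.int(samples$sample, samples$mutation_count)
    ev_site <- rep.int(samples$tumor_site, samples$mutation_count)
    ev_gene <- gene_syms[sample.int(length(gene_syms), total,
                                    replace = TRUE, prob = gene_w)]
    # draw SNV event rows gene by gene; the target (gene, site) stratum is
    # EA-tilted, everything else uniform over the enumerated events
    ev_row <- integer(total)
    for (g in unique(ev_gene)) {
      tab <- scored_tables[[g]]
      idx <- which(ev_gene == g)
      tilted <- if (!is.null(target_gene) && g == target_gene &&
                    !is.null(target_site))
        idx[ev_site[idx] == target_site] else integer(0)
      plain <- setdiff(idx, tilted)
      if (length(plain))
        ev_row[plain] <- sample.int(nrow(tab), length(plain), replace = TRUE)
      if (length(tilted)) {
        w <- ifelse(is.na(tab$ea), 1, exp(lambda * tab$ea / 100))
        ev_row[tilted] <- sample.int(nrow(tab), length(tilted),
                                     replace = TRUE, prob = w)
      }
    }
    rows <- purrr::map(unique(ev_gene), function(g) {
      idx <- which(ev_gene == g)
      tab <- scored_tables[[g]][ev_row[idx],
                                c("protein_pos", "ref_aa", "alt_aa",
                                  "class", "ea", "codon")]
      tibble::tibble(sample = ev_sample[idx], gene = g,
                     tumor_site = ev_site[idx], origin = "somatic",
                     hgvs_p = dplyr::case_when(
                       tab$class == "missense" ~
                         paste0("p.", tab$ref_aa, tab$protein_pos,
                                tab$alt_aa),
                       tab$class == "synonymous" ~
                         paste0("p.", tab$ref_aa, tab$codon, "="),
                       .default = paste0("p.", tab$ref_aa, tab$codon, "*")
                     ),
                     protein_pos = tab$protein_pos, ref_aa = tab$ref_aa,
                     alt_aa = tab$alt_aa, category = tab$class,
                     ea = tab$ea)
    })
    variants <- purrr::list_rbind(rows)
    list(samples = samples, variants = variants,
         truth = list(target_gene = target_gene, target_site = target_site,
                      lambda = lambda, seed = seed))
  })
}

#' Simulate gene ages with a planted age-mutability trend
#'
#' Samples a phylostratum (1 = origin of life, oldest; 19 = primates,
#' youngest) per gene, tilted so that high-mutability genes skew young:
#' the weight of age `a` for a gene with standardized rate rank `z` in
#' `[-1, 1]` is `exp(tilt * z * (a - 10) / 9)`. `tilt = 0` gives no
#' correlation; positive `tilt` makes the per-bin median phylostratum rise
#' (calendar age fall) with the mutation-rate bin.
#'
#' @param gene_rates Tibble with `gene` and `rate`.
#' @param tilt Correlation strength (default 1.5).
#' @param seed Integer seed.
#' @return List with `ages` (tibble `gene`, `phylostratum`) and `truth`
#'   (`tilt`, expected correlation sign).
#' @export
simulate_ages <- function(gene_rates, tilt = 1.5, seed) {
  stopifnot(all(c("gene", "rate") %in% names(gene_rates)))
  withr::with_seed(seed, {
    n <- nrow(gene_rates)
    z <- 2 * (rank(gene_rates$rate, ties.method = "average") - 1) /
      max(1, n - 1) - 1
    ages <- vapply(z, function(zi) {
      w <- exp(tilt * zi * (1:19 - 10) / 9)
      sample.int(19, 1, prob = w)
    }, integer(1))
    list(ages = tibble::tibble(gene = gene_rates$gene, phylostratum = ages),
         truth = list(tilt = tilt,
                      correlation_sign = sign(tilt), seed = seed))
  })
}

# unit vector in a uniformly random direction
random_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Simulate a Calpha structure with a planted spatial cluster
#'
#' Places residues on a self-avoiding random walk with exact 3.8-Angstrom
#' steps. Residues in `cluster_sites` are steered into a ball of
#' `cluster_radius` around a common center; a fraction of the remaining
#' residues is omitted from the output ("disordered"), cluster sites are
#' always resolved. Deterministic per seed.
#'
#' @param protein_length Number of residues.
#' @param cluster_sites Integer positions to plant inside the cluster ball
#'   (`NULL` for none; all must lie within the protein).
#' @param omit_frac Fraction of non-cluster residues left unresolved
#'   (default 0.15).
#' @param cluster_radius Ball radius in Angstrom (default 10).
#' @param step Calpha-Calpha step length (default 3.8).
#' @param min_sep Self-avoidance distance between non-consecutive residues
#'   (default 3).
#' @param seed Integer seed.
#' @return List with `structure` (a [structure_model()] of the resolved
#'   residues) and `truth` (`cluster_sites`, `omitted`).
#' @export
simulate_structure <- function(protein_length, cluster_sites = NULL,
                               omit_frac = 0.15, cluster_radius = 10,
                               step = 3.8, min_sep = 3, seed) {
  cluster_sites <- sort(unique(as.integer(cluster_sites)))
  if (length(cluster_sites) &&
      (min(cluster_sites) < 1 || max(cluster_sites) > protein_length))
    stop("cluster sites outside the protein", call. = FALSE)
  # loose packing bound for min_sep-separated points in the ball
  if (length(cluster_sites) > floor((cluster_radius / min_sep + 1)^3))
    stop("planted cluster larger than the ball can hold", call. = FALSE)
  withr::with_seed(seed, {
    center <- c(0, 0, 0)
    xyz <- matrix(NA_real_, protein_length, 3)
    xyz[1, ] <- center + random_direction() * stats::runif(1, 0, 2)
    next_cluster <- function(i)
      if (length(cluster_sites)) cluster_sites[cluster_sites >= i][1] else NA
    for (i in 2:protein_length) {
      prev <- xyz[i - 1, ]
      nc <- next_cluster(i)
      d <- sqrt(sum((prev - center)^2))
      # head for the ball early enough to arrive in time (2 A of slack)
      forced <- !is.na(nc) &&
        d > cluster_radius - step + step * (nc - i) - 2
      placed <- FALSE
      best <- NULL; best_sep <- -Inf
      for (try in 1:60) {
        dir <- if (forced) {
          to_c <- center - prev
          nt <- sqrt(sum(to_c^2))
          if (nt < 1e-8) random_direction() else {
            v <- to_c / nt + 0.15 * random_direction()
            v / sqrt(sum(v^2))
          }
        } else random_direction()
        cand <- prev + step * dir
        in_ball_ok <- is.na(nc) || nc != i ||
          sqrt(sum((cand - center)^2)) <= cluster_radius
        sep <- if (i > 2)
          min(sqrt(rowSums((xyz[1:(i - 2), , drop = FALSE] -
                              matrix(cand, i - 2, 3, byrow = TRUE))^2)))
        else Inf
        if (in_ball_ok && sep > best_sep) { best <- cand; best_sep <- sep }
        if (in_ball_ok && sep >= min_sep) {
          xyz[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) {
        if (is.null(best)) {
          # exact unperturbed step toward the center always reaches the ball
          to_c <- center - prev
          best <- prev + step * to_c / sqrt(sum(to_c^2))
        }
        xyz[i, ] <- best  # accept the least-crowded feasible candidate
      }
    }
    omit <- integer(0)
    pool <- setdiff(seq_len(protein_length), cluster_sites)
    if (omit_frac > 0 && length(pool))
      omit <- sort(sample(pool, round(omit_frac * length(pool))))
    keep <- setdiff(seq_len(protein_length), omit)
    structure_out <- structure_model(tibble::tibble(
      chain = "A", resno = keep, aa = "A",
      x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3]
    ))
    list(structure = structure_out,
         truth = list(cluster_sites = cluster_sites, omitted = omit,
                      seed = seed))
  })
}

#' Write a planted-truth sidecar
#'
#' Serializes the `truth` element any generator returns to JSON alongside
#' a dataset.
#'
#' @param truth Truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
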