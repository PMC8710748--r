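test_that("alignment generator is deterministic and byte-stable", {
  a <- simulate_msa(n_sequences = 8, n_columns = 30, seed = 5)
  b <- simulate_msa(n_sequences = 8, n_columns = 30, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(a$msa, fa)
  write_msa_fasta(b$msa, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth$important_sites, b$truth$important_sites)
  # and the FASTA round-trips through the reader
  back <- read_msa_fasta(fa, query = "query")
  expect_identical(back$matrix, a$msa$matrix)
})

test_that("frozen important columns are invariant and score rho = 1", {
  sim <- simulate_msa(n_sequences = 12, n_columns = 60, rate_ratio = Inf,
                      seed = 19)
  prof <- compute_rvet(sim$msa)
  expect_true(all(prof$rho[sim$truth$important_sites] == 1))
  expect_warning(simulate_msa(n_sequences = 4, n_columns = 10,
                              rate_ratio = 1, seed = 1), "not slower")
})

test_that("trace ranking recovers planted important sites (AUC >= 0.9)", {
  sim <- simulate_msa(seed = 1)  # default study conditions: 32 x 200
  prof <- compute_rvet(sim$msa)
  imp <- sim$truth$important_sites
  auc <- ranking_auc(prof$et_score[imp], prof$et_score[-imp])
  expect_gte(auc, 0.9)
})

test_that("gene sets are valid coding models with planted hot genes", {
  gs <- simulate_gene_set(n_genes = 12, hot_genes = 2, seed = 41)
  expect_length(gs$genes, 12)
  for (g in gs$genes) {
    expect_s3_class(g, "gene_model")
    expect_equal(nchar(g$cds), 3 * g$n_codons)
  }
  expect_equal(sort(unname(gs$multipliers[gs$truth$hot_genes])), c(8, 8))
  expect_true(all(gs$multipliers[setdiff(names(gs$genes),
                                         gs$truth$hot_genes)] == 1))
  expect_equal(gs$lengths$cds_length_bp,
               vapply(gs$genes, function(g) nchar(g$cds), integer(1)),
               ignore_attr = TRUE)
})

test_that("cohorts span all three mutation-load groups and round-trip", {
  gs <- simulate_gene_set(n_genes = 8, codon_range = c(60, 200),
                          hot_genes = 0, seed = 3)
  st <- score_gene_set(gs, seed = 3)
  co <- simulate_cohort(st, gs$lengths, n_samples = 120, seed = 13)
  expect_equal(nrow(co$variants), sum(co$samples$mutation_count))
  mlg <- assign_mlg(co$samples)
  expect_true(all(c("low", "medium", "high") %in% mlg$mlg))

  # per-gene counts within an MLG sum to the group's mutation events
  joined <- dplyr::left_join(co$variants, mlg[, c("sample", "mlg")],
                             by = "sample")
  med <- joined[joined$mlg == "medium", ]
  expect_equal(sum(table(med$gene)), nrow(med))

  # the variant TSV round-trips through the shared reader
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(co$variants[, c("sample", "gene", "tumor_site",
                                     "origin", "hgvs_p")], path)
  back <- read_variants_tsv(path)
  expect_equal(nrow(back), nrow(co$variants))
  mis <- co$variants$category == "missense"
  expect_equal(back$protein_pos[mis], co$variants$protein_pos[mis])
  expect_equal(back$ref_aa[mis], co$variants$ref_aa[mis])
  expect_equal(back$alt_aa[mis], co$variants$alt_aa[mis])
  expect_equal(back$category, co$variants$category)

  expect_error(simulate_cohort(st, gs$lengths, target_gene = "NOPE",
                               target_site = "site01", seed = 1),
               "absent")
})

test_that("without multipliers, normalized gene rates are comparable", {
  gs <- simulate_gene_set(n_genes = 10, codon_range = c(150, 500),
                          hot_genes = 0, seed = 23)
  st <- score_gene_set(gs, seed = 23)
  co <- simulate_cohort(st, gs$lengths, n_samples = 260, seed = 29)
  counts <- dplyr::count(co$variants, .data$gene)
  counts <- dplyr::left_join(counts, gs$lengths, by = "gene")
  rate <- normalized_rate(counts$n, counts$cds_length_bp, 260)
  expect_lt(stats::sd(rate) / mean(rate), 0.2)  # null: no planted spread
})

test_that("hot genes stand out in normalized rates", {
  gs <- simulate_gene_set(n_genes = 12, codon_range = c(150, 500),
                          hot_genes = 2, hot_multiplier = 8, seed = 51)
  st <- score_gene_set(gs, seed = 51)
  co <- simulate_cohort(st, gs$lengths, gs$multipliers, n_samples = 260,
                        seed = 53)
  counts <- dplyr::count(co$variants, .data$gene)
  counts <- dplyr::left_join(counts, gs$lengths, by = "gene")
  counts$rate <- normalized_rate(counts$n, counts$cds_length_bp, 260)
  top2 <- counts$gene[order(-counts$rate)][1:2]
  expect_setequal(top2, gs$truth$hot_genes)
})

test_that("age generator respects bounds and planted correlation sign", {
  rates <- withr::with_seed(61, tibble::tibble(
    gene = sprintf("g%05d", 1:10000), rate = stats::rexp(10000)))
  tilted <- simulate_ages(rates, tilt = 1.5, seed = 62)
  expect_true(all(tilted$ages$phylostratum %in% 1:19))
  # positive tilt: high-rate genes skew young (higher phylostratum index)
  expect_gt(stats::cor(rates$rate, tilted$ages$phylostratum,
                       method = "spearman"), 0.1)
  flat <- simulate_ages(rates, tilt = 0, seed = 63)
  expect_lt(abs(stats::cor(rates$rate, flat$ages$phylostratum,
                           method = "spearman")), 0.1)
})

test_that("structure generator honors geometry contracts", {
  sim <- simulate_structure(80, cluster_sites = c(10, 30, 50, 70),
                            omit_frac = 0.2, seed = 7)
  st <- sim$structure
  # consecutive resolved residues that are sequence-adjacent sit 3.8 A apart
  xyz <- as.matrix(st[, c("x", "y", "z")])
  adj <- which(diff(st$resno) == 1)
  steps <- sqrt(rowSums((xyz[adj + 1, , drop = FALSE] -
                           xyz[adj, , drop = FALSE])^2))
  expect_true(all(abs(steps - 3.8) < 1e-9))
  # planted cluster sites are always resolved and inside a 10 A ball of
  # their common centroid (pairwise distance <= 20 A)
  idx <- match(c(10, 30, 50, 70), st$resno)
  expect_false(anyNA(idx))
  expect_lte(max(dist(xyz[idx, ])), 20)
  # omit fraction 0 resolves everything; enrichment is then saturated
  full <- simulate_structure(40, omit_frac = 0, seed = 9)
  expect_equal(nrow(full$structure), 40)
  sat <- ordered_enrichment(c(4, 17, 30), full$structure,
                            protein_length = 40)
  expect_equal(sat$p_ordered, 1)
  expect_error(simulate_structure(30, cluster_sites = c(5, 40), seed = 1),
               "outside")
})

test_that("planted spatial clusters are detected", {
  sim <- simulate_structure(150, cluster_sites = c(12, 45, 80, 110, 140),
                            seed = 5)
  res <- spatial_clustering(c(12, 45, 80, 110, 140), sim$structure,
                            P = 2000, seed = 6)
  expect_lt(res$p_spatial, 0.01)
})

test_that("truth sidecars serialize to JSON", {
  sim <- simulate_msa(n_sequences = 6, n_columns = 12, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$important_sites, sim$truth$important_sites)
  expect_equal(back$seed, 2)
})
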