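toy_gene <- function(codons) {
  gene_model("TOY", paste(c(codons, "TGA"), collapse = ""))
}

test_that("gene models validate their CDS", {
  g <- gene_model("OK", "ATGGCTTGA")
  expect_equal(g$protein, "MA")
  expect_error(gene_model("X", "ATGGCTTG"), "divisible by 3")
  expect_error(gene_model("X", "GCTGCTTGA"), "start with ATG")
  expect_error(gene_model("X", "ATGGCTGCT"), "stop codon")
  expect_error(gene_model("X", "ATGTGAGCTTGA"), "internal stop")
  expect_error(gene_model("X", "ATGGCNTGA"), "A, C, G, T")
})

test_that("single-codon enumerations match the genetic code", {
  # ATG: all 9 substitutions are missense
  atg <- enumerate_snvs(gene_model("A1", "ATGTGA"))
  atg1 <- atg[atg$codon == 1, ]
  expect_equal(nrow(atg1), 9)
  expect_true(all(atg1$class == "missense"))

  # TGG: 7 missense, 2 nonsense (TAG, TGA), 0 synonymous
  tgg <- enumerate_snvs(gene_model("W1", "ATGTGGTGA"))
  tgg2 <- tgg[tgg$codon == 2, ]
  expect_equal(sum(tgg2$class == "missense"), 7)
  expect_equal(sum(tgg2$class == "nonsense"), 2)
  expect_equal(sum(tgg2$class == "synonymous"), 0)
})

test_that("enumeration partitions all 9-per-codon events, incl. stop", {
  genes <- simulate_gene_set(n_genes = 6, codon_range = c(10, 60),
                             hot_genes = 0, seed = 91)$genes
  for (g in genes) {
    tab <- enumerate_snvs(g)
    cc <- attr(tab, "class_counts")
    expect_equal(sum(cc), 9 * g$n_codons)
    expect_equal(nrow(tab), 9 * g$n_codons)
    # stop codons contribute no missense rows
    stop_rows <- tab[tab$ref_aa == "*", ]
    expect_true(all(stop_rows$class != "missense"))
    expect_true(all(is.na(stop_rows$protein_pos)))
  }
})

test_that("sensitivity is the ET-score complement", {
  prof <- tibble::tibble(residue = 1:3, et_score = c(100, 0.01, 50))
  s <- compute_sensitivity(prof)
  expect_equal(s$s, c(0, 0.9999, 0.5))
})

test_that("severity magnitudes are row-normalized with zero diagonal", {
  sev <- severity_from_logodds(blosum62())
  expect_true(all(diag(sev) == 0))
  for (a in rownames(sev)) {
    off <- sev[a, setdiff(colnames(sev), a)]
    expect_equal(min(off), 0)
    expect_equal(max(off), 1)
  }
  # hand normalization of the W row: max off-diag B = 2 (Y), min = -4
  # (D or N); B(W, G) = -2 so m = (2 - (-2)) / (2 - (-4)) = 4/6
  b <- blosum62()
  expect_equal(sev["W", "G"], (2 - b["W", "G"]) / (2 - (-4)))
  expect_equal(sev["W", "G"], 4 / 6)
  expect_error(severity_from_logodds(matrix(0, 3, 3)))
  aa <- rownames(b)
  ws <- testthat::capture_warnings(
    const <- severity_from_logodds(matrix(1, 20, 20,
                                          dimnames = list(aa, aa))))
  expect_true(any(grepl("constant", ws)))
  expect_true(all(const[row(const) != col(const)] == 1))
})

test_that("10-codon action table matches the brute-force oracle row-for-row", {
  g <- gene_model("TOY", "ATGGCTTGGAAACGCTTGGATCAGTACTGTTGA")  # 10 + stop
  prof <- simulate_profile(nchar(g$protein), g$protein, seed = 8)
  sev <- severity_from_logodds()
  got <- ea_score(enumerate_snvs(g), prof, sev)
  got <- got[order(got$cds_pos, got$alt_nt), ]
  sens_by_pos <- (100 - prof$et_score) / 100
  want <- oracle_action_table(g$cds, sens_by_pos, sev)
  for (col in c("cds_pos", "ref_nt", "alt_nt", "codon", "ref_aa", "alt_aa",
                "class"))
    expect_equal(got[[col]], want[[col]], info = col)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$ea, want$ea, tolerance = 1e-12)
})

test_that("EA is percentile-based and transform-invariant", {
  g <- gene_model("TOY", "ATGGCTTGGAAACGCTTGGATCAGTACTGTTGA")
  prof <- simulate_profile(nchar(g$protein), g$protein, seed = 8)
  tab <- ea_score(enumerate_snvs(g), prof)
  mis <- tab[tab$class == "missense", ]
  # equal raw action implies equal EA (average rank); distinct implies order
  expect_equal(order(mis$ea), order(rank(mis$r, ties.method = "average")))
  groups <- split(mis$ea, match(mis$r, unique(mis$r)))
  expect_true(all(vapply(groups, function(x) diff(range(x)) == 0,
                         logical(1))))

  # a strictly increasing transform of r leaves every ea unchanged
  # (doubling is exact in floating point, so ties are preserved bit-for-bit)
  expect_equal(mis$ea,
               100 * rank(2 * mis$r, ties.method = "average") / nrow(mis),
               tolerance = 1e-12)

  # a table reduced to a single missense event scores ea = 100
  one <- tab[which(tab$class == "missense")[1], ]
  attr(one, "gene_symbol") <- "TOY"
  attr(one, "protein") <- g$protein
  class(one) <- class(tab)
  one$ea <- NULL
  expect_equal(ea_score(one, prof)$ea, 100)
})

test_that("missing sensitivities follow the configured policy", {
  g <- gene_model("TOY", "ATGGCTTGGTGA")
  prof <- simulate_profile(2, seed = 3)  # covers positions 1-2 of 3
  expect_error(ea_score(enumerate_snvs(g), prof), "without an ET score")
  expect_message(
    tab <- ea_score(enumerate_snvs(g), prof,
                    missing_sensitivity = "median"),
    "median sensitivity"
  )
  expect_false(anyNA(tab$ea[tab$class == "missense"]))
})

test_that("variant scoring rejects and flags as contracted", {
  g <- gene_model("TOY", "ATGGCTTGGAAACGCTTGGATCAGTACTGTTGA")
  prof <- simulate_profile(nchar(g$protein), g$protein, seed = 8)
  tab <- ea_score(enumerate_snvs(g), prof)
  protein <- strsplit(g$protein, "")[[1]]

  variants <- tibble::tibble(
    gene = "TOY",
    protein_pos = c(2L, 2L, 3L, 99L, 4L),
    ref_aa = c(protein[2], protein[2], "Q", "A", protein[4]),
    alt_aa = c("P", protein[2], "P", "V", "W")
  )
  scored <- score_variants(variants, tab)
  expect_equal(scored$status,
               c("scored", "synonymous", "ref_mismatch", "out_of_range",
                 "scored"))
  expect_equal(attr(scored, "n_rejected"), 3)

  # amino-acid-level EA equals the mean over producing SNV events
  aa <- aa_level_ea(tab)
  hit <- aa[aa$protein_pos == 2 & aa$alt_aa == "P", ]
  expect_equal(scored$ea[1], hit$ea)
  ev <- tab[tab$class == "missense" & tab$protein_pos == 2 &
              tab$alt_aa == "P", ]
  expect_equal(hit$ea, mean(ev$ea))

  # K4 -> W is not reachable by one SNV: flagged and percentile-scored
  expect_true(scored$multi_nt[5])
  expect_gte(scored$ea[5], 0)
  expect_lte(scored$ea[5], 100)
  expect_false(any(scored$multi_nt[1]))
})

test_that("a radical change at the most important site tops the gene", {
  g <- gene_model("TOY", "ATGGCTTGGAAACGCTTGGATCAGTACTGTTGA")
  prof <- simulate_profile(nchar(g$protein), g$protein, seed = 8)
  tab <- ea_score(enumerate_snvs(g), prof)
  mis <- tab[tab$class == "missense", ]
  best <- mis[which.max(mis$r), ]
  v <- score_variants(tibble::tibble(gene = "TOY",
                                     protein_pos = best$protein_pos,
                                     ref_aa = best$ref_aa,
                                     alt_aa = best$alt_aa), tab)
  expect_gte(v$ea, max(aa_level_ea(tab)$ea) - 1e-12)
})

test_that("tier boundaries follow the severe/mixed/benign convention", {
  v <- tibble::tibble(ea = c(85, 50, 10, 80, 30, 29.999, NA))
  tiers <- tier_variants(v)
  expect_equal(as.character(tiers$tier),
               c("severe", "mixed", "benign", "severe", "mixed", "benign",
                 NA))
  # EA70 calibration: ea ~ 74 becomes severe
  expect_equal(as.character(tier_variants(tibble::tibble(ea = 74),
                                          severe_min = 70)$tier), "severe")
  expect_error(tier_variants(v, severe_min = 30, benign_max = 30),
               "exceed")
})

test_that("tier reports count, percentage and unique residues by origin", {
  v <- tibble::tibble(
    origin = rep(c("somatic", "germline"), c(335, 4)),
    protein_pos = c(rep(1:34, length.out = 41), 101:394, 1:4),
    ea = c(rep(90, 41), rep(50, 294), rep(90, 4))
  )
  rep1 <- tier_report(tier_variants(v))
  som <- rep1[rep1$origin == "somatic", ]
  expect_equal(som$n_total, 335)
  expect_equal(som$n_severe, 41)
  expect_equal(som$pct_severe, 12)   # 41/335 prints as 12%
  expect_equal(som$n_unique_severe_residues, 34)

  # empty input: zero-row summary, no crash
  empty <- tier_report(tier_variants(tibble::tibble(ea = double(),
                                                    protein_pos = integer(),
                                                    origin = character())))
  expect_equal(nrow(empty), 0)

  # half-away-from-zero percent rounding at one decimal
  v2 <- tier_variants(tibble::tibble(origin = "g", protein_pos = 1:400,
                                     ea = c(rep(90, 46), rep(10, 354))))
  expect_equal(tier_report(v2, digits = 1)$pct_severe, 11.5)
})

test_that("bootstrap p-values respect bounds, symmetry and the seed", {
  g <- gene_model("TOY", paste(c("ATG", rep(c("GCT", "TGG", "AAA", "CGC",
                                              "TTG"), 8), "TGA"),
                               collapse = ""))
  tab <- ea_score(enumerate_snvs(g),
                  simulate_profile(nchar(g$protein), g$protein, seed = 2))
  bg <- tab$ea[tab$class == "missense"]

  # an observation beyond the entire background at B = 999 leaves zero
  # exceedances, so the +1 correction gives exactly p = 2/(B+1)
  top <- ea_bootstrap(max(bg) + 1, bg, B = 999, seed = 3)
  expect_equal(top$p_value, 2 * (0 + 1) / (999 + 1))
  # the single largest background value: resample means tie with the
  # observation, which counts toward the tail (>= convention), so the
  # p-value stays above the correction floor yet clearly significant
  top2 <- ea_bootstrap(max(bg), bg, B = 999, seed = 3)
  expect_gte(top2$p_value, 2 / (999 + 1))
  expect_lt(top2$p_value, 0.05)

  # observed mean equal to the background mean: p near 1
  mid <- ea_bootstrap(bg, bg, B = 2000, seed = 4)
  expect_gt(mid$p_value, 0.5)

  expect_equal(ea_bootstrap(bg[1:5], bg, B = 500, seed = 7)$p_value,
               ea_bootstrap(bg[1:5], bg, B = 500, seed = 7)$p_value)
  expect_error(ea_bootstrap(numeric(0), bg), "observed")
  expect_warning(ea_bootstrap(bg[1], bg, B = 50, seed = 1), "coarse")

  td <- tidy(top)
  expect_equal(td$p.value, top$p_value)
  expect_equal(glance(top)$B, 999)
})
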