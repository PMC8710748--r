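# Independent oracles: deliberately naive re-derivations used to check the
# package's fast paths. Nothing here calls package internals beyond
# constructors.

# hand-entered standard genetic code, codons ordered base1/base2/base3 over
# T, C, A, G (classic translation-table layout)
oracle_genetic_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(sapply(b, function(p1)
    sapply(b, function(p2) paste0(p1, p2, b))))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

# pairwise fractional-identity distance by explicit double loop
oracle_identity_distance <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- if (!any(ok)) 1 else 1 - sum(mat[i, ok] == mat[j, ok]) / sum(ok)
  }
  d
}

# naive UPGMA returning the nested partitions (list over n = 1..N of integer
# group labels); ties broken by first minimal pair in row-major scan
oracle_upgma_partitions <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  partitions <- vector("list", n)
  active <- seq_len(n)
  cur <- seq_len(n)                     # cluster id per original leaf
  partitions[[n]] <- cur
  dd <- d
  step <- n
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      v <- dd[active[ii], active[jj]]
      if (v < bestv) { bestv <- v; best <- c(active[ii], active[jj]) }
    }
    a <- best[1]; b <- best[2]
    # merge b into a with size-weighted average linkage
    for (k in active) {
      if (k %in% c(a, b)) next
      dd[a, k] <- dd[k, a] <-
        (sizes[a] * dd[a, k] + sizes[b] * dd[b, k]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    cur[cur == b] <- a
    active <- setdiff(active, b)
    step <- step - 1
    partitions[[step]] <- cur
  }
  lapply(partitions, function(p) as.integer(factor(p)))
}

# direct rvET evaluation: rho_i = 1 + sum_n (1/n) sum_g entropy(g, i)
oracle_rvet <- function(rows, query_index = 1) {
  mat <- do.call(rbind, strsplit(rows, ""))
  N <- nrow(mat)
  parts <- oracle_upgma_partitions(oracle_identity_distance(rows))
  qcols <- which(mat[query_index, ] != "-")
  ent <- function(chars) {
    chars <- chars[chars != "-"]
    if (length(chars) < 2) return(0)
    p <- table(chars) / length(chars)
    -sum(p * log(p))
  }
  rho <- sapply(qcols, function(col) {
    tot <- 1
    for (n in 1:(N - 1)) {
      grp <- parts[[n]]
      for (g in unique(grp))
        tot <- tot + ent(mat[grp == g, col]) / n
    }
    tot
  })
  list(residue = seq_along(qcols), rho = rho,
       et_score = 100 * rank(rho) / length(rho))
}

# brute-force SNV enumeration + EA scoring of a CDS with the hand-entered
# code table; returns rows ordered by (cds_pos, alt_nt)
oracle_action_table <- function(cds, sens_by_pos, severity) {
  bases <- c("A", "C", "G", "T")
  nts <- strsplit(cds, "")[[1]]
  rows <- list()
  for (p in seq_along(nts)) {
    ci <- (p - 1) %/% 3 + 1
    cod <- paste(nts[(3 * ci - 2):(3 * ci)], collapse = "")
    for (alt in setdiff(bases, nts[p])) {
      acod <- cod
      substr(acod, (p - 1) %% 3 + 1, (p - 1) %% 3 + 1) <- alt
      ra <- oracle_genetic_code[[cod]]
      aa <- oracle_genetic_code[[acod]]
      cls <- if (ra == aa) "synonymous" else
        if (ra == "*" || aa == "*") "nonsense" else "missense"
      rows[[length(rows) + 1]] <- data.frame(
        cds_pos = p, ref_nt = nts[p], alt_nt = alt, codon = ci,
        ref_aa = ra, alt_aa = aa, class = cls, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  mis <- tab$class == "missense"
  r <- rep(NA_real_, nrow(tab))
  r[mis] <- sens_by_pos[tab$codon[mis]] *
    severity[cbind(tab$ref_aa[mis], tab$alt_aa[mis])]
  ea <- rep(NA_real_, nrow(tab))
  ea[mis] <- 100 * rank(r[mis]) / sum(mis)
  tab$r <- r
  tab$ea <- ea
  tab[order(tab$cds_pos, tab$alt_nt), ]
}

# exhaustive hypergeometric upper tail: draw k of L positions at random,
# P(overlap with the ordered set >= observed overlap)
oracle_hyper_upper <- function(L, ordered, k, x) {
  subsets <- utils::combn(L, k)
  mean(apply(subsets, 2, function(s) sum(s %in% ordered)) >= x)
}

# small helpers shared by tests
toy_structure <- function(coords) {
  structure_model(data.frame(resno = seq_len(nrow(coords)),
                             x = coords[, 1], y = coords[, 2],
                             z = coords[, 3]))
}

ranking_auc <- function(score_pos, score_neg) {
  # AUC for "positives have LOWER scores"
  mean(outer(score_pos, score_neg, "<")) +
    0.5 * mean(outer(score_pos, score_neg, "=="))
}
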