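---
title: "Decoding missense variants with evolutionary trace and evolutionary action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding missense variants with evolutionary trace and evolutionary action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoaction)
library(dplyr)
```

## The model

Most coding variants found in tumors and in the germline are missense
variants of unknown significance (VUS). `evoaction` implements a pipeline
that ranks them objectively from two evolutionary signals:

1. **Evolutionary trace (ET)** ranks each residue of a protein by how its
   variation partitions across a phylogenetic tree of homologs. For an
   alignment of $N$ sequences, a rooted guide tree is cut at its $n - 1$
   deepest nodes to give nested partitions $P(n)$, $n = 1 \dots N-1$, and
   the real-valued trace of column $i$ is

   $$\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g \in P(n)} S(g, i),$$

   where $S(g, i)$ is the Shannon entropy (natural log) of the non-gap
   amino-acid frequencies of column $i$ within group $g$. A column that is
   invariant everywhere scores the minimum $\rho = 1$; variation that cuts
   across deep branches is weighted most heavily (the $1/n$ factor), while
   variation confined to shallow subfamilies contributes little. $\rho$ is
   converted to a percentile `et_score` in $(0, 100]$ (average rank on
   ties), so 0 marks the evolutionarily most important residues. Residues
   are tiered for structural mapping either by fixed percentile cutoffs
   (default tier 1 $\le 2$, tier 2 $\le 4$) or by target counts derived
   from the sorted score list, which is the practical strategy when tier 1
   alone already holds the desired number of residues.

2. **Evolutionary action (EA)** scores a missense change as the product of
   the site's functional sensitivity $s_i = (100 - \mathrm{et}_i)/100$ and
   the magnitude $m_{ab} \in [0,1]$ of the amino-acid substitution, then
   percentile-normalizes the raw action $r = s_i\, m_{ab}$ against **all
   possible single-nucleotide substitutions** of the gene's coding
   sequence: every nucleotide has 3 alternatives, so a gene of $C$ codons
   defines $9C$ SNV events, partitioned into missense, synonymous and
   nonsense by the standard genetic code. EA is the within-gene percentile
   of $r$ over missense events, so EA 100 is the most damaging change the
   gene can reach in one nucleotide and, by construction, a fifth of all
   possible missense events score EA $\ge 80$. A protein-level change
   reachable by several distinct SNVs gets the mean EA of those events.

Observed variants are tiered **severe** (EA $\ge 80$; $\ge 70$ for genes
calibrated against a known active-site mutant), **mixed** (30–79) and
**benign** ($< 30$), and an observed variant set is compared with the
all-substitution background by a bootstrap test on the mean EA.

At cohort level, samples are stratified into **mutation-load groups**
(low $\le 40$, medium 41–700, high $\ge 701$ mutations per sample), gene
mutation counts are normalized to **mutations per 100 bp of coding
sequence per 1,000 patients**, ranked, and split into 35 equal bins whose
gene-age (phylostratum) medians expose the age–mutability trend. The
**selection index** for a gene in a tumor type is
$si = (mut \cdot 100 / tot)\,/\,(med / 1000)$ — the percentage of samples
carrying damaging mutations (EA $\ge 60$), normalized by the type's median
burden in thousands — and a tumor type is flagged when its $si$ exceeds
the cross-type upper 99% confidence bound
$\bar{si} + t_{0.995, k-1}\, sd/\sqrt{k}$.

Finally, per-residue scores and flagged sites are mapped onto Cα
coordinates; co-localization with **ordered regions** (residues resolved
in the coordinate file, or a user-supplied order mask) is tested with the
hypergeometric upper tail, and spatial clustering with a permutation test
on the mean pairwise Cα distance.

## A worked example

```{r trace}
sim <- simulate_msa(seed = 1)          # 32 sequences x 200 columns
profile <- compute_rvet(sim$msa)
head(profile, 3)
```

```{r ea}
gene <- gene_model("TOY", "ATGGCTTGGAAACGCTTGGATCAGTACTGTTGA")
prof <- simulate_profile(nchar(gene$protein), gene$protein, seed = 8)
scored <- ea_score(enumerate_snvs(gene), prof)
variants <- score_variants(
  parse_hgvs(c("p.A2P", "p.Trp3Arg")) |>
    transmute(gene = "TOY", protein_pos = position, ref_aa, alt_aa),
  scored)
tier_variants(variants)[, c("protein_pos", "ref_aa", "alt_aa", "ea", "tier")]
```

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `tier1_max`, `tier2_max` | 2, 4 | ET percentile | focused structural maps; count mode (`tier1_n`) available when tier 1 is already large |
| `severe_min`, `benign_max` | 80, 30 | EA | the severe boundary is inclusive (EA = 80 is severe) so the three tiers partition $[0, 100]$; genes calibrated on a benchmarked active-site mutant use 70 |
| `ea_min` (selection scan) | 60 | EA | damaging-mutation threshold for counting mutated samples |
| `min_mutated_samples` | 3 | samples | a tumor type qualifies for the scan only with at least 3 mutated samples |
| `low_max`, `high_min` | 40, 701 | mutations/sample | mutation-load group boundaries |
| `n_bins` | 35 | bins | equal-size mutability bins per load group |
| `B` (bootstrap) | 100,000 | resamples | published resampling depth; tests use smaller B for speed |
| `max_gap_frac` | 0.5 | fraction | rows gapped above this fraction of query columns are dropped before tracing |

## Design choices

* **Guide tree.** The trace needs a rooted binary tree with nested
  partitions; we use UPGMA (average linkage) on fractional-identity
  distance, scored over mutually non-gap columns. It is deterministic,
  standard, and any tie in merge order only permutes groups within a
  level, which the entropy sum does not see. The partition at level $n$
  is exactly the $n$-group cut of the dendrogram.
* **Gap handling.** Gaps never enter frequency counts; all-gap groups
  contribute zero entropy; columns where the query is gapped are excluded
  from the profile (they have no query residue number); heavily gapped
  homolog rows can be dropped up front. This is the simplest behavior
  consistent with a gap-reducing trace, and it is isolated behind
  `max_gap_frac` and the `aa_msa` column map so alternative weightings
  can be swapped in.
* **Entropy log base.** Natural log. The base rescales $\rho$ but can
  never reorder it, and only ranks reach the percentile score.
* **Ties.** Average rank everywhere (ET percentile, EA percentile), which
  makes both scores invariant under row reordering and id renaming.
* **Severity matrix.** The magnitude $m_{ab}$ is a row-wise min–max
  normalization of a standard symmetric amino-acid log-odds matrix
  (BLOSUM62 shipped in source): the most-favored substitution from each
  residue scores 0, the least-favored 1, the diagonal 0. The published EA
  method trains substitution-odds tables stratified by ET percentile;
  those tables are not public, so the product-and-percentile form here is
  an explicit approximation, isolated behind the `severity_matrix`
  interface.
* **Stop codons.** The enumeration classifies any event that creates *or*
  destroys a stop as nonsense, so missense + synonymous + nonsense
  partition all $9C$ events and stop codons contribute no missense rows.
* **Bootstrap statistic and tails.** The resampling depth (100,000) is the
  field's convention, but the statistic is open; we resample the
  SNV-event-weighted background EA (an amino-acid change reachable by two
  SNVs counts twice), use the mean as statistic, and report a two-sided
  p-value with the $(c+1)/(B+1)$ correction. Resample means tied with the
  observed statistic count toward the tail — the conservative convention —
  so the p-value for an observation equal to the background maximum sits
  above the $2/(B+1)$ floor.
* **Selection-index confidence bound.** The cross-type bound is a
  t-interval on the mean of the per-type $si$ values, the simplest
  construction for an upper 99% limit over a handful of types; a percentile
  bootstrap bound is available behind `ci = "bootstrap"` and the output
  labels the method used.
* **Ordered regions.** Operationalized as "resolved in the supplied
  coordinate file" (first model, Cα only, insertion codes rejected); a
  disorder mask can be passed explicitly instead.

## What the generators emulate — and what they do not

`simulate_msa` evolves sequences down a random binary tree under an
equal-exchange substitution process with two rate classes (default: 32
sequences, 200 columns, 20% important sites, 10:1 rate ratio). That is all
the trace consumes — rate classes distributed over a tree — but it is not
a named empirical substitution model, produces gapless alignments by
default, and plants no correlated or epistatic sites.

`simulate_cohort` draws per-sample burdens log-uniform across four orders
of magnitude (so all three load groups are populated, matching the
spread seen in tumor cohorts), assigns mutations to genes proportional to
CDS length times a mutability multiplier, and draws SNV events uniformly
from the enumerated tables — except the planted selection target, whose
events in one tumor site are tilted with probability
$\propto e^{\lambda\,\mathrm{EA}/100}$ ($\lambda = 3$). The burden draw is
stratified (systematic log-uniform quantiles, permuted) within each tumor
site: marginally the distribution is unchanged, but per-site medians are
comparable, which is the regime the selection index's median
normalization assumes — real tumor types differ in median burden, and the
index deliberately divides that difference out. The default cohort is
1,560 samples over 13 tumor sites (120 per site), a desk-scale stand-in
for cohorts two orders of magnitude larger; recovery experiments plant
the target on a short gene because a long gene saturates (nearly every
medium-burden sample carries some damaging event in it) and leaves no
contrast for any method to find. No trinucleotide mutational signatures,
indel length structure, or gene–gene correlation are modeled.

`simulate_ages` tilts phylostratum sampling (1 = origin of life, 19 =
primates) so that high-rate genes skew young; `simulate_structure` builds
a self-avoiding 3.8 Å Cα walk, steers planted cluster residues into a
10 Å ball, and omits a fraction of the remaining residues as disordered.

Passing the planted-truth tests therefore shows the estimators recover
signal of the assumed form at these sizes; it does not certify
performance on real alignments (alignment error, gap structure,
covariation) or real cohorts (signatures, subclonality, driver
co-occurrence).

## Numerical and degenerate-input behavior

Percent summaries round half away from zero at a configurable precision.
Empty variant sets give zero-row reports rather than errors; a tumor
type with fewer than the minimum mutated samples is excluded from the
scan, and fewer than two qualifying types leaves the confidence bound
undefined with nothing flagged. Zero flagged sites give a null
co-localization result; fewer than two resolved flagged sites give a null
spatial result. Positions without an ET score error under the strict
policy or take the median sensitivity under the lenient one, with a
message either way. All sequence and CDS coordinates are 1-based closed,
matching HGVS convention, and every generator is a pure function of its
seed.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the trace at 32 × 200
(planted-site AUC), EA enumeration up to a 500-codon gene (~13,500 SNV
events), twenty 1,560-sample cohorts for the selection-scan recovery,
2,100 genes × 35 bins for the age trend, a 150-residue fold with 10,000
permutations for spatial clustering, and 200 null bootstraps at
B = 2,000 for calibration. These sizes were chosen so the full pipeline
exercises every stage in minutes on a laptop while keeping each planted
signal comfortably above its detection threshold.

## Known limitations

The trace's gap weighting and homolog pre-selection are simplified
relative to the reference implementation, and the EA severity table is a
stand-in for trained ET-stratified odds tables, so absolute EA values for
real proteins will differ from published ones even though the percentile
construction, tiering and downstream statistics are faithful. Splice
effects, indels and frameshifts are counted but never scored. The
selection scan inherits the noise of per-type medians in small cohorts;
its confidence bound is a bound on the mean index, not a prediction
interval, so isolated modest exceedances deserve skepticism.
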