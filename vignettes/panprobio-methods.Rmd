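---
title: "panprobio: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panprobio: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panprobio)
```

# Scope

panprobio implements a comparative-genomics and microbiome-association
pipeline for bacterial strain collections, aimed at the kind of question a
probiotic-genomics study asks: which genomes are trustworthy, how diverse is
each species' gene repertoire, which strain combinations complement each
other functionally, and how do the species behave in case/control gut
metagenomes. Every stage is driven either by user-supplied tables (metadata,
homology-search hits, KO assignments, abundance profiles) or by the
package's own seeded generators, so the full pipeline is testable with no
external downloads or search binaries.

# Genome quality control

Three gates are applied in order:

1. **Draft-assembly criteria.** `hmp_draft_pass()` requires (i) at least
   98% of the assembly in contigs longer than 500 bp, (ii) scaffold N50
   above 20 kb, (iii) contig N50 above 20 kb, (iv) mean contig length above
   10 kb, and (v) more than 90% of a reference core-gene set detected.
   Criteria (ii)–(v) are strict inequalities ("more than"); criterion (i)
   is `>= 0.98` ("98% must be present"). We read the wording literally and
   test the boundaries explicitly, because QC gates are exactly the kind of
   code where off-by-one-epsilon behaviour silently changes cohort
   composition. The core-gene catalogue is a configurable input — the
   package does not ship one. The contig-fraction denominator is the total
   assembly length (the alternative, the contig sum, differs only when
   scaffolding gaps are large).
2. **Completeness/contamination.** `checkm_gate()` passes only genomes
   with completeness above 95% and contamination below 5%, both strict.
   The package consumes these as numbers; it does not run the assessment
   tool itself.
3. **Intra-species identity purity.** Within a species, every genome pair
   must exceed 93% ANI. When a pair fails, `intra_species_purity_filter()`
   iteratively drops the genome with the lowest mean intra-species ANI and
   re-checks. The removal order is our choice (the rule is not fully
   specified by the gate itself): removing the most "mis-distributed"
   genome per step is greedy but deterministic, and the result is a fixed
   point — re-running the filter on the retained set removes nothing.

Isolation sources are classified friendly/unfriendly/unknown by a
case-insensitive keyword table (`friendliness_keywords()`), seeded with
food-fermentation and clinical/environmental vocabulary; callers can
extend or replace it.

# Fragment-based ANI and AAI

`one_way_identity()` cuts the query into consecutive fragments (defaults:
1,020 bp for nucleotides, 300 aa for proteins), places each fragment on the
reference by exact k-mer seeding (k = 11 nt / 4 aa) with diagonal voting,
and scores the winning placement ungapped. Fragments are accepted at >= 30%
identity over >= 70% of the fragment — the conventional fragment-ANI
acceptance rule — and the one-way value is the mean identity of accepted
fragments. `symmetric_identity()` is the mean of the two directions, which
makes ANI/AAI symmetric by construction; AAI is the identical procedure on
amino-acid sequences.

Design notes:

* The identity denominator is the number of aligned columns of the
  fragment, not the nominal fragment length; coverage is accounted
  separately by the 70% rule.
* Ties in the modal diagonal are broken toward the smallest reference
  offset, so results are deterministic.
* "No accepted fragments" is reported as a flagged `NA`, never as 0 —
  an identity of zero is a measurement, absence of alignment is not.
* There are no indels in the placement model. This is adequate for the
  package's use (collinear genomes, synthetic benchmarks, within-species
  comparisons); genomes with heavy rearrangement or high indel density
  would need an external aligner, which is deliberately out of scope.

Species-level AAI (`aai_stats()`) matches core-protein sets between every
strain pair by reciprocal best hits; a strain-pair AAI is the mean RBH
identity, a species-pair value is the mean over its cross-species strain
pairs, and the intra-species AAI standard deviation (an input to the
openness regression below) is the SD of within-species strain-pair values
(defined as 0 for a species with a single pair). Per-protein-pair identity
is counted over the shorter sequence (local-alignment identity times
coverage); raw local-alignment identity alone would rate two unrelated
proteins highly on the strength of a few chance residues. At a 70% AAI
cutoff, `aai_clusters()` returns single-linkage components.

# Pan-genome and openness

`cluster_gene_families()` clusters proteins greedily: sequences sorted
longest-first (ties broken lexicographically), each sequence joining the
first representative it matches at >= 95% identity over >= 90% of the
shorter sequence, else founding a new family. Identity and coverage come
from local alignment; a shared-8-mer prescreen skips impossible
representatives, and is loss-free for the default thresholds: a region at
>= 95% identity spanning >= 90% of the shorter sequence has mismatch
density at most 5%, so it must contain a run of at least 8 exact matches.
The greedy result is checked against a brute-force oracle in the test
suite.

The pan-genome index is

$$\mathrm{PI} = \frac{\text{pan-genome family count}}
                     {\text{mean per-genome family count}}$$

with openness levels A (PI <= 1.5, relatively conserved), B (1.5 < PI <= 3,
half-open), and C (PI > 3, relatively open). Note the orientation: the
quantity is pan over mean, which is >= 1 for non-empty genomes and grows
with repertoire diversity — this is the only orientation under which the
published per-species index values (all >= 1.24, open species largest) and
the openness semantics are consistent, even though openness indices are
sometimes verbally described in the inverted form. The denominator counts
deduplicated families per genome by default (`count = "genes"` uses raw
gene counts instead).

`rarefaction_curves()` averages pan (union) and core (intersection) sizes
over random genome orderings; 100 permutations by default, seeded.
`openness_correlates()` regresses PI on isolation-source count, genome
count and intra-species AAI SD — per-factor Pearson R² plus a combined
three-predictor OLS with the overall-F p-value; constant predictors are
flagged and excluded.

# Annotation filtering and functional comparisons

`filter_hits()` applies the database-specific acceptance rules (KEGG: query
coverage >= 50%; ARDB: query and subject coverage >= 40% and identity
strictly above the per-gene recommended threshold; VFDB and CAZy: query
coverage >= 50% and identity >= 60%), then keeps one best accepted hit per
query per database (highest identity, ties by subject identifier). Query
coverage is alignment length over query length; the best-hit policy
prevents one gene from contributing to several features. ARDB rows lacking
their per-gene threshold are rejected with a warning rather than silently
passed.

`feature_enrichment_matrix()` reproduces the "how many other species are
significantly weaker" display: per feature and species pair an unpaired
rank-sum test on strain-level counts, BH adjustment jointly across all
tests in the call (one figure panel = one correction family; a per-feature
switch would be easy to add but the joint family is the default), and a
cell counts the species beaten at q < 0.05. `risk_burden_compare()` tests
summed virulence/resistance gene counts between friendly and unfriendly
source groups, with `*`/`**` stars at p < 0.05 / p < 0.01.

# KEGG-module complementarity

Module integrity is the fraction of a module's required ("key/essential")
KOs present in a genome; the total T(G) sums integrities over modules. For
a pair, KO sets are merged and

$$\mathrm{ratio} = \frac{T(A \cup B) - \max(T_A, T_B)}{\max(T_A, T_B)}.$$

The baseline is a design choice: we measure gain over the **better** single
genome, which is conservative (a `baseline = "mean"` option divides by the
mean of the two instead; the numerator is unchanged). Because integrity is
monotone under set union, the ratio is never negative, and it is symmetric
in the pair. The degenerate case T_A = T_B = 0 yields 0 when the merged
total is also 0, and is flagged `infinite-improvement` (excluded from
species-level means) when merging creates integrity out of nothing.
Module definitions are flat required-KO sets; KEGG's boolean module
expressions (AND/OR complexes) are not interpreted.

`enumerate_cross_species_pairs()` lists all unordered strain pairs with
different species labels and carries the closed-form count
C(N,2) − Σ C(n_s,2) as a cross-check. `species_pair_summary()` averages
ratios per species pair, ranks them descending and assigns terciles
(top/middle/last third by rank), matching the way species-pair
complementarities are usually displayed; infinite-flagged strain pairs are
excluded from means.

# Case/control enrichment and co-abundance networks

`differential_enrichment()` tests each species' relative abundances
between case and control samples (unpaired two-sided rank-sum), adjusts
with BH across species, and assigns a direction — the group with the
higher **mean rank**, not the higher mean abundance, which is robust to the
heavy tails of abundance data — only when q < 0.05. All-zero species are
skipped and reported.

`build_coabundance_network()` takes the enriched species as nodes and
computes Pearson correlations over **all** samples, case and control
pooled. An edge requires raw p < 0.05 and cc > 0.4 (positive) or
cc < −0.1 (negative); the p-values are deliberately not
multiplicity-corrected, because the edge rule is stated on raw p (unlike
node selection, which uses q). Edge widths bin on |cc| (thick >= 0.7,
medium in [0.4, 0.7), thin in (0.1, 0.4)); nodes carry direction, mean
abundance with its decade bin (1/10 … 1/10^6, below that "<1/10^6"),
degree, and top-10 flags for degree and abundance with lexicographic tie
breaks. Networks export to GraphML for external layout tools.

A methodological caveat we reproduce rather than "fix": Pearson
correlation on relative abundances is compositionally fragile (closure
induces spurious negative dependence, and a strong group effect shared by
two species induces real pooled correlation). The package follows the
stated procedure; users wanting compositionally robust networks should
transform their data upstream.

`mapping_ratio_compare()` handles the read-mapping validation route:
per-sample mapped/total ratios compared between groups per target, BH
across targets.

# Shared statistical core

All group comparisons route through `ranksum()`: exact enumeration of the
rank-sum null when both groups have at most 12 observations and there are
no ties, otherwise the tie-corrected normal approximation with continuity
correction. The switchover is configurable; 12 keeps exact enumeration
instant while covering the strain-count scales where the approximation is
weakest. Two-sided p-values throughout; direction is extracted separately
from mean ranks. `bh_fdr()` is Benjamini–Hochberg step-up (q >= p
elementwise, monotone); `pearson_cor()` uses the t transform with n − 2
degrees of freedom and flags constant input instead of erroring.

# Synthetic data and what the tests do (and do not) show

The generators produce every input the pipeline consumes, with the planted
truth returned alongside:

* `sim_pangenome()` plants gene families (core in every genome, accessory
  per genome with fixed probability). Ancestor proteins are random
  sequences kept mutually dissimilar — an ancestor is resampled if it
  shares any 8-mer with a previous one, which keeps inter-family identity
  far below the clustering threshold — and per-genome copies mutate at
  most 0.5% of residues, so within-family pairs stay >= 99% identical.
  Clustering at 95%/90% therefore recovers the planted families exactly,
  and the planted PI equals the closed-form pan/mean ratio of the
  constructed sets.
* `sim_divergence_pair()` substitutes sites at rate d with no indels; the
  realized substitution count is the oracle for fragment-ANI accuracy
  (recovery within ±0.5 of 100·(1−d) across d = 0.01…0.07).
* `sim_ko_pair()` realizes a target complementarity ratio exactly as
  r = C/(2B + C) from B fully shared and C disjoint-half modules, erroring
  on unrepresentable targets.
* `sim_abundance()` draws log-normal abundances (log10 means over ~3
  decades, log10 SD 0.5 — a realistic dynamic range for species-level
  stool profiles), multiplies planted species by `effect_fold` in their
  group, renormalizes each sample to the declared scale, and gives a block
  of species a shared latent factor. The block's target correlation is
  specified on the observed abundance scale; internally the latent
  log-scale correlation is set by inverting the log-normal correlation
  formula, and renormalization attenuates it mildly (realized block
  correlations cluster around ~0.75 for a 0.8 target at the default
  geometry). Block species share one enrichment direction, since opposite
  group effects would cancel pooled correlation.

Two honest consequences of compositionality are worth knowing when reading
test output. First, planting strong effects on some species slightly
depresses all others in that group after renormalization, so a few
background species can be genuinely (not spuriously) called in the
opposite direction. Second, pooled group effects induce real cross-species
correlation; the network-recovery benchmark therefore uses the
block-plus-independent-background scenario (no group effect), where
"spurious edge" is well defined. The defaults — 100 case and 100 control
samples, 100 species, 4-fold effects, a 5-species block at 0.8 — are the
study conditions for all recovery claims; tests at these sizes run in
seconds to a couple of minutes.

What passing tests do **not** show about real data: no phylogenetic
gain/loss structure in gene repertoires, no indels or rearrangements in
the divergence model, no KEGG boolean logic, no sequencing noise or
unclassified mass in abundance tables, and cohort effects are absent. The
generators are benchmarks for correctness of the implementations, not
emulators of biological complexity.

# Problem sizes and reproducibility

The test suite and the acceptance script (`scripts/acceptance.R`) run the
oracle-equivalence sweeps at 100 clustering instances (<= 30 sequences
each), all rank-sum group splits with n <= 12, and 1,000 random module
systems; recovery runs use 20 kb divergence pairs and 200-sample abundance
tables. These sizes give tight Monte-Carlo error on every calibration
claim while keeping a full run in minutes on one core. All randomness
flows from a single seed argument; regeneration with the same seed is
byte-identical.

# Known limitations

* The fragment identity engine assumes collinearity; it is not a
  replacement for whole-genome aligners on rearranged genomes.
* Greedy longest-first clustering depends on input order only through the
  documented sort; it does not split paralogs and has no notion of
  orthology beyond single linkage to a representative.
* The co-abundance network inherits every weakness of Pearson-on-relative
  -abundance analysis (by design, see above).
* The purity filter's removal order is one reasonable policy among
  several; with pathological identity matrices, different orders can
  retain different (equally valid) maximal consistent sets.
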