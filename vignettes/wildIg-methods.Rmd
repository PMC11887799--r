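---
title: "Models and methods behind wildIg"
author: "wildIg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wildIg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildIg)
```

wildIg implements two linked analyses of humoral immunity against the gut
microbiota, motivated by experiments that compare conventional laboratory
mice with mice released into an outdoor enclosure ("rewilded" animals): the
scoring of antibody binding to individual gut taxa from sorted-fraction 16S
sequencing (IgG-seq / IgM-seq), and the inference of B cell clones from
annotated single-cell receptor rearrangements together with repertoire-level
statistics. This vignette explains the underlying models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The antibody-binding score

In an IgG-seq or IgM-seq experiment, fecal bacteria are incubated with
autologous plasma, stained with anti-IgG or anti-IgM beads, and sorted into
an antibody-**bound** and an **unbound** fraction, with the pre-sort
community kept as the **input**; each fraction is profiled by 16S
sequencing. For taxon $t$ in sample $j$ the Ig score is

$$ s_{t,j} \;=\; \log_2 \frac{p^{\mathrm{bound}}_{t,j}}
   {p^{\mathrm{unbound}}_{t,j}}, $$

where $p$ denotes relative abundance after adding a pseudocount
$\varepsilon$ to every count. Positive scores mean preferential antibody
targeting. Choices worth spelling out:

* **Log base.** The published description says only "log ratio"; we fix
  base 2 and record it in the result object, so scores read as fold changes
  in doublings.
* **Pseudocount.** $\varepsilon = 1$ (Laplace smoothing) on every count in
  every fraction, configurable. It guarantees finite scores; its distortion
  of a proportion is bounded by roughly $2\varepsilon/N$ at depth $N$, which
  is negligible at the depths simulated here ($N = 5 \times 10^4$).
* **Prevalence rule.** Taxa detected (bound + unbound count > 0) in fewer
  than `minPrevalence = 2` samples are dropped and listed in the result
  metadata. No prevalence rule is stated in the published description; two
  samples is the weakest rule that prevents single-sample artifacts.
* **Fold differences between groups.** `taxonTests()` reports the
  difference of group means of log2 scores (rewilded minus laboratory),
  which equals the log2 fold change of the geometric-mean enrichment
  ratios. A ratio-of-means reading of "mean fold difference" is also
  defensible; we chose the difference-of-log-means form because scores are
  already on a log scale and group means of logs are the conventional
  summary. P values are two-sided Mann-Whitney U tests, exact by complete
  enumeration of group assignments whenever $n_1 n_2 \le 64$ (ties handled
  by midranks), and a tie-corrected normal approximation otherwise. Raw P
  values are reported (as in the source figures); a Benjamini-Hochberg
  column is added for convenience.

Under the sorting model below, scores converge to
$\log_2\!\big(b_t/(1-b_t)\big)$ as depth grows — the log-odds of the binding
probability — so ranking taxa by mean score ranks them by binding
probability.

## Ordination and group inference

Sample score profiles are compared through pairwise Pearson correlations
$r_{ij}$, converted to distances as $d_{ij} = \sqrt{2(1 - r_{ij})}$. This
conversion, rather than $1 - r$, is deliberate: $\sqrt{2(1-r)}$ equals the
Euclidean distance between z-scored profiles (scaled by $1/\sqrt{m}$), so
the distance matrix is Euclidean-embeddable and classical scaling yields no
negative eigenvalues from the conversion itself. The plain $1 - r$ variant
remains available by flag. Principal coordinates analysis is classical
metric scaling (double-centering of $-\tfrac12 D^2$); negative eigenvalues,
when they occur, are reported but their axes dropped.

Group separation is tested by one-way PERMANOVA:
$SS_{\mathrm{total}} = \tfrac1n \sum_{i<j} d_{ij}^2$,
$SS_{\mathrm{within}} = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = \big(SS_{\mathrm{between}}/(g-1)\big) /
\big(SS_{\mathrm{within}}/(n-g)\big)$. Two details matter for small
designs:

* When the number of distinct relabelings is at most 10,000, the null is
  enumerated completely and P is exact (the four-sample worked example in
  the test suite has exactly three distinct balanced partitions and
  $P = 1/3$).
* Otherwise P uses random permutations with the identity included:
  $P = (1 + \#\{F_\pi \ge F_{\mathrm{obs}}\})/(1 + n_\pi)$, the standard
  positively biased (never anti-conservative) estimator, so
  $P \ge 1/(n_\pi + 1)$. Ties in $F$ count as exceedances. The default is
  999 permutations.

## Clonal inference from rearrangements

The package consumes already-annotated heavy-chain rearrangements in the
AIRR tab-separated layout (V(D)J annotation itself is out of scope).
Quality control retains records with non-empty V and J calls, locus
agreement among the V/J/constant-region calls (IGH/IGK/IGL prefixes), fewer
than 10 noninformative N positions in the full sequence alignment, a CDR3
junction devoid of N, a junction length divisible by 3, and a productive
rearrangement. One reading deserves a note: "noninformative positions" are
counted as characters outside A/C/G/T *excluding* alignment gap characters
(`.` and `-`), since IMGT-gapped alignments would otherwise always fail.

Clones are then inferred in the conventional way:

1. **Partition** by allele-stripped V gene, J gene and junction length
   (ambiguous comma-separated calls resolve to the first listed gene).
2. **Nearest-neighbor distances.** For every sequence with a partition
   mate, the minimum normalized Hamming distance on the junction
   (N positions excluded from numerator and denominator). The distribution
   is typically bimodal: a near-zero clonal mode and a background mode of
   unrelated sequences. Hamming distance with uniform weights is the
   simplest model consistent with a nearest-neighbor distance distribution;
   substitution-weighted variants are out of scope.
3. **Threshold.** A two-component univariate Gaussian mixture is fitted by
   EM (k-means initialization, restart cap of 100) and the threshold is the
   point between the component means where the posterior responsibilities
   cross. Before fitting, a kernel-density screen requires at least two
   modes (heights at least 5% of the peak); a single-mode distribution and
   component means closer than one standard deviation both raise a labelled
   error advising a manual threshold. If the EM crossing cannot be
   bracketed, the threshold falls back to the KDE valley between the two
   dominant modes. Estimation can be pooled or per-environment
   (`by =` argument); the default pools, since per-environment estimates on
   small repertoires are noisy. At least 50 distances are required. When
   estimation is skipped entirely, the default cutoff is 0.03, the value
   typically fitted on data of this kind, and always overridable.
4. **Single-linkage clustering** within each partition, cut at the
   threshold. Cutting a single-linkage tree at $\theta$ is exactly the
   connected components of the graph joining pairs at distance
   $\le \theta$, which is what the property tests verify by brute force.
   Determinism does not depend on input order: partitions are visited in
   sorted key order and records sorted by `sequence_id`.
5. **Duplicate collapse.** Within a clone, records with identical aligned
   V(D)J sequences merge unless they differ in B cell compartment or
   constant-region call; the merged record keeps the smallest
   `sequence_id` and a `duplicate_count`.

## Repertoire statistics

* **Mutation frequency** counts mismatches between the observed and
  germline alignments over positions where both carry an unambiguous base,
  pooling replacement and silent changes (as the source methods do); clone
  medians summarize clonal mutation load.
* **Diversity** is computed over clone relative sizes: richness (Hill
  order 0) and Simpson's index in the *inverse* form (Hill order 2,
  $1/\sum p_i^2$), the repertoire convention for "effective number of
  clones"; the Gini-Simpson form is available by flag since the published
  description does not pin the form down. Group uncertainty uses a cell
  bootstrap: each replicate resamples cells with replacement to the common
  size $n = \min$ group cell count and recomputes both indices; the delta
  distribution of replicate-wise differences carries a 95% percentile
  interval. Resampling cells (not clones) to a common depth was chosen
  because richness is depth-sensitive; the published description of the
  bootstrap leaves the scheme open. Diversity can be computed over clones
  (default) or unique sequences by passing the appropriate identifier
  vector.
* **Kolmogorov-Smirnov comparisons** of mutation-frequency distributions
  use the two-sided $D$ statistic with an asymptotic P value by default; the
  exact small-sample null is available and is checked against a complete
  enumeration oracle in the tests.
* **Constant-region usage** is the per-group frequency of allele-stripped
  constant-region genes among records with a call; uncalled records are
  counted separately rather than silently dropped.
* **Clonal networks** have one node per BCR-containing cell and an edge
  between same-clone cells at junction distance at most the threshold; the
  edge list is sorted and deterministic, and `asIgraph()` hands the graph
  to igraph for anything beyond export.

## What the simulators emulate — and what they do not

`simulateIgSeq()` models the sort probabilistically: a sample's community
$a$ is drawn from a Dirichlet around its group base (concentration 200 by
default, a moderate mouse-to-mouse variability), the input fraction is a
multinomial of depth $N$ from $a$, and the bound/unbound fractions are
multinomials from $a_t b_t$ and $a_t (1 - b_t)$ (normalized) — exactly
complementary partitions of the community in expectation. Column losses,
carryover between fractions, staining efficiency and chimeras are *not*
modeled; no data are available to calibrate them. The default community has
30 taxa across six orders with laboratory abundances on a Zipf-like
$1/i^{0.7}$ profile; the rewilded group doubles the Clostridiales block and
scales Erysipelotrichales by 0.4 (the direction reported for these data),
raises IgM binding odds of the Clostridiales block threefold, raises IgG
binding odds of Lactobacillaceae and lowers Akkermansia's. Binding
probabilities are spread over logits $-2.2\ldots2.2$ in a fixed scrambled
order so binding rank and abundance rank are unrelated. Sequencing depth
per fraction defaults to $N = 50{,}000$ reads — the source does not report
per-fraction depths, so this is a typical 16S depth chosen once. Group
sizes default to 8 samples per group, the study design.

`simulateRepertoire()` draws clone sizes from a power law (exponent 2.5,
truncated at 100), gives each clone a germline with the junction embedded
in a 300-nt gapless alignment, and mutates members with independent
per-site Bernoulli substitutions at the group's hypermutation rate —
uniform across positions and target bases, with no hot/cold spots (none
are specified in the source). Junctions of distinct clones in the same
V/J/length partition are kept at normalized distance at least 0.3, so true
clones are unambiguous and recoverable. Defaults follow the study
conditions where stated: 1381 laboratory and 1178 rewilded cells (the
captured productive heavy chains), a slightly higher mutation rate in
rewilded animals (0.013 vs 0.010 per site, giving the modest rightward
shift of clone mutation loads), and a raised IGHD constant-region weight in
the rewilded group (0.25 vs 0.12). Two percent of records receive a
deliberate QC defect (cycling through the six failure modes) and two
percent are duplicated verbatim to exercise duplicate collapse. The
generator does not model sequencing error, paired light chains, allelic
inclusion or compartment-specific mutation rates — so passing tests
demonstrate correctness of the inference machinery under the stated
generative model, not robustness to every artifact of real repertoires.

## Problem sizes and numerical notes

The test suite and the acceptance script size their simulations for
precision rather than bulk: deep sorts ($10^6$ reads) for the closed-form
score check, 500 replicates for PERMANOVA null calibration (the rejection
rate at $\alpha = 0.05$ must fall inside the binomial 99% band
[0.028, 0.078]), 100 replicates for preset power, 2000-cell repertoires for
clone recovery (adjusted Rand index vs ground truth $\ge 0.99$) and
mutation-rate recovery ($\pm 0.002$ of $\mu = 0.01$), and 200 random
repertoires of up to 50 sequences for the clustering-vs-components
equivalence. All randomized operations take explicit integer seeds, fixed
seeds reproduce outputs byte-exactly, and degenerate inputs (all-zero
counts without pseudocount, constant profiles, all-identical distances,
unimodal distance distributions, groups of size one) raise labelled errors
rather than propagating NaNs.

Known limitations: PERMANOVA is one-way only (no strata, no PERMDISP
companion); the distance threshold fit assumes two Gaussian components on
the raw distance scale; exact Mann-Whitney enumeration is quadratic in
$\binom{n}{n_1}$ and is capped at $n_1 n_2 \le 64$ by default; and IgA-seq
is deliberately unsupported (fecal IgA precludes the autologous plasma
assay this package models).
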