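# wildIg

Tools for asking two questions about humoral immunity and the gut
microbiota, in the setting of laboratory mice "rewilded" into an outdoor
enclosure:

1. **Which gut taxa do circulating IgG and IgM target, and does that differ
   between environments?** From IgG-seq / IgM-seq experiments — fecal
   bacteria incubated with autologous plasma, sorted into antibody-bound and
   unbound fractions, each profiled by 16S sequencing — the package computes
   per-taxon **Ig scores**

   $$ s_{t,j} = \log_2\!\frac{p^{\mathrm{bound}}_{t,j}}{p^{\mathrm{unbound}}_{t,j}} $$

   (relative abundances with pseudocount), ordinates samples by PCoA on
   Pearson-correlation distances $\sqrt{2(1-r)}$, tests group separation by
   PERMANOVA (exact by enumeration on small designs), and contrasts taxa
   between groups with exact tie-aware Mann-Whitney U tests.

2. **How does the B cell receptor repertoire change?** From annotated
   single-cell heavy-chain rearrangements (AIRR tab-separated layout) the
   package runs the standard clonal-inference chain — a six-rule QC filter,
   partitioning by V gene / J gene / junction length, nearest-neighbor
   junction Hamming distances, a Gaussian-mixture distance threshold,
   single-linkage clonal clustering, duplicate collapse — and computes
   somatic-hypermutation profiles, clone diversity (richness and inverse
   Simpson) with bootstrap group deltas, Kolmogorov-Smirnov comparisons,
   constant-region usage and clonal networks.

Both arms come with a first-class synthetic-data module
(`simulateIgSeq()`, `simulateRepertoire()`) that generates experiments with
known ground truth — binding probabilities per taxon, true clone labels,
true mutation rates — so every inference step is testable without any
external data. See `vignette("wildIg-methods")` for models, parameter
choices and limitations.

## Worked example

```r
library(wildIg)

## simulate a sorted-fraction experiment: 30 taxa, 8 mice per group
sim <- simulateIgSeq(igseqPreset(), seed = 17)
st  <- scoreTable(sim$IgG$bound, sim$IgG$unbound)
st
#> IgScoreTable: 30 taxa x 16 samples (IgG, log2, pseudocount 1)

permanova(correlationDistance(st), groupLabels(st), nPerm = 999, seed = 17)
#> PERMANOVA: pseudo-F = 33.9764, P =   0.001 (random permutations, 999 permutations)

tt <- taxonTests(st)
head(tt[order(tt$P), c("taxon", "family", "meanFoldDifference", "U", "P")], 4)
#>                  taxon           family meanFoldDifference  U            P
#> 25       Lactobacillus Lactobacillaceae          1.3410968  0 0.0001554002
#> 26   Ligilactobacillus Lactobacillaceae          1.3468616  0 0.0001554002
#> 27 Limosilactobacillus Lactobacillaceae          1.3695856  0 0.0001554002
#> 28         Akkermansia  Akkermansiaceae         -1.8077810 64 0.0001554002
```

The groups separate strongly (pseudo-F ≈ 34, P = 0.001, the permutation
floor at 999 permutations), and the taxa the preset perturbs are the taxa
recovered: Lactobacillaceae gain ~1.3 log2 units of IgG targeting in the
rewilded group, Akkermansia loses ~1.8 (U = 0 / U = 64 are complete group
separations; P = 1/6435 is the exact enumeration floor for 8 vs 8).

```r
## simulate a repertoire (1381 laboratory / 1178 rewilded cells), infer clones
rep <- simulateRepertoire(repertoirePreset(), seed = 17)
qc  <- qcFilter(rep)
qc$report
#> QcReport: 2558/2610 records pass
nn  <- estimateThreshold(nearestNeighborDistances(qc$set), seed = 17)
nn
#> NearestNeighborDistribution: 2430 distances, threshold 0.1722 (gmm)
assignClones(qc$set, threshold(nn))
#> CloneAssignment: 2558 sequences in 1345 clones (threshold 0.172223)
```

The fitted threshold sits in the valley between the clonal mode (mutated
copies of the same junction, distances near 0) and the background mode
(unrelated junctions, distances near 0.7); any cutoff in that valley yields
the same clones, and on this simulation the inferred clones match the
generator's true labels with adjusted Rand index 1.0.

## Command line

Every step is also a subcommand of a thin Rscript front end:

```sh
WILDIG=$(Rscript -e 'cat(system.file("cli", "wildig.R", package = "wildIg"))')
Rscript $WILDIG simulate-igseq --seed 17 --out-dir sim
Rscript $WILDIG score --bound sim/igg_bound.tsv --unbound sim/igg_unbound.tsv \
    --metadata sim/metadata.tsv --out-dir out
Rscript $WILDIG permanova --scores out/igg_scores.tsv --metadata sim/metadata.tsv \
    --n-perm 999 --seed 17 --out-dir out
```

Subcommands: `simulate-igseq`, `simulate-bcr`, `score`, `ordinate`,
`permanova`, `taxon-tests`, `filter-bcr`, `clone`, `mutfreq`, `diversity`,
`isotype-usage`, `network`. Global flags `--seed` (default 17),
`--out-dir`, `--log-level`, and `--config` (a key=value file mirroring any
flag). Logs go to standard error only; outputs are deterministic
tab-separated files, byte-identical under a fixed seed.

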