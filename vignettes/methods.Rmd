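---
title: "Cross-species co-expression analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-expression analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcoex)
```

# The problem and the inference principle

In a defined microbial community sequenced as one RNA pool, direct
observation of metabolic exchange is rarely possible. The pipeline in this
package leans on guilt-by-association: features (genes, metabolic modules,
biosynthetic gene clusters) of *different* organisms whose expression
profiles co-vary across many community samples are candidates for an
ecological relationship — cross-feeding when a producer pathway tracks a
consumer pathway, competition when specialized-metabolite clusters
anti-correlate. Co-expression is evidence, not proof: a shared environment
moves many pathways in many organisms at once, and the package's own
synthetic benchmark (below) quantifies exactly this failure mode.

# Normalization model

Raw read counts confound three things: sequencing depth of the sample,
the relative abundance of each organism, and per-gene regulation. Only the
last is of interest here. The pipeline therefore:

* removes genes with fewer than `minCount = 10` reads in at least
  `ceiling(0.5 * n_samples)` samples (all samples count towards the
  denominator — a deterministic reading of "half of the samples");
* computes, per taxon, TMM scaling factors on the taxon's own submatrix
  (`edgeR::calcNormFactors`), over the samples where the taxon is present;
* expresses each count as per-taxon CPM,
  `count / (taxon library size × factor) × 1e6`, and applies
  `arcsinh(x) = ln(x + √(x²+1))`, which is defined at zero and log-like in
  the tail.

Treating a taxon as *present* in a sample requires
`minSpeciesReads = 1000` assigned reads (configurable). Below that, the
taxon's values are missing (`NA`), never zero: a sample with ~100 reads for
an organism carries almost no information about its per-gene regulation,
and zeros there would manufacture correlation. Presence also defines the
shared-sample set of every cross-species correlation.

The per-taxon CPM unit was chosen because the analysis never compares
absolute levels across taxa — only profiles — and CPM makes factors
comparable across taxa of very different sequencing depth. No
between-taxon normalization is attempted, and no mean–variance weighting
(voom-style) is applied.

TMM parameters are the canonical defaults (M-trim 0.30, A-trim 0.05,
precision weighting, reference column = upper quartile closest to the mean
upper quartile). The test suite checks the pipeline's factors to 1e-8
against an independently coded implementation of the trimmed-M formulas on
50 random negative-binomial matrices.

# Module scoring semantics

A metabolic module is an ordered list of reaction steps; each step lists
alternative KOs, possibly complexes (`K1+K2`). Gene values contributing to
one KO are summed on the CPM scale and arcsinh-transformed at KO level.
Scoring then uses:

* alternative abundance = **min** over complex members (a complex is
  limited by its scarcest subunit; absent members count 0);
* step abundance = **max** over alternatives (any route suffices);
* a step is **detected** iff some alternative has all members present in
  the KO matrix (presence after the low-expression filter, not a value
  threshold);
* coverage = detected steps / total steps; modules below
  `minCoverage = 0.5` are dropped;
* module score per sample = **median** over detected steps only.

The min/max/median conventions are this package's explicit choices; module
abundance tools differ in detail, so the estimator is isolated behind a
single argument (`estimator = "median"` or `"mean"`) and undetected steps
are excluded rather than zero-filled — zero-filling would make the
coverage concept redundant. Scores are invariant to step order and to
removal of undetected steps (tested).

# BGC boundary refinement

Automated BGC detection fixes region boundaries by rule-based offsets and
often includes bystander genes. Refinement walks each region's genes in
coordinate order and breaks between genomic neighbours when

* the intergenic distance (`next.start − prev.end − 1`, 1-based inclusive
  coordinates throughout) exceeds `maxGap = 300` bp, or
* their expression correlation is not above `rMin = 0.5`, or
* either gene lacks an expression row (filtered genes cannot be
  correlated; they break chains and are recorded as unassigned).

Runs become sub-clusters suffixed `a`, `b`, … in coordinate order. The
neighbour-pair ("adjacent") chaining was chosen over all-pair linkage for
determinism and locality — whether the original procedure correlated
neighbours or each gene against a cluster mean is not decidable from its
description — and an all-pair single-linkage variant is available behind
`linkage = "single"`. Coarsening is monotone: raising `maxGap` or lowering
`rMin` never increases the number of sub-clusters.

Retention then requires: (a) at least one core biosynthetic gene passing
the expression filter; (b) at most 70% of member genes failing the filter;
(c) some core gene with r > 0.5 to another member. A singleton cluster
fails (c) vacuously and is discarded unless it constitutes the entire
region, in which case it is retained with a flag — the core-co-expression
rule is simply undefined for it. These two automatic rules take the place
of manual curation; a config-level include/exclude list can reproduce any
residual hand curation. Every discard is logged with its rule.

Cluster activity is summarized either by the eigengene — first principal
component of the members' scaled `log2(count+1)` profiles, unit norm,
sign-aligned to the mean profile — or, for cluster–cluster association, by
the Fisher-z average of all inter-cluster gene–gene Pearson correlations
(`tanh(mean(atanh r))`, values clipped at 1 − 1e−6 before `atanh`).

# Correlation, filtering and scaling

Pearson and Spearman correlations are computed per feature pair over the
samples where both taxa are present and both values are non-missing,
pooling all conditions (co-expression across samples, not across condition
means). Pairs with fewer than `minShared = 5` shared samples are withheld
rather than reported — a floor the analysis needs even though none is
inherent to the estimator. Edges with `|r − ρ| > 0.3` are removed as
outlier-driven; the boundary value itself is kept, and the comparison
carries a 1e−12 guard so that decimal thresholds behave as written under
binary floating point. The filter applies at module/cluster level by
default and is optional at gene level. Filtering happens on `r`, before
power scaling, because the discrepancy criterion is defined on
correlations, not weights.

Surviving correlations become signed adjacency weights
`w = sign(r)·|r|^β` with `β = 6` by default; `pickSoftThreshold()`
reproduces the usual scale-free-fit selection (connectivity
`k_i = Σ|r|^β`, log-binned degree distribution, signed fit index
`−sign(slope)·R²`, smallest β reaching fit 0.8). Thresholded networks
never contain self-edges or duplicate pairs; within-species module edges
are annotated with the Jaccard fraction of shared KOs so interpretation
can exclude edges inflated by shared enzymes.

# Bootstrap mean-shift test

For a module expressed by several taxa, the observed set is the
cross-species correlations of its matched profiles (after the discrepancy
filter). The null pool is, by default, the union of all cross-species
correlation values in the analysis set — the most conservative
exchangeability assumption consistent with asking whether a set's mean is
"higher than expected by chance"; per-category pools are configurable. The
test draws `B = 50000` sets of equal size with replacement and reports
both one-sided, add-one-corrected empirical p-values
`(1 + #extreme)/(B + 1)`, so p is never zero and never below `1/(B+1)`.
The pool is sorted internally so results are independent of input order;
all draws flow from a single seed. No multiplicity correction is applied
by default (raw p at α = 0.05, both directions reported); a
Benjamini–Hochberg adjustment can be applied downstream with
`p.adjust`. Whether the original analysis resampled correlation values or
underlying samples is not stated in its description; this implementation
resamples correlation values, as written.

# The synthetic community generator

`simulateCommunity()` emulates the data-generating process the pipeline is
built for, at configurable scale:

* **counts**: `NB(mean = lib_s · relAb_{t,s} · prop_{g,s}, size = 1/φ)`
  with dispersion `φ = 0.1` (a biological CV of ~0.3, typical of
  controlled, replicated RNA-seq experiments);
* **library sizes** log-uniform over 1e5–1e7 — the wide per-sample depth
  variation of large multiplexed runs, and the driver of the raw-count
  correlation bias the normalization must remove;
* **relative abundances**: per-taxon log random walks (step s.d. 0.2)
  renormalized per sample, so composition shifts smoothly and taxa can
  sink below the presence floor;
* **expression programs**: six latent programs per taxon following
  standardized AR(1) trajectories (φ = 0.3). AR(1) was chosen over random
  walks deliberately: independent integrated processes exhibit spurious
  correlation, which would contaminate the ground truth itself;
* **loadings**: most genes respond weakly to their program
  (`Unif(0.2, 0.6)`), as housekeeping genes do; the genes of a *planted*
  program are a coherent, strongly regulated pathway (`Unif(0.8, 1.2)`);
* **confounding**: a shared environmental AR(1) trajectory enters every
  program with taxon-specific `N(0, confounderStrength)` loadings
  (default 0.25 — a modest shared environment);
* **planted interactions**: a pair of programs in two taxa shares a
  trajectory with a stated sign and coupling `c`; the partner's trajectory
  is `sign·(c·u + √(1−c²)·w)`, so `c = 1` gives equality up to sign and
  `c = 0` independence;
* gene-level log-normal noise (s.d. 0.3), log-normal baselines (s.d. 1.2),
  and within-taxon renormalization to expression proportions — which
  makes the data genuinely compositional, the property the per-taxon TMM
  step exists to handle.

All randomness flows from one seed through `withr::with_seed`; the
caller's RNG state is untouched. `simulateModuleDb()` assigns every gene a
KO and maps a designated producer and consumer module exactly onto the
planted programs' genes (reserved KOs, several genes per KO, round-robin
over ten single-KO steps), with background modules drawn from the
remaining KO pool. `simulateToyGenome()` lays out genes with exact
intergenic gaps for boundary-rule fixtures.

What the generator does **not** emulate: strain-level genome structure,
within-sample spatial effects, varying gene lengths (counts are treated as
already length-independent), taxonomic misassignment of reads, or any
attempt to fit the real communities the analysis was developed on. Passing
the planted-recovery benchmark therefore demonstrates correctness of the
pipeline's statistical machinery under its own assumptions, not
performance on real metatranscriptomes.

# Benchmark conditions and what the tests show

The test suite exercises the pipeline at these problem sizes, chosen as
the package's reference study conditions:

* planted-interaction recovery: 8 taxa × 300 genes × 40 samples, one
  planted pair at coupling 0.9, a 12-module database, 10 seeds; the
  planted producer/consumer pair must top the cross-species edge ranking
  in ≥ 9 of 10 seeds.
* confounding caveat: the same community with `confounderStrength = 2`
  (loadings of ±2 give pairwise correlations near 0.8 by themselves) and
  nothing planted; spurious cross-species gene edges with |r| > 0.8 must
  appear in most seeds — co-expression alone cannot separate interaction
  from shared environment, which is why the package reports evidence, not
  conclusions.
* de-biasing: 6 taxa × 100 genes × 30 samples without confounding; mean
  cross-species correlation of raw counts exceeds 0.3, and falls within
  ±0.05 of zero after per-taxon TMM CPM.
* bootstrap calibration: pool of 200 N(0,1) values, sets of 20, B = 2000,
  1000 replicates; the type-I error at α = 0.05 must lie in 0.05 ± 0.01,
  and power must rise monotonically over mean shifts 0.1, 0.25, 0.5.

# Numerical choices and degenerate inputs

* Decimal thresholds (discrepancy 0.3) are compared with a 1e−12 guard so
  that differences like `0.9 − 0.6` behave as written.
* Fisher-z averaging clips |r| at 1 − 1e−6 before `atanh`.
* Zero-variance features yield undefined correlations: recorded with
  reason, never silently dropped and never emitted as edges.
* A sample sharing no expressed gene with the TMM reference gets factor 1
  with a warning; taxa present in fewer than two samples are dropped with
  a warning.
* Constant gene rows are dropped from eigengene computation (warning); an
  all-constant cluster is an error. The eigengene's sign is fixed by
  non-negative correlation with the members' mean profile.
* Spearman ties receive average ranks.
* `readGmmDatabase` rejects modules without steps; count readers name the
  offending cell on any negative or non-integral entry.

# Known limitations

* Correlation-based evidence cannot distinguish interaction from shared
  environmental response; the bootstrap tests mean shifts against an
  exchangeable pool, not causality.
* The adjacent-pair BGC chaining is one of several defensible readings of
  "co-located and co-expressed"; the single-linkage variant is provided
  for sensitivity analysis.
* Module scoring semantics beyond the documented min/max/median rules
  (e.g. weighting steps by KO multiplicity) are out of scope.
* The pipeline consumes annotation outputs (GFF3, KO tables, region
  tables); it does not predict genes, assign KOs or detect BGCs.
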