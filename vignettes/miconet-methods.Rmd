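---
title: "Methods and design notes for miconet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for miconet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`miconet` analyses grouped OTU count tables from dietary intervention
trials: community profiling, RMT-thresholded signed co-occurrence
networks with random-network baselines, the null-calibrated cohesion
index, and the standard growth-performance metrics. This vignette records
the statistical models, the tunable parameters, and the design decisions
taken where the methods literature leaves the recipe open.

## Data model

The central container, `OtuExperiment`, extends `SummarizedExperiment`:
one integer assay `counts` with OTUs in rows and samples in columns,
`colData$group` for the dietary group and `rowData$lineage`/`genus` for
taxonomy. Validity enforces non-negative integral counts, unique
identifiers, at least 2 × 2 entries and a positive total per sample.
Orientation of input files is always stated by the caller
(`readOtuTable(..., orientation =)`), never guessed: silently transposed
tables are a classic microbiome bug.

All downstream matrices keep the OTU-by-sample orientation;
`relativeAbundance()` closes each sample to 1 and every subsequent stage
works on proportions, so no stage depends on sequencing depth.

## Community profiling

* **Simpson index.** Reported in the dominance form D = Σᵢ pᵢ², under
  which lower D means higher diversity; a point mass gives D = 1 and the
  uniform composition over S taxa gives the minimum 1/S. The complement
  1 − D (Gini–Simpson) is available via `complement = TRUE` for
  comparison with tools that report that variant. Samples are not
  rarefied before diversity: proportions already remove depth, and
  rarefaction would discard counts without changing D's expectation
  materially at amplicon depths.
* **Ordination.** Bray–Curtis dissimilarity (`vegan::vegdist`) followed by
  classical metric scaling (Gower double-centering, eigendecomposition,
  coordinates scaled by √λ). Negative eigenvalues are reported, never
  silently dropped; the proportion explained is computed over positive
  eigenvalues only. No Lingoes/Cailliez correction is applied by default
  (a `correction = "cailliez"` flag exists) so axes stay comparable with
  common vegan-style output.
* **Differential abundance.** A STAMP-style two-group comparison:
  two-sided Welch's *t* per OTU on proportions with Benjamini–Hochberg
  q-values. This is the standard two-group default of that class of
  tools; no claim of bit-compatibility with any GUI implementation is
  made. Zero-variance conventions: an OTU constant at the same value in
  both groups gets p = 1; constant at different values gets p = 0.
* **Group summaries.** One-way ANOVA with Tukey HSD
  (`stats::aov`/`TukeyHSD`) and a compact letter display (via
  `multcomp::cld`, with a deterministic insert-and-absorb fallback for
  degenerate zero-variance fits). SE is sd/√n.

## Co-occurrence networks

Counts are log-transformed (ln(count + pseudocount), default pseudocount
1) and pairwise Spearman correlations computed with average-rank ties and
*t*-approximation p-values; constant OTUs get ρ = 0, p = 1. Because the
log map is strictly monotone the Spearman matrix is unchanged by it; the
transform is kept for parity with the conventional recipe and for
Pearson-based variants.

**RMT threshold selection.** For each cutoff s on a grid (default
0.30–0.99 by 0.01, the molecular-ecological-network convention), entries
with |ρ| < s are zeroed, rows without off-diagonal support dropped, and
the eigenvalue spectrum of the pruned matrix examined. The
nearest-neighbour spacing distribution (NNSD) of the unfolded spectrum is
chi-square-tested against the Poisson law exp(−d) and the Wigner surmise
(πd/2)exp(−πd²/4); the network cutoff is the point where spectral
statistics transition from Wigner (correlated system) to Poisson
(noise). Numerical choices, all recorded in the scan output:

* *Unfolding*: a Hyman-filtered monotone cubic spline with 10 knots fitted
  to the empirical cumulative spectral density; a plain mean-spacing
  normalization is available (`unfolding = "mean"`) and serves as the
  brute-force oracle in the test suite.
* *Degeneracies*: eigenvalues closer than 1e-8 are collapsed to one level
  before unfolding. Correlation matrices estimated from few samples are
  rank-deficient, and the resulting multiplicities would contribute a
  spike of zero spacings that mimics the Poisson law's excess at zero.
* *Chi-square binning*: up to 20 equal-probability bins of the reference
  law, reduced so every expected count is ≥ 5; significance 0.05 for both
  tests.
* *Decision rule*: a cutoff is flagged when Poisson is accepted
  (p > 0.05) and Wigner rejected (p ≤ 0.05). On small matrices the
  per-cutoff p-values fluctuate, so the chosen cutoff is the smallest one
  opening a run of ≥ 3 consecutive flagged cutoffs (falling back to the
  smallest isolated flag when no run exists). Isolated one-point flags at
  low cutoffs were observed to be chi-square noise, not the transition.
* *Minimum order*: 20; below that the NNSD has too few spacings to test,
  and the scan reports "none found" so the caller can widen the bounds.

Networks are built on |ρ| ≥ cutoff with the signed correlation retained as
an edge attribute — negative associations matter for the competition
interpretation — and only OTUs with at least one supra-threshold edge
become nodes, so N is cutoff-dependent. Topology: N, E, avgK = 2E/N,
average local clustering (degree-1 nodes counted as 0), average geodesic
distance on the giant component, and modularity of a greedy agglomerative
partition (deterministic; algorithm choice is ours since threshold-based
network tools rarely state theirs). Random baselines are R
degree-preserving double-edge-swap randomizations (10 × E attempted swaps
each) with z-scores per index.

An optional prevalence filter (`minPrevalence` in `runConfig()`) restricts
network construction to OTUs present in at least that many samples of the
group; the default is 0 (off), since requiring it is a convention of some
web pipelines rather than a property of the method.

## Cohesion

Observed pairwise correlations (Pearson on proportions by default — the
original metric's choice; Spearman available to match the network
convention) are corrected by a taxon-shuffle null: the focal taxon's
abundances are permuted across samples, correlations with all partners
recomputed, and the average over `rNull` iterations (default 200)
subtracted. The corrected matrix is symmetrized over the two focal
choices of each pair. A row-shuffle variant was considered and rejected:
permuting whole samples preserves exactly the compositional coupling the
null is supposed to isolate. Per taxon, positive (negative)
connectedness is the mean of its positive (negative) corrected
correlations; per sample, positive and negative cohesion are the
abundance-weighted sums of the two vectors. Because abundances are
proportions, |cohesion| is bounded by the largest |connectedness|, and
cohesion is invariant to sequencing depth by construction. Raw counts as
weights were rejected for exactly that reason.

`runPipeline()` calibrates one connectedness vector on **all samples
pooled** and lets group structure enter through abundance weighting and
the downstream ANOVA/ratio contrast. The phrase "averaged over the total
number of samples" in trial write-ups is ambiguous between pooled and
per-group calibration; pooled is the cited cohesion method's convention,
and in our synthetic experiments a per-group calibration recovered the
planted high-cohesion group in only ~60% of seeds (the dominant taxon's
connectedness estimate is noise-limited at n = 9) versus ~90% pooled.
Connectedness uses all null-corrected correlations, not only
network-significant ones; a cutoff option would be a sensitivity
analysis, not the default.

## Growth metrics

The eight standard indices (WGR, SGR, FCR, FI, SR, CF, HSI, VSI) are
computed per replicate cage and then summarized by ANOVA/Tukey. SGR is
100·(ln FBW − ln IBW)/days and WGR is 100·(FBW − IBW)/IBW — the
difference and ratio forms, which are the only readings consistent with
each other (WGR = 100·(exp(SGR·days/100) − 1) is asserted as an
invariant). Cage totals are mean weight × fish count; FI is normalized
per 100 g of mean biomass per day. Group means are means of per-cage
metrics, which differs slightly from recomputing a metric on group-mean
weights; both conventions appear in trial tables.

## Synthetic communities

`simulateCommunity()` draws counts by a Gaussian copula: within-block
taxa share a latent correlation ρ, latents are mapped through log-normal
multipliers (scale σ = 1) onto a fixed gamma-distributed weight skeleton,
the dominant taxon is pinned at its target proportion (with a small
logit-scale jitter, sd 0.05), compositions are closed, and counts drawn
multinomially at a log-normal depth (mean 20,000, CV 0.3 — a realistic
amplicon scale). A plain Dirichlet-multinomial cannot plant specific
pairwise correlations, which the network and cohesion stages need.

The defaults emulate a three-diet feeding trial: 9 samples per group
(six intestines per tank and three tanks are typical; per-group n is a
modelling choice, not a claim about any particular study), 60 OTUs, D1
dominated by one genus at 97.6%, D2/D3 by another at 76.7%, and planted
blocks of (6 @ ρ=0.6), (2 × 10 @ ρ=0.85) and (5 @ ρ=0.7) respectively, so
network density and cohesion peak in D2. Dominant taxa are excluded from
blocks so dominance and network structure are separately tunable; block
taxa get 3× skeleton weight within their group so the interacting taxa
are also the abundant ones.

What the generator does **not** emulate: taxonomic misassignment, chimeras
and other upstream artefacts; over-dispersion beyond the
lognormal-multinomial; phylogenetic correlation between related taxa; and
real effect sizes — a passing regression test shows the pipeline recovers
structure of the planted kind and scale, not that any real dataset has
that structure.

## Test problem sizes and numerical conventions

The suite exercises: null calibration at m = 20 taxa, n = 30 samples,
`rNull` = 200 (20 seeds for centring, 50 for the group-contrast
false-positive rate); NNSD discrimination on 200 spacings / order-200 GOE
matrices (100 replicates each, spectrum bulk between the 10th and 90th
percentile); planted-edge recovery at n = 40 samples and depth 20,000;
type-I calibration on 2,000 null features (Welch) and 2,000 replicates of
3 × 3 ANOVA. These sizes make the behaviour of each statistic visible
while keeping the default test run fast; all are plain function arguments
and scale up freely.

Tie-breaking and degenerate-input conventions, collected: constant OTUs
get ρ = 0, p = 1; zero-variance Welch comparisons get p = 1 (equal means)
or p = 0; compact letters fall back to an insert-and-absorb assignment
when the model fit is degenerate; empty networks are legal (warned) from
`buildNetwork` and an error from `networkTopology`; FCR is NA with a
warning when no weight was gained; the pipeline derives per-stage RNG
substreams deterministically from one seed so stage order cannot perturb
results.

## Interface

The package's functions are the interface; `runPipeline()` is the one-call
driver and writes TSV/GraphML/JSON outputs for downstream tooling, so no
separate shell entry point is needed. GraphML was preferred over GEXF for
parser support, with the edge sign stored both numerically and
categorically.

## Limitations

* Correlation-based networks on compositional data inherit the usual
  caveats: closure induces weak negative coupling (≈ −1/(m−1)) that the
  taxon-shuffle null deliberately leaves in place, since it is a real
  property of proportions.
* With few samples per group, Spearman values are coarse and per-group
  RMT cutoffs (and hence edge counts) vary between datasets; comparisons
  of network density across groups are qualitative at that scale.
* The NNSD chi-square has limited power below ~50 spacings; the scan
  reports the full table so borderline decisions can be inspected.
* Modularity uses greedy agglomeration; other community algorithms give
  different partitions and slightly different modularity values.
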