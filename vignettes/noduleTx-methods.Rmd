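---
title: "Methods: statistics behind the nodule BNF transcriptome pipeline"
author: "noduleTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics behind the nodule BNF transcriptome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleTx)
```

This vignette documents the models, parameter choices and numerical
conventions of noduleTx, in the spirit of the long-form methods vignettes of
the differential-expression and network packages it is modelled on. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experimental design being modelled

The pipeline targets a two-group bulk RNA-seq comparison of legume root
nodules: genotypes with high versus low biological nitrogen fixation (BNF)
efficiency, measured by the acetylene reduction assay (ARA; ethylene
concentration in µmol/mL after incubation). The default layout is 2 BNF
classes × 4 genotypes × 3 biological replicates = 24 samples, with two
diploid and two tetraploid genotypes per class. Ploidy is carried as a
stratification label and trait, not as a model covariate: the differential
expression contrast is the single high-vs-low comparison with the low-BNF
class as reference.

## Normalization and replicate QC

Size factors are median-of-ratios: $s_j = \mathrm{median}_{i \in R}\,
(k_{ij} / (\prod_j k_{ij})^{1/m})$ over the reference set $R$ of genes with
no zero count, rescaled to unit geometric mean. If no gene is positive in
every sample the function stops and points to a pseudo-reference fallback
rather than silently changing the estimator.

QC works on $\log_2(k_{ij}/s_j + 1)$: pairwise Pearson $r$, complete-linkage
clustering of samples under $d = 1 - r$, and PCA on the centred,
gene-standardized matrix. A constant sample column makes $r$ undefined for
its pairs; it is reported as missing with a warning, never coerced to zero.
This log transform is deliberate: replicate QC conclusions here are
structural (which samples cluster), not value-exact, so a regularized log
is unnecessary.

## The differential expression test

Counts are modelled as negative binomial,
$K_{ij} \sim \mathrm{NB}(\mu_{ij} = s_j q_{ij},\ \alpha_i)$ with
$\log q_{ij} = \beta_{0i} + \beta_{1i} x_j$ and $x_j$ the high-BNF
indicator. The test is a deliberately simple, fully documented NB Wald
test — the scientific content of this stage is the contrast design and the
decision thresholds, not the estimator:

* **Dispersion.** Per gene, a method-of-moments estimate from the pooled
  within-group variance of normalized counts
  ($s^2 \approx \xi\mu + \alpha\mu^2$ with $\xi = \overline{1/s_j}$
  absorbing the shot-noise term), clipped to $[10^{-8}, 10]$, then shrunk
  50% toward a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across
  genes by least squares. The 50/50 shrink stabilizes the estimate at
  $n = 12$–$24$ samples without the machinery of empirical-Bayes
  moderation.
* **Fit.** IRLS for the NB GLM with fixed dispersion and $\log s_j$
  offsets. Because all genes share one design, each iteration reduces to
  closed-form 2×2 normal equations from row sums, so the whole matrix is
  fitted vectorized.
* **Inference.** The Wald statistic $\hat\beta_1/\mathrm{se}(\hat\beta_1)$
  is referred to a $t$ distribution with $n - 2$ degrees of freedom rather
  than a normal: with estimated dispersion at small $n$, the normal
  reference is visibly anticonservative (the package's null-bundle
  calibration test quantifies this), while the $t_{n-2}$ reference keeps
  the null rejection fraction near nominal even with genotype-level random
  effects inflating within-group correlation.
* **Decision rule.** Genes with raw mean count below 2 are labelled
  `low_count`, receive no p-value, and are excluded from the BH adjustment
  (the multiple-testing burden covers tested genes only). A tested gene is
  `de_up`/`de_down` iff $|\log_2 FC| > 1$ and BH-adjusted $p < 0.05$;
  positive fold changes mean higher expression in the high-BNF class.

The test is never validated by identity with any external DE tool; its
acceptance contract is error control and power on synthetic data with known
truth (FDR ≤ 0.10 at nominal 0.05 on null bundles; recall ≥ 0.8 for planted
$|\log_2 FC| = 2$ at base mean ≥ 50 with 2 × 12 samples). Independent
filtering and outlier handling of production DE tools are intentionally not
emulated.

## NCR peptide scanning

NCR (nodule-specific cysteine-rich) peptides are short secreted
defensin-like peptides with 4 or 6 conserved cysteines. The scanner
adjudicates every input protein with an explicit verdict and reason,
checking criteria in a fixed order (parse, cysteine count, spacing, length,
signal peptide) so that a record violating several criteria reports the
first.

* **Grammar.** The published motif is cited but not reproduced in the
  source literature available to us, so the spacing grammar is an explicit,
  configurable default:
  4C = `C-X(4..12)-C-X(8..30)-C-X(3..12)-C`, and 6C inserts two further
  cysteines at `X(1..12)` gaps. Tests plant ground truth with the same
  grammar, so the contract is internal consistency, not fidelity to any
  specific published pattern.
* **Length.** The length filter is < 150 amino-acid residues of the
  preprotein. (The source literature states the threshold in "bp" in one
  place and reverses the inequality in another; since the scanned objects
  are protein sequences, residues and "<" are the only consistent
  reading, and the threshold is exposed as `maxLength`.)
* **Signal peptide.** Dedicated predictors are external tools, so the
  package uses a documented hydropathy heuristic: present iff the first 30
  residues contain a 7-residue window of mean Kyte–Doolittle hydropathy
  ≥ 1.6; cleavage after the first small residue (A/G/S/C/T) in positions
  15–35 following the window, else window end + 5. An external prediction
  table, when supplied, overrides the heuristic verbatim, and unsupportive
  external evidence (localization, BLAST) downgrades structurally passing
  candidates to `unconfirmed` instead of `confirmed` — mirroring how
  in-silico adjudication narrows a structural candidate list.
* **Physicochemistry.** MW from average residue masses (free amino-acid
  masses minus $(n-1)$ waters); net charge from a Henderson–Hasselbalch
  model with an EMBOSS-style pKa table; pI by bisection on that charge
  (tolerance $10^{-9}$, so the charge at the reported pI is ~0); GRAVY as
  mean Kyte–Doolittle hydropathy. `X` residues contribute an average mass,
  zero hydropathy and no charge, and flag the record approximate.

Cysteine counting uses the mature region when a cleavage site is predicted
and the full sequence otherwise; the region used is recorded per candidate.
Cysteine positions are reported 0-based.

## Duplication modes and expression divergence

The mode distribution of DEGs is compared with the expressed background
two ways: a global Pearson χ² goodness-of-fit of observed DEG counts
against expected counts from background proportions (df = modes − 1 = 5),
and per-mode two-tailed Fisher exact tests whose p-value sums
hypergeometric probabilities no larger than the observed table's (tie
tolerance $1 + 10^{-7}$, the convention of standard implementations). By
default the background is all expressed classified genes *including* the
DEGs — the natural reading of comparing DEGs against "all expressed
genes" — with an option to exclude them, since either convention is
defensible. Genes missing from the catalog are reported as unclassified
and excluded from proportions rather than defaulted.

Expression divergence of duplicate pairs uses a resampled null: draw
10,000 distinct unordered gene pairs uniformly from all expressed genes
(not only duplicates — random pairs define the null), compute Pearson $r$
of their $\log_2(\text{normalized} + 1)$ profiles, and take the empirical
95% quantile (inclusive/type-7 convention, fixed) as the cutoff $r^*$. A
pair below $r^*$ has diverged at α = 0.05. The cutoff is always estimated
from the data at hand, never hard-coded: the published value of 0.67 for
this statistic is a dataset-specific realization, and on synthetic data
with 24 samples the same procedure yields ≈ 0.35–0.4. Only pairs with at
least one DE member are classified when DE results are supplied; pairs
with a constant profile are `undefined`; per-mode diverged fractions are
reported over defined pairs.

The log transform for profile correlations is a package choice (the source
does not state one): raw counts would let library size dominate every
correlation.

## Co-expression modules

The variance-stabilizing transform of production DE packages is replaced by
the documented $\log_2(k/s_j + 1)$; the network stage's conclusions
(filter membership, module recovery) are structural, and no acceptance
check compares transformed values to an external tool. Genes are kept iff
the transformed value reaches 10 in at least 3 samples (boundary
inclusive).

Adjacency is signed hybrid, $a_{ij} = \mathrm{cor}(i,j)^6$ for positive
correlations and 0 otherwise, so anti-correlated genes share no edge.
The standard TOM follows,
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$, applied directly to the (already
non-negative) signed-hybrid adjacency.

Module detection replaces the dynamic tree-cut heuristics of the reference
network package with a transparent three-step procedure: average-linkage
clustering on $1 - \mathrm{TOM}$; a static cut at the 0.99 quantile of
merge heights (exposed as `cutQuantile`); clusters below
`minModuleSize = 20` sent to grey; then iterative merging of the closest
module pair while eigengene dissimilarity $1 - \mathrm{cor}$ is below
`mergeCutHeight = 0.45` (0 disables merging). The dynamic algorithm's
branch-shape heuristics are not part of the published analysis parameters,
so the contract here is module recovery on planted two-block data
(adjusted Rand ≥ 0.9, eigengene–latent correlation ≥ 0.95), not
label-for-label agreement with any specific cut algorithm. Modules are
named by the conventional color sequence, largest first.

Eigengenes are the first right singular vector of the gene-standardized
module submatrix (unit norm over samples), sign-oriented to correlate
positively with the module's mean standardized profile, with the variance
explained reported. Module–trait correlations are Pearson with two-sided
p, flagged at $p < 0.01$; binary traits are coded 0/1 (high BNF = 1,
tetraploid = 1) and genotypes one-hot. Term enrichment is the upper-tail
hypergeometric $P[X \ge k]$ with BH FDR within module, enriched at
FDR < 0.05; the universe is the post-filter gene set — the population that
was actually tested — not the whole genome.

One published network parameter, an "adjacency threshold = 2" for edge
export, cannot be an adjacency value (adjacency lies in [0, 1]); the
edge-list export therefore takes a free threshold and documents that values
above 1 select nothing.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every acceptance property is evaluated.

* **Counts.** NB with gene means log-normal (log-mean $\log 150$, log-sd
  1.2), dispersion trend $\alpha_i = \alpha_0 + 2/\mu_i$ with
  $\alpha_0 = 0.05$, and library sizes log-uniform over
  $[5\times10^5, 2\times10^6]$ reads — scaled-down but shaped like a bulk
  RNA-seq experiment, chosen for testability since the emulated study
  deposits no raw data to calibrate against.
* **DE genes.** A fixed fraction (floor rule), $|\log_2 FC|$ uniform on a
  configurable interval, 75% up-regulated by default — echoing the roughly
  3:1 up/down asymmetry observed in the emulated study.
* **Genotype effects.** Log-normal multipliers (log2-sd 0.15) per
  genotype × gene, so replicate QC has real structure and the DE test is
  exercised under within-group correlation, not an idealized iid null.
* **Pairs and modules.** Conserved duplicate pairs share a per-sample
  latent log2 profile (sd 1) plus sd-0.1 noise; diverged pairs get
  independent profiles. Half of the DE genes (at most) join pairs as the
  first member so pair divergence is assessable under the ≥ 1-DE-member
  rule without forcing every DEG into a duplicate pair. Latent
  co-expression factors load a configurable gene fraction with loadings
  uniform on [0.6, 1].
* **Traits.** Ethylene per genotype from group-shifted gammas
  (low: shape 3 × scale 0.20; high: shape 6 × scale 0.35, i.e. means ≈ 0.6
  vs 2.1 µmol/mL); fresh mass affine in ethylene with a steeper slope for
  tetraploids (120 vs 60 mg per unit), emulating the clearer mass–ARA
  trend reported for tetraploid plants.
* **Proteins.** Planted NCRs have a 15-residue signal prefix (Met + 13
  hydrophobics + Ala at the cleavage site) and a mature region drawn inside
  the default grammar; each decoy violates exactly one criterion and the
  violated criterion is recorded, so scanner specificity is attributable.
* **Ct table.** $Ct = 30 - \log_2 q$ plus sd-0.05 cycle noise, three
  technical replicates, with a designated constant housekeeping gene — so
  Ct drops one cycle per doubling and 2^−ΔΔCt recovers planted fold
  changes.
* **Determinism.** All stage randomness derives from one seed via
  stage-name hashing (`deriveSeed`), making bundles byte-identical across
  runs and any stage re-runnable in isolation.

What the generator does *not* emulate: read-level artifacts (alignment,
duplication, GC bias), allele-dosage effects of ploidy on expression,
count outliers, and the long-range correlation structure of a real
transcriptome (its random-pair null is much cleaner than real data's,
which is why the real-data divergence cutoff of 0.67 is far above the
synthetic ≈ 0.37). Passing tests therefore demonstrate the statistics are
implemented correctly and behave as designed under NB assumptions — not
that a real nodule dataset would reproduce any published realization
(DEG counts, module counts, cutoffs).

## Numerical conventions and degenerate inputs

* BH adjustment over tested genes only; `padj ≥ p` always.
* Fisher tie tolerance $1+10^{-7}$; enumeration-exact to $10^{-12}$ on all
  margins ≤ 30.
* Empirical quantiles are type-7 (inclusive) everywhere.
* Bisection for pI on [0, 14] to $10^{-9}$; charge monotone in pH so the
  root is unique.
* Degenerate inputs error loudly and name the offender: no all-positive
  gene (size factors), single-level design (DE), empty post-filter matrix,
  constant-gene module (eigengenes), zero expected cell (χ²), missing
  reference-gene Ct.
* Constant profiles: skipped and counted (null cutoff), `undefined`
  (pair divergence), zeroed with warning (adjacency), NA (trait
  correlation).
* Rank-sum tests are exact when both groups have ≤ 12 observations and no
  ties, otherwise a midrank normal approximation.

## Problem sizes used by tests and the acceptance script

The suite runs generator bundles of 300–5,000 genes and 12–24 samples,
20,000-gene catalogs for enrichment recovery, 10,000-pair nulls, 100
simulation repeats for detection rates and 10–20 seeds for
calibration/recovery properties; the full suite and the acceptance script
each complete in a few minutes on one CPU. These sizes are the package's
chosen trade-off between Monte-Carlo precision and turnaround, and the
acceptance properties are formulated (rates, gaps, oracle agreement) so
their expected values do not depend on the scale chosen.

## Known limitations

* The DE test has no outlier handling or independent filtering; extreme
  count outliers will inflate dispersion rather than be flagged.
* The signal-peptide heuristic is a hydropathy rule of thumb; on real
  proteomes it will both miss true signal peptides and call false ones,
  which is why external predictions can override it.
* Module detection with a static cut is less sensitive than dynamic
  branch cutting on nested module structure; `cutQuantile` trades
  resolution against fragmentation.
* The χ² mode test is a goodness-of-fit against fixed background
  proportions; if the background itself is small, its sampling error is
  ignored (the per-mode Fisher tests do account for it).
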