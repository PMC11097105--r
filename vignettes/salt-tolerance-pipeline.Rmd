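---
title: "Methods: trait-based tolerance scoring and co-expression screening along a tidal-flat salinity gradient"
author: "phragnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based tolerance scoring and co-expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phragnet)
```

`phragnet` chains five analyses that together characterize the salt
tolerance of reed stands sampled across a tidal-flat gradient: functional
trait statistics, a fuzzy comprehensive tolerance score, weighted
co-expression module screening against soil salinity, negative-binomial
differential expression with intersection screening, and correlation
networks with enrichment. This vignette documents the models, the
parameters that matter, the numerical conventions, and what the synthetic
validation data do and do not establish.

## Study design emulated by the generator

The sampling design is four tidal-flat groups — low flat outside the dike
(L, five discrete patches A–E), low flat inside the dike (IN), middle (M)
and high (H) — with 15/5/10/10 quadrats of 5 shoots each (200 shoots), 8
sites with two soil depth layers (0–10 cm and 10–20 cm), and 39 retained
RNA samples. Trait distributions are truncated-at-zero normals calibrated
to a per-group mean ± SD reference table; that calibration table is the
only distributional information available for traits, which is why a
(truncated) normal is used. Fresh and dry weight are drawn jointly
(correlation 0.9, pairs violating DW < FW resampled) so the mass
constraint holds; leaf area and leaf dry weight are generated through SLA
so the derived ratio has realistic spread.

Choices the design left open, fixed once here: RNA samples allocate
12/9/9/9 across L/IN/M/H (39 of 48 retained, low flat sampled hardest);
group-mean salinities are 12/5/6.5/4.5 g/kg at 0–10 cm (slightly lower at
10–20 cm), preserving the observed ordering with the low flat saltiest;
the two depth layers share a site effect, making them positively
correlated within a site as in real profiles.

Expression is an additive latent-factor model on the log2 scale,
exponentiated to FPKM: genes of a planted module share a factor with
loadings in [0.9, 1.3] and residual noise SD 0.5 (log2 units). The
default 2000 genes carry eight modules (sizes 120…40); the first three
are "salinity modules" whose factors load 0.75 on the standardized
per-sample site salinity, the rest of the factor variance being module
specific. The 0.75 loading keeps the three modules mutually separable
(their factors correlate ≈ 0.56) while leaving each eigengene–salinity
correlation well above the 0.5 screening threshold at both depths — the
structure the downstream screen assumes. Counts follow
NB(mean = library size × relative abundance, dispersion φ = 0.1), library
sizes uniform in [0.8, 1.2] million, with 5% of genes planted
differentially expressed at |log2FC| = 2 (random sign on the non-reference
group).

What the generator deliberately does **not** emulate: read-level
artifacts, batch effects, spatial autocorrelation among patches, tagwise
dispersion heterogeneity, and correlated module factors beyond the
salinity loading. Passing recovery tests therefore demonstrates that the
implementation detects the structure it is specified to detect — not that
real estuarine transcriptomes satisfy these assumptions.

## Trait metrics

SLA = LA/LDW (cm²/g). LDMC defaults to the dimensionless dry-to-fresh
ratio DW/FW, the standard leaf-economics definition, which also matches
the magnitude (0.4–0.5) of published stand summaries; an alternative
"paper-literal" mode evaluates the expression 1 − (FW − DW)/DW verbatim
for audit — it is not a fraction and is not used downstream. CV uses the
sample SD (n − 1). The one-way ANOVA is reconstructed from group
summaries: MS_between from means weighted by n, MS_within pooled from
SDs; this is algebraically identical to the raw-data ANOVA, which the
test suite verifies to 10⁻¹⁰ relative tolerance on generated data.

## Fuzzy comprehensive evaluation

Pipeline order: raw indicators → min–max memberships (negative indicators
reflected, μ ↦ 1 − μ) → correlation-matrix PCA **of the memberships** →
min–max membership of each retained component's scores → weights from
variance contributions → D = Σ μ(X_i) W_i. Running the PCA on memberships
rather than raw traits makes every stated equation participate and gives
D exact invariance under positive affine rescaling of any indicator
(membership absorbs location/scale; correlation PCA is scale-free).

Numerical conventions: components are retained by the Kaiser rule
(eigenvalue ≥ 1, minimum one) since published examples show two retained
indices but no explicit rule; each component's sign is oriented so its
loading sum is nonnegative (in membership space all indicators point
"positive"), because PC signs are otherwise arbitrary and D is not
sign-invariant; ranking ties break stably by unit order. All seven
default indicators (FW, DW, height, basal diameter, LDMC, SLA, SPAD) are
treated as positive-direction; directions are configurable per indicator.
Constant indicator columns and constant component scores are explicit
degenerate-input errors, never silently imputed.

## Co-expression screening

The network is unsigned, a_ij = |cor|^β with Pearson correlation
(Pearson is the correlation named throughout the source methodology) and
default β = 14. Expression is pre-filtered to genes reaching FPKM ≥ 20 in
at least one sample — the literal reading of removing genes below the
floor "in all samples". The topological overlap

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

is computed densely; the package targets desk-scale matrices (thousands
of genes), not the blockwise regime.

**Module cut.** Modules come from average-linkage clustering of 1 − TOM
with a *static absolute* cut, default 0.99, then a minimum size of 30.
A cut expressed as a fraction of the maximum merge height was evaluated
and rejected: soft-thresholded TOM dissimilarities concentrate in a
narrow band just below 1 (unrelated genes sit at ≈ 1 by construction), so
proportional cuts land below every merge and shred the tree into
singletons. The absolute scale of TOM dissimilarity is meaningful —
background pairs are ≈ 1 regardless of the data — which is exactly what a
fixed cut just under 1 exploits; it is fully deterministic, unlike
dynamic tree cutting. Clusters are labelled M1, M2, … by decreasing size
with ties broken by the lexicographically smallest member gene, so module
names are reproducible.

Eigengenes are the first principal component of the gene-standardized
module submatrix, unit variance, sign-aligned with the module's mean
standardized profile (a size-1 module's eigengene is its standardized
profile). Module screening requires |r| > 0.5 between the eigengene and
soil salinity at **both** depths; the absolute value is used because a
strongly negatively salt-correlated module is equally salt-relevant and
no sign convention is prescribed. Hub genes require |kME| > 0.8 and
|GS| > 0.5, both strict, with GS computed by default against the 0–10 cm
salinity (the screened phenotype is configurable).

## Differential expression and screening

TMM factors follow the classic trim-and-weight construction: M/A values
against a reference sample (upper-quartile auto-selection), genes zero in
either sample removed, 30% tails trimmed on M and 5% on A,
inverse-asymptotic-variance weighted mean, factors rescaled to geometric
mean 1. The test equalizes samples to a common effective library
(pseudo-counts), then conditions the rounded group sums on their total
under a common-dispersion NB model; the p-value sums the probabilities of
all outcomes no more probable than the observed split. The common
dispersion is a pooled method-of-moments estimate (solving
var = μ + φμ² within groups, pooled across genes, floored at 10⁻⁴) —
deterministic and adequate at desk scale; tagwise empirical-Bayes
shrinkage is deliberately out of scope. Fold changes use normalized group
means with a 0.125 prior count so zeros never produce infinite log
ratios. DEGs are |log2FC| > 1 and BH FDR < 0.05, strict inequalities.

Contrasts are oriented "other group vs reference L" (and "vs patch E" for
a degeneration screen — the same operations with a different reference;
no separate code path). Cross-contrast intersections are per-direction;
the core set is hub ∩ (common_up ∪ common_down), with per-gene provenance
(module, kME, GS, direction).

## Networks and enrichment

Correlation-network edges require |r| ≥ 0.8 and BH FDR < 0.05 (both
configurable; no cutoff is prescribed by the source methodology, and 0.8
is a conventional "strong correlation" default). Hubness is degree and
|r|-weighted degree with deterministic gene-id tie-breaks. Enrichment is
one-sided hypergeometric over-representation, P(X ≥ k), with terms
intersected with the universe first; the universe defaults to all genes
surviving the expression filter, standard SEA practice. Depletion testing
is out of scope.

## Validation strategy and problem sizes

Every operation is tested against an independent oracle: TOM against a
triple-loop evaluation of the formula, BH against the O(m²) step-up
definition, the exact test's φ→0 limit against the closed-form binomial
tail, SEA p-values against direct pmf summation across universe sizes up
to 200, summary-ANOVA against `lm`/`anova` on raw data, and TMM against
both an independently coded trim formula and edgeR's implementation.
Recovery experiments run at the design's default sizes (2000 genes × 39
samples; 5 vs 5 samples for count contrasts, 10–20 simulation seeds),
which keeps the full suite in the low minutes on a single core while
leaving the planted effects comfortably detectable. The hub-screen
recovery check runs at residual noise SD 0.3 — the "low noise" regime in
which near-complete hub capture is the planted expectation.

## Known limitations

* The static 0.99 cut is robust for soft-thresholded TOM but is not a
  general substitute for dynamic tree cutting on shallow dendrograms
  (e.g. unthresholded correlation distances).
* The common-dispersion exact test is anti-conservative under strong
  tagwise dispersion heterogeneity, which the generator does not plant.
* The fuzzy score's Kaiser retention can change the number of retained
  components under small perturbations when an eigenvalue sits near 1;
  weights then change discontinuously. This mirrors the stated procedure
  rather than smoothing over it.
* Published module counts and gene-set sizes from the real deposited
  dataset depend on that data and on specific tool versions; they are
  mirrored structurally, not numerically, by this package.
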