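---
title: "Statistical methods behind pluriomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind pluriomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pluriomics implements the statistical chain used to analyze a time-resolved
multi-omics study of mESCs leaving serum/LIF (S/L) culture under 2i or
Cdk8/19 inhibition. This vignette explains each model, the parameters that
matter, the choices made where the methodology was genuinely open, and what
the synthetic-data tests do and do not establish.

## Data model and preprocessing

Measurements are log2 reporter intensities organized as features × samples,
with a per-sample design (cell line, treatment, timepoint, plex,
replicate). Every plex contains at least one S/L reference channel, and all
inference downstream happens on **log2 ratios against the same-plex
reference mean**, which cancels any per-feature, per-plex additive batch
term by construction.

*Cyclic loess* (`cyclic_loess_normalize`) removes intensity-dependent bias
within a plex: for every sample pair, M = x_i − x_j is smoothed against
A = (x_i + x_j)/2 with `stats::lowess` and half the fitted trend is moved
between the members. Defaults: span 0.7, 3 passes over all pairs. The span
is wide because reporter-ion bias is smooth and low-frequency; a narrow
span would chase noise. Missing values are dropped pairwise; a pair with
fewer than 10 complete features is skipped. The procedure preserves each
plex's grand mean to numerical precision.

*Batch adjustment* (`batch_adjust_eb`) is a parametric empirical-Bayes
location/scale adjustment in the ComBat style: features are standardized
under a model keeping treatment × timepoint covariates, per-batch
per-feature locations get a Normal prior and scales an inverse-gamma prior
with method-of-moments hyperpriors, and the shrunken batch terms are
removed. Batches with fewer than 3 samples fall back to location-only
adjustment. A batch nested 1:1 within a covariate level is refused by name
— no adjustment can separate the two. Note that ratio formation already
removes additive plex effects; the adjustment matters when abundances
(not ratios) are analyzed jointly across plexes, e.g. for PCA. Re-running
the adjustment drifts the values by less than 1e-3 on average (signed);
individual values do move on a second pass because the scale shrinkage
re-divides by slightly different shrunken variances — reference
implementations behave identically, and the test suite checks ours against
one.

*Trajectories* (`collapse_and_zscore`) are means over cell lines per
treatment × timepoint, z-scored per feature with the sample (n−1) standard
deviation; constant rows map to zeros rather than NaN so that downstream
clustering keeps its row indexing. Two z-scoring modes exist because the
choice is a genuine interpretation question: `concatenated` (default)
scales the joined 2i + Cdk8/19i trajectory, so cross-treatment amplitude
differences survive and clusters can separate "2i-only" from "shared"
behavior; `per_treatment` scales each treatment separately, which
emphasizes shape over amplitude. The day-0 reference point (ratio 0 by
construction) is excluded from trajectories and correlations by default:
it is identical for every feature and only inflates correlations.

## Moderated differential testing

Per treatment × timepoint contrast, the replicate unit is the cell line
(n = 4 by default). `estimate_variance_prior` fits the scaled
inverse-chi-square prior by matching mean and variance of log s² to the
scaled-F distribution, solving trigamma equations by Newton iteration.
When the dispersion of log s² does not exceed the pure sampling
contribution the prior degrees of freedom are infinite and the test
becomes a z-test against s₀; with exactly constant observed variances s₀²
is set to that common value. `moderated_ttest` then uses
s̃² = (d₀s₀² + d·s²)/(d₀ + d) with d₀ + d degrees of freedom. Each contrast
gets its own prior and its own BH family, matching per-timepoint regulated
counts; the regulated call requires q < 0.05 **and** |log2FC| ≥ 0.1. The
fold-change gate applies to metabolites as well (configurable) — the
uniform rule is simpler to reason about and the gate is small relative to
metabolite effect sizes.

## Overlap statistics

`hypergeom_overlap` accumulates the upper tail P(X ≥ k) from log-binomial
coefficients with a log-sum-exp, so log p stays exact far below the double
underflow threshold; the representation factor RF = kN/(Kn) expresses the
overlap relative to its independence expectation. The statistic also
reports the point probability P(X = k): published overlap analyses are not
unanimous about which quantity they print, and for strongly enriched
overlaps the two differ by roughly the ratio of the first tail term to the
tail sum. Carrying both makes results comparable with either convention;
the enrichment test proper is always the tail.

## Trend clustering

The gap statistic uses W_k = Σ_r (1/(2n_r)) Σ pairwise squared Euclidean
distances (equal to the within-cluster sum of squares), B = 50 reference
sets drawn uniformly over each dimension's observed range, and the
one-standard-error rule: the chosen K is the smallest k with
Gap(k) ≥ Gap(k+1) − s_{k+1}. Defaults k_max = 20 and 25 k-means restarts;
k-means itself is `stats::kmeans` (Hartigan–Wong) seeded explicitly, with
cluster labels relabelled by decreasing size so output is stable across
platforms. Reference sets are drawn in the original coordinate system
(not PCA-rotated): trajectory dimensions are already on a common z-scale,
and the original-box null is the variant whose dispersion curve we can
cross-check exactly.

## Preranked enrichment

`gsea_preranked` walks the list sorted by decreasing score; hits increment
the running sum by |score|^p/N_R (p = 1, the classic weighted statistic)
and misses decrement by 1/(N − N_hits); ES is the signed extreme. The null
is gene-set permutation — the only null available for preranked input —
with n_perm = 1000 by default; NES divides ES by the mean |null ES| of
matching sign, and FDR follows the standard pooled-NES ratio, clipped to
[0, 1]. Score ties are broken by stable input order, which is documented
because ES depends on it. Set-size bounds after intersection default to
[5, 500].

## Phosphoproteomics and Gsk3 substrate inference

Class-I sites are those with localization probability ≥ 0.75 (inclusive);
the threshold is the field's convention for the term. The Gsk3 consensus
is S/T-X-X-X-pS/pT: the kinase phosphorylates an S/T four residues
N-terminal of a pre-phosphorylated priming site, so in a 15-mer window
centered on the site the priming candidate sits at center + 4.

The substrate call uses peptidoform logic on multiplicity-resolved rows:
for a class-I, motif-positive site with a di-phosphorylated form and a
priming-only mono-phosphorylated form at +4, loss of the kinase's activity
should collapse the di form (log2FC ≤ −0.5, q < 0.05 at ≥ 1 early 2i
timepoint; the early window is 0.5–6 h) while the priming form persists
(log2FC ≥ 0 or non-significant at the same timepoint). Pairs where both
forms collapse are `rejected` — whole-site loss is not kinase-specific —
and motif sites without the pattern or without a paired mono form are
`motif_only`.

## Metabolomics

Features must be observed in ≥ 75% of the samples of at least one
treatment. Missing cells are MEC when an entire (feature, treatment) block
is missing and MAR otherwise. MAR cells are drawn from the feature's
observed Normal within the same treatment (falling back to all treatments
below 2 observations; sd 0 gives the deterministic mean). MEC cells are
treated as left-censored: each is drawn uniformly from (q − 0.5, q], where
q is the 2.5th percentile of the receiving sample's observed values. The
"2.5" is interpreted as a per-sample percentile bounding the draws from
above, with the draw-interval width fixed at 0.5 log2 units — this
reproduces deterministic left-censored behavior with a bounded, seeded
randomization; the interpretation is ours and is configurable
(`impute_config`). Imputation never alters observed cells. Quantile
centering subtracts each sample's median and restores the grand median,
making all sample medians equal. A whole sample with > 50% missingness is
dropped before analysis with a message.

## Protein–mRNA divergence

Per joined (feature, treatment, timepoint), `classify_posttranscriptional`
assigns exactly one class. "mRNA flat" requires **both** non-significance
(q ≥ 0.05) and |log2FC| < 0.1 — stricter than either alone, so a large but
noisy transcript change is not mistaken for quiescence. The per-feature
verdict (`summarize_divergence`) calls a feature post-transcriptional in a
treatment when it is divergent at ≥ 2 timepoints, its mRNA is not
significant at any protein-regulated timepoint, and the transcript is
quiet across the whole course (never q < 0.01 at any contrast). The
two-timepoint requirement exists because single-contrast protein false
positives pair with genuinely quiet mRNAs and would otherwise masquerade
as divergence; the across-course quiet rule encodes what the verdict
means — the transcript did not move while the protein did.

The negative control for this classifier permutes mRNA feature ids
*within the set of features eligible for the verdict* (protein regulated
at ≥ 2 timepoints). A whole-matrix shuffle is not informative: most
features are null, a planted divergent feature's own mRNA and a random
null partner are identically distributed, and no rule can tell them apart.
Within the eligible set, permuted partners almost all carry real mRNA
changes and are rejected; the residual recovery rate has an analytic floor
of roughly (number of planted divergent features − 1)/(eligible features),
which the test configuration keeps well below the 0.1 acceptance bound.

## The synthetic study

`simulate_study`, `simulate_phospho_layer` and `simulate_metabolome`
emulate the study design: 4 cell lines; proteome timepoints 0, 1, 2, 4, 7,
10, 14 days in two 8-channel plexes per cell line (one per treatment, each
with two S/L reference channels); phospho timepoints 0, 0.5, 1, 2, 6 h in
one 11-channel plex per cell line; metabolome 3 treatments × 4 lines × 4
replicates. Baselines are Normal(25, 2) log2 units; planted features
follow four trajectory shapes (early-saturating rise, linear rise,
transient pulse, late plateau), rescaled so the realized peak equals the
drawn amplitude of (4–6) × noise_sd; batch offsets are per-feature
Normal(0, 0.3) per plex; channel noise is Normal(0, 0.2). Reference
channels carry half the channel noise, modeling their doubled-input
loading — without this, the shared reference error correlates ratios
across timepoints and null proteins acquire coherent false trajectories.
The mRNA layer repeats the protein effects at half the noise (transcript
log2 ratios being averages over sequencing libraries), except for planted
post-transcriptional features whose mRNA effect is zero. Metabolite
missingness is uniform MAR at 5% plus whole-treatment MEC blocks for 5% of
features. One RNG stream per layer is derived from the master seed with
fixed offsets (Mersenne-Twister, inversion normals), so toggling one layer
never perturbs another and fixed seeds give bit-identical output.

What the generator does **not** emulate: reporter-ion ratio compression
and interference, peptide-to-protein inference ambiguity,
intensity-dependent missingness in the proteome, non-additive batch
effects, and correlated biological pathways (features are independent
given their planted labels). Passing tests therefore establish the
statistical machinery under the stated noise model, not performance on
any real dataset.

## Problem sizes and numerical choices

Tests run the simulations at reduced but statistically adequate scale,
chosen as a balance between Monte-Carlo precision and a single-CPU run:
type-I calibration at 20 seeds × 5000 null features; FDR control at 50
seeds × 800 features; prior recovery on 10,000 variances; gap-statistic
recovery at 20 seeds with B = 50; GSEA uniformity on 500 random sets at
200 permutations (the planted-set check uses the full 1000); substrate
inference at the full default scale of 5000 peptidoforms with 50 planted
substrates; divergence classification at 2000 proteins with 12 planted
divergent features (see the negative-control floor above). Degenerate
inputs follow explicit rules rather than erroring mid-pipeline: constant
trajectories z-score to zero and are skipped in correlations with a
recorded reason, constant centroids are flagged, sd-0 imputation is
deterministic, and k-means with K equal to the row count returns the
identity clustering.

## Limitations

The moderated test treats cell lines as exchangeable replicates; genuine
cell-line × treatment interactions would appear as inflated residual
variance, not as separate effects. The divergence classifier compares
matched nominal timepoints and does not model transcription→translation
lag beyond the nearest-earlier mapping. The GSEA FDR uses the standard
pooled-NES construction, which is conservative for very small set
collections. MEC imputation encodes a hard left-censoring assumption; if a
whole condition is missing for technical rather than abundance reasons,
imputed values will be biased low by design.
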