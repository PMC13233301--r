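---
title: "Linking an exposure EWAS and a disease EWAS through shared methylated regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking an exposure EWAS and a disease EWAS through shared methylated regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the design

A molecular marker can support a mediation-like interpretation of an
exposure–disease association if it is associated with the exposure in one
study and with the disease in another, in a compatible direction. mitmethyl
implements this "meet-in-the-middle" logic for DNA methylation:

1. **Exposure arm.** In a birth cohort, each CpG probe's M-value is
   regressed on a periconceptional folate dose (five sources: total, food,
   fortified, natural, supplemental), adjusting for case status, sex, array
   batch, ten reference-free cell-composition components and ten ancestry
   components.
2. **Disease arm.** In two blast datasets — Set A (leukemic blasts vs
   sorted CD19+CD34+ pre-B controls on a 450k-style array) and Set B (a
   second, smaller EPIC-style collection) — probes are regressed on a
   blast indicator controlling for leukemia subtype and batch, and the two
   results are combined per probe by a sample-size-weighted z-score
   meta-analysis on the probes shared by both arrays.
3. **Regions.** Each per-probe p-value track is reduced to differentially
   methylated regions (DMRs) with a spatially corrected combination
   (distance-binned autocorrelation, Stouffer–Liptak smoothing,
   seed-and-merge, Šidák correction).
4. **The middle.** Exposure DMRs are intersected with disease DMRs;
   each overlapping pair gets a direction on both sides by averaging
   member-probe coefficients; pairs whose Set A and Set B directions
   disagree are discarded; and the concordant fraction is tested against
   chance (1/2) with an exact two-sided binomial test, overall and within
   demographic strata (Hispanic ethnicity; household income split at
   $75,000, the boundary dollar counting as high).

Because the cohorts this design comes from are restricted-access biobank
data, the package ships a first-class simulator instead of data: every
stage can be exercised against planted ground truth.

# Models and statistics

**Scale.** Methylation beta values are clipped to $[10^{-6}, 1-10^{-6}]$
and logit2-transformed: $M = \log_2(\beta/(1-\beta))$. All regressions are
ordinary least squares on M-values; no variance moderation is applied.

**QC.** Probes, then samples, then probes again are dropped when more than
5% of their entries are missing (the order is fixed to make the filter
deterministic; a one-pass rule would depend on traversal order). Remaining
missing cells are imputed by the mean of the $k=10$ nearest complete probes
(Euclidean distance over the samples where the target probe is observed).

**Adjustment components.** Cell composition is estimated reference-free in
the ReFACTor manner: standardise probes, form a rank-$k$ principal
approximation, rank probes by how well it reconstructs them, and take
principal-component scores of the $t$ best-reconstructed probes (defaults
$k=5$, $t=500$, 10 scores). Ancestry components are PCA scores over a
designated list of ancestry-informative probes (10 scores). Both defaults
follow the ten-component adjustment convention of the motivating analysis.

**Supplemental dose coding.** The supplemental source takes the four
observed levels 0, 194, 360, 540 DFE. The pipeline codes it as an ordinal
score 0–3 with a single slope, because the downstream direction-averaging
step needs one signed coefficient per probe; full dummy coding is available
(`supplemental_coding = "factor"`) but the reported contrast is then the
top-dose level and it is not the pipeline default.

**Blast model coding.** The disease regressions include a blast-vs-control
indicator and leukemia subtype. Naive dummy coding of subtype is collinear
with the indicator (every blast has a subtype, no control does), so subtype
is coded with sum-to-zero contrasts among blasts, controls carrying zeros;
the reported effect is the indicator, i.e. the blast–control M difference
at the average subtype.

**Meta-analysis.** Per probe, $z_i = \mathrm{sign}(\hat\beta_i)
\Phi^{-1}(1-p_i/2)$ and
$Z = (\sqrt{n_A} z_A + \sqrt{n_B} z_B)/\sqrt{n_A+n_B}$. The
sample-size-weighted scheme is the default because the two sets come from
different platforms and control types, which makes pooling on a common
effect-variance scale (inverse-variance weighting) questionable; the
inverse-variance scheme is available behind `scheme = "ivw"`. No
genomic-control correction is applied inside the meta-analysis. The meta
statistic deliberately has no "coefficient": region directions downstream
always come from the per-set coefficients.

**DMR calling.** The track's spatial dependence is summarised by Pearson
correlations of $\Phi^{-1}(1-p)$ over probe pairs in 50 bp distance bins up
to 1000 bp; negative estimates are truncated at zero and bins with fewer
than 10 pairs inherit the previous bin (the first bin inherits the lag-0
value of 1 — the conservative choice for sparse chromosomes). Each probe's
p-value is then replaced by the Stouffer–Liptak combination
$Z = \sum z_i / \sqrt{k + 2\sum_{i<j}\sigma_{ij}}$ over its ±1000 bp
neighbourhood; a non-positive denominator (possible because the binned
correlations are not jointly positive definite) falls back to the
independence denominator $k$. Probes with smoothed $p < 0.05$ seed regions;
qualifying probes merge while consecutive gaps are ≤ 1000 bp; regions need
≥ 2 members. The extension threshold equals the seed threshold — only the
seed is stated in the motivating description, and equal thresholds are the
cited method's default behaviour. Regions are scored by Stouffer–Liptak
over their members' *raw* p-values (ACF held at its last bin beyond 1000
bp) and corrected as $1-(1-p)^m$ with
$m = \max(1, \lfloor \text{covered span} / \text{region width} \rfloor)$,
the covered span being the probe-covered extent of the tested track, not a
genome build. Two-sided regression p-values enter the combination through
the one-sided transform with the sign ignored; mixing signed transforms
would let opposite-direction probes cancel a real region.

**Coordinates.** Manifest positions are 1-based points; regions are
0-based half-open intervals (start = first member position − 1,
end = last member position), which makes BED export direct and makes
"touching" regions non-overlapping.

**Concordance.** Each (exposure DMR × disease DMR) pair sharing ≥ 1 base is
one counting unit — with internally non-overlapping region lists
many-to-many overlaps are rare, but the pair convention stays well defined
when they occur. The exposure direction is the sign of the mean exposure
coefficient over the *exposure region's own* member probes, and likewise
for the disease side over the blast region's members (not the
intersection): a region's direction belongs to the whole region. Exact-zero
means are treated as indeterminate and omitted rather than tie-broken. The
two-sided binomial p is the doubled smaller tail capped at 1,
$p = \min(1, 2\min\{P(X\le k), P(X\ge k)\})$ — this convention (rather than
the minimum-likelihood "minlike" rule) is what reproduces published values
such as $p(16, 18) = 0.001312$ and $p(6, 13) = 1$.

**Cohort-table utilities.** Group comparisons from printed summary
statistics use the Welch unequal-variance t-test with Welch–Satterthwaite
degrees of freedom by default; it reproduces published subgroup values
(e.g. 0.006 for the natural-folate comparison in low-income non-Hispanic
White participants) where the pooled test gives 0.008. The pooled variant
is available via `var_equal = TRUE`. Exact r×2 contingency tests for the
four-level supplemental dose are out of scope; the report prints the
contingency tables only.

# What the simulator emulates

`synth_config()` defaults encode the study design: 394 cohort samples
(≈189 cases), Set A with 227 blasts + 6 controls restricted to the ~70%
of probes shared between arrays, Set B with 37 + 10 on the full probe set.
Probes are laid down with exponential inter-probe gaps (mean 500 bp), so
planted regions occasionally contain a gap beyond the 1000 bp merge
distance and the caller's splitting behaviour is exercised rather than
idealised away.

Each cohort sample's M-profile is a convex mixture of latent cell-type
profiles (Dirichlet proportions; each cell type deviates from a shared
bimodal baseline at ~30% of probes, so composition is the dominant
low-rank structure, as in real whole-blood arrays), plus a batch shift, an
ancestry shift at a designated informative-probe list (one latent
coordinate tied to the ethnicity label), planted exposure effects, and
Gaussian noise. Effects are additive on the M scale and quoted on the beta
scale at a 0.5 baseline (delta-beta 0.1 per dose SD corresponds to
log2(0.6/0.4) ≈ 0.585 M units); betas are clipped into (0, 1). Dose columns
are lognormal, loosely matched to published cohort means/SDs (the source
tables give only means and SDs, so the lognormal shape is an arbitrary but
documented choice), with food = fortified + natural, total = food +
supplemental, and supplemental drawn from {0, 194, 360, 540} with the
published frequencies. Blast samples add the planted disease effect at
disease-region probes, with the same sign in both sets unless a region is
flagged set-discordant (`frac_set_discordant`, default 0).

The simulator does **not** model probe chemistry (type I/II), detection
p-values, IDAT-level preprocessing, chromosome-specific structure, or
realistic linkage between neighbouring probes' baselines; passing tests
demonstrate the pipeline's statistical behaviour under the planted model,
not performance on raw array data.

# Numerical and design choices

- Tail transforms use `qnorm(p, lower.tail = FALSE)`; the naive
  `qnorm(1 - p)` overflows to infinity below ~1e-17. p-values are clipped
  to [1e-300, 1 − 1e-16] before probit transforms, and Šidák correction is
  computed as `-expm1(m * log1p(-p))` for precision at small p.
- Zero-variance probes get coefficient 0, p = 1 and a `degenerate` flag;
  rank-deficient designs fail loudly, naming the collinear columns.
- Component scores are SVD-based, hence deterministic up to sign for a
  given input; no randomised solvers are used.
- Subgroup analyses recompute the exposure EWAS on the stratum's samples
  (components computed once on the full cohort and subset), then re-call
  exposure DMRs and re-overlap against the unchanged disease DMRs — the
  disease arm has no demographic covariates to stratify on.
- An empty stratum is an error, mirroring the analysis convention of
  skipping strata too small to analyse rather than returning empty tables.

A known behaviour worth stating: reference-free components estimated on a
matrix that contains a strong, widespread exposure signature can absorb
part of that signature (the exposure axis becomes a low-rank direction),
deflating the exposure EWAS. At the package's study-scale simulations
(20,000 probes, ~200 planted-effect probes) the exposure axis stays below
the noise floor of the component estimation and recovery is unaffected; in
very small matrices with large planted effects the interference is visible.
This mirrors the real trade-off of reference-free adjustment on strongly
affected tissues.

# Problem sizes used by the checks

The packaged checks run at 20,000 probes: 20 uniform-p null tracks for the
false-positive bound, 20 simulated cohorts (n = 200, 5-probe regions,
delta-beta 0.1 per dose SD) for DMR sensitivity, and 10 full pipeline runs
(25 overlap regions each, planted concordance 0.9) for end-to-end recovery,
pooling the concordant fraction across runs and comparing it with the exact
binomial 95% interval of 0.9. The pooled comparison is used because each
run's planted concordant count is itself a Binomial(25, 0.9) draw: judging
every run against its own interval would fail a few percent of runs by
construction, whereas the pooled fraction tests the same recovery claim at
stable power. Calibration checks use 2,000 probes for the
permutation type-I error and 50,000 probes for null genomic inflation.
These sizes were chosen as the smallest at which the distributional
properties being tested are stable across seeds.

# Limitations

- Region-level significance uses Šidák correction only; no FDR variant.
- No heterogeneity statistics accompany the meta-analysis.
- No gene annotation, enrichment testing, or mQTL screening of regions.
- Chromosome X/Y probes are treated like autosomes (included,
  unstratified), matching the motivating analysis' stated inclusion.
- The Welch test from summaries assumes the printed SDs are sample SDs.
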