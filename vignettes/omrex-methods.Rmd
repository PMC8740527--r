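---
title: "Models and methods behind omrex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omrex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrex)
```

`omrex` analyzes DOM remineralization incubations: a natural marine
bacterioplankton community, released from grazing by dilution into
particle-free seawater, consumes the ambient dissolved organic matter in the
dark while abundance, organic carbon, amino acids, untargeted MS1 features
and 16S ASV composition are followed from inoculation (T0) through
stationary phase (~1 week) to a final time point (~90 d). This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic generator does and does not emulate.

## Biomass from cell images

Cells measured in epifluorescence images are reduced to a maximum and a
minimum dimension (µm). Cells with max:min < 1.5 are treated as spheres;
the open question is what the assumed spherical diameter should be for a
slightly elongated cell — we use the mean of the two dimensions, which is
symmetric and reduces exactly to the sphere at max = min. At or above the
1.5 ratio the cell is a rod of width `min_dim`: a cylinder of height
`max − min` capped by hemispheres; a width-based radius is the only choice
under which that height definition is geometrically coherent. The boundary
ratio 1.5 itself takes the rod branch (the sphere rule is a strict
inequality).

Biovolume is aggregated as the arithmetic mean per image and then across
images, and the biovolume-to-carbon power law `C = a V^b` is applied to the
*mean biovolume*, not averaged over per-cell carbons — with b < 1 the two
differ by Jensen's inequality, and the per-image-mean path mirrors how the
image-analysis scripts of such studies work. Both aggregation paths are
reachable (`per_experiment` toggles time-point matching).

Three conversions are built in (EXPORTS 91.71·V^0.686; Gundersen
108.8·V^0.898; Malfatti 103.02·V^0.59, fg C cell⁻¹). All carbon mass
conversions use 12.011 g mol⁻¹. The GF/75 filter corrections (blank
5.3 µg C L⁻¹, retention 0.783) are exposed but not implied in the main
chain, since biomass there comes from abundance × cell carbon.

## Rates, gates and growth efficiency

DOC\* = organic carbon − bacterioplankton biomass carbon; the asterisk
records that an unconstrained non-cellular fraction < 3 µm remains. Rates
are model-I (OLS) slopes: production from BB vs time over T0→stationary,
removal from DOC\* vs time over the same window (short-term) and
stationary→final (long-term). Replicate vials enter as independent points.
OLS is the right error model here because time is essentially error-free;
the symmetric-error (model-II) fits are reserved for cross-variable
regressions (below).

A growth efficiency `BGE = BP / removal rate` is only reported when three
gates all pass: drawdown > 2 × 0.7 = 1.4 µmol C L⁻¹ (twice the analytical
precision of the organic-carbon measurement), and two-tailed p < 0.05 on
each slope. The gates are a pure conjunction; raising any threshold can
only remove reported BGEs.

Uncertainty is propagated from the slopes' relative errors,
`σ_BGE = BGE·√((σ_r/r)² + (σ_BP/BP)²)`. A literal mode evaluating the same
expression with inverted ratios (value/error) is retained behind
`mode = "literal"` because that inverted form circulates in print; on
realistic inputs it yields errors ~40× the propagated ones and cannot
reproduce any tabulated ± value, which the test suite demonstrates rather
than hides.

### Stationary-phase detection

The verbal criterion — "the period demonstrating no cell growth with time"
— needs an estimator. Short rolling-window slope tests (3–4 points) have 1–2
residual degrees of freedom and essentially no power at realistic
observation noise, so they call spurious plateaus days early; testing the
whole trailing series fails in undiluted experiments where a death phase
cancels late growth; and broken-stick fits lock onto the curvature of
ln(logistic) rather than the plateau. `detect_stationary()` therefore uses a
plateau-attainment rule: smooth ln(abundance) with a centered 3-point
rolling mean, take the plateau as the smoothed maximum (under a death phase
this is reached at the end of growth), and report the earliest time within
0.1 log units (~10% of abundance) of it. Two guards keep the semantics
honest: the pre-onset OLS slope must be significantly positive (one-sided
α = 0.05) or a no-growth error is raised, and an onset inside the last
three points means growth never stopped (`NA`, no stationary phase). On
simulated series with a day-7 plateau and 5% abundance noise the estimate
concentrates on days 6–7 with > 90% within ±1 day. The pipeline accepts a
per-experiment override column (`days_to_stationary`) since such studies
often fix the day by inspection.

## Amino-acid degradation indicators

mol% compositions, THAA expressed in carbon units (each amino acid weighted
by its carbon atoms, nmol → µmol), the degradation index
`DI = Σ (mol%_i − µ_i)/σ_i · c_i`, and the combined mol% of GABA +
β-alanine. The DI loadings, reference means and reference sds are
*configuration, not code*: the published loading tables belong to the
degradation-index literature and are not reprinted here, so the package
ships `synthetic_di_coefficients()` — a clearly labelled synthetic stand-in
whose signs follow the chemistry (positive loadings on amino acids enriched
in fresh planktonic protein, negative on those accumulating with
degradation) — and accepts any published table through
`di_coefficients()`. The non-protein amino acids are normalized into mol%
but excluded from the DI unless a coefficient table lists them. Acid-labile
losses (e.g. tryptophan destruction during hydrolysis) are not corrected.

Phase comparisons use a pooled-variance two-tailed t-test on replicate
indicator values; "more degraded" means the DI fell or GABA + β-Ala rose
significantly.

## MS1 feature analysis

Features are kept when their maximum sample area exceeds 3× the process
blank (zero-blank features need only a positive area); raising the factor
is monotone by construction. Z-scores standardize each feature across all
samples with the sample (n − 1) standard deviation — with few samples this
choice is visible and is therefore stated; constant features have no
defined z-score and are dropped with a warning. Because z-scores are
location/scale free per feature, total-area normalization of samples is
optional (`normalize`). Per-class changes between phases are one-sample
t-tests of the feature-level Δz against zero (degenerate all-equal classes
are handled exactly), and the covariate screen uses raw Pearson p < 0.05 by
default with a Benjamini–Hochberg option (`adjust = "BH"`), because the
count-of-significant-features display it feeds conventionally uses raw
p-values.

## ASV community statistics

Log2 fold changes between phases use detection-limit pseudocounts
(1/read-depth added to both phases' relative abundances), keeping fold
changes finite for taxa absent at one phase while leaving abundant taxa
essentially untouched; the responder threshold is log2(3) ≈ 1.58, a
threefold increase. Responder analysis is run on the top-100 ASVs by mean
relative abundance (ties broken by id), which in both the field data and
the generator carry ≳ 90% of the reads.

Shannon–Wiener H (natural log; base is an argument) comes with the
large-sample variance `[Σ p (ln p)² − H²]/N + (S−1)/(2N²)` and Hutcheson's
t-test (`t = ΔH/√(V₁+V₂)`, Welch-style df). Alpha diversity is computed on
non-rarefied counts; rarefaction, where wanted for sensitivity, can be
applied upstream. The indicator statistic is the group-equalized
point-biserial correlation ("r.g"): a Pearson correlation between an ASV's
abundances and 0/1 group membership with samples weighted `N/(K·n_g)` so
each group counts equally; for equal group sizes it is the ordinary
point-biserial. Each ASV is tested on its best group with the
max-over-groups statistic under label permutations
(`p = (1 + #{perm ≥ obs})/(1 + n_perm)`, deterministic under a seed);
designs of ≤ 8 samples can enumerate every distinct relabelling instead,
where p becomes a simple fraction with the observed arrangement included.
The full multi-level site-combination search of the indicator-species
literature is out of scope; only the single-group association form is
implemented.

## Shared statistics

`sma_fit()` is the standardized major axis: slope = sign(r)·sd(y)/sd(x)
through the centroid, p from the correlation test — the appropriate
model-II line when both variables carry error, as in rate-vs-DI or
diversity-vs-degradation regressions. Which model-II variant (SMA vs ranged
major axis) such studies use is rarely stated; SMA was chosen as the common
default and the choice is isolated in one function. "Non-linear model-II"
relationships (e.g. exponential rate-vs-DI fits) are implemented as least
squares on ln y (`exponential_fit()`), an interpretation flagged as such:
r² and p refer to the transformed scale. `two_sample_compare()` routes
through Shapiro–Wilk at α = 0.05 per sample to a pooled-variance t-test or
a Mann–Whitney test and reports which route was taken.

## The synthetic generator

`simulation_params()` defaults *are* the study conditions: initial DOC\*
54–61 µmol C L⁻¹; triplicate organic-carbon vials with σ = 0.7 µmol C L⁻¹
Gaussian noise; growth plateauing at day 7 (6–10 observed) and monitored to
day 90; BGE defaults 0.30 within the observed 0.15–0.45; biovolumes
0.03–0.09 µm³; abundance observation noise 5% (the level at which parallel
incubation vials agreed); THAA starting at 1.45 µmol C L⁻¹ and declining by
33% of the DOC\* decline while the composition mixes from a fresh toward a
degraded endmember (so GABA + β-Ala rises and DI falls monotonically);
~1831 MS1 features in six classes with the amino-acid-like class decaying
by 0.35 log units — calibrated so its planted z-score change is ≈ −1, one
standard deviation — and 10% of features parked below 3× blank; 492 ASVs at
read depths 10,951–44,686 with a six-taxon stable dominant block (45%
combined, mimicking SAR11/SAR86) and 25 planted responders.

Choices worth defending explicitly:

* `bp_rate_true = 0.15` µmol C L⁻¹ d⁻¹ sits inside the observed production
  range and yields DOC\* drawdowns of 2.25–4.5 µmol C L⁻¹ across BGE
  0.2–0.4 — inside the 1–5 µmol C L⁻¹ the incubations showed.
* Organic carbon is generated as the *inverse* of the efficiency quotient,
  `OC(t) = DOC₀ + BB(t) − (BB(t) − BB(0))/BGE + ε`, so the analysis chain
  closes the loop exactly at zero noise and recovers the generating BGE to
  within ±0.03 (bias ≤ 0.015 at BGE 0.4, from ratio-estimator curvature)
  over 200 replicates at the study noise level.
* Responder folds are planted on the realized relative-abundance scale:
  responders get exactly fold × base and the stable remainder shrinks to
  compensate. Multiplying before renormalization would deflate every
  realized fold by the normalization constant (~1.7 at these settings), so
  "planted threefold" would not mean threefold. Fold factors default to
  U[4, 12], matching the predominantly strong (> fourfold) responses such
  incubations show; the mild compensatory decline of the stable taxa is
  itself realistic.
* The Dirichlet-multinomial total concentration is `50 · n_asvs` (mean
  per-ASV concentration 50). This puts mid-rank relative-abundance CVs
  near 10%, consistent with the parallel-vial agreement; a *total*
  concentration of ~50 would give composition noise larger than the
  signals any of the downstream analyses are asked to detect.

What the generator does **not** emulate: grazer and viral dynamics (the
undiluted death phase is a phenomenological exponential), iron limitation
or priming mechanisms, taxonomy-linked ecological structure (taxonomy
strings are synthetic labels), chromatographic artifacts, compositional
correlations among amino acids beyond the two-endmember mixing line, and
batch effects across MS runs. Passing tests therefore certify the
*statistical machinery* — estimator consistency, gate logic, calibration of
permutation and correlation screens — not the ecological fidelity of any
particular field data set.

## Numerical conventions and degenerate inputs

* OLS fits require ≥ 3 points and positive time variance; exact fits
  (zero residual) report p = 0 for a nonzero slope and p = 1 otherwise.
* Zero-variance phases in t-tests are handled exactly (p = 1 for equal
  means, p = 0 otherwise) instead of erroring.
* Ties in top-N selection break by ASV id; permutation p-values never fall
  below 1/(n_perm + 1); exhaustive enumeration includes the observed
  arrangement in the denominator.
* `log2_fold_change` with both abundances zero and no pseudocount is NA,
  never ±Inf; with a one-sided zero it is ±Inf only when pseudocounts are
  explicitly disabled.
* All generators are pure functions of `(params, seed)` and restore the
  caller's RNG state; `run_pipeline()` writes outputs atomically and embeds
  the seed in `run_log.yml`.

## Problem sizes used in the shipped checks

Monte-Carlo recovery runs 200 replicates per BGE level (0.20/0.30/0.40);
responder recovery 5 seeds × 4 experiments × 492 ASVs; permutation
calibration 999 permutations over 30 null taxa; the full suite completes in
about a minute on one core. These sizes were chosen to make the binomial /
Monte-Carlo error of each check several times smaller than the tolerance it
asserts.

## Known limitations

* The stationary-onset estimator assumes roughly daily sampling around the
  plateau; sparse sampling widens its ±1-day resolution accordingly.
* Long-term biomass for DOC\* correction is carried forward from the last
  abundance observation (biomass is a ≲ 2% correction at those time
  scales).
* The r.g permutation test permutes sample labels freely and so assumes
  exchangeability across experiments when phases are pooled.
* DI values computed with the synthetic coefficient table are internally
  consistent (ordering, scale invariance) but not comparable to published
  DI scores; substitute the published loadings for real data.
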