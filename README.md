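# omrex

Quantitative analysis of seawater dissolved-organic-matter (DOM)
remineralization experiments — the dark-incubation design in which a natural
bacterioplankton community is diluted into particle-free seawater and its
consumption of the accumulated DOM pool is followed for days to months.
`omrex` implements the full analysis chain used for the 2018 summer
incubations at Ocean Station Papa (NE Pacific, EXPORTS field campaign) as a
tested, reusable R package, together with a synthetic-data generator so every
stage can be exercised end to end without any field data.

## What it computes

**Bacterioplankton biomass.** Cell dimensions from epifluorescence images are
converted to biovolumes — spheres when the max:min dimension ratio is < 1.5,
rods (cylinder + hemispherical caps) otherwise:

    V_sphere = 4/3 π r³,  r = ((d_max + d_min)/2)/2
    V_rod    = 4/3 π r³ + π r² h,  r = d_min/2, h = d_max − d_min

and to carbon by a power law `C_cell = a·V^b` (built-in conversions: EXPORTS
91.71·V^0.686, Gundersen 108.8·V^0.898, Malfatti 103.02·V^0.59, all fg C per
cell). Bulk biomass (BB, µmol C L⁻¹) follows from cell abundance, with GF/75
filter blank (5.3 µg C L⁻¹) and retention (78.3%) corrections available.

**DOC\* removal, production and growth efficiency.** DOC\* = measured organic
carbon − BB. Bacterial production (BP) is the model-I (OLS) slope of BB vs
time from T0 to stationary phase; the DOC\* removal rate is the magnitude of
the corresponding negative slope. Bacterial growth efficiency is

    BGE = BP / DOC* removal rate

with uncertainty propagated from the two slopes' relative standard errors.
A BGE is reported only when the DOC\* drawdown exceeds twice the 0.7 µmol C
L⁻¹ analytical precision (1.4 µmol C L⁻¹) and both regressions are
significant at α = 0.05. Stationary onset is detected from ln(abundance) by
a plateau-attainment rule with a significance-checked growth phase before it.

**Organic-matter quality.** From total hydrolyzable amino acid (THAA)
concentration tables: mol% compositions, THAA carbon, the degradation index
(DI, a weighted sum of standardized mol% values — lower = more degraded) and
the combined mol% of the non-protein amino acids GABA + β-alanine (rises
with degradation), with two-sample phase tests and a diagenetic direction
call.

**Untargeted MS1 features.** 3× process-blank filtering, per-feature
z-scoring across samples, compound-class summaries of z-score changes
between initial and stationary phases, and per-feature Pearson screens
against bioavailability covariates.

**16S ASV community statistics.** Relative abundances, top-N selection with
coverage, log2 fold-change responder calls at log2(3) ≈ 1.58 (threefold)
with detection-limit pseudocounts, Shannon–Wiener H with its large-sample
variance and Hutcheson's t-test, and a group-equalized point-biserial
("r.g") indicator statistic with permutation p-values (exhaustive
enumeration on small designs).

## Worked example

The package ships the per-experiment results table of the Station Papa
incubations (`osp_rate_table()`: 18 experiment × treatment rows across 5,
35, 50 and 95 m). Summarizing it reproduces the study-level numbers:

```r
library(omrex)

s <- summarize_experiments(osp_rate_table())
summary_value(s, "all", "all", "short_rate")        # 0.191
summary_value(s, "all", "all", "short_rate", "sd")  # 0.0808
100 * summary_value(s, "all", "all", "bge")         # 30.8
100 * summary_value(s, "subsurface", "all", "bge")  # 28
```

The ten experiments with significant short-term DOC\* removal average
0.19 ± 0.08 µmol C L⁻¹ d⁻¹, and their growth efficiencies (EXPORTS
conversion) 31 ± 7%, subsurface mean 28% — i.e. roughly a third of the
consumed carbon became biomass. A single efficiency from printed rate
cells:

```r
bge(0.05, 0.11)                          # 0.4545
bge_error(0.389, 0.18, 0.03, 0.07, 0.01) # 0.0854
```

A fully synthetic closed loop — generate an incubation with a known growth
efficiency, then recover it:

```r
p  <- simulation_params(n_experiments = 1, bge_true = 0.30)
g  <- simulate_growth(p, seed = 1)
oc <- simulate_doc(p, seed = 2)
bb <- estimate_biomass(g$cells, g$abundance)
r  <- experiment_rates(oc$time_days, oc$oc_umol_l,
                       bb$time_days, bb$bb_umol_c_per_l,
                       t_stationary = 7)
r$bp / r$short_rate                      # 0.317 (true 0.30)
```

`simulate_bundle()` writes a complete input bundle (abundance, cell
dimensions, organic carbon, THAA, MS1 features + blanks, ASV counts +
metadata) and `run_pipeline()` analyzes it into report tables
(`table2.csv`, `thaa_indicators.csv`, `class_changes.csv`,
`diversity.csv`, `responders.csv`, `indicators.csv`, ...), deterministic
under the configured seed. See the methods vignette
(`vignettes/omrex-methods.Rmd`) for the model assumptions and numerical
choices.

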