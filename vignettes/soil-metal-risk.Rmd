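---
title: "Assessing heavy-metal pollution and ecological risk in irrigated soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing heavy-metal pollution and ecological risk in irrigated soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
```

## The problem

Long-term sewage irrigation deposits heavy metals in the top 0–20 cm of
agricultural soil. Given a table of georeferenced topsoil samples with
concentrations of the seven-metal panel As, Hg, Cd, Cr, Pb, Cu and Zn
(mg/kg dry soil), `metalrisk` answers three questions: *how polluted is each
sample and district* (index computation and grading), *where does the
contamination likely come from* (correlation structure and per-district
PCA), and *how is it distributed in space* (inverse-distance-weighted
surfaces). A seeded synthetic-campaign generator makes the whole pipeline
runnable and testable without field data.

## Indices and their grading

Three standard indices are computed per sample, each against the reference
tables in `reference_set()`:

* **Geo-accumulation index** $I_{geo} = \log_2\!\big(C_i / (1.5\,B_i)\big)$,
  with $B_i$ the local geochemical background. The 1.5 margin absorbs the
  natural fluctuation of background levels. Seven grades from
  *unpolluted* ($I_{geo} < 0$) to *extremely polluted* ($I_{geo} \ge 5$).
* **Nemerow composite index** over the single pollution indices
  $P_i = C_i / S_i$ (with $S_i$ the agricultural risk screening standard):
  $P_N = \sqrt{(\bar P^2 + P_{max}^2)/2}$. It deliberately over-weights the
  worst metal. Five classes from *clean* ($P_N \le 0.7$) to *heavily
  polluted* ($P_N > 3$).
* **Potential ecological risk** $E_r^i = T_i\, C_i / S_i$ per metal, with
  $T_i$ the Hakanson toxic response factor (Cd 30, Hg 40, As 10, Pb 5,
  Cr 2, Cu 5, Zn 1), and the composite $PERI = \sum_i E_r^i$. $E_r < 40$
  is low pollution; $PERI \le 150$ is low risk.

Grading rules are deliberately per-scheme. The published class definitions
are inconsistent about which side a boundary belongs to — the
geo-accumulation grades are left-closed ($1 \le I_{geo} < 2$) while the
Nemerow and PERI classes are right-closed ($0.7 < P_N \le 1$) — so each
`grade_scheme` carries its own `boundary_rule` instead of the package
imposing one convention. Classification is total on finite inputs and
monotone in the index value; non-finite values are refused rather than
silently binned.

Two conventions worth stating explicitly:

* **Nemerow dialect.** The composite is sometimes written with an
  arithmetic rather than a root-mean-square combination of $\bar P$ and
  $P_{max}$. The RMS form is the standard one and matches the 0.7/1/2/3
  class cut-offs, so it is the default; `nemerow(..., "arithmetic")` and
  the pipeline's `nemerow_dialect` option expose the literal arithmetic
  reading. The choice is logged with every run.
* **Single-index grading.** `index_table()` grades the bare ratio
  $P_i = C_i/S_i$ with the same 0.7/1/2/3 cut-offs as the composite, the
  usual single-index convention; there is no separate published scale
  for it.

**Below-detection policy.** $E_r$ and $P_N$ are linear in concentration and
accept zeros. $I_{geo}$ is a log ratio, so for that index only,
non-positive concentrations are substituted by half the reference set's
detection limit before the logarithm. Detection limits are advisory: the
reader flags below-detection tokens (`<DL`) and non-positive values
(`below_detection:<metal>` in the `flags` column) but never rejects a
sample for them.

**Rounding.** All internal values are full precision. Report writers round
half-away-from-zero to two decimals (`round_half_up()`), the convention of
the published tables, and every rounded report file has a `_raw` companion.

## Descriptive statistics, correlation, PCA

`district_summary()` reports per-district min/max/mean and the coefficient
of variation $CV = 100\,s/\bar x$ with the $n-1$ standard deviation, hence
the two-sample minimum per district. `metal_correlation()` pools all
districts into one Pearson matrix with two-sided p-values from the $t$
distribution on $n-2$ degrees of freedom and the usual star annotation
(* $p<0.05$, ** $p<0.01$, kept as a separate annotation column); no
multiple-testing correction is applied, matching the reporting convention
the matrix mirrors.

PCA (`metal_pca()`, `pca_by_district()`) standardizes each metal to
z-scores and eigendecomposes the correlation matrix, so eigenvalues sum to
the number of metals and a component's contribution rate is its eigenvalue
over seven. Components with eigenvalue $\ge 1$ are retained (Kaiser
criterion). Loadings are unrotated
$\mathbf{v}_j\sqrt{\lambda_j}$; an eigenvector's sign is arbitrary, so each
component is flipped to make its largest-magnitude loading positive, which
makes runs reproducible. PCA is run per district by default because source
structure differs between districts; `pca_scope = "pooled"` is available.
Groups with no more samples than variables are logged and skipped rather
than aborting a run.

## Spatial interpolation

`idw()` interpolates scattered values onto a `make_grid()` raster with
weights $d^{-p}$, $p = 2$ by default and all points as neighbours unless
`max_neighbors` is set — none of these is dictated by the method itself, so
they are plain defaults, logged per run. A cell within `snap_tol`
(default 1 nm) of a sample takes the sample's value exactly; coincident
input points must agree or be explicitly pre-averaged. The surface is
bounded by the input range and scale-equivariant. Coordinates are assumed
planar (projected metres); no great-circle distances. Grids export as long
CSV or ESRI ASCII rasters.

## The synthetic campaign generator

`study_district_specs()` ships a three-district design — Xiaodian (n = 35),
Jinyuan (n = 35), Qingxu (n = 40) — with per-metal target means and CVs per
district and a single pooled 7×7 correlation target. `generate_samples()`
draws each metal as a lognormal, chosen because the targets' CVs are
moderate to large (Hg up to 127%) and concentrations are positive and
right-skewed; dependence comes from a Gaussian copula applied on the latent
normal scale, where the correlation target is specified. The small
difference between latent-scale and observed-scale Pearson correlation is
accepted: all target correlations are modest ($|r| \le 0.5$).

Parameters start from the closed form $\sigma^2 = \ln(1 + CV^2)$,
$\mu = \ln(\text{mean}) - \sigma^2/2$. Records falling outside per-metal
plausibility bounds — $[0,\, 2\times\text{target max}]$ by default, wide
enough not to clip the bulk of the distribution, unlike truncation at the
observed extremes — are redrawn, capped at 1,000 rounds. Because rejection
thins the right tail, which at Hg-like CVs would depress the delivered CV
by around 10%, the solver moment-matches the *truncated* lognormal to the
targets (a two-parameter optimisation from the closed-form start). When no
parameters can satisfy the bounds the solver falls back to the closed form
and the rejection cap reports the design as unsatisfiable, naming the
metal. Coordinates are uniform in each district's bounding box; the boxes
are arbitrary planar extents, as the emulated campaign publishes no
coordinates. Everything is a pure function of the seed.

What the generator does *not* emulate: spatial autocorrelation (an optional
linear gradient hook was considered and dropped — there is no quantitative
gradient to calibrate against), district-specific correlation structure
(one pooled target), measurement error and censoring at detection limits,
and any PCA loading structure beyond what the correlation target implies.
Tests that pass on synthetic campaigns therefore validate the pipeline's
arithmetic and bookkeeping, not geostatistical behaviour on real fields.

## Numerical checks the suite enforces

At n = 10,000 per district the generated means recover their targets within
2% and CVs within 5%, and latent-scale correlations sit within 0.05 of the
target matrix. Index values agree with an independent straight-line
re-evaluation of the formulas to 1e-10 across 1,000 random samples; every
published class boundary is tested from both sides; PCA eigenvalues sum to
the metal count within 1e-8 and loadings reconstruct the correlation
matrix; IDW is exact at sample locations and bounded on random fields; and
a seeded pipeline run is byte-identical across repetitions. Routine test
fixtures use 30–110 samples so the default suite stays fast; the recovery
checks are the only ones run at n = 10,000.

## A worked run

```{r, eval = FALSE}
samples <- study_fixture(seed = 1)          # 110 synthetic records
summ <- district_summary(samples)
idx <- index_table(samples)
dplyr::filter(idx, index_name == "PERI") |>
  dplyr::group_by(district) |>
  dplyr::summarise(mean_peri = mean(value))

out <- run_pipeline(run_config(simulate = TRUE, out_dir = "report", seed = 1))
```

The bundle written by `run_pipeline()` mirrors the standard report shapes:
district summary, correlation with stars, PCA bookkeeping and loadings,
geo-accumulation grade frequencies, Nemerow and PERI district summaries,
per-district Er ranges, the per-sample long table, and a parameter log that
records the reference values actually used, so nonstandard overrides are
auditable.

## Known limitations

* District PERI ordering and similar rank statements are always computed
  from the data at hand, never hard-coded.
* The pooled correlation target is applied to every district; real
  campaigns differ by district.
* IDW is a deterministic interpolator: no uncertainty surface, no
  variogram structure. Kriging is out of scope.
* Reference tables ship for one study region (Taiyuan backgrounds,
  GB15618-2018 screening values); other regions must override them via
  `reference_set()` or a YAML/TOML config. pH-dependent screening values
  are not modelled — a config override covers those uses.
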