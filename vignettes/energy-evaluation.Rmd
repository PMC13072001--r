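---
title: "Energy evaluation of sow feeds by indirect calorimetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy evaluation of sow feeds by indirect calorimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowcal)
```

This vignette is the package's account of its science: the measurement
model, the conventions and constants it commits to, what the synthetic
trial generator does and does not emulate, and the numerical and design
choices a maintainer would want spelled out.

## The measurement model

An open-circuit respiration chamber measures O2 depletion and CO2/CH4
enrichment between inlet and exhaust air, together with exhaust flow.
`integrate_gas_day()` turns these traces into daily gas volumes by
trapezoidal integration of concentration-difference × flow, and
`brouwer_thp()` converts volumes plus urinary nitrogen into total heat
production:

$$\mathrm{THP\,(kJ)} = 16.18\,V_{O_2} + 5.02\,V_{CO_2} - 2.17\,V_{CH_4} - 5.99\,\mathrm{UN}$$

with volumes in litres per day and urinary N in grams per day. The
coefficients live in `energy_constants()` as positive magnitudes; the
signs belong to the formula. The respiratory quotient
$RQ = V_{CO_2}/V_{O_2}$ indexes substrate oxidation (near 1 on
carbohydrate-rich fed days, 0.7–0.8 when fasting shifts oxidation to
body fat).

From one sow-period, `diet_energy_values()` assembles the energy cascade
per kg of dietary dry matter (DM):

* **DE** — gross energy intake minus fecal energy, over DM intake.
* **ME** — DE minus urinary energy and methane energy. The chamber
  measures CH4 as a volume; its energy content uses the combustion
  enthalpy 39.54 kJ/L. The source trial reports methane only as a
  percentage of DE and never prints its conversion factor, so this is a
  package convention, configurable in `energy_constants()`.
* **RE** — metabolizability intake minus heat: ME intake (kJ/kg
  BW^0.75/d) minus the mean Brouwer THP of the fed days.
* **REP/REL** — retained energy as protein is retained N × 6.25 ×
  23.86 kJ/g (the retained-protein energy convention of the
  energy-partition literature); lipid retention is the remainder, so
  RE = REP + REL holds exactly by construction.
* **NE** — retained energy plus fasting heat production, scaled back to
  feed: $(RE + FHP) \times BW^{0.75} / DMI$. FHP approximates the
  maintenance heat the animal would produce with no feed; adding it to
  RE credits the diet with maintenance as well as retention.

Metabolic body weight BW^0.75 is the scaling basis for all rates, the
standard allometry for energy metabolism in pigs.

### Fasting heat production

FHP is computed from the overnight fasting window (22:00–06:00 in the
reference schedule). Two conventions are explicit and configurable:

* The 8 h window is extrapolated **linearly** (×3) to a daily rate. The
  fasting state has no feed-driven diurnal rhythm, so a constant rate is
  the natural assumption; no alternative scaling is claimed by the data.
* The Brouwer urinary-N term is **included**, with the fasting day's
  urine collection prorated to the window length (`include_n_term =
  FALSE` omits it). The N term is below 1% of THP at typical values, so
  the choice is close to immaterial, but it is stated rather than
  hidden.

Gas volumes are treated as already expressed at a common reference
condition; an STP correction is deliberately not applied because chamber
calibration details are site-specific. No washout/lag deconvolution is
attempted (open-circuit steady state assumed) — a known limitation for
short windows.

## The difference method

A test diet replaces a fraction $r$ of the basal diet with the test
ingredient ($r = 0.289$ in the reference design). Energy densities mix
linearly in the substitution, so the ingredient value is

$$E_{ing} = \frac{E_{test} - (1 - r)\,E_{basal}}{r}.$$

`ingredient_energy_per_sow()` applies this per (test sow, basal
reference) pair and averages; ME/DE and NE/ME ratios are computed from
the averaged values. Because $r < 1$, measurement error is amplified by
$\sqrt{1 + (1-r)^2}/r$ (about 4.2× at $r = 0.289$ when test and basal
errors are comparable) — the reason ingredient-level ratios can
innocently exceed 100%. Such values are flagged, never clipped.

$r$ is taken as the as-fed inclusion with energies on a DM basis; the
small DM mismatch between the ingredient and the replaced basal fraction
is a documented approximation. The mineral/premix fraction (constant
2.95% across diets, contributing essentially no GE) is treated as part
of the basal fraction.

## Prediction equations

`pearson_matrix()` screens composition against energy values with
two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$. Hemicellulose is
never stored in composition tables — it is always derived as NDF − ADF
at the point of use, keeping the assayed table the single source of
truth.

`stepwise_select()` implements SAS-style stepwise regression: the
candidate with the smallest partial-F p-value enters while below
`slentry`; after each entry any retained term with p above `slstay`
leaves; ties break by candidate order; a visited-state guard stops the
classical enter/remove cycle that occurs when a variable's p-value falls
between the two thresholds. All visited models are ranked by (overall-F
significance at 0.05, R² descending, RMSE ascending), and RMSE is the
residual standard error $\sqrt{SSE/(n-k-1)}$.

**Default thresholds.** The defaults are `slentry = 0.25`, `slstay =
0.15`. With only ten ingredient observations, single-predictor partial
p-values for genuinely predictive fibre fractions sit in the 0.15–0.20
range; a 0.15 entry gate admits nothing at this sample size, while 0.25
is a conventional screening level for small-n variable selection. On the
packaged ten-barley table this path enters ADF (p = 0.17), then TDF
(p = 0.019), both of which stay (p = 0.008 and 0.019), yielding

```{r}
tab <- merge(
  as.data.frame(read_composition_table(
    system.file("extdata", "barley10.csv", package = "sowcal"),
    basis = "dm")),
  read.csv(system.file("extdata", "barley_energy.csv", package = "sowcal")),
  by.x = "sample_id", by.y = "ingredient_id")
stepwise_select(tab, "ne", c("cp", "ndf", "adf", "ash", "ee",
                             "starch", "idf", "sdf", "tdf"))
```

No multiplicity correction is applied and all p-values are two-sided,
matching standard feed-evaluation practice at these sample sizes.

## The synthetic trial generator

`trial_ground_truth()` + `simulate_trial()` emulate the reference study
conditions: sows of BW 213 ± 17.8 kg fed at 544 kJ ME/kg BW^0.75/d, one
basal diet plus test diets at 28.9% substitution, three 24 h fed
calorimetry days and one 22:00–06:00 fasting window, total collection of
feces and urine, fed RQ in 0.93–1.00, fasted RQ in 0.76–0.83, FHP in
348–380 kJ/kg BW^0.75/d, ingredient NE in 7.85–11.85 MJ/kg DM with NE/ME
in 0.62–0.81 and ME/DE in 0.87–0.99.

The generator works **backwards from the truth**: it fixes the diet's
DE/ME/NE, derives the feed allowance from the target ME intake, derives
excreta energies from the DE→ME gap, derives daily heat from
RE = NE·DMI − FHP·BW^0.75, and then inverts the Brouwer equation jointly
with the target RQ to obtain gas volumes:

$$V_{O_2} = \frac{THP + 5.99\,UN + 2.17\,V_{CH_4}}{16.18 + 5.02\,RQ},
\qquad V_{CO_2} = RQ \cdot V_{O_2}.$$

Infeasible targets (an implied negative THP or urinary energy) fail
loudly, naming the offending parameter. A single global seed spawns
substreams for ingredients, sows, and noise, so enlarging the sow count
never perturbs the ingredient draws.

**Noise model.** Four mean-one lognormal scales: `gas_cv` (default
0.05) applied both as a per-day calibration factor — the dominant error
in chamber work — and as per-minute trace jitter; `fecal_cv` (0.05) on
fecal mass; `urine_cv` (0.08) on urinary energy; `ge_assay_cv` (0.015)
on bomb-calorimetry assays. These defaults were set once from typical
chamber and assay repeatability and produce per-sow diet-NE scatter of a
few tenths of an MJ/kg DM, consistent with the between-sow variability
the reference tables imply.

**What the generator does not emulate** — and hence what passing
recovery tests do not prove about real data: circadian THP structure
(traces are flat within a day), chamber washout dynamics, gestation-day
drift in FHP, refusals/spillage, and basis errors in feed analysis. One
deliberate deviation: the published nitrogen-balance rows are column
means whose components do not close (intake − feces − urine ≠
retention there), so the generator enforces the closed identity with
fecal N near 9 g/d and urinary N near 2.9 g/d — the published
magnitudes — letting retention be the derived remainder.

## Numerical choices

* **Windows.** Day windows are half-open for bookkeeping, but a sample
  falling exactly on the right boundary is used as the final trapezoid
  edge (it carries zero measure, so adjacent windows sharing the
  boundary sample count every interval exactly once). This makes the
  integral of a full-day trace exact rather than one sampling interval
  short.
* **Gap detection.** A sampling gap is judged against
  max(`gap_warn_min`, 1.5 × median sampling interval), so coarse but
  regular sampling is not misread as missing coverage, while a genuine
  hole in 1-minute data still warns at the 10-minute default.
* **Negative values.** Negative integrated volumes (calibration drift)
  and negative digestibilities (endogenous losses exceeding intake of a
  scarce analyte) are flagged with warnings and returned unchanged —
  silently clipping would hide exactly the data problems a balance trial
  needs to surface.
* **Exact fits.** When a model fits perfectly (zero residual), term
  p-values are treated as perfectly significant rather than NaN, so
  stepwise selection terminates cleanly.
* **Percent scale.** All percentages are stored on the 0–100 scale, as
  in proximate-analysis tables; energies are kJ internally with MJ only
  at I/O boundaries.

## Validation strategy and problem sizes

The test-suite checks fall in three tiers. Deterministic reproduction:
the packaged composition/energy tables reproduce the published summary
statistics, correlations (IDF–TDF 0.97, ADF–IDF 0.94,
hemicellulose–NDF 0.99), and the NE equation's fit statistics
(R² 0.66, RMSE 0.91), and the basal diet's NE reconstructs from its
RE + FHP components to within rounding of the printed inputs.
Noiseless round trips: a zero-noise simulated trial reproduces diet and
ingredient energies to machine precision. Stochastic recovery, at sizes
chosen to keep the whole suite around half a minute: 200 replicates of a
two-sow trial at 10-minute trace resolution for difference-method bias
and the 1/r error-amplification law, and 150 replicates of the stepwise
recovery experiment.

Two statistical points of honesty in that last experiment. The candidate
pool excludes IDF and SDF because the generator builds TDF = IDF + SDF
exactly; with the truth variable's own additive components in the pool,
"recovery" is ill-defined (IDF substitutes for TDF at r ≈ 0.97 with no
loss of fit). And coefficient calibration is assessed per coefficient on
the refit of the identified support: at n = 10 the ±2·SE interval covers
at the t₇ rate of 91.4%, not 95%, and the SEs reported inside an
overfitted selected model understate post-selection uncertainty.

## Known limitations

* Apparent (not true) digestibility: no endogenous-loss correction.
* The RE partition uses the retained-N route only; no isotope or
  comparative-slaughter cross-check is possible in silico.
* The stepwise equations are descriptive screening tools at n = 10;
  they are not validated for extrapolation beyond the composition ranges
  of the packaged table.
* The generator's flat within-day traces make integration errors look
  smaller than they would be with real circadian structure; recovery
  tolerances should not be read as chamber accuracy claims.
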