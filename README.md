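# sowcal

Indirect-calorimetry energy evaluation of feed ingredients for gestating
sows: from respiration-chamber gas exchange and total-collection balance
data to digestible (DE), metabolizable (ME), and net energy (NE) values,
difference-method ingredient energies, and stepwise NE prediction
equations.

## Who this is for

Swine-nutrition researchers running (or re-analysing) respiration-chamber
trials in which a test ingredient replaces part of a basal diet, and
anyone who needs a tested, reproducible implementation of the standard
energy-balance arithmetic used in feed evaluation. The package ships the
complete chain as composable functions, plus a synthetic-trial generator
so every stage can be validated by parameter recovery without live-animal
data.

## The method

Total heat production of a sow in an open-circuit chamber follows the
Brouwer equation from daily gas volumes and urinary nitrogen:

    THP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) − 2.17 CH4 (L) − 5.99 UN (g)

Daily volumes come from trapezoidal integration of
concentration-difference × flow over each 24 h window; fasting heat
production (FHP) uses the overnight 22:00–06:00 fasting window scaled
linearly to a daily rate per kg metabolic body weight (BW^0.75).

The energy cascade per kg dietary dry matter is

    DE = (GE intake − fecal GE) / DMI
    ME = DE − (urinary GE + 39.54 kJ/L × CH4) / DMI
    RE = ME intake − THP          (kJ/kg BW^0.75/d)
    REP = retained N × 6.25 × 23.86 kJ/g;  REL = RE − REP
    NE = (RE + FHP) × BW^0.75 / DMI

With a test diet formulated by replacing fraction *r* of the basal diet
(0.289 in the reference design), ingredient energy follows the difference
method:

    E_ingredient = (E_test − (1 − r) × E_basal) / r

Finally, NE prediction equations are built by SAS-style stepwise
regression of ingredient NE on chemical composition (partial-F entry and
stay tests), ranked by significance, R², and RMSE.

## Worked example

Using the packaged ten-barley composition and energy tables:

```r
library(sowcal)

comp <- read_composition_table(
  system.file("extdata", "barley10.csv", package = "sowcal"), basis = "dm")
energy <- read.csv(
  system.file("extdata", "barley_energy.csv", package = "sowcal"))

summarize_ingredients(energy)
#>   energy   mean       sd        cv   min   max  n
#> 1     de 15.017 1.546257 10.296714 12.08 17.28 10
#> 2     me 13.879 1.295818  9.336535 11.74 16.12 10
#> 3     ne  9.964 1.381627 13.866189  7.85 11.85 10

tab <- merge(as.data.frame(comp), energy,
             by.x = "sample_id", by.y = "ingredient_id")
stepwise_select(tab, "ne", c("cp", "ndf", "adf", "ash", "ee",
                             "starch", "idf", "sdf", "tdf"))
#> Stepwise selection for 'ne' (n = 10, entry 0.25 / stay 0.15)
#>   enter adf          p = 0.1725
#>   enter tdf          p = 0.0187
#> Selected equation:
#>   ne = 4.33 - 3.92 adf + 1.24 tdf
#>   n = 10, R2 = 0.664, RMSE = 0.908, p = 0.022
```

The mean barley DE/ME/NE are 15.02, 13.88, and 9.96 MJ/kg DM, with NE
ranging 7.85–11.85: wide variation, meaning different barley sources do
not deliver the same feeding value. The selected equation predicts NE
from acid-detergent fibre (negative: lignified fibre dilutes usable
energy) and total dietary fibre at an R² of 0.66.

A fully synthetic trial, recovered end to end:

```r
truth <- trial_ground_truth(seed = 7, n_ingredients = 2, sows_per_diet = 2,
                            noise = list(gas_cv = 0, fecal_cv = 0,
                                         urine_cv = 0, ge_assay_cv = 0))
report <- run_pipeline(simulate_trial(truth, resolution_min = 10),
                       run_stats = FALSE)
report$ingredient_values[, c("ingredient_id", "de", "me", "ne")]
#>   ingredient_id       de       me        ne
#> 1        SYN-01 12.24182 11.81335  9.301989
#> 2        SYN-02 15.00076 13.83966 10.965455
```

which matches `truth$ingredients$energy` to machine precision; with the
default measurement-noise settings the recovery error grows by roughly
`sqrt(1 + (1 − r)²)/r` ≈ 4.2× the diet-level error, the intrinsic
amplification of the difference method.

## Package layout

- `read_composition_table()`, `convert_basis()` — composition tables with
  analyte-synonym headers and basis conversion
- `integrate_gas_day()`, `brouwer_thp()`, `respiratory_quotient()`,
  `fasting_heat_production()` — chamber calorimetry
- `digestibility_coefficient()`, `nitrogen_balance()`,
  `diet_energy_values()`, `energy_ratio_suite()` — balance arithmetic
- `ingredient_energy()`, `ingredient_energy_per_sow()`,
  `summarize_ingredients()` — difference method
- `pearson_matrix()`, `ols_fit()`, `stepwise_select()`, `describe()` —
  statistics and prediction equations
- `trial_ground_truth()`, `sample_ingredients()`, `simulate_sow_period()`,
  `simulate_trial()` — synthetic-trial generation
- `run_pipeline()`, `write_report()` — end-to-end orchestration

See `vignettes/energy-evaluation.Rmd` for the methods account: model
assumptions, parameter defaults, the noise model, and known limitations.
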