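# Synthetic sow calorimetry trials from known ground truth.
#
# The generator emulates the reference trial design: gestating sows of
# BW ~ 213 +/- 17.8 kg fed at 544 kJ ME/kg BW^0.75/d, a corn--soybean
# basal diet and test diets with 28.9% ingredient substitution, three fed
# calorimetry days and one overnight (22:00-06:00) fasting window, total
# collection of feces and urine. Gas traces are built by inverting the
# Brouwer equation jointly with the target respiratory quotient, so a
# noiseless simulation round-trips through the pipeline exactly.

# per-analyte uniform sampling ranges (DM basis) spanning the reference
# ten-barley composition table
.barley_ranges <- list(
  dm = c(88.70, 91.22), cp = c(9.29, 14.26), ndf = c(21.79, 39.54),
  adf = c(3.65, 6.07), ash = c(2.10, 3.62), ee = c(1.54, 2.34),
  starch = c(44.01, 57.71), idf = c(12.02, 17.35), sdf = c(4.77, 6.12),
  ca = c(0.04, 0.08), p = c(0.22, 0.38)
)

#' Draw synthetic barley-like ingredients with energy ground truth
#'
#' Compositions are drawn uniformly within the observed per-analyte
#' ranges of the ten-barley reference table, with `tdf = idf + sdf`
#' enforced by construction. True net energy is drawn in
#' \[7.85, 11.85\] MJ/kg DM; ME is derived from an NE/ME ratio drawn in
#' \[0.62, 0.81\] and DE from an ME/DE ratio in \[0.87, 0.99\],
#' bracketing the observed conversion efficiencies.
#'
#' @param n number of ingredients.
#' @param seed optional integer seed (restores the RNG stream it found).
#' @return List with `composition` (a `feed_composition`, basis DM) and
#'   `energy` (data frame `ingredient_id`, `de`, `me`, `ne`).
#' @export
sample_ingredients <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (n == 0) {
    comp <- data.frame(sample_id = character(0))
    attr(comp, "basis") <- "dm"
    class(comp) <- c("feed_composition", "data.frame")
    return(list(composition = comp,
                energy = data.frame(ingredient_id = character(0),
                                    de = numeric(0), me = numeric(0),
                                    ne = numeric(0))))
  }
  draw <- function(rg) stats::runif(n, rg[1], rg[2])
  comp <- data.frame(sample_id = sprintf("SYN-%02d", seq_len(n)),
                     lapply(.barley_ranges, draw),
                     stringsAsFactors = FALSE)
  comp$tdf <- comp$idf + comp$sdf
  comp <- comp[, c("sample_id", "dm", "cp", "ndf", "adf", "ash", "ee",
                   "starch", "idf", "sdf", "tdf", "ca", "p")]
  attr(comp, "basis") <- "dm"
  class(comp) <- c("feed_composition", "data.frame")

  ne <- stats::runif(n, 7.85, 11.85)
  me <- ne / stats::runif(n, 0.62, 0.81)
  de <- me / stats::runif(n, 0.87, 0.99)
  list(composition = comp,
       energy = data.frame(ingredient_id = comp$sample_id,
                           de = de, me = me, ne = ne,
                           stringsAsFactors = FALSE))
}

#' Ground truth for a synthetic calorimetry trial
#'
#' Draws the complete state a trial simulation needs: ingredient
#' compositions and energies, per-sow body weight, fasting heat
#' production, and fed/fasted respiratory quotients, the basal-diet
#' energies, and the measurement-noise scales. A single global seed
#' spawns independent substreams for ingredients, sows, and noise, so
#' changing the number of sows does not perturb the ingredient draws.
#'
#' Defaults reproduce the reference study conditions: BW 213 +/- 17.8 kg,
#' FHP in 348-380 kJ/kg BW^0.75/d, fed RQ in 0.93-1.00, fasted RQ in
#' 0.76-0.83, basal DE/ME/NE 15.62/14.37/12.23 MJ/kg DM, substitution
#' rate 0.289.
#'
#' @param seed integer seed.
#' @param n_ingredients number of test ingredients.
#' @param sows_per_diet sows observed on each diet.
#' @param noise list of multiplicative lognormal CVs: `gas_cv` (per-day
#'   gas-volume calibration and per-minute trace jitter), `fecal_cv`
#'   (fecal mass), `urine_cv` (urinary energy), `ge_assay_cv` (bomb
#'   calorimetry of feed and feces). Set all to 0 for a noiseless trial.
#' @param basal basal-diet truth: list with `de`, `me`, `ne` (MJ/kg DM),
#'   `cp` (% DM), `ge_dig_pct`.
#' @param substitution_rate as-fed inclusion of the test ingredient.
#' @param bw_mean,bw_sd sow body-weight distribution, kg.
#' @param fhp_range fasting heat production range, kJ/kg BW^0.75/d.
#' @param fed_rq_range,fasted_rq_range respiratory-quotient ranges.
#' @return List of class `trial_ground_truth`.
#' @export
trial_ground_truth <- function(seed = 1,
                               n_ingredients = 10,
                               sows_per_diet = 4,
                               noise = list(gas_cv = 0.05, fecal_cv = 0.05,
                                            urine_cv = 0.08,
                                            ge_assay_cv = 0.015),
                               basal = list(de = 15.62, me = 14.37,
                                            ne = 12.23, cp = 13.74,
                                            ge_dig_pct = 87.95),
                               substitution_rate = 0.289,
                               bw_mean = 213, bw_sd = 17.8,
                               fhp_range = c(348, 380),
                               fed_rq_range = c(0.93, 1.00),
                               fasted_rq_range = c(0.76, 0.83)) {
  stopifnot(all(unlist(noise) >= 0))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)

  ing <- sample_ingredients(n_ingredients, seed = sub_seeds[1])

  set.seed(sub_seeds[2])
  n_diets <- n_ingredients + 1L
  n_sows <- n_diets * sows_per_diet
  sows <- data.frame(
    sow_id = sprintf("SOW-%03d", seq_len(n_sows)),
    bw_kg = stats::rnorm(n_sows, bw_mean, bw_sd),
    fhp_kj_kg075 = stats::runif(n_sows, fhp_range[1], fhp_range[2]),
    fed_rq = stats::runif(n_sows, fed_rq_range[1], fed_rq_range[2]),
    fasted_rq = stats::runif(n_sows, fasted_rq_range[1], fasted_rq_range[2]),
    stringsAsFactors = FALSE
  )
  # GE digestibility of the test diets, bracketing the observed range
  test_ge_dig <- stats::runif(n_ingredients, 82.5, 85.7)

  r <- substitution_rate
  test_ids <- if (n_ingredients > 0) {
    paste0("TD-", ing$energy$ingredient_id)
  } else character(0)
  diets <- data.frame(
    diet_id = c("basal", test_ids),
    ingredient_id = c(NA_character_, ing$energy$ingredient_id),
    de = c(basal$de, (1 - r) * basal$de + r * ing$energy$de),
    me = c(basal$me, (1 - r) * basal$me + r * ing$energy$me),
    ne = c(basal$ne, (1 - r) * basal$ne + r * ing$energy$ne),
    cp = c(basal$cp, (1 - r) * basal$cp + r * ing$composition$cp[
      match(ing$energy$ingredient_id, ing$composition$sample_id)]),
    ge_dig_pct = c(basal$ge_dig_pct, test_ge_dig),
    stringsAsFactors = FALSE
  )
  diets$ge <- diets$de / (diets$ge_dig_pct / 100)
  diets$substitution_rate <- c(NA_real_, rep(r, n_ingredients))

  design <- data.frame(
    diet_id = rep(diets$diet_id, each = sows_per_diet),
    sow_id = sows$sow_id,
    stringsAsFactors = FALSE
  )

  structure(list(seed = seed, noise_seed = sub_seeds[3],
                 ingredients = ing, basal = basal, diets = diets,
                 sows = sows, design = design,
                 substitution_rate = r, noise = noise),
            class = "trial_ground_truth")
}

# mean-one multiplicative lognormal factor(s)
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Simulate one sow-period on one diet
#'
#' From the sow and diet ground truth, derives the feed allowance that
#' meets the target ME intake, the daily excreta and gas-exchange
#' quantities consistent with the diet's DE/ME/NE, and emits minute-level
#' chamber traces for the fed days and the overnight fasting window.
#' Daily gas volumes are obtained by inverting the Brouwer equation
#' jointly with the target respiratory quotient:
#' `vo2 = (THP + 5.99 UN + 2.17 vCH4) / (16.18 + 5.02 RQ)`,
#' `vco2 = RQ * vo2`.
#'
#' Noise model: a per-day lognormal calibration factor and per-minute
#' lognormal jitter on the gas traces (both at `gas_cv`), lognormal
#' factors on fecal mass (`fecal_cv`), urinary energy (`urine_cv`), and
#' bomb-calorimetry GE assays (`ge_assay_cv`), all mean-one.
#'
#' @param sow one row of the truth's `sows` table (list-like: `sow_id`,
#'   `bw_kg`, `fhp_kj_kg075`, `fed_rq`, `fasted_rq`).
#' @param diet one row of the truth's `diets` table (list-like:
#'   `diet_id`, `de`, `me`, `ne`, `ge`, `cp`).
#' @param noise noise CV list (see [trial_ground_truth()]); `NULL` means
#'   noiseless.
#' @param period period number recorded in the outputs.
#' @param n_fed_days number of fed calorimetry days.
#' @param resolution_min trace sampling interval, minutes.
#' @param flow_l_min chamber exhaust flow, L/min.
#' @param start POSIXct midnight starting the first fed day.
#' @param constants an [energy_constants()] bundle.
#' @param ch4_pct_de methane energy as % of DE.
#' @param fecal_ge_mj_kg fecal gross energy per kg as-collected.
#' @param cp_dig_pct apparent CP digestibility used to split fecal
#'   nitrogen.
#' @param urine_n_g_d daily urinary nitrogen, g.
#' @return List with `gas` (trace data frame), `collections`,
#'   `sow_period` (one row), and `truth` (the implied daily quantities).
#' @export
simulate_sow_period <- function(sow, diet, noise = NULL, period = 1L,
                                n_fed_days = 3, resolution_min = 1,
                                flow_l_min = 500,
                                start = as.POSIXct("2025-01-06 00:00:00",
                                                   tz = "UTC"),
                                constants = energy_constants(),
                                ch4_pct_de = 0.8,
                                fecal_ge_mj_kg = 4.5,
                                cp_dig_pct = 81,
                                urine_n_g_d = 2.9) {
  if (is.null(noise)) {
    noise <- list(gas_cv = 0, fecal_cv = 0, urine_cv = 0, ge_assay_cv = 0)
  }
  k <- constants
  mbw <- sow$bw_kg^0.75
  dmi <- k$feeding_level_kj_me_kg075 * mbw / (diet$me * 1000)

  fecal_ge_d <- (diet$ge - diet$de) * dmi                   # MJ/d
  ch4_e_d <- ch4_pct_de / 100 * diet$de * dmi               # MJ/d
  vch4 <- ch4_e_d * 1000 / k$ch4_energy_kj_l                # L/d
  ue_d <- (diet$de - diet$me) * dmi - ch4_e_d               # MJ/d
  if (ue_d <= 0) {
    stop(sprintf("infeasible targets: ch4_pct_de = %g leaves urinary energy %.3f MJ/d <= 0",
                 ch4_pct_de, ue_d))
  }
  n_intake <- dmi * 1000 * diet$cp / 100 / k$n_to_protein   # g/d
  n_feces <- n_intake * (1 - cp_dig_pct / 100)
  n_urine <- urine_n_g_d
  n_ret <- n_intake - n_feces - n_urine

  me_intake_d <- diet$me * 1000 * dmi                       # kJ/d
  re_d <- diet$ne * 1000 * dmi - sow$fhp_kj_kg075 * mbw     # kJ/d
  thp_d <- me_intake_d - re_d                               # kJ/d
  if (thp_d <= 0) {
    stop(sprintf("infeasible targets: implied fed THP %.0f kJ/d <= 0 (ne = %.2f, fhp = %.0f)",
                 thp_d, diet$ne, sow$fhp_kj_kg075))
  }
  vo2 <- (thp_d + k$urinary_n_kj_g * n_urine + k$ch4_kj_l * vch4) /
    (k$o2_kj_l + k$co2_kj_l * sow$fed_rq)
  if (vo2 <= 0) stop("infeasible targets: implied fed vO2 <= 0")
  vco2 <- sow$fed_rq * vo2

  trace <- function(day_start, minutes_len, vols, state) {
    tick <- seq(0, minutes_len, by = resolution_min)
    conc <- lapply(vols, function(v) v / (flow_l_min * minutes_len))
    jit <- function(x) x * .ln_noise(length(tick), noise$gas_cv)
    data.frame(
      sow_id = sow$sow_id,
      timestamp = day_start + 60 * tick,
      o2_conc = jit(rep(conc[[1]], length(tick))),
      co2_conc = jit(rep(conc[[2]], length(tick))),
      ch4_conc = jit(rep(conc[[3]], length(tick))),
      flow_l_min = flow_l_min,
      state = state,
      stringsAsFactors = FALSE
    )
  }

  gas <- vector("list", n_fed_days + 1L)
  for (d in seq_len(n_fed_days)) {
    cal <- .ln_noise(3, noise$gas_cv) # per-day calibration factor per gas
    tr <- trace(start + (d - 1) * 86400, 1440,
                list(vo2 * cal[1], vco2 * cal[2], vch4 * cal[3]),
                "fed")
    # consecutive days share the midnight boundary sample; keep it once
    if (d > 1) tr <- tr[-1, , drop = FALSE]
    gas[[d]] <- tr
  }

  # fasting window: 22:00 on the day after the last fed day to 06:00
  fast_start <- start + n_fed_days * 86400 + 22 * 3600
  fast_end <- fast_start + 8 * 3600
  thp_fast_d <- sow$fhp_kj_kg075 * mbw
  vch4_fast <- 2 # L/d, residual hindgut fermentation
  n_urine_fast <- n_urine
  vo2_f <- (thp_fast_d + k$urinary_n_kj_g * n_urine_fast +
              k$ch4_kj_l * vch4_fast) /
    (k$o2_kj_l + k$co2_kj_l * sow$fasted_rq)
  if (vo2_f <= 0) stop("infeasible targets: implied fasting vO2 <= 0")
  vco2_f <- sow$fasted_rq * vo2_f
  cal_f <- .ln_noise(3, noise$gas_cv)
  gas[[n_fed_days + 1L]] <- trace(
    fast_start, 480,
    list(vo2_f / 3 * cal_f[1], vco2_f / 3 * cal_f[2], vch4_fast / 3 * cal_f[3]),
    "fasted")
  gas <- do.call(rbind, gas)

  ge_noise <- .ln_noise(2, noise$ge_assay_cv)
  collections <- data.frame(
    sow_id = sow$sow_id, period = period,
    kind = c("feces", "urine", "urine"),
    state = c("fed", "fed", "fasted"),
    mass_kg_d = c(fecal_ge_d / fecal_ge_mj_kg * .ln_noise(1, noise$fecal_cv),
                  NA, NA),
    ge = c(fecal_ge_mj_kg * ge_noise[1],
           ue_d * .ln_noise(1, noise$urine_cv), NA),
    n_g_d = c(n_feces, n_urine, n_urine_fast),
    dm_pct = c(25, NA, NA),
    stringsAsFactors = FALSE
  )

  sow_period <- data.frame(
    sow_id = sow$sow_id, period = period, diet_id = diet$diet_id,
    bw_kg = sow$bw_kg, dm_intake_kg_d = dmi,
    feed_ge_mj_kg_dm = diet$ge * ge_noise[2],
    n_intake_g_d = n_intake,
    fed_start = format(start, "%Y-%m-%d"), n_fed_days = n_fed_days,
    fast_start = fast_start, fast_end = fast_end,
    stringsAsFactors = FALSE
  )

  list(gas = gas, collections = collections, sow_period = sow_period,
       truth = list(dmi = dmi, vo2_l = vo2, vco2_l = vco2, vch4_l = vch4,
                    thp_kj_d = thp_d, re_kj_d = re_d,
                    n_retained_g_d = n_ret, ue_mj_d = ue_d))
}

#' Simulate a complete calorimetry trial
#'
#' Simulates every sow-period in the truth's design (basal plus test
#' diets, `sows_per_diet` sows each) and collects the pipeline inputs
#' into one bundle. With `dir` given, the bundle is also written as the
#' CSV files the pipeline readers consume, plus ground-truth tables for
#' test harnesses (`ingredient_truth.csv`, `sow_truth.csv`,
#' `diet_truth.csv`). Identical seeds produce identical bundles.
#'
#' @param truth a [trial_ground_truth()].
#' @param dir optional output directory (created if missing).
#' @param n_fed_days,resolution_min,flow_l_min passed to
#'   [simulate_sow_period()].
#' @param ... further arguments passed to [simulate_sow_period()].
#' @return List of class `sow_trial` with `gas`, `collections`,
#'   `sow_periods`, `diets`, `composition`, and `truth`.
#' @export
simulate_trial <- function(truth, dir = NULL, n_fed_days = 3,
                           resolution_min = 1, flow_l_min = 500, ...) {
  stopifnot(inherits(truth, "trial_ground_truth"))
  set.seed(truth$noise_seed)
  gas <- list(); col <- list(); sp <- list()
  for (i in seq_len(nrow(truth$design))) {
    diet <- truth$diets[truth$diets$diet_id == truth$design$diet_id[i], ]
    sow <- truth$sows[truth$sows$sow_id == truth$design$sow_id[i], ]
    one <- simulate_sow_period(sow, diet, noise = truth$noise,
                               n_fed_days = n_fed_days,
                               resolution_min = resolution_min,
                               flow_l_min = flow_l_min, ...)
    gas[[i]] <- one$gas; col[[i]] <- one$collections
    sp[[i]] <- one$sow_period
  }
  out <- list(gas = do.call(rbind, gas),
              collections = do.call(rbind, col),
              sow_periods = do.call(rbind, sp),
              diets = truth$diets,
              composition = truth$ingredients$composition,
              truth = truth)
  class(out) <- "sow_trial"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_results(out$gas, file.path(dir, "gas.csv"))
    write_results(out$collections, file.path(dir, "collections.csv"))
    write_results(out$sow_periods, file.path(dir, "sow_periods.csv"))
    write_results(out$diets, file.path(dir, "diet_truth.csv"))
    write_results(as.data.frame(out$composition),
                  file.path(dir, "composition.csv"))
    write_results(truth$ingredients$energy,
                  file.path(dir, "ingredient_truth.csv"))
    write_results(truth$sows, file.path(dir, "sow_truth.csv"))
  }
  out
}

#' @export
print.sow_trial <- function(x, ...) {
  cat(sprintf("Synthetic calorimetry trial: %d diets, %d sow-periods, %d gas records\n",
              nrow(x$diets), nrow(x$sow_periods), nrow(x$gas)))
  invisible(x)
}
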