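# End-to-end orchestration: calorimetry -> balance -> difference method
# -> statistics, for in-memory bundles or on-disk CSV inputs.

#' Run the full energy-evaluation pipeline
#'
#' Takes a trial bundle (from [simulate_trial()]) or a directory of CSV
#' inputs (`gas.csv`, `collections.csv`, `sow_periods.csv`,
#' `diet_truth.csv`, optionally `composition.csv`) and executes every
#' stage: daily gas integration and Brouwer heat production, fasting heat
#' production from the fasting window, per-sow-period energy balance,
#' per-diet means, difference-method ingredient energies, and -- when
#' ingredient compositions are available -- the correlation matrix and
#' stepwise prediction equation for ingredient NE.
#'
#' @param trial a `sow_trial` bundle or a directory path.
#' @param constants an [energy_constants()] bundle.
#' @param basal_diet_id identifier of the basal (reference) diet.
#' @param run_stats compute the correlation matrix and stepwise equation
#'   over recovered ingredient values.
#' @param stepwise_candidates candidate predictors for the NE equation.
#' @param slentry,slstay stepwise thresholds (see [stepwise_select()]).
#' @param min_coverage minimum fasting-window coverage (fraction).
#' @return List of class `trial_report`: `sow_results` (energy balance
#'   per sow-period), `diet_summary` (per-diet means),
#'   `ingredient_values`, `ingredient_summary`, and optionally
#'   `correlations` and `stepwise`.
#' @examples
#' \donttest{
#' truth <- trial_ground_truth(seed = 7, n_ingredients = 2,
#'                             sows_per_diet = 2,
#'                             noise = list(gas_cv = 0, fecal_cv = 0,
#'                                          urine_cv = 0, ge_assay_cv = 0))
#' trial <- simulate_trial(truth, resolution_min = 10)
#' rep <- run_pipeline(trial, run_stats = FALSE)
#' rep$ingredient_values
#' }
#' @export
run_pipeline <- function(trial,
                         constants = energy_constants(),
                         basal_diet_id = "basal",
                         run_stats = TRUE,
                         stepwise_candidates = c("cp", "ndf", "adf", "ash",
                                                 "ee", "starch", "tdf"),
                         slentry = 0.25, slstay = 0.15,
                         min_coverage = 0.9) {
  if (is.character(trial)) {
    dir <- trial
    trial <- list(
      gas = read_gas_records(file.path(dir, "gas.csv")),
      collections = read_collection_records(file.path(dir, "collections.csv")),
      sow_periods = read_sow_periods(file.path(dir, "sow_periods.csv")),
      diets = utils::read.csv(file.path(dir, "diet_truth.csv"),
                              stringsAsFactors = FALSE)
    )
    comp_path <- file.path(dir, "composition.csv")
    if (file.exists(comp_path)) {
      trial$composition <- read_composition_table(comp_path, basis = "dm")
    }
  }
  sp <- trial$sow_periods
  if (!"metabolic_bw" %in% names(sp)) sp$metabolic_bw <- sp$bw_kg^0.75
  if (is.character(sp$fast_start)) {
    sp$fast_start <- as.POSIXct(sp$fast_start, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M:%S"))
    sp$fast_end <- as.POSIXct(sp$fast_end, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S"))
  }

  results <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    row <- sp[i, ]
    gas_sow <- trial$gas[trial$gas$sow_id == row$sow_id, , drop = FALSE]
    col_sow <- trial$collections[
      trial$collections$sow_id == row$sow_id &
        trial$collections$period == row$period, , drop = FALSE]
    feces <- col_sow[col_sow$kind == "feces", , drop = FALSE]
    has_state <- "state" %in% names(col_sow)
    urine_fed <- col_sow[col_sow$kind == "urine" &
                           (if (has_state) col_sow$state == "fed" else TRUE),
                         , drop = FALSE]
    urine_fast <- if (has_state) {
      col_sow[col_sow$kind == "urine" & col_sow$state == "fasted", ,
              drop = FALSE]
    } else col_sow[0, , drop = FALSE]
    if (nrow(feces) == 0 || nrow(urine_fed) == 0) {
      stop(sprintf("sow '%s' period %s: missing feces or urine collection",
                   row$sow_id, row$period))
    }

    fed_gas <- gas_sow[gas_sow$state == "fed", , drop = FALSE]
    day0 <- as.POSIXct(paste(row$fed_start, "00:00:00"), tz = "UTC")
    fed_days <- do.call(rbind, lapply(seq_len(row$n_fed_days), function(d) {
      v <- integrate_gas_day(fed_gas, day0 + (d - 1) * 86400,
                             day0 + d * 86400)
      calorimetry_day(row$sow_id, as.Date(day0) + (d - 1), "fed",
                      v$vo2_l, v$vco2_l, v$vch4_l,
                      urinary_n_g = urine_fed$n_g_d[1],
                      constants = constants)
    }))

    fast_gas <- gas_sow[gas_sow$state == "fasted", , drop = FALSE]
    fast_n <- if (nrow(urine_fast)) urine_fast$n_g_d[1] else urine_fed$n_g_d[1]
    fhp <- fasting_heat_production(fast_gas, row$fast_start, row$fast_end,
                                   urinary_n_g = fast_n, bw_kg = row$bw_kg,
                                   constants = constants,
                                   min_coverage = min_coverage)

    results[[i]] <- diet_energy_values(
      sow = as.list(row),
      feces = list(mass_kg_d = feces$mass_kg_d[1], ge_mj_kg = feces$ge[1],
                   n_g_d = feces$n_g_d[1]),
      urine = list(ge_mj_d = urine_fed$ge[1], n_g_d = urine_fed$n_g_d[1]),
      fed_days = fed_days, fhp_kj_kg075_d = fhp$fhp_kj_kg075_d,
      constants = constants
    )
  }
  sow_results <- do.call(rbind, results)

  num <- vapply(sow_results, is.numeric, logical(1))
  diet_summary <- stats::aggregate(sow_results[, num],
                                   by = list(diet_id = sow_results$diet_id),
                                   FUN = mean)

  diets <- trial$diets
  test_ids <- diets$diet_id[!is.na(diets$ingredient_id) &
                              diets$diet_id != basal_diet_id]
  basal_rows <- sow_results[sow_results$diet_id == basal_diet_id, , drop = FALSE]
  if (nrow(basal_rows) == 0 && length(test_ids)) {
    stop("no results for basal diet '", basal_diet_id,
         "'; cannot apply the difference method")
  }
  basal_mean <- if (nrow(basal_rows)) {
    as.data.frame(lapply(basal_rows[, c("de_mj_kg_dm", "me_mj_kg_dm",
                                        "ne_mj_kg_dm")], mean))
  } else NULL

  ingredient_values <- NULL
  if (length(test_ids)) {
    vals <- lapply(test_ids, function(td) {
      rows <- sow_results[sow_results$diet_id == td, , drop = FALSE]
      r <- diets$substitution_rate[diets$diet_id == td]
      bm <- basal_mean[rep(1, nrow(rows)), , drop = FALSE]
      ingredient_energy_per_sow(rows, bm, r,
                                ingredient_id = diets$ingredient_id[
                                  diets$diet_id == td])
    })
    ingredient_values <- do.call(rbind, vals)
  }

  report <- list(sow_results = sow_results, diet_summary = diet_summary,
                 ingredient_values = ingredient_values,
                 ingredient_summary = if (!is.null(ingredient_values))
                   summarize_ingredients(ingredient_values) else NULL,
                 constants = constants)

  if (run_stats && !is.null(ingredient_values) &&
      !is.null(trial$composition) && nrow(ingredient_values) >= 4) {
    tab <- merge(as.data.frame(trial$composition),
                 ingredient_values[, c("ingredient_id", "de", "me", "ne")],
                 by.x = "sample_id", by.y = "ingredient_id")
    vars <- intersect(c("cp", "ndf", "adf", "hemicellulose", "ash", "ee",
                        "starch", "idf", "sdf", "tdf", "de", "me", "ne"),
                      c(names(tab), "hemicellulose"))
    report$correlations <- pearson_matrix(tab, variables = vars)
    cand <- intersect(stepwise_candidates, names(tab))
    report$stepwise <- stepwise_select(tab, "ne", cand,
                                       slentry = slentry, slstay = slstay)
  }
  class(report) <- "trial_report"
  report
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Energy-evaluation trial report\n")
  cat(sprintf("  %d sow-period(s), %d diet(s)\n",
              nrow(x$sow_results), nrow(x$diet_summary)))
  if (!is.null(x$ingredient_summary)) {
    cat("  Ingredient energy values (MJ/kg DM):\n")
    print(x$ingredient_summary, digits = 4)
  }
  if (!is.null(x$stepwise)) {
    cat("  Selected NE prediction equation:\n    ")
    print(x$stepwise$best)
  }
  invisible(x)
}

#' Write a trial report to CSV files
#'
#' Writes the per-sow results, per-diet summary, and ingredient values to
#' tidy CSVs under `dir`, plus the correlation matrix when present.
#'
#' @param report a `trial_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(report$sow_results, file.path(dir, "sow_results.csv"))
  write_results(report$diet_summary, file.path(dir, "diet_summary.csv"))
  if (!is.null(report$ingredient_values)) {
    write_results(report$ingredient_values,
                  file.path(dir, "ingredient_values.csv"))
    write_results(report$ingredient_summary,
                  file.path(dir, "ingredient_summary.csv"))
  }
  if (!is.null(report$correlations)) {
    write_correlation(report$correlations, file.path(dir, "correlations.csv"))
  }
  invisible(dir)
}
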