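# Shared helpers: packaged fixtures and small synthetic objects built in code.

fixture_path <- function(name) {
  system.file("extdata", name, package = "sowcal")
}

read_fixture <- function(name) {
  utils::read.csv(fixture_path(name), stringsAsFactors = FALSE)
}

barley_composition <- function() {
  read_composition_table(fixture_path("barley10.csv"), basis = "dm")
}

# Table-1 composition merged with the ingredient energy values, the input
# of the correlation/stepwise analyses
barley_table <- function() {
  merge(as.data.frame(barley_composition()),
        read_fixture("barley_energy.csv"),
        by.x = "sample_id", by.y = "ingredient_id")
}

noiseless_cv <- list(gas_cv = 0, fecal_cv = 0, urine_cv = 0, ge_assay_cv = 0)

# a ground truth whose single test ingredient has fixed energy values
truth_with_fixed_ingredient <- function(seed, r, de = 15.0, me = 13.5,
                                        ne = 10.0, sows_per_diet = 2,
                                        noise = NULL) {
  args <- list(seed = seed, n_ingredients = 1, sows_per_diet = sows_per_diet,
               substitution_rate = r)
  if (!is.null(noise)) args$noise <- noise
  truth <- do.call(trial_ground_truth, args)
  truth$ingredients$energy[1, c("de", "me", "ne")] <- list(de, me, ne)
  i <- 2 # row 1 is the basal diet
  truth$diets$de[i] <- (1 - r) * truth$basal$de + r * de
  truth$diets$me[i] <- (1 - r) * truth$basal$me + r * me
  truth$diets$ne[i] <- (1 - r) * truth$basal$ne + r * ne
  truth$diets$ge[i] <- truth$diets$de[i] / (truth$diets$ge_dig_pct[i] / 100)
  truth
}

# constant-concentration gas trace helper
constant_trace <- function(start, minutes, o2, co2 = 0, ch4 = 0,
                           flow = 500, by = 1, state = "fed",
                           sow_id = "S1") {
  tick <- seq(0, minutes, by = by)
  data.frame(sow_id = sow_id, timestamp = start + 60 * tick,
             o2_conc = o2, co2_conc = co2, ch4_conc = ch4,
             flow_l_min = flow, state = state, stringsAsFactors = FALSE)
}

utc <- function(x) as.POSIXct(x, tz = "UTC")
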