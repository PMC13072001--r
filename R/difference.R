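# Difference method: ingredient energy values from basal-diet and
# test-diet energy under proportional substitution.

#' Ingredient energy by the difference method
#'
#' With a test diet formulated by replacing a fraction `r` of the basal
#' diet with the test ingredient, the ingredient's energy density is
#' `(e_test - (1 - r) * e_basal) / r`. Exactly linear in both diet
#' energies; substituting the result back reproduces
#' `e_test = r * e_ing + (1 - r) * e_basal`.
#'
#' @param e_test test-diet energy, MJ/kg DM.
#' @param e_basal basal-diet energy, MJ/kg DM.
#' @param r substitution fraction, in (0, 1].
#' @return Ingredient energy, MJ/kg DM (vectorised).
#' @examples
#' ingredient_energy(15.53, 15.62, 0.289)
#' @export
ingredient_energy <- function(e_test, e_basal, r) {
  if (any(r <= 0 | r > 1)) stop("substitution rate 'r' must lie in (0, 1]")
  (e_test - (1 - r) * e_basal) / r
}

#' Ingredient DE/ME/NE from paired sow-period results
#'
#' Applies [ingredient_energy()] to each (test, basal) pair of
#' energy-balance results for DE, ME, and NE, averages across pairs, and
#' computes the ME/DE and NE/ME percentages from the averaged values.
#' Ratios above 100 are possible under measurement noise; they are
#' tolerated with a warning.
#'
#' @param test,basal `energy_balance` data frames with equal row counts;
#'   row i of `test` is paired with row i of `basal`.
#' @param r substitution fraction in (0, 1].
#' @param ingredient_id identifier recorded in the result.
#' @return One-row data frame of class `ingredient_energy` with `de`,
#'   `me`, `ne` (MJ/kg DM), `me_de_pct`, `ne_me_pct`, `n_observations`.
#' @export
ingredient_energy_per_sow <- function(test, basal, r, ingredient_id = "ingredient") {
  if (NROW(test) == 0) stop("no (test, basal) pairs supplied")
  if (NROW(test) != NROW(basal)) stop("'test' and 'basal' must pair row by row")
  need <- c("de_mj_kg_dm", "me_mj_kg_dm", "ne_mj_kg_dm")
  .require_columns(as.data.frame(test), need, "test results")
  .require_columns(as.data.frame(basal), need, "basal results")

  de <- mean(ingredient_energy(test$de_mj_kg_dm, basal$de_mj_kg_dm, r))
  me <- mean(ingredient_energy(test$me_mj_kg_dm, basal$me_mj_kg_dm, r))
  ne <- mean(ingredient_energy(test$ne_mj_kg_dm, basal$ne_mj_kg_dm, r))

  me_de <- 100 * me / de
  ne_me <- 100 * ne / me
  if (any(c(me_de, ne_me) > 100)) {
    warning(sprintf("ingredient '%s': energy ratio above 100%% (noise)",
                    ingredient_id), call. = FALSE)
  }
  if (de < me) {
    warning(sprintf("ingredient '%s': DE < ME (noise beyond physical ordering)",
                    ingredient_id), call. = FALSE)
  }
  out <- data.frame(
    ingredient_id = ingredient_id, de = de, me = me, ne = ne,
    me_de_pct = me_de, ne_me_pct = ne_me,
    n_observations = NROW(test), stringsAsFactors = FALSE
  )
  class(out) <- c("ingredient_energy", "data.frame")
  out
}

#' Summarise ingredient energy values
#'
#' Mean, minimum, maximum, and coefficient of variation
#' (`100 x sd / mean`, sample SD on n-1 df) of DE, ME, and NE across a
#' set of ingredients. With a single ingredient the CV is undefined and
#' reported as `NA`.
#'
#' @param values data frame with columns `de`, `me`, `ne` (one row per
#'   ingredient), e.g. rows built by [ingredient_energy_per_sow()].
#' @return Data frame with one row per energy (`de`, `me`, `ne`) and
#'   columns `mean`, `sd`, `cv`, `min`, `max`, `n`.
#' @export
summarize_ingredients <- function(values) {
  .require_columns(as.data.frame(values), c("de", "me", "ne"), "ingredient values")
  one <- function(v, nm) {
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(energy = nm, mean = mean(v), sd = s,
               cv = if (is.na(s)) NA_real_ else 100 * s / mean(v),
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  }
  rbind(one(values$de, "de"), one(values$me, "me"), one(values$ne, "ne"))
}
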