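# Per-sow-period balance arithmetic: apparent total-tract digestibility,
# nitrogen balance, diet DE/ME/NE, and the retained-energy partition.

#' Apparent total-tract digestibility coefficient
#'
#' `100 x (intake - fecal) / intake`. Values below zero are possible when
#' endogenous losses exceed intake of a scarce analyte; they are flagged
#' with a warning and returned unchanged, never clipped.
#'
#' @param intake_qty daily intake of the analyte (> 0).
#' @param fecal_qty daily fecal output of the analyte (>= 0).
#' @return Digestibility in percent (vectorised).
#' @export
digestibility_coefficient <- function(intake_qty, fecal_qty) {
  if (any(intake_qty <= 0)) stop("intake must be > 0 to compute digestibility")
  if (any(fecal_qty < 0)) stop("fecal quantity must be >= 0")
  d <- 100 * (intake_qty - fecal_qty) / intake_qty
  if (any(d < 0)) {
    warning("negative digestibility (fecal output exceeds intake); ",
            "returned unclipped", call. = FALSE)
  }
  d
}

#' Nitrogen balance
#'
#' Retained nitrogen as intake minus fecal and urinary excretion.
#'
#' @param n_intake,n_feces,n_urine daily nitrogen flows, g/d (all >= 0).
#' @return List with `n_retained_g_d` and the three components.
#' @export
nitrogen_balance <- function(n_intake, n_feces, n_urine) {
  if (any(c(n_intake, n_feces, n_urine) < 0)) {
    stop("nitrogen flows must be >= 0")
  }
  list(
    n_intake_g_d = n_intake,
    n_feces_g_d = n_feces,
    n_urine_g_d = n_urine,
    n_retained_g_d = n_intake - n_feces - n_urine
  )
}

#' Diet energy values and retained-energy partition for one sow-period
#'
#' Combines intake, total-collection, and calorimetry data into the full
#' energy balance of one sow on one diet:
#'
#' * `DE = (GE intake - fecal GE) / DMI` (MJ/kg DM)
#' * `ME = DE - (urinary GE + CH4 energy) / DMI`, with CH4 energy at
#'   `ch4_energy_kj_l` (39.54 kJ/L by default) times the mean daily CH4
#'   volume
#' * `ME intake` in kJ/kg BW^0.75/d; `THP` as the mean Brouwer heat of
#'   the fed days per kg BW^0.75
#' * `RE = ME intake - THP`; `REP = retained N x 6.25 x 23.86` per kg
#'   BW^0.75; `REL = RE - REP`
#' * `NE = (RE + FHP) x BW^0.75 / DMI` (MJ/kg DM)
#'
#' together with the energy-utilisation ratios UE/DE, CH4-E/DE, ME/DE,
#' and NE/ME (the first three sum to 100 by construction).
#'
#' @param sow list or one-row data frame with `sow_id`, `period`,
#'   `diet_id`, `bw_kg`, `dm_intake_kg_d`, `feed_ge_mj_kg_dm`, and
#'   `n_intake_g_d`.
#' @param feces list with `mass_kg_d`, `ge_mj_kg` (as-collected), and
#'   `n_g_d`.
#' @param urine list with `ge_mj_d` and `n_g_d`.
#' @param fed_days data frame of fed-state daily calorimetry (columns
#'   `vo2_l`, `vco2_l`, `vch4_l`, `urinary_n_g`; see [calorimetry_day()]).
#' @param fhp_kj_kg075_d fasting heat production, kJ/kg BW^0.75/d.
#' @param constants an [energy_constants()] bundle.
#' @param digestibility optional named vector of nutrient digestibilities
#'   (percent) to carry along in the result.
#' @return One-row data frame of class `energy_balance`.
#' @export
diet_energy_values <- function(sow, feces, urine, fed_days, fhp_kj_kg075_d,
                               constants = energy_constants(),
                               digestibility = NULL) {
  if (is.null(fed_days) || nrow(fed_days) == 0) {
    stop("no fed-state calorimetry days supplied")
  }
  if (sow$dm_intake_kg_d <= 0) stop("dm_intake_kg_d must be > 0")
  if (sow$bw_kg <= 0) stop("bw_kg must be > 0")
  .require_columns(fed_days, c("vo2_l", "vco2_l", "vch4_l", "urinary_n_g"),
                   "fed_days")

  dmi <- sow$dm_intake_kg_d
  mbw <- sow$bw_kg^0.75

  ge_intake <- sow$feed_ge_mj_kg_dm * dmi                  # MJ/d
  fecal_ge <- feces$mass_kg_d * feces$ge_mj_kg             # MJ/d
  de <- (ge_intake - fecal_ge) / dmi                       # MJ/kg DM

  vch4 <- mean(fed_days$vch4_l)                            # L/d
  ch4_e_mj <- constants$ch4_energy_kj_l * vch4 / 1000      # MJ/d
  ue_mj <- urine$ge_mj_d                                   # MJ/d
  me <- de - (ue_mj + ch4_e_mj) / dmi                      # MJ/kg DM

  me_intake <- me * 1000 * dmi / mbw                       # kJ/kg^0.75/d
  thp_daily <- brouwer_thp(fed_days$vo2_l, fed_days$vco2_l,
                           fed_days$vch4_l, fed_days$urinary_n_g, constants)
  thp <- mean(thp_daily) / mbw                             # kJ/kg^0.75/d

  if (is.null(sow$n_intake_g_d)) {
    stop("sow$n_intake_g_d is required (daily nitrogen intake, g/d)")
  }
  nb <- nitrogen_balance(n_intake = sow$n_intake_g_d,
                         n_feces = feces$n_g_d, n_urine = urine$n_g_d)

  re <- me_intake - thp                                    # kJ/kg^0.75/d
  rep_ <- nb$n_retained_g_d * constants$n_to_protein *
    constants$protein_energy_kj_g / mbw                    # kJ/kg^0.75/d
  rel <- re - rep_
  ne <- (re + fhp_kj_kg075_d) * mbw / dmi / 1000           # MJ/kg DM

  ue_pct_de <- 100 * ue_mj / (de * dmi)
  ch4_pct_de <- 100 * ch4_e_mj / (de * dmi)

  if (!is.na(ne) && (de < me || me < ne)) {
    warning("energy ordering DE >= ME >= NE violated; check inputs",
            call. = FALSE)
  }

  out <- data.frame(
    sow_id = sow$sow_id, period = sow$period, diet_id = sow$diet_id,
    bw_kg = sow$bw_kg, metabolic_bw = mbw, dm_intake_kg_d = dmi,
    de_mj_kg_dm = de, me_mj_kg_dm = me, ne_mj_kg_dm = ne,
    me_intake_kj_kg075 = me_intake, thp_kj_kg075 = thp,
    fhp_kj_kg075 = fhp_kj_kg075_d,
    re_kj_kg075 = re, rep_kj_kg075 = rep_, rel_kj_kg075 = rel,
    n_intake_g_d = nb$n_intake_g_d, n_feces_g_d = nb$n_feces_g_d,
    n_urine_g_d = nb$n_urine_g_d, n_retained_g_d = nb$n_retained_g_d,
    ue_pct_de = ue_pct_de, ch4_pct_de = ch4_pct_de,
    me_de_pct = 100 * me / de, ne_me_pct = 100 * ne / me,
    rq_fed = mean(respiratory_quotient(fed_days$vo2_l, fed_days$vco2_l)),
    stringsAsFactors = FALSE
  )
  if (!is.null(digestibility)) {
    for (an in names(digestibility)) {
      out[[paste0("dig_", tolower(an), "_pct")]] <- digestibility[[an]]
    }
  }
  class(out) <- c("energy_balance", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Energy-utilisation ratio suite
#'
#' Extracts the UE/DE, CH4-E/DE, ME/DE, and NE/ME percentages from an
#' energy-balance row and verifies the closure identity
#' `UE/DE + CH4/DE + ME/DE = 100` (within 0.05, warning otherwise).
#'
#' @param r an `energy_balance` row (or data frame with the ratio
#'   columns).
#' @return List with the four ratios and `closure` (their sum over DE).
#' @export
energy_ratio_suite <- function(r) {
  need <- c("ue_pct_de", "ch4_pct_de", "me_de_pct", "ne_me_pct")
  .require_columns(as.data.frame(r), need, "energy balance")
  closure <- r$ue_pct_de + r$ch4_pct_de + r$me_de_pct
  if (any(abs(closure - 100) > 0.05)) {
    warning(sprintf("UE/DE + CH4/DE + ME/DE = %.3f departs from 100", closure),
            call. = FALSE)
  }
  list(ue_pct_de = r$ue_pct_de, ch4_pct_de = r$ch4_pct_de,
       me_de_pct = r$me_de_pct, ne_me_pct = r$ne_me_pct, closure = closure)
}

#' @export
print.energy_balance <- function(x, ...) {
  cat(sprintf("Energy balance: %d sow-period(s)\n", nrow(x)))
  cols <- c("sow_id", "diet_id", "de_mj_kg_dm", "me_mj_kg_dm", "ne_mj_kg_dm",
            "re_kj_kg075", "fhp_kj_kg075")
  print(as.data.frame(x)[, intersect(cols, names(x)), drop = FALSE],
        digits = 4, ...)
  invisible(x)
}
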