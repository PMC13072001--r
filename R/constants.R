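#' Energy-system constants
#'
#' Bundle of the physical and convention constants used throughout the
#' energy evaluation: the Brouwer gas/urinary-nitrogen coefficients for
#' total heat production, the combustion enthalpy of methane, the energy
#' content of retained body protein, the nitrogen-to-protein factor, and
#' the trial feeding level.
#'
#' All coefficients are stored as positive magnitudes; the signs of the
#' methane and urinary-nitrogen terms are carried by the Brouwer formula
#' itself, not by the constant table. All internal energies are in kJ;
#' megajoules appear only at I/O boundaries.
#'
#' @param o2_kj_l kJ of heat per litre of O2 consumed (Brouwer).
#' @param co2_kj_l kJ per litre of CO2 produced (Brouwer).
#' @param ch4_kj_l kJ per litre of CH4 produced, subtracted in the Brouwer
#'   equation (magnitude).
#' @param urinary_n_kj_g kJ per gram of urinary nitrogen, subtracted in the
#'   Brouwer equation (magnitude).
#' @param ch4_energy_kj_l combustion enthalpy of methane, kJ/L, used to
#'   convert exhaled CH4 volume to an energy loss when deriving ME from DE.
#' @param protein_energy_kj_g energy content of retained body protein,
#'   kJ/g, used for the retained-energy-as-protein term.
#' @param n_to_protein nitrogen-to-crude-protein conversion factor.
#' @param feeding_level_kj_me_kg075 target ME allowance, kJ ME per kg
#'   metabolic body weight (BW^0.75) per day (1.3 x maintenance for
#'   gestating sows).
#' @param substitution_rate_default default as-fed inclusion fraction of a
#'   test ingredient replacing the basal diet in the difference method.
#'
#' @return A list of class `"energy_constants"`.
#' @examples
#' k <- energy_constants()
#' k$o2_kj_l
#' @export
energy_constants <- function(o2_kj_l = 16.18,
                             co2_kj_l = 5.02,
                             ch4_kj_l = 2.17,
                             urinary_n_kj_g = 5.99,
                             ch4_energy_kj_l = 39.54,
                             protein_energy_kj_g = 23.86,
                             n_to_protein = 6.25,
                             feeding_level_kj_me_kg075 = 544,
                             substitution_rate_default = 0.289) {
  k <- list(
    o2_kj_l = o2_kj_l,
    co2_kj_l = co2_kj_l,
    ch4_kj_l = ch4_kj_l,
    urinary_n_kj_g = urinary_n_kj_g,
    ch4_energy_kj_l = ch4_energy_kj_l,
    protein_energy_kj_g = protein_energy_kj_g,
    n_to_protein = n_to_protein,
    feeding_level_kj_me_kg075 = feeding_level_kj_me_kg075,
    substitution_rate_default = substitution_rate_default
  )
  bad <- names(k)[!vapply(k, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("energy constants must be single positive numbers: ",
         paste(bad, collapse = ", "))
  }
  if (k$substitution_rate_default > 1) {
    stop("'substitution_rate_default' must lie in (0, 1]")
  }
  class(k) <- "energy_constants"
  k
}

#' @export
print.energy_constants <- function(x, ...) {
  cat("Energy-system constants\n")
  cat(sprintf("  Brouwer: %.2f O2 + %.2f CO2 - %.2f CH4 - %.2f urinary N  (kJ; L, L, L, g)\n",
              x$o2_kj_l, x$co2_kj_l, x$ch4_kj_l, x$urinary_n_kj_g))
  cat(sprintf("  CH4 energy: %.2f kJ/L   protein energy: %.2f kJ/g   N->CP: %.2f\n",
              x$ch4_energy_kj_l, x$protein_energy_kj_g, x$n_to_protein))
  cat(sprintf("  feeding level: %g kJ ME/kg BW^0.75/d   default substitution: %.3f\n",
              x$feeding_level_kj_me_kg075, x$substitution_rate_default))
  invisible(x)
}
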