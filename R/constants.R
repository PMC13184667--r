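#' Physical constants for epithelial transport calculations
#'
#' Bundles the Faraday constant, gas constant, absolute temperature and the
#' molar volume of water. All internal computations in proxtub are MKSA:
#' concentrations in mol m^-3 (numerically equal to mM), potentials in V,
#' pressures in Pa, solute fluxes in mol m^-2 s^-1 and water flows in
#' m^3 m^-2 s^-1 (= m s^-1), everything per unit apical membrane area.
#'
#' @param temperature Absolute temperature (K). Default 310 K (body
#'   temperature of the mammalian kidney preparations the model describes).
#' @return An object of class `physical_constants` with fields `F` (C mol^-1),
#'   `R` (J mol^-1 K^-1), `T` (K), `Vw` (m^3 mol^-1) and the derived thermal
#'   voltage `RT_F` (V).
#' @examples
#' const <- physical_constants()
#' const$RT_F  # about 26.7 mV at 310 K
#' @export
physical_constants <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  const <- list(
    F  = 96485.33212,   # C mol^-1
    R  = 8.31446262,    # J mol^-1 K^-1
    T  = temperature,   # K
    Vw = 1.80686e-5     # m^3 mol^-1, molar volume of liquid water
  )
  const$RT   <- const$R * const$T
  const$RT_F <- const$RT / const$F
  class(const) <- "physical_constants"
  const
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (MKSA):\n")
  cat(sprintf("  F  = %.5f C/mol\n  R  = %.8f J/(mol K)\n  T  = %g K\n", x$F, x$R, x$T))
  cat(sprintf("  Vw = %.5g m^3/mol\n  RT/F = %.4f mV\n", x$Vw, 1e3 * x$RT_F))
  invisible(x)
}

# Unit conversions between internal MKSA and the units used in the renal
# physiology literature. mol m^-3 and mM coincide, so concentrations need
# no conversion.

#' Unit conversions for presentation
#'
#' Internal quantities are MKSA per unit apical membrane area; the physiology
#' literature reports pressures in atm, volumes in nL cm^-2, solute fluxes in
#' pmol cm^-2 s^-1, water flows in nL cm^-2 s^-1 and currents in uA cm^-2.
#' Each pair below round-trips to machine precision.
#'
#' @param x Numeric vector in the unit named by the function (source unit).
#' @return Numeric vector in the target unit.
#' @name units
#' @examples
#' atm_to_Pa(1)                     # 101325 Pa
#' Pa_to_atm(atm_to_Pa(1.00074))    # identity round-trip
#' flux_to_pmol_cm2_s(5.41e-6)      # 541 pmol cm^-2 s^-1
NULL

#' @rdname units
#' @export
atm_to_Pa <- function(x) x * 101325

#' @rdname units
#' @export
Pa_to_atm <- function(x) x / 101325

#' @rdname units
#' @export
nL_cm2_to_m3_m2 <- function(x) x * 1e-8

#' @rdname units
#' @export
m3_m2_to_nL_cm2 <- function(x) x * 1e8

#' @rdname units
#' @export
flux_to_pmol_cm2_s <- function(x) x * 1e8

#' @rdname units
#' @export
pmol_cm2_s_to_flux <- function(x) x * 1e-8

#' @rdname units
#' @export
current_to_uA_cm2 <- function(x) x * 100

#' @rdname units
#' @export
uA_cm2_to_current <- function(x) x / 100

#' Convert a per-tubule-length transport maximum to a per-luminal-area flux
#'
#' Micro-perfusion studies report glucose transport maxima per millimetre of
#' tubule length. For a cylindrical lumen of diameter `diameter_um` the luminal
#' surface per mm length is pi * d * 1 mm, which converts a rate in
#' pmol mm^-1 min^-1 into pmol cm^-2 s^-1. With Vmax = 20 pmol mm^-1 min^-1
#' and a 20 um lumen this gives the 530 pmol cm^-2 s^-1 scale used to anchor
#' the SGLT1 permeability.
#'
#' @param vmax_pmol_mm_min Transport maximum (pmol per mm tubule length per minute).
#' @param diameter_um Luminal diameter (micrometres).
#' @return Flux in pmol cm^-2 s^-1.
#' @examples
#' per_tubule_length_to_area_flux(20, 20)  # about 530
#' @export
per_tubule_length_to_area_flux <- function(vmax_pmol_mm_min, diameter_um) {
  stopifnot(diameter_um > 0)
  area_cm2_per_mm <- pi * (diameter_um * 1e-4) * 0.1   # cm^2 of lumen per mm length
  vmax_pmol_mm_min / area_cm2_per_mm / 60
}
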