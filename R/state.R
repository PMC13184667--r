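# EpithelialState: the unknowns of the coupled system plus the algebraically
# slaved quantities. Free unknowns (solved by Newton):
#   cell concentrations  cNaC, cKC, cClC, cGlucC
#   lis  concentrations  cNaL, cKL, cGlucL     (cClL slaved to electroneutrality)
#   potentials           psiC, psiL, psiO      (V, vs the serosal reference)
#   lis pressure         pL                    (Pa)
# Slaved: cClL, cAC, pC, volC, volL.

state_unknowns <- c("cNaC", "cKC", "cClC", "cGlucC",
                    "cNaL", "cKL", "cGlucL",
                    "psiC", "psiL", "psiO", "pL")

#' Build a complete epithelial state from the free unknowns
#'
#' Applies the algebraic closures: cell impermeant concentration from
#' electroneutrality, lis Cl from lis electroneutrality, cell pressure from the
#' compliance model, cell volume from the fixed impermeant content, lis volume
#' from the lateral-membrane compliance.
#'
#' @param x Named numeric vector with entries `cNaC, cKC, cClC, cGlucC, cNaL,
#'   cKL, cGlucL, psiC, psiL, psiO, pL` (MKSA units).
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @return An object of class `epithelial_state`: the unknowns plus `cClL`,
#'   `cAC`, `pC`, `volC`, `volL` and the compartment osmolarities `osmC`,
#'   `osmL`.
#' @export
complete_state <- function(x, params, baths) {
  x <- x[state_unknowns]
  if (any(is.na(x))) stop("state vector must contain all of: ",
                          paste(state_unknowns, collapse = ", "))
  st <- as.list(x)
  g <- params$geometry
  st$cAC  <- impermeant_concentration(st$cNaC, st$cKC, st$cClC, g$zA)
  st$cClL <- lis_chloride(st$cNaL, st$cKL)
  st$pC   <- cell_pressure(g, baths$pO, st$pL, baths$pS)
  st$volC <- if (g$DcMA > 0) cell_volume(g, st$cAC) else g$volCRef
  st$volL <- lis_volume(g, st$pL, st$pC)
  st$osmC <- st$cNaC + st$cKC + st$cClC + st$cGlucC + st$cAC
  st$osmL <- st$cNaL + st$cKL + st$cClL + st$cGlucL
  class(st) <- "epithelial_state"
  st
}

# Inverse of complete_state: the free-unknown vector.
state_vector <- function(state) {
  vapply(state_unknowns, function(nm) state[[nm]], numeric(1))
}

#' @export
print.epithelial_state <- function(x, ...) {
  cat("Epithelial state (concentrations mM, potentials mV, pressures atm, volumes nL/cm^2):\n")
  cat(sprintf("  cell: Na %.3g  K %.4g  Cl %.4g  Gluc %.3g  A^%.3g- %.4g   (osm %.4f mosM)\n",
              x$cNaC, x$cKC, x$cClC, x$cGlucC, 1, x$cAC, x$osmC))
  cat(sprintf("  lis : Na %.4f  K %.3f  Cl %.4f  Gluc %.3f          (osm %.4f mosM)\n",
              x$cNaL, x$cKL, x$cClL, x$cGlucL, x$osmL))
  cat(sprintf("  psi(cell) %.2f  psi(lis) %.3f  V_trans %.3f mV\n",
              1e3 * x$psiC, 1e3 * x$psiL, 1e3 * x$psiO))
  cat(sprintf("  p(cell) %.5f  p(lis) %.5f atm;  vol(cell) %.4g  vol(lis) %.4g nL/cm^2\n",
              Pa_to_atm(x$pC), Pa_to_atm(x$pL),
              m3_m2_to_nL_cm2(x$volC), m3_m2_to_nL_cm2(x$volL)))
  invisible(x)
}

#' Membrane potential for one of the five membranes
#'
#' Returns `psi_I - psi_II` where (I, II) follows the positive flux direction:
#' (lumen, cell) for `am`, (cell, lis) for `lm`, (cell, serosa) for `sm`,
#' (lumen, lis) for `tj`, (lis, serosa) for `ibm`. The serosal bath is the
#' electrical reference (`psi_s = 0`), so the luminal potential `psiO` is the
#' transepithelial potential.
#'
#' @param state An [complete_state()] object (or any list with `psiC`, `psiL`,
#'   `psiO`).
#' @param baths A [bath_composition()] object (provides the serosal reference).
#' @param membrane One of `"am"`, `"lm"`, `"sm"`, `"tj"`, `"ibm"`.
#' @return Potential difference (V).
#' @export
membrane_potential <- function(state, baths, membrane) {
  psiS <- baths$psiS
  switch(membrane,
         am  = state$psiO - state$psiC,
         lm  = state$psiC - state$psiL,
         sm  = state$psiC - psiS,
         tj  = state$psiO - state$psiL,
         ibm = state$psiL - psiS,
         stop(sprintf("unknown membrane '%s'", membrane)))
}
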