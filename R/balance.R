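# Algebraic closures and mass/charge balance residuals.

#' Cell impermeant-anion concentration from electroneutrality
#'
#' `cAC = (cNaC + cKC - cClC) / (-zA)`; substituting back makes the cell
#' charge balance `cNaC + cKC - cClC + zA cAC` vanish exactly.
#'
#' @param cNaC,cKC,cClC Cell ion concentrations (mol m^-3).
#' @param zA Mean valence of the impermeant anions (negative).
#' @return Impermeant concentration (mol m^-3).
#' @export
impermeant_concentration <- function(cNaC, cKC, cClC, zA) {
  stopifnot(zA < 0)
  surplus <- cNaC + cKC - cClC
  # an impermeant-free cell sits exactly on this boundary; tolerate round-off
  if (surplus < 0 && surplus > -1e-9 * max(1, cClC)) surplus <- 0
  if (surplus < 0)
    stop("cell cation deficit: cNaC + cKC < cClC implies negative impermeant content")
  surplus / (-zA)
}

#' Lis chloride from electroneutrality
#'
#' The lateral intercellular space contains no impermeant species, so
#' `cClL = cNaL + cKL` exactly.
#'
#' @param cNaL,cKL Lis cation concentrations (mol m^-3).
#' @return Lis Cl concentration (mol m^-3).
#' @export
lis_chloride <- function(cNaL, cKL) {
  stopifnot(cNaL >= 0, cKL >= 0)
  cNaL + cKL
}

#' Cell hydrostatic pressure from the compliance model
#'
#' `pC = (muAm pO + muLm pL + muSm pS) / (muAm + muLm + muSm)`; a weighted
#' mean, so always between the smallest and largest of the three pressures.
#'
#' @param geometry Geometry/compliance list (see [model_parameters()]).
#' @param pO,pL,pS Luminal, lis and serosal pressures (Pa).
#' @return Cell pressure (Pa).
#' @export
cell_pressure <- function(geometry, pO, pL, pS) {
  tot <- geometry$muAm + geometry$muLm + geometry$muSm
  if (tot <= 0) stop("compliance weights must not all be zero")
  (geometry$muAm * pO + geometry$muLm * pL + geometry$muSm * pS) / tot
}

#' Lis volume from the lateral-membrane compliance
#'
#' `volL = volLisRef * (1 + muLm (pL - pC))`; equal to the reference volume at
#' pressure equality, linear in the transmural pressure difference.
#'
#' @param geometry Geometry/compliance list.
#' @param pL,pC Lis and cell pressures (Pa).
#' @return Lis volume (m^3 per m^2 apical area).
#' @export
lis_volume <- function(geometry, pL, pC) {
  v <- geometry$volLisRef * (1 + geometry$muLm * (pL - pC))
  if (v <= 0) stop("lis volume collapsed to a non-positive value")
  v
}

#' Cell volume from the fixed impermeant content
#'
#' The functional syncytium holds a fixed amount `Dc * MA` of impermeant
#' anion, so `volC = Dc MA / cAC`: osmotic water equilibration of the cell is
#' expressed as volume slaved to impermeant dilution.
#'
#' @param geometry Geometry/compliance list.
#' @param cAC Impermeant concentration (mol m^-3), positive.
#' @return Cell volume (m^3 per m^2 apical area).
#' @export
cell_volume <- function(geometry, cAC) {
  if (cAC <= 0) stop("cell volume undefined for non-positive impermeant concentration")
  geometry$DcMA / cAC
}

#' Open-circuit current residual
#'
#' The transepithelial clamp condition: `Iclamp - (I_Na^am + I_Na^tj + I_K^am
#' + I_K^tj + I_Cl^am + I_Cl^tj)` with `I_j = z_j F J_j`. At open circuit
#' (`Iclamp = 0`) the residual vanishes at the solution, which fixes the
#' transepithelial potential.
#'
#' @param fluxes A flux set from [evaluate_fluxes()].
#' @param Iclamp Imposed transepithelial current (A m^-2), default 0.
#' @param constants A [physical_constants()] object.
#' @return Current residual (A m^-2).
#' @export
open_circuit_residual <- function(fluxes, Iclamp = 0, constants = physical_constants()) {
  am <- fluxes$solute$am; tj <- fluxes$solute$tj
  apical_current <- constants$F *
    (am[["Na"]] + am[["K"]] - am[["Cl"]] + tj[["Na"]] + tj[["K"]] - tj[["Cl"]])
  Iclamp - apical_current
}

#' Evaluate all membrane fluxes at a state
#'
#' Computes the five water flows (water first: the junctional solvent-drag
#' fluxes need them), every per-membrane solute flux, the per-pathway chord
#' conductances and the pump current.
#'
#' @param state A completed state from [complete_state()].
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @return A list of class `flux_set`:
#'   * `solute`: per membrane (`am`, `lm`, `sm`, `tj`, `ibm`) a named vector
#'     of total species fluxes (mol m^-2 s^-1), positive in the transport
#'     direction;
#'   * `water`: named vector of volume flows (m s^-1) for the five membranes
#'     plus `sglt1` (apical water co-transported with glucose);
#'   * `detail`: per-pathway fluxes (ENaC, apical cotransport, SGLT1, pump,
#'     channels, GLUT1, serosal recirculation);
#'   * `conductance`: per-pathway chord conductances (S m^-2) by membrane;
#'   * `Ipump`: pump current (A m^-2).
#' @export
evaluate_fluxes <- function(state, params, baths) {
  const <- params$constants
  pm <- params$perm; sg <- params$sigma
  V <- list(am = membrane_potential(state, baths, "am"),
            lm = membrane_potential(state, baths, "lm"),
            sm = membrane_potential(state, baths, "sm"),
            tj = membrane_potential(state, baths, "tj"),
            ibm = membrane_potential(state, baths, "ibm"))

  cellOsm <- state$osmC; lisOsm <- state$osmL
  lumOsm <- sum(baths$o); serOsm <- sum(baths$s)
  cLis <- c(Na = state$cNaL, K = state$cKL, Cl = state$cClL, Gluc = state$cGlucL)

  JVam <- cell_membrane_water_flow(params$lp$am, lumOsm, cellOsm, baths$pO, state$pC, const)
  JVlm <- cell_membrane_water_flow(params$lp$lm, cellOsm, lisOsm, state$pC, state$pL, const)
  JVsm <- cell_membrane_water_flow(params$lp$sm, cellOsm, serOsm, state$pC, baths$pS, const)
  JVtj <- junction_water_flow(params$lp$tj, sg$tj, baths$o, cLis, baths$pO, state$pL, const)
  JVibm <- junction_water_flow(params$lp$ibm, sg$ibm, cLis, baths$s, state$pL, baths$pS, const)

  # apical membrane --------------------------------------------------------
  J_enac <- ghk_flux(pm$am$Na, 1, V$am, baths$o[["Na"]], state$cNaC, const)
  J_amck <- nak2cl_flux(params$nak2cl$kAm,
                        baths$o[["Na"]], baths$o[["K"]], baths$o[["Cl"]],
                        state$cNaC, state$cKC, state$cClC)
  # SGLT1 takes the apical potential in the cell-minus-lumen convention
  J_sglt <- sglt1_fluxes(params$sglt1, baths$o[["Gluc"]], state$cGlucC,
                         baths$o[["Na"]], state$cNaC, -V$am, const)
  am <- c(Na = J_enac + J_amck[["Na"]] + J_sglt[["Na"]],
          K = J_amck[["K"]], Cl = J_amck[["Cl"]], Gluc = J_sglt[["Gluc"]])

  # lateral membrane (cell -> lis positive); GLUT1 is basolateral and splits
  # between the lateral (fraction fLm) and serosal faces
  J_pump <- pump_fluxes(params$pump, state$cNaC, state$cKL, V$lm)
  J_lmK  <- ghk_flux(pm$lm$K, 1, V$lm, state$cKC, state$cKL, const)
  J_lmCl <- ghk_flux(pm$lm$Cl, -1, V$lm, state$cClC, state$cClL, const)
  fLm <- params$glut1$fLm
  J_glut_lm <- fLm * glut1_flux(params$glut1$Jmax, params$glut1$K,
                                state$cGlucC, state$cGlucL)
  lm <- c(Na = J_pump[["Na"]], K = J_pump[["K"]] + J_lmK, Cl = J_lmCl,
          Gluc = J_glut_lm)

  # serosal membrane (cell -> serosa positive) -----------------------------
  J_smK  <- ghk_flux(pm$sm$K, 1, V$sm, state$cKC, baths$s[["K"]], const)
  J_smCl <- ghk_flux(pm$sm$Cl, -1, V$sm, state$cClC, baths$s[["Cl"]], const)
  J_smck <- nak2cl_flux(params$nak2cl$kSm,
                        state$cNaC, state$cKC, state$cClC,
                        baths$s[["Na"]], baths$s[["K"]], baths$s[["Cl"]])
  J_glut_sm <- (1 - fLm) * glut1_flux(params$glut1$Jmax, params$glut1$K,
                                      state$cGlucC, baths$s[["Gluc"]])
  sm <- c(Na = J_smck[["Na"]], K = J_smK + J_smck[["K"]],
          Cl = J_smCl + J_smck[["Cl"]], Gluc = J_glut_sm)

  # tight junction (lumen -> lis positive) ---------------------------------
  tj <- c(
    Na = solvent_drag_ion_flux(pm$tj$Na, 1, sg$tj[["Na"]], V$tj, JVtj,
                               baths$o[["Na"]], state$cNaL, const),
    K = solvent_drag_ion_flux(pm$tj$K, 1, sg$tj[["K"]], V$tj, JVtj,
                              baths$o[["K"]], state$cKL, const),
    Cl = ghk_flux(pm$tj$Cl, -1, V$tj, baths$o[["Cl"]], state$cClL, const),
    Gluc = convective_neutral_flux(pm$tj$Gluc, sg$tj[["Gluc"]], JVtj,
                                   baths$o[["Gluc"]], state$cGlucL)
  )

  # interspace basement membrane (lis -> serosa positive) ------------------
  ibm <- c(
    Na = solvent_drag_ion_flux(pm$ibm$Na, 1, sg$ibm[["Na"]], V$ibm, JVibm,
                               state$cNaL, baths$s[["Na"]], const),
    K = solvent_drag_ion_flux(pm$ibm$K, 1, sg$ibm[["K"]], V$ibm, JVibm,
                              state$cKL, baths$s[["K"]], const),
    Cl = solvent_drag_ion_flux(pm$ibm$Cl, -1, sg$ibm[["Cl"]], V$ibm, JVibm,
                               state$cClL, baths$s[["Cl"]], const),
    Gluc = convective_neutral_flux(pm$ibm$Gluc, sg$ibm[["Gluc"]], JVibm,
                                   state$cGlucL, baths$s[["Gluc"]])
  )

  # chord conductances (diagnostic layer for the bridge circuit) -----------
  G <- list(
    am = c(ENaC = ghk_chord_conductance(pm$am$Na, 1, V$am, baths$o[["Na"]],
                                        state$cNaC, const),
           SGLT1 = if (params$sglt1$Pmax == 0 ||
                       any(c(baths$o[["Gluc"]], state$cGlucC,
                             baths$o[["Na"]], state$cNaC) <= 0)) 0 else
             sglt1_conductance(params$sglt1, baths$o[["Gluc"]],
                               state$cGlucC, baths$o[["Na"]],
                               state$cNaC, -V$am, const)),
    lm = c(K = ghk_chord_conductance(pm$lm$K, 1, V$lm, state$cKC, state$cKL, const),
           Cl = ghk_chord_conductance(pm$lm$Cl, -1, V$lm, state$cClC, state$cClL, const),
           pump = pump_current(params$pump, state$cNaC, state$cKL, V$lm, const)$conductance),
    sm = c(K = ghk_chord_conductance(pm$sm$K, 1, V$sm, state$cKC, baths$s[["K"]], const),
           Cl = ghk_chord_conductance(pm$sm$Cl, -1, V$sm, state$cClC, baths$s[["Cl"]], const)),
    tj = c(Na = ghk_chord_conductance(pm$tj$Na, 1, V$tj, baths$o[["Na"]], state$cNaL, const),
           K = ghk_chord_conductance(pm$tj$K, 1, V$tj, baths$o[["K"]], state$cKL, const),
           Cl = ghk_chord_conductance(pm$tj$Cl, -1, V$tj, baths$o[["Cl"]], state$cClL, const)),
    ibm = c(Na = ghk_chord_conductance(pm$ibm$Na, 1, V$ibm, state$cNaL, baths$s[["Na"]], const),
            K = ghk_chord_conductance(pm$ibm$K, 1, V$ibm, state$cKL, baths$s[["K"]], const),
            Cl = ghk_chord_conductance(pm$ibm$Cl, -1, V$ibm, state$cClL, baths$s[["Cl"]], const))
  )

  structure(list(
    solute = list(am = am, lm = lm, sm = sm, tj = tj, ibm = ibm),
    water = c(am = JVam, lm = JVlm, sm = JVsm, tj = JVtj, ibm = JVibm,
              sglt1 = J_sglt[["W"]]),
    detail = list(am_ENaC = J_enac, am_NaK2Cl = J_amck, sglt1 = J_sglt,
                  pump = J_pump, lm_K = J_lmK, lm_Cl = J_lmCl,
                  glut1_lm = J_glut_lm, glut1_sm = J_glut_sm,
                  sm_K = J_smK, sm_Cl = J_smCl, sm_NaK2Cl = J_smck),
    conductance = G,
    Ipump = pump_current(params$pump, state$cNaC, state$cKL, V$lm, const)$current,
    potentials = unlist(V)
  ), class = "flux_set")
}

# Relative scaling: each balance residual divided by the larger of the signed
# influx and efflux sums (with a small floor), so "residual < tol" means the
# compartment conserves to a relative tolerance. Using max(|in|, |out|) rather
# than a sum of absolute terms keeps the scaled residual differentiable away
# from the solution (a summed scale saturates at -1/+1 with zero gradient).
scaled_balance <- function(inflow, outflow, floor) {
  (inflow - outflow) / max(floor, abs(inflow), abs(outflow))
}

#' Steady-state residual vector
#'
#' Per-compartment, per-species mass balances, the two water balances and the
#' open-circuit condition, all per unit apical area. Residuals are scaled by
#' the gross flux through each compartment so that a converged state has
#' `max |residual|` below the solver tolerance in relative terms.
#'
#' @param x Named vector of the free unknowns (see [complete_state()]), or a
#'   completed state.
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @param Iclamp Transepithelial clamp current (A m^-2), 0 for open circuit.
#' @return Named numeric vector of 11 scaled residuals, with attributes
#'   `raw` (unscaled residuals), `state` and `fluxes`.
#' @export
assemble_residuals <- function(x, params, baths, Iclamp = 0) {
  state <- if (inherits(x, "epithelial_state")) x else complete_state(x, params, baths)
  fl <- evaluate_fluxes(state, params, baths)
  s <- fl$solute; w <- fl$water
  floor_J <- 1e-9   # mol m^-2 s^-1
  floor_V <- 1e-11  # m s^-1
  floor_I <- 1e-6   # A m^-2

  inflow <- c(
    cell_Na = s$am[["Na"]], cell_K = s$am[["K"]], cell_Cl = s$am[["Cl"]],
    cell_Gluc = s$am[["Gluc"]],
    cell_water = w[["am"]] + w[["sglt1"]],
    lis_Na = s$lm[["Na"]] + s$tj[["Na"]], lis_K = s$lm[["K"]] + s$tj[["K"]],
    lis_Cl = s$lm[["Cl"]] + s$tj[["Cl"]],
    lis_Gluc = s$lm[["Gluc"]] + s$tj[["Gluc"]],
    lis_water = w[["lm"]] + w[["tj"]],
    open_circuit = Iclamp)
  outflow <- c(
    cell_Na = s$lm[["Na"]] + s$sm[["Na"]], cell_K = s$lm[["K"]] + s$sm[["K"]],
    cell_Cl = s$lm[["Cl"]] + s$sm[["Cl"]],
    cell_Gluc = s$lm[["Gluc"]] + s$sm[["Gluc"]],
    cell_water = w[["lm"]] + w[["sm"]],
    lis_Na = s$ibm[["Na"]], lis_K = s$ibm[["K"]], lis_Cl = s$ibm[["Cl"]],
    lis_Gluc = s$ibm[["Gluc"]],
    lis_water = w[["ibm"]],
    open_circuit = params$constants$F *
      (s$am[["Na"]] + s$am[["K"]] - s$am[["Cl"]] +
       s$tj[["Na"]] + s$tj[["K"]] - s$tj[["Cl"]]))
  floors <- stats::setNames(c(rep(floor_J, 4), floor_V, rep(floor_J, 4),
                              floor_V, floor_I), names(inflow))

  raw <- inflow - outflow
  gross <- pmax(floors, abs(inflow), abs(outflow))
  # the apical currents largely cancel at open circuit: scale that residual by
  # the gross current traffic, not by the (near-zero) net
  gross[["open_circuit"]] <- max(floor_I, abs(Iclamp), params$constants$F *
    sum(abs(c(s$am[c("Na", "K", "Cl")], s$tj[c("Na", "K", "Cl")]))))
  res <- raw / gross
  attr(res, "raw") <- raw
  attr(res, "gross") <- gross
  attr(res, "state") <- state
  attr(res, "fluxes") <- fl
  res
}
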