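# Membrane transport laws. Each function is pure: fluxes from concentrations,
# potential, pressure and parameters. Sign convention throughout: flux > 0 from
# compartment I to compartment II, with I -> II the transport direction
# (lumen -> cell -> lis/serosa, lumen -> lis, lis -> serosa).

# Constant-field kernel w*(cI*exp(w) - cII)/(exp(w) - 1), the shared core of the
# GHK, Hertz and convective flux laws. Removable singularity at w = 0 handled by
# a 3-term Taylor expansion; switchover at |w| < 1e-6 keeps the relative error
# below ~1e-13 on either branch.
cfield_kernel <- function(w, cI, cII) {
  if (!all(is.finite(c(w, cI, cII)))) stop("non-finite input to constant-field kernel")
  if (abs(w) < 1e-6) {
    # numerator/denominator expanded to O(w^2)
    num <- (cI - cII) + w * cI + w^2 * cI / 2
    den <- 1 + w / 2 + w^2 / 6
    num / den
  } else {
    ew <- exp(w)
    w * (cI * ew - cII) / (ew - 1)
  }
}

#' Goldman-Hodgkin-Katz electrodiffusion flux
#'
#' Constant-field flux of an ion across a membrane,
#' `J = P * u * (cI * exp(u) - cII) / (exp(u) - 1)` with `u = zFV/RT`.
#' The flux is positive from side I to side II, vanishes exactly at the Nernst
#' potential `E = (RT/zF) log(cII/cI)`, and reduces to Fick diffusion
#' `P * (cI - cII)` at `V = 0`.
#'
#' @param P Ion permeability (m s^-1), non-negative.
#' @param z Ion valence (integer, nonzero).
#' @param V Membrane potential psi_I - psi_II (V).
#' @param cI,cII Concentrations on sides I and II (mol m^-3), non-negative.
#' @param constants A [physical_constants()] object.
#' @return Solute flux (mol m^-2 s^-1).
#' @seealso [ghk_chord_conductance()], [solvent_drag_ion_flux()]
#' @export
ghk_flux <- function(P, z, V, cI, cII, constants = physical_constants()) {
  if (!all(is.finite(c(P, z, V, cI, cII)))) stop("non-finite input to ghk_flux")
  stopifnot(P >= 0, cI >= 0, cII >= 0, z != 0)
  u <- z * V / constants$RT_F
  P * cfield_kernel(u, cI, cII)
}

#' Chord (integral) conductance of a GHK pathway
#'
#' Returns `G` such that the electrical current `z F * ghk_flux(...)` equals
#' `G * (V - E)` with `E` the Nernst potential. The removable singularity at
#' `V = E` is resolved by a symmetric secant around `E` (the chord tends to the
#' slope conductance there). In the small-signal symmetric limit
#' (`cI = cII = c`, `V -> 0`) `G -> z^2 F^2 P c / (RT)`.
#'
#' @inheritParams ghk_flux
#' @return Conductance (S m^-2), non-negative.
#' @export
ghk_chord_conductance <- function(P, z, V, cI, cII, constants = physical_constants()) {
  if (!all(is.finite(c(P, z, V, cI, cII)))) stop("non-finite input")
  if (cI == 0 && cII == 0) stop("chord conductance undefined for cI = cII = 0")
  if (P == 0) return(0)
  if (cI <= 0 || cII <= 0) stop("chord conductance requires positive concentrations")
  E <- constants$RT_F / z * log(cII / cI)
  current <- function(v) z * constants$F * ghk_flux(P, z, v, cI, cII, constants)
  if (abs(V - E) < 1e-9) {
    d <- 1e-7
    (current(E + d) - current(E - d)) / (2 * d)
  } else {
    current(V) / (V - E)
  }
}

#' Na:K:2Cl cotransporter flux
#'
#' Electroneutral 1Na:1K:2Cl cotransport driven by the chemical potential
#' difference of the ion product, `J_j = r_j * k * (cNaI*cKI*cClI^2 -
#' cNaII*cKII*cClII^2)` with `r = 1` for Na and K and `r = 2` for Cl. Used for
#' apical K/Cl uptake and, with the sides reversed, for the serosal
#' ion-recirculation carrier.
#'
#' @param k Rate constant (mol m^-2 s^-1 per (mol m^-3)^4), non-negative.
#' @param cNaI,cKI,cClI Side-I concentrations (mol m^-3).
#' @param cNaII,cKII,cClII Side-II concentrations (mol m^-3).
#' @return Named vector `c(Na=, K=, Cl=)` of fluxes (mol m^-2 s^-1), positive
#'   I -> II; net charge flux is zero by construction.
#' @export
nak2cl_flux <- function(k, cNaI, cKI, cClI, cNaII, cKII, cClII) {
  conc <- c(cNaI, cKI, cClI, cNaII, cKII, cClII)
  if (!all(is.finite(c(k, conc)))) stop("non-finite input to nak2cl_flux")
  stopifnot(k >= 0, all(conc >= 0))
  drive <- k * (cNaI * cKI * cClI^2 - cNaII * cKII * cClII^2)
  c(Na = drive, K = drive, Cl = 2 * drive)
}

#' SGLT1 parameter set
#'
#' @param Pmax Maximal permeability of the composite (glucose + 2 Na) particle
#'   (m s^-1), referenced to a 1 mol m^-3 normalisation of the Na activity
#'   factor (see [sglt1_fluxes()]).
#' @param Km Luminal-glucose half-saturation constant of the self-inhibition
#'   permeability (mol m^-3). Default 1.0 mM.
#' @param nW Water molecules co-transported per glucose molecule
#'   (dimensionless, 0-600 explored; 264 for human, 424 for rabbit SGLT1).
#' @return A list of class `sglt1_parameters`.
#' @export
sglt1_parameters <- function(Pmax, Km = 1.0, nW = 264) {
  stopifnot(Pmax >= 0, Km > 0, nW >= 0)
  structure(list(Pmax = Pmax, Km = Km, nW = nW), class = "sglt1_parameters")
}

# Composite SGLT1 activity: glucose times squared Na, normalised by a 1 mM
# reference so the product keeps concentration units and Pmax keeps m/s.
sglt1_activity <- function(cGluc, cNa) cGluc * cNa^2  # (mol m^-3)^3; /cref^2 with cref = 1

#' SGLT1 coupled Na/glucose/water fluxes
#'
#' One glucose and two Na cross the apical membrane together as a divalent
#' particle through a constant-field barrier. `Vam` is the apical membrane
#' potential in the voltage-clamp convention (cell minus lumen, about -60 to
#' -80 mV at rest), the convention in which the reversal potential
#' [sglt1_reversal_potential()] is stated. With `u = -2 F Vam / RT`,
#' composite activities `Xo = cGlucO * cNaO^2`, `Xc = cGlucC * cNaC^2`
#' (normalised by a 1 mM reference concentration squared) and the
#' self-inhibition permeability `P = Pmax * Km / (cGlucO + Km)`,
#' `JNa = P * u * (Xo exp(u) - Xc)/(exp(u) - 1)`, `JGluc = JNa/2`, and
#' `JW = nW * JGluc * Vw`. The Na flux is positive (influx) for
#' `Vam < Vrev` and vanishes exactly at `Vam = Vrev`.
#'
#' @param params An [sglt1_parameters()] object.
#' @param cGlucO,cGlucC Luminal and cell glucose (mol m^-3).
#' @param cNaO,cNaC Luminal and cell Na (mol m^-3).
#' @param Vam Apical membrane potential psi_cell - psi_lumen (V).
#' @param constants A [physical_constants()] object.
#' @return Named vector `c(Na=, Gluc=, W=)`: solute fluxes in mol m^-2 s^-1,
#'   water flow in m s^-1, all positive lumen -> cell.
#' @export
sglt1_fluxes <- function(params, cGlucO, cGlucC, cNaO, cNaC, Vam,
                         constants = physical_constants()) {
  conc <- c(cGlucO, cGlucC, cNaO, cNaC)
  if (!all(is.finite(c(conc, Vam)))) stop("non-finite input to sglt1_fluxes")
  stopifnot(all(conc >= 0))
  if (params$Km + cGlucO <= 0) stop("Km + cGlucO must be positive")
  P <- params$Pmax * params$Km / (cGlucO + params$Km)
  u <- -2 * Vam / constants$RT_F
  JNa <- P * cfield_kernel(u, sglt1_activity(cGlucO, cNaO), sglt1_activity(cGlucC, cNaC))
  JGluc <- JNa / 2
  c(Na = JNa, Gluc = JGluc, W = params$nW * JGluc * constants$Vw)
}

#' SGLT1 reversal potential
#'
#' Potential at which the electrically charged Na flux through SGLT1 reverses:
#' `Vrev = (RT / 2F) log(cGlucO cNaO^2 / (cGlucC cNaC^2))`, in the
#' cell-minus-lumen convention of [sglt1_fluxes()] (positive under
#' physiological gradients, so the resting potential lies far below it and
#' SGLT1 runs inward).
#'
#' @inheritParams sglt1_fluxes
#' @return Potential (V).
#' @export
sglt1_reversal_potential <- function(cGlucO, cGlucC, cNaO, cNaC,
                                     constants = physical_constants()) {
  conc <- c(cGlucO, cGlucC, cNaO, cNaC)
  if (!all(is.finite(conc)) || any(conc <= 0))
    stop("sglt1_reversal_potential requires strictly positive concentrations")
  constants$RT_F / 2 *
    log(sglt1_activity(cGlucO, cNaO) / sglt1_activity(cGlucC, cNaC))
}

#' SGLT1 integral conductance
#'
#' Chord conductance of the SGLT1 current: `G` such that the SGLT1 electrical
#' current (inward-negative convention, `-F * JNa`) equals `G * (Vam - Vrev)`.
#' Nearly linear over the physiological range (-100 to -40 mV).
#'
#' @inheritParams sglt1_fluxes
#' @return Conductance (S m^-2), non-negative.
#' @export
sglt1_conductance <- function(params, cGlucO, cGlucC, cNaO, cNaC, Vam,
                              constants = physical_constants()) {
  if (params$Pmax == 0) return(0)
  Vrev <- sglt1_reversal_potential(cGlucO, cGlucC, cNaO, cNaC, constants)
  current <- function(v)
    -constants$F * sglt1_fluxes(params, cGlucO, cGlucC, cNaO, cNaC, v, constants)[["Na"]]
  if (abs(Vam - Vrev) < 1e-9) {
    d <- 1e-7
    (current(Vrev + d) - current(Vrev - d)) / (2 * d)
  } else {
    current(Vam) / (Vam - Vrev)
  }
}

#' GLUT1 symmetric saturating carrier flux
#'
#' Stein's equation for a symmetric facilitated-diffusion carrier:
#' `J = Jmax * K * (cI - cII) / ((K + cI)(K + cII))`. Antisymmetric in its
#' concentration arguments and bounded by `|J| <= Jmax`.
#'
#' @param Jmax Maximal carrier flux (mol m^-2 s^-1).
#' @param K Half-saturation constant (mol m^-3).
#' @param cI,cII Glucose concentrations on the two sides (mol m^-3).
#' @return Glucose flux (mol m^-2 s^-1), positive I -> II.
#' @export
glut1_flux <- function(Jmax, K, cI, cII) {
  if (!all(is.finite(c(Jmax, K, cI, cII)))) stop("non-finite input to glut1_flux")
  stopifnot(Jmax >= 0, K > 0, cI >= 0, cII >= 0)
  Jmax * K * (cI - cII) / ((K + cI) * (K + cII))
}

#' Pump parameter set (3Na:2K ATPase with electromotive force)
#'
#' @param Ppump Pump rate coefficient (mol s^-1 V^-1 per m^2 apical area).
#' @param Epump Electromotive force of the pump (V), positive; the pump current
#'   reverses at `Vlm = -Epump`.
#' @param KNa Half-saturation of cytosolic Na (mol m^-3). Default 3.4 mM.
#' @param KK Half-saturation of lis K (mol m^-3). Default 0.75 mM.
#' @return A list of class `pump_parameters`.
#' @export
pump_parameters <- function(Ppump, Epump, KNa = 3.4, KK = 0.75) {
  stopifnot(Ppump >= 0, KNa > 0, KK > 0)
  structure(list(Ppump = Ppump, Epump = Epump, KNa = KNa, KK = KK),
            class = "pump_parameters")
}

pump_saturation <- function(params, cNaC, cKL) {
  (cNaC / (params$KNa + cNaC))^3 * (cKL / (params$KK + cKL))^2
}

#' Na/K pump fluxes
#'
#' Active cation fluxes of the lateral 3Na:2K ATPase:
#' `JNa = Ppump * (cNaC/(KNa+cNaC))^3 * (cKL/(KK+cKL))^2 * (Vlm + Epump)` and
#' `JK = -(2/3) JNa`. `JNa` is positive cell -> lis (forward pumping) when
#' `Vlm > -Epump` and vanishes at the reversal potential `Vlm = -Epump`.
#'
#' @param params A [pump_parameters()] object.
#' @param cNaC Cytosolic Na (mol m^-3).
#' @param cKL K in the lateral intercellular space (mol m^-3).
#' @param Vlm Lateral membrane potential psi_cell - psi_lis (V).
#' @return Named vector `c(Na=, K=)` (mol m^-2 s^-1), positive cell -> lis.
#' @export
pump_fluxes <- function(params, cNaC, cKL, Vlm) {
  if (!all(is.finite(c(cNaC, cKL, Vlm)))) stop("non-finite input to pump_fluxes")
  stopifnot(cNaC >= 0, cKL >= 0)
  JNa <- params$Ppump * pump_saturation(params, cNaC, cKL) * (Vlm + params$Epump)
  c(Na = JNa, K = -2 / 3 * JNa)
}

#' Pump current and conductance
#'
#' With one net charge translocated per 3Na:2K cycle the pump current is
#' `I = F * JNa / 3`, equivalently `I = Gpump * (Vlm + Epump)` with
#' `Gpump = (F Ppump / 3) * saturation`. The current is exactly linear in
#' `Vlm` at fixed concentrations.
#'
#' @inheritParams pump_fluxes
#' @param constants A [physical_constants()] object.
#' @return List with `current` (A m^-2) and `conductance` (S m^-2).
#' @export
pump_current <- function(params, cNaC, cKL, Vlm, constants = physical_constants()) {
  G <- constants$F * params$Ppump / 3 * pump_saturation(params, cNaC, cKL)
  list(current = G * (Vlm + params$Epump), conductance = G)
}

#' Pump electromotive force from the free energy of ATP hydrolysis
#'
#' With 3 Na extruded per ATP, the reversal potential of the pump current is
#' `Vrev = dGATP / (3F)` (negative for hydrolysis) and `Epump = -Vrev`.
#' Well-aerated cells with dGATP of about -58 kJ/mol give Vrev near -200 mV.
#'
#' @param dGATP Free energy of ATP hydrolysis (J mol^-1), non-positive.
#' @param constants A [physical_constants()] object.
#' @return List with `Epump` and `Vrev` (V).
#' @export
epump_from_dg <- function(dGATP, constants = physical_constants()) {
  if (!is.finite(dGATP)) stop("non-finite dGATP")
  if (dGATP > 0) stop("dGATP must be non-positive (hydrolysis releases energy)")
  Vrev <- dGATP / (3 * constants$F)
  list(Epump = -Vrev, Vrev = Vrev)
}

#' Hertz solvent-drag electrodiffusion flux
#'
#' Combined electrodiffusion and convection of an ion through a water-conducting
#' pore with reflection coefficient `sigma`. With `u = zFV/RT` and Peclet number
#' `Pe = Jv (1 - sigma) / P` the field and drag terms combine in a single
#' exponent `w = u + Pe`:
#' `J = P * w * (cI exp(w) - cII)/(exp(w) - 1)`
#' (note `P * w = P * u + Jv (1 - sigma)`). The law reduces exactly to
#' [ghk_flux()] as `Jv -> 0` or `sigma -> 1`, and to
#' [convective_neutral_flux()] as `V -> 0`.
#'
#' @inheritParams ghk_flux
#' @param sigma Reflection coefficient in `[0, 1]`.
#' @param Jv Volume flow through the pore (m s^-1), positive I -> II.
#' @return Solute flux (mol m^-2 s^-1), positive I -> II.
#' @export
solvent_drag_ion_flux <- function(P, z, sigma, V, Jv, cI, cII,
                                  constants = physical_constants()) {
  if (!all(is.finite(c(P, z, sigma, V, Jv, cI, cII)))) stop("non-finite input")
  stopifnot(sigma >= 0, sigma <= 1, P >= 0, cI >= 0, cII >= 0, z != 0)
  if (sigma == 1 || Jv == 0) return(ghk_flux(P, z, V, cI, cII, constants))
  if (P == 0) stop("P must be positive when Jv is nonzero and sigma < 1")
  w <- z * V / constants$RT_F + Jv * (1 - sigma) / P
  P * cfield_kernel(w, cI, cII)
}

#' Convective flux of an electroneutral solute through a leaky barrier
#'
#' Solvent drag with diffusion for a neutral species: with
#' `Pe = Jv (1 - sigma)/P`,
#' `J = Jv (1 - sigma) (cI exp(Pe) - cII)/(exp(Pe) - 1)`, which tends to the
#' Fick flux `P (cI - cII)` as `Jv -> 0` and to pure drag
#' `Jv (1 - sigma) c` for a uniform solution.
#'
#' @inheritParams solvent_drag_ion_flux
#' @return Solute flux (mol m^-2 s^-1), positive I -> II.
#' @export
convective_neutral_flux <- function(P, sigma, Jv, cI, cII) {
  if (!all(is.finite(c(P, sigma, Jv, cI, cII)))) stop("non-finite input")
  stopifnot(sigma >= 0, sigma <= 1, P >= 0, cI >= 0, cII >= 0)
  if (sigma == 1) return(0)
  if (Jv == 0) return(P * (cI - cII))
  if (P == 0) stop("P must be positive when Jv is nonzero and sigma < 1")
  Pe <- Jv * (1 - sigma) / P
  P * cfield_kernel(Pe, cI, cII)
}

#' Osmotic water flow across a cell membrane
#'
#' Water crosses the cell membranes (apical, lateral, serosal) through AQP1
#' with reflection coefficient unity:
#' `JV = Lp * (RT (sum cII - sum cI) + pI - pII)`,
#' positive from side I to side II (toward the osmotically richer /
#' lower-pressure side).
#'
#' @param Lp Hydraulic conductance (m s^-1 Pa^-1).
#' @param sumOsmI,sumOsmII Total osmolyte concentrations on the two sides
#'   (mol m^-3); glucose counts as a full osmolyte.
#' @param pI,pII Hydrostatic pressures (Pa).
#' @param constants A [physical_constants()] object.
#' @return Volume flow (m s^-1), positive I -> II.
#' @export
cell_membrane_water_flow <- function(Lp, sumOsmI, sumOsmII, pI, pII,
                                     constants = physical_constants()) {
  if (!all(is.finite(c(Lp, sumOsmI, sumOsmII, pI, pII)))) stop("non-finite input")
  stopifnot(Lp >= 0)
  Lp * (constants$RT * (sumOsmII - sumOsmI) + pI - pII)
}

#' Water flow across a leaky junctional barrier
#'
#' Kedem-Katchalsky volume flow with per-species reflection coefficients:
#' `JV = Lp * (RT * sum_i sigma_i (cTo_i - cFrom_i) + pFrom - pTo)`,
#' positive from -> to. For the tight junction `from` is the lumen and `to`
#' the lateral intercellular space; for the interspace basement membrane
#' `from` is the lis and `to` the serosal bath.
#'
#' @param Lp Hydraulic conductance (m s^-1 Pa^-1).
#' @param sigma Named vector of reflection coefficients in `[0, 1]`.
#' @param cFrom,cTo Named concentration vectors (mol m^-3); names must match
#'   `sigma`.
#' @param pFrom,pTo Hydrostatic pressures (Pa).
#' @param constants A [physical_constants()] object.
#' @return Volume flow (m s^-1), positive from -> to.
#' @export
junction_water_flow <- function(Lp, sigma, cFrom, cTo, pFrom, pTo,
                                constants = physical_constants()) {
  stopifnot(Lp >= 0, all(sigma >= 0), all(sigma <= 1))
  nm <- names(sigma)
  if (is.null(nm) || !all(nm %in% names(cFrom)) || !all(nm %in% names(cTo)))
    stop("species names of sigma and the concentration vectors must match")
  osm <- sum(sigma * (unlist(cTo)[nm] - unlist(cFrom)[nm]))
  Lp * (constants$RT * osm + pFrom - pTo)
}

#' Convert between hydraulic conductance and osmotic permeability
#'
#' `Pf = RT Lp / Vw`; the two parameterisations of water permeability used in
#' the literature. Inverse round-trips are identities.
#'
#' @param Lp Hydraulic conductance (m s^-1 Pa^-1).
#' @param Pf Osmotic permeability (m s^-1).
#' @param constants A [physical_constants()] object.
#' @return The converted value.
#' @export
lp_to_pf <- function(Lp, constants = physical_constants()) {
  stopifnot(Lp >= 0)
  constants$RT * Lp / constants$Vw
}

#' @rdname lp_to_pf
#' @export
pf_to_lp <- function(Pf, constants = physical_constants()) {
  stopifnot(Pf >= 0)
  Pf * constants$Vw / constants$RT
}
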