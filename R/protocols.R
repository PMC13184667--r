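# Protocol drivers: the in-silico experiments (EMF sweep, glucose step,
# isosmotic tuning, VRAC activation, water-pathway sweeps, ATP accounting)
# and the calibration machinery for the reference parameter fixture.

#' Osmolarity of the absorbed fluid
#'
#' Total solute flux leaving the lateral intercellular space across the
#' interspace basement membrane divided by the accompanying volume flow:
#' `(J_Na + J_K + J_Cl + J_Gluc) / J_V` at the ibm, in mosM. Isosmotic
#' reabsorption means this matches the bath osmolarity.
#'
#' @param fluxes A flux set from [evaluate_fluxes()].
#' @return Absorbate osmolarity (mosM = mol m^-3).
#' @export
absorbate_osmolarity <- function(fluxes) {
  jv <- fluxes$water[["ibm"]]
  if (!is.finite(jv) || jv <= 0)
    stop("absorbate osmolarity undefined: no outward volume flow across the ibm")
  sum(fluxes$solute$ibm) / jv
}

#' ATP hydrolysis rate of the Na/K pump
#'
#' With the 3 Na : 1 ATP stoichiometry, the ATP consumption rate is one third
#' of the active Na flux, in the same units.
#'
#' @param JNaPump Active Na flux through the pump.
#' @return ATP hydrolysis rate.
#' @export
atp_rate <- function(JNaPump) JNaPump / 3

#' Observables of a solved steady state
#'
#' Named summary used by the calibration targets and the protocol tables,
#' in the units of the physiological literature.
#'
#' @param state A solved state (with flux attribute) from
#'   [newton_steady_state()].
#' @param baths The bath composition it was solved under.
#' @return Named numeric vector.
#' @export
steady_observables <- function(state, baths) {
  fl <- state_fluxes(state)
  absorb <- if (fl$water[["ibm"]] > 0) absorbate_osmolarity(fl) else NA_real_
  c(JNaPump_pmol = flux_to_pmol_cm2_s(fl$detail$pump[["Na"]]),
    JGlucAm_pmol = flux_to_pmol_cm2_s(fl$solute$am[["Gluc"]]),
    Vcell_mV = 1e3 * state$psiC,
    Vlis_mV = 1e3 * state$psiL,
    Vtrans_mV = 1e3 * state$psiO,
    cNaC_mM = state$cNaC, cKC_mM = state$cKC, cClC_mM = state$cClC,
    cGlucC_mM = state$cGlucC,
    cNaL_mM = state$cNaL, cKL_mM = state$cKL, cClL_mM = state$cClL,
    cGlucL_mM = state$cGlucL,
    osmC_mosM = state$osmC, osmL_mosM = state$osmL,
    volC_nL = m3_m2_to_nL_cm2(state$volC),
    volL_nL = m3_m2_to_nL_cm2(state$volL),
    pL_atm = Pa_to_atm(state$pL),
    dpL_Pa = state$pL - baths$pS,
    JVam_nL = m3_m2_to_nL_cm2(fl$water[["am"]]),
    JVsglt_nL = m3_m2_to_nL_cm2(fl$water[["sglt1"]]),
    JVtj_nL = m3_m2_to_nL_cm2(fl$water[["tj"]]),
    JVibm_nL = m3_m2_to_nL_cm2(fl$water[["ibm"]]),
    absorbate_mosM = absorb,
    ATP_pmol = flux_to_pmol_cm2_s(atp_rate(fl$detail$pump[["Na"]])))
}

protocol_result <- function(protocol, table, states, extra = list()) {
  structure(c(list(protocol = protocol, table = table, states = states), extra),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol '%s' (%d rows)\n", x$protocol, nrow(x$table)))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Sweep the free energy of ATP hydrolysis
#'
#' For each dG_ATP value, the pump electromotive force is set via
#' [epump_from_dg()] and the steady state re-solved by continuation from the
#' previous solution. Reports the pump reversal potential, the cellular cation
#' concentrations and the cell potential: cytosolic Na rises and K falls as
#' the energy supply (|dG_ATP|) decreases.
#'
#' @param params A [model_parameters()] object (reference pump EMF is
#'   overridden per point).
#' @param baths A [bath_composition()] object.
#' @param dGValues Free energies of ATP hydrolysis (J mol^-1, non-positive),
#'   ordered; continuation follows the given order.
#' @param settings A [solver_settings()] object.
#' @return A `protocol_result` with columns `dG_kJ_mol`, `Vrev_mV`, `cNa_mM`,
#'   `cK_mM`, `Vcell_mV`.
#' @export
epump_sweep <- function(params, baths, dGValues,
                        settings = solver_settings()) {
  if (length(dGValues) == 0)
    return(protocol_result("epump_sweep",
                           data.frame(dG_kJ_mol = numeric(0), Vrev_mV = numeric(0),
                                      cNa_mM = numeric(0), cK_mM = numeric(0),
                                      Vcell_mV = numeric(0)),
                           list()))
  stopifnot(all(dGValues <= 0))
  states <- vector("list", length(dGValues))
  rows <- vector("list", length(dGValues))
  guess <- NULL
  for (i in seq_along(dGValues)) {
    em <- epump_from_dg(dGValues[i], params$constants)
    pi <- param_set(params, "pump.Epump", em$Epump)
    st <- newton_steady_state(pi, baths, guess = guess, settings = settings)
    guess <- st
    states[[i]] <- st
    rows[[i]] <- data.frame(dG_kJ_mol = dGValues[i] / 1e3,
                            Vrev_mV = 1e3 * em$Vrev,
                            cNa_mM = st$cNaC, cK_mM = st$cKC,
                            Vcell_mV = 1e3 * st$psiC)
  }
  protocol_result("epump_sweep", do.call(rbind, rows), states)
}

# Solve the zero-capacitance algebraic subsystem: potentials re-equilibrate
# instantly after a perturbation while concentrations, pressures and volumes
# are still at their old values. Equations: zero net charge flux into the
# cell and into the lis, and the open-circuit condition.
instantaneous_potentials <- function(state, params, baths,
                                     settings = solver_settings()) {
  base <- state_vector(state)
  resfun <- function(psi) {
    x <- base
    x[c("psiC", "psiL", "psiO")] <- psi
    st <- complete_state(x, params, baths)
    fl <- evaluate_fluxes(st, params, baths)
    s <- fl$solute
    F <- params$constants$F
    cell <- F * ((s$am[["Na"]] + s$am[["K"]] - s$am[["Cl"]]) -
                 (s$lm[["Na"]] + s$lm[["K"]] - s$lm[["Cl"]]) -
                 (s$sm[["Na"]] + s$sm[["K"]] - s$sm[["Cl"]]))
    lis <- F * ((s$lm[["Na"]] + s$lm[["K"]] - s$lm[["Cl"]]) +
                (s$tj[["Na"]] + s$tj[["K"]] - s$tj[["Cl"]]) -
                (s$ibm[["Na"]] + s$ibm[["K"]] - s$ibm[["Cl"]]))
    oc <- open_circuit_residual(fl, 0, params$constants)
    c(cell, lis, oc) / 1  # A m^-2; O(1) scaling adequate for the 3x3 solve
  }
  set <- settings; set$newtonTol <- 1e-9
  sol <- newton_core(resfun, base[c("psiC", "psiL", "psiO")], set)
  x <- base
  x[c("psiC", "psiL", "psiO")] <- sol$x
  st <- complete_state(x, params, baths)
  attr(st, "fluxes") <- evaluate_fluxes(st, params, baths)
  st
}

#' Bilateral glucose concentration step
#'
#' Monoexponential increase of the glucose concentration in both baths
#' (default 1 -> 5 mM, tau = 1 ms), integrated with BDF2 and event-aligned
#' initial refinement. Also reports the instantaneous (zero-capacitance)
#' response at t = 0+: the depolarisation-driven jump of the pump flux before
#' any concentration has changed, and the corresponding pump current
#' increment F * dJ / 3.
#'
#' @param params A [model_parameters()] object.
#' @param settings A [solver_settings()] object.
#' @param gluc_from,gluc_to Initial and final glucose (mol m^-3).
#' @param tau Time constant of the forcing (s).
#' @param horizon Simulated time (s).
#' @param baths Template [bath_composition()]; its glucose entries are
#'   replaced by the forcing.
#' @return A `protocol_result` whose `table` is the transient history table;
#'   extra fields `history`, `initial`, `instant` (t = 0+ state) and
#'   `pump_jump` (list with fluxes in pmol cm^-2 s^-1 and `dI_uA_cm2`).
#' @export
glucose_step_protocol <- function(params, settings = solver_settings(),
                                  gluc_from = 1, gluc_to = 5, tau = 0.001,
                                  horizon = 100, baths = bath_composition()) {
  gl <- function(t) gluc_from + (gluc_to - gluc_from) * (1 - exp(-t / tau))
  bfun <- function(t) {
    g <- gl(t)
    bath_composition(Na = baths$o[["Na"]], K = baths$o[["K"]],
                     Cl = baths$o[["Cl"]], Gluc = g,
                     Na_s = baths$s[["Na"]], K_s = baths$s[["K"]],
                     Cl_s = baths$s[["Cl"]], Gluc_s = g,
                     pO = baths$pO, pS = baths$pS)
  }
  init <- newton_steady_state(params, bfun(0), settings = settings)
  attr_init_fl <- state_fluxes(init)

  # zero-capacitance response to the completed step, concentrations frozen
  instant <- instantaneous_potentials(init, params, bfun(20 * tau))
  J0 <- attr_init_fl$detail$pump[["Na"]]
  J1 <- state_fluxes(instant)$detail$pump[["Na"]]
  pump_jump <- list(
    J_before_pmol = flux_to_pmol_cm2_s(J0),
    J_after_pmol = flux_to_pmol_cm2_s(J1),
    dI_uA_cm2 = current_to_uA_cm2(params$constants$F * (J1 - J0) / 3))

  hist <- run_transient(params, bfun, horizon, settings, init = init)
  protocol_result("glucose_step", hist$table, hist$states,
                  list(history = hist, initial = init, instant = instant,
                       pump_jump = pump_jump))
}

#' Tune the serosal recirculation carrier for isosmotic reabsorption
#'
#' Scalar root-find on the serosal 1Na:1K:2Cl cotransporter rate constant so
#' that the absorbate osmolarity matches the serosal bath osmolarity within
#' `tolerance`. Bracketing + root polishing (robustness over speed); reports
#' the baseline and tuned states.
#'
#' @param params A [model_parameters()] object (its `nak2cl$kSm` is the free
#'   scalar; the baseline uses `kSm = 0`).
#' @param baths A [bath_composition()] object.
#' @param tolerance Isosmolarity tolerance (mosM). Default 0.1.
#' @param kMax Upper end of the scanned interval for the rate constant.
#' @param settings A [solver_settings()] object.
#' @return List with `kSm`, `baseline` and `tuned` solved states, and
#'   `result` (a two-row `protocol_result` table: baseline vs isosmotic).
#' @export
tune_isosmotic_recirculation <- function(params, baths, tolerance = 0.1,
                                         kMax = NULL,
                                         settings = solver_settings(newtonTol = 1e-9)) {
  p0 <- param_set(params, "nak2cl.kSm", 0)
  base <- newton_steady_state(p0, baths, settings = settings)
  target <- bath_osmolarity(baths, "s")
  f_base <- absorbate_osmolarity(state_fluxes(base)) - target
  if (f_base <= 0)
    stop("baseline absorbate is not hyperosmotic; nothing to tune")
  # generous scan ceiling: a carrier turnover of up to ~1e-3 mol m^-2 s^-1
  # at the serosal ion product (far beyond any physiological recirculation)
  if (is.null(kMax)) kMax <- 1e-3 /
      (baths$s[["Na"]] * baths$s[["K"]] * baths$s[["Cl"]]^2)

  # The steady-state branch can fold in the strongly swollen regime, so every
  # evaluation is continued from the solved state at the current lower bracket
  # end (one-sided continuation in k): the tracked branch stays consistent.
  state_lo <- base
  eval_k <- function(k, from) {
    pk <- param_set(params, "nak2cl.kSm", k)
    # near the fold of the swollen branch the Jacobian degenerates; retry at a
    # relaxed inner tolerance (still far tighter than the root-find needs)
    st <- tryCatch(
      newton_steady_state(pk, baths, guess = from, settings = settings),
      proxtub_newton_failure = function(e) {
        relaxed <- settings; relaxed$newtonTol <- 1e-7
        newton_steady_state(pk, baths, guess = from, settings = relaxed)
      })
    list(state = st, f = absorbate_osmolarity(state_fluxes(st)) - target)
  }
  finish <- function(k, state) {
    tab <- rbind(
      data.frame(condition = "baseline", kSm = 0,
                 t(steady_observables(base, baths))),
      data.frame(condition = "isosmotic", kSm = k,
                 t(steady_observables(state, baths))))
    list(kSm = k, baseline = base, tuned = state,
         result = protocol_result("tune_isosmotic", tab, list(base, state)))
  }

  # expand a bracket from zero by continuation
  hi <- kMax / 50
  ev <- eval_k(hi, state_lo)
  f_hi <- ev$f
  tries <- 0
  lo <- 0; f_lo <- f_base
  while (f_hi > 0 && hi < kMax && tries < 30) {
    if (abs(f_hi) < tolerance) return(finish(hi, ev$state))
    lo <- hi; f_lo <- f_hi; state_lo <- ev$state
    hi <- hi * 2
    ev <- eval_k(hi, state_lo)
    f_hi <- ev$f
    tries <- tries + 1
  }
  if (f_hi > 0)
    stop(sprintf("no isosmotic point in the scanned interval [0, %.3g] (residual %.3g mosM)",
                 hi, f_hi))
  if (abs(f_hi) < tolerance) return(finish(hi, ev$state))
  for (i in 1:80) {
    mid <- if (is.finite(f_lo) && is.finite(f_hi) && (f_lo - f_hi) > 0) {
      m <- lo + f_lo * (hi - lo) / (f_lo - f_hi)   # secant proposal
      if (m <= lo || m >= hi) (lo + hi) / 2 else m
    } else (lo + hi) / 2
    ev <- eval_k(mid, state_lo)
    if (abs(ev$f) < tolerance) return(finish(mid, ev$state))
    if (ev$f > 0) { lo <- mid; f_lo <- ev$f; state_lo <- ev$state }
    else { hi <- mid; f_hi <- ev$f }
    if ((hi - lo) < 1e-9 * kMax) {
      # the branch jumps over the band: accept the closer side if it is
      # within twice the tolerance, otherwise report the bracket
      if (abs(f_hi) < 2 * tolerance) return(finish(hi, ev$state))
      if (abs(f_lo) < 2 * tolerance) return(finish(lo, state_lo))
      break
    }
  }
  stop("isosmotic tuning did not converge to the requested tolerance")
}

#' Volume regulation by VRAC activation
#'
#' Root-find on a multiplier of the lateral-membrane Cl permeability so that
#' the solved cell volume returns to `targetVolume` (volume-regulated anion
#' channel activation after recirculation-induced swelling). Cell Cl and
#' volume decrease monotonically with the extra Cl permeability.
#'
#' @param params A [model_parameters()] object (typically with the tuned
#'   recirculation carrier active).
#' @param baths A [bath_composition()] object.
#' @param targetVolume Target cell volume (m^3 m^-2).
#' @param tolerance Relative volume tolerance. Default 1e-3.
#' @param settings A [solver_settings()] object.
#' @param baseline Optional pre-solved swollen state used as the starting
#'   point (recommended: the tuned state of
#'   [tune_isosmotic_recirculation()]).
#' @return List with `PClLm` (the tuned permeability), `multiplier`, `state`,
#'   and `baseline`.
#' @export
vrac_activation <- function(params, baths, targetVolume, tolerance = 1e-3,
                            settings = solver_settings(newtonTol = 1e-9),
                            baseline = NULL) {
  base <- if (is.null(baseline)) newton_steady_state(params, baths, settings = settings)
          else baseline
  if (base$volC <= targetVolume * (1 + tolerance))
    stop("cell is not swollen beyond the target; VRAC activation has nothing to do")
  P0 <- params$perm$lm$Cl
  # one-sided continuation in the permeability multiplier: evaluations start
  # from the solved state at the current lower bracket end
  state_lo <- base
  eval_m <- function(m, from) {
    pm <- param_set(params, "perm.lm.Cl", P0 * m)
    st <- tryCatch(
      newton_steady_state(pm, baths, guess = from, settings = settings),
      proxtub_newton_failure = function(e) {
        relaxed <- settings; relaxed$newtonTol <- 1e-7
        newton_steady_state(pm, baths, guess = from, settings = relaxed)
      })
    list(state = st, f = st$volC / targetVolume - 1)
  }
  lo <- 1; f_lo <- base$volC / targetVolume - 1
  hi <- 2
  ev <- eval_m(hi, state_lo)
  f_hi <- ev$f
  tries <- 0
  while (f_hi > 0 && tries < 40) {
    lo <- hi; f_lo <- f_hi; state_lo <- ev$state
    hi <- hi * 1.5
    ev <- eval_m(hi, state_lo)
    f_hi <- ev$f
    tries <- tries + 1
  }
  if (f_hi > 0) stop("scanned Cl-permeability range cannot deflate the cell to the target")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    ev <- eval_m(mid, state_lo)
    if (abs(ev$f) < tolerance)
      return(list(PClLm = P0 * mid, multiplier = mid, state = ev$state,
                  baseline = base))
    if (ev$f > 0) { lo <- mid; f_lo <- ev$f; state_lo <- ev$state }
    else { hi <- mid; f_hi <- ev$f }
  }
  stop("VRAC tuning did not converge")
}

#' Sweep the SGLT1 water:glucose coupling ratio
#'
#' Re-solves the steady state for each `nW` (water molecules per glucose
#' through SGLT1) and decomposes the transepithelial water uptake into the
#' apical AQP1 osmotic component, the SGLT1 cotransported component and the
#' paracellular (Claudin-2) component. The AQP1 and SGLT1 components vary
#' inversely while the total exit flow across the ibm stays nearly constant.
#'
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @param nWValues Coupling ratios to scan (0-600).
#' @param settings A [solver_settings()] object.
#' @return A `protocol_result` with columns `nW`, `JVaqp_nL`, `JVsglt_nL`,
#'   `JVtj_nL`, `JVibm_nL`, `JVcell_nL`, `JNaPump_pmol`, `Vtrans_mV`.
#' @export
nw_sweep <- function(params, baths, nWValues, settings = solver_settings()) {
  stopifnot(all(nWValues >= 0))
  states <- vector("list", length(nWValues))
  rows <- vector("list", length(nWValues))
  guess <- NULL
  for (i in seq_along(nWValues)) {
    pi <- param_set(params, "sglt1.nW", nWValues[i])
    st <- newton_steady_state(pi, baths, guess = guess, settings = settings)
    guess <- st
    fl <- state_fluxes(st)
    states[[i]] <- st
    rows[[i]] <- data.frame(
      nW = nWValues[i],
      JVaqp_nL = m3_m2_to_nL_cm2(fl$water[["am"]]),
      JVsglt_nL = m3_m2_to_nL_cm2(fl$water[["sglt1"]]),
      JVtj_nL = m3_m2_to_nL_cm2(fl$water[["tj"]]),
      JVibm_nL = m3_m2_to_nL_cm2(fl$water[["ibm"]]),
      JVcell_nL = m3_m2_to_nL_cm2(fl$water[["am"]] + fl$water[["sglt1"]]),
      JNaPump_pmol = flux_to_pmol_cm2_s(fl$detail$pump[["Na"]]),
      Vtrans_mV = 1e3 * st$psiO)
  }
  protocol_result("nw_sweep", do.call(rbind, rows), states)
}

#' Water uptake as a function of active Na flux
#'
#' Scales the pump rate coefficient over a physiological range and records the
#' translateral (`JVcell` = AQP1 + SGLT1) and paracellular (Claudin-2) water
#' flows against the active Na flux; at transepithelial osmotic equilibrium
#' both depend linearly on the pump flux.
#'
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @param pumpScale Multipliers of the reference pump rate (e.g. 0.25-1.5).
#' @param settings A [solver_settings()] object.
#' @return A `protocol_result`; extra field `fit` holds the linear regression
#'   of `JVibm` on `JNaPump` (`slope`, `intercept`, `r2`).
#' @export
pump_water_relation <- function(params, baths,
                                pumpScale = c(0.25, 0.5, 0.75, 1, 1.25, 1.5),
                                settings = solver_settings()) {
  P0 <- params$pump$Ppump
  states <- vector("list", length(pumpScale))
  rows <- vector("list", length(pumpScale))
  guess <- NULL
  for (i in order(abs(pumpScale - 1))) {   # continuation outward from 1x
    pi <- param_set(params, "pump.Ppump", P0 * pumpScale[i])
    st <- newton_steady_state(pi, baths, guess = guess, settings = settings)
    guess <- st
    fl <- state_fluxes(st)
    states[[i]] <- st
    rows[[i]] <- data.frame(
      scale = pumpScale[i],
      JNaPump_pmol = flux_to_pmol_cm2_s(fl$detail$pump[["Na"]]),
      JVcell_nL = m3_m2_to_nL_cm2(fl$water[["am"]] + fl$water[["sglt1"]]),
      JVtj_nL = m3_m2_to_nL_cm2(fl$water[["tj"]]),
      JVibm_nL = m3_m2_to_nL_cm2(fl$water[["ibm"]]))
  }
  tab <- do.call(rbind, rows)
  fit <- stats::lm(JVibm_nL ~ JNaPump_pmol, data = tab)
  protocol_result("pump_water_relation", tab, states,
                  list(fit = list(slope = unname(stats::coef(fit)[2]),
                                  intercept = unname(stats::coef(fit)[1]),
                                  r2 = summary(fit)$r.squared)))
}

#' Metabolic cost of isosmotic transport across the SGLT1 coupling ratios
#'
#' For each `nW`: the baseline (no recirculation) active Na flux, ibm fluid
#' uptake and ATP rate, the same quantities after tuning the recirculation
#' carrier to isosmolarity, and the extra ATP cost `dATP`. The cost of
#' isosmotic transport decreases as more water rides on SGLT1.
#'
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @param nWValues Coupling ratios (e.g. `c(0, 200, 400, 600)`).
#' @param tolerance Isosmolarity tolerance (mosM) passed to the tuner.
#' @param settings A [solver_settings()] object.
#' @return A `protocol_result` with one row per `nW`.
#' @export
table_atp_accounting <- function(params, baths, nWValues = c(0, 200, 400, 600),
                                 tolerance = 0.1,
                                 settings = solver_settings()) {
  rows <- vector("list", length(nWValues))
  states <- vector("list", length(nWValues))
  for (i in seq_along(nWValues)) {
    pn <- param_set(params, "sglt1.nW", nWValues[i])
    tuned <- tune_isosmotic_recirculation(pn, baths, tolerance = tolerance,
                                          settings = settings)
    fb <- state_fluxes(tuned$baseline); ft <- state_fluxes(tuned$tuned)
    JNab <- flux_to_pmol_cm2_s(fb$detail$pump[["Na"]])
    JNai <- flux_to_pmol_cm2_s(ft$detail$pump[["Na"]])
    rows[[i]] <- data.frame(
      nW = nWValues[i],
      JNa_base_pmol = JNab,
      JVibm_base_nL = m3_m2_to_nL_cm2(fb$water[["ibm"]]),
      ATP_base_pmol = atp_rate(JNab),
      kSm = tuned$kSm,
      JNa_iso_pmol = JNai,
      JVibm_iso_nL = m3_m2_to_nL_cm2(ft$water[["ibm"]]),
      ATP_iso_pmol = atp_rate(JNai),
      dATP_pmol = atp_rate(JNai) - atp_rate(JNab))
    states[[i]] <- list(baseline = tuned$baseline, isosmotic = tuned$tuned)
  }
  protocol_result("atp_accounting", do.call(rbind, rows), states)
}

# --- calibration ------------------------------------------------------------

#' Calibrate free parameters against steady-state observables
#'
#' Bounded least-squares minimisation (Levenberg-Marquardt on log-transformed
#' parameters, keeping them positive) of weighted relative deviations between
#' solved-state observables and target values. Targets may refer to different
#' bath glucose concentrations; the steady state is re-solved per condition
#' with warm starts.
#'
#' @param params Starting [model_parameters()] object.
#' @param baths A [bath_composition()] template.
#' @param targets Data frame with columns `observable` (a name from
#'   [steady_observables()]), `value`, optional `weight` (default 1) and
#'   optional `glucose` (mol m^-3; `NA` = the template baths).
#' @param free Character vector of dotted parameter paths (e.g.
#'   `"pump.Ppump"`, `"perm.lm.K"`), or a list whose elements are character
#'   vectors of paths tied to a single shared value (e.g. the cation
#'   permeabilities of a non-selective pore); all must be positive quantities.
#' @param settings A [solver_settings()] object.
#' @param maxIter Levenberg-Marquardt iteration cap.
#' @param factor_bounds Multiplicative search bounds around the start values.
#' @param lower,upper Optional named vectors (by the first path of each free
#'   group, natural scale) overriding the default bounds, e.g. to cap a
#'   fraction at 1.
#' @return List with `params` (calibrated), `residuals` (per-target table of
#'   achieved vs target values) and `fit` (the `nls.lm` object).
#' @export
calibrate_reference <- function(params, baths, targets, free,
                                settings = solver_settings(), maxIter = 50,
                                factor_bounds = 100, lower = NULL, upper = NULL) {
  stopifnot(all(c("observable", "value") %in% names(targets)))
  if (is.null(targets$weight)) targets$weight <- 1
  if (is.null(targets$glucose)) targets$glucose <- NA_real_
  if (!is.list(free)) free <- as.list(free)
  start <- vapply(free, function(p) param_get(params, p[[1]]), numeric(1))
  names(start) <- vapply(free, function(p) p[[1]], character(1))
  if (any(start <= 0)) stop("all free parameters must start positive")

  conds <- unique(targets$glucose)
  warm <- new.env()
  bath_for <- function(g) {
    if (is.na(g)) return(baths)
    bath_composition(Na = baths$o[["Na"]], K = baths$o[["K"]],
                     Cl = baths$o[["Cl"]], Gluc = g,
                     Na_s = baths$s[["Na"]], K_s = baths$s[["K"]],
                     Cl_s = baths$s[["Cl"]], Gluc_s = g,
                     pO = baths$pO, pS = baths$pS)
  }

  set_free <- function(p, logTheta) {
    for (i in seq_along(free))
      for (path in free[[i]]) p <- param_set(p, path, exp(logTheta[i]))
    p
  }

  resid_fn <- function(logTheta) {
    p <- set_free(params, logTheta)
    out <- numeric(nrow(targets))
    for (g in conds) {
      key <- paste0("g", g)
      st <- tryCatch(
        newton_steady_state(p, bath_for(g),
                            guess = get0(key, envir = warm, inherits = FALSE),
                            settings = settings),
        error = function(e) NULL)
      rowsel <- which(is.na(targets$glucose) == is.na(g) &
                        (is.na(g) | targets$glucose == g))
      if (is.null(st)) { out[rowsel] <- 10; next }   # penalise failed solves
      warm[[key]] <- st
      obs <- steady_observables(st, bath_for(g))
      tv <- targets$value[rowsel]
      ov <- obs[targets$observable[rowsel]]
      out[rowsel] <- targets$weight[rowsel] * (ov - tv) / pmax(abs(tv), 1e-3)
    }
    out
  }

  lo <- start / factor_bounds
  hi <- start * factor_bounds
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  fit <- minpack.lm::nls.lm(
    par = log(start), fn = resid_fn,
    lower = log(lo), upper = log(hi),
    control = minpack.lm::nls.lm.control(maxiter = maxIter, ptol = 1e-12,
                                         ftol = 1e-12))
  p <- set_free(params, fit$par)
  rel_dev <- resid_fn(fit$par) / targets$weight
  residuals <- cbind(targets,
                     achieved = targets$value + rel_dev * pmax(abs(targets$value), 1e-3),
                     rel_dev = rel_dev)
  list(params = p, residuals = residuals, fit = fit)
}
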