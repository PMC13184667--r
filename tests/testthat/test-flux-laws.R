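const <- physical_constants()

test_that("GHK flux: Fick limit, symmetric closed form and Nernst equilibrium", {
  expect_equal(ghk_flux(1, 1, 0, 2, 1, const), 1)            # V = 0 -> Fick
  # symmetric concentrations: J = P * u * c
  expect_equal(ghk_flux(1, 1, const$RT_F, 1, 1, const), 1, tolerance = 1e-12)
  expect_equal(ghk_flux(2, -1, -0.013, 5, 5, const),
               2 * (0.013 / const$RT_F) * 5, tolerance = 1e-12)
  # zero flux exactly at the Nernst potential
  expect_equal(ghk_flux(1, 1, const$RT_F * log(10), 1, 10, const), 0,
               tolerance = 1e-15)
  expect_equal(ghk_flux(3e-7, -1, -const$RT_F / 1 * log(150 / 16), 16, 150,
                        const), 0, tolerance = 1e-18)
  expect_error(ghk_flux(1, 1, NaN, 1, 1, const), "non-finite")
})

test_that("GHK flux is continuous across the V = 0 series switchover", {
  for (z in c(-1, 1)) {
    below <- ghk_flux(1, z, 0.99e-6 * const$RT_F / z, 3, 1, const)
    above <- ghk_flux(1, z, 1.01e-6 * const$RT_F / z, 3, 1, const)
    expect_equal(below, above, tolerance = 1e-7)
  }
})

test_that("chord conductance satisfies the current identity on random states", {
  set.seed(42)
  for (i in 1:1000) {
    z <- sample(c(-1, 1), 1)
    cI <- random_conc(1); cII <- random_conc(1)
    V <- stats::runif(1, -0.1, 0.1)
    P <- 10^stats::runif(1, -9, -5)
    E <- const$RT_F / z * log(cII / cI)
    if (abs(V - E) < 1e-6) next
    G <- ghk_chord_conductance(P, z, V, cI, cII, const)
    I <- z * const$F * ghk_flux(P, z, V, cI, cII, const)
    expect_gt(G, 0)
    expect_equal(I, G * (V - E), tolerance = 1e-10)
  }
})

test_that("chord conductance limits: small-signal value, zero permeability", {
  c0 <- 10; P <- 2e-7
  expect_equal(ghk_chord_conductance(P, 1, 1e-9, c0, c0, const),
               const$F^2 * P * c0 / const$RT, tolerance = 1e-6)
  expect_identical(ghk_chord_conductance(0, 1, 0.05, 10, 20, const), 0)
  expect_error(ghk_chord_conductance(1e-7, 1, 0, 0, 0, const), "cI = cII = 0")
})

test_that("Na:K:2Cl cotransport: equilibrium, stoichiometry, direct value", {
  # product equilibrium
  expect_equal(unname(nak2cl_flux(1e-12, 10, 10, 10, 10, 10, 10)), c(0, 0, 0))
  # 1:1:2 stoichiometry on arbitrary states
  set.seed(7)
  for (i in 1:50) {
    cc <- random_conc(6)
    J <- nak2cl_flux(3e-14, cc[1], cc[2], cc[3], cc[4], cc[5], cc[6])
    expect_equal(J[["Cl"]], 2 * J[["Na"]])
    expect_equal(J[["Na"]], J[["K"]])
  }
  # direct evaluation of the mass-action drive
  J <- nak2cl_flux(1e-12, 146, 4, 150, 10, 140, 16)
  expect_equal(J[["Na"]], 1e-12 * (146 * 4 * 150^2 - 10 * 140 * 16^2))
})

test_that("SGLT1: reversal potential, zero flux there, stoichiometry", {
  # closed-form reversal potential for the printed configuration
  expect_equal(1e3 * sglt1_reversal_potential(6, 8, 146, 10, const),
               67.7776, tolerance = 1e-4)
  # symmetric conditions and Na-scaling invariance
  expect_equal(sglt1_reversal_potential(5, 5, 100, 100, const), 0)
  expect_equal(sglt1_reversal_potential(6, 8, 146 * 3, 10 * 3, const),
               sglt1_reversal_potential(6, 8, 146, 10, const))
  expect_error(sglt1_reversal_potential(0, 8, 146, 10, const), "positive")

  sg <- sglt1_parameters(Pmax = 1e-10, Km = 1, nW = 264)
  Vrev <- sglt1_reversal_potential(6, 8, 146, 10, const)
  J <- sglt1_fluxes(sg, 6, 8, 146, 10, Vrev, const)
  expect_equal(unname(J), c(0, 0, 0), tolerance = 1e-22)
  # 2 Na : 1 glucose : nW water on arbitrary states
  set.seed(13)
  for (i in 1:50) {
    cc <- random_conc(4)
    J <- sglt1_fluxes(sg, cc[1], cc[2], cc[3], cc[4], stats::runif(1, -0.1, 0.05),
                      const)
    expect_equal(J[["Na"]], 2 * J[["Gluc"]])
    expect_equal(J[["W"]], 264 * J[["Gluc"]] * const$Vw)
  }
})

test_that("SGLT1 self-inhibition kinetics reproduce saturating MM-type uptake", {
  # Pmax anchored so the saturating glucose flux is 530 pmol/cm2/s at -60 mV
  cfg <- list(cNaO = 146, cNaC = 10, cGlucC = 8, Vam = -0.060)
  Jinf1 <- sglt1_fluxes(sglt1_parameters(1, 1, 0), 1e9, cfg$cGlucC, cfg$cNaO,
                        cfg$cNaC, cfg$Vam, const)[["Gluc"]]
  sg <- sglt1_parameters(Pmax = 5.3e-6 / Jinf1, Km = 1, nW = 0)
  cs <- seq(0.1, 6, by = 0.1)
  J <- vapply(cs, function(c)
    sglt1_fluxes(sg, c, cfg$cGlucC, cfg$cNaO, cfg$cNaC, cfg$Vam, const)[["Gluc"]],
    numeric(1))
  # the curve is itself Michaelis-Menten shaped: J*(c+Km)/c is constant up to
  # the small cell-side offset of the constant-field drive
  scaled <- J * (cs + sg$Km) / cs
  expect_lt(diff(range(scaled)) / mean(scaled), 0.01)
  # and it tracks the literature fit 530*c/(0.6+c), deviating by less than
  # 15% of the transport maximum anywhere on 0-6 mM
  MM <- 5.3e-6 * cs / (0.6 + cs)
  expect_lt(max(abs(J - MM)) / 5.3e-6, 0.15)
  # saturated region agrees to within the half-saturation mismatch (the
  # printed fit uses 0.6 mM where the self-inhibition constant is 1.0 mM)
  expect_lt(max(abs(J - MM)[cs >= 4] / MM[cs >= 4]), 0.1)
})

test_that("SGLT1 conductance: chord identity and near-linear I-V", {
  sg <- sglt1_parameters(Pmax = 1.1e-10, Km = 1, nW = 264)
  set.seed(23)
  for (i in 1:200) {
    cc <- random_conc(4)
    V <- stats::runif(1, -0.12, 0.02)
    Vrev <- sglt1_reversal_potential(cc[1], cc[2], cc[3], cc[4], const)
    if (abs(V - Vrev) < 1e-6) next
    G <- sglt1_conductance(sg, cc[1], cc[2], cc[3], cc[4], V, const)
    I <- -const$F * sglt1_fluxes(sg, cc[1], cc[2], cc[3], cc[4], V, const)[["Na"]]
    expect_equal(I, G * (V - Vrev), tolerance = 1e-10)
    expect_gte(G, 0)
  }
  expect_identical(sglt1_conductance(sglt1_parameters(0, 1, 0),
                                     6, 8, 146, 10, -0.06, const), 0)
  # linearity between -100 and -40 mV: midpoint within 2% of the straight line
  cur <- function(v) -const$F *
    sglt1_fluxes(sg, 6, 8, 146, 10, v, const)[["Na"]]
  lin <- (cur(-0.100) + cur(-0.040)) / 2
  expect_lt(abs(cur(-0.070) - lin) / abs(lin), 0.02)
})

test_that("GLUT1 carrier: antisymmetry, saturation bound, zero at equality", {
  expect_equal(glut1_flux(1e-5, 5, 3, 3), 0)
  set.seed(5)
  for (i in 1:50) {
    ab <- random_conc(2)
    expect_equal(glut1_flux(1e-5, 5, ab[1], ab[2]),
                 -glut1_flux(1e-5, 5, ab[2], ab[1]))
    expect_lte(abs(glut1_flux(1e-5, 5, ab[1], ab[2])), 1e-5)
  }
  # saturation limit cI -> Inf, cII = 0
  expect_equal(glut1_flux(1e-5, 5, 1e12, 0), 1e-5, tolerance = 1e-6)
})

test_that("pump: reversal, half-saturation algebra, stoichiometry, current", {
  pp <- pump_parameters(Ppump = 3.9e-4, Epump = 0.2)
  expect_equal(unname(pump_fluxes(pp, 10, 4, -0.2)), c(0, 0))
  # at half-saturation of both sites the rate collapses to Ppump*(V+E)/32
  J <- pump_fluxes(pp, 3.4, 0.75, -0.07)
  expect_equal(J[["Na"]], pp$Ppump * (-0.07 + 0.2) / 32, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    cc <- random_conc(2)
    V <- stats::runif(1, -0.1, 0)
    J <- pump_fluxes(pp, cc[1], cc[2], V)
    expect_equal(J[["K"]], -2 / 3 * J[["Na"]])
    pc <- pump_current(pp, cc[1], cc[2], V, const)
    expect_equal(pc$current, const$F * J[["Na"]] / 3, tolerance = 1e-12)
    expect_equal(pc$current / (V + pp$Epump), pc$conductance, tolerance = 1e-10)
  }
  # the printed flux-to-current conversion: a 541 -> 726 pmol/cm2/s jump is
  # an extra 5.95 uA/cm2 of pump current
  dI <- const$F * pmol_cm2_s_to_flux(726 - 541) / 3
  expect_equal(current_to_uA_cm2(dI), 5.95, tolerance = 1e-3)
})

test_that("pump EMF follows the free energy of ATP hydrolysis", {
  expect_equal(1e3 * epump_from_dg(-58e3, const)$Vrev, -200, tolerance = 2)
  expect_equal(1e3 * epump_from_dg(-29e3, const)$Vrev, -100, tolerance = 1)
  expect_equal(epump_from_dg(0, const)$Epump, 0)
  expect_error(epump_from_dg(10, const), "non-positive")
  # linear in dGATP, Epump = -Vrev
  em <- epump_from_dg(-40.6e3, const)
  expect_equal(em$Epump, -em$Vrev)
  expect_equal(em$Vrev, -40.6e3 / (3 * const$F))
})

test_that("solvent-drag flux reduces to its stated limits", {
  set.seed(17)
  for (i in 1:200) {
    cc <- random_conc(2)
    V <- stats::runif(1, -0.05, 0.05)
    P <- 10^stats::runif(1, -8, -5)
    Jv <- stats::runif(1, -1, 1) * 1e-7
    sig <- stats::runif(1)
    z <- sample(c(-1, 1), 1)
    # Jv -> 0 recovers GHK exactly
    expect_equal(solvent_drag_ion_flux(P, z, sig, V, 0, cc[1], cc[2], const),
                 ghk_flux(P, z, V, cc[1], cc[2], const), tolerance = 1e-12)
    # V -> 0 recovers the neutral convective flux
    expect_equal(solvent_drag_ion_flux(P, z, sig, 0, Jv, cc[1], cc[2], const),
                 convective_neutral_flux(P, sig, Jv, cc[1], cc[2]),
                 tolerance = 1e-9)
    # full reflection shuts off the drag term entirely
    expect_equal(solvent_drag_ion_flux(P, z, 1, V, Jv, cc[1], cc[2], const),
                 ghk_flux(P, z, V, cc[1], cc[2], const), tolerance = 1e-12)
  }
  expect_error(solvent_drag_ion_flux(0, 1, 0.5, 0.01, 1e-8, 1, 1, const),
               "P must be positive")
})

test_that("neutral convective flux: drag, diffusive limit, full reflection", {
  expect_equal(convective_neutral_flux(1e-7, 0.2, 3e-8, 5, 5),
               3e-8 * 0.8 * 5, tolerance = 1e-12)   # uniform solution
  expect_equal(convective_neutral_flux(1, 0.3, 0, 2, 1), 1)  # Fick limit
  expect_identical(convective_neutral_flux(1e-7, 1, 3e-8, 9, 1), 0)
  # continuity as Jv -> 0
  expect_equal(convective_neutral_flux(1e-7, 0.2, 1e-15, 2, 1),
               1e-7, tolerance = 1e-6)
})

test_that("water flows: equilibria, unit osmotic response, linearity", {
  expect_equal(cell_membrane_water_flow(1e-11, 300, 300, 1e5, 1e5, const), 0)
  # 1 mosM excess on side II pulls water toward II at Lp*RT
  expect_equal(cell_membrane_water_flow(1e-11, 300, 301, 1e5, 1e5, const),
               1e-11 * const$RT, tolerance = 1e-12)
  expect_equal(cell_membrane_water_flow(2e-11, 300, 305, 1e5, 1e5, const),
               2 * cell_membrane_water_flow(1e-11, 300, 305, 1e5, 1e5, const))

  sig <- c(Na = 0.7, K = 0.7, Cl = 0.45, Gluc = 0.8)
  cA <- c(Na = 146, K = 4, Cl = 150, Gluc = 6)
  expect_equal(junction_water_flow(1e-11, sig, cA, cA, 1e5, 1e5, const), 0)
  # all-zero sigma leaves a purely pressure-driven flow
  expect_equal(junction_water_flow(1e-11, sig * 0, cA, cA * 2, 1e5 + 50, 1e5,
                                   const), 1e-11 * 50)
  # a mildly hyperosmotic but clearly hyperbaric lis drives outward ibm flow
  # (the low reflection coefficient makes the pressure term dominant)
  sib <- c(Na = 0.03, K = 0.03, Cl = 0.03, Gluc = 0.03)
  lis <- cA + c(0.45, 0.05, 0.45, 0.05)   # ~1 mosM excess
  jv <- junction_water_flow(7.4e-10, sib, lis, cA, atm_to_Pa(1.002),
                            atm_to_Pa(1), const)
  expect_gt(jv, 0)
  expect_error(junction_water_flow(1e-11, c(Na = 0.5), list(K = 1), list(K = 1),
                                   0, 0, const), "names")
})

test_that("Lp <-> Pf conversion round-trips and scales with temperature", {
  expect_identical(lp_to_pf(0, const), 0)
  lp <- 1.3e-11
  expect_equal(pf_to_lp(lp_to_pf(lp, const), const), lp, tolerance = 1e-14)
  c2 <- physical_constants(2 * const$T)
  expect_equal(lp_to_pf(lp, c2), 2 * lp_to_pf(lp, const))
})
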