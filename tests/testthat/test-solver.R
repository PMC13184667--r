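test_that("finite-difference Jacobian is exact for linear and quadratic maps", {
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  lin <- function(x) as.numeric(A %*% x) + c(1, -2)
  J <- finite_difference_jacobian(lin, c(0.3, -0.7), fdStep = 1e-6)
  expect_equal(J, A, tolerance = 1e-7)
  Jf <- finite_difference_jacobian(lin, c(0.3, -0.7), fdStep = 1e-6,
                                   method = "forward")
  expect_equal(Jf, A, tolerance = 1e-6)
  # central differences are O(h^2) on a quadratic
  quad <- function(x) x^2
  d <- finite_difference_jacobian(quad, 1, fdStep = 1e-5)[1, 1]
  expect_equal(d, 2, tolerance = 1e-9)
  expect_error(finite_difference_jacobian(function(x) NaN, 1), "not finite")
})

test_that("a dead epithelium settles exactly at the bath composition", {
  p <- dead_parameters()
  b <- bath_composition()
  st <- newton_steady_state(p, b)
  expect_equal(st$cNaC, 146, tolerance = 1e-6)
  expect_equal(st$cKC, 4, tolerance = 1e-6)
  expect_equal(st$cClC, 150, tolerance = 1e-6)
  expect_equal(st$cGlucC, 6, tolerance = 1e-6)
  expect_equal(st$cNaL, 146, tolerance = 1e-6)
  expect_equal(1e3 * st$psiO, 0, tolerance = 1e-6)   # mV
  expect_equal(1e3 * st$psiC, 0, tolerance = 1e-6)
  fl <- state_fluxes(st)
  expect_lt(max(abs(unlist(fl$solute))), 1e-13)
  expect_lt(max(abs(fl$water)), 1e-15)
})

test_that("the steady state does not depend on the starting guess", {
  p <- toy_parameters()
  b <- bath_composition()
  st1 <- newton_steady_state(p, b)
  g2 <- default_initial_guess(p, b)
  g2[c("cNaC", "cKC", "cClC")] <- c(25, 110, 40)
  g2["psiC"] <- -0.04
  st2 <- newton_steady_state(p, b, guess = g2)
  for (nm in proxtub:::state_unknowns)
    expect_equal(st1[[nm]], st2[[nm]], tolerance = 1e-8)
})

test_that("a solved steady state is a fixed point of the transient scheme", {
  p <- toy_parameters()
  b <- bath_composition()
  st <- newton_steady_state(p, b)
  hist <- run_transient(p, b, horizon = 0.5,
                        settings = solver_settings(dt = 0.025, refineUntil = 0),
                        init = st)
  final <- hist$states[[length(hist$states)]]
  for (nm in proxtub:::state_unknowns)
    expect_equal(final[[nm]], st[[nm]],
                 tolerance = 1e-9 * max(1, abs(st[[nm]])))
})

test_that("the transient relaxes to the steady state of the new baths", {
  p <- toy_parameters()
  b0 <- bath_composition(Gluc = 1)
  b1 <- bath_composition(Gluc = 1.5)
  st0 <- newton_steady_state(p, b0)
  # step the baths and integrate long enough to re-equilibrate the cell pools
  hist <- run_transient(p, function(t) b1, horizon = 60,
                        settings = solver_settings(dt = 0.25, refineUntil = 0),
                        init = st0)
  target <- newton_steady_state(p, b1, guess = st0)
  final <- hist$states[[length(hist$states)]]
  expect_equal(final$cGlucC, target$cGlucC, tolerance = 5e-3)
  expect_equal(final$cNaC, target$cNaC, tolerance = 5e-3)
  expect_equal(1e3 * final$psiC, 1e3 * target$psiC, tolerance = 1e-2)
})

test_that("transient integration shows second-order convergence in dt", {
  p <- toy_parameters()
  b1 <- bath_composition(Gluc = 1.2)
  st0 <- newton_steady_state(p, bath_composition(Gluc = 1))
  run_to <- function(dt) {
    hist <- run_transient(p, function(t) b1, horizon = 2,
                          settings = solver_settings(dt = dt, refineUntil = 0),
                          init = st0)
    state_vector(hist$states[[length(hist$states)]])
  }
  x1 <- run_to(0.25); x2 <- run_to(0.125); x4 <- run_to(0.0625)
  # Richardson: error(dt) ~ C dt^p -> p = log2(|x1-x2| / |x2-x4|)
  num <- sqrt(sum(((x1 - x2) / proxtub:::unknown_typical)^2))
  den <- sqrt(sum(((x2 - x4) / proxtub:::unknown_typical)^2))
  p_obs <- log2(num / den)
  expect_gt(p_obs, 1.9)
})

test_that("the per-step ledgers of a transient close to 1e-6 relative", {
  p <- toy_parameters()
  b1 <- bath_composition(Gluc = 2)
  st0 <- newton_steady_state(p, bath_composition(Gluc = 1))
  dt <- 0.05
  hist <- run_transient(p, function(t) b1, horizon = 3,
                        settings = solver_settings(dt = dt, refineUntil = 0),
                        init = st0)
  X <- sapply(hist$states, proxtub:::conserved_quantities)
  # pure BDF2 interior steps: re-evaluate the fluxes independently at each
  # stored state and verify the three-point balance
  for (n in seq(4, ncol(X), by = 7)) {
    fl <- evaluate_fluxes(hist$states[[n]], p, b1)
    rate <- proxtub:::conserved_rates(fl)
    lhs <- (3 * X[, n] - 4 * X[, n - 1] + X[, n - 2]) / (2 * dt)
    rel <- abs(lhs - rate) / pmax(abs(rate), abs(lhs), abs(X[, n]) / (2 * dt) * 1e-2)
    expect_lt(max(rel), 1e-6)
  }
  # cumulative trapezoid cross-check of the transepithelial ledgers
  content <- function(st) c(Na = st$volC * st$cNaC + st$volL * st$cNaL,
                            Gluc = st$volC * st$cGlucC + st$volL * st$cGlucL)
  rates <- sapply(seq_along(hist$states), function(i) {
    fl <- evaluate_fluxes(hist$states[[i]], p, b1)
    vapply(c("Na", "Gluc"), function(sp)
      fl$solute$am[[sp]] + fl$solute$tj[[sp]] -
        fl$solute$sm[[sp]] - fl$solute$ibm[[sp]], numeric(1))
  })
  n <- length(hist$states)
  stored <- content(hist$states[[n]]) - content(hist$states[[1]])
  integrated <- apply(rates, 1, function(r) sum((r[-1] + r[-n]) / 2) * dt)
  for (sp in c("Na", "Gluc"))
    expect_lt(abs(stored[[sp]] - integrated[[sp]]),
              0.05 * max(abs(integrated[[sp]]), 1e-10))
})

test_that("newton failure reports carry a residual trace", {
  p <- toy_parameters()
  b <- bath_composition()
  bad <- solver_settings(maxIter = 2, newtonTol = 1e-14)
  err <- tryCatch(newton_steady_state(p, b, settings = bad),
                  proxtub_newton_failure = function(e) e)
  expect_s3_class(err, "proxtub_newton_failure")
  expect_true(length(err$residual_trace) >= 1)
})
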