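# Newton-Raphson steady-state solution and BDF2 transient integration.

#' Solver settings
#'
#' @param newtonTol Convergence tolerance on the maximum scaled residual.
#' @param maxIter Newton iteration cap.
#' @param fdStep Relative finite-difference step for the Jacobian.
#' @param dt Transient time step (s).
#' @param damping Initial Newton step-length factor in (0, 1]; the step is
#'   halved further whenever an iterate is inadmissible or the residual norm
#'   fails to decrease.
#' @param refineDt,refineUntil Event-aligned refinement for fast forcings: a
#'   finer step `refineDt` is used from t = 0 until `refineUntil` (s) before
#'   switching to `dt`. Set `refineUntil = 0` to disable.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(newtonTol = 1e-10, maxIter = 150, fdStep = 1e-7,
                            dt = 0.01, damping = 1, refineDt = 1e-4,
                            refineUntil = 0.01) {
  stopifnot(newtonTol > 0, maxIter >= 1, fdStep > 0, dt > 0,
            damping > 0, damping <= 1, refineDt > 0, refineUntil >= 0)
  structure(list(newtonTol = newtonTol, maxIter = maxIter, fdStep = fdStep,
                 dt = dt, damping = damping, refineDt = refineDt,
                 refineUntil = refineUntil),
            class = "solver_settings")
}

# Typical magnitudes of the free unknowns, used to size finite-difference
# steps: concentrations O(1-150) mM, potentials O(1) mV, pressures O(1e5) Pa.
unknown_typical <- c(rep(1, 7), 1e-3, 1e-3, 1e-3, 100)

#' Finite-difference Jacobian
#'
#' Column-wise difference approximation of `d residual / d x` with a relative
#' step `fdStep` on each unknown (absolute step `fdStep * max(|x_i|,
#' typical_i)`).
#'
#' @param residualFn Function mapping an unknown vector to a residual vector.
#' @param x Point at which to differentiate.
#' @param fdStep Relative step size.
#' @param typical Typical magnitudes per unknown (floor for the absolute
#'   step); defaults to 1.
#' @param method `"central"` (O(h^2), default) or `"forward"` (O(h), half the
#'   cost).
#' @return Jacobian matrix (length(residual) x length(x)).
#' @export
finite_difference_jacobian <- function(residualFn, x, fdStep = 1e-7,
                                       typical = NULL,
                                       method = c("central", "forward")) {
  method <- match.arg(method)
  if (is.null(typical)) typical <- rep(1, length(x))
  r0 <- residualFn(x)
  if (any(!is.finite(r0))) stop("residual not finite at the expansion point")
  J <- matrix(NA_real_, length(r0), length(x))
  for (i in seq_along(x)) {
    h <- fdStep * max(abs(x[i]), typical[i])
    xp <- x; xp[i] <- x[i] + h
    rp <- residualFn(xp)
    if (method == "central") {
      xm <- x; xm[i] <- x[i] - h
      rm <- residualFn(xm)
      J[, i] <- (rp - rm) / (2 * h)
    } else {
      J[, i] <- (rp - r0) / h
    }
    if (any(!is.finite(J[, i])))
      stop(sprintf("non-finite residual while probing unknown %d", i))
  }
  J
}

# Damped Newton iteration on an arbitrary residual function. Inadmissible
# iterates (the residual function signals an error, e.g. negative
# concentrations) trigger step halving. When a Jacobian cache environment is
# supplied (transient stepping) the factorised model is reused across calls
# and only rebuilt when progress stalls; without one, a fresh Jacobian is
# computed every iteration (full Newton). Failure raises a condition carrying
# the residual trace.
newton_core <- function(residualFn, x0, settings, jac_env = NULL) {
  safe_res <- function(x) tryCatch(residualFn(x), error = function(e) NULL)
  r <- safe_res(x0)
  if (is.null(r)) stop("initial guess is not physically admissible")
  x <- x0
  trace <- max(abs(r))
  J <- if (!is.null(jac_env)) jac_env$J else NULL
  fresh <- FALSE     # was J computed at the current iterate?
  central <- FALSE   # escalate to O(h^2) differences when progress stalls
  # like finite_difference_jacobian, but an inadmissible probe (e.g. when an
  # iterate sits on the electroneutrality boundary) falls back to the
  # opposite one-sided difference for that column
  build_jac <- function(x, method) {
    r0 <- safe_res(x)
    if (is.null(r0)) return(NULL)
    J <- matrix(NA_real_, length(r0), length(x))
    typ <- if (length(x) == length(unknown_typical)) unknown_typical
           else rep(1, length(x))
    for (i in seq_along(x)) {
      h <- settings$fdStep * max(abs(x[i]), typ[i])
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      rp <- safe_res(xp)
      rm <- if (method == "central" || is.null(rp)) safe_res(xm) else NULL
      J[, i] <- if (!is.null(rp) && !is.null(rm)) (rp - rm) / (2 * h)
                else if (!is.null(rp)) (rp - r0) / h
                else if (!is.null(rm)) (r0 - rm) / h
                else return(NULL)
    }
    if (any(!is.finite(J))) NULL else J
  }

  for (it in seq_len(settings$maxIter)) {
    if (max(abs(r)) < settings$newtonTol)
      return(list(x = x, residuals = r, iterations = it - 1L,
                  converged = TRUE, trace = trace))
    if (is.null(J)) {
      J <- build_jac(x, if (central) "central" else "forward")
      if (is.null(J) && central) J <- build_jac(x, "forward")
      if (is.null(J))
        newton_failure("jacobian probing left the admissible region", trace)
      fresh <- TRUE
      if (!is.null(jac_env)) jac_env$J <- J
    }
    # column scaling by the typical unknown magnitudes keeps the linear solve
    # well conditioned (pressures are O(1e5) Pa, concentrations O(1) mM);
    # a truncated-SVD minimum-norm step keeps the near-null directions (a
    # pressure shift osmotically compensated to ~1 part in 1e6) from
    # dominating the update near convergence
    typ <- if (length(x) == length(unknown_typical)) unknown_typical
           else rep(1, length(x))
    dx <- tryCatch({
      sv <- svd(sweep(J, 2, typ, `*`))
      keep <- sv$d > 1e-14 * sv$d[1]
      typ * (sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], -r)) / sv$d[keep]))[, 1]
    }, error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      if (!fresh) { J <- NULL; next }
      newton_failure("singular Jacobian", trace)
    }
    lambda <- settings$damping
    accepted <- FALSE
    for (half in 1:12) {
      xn <- x + lambda * dx
      rn <- safe_res(xn)
      if (!is.null(rn) && all(is.finite(rn)) &&
          (max(abs(rn)) < max(abs(r)) || max(abs(rn)) < settings$newtonTol)) {
        x <- xn; r <- rn; accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    trace <- c(trace, max(abs(r)))
    if (!accepted) {
      if (!fresh) { J <- NULL; next }   # stale Jacobian: rebuild and retry
      if (!central) { central <- TRUE; J <- NULL; next }  # O(h^2) rescue
      newton_failure("step rejected after 12 halvings", trace)
    }
    # slow progress under a reused Jacobian: rebuild at the new iterate
    if (lambda < settings$damping || is.null(jac_env)) { J <- NULL }
    fresh <- FALSE
  }
  if (max(abs(r)) < settings$newtonTol)
    return(list(x = x, residuals = r, iterations = settings$maxIter,
                converged = TRUE, trace = trace))
  newton_failure(sprintf("no convergence in %d iterations", settings$maxIter), trace)
}

# One or two plain Newton steps with a fresh Jacobian, keeping the best
# iterate; used to polish a converged quasi-Newton solution.
polish_root <- function(residualFn, x, settings) {
  r <- tryCatch(residualFn(x), error = function(e) NULL)
  if (is.null(r)) return(x)
  typ <- if (length(x) == length(unknown_typical)) unknown_typical
         else rep(1, length(x))
  for (k in 1:2) {
    if (max(abs(r)) < 1e-14) break
    J <- tryCatch(
      finite_difference_jacobian(residualFn, x, settings$fdStep,
                                 unknown_typical, method = "forward"),
      error = function(e) NULL)
    if (is.null(J)) break
    dx <- tryCatch({
      sv <- svd(sweep(J, 2, typ, `*`))
      keep <- sv$d > 1e-14 * sv$d[1]
      typ * (sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], -r)) / sv$d[keep]))[, 1]
    }, error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) break
    xn <- x + dx
    rn <- tryCatch(residualFn(xn), error = function(e) NULL)
    if (is.null(rn) || !all(is.finite(rn)) || max(abs(rn)) >= max(abs(r))) break
    x <- xn; r <- rn
  }
  x
}

newton_failure <- function(msg, trace) {
  cond <- structure(class = c("proxtub_newton_failure", "error", "condition"),
                    list(message = paste0("Newton iteration failed: ", msg,
                                          " (last residuals: ",
                                          paste(signif(utils::tail(trace, 4), 3),
                                                collapse = ", "), ")"),
                         call = NULL, residual_trace = trace))
  stop(cond)
}

#' Default initial guess for the steady-state solver
#'
#' A physically admissible state: lis close to the serosal bath, cell with
#' low Na / high K, a -70 mV cell potential and a slightly hyperbaric lis.
#'
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @return Named unknown vector.
#' @export
default_initial_guess <- function(params, baths) {
  s <- baths$s
  c(cNaC = 15, cKC = 130, cClC = 25, cGlucC = max(baths$o[["Gluc"]], 0.1),
    cNaL = s[["Na"]], cKL = s[["K"]] * 1.02, cGlucL = max(0.8 * s[["Gluc"]], 1e-3),
    psiC = -0.07, psiL = -5e-4, psiO = -5e-4, pL = baths$pS + 50)
}

#' Solve the coupled nonlinear system for a steady state
#'
#' Damped Newton-Raphson on the 11 free unknowns with a finite-difference
#' Jacobian, iterated until the maximum scaled mass/charge/water balance
#' residual falls below `newtonTol`.
#'
#' @param params A [model_parameters()] object.
#' @param baths A [bath_composition()] object.
#' @param guess Initial unknown vector or `epithelial_state`; defaults to
#'   [default_initial_guess()].
#' @param settings A [solver_settings()] object.
#' @param Iclamp Transepithelial clamp current (A m^-2); 0 = open circuit.
#' @return The converged [complete_state()] with attributes `fluxes`
#'   (a flux set), `residuals` (scaled), and `iterations`.
#' @export
newton_steady_state <- function(params, baths, guess = NULL,
                                settings = solver_settings(), Iclamp = 0) {
  x0 <- if (is.null(guess)) default_initial_guess(params, baths)
        else if (inherits(guess, "epithelial_state")) state_vector(guess)
        else guess[state_unknowns]
  # Newton iterates on the raw balances divided by a frozen scale vector (the
  # gross compartment traffic at the current anchor point); the scale is
  # refreshed between outer rounds until the fully relative residual of
  # assemble_residuals() meets the tolerance.
  scale0 <- as.numeric(attr(assemble_residuals(x0, params, baths, Iclamp), "gross"))
  sol <- NULL
  for (round in 1:6) {
    resfun <- function(x)
      as.numeric(attr(assemble_residuals(x, params, baths, Iclamp), "raw")) / scale0
    sol <- newton_core(resfun, x0, settings)
    rel <- assemble_residuals(sol$x, params, baths, Iclamp)
    if (max(abs(rel)) < settings$newtonTol) break
    x0 <- sol$x
    scale0 <- as.numeric(attr(rel, "gross"))
  }
  res <- assemble_residuals(sol$x, params, baths, Iclamp)
  if (max(abs(res)) >= settings$newtonTol)
    newton_failure("relative residual above tolerance after rescaling rounds",
                   max(abs(res)))
  out <- attr(res, "state")
  attr(out, "fluxes") <- attr(res, "fluxes")
  attr(out, "residuals") <- res
  attr(out, "iterations") <- sol$iterations
  out
}

#' Fluxes of a solved state
#'
#' @param state A state returned by [newton_steady_state()] or stored in a
#'   transient history.
#' @return The attached flux set, or `NULL` if none.
#' @export
state_fluxes <- function(state) attr(state, "fluxes")

# --- transient integration --------------------------------------------------

# The integrated ("conserved") quantities: compartment volumes and
# volume-concentration products, per unit apical area.
conserved_quantities <- function(state) {
  c(mCNa = state$volC * state$cNaC, mCK = state$volC * state$cKC,
    mCCl = state$volC * state$cClC, mCGluc = state$volC * state$cGlucC,
    volC = state$volC,
    mLNa = state$volL * state$cNaL, mLK = state$volL * state$cKL,
    mLCl = state$volL * state$cClL, mLGluc = state$volL * state$cGlucL,
    volL = state$volL)
}

# Net accumulation rates matching conserved_quantities, from a flux set.
conserved_rates <- function(fl) {
  s <- fl$solute; w <- fl$water
  c(mCNa = s$am[["Na"]] - s$lm[["Na"]] - s$sm[["Na"]],
    mCK = s$am[["K"]] - s$lm[["K"]] - s$sm[["K"]],
    mCCl = s$am[["Cl"]] - s$lm[["Cl"]] - s$sm[["Cl"]],
    mCGluc = s$am[["Gluc"]] - s$lm[["Gluc"]] - s$sm[["Gluc"]],
    volC = w[["am"]] + w[["sglt1"]] - w[["lm"]] - w[["sm"]],
    mLNa = s$lm[["Na"]] + s$tj[["Na"]] - s$ibm[["Na"]],
    mLK = s$lm[["K"]] + s$tj[["K"]] - s$ibm[["K"]],
    mLCl = s$lm[["Cl"]] + s$tj[["Cl"]] - s$ibm[["Cl"]],
    mLGluc = s$lm[["Gluc"]] + s$tj[["Gluc"]] - s$ibm[["Gluc"]],
    volL = w[["lm"]] + w[["tj"]] - w[["ibm"]])
}

# Typical magnitudes for scaling the transient residuals.
conserved_floor <- c(rep(1e-9, 4), 1e-11, rep(1e-9, 4), 1e-11)

transient_residual <- function(x, params, baths, stencil, dt, Iclamp = 0,
                               scale = NULL) {
  state <- complete_state(x, params, baths)
  fl <- evaluate_fluxes(state, params, baths)
  Xn <- conserved_quantities(state)
  rate <- conserved_rates(fl)
  dXdt <- if (is.null(stencil$Xnm2)) {
    (Xn - stencil$Xnm1) / dt                         # backward Euler startup
  } else {
    (3 * Xn - 4 * stencil$Xnm1 + stencil$Xnm2) / (2 * dt)
  }
  raw <- c(dXdt - rate,
           open_circuit = open_circuit_residual(fl, Iclamp, params$constants))
  if (is.null(scale)) {
    gross_I <- params$constants$F *
      sum(abs(c(fl$solute$am[c("Na", "K", "Cl")], fl$solute$tj[c("Na", "K", "Cl")])))
    # the difference quotient cancels terms of size |X|/dt; scaling must stay
    # above the round-off floor of that cancellation or small steps from a
    # steady state can never meet the tolerance
    scale <- c(pmax(conserved_floor, abs(rate), abs(dXdt),
                    1e-2 * abs(stencil$Xnm1) / dt),
               max(1e-6, gross_I))
  }
  res <- raw / scale
  attr(res, "scale") <- scale
  attr(res, "state") <- state
  attr(res, "fluxes") <- fl
  res
}

#' Advance the transient solution by one implicit step
#'
#' Solves the second-order three-point backward-difference (BDF2) equations
#' `(3 X^n - 4 X^(n-1) + X^(n-2)) / (2 dt) = rates(X^n)` for the conserved
#' quantities (compartment volumes and volume-concentration products), coupled
#' with the algebraic constraints and the open-circuit condition, by the same
#' damped Newton iteration as the steady solver. With only one history level
#' available a backward-Euler (BDF1) startup step is taken.
#'
#' @param history A list of at least one record `list(time=, state=)`; the
#'   last two records supply the stencil.
#' @param params,baths Model parameters and (current) bath composition.
#' @param settings A [solver_settings()] object (`settings$dt` is the step).
#' @param jac_env Optional environment caching the Jacobian across steps.
#' @return The new [complete_state()] (with flux attribute) at
#'   `t = last time + dt`.
#' @export
bdf2_step <- function(history, params, baths, settings, jac_env = NULL) {
  n <- length(history)
  stopifnot(n >= 1)
  last <- history[[n]]$state
  stencil <- list(Xnm1 = conserved_quantities(last),
                  Xnm2 = if (n >= 2) conserved_quantities(history[[n - 1]]$state))
  x0 <- state_vector(last)
  scale0 <- attr(transient_residual(x0, params, baths, stencil, settings$dt),
                 "scale")
  resfun <- function(x)
    as.numeric(transient_residual(x, params, baths, stencil, settings$dt,
                                  scale = scale0))
  sol <- newton_core(resfun, x0, settings, jac_env = jac_env)
  # the reused-Jacobian iteration stops just under the tolerance; one or two
  # fresh full-Newton steps contract the per-step solution error to the
  # round-off floor so it cannot mask the O(dt^2) truncation error
  sol$x <- polish_root(resfun, sol$x, settings)
  res <- transient_residual(sol$x, params, baths, stencil, settings$dt)
  out <- attr(res, "state")
  attr(out, "fluxes") <- attr(res, "fluxes")
  out
}

#' Integrate the transient response to time-dependent baths
#'
#' Runs the BDF2 scheme from a steady (or supplied) initial state under a
#' piecewise-smooth bath forcing. The first 'refineUntil' seconds are resolved
#' with the finer step `refineDt` (fast forcings such as a tau = 1 ms
#' concentration step), then the scheme restarts on the coarse step `dt`.
#' After a step change of dt the first step of each phase is backward Euler.
#'
#' @param params A [model_parameters()] object.
#' @param baths_fn Either a [bath_composition()] (constant baths) or a
#'   function of time returning one.
#' @param horizon Final time (s).
#' @param settings A [solver_settings()] object.
#' @param init Initial state; default: steady state at `baths_fn(0)`.
#' @return An object of class `transient_history`: list with `times`,
#'   `states` (list of completed states with flux attributes) and `table`
#'   (data frame of state variables and key fluxes per step).
#' @export
run_transient <- function(params, baths_fn, horizon,
                          settings = solver_settings(), init = NULL) {
  bfun <- if (inherits(baths_fn, "bath_composition")) function(t) baths_fn else baths_fn
  if (is.null(init))
    init <- newton_steady_state(params, bfun(0), settings = settings)
  history <- list(list(time = 0, state = init))
  jac_env <- new.env()

  phases <- if (settings$refineUntil > 0 && settings$refineUntil < horizon) {
    list(c(settings$refineDt, min(settings$refineUntil, horizon)),
         c(settings$dt, horizon))
  } else list(c(settings$dt, horizon))

  t <- 0
  for (ph in phases) {
    dt <- ph[1]; tend <- ph[2]
    phase_start <- length(history)   # BDF1 restart at each phase boundary
    set <- settings; set$dt <- dt
    jac_env$J <- NULL
    while (t < tend - 1e-12) {
      nlev <- length(history) - phase_start + 1   # levels within this phase
      hist_window <- if (nlev >= 2) history[(length(history) - 1):length(history)]
                     else history[length(history)]
      tn <- t + dt
      st <- tryCatch(
        bdf2_step(hist_window, params, bfun(tn), set, jac_env = jac_env),
        proxtub_newton_failure = function(e) e)
      if (inherits(st, "condition")) {
        # first retry the same step with full (uncached) Newton, which keeps
        # the three-point stencil intact
        jac_env$J <- NULL
        st <- tryCatch(bdf2_step(hist_window, params, bfun(tn), set),
                       proxtub_newton_failure = function(e) e)
      }
      if (inherits(st, "condition")) {
        # bounded dt-halving retry with backward-Euler sub-steps
        st <- retry_substeps(history[[length(history)]]$state, params, bfun,
                             t, dt, set, depth = 4)
        jac_env$J <- NULL
        phase_start <- length(history) + 1  # next step restarts the stencil
      }
      t <- tn
      history[[length(history) + 1]] <- list(time = t, state = st)
    }
  }
  structure(list(times = vapply(history, `[[`, numeric(1), "time"),
                 states = lapply(history, `[[`, "state"),
                 table = history_table(history)),
            class = "transient_history")
}

# Cover the failing interval [t0, t0 + dt] with 2, 4, ... backward-Euler
# sub-steps (bounded retries), returning the state at t0 + dt.
retry_substeps <- function(state, params, bfun, t0, dt, settings, depth) {
  for (k in seq_len(depth)) {
    n <- 2^k
    sub <- settings; sub$dt <- dt / n
    st <- state
    ok <- TRUE
    for (j in seq_len(n)) {
      tj <- t0 + j * dt / n
      st <- tryCatch(
        bdf2_step(list(list(time = tj - dt / n, state = st)),
                  params, bfun(tj), sub),
        proxtub_newton_failure = function(e) e)
      if (inherits(st, "condition")) { ok <- FALSE; break }
    }
    if (ok) return(st)
  }
  stop("transient step failed even after dt halving")
}

history_table <- function(history) {
  rows <- lapply(history, function(rec) {
    st <- rec$state
    fl <- attr(st, "fluxes")
    base <- c(time = rec$time, unlist(st[c(state_unknowns, "cClL", "cAC", "pC",
                                           "volC", "volL", "osmC", "osmL")]))
    if (!is.null(fl)) {
      sol <- unlist(fl$solute)            # am.Na, am.K, ...
      base <- c(base, sol,
                JV = fl$water, JNaPump = fl$detail$pump[["Na"]],
                Ipump = fl$Ipump)
    }
    base
  })
  # the initial record may lack fluxes; align columns on the richest row
  nm <- names(rows[[which.max(lengths(rows))]])
  tab <- do.call(rbind, lapply(rows, function(r) {
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    out[names(r)] <- r
    out
  }))
  as.data.frame(tab)
}

#' @export
print.transient_history <- function(x, ...) {
  cat(sprintf("Transient history: %d records, t in [%g, %g] s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
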