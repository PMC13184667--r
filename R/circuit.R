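# Equivalent five-resistor bridge: lumped membrane resistances from chord
# conductances, branch currents under an injected transepithelial current step,
# and the resulting transepithelial potential change. Mapping: R1 = apical,
# R2 = serosal, R3 = lateral (the bridge arm between the cell and lis nodes),
# R4 = tight junction, R5 = interspace basement membrane, so that the two
# series paths are transcellular (R1 + R2) and paracellular (R4 + R5).

#' Lump per-pathway chord conductances into the five bridge resistances
#'
#' Each membrane resistance is the reciprocal of the summed chord conductances
#' of its ion pathways (channels, SGLT1, pump).
#'
#' @param fluxes A flux set from [evaluate_fluxes()].
#' @return Named vector `c(R1=, R2=, R3=, R4=, R5=)` (Ohm m^2):
#'   `R1` apical, `R2` serosal, `R3` lateral, `R4` tight junction, `R5`
#'   interspace basement membrane.
#' @export
lump_resistances <- function(fluxes) {
  G <- vapply(fluxes$conductance[c("am", "sm", "lm", "tj", "ibm")], sum, numeric(1))
  if (any(!is.finite(G)) || any(G <= 0))
    stop("every membrane needs a positive, finite total conductance")
  r <- 1 / G
  names(r) <- c("R1", "R2", "R3", "R4", "R5")
  r
}

#' Solve the bridge circuit for the branch currents
#'
#' Direct linear solve of the five Kirchhoff equations: two loop equations
#' (`I1 R1 + I3 R3 - I4 R4 = 0`, `I3 R3 + I5 R5 - I2 R2 = 0`), the source
#' condition `I2 + I5 = dItrans` and the two node laws `I1 = I2 + I3`,
#' `I4 = I3 + I5`. At Wheatstone balance (`R1 R5 = R2 R4`) the bridge current
#' `I3` vanishes.
#'
#' @param R Named vector `R1..R5` (Ohm m^2), all positive.
#' @param dItrans Injected transepithelial current step (A m^-2).
#' @return Object of class `bridge_circuit`: list with `R`, `dItrans`,
#'   branch currents `I` (`I1..I5`, A m^-2) and `Vtrans` (V).
#' @export
solve_bridge <- function(R, dItrans) {
  stopifnot(length(R) == 5, all(is.finite(R)), all(R > 0), is.finite(dItrans))
  R <- unname(R)
  A <- rbind(
    c(R[1],    0, R[3], -R[4],    0),
    c(0,   -R[2], R[3],     0, R[5]),
    c(0,       1,    0,     0,    1),
    c(1,      -1,   -1,     0,    0),
    c(0,       0,   -1,     1,   -1))
  b <- c(0, 0, dItrans, 0, 0)
  I <- tryCatch(solve(A, b), error = function(e)
    stop("singular bridge system: ", conditionMessage(e)))
  names(I) <- paste0("I", 1:5)
  Rn <- stats::setNames(R, paste0("R", 1:5))
  structure(list(R = Rn, dItrans = dItrans, I = I,
                 Vtrans = I[["I1"]] * R[1] + I[["I2"]] * R[2]),
            class = "bridge_circuit")
}

#' Transepithelial potential of a solved bridge
#'
#' `Vtrans = I1 R1 + I2 R2`, identical (to rounding) to `I4 R4 + I5 R5`.
#'
#' @param circuit A solved [solve_bridge()] object.
#' @return Potential (V).
#' @export
transepithelial_potential <- function(circuit) {
  if (!inherits(circuit, "bridge_circuit") || is.null(circuit$I))
    stop("circuit must be solved first (see solve_bridge)")
  with(circuit, {
    v1 <- I[["I1"]] * R[["R1"]] + I[["I2"]] * R[["R2"]]
    v2 <- I[["I4"]] * R[["R4"]] + I[["I5"]] * R[["R5"]]
    if (abs(v1 - v2) > 1e-9 * max(abs(v1), abs(v2), 1e-300))
      warning("bridge consistency identity violated beyond rounding")
    v1
  })
}

#' @export
print.bridge_circuit <- function(x, ...) {
  cat("Five-resistor bridge (Ohm m^2):\n  ")
  cat(sprintf("%s = %.4g", names(x$R), x$R), sep = "  ")
  cat(sprintf("\n  dItrans = %.4g A/m^2 -> Vtrans = %.4g mV\n",
              x$dItrans, 1e3 * x$Vtrans))
  invisible(x)
}
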