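#' Bath composition
#'
#' Luminal ("outer") and serosal ("inner") bathing solutions. Both baths are
#' well stirred and constant within one simulation; the serosal potential is
#' the electrical reference (psi_s = 0).
#'
#' @param Na,K,Cl,Gluc Luminal concentrations (mol m^-3 = mM).
#' @param Na_s,K_s,Cl_s,Gluc_s Serosal concentrations; default symmetric baths.
#' @param pO,pS Luminal and serosal hydrostatic pressures (Pa).
#' @return An object of class `bath_composition` with fields `o` and `s`
#'   (named concentration vectors), `pO`, `pS`, `psiS`.
#' @examples
#' b <- bath_composition()           # physiological saline with 6 mM glucose
#' bath_osmolarity(b, "s")           # 306 mosM
#' @export
bath_composition <- function(Na = 146, K = 4, Cl = 150, Gluc = 6,
                             Na_s = Na, K_s = K, Cl_s = Cl, Gluc_s = Gluc,
                             pO = atm_to_Pa(1), pS = atm_to_Pa(1)) {
  o <- c(Na = Na, K = K, Cl = Cl, Gluc = Gluc)
  s <- c(Na = Na_s, K = K_s, Cl = Cl_s, Gluc = Gluc_s)
  if (any(c(o, s) < 0)) stop("bath concentrations must be non-negative")
  structure(list(o = o, s = s, pO = pO, pS = pS, psiS = 0),
            class = "bath_composition")
}

#' Total osmolarity of a bath
#'
#' Sum of all solute concentrations (glucose counted as a full osmolyte).
#'
#' @param baths A [bath_composition()] object.
#' @param side `"o"` (luminal) or `"s"` (serosal).
#' @return Osmolarity (mosM = mol m^-3).
#' @export
bath_osmolarity <- function(baths, side = c("s", "o")) {
  side <- match.arg(side)
  sum(baths[[side]])
}

membranes <- c("am", "lm", "sm", "tj", "ibm")
species   <- c("Na", "K", "Cl", "Gluc")

#' Model parameter set for one epithelium instance
#'
#' Collects every physical constant, permeability, kinetic constant and
#' geometry/compliance value of the five-membrane model. Membrane wiring:
#' the apical membrane carries ENaC (conductive Na), the apical Na:K:2Cl
#' cotransporter, SGLT1 and AQP1 water; the lateral membrane carries the
#' Na/K pump, K and Cl channels, GLUT1 and water; the serosal membrane
#' carries K and Cl channels, the recirculation Na:K:2Cl carrier and water;
#' the tight junction passes Na and K by solvent-drag electrodiffusion
#' (Claudin-2), Cl by pure electrodiffusion (Claudin-17/10a, water
#' impermeable) and glucose convectively; the interspace basement membrane
#' passes all species by solvent-drag electrodiffusion / convection with a
#' low reflection coefficient.
#'
#' @param perm Nested list of ionic permeabilities (m s^-1):
#'   `am$Na`, `lm$K`, `lm$Cl`, `sm$K`, `sm$Cl`,
#'   `tj$Na`, `tj$K`, `tj$Cl`, `tj$Gluc`, `ibm$Na`, `ibm$K`, `ibm$Cl`,
#'   `ibm$Gluc`.
#' @param lp Named list/vector of hydraulic conductances (m s^-1 Pa^-1) for
#'   `am`, `lm`, `sm`, `tj`, `ibm`.
#' @param sigma List with named vectors `tj` and `ibm` of reflection
#'   coefficients for Na, K, Cl, Gluc (each in `[0, 1]`); cell membranes have
#'   an implicit reflection coefficient of 1.
#' @param pump A [pump_parameters()] object.
#' @param sglt1 An [sglt1_parameters()] object.
#' @param glut1 List with `Jmax` (mol m^-2 s^-1), `K` (mol m^-3) and `fLm`,
#'   the fraction of the basolateral carrier facing the lateral intercellular
#'   space (the remainder faces the serosal bath directly).
#' @param nak2cl List with apical rate `kAm` and serosal recirculation rate
#'   `kSm` (both in the units of [nak2cl_flux()]); `kSm = 0` in the
#'   non-recirculating reference state.
#' @param geometry List with compliance weights `muAm`, `muLm`, `muSm`
#'   (Pa^-1), reference lis volume `volLisRef` (m^3 m^-2), impermeant anion
#'   content `DcMA` (mol m^-2, the product of cell density and per-cell
#'   content), mean impermeant valence `zA` (< 0), and `volCRef` (m^3 m^-2),
#'   the fixed cell volume used only when `DcMA = 0` (impermeant-free cell).
#' @param temperature Absolute temperature (K).
#' @return An object of class `model_parameters`.
#' @seealso [reference_parameters()] for the calibrated fixture,
#'   [load_parameters()] / [save_parameters()] for file round-trips.
#' @export
model_parameters <- function(perm, lp, sigma, pump, sglt1, glut1, nak2cl,
                             geometry, temperature = 310) {
  p <- structure(list(
    temperature = temperature,
    constants = physical_constants(temperature),
    perm = perm, lp = lp, sigma = sigma, pump = pump, sglt1 = sglt1,
    glut1 = glut1, nak2cl = nak2cl, geometry = geometry
  ), class = "model_parameters")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  need <- list(am = "Na", lm = c("K", "Cl"), sm = c("K", "Cl"),
               tj = species, ibm = species)
  for (m in names(need)) {
    for (sp in need[[m]]) {
      v <- p$perm[[m]][[sp]]
      if (is.null(v) || !is.finite(v) || v < 0)
        stop(sprintf("permeability perm.%s.%s missing or negative", m, sp))
    }
  }
  lps <- unlist(p$lp[membranes])
  if (length(lps) != 5 || any(!is.finite(lps)) || any(lps < 0))
    stop("hydraulic conductances lp.{am,lm,sm,tj,ibm} must all be finite and >= 0")
  for (m in c("tj", "ibm")) {
    s <- unlist(p$sigma[[m]])[species]
    if (any(is.na(s)) || any(s < 0) || any(s > 1))
      stop(sprintf("reflection coefficients sigma.%s must be in [0, 1] for %s",
                   m, paste(species, collapse = ", ")))
  }
  stopifnot(p$pump$Ppump >= 0, p$pump$KNa > 0, p$pump$KK > 0)
  stopifnot(p$sglt1$Pmax >= 0, p$sglt1$Km > 0, p$sglt1$nW >= 0)
  stopifnot(p$glut1$Jmax >= 0, p$glut1$K > 0,
            p$glut1$fLm >= 0, p$glut1$fLm <= 1)
  stopifnot(p$nak2cl$kAm >= 0, p$nak2cl$kSm >= 0)
  g <- p$geometry
  stopifnot(g$muAm >= 0, g$muLm >= 0, g$muSm >= 0,
            g$muAm + g$muLm + g$muSm > 0,
            g$volLisRef > 0, g$DcMA >= 0, g$zA < 0)
  if (g$DcMA == 0 && (is.null(g$volCRef) || g$volCRef <= 0))
    stop("an impermeant-free cell (DcMA = 0) needs a positive volCRef")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Proximal-tubule epithelium parameters (per m^2 apical membrane)\n")
  cat(sprintf("  T = %g K;  Epump = %.1f mV;  Ppump = %.4g mol s^-1 V^-1 m^-2\n",
              x$temperature, 1e3 * x$pump$Epump, x$pump$Ppump))
  cat(sprintf("  SGLT1: Pmax = %.4g m/s, Km = %g mM, nW = %g\n",
              x$sglt1$Pmax, x$sglt1$Km, x$sglt1$nW))
  cat(sprintf("  cotransport: apical k = %.4g, serosal (recirculation) k = %.4g\n",
              x$nak2cl$kAm, x$nak2cl$kSm))
  for (m in membranes) {
    pm <- x$perm[[m]]
    cat(sprintf("  %-3s P(m/s): %s;  Lp = %.3g m s^-1 Pa^-1\n", m,
                paste(sprintf("%s=%.3g", names(pm), unlist(pm)), collapse = ", "),
                x$lp[[m]]))
  }
  invisible(x)
}

# Get / set a parameter by dotted path, e.g. "pump.Ppump" or "perm.lm.K".
# Used by the calibration machinery and the parameter file reader.
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- params
  for (pt in parts) {
    v <- v[[pt]]
    if (is.null(v)) stop(sprintf("unknown parameter path '%s'", path))
  }
  v
}

param_set <- function(params, path, value) {
  value <- unname(value)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- paste0("params", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  params$constants <- physical_constants(params$temperature)
  validate_parameters(params)
  params
}

#' Derived cell impermeant-anion content
#'
#' Product Dc * MA: the fixed amount of impermeant anion per unit apical area.
#' @param params A [model_parameters()] object.
#' @return mol m^-2.
#' @keywords internal
impermeant_content <- function(params) params$geometry$DcMA
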