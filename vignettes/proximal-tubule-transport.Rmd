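---
title: "An epithelial transport model of the proximal tubule S3 segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An epithelial transport model of the proximal tubule S3 segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxtub)
```

## The model

proxtub describes the S3 (straight) segment of the kidney proximal tubule as
a minimal epithelium: one lumped cell compartment (the "functional
syncytium") and one lateral intercellular space (lis), bathed on both sides
by well-stirred salines of Na⁺, K⁺, Cl⁻ and glucose, and bounded by five
membranes — apical (am), lateral (lm), serosal (sm), tight junction (tj) and
the interspace basement membrane (ibm). All quantities are per unit apical
membrane area, in MKSA units internally.

The transport machinery, membrane by membrane:

* **apical**: a conductive Na⁺ channel (ENaC, Goldman–Hodgkin–Katz
  electrodiffusion), an electroneutral 1Na:1K:2Cl cotransporter (mass-action
  drive on the ion product), SGLT1 (2Na⁺:1 glucose crossing a constant-field
  barrier as one divalent particle, with `nW` water molecules per glucose),
  and AQP1 water (reflection coefficient 1);
* **lateral**: the 3Na:2K ATPase with an explicit electromotive force
  `Epump` tied to the free energy of ATP hydrolysis (`Vrev = dG_ATP/3F`),
  K⁺ and Cl⁻ channels, a share of the basolateral GLUT1 carrier (Stein's
  symmetric saturating form), and water;
* **serosal**: K⁺ and Cl⁻ channels, the remaining GLUT1 share, an optional
  1Na:1K:2Cl recirculation carrier (off in the reference state), and water;
* **tight junction**: Na⁺ and K⁺ by Hertz solvent-drag electrodiffusion
  through the water-permeable claudin-2 pore, Cl⁻ by pure electrodiffusion
  (claudin-17/10a, water-impermeable), glucose convectively;
* **ibm**: all four species by solvent drag/convection with a low reflection
  coefficient (0.03), and a high hydraulic conductance.

The steady state is the root of eleven coupled balances: per-species mass
balances for cell and lis, two water balances, and the open-circuit
condition on the apical-side currents. Electroneutrality is enforced
*structurally*: the cell's impermeant-anion concentration is slaved to the
ionic charge surplus (`cAC = (cNa + cK - cCl)/(-zA)`), the cell volume to
the fixed impermeant content (`volC = Dc·MA / cAC`), and the lis Cl⁻ to its
cation sum. With those closures the Cl⁻ and water balances implicitly
determine the electrical potentials, so no separate charge ODE is needed,
and both electroneutrality identities hold to machine precision at every
iterate. The transepithelial potential is whatever value zeroes the summed
apical and junctional currents.

Transients integrate `d(vol)/dt` and `d(vol·C)/dt` for both compartments
with a three-point, second-order backward-difference scheme, the algebraic
closures applied at every time level; the first step of a run (or after a
step-size change) is backward Euler because the three-point stencil needs
two history levels.

### Sign conventions

Fluxes are positive in the transport direction: lumen→cell, cell→lis,
cell→serosa, lumen→lis, lis→serosa. Potentials are referenced to the
serosal bath. The GHK, Hertz and pump laws take the potential difference
ψ(I) − ψ(II) along the flux direction, which makes each law vanish exactly
at its thermodynamic equilibrium (Nernst, or `Vlm = -Epump` for the pump).
The SGLT1 functions are the one exception: they take the apical membrane
potential in the voltage-clamp convention (cell minus lumen, about −80 mV
at rest), because that is the convention in which its reversal potential
`Vrev = (RT/2F) ln(cGlucO·cNaO² / (cGlucC·cNaC²))` and its near-linear I–V
relation between −100 and −40 mV are stated.

## Parameters

Fixed constants (taken as given): T = 310 K; pump half-saturations
K_Na = 3.4 mM (cytosolic site) and K_K = 0.75 mM (lis site); SGLT1
self-inhibition constant 1.0 mM; tight-junction reflection coefficients
σ_Na = σ_K = 0.7, σ_Cl = 0.45, σ_glucose = 0.8; ibm reflection coefficients
0.03 for every species; bath composition 146/4/150 mM Na/K/Cl with 1–6 mM
glucose (306.0 mosM at 6 mM).

Everything else — membrane permeabilities, hydraulic conductances, the pump
rate coefficient, carrier capacities, compliance weights and geometry — is
the calibrated content of the packaged reference fixture
(`reference_parameters()`), produced by `calibrate_reference()`:
a bounded Levenberg–Marquardt least-squares fit of weighted relative
deviations between solved-state observables and the reference operating
point, run at two bath conditions (1 mM and 6 mM bilateral glucose) with
warm-started solves. The full parameter listing of the source model was
never published, so the fixture is this package's own construction,
anchored to literature-reported observables:

* at 1 mM glucose: pump flux ≈ 541 pmol cm⁻²s⁻¹, cell potential ≈ −78.5 mV,
  cell glucose ≈ 1.88 mM, lis volume ≈ 33 nL cm⁻², a slightly hyperbaric
  lis, ibm fluid flow ≈ 4.9 nL cm⁻²s⁻¹;
* at 6 mM glucose: cell Na/K/Cl ≈ 10/136/16 mM, cell volume ≈ 1022 nL cm⁻²,
  cell osmolarity ≈ 307 mosM, and — decisive for the science — an absorbate
  of ≈ 345 mosM leaving the ibm while the baths sit at 306 mosM.

Several deliberate structural choices shape the fixture:

* **GLUT1 faces both basolateral membranes.** The reported pre-step lis
  glucose (0.91 mM, *below* the 1.0 mM baths) is unreachable if all glucose
  leaving the cell enters the lis: the drag-dominated ibm cannot export
  hundreds of pmol against its gradient. A lateral fraction `fLm` of the
  carrier (calibrated ≈ 0.96 of capacity, but self-limited by the small
  cell–lis gradient) with the remainder facing the serosal bath makes the
  lis glucose a drag-dilution value, as reported.
* **zA = −0.95.** The mean impermeant valence follows from the reported cell
  composition: charge balance with Na/K/Cl of 9.87/136/16.3 mM and a total
  cell osmolarity of 307.1 mosM (glucose counted as a full osmolyte) pins
  `cAC ≈ 136 mM` and hence `zA ≈ −0.95`.
* **A large electroneutral apical NaK2Cl throughput.** Voltage-insensitive
  apical Na entry lets the pump respond to recirculation without being
  throttled by depolarisation, and gives the lateral Cl⁻ pathway a baseline
  load that can scale when the recirculation carrier is activated.
* **An open serosal water loop.** The serosal membrane's hydraulic
  conductance admits the water that accompanies recirculated ions
  (serosa → cell → lis); without it, recirculation concentrates instead of
  dilutes and no isosmotic point exists.

## What the reference epithelium reproduces — and what it does not

The packaged fixture, solved by the package itself, shows: a hyperosmotic
absorbate of ≈ 345 mosM at 6 mM glucose without recirculation; conversion
to an isosmotic 306 ± 0.1 mosM by tuning the serosal recirculation carrier,
at the cost of a higher pump flux and ATP rate, raised cell Cl⁻ and cell
swelling; monotonically rising cell Na⁺ and falling cell K⁺ as the pump EMF
is reduced from 200 to 100 mV; an SGLT1/AQP1 water crosstalk in which the
two apical water components vary inversely while the total exit flow
changes by only ~1–2% as `nW` sweeps 0–600; and transepithelial water
uptake that is linear in the active Na⁺ flux (R² > 0.999). The extra ATP
cost of isosmotic transport is positive and decreases with `nW`.

Known quantitative departures from the reference description, all
consequences of the unpublished parameter appendix and of faithfully
implemented reported kinetics:

* The SGLT1 self-inhibition permeability `P = Pmax·Km/(cGlucO + Km)` with
  Km = 1.0 mM caps the 6 mM/1 mM glucose-flux ratio near 1.7, so the pair
  of reported pump fluxes (541 at 1 mM, 1432 at 6 mM, ratio 2.6) cannot be
  met simultaneously; the fixture compromises at ≈ 880 and ≈ 1360.
  ATP-accounting magnitudes consequently differ while every direction and
  trend is preserved.
* The reported lis state (2.7 mosM above the serosal bath at ≈ +100–175 Pa)
  would give an *inward* ibm water flow under the stated reflection
  coefficient of 0.03; the solved lis therefore sits a little lower
  osmotically than reported.
* The isosmotic point requires a stronger recirculation flux than the
  reference description reports: the tuned cell swells by a comparable
  factor (≈ 1.5×) but accumulates more Cl⁻, and it is depolarised, which
  pins cell Cl⁻ well above the lateral-membrane equilibrium. Consequently
  volume-regulated anion channel (VRAC) activation — an increase of the
  lateral Cl⁻ permeability — recovers only part of the swelling;
  `vrac_activation()` documents its reachable range instead of promising a
  full return to the baseline volume.

Because the reference fixture *is* the study's synthetic data source, these
are the conditions under which all protocol tests run. Passing tests show
that the implemented physics produces the reference phenomenology under a
self-consistent parameterisation; they do not show that this particular
parameter set describes any real tubule, and none of the fixture's
magnitudes should be read as measurements.

## Numerics

* **Unknowns and scaling.** Eleven free unknowns (7 concentrations in mM,
  3 potentials in V, the lis pressure in Pa). Newton's method iterates on
  residuals divided by a frozen per-balance scale (the gross compartment
  traffic at the current anchor, refreshed between outer rounds), with the
  linear step column-scaled by typical magnitudes (1 mM, 1 mV, 100 Pa) and
  solved by truncated-SVD minimum-norm (cut at 1e-14 of the largest
  singular value): the system carries a genuinely stiff direction — a lis
  pressure shift osmotically compensated to about one part in 1e6.
* **Finite differences.** Jacobians use one-sided differences with relative
  step 1e-7 (floored by the typical magnitudes); when a fresh Jacobian step
  is rejected the solver escalates to central differences, and probes that
  leave the physically admissible region (possible exactly on the
  electroneutrality boundary of an impermeant-free cell) fall back to the
  opposite one-sided difference.
* **Convergence.** Default tolerance 1e-10 on the maximum scaled residual,
  which makes every per-compartment ledger close to better than one part in
  1e10 of its gross traffic. The root-finding protocols (isosmotic tuning,
  VRAC) solve their intermediate points at 1e-9 and fall back to 1e-7 close
  to the fold of the strongly swollen branch, where the Jacobian
  degenerates; bracketing there uses one-sided continuation in the tuned
  parameter so the tracked solution branch stays consistent.
* **Transients.** BDF2 with backward-Euler startup; each step reuses the
  previous Jacobian (quasi-Newton) and then polishes the converged point
  with one or two fresh full-Newton steps, so per-step solution noise stays
  far below the O(dt²) truncation error — the property-test measures an
  observed order of ≈ 2 by Richardson extrapolation on a smooth relaxation
  (dt = 0.25/0.125/0.0625 s over 2 s, sizes chosen to keep the suite
  fast). A failed cached step retries with full Newton before any
  dt-halving, which keeps the three-point stencil intact. Fast forcings
  (the τ = 1 ms glucose step) are resolved by an event-aligned refinement
  phase (dt = 0.1 ms for the first 10 ms).
* **Flux-law singularities.** All constant-field kernels switch to a
  three-term series expansion for |exponent| < 1e-6; chord conductances at
  their removable reversal singularity use a symmetric secant.
* **Degenerate inputs.** An impermeant-free cell (`DcMA = 0`) has no volume
  anchor and uses a fixed reference volume; this is the configuration in
  which a pump-free epithelium relaxes exactly to the bath composition.
  With impermeant content and the pump off, no steady state exists at all —
  the classical Donnan swelling catastrophe — which is why the "dead
  epithelium" tests use the impermeant-free variant.

## The bridge-circuit layer

The five-resistor bridge (apical, serosal, lateral, junctional and ibm
resistances lumped from the chord conductances of a solved state) is a
small-signal diagnostic: it answers how the transepithelial potential
responds to an injected current step. The five simultaneous equations
are solved directly in their stated form; their two loop laws and two
node laws are not sign-consistent with a single physical current-direction
convention, so the implementation treats the algebraic consequences that
*do* follow from the system — the equality of the two transepithelial
potential expressions, charge conservation at both nodes, and the vanishing
of the lateral arm at Wheatstone balance — as the binding contracts, and
checks the physical bounds (positive slope resistance, essentially the
paracellular series resistance for this leaky epithelium) only on circuits
lumped from solved model states.

## Worked example

```{r example, eval = FALSE}
params <- reference_parameters()
baths  <- bath_composition(Gluc = 6)        # 146/4/150/6 mM, 306 mosM

state <- newton_steady_state(params, baths)
state
absorbate_osmolarity(state_fluxes(state))   # ~345 mosM: hyperosmotic

tuned <- tune_isosmotic_recirculation(params, baths, tolerance = 0.1)
absorbate_osmolarity(state_fluxes(tuned$tuned))  # ~306 mosM: isosmotic
```

## Limitations

Beyond the calibration departures above: the model has no bicarbonate or
proton species (no NHE3), no axial gradients along the tubule, no
multi-cell spatial structure, no electrical capacitance (potentials are
instantaneous), and instantaneous water–solute coupling in SGLT1. The
recirculation and VRAC protocols operate on a lumped, well-stirred serosal
bath, so they cannot represent recapture of solutes within an unstirred
serosal layer.
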