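Package: proxtub
Title: Epithelial Transport Model of the Kidney Proximal Tubule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-membrane, two-internal-compartment model of ion, glucose,
    and water transport across the S3 segment of the kidney proximal tubule.
    Membrane fluxes follow Goldman-Hodgkin-Katz electrodiffusion, saturating
    carrier kinetics (SGLT1, GLUT1, Na:K:2Cl cotransport), an electrogenic
    3Na:2K ATPase with an explicit electromotive force tied to the free energy
    of ATP hydrolysis, Hertz solvent-drag electrodiffusion across the
    paracellular barriers, and Kedem-Katchalsky osmotic water flow. The coupled
    nonlinear steady-state and transient (BDF2) systems are solved by a damped
    Newton-Raphson method with finite-difference Jacobians. Protocol drivers
    reproduce in-silico experiments on isosmotic fluid reabsorption, ion
    recirculation through a serosal 1Na:1K:2Cl cotransporter, and the crosstalk
    between AQP1, SGLT1 and paracellular water pathways.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
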