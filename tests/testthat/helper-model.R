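# Small parameter sets built in code for the unit tests. toy_parameters() is a
# plausible but uncalibrated epithelium (fast to solve); dead_parameters() has
# no pump and no impermeant cell content, so the bath-equal state is an exact
# equilibrium.

toy_parameters <- function(Ppump = 3.9e-4, kSm = 0, nW = 264) {
  em <- epump_from_dg(-58e3)
  model_parameters(
    perm = list(
      am = list(Na = 3.6e-10),
      lm = list(K = 6e-7, Cl = 6e-9),
      sm = list(K = 2e-8, Cl = 3e-9),
      tj = list(Na = 1e-7, K = 1e-7, Cl = 1.5e-6, Gluc = 4e-7),
      ibm = list(Na = 2e-5, K = 2e-5, Cl = 2e-5, Gluc = 4e-7)),
    lp = list(am = 5e-12, lm = 1e-11, sm = 5e-12, tj = 4e-11, ibm = 7.4e-10),
    sigma = list(tj = c(Na = 0.7, K = 0.7, Cl = 0.45, Gluc = 0.8),
                 ibm = c(Na = 0.03, K = 0.03, Cl = 0.03, Gluc = 0.03)),
    pump = pump_parameters(Ppump = Ppump, Epump = em$Epump),
    sglt1 = sglt1_parameters(Pmax = 8e-11, Km = 1, nW = nW),
    glut1 = list(Jmax = 6e-5, K = 20, fLm = 0.05),
    nak2cl = list(kAm = 2e-14, kSm = kSm),
    geometry = list(muAm = 8e-4, muLm = 1.6e-3, muSm = 8e-4,
                    volLisRef = 3.2e-7, DcMA = 1.39e-3, zA = -0.95,
                    volCRef = 1e-5))
}

dead_parameters <- function() {
  p <- toy_parameters(Ppump = 0)
  p$pump$Epump <- 0
  p$geometry$DcMA <- 0
  p
}

# random admissible flux-law inputs for property tests
random_conc <- function(n, lo = 0.5, hi = 200) exp(stats::runif(n, log(lo), log(hi)))
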