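# Shared builders for synthetic test scenarios.

# Minimal noiseless two-order scenario planting the m/z-degenerate
# dimer 4+ / trimer 6+ pair.
degenerateScenario <- function(seed = 1L) {
  oligomerScenario(
    peptide = abeta40Spec(),
    abundanceByN = c("2" = 0.5, "3" = 0.5),
    chargeEnvelope = list("2" = c("4" = 1), "3" = c("6" = 1)),
    growthModel = "isotropic", growthParams = c(sigma_monomer = 680),
    noiseCv = 0, seed = seed)
}

# Single-compound helpers used across classifier tests.
testLigand <- function(id = "cpd", mass = 228.2, lMax = 4L, jMax = 6L) {
  ligandSpec(id, mass, lMax, jMax)
}

assignApoHolo <- function(scenario, binding, ligand) {
  pep <- scenario@peptide
  cal <- scenario@calibration
  apo <- simulateApo(scenario)
  holo <- simulateHolo(scenario, binding, ligand)
  apoAsg <- assignSpectrum(apo, pep, calibration = cal)
  prior <- growthPriorFromAssignment(apoAsg, pep, cal)
  list(
    apo = apoAsg,
    holo = assignSpectrum(holo, pep, ligand, calibration = cal,
                          growthPrior = prior))
}

# Exact truncated-renormalised Poisson pmf over 0..lMax.
truncPoisPmf <- function(lambda, lMax) {
  w <- dpois(0:lMax, lambda)
  w / sum(w)
}
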