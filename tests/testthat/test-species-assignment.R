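# Brute-force enumeration oracle: every (n, z, l) and ligand multimer (j, z)
# within tolerance, computed with explicit loops, independent of the
# vectorised grid used by the implementation.
oracleCandidates <- function(mz, peptide, ligand = NULL, tolPpm = 50) {
  hits <- 0
  found <- list()
  ls <- if (is.null(ligand)) 0 else 0:ligand@lMax
  for (n in 1:peptide@nMax)
    for (z in peptide@chargeRange[1]:peptide@chargeRange[2])
      for (l in ls) {
        lm <- if (is.null(ligand)) 0 else ligand@ligandMass
        th <- (n * peptide@monomerMass + l * lm + z * 1.007276) / z
        if (abs((mz - th) / th * 1e6) <= tolPpm)
          found[[length(found) + 1]] <- c(n = n, z = z, l = l)
      }
  if (!is.null(ligand))
    for (j in 1:ligand@jMax)
      for (z in 1:2) {
        th <- (j * ligand@ligandMass + z * 1.007276) / z
        if (abs((mz - th) / th * 1e6) <= tolPpm)
          found[[length(found) + 1]] <- c(j = j, z = z)
      }
  found
}

test_that("candidate enumeration matches the brute-force oracle", {
  pep <- peptideSpec("Abeta40", 4461, c(1L, 10L), 6L)
  lig <- testLigand(mass = 228.2)
  probes <- c(speciesMz(1, 1, 0, pep),               # singly charged monomer
              4461 / 2 + 1.007276,                   # degenerate family
              speciesMz(4, 7, 2, pep, lig),          # adducted tetramer
              multimerMz(3, 1, lig),                 # ligand trimer
              3000.0)                                # off-grid
  for (mz in probes) {
    cand <- enumerateCandidates(data.frame(mz = mz), pep, lig)
    expect_equal(nrow(cand), length(oracleCandidates(mz, pep, lig)),
                 info = paste("m/z", round(mz, 3)))
  }
})

test_that("the degenerate family and the unique monomer behave as expected", {
  pep <- peptideSpec("Abeta40", 4461, c(1L, 10L), 6L)
  cand <- enumerateCandidates(data.frame(mz = 4461 / 2 + 1.007276), pep)
  key <- paste(cand$n, cand$z)
  expect_true(all(c("2 4", "3 6") %in% key))
  # monomer 1+ sits on the (k, k) degeneracy family: every n = z species
  c1 <- enumerateCandidates(data.frame(mz = speciesMz(1, 1, 0, pep)), pep)
  expect_equal(nrow(c1), pep@nMax)
  expect_equal(c1$n, c1$z)
  # tetramer 7+ is coprime and its multiples leave the grid: unique match
  c47 <- enumerateCandidates(data.frame(mz = speciesMz(4, 7, 0, pep)), pep)
  expect_equal(nrow(c47), 1)
  expect_equal(c(c47$n, c47$z, c47$l), c(4, 7, 0))
  # far off any grid value
  c0 <- enumerateCandidates(data.frame(mz = speciesMz(1, 1, 0, pep) + 10), pep)
  expect_equal(nrow(c0), 0)
})

test_that("degeneracy resolution follows the drift-time evidence", {
  sc <- degenerateScenario()
  pk <- simulateApo(sc)
  tr <- attr(pk, "truth")
  pep <- abeta40Spec()
  prior <- new("GrowthFit", model = "isotropic",
               params = c(sigma_monomer = 680), rss = 0, aicc = NA_real_,
               selected = TRUE)
  for (i in 1:2) {
    cand <- enumerateCandidates(pk[i, ], pep)
    res <- resolveDegeneracy(cand, pk[i, ], pep,
                             calibration = sc@calibration,
                             growthPrior = prior)
    expect_equal(res$n, tr$n[i])
    expect_equal(res$z, tr$z[i])
    expect_false(res$degenerate)
  }
  # single candidate needs no drift information
  c1 <- enumerateCandidates(data.frame(mz = speciesMz(5, 7, 0, pep)), pep)
  r1 <- resolveDegeneracy(c1, data.frame(mz = 1, drift_time = 0,
                                         intensity = 1), pep)
  expect_equal(c(r1$n, r1$z), c(5, 7))
  # multiple candidates without a calibration cannot be resolved
  cand <- enumerateCandidates(pk[1, ], pep)
  r2 <- resolveDegeneracy(cand, pk[1, ], pep, calibration = NULL)
  expect_identical(r2$species_class, "unassigned")
  expect_true(r2$degenerate)
})

test_that("noiseless apo spectra are re-assigned perfectly", {
  sc <- defaultScenario(noiseCv = 0)
  pk <- simulateApo(sc)
  tr <- attr(pk, "truth")
  res <- assignSpectrum(pk, abeta40Spec(), calibration = sc@calibration)
  expect_equal(res$assignments$n, tr$n)
  expect_equal(res$assignments$z, tr$z)
  expect_true(all(res$assignments$species_class == "oligomer"))
  expect_true(all(abs(res$assignments$mass_error_ppm) < 1e-6))
  expect_equal(sum(res$oligomers), 1, tolerance = 1e-9)
})

test_that("assignment is invariant to peak-list ordering", {
  sc <- defaultScenario(noiseCv = 0.05, seed = 3L)
  pk <- simulateApo(sc)
  res1 <- assignSpectrum(pk, abeta40Spec(), calibration = sc@calibration)
  shuffled <- pk[withr::with_seed(1, sample(nrow(pk))), ]
  res2 <- assignSpectrum(shuffled, abeta40Spec(), calibration = sc@calibration)
  a1 <- res1$assignments[order(res1$assignments$mz,
                               res1$assignments$drift_time), ]
  a2 <- res2$assignments[order(res2$assignments$mz,
                               res2$assignments$drift_time), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("widening the tolerance never unassigns peaks", {
  sc <- defaultScenario(noiseCv = 0.05, seed = 8L)
  pk <- simulateApo(sc)
  nAssigned <- vapply(c(5, 20, 50, 200, 1000), function(tol) {
    res <- assignSpectrum(pk, abeta40Spec(),
                          config = assignmentConfig(tolerancePpm = tol),
                          calibration = sc@calibration)
    sum(res$assignments$species_class != "unassigned")
  }, numeric(1))
  expect_true(all(diff(nAssigned) >= 0))
})

test_that("ligand-only spectra are assigned as multimers", {
  lig <- testLigand(mass = 310.5, jMax = 5L)
  pep <- abeta40Spec()
  cal <- syntheticCalibration()
  mz <- multimerMz(2:5, 1, lig)
  # drifts consistent with compact (spherical) ligand aggregates, so the
  # j vs 2j/2+ degeneracy (e.g. dimer 1+ vs tetramer 2+) resolves correctly
  td <- invertCcs(predictSpherical(2:5, lig@ligandMass), mz, 1L,
                  (2:5) * lig@ligandMass, cal)
  pk <- data.frame(mz = mz, drift_time = td, intensity = c(4, 3, 2, 1))
  res <- assignSpectrum(pk, pep, lig, calibration = cal)
  expect_true(all(res$assignments$species_class == "ligand_multimer"))
  expect_equal(res$assignments$j, 2:5)
  expect_length(res$oligomers, 0)
})

test_that("the intensity floor suppresses weak peaks", {
  pep <- abeta40Spec()
  pk <- data.frame(mz = c(speciesMz(1, 3, 0, pep), speciesMz(1, 4, 0, pep)),
                   drift_time = c(4, 3), intensity = c(1000, 0.1))
  res <- assignSpectrum(pk, pep, config = assignmentConfig())
  expect_equal(nrow(res$assignments), 1)
  expect_equal(res$assignments$intensity, 1000)
  expect_error(assignSpectrum(pk[0, ], pep), "empty")
})
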