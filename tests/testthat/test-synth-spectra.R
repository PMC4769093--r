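test_that("noiseless apo spectra have analytically known peaks", {
  sc <- oligomerScenario(abeta40Spec(), c("1" = 1),
                         list("1" = c("3" = 0.6, "4" = 0.4)),
                         noiseCv = 0, seed = 1L)
  pk <- simulateApo(sc)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$mz),
               sort(speciesMz(1, 3:4, 0, abeta40Spec())))
  expect_equal(sort(pk$intensity), c(0.4, 0.6))
})

test_that("degenerate dimer 4+ / trimer 6+ peaks share m/z but not drift", {
  pk <- simulateApo(degenerateScenario())
  expect_equal(nrow(pk), 2)
  expect_equal(pk$mz[1], pk$mz[2])
  expect_gt(abs(pk$drift_time[1] - pk$drift_time[2]), 0.1)
  # higher order has lower reduced CCS hence shorter drift
  tr <- attr(pk, "truth")
  expect_lt(pk$drift_time[tr$n == 3], pk$drift_time[tr$n == 2])
})

test_that("generation is deterministic for a fixed seed", {
  sc <- defaultScenario(noiseCv = 0.1, seed = 99L)
  expect_identical(simulateApo(sc), simulateApo(sc))
  lig <- testLigand()
  b <- bindingScenario("non_specific")
  expect_identical(simulateHolo(sc, b, lig), simulateHolo(sc, b, lig))
  # different seed changes noisy intensities
  sc2 <- defaultScenario(noiseCv = 0.1, seed = 100L)
  expect_false(identical(simulateApo(sc)$intensity, simulateApo(sc2)$intensity))
})

test_that("drift time increases with CCS within a charge state", {
  sc <- defaultScenario(noiseCv = 0)
  pk <- simulateApo(sc)
  tr <- attr(pk, "truth")
  for (z in unique(tr$z)) {
    idx <- tr$z == z
    if (sum(idx) > 1) {
      ord <- order(tr$n[idx])
      expect_true(all(diff(pk$drift_time[idx][ord]) > 0))
    }
  }
})

test_that("negative binding reproduces the apo spectrum exactly", {
  sc <- defaultScenario(noiseCv = 0.05, seed = 5L)
  holo <- simulateHolo(sc, bindingScenario("negative"), testLigand())
  expect_identical(holo, simulateApo(sc))
})

test_that("specific binding plants exact binomial intensity ratios", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  holo <- simulateHolo(sc, bindingScenario("specific", nSites = 2,
                                           occupancy = 0.5), lig)
  tr <- attr(holo, "truth")
  m3 <- tr$n == 1 & tr$z == 3 & !is.na(tr$l)
  prof <- holo$intensity[m3][order(tr$l[m3])]
  expect_equal(prof[1:3] / prof[1], c(1, 2, 1))
})

test_that("non-specific binding plants a truncated Poisson: P(0) = P(1) at rate 1", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand(lMax = 4L)
  holo <- simulateHolo(sc, bindingScenario("non_specific", poissonRate = 1), lig)
  tr <- attr(holo, "truth")
  m3 <- tr$n == 1 & tr$z == 3
  i <- holo$intensity[m3][order(tr$l[m3])]
  expect_equal(i[1], i[2], tolerance = 1e-9)
  expect_equal(i / sum(i), truncPoisPmf(1, 4), tolerance = 1e-9)
})

test_that("adduct splitting conserves each charge state's ion current", {
  sc <- defaultScenario(noiseCv = 0)
  apo <- simulateApo(sc)
  trA <- attr(apo, "truth")
  lig <- testLigand()
  for (mode in c("specific", "non_specific")) {
    holo <- simulateHolo(sc, bindingScenario(mode), lig)
    trH <- attr(holo, "truth")
    for (z in 3:4) {
      apoI <- sum(apo$intensity[trA$n == 1 & trA$z == z])
      holoI <- sum(holo$intensity[trH$n == 1 & trH$z == z], na.rm = TRUE)
      expect_equal(holoI, apoI, tolerance = 1e-12)
    }
  }
})

test_that("specific-mode depletion removes oligomers above the cutoff", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  holo <- simulateHolo(sc, bindingScenario("specific", depletionFactor = 0,
                                           depletionCutoff = 3L), lig)
  tr <- attr(holo, "truth")
  expect_lte(max(tr$n, na.rm = TRUE), 3)
})

test_that("colloidal mode adds a ligand multimer series", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  holo <- simulateHolo(sc, bindingScenario("colloidal",
                                           colloidRange = c(2L, 5L)), lig)
  tr <- attr(holo, "truth")
  mult <- tr$species_class == "ligand_multimer"
  expect_equal(sort(tr$j[mult]), 2:5)
  expect_equal(holo$mz[mult][order(tr$j[mult])],
               multimerMz(2:5, 1L, lig))
  # geometric decay of the series
  i <- holo$intensity[mult][order(tr$j[mult])]
  expect_equal(i[-1] / i[-length(i)], rep(0.7, 3), tolerance = 1e-9)
})

test_that("simulateScreen is per-compound deterministic with unique ids", {
  sc <- defaultScenario(noiseCv = 0.05, seed = 11L)
  plate <- plateFromTable(focusedScreenPlate())
  sim1 <- simulateScreen(plate, sc)
  sim2 <- simulateScreen(plate, sc)
  expect_equal(length(sim1), 20)
  expect_identical(sim1, sim2)
  # all-negative plate equals apo under each compound's derived seed
  neg <- lapply(plate, function(x) list(ligand = x$ligand,
                                        binding = bindingScenario("negative")))
  simN <- simulateScreen(neg, sc)
  for (id in c("1", "14")) {
    scI <- sc
    scI@seed <- as.integer((sc@seed + amyloidIMS:::stringHash31(id)) %% 2147483647)
    expect_identical(simN[[id]], simulateApo(scI))
  }
  expect_error(simulateScreen(c(plate, plate[1]), sc), "duplicate")
})

test_that("scenario validity catches inconsistent abundance maps", {
  expect_error(oligomerScenario(abeta40Spec(), c("7" = 1),
                                list("7" = c("3" = 1))),
               "nMax")
  expect_error(oligomerScenario(abeta40Spec(), c("1" = 0.5),
                                list("1" = c("3" = 1))),
               "sum to 1")
})
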