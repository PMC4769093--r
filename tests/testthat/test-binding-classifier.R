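test_that("stoichiometry profiles are normalised and pool across charges", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  x <- assignApoHolo(sc, bindingScenario("specific", nSites = 2,
                                         occupancy = 0.5), lig)
  prof <- buildProfile(x$holo, lMax = lig@lMax)
  expect_equal(sum(pooledProfile(prof)), 1, tolerance = 1e-12)
  expect_equal(pooledProfile(prof)[1:3], c(0.25, 0.5, 0.25),
               tolerance = 1e-9)
  expect_true(all(abs(rowSums(prof@perCharge) - 1) < 1e-9))
})

test_that("a bare monomer peak gives the trivial profile", {
  a <- data.frame(mz = 1488, drift_time = 4, intensity = 10,
                  n = 1L, z = 3L, l = 0L, j = NA_integer_,
                  species_class = "oligomer", mass_error_ppm = 0,
                  degenerate = FALSE)
  prof <- buildProfile(a, lMax = 4L)
  expect_equal(pooledProfile(prof), c(1, 0, 0, 0, 0))
  expect_error(buildProfile(a[0, ], lMax = 4L), "no assigned")
})

test_that("binomial fits recover exact binomial profiles", {
  f3 <- fitBinomial(dbinom(0:4, 3, 0.3))
  expect_equal(unname(f3["N"]), 3)
  expect_equal(unname(f3["p"]), 0.3, tolerance = 1e-9)
  expect_lt(f3["rss"], 1e-18)
  f1 <- fitBinomial(dbinom(0:4, 1, 0.6))
  expect_equal(unname(f1["N"]), 1)
  expect_equal(unname(f1["p"]), 0.6, tolerance = 1e-9)
  # all mass at l = 0 is degenerate
  d <- fitBinomial(c(1, 0, 0, 0, 0))
  expect_true(attr(d, "degenerate"))
  expect_true(is.na(d["N"]))
})

test_that("truncated Poisson fits recover exact Poisson profiles", {
  fp <- fitPoisson(truncPoisPmf(1.0, 4))
  expect_equal(unname(fp["lambda"]), 1.0, tolerance = 1e-6)
  expect_lt(fp["rss"], 1e-18)
  d <- fitPoisson(c(1, 0, 0, 0, 0))
  expect_true(attr(d, "degenerate"))
  expect_equal(unname(d["lambda"]), 0)
})

test_that("each distribution family fits its own shape better", {
  # Poisson-shaped data: Poisson wins
  pois <- truncPoisPmf(0.8, 4)
  expect_gt(fitBinomial(pois)["rss"], fitPoisson(pois)["rss"])
  # strongly binomial data: binomial wins
  bino <- dbinom(0:4, 2, 0.9)
  expect_gt(fitPoisson(bino)["rss"], fitBinomial(bino)["rss"])
})

test_that("the binomial-Poisson margin shrinks toward the Poisson limit", {
  # Binomial(N, p) -> Poisson(Np) as N grows at fixed Np = 1
  margins <- vapply(c(2, 5, 10, 20), function(N) {
    prof <- dbinom(0:8, N, 1 / N)
    prof <- prof / sum(prof)
    abs(fitPoisson(prof)["rss"] - fitBinomial(prof)["rss"])
  }, numeric(1))
  expect_true(all(diff(margins) < 0))
})

test_that("classifier recovers every planted mode on noiseless data", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  for (mode in c("negative", "specific", "non_specific", "colloidal")) {
    x <- assignApoHolo(sc, bindingScenario(mode), lig)
    v <- classifyBinding(x$holo, x$apo, lig)
    expect_identical(bindingMode(v), mode)
  }
})

test_that("specific binding reports oligomer depletion against apo", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  x <- assignApoHolo(sc, bindingScenario("specific", nSites = 2,
                                         occupancy = 0.3,
                                         depletionFactor = 0), lig)
  v <- classifyBinding(x$holo, x$apo, lig)
  expect_identical(bindingMode(v), "specific")
  expect_equal(unname(v@binomialFit["N"]), 2)
  expect_equal(unname(v@binomialFit["p"]), 0.3, tolerance = 0.01)
  expect_lt(v@depletion["max_n_holo"], v@depletion["max_n_apo"])
  expect_lt(v@depletion["oligomer_fraction_holo"],
            v@depletion["oligomer_fraction_apo"])
})

test_that("bound fraction is invariant to uniform intensity rescaling", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  x <- assignApoHolo(sc, bindingScenario("non_specific"), lig)
  v1 <- classifyBinding(x$holo, x$apo, lig)
  scaled <- x$holo
  scaled$assignments$intensity <- scaled$assignments$intensity * 1e4
  v2 <- classifyBinding(scaled, x$apo, lig)
  expect_equal(boundFraction(v2), boundFraction(v1), tolerance = 1e-12)
  expect_identical(bindingMode(v2), bindingMode(v1))
})

test_that("a missing apo reference yields a verdict with a warning", {
  sc <- defaultScenario(noiseCv = 0)
  lig <- testLigand()
  x <- assignApoHolo(sc, bindingScenario("specific"), lig)
  expect_warning(v <- classifyBinding(x$holo, NULL, lig), "apo")
  expect_identical(bindingMode(v), "specific")
  expect_true(is.na(v@depletion["max_n_apo"]))
})

test_that("mode recovery holds under 5% intensity noise", {
  # lighter companion of the acceptance-scale study: 10 replicates per mode
  lig <- testLigand()
  for (mode in c("negative", "specific", "non_specific", "colloidal")) {
    hits <- sum(vapply(1:10, function(r) {
      sc <- defaultScenario(noiseCv = 0.05, seed = 2000L + r)
      x <- assignApoHolo(sc, bindingScenario(mode), lig)
      bindingMode(classifyBinding(x$holo, x$apo, lig)) == mode
    }, logical(1)))
    expect_gte(hits, 9)
  }
})
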