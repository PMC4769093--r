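#' Describe a synthetic oligomer spectrum scenario
#'
#' A scenario fixes everything needed to generate a reproducible synthetic
#' ESI-IMS-MS peak list: the peptide, the relative abundance of each oligomer
#' order, the charge states (with weights) each order populates, the growth
#' model that generates the "true" CCS of each order (and hence, through the
#' scenario calibration, its drift time), the multiplicative intensity noise
#' level, and the seed.
#'
#' @param peptide A \code{PeptideSpec}.
#' @param abundanceByN Named numeric vector, names are oligomer orders;
#'   non-negative, sums to 1.
#' @param chargeEnvelope Named list (same names as \code{abundanceByN});
#'   each element a named numeric vector of charge-state weights, names are
#'   charges.
#' @param growthModel One of \code{"isotropic"}, \code{"linear"},
#'   \code{"spherical"} — the true CCS-vs-n law of the scenario.
#' @param growthParams Named numeric: \code{sigma_monomer} (isotropic),
#'   \code{a} and \code{k} (linear), or \code{rho} (spherical).
#' @param noiseCv Coefficient of variation of multiplicative lognormal
#'   intensity noise; 0 disables noise.
#' @param seed Integer seed; generation is byte-identical for a fixed seed.
#' @param calibration The \linkS4class{CcsCalibration} used to turn true CCS
#'   values into drift times (and back, downstream).
#' @return An \code{OligomerScenario}.
#' @export
oligomerScenario <- function(peptide, abundanceByN, chargeEnvelope,
                             growthModel = "isotropic",
                             growthParams = c(sigma_monomer = 680),
                             noiseCv = 0, seed = 1L,
                             calibration = syntheticCalibration()) {
  new("OligomerScenario", peptide = peptide,
      abundanceByN = abundanceByN, chargeEnvelope = chargeEnvelope,
      growthModel = growthModel, growthParams = growthParams,
      noiseCv = as.numeric(noiseCv), seed = as.integer(seed),
      calibration = calibration)
}

#' Describe a planted ligand-binding signature
#'
#' The four binding modes leave distinct fingerprints in a native mass
#' spectrum: a specific binder distributes adduct intensity binomially over
#' its \code{nSites} sites; a non-specific binder adducts randomly during
#' ionisation, giving a (truncated) Poisson distribution; a colloidal
#' aggregator self-associates into ligand-only multimer series and sequesters
#' peptide into peptide+jL species; a negative compound leaves the spectrum
#' identical to the apo peptide.
#'
#' @param mode One of \code{"specific"}, \code{"non_specific"},
#'   \code{"colloidal"}, \code{"negative"}.
#' @param nSites Number of binding sites N (specific mode).
#' @param occupancy Per-site occupancy p in [0, 1] (specific mode).
#' @param poissonRate Mean adduct count lambda > 0 (non-specific mode).
#' @param colloidRange Inclusive integer range of ligand self-multimer
#'   orders j (colloidal mode).
#' @param depletionFactor Multiplier in [0, 1] applied to the abundances of
#'   oligomers above \code{depletionCutoff} (specific mode; 0 removes them,
#'   emulating inhibitors under which only low-order oligomers survive).
#' @param depletionCutoff Largest oligomer order left untouched by
#'   depletion.
#' @return A \code{BindingScenario}.
#' @export
bindingScenario <- function(mode, nSites = 2L, occupancy = 0.3,
                            poissonRate = 1.0, colloidRange = c(2L, 5L),
                            depletionFactor = 0, depletionCutoff = 3L) {
  new("BindingScenario", mode = mode, nSites = as.integer(nSites),
      occupancy = as.numeric(occupancy), poissonRate = as.numeric(poissonRate),
      colloidRange = as.integer(colloidRange),
      depletionFactor = as.numeric(depletionFactor),
      depletionCutoff = as.integer(depletionCutoff))
}

# True CCS of oligomer order n under the scenario's growth law.
scenarioCcs <- function(scenario, n) {
  p <- scenario@growthParams
  switch(scenario@growthModel,
    isotropic = predictIsotropic(n, p[["sigma_monomer"]]),
    linear = predictLinear(n, p[["a"]], p[["k"]]),
    spherical = predictSpherical(n, scenario@peptide@monomerMass,
                                 if ("rho" %in% names(p)) p[["rho"]] else 0.44))
}

# Lognormal multiplicative noise factors with unit mean and the given CV.
noiseFactors <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic skeleton of the apo spectrum: one row per (n, z) with mz,
# noiseless intensity, true ccs and drift time. Row order is fixed
# (ascending n, then z) so noise draws are reproducible.
apoSkeleton <- function(scenario) {
  pep <- scenario@peptide
  cal <- scenario@calibration
  rows <- list()
  for (nName in as.character(sort(as.integer(names(scenario@abundanceByN))))) {
    n <- as.integer(nName)
    env <- scenario@chargeEnvelope[[nName]]
    ab <- scenario@abundanceByN[[nName]]
    ccs <- scenarioCcs(scenario, n)
    for (zName in as.character(sort(as.integer(names(env))))) {
      z <- as.integer(zName)
      mz <- speciesMz(n, z, 0L, pep)
      td <- invertCcs(ccs, mz, z, n * pep@monomerMass, cal)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, z = z, mz = mz, drift_time = td,
        intensity = ab * env[[zName]], ccs = ccs)
    }
  }
  do.call(rbind, rows)
}

# Apply noise and strip truth columns, keeping planted (n, z, l) as
# attribute "truth" for oracle tests.
finishPeaks <- function(skel, scenario, seed = scenario@seed) {
  fac <- withSeed(seed, noiseFactors(nrow(skel), scenario@noiseCv))
  skel$intensity <- skel$intensity * fac
  peaks <- data.frame(mz = skel$mz, drift_time = skel$drift_time,
                      intensity = skel$intensity)
  truthCols <- intersect(c("n", "z", "l", "j", "species_class"), names(skel))
  attr(peaks, "truth") <- skel[truthCols]
  peaks
}

#' Simulate an apo (peptide-only) spectrum
#'
#' One peak per populated (oligomer order, charge) pair: m/z from the
#' protonation relation, intensity = oligomer abundance x charge weight x
#' multiplicative lognormal noise, drift time obtained by pushing the growth
#' model's true CCS through the inverse of the scenario calibration.
#'
#' The planted truth (n, z per peak) is attached as attribute
#' \code{"truth"} so downstream assignment can be validated against it.
#'
#' @param scenario An \linkS4class{OligomerScenario}.
#' @return data.frame of peaks (\code{mz}, \code{drift_time},
#'   \code{intensity}) with attribute \code{truth}.
#' @export
simulateApo <- function(scenario) {
  stopifnot(is(scenario, "OligomerScenario"))
  validObject(scenario)
  skel <- apoSkeleton(scenario)
  skel$l <- 0L
  skel$species_class <- "oligomer"
  finishPeaks(skel, scenario)
}

# Distribute the monomer charge-state peaks of a skeleton over ligand-adduct
# counts l = 0..lMax with the given pmf weights (sum 1), conserving the
# charge state's total intensity. CCS of a bound monomer is scaled by
# (bound mass / monomer mass)^(2/3): the adduct adds volume, not shape.
adductSplit <- function(skel, weights, scenario, ligand) {
  pep <- scenario@peptide
  cal <- scenario@calibration
  lVals <- seq_along(weights) - 1L
  mono <- skel[skel$n == 1L, , drop = FALSE]
  rest <- skel[skel$n != 1L, , drop = FALSE]
  if (nrow(rest)) {
    rest$l <- 0L
    rest$species_class <- "oligomer"
  } else {
    rest <- NULL
  }
  out <- list(rest)
  for (i in seq_len(nrow(mono))) {
    z <- mono$z[i]
    mass <- pep@monomerMass + lVals * ligand@ligandMass
    mz <- speciesMz(1L, z, lVals, pep, ligand)
    ccs <- mono$ccs[i] * (mass / pep@monomerMass)^(2 / 3)
    td <- invertCcs(ccs, mz, z, mass, cal)
    out[[length(out) + 1L]] <- data.frame(
      n = 1L, z = z, l = lVals, mz = mz, drift_time = td,
      intensity = mono$intensity[i] * weights, ccs = ccs,
      species_class = "oligomer")
  }
  res <- do.call(rbind, out)
  res[order(res$n, res$z, if (!is.null(res$l)) res$l else 0), , drop = FALSE]
}

#' Simulate a holo (peptide + compound) spectrum
#'
#' Applies the planted binding signature of \code{binding} to the apo
#' scenario. Ligand adducts are planted on monomer charge states (the
#' species on which adduct counts are read out); oligomer depletion scales
#' down the peaks of orders above the depletion cutoff. A colloidal compound
#' contributes ligand-only multimer ions jL (singly charged) with
#' geometrically decaying intensity and distributes monomer intensity over
#' peptide+jL adducts with the same decay; a negative compound returns
#' exactly the apo spectrum.
#'
#' @param scenario An \linkS4class{OligomerScenario}.
#' @param binding A \linkS4class{BindingScenario}.
#' @param ligand A \linkS4class{LigandSpec}.
#' @param colloidDecay Geometric decay ratio of colloidal multimer and
#'   adduct series intensities.
#' @param colloidIntensity Intensity of the first ligand multimer peak,
#'   as a fraction of the tallest apo peak.
#' @return data.frame of peaks with attribute \code{truth} (planted n, z,
#'   l, species class per peak).
#' @export
simulateHolo <- function(scenario, binding, ligand, colloidDecay = 0.7,
                         colloidIntensity = 0.3) {
  stopifnot(is(scenario, "OligomerScenario"), is(binding, "BindingScenario"),
            is(ligand, "LigandSpec"))
  validObject(scenario); validObject(binding); validObject(ligand)
  if (binding@mode == "negative") return(simulateApo(scenario))

  skel <- apoSkeleton(scenario)
  cal <- scenario@calibration

  if (binding@mode == "specific") {
    if (binding@nSites < 1) stop("specific mode needs nSites >= 1")
    if (binding@nSites > ligand@lMax)
      stop("nSites exceeds the ligand lMax")
    depleted <- skel$n > binding@depletionCutoff
    skel$intensity[depleted] <- skel$intensity[depleted] * binding@depletionFactor
    skel <- skel[skel$intensity > 0, , drop = FALSE]
    w <- stats::dbinom(0:ligand@lMax, binding@nSites, binding@occupancy)
    skel <- adductSplit(skel, w, scenario, ligand)
    skel$species_class <- "oligomer"
  } else if (binding@mode == "non_specific") {
    w <- stats::dpois(0:ligand@lMax, binding@poissonRate)
    w <- w / sum(w)  # truncated and renormalised: a proper distribution
    skel <- adductSplit(skel, w, scenario, ligand)
    skel$species_class <- "oligomer"
  } else if (binding@mode == "colloidal") {
    jAdduct <- 0:ligand@lMax
    w <- colloidDecay^jAdduct
    w <- w / sum(w)
    skel <- adductSplit(skel, w, scenario, ligand)
    skel$species_class <- "oligomer"
    base <- max(skel$intensity)
    js <- seq(binding@colloidRange[1], binding@colloidRange[2])
    mzJ <- multimerMz(js, 1L, ligand)
    ccsJ <- predictSpherical(js, ligand@ligandMass)
    tdJ <- invertCcs(ccsJ, mzJ, 1L, js * ligand@ligandMass, cal)
    mult <- data.frame(n = NA_integer_, z = 1L, l = NA_integer_, mz = mzJ,
                       drift_time = tdJ,
                       intensity = base * colloidIntensity *
                         colloidDecay^(js - js[1]),
                       ccs = ccsJ, species_class = "ligand_multimer")
    mult$j <- js
    skel$j <- NA_integer_
    skel <- rbind(skel, mult[names(skel)])
  }
  if (!"l" %in% names(skel)) skel$l <- 0L
  finishPeaks(skel, scenario)
}

#' Simulate a screening plate
#'
#' One synthetic holo spectrum per compound, with a per-compound seed
#' derived deterministically from the scenario seed and the compound id
#' (31-bit polynomial string hash), so plates are reproducible compound by
#' compound.
#'
#' @param plate List of per-compound entries, each a list with elements
#'   \code{ligand} (a \linkS4class{LigandSpec}) and \code{binding}
#'   (a \linkS4class{BindingScenario}). Compound ids must be unique.
#' @param scenario The shared apo \linkS4class{OligomerScenario}.
#' @inheritParams simulateHolo
#' @return Named list of peak-list data.frames, one per compound id.
#' @export
simulateScreen <- function(plate, scenario, colloidDecay = 0.7,
                           colloidIntensity = 0.3) {
  ids <- vapply(plate, function(x) x$ligand@compoundId, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound ids in plate")
  out <- vector("list", length(plate))
  names(out) <- ids
  for (i in seq_along(plate)) {
    sc <- scenario
    sc@seed <- as.integer((scenario@seed + stringHash31(ids[i])) %% 2147483647)
    out[[i]] <- simulateHolo(sc, plate[[i]]$binding, plate[[i]]$ligand,
                             colloidDecay = colloidDecay,
                             colloidIntensity = colloidIntensity)
  }
  out
}

#' Reference peptide and scenario constructors
#'
#' \code{abeta40Spec} describes recombinant Met-Abeta40 (the 40-residue
#' amyloid-beta peptide with an extra N-terminal methionine, average mass
#' 4461.0 Da), monomers predominantly 3+/4+ charged, oligomers considered up
#' to hexamer. \code{hiappSpec} describes human islet amyloid polypeptide
#' (average mass 3903.3 Da). \code{defaultScenario} builds the standard
#' synthetic apo condition used across the package: a monomer-dominated
#' oligomer ladder up to hexamer (abundances 0.55, 0.18, 0.11, 0.07, 0.05,
#' 0.04), two charge states per order including the m/z-degenerate dimer 4+
#' / trimer 6+ pair, isotropic growth truth with a 680 A^2 monomer CCS, and
#' the fixed synthetic calibration.
#'
#' @param chargeRange,nMax See [peptideSpec()].
#' @return A \code{PeptideSpec} or \code{OligomerScenario}.
#' @name referenceScenarios
NULL

#' @rdname referenceScenarios
#' @export
abeta40Spec <- function(chargeRange = c(2L, 10L), nMax = 6L) {
  peptideSpec("Abeta40", 4461.0, chargeRange, nMax)
}

#' @rdname referenceScenarios
#' @export
hiappSpec <- function(chargeRange = c(2L, 10L), nMax = 6L) {
  peptideSpec("hIAPP", 3903.3, chargeRange, nMax)
}

#' @rdname referenceScenarios
#' @param peptide Peptide the scenario is built around.
#' @param noiseCv,seed,calibration See [oligomerScenario()].
#' @export
defaultScenario <- function(peptide = abeta40Spec(), noiseCv = 0.05,
                            seed = 1L, calibration = syntheticCalibration()) {
  oligomerScenario(
    peptide = peptide,
    abundanceByN = c("1" = 0.55, "2" = 0.18, "3" = 0.11, "4" = 0.07,
                     "5" = 0.05, "6" = 0.04),
    chargeEnvelope = list(
      "1" = c("3" = 0.6, "4" = 0.4),
      "2" = c("4" = 0.5, "5" = 0.5),
      "3" = c("5" = 0.5, "6" = 0.5),
      "4" = c("6" = 0.5, "7" = 0.5),
      "5" = c("7" = 0.5, "8" = 0.5),
      "6" = c("8" = 0.5, "9" = 0.5)),
    growthModel = "isotropic",
    growthParams = c(sigma_monomer = 680),
    noiseCv = noiseCv, seed = seed, calibration = calibration)
}

#' The 20-compound focused screening plate
#'
#' Layout of the focused amyloid-beta inhibitor screen: 20 compounds with
#' synthetic ligand masses (the screen's real compound masses are not
#' tabulated anywhere reusable, so evenly spaced drug-like masses stand in),
#' the binding mode each compound shows against Abeta40 (compounds 3 and 16
#' specific, 9 colloidal, 15 and 17 non-specific, remainder negative) and
#' against hIAPP (identical except compound 3 non-specific and compound 9
#' negative).
#'
#' @return data.frame with columns \code{compound_id}, \code{well},
#'   \code{ligand_mass}, \code{mode_ab40}, \code{mode_hiapp}.
#' @export
focusedScreenPlate <- function() {
  id <- as.character(1:20)
  well <- paste0(rep(c("A", "B"), each = 12), 1:12)[1:20]
  mass <- 228.2 + 13.7 * (0:19)
  modeA <- rep("negative", 20)
  modeA[c(3, 16)] <- "specific"
  modeA[9] <- "colloidal"
  modeA[c(15, 17)] <- "non_specific"
  modeH <- modeA
  modeH[3] <- "non_specific"
  modeH[9] <- "negative"
  data.frame(compound_id = id, well = well, ligand_mass = mass,
             mode_ab40 = modeA, mode_hiapp = modeH,
             stringsAsFactors = FALSE)
}

#' Build a simulation plate from a compound table
#'
#' @param compounds data.frame with columns \code{compound_id},
#'   \code{ligand_mass} and a mode column (\code{modeColumn}) naming the
#'   planted binding mode per compound.
#' @param modeColumn Which column holds the planted modes.
#' @param lMax,jMax Passed to [ligandSpec()].
#' @return List of per-compound entries suitable for [simulateScreen()].
#' @export
plateFromTable <- function(compounds, modeColumn = "mode_ab40",
                           lMax = 4L, jMax = 6L) {
  lapply(seq_len(nrow(compounds)), function(i) {
    list(ligand = ligandSpec(compounds$compound_id[i],
                             compounds$ligand_mass[i], lMax, jMax),
         binding = bindingScenario(compounds[[modeColumn]][i]))
  })
}
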