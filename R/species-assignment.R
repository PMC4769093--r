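#' Assignment configuration
#'
#' @param tolerancePpm m/z matching tolerance in parts per million. The
#'   default of 50 ppm is loose enough for average-mass arithmetic on
#'   quadrupole-time-of-flight envelopes.
#' @param driftConsistencyWeight Weight of the drift-time term when ranking
#'   degenerate candidates (reserved; candidates are currently ranked by
#'   absolute drift-time residual).
#' @param minRelIntensity Peaks below this fraction of the base peak are
#'   ignored (noise floor), default 0.5\%.
#' @param colloidThreshold Summed ligand-multimer intensity (relative to the
#'   base peak) above which a compound is called colloidal, default 2\%.
#' @param bindThreshold Bound fraction below which a compound is called
#'   negative, default 5\%.
#' @return An \code{AssignmentConfig}.
#' @export
assignmentConfig <- function(tolerancePpm = 50, driftConsistencyWeight = 1,
                             minRelIntensity = 0.005,
                             colloidThreshold = 0.02, bindThreshold = 0.05) {
  new("AssignmentConfig", tolerancePpm = tolerancePpm,
      driftConsistencyWeight = driftConsistencyWeight,
      minRelIntensity = minRelIntensity,
      colloidThreshold = colloidThreshold, bindThreshold = bindThreshold)
}

# Full theoretical species grid for a peptide/ligand pair: every
# (n, z, l) oligomer-adduct combination plus ligand self-multimers
# (j, z in 1..2). One row per species with its m/z and neutral mass.
candidateGrid <- function(peptide, ligand = NULL, config = assignmentConfig()) {
  zs <- seq(peptide@chargeRange[1], peptide@chargeRange[2])
  ls <- if (is.null(ligand)) 0L else 0:ligand@lMax
  g <- expand.grid(n = seq_len(peptide@nMax), z = zs, l = ls,
                   KEEP.OUT.ATTRS = FALSE)
  lMass <- if (is.null(ligand)) 0 else ligand@ligandMass
  g$mass <- g$n * peptide@monomerMass + g$l * lMass
  g$mz <- (g$mass + g$z * PROTON_MASS) / g$z
  g$species_class <- "oligomer"
  g$j <- NA_integer_
  if (!is.null(ligand) && ligand@jMax >= 1) {
    m <- expand.grid(j = seq_len(ligand@jMax), z = 1:2,
                     KEEP.OUT.ATTRS = FALSE)
    m$n <- NA_integer_
    m$l <- NA_integer_
    m$mass <- m$j * ligand@ligandMass
    m$mz <- (m$mass + m$z * PROTON_MASS) / m$z
    m$species_class <- "ligand_multimer"
    g <- rbind(g, m[names(g)])
  }
  g
}

#' Enumerate candidate species for one peak
#'
#' All (n, z, l) oligomer-adduct combinations and ligand self-multimers
#' whose theoretical m/z lies within the ppm tolerance of the observed peak.
#' An m/z-degenerate peak (e.g. dimer 4+ / trimer 6+) yields several
#' candidates; an empty result means the peak matches nothing on the grid.
#'
#' @param peak One-row data.frame (or list) with \code{mz}.
#' @param peptide A \code{PeptideSpec}.
#' @param ligand A \code{LigandSpec} or NULL.
#' @param config An \code{AssignmentConfig}.
#' @return data.frame of candidates with columns \code{n}, \code{z},
#'   \code{l}, \code{j}, \code{species_class}, \code{mass_error_ppm},
#'   \code{mz_theory}, \code{mass}.
#' @export
enumerateCandidates <- function(peak, peptide, ligand = NULL,
                                config = assignmentConfig()) {
  grid <- candidateGrid(peptide, ligand, config)
  matchCandidates(peak$mz[1], grid, config@tolerancePpm)
}

matchCandidates <- function(mzObs, grid, tolerancePpm) {
  ppm <- (mzObs - grid$mz) / grid$mz * 1e6
  hit <- abs(ppm) <= tolerancePpm
  out <- grid[hit, c("n", "z", "l", "j", "species_class"), drop = FALSE]
  out$mass_error_ppm <- ppm[hit]
  out$mz_theory <- grid$mz[hit]
  out$mass <- grid$mass[hit]
  rownames(out) <- NULL
  out
}

# Growth prior anchored on unambiguous peaks. Peaks matching exactly one
# grid species carry label-independent CCS information: their estimated CCS
# (scaled back to the bare oligomer by removing the adduct-mass contribution)
# anchors the CCS-vs-n law used to resolve the ambiguous, m/z-degenerate
# peaks. With anchors at >= 3 distinct orders the full model comparison is
# fitted; with fewer the isotropic scale has a closed-form estimate; with
# none the function returns NULL (callers fall back to the spherical-seeded
# default prior).
anchorPrior <- function(peaks, grid, peptide, config, calibration) {
  anch <- list()
  for (i in seq_len(nrow(peaks))) {
    cand <- matchCandidates(peaks$mz[i], grid, config@tolerancePpm)
    if (nrow(cand) == 1 && cand$species_class == "oligomer") {
      ccs <- estimateCcs(peaks$drift_time[i], peaks$mz[i], cand$z, cand$mass,
                         calibration)
      bare <- ccs / (cand$mass / (cand$n * peptide@monomerMass))^(2 / 3)
      anch[[length(anch) + 1L]] <-
        data.frame(n = cand$n, ccs = bare, intensity = peaks$intensity[i])
    }
  }
  if (!length(anch)) return(NULL)
  anch <- do.call(rbind, anch)
  if (length(unique(anch$n)) >= 3) {
    ser <- do.call(rbind, lapply(split(anch, anch$n), function(s)
      s[which.max(s$intensity), c("n", "ccs")]))
    return(fitGrowth(ser, peptide@monomerMass))
  }
  sig <- sum(anch$ccs * anch$n^(2 / 3)) / sum(anch$n^(4 / 3))
  new("GrowthFit", model = "isotropic", params = c(sigma_monomer = sig),
      rss = 0, aicc = NA_real_, selected = TRUE)
}

# CCS predicted for a candidate row under a growth prior. With no prior
# supplied, the monomer CCS is seeded from the fixed-density spherical model
# and scaled isotropically (n^(2/3)); ligand adducts scale the CCS by
# (total mass / bare oligomer mass)^(2/3). Ligand multimers always use the
# spherical model on their own mass.
candidateCcs <- function(cand, peptide, ligand, growthPrior) {
  bare <- function(n) {
    if (is.null(growthPrior))
      return(predictSpherical(1, peptide@monomerMass) * n^(2 / 3))
    fit <- growthPrior
    if (is(fit, "GrowthModelComparison")) fit <- fit@fits[[fit@selected]]
    p <- fit@params
    switch(fit@model,
      isotropic = predictIsotropic(n, p[["sigma_monomer"]]),
      linear = predictLinear(n, p[["a"]], p[["k"]]),
      spherical = predictSpherical(n, peptide@monomerMass, p[["rho"]]))
  }
  vapply(seq_len(nrow(cand)), function(i) {
    if (cand$species_class[i] == "ligand_multimer")
      return(predictSpherical(cand$j[i], ligand@ligandMass))
    ccs <- bare(cand$n[i])
    ccs * (cand$mass[i] / (cand$n[i] * peptide@monomerMass))^(2 / 3)
  }, numeric(1))
}

#' Resolve an m/z-degenerate candidate set with drift time
#'
#' When several species share a peak's m/z, their predicted drift times
#' differ (the reduced CCS falls with charge along a degeneracy family), so
#' the ion mobility dimension separates them: each candidate's CCS is
#' predicted from the growth prior, converted to a drift time through the
#' calibration inverse, and the candidate nearest the observed drift wins.
#' Ties break toward smaller oligomer order (parsimony).
#'
#' @param candidates Output of [enumerateCandidates()].
#' @param peak One-row data.frame with \code{mz}, \code{drift_time},
#'   \code{intensity}.
#' @param peptide,ligand Species descriptions.
#' @param calibration A \linkS4class{CcsCalibration}, or NULL. With no
#'   calibration a multi-candidate peak cannot be resolved and is returned
#'   unassigned with \code{degenerate = TRUE}.
#' @param growthPrior A \linkS4class{GrowthFit} /
#'   \linkS4class{GrowthModelComparison} giving expected CCS vs n, or NULL
#'   for the default prior (spherical-seeded isotropic; see Details in the
#'   package vignette).
#' @return One-row data.frame: \code{n}, \code{z}, \code{l},
#'   \code{species_class}, \code{mass_error_ppm}, \code{degenerate}.
#' @export
resolveDegeneracy <- function(candidates, peak, peptide, ligand = NULL,
                              calibration = NULL, growthPrior = NULL) {
  unassigned <- function(flag) data.frame(
    n = NA_integer_, z = NA_integer_, l = NA_integer_, j = NA_integer_,
    species_class = "unassigned", mass_error_ppm = NA_real_,
    degenerate = flag)
  if (nrow(candidates) == 0) return(unassigned(FALSE))
  if (nrow(candidates) == 1) {
    c1 <- candidates
  } else {
    if (is.null(calibration)) return(unassigned(TRUE))
    ccs <- candidateCcs(candidates, peptide, ligand, growthPrior)
    td <- invertCcs(ccs, candidates$mz_theory, candidates$z,
                    candidates$mass, calibration)
    resid <- abs(td - peak$drift_time[1])
    ord <- order(resid, candidates$n)  # ties toward smaller n
    c1 <- candidates[ord[1], , drop = FALSE]
  }
  data.frame(n = c1$n, z = c1$z, l = c1$l, j = c1$j,
             species_class = c1$species_class,
             mass_error_ppm = c1$mass_error_ppm, degenerate = FALSE)
}

#' Assign every peak of a spectrum to a species
#'
#' Peaks below the relative-intensity floor are dropped; each remaining peak
#' is matched against the theoretical species grid and degeneracies are
#' resolved by drift time. When a calibration is supplied but no growth
#' prior, the prior is first anchored on the spectrum's unambiguous
#' (single-candidate) peaks, whose estimated CCS values pin down the
#' CCS-vs-n law before the degenerate peaks are resolved against it. A
#' summary table of relative oligomer abundances
#' (summed assigned intensity per oligomer order, normalised to 1) is
#' attached.
#'
#' @param peaks data.frame of peaks (\code{mz}, \code{drift_time},
#'   \code{intensity}).
#' @inheritParams resolveDegeneracy
#' @param config An \code{AssignmentConfig}.
#' @return List with elements \code{assignments} (data.frame: peak columns
#'   plus \code{n}, \code{z}, \code{l}, \code{species_class},
#'   \code{mass_error_ppm}, \code{degenerate}) and \code{oligomers} (named
#'   numeric: relative abundance by oligomer order, summing to 1).
#' @export
assignSpectrum <- function(peaks, peptide, ligand = NULL,
                           config = assignmentConfig(), calibration = NULL,
                           growthPrior = NULL) {
  if (nrow(peaks) == 0) stop("empty peak list")
  floorAbs <- config@minRelIntensity * max(peaks$intensity)
  kept <- peaks[peaks$intensity >= floorAbs, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("all peaks fall below the relative-intensity floor")
    return(list(assignments = data.frame(), oligomers = numeric()))
  }
  grid <- candidateGrid(peptide, ligand, config)
  if (is.null(growthPrior) && !is.null(calibration))
    growthPrior <- anchorPrior(kept, grid, peptide, config, calibration)
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    cand <- matchCandidates(kept$mz[i], grid, config@tolerancePpm)
    res <- resolveDegeneracy(cand, kept[i, ], peptide, ligand,
                             calibration, growthPrior)
    cbind(kept[i, c("mz", "drift_time", "intensity")], res)
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  olig <- assignments[assignments$species_class == "oligomer", , drop = FALSE]
  oligomers <- numeric()
  if (nrow(olig)) {
    tot <- tapply(olig$intensity, olig$n, sum)
    oligomers <- as.numeric(tot) / sum(tot)
    names(oligomers) <- names(tot)
  }
  list(assignments = assignments, oligomers = oligomers)
}

#' CCS series and growth prior from an assigned spectrum
#'
#' \code{oligomerCcsSeries} estimates one CCS per assigned oligomer order
#' (bare peaks only, lowest observed charge state per order, most intense
#' peak on ties), the conventional series for growth-model analysis.
#' \code{growthPriorFromAssignment} fits the growth-model comparison to that
#' series, giving a data-derived CCS-vs-n prior; assigning an apo reference
#' first and feeding its prior into the assignment of ligand-bound spectra
#' (whose oligomer-depleted peak sets may lack unambiguous anchor peaks)
#' makes degeneracy resolution consistent across a screen.
#'
#' @param assignments Output of [assignSpectrum()] (list or data.frame).
#' @param peptide A \code{PeptideSpec}.
#' @param calibration The \linkS4class{CcsCalibration} used in assignment.
#' @return \code{oligomerCcsSeries}: data.frame (\code{n}, \code{ccs},
#'   \code{z}); \code{growthPriorFromAssignment}: a
#'   \linkS4class{GrowthModelComparison}, or NULL if fewer than 3 orders are
#'   available.
#' @export
oligomerCcsSeries <- function(assignments, peptide, calibration) {
  a <- if (is.list(assignments) && !is.data.frame(assignments))
    assignments$assignments else assignments
  olig <- a[a$species_class == "oligomer" & !is.na(a$l) & a$l == 0, ,
            drop = FALSE]
  if (nrow(olig) == 0) return(data.frame(n = integer(), ccs = numeric(),
                                         z = integer()))
  rows <- lapply(split(olig, olig$n), function(s) {
    s <- s[s$z == min(s$z), , drop = FALSE]
    s[which.max(s$intensity), , drop = FALSE]
  })
  do.call(rbind, lapply(rows, function(r) data.frame(
    n = r$n,
    ccs = estimateCcs(r$drift_time, r$mz, r$z, r$n * peptide@monomerMass,
                      calibration),
    z = r$z)))
}

#' @rdname oligomerCcsSeries
#' @export
growthPriorFromAssignment <- function(assignments, peptide, calibration) {
  ser <- oligomerCcsSeries(assignments, peptide, calibration)
  if (nrow(ser) < 3) return(NULL)
  fitGrowth(ser, peptide@monomerMass)
}

#' Write species assignments as CSV
#'
#' @param assignments The \code{assignments} element of [assignSpectrum()]
#'   output.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}
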