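#' Ligand-adduct stoichiometry profile
#'
#' Normalised intensity over the number of bound ligands l = 0..lMax, per
#' peptide charge state and pooled (intensity-weighted mean over charge
#' states). Profiles are built on monomer charge states by default: adduct
#' counts are read out on the monomer ions, and higher oligomers of the
#' screened amyloid peptides are not themselves observed to bind.
#'
#' @param assignments Output of [assignSpectrum()] (the list or its
#'   \code{assignments} data.frame).
#' @param lMax Largest adduct count of the profile support.
#' @param monomerOnly Restrict to monomer (n = 1) charge states.
#' @return A \linkS4class{StoichiometryProfile}.
#' @export
buildProfile <- function(assignments, lMax, monomerOnly = TRUE) {
  a <- if (is.list(assignments) && !is.data.frame(assignments))
    assignments$assignments else assignments
  pep <- a[a$species_class == "oligomer" & !is.na(a$l), , drop = FALSE]
  if (monomerOnly) pep <- pep[pep$n == 1L, , drop = FALSE]
  if (nrow(pep) == 0) stop("no assigned peptide peaks to profile")
  lMax <- as.integer(lMax)
  zs <- sort(unique(pep$z))
  perCharge <- matrix(0, nrow = length(zs), ncol = lMax + 1,
                      dimnames = list(zs, 0:lMax))
  weight <- numeric(length(zs))
  for (i in seq_along(zs)) {
    sub <- pep[pep$z == zs[i], , drop = FALSE]
    v <- numeric(lMax + 1)
    for (r in seq_len(nrow(sub))) {
      li <- sub$l[r]
      if (li <= lMax) v[li + 1] <- v[li + 1] + sub$intensity[r]
    }
    weight[i] <- sum(v)
    perCharge[i, ] <- if (weight[i] > 0) v / weight[i] else v
  }
  keep <- weight > 0
  perCharge <- perCharge[keep, , drop = FALSE]
  weight <- weight[keep]
  pooled <- as.numeric(colSums(perCharge * (weight / sum(weight))))
  pooled <- pooled / sum(pooled)
  new("StoichiometryProfile", perCharge = perCharge, pooled = pooled,
      lMax = lMax)
}

profileVector <- function(profile) {
  if (is(profile, "StoichiometryProfile")) profile@pooled else {
    p <- as.numeric(profile)
    p / sum(p)
  }
}

#' Fit a binomial adduct-count distribution
#'
#' Specific binding at N equivalent sites with per-site occupancy p gives
#' adduct counts distributed Binomial(N, p). N is searched over the integers
#' 1..lMax; for each N the occupancy has the closed-form estimate
#' p = mean(l) / N, and the (N, p) pair with the lowest residual sum of
#' squares against the observed profile is returned.
#'
#' @param profile A \linkS4class{StoichiometryProfile} or a numeric profile
#'   over l = 0..lMax (normalised internally).
#' @return Named numeric \code{c(N, p, rss)}; if the profile has all its
#'   mass at l = 0 the fit is degenerate (attribute \code{degenerate}, N is
#'   NA).
#' @export
fitBinomial <- function(profile) {
  p <- profileVector(profile)
  lMax <- length(p) - 1L
  meanL <- sum((0:lMax) * p)
  if (meanL == 0) {
    out <- c(N = NA_real_, p = 0, rss = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  best <- NULL
  for (N in seq_len(lMax)) {
    ph <- min(meanL / N, 1)
    pmf <- stats::dbinom(0:lMax, N, ph)
    rss <- sum((p - pmf)^2)
    if (is.null(best) || rss < best["rss"] - 1e-15)
      best <- c(N = N, p = ph, rss = rss)
  }
  attr(best, "degenerate") <- FALSE
  best
}

# Mean of a Poisson truncated to 0..lMax, as a function of lambda.
truncPoisMean <- function(lambda, lMax) {
  w <- stats::dpois(0:lMax, lambda)
  sum((0:lMax) * w) / sum(w)
}

#' Fit a truncated Poisson adduct-count distribution
#'
#' Non-specific adduction during ionisation gives Poisson-distributed adduct
#' counts; with the support truncated at lMax the distribution is
#' renormalised and the rate is estimated by matching the truncated mean to
#' the observed mean adduct count (the maximum-likelihood condition), via a
#' one-dimensional root search.
#'
#' @inheritParams fitBinomial
#' @return Named numeric \code{c(lambda, rss)}; degenerate (lambda = 0)
#'   when all mass sits at l = 0.
#' @export
fitPoisson <- function(profile) {
  p <- profileVector(profile)
  lMax <- length(p) - 1L
  meanL <- sum((0:lMax) * p)
  if (meanL == 0) {
    out <- c(lambda = 0, rss = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  upper <- 100
  if (truncPoisMean(upper, lMax) <= meanL) {
    lam <- upper
  } else {
    lam <- stats::uniroot(function(l) truncPoisMean(l, lMax) - meanL,
                          interval = c(1e-9, upper), tol = 1e-10)$root
  }
  pmf <- stats::dpois(0:lMax, lam)
  pmf <- pmf / sum(pmf)
  out <- c(lambda = lam, rss = sum((p - pmf)^2))
  attr(out, "degenerate") <- FALSE
  out
}

oligomerMetrics <- function(assignments) {
  a <- if (is.list(assignments) && !is.data.frame(assignments))
    assignments$assignments else assignments
  pep <- a[a$species_class == "oligomer", , drop = FALSE]
  if (nrow(pep) == 0)
    return(c(max_n = NA_real_, oligomer_fraction = NA_real_))
  c(max_n = max(pep$n),
    oligomer_fraction = sum(pep$intensity[pep$n >= 2]) / sum(pep$intensity))
}

#' Classify a compound's binding mode
#'
#' Decision cascade over the assigned holo spectrum:
#' \enumerate{
#'   \item colloidal — ligand self-multimer assignments at two or more
#'     multimer orders carrying more summed intensity than
#'     \code{colloidThreshold} of the base peak (ligand self-association
#'     contaminates everything else, so it is checked first);
#'   \item negative — bound fraction (intensity of peptide ions with l >= 1
#'     over all peptide-ion intensity) below \code{bindThreshold};
#'   \item specific vs non-specific — whichever of the binomial and
#'     truncated-Poisson fits leaves the smaller residual on the pooled
#'     monomer stoichiometry profile.
#' }
#' Oligomer-depletion metrics (largest observed oligomer order and fraction
#' of peptide ion current in oligomers, holo vs apo) are reported alongside
#' the verdict; the margin (poisson rss - binomial rss) is reported so users
#' can apply their own cutoff.
#'
#' @param holo Output of [assignSpectrum()] for the peptide + compound
#'   spectrum.
#' @param apo Output of [assignSpectrum()] for the peptide-alone reference,
#'   or NULL (depletion metrics are then NA, with a warning).
#' @param ligand The \code{LigandSpec} of the compound.
#' @param config An \code{AssignmentConfig} (thresholds).
#' @param compoundId Identifier recorded in the verdict.
#' @return A \linkS4class{BindingVerdict}.
#' @export
classifyBinding <- function(holo, apo = NULL, ligand,
                            config = assignmentConfig(),
                            compoundId = ligand@compoundId) {
  a <- if (is.list(holo) && !is.data.frame(holo)) holo$assignments else holo
  if (nrow(a) == 0) stop("empty holo assignment set")
  basePeak <- max(a$intensity)

  mult <- a[a$species_class == "ligand_multimer", , drop = FALSE]
  colloidOrders <- length(unique(mult$j[!is.na(mult$j)]))
  colloidIntensity <- if (nrow(mult)) sum(mult$intensity) / basePeak else 0
  colloidEvidence <- c(orders = colloidOrders,
                       rel_intensity = colloidIntensity)

  pep <- a[a$species_class == "oligomer", , drop = FALSE]
  if (nrow(pep) == 0) stop("no assigned peptide peaks in holo spectrum")
  bound <- sum(pep$intensity[!is.na(pep$l) & pep$l >= 1]) / sum(pep$intensity)

  binFit <- c(N = NA_real_, p = NA_real_, rss = NA_real_)
  poiFit <- c(lambda = NA_real_, rss = NA_real_)
  margin <- NA_real_
  prof <- tryCatch(buildProfile(a, lMax = ligand@lMax), error = function(e) NULL)
  if (!is.null(prof)) {
    b <- fitBinomial(prof)
    q <- fitPoisson(prof)
    if (!isTRUE(attr(b, "degenerate"))) binFit <- b[c("N", "p", "rss")]
    if (!isTRUE(attr(q, "degenerate"))) poiFit <- q[c("lambda", "rss")]
    if (!any(is.na(c(binFit["rss"], poiFit["rss"]))))
      margin <- unname(poiFit["rss"] - binFit["rss"])
  }

  mode <- if (colloidOrders >= 2 && colloidIntensity > config@colloidThreshold) {
    "colloidal"
  } else if (bound < config@bindThreshold) {
    "negative"
  } else if (!is.na(margin) && margin >= 0) {
    "specific"
  } else {
    "non_specific"
  }

  mh <- oligomerMetrics(a)
  if (is.null(apo)) {
    warning("no apo reference supplied; depletion metrics omitted")
    ma <- c(max_n = NA_real_, oligomer_fraction = NA_real_)
  } else {
    ma <- oligomerMetrics(apo)
  }
  depletion <- c(max_n_holo = unname(mh["max_n"]),
                 max_n_apo = unname(ma["max_n"]),
                 oligomer_fraction_holo = unname(mh["oligomer_fraction"]),
                 oligomer_fraction_apo = unname(ma["oligomer_fraction"]))

  new("BindingVerdict", compoundId = as.character(compoundId), mode = mode,
      binomialFit = binFit, poissonFit = poiFit,
      boundFraction = unname(bound), colloidEvidence = colloidEvidence,
      depletion = depletion,
      margin = if (is.na(margin)) NA_real_ else unname(margin))
}
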