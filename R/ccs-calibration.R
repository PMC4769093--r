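#' Correct a travelling-wave drift time for m/z-dependent transit
#'
#' Travelling-wave drift times include a mobility-independent, m/z-dependent
#' transit contribution (the enhanced-duty-cycle delay). The corrected drift
#' time is
#' \deqn{t_d' = t_d - c \sqrt{m/z} / 1000}
#' where \code{c} is an instrument constant.
#'
#' @param td Observed drift time in ms. Vectorised.
#' @param mz m/z of the ion in Thomson. Vectorised.
#' @param edcDelay EDC delay coefficient (instrument constant).
#' @return Corrected drift time in ms; errors if the correction leaves no
#'   positive drift (the ion would have to be faster than mobility-independent
#'   transit allows).
#' @export
correctDrift <- function(td, mz, edcDelay = 1.41) {
  if (any(td < 0)) stop("drift time must be >= 0")
  tdp <- td - edcDelay * sqrt(mz) / 1000
  if (any(tdp <= 0))
    stop("corrected drift time <= 0: drift shorter than the ",
         "mobility-independent transit; check edcDelay and units")
  tdp
}

# Reduced CCS: divides out charge and the ion-gas reduced-mass factor, the
# quantity that the travelling-wave power law is linear in (on log scales).
reducedCcs <- function(ccs, z, ionMass, gasMass) {
  ccs / (z * sqrt(1 / ionMass + 1 / gasMass))
}

#' Fit a travelling-wave CCS calibration
#'
#' Travelling-wave ion mobility has no first-principles drift-time-to-CCS
#' relation; it is calibrated against species of known (drift-tube) CCS,
#' typically denatured proteins and peptides. Each calibrant's literature CCS
#' is reduced by charge and reduced mass,
#' \deqn{\Omega' = \Omega_{ref} / (z \sqrt{1/m + 1/m_{gas}})}
#' and a power law \eqn{\Omega' = A t_d'^B} is fitted by least squares of
#' \eqn{\ln \Omega'} on \eqn{\ln t_d'}.
#'
#' @param calibrants data.frame with columns \code{identity}, \code{mass}
#'   (Da), \code{charge}, \code{reference_ccs} (A^2, from drift-tube
#'   measurements), \code{observed_drift} (ms). At least 3 calibrants with
#'   distinct corrected drifts.
#' @param edcDelay EDC delay coefficient; see [correctDrift()].
#' @param gasMass Drift-gas mass in Da (default nitrogen).
#' @return A \linkS4class{CcsCalibration}.
#' @examples
#' cal <- data.frame(identity = letters[1:4], mass = c(2e3, 4e3, 8e3, 12e3),
#'                   charge = c(2, 3, 5, 6),
#'                   reference_ccs = c(500, 800, 1400, 1800),
#'                   observed_drift = c(3, 4.5, 6, 8))
#' fitCalibration(cal, edcDelay = 0)
#' @export
fitCalibration <- function(calibrants, edcDelay = 1.41, gasMass = N2_MASS) {
  needed <- c("mass", "charge", "reference_ccs", "observed_drift")
  if (!all(needed %in% names(calibrants)))
    stop("calibrant table must have columns: identity, ",
         paste(needed, collapse = ", "))
  if (nrow(calibrants) < 3)
    stop("at least 3 calibrants are required to fit the power law")
  mzCal <- (calibrants$mass + calibrants$charge * PROTON_MASS) /
    calibrants$charge
  tdp <- correctDrift(calibrants$observed_drift, mzCal, edcDelay)
  if (length(unique(signif(tdp, 12))) < 2)
    stop("calibrants have identical corrected drifts; fit is singular")
  omegap <- reducedCcs(calibrants$reference_ccs, calibrants$charge,
                       calibrants$mass, gasMass)
  fit <- stats::lm(log(omegap) ~ log(tdp))
  B <- unname(stats::coef(fit)[2])
  A <- exp(unname(stats::coef(fit)[1]))
  # direct 1 - rss/tss (summary.lm warns on exact synthetic fits)
  y <- log(omegap)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  r2 <- min(max(r2, 0), 1)
  new("CcsCalibration", A = A, B = B, edcDelay = edcDelay,
      gasMass = gasMass, rSquared = r2, calibrants = calibrants)
}

#' Estimate the CCS of an ion from its drift time
#'
#' Applies the fitted power law to the corrected drift time and restores the
#' charge and reduced-mass factors:
#' \deqn{\Omega = A t_d'^B \; z \sqrt{1/m + 1/m_{gas}}}
#'
#' @param td Observed drift time in ms. Vectorised.
#' @param mz m/z in Thomson. Vectorised.
#' @param z Ion charge.
#' @param ionMass Ion mass in Da.
#' @param calibration A \linkS4class{CcsCalibration}.
#' @return Estimated collision cross section in A^2.
#' @seealso [invertCcs()] for the inverse mapping.
#' @export
estimateCcs <- function(td, mz, z, ionMass, calibration) {
  stopifnot(is(calibration, "CcsCalibration"))
  tdp <- correctDrift(td, mz, calibration@edcDelay)
  calibration@A * tdp^calibration@B * z *
    sqrt(1 / ionMass + 1 / calibration@gasMass)
}

#' Drift time at which an ion of known CCS would arrive
#'
#' Exact inverse of [estimateCcs()] composed with [correctDrift()]; used to
#' synthesise drift times for planted CCS values and to predict the drift of
#' candidate assignments when resolving m/z degeneracy.
#'
#' @param ccs Collision cross section in A^2. Vectorised.
#' @param mz m/z in Thomson. Vectorised.
#' @param z Ion charge.
#' @param ionMass Ion mass in Da.
#' @param calibration A \linkS4class{CcsCalibration}.
#' @return Observed drift time in ms (EDC transit added back).
#' @export
invertCcs <- function(ccs, mz, z, ionMass, calibration) {
  stopifnot(is(calibration, "CcsCalibration"))
  if (any(ccs <= 0)) stop("ccs must be > 0")
  if (calibration@B == 0) stop("calibration exponent B = 0 is not invertible")
  omegap <- reducedCcs(ccs, z, ionMass, calibration@gasMass)
  tdp <- (omegap / calibration@A)^(1 / calibration@B)
  tdp + calibration@edcDelay * sqrt(mz) / 1000
}

#' Read a calibrant table from CSV
#'
#' Columns: \code{identity}, \code{mass}, \code{charge},
#' \code{reference_ccs}, \code{observed_drift}.
#'
#' @param path CSV path.
#' @return data.frame of calibrants.
#' @export
readCalibrants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("identity", "mass", "charge", "reference_ccs", "observed_drift")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("calibrant table missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Store / load a fitted calibration as JSON
#'
#' @param calibration A \linkS4class{CcsCalibration}.
#' @param path JSON path.
#' @return \code{writeCalibration} returns the path invisibly;
#'   \code{readCalibration} returns a \linkS4class{CcsCalibration} (without
#'   the calibrant table, which is not serialised).
#' @export
writeCalibration <- function(calibration, path) {
  jsonlite::write_json(
    list(A = calibration@A, B = calibration@B,
         edc_delay = calibration@edcDelay, gas_mass = calibration@gasMass,
         r_squared = calibration@rSquared),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CcsCalibration", A = x$A, B = x$B, edcDelay = x$edc_delay,
      gasMass = x$gas_mass,
      rSquared = if (is.null(x$r_squared)) NA_real_ else as.numeric(x$r_squared),
      calibrants = data.frame())
}

#' A fixed synthetic travelling-wave calibration
#'
#' A plausible Synapt-like power law (A = 550, B = 0.55, EDC delay 1.41,
#' nitrogen drift gas) used as the scenario calibration by the synthetic
#' spectrum generator and as a convenient default elsewhere. It is synthetic:
#' it does not reproduce any particular instrument.
#'
#' @param A,B,edcDelay,gasMass Override the defaults.
#' @return A \linkS4class{CcsCalibration} with an empty calibrant table and
#'   \code{rSquared = NA}.
#' @export
syntheticCalibration <- function(A = 550, B = 0.55, edcDelay = 1.41,
                                 gasMass = N2_MASS) {
  new("CcsCalibration", A = A, B = B, edcDelay = edcDelay, gasMass = gasMass,
      rSquared = NA_real_, calibrants = data.frame())
}
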