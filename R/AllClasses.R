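#' @import methods
NULL

#' Mass of a proton in Daltons
#'
#' Positive-mode electrospray charges species by protonation; observed m/z
#' values are therefore (neutral mass + z * proton mass) / z. The electron
#' mass correction is negligible at the tolerances used here.
#'
#' @format A length-one numeric, 1.007276 Da.
#' @export
PROTON_MASS <- 1.007276

#' Mass of dinitrogen in Daltons
#'
#' Default drift gas for travelling-wave ion mobility; enters the reduced-mass
#' term of the collision cross section calibration.
#'
#' @format A length-one numeric, 28.0134 Da.
#' @export
N2_MASS <- 28.0134

#' @rdname peptideSpec
#' @export
setClass("PeptideSpec",
  representation(
    name = "character",
    monomerMass = "numeric",
    chargeRange = "integer",
    nMax = "integer"
  )
)

setValidity("PeptideSpec", function(object) {
  msg <- character()
  if (length(object@monomerMass) != 1 || !is.finite(object@monomerMass) ||
      object@monomerMass <= 0)
    msg <- c(msg, "monomerMass must be a single positive number")
  if (length(object@chargeRange) != 2 || any(is.na(object@chargeRange)) ||
      object@chargeRange[1] < 1 || object@chargeRange[2] < object@chargeRange[1])
    msg <- c(msg, "chargeRange must be an increasing integer pair with lower bound >= 1")
  if (length(object@nMax) != 1 || is.na(object@nMax) || object@nMax < 1)
    msg <- c(msg, "nMax must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ligandSpec
#' @export
setClass("LigandSpec",
  representation(
    compoundId = "character",
    ligandMass = "numeric",
    lMax = "integer",
    jMax = "integer"
  )
)

setValidity("LigandSpec", function(object) {
  msg <- character()
  if (length(object@ligandMass) != 1 || !is.finite(object@ligandMass) ||
      object@ligandMass <= 0)
    msg <- c(msg, "ligandMass must be a single positive number")
  if (length(object@lMax) != 1 || is.na(object@lMax) || object@lMax < 0)
    msg <- c(msg, "lMax must be >= 0")
  if (length(object@jMax) != 1 || is.na(object@jMax) || object@jMax < 1)
    msg <- c(msg, "jMax must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname assignmentConfig
#' @export
setClass("AssignmentConfig",
  representation(
    tolerancePpm = "numeric",
    driftConsistencyWeight = "numeric",
    minRelIntensity = "numeric",
    colloidThreshold = "numeric",
    bindThreshold = "numeric"
  )
)

setValidity("AssignmentConfig", function(object) {
  msg <- character()
  if (object@tolerancePpm <= 0)
    msg <- c(msg, "tolerancePpm must be > 0")
  if (object@minRelIntensity < 0 || object@minRelIntensity >= 1)
    msg <- c(msg, "minRelIntensity must be in [0, 1)")
  if (object@colloidThreshold < 0) msg <- c(msg, "colloidThreshold must be >= 0")
  if (object@bindThreshold < 0 || object@bindThreshold > 1)
    msg <- c(msg, "bindThreshold must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname fitCalibration
#' @export
setClass("CcsCalibration",
  representation(
    A = "numeric",
    B = "numeric",
    edcDelay = "numeric",
    gasMass = "numeric",
    rSquared = "numeric",
    calibrants = "data.frame"
  )
)

setValidity("CcsCalibration", function(object) {
  msg <- character()
  if (object@A <= 0) msg <- c(msg, "power-law scale A must be > 0")
  if (object@B <= 0 || object@B >= 2)
    msg <- c(msg, "power-law exponent B must lie in (0, 2)")
  if (!is.na(object@rSquared) && (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@gasMass <= 0) msg <- c(msg, "gasMass must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname fitGrowth
#' @export
setClass("GrowthFit",
  representation(
    model = "character",
    params = "numeric",
    rss = "numeric",
    aicc = "numeric",
    selected = "logical"
  )
)

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (!object@model %in% c("isotropic", "linear", "spherical"))
    msg <- c(msg, "model must be one of isotropic, linear, spherical")
  if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname fitGrowth
#' @export
setClass("GrowthModelComparison",
  representation(
    fits = "list",
    selected = "character",
    series = "data.frame"
  )
)

setValidity("GrowthModelComparison", function(object) {
  msg <- character()
  if (!all(vapply(object@fits, is, logical(1), "GrowthFit")))
    msg <- c(msg, "fits must all be GrowthFit objects")
  nsel <- sum(vapply(object@fits, function(f) f@selected, logical(1)))
  if (nsel != 1)
    msg <- c(msg, "exactly one model must be selected")
  if (length(msg)) msg else TRUE
})

#' @rdname oligomerScenario
#' @export
setClass("OligomerScenario",
  representation(
    peptide = "PeptideSpec",
    abundanceByN = "numeric",
    chargeEnvelope = "list",
    growthModel = "character",
    growthParams = "numeric",
    noiseCv = "numeric",
    seed = "integer",
    calibration = "CcsCalibration"
  )
)

setValidity("OligomerScenario", function(object) {
  msg <- character()
  ab <- object@abundanceByN
  if (is.null(names(ab)) || any(is.na(suppressWarnings(as.integer(names(ab))))))
    msg <- c(msg, "abundanceByN must be named by integer oligomer order")
  if (any(ab < 0) || abs(sum(ab) - 1) > 1e-8)
    msg <- c(msg, "abundances must be >= 0 and sum to 1")
  if (length(names(ab)) &&
      any(as.integer(names(ab)) > object@peptide@nMax))
    msg <- c(msg, "abundanceByN references oligomer order beyond nMax")
  if (!identical(sort(names(object@chargeEnvelope)), sort(names(ab))))
    msg <- c(msg, "chargeEnvelope must cover exactly the orders in abundanceByN")
  if (!object@growthModel %in% c("isotropic", "linear", "spherical"))
    msg <- c(msg, "growthModel must be one of isotropic, linear, spherical")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname bindingScenario
#' @export
setClass("BindingScenario",
  representation(
    mode = "character",
    nSites = "integer",
    occupancy = "numeric",
    poissonRate = "numeric",
    colloidRange = "integer",
    depletionFactor = "numeric",
    depletionCutoff = "integer"
  )
)

setValidity("BindingScenario", function(object) {
  msg <- character()
  if (!object@mode %in% c("specific", "non_specific", "colloidal", "negative"))
    msg <- c(msg, "mode must be specific, non_specific, colloidal or negative")
  if (object@mode == "specific") {
    if (is.na(object@nSites) || object@nSites < 1)
      msg <- c(msg, "specific mode needs nSites >= 1")
    if (is.na(object@occupancy) || object@occupancy < 0 || object@occupancy > 1)
      msg <- c(msg, "specific mode needs occupancy in [0, 1]")
    if (is.na(object@depletionFactor) || object@depletionFactor < 0 ||
        object@depletionFactor > 1)
      msg <- c(msg, "depletionFactor must lie in [0, 1]")
  }
  if (object@mode == "non_specific" &&
      (is.na(object@poissonRate) || object@poissonRate <= 0))
    msg <- c(msg, "non_specific mode needs poissonRate > 0")
  if (object@mode == "colloidal" &&
      (length(object@colloidRange) != 2 || any(is.na(object@colloidRange)) ||
       object@colloidRange[1] < 1 ||
       object@colloidRange[2] < object@colloidRange[1]))
    msg <- c(msg, "colloidal mode needs an increasing colloidRange pair >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname buildProfile
#' @export
setClass("StoichiometryProfile",
  representation(
    perCharge = "matrix",
    pooled = "numeric",
    lMax = "integer"
  )
)

setValidity("StoichiometryProfile", function(object) {
  msg <- character()
  if (length(object@pooled) != object@lMax + 1)
    msg <- c(msg, "pooled profile must have lMax + 1 entries")
  if (abs(sum(object@pooled) - 1) > 1e-9)
    msg <- c(msg, "pooled profile must sum to 1")
  if (nrow(object@perCharge) > 0) {
    sums <- rowSums(object@perCharge)
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, "per-charge profiles must each sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname classifyBinding
#' @export
setClass("BindingVerdict",
  representation(
    compoundId = "character",
    mode = "character",
    binomialFit = "numeric",
    poissonFit = "numeric",
    boundFraction = "numeric",
    colloidEvidence = "numeric",
    depletion = "numeric",
    margin = "numeric"
  )
)

setValidity("BindingVerdict", function(object) {
  msg <- character()
  if (!object@mode %in% c("specific", "non_specific", "colloidal", "negative",
                          "failed"))
    msg <- c(msg, "unknown binding mode")
  if (!is.na(object@boundFraction) &&
      (object@boundFraction < -1e-9 || object@boundFraction > 1 + 1e-9))
    msg <- c(msg, "boundFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname runScreen
#' @export
setClass("ScreenReport",
  representation(
    verdicts = "list",
    table = "data.frame",
    summary = "integer",
    seed = "integer"
  )
)

setValidity("ScreenReport", function(object) {
  msg <- character()
  if (!all(vapply(object@verdicts, is, logical(1), "BindingVerdict")))
    msg <- c(msg, "verdicts must all be BindingVerdict objects")
  if (length(object@verdicts) && sum(object@summary) != length(object@verdicts))
    msg <- c(msg, "summary counts must sum to the number of compounds")
  if (length(msg)) msg else TRUE
})
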