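#' Binding mode of a verdict
#'
#' @param object A \linkS4class{BindingVerdict}.
#' @return Character scalar, one of \code{"specific"}, \code{"non_specific"},
#'   \code{"colloidal"}, \code{"negative"}.
#' @export
setGeneric("bindingMode", function(object) standardGeneric("bindingMode"))

#' Fraction of peptide ion current carried by ligand-bound species
#'
#' @param object A \linkS4class{BindingVerdict}.
#' @return Numeric in [0, 1].
#' @export
setGeneric("boundFraction", function(object) standardGeneric("boundFraction"))

#' Model selected by growth-model comparison
#'
#' @param object A \linkS4class{GrowthModelComparison}.
#' @return Character scalar naming the selected model.
#' @export
setGeneric("selectedModel", function(object) standardGeneric("selectedModel"))

#' Fitted parameters of a growth model or calibration
#'
#' @param object A \linkS4class{GrowthFit}, \linkS4class{GrowthModelComparison}
#'   or \linkS4class{CcsCalibration}.
#' @param ... Passed on to methods; for \code{GrowthModelComparison},
#'   \code{model} selects which fit.
#' @return Named numeric vector of parameter estimates.
#' @export
setGeneric("fitParams", function(object, ...) standardGeneric("fitParams"))

#' Per-compound result table of a screen report
#'
#' @param object A \linkS4class{ScreenReport}.
#' @return A data.frame with one row per compound (id, well, mode,
#'   bound fraction, fit margin, depletion summary).
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' Counts of compounds per binding mode
#'
#' @param object A \linkS4class{ScreenReport}.
#' @return Named integer vector over the four binding modes.
#' @export
setGeneric("modeCounts", function(object) standardGeneric("modeCounts"))

#' Pooled ligand-stoichiometry profile
#'
#' @param object A \linkS4class{StoichiometryProfile}.
#' @return Numeric vector of normalised intensities over ligand counts
#'   l = 0..lMax (sums to 1).
#' @export
setGeneric("pooledProfile", function(object) standardGeneric("pooledProfile"))

setMethod("bindingMode", "BindingVerdict", function(object) object@mode)

setMethod("boundFraction", "BindingVerdict", function(object) object@boundFraction)

setMethod("selectedModel", "GrowthModelComparison",
          function(object) object@selected)

setMethod("fitParams", "GrowthFit", function(object, ...) object@params)

setMethod("fitParams", "GrowthModelComparison", function(object, model = NULL, ...) {
  if (is.null(model)) model <- object@selected
  object@fits[[model]]@params
})

setMethod("fitParams", "CcsCalibration", function(object, ...) {
  c(A = object@A, B = object@B, edcDelay = object@edcDelay,
    gasMass = object@gasMass, rSquared = object@rSquared)
})

setMethod("reportTable", "ScreenReport", function(object) object@table)

setMethod("modeCounts", "ScreenReport", function(object) object@summary)

setMethod("pooledProfile", "StoichiometryProfile", function(object) object@pooled)

setMethod("show", "PeptideSpec", function(object) {
  cat("PeptideSpec:", object@name, "\n")
  cat("  monomer mass:", format(object@monomerMass), "Da (average)\n")
  cat("  charge range:", object@chargeRange[1], "-", object@chargeRange[2],
      " n_max:", object@nMax, "\n")
})

setMethod("show", "LigandSpec", function(object) {
  cat("LigandSpec:", object@compoundId, "\n")
  cat("  ligand mass:", format(object@ligandMass), "Da",
      " l_max:", object@lMax, " j_max:", object@jMax, "\n")
})

setMethod("show", "CcsCalibration", function(object) {
  cat("CcsCalibration (travelling-wave power law)\n")
  cat(sprintf("  ccs' = %.6g * td'^%.6g   (reduced units)\n",
              object@A, object@B))
  cat(sprintf("  EDC delay coefficient: %.4g; drift gas mass: %.4f Da\n",
              object@edcDelay, object@gasMass))
  cat(sprintf("  r-squared: %s over %d calibrants\n",
              ifelse(is.na(object@rSquared), "NA", sprintf("%.6f", object@rSquared)),
              nrow(object@calibrants)))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit [%s]%s rss=%.6g aicc=%.6g\n", object@model,
              if (object@selected) " (selected)" else "",
              object@rss, object@aicc))
  if (length(object@params))
    cat("  params:", paste(names(object@params),
                           signif(object@params, 6), sep = "=", collapse = " "),
        "\n")
})

setMethod("show", "GrowthModelComparison", function(object) {
  cat("Growth model comparison (", nrow(object@series), " CCS points )\n",
      sep = "")
  for (f in object@fits) show(f)
  cat("Selected model:", object@selected, "\n")
})

setMethod("show", "BindingVerdict", function(object) {
  cat(sprintf("BindingVerdict [%s]: %s\n", object@compoundId, object@mode))
  cat(sprintf("  bound fraction: %.4f  margin (poisson rss - binomial rss): %.4g\n",
              object@boundFraction, object@margin))
  if (!any(is.na(object@binomialFit)))
    cat(sprintf("  binomial fit: N=%d p=%.3f rss=%.4g\n",
                as.integer(object@binomialFit["N"]), object@binomialFit["p"],
                object@binomialFit["rss"]))
  if (!any(is.na(object@poissonFit)))
    cat(sprintf("  poisson fit: lambda=%.3f rss=%.4g\n",
                object@poissonFit["lambda"], object@poissonFit["rss"]))
  if (!any(is.na(object@depletion)))
    cat(sprintf("  depletion: max n %d (apo %d); oligomer fraction %.3f (apo %.3f)\n",
                as.integer(object@depletion["max_n_holo"]),
                as.integer(object@depletion["max_n_apo"]),
                object@depletion["oligomer_fraction_holo"],
                object@depletion["oligomer_fraction_apo"]))
})

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport:", length(object@verdicts), "compounds\n")
  cnt <- object@summary
  cat("  ", paste(names(cnt), cnt, sep = "=", collapse = "  "), "\n")
})
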