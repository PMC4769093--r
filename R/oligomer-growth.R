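#' Growth-model CCS predictions
#'
#' Three idealised models describe how the collision cross section of an
#' oligomer scales with its order n:
#' \itemize{
#'   \item isotropic: \eqn{\sigma_n = \sigma_{monomer} n^{2/3}} — the
#'     assembly grows equally in all dimensions, so area scales as
#'     volume^(2/3);
#'   \item linear: \eqn{\sigma_n = a n + k} — growth in a single dimension
#'     (fibril-like), where \code{a} is the cross section contributed by a
#'     monomer within the fibril and \code{k} the size of the fibril cap;
#'   \item spherical: the oligomer is a perfect sphere of typical protein
#'     density \eqn{\rho} (0.44 Da/A^3): volume \eqn{V = n M / \rho}, radius
#'     \eqn{r = (3V/4\pi)^{1/3}}, cross section \eqn{\pi r^2}. This model
#'     has no free parameters once the density is fixed.
#' }
#'
#' @param n Oligomer order (>= 1). Vectorised.
#' @param sigmaMonomer Monomer CCS in A^2 (isotropic model).
#' @param a,k Linear model parameters (A^2 per monomer; cap size in A^2).
#' @param monomerMass Average monomer mass in Da (spherical model).
#' @param rho Assumed density in Da/A^3 (spherical model), default 0.44.
#' @return Predicted CCS in A^2.
#' @name growthModels
NULL

#' @rdname growthModels
#' @export
predictIsotropic <- function(n, sigmaMonomer) {
  if (any(n < 1)) stop("oligomer order must be >= 1")
  if (sigmaMonomer <= 0) stop("sigmaMonomer must be > 0")
  sigmaMonomer * n^(2 / 3)
}

#' @rdname growthModels
#' @export
predictLinear <- function(n, a, k) {
  if (any(n < 1)) stop("oligomer order must be >= 1")
  a * n + k
}

#' @rdname growthModels
#' @export
predictSpherical <- function(n, monomerMass, rho = 0.44) {
  if (any(n < 1)) stop("oligomer order must be >= 1")
  if (any(monomerMass <= 0)) stop("monomerMass must be > 0")
  if (any(rho <= 0)) stop("density rho must be > 0")
  V <- n * monomerMass / rho
  r <- (3 * V / (4 * pi))^(1 / 3)
  pi * r^2
}

# Small-sample corrected information criterion on Gaussian residuals with
# k fitted model parameters; the fixed-density spherical model has k = 0.
aiccFromRss <- function(rss, nObs, k) {
  if (nObs - k - 1 <= 0) return(Inf)
  nObs * log(rss / nObs) + 2 * k + 2 * k * (k + 1) / (nObs - k - 1)
}

#' Fit and compare oligomer growth models on a CCS series
#'
#' Least-squares fits of the isotropic, linear and spherical models to the
#' per-oligomer CCS series (conventionally the CCS of the lowest charge
#' state of each order), with model selection by lowest small-sample
#' corrected information criterion (AICc).
#'
#' CCS measurement error is multiplicative (a relative reproducibility),
#' so by default residuals are taken on the log scale, where their variance
#' is constant and the Gaussian AICc is the matching criterion. On the log
#' scale the isotropic model is linear with closed-form scale
#' \eqn{\ln\hat\sigma_m = \mathrm{mean}(\ln\sigma_i - \tfrac23 \ln n_i)};
#' the linear model is fitted by nested nonlinear least squares (initialised
#' at the ordinary regression solution); the spherical model is parameter
#' free with the density fixed (set \code{fitRho = TRUE} to fit the density
#' as one parameter). An exact fit (zero residual) always wins selection.
#' \code{logResiduals = FALSE} gives plain absolute-scale least squares.
#'
#' @param series data.frame with columns \code{n} (distinct orders >= 1) and
#'   \code{ccs} (A^2); at least 3 points. A \code{z} column, if present, is
#'   carried through but not used by the fit.
#' @param monomerMass Average monomer mass in Da (needed by the spherical
#'   model).
#' @param rho Density for the spherical model, Da/A^3.
#' @param fitRho Fit the density instead of fixing it (then the spherical
#'   model carries one parameter in the AICc).
#' @param logResiduals Fit on the log scale (default) or the absolute scale.
#' @return A \linkS4class{GrowthModelComparison} holding the three
#'   \linkS4class{GrowthFit}s and the name of the selected model. Each fit's
#'   \code{rss} is on the fitting scale.
#' @examples
#' s <- data.frame(n = 1:6, ccs = predictLinear(1:6, a = 250, k = 380))
#' selectedModel(fitGrowth(s, monomerMass = 4461))
#' @export
fitGrowth <- function(series, monomerMass, rho = 0.44, fitRho = FALSE,
                      logResiduals = TRUE) {
  stopifnot(all(c("n", "ccs") %in% names(series)))
  if (anyDuplicated(series$n)) stop("oligomer orders must be distinct")
  if (any(series$n < 1) || any(series$ccs <= 0))
    stop("require n >= 1 and ccs > 0")
  if (nrow(series) < 3)
    stop("at least 3 (n, ccs) points are required to compare growth models")
  n <- series$n
  ccs <- series$ccs
  nObs <- length(n)
  resid2 <- function(pred) {
    if (logResiduals) sum((log(ccs) - log(pred))^2)
    else sum((ccs - pred)^2)
  }

  if (logResiduals) {
    sigmaHat <- exp(mean(log(ccs) - (2 / 3) * log(n)))
  } else {
    sigmaHat <- sum(ccs * n^(2 / 3)) / sum(n^(4 / 3))
  }
  rssIso <- resid2(predictIsotropic(n, sigmaHat))
  iso <- new("GrowthFit", model = "isotropic",
             params = c(sigma_monomer = sigmaHat), rss = rssIso,
             aicc = aiccFromRss(rssIso, nObs, 1), selected = FALSE)

  co <- stats::coef(stats::lm(ccs ~ n))
  ak <- c(unname(co[2]), unname(co[1]))
  if (ak[1] * min(n) + ak[2] <= 0)  # fallback start if the line dips <= 0
    ak <- c((max(ccs) - min(ccs)) / (max(n) - min(n)), min(ccs) / 2)
  rssLin <- resid2(predictLinear(n, ak[1], ak[2]))
  if (logResiduals && rssLin > 1e-18) {
    obj <- function(p) {
      pred <- p[1] * n + p[2]
      if (any(pred <= 0)) return(1e10)
      sum((log(ccs) - log(pred))^2)
    }
    opt <- stats::optim(ak, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    ak <- opt$par
    rssLin <- opt$value
  }
  lin <- new("GrowthFit", model = "linear",
             params = c(a = ak[1], k = ak[2]), rss = rssLin,
             aicc = aiccFromRss(rssLin, nObs, 2), selected = FALSE)

  if (fitRho) {
    obj <- function(r) resid2(predictSpherical(n, monomerMass, r))
    opt <- stats::optimize(obj, interval = c(1e-3, 10), tol = 1e-12)
    sph <- new("GrowthFit", model = "spherical",
               params = c(rho = opt$minimum), rss = opt$objective,
               aicc = aiccFromRss(opt$objective, nObs, 1), selected = FALSE)
  } else {
    rssSph <- resid2(predictSpherical(n, monomerMass, rho))
    sph <- new("GrowthFit", model = "spherical", params = c(rho = rho),
               rss = rssSph, aicc = aiccFromRss(rssSph, nObs, 0),
               selected = FALSE)
  }

  fits <- list(isotropic = iso, linear = lin, spherical = sph)
  aiccs <- vapply(fits, function(f) f@aicc, numeric(1))
  nPar <- c(isotropic = 1, linear = 2,
            spherical = if (fitRho) 1 else 0)
  # AICc ties (e.g. two exact fits, both -Inf) break toward parsimony
  sel <- names(fits)[order(aiccs, nPar[names(fits)])[1]]
  fits[[sel]]@selected <- TRUE
  new("GrowthModelComparison", fits = fits, selected = sel,
      series = as.data.frame(series))
}
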