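#' Run a compound screen
#'
#' Assigns and classifies one holo spectrum per compound against a shared
#' apo reference, and tallies the verdicts. A compound whose peak list
#' cannot be read or classified is recorded with mode \code{"failed"} and
#' the screen continues.
#'
#' @param platePeaks Named list of peak-list data.frames (names are compound
#'   ids), or a directory containing \code{<compound_id>.csv} peak lists.
#' @param apoPeaks Peak-list data.frame for the peptide-alone reference.
#' @param peptide A \code{PeptideSpec}.
#' @param compounds data.frame with columns \code{compound_id},
#'   \code{ligand_mass} and optionally \code{well}.
#' @param config An \code{AssignmentConfig}.
#' @param calibration A \linkS4class{CcsCalibration} used for degeneracy
#'   resolution.
#' @param growthPrior Optional growth fit used as CCS prior in assignment.
#' @param lMax,jMax Adduct and self-multimer bounds for each compound.
#' @param seed Seed recorded in the report (for synthetic plates).
#' @return A \linkS4class{ScreenReport}.
#' @export
runScreen <- function(platePeaks, apoPeaks, peptide, compounds,
                      config = assignmentConfig(), calibration = NULL,
                      growthPrior = NULL, lMax = 4L, jMax = 6L, seed = NA_integer_) {
  stopifnot(all(c("compound_id", "ligand_mass") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id))
    stop("duplicate compound ids in compound table")
  ids <- as.character(compounds$compound_id)
  if (is.character(platePeaks) && length(platePeaks) == 1 &&
      dir.exists(platePeaks)) {
    dirPath <- platePeaks
    platePeaks <- stats::setNames(
      file.path(dirPath, paste0(ids, ".csv")), ids)
  }
  apoAssign <- assignSpectrum(apoPeaks, peptide, ligand = NULL,
                              config = config, calibration = calibration,
                              growthPrior = growthPrior)
  # The apo reference fixes the peptide's CCS-vs-n law; holo spectra (often
  # oligomer-depleted and short of unambiguous peaks) are assigned under it.
  if (is.null(growthPrior) && !is.null(calibration))
    growthPrior <- growthPriorFromAssignment(apoAssign, peptide, calibration)
  verdicts <- vector("list", length(ids))
  names(verdicts) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    lig <- ligandSpec(id, compounds$ligand_mass[i], lMax, jMax)
    verdicts[[i]] <- tryCatch({
      pk <- platePeaks[[id]]
      if (is.character(pk)) pk <- readPeakList(pk)
      if (is.null(pk)) stop("no peak list for compound ", id)
      holo <- assignSpectrum(pk, peptide, ligand = lig, config = config,
                             calibration = calibration,
                             growthPrior = growthPrior)
      classifyBinding(holo, apoAssign, lig, config, compoundId = id)
    }, error = function(e) {
      message("compound ", id, " failed: ", conditionMessage(e))
      new("BindingVerdict", compoundId = id, mode = "failed",
          binomialFit = c(N = NA_real_, p = NA_real_, rss = NA_real_),
          poissonFit = c(lambda = NA_real_, rss = NA_real_),
          boundFraction = NA_real_,
          colloidEvidence = c(orders = 0, rel_intensity = 0),
          depletion = c(max_n_holo = NA_real_, max_n_apo = NA_real_,
                        oligomer_fraction_holo = NA_real_,
                        oligomer_fraction_apo = NA_real_),
          margin = NA_real_)
    })
  }
  modes <- vapply(verdicts, function(v) v@mode, character(1))
  levelsAll <- c("specific", "non_specific", "colloidal", "negative", "failed")
  counts <- vapply(levelsAll, function(m) sum(modes == m), integer(1))
  if (counts["failed"] == 0L) counts <- counts[levelsAll[1:4]]
  tab <- data.frame(
    compound_id = ids,
    well = if ("well" %in% names(compounds)) compounds$well else NA_character_,
    mode = modes,
    bound_fraction = vapply(verdicts, function(v) v@boundFraction, numeric(1)),
    margin = vapply(verdicts, function(v) v@margin, numeric(1)),
    max_n_holo = vapply(verdicts, function(v)
      unname(v@depletion["max_n_holo"]), numeric(1)),
    max_n_apo = vapply(verdicts, function(v)
      unname(v@depletion["max_n_apo"]), numeric(1)),
    oligomer_fraction_holo = vapply(verdicts, function(v)
      unname(v@depletion["oligomer_fraction_holo"]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("ScreenReport", verdicts = verdicts, table = tab,
      summary = counts, seed = as.integer(seed))
}

#' Compare per-compound verdicts between two targets
#'
#' @param reportA,reportB \linkS4class{ScreenReport}s over the same
#'   compound ids.
#' @return List with \code{agreement} (number of compounds whose mode
#'   matches) and \code{table} (per-compound modes and agreement flag).
#' @export
compareTargets <- function(reportA, reportB) {
  ta <- reportA@table
  tb <- reportB@table
  if (!setequal(ta$compound_id, tb$compound_id) ||
      length(ta$compound_id) != length(tb$compound_id))
    stop("reports cover different compound ids")
  tb <- tb[match(ta$compound_id, tb$compound_id), ]
  tab <- data.frame(compound_id = ta$compound_id,
                    mode_a = ta$mode, mode_b = tb$mode,
                    agree = ta$mode == tb$mode, stringsAsFactors = FALSE)
  list(agreement = sum(tab$agree), table = tab)
}

blosum62Matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Ungapped percent identity and similarity of two sequence motifs
#'
#' Positional comparison of two equal-length amino-acid motifs, no gaps.
#' Identity is the percentage of identical positions; similarity counts a
#' position as conserved when the residues are identical or have a positive
#' BLOSUM62 substitution score. Percentages are rounded to the nearest
#' integer. The amyloidogenic core motifs of hIAPP and amyloid-beta
#' (NNFGAIL vs SNKGAII) score 57\% identity and 86\% similarity under this
#' rule.
#'
#' @param seqA,seqB Equal-length one-letter amino-acid strings.
#' @return Named numeric \code{c(identity, similarity)} in percent.
#' @examples
#' motifIdentitySimilarity("NNFGAIL", "SNKGAII")
#' @export
motifIdentitySimilarity <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b))
    stop("motifs must have equal length for ungapped comparison")
  if (length(a) == 0) stop("empty motif")
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  if (!all(c(a, b) %in% aa))
    stop("invalid residue code: ",
         paste(setdiff(c(a, b), aa), collapse = ", "))
  m <- blosum62Matrix()
  ident <- a == b
  score <- m[cbind(a, b)]
  simil <- ident | score > 0
  c(identity = round(100 * mean(ident)),
    similarity = round(100 * mean(simil)))
}

#' Write a screen report to JSON
#'
#' @param report A \linkS4class{ScreenReport}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeScreenReport <- function(report, path) {
  jsonlite::write_json(
    list(seed = report@seed,
         summary = as.list(report@summary),
         compounds = report@table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
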