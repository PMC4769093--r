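#' Describe the target peptide
#'
#' A peptide is characterised by its average monomer mass, the charge states
#' its ions are expected to carry, and the largest oligomer order considered
#' during species assignment. Average (not monoisotopic) masses are used
#' throughout because kDa-scale amyloid oligomers are observed as unresolved
#' isotope envelopes on quadrupole-time-of-flight instruments.
#'
#' @param name Peptide name (free text).
#' @param monomerMass Average monomer mass in Da; must be positive.
#' @param chargeRange Inclusive integer interval of charges to consider,
#'   lower bound >= 1.
#' @param nMax Largest oligomer order considered.
#' @return A \code{PeptideSpec} object.
#' @examples
#' peptideSpec("Abeta40", 4461.0, c(2, 10), nMax = 6)
#' @export
peptideSpec <- function(name, monomerMass, chargeRange = c(1L, 8L), nMax = 6L) {
  new("PeptideSpec", name = as.character(name),
      monomerMass = as.numeric(monomerMass),
      chargeRange = as.integer(chargeRange), nMax = as.integer(nMax))
}

#' Describe a screened small molecule
#'
#' @param compoundId Compound identifier (free text).
#' @param ligandMass Average mass of the ligand in Da.
#' @param lMax Largest number of ligand adducts considered on a peptide ion.
#' @param jMax Largest ligand self-multimer order considered (colloidal
#'   aggregators produce jL series of ligand-only ions).
#' @return A \code{LigandSpec} object.
#' @examples
#' ligandSpec("16", 354.4, lMax = 4, jMax = 6)
#' @export
ligandSpec <- function(compoundId, ligandMass, lMax = 4L, jMax = 6L) {
  new("LigandSpec", compoundId = as.character(compoundId),
      ligandMass = as.numeric(ligandMass),
      lMax = as.integer(lMax), jMax = as.integer(jMax))
}

#' m/z of a protonated peptide-oligomer / ligand-adduct species
#'
#' Positive-mode m/z of an oligomer of order \code{n} carrying \code{l}
#' ligand adducts and \code{z} protons:
#' \deqn{m/z = (n M + l M_L + z m_H) / z}
#' The relation is degenerate under simultaneous scaling of (n, z, l): the
#' dimer 4+ and trimer 6+ ions of a peptide share the same m/z and can only
#' be separated by ion mobility.
#'
#' @param n Oligomer order (>= 1). Vectorised.
#' @param z Charge (>= 1). Vectorised.
#' @param l Number of ligand adducts (>= 0). Vectorised.
#' @param peptide A \code{PeptideSpec}.
#' @param ligand A \code{LigandSpec}, required when any \code{l > 0}.
#' @return m/z in Thomson.
#' @examples
#' p <- peptideSpec("toy", 1000)
#' speciesMz(1, 1, 0, p)            # 1001.007276
#' speciesMz(2, 4, 0, p) == speciesMz(3, 6, 0, p)
#' @export
speciesMz <- function(n, z, l = 0L, peptide, ligand = NULL) {
  if (any(z < 1)) stop("charge z must be >= 1")
  if (any(n < 1)) stop("oligomer order n must be >= 1")
  if (any(l < 0)) stop("ligand count l must be >= 0")
  ligandMass <- if (is.null(ligand)) 0 else ligand@ligandMass
  if (any(l > 0) && is.null(ligand))
    stop("ligand spec required when l > 0")
  (n * peptide@monomerMass + l * ligandMass + z * PROTON_MASS) / z
}

#' m/z of a ligand self-multimer ion
#'
#' Colloidal aggregators self-associate and appear as ligand-only multimer
#' series jL at (j * M_L + z * m_H) / z.
#'
#' @param j Multimer order (>= 1). Vectorised.
#' @param z Charge (>= 1). Vectorised.
#' @param ligand A \code{LigandSpec}.
#' @return m/z in Thomson.
#' @export
multimerMz <- function(j, z = 1L, ligand) {
  if (any(z < 1)) stop("charge z must be >= 1")
  if (any(j < 1)) stop("multimer order j must be >= 1")
  (j * ligand@ligandMass + z * PROTON_MASS) / z
}

#' Read a centroided peak list
#'
#' Reads a delimited text peak list with header columns \code{mz},
#' \code{drift_time} and \code{intensity} (comma-separated, "." decimal).
#' Rows with non-numeric or missing values, non-positive m/z, negative drift
#' time or negative intensity are rejected; the rejection count is attached
#' as attribute \code{"rejected"} and reported via a message.
#'
#' @param path Path to the file.
#' @param sep Field separator, default comma.
#' @return A data.frame with columns \code{mz}, \code{drift_time},
#'   \code{intensity}, sorted by ascending m/z, with attribute
#'   \code{rejected} giving the number of discarded rows.
#' @seealso [writePeakList()]
#' @export
readPeakList <- function(path, sep = ",") {
  if (!file.exists(path)) stop("peak list not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          colClasses = "character",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("mz", "drift_time", "intensity")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("peak list is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[needed]
  num <- lapply(df, function(x) suppressWarnings(as.numeric(x)))
  bad <- Reduce(`|`, lapply(num, is.na))
  out <- data.frame(mz = num$mz, drift_time = num$drift_time,
                    intensity = num$intensity)[!bad, , drop = FALSE]
  invalid <- out$mz <= 0 | out$drift_time < 0 | out$intensity < 0
  out <- out[!invalid, , drop = FALSE]
  rejected <- sum(bad) + sum(invalid)
  if (rejected > 0)
    message(rejected, " malformed row(s) rejected while reading ", path)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a centroided peak list
#'
#' Writes peaks as CSV with header \code{mz,drift_time,intensity} at 15
#' significant digits, so a read/write round trip is lossless well past the
#' 6 significant figures guaranteed by the format contract.
#'
#' @param peaks data.frame with columns \code{mz}, \code{drift_time},
#'   \code{intensity}.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @seealso [readPeakList()]
#' @export
writePeakList <- function(peaks, path) {
  stopifnot(all(c("mz", "drift_time", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 0) {
    if (any(peaks$mz <= 0) || any(peaks$drift_time < 0) ||
        any(peaks$intensity < 0))
      stop("invalid peaks: require mz > 0, drift_time >= 0, intensity >= 0")
  }
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  lines <- c("mz,drift_time,intensity",
             if (nrow(peaks)) paste(fmt(peaks$mz), fmt(peaks$drift_time),
                                    fmt(peaks$intensity), sep = ","))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit hash of a string, for deriving per-compound seeds.
# Polynomial rolling hash over UTF-8 bytes, base 31, modulo 2^31 - 1.
stringHash31 <- function(s) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% m
  h
}
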