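#' @import methods
NULL

## Mass of a proton in Da, used for all charge-state arithmetic.
PROTON_MASS <- 1.007276

#' MassSpectrum: a continuous (profile) MALDI-TOF trace
#'
#' Container for a raw or processed profile spectrum: paired m/z and
#' intensity arrays plus the acquisition mode. Linear mode gives broad,
#' unresolved peaks (intact proteins, ~20-150 kDa); reflector mode gives
#' isotope-resolved peptide peaks (fingerprints, 0.7-6.5 kDa).
#'
#' @slot mz numeric, strictly increasing m/z values (Th).
#' @slot intensity numeric, non-negative intensities, same length as `mz`.
#' @slot mode character, `"linear"` or `"reflector"`.
#' @slot metadata named list of free-form provenance (clone, method,
#'   replicate, plate, ...). Unknown keys are preserved verbatim.
#' @export
setClass("MassSpectrum",
  representation(
    mz = "numeric",
    intensity = "numeric",
    mode = "character",
    metadata = "list"
  ),
  prototype(mz = numeric(), intensity = numeric(), mode = "reflector",
            metadata = list())
)

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@mode) != 1L || !object@mode %in% c("linear", "reflector"))
    msg <- c(msg, "mode must be 'linear' or 'reflector'")
  if (length(msg)) msg else TRUE
})

#' Construct a MassSpectrum
#'
#' @param mz numeric m/z values. Sorted if not already increasing (with a
#'   warning); exact duplicates are collapsed by keeping the maximum
#'   intensity.
#' @param intensity numeric intensities, same length as `mz`.
#' @param mode `"linear"` or `"reflector"`.
#' @param metadata named list of provenance strings.
#' @return A [MassSpectrum-class] object.
#' @examples
#' s <- massSpectrum(c(1000, 1000.5), c(5, 6))
#' mz(s)
#' @export
massSpectrum <- function(mz, intensity, mode = c("reflector", "linear"),
                         metadata = list()) {
  mode <- match.arg(mode)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z values not strictly increasing; sorting")
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      keep <- !duplicated(mz)
      intensity <- vapply(split(intensity, match(mz, unique(mz))), max,
                          numeric(1))
      mz <- mz[keep]
    }
  }
  new("MassSpectrum", mz = mz, intensity = intensity, mode = mode,
      metadata = metadata)
}

#' MassPeaks: a centroided peak list
#'
#' The matching currency of the package: discrete peak m/z values with
#' intensities and (optionally) signal-to-noise ratios, possibly deisotoped.
#'
#' @slot mz numeric, strictly increasing m/z (Th).
#' @slot intensity numeric, same length.
#' @slot snr numeric signal-to-noise ratios (same length, or length 0 when
#'   not available).
#' @slot isDeisotoped logical flag.
#' @slot metadata named list (source provenance; extra CSV columns end up
#'   here on read).
#' @export
setClass("MassPeaks",
  representation(
    mz = "numeric",
    intensity = "numeric",
    snr = "numeric",
    isDeisotoped = "logical",
    metadata = "list"
  ),
  prototype(mz = numeric(), intensity = numeric(), snr = numeric(),
            isDeisotoped = FALSE, metadata = list())
)

setValidity("MassPeaks", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@snr) && length(object@snr) != length(object@mz))
    msg <- c(msg, "snr must be empty or the same length as mz")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (length(object@snr) && any(object@snr < 0))
    msg <- c(msg, "snr must be non-negative")
  if (length(object@isDeisotoped) != 1L)
    msg <- c(msg, "isDeisotoped must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct a MassPeaks peak list
#'
#' @param mz numeric peak m/z values (sorted internally).
#' @param intensity numeric peak intensities (default 1 for bare mass lists).
#' @param snr optional numeric signal-to-noise ratios.
#' @param isDeisotoped logical, whether isotope envelopes were collapsed.
#' @param metadata named list.
#' @return A [MassPeaks-class] object.
#' @examples
#' p <- massPeaks(c(1200.5, 988.1), c(10, 20))
#' mz(p)  # sorted
#' @export
massPeaks <- function(mz, intensity = rep(1, length(mz)), snr = numeric(),
                      isDeisotoped = FALSE, metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  snr <- as.numeric(snr)
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (length(snr)) snr <- snr[o]
  if (anyDuplicated(mz)) {
    keep <- !duplicated(mz)
    grp <- match(mz, unique(mz))
    intensity <- as.numeric(vapply(split(intensity, grp), max, numeric(1)))
    if (length(snr)) snr <- as.numeric(vapply(split(snr, grp), max, numeric(1)))
    mz <- mz[keep]
  }
  new("MassPeaks", mz = mz, intensity = intensity, snr = snr,
      isDeisotoped = isDeisotoped, metadata = metadata)
}

#' ProteinChain: one antibody polypeptide
#'
#' @slot chainId character, e.g. `"HC"` or `"LC"`.
#' @slot residues character, the amino-acid sequence (20 canonical letters).
#' @slot cysState character, `"reduced"` (free thiols; the fingerprinting
#'   protocols omit alkylation) or `"carbamidomethyl"`.
#' @export
setClass("ProteinChain",
  representation(chainId = "character", residues = "character",
                 cysState = "character"),
  prototype(cysState = "reduced")
)

setValidity("ProteinChain", function(object) {
  msg <- character()
  if (length(object@residues) != 1L || !nzchar(object@residues))
    msg <- c(msg, "residues must be a non-empty string")
  else {
    aa <- strsplit(object@residues, "")[[1]]
    bad <- setdiff(unique(aa), AA_LETTERS)
    if (length(bad))
      msg <- c(msg, paste0("unknown residue letter(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (!object@cysState %in% c("reduced", "carbamidomethyl"))
    msg <- c(msg, "cysState must be 'reduced' or 'carbamidomethyl'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinChain
#'
#' @param chainId chain label, e.g. `"HC"`, `"LC"`.
#' @param residues amino-acid string in the 20-letter canonical alphabet.
#' @param cysState `"reduced"` (default) or `"carbamidomethyl"`.
#' @return A [ProteinChain-class] object.
#' @examples
#' proteinChain("LC", "DIVMTQSPSS")
#' @export
proteinChain <- function(chainId, residues,
                         cysState = c("reduced", "carbamidomethyl")) {
  cysState <- match.arg(cysState)
  new("ProteinChain", chainId = as.character(chainId),
      residues = toupper(as.character(residues)), cysState = cysState)
}

#' LibraryEntry: one fingerprint with its clone metadata
#'
#' @slot clone clone designation (unique together with `method`).
#' @slot abbreviation short display name.
#' @slot isotype e.g. `"IgG1"`.
#' @slot antigen e.g. `"RBD"`, `"S1"`, `"N"`.
#' @slot source producing laboratory / provenance.
#' @slot method `"acid"` or `"trypsin"` (the cleavage chemistry).
#' @slot peaks the fingerprint [MassPeaks-class].
#' @export
setClass("LibraryEntry",
  representation(clone = "character", abbreviation = "character",
                 isotype = "character", antigen = "character",
                 source = "character", method = "character",
                 peaks = "MassPeaks"),
  prototype(abbreviation = "", isotype = "", antigen = "", source = "",
            method = "acid")
)

setValidity("LibraryEntry", function(object) {
  msg <- character()
  if (length(object@clone) != 1L || !nzchar(object@clone))
    msg <- c(msg, "clone must be a non-empty string")
  if (!object@method %in% c("acid", "trypsin"))
    msg <- c(msg, "method must be 'acid' or 'trypsin'")
  if (length(msg)) msg else TRUE
})

#' Construct a LibraryEntry
#'
#' @param clone clone designation.
#' @param peaks a [MassPeaks-class] fingerprint.
#' @param method cleavage method, `"acid"` or `"trypsin"`.
#' @param abbreviation,isotype,antigen,source optional metadata strings.
#' @return A [LibraryEntry-class] object.
#' @export
libraryEntry <- function(clone, peaks, method = c("acid", "trypsin"),
                         abbreviation = "", isotype = "", antigen = "",
                         source = "") {
  method <- match.arg(method)
  new("LibraryEntry", clone = as.character(clone), peaks = peaks,
      method = method, abbreviation = as.character(abbreviation),
      isotype = as.character(isotype), antigen = as.character(antigen),
      source = as.character(source))
}

#' FingerprintLibrary: a searchable collection of fingerprints
#'
#' @slot entries list of [LibraryEntry-class] objects; `clone` + `method`
#'   is unique within a library.
#' @slot provenance free-text description of where the library came from.
#' @export
setClass("FingerprintLibrary",
  representation(entries = "list", provenance = "character"),
  prototype(entries = list(), provenance = "")
)

setValidity("FingerprintLibrary", function(object) {
  msg <- character()
  if (length(object@entries)) {
    ok <- vapply(object@entries, is, logical(1), class2 = "LibraryEntry")
    if (!all(ok)) msg <- c(msg, "entries must all be LibraryEntry objects")
    else {
      key <- vapply(object@entries,
                    function(e) paste(e@clone, e@method, sep = "\r"),
                    character(1))
      if (anyDuplicated(key))
        msg <- c(msg, "clone + method must be unique within a library")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintLibrary
#'
#' @param entries list of [LibraryEntry-class] objects.
#' @param provenance free-text provenance.
#' @return A [FingerprintLibrary-class] object.
#' @export
fingerprintLibrary <- function(entries = list(), provenance = "") {
  new("FingerprintLibrary", entries = entries,
      provenance = as.character(provenance))
}

#' MassMeasurement: replicate mass determinations with a 95% CI
#'
#' @slot kind `"intact"` or `"light_chain"`.
#' @slot replicates numeric replicate masses in Da (>= 2 for a CI).
#' @slot mean mean mass (Da).
#' @slot halfWidth95 half-width of the Student-t 95% confidence interval
#'   (Da): `qt(0.975, n - 1) * sd / sqrt(n)`.
#' @export
setClass("MassMeasurement",
  representation(kind = "character", replicates = "numeric",
                 mean = "numeric", halfWidth95 = "numeric")
)

setValidity("MassMeasurement", function(object) {
  msg <- character()
  if (!object@kind %in% c("intact", "light_chain"))
    msg <- c(msg, "kind must be 'intact' or 'light_chain'")
  if (length(object@replicates) < 2L)
    msg <- c(msg, "at least 2 replicates are required for a CI")
  else {
    if (object@mean < min(object@replicates) - 1e-9 ||
        object@mean > max(object@replicates) + 1e-9)
      msg <- c(msg, "mean must lie within the replicate range")
    if (object@halfWidth95 < 0)
      msg <- c(msg, "halfWidth95 must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MassMeasurement from replicate masses
#'
#' The 95% confidence half-width uses the Student-t quantile with `n - 1`
#' degrees of freedom: `qt(0.975, n - 1) * sd / sqrt(n)`.
#'
#' @param replicates numeric vector of replicate masses (Da), length >= 2.
#' @param kind `"intact"` or `"light_chain"`.
#' @return A [MassMeasurement-class] object.
#' @examples
#' m <- massMeasurement(c(148210, 148225, 148218), "intact")
#' halfWidth95(m)
#' @export
massMeasurement <- function(replicates, kind = c("intact", "light_chain")) {
  kind <- match.arg(kind)
  replicates <- as.numeric(replicates)
  if (length(replicates) < 2L)
    stop("at least 2 replicates are required for a confidence interval")
  n <- length(replicates)
  hw <- stats::qt(0.975, df = n - 1) * stats::sd(replicates) / sqrt(n)
  new("MassMeasurement", kind = kind, replicates = replicates,
      mean = mean(replicates), halfWidth95 = hw)
}
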