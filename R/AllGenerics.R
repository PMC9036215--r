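#' Accessors for spectra, peak lists and libraries
#'
#' `mz()`, `intensity()`, `snr()`, `acquisitionMode()`, `spectrumMetadata()`
#' extract the corresponding slots; `nPeaks()` counts peaks in a
#' [MassPeaks-class], [LibraryEntry-class] or per entry of a
#' [FingerprintLibrary-class]; `entries()` returns a library's entry list.
#'
#' @param object a package object.
#' @return The slot contents (vectors, lists or counts).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("snr", function(object) standardGeneric("snr"))
#' @rdname accessors
#' @export
setGeneric("acquisitionMode",
           function(object) standardGeneric("acquisitionMode"))
#' @rdname accessors
#' @export
setGeneric("spectrumMetadata",
           function(object) standardGeneric("spectrumMetadata"))
#' @rdname accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("isDeisotoped", function(object) standardGeneric("isDeisotoped"))
#' @rdname accessors
#' @export
setGeneric("chainId", function(object) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("halfWidth95", function(object) standardGeneric("halfWidth95"))

#' @rdname accessors
#' @export
setMethod("mz", "MassSpectrum", function(object) object@mz)
#' @rdname accessors
#' @export
setMethod("mz", "MassPeaks", function(object) object@mz)
#' @rdname accessors
#' @export
setMethod("intensity", "MassSpectrum", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("intensity", "MassPeaks", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("snr", "MassPeaks", function(object) object@snr)
#' @rdname accessors
#' @export
setMethod("acquisitionMode", "MassSpectrum", function(object) object@mode)
#' @rdname accessors
#' @export
setMethod("spectrumMetadata", "MassSpectrum", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("spectrumMetadata", "MassPeaks", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("isDeisotoped", "MassPeaks", function(object) object@isDeisotoped)
#' @rdname accessors
#' @export
setMethod("nPeaks", "MassPeaks", function(object) length(object@mz))
#' @rdname accessors
#' @export
setMethod("nPeaks", "LibraryEntry", function(object) length(object@peaks@mz))
#' @rdname accessors
#' @export
setMethod("nPeaks", "FingerprintLibrary", function(object)
  vapply(object@entries, function(e) length(e@peaks@mz), integer(1)))
#' @rdname accessors
#' @export
setMethod("entries", "FingerprintLibrary", function(object) object@entries)
#' @rdname accessors
#' @export
setMethod("chainId", "ProteinChain", function(object) object@chainId)
#' @rdname accessors
#' @export
setMethod("residues", "ProteinChain", function(object) object@residues)
#' @rdname accessors
#' @export
setMethod("halfWidth95", "MassMeasurement", function(object)
  object@halfWidth95)

#' @rdname accessors
#' @export
setMethod("length", "MassPeaks", function(x) length(x@mz))

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum (", object@mode, " mode): ", length(object@mz),
      " points", sep = "")
  if (length(object@mz))
    cat(sprintf(", m/z %.1f-%.1f", object@mz[1], object@mz[length(object@mz)]))
  cat("\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), unlist(object@metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "MassPeaks", function(object) {
  cat("MassPeaks: ", length(object@mz), " peaks",
      if (object@isDeisotoped) " (deisotoped)" else "", sep = "")
  if (length(object@mz))
    cat(sprintf(", m/z %.2f-%.2f", object@mz[1],
                object@mz[length(object@mz)]))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "ProteinChain", function(object) {
  cat("ProteinChain ", object@chainId, ": ", nchar(object@residues),
      " residues (Cys ", object@cysState, ")\n", sep = "")
  invisible(NULL)
})

setMethod("show", "LibraryEntry", function(object) {
  cat("LibraryEntry ", object@clone, " [", object@method, "]: ",
      length(object@peaks@mz), " peaks", sep = "")
  if (nzchar(object@isotype)) cat(";", object@isotype)
  if (nzchar(object@antigen)) cat(" anti-", object@antigen, sep = "")
  cat("\n")
  invisible(NULL)
})

setMethod("show", "FingerprintLibrary", function(object) {
  cat("FingerprintLibrary:", length(object@entries), "entries\n")
  if (length(object@entries)) {
    m <- table(vapply(object@entries, function(e) e@method, character(1)))
    cat("  methods:", paste(names(m), m, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "MassMeasurement", function(object) {
  cat(sprintf("MassMeasurement (%s): %.1f +/- %.1f Da (95%% CI, n=%d)\n",
              object@kind, object@mean, object@halfWidth95,
              length(object@replicates)))
  invisible(NULL)
})
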