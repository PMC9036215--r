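#' Build subclass references from constant-region sequences
#'
#' Digests CH2-CH3 (Fc constant-region) sequences in silico with both
#' cleavage chemistries and stores the resulting theoretical mass lists per
#' subclass. FASTA headers must start with the subclass label (e.g.
#' `>IgG1 species=mouse ...`); duplicate subclass labels are treated as
#' allelic variants and their mass lists are unioned.
#'
#' @param fcSequences path to a FASTA file of CH2-CH3 sequences, or a list
#'   of [ProteinChain-class] objects whose `chainId` is the subclass label.
#'   Defaults to the synthetic murine IgG1/IgG2a/IgG2b/IgG3 reference set
#'   bundled with the package (see [syntheticSubclassFasta()]); supply your
#'   own FASTA of real constant-region sequences for production use.
#' @param paramsAcid,paramsTrypsin [digestParams()] for the two methods.
#' @param species species annotation stored on each reference.
#' @return A list of class `SubclassReferenceSet`: per subclass a list with
#'   `subclass`, `species`, `chains` and `peptideMasses` (named list
#'   `acid` / `trypsin` of sorted m/z vectors).
#' @export
buildSubclassReference <- function(fcSequences = syntheticSubclassFasta(),
                                   paramsAcid = digestParams("acid_asp"),
                                   paramsTrypsin = digestParams("trypsin"),
                                   species = "mouse") {
  chains <- if (is.character(fcSequences)) readChainsFasta(fcSequences)
            else fcSequences
  if (!length(chains)) stop("parameter error: no constant-region sequences")
  labels <- vapply(chains, chainId, character(1))
  ## strip allele suffixes like "IgG1.2" / "IgG1_b" to group variants
  subclass <- sub("[._-].*$", "", labels)
  if (length(unique(subclass)) < 2L)
    stop("parameter error: at least 2 subclasses are required")
  refs <- lapply(split(chains, subclass), function(variants) {
    masses <- lapply(list(acid = paramsAcid, trypsin = paramsTrypsin),
                     function(p) {
      m <- sort(unlist(lapply(variants, theoreticalFingerprint, params = p),
                       use.names = FALSE))
      if (length(m)) m[c(TRUE, diff(m) > 1e-4)] else numeric()
    })
    list(subclass = chainId(variants[[1]]), species = species,
         chains = variants, peptideMasses = masses)
  })
  ## keep the original first-seen subclass order
  refs <- refs[unique(subclass)]
  names(refs) <- unique(subclass)
  structure(refs, class = "SubclassReferenceSet")
}

#' Path to the bundled synthetic murine subclass FASTA
#'
#' CH2-CH3 stand-in sequences for murine IgG1, IgG2a, IgG2b and IgG3.
#' These are synthetic sequences (generated once, at realistic amino-acid
#' composition and inter-subclass divergence), not database entries; they
#' exercise the subclass-calling machinery and calibrate its simulation
#' tests, but real constant-region sequences should be supplied for real
#' samples.
#'
#' @return File path of the FASTA inside the installed package.
#' @export
syntheticSubclassFasta <- function() {
  system.file("extdata", "synthetic_murine_igg_ch2ch3.fasta",
              package = "mAbFingerprint", mustWork = TRUE)
}

#' Determine the antibody subclass from a fingerprint
#'
#' Counts matching peptides between the sample peak list and each
#' subclass's theoretical constant-region mass list (one-to-one matching
#' under `dmz`, intensities ignored); the subclass with the most matches is
#' called. Ties are reported as indecisive with the lexicographically first
#' subclass. A call is `decisive` when the margin to the runner-up reaches
#' `minMargin`.
#'
#' @param sample a [MassPeaks-class].
#' @param refs a `SubclassReferenceSet` from [buildSubclassReference()].
#' @param method `"acid"` or `"trypsin"` -- must match the sample's
#'   cleavage chemistry.
#' @param dmz mass tolerance in Da (default 0.3).
#' @param minMargin minimal best-to-second margin for a decisive call
#'   (default 2).
#' @param discriminativeOnly drop masses shared between subclasses (within
#'   `dmz`) before counting; improves margins but deviates from plain
#'   match counting, so off by default.
#' @return List of class `SubclassCall`: `best`, `counts` (named integer),
#'   `margin`, `decisive`, `tie`.
#' @export
determineSubclass <- function(sample, refs, method = c("acid", "trypsin"),
                              dmz = 0.3, minMargin = 2L,
                              discriminativeOnly = FALSE) {
  stopifnot(is(sample, "MassPeaks"), inherits(refs, "SubclassReferenceSet"))
  method <- match.arg(method)
  if (!length(sample@mz)) stop("parameter error: empty sample peak list")
  lists <- lapply(refs, function(r) {
    if (is.null(r$peptideMasses[[method]]))
      stop("parameter error: method '", method, "' missing in references")
    r$peptideMasses[[method]]
  })
  if (discriminativeOnly) {
    lists <- lapply(seq_along(lists), function(i) {
      others <- sort(unlist(lists[-i], use.names = FALSE))
      keep <- vapply(lists[[i]], function(m)
        !length(others) || min(abs(others - m)) > dmz, logical(1))
      lists[[i]][keep]
    })
    names(lists) <- names(refs)
  }
  counts <- vapply(lists, function(m)
    matchCount(sample, m, dmz)$nMatching, integer(1))
  o <- order(-counts, names(counts))
  best <- names(counts)[o[1]]
  margin <- if (length(counts) > 1L) counts[o[1]] - counts[o[2]] else
    counts[o[1]]
  tie <- length(counts) > 1L && margin == 0L
  structure(list(best = best, counts = counts[o],
                 margin = as.integer(margin),
                 decisive = !tie && margin >= minMargin, tie = tie),
            class = "SubclassCall")
}

#' @export
print.SubclassCall <- function(x, ...) {
  cat("Subclass call:", x$best,
      if (x$tie) "(tie, indecisive)"
      else if (x$decisive) "(decisive)" else "(margin below threshold)",
      "\n  matching peptides:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
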