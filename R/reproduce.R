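#' Reproduce the full-scale antibody-panel analysis from raw spectra
#'
#' Driver for re-running the complete workflow on a local copy of a real
#' measurement campaign (raw spectra are not bundled; the public deposit
#' must be downloaded separately). The expected layout under `dataDir` is
#'
#' * `fingerprints/<clone>_<method>.<ext>` -- reflector-mode fingerprint
#'   spectra, `method` in `acid`/`trypsin`, `ext` one of `mzML`, `txt`,
#'   `csv`;
#' * `masses/<clone>_<kind>_<rep>.<ext>` -- linear-mode spectra, `kind` in
#'   `intact`/`light`, `rep` 1..3;
#' * the reference antibody's files under the clone id given by
#'   `referenceId`.
#'
#' Fingerprints are processed with [detectPeaks()] into a
#' [FingerprintLibrary-class]; every fingerprint is then matched back
#' against the library ([rankLibrary()]) to obtain self-match fractions and
#' decision margins, and the linear-mode replicates are reduced to a
#' [massRecordTable()] and a CI-overlap uniqueness analysis.
#'
#' @param dataDir directory with the layout above.
#' @param referenceId clone id of the reference antibody (default
#'   `"NIST-mAb-8671"`).
#' @param processing a [processingParams()] list.
#' @param dmz match tolerance in Da.
#' @return List: `library`, `rankings` (per sample), `selfMatchFractions`,
#'   `margins`, `massRecords`, `uniqueness`.
#' @export
reproduceStudy <- function(dataDir, referenceId = "NIST-mAb-8671",
                           processing = processingParams(), dmz = 0.3) {
  fpDir <- file.path(dataDir, "fingerprints")
  if (!dir.exists(fpDir))
    stop("data error: no 'fingerprints' directory under ", dataDir,
         "; a local copy of the raw-spectra deposit is required")
  fpFiles <- list.files(fpDir, full.names = TRUE)
  info <- regmatches(basename(fpFiles),
                     regexec("^(.+)_(acid|trypsin)\\.[^.]+$",
                             basename(fpFiles)))
  keep <- lengths(info) == 3L
  fpFiles <- fpFiles[keep]
  info <- info[keep]
  if (!length(fpFiles)) stop("data error: no fingerprint spectra found")
  ents <- vector("list", length(fpFiles))
  for (i in seq_along(fpFiles)) {
    spec <- readSpectrum(fpFiles[i], mode = "reflector")
    ents[[i]] <- libraryEntry(info[[i]][2], detectPeaks(spec, processing),
                              method = info[[i]][3])
  }
  lib <- fingerprintLibrary(ents, provenance = dataDir)

  rankings <- lapply(seq_along(ents), function(i)
    rankLibrary(ents[[i]]@peaks, lib, dmz,
                methodFilter = ents[[i]]@method))
  names(rankings) <- vapply(ents, function(e)
    paste(e@clone, e@method, sep = "_"), character(1))
  selfFrac <- vapply(rankings, function(r) r$fraction[1], numeric(1))
  margins <- vapply(rankings, function(r)
    if (nrow(r) >= 3L) decisionMargin(r, excludeSelf = TRUE) else
      NA_integer_, integer(1))

  massDir <- file.path(dataDir, "masses")
  records <- NULL
  uniq <- NULL
  if (dir.exists(massDir)) {
    mfiles <- list.files(massDir, full.names = TRUE)
    minfo <- regmatches(basename(mfiles),
                        regexec("^(.+)_(intact|light)_(\\d+)\\.[^.]+$",
                                basename(mfiles)))
    keep <- lengths(minfo) == 4L
    mfiles <- mfiles[keep]
    minfo <- minfo[keep]
    clones <- unique(vapply(minfo, `[`, character(1), 2))
    getMeas <- function(clone, kind) {
      sel <- vapply(minfo, function(m)
        m[2] == clone && m[3] == kind, logical(1))
      if (sum(sel) < 2L) return(NULL)
      reps <- vapply(mfiles[sel], function(f) {
        s <- readSpectrum(f, mode = "linear")
        if (kind == "intact") intactMass(s) else lightChainMass(s)
      }, numeric(1))
      massMeasurement(reps, if (kind == "intact") "intact" else
        "light_chain")
    }
    refI <- getMeas(referenceId, "intact")
    refL <- getMeas(referenceId, "light")
    if (!is.null(refI) && !is.null(refL)) {
      rows <- list()
      for (cl in setdiff(clones, referenceId)) {
        mi <- getMeas(cl, "intact")
        ml <- getMeas(cl, "light")
        if (is.null(mi) || is.null(ml)) next
        di <- relativeMass(mi, refI)
        dl <- relativeMass(ml, refL)
        rows[[cl]] <- c(di$delta, di$halfWidth95, dl$delta, dl$halfWidth95)
      }
      if (length(rows) >= 2L) {
        m <- do.call(rbind, rows)
        records <- massRecordTable(names(rows), m[, 1], m[, 2], m[, 3],
                                   m[, 4], referenceId)
        uniq <- list(both = countUnique(records, "both"),
                     light_only = countUnique(records, "light_only"))
      }
    }
  }
  list(library = lib, rankings = rankings, selfMatchFractions = selfFrac,
       margins = margins, massRecords = records, uniqueness = uniq)
}
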