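#' Count matching peaks between a sample and a library fingerprint
#'
#' Pairs sample peaks with entry peaks one-to-one under the mass tolerance
#' `dmz`, maximising the number of matched pairs: an ordered sweep over
#' both sorted lists assigns each sample peak the lowest-m/z entry peak
#' still unused within `+/- dmz`. Because each sample peak's candidates
#' form a contiguous, monotonically advancing block of the entry list,
#' this sweep attains the maximum-cardinality one-to-one matching, and it
#' is deterministic. One-to-one consumption means a dense noisy sample
#' cannot inflate the count; in the typical fingerprint regime (peak
#' spacing > 2 * dmz) the pairing is simply nearest-peak assignment.
#'
#' @param sample a [MassPeaks-class] (or numeric mass vector).
#' @param entry a [MassPeaks-class] (or numeric mass vector).
#' @param dmz mass tolerance in Da (> 0), default 0.3.
#' @return List of class `MatchResult`: `nMatching`, `fraction`
#'   (`nMatching / nPeaks(sample)`; NaN for an empty sample) and
#'   `matchedPairs` (data.frame with `sampleMz`, `entryMz`, `deltaM`).
#' @examples
#' matchCount(massPeaks(c(1000, 2000)), massPeaks(c(1000.05, 3000)),
#'            dmz = 0.1)$nMatching  # 1
#' @export
matchCount <- function(sample, entry, dmz = 0.3) {
  if (dmz <= 0) stop("dmz must be positive")
  s <- if (is(sample, "MassPeaks")) sample@mz else sort(as.numeric(sample))
  e <- if (is(entry, "MassPeaks")) entry@mz else sort(as.numeric(entry))
  si <- integer()
  ei <- integer()
  if (length(s) && length(e)) {
    lo <- findInterval(s - dmz, e) + 1L
    hi <- findInterval(s + dmz, e)
    j <- 1L
    for (i in seq_along(s)) {
      a <- max(j, lo[i])
      if (a <= hi[i]) {
        si <- c(si, i)
        ei <- c(ei, a)
        j <- a + 1L
      }
    }
  }
  mp <- data.frame(sampleMz = s[si], entryMz = e[ei],
                   deltaM = s[si] - e[ei])
  structure(list(nMatching = nrow(mp),
                 fraction = nrow(mp) / length(s),
                 matchedPairs = mp),
            class = "MatchResult")
}

#' Rank a fingerprint library against a sample spectrum
#'
#' Compares the sample peak list with every library entry via
#' [matchCount()] and sorts the entries by descending number of matching
#' peptides; ties break by matched fraction, then clone name. A library
#' entry identical to the sample therefore ranks first with fraction 1
#' (the 100% self-match).
#'
#' @param sample a [MassPeaks-class].
#' @param library a [FingerprintLibrary-class].
#' @param dmz mass tolerance in Da (default 0.3).
#' @param methodFilter restrict to entries of one cleavage method
#'   (`"acid"`, `"trypsin"`) or `NULL` for all. Matching across methods is
#'   meaningless, so per-method libraries are the norm.
#' @param query optional metadata filter applied first (see
#'   [filterLibrary()]).
#' @return A data.frame of class `MatchRanking` with one row per entry:
#'   `rank`, `clone`, `abbreviation`, `isotype`, `antigen`, `source`,
#'   `method`, `nPeaks`, `nMatching`, `fraction`. The per-entry
#'   `MatchResult` objects are attached as attribute `"results"`.
#' @export
rankLibrary <- function(sample, library, dmz = 0.3, methodFilter = NULL,
                        query = NULL) {
  stopifnot(is(sample, "MassPeaks"), is(library, "FingerprintLibrary"))
  if (!is.null(query)) library <- filterLibrary(library, query)
  ents <- library@entries
  if (!is.null(methodFilter))
    ents <- Filter(function(e) e@method == methodFilter, ents)
  if (!length(ents)) {
    out <- data.frame(rank = integer(), clone = character(),
                      abbreviation = character(), isotype = character(),
                      antigen = character(), source = character(),
                      method = character(), nPeaks = integer(),
                      nMatching = integer(), fraction = numeric())
    class(out) <- c("MatchRanking", "data.frame")
    return(out)
  }
  res <- lapply(ents, function(e) matchCount(sample, e@peaks, dmz))
  out <- data.frame(
    clone = vapply(ents, function(e) e@clone, character(1)),
    abbreviation = vapply(ents, function(e) e@abbreviation, character(1)),
    isotype = vapply(ents, function(e) e@isotype, character(1)),
    antigen = vapply(ents, function(e) e@antigen, character(1)),
    source = vapply(ents, function(e) e@source, character(1)),
    method = vapply(ents, function(e) e@method, character(1)),
    nPeaks = vapply(ents, function(e) length(e@peaks@mz), integer(1)),
    nMatching = vapply(res, function(r) r$nMatching, integer(1)),
    fraction = vapply(res, function(r) r$fraction, numeric(1)),
    stringsAsFactors = FALSE
  )
  o <- order(-out$nMatching, -out$fraction, out$clone)
  out <- out[o, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "results") <- res[o]
  class(out) <- c("MatchRanking", "data.frame")
  out
}

#' Filter a fingerprint library by a metadata query
#'
#' Case-insensitive substring search over all metadata fields (clone,
#' abbreviation, isotype, antigen, source, method): e.g. query `"RBD"`
#' keeps only entries whose antigen (or any other field) contains "RBD".
#' The empty query is the identity. The input library is not modified.
#'
#' @param library a [FingerprintLibrary-class].
#' @param query character scalar.
#' @return A new [FingerprintLibrary-class] with the matching entries.
#' @export
filterLibrary <- function(library, query) {
  stopifnot(is(library, "FingerprintLibrary"))
  query <- as.character(query)
  if (!nzchar(query)) return(library)
  keep <- vapply(library@entries, function(e) {
    fields <- c(e@clone, e@abbreviation, e@isotype, e@antigen, e@source,
                e@method)
    any(grepl(query, fields, ignore.case = TRUE, fixed = FALSE))
  }, logical(1))
  fingerprintLibrary(library@entries[keep], library@provenance)
}

#' Decision margin of a ranked match table
#'
#' The difference in matching peptides between the best and the second-best
#' library hit, the quantity a user inspects to decide whether the best
#' match identifies the clone. With `excludeSelf = TRUE`, a leading
#' self-match (fraction 1 with all sample peaks matched) is dropped first,
#' so the margin refers to the best true candidate.
#'
#' @param ranking a `MatchRanking` data.frame from [rankLibrary()].
#' @param excludeSelf drop a leading 100% self-match first (default FALSE).
#' @return Integer margin `nMatching[1] - nMatching[2]`.
#' @examples
#' \dontrun{decisionMargin(ranking)  # counts 37, 18, ... -> 19}
#' @export
decisionMargin <- function(ranking, excludeSelf = FALSE) {
  stopifnot(is.data.frame(ranking))
  nm <- ranking$nMatching
  if (excludeSelf && nrow(ranking) && ranking$fraction[1] >= 1)
    nm <- nm[-1]
  if (length(nm) < 2L)
    stop("undefined margin: fewer than 2 ranked results")
  as.integer(nm[1] - nm[2])
}

#' Persist and load fingerprint libraries as plain-text directories
#'
#' A library directory holds one metadata table `library.csv` (columns
#' `clone`, `abbreviation`, `isotype`, `antigen`, `source`, `method`,
#' `peak_file`) plus one peak-list CSV per entry under `peaks/`. The layout
#' is diff-able and append-only.
#'
#' @param library a [FingerprintLibrary-class].
#' @param dir directory path (created by `writeLibrary`).
#' @return `writeLibrary()` returns `dir` invisibly; `readLibrary()` a
#'   [FingerprintLibrary-class].
#' @export
writeLibrary <- function(library, dir) {
  stopifnot(is(library, "FingerprintLibrary"))
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  ents <- library@entries
  files <- vapply(ents, function(e)
    file.path("peaks", paste0(gsub("[^A-Za-z0-9._-]", "_", e@clone), "_",
                              e@method, ".csv")), character(1))
  for (i in seq_along(ents))
    writePeakList(ents[[i]]@peaks, file.path(dir, files[i]))
  meta <- data.frame(
    clone = vapply(ents, function(e) e@clone, character(1)),
    abbreviation = vapply(ents, function(e) e@abbreviation, character(1)),
    isotype = vapply(ents, function(e) e@isotype, character(1)),
    antigen = vapply(ents, function(e) e@antigen, character(1)),
    source = vapply(ents, function(e) e@source, character(1)),
    method = vapply(ents, function(e) e@method, character(1)),
    peak_file = files, stringsAsFactors = FALSE
  )
  utils::write.csv(meta, file.path(dir, "library.csv"), row.names = FALSE)
  if (nzchar(library@provenance))
    writeLines(library@provenance, file.path(dir, "PROVENANCE.txt"))
  invisible(dir)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(dir) {
  meta_path <- file.path(dir, "library.csv")
  if (!file.exists(meta_path))
    stop("not a library directory (missing library.csv): ", dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  ents <- lapply(seq_len(nrow(meta)), function(i) {
    libraryEntry(meta$clone[i],
                 readPeakList(file.path(dir, meta$peak_file[i])),
                 method = meta$method[i],
                 abbreviation = meta$abbreviation[i],
                 isotype = meta$isotype[i], antigen = meta$antigen[i],
                 source = meta$source[i])
  })
  prov_path <- file.path(dir, "PROVENANCE.txt")
  prov <- if (file.exists(prov_path))
    paste(readLines(prov_path, warn = FALSE), collapse = "\n") else ""
  fingerprintLibrary(ents, prov)
}

#' Add an entry to a library directory
#'
#' @param dir library directory (created if absent).
#' @param entry a [LibraryEntry-class].
#' @return The updated [FingerprintLibrary-class], invisibly.
#' @export
libraryAdd <- function(dir, entry) {
  stopifnot(is(entry, "LibraryEntry"))
  lib <- if (file.exists(file.path(dir, "library.csv"))) readLibrary(dir)
         else fingerprintLibrary()
  lib <- fingerprintLibrary(c(lib@entries, list(entry)), lib@provenance)
  writeLibrary(lib, dir)
  invisible(lib)
}
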