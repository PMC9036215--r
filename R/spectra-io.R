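#' Read a profile spectrum from disk
#'
#' Accepts PSI-standard mzML (first spectrum of the file, via the `mzR`
#' package) and plain-text exports: whitespace- or comma-separated two-column
#' (m/z, intensity) files, with lines beginning with `#` skipped. A leading
#' header line of column names is tolerated.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mzml"`, `"xy_text"` or `"csv"`.
#' @param mode acquisition mode to record, `"reflector"` or `"linear"`;
#'   `"auto"` guesses linear for spectra reaching above 10 kTh.
#' @param metadata named list merged into the spectrum metadata.
#' @return A [MassSpectrum-class]. Non-monotone m/z values are sorted with a
#'   warning; fewer than 2 data points is a format error.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# demo", "1000.0 5.0", "1000.5 6.0"), f)
#' s <- readSpectrum(f)
#' mz(s)
#' @export
readSpectrum <- function(path, format = c("auto", "mzml", "xy_text", "csv"),
                         mode = c("auto", "reflector", "linear"),
                         metadata = list()) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read spectrum: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mzml = "mzml",
      csv = "csv",
      txt = , xy = , tab = , tsv = , dat = "xy_text",
      stop("cannot resolve spectrum format from extension '.", ext, "'")
    )
  }
  if (format == "mzml") {
    xy <- .readMzml(path)
  } else {
    xy <- .readXY(path, sep = if (format == "csv") "," else "")
  }
  if (nrow(xy) < 2L)
    stop("format error: spectrum has fewer than 2 data points: ", path)
  if (mode == "auto")
    mode <- if (max(xy[[1]]) > 10000) "linear" else "reflector"
  md <- utils::modifyList(list(file = basename(path)), metadata)
  massSpectrum(xy[[1]], pmax(xy[[2]], 0), mode = mode, metadata = md)
}

.readMzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  if (mzR::runInfo(h)$scanCount < 1L)
    stop("format error: mzML file contains no spectra: ", path)
  p <- mzR::peaks(h, 1L)
  data.frame(mz = p[, 1], intensity = p[, 2])
}

.readXY <- function(path, sep = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    stop("format error: no data lines in ", path)
  ## tolerate a header line of column names
  first <- strsplit(trimws(lines[1]),
                    if (nzchar(sep)) sep else "[[:space:]]+")[[1]]
  skip_header <- suppressWarnings(any(is.na(as.numeric(first[1:2]))))
  if (skip_header) lines <- lines[-1]
  if (!length(lines))
    stop("format error: no data lines in ", path)
  xy <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          col.names = c("mz", "intensity"),
                          colClasses = "numeric", fill = FALSE)
  if (anyNA(xy))
    stop("format error: non-numeric values in ", path)
  xy
}

#' Write a profile spectrum to disk
#'
#' @param spec a [MassSpectrum-class].
#' @param path output path.
#' @param format `"auto"` (by extension), `"mzml"`, `"xy_text"` or `"csv"`.
#' @return `path`, invisibly. `readSpectrum()` is its inverse to float
#'   round-trip precision.
#' @export
writeSpectrum <- function(spec, path,
                          format = c("auto", "mzml", "xy_text", "csv")) {
  stopifnot(is(spec, "MassSpectrum"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", csv = "csv", "xy_text")
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("writing mzML requires the 'mzR' package")
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
      peaksCount = length(spec@mz), totIonCurrent = sum(spec@intensity),
      retentionTime = 0, basePeakMZ = if (length(spec@mz))
        spec@mz[which.max(spec@intensity)] else 0,
      basePeakIntensity = if (length(spec@intensity))
        max(spec@intensity) else 0,
      collisionEnergy = 0, ionisationEnergy = 0, lowMZ = min(spec@mz),
      highMZ = max(spec@mz), precursorScanNum = 0L, precursorMZ = 0,
      precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
      mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
      mergedResultEndScanNum = 0L, injectionTime = 0, filterString = "",
      spectrumId = "scan=1", centroided = FALSE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = min(spec@mz),
      scanWindowUpperLimit = max(spec@mz), stringsAsFactors = FALSE
    )
    mzR::writeMSData(list(cbind(spec@mz, spec@intensity)), file = path,
                     header = hdr)
  } else {
    sep <- if (format == "csv") "," else " "
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(paste0("%.*f", sep, "%.6g"), 6L, spec@mz,
                       spec@intensity), con)
  }
  invisible(path)
}

#' Read and write centroided peak lists (CSV)
#'
#' The on-disk dialect is a CSV with header `mz,intensity,snr` (the `snr`
#' column may be absent). Extra columns are preserved in the peak list's
#' metadata under their column names, so user annotations survive a
#' round-trip.
#'
#' @param path CSV path.
#' @return `readPeakList()` returns a [MassPeaks-class];
#'   `writePeakList()` returns `path` invisibly. m/z round-trips to 6
#'   decimal places.
#' @examples
#' p <- massPeaks(c(1000.123456, 2000.5), c(10, 3))
#' f <- tempfile(fileext = ".csv")
#' writePeakList(p, f)
#' mz(readPeakList(f))
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("cannot read peak list: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("format error: peak-list CSV must have 'mz' and 'intensity' columns")
  snr <- if ("snr" %in% names(df)) as.numeric(df$snr) else numeric()
  if (length(snr) && all(is.na(snr))) snr <- numeric()
  extra <- setdiff(names(df), c("mz", "intensity", "snr"))
  md <- if (length(extra)) as.list(df[extra]) else list()
  massPeaks(df$mz, df$intensity, snr = snr, metadata = md)
}

#' @rdname readPeakList
#' @param peaks a [MassPeaks-class] to serialise.
#' @export
writePeakList <- function(peaks, path) {
  stopifnot(is(peaks, "MassPeaks"))
  df <- data.frame(mz = sprintf("%.6f", peaks@mz),
                   intensity = peaks@intensity)
  df$snr <- if (length(peaks@snr)) peaks@snr else NA_real_
  extra <- peaks@metadata[vapply(peaks@metadata,
                                 function(x) length(x) == nrow(df),
                                 logical(1))]
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
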