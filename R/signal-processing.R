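#' Processing parameters for fingerprint spectra
#'
#' Bundles the knobs used to turn a raw reflector-mode trace into a
#' deisotoped peak list. Savitzky-Golay needs an odd window, so even values
#' are coerced up to the next odd integer (e.g. 50 becomes 51). The default
#' window is 9 points: on an isotope-resolved reflector grid the smoothing
#' window must stay comparable to one peak width, unlike the much wider
#' 51-point window appropriate for broad linear-mode peaks (see
#' [apexMass()]).
#'
#' @param sgWindow Savitzky-Golay window in points (coerced odd, default 9).
#' @param sgOrder Savitzky-Golay polynomial order (default 2).
#' @param baselineIterations SNIP clipping iterations (default 100).
#' @param snrMin minimal signal-to-noise ratio for a peak (default 3).
#' @param minRelIntensity minimal intensity as a fraction of the base peak
#'   (default 0.01).
#' @param deisotope collapse isotope envelopes after picking (default TRUE;
#'   reflector spectra resolve isotopes).
#' @param isotopeSpacing isotopologue spacing in Da (default 1.00235).
#' @param dmz mass tolerance in Da used for matching and for isotope
#'   grouping (default 0.3; user-settable to track calibration quality).
#' @param halfWindowMz neighbourhood half-width in Da a peak apex must
#'   dominate (default 0.3; must stay below the isotope spacing).
#' @return A list of class `ProcessingParams`.
#' @export
processingParams <- function(sgWindow = 9, sgOrder = 2,
                             baselineIterations = 100, snrMin = 3,
                             minRelIntensity = 0.01, deisotope = TRUE,
                             isotopeSpacing = 1.00235, dmz = 0.3,
                             halfWindowMz = 0.3) {
  sgWindow <- as.integer(sgWindow)
  if (sgWindow %% 2L == 0L) sgWindow <- sgWindow + 1L
  if (sgWindow < sgOrder + 2) stop("sgWindow must be >= sgOrder + 2")
  if (snrMin <= 0) stop("snrMin must be positive")
  if (dmz <= 0) stop("dmz must be positive")
  if (minRelIntensity < 0 || minRelIntensity >= 1)
    stop("minRelIntensity must be in [0, 1)")
  structure(list(sgWindow = sgWindow, sgOrder = as.integer(sgOrder),
                 baselineIterations = as.integer(baselineIterations),
                 snrMin = snrMin, minRelIntensity = minRelIntensity,
                 deisotope = isTRUE(deisotope),
                 isotopeSpacing = isotopeSpacing, dmz = dmz,
                 halfWindowMz = halfWindowMz),
            class = "ProcessingParams")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing via `signal::sgolayfilt`. Endpoints
#' are handled by the filter's edge rows, i.e. polynomial fits on the
#' truncated window, so the output has the same length as the input and
#' polynomials up to `order` are reproduced exactly.
#'
#' @param spec a [MassSpectrum-class].
#' @param window odd window length in points (even values coerced up).
#' @param order polynomial order.
#' @return A smoothed [MassSpectrum-class] (negative filter ringing is
#'   clamped to zero).
#' @export
smoothSavitzkyGolay <- function(spec, window = 51, order = 2) {
  stopifnot(is(spec, "MassSpectrum"))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(spec@mz)
  if (window > n)
    stop("parameter error: smoothing window (", window,
         ") exceeds data length (", n, ")")
  y <- signal::sgolayfilt(spec@intensity, p = order, n = window)
  initialize(spec, intensity = pmax(y, 0))
}

## Raw numeric SG smoothing (no clamping), used where the exact filtered
## trace is wanted (apex picking).
.sgSmooth <- function(y, window, order) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  signal::sgolayfilt(y, p = order, n = window)
}

#' SNIP baseline estimation and subtraction
#'
#' Statistics-sensitive non-linear iterative peak-clipping (SNIP) with the
#' usual log-log-square-root compression: at iteration `i` each point is
#' replaced by the minimum of itself and the mean of its neighbours `i`
#' points away. The clipping window grows with the iteration count, so
#' `iterations` bounds the half-width (in points) of the widest structure
#' treated as baseline.
#'
#' @param spec a [MassSpectrum-class].
#' @param iterations clipping iterations (default 100).
#' @param returnBaseline if TRUE, return the estimated baseline instead of
#'   the corrected spectrum.
#' @return A [MassSpectrum-class] with the baseline subtracted (intensities
#'   clamped at zero).
#' @export
baselineCorrect <- function(spec, iterations = 100, returnBaseline = FALSE) {
  stopifnot(is(spec, "MassSpectrum"))
  if (!length(spec@mz)) stop("empty spectrum")
  b <- .snipBaseline(spec@intensity, as.integer(iterations))
  if (returnBaseline) return(initialize(spec, intensity = b))
  initialize(spec, intensity = pmax(spec@intensity - b, 0))
}

.snipBaseline <- function(y, iterations) {
  n <- length(y)
  v <- log(log(sqrt(pmax(y, 0) + 1) + 1) + 1)  # LLS compression
  kmax <- min(iterations, (n - 1L) %/% 2L)
  if (kmax >= 1L) for (k in seq_len(kmax)) {
    idx <- (k + 1L):(n - k)
    w <- (v[idx - k] + v[idx + k]) / 2
    v[idx] <- pmin(v[idx], w)
  }
  (exp(exp(v) - 1) - 1)^2 - 1
}

## Robust per-point noise model: median (centre) and MAD x 1.4826 (scale)
## of the signal in non-overlapping windows of `width` points, linearly
## interpolated. The centre captures any pedestal left by baseline
## subtraction; the scale is robust to sparse peaks.
.noiseProfile <- function(y, width = 250L) {
  n <- length(y)
  if (n <= width) {
    return(list(center = rep(stats::median(y), n),
                scale = rep(max(stats::mad(y), 1e-12), n)))
  }
  nseg <- max(2L, n %/% width)
  bounds <- floor(seq(1L, n + 1L, length.out = nseg + 1L))
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  med <- numeric(nseg)
  sca <- numeric(nseg)
  for (i in seq_len(nseg)) {
    seg <- y[bounds[i]:(bounds[i + 1L] - 1L)]
    med[i] <- stats::median(seg)
    sca[i] <- stats::mad(seg)
  }
  sca <- pmax(sca, max(sca) * 1e-6, 1e-12)
  xs <- seq_len(n)
  list(center = stats::approx(mids, med, xout = xs, rule = 2)$y,
       scale = stats::approx(mids, sca, xout = xs, rule = 2)$y)
}

## Running maximum over a +/- h point window (vectorised).
.runningMax <- function(y, h) {
  n <- length(y)
  out <- y
  for (k in seq_len(h)) {
    out <- pmax(out, c(y[-seq_len(k)], rep(-Inf, k)),
                c(rep(-Inf, k), y[seq_len(n - k)]))
  }
  out
}

#' Detect peaks in a profile spectrum
#'
#' Applies Savitzky-Golay smoothing and SNIP baseline subtraction per
#' `params`, then reports local maxima whose signal-to-noise ratio reaches
#' `snrMin` and whose intensity reaches `minRelIntensity` of the base peak.
#' The noise sigma is a windowed median-absolute-deviation estimate
#' (MAD x 1.4826), robust to sparse peaks, and the SNR uses the noise
#' *level* convention of vendor MALDI software -- twice that sigma -- so
#' ordinary noise maxima score SNR ~1 and the default `snrMin = 3` admits
#' only genuine peaks. With `params$deisotope` set, isotope envelopes are
#' collapsed to their monoisotopic members.
#'
#' @param spec a [MassSpectrum-class] (raw; preprocessing is applied here).
#' @param params a [processingParams()] list.
#' @return A [MassPeaks-class]; empty input gives an empty peak list. Peak
#'   m/z are strictly increasing and every peak is a local maximum of the
#'   processed trace.
#' @export
detectPeaks <- function(spec, params = processingParams()) {
  stopifnot(is(spec, "MassSpectrum"))
  n <- length(spec@mz)
  if (n == 0L)
    return(massPeaks(numeric(), numeric(), metadata = spec@metadata))
  y <- spec@intensity
  if (n > params$sgWindow)
    y <- .sgSmooth(y, params$sgWindow, params$sgOrder)
  if (params$baselineIterations > 0L)
    y <- y - .snipBaseline(y, params$baselineIterations)
  if (n < 3L)
    return(massPeaks(numeric(), numeric(), metadata = spec@metadata))
  ## noise model estimated before zero-clamping so the MAD sees the full
  ## (signed) noise distribution; the centre removes the pedestal SNIP
  ## leaves (it clips towards the noise minima)
  np <- .noiseProfile(y)
  y <- pmax(y - np$center, 0)
  ## a peak must dominate a +/- halfWindowMz neighbourhood, not just its
  ## two direct neighbours, so correlated noise wiggles do not register
  spacing <- stats::median(diff(spec@mz))
  h <- max(1L, min(n %/% 2L - 1L,
                   as.integer(round(params$halfWindowMz / spacing))))
  left <- c(Inf, y[-n])
  right <- c(y[-1], Inf)
  is_max <- y > left & y >= right & y > 0 & y >= .runningMax(y, h)
  idx <- which(is_max)
  if (length(idx)) {
    ## SNR convention: apex over the noise LEVEL, taken as twice the robust
    ## sigma (the peak-to-peak-style definition vendor software uses), so
    ## stray noise maxima (~2-4 sigma) sit well below snrMin = 3
    s <- y[idx] / (2 * np$scale[idx])
    keep <- s >= params$snrMin & y[idx] >= params$minRelIntensity * max(y)
    idx <- idx[keep]
    s <- s[keep]
  } else s <- numeric()
  pk <- massPeaks(spec@mz[idx], y[idx], snr = s, metadata = spec@metadata)
  if (params$deisotope)
    pk <- deisotope(pk, spacing = params$isotopeSpacing,
                    tol = min(params$dmz, 0.1))
  pk
}

#' Collapse isotope envelopes to monoisotopic peaks
#'
#' Greedy, most-intense-first envelope seeding without an intensity model:
#' starting from the most intense unassigned peak, the envelope is extended
#' stepwise up and down in m/z by `spacing / z` (within `tol`) over
#' unassigned peaks; the whole chain is replaced by its lowest-m/z member.
#' Charge 1 only by default, since MALDI fingerprint ions are predominantly
#' singly charged.
#'
#' @param peaks a [MassPeaks-class] (centroided).
#' @param spacing isotopologue spacing in Da (default 1.00235).
#' @param chargeMax maximal charge considered (default 1).
#' @param tol tolerance in Da for the spacing match (default 0.05).
#' @return A deisotoped [MassPeaks-class]. Never increases the peak count
#'   and is idempotent.
#' @examples
#' p <- massPeaks(c(1000.000, 1001.003, 1002.006), c(100, 80, 40))
#' mz(deisotope(p))
#' @export
deisotope <- function(peaks, spacing = 1.00235, chargeMax = 1L, tol = 0.05) {
  stopifnot(is(peaks, "MassPeaks"))
  n <- length(peaks@mz)
  if (n < 2L)
    return(initialize(peaks, isDeisotoped = TRUE))
  assigned <- integer(n)  # envelope id, 0 = unassigned
  env <- 0L
  for (i in order(peaks@intensity, decreasing = TRUE)) {
    if (assigned[i]) next
    env <- env + 1L
    assigned[i] <- env
    for (z in seq_len(chargeMax)) {
      step <- spacing / z
      members <- i
      ## walk down then up from the seed over unassigned neighbours
      for (dir in c(-1, 1)) {
        cur <- peaks@mz[i]
        repeat {
          target <- cur + dir * step
          cand <- which(assigned == 0L & abs(peaks@mz - target) <= tol)
          if (!length(cand)) break
          j <- cand[which.min(abs(peaks@mz[cand] - target))]
          assigned[j] <- env
          members <- c(members, j)
          cur <- peaks@mz[j]
        }
      }
      if (length(members) > 1L) break  # envelope found at this charge
    }
  }
  keep <- vapply(split(seq_len(n), assigned), function(ix) ix[which.min(
    peaks@mz[ix])], integer(1))
  keep <- sort(unname(keep))
  massPeaks(peaks@mz[keep], peaks@intensity[keep],
            snr = if (length(peaks@snr)) peaks@snr[keep] else numeric(),
            isDeisotoped = TRUE, metadata = peaks@metadata)
}

#' Apex m/z of a smoothed broad peak
#'
#' The automated counterpart of picking the maximum of a Savitzky-Golay
#' smoothed linear-mode peak by hand: the trace is restricted to
#' `windowMz`, smoothed, and the m/z of the global maximum returned. Ties
#' are broken towards the lowest m/z and flagged.
#'
#' @param spec a [MassSpectrum-class].
#' @param windowMz numeric length-2 `(lo, hi)` window in Th.
#' @param sgWindow smoothing window in points (coerced odd; default 51).
#' @param sgOrder polynomial order (default 2).
#' @return A list with `mz` (apex), `intensity` (smoothed apex height),
#'   `snr` (apex over windowed-MAD noise) and `flat` (TRUE when the maximum
#'   was not unique).
#' @export
apexMass <- function(spec, windowMz, sgWindow = 51, sgOrder = 2) {
  stopifnot(is(spec, "MassSpectrum"), length(windowMz) == 2L)
  sel <- spec@mz >= windowMz[1] & spec@mz <= windowMz[2]
  if (!any(sel))
    stop("detection error: no data points in window [", windowMz[1], ", ",
         windowMz[2], "]")
  y <- spec@intensity[sel]
  x <- spec@mz[sel]
  sgWindow <- as.integer(sgWindow)
  if (sgWindow %% 2L == 0L) sgWindow <- sgWindow + 1L
  if (length(y) < sgWindow)
    stop("parameter error: window contains ", length(y),
         " points, fewer than the smoothing window (", sgWindow, ")")
  ys <- .sgSmooth(y, sgWindow, sgOrder)
  i <- which.max(ys)
  flat <- sum(ys == ys[i]) > 1L
  ## apex height above the window's median level, over the noise level
  ## (2 x robust sigma, as in detectPeaks)
  noise <- 2 * stats::mad(ys)
  list(mz = x[i], intensity = ys[i],
       snr = if (noise > 0) (ys[i] - stats::median(ys)) / noise else Inf,
       flat = flat)
}
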