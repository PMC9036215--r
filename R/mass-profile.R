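#' Intact antibody mass from a linear-mode spectrum
#'
#' The intact mass M is computed from the apex of the doubly charged
#' species: the trace in `searchWindow` is Savitzky-Golay smoothed, the
#' apex m/z picked, and `M = 2 * apex - 2 * 1.007276`. Broad asymmetric
#' ~150 kDa peaks make absolute calibration unreliable, so intact masses
#' are normally used relative to a reference antibody measured on the same
#' plate (see [relativeMass()]).
#'
#' @param spec a linear-mode [MassSpectrum-class] covering the window.
#' @param searchWindow `(lo, hi)` m/z window for the 2+ species, default
#'   `c(60000, 90000)`.
#' @param sgWindow smoothing window in points (default 51).
#' @param snrMin minimal apex signal-to-noise ratio (default 3); below it a
#'   detection error is raised.
#' @return Intact mass M in Da.
#' @examples
#' \dontrun{intactMass(spec)  # apex 75000 -> 149997.985 Da}
#' @export
intactMass <- function(spec, searchWindow = c(60000, 90000), sgWindow = 51,
                       snrMin = 3) {
  apex <- apexMass(spec, searchWindow, sgWindow)
  if (is.finite(apex$snr) && apex$snr < snrMin)
    stop("detection error: no peak with SNR >= ", snrMin,
         " in the intact-mass window")
  2 * apex$mz - 2 * PROTON_MASS
}

#' Light-chain mass from a linear-mode spectrum of a reduced antibody
#'
#' Uses the singly charged light-chain species near 23 kDa:
#' `M = apex - 1.007276`.
#'
#' @inheritParams intactMass
#' @param searchWindow `(lo, hi)` window, default `c(20000, 27000)`.
#' @return Light-chain mass in Da.
#' @export
lightChainMass <- function(spec, searchWindow = c(20000, 27000),
                           sgWindow = 51, snrMin = 3) {
  apex <- apexMass(spec, searchWindow, sgWindow)
  if (is.finite(apex$snr) && apex$snr < snrMin)
    stop("detection error: no peak with SNR >= ", snrMin,
         " in the light-chain window")
  apex$mz - PROTON_MASS
}

#' Mass relative to a reference antibody, with a 95% CI
#'
#' Both the sample and the reference are measured in replicates (typically
#' triplicates); the relative mass is the difference of the replicate
#' means. The default 95% half-width is the Welch two-sample t-interval on
#' that difference, `qt(0.975, df) * sqrt(s_s^2/n_s + s_r^2/n_r)` with the
#' Welch-Satterthwaite degrees of freedom -- the standard small-n treatment
#' of a difference of two means with independent errors, and the
#' construction whose simulated coverage stays at the nominal 95%. When
#' either measurement has zero replicate variance it reduces to the
#' single-measurement Student-t interval. `ciMethod = "propagate"` instead
#' combines the two per-measurement intervals in quadrature
#' (`sqrt(hw_s^2 + hw_r^2)`); that reads directly off the individual CIs
#' but over-covers (~99% at n = 3).
#'
#' @param sample,reference [MassMeasurement-class] objects (>= 2 replicates
#'   each) of the same kind.
#' @param ciMethod `"welch"` (default) or `"propagate"`.
#' @return List with `delta` (Da), `halfWidth95` (Da) and `kind`.
#' @examples
#' s <- massMeasurement(c(10, 12, 14), "intact")
#' r <- massMeasurement(c(0, 0, 0), "intact")
#' relativeMass(s, r)  # delta 12, halfWidth95 4.968
#' @export
relativeMass <- function(sample, reference,
                         ciMethod = c("welch", "propagate")) {
  stopifnot(is(sample, "MassMeasurement"), is(reference, "MassMeasurement"))
  ciMethod <- match.arg(ciMethod)
  if (sample@kind != reference@kind)
    warning("comparing measurements of different kinds: ", sample@kind,
            " vs ", reference@kind)
  hw <- if (ciMethod == "propagate") {
    sqrt(sample@halfWidth95^2 + reference@halfWidth95^2)
  } else {
    ns <- length(sample@replicates)
    nr <- length(reference@replicates)
    vs <- stats::var(sample@replicates) / ns
    vr <- stats::var(reference@replicates) / nr
    se2 <- vs + vr
    if (se2 == 0) 0 else {
      df <- se2^2 / (vs^2 / (ns - 1) + vr^2 / (nr - 1))
      stats::qt(0.975, df) * sqrt(se2)
    }
  }
  list(delta = sample@mean - reference@mean, halfWidth95 = hw,
       kind = sample@kind)
}

#' Do two confidence intervals overlap?
#'
#' Intervals are closed: touching endpoints count as overlap.
#'
#' @param a,b lists with `delta` and `halfWidth95` (as returned by
#'   [relativeMass()]), or numeric length-2 vectors `(delta, halfWidth95)`.
#' @return TRUE iff `|delta_a - delta_b| <= hw_a + hw_b`.
#' @export
ciOverlap <- function(a, b) {
  a <- .asInterval(a)
  b <- .asInterval(b)
  abs(a[1] - b[1]) <= a[2] + b[2]
}

.asInterval <- function(x) {
  if (is.list(x)) x <- c(x$delta, x$halfWidth95)
  x <- as.numeric(x)
  stopifnot(length(x) == 2L, all(is.finite(x)))
  x
}

#' Build a table of per-clone relative masses
#'
#' Convenience constructor for the record table consumed by
#' [countUnique()]: one row per clone with light-chain and intact deltas
#' (vs the reference) and their 95% half-widths.
#'
#' @param clone character vector of clone names.
#' @param deltaIntact,hwIntact,deltaLight,hwLight numeric vectors.
#' @param referenceId identifier of the reference antibody.
#' @return A data.frame of class `MassRecordTable`.
#' @export
massRecordTable <- function(clone, deltaIntact, hwIntact, deltaLight,
                            hwLight, referenceId = "reference") {
  df <- data.frame(clone = as.character(clone),
                   deltaIntact = as.numeric(deltaIntact),
                   hwIntact = as.numeric(hwIntact),
                   deltaLight = as.numeric(deltaLight),
                   hwLight = as.numeric(hwLight),
                   referenceId = as.character(referenceId),
                   stringsAsFactors = FALSE)
  if (anyNA(df[2:5]) || any(!is.finite(as.matrix(df[2:5]))))
    stop("all deltas and half-widths must be finite")
  if (any(df$hwIntact < 0) || any(df$hwLight < 0))
    stop("half-widths must be non-negative")
  if (!all(nzchar(df$referenceId))) stop("referenceId must be non-empty")
  class(df) <- c("MassRecordTable", "data.frame")
  df
}

#' Count antibodies unique by mass profile
#'
#' Two clones are *indistinguishable* when their confidence intervals
#' overlap in the considered dimension(s): with `dims = "both"` they must
#' overlap in both the light-chain and the intact dimension to be
#' confusable (a disjoint interval in either dimension separates them);
#' with `dims = "light_only"` only the light-chain dimension is used. A
#' clone is *unique* when no other clone is indistinguishable from it.
#' Clusters are the connected components of the indistinguishability graph,
#' so either a pairwise-uniqueness count or a cluster-based count can be
#' derived from the result.
#'
#' @param records a [massRecordTable()] data.frame with >= 2 rows.
#' @param dims `"both"` (default) or `"light_only"`.
#' @return List with `nUnique`, `uniqueClones` (character vector),
#'   `clusters` (list of character vectors, singletons included) and the
#'   logical adjacency `matrix`.
#' @export
countUnique <- function(records, dims = c("both", "light_only")) {
  dims <- match.arg(dims)
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  n <- nrow(records)
  adj <- matrix(FALSE, n, n, dimnames = list(records$clone, records$clone))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      light <- abs(records$deltaLight[i] - records$deltaLight[j]) <=
        records$hwLight[i] + records$hwLight[j]
      ok <- if (dims == "light_only") light else {
        light && abs(records$deltaIntact[i] - records$deltaIntact[j]) <=
          records$hwIntact[i] + records$hwIntact[j]
      }
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  uniq <- rowSums(adj) == 0L
  ## connected components by BFS
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  clusters <- split(records$clone, comp)
  names(clusters) <- NULL
  list(nUnique = sum(uniq), uniqueClones = records$clone[uniq],
       clusters = clusters, matrix = adj)
}
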