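## Fixed amino-acid frequency table (Swiss-Prot-like composition) used for
## all synthetic variable regions; versioned here for reproducibility.
AA_FREQ <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed in [1, 2^31 - 2] from a base seed and string tags,
## so independent simulation streams never share a seed.
.subSeed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% 2147483647
  as.integer(h) + 1L
}

#' Parameters of the synthetic antibody study
#'
#' Defaults emulate the measurement conditions of a reflector-mode
#' fingerprint / linear-mode mass workflow: stochastic per-peptide detection
#' (80%), external-calibration error (30 ppm sd), 1% additive noise,
#' isotope-resolved peaks of 0.15 Da FWHM at m/z 2000 (widening
#' proportionally with m/z), replicate-to-replicate mass scatter of 15 Da
#' (intact) and 2 Da (light chain), and a shared per-plate calibration
#' offset that makes relative masses more reproducible than absolute ones.
#'
#' @param seed integer master seed; every simulator derives its own
#'   sub-seed from it, so a given object is reproducible in isolation.
#' @param nClones total number of clones in a benchmark (default 36,
#'   a NIST-style reference plus 35 study antibodies is the scale of a
#'   realistic panel; identification studies use 50).
#' @param nSisterPairs number of sister-clone pairs (identical sequences)
#'   among the `nClones` (default 1).
#' @param detectionProb per-peptide Bernoulli detection probability
#'   (default 0.8).
#' @param calibPpmSd calibration error sd in ppm (default 30).
#' @param noiseSdRel additive noise sd as a fraction of the base peak
#'   (default 0.01).
#' @param peakFwhm reflector peak FWHM in Da at m/z 2000 (default 0.15).
#' @param replicateMassSdIntact,replicateMassSdLight replicate mass scatter
#'   in Da (defaults 15 and 2).
#' @param plateOffsetSdIntact,plateOffsetSdLight sd of the shared per-plate
#'   calibration offset in Da (defaults 40 and 5).
#' @param nNoisePeaks spurious (non-peptide) peaks added to simulated peak
#'   lists (default 3).
#' @param hcLength,lcLength variable+CH1 region length of the heavy chain
#'   and total light-chain length in residues (defaults 220 and 214).
#' @return A list of class `SimulationParams`.
#' @export
simulationParams <- function(seed = 1L, nClones = 36L, nSisterPairs = 1L,
                             detectionProb = 0.8, calibPpmSd = 30,
                             noiseSdRel = 0.01, peakFwhm = 0.15,
                             replicateMassSdIntact = 15,
                             replicateMassSdLight = 2,
                             plateOffsetSdIntact = 40,
                             plateOffsetSdLight = 5,
                             nNoisePeaks = 3L,
                             hcLength = 220L, lcLength = 214L) {
  if (detectionProb < 0 || detectionProb > 1)
    stop("detectionProb must be in [0, 1]")
  sds <- c(calibPpmSd, noiseSdRel, peakFwhm, replicateMassSdIntact,
           replicateMassSdLight, plateOffsetSdIntact, plateOffsetSdLight)
  if (any(sds < 0)) stop("all spreads must be non-negative")
  structure(list(seed = as.integer(seed), nClones = as.integer(nClones),
                 nSisterPairs = as.integer(nSisterPairs),
                 detectionProb = detectionProb, calibPpmSd = calibPpmSd,
                 noiseSdRel = noiseSdRel, peakFwhm = peakFwhm,
                 replicateMassSdIntact = replicateMassSdIntact,
                 replicateMassSdLight = replicateMassSdLight,
                 plateOffsetSdIntact = plateOffsetSdIntact,
                 plateOffsetSdLight = plateOffsetSdLight,
                 nNoisePeaks = as.integer(nNoisePeaks),
                 hcLength = as.integer(hcLength),
                 lcLength = as.integer(lcLength)),
            class = "SimulationParams")
}

#' Generate a synthetic antibody clone with known ground truth
#'
#' The heavy chain is a random variable/CH1 region (drawn per-residue from
#' the package's fixed amino-acid frequency table) followed by the
#' subclass's CH2-CH3 constant region; the light chain is fully random.
#' True masses are average-mass sums of the chains (intact = 2 HC + 2 LC);
#' disulfide and glycan chemistry are not modelled because the downstream
#' analysis consumes relative masses only.
#'
#' @param cloneId clone identifier string.
#' @param subclass one of the subclasses in `refs` (default `"IgG1"`).
#' @param params a [simulationParams()] list.
#' @param refs a `SubclassReferenceSet` supplying constant regions
#'   (default: the bundled synthetic murine set).
#' @return A list of class `SyntheticClone`: `cloneId`, `subclass`,
#'   `heavyChain`, `lightChain` ([ProteinChain-class]), `trueIntactMass`,
#'   `trueLightMass`, `sisterOf` (NA or a clone id).
#' @export
generateClone <- function(cloneId, subclass = "IgG1",
                          params = simulationParams(),
                          refs = buildSubclassReference()) {
  if (!subclass %in% names(refs))
    stop("unknown subclass '", subclass, "'")
  const <- residues(refs[[subclass]]$chains[[1]])
  .withSeed(.subSeed(params$seed, "clone", cloneId), {
    hcVar <- paste(sample(names(AA_FREQ), params$hcLength, replace = TRUE,
                          prob = AA_FREQ), collapse = "")
    lcSeq <- paste(sample(names(AA_FREQ), params$lcLength, replace = TRUE,
                          prob = AA_FREQ), collapse = "")
    hc <- proteinChain("HC", paste0(hcVar, const))
    lc <- proteinChain("LC", lcSeq)
    structure(list(
      cloneId = as.character(cloneId), subclass = subclass,
      heavyChain = hc, lightChain = lc,
      trueIntactMass = 2 * peptideMass(residues(hc), "average") +
        2 * peptideMass(residues(lc), "average"),
      trueLightMass = peptideMass(residues(lc), "average"),
      sisterOf = NA_character_), class = "SyntheticClone")
  })
}

#' Make a sister clone (identical sequences, new identity)
#'
#' @param clone a `SyntheticClone`.
#' @param cloneId identifier of the sister.
#' @return A `SyntheticClone` sharing the chains, with `sisterOf` set.
#' @export
sisterClone <- function(clone, cloneId) {
  stopifnot(inherits(clone, "SyntheticClone"))
  out <- clone
  out$cloneId <- as.character(cloneId)
  out$sisterOf <- clone$cloneId
  out
}

## Theoretical [M+H]+ fingerprint of a clone for a cleavage method.
.cloneFingerprint <- function(clone, method = c("acid", "trypsin")) {
  method <- match.arg(method)
  params <- digestParams(if (method == "acid") "acid_asp" else "trypsin",
                         mzRange = c(700, 6500))
  theoreticalFingerprint(list(clone$heavyChain, clone$lightChain), params)
}

#' Simulate a fingerprint at the peak-list level
#'
#' Fast counterpart of [simulateFingerprint()] for simulation studies:
#' each theoretical peptide is kept with probability `detectionProb`, its
#' m/z shifted by a normal calibration error of `calibPpmSd` ppm,
#' log-normal intensities assigned, and `nNoisePeaks` spurious peaks added
#' uniformly over the mass range.
#'
#' @param clone a `SyntheticClone`.
#' @param method `"acid"` or `"trypsin"`.
#' @param params a [simulationParams()] list.
#' @param replicate replicate index (independent randomness per replicate).
#' @return A deisotoped [MassPeaks-class] with clone metadata.
#' @export
simulateFingerprintPeaks <- function(clone, method = c("acid", "trypsin"),
                                     params = simulationParams(),
                                     replicate = 1L) {
  method <- match.arg(method)
  masses <- .cloneFingerprint(clone, method)
  .withSeed(.subSeed(params$seed, "fp", clone$cloneId, method, replicate), {
    keep <- stats::runif(length(masses)) < params$detectionProb
    m <- masses[keep]
    m <- m * (1 + stats::rnorm(length(m), 0, params$calibPpmSd * 1e-6))
    int <- stats::rlnorm(length(m), meanlog = log(100), sdlog = 1)
    if (params$nNoisePeaks > 0L) {
      nm <- stats::runif(params$nNoisePeaks, 700, 6500)
      m <- c(m, nm)
      int <- c(int, stats::rlnorm(length(nm), meanlog = log(20), sdlog = 0.5))
    }
    massPeaks(m, int, isDeisotoped = TRUE,
              metadata = list(clone = clone$cloneId, method = method,
                              replicate = as.character(replicate)))
  })
}

#' Simulate a reflector-mode fingerprint profile spectrum
#'
#' Full forward model of a MALDI reflector acquisition: for each detected
#' peptide (Bernoulli `detectionProb`), Gaussian peaks at the first three
#' isotopologues (1.00235 Da spacing; relative abundances from a Poisson
#' approximation with rate proportional to mass), the whole pattern shifted
#' by a normal calibration error in ppm; plus an exponentially decaying
#' baseline and additive Gaussian noise.
#'
#' @inheritParams simulateFingerprintPeaks
#' @param mzStep grid step in Th (default 0.02).
#' @return A reflector-mode [MassSpectrum-class] over m/z 700-6500.
#' @export
simulateFingerprint <- function(clone, method = c("acid", "trypsin"),
                                params = simulationParams(),
                                replicate = 1L, mzStep = 0.02) {
  method <- match.arg(method)
  masses <- .cloneFingerprint(clone, method)
  grid <- seq(700, 6500, by = mzStep)
  .withSeed(.subSeed(params$seed, "fpspec", clone$cloneId, method,
                     replicate), {
    keep <- stats::runif(length(masses)) < params$detectionProb
    m0 <- masses[keep]
    m0 <- m0 * (1 + stats::rnorm(length(m0), 0, params$calibPpmSd * 1e-6))
    base_int <- stats::rlnorm(length(m0), meanlog = log(100), sdlog = 1)
    y <- numeric(length(grid))
    for (i in seq_along(m0)) {
      lambda <- 4.9384e-4 * m0[i]  # averagine-like isotope rate
      iso <- stats::dpois(0:2, lambda)
      iso <- iso / max(iso)
      fwhm <- params$peakFwhm * m0[i] / 2000
      sdv <- fwhm / 2.354820045
      for (k in 0:2) {
        center <- m0[i] + k * 1.00235
        lo <- max(1L, ceiling((center - 5 * sdv - 700) / mzStep) + 1L)
        hi <- min(length(grid), floor((center + 5 * sdv - 700) / mzStep) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        y[idx] <- y[idx] +
          base_int[i] * iso[k + 1L] * exp(-((grid[idx] - center)^2) /
                                            (2 * sdv^2))
      }
    }
    basepeak <- if (length(m0)) max(y) else 100
    baseline <- 0.05 * basepeak * exp(-(grid - 700) / 1500)
    noise <- stats::rnorm(length(grid), 0, params$noiseSdRel * basepeak)
    massSpectrum(grid, pmax(y + baseline + noise, 0), mode = "reflector",
                 metadata = list(clone = clone$cloneId, method = method,
                                 replicate = as.character(replicate)))
  })
}

## Exponentially modified Gaussian (tail towards high m/z), the asymmetric
## line shape of linear-mode MALDI peaks.
.emg <- function(x, mu, sigma, tau) {
  z <- (sigma / tau - (x - mu) / sigma) / sqrt(2)
  out <- (1 / (2 * tau)) *
    exp(0.5 * (sigma / tau)^2 - (x - mu) / tau) *
    2 * stats::pnorm(-z * sqrt(2))
  out[!is.finite(out)] <- 0
  out
}

#' Simulate a linear-mode intact or light-chain spectrum
#'
#' A broad, asymmetric (exponentially modified Gaussian) peak at the m/z of
#' the measured species -- `[M+2H]2+` near 75 kTh for the intact antibody,
#' `[M+H]+` near 23 kTh for the light chain -- with per-replicate mass
#' jitter plus a calibration offset shared by every spectrum on the same
#' plate. The plate offset cancels in relative masses, mirroring why
#' high-mass MALDI measurements are referenced to a co-spotted standard.
#'
#' @param clone a `SyntheticClone`.
#' @param kind `"intact"` or `"light_chain"`.
#' @param replicate replicate index.
#' @param params a [simulationParams()] list.
#' @param plate plate label; spectra sharing it share the offset.
#' @return A linear-mode [MassSpectrum-class].
#' @export
simulateMassSpectrum <- function(clone, kind = c("intact", "light_chain"),
                                 replicate = 1L,
                                 params = simulationParams(),
                                 plate = "plate1") {
  kind <- match.arg(kind)
  trueMass <- if (kind == "intact") clone$trueIntactMass else
    clone$trueLightMass
  z <- if (kind == "intact") 2 else 1
  repSd <- if (kind == "intact") params$replicateMassSdIntact else
    params$replicateMassSdLight
  plateSd <- if (kind == "intact") params$plateOffsetSdIntact else
    params$plateOffsetSdLight
  plateOffset <- .withSeed(.subSeed(params$seed, "plate", plate, kind),
                           stats::rnorm(1, 0, plateSd))
  .withSeed(.subSeed(params$seed, "mass", clone$cloneId, kind, replicate,
                     plate), {
    mass <- trueMass + stats::rnorm(1, 0, repSd) + plateOffset
    center <- (mass + z * PROTON_MASS) / z
    ## line widths: broad, mildly tailed intact peak; sharper light chain.
    ## The exponential tail biases the apex high by ~tau, the bias the
    ## downstream relative-mass analysis cancels.
    if (kind == "intact") {
      grid <- seq(50000, 100000, by = 2)
      sigma <- 150; tau <- 10
    } else {
      grid <- seq(15000, 30000, by = 0.25)
      sigma <- 25; tau <- 0.8
    }
    shape <- .emg(grid, center, sigma, tau)
    y <- 100 * shape / max(shape)
    noise <- stats::rnorm(length(grid), 0, params$noiseSdRel * 100)
    massSpectrum(grid, pmax(y + noise, 0), mode = "linear",
                 metadata = list(clone = clone$cloneId, kind = kind,
                                 replicate = as.character(replicate),
                                 plate = plate))
  })
}

#' Generate a full synthetic benchmark study
#'
#' Builds the complete ground-truth study every other module can be tested
#' against: `nClones` synthetic clones (of which `nSisterPairs` pairs are
#' sequence-identical sisters), a fingerprint library with acid and trypsin
#' entries per clone, triplicate intact and light-chain mass measurements
#' relative to a synthetic reference antibody, and a truth manifest.
#'
#' @param params a [simulationParams()] list.
#' @param refs subclass references used for constant regions.
#' @param massSpectra if TRUE (default) derive mass records from simulated
#'   linear-mode spectra via [intactMass()]/[lightChainMass()]; if FALSE,
#'   draw replicate masses directly (faster, same statistical model).
#' @return A list of class `SyntheticBenchmark`: `library`
#'   ([FingerprintLibrary-class] with `2 * nClones` entries), `massRecords`
#'   (a [massRecordTable()] with `nClones` rows), `truth` (data.frame:
#'   `cloneId`, `subclass`, `sisterOf`, `trueIntactMass`, `trueLightMass`),
#'   `clones`, `reference`.
#' @export
makeBenchmark <- function(params = simulationParams(),
                          refs = buildSubclassReference(),
                          massSpectra = TRUE) {
  subclasses <- names(refs)
  nDistinct <- params$nClones - params$nSisterPairs
  if (nDistinct < 1L) stop("nClones must exceed nSisterPairs")
  clones <- vector("list", params$nClones)
  for (i in seq_len(nDistinct))
    clones[[i]] <- generateClone(sprintf("SYN-%03d", i),
                                 subclasses[(i - 1L) %% length(subclasses) + 1L],
                                 params, refs)
  if (params$nSisterPairs > 0L)
    for (k in seq_len(params$nSisterPairs))
      clones[[nDistinct + k]] <- sisterClone(clones[[k]],
                                             sprintf("SYN-%03d-sis", k))
  names(clones) <- vapply(clones, `[[`, character(1), "cloneId")

  reference <- generateClone("REF", subclasses[1], params, refs)

  ents <- list()
  for (cl in clones) for (method in c("acid", "trypsin"))
    ents[[length(ents) + 1L]] <- libraryEntry(
      cl$cloneId, simulateFingerprintPeaks(cl, method, params),
      method = method, abbreviation = cl$cloneId, isotype = cl$subclass,
      antigen = "synthetic", source = "simulator")
  lib <- fingerprintLibrary(ents, provenance = sprintf(
    "synthetic benchmark, seed %d, %d clones", params$seed, params$nClones))

  measure <- function(cl, kind) {
    if (massSpectra) {
      reps <- vapply(1:3, function(r) {
        s <- simulateMassSpectrum(cl, kind, r, params)
        if (kind == "intact") intactMass(s) else lightChainMass(s)
      }, numeric(1))
    } else {
      sd_ <- if (kind == "intact") params$replicateMassSdIntact else
        params$replicateMassSdLight
      true <- if (kind == "intact") cl$trueIntactMass else cl$trueLightMass
      reps <- .withSeed(.subSeed(params$seed, "repmass", cl$cloneId, kind),
                        stats::rnorm(3, true, sd_))
    }
    massMeasurement(reps, kind)
  }
  refIntact <- measure(reference, "intact")
  refLight <- measure(reference, "light_chain")
  rec <- lapply(clones, function(cl) {
    di <- relativeMass(measure(cl, "intact"), refIntact)
    dl <- relativeMass(measure(cl, "light_chain"), refLight)
    c(di$delta, di$halfWidth95, dl$delta, dl$halfWidth95)
  })
  rec <- do.call(rbind, rec)
  records <- massRecordTable(names(clones), rec[, 1], rec[, 2], rec[, 3],
                             rec[, 4], referenceId = "REF")

  truth <- data.frame(
    cloneId = names(clones),
    subclass = vapply(clones, `[[`, character(1), "subclass"),
    sisterOf = vapply(clones, `[[`, character(1), "sisterOf"),
    trueIntactMass = vapply(clones, `[[`, numeric(1), "trueIntactMass"),
    trueLightMass = vapply(clones, `[[`, numeric(1), "trueLightMass"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(library = lib, massRecords = records, truth = truth,
                 clones = clones, reference = reference, params = params),
            class = "SyntheticBenchmark")
}
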