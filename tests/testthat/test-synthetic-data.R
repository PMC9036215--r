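test_that("clone generation is deterministic and subclass-anchored", {
  refs <- testRefs()
  p <- simulationParams(seed = 5)
  a <- generateClone("X1", "IgG1", p, refs)
  b <- generateClone("X1", "IgG1", p, refs)
  expect_identical(residues(a$heavyChain), residues(b$heavyChain))
  expect_identical(a$trueIntactMass, b$trueIntactMass)

  # heavy chain carries the subclass constant region
  const <- residues(refs$IgG1$chains[[1]])
  expect_true(endsWith(residues(a$heavyChain), const))

  # true masses equal average-mass sums of the chains
  expect_equal(a$trueIntactMass,
               2 * peptideMass(residues(a$heavyChain), "average") +
                 2 * peptideMass(residues(a$lightChain), "average"))

  # different clone ids diverge in sequence and tryptic fingerprint
  set.seed(1)
  differing <- vapply(1:25, function(i) {
    c1 <- generateClone(paste0("A", i), "IgG1", p, refs)
    c2 <- generateClone(paste0("B", i), "IgG1", p, refs)
    f1 <- theoreticalFingerprint(c1$lightChain, digestParams("trypsin"))
    f2 <- theoreticalFingerprint(c2$lightChain, digestParams("trypsin"))
    !identical(round(f1, 4), round(f2, 4))
  }, logical(1))
  expect_true(all(differing))
})

test_that("sister clones share sequences and theoretical fingerprints", {
  refs <- testRefs()
  p <- simulationParams(seed = 6)
  a <- generateClone("S1", "IgG2b", p, refs)
  s <- sisterClone(a, "S1-sis")
  expect_equal(s$sisterOf, "S1")
  expect_identical(residues(s$heavyChain), residues(a$heavyChain))
  pa <- digestParams("acid_asp")
  expect_identical(
    theoreticalFingerprint(list(a$heavyChain, a$lightChain), pa),
    theoreticalFingerprint(list(s$heavyChain, s$lightChain), pa))
})

test_that("simulators are pure functions of their seeds", {
  refs <- testRefs()
  p <- simulationParams(seed = 7)
  cl <- generateClone("D1", "IgG1", p, refs)
  f1 <- simulateFingerprintPeaks(cl, "acid", p, replicate = 2)
  f2 <- simulateFingerprintPeaks(cl, "acid", p, replicate = 2)
  expect_identical(mz(f1), mz(f2))
  f3 <- simulateFingerprintPeaks(cl, "acid", p, replicate = 3)
  expect_false(identical(mz(f1), mz(f3)))

  s1 <- simulateMassSpectrum(cl, "intact", 1, p)
  s2 <- simulateMassSpectrum(cl, "intact", 1, p)
  expect_identical(intensity(s1), intensity(s2))

  # the RNG state of the session is left untouched
  set.seed(1234)
  before <- .Random.seed
  invisible(simulateFingerprintPeaks(cl, "trypsin", p))
  expect_identical(.Random.seed, before)
})

test_that("noise-free fingerprints are recovered completely after processing", {
  refs <- testRefs()
  p0 <- simulationParams(seed = 7, detectionProb = 1, calibPpmSd = 0,
                         noiseSdRel = 0)
  cl <- generateClone("RT-1", "IgG2a", p0, refs)
  theo <- theoreticalFingerprint(list(cl$heavyChain, cl$lightChain),
                                 digestParams("trypsin",
                                              mzRange = c(700, 6500)))
  spec <- simulateFingerprint(cl, "trypsin", p0)
  # geometric completeness check: SNR/intensity thresholds are nuisance
  # parameters at zero noise, so they are set permissive; the tiny
  # intensity floor only rejects numerical baseline artifacts, which sit
  # three orders of magnitude below any simulated peptide
  pk <- detectPeaks(spec, processingParams(minRelIntensity = 1e-4,
                                           snrMin = 0.5))
  # completeness holds for peptides isolated from other peptides: no
  # neighbour within the apex-dominance window (0.5 Da) nor within 0.3 Da
  # of the k*1.00235 isotope ladder; closer pairs merge in averagine-free
  # deisotoping or apex suppression
  isolated <- vapply(theo, function(m) {
    g <- abs(theo - m)
    g <- g[g > 1e-9]
    all(g > 0.5) && all(vapply(1:3, function(k)
      all(abs(g - k * 1.00235) > 0.3), logical(1)))
  }, logical(1))
  miss <- vapply(theo, function(m) min(abs(mz(pk) - m)), numeric(1))
  expect_true(all(miss[isolated] <= 0.3))

  # zero detection probability: nothing but baseline and noise
  pz <- simulationParams(seed = 7, detectionProb = 0)
  quiet <- simulateFingerprint(cl, "trypsin", pz)
  expect_equal(length(detectPeaks(quiet, processingParams(snrMin = 5))), 0L)
})

test_that("linear-mode round trips recover true masses within bias bounds", {
  refs <- testRefs()
  pz <- simulationParams(seed = 3, replicateMassSdIntact = 0,
                         replicateMassSdLight = 0, plateOffsetSdIntact = 0,
                         plateOffsetSdLight = 0, noiseSdRel = 0)
  cl <- generateClone("M1", "IgG1", pz, refs)
  mi <- intactMass(simulateMassSpectrum(cl, "intact", 1, pz))
  expect_lt(abs(mi - cl$trueIntactMass) / cl$trueIntactMass, 2e-4)
  ml <- lightChainMass(simulateMassSpectrum(cl, "light_chain", 1, pz))
  expect_lt(abs(ml - cl$trueLightMass) / cl$trueLightMass, 5e-5)
})

test_that("plate offsets cancel in relative masses but not absolute ones", {
  refs <- testRefs()
  p <- simulationParams(seed = 17, plateOffsetSdIntact = 200,
                        replicateMassSdIntact = 5)
  cl <- generateClone("P1", "IgG1", p, refs)
  ref <- generateClone("PREF", "IgG1", p, refs)
  getRep <- function(c_) vapply(1:3, function(r)
    intactMass(simulateMassSpectrum(c_, "intact", r, p)), numeric(1))
  mS <- massMeasurement(getRep(cl), "intact")
  mR <- massMeasurement(getRep(ref), "intact")
  rel <- relativeMass(mS, mR)
  trueDelta <- cl$trueIntactMass - ref$trueIntactMass
  # relative mass lands near truth despite a large shared plate offset
  expect_lt(abs(rel$delta - trueDelta), 60)
})

test_that("benchmark bundles have the contracted shape", {
  p <- simulationParams(seed = 23, nClones = 8, nSisterPairs = 1)
  bench <- makeBenchmark(p, testRefs(), massSpectra = FALSE)
  expect_equal(length(entries(bench$library)), 16L)  # acid + trypsin
  expect_equal(nrow(bench$massRecords), 8L)
  expect_equal(sum(!is.na(bench$truth$sisterOf)), 1L)
  expect_setequal(bench$truth$cloneId, bench$massRecords$clone)

  # well-separated random clones: only the sister pair is confusable
  u <- countUnique(bench$massRecords, "both")
  sisters <- bench$truth$cloneId[!is.na(bench$truth$sisterOf)]
  partner <- bench$truth$sisterOf[!is.na(bench$truth$sisterOf)]
  expect_false(sisters %in% u$uniqueClones)
  expect_false(partner %in% u$uniqueClones)
})

test_that("identification degrades monotonically with detection probability", {
  refs <- testRefs()
  base <- simulationParams(seed = 29, nClones = 12, nSisterPairs = 0)
  clones <- lapply(1:12, function(i)
    generateClone(sprintf("DG-%02d", i), names(refs)[(i - 1) %% 4 + 1],
                  base, refs))
  lib <- fingerprintLibrary(lapply(clones, function(cl)
    libraryEntry(cl$cloneId, simulateFingerprintPeaks(cl, "acid", base),
                 "acid")))
  hitRate <- function(dp) {
    p <- simulationParams(seed = 29, detectionProb = dp, nClones = 12,
                          nSisterPairs = 0)
    hits <- vapply(seq_along(clones), function(i) {
      smp <- simulateFingerprintPeaks(clones[[i]], "acid", p,
                                      replicate = 50 + i)
      rankLibrary(smp, lib, 0.3)$clone[1] == clones[[i]]$cloneId
    }, logical(1))
    mean(hits)
  }
  rates <- vapply(c(1.0, 0.8, 0.5), hitRate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1.0)
})
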