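test_that("cleavage-site rules match rule-by-rule enumeration", {
  expect_equal(cleavageSites(proteinChain("x", "AKRPCK"), "trypsin"), 2L)
  expect_equal(cleavageSites(proteinChain("x", "GADG"), "acid_asp"),
               c(2L, 3L))
  expect_equal(cleavageSites(proteinChain("x", "AAAA"), "trypsin"),
               integer())
  # D at the termini yields only valid internal sites
  expect_equal(cleavageSites(proteinChain("x", "DAAD"), "acid_asp"),
               c(1L, 3L))
})

test_that("peptide enumeration handles missed cleavages and tiling", {
  noRange <- function(enzyme, mm)
    digestParams(enzyme, maxMissed = mm, mzRange = NULL)
  g0 <- enumeratePeptides(proteinChain("x", "GADG"), noRange("acid_asp", 0))
  expect_setequal(g0$sequence, c("GA", "D", "G"))
  g2 <- enumeratePeptides(proteinChain("x", "GADG"), noRange("acid_asp", 2))
  expect_setequal(g2$sequence, c("GA", "D", "G", "GAD", "DG", "GADG"))

  # maxMissed = 0 tiles the chain exactly
  set.seed(21)
  for (i in 1:10) {
    ch <- randomChain(40)
    for (enz in c("trypsin", "acid_asp")) {
      pep <- enumeratePeptides(ch, noRange(enz, 0))
      expect_equal(paste(pep$sequence, collapse = ""), residues(ch))
    }
  }
})

test_that("enumeration equals brute-force substring digestion", {
  set.seed(31)
  for (i in 1:25) {
    ch <- randomChain(50)
    for (enz in c("trypsin", "acid_asp")) for (mm in c(0L, 2L, 5L)) {
      got <- enumeratePeptides(ch, digestParams(enz, maxMissed = mm,
                                                mzRange = NULL))
      want <- bruteDigest(residues(ch), enz, mm)
      expect_equal(nrow(got), nrow(want))
      key <- function(d) sort(paste(d$start, d$end, d$missedCleavages))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("peptide masses match the standard residue-mass table", {
  expect_equal(peptideMass("G"), 75.032028, tolerance = 1e-6)
  expect_equal(peptideMz("G"), 76.039304, tolerance = 1e-6)
  expect_equal(peptideMass("GG"), 132.053492, tolerance = 1e-6)
  expect_error(peptideMass(""), "alphabet error")
  expect_error(peptideMass("GXG"), "alphabet error")

  # carbamidomethylation adds 57.02146 per cysteine (mono)
  expect_equal(peptideMass("ACCA", cysState = "carbamidomethyl") -
                 peptideMass("ACCA"), 2 * 57.021464, tolerance = 1e-6)

  # additivity: M(AB) = M(A) + M(B) - water, any split
  set.seed(41)
  for (i in 1:20) {
    s <- residues(randomChain(20))
    k <- sample(1:19, 1)
    expect_equal(peptideMass(s),
                 peptideMass(substr(s, 1, k)) +
                   peptideMass(substr(s, k + 1, 20)) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("theoretical fingerprints dedupe and respect the m/z window", {
  ch <- proteinChain("x", "GADG")
  p <- digestParams("acid_asp", maxMissed = 2, mzRange = NULL)
  fp <- theoreticalFingerprint(ch, p)
  expect_equal(fp, sort(peptideMz(c("GA", "GAD", "GADG", "D", "DG", "G"))),
               tolerance = 1e-9)
  # two identical chains collapse to one list
  expect_equal(theoreticalFingerprint(list(ch, ch), p), fp)
  # empty after range filtering
  expect_length(theoreticalFingerprint(ch, digestParams(
    "acid_asp", maxMissed = 0, mzRange = c(5000, 6000))), 0)
})

test_that("sequence coverage counts residues under matched peptides", {
  ch <- randomChain(60, "HC")
  p <- digestParams("trypsin", maxMissed = 1, mzRange = NULL)
  full <- massPeaks(theoreticalFingerprint(ch, p))
  cov <- sequenceCoverage(full, ch, p, dmz = 0.3)
  expect_equal(cov$coverage, 1.0)
  expect_equal(sequenceCoverage(massPeaks(numeric()), ch, p,
                                dmz = 0.3)$coverage, 0)

  # constructed partial coverage: peptides covering residues 1-5 of 10
  ch10 <- proteinChain("x", "GGGGKAAAAA")
  p0 <- digestParams("trypsin", maxMissed = 0, mzRange = NULL)
  pep <- enumeratePeptides(ch10, p0)
  first <- massPeaks(pep$mzCharged[pep$end <= 5])
  expect_equal(sequenceCoverage(first, ch10, p0, dmz = 0.1)$coverage, 0.5)
})

test_that("coverage is monotone in dmz and maxMissed", {
  set.seed(51)
  ch <- randomChain(80)
  p2 <- digestParams("trypsin", maxMissed = 2, mzRange = NULL)
  theo <- theoreticalFingerprint(ch, p2)
  obs <- massPeaks(theo[seq(1, length(theo), by = 2)] +
                     runif(ceiling(length(theo) / 2), -0.2, 0.2))
  covs <- vapply(c(0.05, 0.1, 0.2, 0.3), function(d)
    sequenceCoverage(obs, ch, p2, dmz = d)$coverage, numeric(1))
  expect_true(all(diff(covs) >= 0))
  covm <- vapply(0:3, function(mm)
    sequenceCoverage(obs, ch, digestParams("trypsin", maxMissed = mm,
                                           mzRange = NULL),
                     dmz = 0.3)$coverage, numeric(1))
  expect_true(all(diff(covm) >= 0))
})

test_that("FASTA chains parse with comments, headers and validation", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("# comment", ">HC some antibody heavy chain", "GAV",
               "DKR", ">LC", "GGS"), f)
  chains <- readChainsFasta(f)
  expect_named(chains, c("HC", "LC"))
  expect_equal(residues(chains$HC), "GAVDKR")
  writeLines(c(">empty"), f)
  expect_error(readChainsFasta(f), "empty sequence")
})
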