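test_that("match counting is one-to-one within the tolerance", {
  r <- matchCount(massPeaks(c(1000.00, 2000.00)),
                  massPeaks(c(1000.05, 3000.00)), dmz = 0.1)
  expect_equal(r$nMatching, 1L)
  expect_equal(r$matchedPairs$entryMz, 1000.05)

  five <- massPeaks(c(800, 900, 1000, 1100, 1200))
  self <- matchCount(five, five, dmz = 0.3)
  expect_equal(self$nMatching, 5L)
  expect_equal(self$fraction, 1.0)

  # a cluster of entry peaks cannot be double-counted
  r2 <- matchCount(massPeaks(c(1000.0, 1000.1)), massPeaks(1000.05),
                   dmz = 0.3)
  expect_equal(r2$nMatching, 1L)
  expect_equal(matchCount(massPeaks(numeric()), five, 0.3)$nMatching, 0L)
})

test_that("pair counts are symmetric and monotone in dmz", {
  set.seed(81)
  for (i in 1:20) {
    a <- sort(runif(30, 700, 4000))
    b <- sort(runif(30, 700, 4000))
    n1 <- matchCount(massPeaks(a), massPeaks(b), 0.5)$nMatching
    n2 <- matchCount(massPeaks(b), massPeaks(a), 0.5)$nMatching
    expect_equal(n1, n2)
    counts <- vapply(c(0.05, 0.2, 0.5, 1), function(d)
      matchCount(massPeaks(a), massPeaks(b), d)$nMatching, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("greedy pairing equals exhaustive maximum bipartite matching", {
  set.seed(91)
  for (i in 1:100) {
    s <- sort(runif(50, 700, 6500))
    e <- sort(runif(50, 700, 6500))
    got <- matchCount(massPeaks(s), massPeaks(e), dmz = 0.3)$nMatching
    expect_equal(got, maxMatchingOracle(s, e, 0.3))
  }
  # dense regime where greedy and optimal could differ is exercised too
  for (i in 1:20) {
    s <- sort(runif(40, 1000, 1020))
    e <- sort(runif(40, 1000, 1020))
    expect_equal(matchCount(massPeaks(s), massPeaks(e), 0.3)$nMatching,
                 maxMatchingOracle(s, e, 0.3))
  }
})

makeTestLibrary <- function(n = 10, seed = 101, method = "acid") {
  set.seed(seed)
  ents <- lapply(seq_len(n), function(i)
    libraryEntry(sprintf("lib%02d", i),
                 massPeaks(sort(runif(40, 700, 6500)), runif(40, 10, 100)),
                 method = method,
                 isotype = sample(c("IgG1", "IgG2a"), 1),
                 antigen = sample(c("RBD", "S1", "N"), 1)))
  fingerprintLibrary(ents)
}

test_that("a library containing the sample ranks it first at 100%", {
  lib <- makeTestLibrary(10)
  sample <- entries(lib)[[4]]@peaks
  for (dmz in c(0.01, 0.1, 0.3, 1)) {
    rk <- rankLibrary(sample, lib, dmz = dmz)
    expect_equal(rk$clone[1], "lib04")
    expect_equal(rk$fraction[1], 1.0)
    expect_equal(rk$nMatching[1], length(sample))
  }
  # disjoint-mass entries + one identical: margin is the full peak count
  base <- massPeaks(seq(1000, 2950, by = 50))
  ents <- lapply(1:10, function(i)
    libraryEntry(paste0("off", i), massPeaks(mz(base) + i * 7 + 3), "acid"))
  lib2 <- fingerprintLibrary(c(ents, list(libraryEntry("hit", base,
                                                       "acid"))))
  rk2 <- rankLibrary(base, lib2, dmz = 0.3)
  expect_equal(rk2$clone[1], "hit")
  expect_equal(decisionMargin(rk2), length(base))
})

test_that("ranking is complete, ordered, and method-filtered", {
  lib <- makeTestLibrary(8)
  sample <- massPeaks(sort(runif(40, 700, 6500)))
  rk <- rankLibrary(sample, lib, 0.3)
  expect_equal(nrow(rk), 8L)
  expect_true(all(diff(rk$nMatching) <= 0))
  expect_equal(rk$rank, 1:8)

  tryp <- fingerprintLibrary(list(
    libraryEntry("t1", massPeaks(c(1000, 2000)), "trypsin"),
    libraryEntry("a1", massPeaks(c(1000, 2000)), "acid")))
  expect_equal(rankLibrary(massPeaks(c(1000, 2000)), tryp, 0.3,
                           methodFilter = "trypsin")$clone, "t1")
  empty <- rankLibrary(sample, fingerprintLibrary(), 0.3)
  expect_equal(nrow(empty), 0L)
})

test_that("metadata filtering is case-insensitive substring search", {
  lib <- makeTestLibrary(12, seed = 111)
  nRBD <- sum(vapply(entries(lib), function(e) e@antigen == "RBD",
                     logical(1)))
  expect_equal(length(entries(filterLibrary(lib, "rbd"))), nRBD)
  expect_equal(length(entries(filterLibrary(lib, ""))), 12L)
  expect_equal(length(entries(filterLibrary(lib, "zzz"))), 0L)
  # original library untouched
  expect_equal(length(entries(lib)), 12L)
})

test_that("decision margins follow the ranked counts", {
  fake <- function(counts) {
    df <- data.frame(nMatching = counts,
                     fraction = counts / max(counts))
    df[order(-df$nMatching), , drop = FALSE]
  }
  expect_equal(decisionMargin(fake(c(37, 18, 10))), 19L)
  expect_equal(decisionMargin(fake(c(8, 8, 8))), 0L)
  expect_equal(decisionMargin(fake(c(10, 3, 3))), 7L)
  expect_equal(decisionMargin(fake(c(3, 10, 3))), 7L)  # order-invariant
  expect_error(decisionMargin(fake(5)), "undefined margin")
})

test_that("library directories round-trip entries and metadata", {
  dir <- withr::local_tempdir()
  lib <- makeTestLibrary(5, seed = 121)
  writeLibrary(lib, dir)
  lib2 <- readLibrary(dir)
  expect_equal(length(entries(lib2)), 5L)
  for (i in 1:5) {
    expect_equal(entries(lib2)[[i]]@clone, entries(lib)[[i]]@clone)
    expect_equal(mz(entries(lib2)[[i]]@peaks), mz(entries(lib)[[i]]@peaks),
                 tolerance = 1e-6)
    expect_equal(entries(lib2)[[i]]@antigen, entries(lib)[[i]]@antigen)
  }
  libraryAdd(dir, libraryEntry("extra", massPeaks(c(1000, 1500)),
                               "trypsin"))
  expect_equal(length(entries(readLibrary(dir))), 6L)
})
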