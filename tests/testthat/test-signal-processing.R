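test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  x <- seq(1000, 1100, by = 0.1)
  const <- massSpectrum(x, rep(7, length(x)))
  expect_equal(intensity(smoothSavitzkyGolay(const, 51, 2)),
               rep(7, length(x)), tolerance = 1e-9)

  line <- massSpectrum(x, 0.5 * (x - 1000) + 2)
  expect_equal(intensity(smoothSavitzkyGolay(line, 51, 2)),
               0.5 * (x - 1000) + 2, tolerance = 1e-9)

  # Monte-Carlo: smoothing reduces residual noise variance
  set.seed(7)
  clean <- 50 + 20 * sin((x - 1000) / 5)
  noisy <- massSpectrum(x, pmax(clean + rnorm(length(x)), 0))
  sm <- smoothSavitzkyGolay(noisy, 21, 2)
  expect_lt(var(intensity(sm) - clean), var(intensity(noisy) - clean))

  expect_error(smoothSavitzkyGolay(massSpectrum(1:10, 1:10), 51),
               "exceeds data length")
})

test_that("even smoothing windows are coerced to the next odd integer", {
  expect_equal(processingParams(sgWindow = 50)$sgWindow, 51L)
  expect_equal(processingParams(sgWindow = 9)$sgWindow, 9L)
  expect_error(processingParams(snrMin = 0), "positive")
  expect_error(processingParams(dmz = -1), "positive")
})

test_that("SNIP baseline removes flat and sloped backgrounds", {
  x <- seq(1000, 1200, by = 0.1)
  flat <- massSpectrum(x, rep(100, length(x)))
  expect_true(all(abs(intensity(baselineCorrect(flat, 100))) < 1))

  # narrow Gaussian on a linear ramp: apex height preserved within 5%
  ramp <- 10 + 0.05 * (x - 1000)
  peak <- 80 * exp(-((x - 1100)^2) / (2 * 0.05^2))
  s <- massSpectrum(x, ramp + peak)
  corr <- baselineCorrect(s, 100)
  apex <- max(intensity(corr))
  expect_lt(abs(apex - 80) / 80, 0.05)

  # already baseline-free: total ion current changes < 2%
  s0 <- massSpectrum(x, peak)
  corr0 <- baselineCorrect(s0, 100)
  expect_lt(abs(sum(intensity(corr0)) - sum(peak)) / sum(peak), 0.02)
})

test_that("peak detection finds real peaks and rejects pure noise", {
  params <- processingParams(deisotope = FALSE)
  one <- gaussianSpectrum(1000, 50, noise_sd = 1, range = c(950, 1050),
                          seed = 1)
  pk <- detectPeaks(one, params)
  expect_equal(length(pk), 1L)
  expect_lt(abs(mz(pk) - 1000), 0.05)

  two <- gaussianSpectrum(c(1000, 1010), c(50, 40), noise_sd = 1,
                          range = c(950, 1050), seed = 2)
  pk2 <- detectPeaks(two, params)
  expect_equal(length(pk2), 2L)
  expect_true(all(diff(mz(pk2)) > 0))

  # pure Gaussian noise at snrMin = 5: no peaks in >= 95% of trials
  set.seed(42)
  clean <- replicate(100, {
    noise <- gaussianSpectrum(numeric(), numeric(), noise_sd = 1,
                              range = c(950, 1050))
    length(detectPeaks(noise, processingParams(snrMin = 5,
                                               deisotope = FALSE)))
  })
  expect_gte(mean(clean == 0), 0.95)

  expect_equal(length(detectPeaks(massSpectrum(numeric(), numeric()))), 0L)
})

test_that("every reported peak is a local maximum of the processed trace", {
  s <- gaussianSpectrum(seq(1000, 1400, by = 50), rep(40, 9), noise_sd = 1,
                        range = c(950, 1450), seed = 3)
  pk <- detectPeaks(s, processingParams(deisotope = FALSE))
  expect_gt(length(pk), 0)
  expect_true(all(diff(mz(pk)) > 0))
  # apexes sit on grid points of the spectrum
  expect_true(all(mz(pk) %in% mz(s)))
})

test_that("deisotoping collapses envelopes, is idempotent, never adds peaks", {
  env <- massPeaks(c(1000.000, 1001.003, 1002.006), c(100, 80, 40))
  d <- deisotope(env)
  expect_equal(mz(d), 1000.000)
  expect_true(isDeisotoped(d))

  single <- massPeaks(1500.5, 10)
  expect_equal(mz(deisotope(single)), 1500.5)

  two_env <- massPeaks(c(1000.0, 1001.002, 2000.0, 2001.003, 2002.005),
                       c(100, 50, 90, 70, 30))
  d2 <- deisotope(two_env)
  expect_equal(mz(d2), c(1000.0, 2000.0))

  # idempotence and monotone peak count on random peak sets
  set.seed(11)
  for (i in 1:20) {
    p <- massPeaks(sort(runif(30, 1000, 1100)), runif(30, 1, 100))
    d1 <- deisotope(p)
    expect_lte(length(d1), length(p))
    expect_equal(mz(deisotope(d1)), mz(d1))
  }
})

test_that("apex picking matches brute-force argmax after smoothing", {
  # symmetric Gaussian: apex within one bin of the centre
  s <- gaussianSpectrum(75000, 100, sigma = 150, range = c(60000, 90000),
                        step = 2, noise_sd = 0.5, seed = 4)
  a <- apexMass(s, c(60000, 90000), sgWindow = 51)
  expect_lt(abs(a$mz - 75000), 10)

  # skewed peak: equals direct argmax of the identically smoothed trace
  x <- seq(60000, 90000, by = 2)
  skew <- 100 * exp(-(x - 74000) / 800) * pnorm((x - 74000) / 300)
  sk <- massSpectrum(x, skew, mode = "linear")
  a2 <- apexMass(sk, c(60000, 90000), sgWindow = 51)
  ys <- signal::sgolayfilt(skew, p = 2, n = 51)
  expect_equal(a2$mz, x[which.max(ys)])

  expect_error(apexMass(sk, c(95000, 99000)), "no data points")
  expect_error(apexMass(massSpectrum(1:30, rnorm(30)^2), c(1, 30),
                        sgWindow = 51), "fewer than the smoothing window")
})
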