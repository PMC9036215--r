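# Shared fixtures and independent oracles.

# Profile spectrum with Gaussian peaks on an optional baseline and noise.
gaussianSpectrum <- function(centers, heights, sigma = 0.05,
                             range = c(700, 1500), step = 0.02,
                             noise_sd = 0, baseline = 0, mode = "reflector",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(range[1], range[2], by = step)
  y <- rep(0, length(grid))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-((grid - centers[i])^2) / (2 * sigma^2))
  if (length(baseline) == 1L) baseline <- rep(baseline, length(grid))
  if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
  massSpectrum(grid, pmax(y + baseline, 0), mode = mode)
}

# Random peptide-like chain from a fixed alphabet.
randomChain <- function(n = 50, id = "X") {
  proteinChain(id, paste(sample(c("G", "A", "S", "P", "V", "T", "C", "L",
                                  "N", "D", "Q", "K", "E", "M", "H", "F",
                                  "R", "Y", "W", "I"), n, replace = TRUE),
                         collapse = ""))
}

# Independent digestion oracle: enumerate ALL substrings and keep those
# whose boundaries are cleavage-consistent with at most maxMissed internal
# sites. Site rules re-derived here, independently of cleavageSites().
bruteDigest <- function(seqstr, enzyme, maxMissed) {
  aa <- strsplit(seqstr, "")[[1]]
  n <- length(aa)
  sites <- integer()
  if (enzyme == "trypsin") {
    for (i in seq_len(n - 1))
      if (aa[i] %in% c("K", "R") && aa[i + 1] != "P")
        sites <- c(sites, i)
  } else {
    for (i in seq_len(n - 1))
      if (aa[i + 1] == "D" || aa[i] == "D") sites <- c(sites, i)
    sites <- sort(unique(sites))
  }
  valid <- c(0L, sites, n)
  out <- character()
  starts <- integer()
  ends <- integer()
  missed <- integer()
  for (s in seq_len(n)) for (e in s:n) {
    if (!((s - 1L) %in% valid) || !(e %in% valid)) next
    internal <- sum(sites > s - 1L & sites < e)
    if (internal > maxMissed) next
    out <- c(out, substr(seqstr, s, e))
    starts <- c(starts, s)
    ends <- c(ends, e)
    missed <- c(missed, internal)
  }
  data.frame(start = starts, end = ends, sequence = out,
             missedCleavages = missed, stringsAsFactors = FALSE)
}

# Independent maximum bipartite matching oracle (Kuhn's augmenting paths)
# between two sorted mass lists under tolerance dmz.
maxMatchingOracle <- function(s, e, dmz) {
  adj <- lapply(seq_along(s), function(i) which(abs(e - s[i]) <= dmz))
  matchE <- rep(0L, length(e))
  count <- 0L
  for (start in seq_along(s)) {
    seen <- rep(FALSE, length(e))
    aug <- function(i) {
      for (j in adj[[i]]) {
        if (!seen[j]) {
          seen[j] <<- TRUE
          if (matchE[j] == 0L || aug(matchE[j])) {
            matchE[j] <<- i
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(start)) count <- count + 1L
  }
  count
}

# Cached subclass references (built once per test run).
testRefs <- local({
  refs <- NULL
  function() {
    if (is.null(refs)) refs <<- buildSubclassReference()
    refs
  }
})
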