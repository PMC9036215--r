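## Standard residue masses (Da) for the 20 canonical amino acids.
## Monoisotopic values from the IUPAC 2021 atomic masses as tabulated by
## Unimod; average values from the standard atomic weights.
MONO_RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

AVG_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

AA_LETTERS <- names(MONO_RESIDUE_MASS)

WATER_MONO <- 18.010565
WATER_AVG <- 18.0153
CAM_MONO <- 57.021464   # carbamidomethyl on Cys
CAM_AVG <- 57.0513

#' In-silico digestion parameters
#'
#' @param enzyme `"trypsin"` (cleaves after K/R except before P) or
#'   `"acid_asp"` (dilute-acid hydrolysis modelled as cleavage both before
#'   and after every aspartate, i.e. Asp-N plus Asp-C specificity).
#' @param maxMissed maximal missed cleavages per peptide. Defaults: 2 for
#'   trypsin (a 15-min digest is incomplete), 5 for acid (partial acidic
#'   hydrolysis leaves many sites uncut).
#' @param massType `"mono"` or `"average"`.
#' @param mzRange numeric `(lo, hi)` filter on the singly protonated m/z,
#'   default `c(700, 7000)` to match reflector-mode acquisition.
#' @param charge charge state for the m/z filter (default 1).
#' @return A list of class `DigestParams`.
#' @export
digestParams <- function(enzyme = c("trypsin", "acid_asp"),
                         maxMissed = NULL,
                         massType = c("mono", "average"),
                         mzRange = c(700, 7000), charge = 1L) {
  enzyme <- match.arg(enzyme)
  massType <- match.arg(massType)
  if (is.null(maxMissed))
    maxMissed <- if (enzyme == "acid_asp") 5L else 2L
  maxMissed <- as.integer(maxMissed)
  if (maxMissed < 0L) stop("maxMissed must be >= 0")
  if (!is.null(mzRange)) {
    if (length(mzRange) != 2L || mzRange[1] >= mzRange[2])
      stop("mzRange must be (lo, hi) with lo < hi")
  }
  structure(list(enzyme = enzyme, maxMissed = maxMissed,
                 massType = massType, mzRange = mzRange,
                 charge = as.integer(charge)),
            class = "DigestParams")
}

#' Cleavage sites of an enzyme or chemistry on a chain
#'
#' Returns inter-residue positions: a site `i` means cleavage between
#' residues `i` and `i + 1`. Trypsin cuts after K or R unless the next
#' residue is P; dilute-acid hydrolysis cuts both before and after every D
#' (the union of Asp-N and Asp-C specificity).
#'
#' @param chain a [ProteinChain-class].
#' @param enzyme `"trypsin"` or `"acid_asp"`.
#' @return Sorted integer vector of internal cleavage positions (the chain
#'   termini are implicit and never included).
#' @examples
#' cleavageSites(proteinChain("x", "AKRPCK"), "trypsin")  # 2
#' cleavageSites(proteinChain("x", "GADG"), "acid_asp")   # 2 3
#' @export
cleavageSites <- function(chain, enzyme = c("trypsin", "acid_asp")) {
  stopifnot(is(chain, "ProteinChain"))
  enzyme <- match.arg(enzyme)
  aa <- strsplit(chain@residues, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(integer())
  sites <- if (enzyme == "trypsin") {
    which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  } else {
    d <- which(aa == "D")
    sort(unique(c(d - 1L, d)))  # before and after each D
  }
  sites <- sites[sites >= 1L & sites <= n - 1L]
  as.integer(sites)
}

#' Enumerate in-silico peptides of a chain
#'
#' All peptides delimited by consecutive cleavage sites with at most
#' `maxMissed` internal sites skipped, including the chain termini, filtered
#' to those whose `[M+zH]z+` m/z falls in `mzRange` (when set). With
#' `maxMissed = 0` the peptides tile the chain exactly.
#'
#' @param chain a [ProteinChain-class].
#' @param params a [digestParams()] list.
#' @return A data.frame with columns `chainId`, `start`, `end` (1-based
#'   inclusive), `sequence`, `missedCleavages`, `massMono`, `massAvg`, `mzCharged`.
#' @examples
#' enumeratePeptides(proteinChain("x", "GADG"),
#'                   digestParams("acid_asp", maxMissed = 0, mzRange = NULL))
#' @export
enumeratePeptides <- function(chain, params = digestParams()) {
  stopifnot(is(chain, "ProteinChain"), inherits(params, "DigestParams"))
  n <- nchar(chain@residues)
  sites <- cleavageSites(chain, params$enzyme)
  bounds <- c(0L, sites, n)  # segment boundaries as "after residue i"
  nseg <- length(bounds) - 1L
  out <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    jmax <- min(nseg, i + params$maxMissed)
    js <- i:jmax
    out[[i]] <- data.frame(
      start = bounds[i] + 1L,
      end = bounds[js + 1L],
      missedCleavages = js - i
    )
  }
  pep <- do.call(rbind, out)
  pep$sequence <- substring(chain@residues, pep$start, pep$end)
  pep$massMono <- peptideMass(pep$sequence, "mono", chain@cysState)
  pep$massAvg <- peptideMass(pep$sequence, "average", chain@cysState)
  m <- if (params$massType == "mono") pep$massMono else pep$massAvg
  z <- params$charge
  pep$mzCharged <- (m + z * PROTON_MASS) / z
  if (!is.null(params$mzRange))
    pep <- pep[pep$mzCharged >= params$mzRange[1] &
               pep$mzCharged <= params$mzRange[2], , drop = FALSE]
  pep <- data.frame(chainId = rep(chain@chainId, nrow(pep)), pep,
                    stringsAsFactors = FALSE)
  rownames(pep) <- NULL
  pep[order(pep$start, pep$end), , drop = FALSE]
}

#' Neutral peptide mass and charged m/z
#'
#' `peptideMass()` returns the neutral mass M = sum of residue masses plus
#' one water (18.010565 Da monoisotopic, 18.0153 Da average).
#' Carbamidomethylation adds 57.021464 Da (mono) per cysteine only when
#' `cysState = "carbamidomethyl"`. `peptideMz()` returns
#' `(M + z * 1.007276) / z`.
#'
#' @param sequence character vector of peptide sequences (canonical 20-letter
#'   alphabet; empty or unknown letters are an error).
#' @param massType `"mono"` or `"average"`.
#' @param cysState `"reduced"` (default) or `"carbamidomethyl"`.
#' @return Numeric vector of masses (Da) or m/z values (Th).
#' @examples
#' peptideMass("G")            # 75.032028
#' peptideMz("G", charge = 1)  # 76.039304
#' @export
peptideMass <- function(sequence, massType = c("mono", "average"),
                        cysState = c("reduced", "carbamidomethyl")) {
  massType <- match.arg(massType)
  cysState <- match.arg(cysState)
  tab <- if (massType == "mono") MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  water <- if (massType == "mono") WATER_MONO else WATER_AVG
  cam <- if (massType == "mono") CAM_MONO else CAM_AVG
  vapply(as.character(sequence), function(s) {
    if (is.na(s) || !nzchar(s))
      stop("alphabet error: empty peptide sequence")
    aa <- strsplit(s, "")[[1]]
    m <- tab[aa]
    if (anyNA(m))
      stop("alphabet error: unknown residue letter(s): ",
           paste(unique(aa[is.na(m)]), collapse = ", "))
    tot <- sum(m) + water
    if (cysState == "carbamidomethyl") tot <- tot + cam * sum(aa == "C")
    tot
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname peptideMass
#' @param charge charge state z (default 1).
#' @export
peptideMz <- function(sequence, charge = 1L, massType = c("mono", "average"),
                      cysState = c("reduced", "carbamidomethyl")) {
  z <- as.integer(charge)
  (peptideMass(sequence, massType, cysState) + z * PROTON_MASS) / z
}

#' Theoretical peptide-mass fingerprint of one or more chains
#'
#' Union of the `[M+zH]z+` m/z values of all in-silico peptides across the
#' supplied chains, sorted and deduplicated within 1e-4 Da (identical
#' peptides from identical chains collapse).
#'
#' @param chains a [ProteinChain-class] or list of them.
#' @param params a [digestParams()] list.
#' @return Sorted numeric vector of m/z values.
#' @export
theoreticalFingerprint <- function(chains, params = digestParams()) {
  if (is(chains, "ProteinChain")) chains <- list(chains)
  mzs <- sort(unlist(lapply(chains, function(ch)
    enumeratePeptides(ch, params)$mzCharged), use.names = FALSE))
  if (!length(mzs)) return(numeric())
  mzs[c(TRUE, diff(mzs) > 1e-4)]
}

#' Sequence coverage of observed peaks over protein chains
#'
#' A theoretical peptide counts as observed when some peak in `observed`
#' lies within `dmz` of its charged m/z; coverage is the fraction of
#' residues (across all chains) contained in at least one observed peptide.
#' Several peak lists (e.g. acid plus trypsin fingerprints, each with its
#' own digestion parameters) combine by the union of their residue masks.
#'
#' @param observed a [MassPeaks-class], or a list of them for combined
#'   coverage.
#' @param chains a [ProteinChain-class] or list of them.
#' @param params a [digestParams()] list, or a list of them parallel to
#'   `observed`.
#' @param dmz mass tolerance in Da (default 0.3).
#' @return List with `coverage` (fraction in [0, 1]), `masks` (per-chain
#'   logical vectors over residues) and `nObservedPeptides`.
#' @export
sequenceCoverage <- function(observed, chains, params = digestParams(),
                             dmz = 0.3) {
  if (is(chains, "ProteinChain")) chains <- list(chains)
  if (is(observed, "MassPeaks")) observed <- list(observed)
  if (inherits(params, "DigestParams"))
    params <- rep(list(params), length(observed))
  stopifnot(length(params) == length(observed))
  masks <- lapply(chains, function(ch)
    logical(nchar(ch@residues)))
  names(masks) <- vapply(chains, chainId, character(1))
  nObs <- 0L
  for (k in seq_along(observed)) {
    obs_mz <- mz(observed[[k]])
    for (ci in seq_along(chains)) {
      pep <- enumeratePeptides(chains[[ci]], params[[k]])
      if (!nrow(pep)) next
      hit <- vapply(pep$mzCharged, function(m)
        length(obs_mz) > 0 && min(abs(obs_mz - m)) <= dmz, logical(1))
      nObs <- nObs + sum(hit)
      for (j in which(hit))
        masks[[ci]][pep$start[j]:pep$end[j]] <- TRUE
    }
  }
  tot <- sum(vapply(masks, length, integer(1)))
  list(coverage = if (tot) sum(vapply(masks, sum, integer(1))) / tot else 0,
       masks = masks, nObservedPeptides = nObs)
}

#' Read protein chains from a FASTA file
#'
#' Minimal FASTA reading for antibody chains: the first whitespace-separated
#' token of each header is the chain id; the full header is kept as a
#' description. Sequences are upper-cased and alphabet-checked against the
#' 20 canonical letters.
#'
#' @param path FASTA file path.
#' @param cysState cysteine state applied to all chains (default
#'   `"reduced"`).
#' @return Named list of [ProteinChain-class] objects.
#' @export
readChainsFasta <- function(path, cysState = c("reduced",
                                               "carbamidomethyl")) {
  cysState <- match.arg(cysState)
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#;]", trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("parameter error: no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  chains <- vector("list", length(hdr))
  ids <- character(length(hdr))
  for (i in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[i]])
    ids[i] <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
    seqs <- if (hdr[i] + 1L > ends[i]) "" else
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    seqs <- gsub("[[:space:]]", "", seqs)
    if (!nzchar(seqs))
      stop("format error: empty sequence for FASTA record '", ids[i], "'")
    chains[[i]] <- proteinChain(ids[i], seqs, cysState)
    attr(chains[[i]], "description") <- header
  }
  names(chains) <- ids
  chains
}
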