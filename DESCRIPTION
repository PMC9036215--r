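Package: mAbFingerprint
Title: Sequence-Independent Identification of Monoclonal Antibodies by
    MALDI-TOF Peptide Mass Fingerprinting
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying monoclonal antibodies without sequence
    information from MALDI-TOF mass spectra. Implements intact and light-chain
    mass profiling relative to a reference antibody with 95% confidence
    intervals and a uniqueness (CI-overlap) analysis; reflector-mode spectral
    processing (Savitzky-Golay smoothing, SNIP baseline subtraction,
    SNR-based peak picking, deisotoping); in-silico digestion (trypsin and
    dilute-acid cleavage at aspartate) with monoisotopic and average peptide
    masses and sequence-coverage scoring; tolerance-based fingerprint-library
    matching with ranked match counts and decision margins; antibody subclass
    calling against constant-region (CH2-CH3) digests; and a synthetic-data
    generator producing fingerprint and intact-mass spectra with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-io.R'
    'signal-processing.R'
    'digestion.R'
    'mass-profile.R'
    'identification.R'
    'subclassing.R'
    'synthetic-data.R'
    'reproduce.R'
    'cli.R'
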