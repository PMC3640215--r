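Package: hftica
Title: Temporal ICA of High-Frequency Resting-State fMRI Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating and characterizing high-frequency (above 0.25 Hz)
    fluctuations in fast-TR resting-state fMRI. Implements discrete-Fourier high-pass
    filtering of voxel time courses, motion-parameter regression, temporal concatenation
    of subjects, PCA prewhitening via truncated singular value decomposition, symmetric
    FastICA extraction of temporally independent components with back-projected spatial
    maps, a subject-consistency variance-ratio filter, spectral band-fraction
    fingerprinting, and rule-based classification of components into pulsation,
    resting-state-network, technical-artifact and cardiac families. Includes a seedable
    multi-subject 4D simulator with known ground-truth sources (skewed RSN-like spectra,
    subject-specific cardiac oscillators, narrowband slice-banded technical artifacts and
    broadband pulsation) so that the full pipeline can be validated end to end, plus
    NIfTI/TSV/JSON/YAML input and output and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
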