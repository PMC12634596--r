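Package: imcoh
Title: Frequency-Specific Intermuscular Coherence of Synergistic Muscles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking muscle synergies to frequency-specific
    intermuscular coherence. Provides a synthetic multi-muscle surface-EMG
    generator with known synergy structure and band-limited common drives,
    non-negative matrix factorization (NMF) extraction of muscle synergies with
    three-criterion rank selection, Hilbert-demodulated Welch coherence between
    muscle pairs with phase-randomization surrogate significance testing,
    data-driven detection of subject-specific frequency layers by NMF of
    concatenated coherence spectra, and linear mixed-effects comparison of
    layer-averaged coherence between synergistic and non-synergistic muscle
    pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
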