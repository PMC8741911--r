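Package: lfpclean
Title: Channel-Independent Artefact Replacement for Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and replaces artefactual segments in chronically
    recorded local field potentials (LFPs) using only the affected
    channel's own history. Windows whose mean squared amplitude exceeds a
    per-channel power threshold are labelled artefactual; a sequence
    forecaster (single-layer LSTM, a dilated convolutional CNN-LSTM, or an
    ARMAX baseline) is trained on artefact-free segments and artefact
    windows are overwritten with recursively generated forecasts so the
    cleaned signal preserves temporal and spectral continuity. Includes a
    seeded synthetic LFP generator with ground-truth artefact injection,
    periodogram and window-power diagnostics, and a composable
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
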