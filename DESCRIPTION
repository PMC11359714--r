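Package: eegdense
Title: Expansion of Low-Density EEG Recordings with Stacked Bidirectional LSTMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-density (60-channel) EEG recordings from
    low-density electrode subsets (9-18 channels) using a two-layer stacked
    bidirectional LSTM trained on windowed multichannel time series. Ships the
    classical spatial-interpolation baselines it is compared against
    (normalized inverse-distance weighting and natural cubic splines along
    electrode lines), a 10-10 scalp montage with azimuthal-equidistant planar
    projection, standard motor-imagery preprocessing (artifact thresholding,
    zero-phase band-pass filtering, baseline correction, round-wise
    cross-validation splits), a synthetic EEG generator with
    distance-decaying spatial correlation and class-dependent
    event-related desynchronization, and a downstream common-spatial-pattern
    plus one-versus-rest classification pipeline for judging reconstruction
    quality on four-class motor imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
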