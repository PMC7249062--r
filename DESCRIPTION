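Package: filternet
Title: Many-to-Many Multi-Scale CNN/LSTM Networks for Dense Time Series
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Builds, trains and evaluates FilterNet-style many-to-many
    neural networks for dense labeling of multichannel sensor time series,
    such as wearable-sensor activity recognition. Provides the FilterNet
    layer module (dropout, 1-D convolution or bidirectional LSTM, average
    pooling and batch normalization) together with its shape, parameter
    and region-of-influence calculus; the prototypical multi-scale
    component architecture and its five reference variants; sliding-window
    inference with Hanning-weighted overlap-add or region-of-influence
    trimming; training with a smoothed, instability-penalized checkpoint
    metric and patience-based early stopping; contiguous n-fold logit
    ensembling; sample-based F1 summaries and event-based evaluation in
    the Ward taxonomy; and a synthetic labeled-series generator for
    end-to-end experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
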