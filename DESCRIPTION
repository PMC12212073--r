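Package: exzd
Title: Ex-Zd Compression for Nanopore Raw Signal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless and lossy compression of raw nanopore sequencing
    signal. Implements the ex-zd record codec, which zig-zag delta
    transforms a read's 16-bit ADC samples and stores the dense one-byte
    deltas verbatim, separately from the rare two-byte exceptions
    (streamvbyte-encoded with their positions); and an optional lossy
    bit-reduction operator that zeroes the n least significant bits of
    every sample by nearest-multiple rounding before lossless encoding.
    Includes SLOW5-ASCII input/output, a minimal binary record container,
    a synthetic ONT-like signal generator (bimodal pore levels, dwell
    segments, Gaussian noise, optional ADC spike artifacts), and an
    analysis layer for value histograms, spike scoring and
    compression-ratio benchmarks against general-purpose codecs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
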