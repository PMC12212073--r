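---
title: "Methods: the ex-zd signal codec, its lossy operator, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ex-zd signal codec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exzd)
```

## The problem

A nanopore sequencer records ionic current as a time series of integer ADC
counts — 11 bits per sample on a PromethION, 13 on a MinION, stored as
signed 16-bit integers with per-read calibration (`pA = (raw + offset) *
range / digitisation`). Raw signal is kept for re-basecalling and
reproducibility, and it is large: roughly ten times the size of the
basecalls. This package implements a record codec specialised for that
signal, a lossy bit-reduction operator that can precede it, a synthetic
signal generator so every experiment here is reproducible without
downloads, and an analysis layer for histograms, spike scoring and
compression benchmarks.

## The lossless record codec

Adjacent signal samples are strongly correlated, so the codec works on
consecutive differences. For one read the pipeline is:

1. **Shift.** Every sample is right-shifted by the smallest count of
   trailing zero bits common to all samples (computed on the
   two's-complement 16-bit pattern; the count of the value 0 is taken as
   16 and the result capped at 15 so the shift fits one byte and all-zero
   reads still round-trip). For native data this shift is almost always 0;
   after lossy n-bit rounding it is at least n, which is where the lossy
   savings feed the lossless stage.
2. **Zig-zag delta.** The first (shifted) sample and the consecutive
   deltas are zig-zag mapped: non-negative `v` to `2v`, negative `v` to
   `2|v| - 1`. Small-magnitude deltas of either sign become small
   non-negative codes.
3. **Partition.** The zig-zag deltas split into *one-byte values*
   (&le; 255), written verbatim one byte each, and *exceptions* (> 255),
   which are stored minus 256 together with their 0-based positions in the
   delta sequence. A single exception is written as two plain 4-byte
   fields; two or more are streamvbyte-encoded — positions first (first
   position verbatim, the rest delta-encoded minus 1, which is well
   defined because positions strictly increase), then values, each block
   preceded by its 4-byte size.

The record layout is: version (1 byte), sample count (8), shift (1),
zig-zagged first sample (2), exception count (4), the exception block, then
the one-byte data. All fields are little-endian; the blob is
self-delimiting given its start offset. The one-byte stream holds no
placeholders at exception positions — the blocks are disjoint, which is
also what makes the closed-form size audit
`16 + exception_block + (num_samples - 1 - n_x)` exact.

Two boundary contracts are worth stating. The zig-zagged *first* sample
must fit two bytes; a read whose first shifted sample zig-zags above 65535
is rejected with an error rather than silently widened. Zig-zag *deltas*
may exceed two nominal bytes for adversarial full-range input; they remain
representable because exception values are carried as unsigned 32-bit
integers through streamvbyte.

The streamvbyte dialect is the scalar convention: control bytes first,
2-bit codes packed least-significant-pair first, minimal little-endian data
bytes (value 0 uses one byte). The version byte of this dialect is 0 and
the container records a codec identifier, so a different dialect could
coexist without ambiguity. Golden byte fixtures in the test suite pin the
layout bit-exactly.

## The lossy operator

`round_low_bits(x, n)` zeroes the n least significant bits by rounding to
the nearest multiple of `2^n`:

```
(x AND NOT(2^n - 1)) + 2^n * bit_(n-1)(x)
```

A tie (low bits exactly `2^(n-1)`) rounds up — the formula's behaviour, and
the package's contract. The operation acts on the two's-complement
pattern, so negative samples also land on their nearest multiple. If
rounding up would leave 16-bit range, the result clamps to the largest
multiple of `2^n` at or below 32767; there, and only there, the error can
reach `2^n - 1` rather than `2^(n-1)`. Real ADC data occupies at most 13
bits and never approaches this boundary, but the codec accepts the full
16-bit range, so the behaviour is defined and tested rather than left
undefined.

Degrading is idempotent and never touches calibration metadata, so the
picoampere conversion stays consistent: an n-bit reduction perturbs the
current by at most `2^(n-1) * range / digitisation` picoamperes.
`eliminate_bits` up to 3 is the validated envelope for basecalling-grade
data; the API and CLI allow up to 8 but warn above 3.

## Why lossy and lossless are synergistic

After n-bit rounding every sample is a multiple of `2^n`, the common shift
is at least n, and the shifted deltas shrink by the same factor. On plain
ex-zd records this mostly reduces the *exception* count — the one-byte data
stays one byte per delta, whatever its entropy. The per-bit file-size
savings therefore materialise at the record-plus-entropy-coder level: the
shifted deltas have roughly one bit less entropy per eliminated bit, which
a general-purpose codec applied over the record realises as a
proportional size cut. This mirrors how signal files pair a record codec
with a general-purpose compressor in practice. The package's per-bit
experiment accordingly measures the zlib-wrapped ex-zd size
(`compression_report(..., "exzd_zlib")`), and on the synthetic defaults
each of the first four eliminated bits cuts it by more than 10%.

The package's general-purpose codecs are zlib (deflate — also the
benchmark baseline pairing `zlib_svb_zd`, i.e. zig-zag delta +
streamvbyte + zlib) and xz, both available from base R's `memCompress()`.
The compression ratio is always *uncompressed / compressed* with the
uncompressed size fixed at 2 bytes per sample; reads are compressed
record-by-record, as signal containers do.

## The synthetic signal model

`synth_model()` emulates the statistics of pore current that matter for a
codec, not the biology that produced it:

* **Levels**: a two-component Gaussian mixture, means at 35% and 65% of
  the ADC range, standard deviations 6% of the range, equal weight. Real
  pore level distributions are k-mer-dependent mixtures of many
  components, but bimodality at this separation reproduces the dynamic
  range and the segment-jump magnitudes a codec sees; the spike artifact
  below is independent of k-mer content, so finer level realism buys
  nothing for these experiments.
* **Dwell**: geometric segment lengths, mean 10 samples — the
  translocation dwell scale of current chemistries at 5 kHz.
* **Noise**: additive Gaussian, standard deviation 1.5% of the ADC range
  (about 31 counts at 11 bits), rounded and clamped to the ADC grid.
* **Spike artifact**: with probability `spike_rate`, a sample whose two
  least significant bits are `11` is displaced up by one onto the `00` of
  the next multiple of 4. This is a phenomenological stand-in for the
  converter artifact seen in real data, where frequency spikes sit at
  values whose low bits transition `11 -> 00`; the true hardware mechanism
  is not modelled. The displacement lives entirely in the two lowest bits,
  so a 2-bit reduction removes it by construction — which is exactly the
  flattening the experiments quantify.

Calibration metadata defaults are PromethION-typical (digitisation 2048,
range 1126.47 pA, 5 kHz). All randomness flows from the model seed; a
fixed seed gives bit-identical datasets.

What passing tests on this generator do **not** show: codec behaviour on
real pore-model level sequences, on RNA signal, or on instrument
idiosyncrasies beyond the injected spike. The lossless contract is
input-independent (tested exhaustively and on adversarial full-range
input), but the measured compression ratios and per-bit savings are
properties of the synthetic statistics and transfer to real data only in
kind, not in digit.

## Quantitative choices in the analysis layer

* **Spike score.** The field observation is qualitative ("adjacent
  frequencies differ substantially"), so the package defines its own
  metric: the mean over interior ADC values `v` (with at least one
  occupied neighbour) of `max(0, log2(c(v) / mean(c(v-1), c(v+1))))`. It
  is 0 for perfectly smooth histograms, contributes exactly 1 at a bin
  twice its flat neighbours, and is insensitive to empty bins (a zero
  count contributes 0, not -Inf). Histograms of degraded data are
  computed on the rounded values at native scale, not re-binned, so a
  2-bit-degraded histogram occupies multiples of 4 and its score collapses
  toward 0.
* **Mode counting.** Bimodality is asserted via `histogram_modes()`: a
  9-bin moving average followed by prominence-filtered peak detection (a
  mode must reach 5% of the global smoothed peak and be separated from
  every higher mode by a valley at least that deep). Without the
  prominence rule, Poisson counting noise at realistic sample counts
  produces hundreds of strict local maxima; with it, the spike-free
  synthetic histogram yields exactly the two mixture modes.
* **Problem sizes.** The simulation experiments use 100 reads of 5000
  samples (500k samples) for compression figures and 40 reads for spike
  scoring — sizes at which the statistics above are stable to well within
  the asserted margins, chosen so the whole suite re-runs in about a
  minute.

## Numerical and degenerate-input notes

* Zig-zag codes and exception values are carried as R doubles; all values
  are below 2^53, so arithmetic is exact. Bit operations use 32-bit
  integer intrinsics on the two's-complement pattern.
* Single-sample reads encode to the 16-byte header (no deltas, no
  exceptions); constant reads produce all-zero one-byte data; all-zero
  reads shift by the 15-bit cap and still round-trip.
* Decoding validates the version byte, every length implied by the
  header, exception positions (range, strict ordering) and trailing
  bytes, each with a distinct error message; a truncated container names
  the field it died in and returns no partial reads.
* `write_slow5_ascii()` formats numbers with up to 15 significant digits,
  C-locale, scientific notation disabled, so files are byte-deterministic
  and metadata round-trips at double precision for realistic calibration
  values.

## Known limitations

* The binary container here is deliberately minimal (magic `EZD0`,
  single read group, no index) — it defines file sizes for experiments
  and is not the BLOW5 format; interoperability with slow5 tooling is via
  SLOW5-ASCII.
* The streamvbyte dialect is the scalar one; containers record a codec id
  so a SIMD-permuted dialect would be detectable, not silently
  mis-decoded.
* Basecalling-level validation of lossy settings is out of scope; the
  package bounds reconstruction error exactly but says nothing about
  downstream model tolerance beyond the documented 3-bit envelope.
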