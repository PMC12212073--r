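# Experiment layer: value histograms, spike scoring, and compression-ratio
# benchmarks. The compression ratio is uncompressed size divided by
# compressed size, with the uncompressed size fixed at 2 bytes per sample
# (signed 16-bit). Bit-reduced histograms are computed on rounded values at
# the native ADC scale, not re-binned.

#' ADC value histogram of a dataset
#'
#' Exact counts per ADC value over the full `[0, 2^adc_bits - 1]` range.
#' Out-of-range samples are clamped with a warning.
#'
#' @param reads Signal-read tibble.
#' @param adc_bits ADC bit depth defining the value range.
#' @return A tibble with columns `value` and `count` (one row per ADC
#'   value), classed `exzd_histogram`.
#' @export
value_histogram <- function(reads, adc_bits = 11L) {
  check_reads(reads)
  top <- 2^adc_bits - 1
  s <- unlist(reads$samples, use.names = FALSE)
  n_out <- sum(s < 0 | s > top)
  if (n_out > 0) {
    warning(n_out, " sample(s) outside [0, ", top, "] were clamped",
            call. = FALSE)
    s <- pmin(pmax(s, 0), top)
  }
  hist <- tibble::tibble(value = 0:top,
                         count = tabulate(s + 1L, nbins = top + 1L))
  class(hist) <- c("exzd_histogram", class(hist))
  attr(hist, "adc_bits") <- as.integer(adc_bits)
  hist
}

#' Spike score of a value histogram
#'
#' Quantifies isolated frequency spikes: the mean, over interior ADC values
#' `v` whose neighbours are not both empty, of
#' `max(0, log2(count(v) / mean(count(v-1), count(v+1))))`. A perfectly
#' smooth histogram scores 0; a bin at twice the level of flat neighbours
#' contributes 1 at that bin. Larger is spikier.
#'
#' @param hist An [value_histogram()] result (or any tibble with `value`
#'   and `count`).
#' @return A single non-negative number.
#' @export
spike_score <- function(hist) {
  counts <- hist$count
  k <- length(counts)
  if (k < 3 || sum(counts > 0) < 3) {
    stop("spike_score: degenerate histogram (need >= 3 occupied bins)",
         call. = FALSE)
  }
  v <- 2:(k - 1)
  neigh <- (counts[v - 1] + counts[v + 1]) / 2
  eligible <- neigh > 0
  if (!any(eligible)) {
    stop("spike_score: degenerate histogram (no bin has occupied neighbours)",
         call. = FALSE)
  }
  contrib <- pmax(0, log2(counts[v][eligible] / neigh[eligible]))
  mean(contrib)
}

#' Modes of a value histogram
#'
#' Counts the modes of a histogram after smoothing with a moving average,
#' using a prominence rule so that counting noise is not mistaken for
#' multimodality: a local maximum is a mode only if it reaches at least
#' `min_prominence` of the global peak and is separated from every higher
#' accepted mode by a valley at least `min_prominence` of the peak below it.
#'
#' @param hist A [value_histogram()] result.
#' @param smooth_bins Width of the moving-average window (default 9 bins).
#' @param min_prominence Fraction of the global smoothed peak (default
#'   0.05) used for both the height floor and the valley depth.
#' @return Sorted vector of ADC values at the accepted modes.
#' @export
histogram_modes <- function(hist, smooth_bins = 9, min_prominence = 0.05) {
  cnt <- hist$count
  k <- length(cnt)
  sm <- as.numeric(stats::filter(cnt, rep(1 / smooth_bins, smooth_bins),
                                 sides = 2))
  sm[is.na(sm)] <- 0
  i <- 2:(k - 1)
  cand <- i[sm[i] > sm[i - 1] & sm[i] > sm[i + 1]]
  if (!length(cand)) return(numeric(0))
  peak <- max(sm)
  accepted <- integer(0)
  for (p in cand[order(sm[cand], decreasing = TRUE)]) {
    if (sm[p] < min_prominence * peak) next
    separated <- vapply(accepted, function(q) {
      min(sm[min(p, q):max(p, q)]) <= sm[p] - min_prominence * peak
    }, logical(1))
    if (all(separated)) accepted <- c(accepted, p)
  }
  sort(hist$value[accepted])
}

COMPRESSION_METHODS <- c("raw", "zlib", "xz", "zlib_svb_zd", "xz_svb_zd",
                         "exzd", "exzd_zlib")

# Per-read compressed byte count for one method. Record-level compression,
# as in BLOW5: each read is compressed independently.
method_bytes <- function(samples, method, eliminate_bits) {
  s <- if (eliminate_bits > 0) degrade_read(samples, eliminate_bits)
       else samples
  int16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
  svb_zd <- function(x) svb_encode(zigzag_encode(delta_chain(x)))$payload
  switch(method,
    raw = 2 * length(s),
    zlib = length(memCompress(int16_raw(s), "gzip")),
    xz = length(memCompress(int16_raw(s), "xz")),
    zlib_svb_zd = length(memCompress(svb_zd(s), "gzip")),
    xz_svb_zd = length(memCompress(svb_zd(s), "xz")),
    exzd = exzd_encoded_size(s, eliminate_bits),
    exzd_zlib = length(memCompress(exzd_encode(s, eliminate_bits), "gzip")),
    stop("unknown method label: ", method, call. = FALSE))
}

#' Compression-ratio benchmark over methods and bit depths
#'
#' For every method and every lossy bit count, compresses each read
#' independently and totals the bytes. Methods: `raw` (verbatim 16-bit),
#' `zlib` / `xz` (general-purpose codec on the 16-bit stream),
#' `zlib_svb_zd` / `xz_svb_zd` (zig-zag delta + streamvbyte, then the
#' general-purpose codec — the pairing used as the lossless baseline in the
#' SLOW5 ecosystem), `exzd` (plain record codec) and `exzd_zlib`
#' (record codec + zlib wrap).
#'
#' @param reads Signal-read tibble.
#' @param methods Character vector from the set above.
#' @param eliminate_bits_list Integer vector of lossy bit counts (0 =
#'   lossless) applied before each method.
#' @return A tibble with one row per method x bits: `method`,
#'   `eliminate_bits`, `uncompressed_bytes` (2 per sample),
#'   `compressed_bytes`, `ratio` (uncompressed / compressed) and
#'   `pct_of_baseline` (size relative to lossless `zlib_svb_zd` when that
#'   method is included, else relative to `raw`). Classed `exzd_report`.
#' @examples
#' reads <- simulate_dataset(synth_model(seed = 1), 3, 800)
#' compression_report(reads, c("raw", "exzd"), 0)
#' @export
compression_report <- function(reads,
                               methods = COMPRESSION_METHODS,
                               eliminate_bits_list = 0L) {
  check_reads(reads)
  bad <- setdiff(methods, COMPRESSION_METHODS)
  if (length(bad)) {
    stop("unknown method label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  uncompressed <- 2 * sum(lengths(reads$samples))
  grid <- expand.grid(method = methods,
                                      eliminate_bits = eliminate_bits_list,
                                      stringsAsFactors = FALSE)
  bytes <- purrr::map2_dbl(grid$method, grid$eliminate_bits, function(m, b) {
    sum(purrr::map_dbl(reads$samples, method_bytes, method = m,
                       eliminate_bits = b))
  })
  report <- tibble::tibble(method = grid$method,
                           eliminate_bits = as.integer(grid$eliminate_bits),
                           uncompressed_bytes = uncompressed,
                           compressed_bytes = bytes,
                           ratio = uncompressed / bytes)
  base_row <- which(report$method == "zlib_svb_zd" &
                      report$eliminate_bits == 0L)
  if (!length(base_row)) {
    base_row <- which(report$method == "raw" & report$eliminate_bits == 0L)
  }
  report$pct_of_baseline <- if (length(base_row)) {
    100 * report$compressed_bytes / report$compressed_bytes[base_row[1]]
  } else {
    NA_real_
  }
  class(report) <- c("exzd_report", class(report))
  report
}

#' Per-bit savings of an encoding method
#'
#' Fractional shrinkage of the compressed size for each additional
#' eliminated bit, from a [compression_report()].
#'
#' @param report An `exzd_report` containing consecutive `eliminate_bits`
#'   values for `method`.
#' @param method Method label to extract.
#' @return Tibble with `eliminate_bits` (n) and `savings_pct`, the
#'   percentage reduction relative to the `n - 1` encoding.
#' @export
per_bit_savings <- function(report, method = "exzd_zlib") {
  rows <- report[report$method == method, ]
  rows <- rows[order(rows$eliminate_bits), ]
  if (nrow(rows) < 2) {
    stop("per_bit_savings: need at least two bit depths for ", method,
         call. = FALSE)
  }
  if (any(diff(rows$eliminate_bits) != 1)) {
    stop("per_bit_savings: eliminate_bits must be consecutive", call. = FALSE)
  }
  tibble::tibble(
    eliminate_bits = rows$eliminate_bits[-1],
    savings_pct = 100 * (1 - rows$compressed_bytes[-1] /
                           rows$compressed_bytes[-nrow(rows)]))
}
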