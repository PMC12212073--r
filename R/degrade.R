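# User-facing lossy operator: n-bit rounding of every sample, feeding the
# lossless record codec. Mirrors the "degrade" workflow of the SLOW5
# toolchain: raw samples change, calibration metadata never does.

#' Codec parameters for lossy bit reduction
#'
#' @param eliminate_bits Number of least significant bits to zero, 0..8.
#'   Values up to 3 are the validated envelope for PromethION DNA/RNA data;
#'   a warning is issued above that.
#' @param instrument_native_bits Native ADC bit depth, informational only
#'   (11 for PromethION, 13 for MinION).
#' @return A `codec_params` list.
#' @examples
#' codec_params(3)
#' @export
codec_params <- function(eliminate_bits = 0L, instrument_native_bits = 11L) {
  if (length(eliminate_bits) != 1 || is.na(eliminate_bits) ||
      eliminate_bits != as.integer(eliminate_bits) ||
      eliminate_bits < 0 || eliminate_bits > 8) {
    stop("codec_params: eliminate_bits must be a single integer in 0..8",
         call. = FALSE)
  }
  if (eliminate_bits > 3) {
    warning("eliminate_bits = ", eliminate_bits,
            " exceeds the validated envelope (<= 3 bits); ",
            "downstream analyses may degrade", call. = FALSE)
  }
  structure(list(eliminate_bits = as.integer(eliminate_bits),
                 instrument_native_bits = as.integer(instrument_native_bits)),
            class = "codec_params")
}

#' Lossy n-bit reduction of one read
#'
#' Applies [round_low_bits()] element-wise. Idempotent; per-sample error at
#' most `2^(n-1)`; length preserved.
#'
#' @param samples Integer-valued vector of signed 16-bit samples.
#' @param params A [codec_params()] object (or a bare bit count 0..8).
#' @return Double vector of rounded samples.
#' @export
degrade_read <- function(samples, params) {
  n <- degrade_bits(params)
  round_low_bits(samples, n)
}

#' Degrade then losslessly encode one read
#'
#' `exzd_encode(degrade_read(samples, params), n)`: the decoded output
#' differs from the input by at most `2^(n-1)` per sample and the stored
#' shift is at least `n`.
#'
#' @inheritParams degrade_read
#' @return Raw vector, the ex-zd blob of the bit-reduced read.
#' @export
degrade_and_encode <- function(samples, params) {
  n <- degrade_bits(params)
  exzd_encode(degrade_read(samples, n), n)
}

#' Degrade every read of a read table
#'
#' Rounds the `samples` column of a signal-read tibble; all metadata
#' columns (calibration, identifiers) are untouched.
#'
#' @param reads A signal-read tibble (see [simulate_dataset()] or
#'   [read_slow5_ascii()]).
#' @inheritParams degrade_read
#' @return The same tibble with degraded `samples`.
#' @export
degrade_reads <- function(reads, params) {
  check_reads(reads)
  n <- degrade_bits(params)
  reads$samples <- purrr::map(reads$samples, round_low_bits, n = n)
  reads
}

degrade_bits <- function(params) {
  if (inherits(params, "codec_params")) return(params$eliminate_bits)
  if (length(params) != 1 || is.na(params) || params != as.integer(params) ||
      params < 0 || params > 8) {
    stop("eliminate_bits must be a single integer in 0..8", call. = FALSE)
  }
  as.integer(params)
}
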