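# Synthetic ONT-like raw signal. The generator emulates the statistics that
# matter for codec experiments: piecewise-constant pore levels drawn from a
# bimodal mixture, geometric dwell, additive Gaussian noise quantized to the
# ADC grid, and an optional injected frequency-spike artifact at values
# whose two least significant bits transition 11 -> 00.

#' Synthetic signal model
#'
#' Defaults describe a PromethION-like 11-bit ADC: two Gaussian level
#' components centred at 35% and 65% of the ADC range with standard
#' deviation 6% of the range and equal weight, geometric segment dwell with
#' mean 10 samples, and Gaussian noise with standard deviation 1.5% of the
#' range. `spike_rate` is the per-sample probability that a sample whose two
#' low bits are `11` is displaced up by one (onto the `00` of the next
#' multiple of 4), the phenomenological stand-in for the ADC spike artifact.
#'
#' @param adc_bits ADC bit depth: 11 (PromethION) or 13 (MinION).
#' @param level_means,level_sds,level_weights Two-component Gaussian mixture
#'   of pore levels, on the ADC scale.
#' @param dwell_mean Mean segment length in samples (geometric).
#' @param noise_sd Within-segment Gaussian noise, ADC counts.
#' @param spike_rate Probability in `[0, 1]` of spike displacement.
#' @param seed Integer seed making simulation reproducible.
#' @return A `synth_model` list.
#' @examples
#' m <- synth_model(spike_rate = 0.3, seed = 7)
#' @export
synth_model <- function(adc_bits = 11L,
                        level_means = NULL,
                        level_sds = NULL,
                        level_weights = c(0.5, 0.5),
                        dwell_mean = 10,
                        noise_sd = NULL,
                        spike_rate = 0,
                        seed = 1L) {
  top <- 2^adc_bits - 1
  if (is.null(level_means)) level_means <- c(0.35, 0.65) * top
  if (is.null(level_sds)) level_sds <- rep(0.06 * top, 2)
  if (is.null(noise_sd)) noise_sd <- 0.015 * top
  model <- structure(list(adc_bits = as.integer(adc_bits),
                          level_means = as.numeric(level_means),
                          level_sds = as.numeric(level_sds),
                          level_weights = as.numeric(level_weights),
                          dwell_mean = as.numeric(dwell_mean),
                          noise_sd = as.numeric(noise_sd),
                          spike_rate = as.numeric(spike_rate),
                          seed = as.integer(seed)),
                     class = "synth_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  with(model, {
    if (!adc_bits %in% 2:15) stop("adc_bits must be in 2..15", call. = FALSE)
    if (length(level_means) != 2 || length(level_sds) != 2 ||
        length(level_weights) != 2) {
      stop("level mixture needs exactly two components", call. = FALSE)
    }
    top <- 2^adc_bits - 1
    if (any(level_means < 0 | level_means > top)) {
      stop("level_means outside [0, ", top, "]", call. = FALSE)
    }
    if (any(level_sds <= 0) || noise_sd <= 0 || dwell_mean < 1) {
      stop("level_sds and noise_sd must be positive, dwell_mean >= 1",
           call. = FALSE)
    }
    if (spike_rate < 0 || spike_rate > 1) {
      stop("spike_rate must be in [0, 1]", call. = FALSE)
    }
  })
  invisible(model)
}

# Draw raw samples with the current RNG state (callers handle seeding).
draw_samples <- function(model, num_samples) {
  top <- 2^model$adc_bits - 1
  n_seg <- max(4L, ceiling(2.5 * num_samples / model$dwell_mean))
  repeat {
    lens <- stats::rgeom(n_seg, 1 / model$dwell_mean) + 1L
    if (sum(lens) >= num_samples) break
    n_seg <- n_seg * 2L
  }
  comp <- 1L + stats::rbinom(n_seg, 1L, model$level_weights[2])
  levels <- stats::rnorm(n_seg, model$level_means[comp],
                         model$level_sds[comp])
  s <- rep(levels, lens)[seq_len(num_samples)] +
    stats::rnorm(num_samples, 0, model$noise_sd)
  s <- pmin(pmax(round(s), 0), top)
  if (model$spike_rate > 0) {
    hit <- s %% 4 == 3 & s < top & stats::runif(num_samples) < model$spike_rate
    s[hit] <- s[hit] + 1
  }
  s
}

#' Simulate one read
#'
#' @param model A [synth_model()].
#' @param num_samples Read length, at least 1.
#' @param seed Seed for this read; `NULL` continues the caller's RNG
#'   stream (used by [simulate_dataset()]). Defaults to `model$seed`.
#' @return A one-row signal-read tibble with PromethION-typical calibration
#'   (digitisation `2^adc_bits`, 5 kHz sampling).
#' @export
simulate_read <- function(model, num_samples, seed = model$seed) {
  validate_model(model)
  if (num_samples < 1) stop("num_samples must be >= 1", call. = FALSE)
  s <- with_seed(seed, draw_samples(model, num_samples))
  signal_reads(read_id = "synth-read-1", samples = list(s),
               digitisation = 2^model$adc_bits, offset = 4,
               range = 1126.47, sampling_rate = 5000)
}

#' Simulate a dataset of independent reads
#'
#' All randomness flows from `model$seed`; the same model yields
#' bit-identical datasets.
#'
#' @param model A [synth_model()].
#' @param num_reads Number of reads, at least 1.
#' @param read_length A fixed length, a vector of per-read lengths, or a
#'   function of the number of reads returning lengths.
#' @return A signal-read tibble with `num_reads` rows.
#' @examples
#' reads <- simulate_dataset(synth_model(seed = 1), 5, 1000)
#' @export
simulate_dataset <- function(model, num_reads, read_length = 5000) {
  validate_model(model)
  if (num_reads < 1) stop("num_reads must be >= 1", call. = FALSE)
  lens <- if (is.function(read_length)) read_length(num_reads)
          else rep_len(as.numeric(read_length), num_reads)
  if (any(lens < 1)) stop("read lengths must be >= 1", call. = FALSE)
  samples <- with_seed(model$seed,
                       lapply(lens, function(L) draw_samples(model, L)))
  signal_reads(read_id = sprintf("synth-read-%d", seq_len(num_reads)),
               samples = samples,
               digitisation = 2^model$adc_bits, offset = 4,
               range = 1126.47, sampling_rate = 5000)
}

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
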