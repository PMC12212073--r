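# Integer transforms the ex-zd record codec is built from. All samples are
# signed 16-bit ADC counts; bit operations act on the two's-complement
# pattern. Values are carried as R doubles where they may exceed .Machine
# integer range after zig-zag mapping (exact up to 2^53).

#' Zig-zag encode signed integers
#'
#' Maps signed integers onto non-negative integers so that values of small
#' magnitude get small codes: a non-negative `v` becomes `2 v`, a negative
#' `v` becomes `2 |v| - 1`. Consecutive-sample deltas in nanopore signal are
#' small and sign-alternating, so this mapping concentrates them near zero
#' where a one-byte representation suffices.
#'
#' @param v Integer-valued vector, each element with magnitude at most
#'   `2^31 - 1`.
#' @return A double vector of non-negative zig-zag codes.
#' @examples
#' zigzag_encode(c(0, 3, -3, 1, -1))
#' @seealso [zigzag_decode()]
#' @export
zigzag_encode <- function(v) {
  v <- check_integerish(v, "v")
  if (any(abs(v) > 2^31 - 1)) {
    stop("zigzag_encode: |v| exceeds 2^31 - 1 for ",
         sum(abs(v) > 2^31 - 1), " element(s)", call. = FALSE)
  }
  ifelse(v >= 0, 2 * v, -2 * v - 1)
}

#' Invert the zig-zag mapping
#'
#' @param z Non-negative integer-valued vector of zig-zag codes.
#' @return A double vector of signed integers with
#'   `zigzag_decode(zigzag_encode(v)) == v`.
#' @examples
#' zigzag_decode(c(0, 6, 5, 2, 1))
#' @export
zigzag_decode <- function(z) {
  z <- check_integerish(z, "z")
  if (any(z < 0)) stop("zigzag_decode: negative code", call. = FALSE)
  ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)
}

#' Delta chain of a sample vector
#'
#' Returns the first sample followed by consecutive differences, the
#' transform that precedes zig-zag encoding in the ex-zd pipeline. Inverted
#' exactly by [inverse_delta()] (a prefix sum).
#'
#' @param samples Integer-valued vector, length at least 1.
#' @return Double vector of the same length: `c(s[1], diff(s))`.
#' @examples
#' delta_chain(c(100, 101, 99, 300))
#' @export
delta_chain <- function(samples) {
  samples <- check_integerish(samples, "samples")
  if (length(samples) < 1) stop("delta_chain: empty input", call. = FALSE)
  c(samples[1], diff(samples))
}

#' @rdname delta_chain
#' @param deltas Output of [delta_chain()].
#' @export
inverse_delta <- function(deltas) {
  if (length(deltas) < 1) stop("inverse_delta: empty input", call. = FALSE)
  cumsum(deltas)
}

#' Common trailing zero bits of a sample vector
#'
#' The minimum, over all samples, of the number of trailing zero bits in the
#' two's-complement 16-bit pattern. This is the right-shift the ex-zd
#' encoder applies before delta transformation; after lossy n-bit rounding
#' it is guaranteed to be at least n. The trailing-zero count of the value 0
#' is taken as 16 and the result is capped at 15 so that the shift is always
#' meaningful for 16-bit data and fits one byte.
#'
#' @param samples Integer-valued vector of signed 16-bit samples.
#' @return A single integer in 0..15.
#' @examples
#' common_trailing_zeros(c(8, 16, 24))  # 3
#' common_trailing_zeros(c(100, 101))   # 0
#' @export
common_trailing_zeros <- function(samples) {
  samples <- check_int16(samples, "samples")
  u <- as.integer(samples %% 65536)  # two's-complement 16-bit pattern
  tz <- rep(16L, length(u))
  nz <- u != 0L
  if (any(nz)) {
    # lowest set bit isolated as a power of two
    lsb <- bitwAnd(u[nz], -u[nz])
    tz[nz] <- as.integer(round(log2(lsb)))
  }
  min(15L, min(tz))
}

#' Lossy bit-wise rounding of the n low bits
#'
#' Zeroes the `n` least significant bits of each sample by rounding to the
#' nearest multiple of `2^n`, ties away from zero toward +Inf:
#' `(x AND NOT(2^n - 1)) + 2^n * bit_(n-1)(x)`. Operating on the
#' two's-complement pattern, negative samples also land on their nearest
#' multiple of `2^n`. If rounding up would exceed the 16-bit maximum the
#' result is clamped to the largest multiple of `2^n` not exceeding 32767
#' (real ADC data, at most 13 bits, never reaches this boundary).
#'
#' The absolute rounding error is at most `2^(n-1)` away from the
#' saturation boundary, and the operation is idempotent.
#'
#' @param x Integer-valued vector of signed 16-bit samples.
#' @param n Number of low bits to zero, 0..8. `n = 0` is the identity.
#' @return Double vector of rounded samples, each a multiple of `2^n`.
#' @examples
#' round_low_bits(c(11, 12, 8), 3)  # 8 16 8
#' @export
round_low_bits <- function(x, n) {
  x <- check_int16(x, "x")
  if (length(n) != 1 || is.na(n) || n != as.integer(n) || n < 0 || n > 8) {
    stop("round_low_bits: n must be a single integer in 0..8", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) return(as.numeric(x))
  xi <- as.integer(x)
  low <- bitwAnd(xi, as.integer(2^n - 1))
  up <- bitwAnd(xi, as.integer(2^(n - 1))) != 0L  # bit n-1: round-up flag
  res <- as.numeric(xi - low) + 2^n * as.numeric(up)
  res[res > 32767] <- 32768 - 2^n
  res
}

# ---- internal validation helpers ----

check_integerish <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (any(is.na(x))) stop(what, " contains NA", call. = FALSE)
  if (any(x != trunc(x))) stop(what, " must be integer-valued", call. = FALSE)
  as.numeric(x)
}

check_int16 <- function(x, what) {
  x <- check_integerish(x, what)
  if (any(x < -32768 | x > 32767)) {
    stop(what, " outside the signed 16-bit range [-32768, 32767]",
         call. = FALSE)
  }
  x
}
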