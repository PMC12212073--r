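# The ex-zd record codec: one read's samples to/from a self-delimiting byte
# blob. Layout (all multi-byte fields little-endian):
#
#   version      1 byte   (0 for this dialect)
#   num_samples  8 bytes
#   shift_bits   1 byte   actual right-shift applied (>= bits eliminated)
#   first_zz     2 bytes  zig-zag of the first (shifted) sample
#   n_x          4 bytes  number of exceptions
#   [exceptions] n_x == 1: position (4B) + value (4B)
#                n_x  > 1: svb(position deltas) with 4B size prefix,
#                          then svb(values) with 4B size prefix
#   one-byte data: (num_samples - 1 - n_x) bytes, the zig-zag deltas <= 255
#
# Exceptions are zig-zag deltas > 255, stored minus 256; their positions are
# 0-based indices into the delta sequence; for n_x > 1 the first position is
# kept and the rest are delta-encoded minus 1 before svb encoding.

EXZD_VERSION <- 0L

# ---- little-endian field helpers ----

le_bytes <- function(x, nbytes) {
  as.raw(x %/% 256^(seq_len(nbytes) - 1) %% 256)
}

le_value <- function(bytes) {
  sum(as.numeric(as.integer(bytes)) * 256^(seq_along(bytes) - 1))
}

#' Encode one read with the ex-zd record codec
#'
#' Losslessly encodes a vector of signed 16-bit ADC samples. The pipeline:
#' right-shift all samples by their common trailing-zero count; zig-zag
#' encode the first sample and the consecutive deltas; split deltas into
#' one-byte values (<= 255), stored verbatim, and exceptions (> 255), stored
#' out-of-band minus 256 together with their positions (streamvbyte-encoded
#' when there is more than one).
#'
#' For lossy use apply [degrade_read()] (or [degrade_and_encode()]) first;
#' rounding away `n` low bits guarantees the common shift is at least `n`.
#'
#' @param samples Integer-valued vector of signed 16-bit samples, length
#'   at least 1.
#' @param eliminate_bits Number of bits removed beforehand by lossy
#'   rounding (0 for lossless). Recorded only through the shift, which is
#'   validated to be at least this value.
#' @return A raw vector: the ex-zd blob.
#' @examples
#' blob <- exzd_encode(c(100, 101, 99, 300))
#' length(blob)  # 26
#' exzd_decode(blob)
#' @export
exzd_encode <- function(samples, eliminate_bits = 0L) {
  samples <- check_int16(samples, "samples")
  n <- length(samples)
  if (n < 1) stop("exzd_encode: empty read", call. = FALSE)
  if (length(eliminate_bits) != 1 || eliminate_bits < 0 || eliminate_bits > 8) {
    stop("exzd_encode: eliminate_bits must be in 0..8", call. = FALSE)
  }
  shift <- common_trailing_zeros(samples)
  if (shift < eliminate_bits) {
    stop("exzd_encode: common trailing zeros (", shift,
         ") below eliminate_bits (", eliminate_bits,
         "); apply round_low_bits first", call. = FALSE)
  }
  parts <- exzd_partition(samples, shift)
  if (parts$first_zz > 65535) {
    stop("exzd_encode: zig-zag first sample ", parts$first_zz,
         " does not fit two bytes", call. = FALSE)
  }
  nx <- length(parts$exc_pos)
  header <- c(as.raw(EXZD_VERSION), le_bytes(n, 8), as.raw(shift),
              le_bytes(parts$first_zz, 2), le_bytes(nx, 4))
  exc <- if (nx == 0) {
    raw(0)
  } else if (nx == 1) {
    c(le_bytes(parts$exc_pos, 4), le_bytes(parts$exc_val, 4))
  } else {
    pt <- c(parts$exc_pos[1], diff(parts$exc_pos) - 1)
    sp <- svb_encode(pt)$payload
    sv <- svb_encode(parts$exc_val)$payload
    c(le_bytes(length(sp), 4), sp, le_bytes(length(sv), 4), sv)
  }
  c(header, exc, as.raw(parts$one_byte))
}

# Shared shift/delta/zigzag/partition step for encode and size audit.
exzd_partition <- function(samples, shift) {
  shifted <- samples / 2^shift
  zz <- zigzag_encode(delta_chain(shifted))
  dz <- zz[-1]
  is_exc <- dz > 255
  list(first_zz = zz[1],
       exc_pos = which(is_exc) - 1,   # 0-based, strictly increasing
       exc_val = dz[is_exc] - 256,
       one_byte = dz[!is_exc])
}

#' Decode an ex-zd blob back to samples
#'
#' Exact inverse of [exzd_encode()]: the zig-zag delta sequence is
#' reconstructed by merging the one-byte data with the exceptions (+256) at
#' their positions, zig-zag decoded, prefix-summed and left-shifted by the
#' stored shift.
#'
#' @param blob Raw vector holding exactly one ex-zd record.
#' @return Double vector of the original signed 16-bit samples.
#' @export
exzd_decode <- function(blob) {
  res <- exzd_parse(blob, 0L)
  if (res$consumed != length(blob)) {
    stop("exzd_decode: ", length(blob) - res$consumed,
         " trailing byte(s) after record", call. = FALSE)
  }
  res$samples
}

# Parse one record starting at 0-based `offset` within `raw_vec`; the blob
# is self-delimiting so only the start offset is needed. Returns samples and
# bytes consumed.
exzd_parse <- function(raw_vec, offset = 0L) {
  if (!is.raw(raw_vec)) stop("exzd_decode: input must be raw", call. = FALSE)
  pos <- offset
  need <- function(k, what) {
    if (k == 0) return(raw(0))
    if (pos + k > length(raw_vec)) {
      stop("exzd_decode: blob truncated in ", what, " (need ", k,
           " byte(s) at offset ", pos, ")", call. = FALSE)
    }
    b <- raw_vec[(pos + 1):(pos + k)]
    pos <<- pos + k
    b
  }
  version <- as.integer(need(1, "version"))
  if (version != EXZD_VERSION) {
    stop("exzd_decode: unsupported version ", version, call. = FALSE)
  }
  n <- le_value(need(8, "num_samples"))
  if (n < 1) stop("exzd_decode: num_samples must be >= 1", call. = FALSE)
  shift <- as.integer(need(1, "shift_bits"))
  first_zz <- le_value(need(2, "first_sample_zz"))
  nx <- le_value(need(4, "num_exceptions"))
  if (nx > n - 1) {
    stop("exzd_decode: ", nx, " exceptions exceed ", n - 1, " deltas",
         call. = FALSE)
  }
  if (nx == 0) {
    exc_pos <- numeric(0); exc_val <- numeric(0)
  } else if (nx == 1) {
    exc_pos <- le_value(need(4, "exception position"))
    exc_val <- le_value(need(4, "exception value"))
  } else {
    sp_len <- le_value(need(4, "position block size"))
    pt <- svb_decode(need(sp_len, "position block"), nx)
    sv_len <- le_value(need(4, "value block size"))
    exc_val <- svb_decode(need(sv_len, "value block"), nx)
    exc_pos <- cumsum(c(pt[1], pt[-1] + 1))
  }
  if (nx > 0) {
    if (any(exc_pos > n - 2)) {
      stop("exzd_decode: exception position ", max(exc_pos),
           " outside delta sequence of length ", n - 1, call. = FALSE)
    }
    if (anyDuplicated(exc_pos) || is.unsorted(exc_pos, strictly = TRUE)) {
      stop("exzd_decode: duplicate or unsorted exception positions",
           call. = FALSE)
    }
  }
  one_byte <- as.numeric(as.integer(need(n - 1 - nx, "one-byte data")))
  dz <- numeric(n - 1)
  if (nx > 0) {
    dz[exc_pos + 1] <- exc_val + 256
    dz[setdiff(seq_len(n - 1), exc_pos + 1)] <- one_byte
  } else {
    dz <- one_byte
  }
  samples <- inverse_delta(zigzag_decode(c(first_zz, dz))) * 2^shift
  list(samples = samples, consumed = pos - offset)
}

#' Closed-form size of an ex-zd record
#'
#' Computes `length(exzd_encode(samples, eliminate_bits))` without
#' assembling the blob: 16 header bytes, the exception block, and one byte
#' per non-exception delta.
#'
#' @inheritParams exzd_encode
#' @return Byte count as a single double.
#' @export
exzd_encoded_size <- function(samples, eliminate_bits = 0L) {
  samples <- check_int16(samples, "samples")
  if (length(samples) < 1) stop("exzd_encoded_size: empty read", call. = FALSE)
  shift <- common_trailing_zeros(samples)
  if (shift < eliminate_bits) {
    stop("exzd_encoded_size: common trailing zeros below eliminate_bits",
         call. = FALSE)
  }
  parts <- exzd_partition(samples, shift)
  nx <- length(parts$exc_pos)
  exc_size <- if (nx == 0) {
    0
  } else if (nx == 1) {
    8
  } else {
    pt <- c(parts$exc_pos[1], diff(parts$exc_pos) - 1)
    8 + svb_size(pt) + svb_size(parts$exc_val)
  }
  16 + exc_size + (length(samples) - 1 - nx)
}

# Encoded svb payload size without assembling it.
svb_size <- function(values) {
  k <- length(values)
  if (k == 0) return(0)
  (k + 3) %/% 4 + sum(1 + (values > 255) + (values > 65535) +
                        (values > 16777215))
}
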