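# Stream variable-byte codec for unsigned 32-bit integers: the exception
# positions and exception values of an ex-zd record are stored in this form.
# Scalar layout: ceil(k/4) control bytes first (2-bit length codes, first
# integer of each group in the least significant bit pair), then the
# little-endian data bytes, each value using its minimal 1..4 bytes.

#' Stream variable-byte encode
#'
#' Encodes a vector of unsigned 32-bit integers as control bytes followed by
#' data bytes. Each value occupies its minimal number of bytes (1 to 4,
#' value 0 uses 1 byte); the 2-bit code `bytes - 1` for integer `i` sits in
#' bits `2*(i mod 4)` of control byte `floor(i/4)`; data bytes are
#' little-endian.
#'
#' @param values Integer-valued vector, each in `[0, 2^32 - 1]`.
#' @return A list with `payload` (raw vector) and `count` (number of
#'   integers); decodable with [svb_decode()] given `count`.
#' @examples
#' svb_encode(c(0, 256, 70000))
#' @export
svb_encode <- function(values) {
  values <- check_integerish(values, "values")
  if (any(values < 0 | values > 2^32 - 1)) {
    stop("svb_encode: value outside [0, 2^32 - 1]", call. = FALSE)
  }
  k <- length(values)
  if (k == 0) return(list(payload = raw(0), count = 0L))
  lens <- 1L + (values > 255) + (values > 65535) + (values > 16777215)
  codes <- lens - 1L
  pad <- c(codes, rep(0L, (-k) %% 4))
  ctrl <- as.integer(colSums(matrix(pad, nrow = 4) * c(1L, 4L, 16L, 64L)))
  bytes <- rbind(values %% 256,
                 (values %/% 256) %% 256,
                 (values %/% 65536) %% 256,
                 (values %/% 16777216) %% 256)
  data <- bytes[cbind(sequence(lens), rep(seq_len(k), lens))]
  list(payload = as.raw(c(ctrl, data)), count = k)
}

#' Stream variable-byte decode
#'
#' Inverse of [svb_encode()]. The number of encoded integers is not
#' self-describing and must be supplied.
#'
#' @param payload Raw vector exactly as produced by [svb_encode()], or the
#'   `payload` element of its return value (a list is accepted).
#' @param count Number of integers encoded in `payload`.
#' @return Double vector of `count` unsigned 32-bit integers.
#' @export
svb_decode <- function(payload, count) {
  if (is.list(payload)) {
    if (missing(count)) count <- payload$count
    payload <- payload$payload
  }
  if (!is.raw(payload)) stop("svb_decode: payload must be raw", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 0) stop("svb_decode: bad count", call. = FALSE)
  if (count == 0) {
    if (length(payload) != 0) {
      stop("svb_decode: ", length(payload),
           " trailing byte(s) after 0 integers", call. = FALSE)
    }
    return(numeric(0))
  }
  nctrl <- (count + 3L) %/% 4L
  if (length(payload) < nctrl) {
    stop("svb_decode: payload truncated in control bytes (need ", nctrl,
         ", have ", length(payload), ")", call. = FALSE)
  }
  ctrl <- as.integer(payload[seq_len(nctrl)])
  codes <- (rep(ctrl, each = 4) %/% c(1L, 4L, 16L, 64L)) %% 4L
  lens <- codes[seq_len(count)] + 1L
  total <- sum(lens)
  if (length(payload) != nctrl + total) {
    stop("svb_decode: payload has ", length(payload), " bytes, expected ",
         nctrl + total, " (", nctrl + total - length(payload),
         " byte shortfall)", call. = FALSE)
  }
  db <- as.numeric(as.integer(payload[nctrl + seq_len(total)]))
  idx <- rep(seq_len(count), lens)
  pow <- 256^(sequence(lens) - 1)
  as.vector(rowsum(db * pow, idx))
}
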