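# Independent brute-force oracles, written against the stated rules only
# and kept free of the package's code paths.

# Nearest multiple of 2^n, ties toward +Inf.
oracle_round_nearest <- function(x, n) {
  m <- 2^n
  floor(x / m + 0.5) * m
}

# Naive per-integer stream variable-byte encoder: scalar loop, minimal
# little-endian byte length per value, 2-bit codes packed low-first.
oracle_svb_encode <- function(values) {
  k <- length(values)
  if (k == 0) return(raw(0))
  ctrl <- integer((k + 3) %/% 4)
  data <- list()
  for (i in seq_len(k)) {
    v <- values[i]
    b <- integer(0)
    repeat {
      b <- c(b, v %% 256)
      v <- v %/% 256
      if (v == 0) break
    }
    ctrl[(i - 1) %/% 4 + 1] <- ctrl[(i - 1) %/% 4 + 1] +
      (length(b) - 1) * 4^((i - 1) %% 4)
    data[[i]] <- b
  }
  as.raw(c(ctrl, unlist(data)))
}

# Independent scalar assembler of the ex-zd record layout, for cross-checks
# of the encoder's byte output on small reads (lossless path, shift
# computed by repeated division).
oracle_exzd_blob <- function(samples) {
  zz1 <- function(v) if (v >= 0) 2 * v else 2 * abs(v) - 1
  le <- function(x, nb) {
    out <- integer(nb)
    for (j in seq_len(nb)) {
      out[j] <- x %% 256
      x <- x %/% 256
    }
    out
  }
  shift <- 0
  while (shift < 15 && all(samples %% (2^(shift + 1)) == 0)) shift <- shift + 1
  s <- samples / 2^shift
  deltas <- c(s[1], diff(s))
  zz <- vapply(deltas, zz1, numeric(1))
  dz <- zz[-1]
  exc_at <- which(dz > 255)
  bytes <- c(0, le(length(samples), 8), shift, le(zz[1], 2),
             le(length(exc_at), 4))
  if (length(exc_at) == 1) {
    bytes <- c(bytes, le(exc_at - 1, 4), le(dz[exc_at] - 256, 4))
  } else if (length(exc_at) > 1) {
    pos0 <- exc_at - 1
    pt <- c(pos0[1], diff(pos0) - 1)
    sp <- oracle_svb_encode(pt)
    sv <- oracle_svb_encode(dz[exc_at] - 256)
    bytes <- c(bytes, le(length(sp), 4), as.integer(sp),
               le(length(sv), 4), as.integer(sv))
  }
  as.raw(c(bytes, dz[dz <= 255]))
}

random_int16_read <- function(n) {
  sample(-32768:32767, n, replace = TRUE)
}
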