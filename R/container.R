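# Minimal binary record container for ex-zd blobs, so file-size experiments
# are well defined. This is deliberately not BLOW5 (no read groups, no
# index): magic "EZD0", a codec identifier, then self-delimiting records.
#
#   magic          4 bytes  "EZD0"
#   codec_id       1 byte   0 = plain ex-zd blobs, 1 = zlib-wrapped blobs
#   eliminate_bits 1 byte   lossy n the records were produced with
#   num_reads      8 bytes  little-endian
#   per record: read_id length (2B) + read_id bytes,
#               digitisation/offset/range/sampling_rate (4 x 8B doubles),
#               blob length (8B), blob

CONTAINER_MAGIC <- charToRaw("EZD0")

#' Pack reads into an ex-zd container file
#'
#' Encodes every read with [degrade_and_encode()] (lossless when
#' `eliminate_bits` is 0) and writes the records with their calibration
#' metadata. With `zlib = TRUE` each blob is additionally deflate-wrapped,
#' mirroring the record-level pairing of ex-zd with a general-purpose codec.
#'
#' @param reads Signal-read tibble.
#' @param path Output path.
#' @param params A [codec_params()] object or bit count 0..8.
#' @param zlib Wrap each blob with zlib compression.
#' @return `path`, invisibly; the file size is `file.size(path)`.
#' @export
pack_container <- function(reads, path, params = codec_params(0L),
                           zlib = FALSE) {
  check_reads(reads)
  bits <- degrade_bits(params)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CONTAINER_MAGIC, con)
  writeBin(as.raw(c(if (zlib) 1L else 0L, bits)), con)
  writeBin(le_bytes(nrow(reads), 8), con)
  for (i in seq_len(nrow(reads))) {
    id <- charToRaw(reads$read_id[i])
    blob <- tryCatch(degrade_and_encode(reads$samples[[i]], bits),
                     error = function(e) {
                       stop("read ", reads$read_id[i], ": ",
                            conditionMessage(e), call. = FALSE)
                     })
    if (zlib) blob <- memCompress(blob, "gzip")
    writeBin(le_bytes(length(id), 2), con)
    writeBin(id, con)
    writeBin(c(reads$digitisation[i], reads$offset[i], reads$range[i],
               reads$sampling_rate[i]), con, size = 8, endian = "little")
    writeBin(le_bytes(length(blob), 8), con)
    writeBin(blob, con)
  }
  invisible(path)
}

#' Unpack an ex-zd container file
#'
#' @param path Path written by [pack_container()].
#' @return A list with `reads` (signal-read tibble) and `params`
#'   (the [codec_params()] the file was packed with).
#' @export
unpack_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw_vec <- readBin(path, "raw", n = file.size(path))
  pos <- 0L
  need <- function(k, what) {
    if (k == 0) return(raw(0))
    if (pos + k > length(raw_vec)) {
      stop("unpack_container: file truncated in ", what, call. = FALSE)
    }
    b <- raw_vec[(pos + 1):(pos + k)]
    pos <<- pos + k
    b
  }
  if (!identical(need(4, "magic"), CONTAINER_MAGIC)) {
    stop("unpack_container: bad magic, not an EZD0 container", call. = FALSE)
  }
  codec_id <- as.integer(need(1, "codec_id"))
  if (!codec_id %in% c(0L, 1L)) {
    stop("unpack_container: unknown codec_id ", codec_id, call. = FALSE)
  }
  bits <- as.integer(need(1, "eliminate_bits"))
  n_reads <- le_value(need(8, "num_reads"))
  read_id <- character(n_reads)
  calib <- matrix(0, n_reads, 4)
  samples <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    id_len <- le_value(need(2, "read_id length"))
    read_id[i] <- rawToChar(need(id_len, "read_id"))
    calib[i, ] <- readBin(need(32, "calibration"), "double", n = 4,
                          size = 8, endian = "little")
    blob_len <- le_value(need(8, "blob length"))
    blob <- need(blob_len, "blob")
    if (codec_id == 1L) blob <- memDecompress(blob, "gzip")
    samples[[i]] <- exzd_decode(blob)
  }
  reads <- signal_reads(read_id, samples,
                        digitisation = calib[, 1], offset = calib[, 2],
                        range = calib[, 3], sampling_rate = calib[, 4])
  list(reads = reads, params = suppressWarnings(codec_params(bits)))
}
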