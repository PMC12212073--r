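# SLOW5-ASCII input/output. The dialect is the minimum needed to exchange
# per-read raw signal with the SLOW5 ecosystem: tab-separated data rows,
# '#'-prefixed header lines of which the last names the columns, and a
# comma-separated raw_signal field. Unknown extra columns round-trip as
# opaque character columns.

SLOW5_REQUIRED <- c("read_id", "digitisation", "offset", "range",
                    "sampling_rate", "len_raw_signal", "raw_signal")

#' Construct a signal-read table
#'
#' The tabular unit the package works on: one row per read with calibration
#' metadata and the raw ADC samples as a list-column.
#'
#' @param read_id Character vector of read identifiers.
#' @param samples List of integer-valued sample vectors (length >= 1 each).
#' @param digitisation,offset,range,sampling_rate Per-read calibration:
#'   ADC levels across the current range, ADC offset, current range in
#'   picoamperes, and sampling rate in Hz.
#' @return A tibble with one row per read.
#' @export
signal_reads <- function(read_id, samples, digitisation = 2048,
                         offset = 0, range = 1126.47,
                         sampling_rate = 5000) {
  reads <- tibble::tibble(read_id = as.character(read_id),
                          digitisation = as.numeric(digitisation),
                          offset = as.numeric(offset),
                          range = as.numeric(range),
                          sampling_rate = as.numeric(sampling_rate),
                          samples = as.list(samples))
  check_reads(reads)
  reads
}

check_reads <- function(reads) {
  if (!is.data.frame(reads)) {
    stop("expected a signal-read data frame", call. = FALSE)
  }
  needed <- c("read_id", "digitisation", "offset", "range",
              "sampling_rate", "samples")
  missing <- setdiff(needed, names(reads))
  if (length(missing)) {
    stop("signal-read table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.list(reads$samples)) {
    stop("samples must be a list-column", call. = FALSE)
  }
  if (any(lengths(reads$samples) < 1)) {
    stop("every read needs at least one sample", call. = FALSE)
  }
  if (any(reads$digitisation <= 0) || any(reads$sampling_rate <= 0)) {
    stop("digitisation and sampling_rate must be positive", call. = FALSE)
  }
  invisible(reads)
}

#' Read a SLOW5-ASCII file
#'
#' @param path Path to a SLOW5 text file. Header lines start with `#`; the
#'   last of them names the columns, which must include
#'   `read_id`, `digitisation`, `offset`, `range`, `sampling_rate`,
#'   `len_raw_signal` and `raw_signal` (comma-separated integers).
#' @return A signal-read tibble (see [signal_reads()]); unknown columns are
#'   kept as character columns.
#' @export
read_slow5_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  first_data <- which(!is_header & nzchar(lines))
  header_idx <- which(is_header)
  if (!length(header_idx)) {
    stop(path, ": no '#' header line", call. = FALSE)
  }
  cols <- strsplit(sub("^#", "", lines[header_idx[length(header_idx)]]),
                   "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SLOW5_REQUIRED, cols)
  if (length(missing)) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(first_data)) {
    return(signal_reads(character(0), list()))
  }
  rows <- strsplit(lines[first_data], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(cols))
  if (length(bad)) {
    stop(path, ": line ", first_data[bad[1]], " has ",
         lengths(rows)[bad[1]], " fields, expected ", length(cols),
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop(path, ": non-numeric ", col, " at line ",
           first_data[which(is.na(v))[1]], call. = FALSE)
    }
    v
  }
  len_raw <- num("len_raw_signal")
  samples <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- suppressWarnings(as.numeric(strsplit(m[i, "raw_signal"], ",",
                                              fixed = TRUE)[[1]]))
    if (anyNA(s) || any(s != trunc(s))) {
      stop(path, ": non-integer raw_signal at line ", first_data[i],
           call. = FALSE)
    }
    if (length(s) != len_raw[i]) {
      stop(path, ": line ", first_data[i], " declares len_raw_signal = ",
           m[i, "len_raw_signal"], " but has ", length(s), " samples",
           call. = FALSE)
    }
    samples[[i]] <- s
  }
  reads <- tibble::tibble(read_id = m[, "read_id"],
                          digitisation = num("digitisation"),
                          offset = num("offset"),
                          range = num("range"),
                          sampling_rate = num("sampling_rate"),
                          samples = samples)
  for (extra in setdiff(cols, SLOW5_REQUIRED)) {
    reads[[extra]] <- unname(m[, extra])
  }
  check_reads(reads)
  reads
}

#' Write a SLOW5-ASCII file
#'
#' Inverse of [read_slow5_ascii()]: stable column order, C-locale number
#' formatting, so output bytes are deterministic for a given table.
#'
#' @param reads Signal-read tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slow5_ascii <- function(reads, path) {
  check_reads(reads)
  extras <- setdiff(names(reads),
                    c(SLOW5_REQUIRED, "samples"))
  cols <- c(SLOW5_REQUIRED, extras)
  num_str <- function(x) format(x, scientific = FALSE, trim = TRUE,
                                digits = 15)
  body <- vapply(seq_len(nrow(reads)), function(i) {
    fields <- c(reads$read_id[i],
                num_str(reads$digitisation[i]),
                num_str(reads$offset[i]),
                num_str(reads$range[i]),
                num_str(reads$sampling_rate[i]),
                as.character(length(reads$samples[[i]])),
                paste(format(reads$samples[[i]], scientific = FALSE,
                             trim = TRUE), collapse = ","),
                vapply(extras, function(e) as.character(reads[[e]][i]),
                       character(1)))
    paste(fields, collapse = "\t")
  }, character(1))
  lines <- c("#slow5_version\t0.2.0",
             "#num_read_groups\t1",
             paste0("#", paste(cols, collapse = "\t")),
             body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert raw ADC samples to picoamperes
#'
#' Applies the standard linear calibration
#' `pA = (raw + offset) * range / digitisation` to every read.
#'
#' @param reads Signal-read tibble.
#' @return The tibble with an added `pa` list-column of numeric currents.
#' @export
to_picoamperes <- function(reads) {
  check_reads(reads)
  reads$pa <- purrr::pmap(
    list(reads$samples, reads$offset, reads$range, reads$digitisation),
    function(s, off, rng, dig) (s + off) * rng / dig)
  reads
}
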