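test_that("the bundled SLOW5 fixture parses exactly", {
  path <- system.file("extdata", "example.slow5", package = "exzd")
  reads <- read_slow5_ascii(path)
  expect_identical(nrow(reads), 2L)
  expect_identical(reads$read_id, c("read-0001", "read-0002"))
  expect_equal(reads$samples[[1]], c(512, 514, 511, 520, 770, 768, 765, 771))
  expect_equal(reads$samples[[2]], c(100, 101, 99, 300, 298))
  expect_equal(reads$offset, c(4, 6.5))
  expect_equal(reads$digitisation, c(2048, 2048))
})

test_that("SLOW5 text round-trips losslessly and deterministically", {
  set.seed(10)
  reads <- signal_reads(
    read_id = sprintf("r%d", 1:5),
    samples = replicate(5, random_int16_read(sample.int(200, 1)),
                        simplify = FALSE),
    digitisation = 2048, offset = round(runif(5, -10, 10), 2),
    range = round(runif(5, 1000, 1500), 3), sampling_rate = 5000)
  p1 <- withr::local_tempfile(fileext = ".slow5")
  p2 <- withr::local_tempfile(fileext = ".slow5")
  write_slow5_ascii(reads, p1)
  back <- read_slow5_ascii(p1)
  expect_equal(back$samples, reads$samples)
  expect_equal(back$offset, reads$offset)
  expect_equal(back$range, reads$range)
  write_slow5_ascii(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  one <- signal_reads("solo", list(7))
  p3 <- withr::local_tempfile(fileext = ".slow5")
  write_slow5_ascii(one, p3)
  expect_equal(read_slow5_ascii(p3)$samples[[1]], 7)
})

test_that("unknown extra columns are preserved as opaque strings", {
  path <- withr::local_tempfile(fileext = ".slow5")
  writeLines(c("#slow5_version\t0.2.0",
               "#read_id\tdigitisation\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal\tmedian_before",
               "r1\t2048\t0\t1200\t4000\t3\t1,2,3\t218.67"), path)
  reads <- read_slow5_ascii(path)
  expect_identical(reads$median_before, "218.67")
  out <- withr::local_tempfile(fileext = ".slow5")
  write_slow5_ascii(reads, out)
  expect_identical(read_slow5_ascii(out)$median_before, "218.67")
})

test_that("malformed SLOW5 input raises errors naming the line", {
  path <- withr::local_tempfile(fileext = ".slow5")
  writeLines(c("#read_id\tdigitisation\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal",
               "r1\t2048\t0\t1200\t4000\t5\t1,2,3,4"), path)
  expect_error(read_slow5_ascii(path), "len_raw_signal")

  writeLines(c("#read_id\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal",
               "r1\t0\t1200\t4000\t1\t1"), path)
  expect_error(read_slow5_ascii(path), "digitisation")

  writeLines(c("#read_id\tdigitisation\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal",
               "r1\t2048\t0\t1200\t4000\t2\t1,x"), path)
  expect_error(read_slow5_ascii(path), "line 2")

  writeLines(c("#read_id\tdigitisation\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal"),
             path)
  expect_identical(nrow(read_slow5_ascii(path)), 0L)
})

test_that("picoampere conversion applies the linear calibration", {
  reads <- signal_reads("r", list(c(0, 100)), digitisation = 2048,
                        offset = 10, range = 1200)
  pa <- to_picoamperes(reads)$pa[[1]]
  expect_equal(pa[1], 10 * 1200 / 2048)
  expect_equal(pa[2], 110 * 1200 / 2048)  # 64.453125
  expect_equal(pa[2], 64.453125)

  # lossy rounding perturbs current by at most 2^(n-1) * range/digitisation
  r2 <- simulate_read(synth_model(seed = 11), 2000)
  for (n in c(2, 3)) {
    d <- degrade_reads(r2, suppressWarnings(codec_params(n)))
    delta <- abs(to_picoamperes(d)$pa[[1]] - to_picoamperes(r2)$pa[[1]])
    bound <- 2^(n - 1) * r2$range[1] / r2$digitisation[1]
    expect_lte(max(delta), bound * (1 + 1e-12))
  }
})
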