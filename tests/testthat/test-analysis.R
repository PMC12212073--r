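test_that("value histograms count exactly and clamp out-of-range input", {
  reads <- signal_reads("r", list(c(5, 5, 7)))
  h <- value_histogram(reads, adc_bits = 4)
  expect_identical(h$value, 0:15)
  expect_identical(h$count[h$value == 5], 2L)
  expect_identical(h$count[h$value == 7], 1L)
  expect_identical(sum(h$count), 3L)
  expect_warning(value_histogram(signal_reads("r", list(c(1, 99))),
                                 adc_bits = 4), "clamped")

  # degraded histograms live on multiples of 2^n at native scale
  d <- simulate_dataset(synth_model(seed = 51), 3, 1000)
  h3 <- value_histogram(degrade_reads(d, 3))
  expect_true(all(h3$value[h3$count > 0] %% 8 == 0))
})

test_that("spike score has the stated closed forms", {
  flat <- tibble::tibble(value = 0:9, count = rep(100L, 10))
  expect_equal(spike_score(flat), 0)
  one_double <- flat
  one_double$count[5] <- 200L
  # the doubled bin contributes log2(2) = 1; its neighbours sit below their
  # own neighbour mean and contribute 0
  expect_equal(spike_score(one_double), 1 / 8)
  expect_error(spike_score(tibble::tibble(value = 0:2,
                                          count = c(1L, 0L, 0L))),
               "degenerate")
})

test_that("compression report follows the ratio definition", {
  reads <- simulate_dataset(synth_model(seed = 52), 5, 2000)
  rep0 <- compression_report(reads, c("raw", "exzd", "zlib_svb_zd"), 0)
  expect_s3_class(rep0, "exzd_report")
  expect_equal(rep0$uncompressed_bytes, rep(2 * 5 * 2000, 3))
  expect_equal(rep0$ratio,
               rep0$uncompressed_bytes / rep0$compressed_bytes)
  expect_equal(rep0$ratio[rep0$method == "raw"], 1)
  expect_equal(
    rep0$pct_of_baseline[rep0$method == "zlib_svb_zd"], 100)
  expect_error(compression_report(reads, "brotli"), "unknown method")
})

test_that("constant-signal reads approach the 2x ex-zd bound", {
  n <- 5000
  reads <- signal_reads("const", list(rep(1000, n)))
  rep0 <- compression_report(reads, c("raw", "exzd"), 0)
  exzd_ratio <- rep0$ratio[rep0$method == "exzd"]
  expect_equal(exzd_ratio, 2 * n / (16 + n - 1))
  expect_gt(exzd_ratio, 1.9)
})

test_that("compressed sizes are non-increasing in eliminated bits", {
  reads <- simulate_dataset(synth_model(seed = 53), 20, 3000)
  rep <- suppressWarnings(
    compression_report(reads, c("exzd", "exzd_zlib"), 0:4))
  for (m in c("exzd", "exzd_zlib")) {
    sizes <- rep$compressed_bytes[rep$method == m][order(
      rep$eliminate_bits[rep$method == m])]
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("autoplot methods return ggplot objects", {
  reads <- simulate_dataset(synth_model(seed = 54), 2, 500)
  h <- value_histogram(reads)
  expect_s3_class(ggplot2::autoplot(h), "ggplot")
  rep <- compression_report(reads, c("raw", "exzd"), 0)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
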