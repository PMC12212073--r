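test_that("the hand-traced golden blob is produced bit-exactly", {
  blob <- exzd_encode(c(100, 101, 99, 300))
  golden <- as.raw(c(
    0x00,                                           # version
    0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, # num_samples = 4
    0x00,                                           # shift_bits = 0
    0xc8, 0x00,                                     # first_sample_zz = 200
    0x01, 0x00, 0x00, 0x00,                         # n_x = 1
    0x02, 0x00, 0x00, 0x00,                         # position = 2
    0x92, 0x00, 0x00, 0x00,                         # exception = 402 - 256
    0x02, 0x03))                                    # one-byte data
  expect_identical(blob, golden)
  expect_identical(length(blob), 26L)
  expect_equal(exzd_decode(blob), c(100, 101, 99, 300))
})

test_that("degenerate records encode and decode", {
  b <- exzd_encode(5)
  expect_identical(length(b), 16L)
  expect_equal(exzd_decode(b), 5)
  # first_sample_zz = 10, n_x = 0, empty one-byte data
  expect_identical(b[11:12], as.raw(c(0x0a, 0x00)))
  expect_true(all(b[13:16] == as.raw(0)))

  const <- rep(1000, 50)
  bc <- exzd_encode(const)
  expect_equal(exzd_decode(bc), const)
  # constant signal: all deltas zero, no exceptions
  expect_identical(length(bc), 16L + 49L)
  expect_true(all(bc[17:65] == as.raw(0)))
})

test_that("encoder bytes match the independent scalar assembler", {
  set.seed(5)
  cases <- c(
    list(c(-5, -5, -5), c(0, 0, 0, 0), c(8, 16, 24), c(-4, 12, 1000, -1000),
         c(2000, 100, 3000, 50, 4000),   # several exceptions
         32767, -32768),
    replicate(50, random_int16_read(sample.int(60, 1)), simplify = FALSE))
  for (s in cases) {
    expect_identical(exzd_encode(s), oracle_exzd_blob(s))
    expect_equal(exzd_decode(exzd_encode(s)), as.numeric(s))
  }
})

test_that("round-trip is the identity on exhaustive tiny and random reads", {
  vals <- -4:4
  for (a in vals) {
    expect_equal(exzd_decode(exzd_encode(a)), a)
    for (b in vals) {
      expect_equal(exzd_decode(exzd_encode(c(a, b))), c(a, b))
    }
  }
  tiny3 <- expand.grid(vals, vals, vals)
  for (i in seq_len(nrow(tiny3))) {
    s <- as.numeric(tiny3[i, ])
    expect_equal(exzd_decode(exzd_encode(s)), s)
  }
  set.seed(6)
  for (i in 1:200) {
    s <- random_int16_read(sample.int(5000, 1))
    expect_equal(exzd_decode(exzd_encode(s)), as.numeric(s))
  }
})

test_that("the closed-form size audit equals the actual length", {
  expect_equal(exzd_encoded_size(c(100, 101, 99, 300)), 26)
  expect_equal(exzd_encoded_size(5), 16)
  set.seed(7)
  for (i in 1:100) {
    s <- random_int16_read(sample.int(2000, 1))
    expect_equal(exzd_encoded_size(s), length(exzd_encode(s)))
  }
})

test_that("exceptions hold exactly the deltas above one byte", {
  set.seed(8)
  s <- random_int16_read(400)
  zz <- zigzag_encode(delta_chain(s))[-1]
  blob <- exzd_encode(s)
  nx <- sum(zz > 255)
  stored_nx <- sum(as.integer(blob[13:16]) * 256^(0:3))
  expect_equal(stored_nx, nx)
  expect_identical(length(blob), as.integer(exzd_encoded_size(s)))
})

test_that("records are self-delimiting within a longer stream", {
  s1 <- c(100, 101, 99, 300)
  s2 <- rep(7, 10)
  stream <- c(exzd_encode(s1), exzd_encode(s2), as.raw(c(0xde, 0xad)))
  p1 <- exzd:::exzd_parse(stream, 0L)
  expect_equal(p1$samples, s1)
  p2 <- exzd:::exzd_parse(stream, p1$consumed)
  expect_equal(p2$samples, s2)
})

test_that("malformed blobs raise named errors", {
  blob <- exzd_encode(c(100, 101, 99, 300))
  bad_version <- blob; bad_version[1] <- as.raw(9)
  expect_error(exzd_decode(bad_version), "version")
  expect_error(exzd_decode(blob[1:20]), "truncated")
  expect_error(exzd_decode(c(blob, as.raw(0))), "trailing")
  bad_pos <- blob; bad_pos[17] <- as.raw(60)  # position beyond the deltas
  expect_error(exzd_decode(bad_pos), "position")
  expect_error(exzd_encode(numeric(0)), "empty")
  expect_error(exzd_encode(c(1, 2), eliminate_bits = 3), "trailing zeros")
})
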