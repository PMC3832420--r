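# nibble, minimal binary and adaptive arithmetic coders

bits_of <- function(bytes, nbits) {
  b <- as.integer(bytes)
  all_bits <- as.integer(sapply(b, function(x) (x %/% 2^(7:0)) %% 2))
  paste(all_bits[seq_len(nbits)], collapse = "")
}

test_that("nibble coding matches the block rule on worked examples", {
  cases <- list(list(v = 0, bits = "1000"),
                list(v = 5, bits = "1101"),
                list(v = 9, bits = "00011001"))
  for (cs in cases) {
    s <- bit_sink()
    nibble_encode(cs$v, s)
    expect_identical(bits_of(sink_bytes(s), sink_bits(s)), cs$bits)
    expect_identical(nibble_decode(bit_source(sink_bytes(s)), 1), as.numeric(cs$v))
  }
  expect_error(nibble_encode(-1, bit_sink()), "natural")
})

test_that("nibble round trip is exhaustive on [0, 65536) with the length law", {
  v <- 0:65535
  s <- bit_sink()
  nibble_encode(v, s)
  bitlen <- pmax(1, floor(log2(pmax(v, 1))) + 1)
  expect_equal(sink_bits(s), sum(4 * ceiling(bitlen / 3)))
  expect_equal(nibble_decode(bit_source(sink_bytes(s)), length(v)), as.numeric(v))
})

test_that("nibble decoding a truncated stream is an error", {
  s <- bit_sink()
  nibble_encode(70000, s)   # multi-block value
  b <- sink_bytes(s)
  expect_error(nibble_decode(bit_source(b[1]), 1), "truncated")
})

test_that("minimal binary coding writes exactly m big-endian bits", {
  s <- bit_sink()
  minimal_binary_encode(c(7, 0), 3, s)
  expect_identical(bits_of(sink_bytes(s), 6), "111000")
  expect_error(minimal_binary_encode(8, 3, bit_sink()), "out of range")
  # rebasing example: [10..17] rebased by min 10 -> values 0..7, m = 3
  vals <- 10:17
  reb <- vals - min(vals)
  expect_identical(bit_width(max(reb)), 3L)
  s2 <- bit_sink()
  minimal_binary_encode(reb, 3, s2)
  expect_equal(sink_bits(s2), length(vals) * 3)  # closed form L * msb(R)
  expect_equal(minimal_binary_decode(bit_source(sink_bytes(s2)), 8, 3) + 10,
               as.numeric(vals))
})

test_that("minimal binary round trips across widths 1..20", {
  set.seed(5)
  for (m in 1:20) {
    v <- c(0, 2^m - 1, sample(0:(2^m - 1), 50, replace = TRUE))
    s <- bit_sink()
    minimal_binary_encode(v, m, s)
    expect_equal(minimal_binary_decode(bit_source(sink_bytes(s)), length(v), m),
                 as.numeric(v))
  }
})

test_that("arithmetic coder compresses a constant stream to almost nothing", {
  seg <- arithmetic_encode(rep(0L, 1000), 2)
  expect_lt(seg$bits, 100)
  expect_identical(arithmetic_decode(bit_source(seg$bytes), 1000, 2, seg$bits),
                   rep(0L, 1000))
  empty <- arithmetic_encode(integer(0), 4)
  expect_equal(empty$bits, 0)
  expect_identical(arithmetic_decode(bit_source(raw(0)), 0, 4, 0), integer(0))
})

test_that("arithmetic round trip holds across alphabets and lengths", {
  set.seed(11)
  for (n in c(2, 3, 16, 64, 256)) {
    sym <- sample(0:(n - 1), 200, replace = TRUE)
    seg <- arithmetic_encode(sym, n)
    expect_identical(arithmetic_decode(bit_source(seg$bytes), 200, n, seg$bits),
                     sym)
  }
  # skewed large case
  sym <- sample(0:3, 10000, replace = TRUE, prob = c(0.85, 0.1, 0.04, 0.01))
  seg <- arithmetic_encode(sym, 4)
  expect_identical(arithmetic_decode(bit_source(seg$bytes), 10000, 4, seg$bits),
                   sym)
  expect_error(arithmetic_encode(c(0L, 5L), 4), "out of range")
})

test_that("decoding with the wrong alphabet fails or mismatches", {
  set.seed(12)
  sym <- sample(0:7, 300, replace = TRUE)
  seg <- arithmetic_encode(sym, 8)
  got <- tryCatch(arithmetic_decode(bit_source(seg$bytes), 300, 5, seg$bits),
                  error = function(e) NULL)
  expect_false(identical(got, sym))
})

test_that("arithmetic code length approaches the empirical entropy", {
  set.seed(13)
  p <- c(0.5, 0.25, 0.15, 0.1)
  N <- 10000
  sym <- sample(0:3, N, replace = TRUE, prob = p)
  H <- -sum(p * log2(p))
  seg <- arithmetic_encode(sym, 4)
  expect_lte(seg$bits, 1.05 * N * H + 64)
})
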