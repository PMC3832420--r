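# integer / string / float / boolean list codecs

test_that("the run-length decision follows the element-count rule", {
  r <- rle_decide(c(5, 5, 5, 2, 2))
  expect_true(r$use_rle)
  expect_equal(r$lengths, c(3, 2))
  expect_equal(r$values, c(5, 2))
  expect_false(rle_decide(c(1, 2, 3))$use_rle)       # 6 stored >= 3
  r0 <- rle_decide(numeric(0))
  expect_false(r0$use_rle)
  expect_length(r0$values, 0)
  # strict inequality: alternating 500 values is exactly the boundary
  expect_false(rle_decide(rep(c(1, 0), 250))$use_rle)
})

test_that("rle expansion always reproduces the input (property)", {
  set.seed(21)
  for (i in 1:50) {
    v <- sample(0:3, sample(1:200, 1), replace = TRUE)
    r <- rle_decide(v)
    expect_equal(rep(r$values, times = r$lengths), as.numeric(v))
    # the chosen branch never stores more elements than the other
    stored_rle <- length(r$lengths) + length(r$values)
    if (r$use_rle) expect_lt(stored_rle, length(v))
    else expect_gte(stored_rle, length(v))
  }
})

test_that("integer lists round-trip with signs, and constants stay tiny", {
  expect_lte(length(encode_int_list(c(0, 0, 0, 0))), 8)
  x <- c(-1, 3, -1)
  expect_equal(decode_int_list(encode_int_list(x)), as.numeric(x))
  set.seed(22)
  for (i in 1:25) {
    v <- random_signed_list(sample(0:500, 1))
    expect_equal(decode_int_list(encode_int_list(v)), as.numeric(v))
  }
  big <- random_signed_list(10000)
  expect_equal(decode_int_list(encode_int_list(big)), as.numeric(big))
  # compression monotonicity on constancy: O(log L), not O(L)
  s10 <- length(encode_int_list(rep(7, 10)))
  s10k <- length(encode_int_list(rep(7, 10000)))
  expect_lte(s10k, s10 + 8)
})

test_that("string lists transpose raggedly and round-trip", {
  for (v in list(c("AB", "CD"), c("A", "BCD"), character(0), "",
                 c("", "XY", ""), c("ACGT", "A", "TTTTTTTT"))) {
    expect_identical(decode_string_list(encode_string_list(v)), v)
  }
  # [] and [""] have distinct encodings
  expect_false(identical(encode_string_list(character(0)),
                         encode_string_list("")))
})

test_that("float lists are bit-exact through the integer representation", {
  expect_identical(decode_float_list(encode_float_list(0)), 0)
  # three equal values collapse through one distinct bit pattern + RLE
  ones <- encode_float_list(c(1, 1, 1))
  expect_identical(decode_float_list(ones), c(1, 1, 1))
  expect_lte(length(ones), 12)
  # random bit patterns, including non-finite and signed-zero payloads
  set.seed(23)
  pats <- c(0, 2^31, runif(200) * (2^32 - 1))
  vals <- compactaln:::.bits_float(floor(pats))
  back <- decode_float_list(encode_float_list(vals))
  expect_identical(compactaln:::.float_bits(back), compactaln:::.float_bits(vals))
  specials <- c(Inf, -Inf, NaN, -0)
  back2 <- decode_float_list(encode_float_list(specials))
  expect_identical(compactaln:::.float_bits(back2), compactaln:::.float_bits(specials))
})

test_that("boolean lists ride the integer path", {
  v <- rep(TRUE, 100)
  enc <- encode_bool_list(v)
  expect_identical(decode_bool_list(enc), v)
  expect_lte(length(enc), 8)
  expect_identical(decode_bool_list(encode_bool_list(logical(0))), logical(0))
  alt <- rep(c(TRUE, FALSE), 250)
  expect_identical(decode_bool_list(encode_bool_list(alt)), alt)
})
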