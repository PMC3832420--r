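# chunked container framing, codec registry, semi-random access

test_that("a collection of N records yields ceiling(N/K) frames + termination", {
  fx <- generate_alignment_fixture(fixture_exome(2500, seed = 41))
  cont <- write_collection(fx$entries, NULL, codec = "gzip", chunk_size = 1000L)
  tab <- attr(cont, "chunk_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_records, c(1000L, 1000L, 500L))
  rc <- read_collection(cont, "alignment")
  expect_identical(rc$entries, fx$entries)
  # termination bytes: 8 x 0xFF then 4 x 0x00 immediately before EOF
  expect_identical(cont[(length(cont) - 11):length(cont)],
                   c(as.raw(rep(0xFF, 8)), as.raw(rep(0, 4))))
})

test_that("an empty collection is termination only and reads back empty", {
  cont <- write_collection(list(), NULL, codec = "bzip2")
  expect_length(cont, 12)
  expect_length(read_collection(cont, "alignment")$entries, 0)
})

test_that("chunk size changes framing overhead only", {
  fx <- generate_alignment_fixture(fixture_exome(3000, seed = 42))
  c_small <- write_collection(fx$entries, NULL, codec = "gzip", chunk_size = 300L)
  c_big <- write_collection(fx$entries, NULL, codec = "gzip", chunk_size = 3000L)
  expect_identical(read_collection(c_small, "alignment")$entries, fx$entries)
  expect_identical(read_collection(c_big, "alignment")$entries, fx$entries)
  # the larger chunking is never larger by more than the framing overhead
  n_extra_frames <- nrow(attr(c_small, "chunk_table")) - 1
  expect_lte(length(c_big), length(c_small) + 17 * n_extra_frames)
})

test_that("general payload compression round-trips both schemes", {
  bytes <- serialize_entries(uniform_chunk(20))
  for (scheme in c("gzip", "bzip2")) {
    z <- compress_payload_general(bytes, scheme)
    expect_identical(decompress_payload_general(z, scheme), bytes)
  }
  expect_identical(
    decompress_payload_general(compress_payload_general(raw(0), "gzip"), "gzip"),
    raw(0))
})

test_that("scanning verifies candidates and skips planted delimiter collisions", {
  # identity codec writes the serialization uncompressed, so delimiter-like
  # byte runs inside records land verbatim in payloads
  register_codec(9L, "identity",
                 compress = function(entries, schema, options)
                   schema_serialize_test(entries, schema),
                 decompress = function(payload, schema)
                   deserialize_entries(payload))
  es <- uniform_chunk(10)
  es[[3]] <- set_unknown_field(
    es[[3]], make_unknown_payload(90L, as.raw(rep(0xFF, 16))))
  cont <- write_collection(es, NULL, codec = "identity", chunk_size = 5L)
  expect_gte(length(delim_candidates_test(cont)), 4)  # 3 real + collisions
  rc <- read_collection(cont, "alignment")
  expect_identical(rc$entries, es)
  # scanning from inside the first payload lands on the second genuine chunk
  tab <- attr(cont, "chunk_table")
  ch <- scan_next_chunk(cont, tab$offset[1] + 20, "alignment")
  expect_equal(ch$offset, tab$offset[2])
  expect_identical(ch$entries, es[6:10])
  # past the last frame: only termination remains
  expect_null(scan_next_chunk(cont, tab$offset[2] + 20, "alignment"))
})

test_that("an unknown registration code on a checksummed frame fails loudly", {
  payload <- as.raw(1:40)
  frame <- c(as.raw(rep(0xFF, 8)), as.raw(77),
             compactaln:::u32_be(length(payload)), payload,
             compactaln:::u32_be(compactaln:::.crc32(payload)))
  cont <- c(frame, as.raw(rep(0xFF, 8)), as.raw(rep(0, 4)))
  expect_error(read_collection(cont, "alignment"), "77")
})

test_that("containers concatenate into one valid collection", {
  fx <- generate_alignment_fixture(fixture_wgs(600, seed = 43))
  a <- write_collection(fx$entries[1:250], NULL, codec = "gzip", chunk_size = 100L)
  b <- write_collection(fx$entries[251:600], NULL, codec = "hybrid-1",
                        chunk_size = 200L,
                        options = list(template = TRUE, domain = TRUE))
  cc <- concatenate_containers(a, b)
  expect_identical(read_collection(cc, "alignment")$entries, fx$entries)
})
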