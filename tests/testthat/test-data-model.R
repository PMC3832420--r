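# record schema, serialization and the unknown-field mechanism

test_that("alignment entries serialize and parse identically", {
  entries <- list(
    entry0(),
    entry0(qi = 3L, pos = 500L,
           sequence_variations = list(
             sequence_variation(5L, 6L, "A", "G", 38L),
             sequence_variation(9L, 10L, "", "TT", c(30L, 31L)),
             sequence_variation(20L, 22L, "CC", "")),
           pair_link = entry_link(900L, 0L, 1L),
           splice_forward_link = entry_link(700L, 0L, 2L),
           softclip_left = "ACG", softclip_left_quality = c(20L, 21L, 22L),
           softclip_right = "T", softclip_right_quality = 40L,
           to_quality = rep(35L, 50L), read_origin_index = 2L,
           matching_reverse_strand = TRUE, score = -12.5))
  back <- deserialize_entries(serialize_entries(entries))
  expect_identical(back, entries)
})

test_that("scores are float32-rounded up front so round trips are bit-exact", {
  e <- entry0(score = 0.1)   # 0.1 is not float32-representable as a double
  expect_identical(e$score, as_float32(0.1))
  expect_identical(deserialize_entries(serialize_entries(list(e)))[[1]]$score,
                   e$score)
})

test_that("unknown fields survive serialization attached to the right entry", {
  e <- entry0()
  expect_identical(set_unknown_field(e, raw(0)), e)
  p1 <- make_unknown_payload(50L, as.raw(1:12))
  p2 <- make_unknown_payload(51L, as.raw(99:90))
  e1 <- set_unknown_field(entry0(qi = 1L), p1)
  e2 <- set_unknown_field(entry0(qi = 2L), p2)
  back <- deserialize_entries(serialize_entries(list(e1, e2)))
  expect_identical(back[[1]]$unknown_fields, p1)
  expect_identical(back[[2]]$unknown_fields, p2)
  expect_error(set_unknown_field(e, as.raw(c(1, 255))), "TLV")
  expect_error(make_unknown_payload(5L, as.raw(1)))  # known-tag range
})

test_that("validate_entry reports violations instead of raising", {
  h <- alignment_header("chr1", 1000L)
  expect_length(validate_entry(entry0(), h), 0)
  bad_target <- entry0()
  bad_target$target_index <- 5L
  expect_length(validate_entry(bad_target, h), 1)
  bad_var <- entry0(sequence_variations = list(
    sequence_variation(1L, 2L, "", "")))
  expect_match(validate_entry(bad_var, h), "both from and to empty")
  bad_ri <- entry0(sequence_variations = list(
    sequence_variation(1L, 60L, "A", "C")))
  expect_match(validate_entry(bad_ri, h), "exceeds query length")
})

test_that("read entries round-trip including pair data", {
  reads <- list(
    read_entry(0L, "ACGT", c(30L, 31L, 32L, 33L)),
    read_entry(1L, "GGCC", qualities = NULL, pair_sequence = "TTAA",
               pair_qualities = c(2L, 2L, 2L, 2L), identifier = "r1",
               description = "lane 3", metadata_index = 7L))
  expect_identical(deserialize_reads(serialize_reads(reads)), reads)
  expect_error(read_entry(0L, "ACGT", 1:3), "one byte per base")
})
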