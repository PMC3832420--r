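# the ACT hybrid codec: decomposition, template, links, modeling, round trip

test_that("decompose_chunk produces columns and residuals in entry order", {
  es <- uniform_chunk(3)
  dc <- decompose_chunk(es)
  expect_length(dc$leftovers, 0)
  expect_equal(dc$columns$position, vapply(es, `[[`, integer(1), "position"))

  es[[2]] <- set_unknown_field(es[[2]], make_unknown_payload(60L, as.raw(1:4)))
  dc2 <- decompose_chunk(es)
  expect_length(dc2$leftovers, 1)
  expect_equal(dc2$leftovers[[1]]$ordinal, 1L)   # 0-based chunk ordinal

  # nested messages: variation counts [2, 0, 1] flatten to columns of length 3
  es2 <- uniform_chunk(3)
  es2[[1]]$sequence_variations <- list(sequence_variation(1L, 2L, "A", "C"),
                                       sequence_variation(5L, 6L, "G", "T"))
  es2[[3]]$sequence_variations <- list(sequence_variation(9L, 10L, "T", "A"))
  dc3 <- decompose_chunk(es2)
  expect_equal(dc3$columns$var_count, c(2, 0, 1))
  expect_length(dc3$columns$var_position, 3)
  expect_identical(recompose_chunk(dc3$columns, dc3$leftovers), es2)
})

test_that("recompose inverts decompose on generated fixtures (property)", {
  for (seed in 1:3) {
    fx <- generate_alignment_fixture(fixture_exome(300, seed = seed))
    dc <- decompose_chunk(fx$entries)
    expect_identical(recompose_chunk(dc$columns, dc$leftovers), fx$entries)
    # column length laws
    expect_length(dc$columns$target_index, length(fx$entries))
    expect_length(dc$columns$var_position, sum(dc$columns$var_count))
  }
})

test_that("template compression collapses runs of equal templates", {
  # identical except query index / position: one run of 5
  tc <- template_compress(uniform_chunk(5))
  expect_equal(as.integer(tc$counts), 5L)
  expect_identical(template_expand(tc), uniform_chunk(5))

  # alternating templates never merge non-consecutive repeats
  ab <- uniform_chunk(4)
  for (i in c(1, 3)) ab[[i]]$mapping_quality <- 10L
  tc2 <- template_compress(ab)
  expect_equal(as.integer(tc2$counts), c(1L, 1L, 1L, 1L))
  expect_identical(template_expand(tc2), ab)

  expect_equal(as.integer(template_compress(uniform_chunk(1))$counts), 1L)

  # differing to_quality does not break a template run (non-template field)
  tq <- uniform_chunk(3)
  for (i in 1:3) tq[[i]]$to_quality <- rep(i * 10L, 50L)
  tc3 <- template_compress(tq)
  expect_equal(as.integer(tc3$counts), 3L)
  expect_identical(template_expand(tc3), tq)

  # expansion law: counts always sum to the entry count
  fx <- generate_alignment_fixture(fixture_rrbs(500, seed = 2))
  tc4 <- template_compress(fx$entries)
  expect_equal(sum(tc4$counts), length(fx$entries))
  expect_identical(template_expand(tc4), fx$entries)
})

test_that("link optimization replaces intra-chunk triples by deltas", {
  es <- uniform_chunk(8)
  # mates at chunk ordinals 4 and 6 (1-based 5 and 7)
  es[[5]]$pair_link <- entry_link(es[[7]]$position, 0L, es[[7]]$fragment_index)
  es[[7]]$pair_link <- entry_link(es[[5]]$position, 0L, es[[5]]$fragment_index)
  # a mate outside the chunk keeps its explicit triple
  es[[2]]$pair_link <- entry_link(999999L, 1L, 0L)
  opt <- optimize_links(es)
  expect_equal(opt[[5]]$pair_link$delta, 2L)
  expect_equal(opt[[7]]$pair_link$delta, -2L)
  expect_identical(opt[[2]]$pair_link, es[[2]]$pair_link)
  expect_null(opt[[1]]$pair_link)
  # involution: optimize then restore recovers identical triples
  expect_identical(restore_links(opt), es)
})

test_that("field modeling stores residuals and inverts exactly", {
  cols <- list(position = c(100, 100, 105, 230),
               query_length = c(100, 100, 100, 100),
               query_aligned_length = c(100, 98, 100, 90),
               target_aligned_length = c(100, 98, 103, 90))
  m <- model_fields(cols)
  expect_equal(m$position, c(100, 0, 5, 125))
  expect_equal(m$query_aligned_length, c(0, 2, 0, 10))
  expect_equal(m$target_aligned_length, c(0, 0, 3, 0))
  expect_equal(unmodel_fields(m), cols)
  # unsorted input yields negative deltas (signed path downstream)
  m2 <- model_fields(list(position = c(50, 20), query_length = 10,
                          query_aligned_length = 10,
                          target_aligned_length = 10))
  expect_equal(m2$position, c(50, -30))
})

test_that("all codec methods round-trip every fixture class", {
  specs <- list(fixture_rnaseq(400, seed = 31), fixture_exome(400, seed = 32),
                fixture_wgs(400, seed = 33), fixture_rrbs(400, seed = 34))
  for (spec in specs) {
    fx <- generate_alignment_fixture(spec)
    for (opts in list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))) {
      payload <- compress_chunk(fx$entries, opts[1], opts[2])
      expect_identical(decompress_chunk(payload), fx$entries)
    }
  }
})

test_that("empty chunks and flag mismatches behave as specified", {
  p <- compress_chunk(list(), template = TRUE, domain = TRUE)
  expect_identical(decompress_chunk(p), list())
  p2 <- compress_chunk(uniform_chunk(4), template = TRUE)
  bad <- p2
  bad[1] <- as.raw(0)   # header claims template off; ACT stream says on
  expect_error(decompress_chunk(bad), "mismatch")
})

test_that("unknown-field payloads ride the left-over stream byte-identically", {
  es <- uniform_chunk(6)
  p1 <- make_unknown_payload(77L, as.raw(1:12))
  p2 <- make_unknown_payload(78L, as.raw(200:190))
  es[[2]] <- set_unknown_field(es[[2]], p1)
  es[[5]] <- set_unknown_field(es[[5]], p2)
  back <- decompress_chunk(compress_chunk(es, template = TRUE, domain = TRUE))
  expect_identical(back[[2]]$unknown_fields, p1)
  expect_identical(back[[5]]$unknown_fields, p2)
  expect_identical(back, es)
})
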