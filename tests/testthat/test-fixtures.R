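# deterministic synthetic generators

test_that("identical spec + seed gives byte-identical output", {
  spec <- fixture_rnaseq(400, seed = 61)
  a <- generate_alignment_fixture(spec)
  b <- generate_alignment_fixture(spec)
  expect_identical(a, b)
  c2 <- generate_alignment_fixture(fixture_rnaseq(400, seed = 62))
  expect_false(identical(a$entries, c2$entries))
  s1 <- generate_sam_fixture(spec)
  s2 <- generate_sam_fixture(spec)
  expect_identical(s1, s2)
  # the generator restores the caller's RNG state
  set.seed(7)
  before <- runif(1)
  set.seed(7)
  invisible(generate_alignment_fixture(spec))
  expect_identical(runif(1), before)
})

test_that("generated entries satisfy the data-model invariants", {
  for (mk in list(fixture_rnaseq, fixture_exome, fixture_wgs, fixture_rrbs)) {
    fx <- generate_alignment_fixture(mk(300, seed = 63))
    expect_length(fx$entries, 300)
    viol <- unlist(lapply(fx$entries, validate_entry, header = fx$header))
    expect_length(viol, 0)
  }
  expect_length(generate_alignment_fixture(fixture_spec(0))$entries, 0)
  expect_error(fixture_spec(substitution_rate = 1.5), "rates")
  expect_error(fixture_spec(-5), "non-negative")
})

test_that("realized substitution counts match the binomial expectation", {
  spec <- fixture_spec(1000, read_length = 100L, substitution_rate = 0.01,
                       indel_rate = 0, softclip_rate = 0, duplicate_rate = 0,
                       seed = 64)
  fx <- generate_alignment_fixture(spec)
  nvar <- sum(lengths(lapply(fx$entries, `[[`, "sequence_variations")))
  mean_expected <- 1000 * 100 * 0.01
  sigma <- sqrt(1000 * 100 * 0.01 * 0.99)
  expect_lt(abs(nvar - mean_expected), 3 * sigma)
})

test_that("paired fixtures carry consistent reciprocal links", {
  fx <- generate_alignment_fixture(fixture_spec(600, paired = TRUE,
                                                duplicate_rate = 0, seed = 65))
  keys <- sprintf("%d:%d:%d",
                  vapply(fx$entries, `[[`, integer(1), "target_index"),
                  vapply(fx$entries, `[[`, integer(1), "position"),
                  vapply(fx$entries, `[[`, integer(1), "fragment_index"))
  for (i in seq_along(fx$entries)) {
    pl <- fx$entries[[i]]$pair_link
    if (is.null(pl)) next
    k <- sprintf("%d:%d:%d", pl$target_index, pl$position, pl$fragment_index)
    j <- match(k, keys)
    expect_false(is.na(j))
    back <- fx$entries[[j]]$pair_link
    expect_equal(sprintf("%d:%d:%d", back$target_index, back$position,
                         back$fragment_index), keys[i])
  }
  # in a sorted paired fixture, link optimization resolves everything intra-chunk
  opt <- optimize_links(fx$entries)
  kinds <- vapply(opt, function(e)
    if (is.null(e$pair_link)) 0L else if (!is.null(e$pair_link$delta)) 2L else 1L,
    integer(1))
  expect_gte(mean(kinds[kinds > 0] == 2L), 0.99)
})

test_that("SAM fixtures parse with standard tooling and match their plan", {
  fx <- generate_sam_fixture(fixture_rnaseq(100, seed = 66))
  samf <- tempfile(fileext = ".sam")
  writeLines(fx$sam, samf)
  bam <- Rsamtools::asBam(samf, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(sb$pos), 100)
  recs <- fx$sam[!startsWith(fx$sam, "@")]
  cigars <- vapply(strsplit(recs, "\t"), `[[`, character(1), 6)
  expect_true(any(grepl("N", cigars)))   # spliced class plants introns
  # perfect-match spec: every CIGAR is <len>M and MD the full length
  pm <- generate_sam_fixture(fixture_spec(50, substitution_rate = 0,
                                          indel_rate = 0, softclip_rate = 0,
                                          seed = 67))
  f <- strsplit(pm$sam[!startsWith(pm$sam, "@")], "\t")
  expect_true(all(vapply(f, `[[`, character(1), 6) == "100M"))
  expect_true(all(grepl("MD:Z:100", vapply(f, function(x) x[13], character(1)))))
})
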