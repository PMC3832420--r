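# SAM interop, sorting/indexing, query-index permutation, FASTQ, tier files

test_that("CIGAR/MD decomposition matches hand-decoded semantics", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:c\tLN:1000",
    "perfect\t0\tc\t11\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10",
    "ins\t0\tc\t11\t60\t5M1I4M\t*\t0\t0\tAAAAAGCCCC\tIIIIIIIIII\tMD:Z:9",
    "clip\t0\tc\t11\t60\t4S6M\t*\t0\t0\tTTTTGGGGGG\tJJJJKKKKKK\tMD:Z:6",
    "del\t16\tc\t21\t60\t4M2D4M\t*\t0\t0\tACGTACGT\tIIIIIIII\tMD:Z:4^CA4",
    "mm\t0\tc\t31\t60\t8M\t*\t0\t0\tACGTACGT\tABCDEFGH\tMD:Z:3G4")
  imp <- import_sam(sam, preserve_soft_clips = TRUE)
  es <- imp$entries
  expect_length(es, 5)
  expect_length(es[[1]]$sequence_variations, 0)
  expect_equal(es[[1]]$position, 10L)   # 1-based SAM -> 0-based internal

  ins <- es[[2]]$sequence_variations[[1]]
  expect_identical(ins[c("from", "to")], list(from = "", to = "G"))
  expect_equal(ins$read_index, 6L)      # 1-based within the read
  expect_equal(ins$position, 5L)

  expect_identical(es[[3]]$softclip_left, "TTTT")
  expect_equal(es[[3]]$softclip_left_quality, as.integer(charToRaw("JJJJ")) - 33L)
  expect_equal(es[[3]]$query_aligned_length, 6L)

  del <- es[[4]]$sequence_variations[[1]]
  expect_identical(del[c("from", "to")], list(from = "CA", to = ""))
  expect_true(es[[4]]$matching_reverse_strand)
  expect_equal(es[[4]]$target_aligned_length, 10L)

  mm <- es[[5]]$sequence_variations[[1]]
  expect_identical(mm[c("from", "to")], list(from = "G", to = "T"))
  expect_equal(mm$to_quality, as.integer(charToRaw("D")) - 33L)

  expect_length(unlist(lapply(es, validate_entry, header = imp$header)), 0)
  expect_error(import_sam(c("@SQ\tSN:c\tLN:99",
    "x\t0\tc\t1\t60\t4M1D4M\t*\t0\t0\tACGTACGT\tIIIIIIII")), "neither MD")
})

test_that("our SAM field parse agrees with Rsamtools on the fixture", {
  fx <- generate_sam_fixture(fixture_exome(120, seed = 51))
  samf <- tempfile(fileext = ".sam")
  writeLines(fx$sam, samf)
  bam <- Rsamtools::asBam(samf, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  imp <- import_sam(fx$sam)
  qi <- vapply(imp$entries, `[[`, integer(1), "query_index")
  # one entry per record here (no splices in the exome class)
  expect_equal(length(imp$entries), length(sb$pos))
  ours <- data.frame(pos = vapply(imp$entries, `[[`, integer(1), "position") + 1L,
                     rev = vapply(imp$entries, `[[`, logical(1),
                                  "matching_reverse_strand"),
                     mapq = vapply(imp$entries, `[[`, integer(1),
                                   "mapping_quality"))
  ord_ours <- order(ours$pos, ours$mapq, ours$rev)
  ord_sb <- order(sb$pos, sb$mapq, sb$strand == "-")
  expect_equal(ours$pos[ord_ours], sb$pos[ord_sb])
  expect_equal(ours$mapq[ord_ours], sb$mapq[ord_sb])
  expect_equal(ours$rev[ord_ours], (sb$strand == "-")[ord_sb])
})

test_that("import -> export is field-identical on the covered surface", {
  for (mk in list(fixture_rnaseq, fixture_exome)) {
    fx <- generate_sam_fixture(mk(150, seed = 52))
    imp <- import_sam(fx$sam, preserve_all_mapped_qualities = TRUE)
    out <- export_sam(imp$entries, imp$header, reference = fx$reference)
    # all fields except the read name (identity lives in the query index)
    orig <- sort(sub("^[^\t]+", "", fx$sam[!startsWith(fx$sam, "@")]))
    got <- sort(sub("^[^\t]+", "", out[!startsWith(out, "@")]))
    expect_identical(got, orig)
  }
})

test_that("exported spliced and indel records re-import identically", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:c\tLN:10000",
    "s1\t0\tc\t101\t60\t20M500N30M\t*\t0\t0\t", # seq filled below
    "s2\t0\tc\t201\t60\t5M2I13M1D10M\t*\t0\t0\t")
  seq1 <- paste(rep("A", 50), collapse = "")
  seq2 <- paste(rep("C", 30), collapse = "")
  sam[3] <- paste0(sam[3], seq1, "\t", strrep("I", 50), "\tMD:Z:50")
  sam[4] <- paste0(sam[4], seq2, "\t", strrep("I", 30), "\tMD:Z:18^G10")
  imp <- import_sam(sam, preserve_all_mapped_qualities = TRUE)
  # splice split: two fragments with reciprocal links
  expect_length(imp$entries, 3)
  e1 <- imp$entries[[1]]
  e2 <- imp$entries[[2]]
  expect_equal(e1$splice_forward_link$position, e2$position)
  expect_equal(e2$splice_backward_link$position, e1$position)
  expect_equal(e2$position, 100L + 20L + 500L)
  # a reference consistent with the planted records, for SEQ reconstruction
  rc <- rep("A", 10000)
  rc[201:218] <- "C"
  rc[219] <- "G"
  rc[220:229] <- "C"
  ref <- list(c = paste(rc, collapse = ""))
  out <- export_sam(imp$entries, imp$header, reference = ref)
  got <- out[!startsWith(out, "@")]
  expect_match(got[1], "\t20M500N30M\t")
  expect_match(got[2], "\t5M2I13M1D10M\t")
  expect_match(got[2], "MD:Z:18\\^G10")
  expect_identical(strsplit(got[1], "\t")[[1]][10], seq1)
  expect_identical(strsplit(got[2], "\t")[[1]][10], seq2)
  # and the full CIGAR/MD round trip re-imports to the same records
  reimp <- import_sam(c(sam[1:2], got), preserve_all_mapped_qualities = TRUE)
  expect_identical(reimp$entries, imp$entries)
})

test_that("ambiguous reads are diverted to the too-many-hits set", {
  sam <- c("@SQ\tSN:c\tLN:1000",
    "a\t0\tc\t1\t0\t4M\t*\t0\t0\tACGT\tIIII\tMD:Z:4\tNH:i:500",
    "b\t0\tc\t10\t60\t4M\t*\t0\t0\tACGT\tIIII\tMD:Z:4\tNH:i:1")
  imp <- import_sam(sam, max_hits = 100)
  expect_equal(imp$tmh, 0L)             # query index of read "a"
  qi <- vapply(imp$entries, `[[`, integer(1), "query_index")
  expect_false(any(qi %in% imp$tmh))    # tmh reads appear in no entry
})

test_that("sorting and the genomic index answer window queries exactly", {
  fx <- generate_alignment_fixture(
    fixture_spec(800, paired = TRUE, sorted = FALSE, seed = 53))
  res <- sort_and_index(fx$entries, chunk_size = 150L)
  pos <- vapply(res$entries, `[[`, integer(1), "position")
  ti <- vapply(res$entries, `[[`, integer(1), "target_index")
  expect_true(all(diff(order(ti, pos)) == 1))
  for (win in list(c(0, 1e5), c(4e5, 5e5), c(999000, 1e6))) {
    got <- query_genomic_window(res$container, res$index, 0L, win[1], win[2])
    brute <- Filter(function(e) e$target_index == 0 && e$position < win[2] &&
                      e$position + e$target_aligned_length > win[1],
                    res$entries)
    expect_identical(got, brute)
  }
  empty <- sort_and_index(list())
  expect_equal(nrow(empty$index), 0)
})

test_that("query-index permutation is bijective and shrinks the column", {
  fx <- generate_alignment_fixture(fixture_rnaseq(2000, seed = 54))
  pm <- permute_query_indices(fx$entries)
  qi_small <- vapply(pm$entries, `[[`, integer(1), "query_index")
  # first-occurrence order, fragments of one read share one small index
  expect_equal(sort(unique(qi_small)), 0:(nrow(pm$map) - 1))
  orig <- vapply(fx$entries, `[[`, integer(1), "query_index")
  expect_equal(pm$map$original[qi_small + 1], orig)
  # all fragments of a read keep a common index
  expect_equal(tapply(qi_small, orig, function(x) length(unique(x))),
               tapply(qi_small, orig, function(x) 1L))
  # map file round trip with block-partial lookup
  f <- tempfile(fileext = ".perm")
  write_permutation_file(pm$map, f, block_size = 64L)
  probe <- c(0L, 63L, 64L, nrow(pm$map) - 1L)
  expect_equal(perm_lookup(f, probe), as.numeric(pm$map$original[probe + 1]))
  expect_error(perm_lookup(f, nrow(pm$map)), "out of range")
  # permutation never enlarges the hybrid-compressed sorted collection
  before <- length(compress_chunk(fx$entries, TRUE, TRUE))
  after <- length(compress_chunk(pm$entries, TRUE, TRUE))
  expect_lte(after, before)
})

test_that("FASTQ import/export round-trips bases and qualities", {
  f1 <- tempfile(fileext = ".fq")
  f2 <- tempfile(fileext = ".fq")
  writeLines(c("@r1/1", "ACGTA", "+", "IIJJK",
               "@r2/1", "GGGCC", "+", "!!##%"), f1)
  writeLines(c("@r1/2", "TTTTA", "+", "ABCDE",
               "@r2/2", "CCAAG", "+", "FGHIJ"), f2)
  reads <- import_fastq(f1, f2)
  expect_length(reads, 2)
  expect_equal(vapply(reads, `[[`, integer(1), "query_index"), 0:1)
  expect_identical(reads[[1]]$pair_sequence, "TTTTA")
  crf <- tempfile(fileext = ".compact-reads")
  write_compact_reads(reads, crf, codec = "bzip2")
  back <- read_compact_reads(crf)
  expect_identical(back, reads)
  o1 <- tempfile()
  o2 <- tempfile()
  export_fastq(back, o1, o2)
  keep <- function(p) readLines(p)[rep(c(FALSE, TRUE, FALSE, TRUE), 2)]
  expect_identical(keep(o1), keep(f1))
  expect_identical(keep(o2), keep(f2))
  # incongruent pair files fail at the offending record
  f3 <- tempfile()
  writeLines(c("@only", "AC", "+", "II"), f3)
  expect_error(import_fastq(f1, f3), "record count")
})

test_that("a Tier II file set round-trips through disk", {
  fx <- generate_sam_fixture(fixture_exome(80, seed = 55))
  imp <- import_sam(fx$sam)
  base <- file.path(tempdir(), "t2set")
  write_tier2(imp, base, codec = "hybrid-1", chunk_size = 50L)
  expect_true(file.exists(paste0(base, ".entries")))
  expect_true(file.exists(paste0(base, ".header")))
  expect_true(file.exists(paste0(base, ".index")))
  t2 <- read_tier2(base)
  expect_identical(t2$entries, imp$entries)
  expect_identical(t2$header$target_names, imp$header$target_names)
})
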