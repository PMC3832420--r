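# SAM-level fixture generator: plants alignments on a generated reference
# and emits SAM text whose CIGAR/MD/SEQ/QUAL fields are consistent with the
# planted events, so the import/export path can be verified field by field
# and cross-checked against independent SAM tooling.

#' Generate a SAM fixture with a matching reference
#'
#' Builds i.i.d. reference sequences, plants reads with substitutions,
#' indels, soft clips and (optionally) splices, and emits SAM records whose
#' CIGAR, MD, SEQ and QUAL are derived from the construction bookkeeping.
#' Deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()]; `n_entries` is interpreted as the number
#'   of SAM records (reads/mates), `target_length` is capped for text-scale
#'   fixtures.
#' @return `list(sam, reference)`: SAM lines and a named list of reference
#'   sequences.
#' @export
generate_sam_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed + 1L, {
    tlen <- min(spec$target_length, 100000L)
    tnames <- paste0("chr", seq_len(spec$n_targets))
    reference <- lapply(seq_len(spec$n_targets), function(i) random_bases(tlen))
    names(reference) <- tnames

    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", tnames, tlen))
    recs <- character(0)
    ql <- spec$read_length
    nrec <- spec$n_entries
    i <- 0L
    ridx <- 0L
    while (i < nrec) {
      paired <- spec$paired && (nrec - i) >= 2L
      qname <- sprintf("read%05d", ridx)
      ridx <- ridx + 1L
      ti <- sample.int(spec$n_targets, 1)
      if (paired) {
        insert <- max(2L * ql + 10L,
                      as.integer(round(rnorm(1, spec$insert_mean, spec$insert_sd))))
        pos1 <- sample.int(tlen - insert - 2L * spec$intron_max - 10L, 1)
        pos2 <- pos1 + insert - ql
        r1 <- plant_sam_record(spec, reference[[ti]], pos1, ql)
        r2 <- plant_sam_record(spec, reference[[ti]], pos2, ql)
        f1 <- 0x1 + 0x40 + 0x20       # FR orientation: mate 2 is reverse
        f2 <- 0x1 + 0x80
        recs <- c(recs,
          sam_line(qname, f1, tnames[ti], r1, "=", pos2 + 1L),
          sam_line(qname, f2, tnames[ti], r2, "=", pos1 + 1L, reverse = TRUE))
        i <- i + 2L
      } else {
        pos1 <- sample.int(tlen - ql - 2L * spec$intron_max - 10L, 1)
        r1 <- plant_sam_record(spec, reference[[ti]], pos1, ql)
        flag <- if (runif(1) < 0.5) 0x10 else 0x0
        recs <- c(recs, sam_line(qname, flag, tnames[ti], r1, "*", 0L,
                                 reverse = bitwAnd(flag, 0x10) != 0))
        i <- i + 1L
      }
    }
    list(sam = c(header, recs), reference = reference)
  })
}

# plant one record at 0-based `pos0`; returns the pieces needed for a line
plant_sam_record <- function(spec, refseq, pos0, ql) {
  clip_l <- if (runif(1) < spec$softclip_rate) sample.int(6L, 1) else 0L
  clip_r <- if (runif(1) < spec$softclip_rate) sample.int(6L, 1) else 0L
  aligned <- ql - clip_l - clip_r
  spliced <- spec$spliced && runif(1) < spec$splice_rate
  seg <- if (spliced) {
    l1 <- sample.int(aligned - 20L, 1) + 10L
    c(l1, aligned - l1)
  } else aligned
  intron <- if (spliced) sample(spec$intron_min:spec$intron_max, 1) else 0L

  cigar <- character(0)
  md <- character(0)
  seqtxt <- if (clip_l > 0) random_bases(clip_l) else ""
  if (clip_l > 0) cigar <- c(cigar, paste0(clip_l, "S"))
  match_run <- 0L
  nm <- 0L
  ref_cur <- pos0
  for (s in seq_along(seg)) {
    span <- seg[s]
    frag_ref <- substr(refseq, ref_cur + 1L, ref_cur + span)
    # substitutions within the fragment
    k <- min(rbinom(1, span, spec$substitution_rate), span)
    at <- if (k > 0) sort(sample.int(span, k)) else integer(0)
    bases <- strsplit(frag_ref, "")[[1]]
    prev <- 0L
    for (a in at) {
      refb <- bases[a]
      alt <- sample(setdiff(BASES, refb), 1)
      bases[a] <- alt
      match_run <- match_run + (a - prev - 1L)
      md <- c(md, as.character(match_run), refb)
      match_run <- 0L
      prev <- a
      nm <- nm + 1L
    }
    match_run <- match_run + (span - prev)
    cigar <- c(cigar, paste0(span, "M"))
    seqtxt <- paste0(seqtxt, paste(bases, collapse = ""))
    ref_cur <- ref_cur + span
    if (s < length(seg)) {
      cigar <- c(cigar, paste0(intron, "N"))
      ref_cur <- ref_cur + intron
    }
  }
  md <- c(md, as.character(match_run))
  if (clip_r > 0) {
    cigar <- c(cigar, paste0(clip_r, "S"))
    seqtxt <- paste0(seqtxt, random_bases(clip_r))
  }
  qual <- rawToChar(as.raw(sample.int(40, nchar(seqtxt), replace = TRUE) + 2L + 33L))
  list(pos0 = pos0, cigar = paste(cigar, collapse = ""),
       md = paste(md, collapse = ""), seq = seqtxt, qual = qual,
       mapq = sample(c(30L, 37L, 60L), 1), nm = nm, reverse = FALSE)
}

sam_line <- function(qname, flag, rname, r, rnext, pnext, reverse = FALSE) {
  if (reverse) flag <- bitwOr(as.integer(flag), 0x10)
  paste(qname, flag, rname, r$pos0 + 1L, r$mapq, r$cigar, rnext, pnext, 0L,
        r$seq, r$qual, paste0("NM:i:", r$nm), paste0("MD:Z:", r$md),
        sep = "\t")
}
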