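# Multi-tier file organization and SAM interoperability.
#
# Tier I   .compact-reads       raw reads (sequence + qualities)
# Tier II  .entries/.header/.index/.tmh   stand-alone alignment data
# Tier III .perm                genomic-order <-> read-order index map
#
# SAM text is parsed directly (tab fields + CIGAR/MD walk) rather than via an
# alignment library, so that Rsamtools remains an independent oracle in the
# tests. Import decomposes CIGAR/MD strings into sequence-variation records;
# spliced records (CIGAR N) are split into fragments connected by splice
# links; mates are connected by pair links. Read names are not preserved:
# read identity is the query index.

parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+|[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(toks[seq(1, length(toks), 2)])
  ops <- toks[seq(2, length(toks), 2)]
  list(lengths = lens, ops = ops)
}

parse_md <- function(md) {
  # tokens: match-run lengths, mismatched ref bases, ^-prefixed deletions
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  toks
}

qual_bytes <- function(qual) {
  if (is.na(qual) || qual == "*") return(NULL)
  as.integer(charToRaw(qual)) - 33L
}

sam_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub("^..:.:", "", hit[1])
}

# An MD cursor: feeds matched/mismatch/deletion events while ref advances.
md_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens
  env$i <- 1L
  env$run <- 0L     # remaining matched bases in current run
  env
}

md_advance_match <- function(mc, len, on_mismatch) {
  # consume `len` aligned (M) bases; calls on_mismatch(offset_within_len, refbase)
  done <- 0L
  while (done < len) {
    if (mc$run > 0) {
      step <- min(mc$run, len - done)
      mc$run <- mc$run - step
      done <- done + step
    } else {
      if (mc$i > length(mc$toks)) stop("MD string shorter than CIGAR")
      tok <- mc$toks[mc$i]
      mc$i <- mc$i + 1L
      if (grepl("^\\d+$", tok)) {
        mc$run <- as.integer(tok)
      } else if (startsWith(tok, "^")) {
        stop("MD deletion where CIGAR expects aligned bases")
      } else {
        on_mismatch(done, tok)
        done <- done + 1L
      }
    }
  }
}

md_take_deletion <- function(mc, len) {
  if (mc$run > 0) stop("MD/CIGAR disagreement at deletion")
  # skip zero-length match runs
  while (mc$i <= length(mc$toks) && mc$toks[mc$i] == "0") mc$i <- mc$i + 1L
  if (mc$i > length(mc$toks) || !startsWith(mc$toks[mc$i], "^"))
    stop("MD lacks deletion bases where CIGAR has D")
  del <- substring(mc$toks[mc$i], 2)
  mc$i <- mc$i + 1L
  if (nchar(del) != len) stop("MD deletion length does not match CIGAR")
  del
}

#' Import SAM records as Tier II alignment entries
#'
#' Decomposes each mapped record's CIGAR and MD evidence into
#' [sequence_variation()] records (1-based SAM positions become 0-based),
#' splits spliced records (CIGAR `N`) into fragments connected by splice
#' links, and connects mates by pair links. Reads whose reported hit count
#' (`NH` tag) exceeds `max_hits` are excluded and listed in the
#' too-many-hits set. Unmapped records are skipped (they belong in Tier I
#' only). Read names are replaced by sequential query indices in order of
#' first appearance.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param preserve_soft_clips keep soft-clipped bases and their qualities.
#' @param preserve_all_mapped_qualities store quality bytes over all aligned
#'   read bases (`to_quality`); otherwise only variation bases keep
#'   qualities.
#' @param max_hits ambiguity threshold for the too-many-hits set.
#' @return `list(entries, header, tmh, query_names)`; `tmh` holds the query
#'   indices excluded for ambiguity, `query_names` the original read name
#'   per query index.
#' @export
import_sam <- function(sam, preserve_soft_clips = TRUE,
                       preserve_all_mapped_qualities = FALSE,
                       max_hits = Inf) {
  lines <- if (length(sam) == 1 && file.exists(sam)) readLines(sam) else sam
  hdr_lines <- lines[startsWith(lines, "@")]
  rec_lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr_lines[startsWith(hdr_lines, "@SQ")]
  target_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  target_lengths <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  header <- alignment_header(target_names, target_lengths)

  recs <- strsplit(rec_lines, "\t", fixed = TRUE)
  qnames <- vapply(recs, `[[`, character(1), 1)
  flags <- as.integer(vapply(recs, `[[`, character(1), 2))
  mapped <- bitwAnd(flags, 0x4) == 0
  uq <- unique(qnames)
  qindex <- match(qnames, uq) - 1L

  # ambiguity: NH tag beyond threshold
  nh <- vapply(recs, function(f) {
    v <- sam_tag(f[-(1:11)], "NH")
    if (is.na(v)) 1L else as.integer(v)
  }, integer(1))
  tmh <- sort(unique(qindex[nh > max_hits]))

  frag_entries <- list()   # per record: list of entries (fragments)
  rec_meta <- list()
  for (r in seq_along(recs)) {
    if (!mapped[r] || nh[r] > max_hits) next
    f <- recs[[r]]
    rname <- f[3]
    ti <- match(rname, target_names) - 1L
    if (is.na(ti)) stop("record ", f[1], " maps to unknown target ", rname)
    pos0 <- as.integer(f[4]) - 1L
    flag <- flags[r]
    seq <- f[10]
    qual <- f[11]
    tags <- f[-(1:11)]
    md <- sam_tag(tags, "MD")
    as_score <- sam_tag(tags, "AS")
    cg <- parse_cigar(f[6])
    if (is.na(md) && any(cg$ops %in% c("M", "X", "=", "D")) &&
        sum(cg$lengths[cg$ops %in% c("X", "D")]) > 0)
      stop("record ", f[1], " has neither MD tag nor reference evidence ",
           "sufficient to derive sequence variations")
    qb <- qual_bytes(qual)
    ql <- if (seq != "*") nchar(seq) else sum(cg$lengths[cg$ops %in% c("M", "I", "S", "=", "X")])
    mc <- md_cursor(if (is.na(md)) parse_md(as.character(
      sum(cg$lengths[cg$ops %in% c("M", "=", "X")]))) else parse_md(md))

    read_cur <- 1L       # 1-based cursor in the full read (incl. soft clips)
    ref_cur <- pos0
    frags <- list()
    cur <- NULL          # accumulating fragment state
    new_frag <- function(p) list(position = p, tal = 0L, qal = 0L,
                                 vars = list(), read_lo = NA_integer_)
    cur <- new_frag(pos0)
    clip_left <- NULL
    clip_left_q <- NULL
    clip_right <- NULL
    clip_right_q <- NULL
    for (k in seq_along(cg$ops)) {
      op <- cg$ops[k]
      len <- cg$lengths[k]
      if (op %in% c("M", "=", "X")) {
        if (is.na(cur$read_lo)) cur$read_lo <- read_cur
        off0 <- cur$tal
        rc0 <- read_cur
        md_advance_match(mc, len, function(off, refbase) {
          readbase <- if (seq == "*") "N" else substr(seq, rc0 + off, rc0 + off)
          v <- sequence_variation(
            position = off0 + off, read_index = rc0 + off,
            from = refbase, to = readbase,
            to_quality = if (!is.null(qb)) qb[rc0 + off])
          cur$vars[[length(cur$vars) + 1L]] <<- v
        })
        cur$tal <- cur$tal + len
        cur$qal <- cur$qal + len
        read_cur <- read_cur + len
        ref_cur <- ref_cur + len
      } else if (op == "I") {
        if (is.na(cur$read_lo)) cur$read_lo <- read_cur
        ins <- if (seq == "*") strrep("N", len) else substr(seq, read_cur, read_cur + len - 1L)
        v <- sequence_variation(
          position = cur$tal, read_index = read_cur, from = "", to = ins,
          to_quality = if (!is.null(qb)) qb[read_cur:(read_cur + len - 1L)])
        cur$vars[[length(cur$vars) + 1L]] <- v
        cur$qal <- cur$qal + len
        read_cur <- read_cur + len
      } else if (op == "D") {
        del <- md_take_deletion(mc, len)
        v <- sequence_variation(position = cur$tal, read_index = read_cur,
                                from = del, to = "")
        cur$vars[[length(cur$vars) + 1L]] <- v
        cur$tal <- cur$tal + len
        ref_cur <- ref_cur + len
      } else if (op == "N") {
        frags[[length(frags) + 1L]] <- cur
        ref_cur <- ref_cur + len
        cur <- new_frag(ref_cur)
      } else if (op == "S") {
        text <- if (seq == "*") strrep("N", len) else substr(seq, read_cur, read_cur + len - 1L)
        qs <- if (!is.null(qb)) qb[read_cur:(read_cur + len - 1L)]
        if (k == 1 || read_cur == 1L) {
          clip_left <- text
          clip_left_q <- qs
        } else {
          clip_right <- text
          clip_right_q <- qs
        }
        read_cur <- read_cur + len
      } else if (op == "H" || op == "P") {
        # hard clips and padding carry no stored bases
      }
    }
    frags[[length(frags) + 1L]] <- cur

    es <- vector("list", length(frags))
    for (s in seq_along(frags)) {
      fr <- frags[[s]]
      e <- alignment_entry(
        query_index = qindex[r], target_index = ti, position = fr$position,
        fragment_index = 0L,  # assigned after grouping
        matching_reverse_strand = bitwAnd(flag, 0x10) != 0,
        query_length = ql, query_aligned_length = fr$qal,
        target_aligned_length = fr$tal,
        mapping_quality = as.integer(f[5]),
        score = if (is.na(as_score)) 0 else as.numeric(as_score),
        sequence_variations = fr$vars)
      if (preserve_all_mapped_qualities && !is.null(qb) && fr$qal > 0 &&
          !is.na(fr$read_lo)) {
        e$to_quality <- qb[fr$read_lo:(fr$read_lo + fr$qal - 1L)]
      }
      if (s == 1 && preserve_soft_clips && !is.null(clip_left)) {
        e$softclip_left <- clip_left
        if (!is.null(clip_left_q)) e$softclip_left_quality <- clip_left_q
      }
      if (s == length(frags) && preserve_soft_clips && !is.null(clip_right)) {
        e$softclip_right <- clip_right
        if (!is.null(clip_right_q)) e$softclip_right_quality <- clip_right_q
      }
      es[[s]] <- e
    }
    frag_entries[[length(frag_entries) + 1L]] <- es
    rec_meta[[length(rec_meta) + 1L]] <-
      list(q = qindex[r], first = bitwAnd(flag, 0x80) == 0,
           paired = bitwAnd(flag, 0x1) != 0)
  }

  # assign fragment indices per query (mate 1 fragments, then mate 2) and
  # wire splice + pair links
  qs <- vapply(rec_meta, `[[`, integer(1), "q")
  entries <- list()
  for (q in unique(qs)) {
    rs <- which(qs == q)
    firsts <- vapply(rec_meta[rs], `[[`, logical(1), "first")
    rs <- rs[order(!firsts)]   # mate 1 first
    fi <- 0L
    rec_first_frag <- integer(length(rs))
    for (a in seq_along(rs)) {
      es <- frag_entries[[rs[a]]]
      rec_first_frag[a] <- fi
      for (s in seq_along(es)) {
        es[[s]]$fragment_index <- fi
        fi <- fi + 1L
      }
      # splice links along the fragment chain
      if (length(es) > 1) {
        for (s in seq_len(length(es) - 1)) {
          es[[s]]$splice_forward_link <- entry_link(
            position = es[[s + 1]]$position,
            target_index = es[[s + 1]]$target_index,
            fragment_index = es[[s + 1]]$fragment_index)
          es[[s + 1]]$splice_backward_link <- entry_link(
            position = es[[s]]$position,
            target_index = es[[s]]$target_index,
            fragment_index = es[[s]]$fragment_index)
        }
      }
      frag_entries[[rs[a]]] <- es
    }
    if (length(rs) == 2 && rec_meta[[rs[1]]]$paired) {
      e1 <- frag_entries[[rs[1]]][[1]]
      e2 <- frag_entries[[rs[2]]][[1]]
      frag_entries[[rs[1]]][[1]]$pair_link <- entry_link(
        position = e2$position, target_index = e2$target_index,
        fragment_index = e2$fragment_index)
      frag_entries[[rs[2]]][[1]]$pair_link <- entry_link(
        position = e1$position, target_index = e1$target_index,
        fragment_index = e1$fragment_index)
    }
    for (a in rs) entries <- c(entries, frag_entries[[a]])
  }
  header$n_queries <- length(uq)
  list(entries = entries, header = header, tmh = tmh, query_names = uq)
}

# --- export ---------------------------------------------------------------

# reconstruct CIGAR body, MD and (optionally) SEQ for one fragment chain
rebuild_record_body <- function(frags, reference = NULL, target_name = NULL) {
  cigar <- character(0)
  md <- character(0)
  seqtxt <- character(0)
  match_run <- 0L
  flush_md_run <- function() {
    md <<- c(md, as.character(match_run))
    match_run <<- 0L
  }
  for (s in seq_along(frags)) {
    e <- frags[[s]]
    refseq <- if (!is.null(reference)) reference[[target_name]]
    cur <- 0L    # ref offset within fragment
    for (v in e$sequence_variations) {
      mlen <- v$position - cur
      if (nchar(v$from) > 0 && nchar(v$to) > 0) next  # mismatches: M runs
      if (mlen > 0) cigar <- c(cigar, paste0(mlen, "M"))
      if (nchar(v$from) == 0) {
        cigar <- c(cigar, paste0(nchar(v$to), "I"))
      } else {
        cigar <- c(cigar, paste0(nchar(v$from), "D"))
      }
      cur <- v$position + nchar(v$from)
    }
    if (e$target_aligned_length - cur > 0 || length(cigar) == 0)
      cigar <- c(cigar, paste0(e$target_aligned_length - cur, "M"))
    # MD and SEQ: walk ref offsets with mismatches and deletions
    evs <- e$sequence_variations
    evs <- evs[order(vapply(evs, `[[`, integer(1), "position"))]
    cur <- 0L
    for (v in evs) {
      if (nchar(v$from) > 0 && nchar(v$to) > 0) {        # mismatch(es)
        for (b in seq_len(nchar(v$from))) {
          gap <- v$position + b - 1L - cur
          match_run <- match_run + gap
          flush_md_run()
          md <- c(md, substr(v$from, b, b))
          cur <- v$position + b
        }
      } else if (nchar(v$from) > 0) {                    # deletion
        match_run <- match_run + (v$position - cur)
        flush_md_run()
        md <- c(md, paste0("^", v$from))
        cur <- v$position + nchar(v$from)
      }
    }
    match_run <- match_run + (e$target_aligned_length - cur)
    if (s < length(frags)) {
      gap <- frags[[s + 1]]$position - (e$position + e$target_aligned_length)
      cigar <- c(cigar, paste0(gap, "N"))
    }
    if (!is.null(reference)) {
      # rebuild the fragment's aligned read bases from reference + variations
      ref_frag <- substr(refseq, e$position + 1L,
                         e$position + e$target_aligned_length)
      out <- character(0)
      cur <- 0L
      for (v in evs) {
        if (nchar(v$from) > 0 && nchar(v$to) > 0) {
          out <- c(out, substr(ref_frag, cur + 1L, v$position), v$to)
          cur <- v$position + nchar(v$from)
        } else if (nchar(v$from) == 0) {
          out <- c(out, substr(ref_frag, cur + 1L, v$position), v$to)
          cur <- v$position
        } else {
          out <- c(out, substr(ref_frag, cur + 1L, v$position))
          cur <- v$position + nchar(v$from)
        }
      }
      out <- c(out, substr(ref_frag, cur + 1L, e$target_aligned_length))
      seqtxt <- c(seqtxt, paste(out, collapse = ""))
    }
  }
  flush_md_run()
  # fold zero-length M ops and merge adjacent ops of the same type
  list(cigar = paste(cigar[cigar != "0M"], collapse = ""),
       md = paste(md, collapse = ""),
       seq = paste(seqtxt, collapse = ""))
}

#' Export Tier II entries as SAM records
#'
#' Inverse of [import_sam()] over the covered-field surface: FLAG bits
#' (paired, strands, first/second of pair), RNAME/POS, MAPQ, CIGAR
#' (including N gaps for spliced fragment chains and S for preserved soft
#' clips), RNEXT/PNEXT, MD and NM tags, and — when `reference` is supplied —
#' SEQ rebuilt from reference plus variations. QUAL is emitted when all
#' mapped qualities were preserved. Read names are `q<query index>`.
#'
#' @param entries alignment entries (link triples, not deltas).
#' @param header the matching [alignment_header()].
#' @param reference optional named list/character of reference sequences,
#'   needed to reconstruct SEQ.
#' @param file optional output path.
#' @return SAM lines (invisibly when `file` is given).
#' @export
export_sam <- function(entries, header, reference = NULL, file = NULL) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", header$target_names,
                     header$target_lengths))
  if (length(entries) > 0) {
    qi <- vnum(entries, "query_index")
    fi <- vnum(entries, "fragment_index")
    for (q in unique(qi)) {
      sel <- which(qi == q)
      sel <- sel[order(fi[sel])]
      group <- entries[sel]
      # split the group in records: a new record starts wherever there is no
      # backward splice link continuing the previous fragment
      recs <- list()
      curr <- list()
      for (e in group) {
        if (length(curr) > 0 && is.null(e$splice_backward_link)) {
          recs[[length(recs) + 1L]] <- curr
          curr <- list()
        }
        curr[[length(curr) + 1L]] <- e
      }
      recs[[length(recs) + 1L]] <- curr
      paired <- length(recs) == 2 && !is.null(recs[[1]][[1]]$pair_link)
      for (ri in seq_along(recs)) {
        frags <- recs[[ri]]
        e1 <- frags[[1]]
        elast <- frags[[length(frags)]]
        tname <- header$target_names[e1$target_index + 1L]
        body <- rebuild_record_body(frags, reference, tname)
        cigar <- body$cigar
        seqtxt <- body$seq
        qualb <- unlist(lapply(frags, `[[`, "to_quality"))
        if (!is.null(e1$softclip_left)) {
          cigar <- paste0(nchar(e1$softclip_left), "S", cigar)
          seqtxt <- paste0(e1$softclip_left, seqtxt)
          qualb <- c(e1$softclip_left_quality, qualb)
        }
        if (!is.null(elast$softclip_right)) {
          cigar <- paste0(cigar, nchar(elast$softclip_right), "S")
          seqtxt <- paste0(seqtxt, elast$softclip_right)
          qualb <- c(qualb, elast$softclip_right_quality)
        }
        flag <- 0L
        if (e1$matching_reverse_strand) flag <- flag + 0x10
        rnext <- "*"
        pnext <- 0L
        if (paired) {
          other <- recs[[3L - ri]][[1]]
          flag <- flag + 0x1 + (if (ri == 1) 0x40 else 0x80)
          if (other$matching_reverse_strand) flag <- flag + 0x20
          rnext <- "="
          pnext <- other$position + 1L
        }
        nm <- sum(vapply(unlist(lapply(frags, `[[`, "sequence_variations"),
                                recursive = FALSE),
                         function(v) max(nchar(v$from), nchar(v$to)), numeric(1)))
        qual <- if (length(qualb) == (nchar(seqtxt))) {
          rawToChar(as.raw(qualb + 33L))
        } else "*"
        lines <- c(lines, paste(
          paste0("q", q), flag, tname, e1$position + 1L, e1$mapping_quality,
          cigar, rnext, pnext, 0L,
          if (nzchar(seqtxt)) seqtxt else "*", qual,
          paste0("NM:i:", nm), paste0("MD:Z:", body$md),
          sep = "\t"))
      }
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# --- sorting, indexing, windows -------------------------------------------

#' Sort entries by genomic position and build an index
#'
#' Accepts unsorted input (alignments can be written before sorting — the
#' whole point of the container supporting both states). Entries are ordered
#' by (target index, position); the index maps each chunk's byte offset to
#' the genomic coordinate of its first entry, which is all
#' [query_genomic_window()] needs for seek-and-scan access.
#'
#' @param entries alignment entries.
#' @param codec,chunk_size,options passed to [write_collection()].
#' @return `list(container, index, entries)`: the sorted container (raw),
#'   its chunk-level genomic index (data frame), and the sorted entries.
#' @export
sort_and_index <- function(entries, codec = "gzip", chunk_size = 10000L,
                           options = list()) {
  ord <- order(vnum(entries, "target_index"), vnum(entries, "position"))
  entries <- entries[ord]
  container <- write_collection(entries, file = NULL, codec = codec,
                                schema = "alignment", chunk_size = chunk_size,
                                options = options)
  list(container = container, index = attr(container, "chunk_table"),
       entries = entries)
}

#' Retrieve entries overlapping a genomic window
#'
#' Seeks into a sorted container using the chunk-level genomic index and
#' scans only the chunks that can overlap `[start, end)` on the target.
#'
#' @param container raw container of genomically sorted entries.
#' @param index chunk table from [sort_and_index()].
#' @param target target index (0-based).
#' @param start,end 0-based half-open window.
#' @export
query_genomic_window <- function(container, index, target, start, end) {
  if (nrow(index) == 0) return(list())
  key <- index$target_index * 2^40 + index$position
  wlo <- target * 2^40 + start
  whi <- target * 2^40 + end
  w <- which(key <= wlo)
  first <- if (length(w)) max(w) else 1L
  out <- list()
  for (k in seq(first, nrow(index))) {
    if (key[k] >= whi) break
    ch <- scan_next_chunk(container, index$offset[k], "alignment")
    if (is.null(ch)) break
    for (e in ch$entries) {
      if (e$target_index == target && e$position < end &&
          e$position + e$target_aligned_length > start) {
        out[[length(out) + 1L]] <- e
      }
    }
  }
  out
}

# --- query index permutation (Tier III) -----------------------------------

#' Permute query indices to genomic order
#'
#' Sorting an alignment shuffles query indices; compressing a sequence of
#' uniformly distributed 32-bit integers costs 32 bits each. Permuting the
#' original indices to small indices that increase monotonically in genomic
#' order (first occurrence order: 0, 1, 2, ...) shrinks the range so the
#' minimal binary code for the column gets cheap. All fragments of one read
#' share one small index. The permutation map (Tier III) recovers the
#' original index for any small index.
#'
#' @param entries genomically sorted alignment entries.
#' @return `list(entries, map)`; `map` is a data frame with columns
#'   `small` and `original`.
#' @export
permute_query_indices <- function(entries) {
  qi <- vnum(entries, "query_index")
  originals <- unique(qi)
  small <- match(qi, originals) - 1L
  for (i in seq_along(entries)) entries[[i]]$query_index <- small[i]
  list(entries = entries,
       map = data.frame(small = seq_along(originals) - 1L,
                        original = originals))
}

#' Write and query a permutation file
#'
#' The `.perm` layout is block-structured for partial lookup: a 12-byte
#' header (magic "PRM1", entry count, block size) followed by fixed-width
#' 4-byte big-endian original indices ordered by small index. A lookup reads
#' only the bytes of the block containing the requested small index, never
#' the whole map.
#'
#' @param map permutation data frame from [permute_query_indices()].
#' @param file output path.
#' @param block_size entries per lookup block.
#' @export
write_permutation_file <- function(map, file, block_size = 1024L) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PRM1"), con)
  writeBin(do.call(c, lapply(c(nrow(map), block_size),
                             function(v) u32_be(v))), con)
  ord <- order(map$small)
  writeBin(do.call(c, lapply(map$original[ord], u32_be)), con)
  invisible(file)
}

#' @rdname write_permutation_file
#' @param small small index (0-based) to look up.
#' @export
perm_lookup <- function(file, small) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "PRM1")) stop("not a permutation file")
  n <- rd_u32_be(readBin(con, "raw", 4))
  block <- rd_u32_be(readBin(con, "raw", 4))
  vapply(small, function(s) {
    if (s < 0 || s >= n) stop("small index ", s, " out of range")
    blk <- s %/% block
    seek(con, 12 + 4 * blk * block)
    vals <- readBin(con, "raw", 4 * min(block, n - blk * block))
    rd_u32_be(vals[(4 * (s %% block) + 1):(4 * (s %% block) + 4)])
  }, numeric(1))
}

# --- Tier II file set -----------------------------------------------------

#' Write and read a Tier II file set
#'
#' `basename.entries` is a chunked container, `basename.header` a JSON
#' header with the target dictionary, `basename.index` a tab-separated
#' chunk-level genomic index, and `basename.tmh` the too-many-hits query
#' index list (one per line; only written when non-empty).
#'
#' @param imported result of [import_sam()] (or a compatible list with
#'   `entries`, `header`, `tmh`).
#' @param basename path prefix for the file set.
#' @param codec,chunk_size,options passed to [write_collection()].
#' @export
write_tier2 <- function(imported, basename, codec = "hybrid-1",
                        chunk_size = 100000L,
                        options = list(template = TRUE, domain = TRUE)) {
  res <- write_collection(imported$entries, paste0(basename, ".entries"),
                          codec = codec, schema = "alignment",
                          chunk_size = chunk_size, options = options)
  h <- imported$header
  jsonlite::write_json(
    list(target_names = h$target_names, target_lengths = h$target_lengths,
         n_queries = h$n_queries, sorted = h$sorted, version = h$version),
    paste0(basename, ".header"), auto_unbox = TRUE)
  utils::write.table(attr(res, "chunk_table"), paste0(basename, ".index"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(imported$tmh) > 0)
    writeLines(as.character(imported$tmh), paste0(basename, ".tmh"))
  invisible(basename)
}

#' @rdname write_tier2
#' @export
read_tier2 <- function(basename) {
  hj <- jsonlite::read_json(paste0(basename, ".header"), simplifyVector = TRUE)
  header <- alignment_header(hj$target_names, hj$target_lengths,
                             n_queries = hj$n_queries, sorted = hj$sorted,
                             version = hj$version)
  col <- read_collection(paste0(basename, ".entries"), "alignment")
  tmh_file <- paste0(basename, ".tmh")
  tmh <- if (file.exists(tmh_file)) as.integer(readLines(tmh_file)) else integer(0)
  list(entries = col$entries, header = header, tmh = tmh,
       index = utils::read.table(paste0(basename, ".index"), header = TRUE,
                                 sep = "\t"))
}
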