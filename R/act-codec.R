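# The ACT (Arithmetic Coding and Template) hybrid chunk codec.
#
# A chunk of alignment entries is compressed by:
#   1. (domain modeling, optional)   replacing intra-chunk link triples by
#      signed entry-offset deltas;
#   2. (template compression, optional) run-length collapsing consecutive
#      entries whose serialized bodies are byte-identical after removing the
#      fast-changing fields query_index, position and to_quality;
#   3. separate field encoding: transposing records into per-field value
#      lists;
#   4. field modeling: position -> successive deltas, aligned length ->
#      residual against query length;
#   5. per-column entropy coding through the list codecs.
# Fields unknown to this codec ride a gzip-compressed Left-Over stream of
# residual records keyed by chunk ordinal. The payload layout is documented
# byte-by-byte in inst/docs/FORMAT.md.

vnum <- function(entries, field) vapply(entries, `[[`, integer(1), field)
vlog <- function(entries, field) vapply(entries, `[[`, logical(1), field)
vdbl <- function(entries, field) vapply(entries, `[[`, numeric(1), field)

opt_present <- function(entries, field) {
  !vapply(entries, function(e) is.null(e[[field]]), logical(1))
}

#' Replace intra-chunk link triples with entry-offset deltas
#'
#' For a link from entry `i` to entry `j` in the same chunk, the triple
#' (position, target index, fragment index) is replaced by the signed delta
#' `j - i`. Links whose triple matches no entry in the chunk (cross-chunk
#' links) or more than one entry (ambiguous; losslessness first) keep the
#' explicit triple. [restore_links()] is the exact inverse.
#'
#' @param entries list of alignment entries in final chunk order.
#' @return The entries with optimizable links in delta form.
#' @export
optimize_links <- function(entries) {
  n <- length(entries)
  if (n == 0) return(entries)
  keys <- sprintf("%d:%d:%d", vnum(entries, "target_index"),
                  vnum(entries, "position"), vnum(entries, "fragment_index"))
  # Several entries may share a triple (duplicate reads). Restoration only
  # reproduces the triple itself, which is equal for every candidate, so any
  # resolution is lossless; candidates are paired by occurrence rank (the
  # k-th link to a triple resolves to the k-th entry with that triple) so
  # that duplicate reads get identical deltas and stay template-compressible.
  rank_within <- function(x) {
    o <- order(x)
    r <- integer(length(x))
    r[o] <- sequence(rle(x[o])$lengths)
    r
  }
  keys2 <- paste0(keys, "#", rank_within(keys))
  link_key <- function(l) {
    if (is.null(l) || is_delta_link(l)) NA_character_
    else sprintf("%d:%d:%d", l$target_index, l$position, l$fragment_index)
  }
  for (field in c("pair_link", "splice_forward_link", "splice_backward_link")) {
    lk <- vapply(entries, function(e) link_key(e[[field]]), character(1))
    j <- match(paste0(lk, "#", rank_within(lk)), keys2)
    j0 <- match(lk, keys)          # rank overflow: fall back to first match
    j[is.na(j)] <- j0[is.na(j)]
    hit <- which(!is.na(j) & j != seq_len(n))
    for (i in hit) {
      entries[[i]][[field]] <- entry_link(delta = j[i] - i)
    }
  }
  entries
}

#' @rdname optimize_links
#' @export
restore_links <- function(entries) {
  n <- length(entries)
  if (n == 0) return(entries)
  pos <- vnum(entries, "position")
  ti <- vnum(entries, "target_index")
  fi <- vnum(entries, "fragment_index")
  back <- function(link, i) {
    if (!is_delta_link(link)) return(link)
    j <- i + link$delta
    if (j < 1 || j > n) stop("link delta points outside the chunk")
    entry_link(position = pos[j], target_index = ti[j], fragment_index = fi[j])
  }
  for (i in seq_len(n)) {
    e <- entries[[i]]
    e["pair_link"] <- list(back(e$pair_link, i))
    e["splice_forward_link"] <- list(back(e$splice_forward_link, i))
    e["splice_backward_link"] <- list(back(e$splice_backward_link, i))
    entries[[i]] <- e
  }
  entries
}

#' Template compression of a chunk
#'
#' Removes the non-template fields (query index, position, to-quality) from
#' each entry and run-length collapses consecutive entries whose remaining
#' serialized bodies are byte-identical. Non-template field values are kept
#' per entry; template fields are emitted once per run together with the
#' repetition count. `sum(counts)` always equals the entry count, and
#' [template_expand()] reproduces the input order exactly.
#'
#' @param entries list of alignment entries.
#' @return `list(counts, templates, query_index, position, to_quality)`
#'   where `templates` holds the first entry of each run.
#' @export
template_compress <- function(entries) {
  counts <- .template_runs(entries)
  starts <- cumsum(c(1L, counts))[seq_along(counts)]
  list(counts = counts,
       templates = entries[starts],
       query_index = vnum(entries, "query_index"),
       position = vnum(entries, "position"),
       to_quality = lapply(entries, `[[`, "to_quality"))
}

#' @rdname template_compress
#' @param tc result of `template_compress()`.
#' @export
template_expand <- function(tc) {
  rows <- rep(seq_along(tc$counts), tc$counts)
  n <- length(rows)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e <- tc$templates[[rows[i]]]
    e$query_index <- as.integer(tc$query_index[i])
    e$position <- as.integer(tc$position[i])
    e["to_quality"] <- list(tc$to_quality[[i]])
    out[[i]] <- e
  }
  out
}

#' Field modeling transforms
#'
#' Expresses designated fields as residuals against predictions from other
#' fields: the position column becomes successive deltas within the chunk
#' (sorted input yields small non-negative deltas), the query aligned length
#' becomes its difference from the query length (a perfect prediction for
#' unclipped, uninserted alignments), and the target aligned length becomes
#' its difference from the query aligned length (zero unless indels or
#' splice structure intervene). `unmodel_fields()` is the exact inverse.
#'
#' @param columns named list with `position`, `query_length`,
#'   `query_aligned_length` and `target_aligned_length` numeric columns.
#' @export
model_fields <- function(columns) {
  p <- columns$position
  if (length(p) > 0) columns$position <- c(p[1], diff(p))
  columns$target_aligned_length <-
    columns$target_aligned_length - columns$query_aligned_length
  columns$query_aligned_length <- columns$query_length - columns$query_aligned_length
  columns
}

#' @rdname model_fields
#' @export
unmodel_fields <- function(columns) {
  columns$position <- cumsum(columns$position)
  columns$query_aligned_length <- columns$query_length - columns$query_aligned_length
  columns$target_aligned_length <-
    columns$target_aligned_length + columns$query_aligned_length
  columns
}

# flatten an optional byte-list field into presence + lengths + values
bytes_columns <- function(values_list, present) {
  kept <- values_list[present]
  list(present = present,
       lengths = as.numeric(lengths(kept)),
       values = as.numeric(unlist(kept, use.names = FALSE)))
}

bytes_rebuild <- function(present, lens, values) {
  out <- vector("list", length(present))
  if (any(present)) {
    grp <- rep(seq_along(lens), lens)
    split_vals <- split(as.integer(values), factor(grp, levels = seq_along(lens)))
    out[which(present)] <- lapply(split_vals, as.integer)
  }
  out
}

link_columns <- function(entries, field) {
  links <- lapply(entries, `[[`, field)
  kind <- vapply(links, function(l) {
    if (is.null(l)) 0L else if (is_delta_link(l)) 2L else 1L
  }, integer(1))
  triples <- links[kind == 1L]
  list(kind = kind,
       position = vapply(triples, `[[`, integer(1), "position"),
       target_index = vapply(triples, `[[`, integer(1), "target_index"),
       fragment_index = vapply(triples, `[[`, integer(1), "fragment_index"),
       delta = vapply(links[kind == 2L], `[[`, integer(1), "delta"))
}

link_rebuild <- function(kind, position, target_index, fragment_index, delta) {
  out <- vector("list", length(kind))
  it <- 0L
  id <- 0L
  for (i in seq_along(kind)) {
    if (kind[i] == 1L) {
      it <- it + 1L
      out[[i]] <- list(position = as.integer(position[it]),
                       target_index = as.integer(target_index[it]),
                       fragment_index = as.integer(fragment_index[it]))
    } else if (kind[i] == 2L) {
      id <- id + 1L
      out[[i]] <- list(delta = as.integer(delta[id]))
    }
  }
  out
}

#' Decompose a chunk into field columns and residual records
#'
#' Separate field encoding: every recognized field value is collected into
#' exactly one per-field column, in entry order. Nested messages contribute a
#' per-entry count column plus flattened field columns (an entry with three
#' sequence variations adds 3 to the count column and three values to each
#' variation column). Entries that carry bytes unknown to this codec emit a
#' residual record holding their chunk ordinal and payload.
#'
#' @param entries list of alignment entries.
#' @return `list(columns, leftovers)`; `recompose_chunk()` inverts.
#' @export
decompose_chunk <- function(entries) {
  n <- length(entries)
  toq <- lapply(entries, `[[`, "to_quality")
  toq_present <- !vapply(toq, is.null, logical(1))
  vars <- lapply(entries, `[[`, "sequence_variations")
  flat <- unlist(vars, recursive = FALSE, use.names = FALSE)
  if (is.null(flat)) flat <- list()
  var_toq <- lapply(flat, `[[`, "to_quality")
  var_toq_present <- !vapply(var_toq, is.null, logical(1))
  scl_present <- opt_present(entries, "softclip_left")
  scr_present <- opt_present(entries, "softclip_right")
  sclq <- lapply(entries, `[[`, "softclip_left_quality")
  scrq <- lapply(entries, `[[`, "softclip_right_quality")
  ro_present <- opt_present(entries, "read_origin_index")

  columns <- list(
    n = n,
    query_index = vnum(entries, "query_index"),
    position = vnum(entries, "position"),
    to_quality = bytes_columns(toq, toq_present),
    target_index = vnum(entries, "target_index"),
    fragment_index = vnum(entries, "fragment_index"),
    matching_reverse_strand = vlog(entries, "matching_reverse_strand"),
    query_length = vnum(entries, "query_length"),
    query_aligned_length = vnum(entries, "query_aligned_length"),
    target_aligned_length = vnum(entries, "target_aligned_length"),
    mapping_quality = vnum(entries, "mapping_quality"),
    score = vdbl(entries, "score"),
    var_count = as.numeric(lengths(vars)),
    var_position = vapply(flat, `[[`, integer(1), "position"),
    var_read_index = vapply(flat, `[[`, integer(1), "read_index"),
    var_from = vapply(flat, `[[`, character(1), "from"),
    var_to = vapply(flat, `[[`, character(1), "to"),
    var_to_quality = bytes_columns(var_toq, var_toq_present),
    pair_link = link_columns(entries, "pair_link"),
    splice_forward_link = link_columns(entries, "splice_forward_link"),
    splice_backward_link = link_columns(entries, "splice_backward_link"),
    softclip_left = list(present = scl_present,
                         text = vapply(entries[scl_present], `[[`, character(1), "softclip_left")),
    softclip_left_quality = bytes_columns(sclq, !vapply(sclq, is.null, logical(1))),
    softclip_right = list(present = scr_present,
                          text = vapply(entries[scr_present], `[[`, character(1), "softclip_right")),
    softclip_right_quality = bytes_columns(scrq, !vapply(scrq, is.null, logical(1))),
    read_origin_index = list(present = ro_present,
                             values = vnum(entries[ro_present], "read_origin_index"))
  )
  ufl <- lapply(entries, `[[`, "unknown_fields")
  has <- which(lengths(ufl) > 0)
  leftovers <- lapply(has, function(i) list(ordinal = i - 1L, payload = ufl[[i]]))
  list(columns = columns, leftovers = leftovers)
}

#' @rdname decompose_chunk
#' @param columns,leftovers as returned by `decompose_chunk()`.
#' @export
recompose_chunk <- function(columns, leftovers = list()) {
  cl <- columns
  n <- cl$n
  toq <- bytes_rebuild(cl$to_quality$present, cl$to_quality$lengths, cl$to_quality$values)
  vtoq <- bytes_rebuild(cl$var_to_quality$present, cl$var_to_quality$lengths,
                        cl$var_to_quality$values)
  nvar <- length(cl$var_position)
  flat_vars <- vector("list", nvar)
  for (j in seq_len(nvar)) {
    flat_vars[[j]] <- list(position = as.integer(cl$var_position[j]),
                           read_index = as.integer(cl$var_read_index[j]),
                           from = cl$var_from[j], to = cl$var_to[j],
                           to_quality = vtoq[[j]])
  }
  var_grp <- rep(seq_len(n), cl$var_count)
  vars_by_entry <- split(flat_vars, factor(var_grp, levels = seq_len(n)))
  pls <- link_rebuild(cl$pair_link$kind, cl$pair_link$position,
                      cl$pair_link$target_index, cl$pair_link$fragment_index,
                      cl$pair_link$delta)
  spf <- link_rebuild(cl$splice_forward_link$kind, cl$splice_forward_link$position,
                      cl$splice_forward_link$target_index,
                      cl$splice_forward_link$fragment_index, cl$splice_forward_link$delta)
  spb <- link_rebuild(cl$splice_backward_link$kind, cl$splice_backward_link$position,
                      cl$splice_backward_link$target_index,
                      cl$splice_backward_link$fragment_index, cl$splice_backward_link$delta)
  scl <- rep(NA_character_, n)
  scl[cl$softclip_left$present] <- cl$softclip_left$text
  scr <- rep(NA_character_, n)
  scr[cl$softclip_right$present] <- cl$softclip_right$text
  sclq <- bytes_rebuild(cl$softclip_left_quality$present,
                        cl$softclip_left_quality$lengths, cl$softclip_left_quality$values)
  scrq <- bytes_rebuild(cl$softclip_right_quality$present,
                        cl$softclip_right_quality$lengths, cl$softclip_right_quality$values)
  ro <- rep(NA_integer_, n)
  ro[cl$read_origin_index$present] <- as.integer(cl$read_origin_index$values)

  qi <- as.integer(cl$query_index)
  pos <- as.integer(cl$position)
  ti <- as.integer(cl$target_index)
  fi <- as.integer(cl$fragment_index)
  strand <- cl$matching_reverse_strand
  ql <- as.integer(cl$query_length)
  qal <- as.integer(cl$query_aligned_length)
  tal <- as.integer(cl$target_aligned_length)
  mq <- as.integer(cl$mapping_quality)
  sc <- cl$score

  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- list(
      query_index = qi[i], target_index = ti[i], position = pos[i],
      fragment_index = fi[i], matching_reverse_strand = strand[i],
      query_length = ql[i], query_aligned_length = qal[i],
      target_aligned_length = tal[i], mapping_quality = mq[i], score = sc[i],
      sequence_variations = vars_by_entry[[i]],
      pair_link = pls[[i]], splice_forward_link = spf[[i]],
      splice_backward_link = spb[[i]],
      softclip_left = if (is.na(scl[i])) NULL else scl[i],
      softclip_left_quality = sclq[[i]],
      softclip_right = if (is.na(scr[i])) NULL else scr[i],
      softclip_right_quality = scrq[[i]],
      to_quality = toq[[i]],
      read_origin_index = if (is.na(ro[i])) NULL else ro[i],
      unknown_fields = raw(0)
    )
  }
  for (lo in leftovers) {
    out[[lo$ordinal + 1L]]$unknown_fields <- lo$payload
  }
  out
}

# --- bit-stream schedule for the column set -------------------------------

wr_bytescol <- function(sink, bc) {
  wr_bool_list(sink, bc$present)
  wr_int_list(sink, bc$lengths)
  wr_int_list(sink, bc$values)
}

rd_bytescol <- function(source) {
  present <- rd_bool_list(source)
  lengths <- rd_int_list(source)
  values <- rd_int_list(source)
  list(present = present, lengths = lengths, values = values)
}

wr_linkcol <- function(sink, lc) {
  wr_int_list(sink, lc$kind)
  wr_int_list(sink, lc$position)
  wr_int_list(sink, lc$target_index)
  wr_int_list(sink, lc$fragment_index)
  wr_int_list(sink, lc$delta)
}

rd_linkcol <- function(source) {
  list(kind = rd_int_list(source), position = rd_int_list(source),
       target_index = rd_int_list(source), fragment_index = rd_int_list(source),
       delta = rd_int_list(source))
}

wr_query_index <- function(sink, qi) {
  # uniform-distribution field: rebase by the minimum and use minimal binary
  if (length(qi) == 0) return(invisible(NULL))
  min_q <- min(qi)
  reb <- qi - min_q
  m <- bit_width(max(reb))
  nibble_encode(c(min_q, m), sink)
  minimal_binary_encode(reb, m, sink)
}

rd_query_index <- function(source, n) {
  if (n == 0) return(numeric(0))
  hdr <- nibble_decode(source, 2)
  minimal_binary_decode(source, n, hdr[2]) + hdr[1]
}

encode_act_stream <- function(entries, template, domain) {
  sink <- bit_sink()
  n <- length(entries)
  nibble_encode(n, sink)
  write_bits(sink, as.numeric(template), 1)
  write_bits(sink, as.numeric(domain), 1)

  if (template) {
    tc <- template_compress(entries)
    counts <- as.numeric(tc$counts)
    rows <- tc$templates
    qi <- tc$query_index
    pos <- tc$position
    toq <- tc$to_quality
    wr_int_list(sink, counts)
  } else {
    rows <- entries
    qi <- vnum(entries, "query_index")
    pos <- vnum(entries, "position")
    toq <- lapply(entries, `[[`, "to_quality")
  }

  wr_query_index(sink, qi)
  # modeled position: successive deltas
  wr_int_list(sink, if (n > 0) c(pos[1], diff(pos)) else numeric(0))
  wr_bytescol(sink, bytes_columns(toq, !vapply(toq, is.null, logical(1))))

  cols <- decompose_chunk(rows)$columns
  wr_int_list(sink, cols$target_index)
  wr_int_list(sink, cols$fragment_index)
  wr_bool_list(sink, cols$matching_reverse_strand)
  wr_int_list(sink, cols$query_length)
  wr_int_list(sink, cols$query_length - cols$query_aligned_length)  # modeled residual
  wr_int_list(sink, cols$target_aligned_length - cols$query_aligned_length)
  wr_int_list(sink, cols$mapping_quality)
  wr_float_list(sink, cols$score)
  wr_int_list(sink, cols$var_count)
  wr_int_list(sink, cols$var_position)
  wr_int_list(sink, cols$var_read_index)
  wr_string_list(sink, cols$var_from)
  wr_string_list(sink, cols$var_to)
  wr_bytescol(sink, cols$var_to_quality)
  wr_linkcol(sink, cols$pair_link)
  wr_linkcol(sink, cols$splice_forward_link)
  wr_linkcol(sink, cols$splice_backward_link)
  wr_bool_list(sink, cols$softclip_left$present)
  wr_string_list(sink, cols$softclip_left$text)
  wr_bytescol(sink, cols$softclip_left_quality)
  wr_bool_list(sink, cols$softclip_right$present)
  wr_string_list(sink, cols$softclip_right$text)
  wr_bytescol(sink, cols$softclip_right_quality)
  wr_bool_list(sink, cols$read_origin_index$present)
  wr_int_list(sink, cols$read_origin_index$values)
  sink_bytes(sink)
}

decode_act_stream <- function(bytes) {
  src <- bit_source(bytes)
  n <- nibble_decode(src, 1)
  template <- read_bits(src, 1) == 1
  domain <- read_bits(src, 1) == 1
  counts <- if (template) rd_int_list(src) else NULL
  if (template && sum(counts) != n) stop("template counts do not sum to entry count")
  qi <- rd_query_index(src, n)
  pos_delta <- rd_int_list(src)
  pos <- cumsum(pos_delta)
  toq_bc <- rd_bytescol(src)
  toq <- bytes_rebuild(toq_bc$present, toq_bc$lengths, toq_bc$values)

  nrows <- if (template) length(counts) else n
  columns <- list(n = nrows)
  columns$query_index <- rep(0, nrows)   # placeholder, replaced per entry
  columns$position <- rep(0, nrows)
  columns$to_quality <- list(present = rep(FALSE, nrows), lengths = numeric(0),
                             values = numeric(0))
  columns$target_index <- rd_int_list(src)
  columns$fragment_index <- rd_int_list(src)
  columns$matching_reverse_strand <- rd_bool_list(src)
  columns$query_length <- rd_int_list(src)
  qal_resid <- rd_int_list(src)
  columns$query_aligned_length <- columns$query_length - qal_resid
  columns$target_aligned_length <- rd_int_list(src) + columns$query_aligned_length
  columns$mapping_quality <- rd_int_list(src)
  columns$score <- rd_float_list(src)
  columns$var_count <- rd_int_list(src)
  columns$var_position <- rd_int_list(src)
  columns$var_read_index <- rd_int_list(src)
  columns$var_from <- rd_string_list(src)
  columns$var_to <- rd_string_list(src)
  columns$var_to_quality <- rd_bytescol(src)
  columns$pair_link <- rd_linkcol(src)
  columns$splice_forward_link <- rd_linkcol(src)
  columns$splice_backward_link <- rd_linkcol(src)
  scl_present <- rd_bool_list(src)
  columns$softclip_left <- list(present = scl_present, text = rd_string_list(src))
  columns$softclip_left_quality <- rd_bytescol(src)
  scr_present <- rd_bool_list(src)
  columns$softclip_right <- list(present = scr_present, text = rd_string_list(src))
  columns$softclip_right_quality <- rd_bytescol(src)
  ro_present <- rd_bool_list(src)
  columns$read_origin_index <- list(present = ro_present, values = rd_int_list(src))

  if (template) {
    rows <- recompose_chunk(columns)
    entries <- template_expand(list(counts = counts, templates = rows,
                                    query_index = qi, position = pos,
                                    to_quality = toq))
  } else {
    columns$query_index <- qi
    columns$position <- pos
    columns$to_quality <- toq_bc
    entries <- recompose_chunk(columns)
  }
  list(entries = entries, template = template, domain = domain)
}

encode_leftover_stream <- function(leftovers) {
  if (length(leftovers) == 0) return(raw(0))
  parts <- list(encode_varint(length(leftovers)))
  for (lo in leftovers) {
    parts <- c(parts, list(encode_varint(lo$ordinal),
                           encode_varint(length(lo$payload)), lo$payload))
  }
  memCompress(do.call(c, parts), type = "gzip")
}

decode_varint_raw <- function(bytes, pos) {
  v <- 0
  shift <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    v <- v + (b %% 128) * 2^shift
    if (b < 128) break
    shift <- shift + 7
  }
  list(value = v, pos = pos)
}

decode_leftover_stream <- function(bytes) {
  if (length(bytes) == 0) return(list())
  buf <- memDecompress(bytes, type = "gzip")
  p <- decode_varint_raw(buf, 1L)
  count <- p$value
  pos <- p$pos
  out <- vector("list", count)
  for (i in seq_len(count)) {
    p <- decode_varint_raw(buf, pos)
    ordinal <- p$value
    p <- decode_varint_raw(buf, p$pos)
    len <- p$value
    pos <- p$pos + len
    out[[i]] <- list(ordinal = as.integer(ordinal),
                     payload = buf[seq.int(p$pos, length.out = len)])
  }
  out
}

#' Compress and decompress a chunk with the hybrid ACT codec
#'
#' `template = FALSE, domain = FALSE` is the H method; enabling template
#' compression gives H+T, and both flags give H+T+D. The options are
#' recorded in the payload header, so `decompress_chunk()` needs no
#' arguments beyond the payload. Round trips are lossless for every field,
#' including unknown-field payloads and link triples.
#'
#' @param entries list of alignment entries (at most the container chunk
#'   size).
#' @param template enable template compression.
#' @param domain enable domain modeling (intra-chunk link optimization).
#' @return `compress_chunk()` returns the raw hybrid payload;
#'   `decompress_chunk()` the original entries.
#' @export
compress_chunk <- function(entries, template = FALSE, domain = FALSE) {
  if (domain) entries <- optimize_links(entries)
  ufl <- lapply(entries, `[[`, "unknown_fields")
  has <- which(lengths(ufl) > 0)
  leftovers <- lapply(has, function(i) list(ordinal = i - 1L, payload = ufl[[i]]))
  act <- encode_act_stream(entries, template, domain)
  left <- encode_leftover_stream(leftovers)
  flags <- as.raw(as.integer(template) + 2L * as.integer(domain))
  c(flags, encode_varint(length(act)), act,
    encode_varint(length(left)), left)
}

#' @rdname compress_chunk
#' @param payload raw vector produced by `compress_chunk()`.
#' @export
decompress_chunk <- function(payload) {
  if (length(payload) < 3) stop("truncated hybrid payload")
  flags <- as.integer(payload[1])
  p <- decode_varint_raw(payload, 2L)
  if (p$pos + p$value - 1L > length(payload)) stop("truncated hybrid payload")
  act <- payload[seq.int(p$pos, length.out = p$value)]
  p <- decode_varint_raw(payload, p$pos + p$value)
  if (p$pos + p$value - 1L > length(payload)) stop("truncated hybrid payload")
  left <- if (p$value > 0) payload[seq.int(p$pos, length.out = p$value)] else raw(0)
  dec <- decode_act_stream(act)
  if (dec$template != (bitwAnd(flags, 1L) == 1L) ||
      dec$domain != (bitwAnd(flags, 2L) == 2L))
    stop("payload options flag mismatch between header and ACT stream")
  entries <- dec$entries
  for (lo in decode_leftover_stream(left)) {
    entries[[lo$ordinal + 1L]]$unknown_fields <- lo$payload
  }
  if (dec$domain) entries <- restore_links(entries)
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a
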