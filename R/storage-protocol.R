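# Chunked container framing with codec registration and semi-random access.
#
# Frame layout (inst/docs/FORMAT.md):
#   delimiter        8 x 0xFF
#   codec code       1 byte
#   payload length   4 bytes, big-endian, >= 1
#   payload          length bytes
#   checksum         CRC32 of the payload, 4 bytes big-endian
# Termination: delimiter followed by 4 x 0x00 immediately before end of
# file. Because payload bytes may mimic the delimiter, readers verify each
# candidate frame (length plausibility, checksum, codec registration,
# decompression) and resume scanning on failure.

DELIMITER <- as.raw(rep(0xFF, 8))
TERMINATOR <- c(as.raw(rep(0xFF, 8)), as.raw(rep(0x00, 4)))

u32_be <- function(v) {
  as.raw(c(v %/% 2^24, (v %/% 2^16) %% 256, (v %/% 2^8) %% 256, v %% 256))
}

rd_u32_be <- function(bytes) {
  b <- as.integer(bytes)
  b[1] * 2^24 + b[2] * 2^16 + b[3] * 2^8 + b[4]
}

# --- codec registry -------------------------------------------------------

.codecs <- new.env(parent = emptyenv())

#' Register or list chunk codecs
#'
#' Codecs are pluggable compress/decompress implementations identified by a
#' one-byte registration code stored at the start of every chunk frame.
#' Built-ins: 0 = gzip, 1 = bzip2 (whole-chunk general compression of the
#' serialized records) and 2 = hybrid-1 (the ACT codec; alignment schema
#' only). Codes 0-31 are reserved for the package.
#'
#' @param code integer registration code (0-255), stable across versions.
#' @param name codec name used in user interfaces.
#' @param compress `function(entries, schema, options) -> raw`.
#' @param decompress `function(payload, schema) -> entries`.
#' @export
register_codec <- function(code, name, compress, decompress) {
  .codecs[[as.character(code)]] <- list(code = as.integer(code), name = name,
                                        compress = compress,
                                        decompress = decompress)
  invisible(name)
}

#' @rdname register_codec
#' @export
codec_registry <- function() {
  codes <- sort(as.integer(ls(.codecs)))
  do.call(rbind, lapply(codes, function(cd) {
    data.frame(code = cd, name = .codecs[[as.character(cd)]]$name)
  }))
}

codec_by_code <- function(code) {
  c <- .codecs[[as.character(as.integer(code))]]
  if (is.null(c)) {
    known <- paste(codec_registry()$name, collapse = ", ")
    stop(sprintf("unknown codec registration code %d (registered: %s)",
                 as.integer(code), known))
  }
  c
}

codec_by_name <- function(name) {
  for (cd in ls(.codecs)) {
    if (.codecs[[cd]]$name == name) return(.codecs[[cd]])
  }
  known <- paste(codec_registry()$name, collapse = ", ")
  stop(sprintf("unknown codec '%s' (registered: %s)", name, known))
}

schema_serialize <- function(entries, schema) {
  switch(schema,
         alignment = .serialize_entries(entries),
         reads = .serialize_reads(entries),
         stop("unknown schema: ", schema))
}

schema_deserialize <- function(bytes, schema) {
  switch(schema,
         alignment = .deserialize_entries(bytes),
         reads = .deserialize_reads(bytes),
         stop("unknown schema: ", schema))
}

register_builtin_codecs <- function() {
  register_codec(0L, "gzip",
    compress = function(entries, schema, options) {
      memCompress(schema_serialize(entries, schema), type = "gzip")
    },
    decompress = function(payload, schema) {
      schema_deserialize(memDecompress(payload, type = "gzip"), schema)
    })
  register_codec(1L, "bzip2",
    compress = function(entries, schema, options) {
      memCompress(schema_serialize(entries, schema), type = "bzip2")
    },
    decompress = function(payload, schema) {
      schema_deserialize(memDecompress(payload, type = "bzip2"), schema)
    })
  register_codec(2L, "hybrid-1",
    compress = function(entries, schema, options) {
      if (!identical(schema, "alignment"))
        stop("the hybrid-1 ACT codec is implemented for the alignment schema only")
      compress_chunk(entries, template = isTRUE(options$template),
                     domain = isTRUE(options$domain))
    },
    decompress = function(payload, schema) {
      if (!identical(schema, "alignment"))
        stop("the hybrid-1 ACT codec is implemented for the alignment schema only")
      decompress_chunk(payload)
    })
}

#' Compress a serialized chunk with a general scheme
#'
#' The gzip and bzip2 whole-chunk codecs: standard stream compression of the
#' concatenated record serialization.
#'
#' @param bytes serialized chunk (raw).
#' @param scheme `"gzip"` or `"bzip2"`.
#' @export
compress_payload_general <- function(bytes, scheme = c("gzip", "bzip2")) {
  scheme <- match.arg(scheme)
  memCompress(bytes, type = scheme)
}

#' @rdname compress_payload_general
#' @param payload compressed raw vector.
#' @export
decompress_payload_general <- function(payload, scheme = c("gzip", "bzip2")) {
  scheme <- match.arg(scheme)
  memDecompress(payload, type = scheme)
}

# --- container writing ----------------------------------------------------

frame_chunk <- function(payload, code) {
  stopifnot(length(payload) >= 1)
  c(DELIMITER, as.raw(code), u32_be(length(payload)), payload,
    u32_be(.crc32(payload)))
}

#' Write a collection of records as a chunked container
#'
#' Splits the collection into chunks of at most `chunk_size` records, each
#' compressed independently with the selected codec and framed for
#' semi-random access, followed by the termination chunk. A collection of N
#' records yields `ceiling(N / chunk_size)` frames.
#'
#' @param entries list of records ([alignment_entry()] or [read_entry()]).
#' @param file output path, or `NULL` to return the container as a raw
#'   vector.
#' @param codec codec name (see [codec_registry()]).
#' @param schema `"alignment"` or `"reads"`.
#' @param chunk_size maximum records per chunk (benchmark default 100,000).
#' @param options codec options: `template` and `domain` flags for
#'   hybrid-1.
#' @return The file path (invisibly), or the raw container when
#'   `file = NULL`. The chunk table is attached as attribute
#'   `chunk_table`: one row per chunk with its byte offset and the
#'   (target, position) of its first record, the raw material of a genomic
#'   index.
#' @export
write_collection <- function(entries, file = NULL, codec = "gzip",
                             schema = c("alignment", "reads"),
                             chunk_size = 100000L, options = list()) {
  schema <- match.arg(schema)
  stopifnot(chunk_size >= 1)
  cd <- codec_by_name(codec)
  n <- length(entries)
  nchunks <- if (n == 0) 0L else ceiling(n / chunk_size)
  frames <- vector("list", nchunks)
  offs <- numeric(nchunks)
  first_target <- integer(nchunks)
  first_pos <- integer(nchunks)
  nrec <- integer(nchunks)
  off <- 0
  for (k in seq_len(nchunks)) {
    lo <- (k - 1L) * chunk_size + 1L
    hi <- min(n, k * chunk_size)
    chunk <- entries[lo:hi]
    payload <- cd$compress(chunk, schema, options)
    frames[[k]] <- frame_chunk(payload, cd$code)
    offs[k] <- off
    nrec[k] <- hi - lo + 1L
    if (schema == "alignment") {
      first_target[k] <- chunk[[1]]$target_index
      first_pos[k] <- chunk[[1]]$position
    }
    off <- off + length(frames[[k]])
  }
  container <- c(do.call(c, c(frames, list(raw(0)))), TERMINATOR)
  tab <- data.frame(chunk = seq_len(nchunks), offset = offs,
                    n_records = nrec,
                    target_index = first_target, position = first_pos)
  if (is.null(file)) {
    attr(container, "chunk_table") <- tab
    return(container)
  }
  writeBin(container, file)
  invisible(structure(file, chunk_table = tab))
}

# --- scanning and reading -------------------------------------------------

delimiter_candidates <- function(bytes, from = 0) {
  # positions (0-based) where 8 consecutive 0xFF start, at or after `from`
  is_ff <- bytes == as.raw(0xFF)
  if (!any(is_ff)) return(numeric(0))
  r <- rle(is_ff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- numeric(0)
  for (i in which(r$values & r$lengths >= 8)) {
    out <- c(out, seq(starts[i], ends[i] - 7))
  }
  out <- out - 1   # 0-based
  out[out >= from]
}

#' Scan for the next decodable chunk
#'
#' Semi-random access: starts at any byte offset, finds the next delimiter,
#' and verifies the candidate frame (length, checksum, codec registration,
#' decompression). A payload byte run that mimics the delimiter is detected
#' as a false positive and scanning resumes. Works directly on an in-memory
#' container (raw vector).
#'
#' @param container raw vector holding a container.
#' @param offset 0-based byte offset to start scanning from.
#' @param schema record schema of the container.
#' @return `list(entries, codec, offset, next_offset)` for the first
#'   verifiable chunk at or after `offset`, or `NULL` when only the
#'   termination chunk remains.
#' @export
scan_next_chunk <- function(container, offset = 0, schema = c("alignment", "reads")) {
  schema <- match.arg(schema)
  total <- length(container)
  for (cand in delimiter_candidates(container, offset)) {
    after <- cand + 8
    # termination: delimiter + four zero bytes immediately before EOF
    if (after + 4 == total &&
        all(container[(after + 1):(after + 4)] == as.raw(0))) {
      return(NULL)
    }
    if (after + 5 > total) next
    code <- as.integer(container[after + 1])
    len <- rd_u32_be(container[(after + 2):(after + 5)])
    if (len < 1 || after + 5 + len + 4 > total) next
    payload <- container[(after + 6):(after + 5 + len)]
    crc <- rd_u32_be(container[(after + 5 + len + 1):(after + 5 + len + 4)])
    if (crc != .crc32(payload)) next
    # a checksum-valid frame is genuine: an unregistered codec here is a
    # loud error, never a silent skip
    cd <- codec_by_code(code)
    entries <- tryCatch(cd$decompress(payload, schema),
                        error = function(e) NULL)
    if (is.null(entries)) next
    return(list(entries = entries, codec = cd$name,
                offset = cand, next_offset = after + 5 + len + 4))
  }
  NULL
}

#' Read back a whole collection
#'
#' @param file path to a container file, or a raw vector.
#' @inheritParams scan_next_chunk
#' @return `list(entries, chunks)` where `chunks` is a data frame with one
#'   row per decoded chunk (offset, codec, record count).
#' @export
read_collection <- function(file, schema = c("alignment", "reads")) {
  schema <- match.arg(schema)
  container <- if (is.raw(file)) file else
    readBin(file, "raw", n = file.size(file))
  entries <- list()
  chunks <- list()
  off <- 0
  repeat {
    ch <- scan_next_chunk(container, off, schema)
    if (is.null(ch)) break
    entries <- c(entries, ch$entries)
    chunks[[length(chunks) + 1L]] <-
      data.frame(offset = ch$offset, codec = ch$codec,
                 n_records = length(ch$entries))
    off <- ch$next_offset
  }
  list(entries = entries,
       chunks = if (length(chunks)) do.call(rbind, chunks)
                else data.frame(offset = numeric(0), codec = character(0),
                                n_records = integer(0)))
}

#' Concatenate two containers
#'
#' Concatenation closure: joining the frame regions of two containers
#' (dropping the first termination) yields a valid container holding both
#' collections in order.
#'
#' @param a,b raw container vectors.
#' @export
concatenate_containers <- function(a, b) {
  stopifnot(length(a) >= length(TERMINATOR),
            all(a[(length(a) - 11):length(a)] == TERMINATOR))
  c(a[seq_len(length(a) - 12)], b)
}
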