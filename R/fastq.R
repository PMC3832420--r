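# Tier I: FASTQ interop and compact-reads containers. FASTQ is read and
# written as plain 4-line records here because no installed R package
# exposes FASTQ qualities; qualities are Phred+33 bytes.

read_fastq_records <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0)
    stop("FASTQ file ", file, " does not contain complete 4-line records")
  n <- length(lines) %/% 4
  idx <- seq_len(n)
  list(id = sub("^@", "", lines[4 * idx - 3]),
       sequence = lines[4 * idx - 2],
       quality = lines[4 * idx])
}

#' Import FASTQ reads as Tier I read entries
#'
#' Assigns sequential query indices (0, 1, 2, ...) in file order. For
#' paired input the two files must be congruent record for record; mate
#' bases and qualities are stored on the same read entry.
#'
#' @param file FASTQ path (single-end, or mate 1 of a pair).
#' @param pair_file optional FASTQ path for mate 2.
#' @param keep_identifiers store the FASTQ identifiers (off by default:
#'   read identity is the query index).
#' @return List of [read_entry()] records.
#' @export
import_fastq <- function(file, pair_file = NULL, keep_identifiers = FALSE) {
  r1 <- read_fastq_records(file)
  r2 <- if (!is.null(pair_file)) read_fastq_records(pair_file)
  if (!is.null(r2) && length(r2$sequence) != length(r1$sequence))
    stop("paired FASTQ files differ in record count (",
         length(r1$sequence), " vs ", length(r2$sequence), ")")
  n <- length(r1$sequence)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(r2) && nchar(r2$sequence[i]) != length(qual_bytes(r2$quality[i])))
      stop("pair record ", i, ": sequence and quality lengths differ")
    out[[i]] <- read_entry(
      query_index = i - 1L,
      sequence = r1$sequence[i],
      qualities = qual_bytes(r1$quality[i]),
      pair_sequence = if (!is.null(r2)) r2$sequence[i],
      pair_qualities = if (!is.null(r2)) qual_bytes(r2$quality[i]),
      identifier = if (keep_identifiers) r1$id[i])
  }
  out
}

#' Export read entries back to FASTQ
#'
#' @param reads list of [read_entry()] records.
#' @param file output FASTQ path for the primary mate.
#' @param pair_file optional output path for mate 2 (required when the
#'   entries carry pair data).
#' @export
export_fastq <- function(reads, file, pair_file = NULL) {
  fmt <- function(id, seq, qual) {
    q <- if (is.null(qual)) strrep("I", nchar(seq)) else rawToChar(as.raw(qual + 33L))
    c(paste0("@", id), seq, "+", q)
  }
  l1 <- character(0)
  l2 <- character(0)
  for (r in reads) {
    id <- if (!is.null(r$identifier)) r$identifier else paste0("q", r$query_index)
    l1 <- c(l1, fmt(id, r$sequence, r$qualities))
    if (!is.null(r$pair_sequence)) {
      if (is.null(pair_file))
        stop("entries carry pair data: pair_file is required")
      l2 <- c(l2, fmt(id, r$pair_sequence, r$pair_qualities))
    }
  }
  writeLines(l1, file)
  if (length(l2) > 0) writeLines(l2, pair_file)
  invisible(file)
}

#' Write and read compact-reads containers
#'
#' Tier I reads stored through the chunked storage protocol with a general
#' codec (the ACT codec is alignment-schema only).
#'
#' @param reads list of [read_entry()] records.
#' @param file output path.
#' @param codec `"gzip"` or `"bzip2"`.
#' @param chunk_size records per chunk.
#' @export
write_compact_reads <- function(reads, file, codec = "gzip",
                                chunk_size = 100000L) {
  write_collection(reads, file, codec = codec, schema = "reads",
                   chunk_size = chunk_size)
}

#' @rdname write_compact_reads
#' @export
read_compact_reads <- function(file) {
  read_collection(file, schema = "reads")$entries
}
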