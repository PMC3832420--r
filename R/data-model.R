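# Structured record schema for reads and alignments. Entries are plain named
# lists in a fixed canonical field order (cheap at 10^5-entry chunk scale);
# absent optional fields are NULL. Serialization is a self-describing
# tag-length-value encoding with stable field tags (inst/docs/FORMAT.md), so
# parsers compiled against an older schema carve unrecognized tags into the
# opaque `unknown_fields` buffer and carry them through losslessly.

#' Construct an alignment entry
#'
#' One aligned read fragment. Coordinates are 0-based half-open internally;
#' SAM import/export converts from/to 1-based. `query_index` is the integer
#' that preserves read identity across storage tiers (replacing read names).
#' A spliced or paired read is represented as several entries sharing one
#' `query_index` and distinguished by `fragment_index`, connected by pair and
#' splice links.
#'
#' @param query_index,target_index,position,fragment_index non-negative
#'   integers; `position` is the leftmost aligned reference base (0-based).
#' @param matching_reverse_strand logical flag.
#' @param query_length,query_aligned_length,target_aligned_length read
#'   length, number of aligned read bases, and reference span.
#' @param mapping_quality integer mapping quality.
#' @param score alignment score; stored as a 32-bit float (the constructor
#'   rounds to float32 so that round trips are bit-exact).
#' @param sequence_variations list of [sequence_variation()] records.
#' @param pair_link,splice_forward_link,splice_backward_link optional
#'   [entry_link()] records.
#' @param softclip_left,softclip_right optional soft-clipped bases.
#' @param softclip_left_quality,softclip_right_quality optional quality
#'   bytes for the clipped bases (integer vectors, 0-255).
#' @param to_quality optional quality bytes over all aligned read bases.
#' @param read_origin_index optional reference into the header's read-origin
#'   (read group) table.
#' @param unknown_fields raw vector of schema-evolution payload bytes; see
#'   [set_unknown_field()].
#' @return A named list with the canonical 21-field layout.
#' @export
alignment_entry <- function(query_index = 0L, target_index = 0L, position = 0L,
                            fragment_index = 0L, matching_reverse_strand = FALSE,
                            query_length = 0L, query_aligned_length = 0L,
                            target_aligned_length = 0L, mapping_quality = 0L,
                            score = 0, sequence_variations = list(),
                            pair_link = NULL, splice_forward_link = NULL,
                            splice_backward_link = NULL,
                            softclip_left = NULL, softclip_left_quality = NULL,
                            softclip_right = NULL, softclip_right_quality = NULL,
                            to_quality = NULL, read_origin_index = NULL,
                            unknown_fields = raw(0)) {
  list(
    query_index = as.integer(query_index),
    target_index = as.integer(target_index),
    position = as.integer(position),
    fragment_index = as.integer(fragment_index),
    matching_reverse_strand = as.logical(matching_reverse_strand),
    query_length = as.integer(query_length),
    query_aligned_length = as.integer(query_aligned_length),
    target_aligned_length = as.integer(target_aligned_length),
    mapping_quality = as.integer(mapping_quality),
    score = as_float32(score),
    sequence_variations = sequence_variations,
    pair_link = pair_link,
    splice_forward_link = splice_forward_link,
    splice_backward_link = splice_backward_link,
    softclip_left = softclip_left,
    softclip_left_quality = if (is.null(softclip_left_quality)) NULL else as.integer(softclip_left_quality),
    softclip_right = softclip_right,
    softclip_right_quality = if (is.null(softclip_right_quality)) NULL else as.integer(softclip_right_quality),
    to_quality = if (is.null(to_quality)) NULL else as.integer(to_quality),
    read_origin_index = if (is.null(read_origin_index)) NULL else as.integer(read_origin_index),
    unknown_fields = unknown_fields
  )
}

#' Round a double to 32-bit float precision
#'
#' Alignment scores are stored as IEEE-754 float32 on disk; constructors
#' apply this rounding up front so in-memory records equal their decoded
#' counterparts bit for bit.
#'
#' @param x numeric vector.
#' @export
as_float32 <- function(x) .bits_float(.float_bits(as.numeric(x)))

#' Construct a sequence variation
#'
#' The decomposition of CIGAR/MD evidence: each record describes one
#' difference between read and reference. An empty `from` is an insertion
#' into the read; an empty `to` is a deletion from the read.
#'
#' @param position 0-based offset of the variation within the alignment,
#'   reference-relative.
#' @param read_index 1-based position within the read (including soft
#'   clips).
#' @param from reference bases ("" for an insertion).
#' @param to read bases ("" for a deletion).
#' @param to_quality optional quality bytes, one per base of `to`.
#' @export
sequence_variation <- function(position, read_index, from, to, to_quality = NULL) {
  list(position = as.integer(position), read_index = as.integer(read_index),
       from = as.character(from), to = as.character(to),
       to_quality = if (is.null(to_quality)) NULL else as.integer(to_quality))
}

#' Construct an entry link
#'
#' A reference from one alignment entry to another (mate or spliced
#' neighbor), either as the explicit triple (position, target index,
#' fragment index) or, inside a chunk after domain optimization, as a signed
#' entry-offset delta. Exactly one form is active.
#'
#' @param position,target_index,fragment_index the linked entry's triple.
#' @param delta signed chunk-ordinal offset to the linked entry.
#' @export
entry_link <- function(position = NULL, target_index = NULL,
                       fragment_index = NULL, delta = NULL) {
  if (!is.null(delta)) {
    if (!is.null(position)) stop("a link is either a triple or a delta, not both")
    return(list(delta = as.integer(delta)))
  }
  list(position = as.integer(position), target_index = as.integer(target_index),
       fragment_index = as.integer(fragment_index))
}

is_delta_link <- function(link) !is.null(link) && !is.null(link$delta)

#' Construct an alignment header
#'
#' Global information shared by all entries of an alignment: the reference
#' target dictionary, collection counts and flags. Stored in the `.header`
#' file of a Tier II set.
#'
#' @param target_names,target_lengths reference sequence dictionary.
#' @param n_queries number of reads in the originating read collection.
#' @param sorted whether entries are sorted by (target, position).
#' @param read_origin_info optional list of read-origin (read group) records.
#' @param version format version string.
#' @export
alignment_header <- function(target_names = character(0),
                             target_lengths = integer(0),
                             n_queries = 0L, sorted = FALSE,
                             read_origin_info = list(),
                             version = "1") {
  stopifnot(length(target_names) == length(target_lengths))
  structure(list(
    target_names = as.character(target_names),
    target_lengths = as.integer(target_lengths),
    n_targets = length(target_names),
    n_queries = as.integer(n_queries),
    sorted = isTRUE(sorted),
    read_origin_info = read_origin_info,
    version = version
  ), class = "alignment_header")
}

#' Construct a read entry (Tier I)
#'
#' @param query_index read identity integer, unique within a reads file.
#' @param sequence nucleotide text.
#' @param qualities integer quality bytes, one per base, or NULL.
#' @param pair_sequence,pair_qualities optional mate data.
#' @param identifier,description optional read name / description text.
#' @param metadata_index optional meta-data reference.
#' @param unknown_fields raw schema-evolution payload.
#' @export
read_entry <- function(query_index, sequence, qualities = NULL,
                       pair_sequence = NULL, pair_qualities = NULL,
                       identifier = NULL, description = NULL,
                       metadata_index = NULL, unknown_fields = raw(0)) {
  if (!is.null(qualities) && nchar(sequence) != length(qualities))
    stop("qualities must have one byte per base")
  list(query_index = as.integer(query_index),
       identifier = identifier, description = description,
       sequence = as.character(sequence),
       qualities = if (is.null(qualities)) NULL else as.integer(qualities),
       pair_sequence = pair_sequence,
       pair_qualities = if (is.null(pair_qualities)) NULL else as.integer(pair_qualities),
       metadata_index = if (is.null(metadata_index)) NULL else as.integer(metadata_index),
       unknown_fields = unknown_fields)
}

#' Attach a schema-evolution payload to an entry
#'
#' Stores a serialized field set from a newer schema on an entry. The
#' payload must parse as well-formed tag-length-value data whose tags lie
#' outside the known alignment schema (use [make_unknown_payload()] to build
#' one). Every codec carries the payload through byte-identically: older
#' software never erases newer fields.
#'
#' @param entry an [alignment_entry()].
#' @param payload raw vector.
#' @export
set_unknown_field <- function(entry, payload) {
  stopifnot(is.raw(payload))
  if (length(payload) > 0 && !.check_unknown_payload(payload))
    stop("payload is not well-formed TLV data with unknown tags")
  entry$unknown_fields <- payload
  entry
}

#' @rdname set_unknown_field
#' @param tag field tag (> 20, outside the known alignment schema).
#' @param bytes raw field payload.
#' @export
make_unknown_payload <- function(tag, bytes) {
  stopifnot(tag > 20, is.raw(bytes))
  c(encode_varint(tag), encode_varint(length(bytes)), bytes)
}

encode_varint <- function(v) {
  out <- raw(0)
  repeat {
    b <- v %% 128
    v <- v %/% 128
    if (v > 0) {
      out <- c(out, as.raw(b + 128))
    } else {
      out <- c(out, as.raw(b))
      break
    }
  }
  out
}

#' Validate an alignment entry against its invariants
#'
#' @param entry an [alignment_entry()].
#' @param header optional [alignment_header()]; enables the target-index
#'   bound check.
#' @return A character vector of violations (empty when the entry is valid).
#' @export
validate_entry <- function(entry, header = NULL) {
  v <- character(0)
  req <- c("query_index", "target_index", "position", "fragment_index",
           "query_length", "query_aligned_length", "target_aligned_length",
           "mapping_quality")
  for (f in req) {
    x <- entry[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      v <- c(v, sprintf("field %s must be a non-negative integer", f))
  }
  if (!is.null(header) && !is.na(entry$target_index) &&
      entry$target_index >= header$n_targets)
    v <- c(v, sprintf("target_index %d out of range (%d targets)",
                      entry$target_index, header$n_targets))
  for (sv in entry$sequence_variations) {
    if (nchar(sv$from) == 0 && nchar(sv$to) == 0)
      v <- c(v, "variation with both from and to empty")
    if (!is.na(sv$read_index) && sv$read_index > entry$query_length)
      v <- c(v, sprintf("variation read_index %d exceeds query length %d",
                        sv$read_index, entry$query_length))
    if (sv$position < 0 || sv$position > entry$target_aligned_length)
      v <- c(v, "variation position outside the aligned span")
    if (!is.null(sv$to_quality) && length(sv$to_quality) != nchar(sv$to))
      v <- c(v, "variation to_quality length does not match to bases")
  }
  if (!is.null(entry$to_quality) &&
      length(entry$to_quality) != entry$query_aligned_length)
    v <- c(v, "to_quality must cover exactly the aligned read bases")
  v
}

#' Serialize and parse records
#'
#' Record-level serialization, before any compression: each record is a
#' varint length prefix followed by its tag-length-value body. This is the
#' byte stream that the gzip and bzip2 whole-chunk codecs compress, and the
#' representation in which template equality is decided.
#'
#' @param entries list of [alignment_entry()] records.
#' @return `serialize_entries()` returns a raw vector;
#'   `deserialize_entries()` its exact inverse.
#' @export
serialize_entries <- function(entries) .serialize_entries(entries)

#' @rdname serialize_entries
#' @param bytes raw vector.
#' @export
deserialize_entries <- function(bytes) .deserialize_entries(bytes)

#' @rdname serialize_entries
#' @param reads list of [read_entry()] records.
#' @export
serialize_reads <- function(reads) .serialize_reads(reads)

#' @rdname serialize_entries
#' @export
deserialize_reads <- function(bytes) .deserialize_reads(bytes)
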