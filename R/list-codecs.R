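# List codecs: homogeneous lists reduced to integers and entropy-coded.
# Layout per integer list (bit-level, self-delimiting; see
# inst/docs/FORMAT.md):
#   rle flag (1 bit)
#   if set:   lengths list, then run-values list (each recursively encoded)
#   if clear: element count (nibble), sign flag (1 bit),
#             distinct symbol count (nibble), symbol table (nibble-coded,
#             zigzag-mapped when the sign flag is set), arithmetic segment
#             bit length (nibble), arithmetic-coded symbol indices.

#' Run-length encoding decision
#'
#' Computes run lengths and run values of an integer list and decides whether
#' run-length encoding pays off: it is used exactly when the total number of
#' stored elements in the `lengths` and `values` lists is strictly smaller
#' than the input length.
#'
#' @param values numeric vector (signed integers allowed).
#' @return `list(use_rle, lengths, values)`.
#' @examples
#' rle_decide(c(5, 5, 5, 2, 2))  # 4 stored elements < 5: use RLE
#' rle_decide(1:3)               # 6 >= 3: pass through
#' @export
rle_decide <- function(values) {
  if (length(values) == 0) {
    return(list(use_rle = FALSE, lengths = numeric(0), values = numeric(0)))
  }
  r <- rle(as.numeric(values))
  use <- (length(r$lengths) + length(r$values)) < length(values)
  list(use_rle = use, lengths = as.numeric(r$lengths), values = r$values)
}

# zigzag bijection: 0, -1, 1, -2, ... -> 0, 1, 2, 3, ...
zigzag_map <- function(v) 2 * abs(v) - (v < 0)
zigzag_unmap <- function(z) ifelse(z %% 2 == 1, -(z + 1) / 2, z / 2)

wr_int_list <- function(sink, values) {
  values <- as.numeric(values)
  r <- rle_decide(values)
  write_bits(sink, as.numeric(r$use_rle), 1)
  if (r$use_rle) {
    wr_int_list(sink, r$lengths)
    wr_int_list(sink, r$values)
    return(invisible(NULL))
  }
  nibble_encode(length(values), sink)
  if (length(values) == 0) return(invisible(NULL))
  signed <- any(values < 0)
  write_bits(sink, as.numeric(signed), 1)
  mapped <- if (signed) zigzag_map(values) else values
  syms <- sort(unique(mapped))
  nibble_encode(length(syms), sink)
  nibble_encode(syms, sink)
  idx <- match(mapped, syms) - 1L
  seg <- arithmetic_encode(idx, length(syms))
  nibble_encode(seg$bits, sink)
  .bw_append(sink$ptr, seg$bytes, seg$bits)
  invisible(NULL)
}

rd_int_list <- function(source) {
  use_rle <- read_bits(source, 1) == 1
  if (use_rle) {
    lengths <- rd_int_list(source)
    vals <- rd_int_list(source)
    if (length(lengths) != length(vals)) stop("corrupt RLE lists")
    return(rep(vals, times = lengths))
  }
  count <- nibble_decode(source, 1)
  if (count == 0) return(numeric(0))
  signed <- read_bits(source, 1) == 1
  nsym <- nibble_decode(source, 1)
  syms <- nibble_decode(source, nsym)
  bits <- nibble_decode(source, 1)
  idx <- arithmetic_decode(source, count, nsym, bits)
  mapped <- syms[idx + 1]
  if (signed) zigzag_unmap(mapped) else mapped
}

#' Encode homogeneous lists to byte sequences
#'
#' Every list kind is reduced to integer lists and coded with the header +
#' RLE-decision + arithmetic-coding scheme. Strings are transposed into
#' positional character columns (first byte of every string, then second,
#' and so on; column `c` holds bytes only from strings longer than `c`,
#' with a separate lengths list disambiguating), 32-bit floats are
#' reinterpreted as their IEEE-754 bit pattern, and booleans map to 0/1.
#' All encodings round-trip exactly.
#'
#' @param values the list to encode: numeric (whole-valued, signed allowed),
#'   character (ASCII/byte strings), numeric float32-representable values, or
#'   logical, respectively.
#' @return A raw vector; decode with the matching `decode_*_list()`.
#' @examples
#' decode_int_list(encode_int_list(c(-1, 3, -1)))
#' decode_string_list(encode_string_list(c("A", "BCD")))
#' @export
encode_int_list <- function(values) {
  s <- bit_sink()
  wr_int_list(s, values)
  sink_bytes(s)
}

#' @rdname encode_int_list
#' @param bytes raw vector produced by the encoder.
#' @export
decode_int_list <- function(bytes) rd_int_list(bit_source(bytes))

wr_string_list <- function(sink, values) {
  nibble_encode(length(values), sink)
  if (length(values) == 0) return(invisible(NULL))
  raws <- lapply(values, charToRaw)
  lens <- lengths(raws)
  wr_int_list(sink, lens)
  maxlen <- if (length(lens)) max(lens) else 0
  for (col in seq_len(maxlen)) {
    keep <- lens >= col
    colv <- vapply(raws[keep], function(r) as.integer(r[col]), integer(1))
    wr_int_list(sink, colv)
  }
  invisible(NULL)
}

rd_string_list <- function(source) {
  count <- nibble_decode(source, 1)
  if (count == 0) return(character(0))
  lens <- rd_int_list(source)
  if (length(lens) != count) stop("corrupt string list")
  maxlen <- if (length(lens)) max(lens) else 0
  mats <- vector("list", count)
  for (i in seq_len(count)) mats[[i]] <- raw(lens[i])
  for (col in seq_len(maxlen)) {
    keep <- which(lens >= col)
    colv <- rd_int_list(source)
    if (length(colv) != length(keep)) stop("corrupt string column")
    for (j in seq_along(keep)) mats[[keep[j]]][col] <- as.raw(colv[j])
  }
  vapply(mats, rawToChar, character(1))
}

#' @rdname encode_int_list
#' @export
encode_string_list <- function(values) {
  s <- bit_sink()
  wr_string_list(s, values)
  sink_bytes(s)
}

#' @rdname encode_int_list
#' @export
decode_string_list <- function(bytes) rd_string_list(bit_source(bytes))

wr_float_list <- function(sink, values) wr_int_list(sink, .float_bits(values))
rd_float_list <- function(source) .bits_float(rd_int_list(source))

#' @rdname encode_int_list
#' @export
encode_float_list <- function(values) {
  s <- bit_sink()
  wr_float_list(s, as.numeric(values))
  sink_bytes(s)
}

#' @rdname encode_int_list
#' @export
decode_float_list <- function(bytes) rd_float_list(bit_source(bytes))

wr_bool_list <- function(sink, values) wr_int_list(sink, as.numeric(values))
rd_bool_list <- function(source) rd_int_list(source) != 0

#' @rdname encode_int_list
#' @export
encode_bool_list <- function(values) {
  s <- bit_sink()
  wr_bool_list(s, as.logical(values))
  sink_bytes(s)
}

#' @rdname encode_int_list
#' @export
decode_bool_list <- function(bytes) rd_bool_list(bit_source(bytes))
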