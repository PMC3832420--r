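#' Create a bit sink
#'
#' A bit sink is a growable byte buffer with a bit cursor. All coders in the
#' package write most-significant-bit first; flushing to bytes pads the final
#' partial byte with zero bits.
#'
#' @return An object of class `bit_sink`.
#' @seealso [bit_source()], [nibble_encode()], [arithmetic_encode()]
#' @export
bit_sink <- function() {
  structure(list(ptr = .bw_new()), class = "bit_sink")
}

#' @rdname bit_sink
#' @param sink a `bit_sink`
#' @return `sink_bits()` returns the number of bits written so far;
#'   `sink_bytes()` returns the flushed buffer as a raw vector.
#' @export
sink_bits <- function(sink) .bw_bits(sink$ptr)

#' @rdname bit_sink
#' @export
sink_bytes <- function(sink) .bw_bytes(sink$ptr)

#' Create a bit source over a raw vector
#'
#' @param bytes raw vector to read from.
#' @return An object of class `bit_source` with a bit cursor starting at 0.
#' @export
bit_source <- function(bytes) {
  stopifnot(is.raw(bytes))
  structure(list(ptr = .br_new(bytes)), class = "bit_source")
}

#' @rdname bit_source
#' @param source a `bit_source`
#' @export
source_pos <- function(source) .br_pos(source$ptr)

#' Write or read raw bits
#'
#' Low-level fixed-width access used by the container framing; `value` is
#' written big-endian in `nbits` bits.
#'
#' @param sink,source bit sink / source.
#' @param value non-negative number (< 2^53).
#' @param nbits number of bits.
#' @return `read_bits()` returns the value as a double.
#' @keywords internal
#' @export
write_bits <- function(sink, value, nbits) {
  invisible(.bw_write_bits(sink$ptr, value, as.integer(nbits)))
}

#' @rdname write_bits
#' @export
read_bits <- function(source, nbits) .br_read_bits(source$ptr, as.integer(nbits))

#' Nibble coding of natural numbers
#'
#' Nibble coding pads the binary representation of a natural number to the
#' left with zeroes until its length is a multiple of three, then splits it
#' into 3-bit blocks, each prefixed with a flag bit that is zero for all
#' blocks except the last. A value therefore occupies
#' `4 * ceil(max(1, bitlen(v)) / 3)` bits.
#'
#' @param values non-negative numeric vector (negative input is an error).
#' @param sink a [bit_sink()] to append to.
#' @return Number of bits written, invisibly for the encoder.
#' @examples
#' s <- bit_sink()
#' nibble_encode(c(0, 5, 9), s)
#' nibble_decode(bit_source(sink_bytes(s)), 3)
#' @export
nibble_encode <- function(values, sink) {
  if (any(values < 0)) stop("nibble coding is defined for natural numbers only")
  invisible(.nibble_encode(sink$ptr, as.numeric(values)))
}

#' @rdname nibble_encode
#' @param source a [bit_source()].
#' @param n how many values to decode.
#' @export
nibble_decode <- function(source, n = 1) {
  .nibble_decode(source$ptr, n)
}

#' Minimal binary coding
#'
#' The optimal code for uniformly distributed values: each value is written
#' in exactly `m` bits, big-endian. Callers derive `m` from the most
#' significant bit of the maximum (rebased) value of the list; see
#' [bit_width()].
#'
#' @param values numeric vector with `0 <= value < 2^m`.
#' @param m bit width, `1 <= m <= 53`.
#' @inheritParams nibble_encode
#' @export
minimal_binary_encode <- function(values, m, sink) {
  invisible(.minbin_encode(sink$ptr, as.numeric(values), as.integer(m)))
}

#' @rdname minimal_binary_encode
#' @param source a [bit_source()].
#' @param n how many values to decode.
#' @export
minimal_binary_decode <- function(source, n, m) {
  .minbin_decode(source$ptr, n, as.integer(m))
}

#' Position of the most significant bit
#'
#' `bit_width(v)` is the number of bits needed to represent `v` in binary;
#' `bit_width(0)` is defined as 1 so that a degenerate constant list still
#' gets a valid minimal binary width.
#'
#' @param v non-negative number.
#' @export
bit_width <- function(v) {
  v <- max(0, floor(max(v)))
  if (v == 0) return(1L)
  as.integer(floor(log2(v)) + 1)
}

#' Adaptive arithmetic coding
#'
#' An adaptive arithmetic coder over a fixed alphabet of `n` symbols,
#' producing a code of near-optimal length for the empirical symbol
#' distribution. The model starts with every count at 1, increments the
#' coded symbol's count after each step, and halves all counts (floor 1)
#' when the total exceeds `max(2^16, 2n)`. The coder is a 32-bit
#' low/high-interval implementation with pending-bit carry resolution;
#' symbol lookup during decoding is O(log n) over a Fenwick tree. The exact
#' algorithm is fixed by the format specification (inst/docs/FORMAT.md); a
#' second, independent pure-R implementation of the same specification is
#' used as a differential test oracle.
#'
#' @param symbols integer vector of symbols in `[0, n)`.
#' @param n alphabet size.
#' @return `arithmetic_encode()` returns `list(bytes, bits)`: the coded
#'   segment and its exact bit length (an empty symbol list yields 0 bits).
#' @examples
#' seg <- arithmetic_encode(rep(0L, 100), n = 2)
#' seg$bits   # far fewer than 100 bits once the model adapts
#' arithmetic_decode(bit_source(seg$bytes), 100, n = 2, nbits = seg$bits)
#' @export
arithmetic_encode <- function(symbols, n) {
  .arith_encode(as.integer(symbols), as.integer(n))
}

#' @rdname arithmetic_encode
#' @param source a [bit_source()] positioned at the start of the segment.
#' @param count number of symbols to decode.
#' @param nbits exact bit length of the coded segment. If `NULL`, the
#'   segment is assumed to extend to the end of the source.
#' @return `arithmetic_decode()` returns the integer symbol vector; the
#'   source cursor is left at the end of the segment.
#' @export
arithmetic_decode <- function(source, count, n, nbits = NULL) {
  if (is.null(nbits)) nbits <- .br_limit(source$ptr) - .br_pos(source$ptr)
  .arith_decode(source$ptr, count, as.integer(n), nbits)
}
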