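# compactaln on-disk format

This file is the normative byte-level description of every format the
package writes. The container is self-defined: it is not interoperable with
other implementations of the same ideas, and does not aim to be.

## 1. Container framing (all `.entries` and `.compact-reads` files)

A container is a sequence of chunk frames followed by a termination chunk.

    frame := delimiter codec-code payload-length payload checksum
      delimiter       8 bytes, all 0xFF
      codec-code      1 byte (registration code, see §2)
      payload-length  4 bytes, unsigned big-endian, >= 1
      payload         payload-length bytes
      checksum        4 bytes, CRC32 (IEEE, reflected) of payload, big-endian

    termination := delimiter 0x00 0x00 0x00 0x00     (immediately before EOF)

Readers may begin scanning at any byte offset: find 8 consecutive 0xFF
bytes, then verify the candidate frame (plausible length, checksum, codec
registration, successful decompression). Any verification failure marks a
false-positive delimiter inside payload data; scanning resumes at the next
candidate. A delimiter followed by four zero bytes at end of file is the
termination. Concatenating the frame regions of two containers (dropping
the first termination) is a valid container.

## 2. Codec registration codes

    0  gzip      payload = gzip stream of the serialized record chunk (§3)
    1  bzip2     payload = bzip2 stream of the serialized record chunk (§3)
    2  hybrid-1  payload = ACT hybrid payload (§5)

Codes 0–31 are reserved for this package; unknown codes are a hard error.

## 3. Record serialization (TLV)

A serialized chunk is the concatenation of records, each framed as

    record := varint(body-length) body

`varint` is base-128, little-endian groups, high bit = continuation. A body
is a sequence of fields, each

    field := varint(tag) varint(length) payload[length]

written in ascending tag order. Parsers skip fields with unknown tags and
accumulate their raw framed bytes (tag + length + payload) into the entry's
`unknown_fields` buffer; serializers append that buffer verbatim after the
known fields. This is the schema-evolution mechanism: newer-schema fields
survive read–modify–write cycles by older software byte-identically.

### Alignment entry tags

    1  query_index            varint
    2  target_index           varint
    3  position               varint (0-based leftmost aligned base)
    4  fragment_index         varint
    5  matching_reverse_strand varint 0/1
    6  query_length           varint
    7  query_aligned_length   varint
    8  target_aligned_length  varint
    9  mapping_quality        varint
    10 score                  4 bytes, IEEE-754 float32, little-endian
    11 sequence_variation     message (repeated)
    12 pair_link              message
    13 splice_forward_link    message
    14 splice_backward_link   message
    15 softclip_left          bytes (ASCII bases)
    16 softclip_left_quality  bytes (one byte per base)
    17 softclip_right         bytes
    18 softclip_right_quality bytes
    19 to_quality             bytes (one per aligned read base)
    20 read_origin_index      varint

    sequence_variation: 1 position varint · 2 read_index varint ·
      3 from bytes · 4 to bytes · 5 to_quality bytes
    link: 1 position varint · 2 target_index varint ·
      3 fragment_index varint · 4 delta varint (zigzag; intra-chunk form —
      a link carries either fields 1–3 or field 4, never both)

### Read entry tags

    1 query_index varint · 2 identifier bytes · 3 description bytes ·
    4 sequence bytes · 5 qualities bytes · 6 pair_sequence bytes ·
    7 pair_qualities bytes · 8 metadata_index varint

## 4. Bit-level codes

All bit streams are most-significant-bit first; flushing pads the final
byte with zero bits.

* **Nibble code** (natural numbers): binary representation left-padded with
  zeroes to a multiple of 3 bits, split into 3-bit blocks; each block is
  preceded by a flag bit, 0 for all blocks except the last. 0 → `1000`,
  5 → `1101`, 9 → `0001 1001`.
* **Minimal binary code**: exactly m bits, big-endian; m is the position of
  the most significant bit of the largest (rebased) value.
* **Arithmetic code**: adaptive, 32-bit low/high interval coder with
  pending-bit carry resolution (encode: interval split by cumulative
  counts, renormalize on `high < 2^31`, `low >= 2^31`, or the middle
  straddle; finish emits one disambiguating bit plus pending bits). Model:
  alphabet of n symbols, all counts start at 1, the coded symbol's count is
  incremented by 1 after each step, and when the total exceeds
  max(2^16, 2n) every count is halved with floor 1.

### Integer list

    int-list := rle-flag(1 bit) ( rle-body | plain-body )
    rle-body := int-list(run-lengths) int-list(run-values)
    plain-body := nibble(count)
                  [ if count > 0:
                    sign-flag(1 bit)
                    nibble(distinct-symbol-count)
                    nibble(symbol)*          ; ascending, zigzag-mapped when
                                             ; sign-flag = 1
                    nibble(arith-bit-length)
                    arith(symbol indices, n = distinct-symbol-count) ]

Run-length encoding is chosen exactly when
`len(run-lengths) + len(run-values) < len(input)`. The signed bijection is
zigzag: 0, −1, 1, −2, … → 0, 1, 2, 3, … The arithmetic segment's exact bit
length is recorded so the decoder (which reads up to 32 bits ahead) can
reposition.

### Other lists

* **Boolean list**: values mapped to 0/1, then int-list.
* **Float list**: IEEE-754 float32 bit patterns as unsigned integers, then
  int-list.
* **String list**: nibble(count); int-list of byte lengths; then positional
  columns: column c holds the c-th byte of every string with length > c
  (ragged transpose), each column an int-list over the 256-symbol byte
  alphabet.
* **Byte-list column** (optional per-row byte vectors): boolean presence
  list, int-list of lengths over present rows, int-list of concatenated
  values.

## 5. ACT hybrid payload (codec 2)

    payload := flags(1 byte: bit0 template, bit1 domain)
               varint(act-length)  act-stream
               varint(leftover-length) leftover-stream

### ACT stream

One continuous bit stream:

    nibble(entry-count) template-flag(1 bit) domain-flag(1 bit)
    [ if template: int-list(run-counts) ]
    query-index column: nibble(min) nibble(m) minimal-binary(count × m)
    int-list(position deltas)            ; successive differences
    byte-list column(to_quality)
    — template-level columns (one row per template run, or per entry) —
    int-list(target_index) int-list(fragment_index)
    bool-list(matching_reverse_strand)
    int-list(query_length)
    int-list(query_length − query_aligned_length)      ; modeled residual
    int-list(target_aligned_length − query_aligned_length) ; modeled residual
    int-list(mapping_quality) float-list(score)
    int-list(variation count per row)
    int-list(var position) int-list(var read_index)
    string-list(var from) string-list(var to)
    byte-list column(var to_quality)
    3 × link column:                         ; pair, splice fwd, splice bwd
        int-list(kind: 0 absent, 1 triple, 2 delta)
        int-list(position | kind=1) int-list(target | kind=1)
        int-list(fragment | kind=1) int-list(delta | kind=2, signed)
    bool-list(softclip_left present) string-list(softclip_left)
    byte-list column(softclip_left_quality)
    bool-list(softclip_right present) string-list(softclip_right)
    byte-list column(softclip_right_quality)
    bool-list(read_origin present) int-list(read_origin values)

Field-modeling inventory (versioned with this document): position →
successive deltas within the chunk; query_aligned_length → residual against
query_length; target_aligned_length → residual against
query_aligned_length; mate/splice positions → handled by link optimization.

Template identity is byte equality of the serialized record body (§3) after
removing tags 1 (query_index), 3 (position), 19 (to_quality) and the
unknown-field buffer; the non-template fields are emitted per entry, the
template fields once per run of consecutive equal templates. The template
comparison is reset at each chunk boundary.

### Left-over stream

gzip stream of: varint(record-count), then per record varint(chunk ordinal,
0-based), varint(byte-length), payload. Holds each entry's unknown-field
bytes; decoding re-attaches them by ordinal.

## 6. Tier files

* `.entries` / `.compact-reads`: containers (§1) over the alignment / read
  schema.
* `.header`: JSON with target_names, target_lengths, n_queries, sorted,
  version.
* `.index`: tab-separated chunk table: chunk, byte offset, record count,
  target_index and position of the chunk's first entry.
* `.tmh`: too-many-hits query indices, one decimal per line.
* `.perm`: `"PRM1"` magic, u32-BE entry count, u32-BE block size, then
  fixed-width u32-BE original query indices ordered by small index
  (block-aligned partial lookup).
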