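# shared builders for hand-constructed chunks

entry0 <- function(qi = 0L, pos = 100L, score = 40, ...) {
  alignment_entry(query_index = qi, target_index = 0L, position = pos,
                  query_length = 50L, query_aligned_length = 50L,
                  target_aligned_length = 50L, mapping_quality = 60L,
                  score = score, ...)
}

# a chunk of n entries identical except query index and position
uniform_chunk <- function(n, pos0 = 100L, step = 10L, ...) {
  lapply(seq_len(n), function(i) {
    entry0(qi = i - 1L, pos = pos0 + (i - 1L) * step, ...)
  })
}

random_signed_list <- function(len, lo = -500, hi = 500) {
  sample(lo:hi, len, replace = TRUE)
}

# internals exercised directly by the storage tests
schema_serialize_test <- function(entries, schema) {
  compactaln:::schema_serialize(entries, schema)
}
delim_candidates_test <- function(container) {
  compactaln:::delimiter_candidates(container, 0)
}
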