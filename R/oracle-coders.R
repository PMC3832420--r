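# Reference ("oracle") coders: a second, independent implementation of the
# documented coding algorithms, written in plain R with no shared code with
# the production C++ coders. Deliberately simple and slow; used only by the
# differential tests. All arithmetic stays below 2^53 so doubles are exact.

ref_bit_sink <- function() new.env(parent = emptyenv())

ref_sink_init <- function() {
  e <- ref_bit_sink()
  e$bits <- integer(0)
  e
}

ref_put_bit <- function(s, b) s$bits <- c(s$bits, as.integer(b))

ref_put_bits <- function(s, v, n) {
  for (i in seq_len(n)) ref_put_bit(s, (v %/% 2^(n - i)) %% 2)
}

ref_sink_bytes <- function(s) {
  bits <- s$bits
  pad <- (8 - length(bits) %% 8) %% 8
  bits <- c(bits, rep(0L, pad))
  m <- matrix(bits, nrow = 8)
  as.raw(colSums(m * 2^(7:0)))
}

# bit vector from raw, MSB first
ref_bits_of <- function(bytes) {
  if (length(bytes) == 0) return(integer(0))
  as.integer(sapply(as.integer(bytes), function(b) (b %/% 2^(7:0)) %% 2))
}

ref_bitlen <- function(v) if (v == 0) 1L else floor(log2(v)) + 1L

ref_nibble_encode <- function(s, v) {
  stopifnot(v >= 0)
  nb <- ref_bitlen(v)
  blocks <- ceiling(nb / 3)
  for (b in seq(blocks - 1, 0)) {
    ref_put_bit(s, if (b == 0) 1L else 0L)
    ref_put_bits(s, (v %/% 8^b) %% 8, 3)
  }
  4L * blocks
}

ref_nibble_decode <- function(bits, pos) {
  v <- 0
  repeat {
    if (pos + 3 > length(bits)) stop("truncated")
    last <- bits[pos]
    v <- v * 8 + bits[pos + 1] * 4 + bits[pos + 2] * 2 + bits[pos + 3]
    pos <- pos + 4
    if (last == 1) break
  }
  list(value = v, pos = pos)
}

# --- arithmetic coder: same specification as the production coder ---

ref_model_init <- function(n) {
  list(freq = rep(1, n), total = n, thresh = max(65536, 2 * n))
}

ref_model_update <- function(m, s) {
  m$freq[s + 1] <- m$freq[s + 1] + 1
  m$total <- m$total + 1
  if (m$total > m$thresh) {
    m$freq <- pmax(1, m$freq %/% 2)
    m$total <- sum(m$freq)
  }
  m
}

REF_FULL <- 2^32
REF_HALF <- 2^31
REF_QUART <- 2^30
REF_THREEQ <- 3 * 2^30

ref_arith_encode <- function(symbols, n) {
  s <- ref_sink_init()
  m <- ref_model_init(n)
  low <- 0
  high <- REF_FULL - 1
  pending <- 0
  emit <- function(b) {
    ref_put_bit(s, b)
    while (pending > 0) {
      ref_put_bit(s, 1L - b)
      pending <<- pending - 1
    }
  }
  for (sym in symbols) {
    cums <- cumsum(m$freq)
    cumLo <- if (sym == 0) 0 else cums[sym]
    cumHi <- cums[sym + 1]
    range <- high - low + 1
    high <- low + floor(range * cumHi / m$total) - 1
    low <- low + floor(range * cumLo / m$total)
    repeat {
      if (high < REF_HALF) {
        emit(0L)
      } else if (low >= REF_HALF) {
        emit(1L)
        low <- low - REF_HALF
        high <- high - REF_HALF
      } else if (low >= REF_QUART && high < REF_THREEQ) {
        pending <- pending + 1
        low <- low - REF_QUART
        high <- high - REF_QUART
      } else break
      low <- low * 2
      high <- high * 2 + 1
    }
    m <- ref_model_update(m, sym)
  }
  if (length(symbols) > 0) {
    pending <- pending + 1
    if (low < REF_QUART) emit(0L) else emit(1L)
  }
  list(bits = length(s$bits), bytes = ref_sink_bytes(s))
}

ref_arith_decode <- function(bytes, nbits, count, n) {
  bits <- ref_bits_of(bytes)
  if (nbits > length(bits)) stop("segment longer than source")
  pos <- 1
  nextbit <- function() {
    b <- if (pos <= nbits) bits[pos] else 0L
    pos <<- pos + 1
    b
  }
  if (count == 0) return(integer(0))
  m <- ref_model_init(n)
  low <- 0
  high <- REF_FULL - 1
  value <- 0
  for (i in 1:32) value <- value * 2 + nextbit()
  out <- integer(count)
  for (i in seq_len(count)) {
    range <- high - low + 1
    target <- floor(((value - low + 1) * m$total - 1) / range)
    cums <- cumsum(m$freq)
    sym <- sum(cums <= target)   # linear search: cum(sym) <= target < cum(sym+1)
    out[i] <- sym
    cumLo <- if (sym == 0) 0 else cums[sym]
    cumHi <- cums[sym + 1]
    high <- low + floor(range * cumHi / m$total) - 1
    low <- low + floor(range * cumLo / m$total)
    repeat {
      if (high < REF_HALF) {
      } else if (low >= REF_HALF) {
        low <- low - REF_HALF
        high <- high - REF_HALF
        value <- value - REF_HALF
      } else if (low >= REF_QUART && high < REF_THREEQ) {
        low <- low - REF_QUART
        high <- high - REF_QUART
        value <- value - REF_QUART
      } else break
      low <- low * 2
      high <- high * 2 + 1
      value <- value * 2 + nextbit()
    }
    if (value < low || value > high) stop("corrupt arithmetic stream")
    m <- ref_model_update(m, sym)
  }
  out
}
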