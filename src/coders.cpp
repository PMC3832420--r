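// Entropy and structured coders: nibble, minimal binary, adaptive arithmetic.
// These are the production coders; R/oracle-coders.R implements the same
// documented algorithms independently and is differentially tested against
// this file. The algorithms themselves are specified in inst/docs/FORMAT.md.

#include <Rcpp.h>
#include "bitio.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bit sink / source handles

// [[Rcpp::export(name = ".bw_new")]]
SEXP bw_new() {
    XPtr<BitWriter> p(new BitWriter(), true);
    return p;
}

// [[Rcpp::export(name = ".bw_bits")]]
double bw_bits(SEXP ptr) {
    XPtr<BitWriter> p(ptr);
    return static_cast<double>(p->total);
}

// [[Rcpp::export(name = ".bw_bytes")]]
RawVector bw_bytes(SEXP ptr) {
    XPtr<BitWriter> p(ptr);
    std::vector<uint8_t> b = p->bytes();
    RawVector out(b.size());
    std::copy(b.begin(), b.end(), out.begin());
    return out;
}

// [[Rcpp::export(name = ".bw_write_bits")]]
void bw_write_bits(SEXP ptr, double value, int nbits) {
    XPtr<BitWriter> p(ptr);
    if (value < 0) stop("negative value in bit write");
    p->put_bits(static_cast<uint64_t>(value), nbits);
}

// Replay `nbits` bits from the front of `bytes` into the sink (bit-misaligned
// segment append; used to splice arithmetic-coded segments into a stream).
// [[Rcpp::export(name = ".bw_append")]]
void bw_append(SEXP ptr, RawVector bytes, double nbits) {
    XPtr<BitWriter> p(ptr);
    uint64_t n = static_cast<uint64_t>(nbits);
    for (uint64_t i = 0; i < n; ++i) {
        uint64_t byte = i >> 3;
        int off = 7 - static_cast<int>(i & 7);
        p->put_bit((bytes[byte] >> off) & 1);
    }
}

// [[Rcpp::export(name = ".br_new")]]
SEXP br_new(RawVector bytes) {
    std::vector<uint8_t> d(bytes.begin(), bytes.end());
    XPtr<BitReader> p(new BitReader(std::move(d)), true);
    return p;
}

// [[Rcpp::export(name = ".br_pos")]]
double br_pos(SEXP ptr) {
    XPtr<BitReader> p(ptr);
    return static_cast<double>(p->pos);
}

// [[Rcpp::export(name = ".br_limit")]]
double br_limit(SEXP ptr) {
    XPtr<BitReader> p(ptr);
    return static_cast<double>(p->limit);
}

// [[Rcpp::export(name = ".br_seek")]]
void br_seek(SEXP ptr, double pos) {
    XPtr<BitReader> p(ptr);
    uint64_t q = static_cast<uint64_t>(pos);
    if (q > p->limit) stop("seek past end of bit source");
    p->pos = q;
}

// [[Rcpp::export(name = ".br_read_bits")]]
double br_read_bits(SEXP ptr, int nbits) {
    XPtr<BitReader> p(ptr);
    double out;
    try {
        out = static_cast<double>(p->get_bits(nbits));
    } catch (std::exception &e) {
        stop("%s", e.what());
    }
    return out;
}

// ---------------------------------------------------------------------------
// Nibble coding: binary representation left-padded with zeroes to a multiple
// of three, split in 3-bit blocks, each prefixed with a flag bit that is zero
// for all blocks except the last.

static int bitlen_u64(uint64_t v) {
    int n = 0;
    while (v) { ++n; v >>= 1; }
    return n < 1 ? 1 : n;
}

static uint64_t nibble_one(BitWriter &bw, uint64_t v) {
    int nb = bitlen_u64(v);
    int blocks = (nb + 2) / 3;
    for (int b = blocks - 1; b >= 0; --b) {
        bw.put_bit(b == 0 ? 1 : 0);
        bw.put_bits((v >> (3 * b)) & 7, 3);
    }
    return static_cast<uint64_t>(blocks) * 4;
}

// [[Rcpp::export(name = ".nibble_encode")]]
double nibble_encode_cpp(SEXP ptr, NumericVector values) {
    XPtr<BitWriter> p(ptr);
    uint64_t bits = 0;
    for (R_xlen_t i = 0; i < values.size(); ++i) {
        double v = values[i];
        if (ISNAN(v) || v < 0) stop("nibble coding requires non-negative values");
        bits += nibble_one(*p, static_cast<uint64_t>(v));
    }
    return static_cast<double>(bits);
}

// [[Rcpp::export(name = ".nibble_decode")]]
NumericVector nibble_decode_cpp(SEXP ptr, double n) {
    XPtr<BitReader> p(ptr);
    R_xlen_t count = static_cast<R_xlen_t>(n);
    NumericVector out(count);
    try {
        for (R_xlen_t i = 0; i < count; ++i) {
            uint64_t v = 0;
            int last = 0;
            do {
                last = p->get_bit();
                v = (v << 3) | p->get_bits(3);
            } while (!last);
            out[i] = static_cast<double>(v);
        }
    } catch (std::exception &e) {
        stop("truncated nibble-coded stream: %s", e.what());
    }
    return out;
}

// ---------------------------------------------------------------------------
// Minimal binary coding: fixed width m bits, big-endian.

// [[Rcpp::export(name = ".minbin_encode")]]
double minbin_encode_cpp(SEXP ptr, NumericVector values, int m) {
    XPtr<BitWriter> p(ptr);
    if (m < 1 || m > 53) stop("minimal binary width m must be in [1, 53]");
    double lim = std::ldexp(1.0, m);
    for (R_xlen_t i = 0; i < values.size(); ++i) {
        double v = values[i];
        if (ISNAN(v) || v < 0 || v >= lim)
            stop("value out of range for %d-bit minimal binary code", m);
        p->put_bits(static_cast<uint64_t>(v), m);
    }
    return static_cast<double>(values.size()) * m;
}

// [[Rcpp::export(name = ".minbin_decode")]]
NumericVector minbin_decode_cpp(SEXP ptr, double n, int m) {
    XPtr<BitReader> p(ptr);
    R_xlen_t count = static_cast<R_xlen_t>(n);
    NumericVector out(count);
    try {
        for (R_xlen_t i = 0; i < count; ++i)
            out[i] = static_cast<double>(p->get_bits(m));
    } catch (std::exception &e) {
        stop("truncated minimal-binary stream: %s", e.what());
    }
    return out;
}

// ---------------------------------------------------------------------------
// Adaptive arithmetic coder (32-bit, carry handled via pending bits).
// Model: all symbol counts start at 1; the coded symbol's count is
// incremented by 1 after each step; when the total exceeds
// max(2^16, 2n) all counts are halved with floor 1. Cumulative counts are
// kept in a Fenwick tree giving O(log n) lookup and update.

namespace {

const uint64_t AC_HALF   = 1ULL << 31;
const uint64_t AC_QUART  = 1ULL << 30;
const uint64_t AC_THREEQ = 3ULL << 30;

struct AdaptiveModel {
    int n;
    std::vector<uint32_t> freq;
    std::vector<uint64_t> tree;   // Fenwick, 1-based
    uint64_t total;
    uint64_t thresh;
    int topbit;

    explicit AdaptiveModel(int n_) : n(n_), freq(n_, 1), tree(n_ + 1, 0) {
        total = 0;
        thresh = std::max<uint64_t>(65536ULL, 2ULL * static_cast<uint64_t>(n));
        topbit = 1;
        while ((topbit << 1) <= n) topbit <<= 1;
        for (int i = 0; i < n; ++i) add(i, 1);
        total = static_cast<uint64_t>(n);
    }
    void add(int i, int64_t d) {
        for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
    }
    uint64_t cum(int i) const {            // sum of freq[0..i-1]
        uint64_t s = 0;
        for (int j = i; j > 0; j -= j & (-j)) s += tree[j];
        return s;
    }
    int find(uint64_t target) const {      // s with cum(s) <= target < cum(s+1)
        int pos = 0;
        for (int pw = topbit; pw > 0; pw >>= 1) {
            int np = pos + pw;
            if (np <= n && tree[np] <= target) { pos = np; target -= tree[np]; }
        }
        return pos;
    }
    void update(int s) {
        add(s, 1);
        freq[s] += 1;
        total += 1;
        if (total > thresh) {
            std::fill(tree.begin(), tree.end(), 0);
            total = 0;
            for (int i = 0; i < n; ++i) {
                freq[i] = std::max<uint32_t>(1u, freq[i] >> 1);
                add(i, freq[i]);
                total += freq[i];
            }
        }
    }
};

struct ArithEncoder {
    BitWriter &bw;
    uint64_t low = 0, high = (1ULL << 32) - 1;
    uint64_t pending = 0;

    explicit ArithEncoder(BitWriter &w) : bw(w) {}
    void emit(int b) {
        bw.put_bit(b);
        while (pending) { bw.put_bit(!b); --pending; }
    }
    void encode(uint64_t cumLo, uint64_t cumHi, uint64_t total) {
        uint64_t range = high - low + 1;
        high = low + range * cumHi / total - 1;
        low  = low + range * cumLo / total;
        for (;;) {
            if (high < AC_HALF) {
                emit(0);
            } else if (low >= AC_HALF) {
                emit(1); low -= AC_HALF; high -= AC_HALF;
            } else if (low >= AC_QUART && high < AC_THREEQ) {
                ++pending; low -= AC_QUART; high -= AC_QUART;
            } else break;
            low <<= 1; high = (high << 1) | 1;
        }
    }
    void finish() {
        ++pending;
        if (low < AC_QUART) emit(0); else emit(1);
    }
};

} // namespace

// Encode `symbols` (0-based, alphabet size n) into a fresh bit segment.
// Returns list(bytes = raw, bits = double).
// [[Rcpp::export(name = ".arith_encode")]]
List arith_encode_cpp(IntegerVector symbols, int n) {
    if (n < 1) stop("alphabet size must be >= 1");
    BitWriter bw;
    AdaptiveModel model(n);
    ArithEncoder enc(bw);
    for (R_xlen_t i = 0; i < symbols.size(); ++i) {
        int s = symbols[i];
        if (s == NA_INTEGER || s < 0 || s >= n)
            stop("symbol %d out of range [0, %d)", s, n);
        enc.encode(model.cum(s), model.cum(s + 1), model.total);
        model.update(s);
    }
    if (symbols.size() > 0) enc.finish();
    std::vector<uint8_t> b = bw.bytes();
    RawVector bytes(b.size());
    std::copy(b.begin(), b.end(), bytes.begin());
    return List::create(_["bytes"] = bytes, _["bits"] = static_cast<double>(bw.total));
}

// Decode `count` symbols from a segment of `nbits` bits starting at the
// current cursor of the bit source; the cursor is left at segment end.
// [[Rcpp::export(name = ".arith_decode")]]
IntegerVector arith_decode_cpp(SEXP ptr, double count, int n, double nbits) {
    XPtr<BitReader> p(ptr);
    if (n < 1) stop("alphabet size must be >= 1");
    R_xlen_t cnt = static_cast<R_xlen_t>(count);
    uint64_t end = p->pos + static_cast<uint64_t>(nbits);
    if (end > p->limit) stop("arithmetic segment extends past end of source");
    IntegerVector out(cnt);
    if (cnt == 0) { p->pos = end; return out; }

    AdaptiveModel model(n);
    uint64_t low = 0, high = (1ULL << 32) - 1, value = 0;
    for (int i = 0; i < 32; ++i)
        value = (value << 1) | static_cast<uint64_t>(p->get_bit_padded(end));

    for (R_xlen_t i = 0; i < cnt; ++i) {
        uint64_t range = high - low + 1;
        uint64_t total = model.total;
        uint64_t target = ((value - low + 1) * total - 1) / range;
        int s = model.find(target);
        out[i] = s;
        uint64_t cumLo = model.cum(s), cumHi = model.cum(s + 1);
        high = low + range * cumHi / total - 1;
        low  = low + range * cumLo / total;
        for (;;) {
            if (high < AC_HALF) {
                // nothing
            } else if (low >= AC_HALF) {
                low -= AC_HALF; high -= AC_HALF; value -= AC_HALF;
            } else if (low >= AC_QUART && high < AC_THREEQ) {
                low -= AC_QUART; high -= AC_QUART; value -= AC_QUART;
            } else break;
            low <<= 1; high = (high << 1) | 1;
            value = (value << 1) | static_cast<uint64_t>(p->get_bit_padded(end));
        }
        if (value < low || value > high)
            stop("corrupt arithmetic-coded stream");
        model.update(s);
    }
    p->pos = end;
    return out;
}

// ---------------------------------------------------------------------------
// IEEE-754 float32 bit reinterpretation (doubles carry the unsigned pattern).

// [[Rcpp::export(name = ".float_bits")]]
NumericVector float_bits_cpp(NumericVector x) {
    NumericVector out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) {
        float f = static_cast<float>(x[i]);
        uint32_t u;
        std::memcpy(&u, &f, 4);
        out[i] = static_cast<double>(u);
    }
    return out;
}

// [[Rcpp::export(name = ".bits_float")]]
NumericVector bits_float_cpp(NumericVector u) {
    NumericVector out(u.size());
    for (R_xlen_t i = 0; i < u.size(); ++i) {
        uint32_t v = static_cast<uint32_t>(u[i]);
        float f;
        std::memcpy(&f, &v, 4);
        out[i] = static_cast<double>(f);
    }
    return out;
}

// [[Rcpp::export(name = ".crc32")]]
double crc32_cpp(RawVector bytes) {
    static uint32_t table[256];
    static bool init = false;
    if (!init) {
        for (uint32_t i = 0; i < 256; ++i) {
            uint32_t c = i;
            for (int k = 0; k < 8; ++k)
                c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
            table[i] = c;
        }
        init = true;
    }
    uint32_t c = 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < bytes.size(); ++i)
        c = table[(c ^ bytes[i]) & 0xFF] ^ (c >> 8);
    c ^= 0xFFFFFFFFu;
    return static_cast<double>(c);
}
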