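#ifndef COMPACTALN_BITIO_H
#define COMPACTALN_BITIO_H

#include <cstdint>
#include <vector>
#include <stdexcept>

// MSB-first bit stream over a growable byte buffer. Flush pads the final
// partial byte with zero bits (format contract: decoders never rely on
// trailing pad bits).
struct BitWriter {
    std::vector<uint8_t> buf;
    uint8_t cur = 0;
    int ncur = 0;           // bits accumulated in cur
    uint64_t total = 0;     // total bits written

    void put_bit(int b) {
        cur = static_cast<uint8_t>((cur << 1) | (b & 1));
        if (++ncur == 8) { buf.push_back(cur); cur = 0; ncur = 0; }
        ++total;
    }
    void put_bits(uint64_t v, int n) {
        for (int i = n - 1; i >= 0; --i) put_bit(static_cast<int>((v >> i) & 1));
    }
    std::vector<uint8_t> bytes() const {
        std::vector<uint8_t> out = buf;
        if (ncur > 0) out.push_back(static_cast<uint8_t>(cur << (8 - ncur)));
        return out;
    }
};

struct BitReader {
    std::vector<uint8_t> data;
    uint64_t pos = 0;       // bit cursor
    uint64_t limit = 0;     // total bits available

    explicit BitReader(std::vector<uint8_t> d) : data(std::move(d)) {
        limit = static_cast<uint64_t>(data.size()) * 8;
    }
    int get_bit() {
        if (pos >= limit) throw std::runtime_error("bit source exhausted");
        uint64_t byte = pos >> 3;
        int off = 7 - static_cast<int>(pos & 7);
        ++pos;
        return (data[byte] >> off) & 1;
    }
    // Used by the arithmetic decoder, which reads up to 32 bits past the end
    // of its segment: bits beyond `end` read as zero without advancing pos
    // past bookkeeping (caller reseeks to `end` when done).
    int get_bit_padded(uint64_t end) {
        if (pos >= end) { ++pos; return 0; }
        return get_bit();
    }
    uint64_t get_bits(int n) {
        uint64_t v = 0;
        for (int i = 0; i < n; ++i) v = (v << 1) | static_cast<uint64_t>(get_bit());
        return v;
    }
};

#endif
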