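// Tag-length-value record serialization for the alignment and read schemas.
// Every field is framed as (tag varint, length varint, payload), so a parser
// compiled against an older schema can carve fields with unknown tags into an
// opaque `unknown_fields` byte buffer and re-emit them verbatim: the
// schema-evolution contract. The field-tag table is documented in
// inst/docs/FORMAT.md and is part of the on-disk format.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

namespace {

// --- alignment entry tags ---
enum {
    T_QUERY_INDEX = 1, T_TARGET_INDEX = 2, T_POSITION = 3, T_FRAGMENT_INDEX = 4,
    T_REVERSE_STRAND = 5, T_QUERY_LENGTH = 6, T_QUERY_ALIGNED = 7,
    T_TARGET_ALIGNED = 8, T_MAPPING_QUALITY = 9, T_SCORE = 10,
    T_VARIATION = 11, T_PAIR_LINK = 12, T_SPLICE_FWD = 13, T_SPLICE_BWD = 14,
    T_SOFTCLIP_LEFT = 15, T_SOFTCLIP_LEFT_Q = 16,
    T_SOFTCLIP_RIGHT = 17, T_SOFTCLIP_RIGHT_Q = 18,
    T_TO_QUALITY = 19, T_READ_ORIGIN = 20
};
// --- sequence variation tags ---
enum { V_POSITION = 1, V_READ_INDEX = 2, V_FROM = 3, V_TO = 4, V_TO_QUALITY = 5 };
// --- entry link tags ---
enum { L_POSITION = 1, L_TARGET_INDEX = 2, L_FRAGMENT_INDEX = 3, L_DELTA = 4 };
// --- read entry tags ---
enum {
    R_QUERY_INDEX = 1, R_IDENTIFIER = 2, R_DESCRIPTION = 3, R_SEQUENCE = 4,
    R_QUALITIES = 5, R_PAIR_SEQUENCE = 6, R_PAIR_QUALITIES = 7, R_METADATA = 8
};

typedef std::vector<uint8_t> ByteVec;

void put_varint(ByteVec &out, uint64_t v) {
    while (v >= 0x80) { out.push_back(static_cast<uint8_t>(v) | 0x80); v >>= 7; }
    out.push_back(static_cast<uint8_t>(v));
}

uint64_t get_varint(const uint8_t *p, size_t n, size_t &pos) {
    uint64_t v = 0;
    int shift = 0;
    for (;;) {
        if (pos >= n) throw std::runtime_error("truncated varint");
        uint8_t b = p[pos++];
        v |= static_cast<uint64_t>(b & 0x7F) << shift;
        if (!(b & 0x80)) break;
        shift += 7;
        if (shift > 63) throw std::runtime_error("malformed varint");
    }
    return v;
}

void put_field_varint(ByteVec &out, int tag, uint64_t v) {
    ByteVec payload;
    put_varint(payload, v);
    put_varint(out, tag);
    put_varint(out, payload.size());
    out.insert(out.end(), payload.begin(), payload.end());
}

void put_field_bytes(ByteVec &out, int tag, const uint8_t *p, size_t n) {
    put_varint(out, tag);
    put_varint(out, n);
    out.insert(out.end(), p, p + n);
}

void put_field_string(ByteVec &out, int tag, SEXP s) {
    const char *c = CHAR(STRING_ELT(s, 0));
    put_field_bytes(out, tag, reinterpret_cast<const uint8_t *>(c), std::strlen(c));
}

void put_field_quals(ByteVec &out, int tag, SEXP q) {
    IntegerVector iv(q);
    ByteVec payload(iv.size());
    for (R_xlen_t i = 0; i < iv.size(); ++i) {
        int v = iv[i];
        if (v == NA_INTEGER || v < 0 || v > 255) Rcpp::stop("quality byte out of range");
        payload[i] = static_cast<uint8_t>(v);
    }
    put_field_bytes(out, tag, payload.data(), payload.size());
}

uint64_t zigzag(int64_t v) { return (static_cast<uint64_t>(v) << 1) ^ static_cast<uint64_t>(v >> 63); }
int64_t unzigzag(uint64_t z) { return static_cast<int64_t>(z >> 1) ^ -static_cast<int64_t>(z & 1); }

bool notnull(SEXP x) { return x != R_NilValue; }

int get_int(SEXP x, const char *what) {
    int v = Rf_asInteger(x);
    if (v == NA_INTEGER) Rcpp::stop("NA in field %s", what);
    return v;
}

// ---- variation ----
void serialize_variation(ByteVec &out, List v) {
    ByteVec body;
    put_field_varint(body, V_POSITION, get_int(v["position"], "variation position"));
    put_field_varint(body, V_READ_INDEX, get_int(v["read_index"], "read_index"));
    put_field_string(body, V_FROM, v["from"]);
    put_field_string(body, V_TO, v["to"]);
    if (notnull(v["to_quality"])) put_field_quals(body, V_TO_QUALITY, v["to_quality"]);
    put_varint(out, T_VARIATION);
    put_varint(out, body.size());
    out.insert(out.end(), body.begin(), body.end());
}

// ---- link (triple form or intra-chunk delta form) ----
void serialize_link(ByteVec &out, int tag, List l) {
    ByteVec body;
    if (l.containsElementNamed("delta")) {
        put_field_varint(body, L_DELTA, zigzag(get_int(l["delta"], "link delta")));
    } else {
        put_field_varint(body, L_POSITION, get_int(l["position"], "link position"));
        put_field_varint(body, L_TARGET_INDEX, get_int(l["target_index"], "link target"));
        put_field_varint(body, L_FRAGMENT_INDEX, get_int(l["fragment_index"], "link fragment"));
    }
    put_varint(out, tag);
    put_varint(out, body.size());
    out.insert(out.end(), body.begin(), body.end());
}

// Serialize one alignment entry body. `with_template_fields` = false drops the
// non-template fields (query index, position, to-quality) to form the
// template key used by template compression.
void serialize_entry_body(ByteVec &out, List e, bool full) {
    if (full) put_field_varint(out, T_QUERY_INDEX, get_int(e["query_index"], "query_index"));
    put_field_varint(out, T_TARGET_INDEX, get_int(e["target_index"], "target_index"));
    if (full) put_field_varint(out, T_POSITION, get_int(e["position"], "position"));
    put_field_varint(out, T_FRAGMENT_INDEX, get_int(e["fragment_index"], "fragment_index"));
    put_field_varint(out, T_REVERSE_STRAND, Rf_asLogical(e["matching_reverse_strand"]) ? 1 : 0);
    put_field_varint(out, T_QUERY_LENGTH, get_int(e["query_length"], "query_length"));
    put_field_varint(out, T_QUERY_ALIGNED, get_int(e["query_aligned_length"], "query_aligned_length"));
    put_field_varint(out, T_TARGET_ALIGNED, get_int(e["target_aligned_length"], "target_aligned_length"));
    put_field_varint(out, T_MAPPING_QUALITY, get_int(e["mapping_quality"], "mapping_quality"));
    {
        float f = static_cast<float>(Rf_asReal(e["score"]));
        uint8_t b[4];
        std::memcpy(b, &f, 4);
        put_field_bytes(out, T_SCORE, b, 4);
    }
    List vars(e["sequence_variations"]);
    for (R_xlen_t i = 0; i < vars.size(); ++i) serialize_variation(out, vars[i]);
    if (notnull(e["pair_link"])) serialize_link(out, T_PAIR_LINK, e["pair_link"]);
    if (notnull(e["splice_forward_link"])) serialize_link(out, T_SPLICE_FWD, e["splice_forward_link"]);
    if (notnull(e["splice_backward_link"])) serialize_link(out, T_SPLICE_BWD, e["splice_backward_link"]);
    if (notnull(e["softclip_left"])) put_field_string(out, T_SOFTCLIP_LEFT, e["softclip_left"]);
    if (notnull(e["softclip_left_quality"])) put_field_quals(out, T_SOFTCLIP_LEFT_Q, e["softclip_left_quality"]);
    if (notnull(e["softclip_right"])) put_field_string(out, T_SOFTCLIP_RIGHT, e["softclip_right"]);
    if (notnull(e["softclip_right_quality"])) put_field_quals(out, T_SOFTCLIP_RIGHT_Q, e["softclip_right_quality"]);
    if (full && notnull(e["to_quality"])) put_field_quals(out, T_TO_QUALITY, e["to_quality"]);
    if (notnull(e["read_origin_index"])) put_field_varint(out, T_READ_ORIGIN, get_int(e["read_origin_index"], "read_origin_index"));
    // unknown fields ride the Left-Over stream under ACT and are re-attached
    // by chunk ordinal, so they are not part of the template key
    if (full && notnull(e["unknown_fields"])) {
        RawVector u(e["unknown_fields"]);
        out.insert(out.end(), u.begin(), u.end());
    }
}

// ---- parsing ----

struct Cursor {
    const uint8_t *p;
    size_t n;
    size_t pos;
    Cursor(const uint8_t *p_, size_t n_) : p(p_), n(n_), pos(0) {}
    bool done() const { return pos >= n; }
    uint64_t varint() { return get_varint(p, n, pos); }
    const uint8_t *take(size_t len) {
        if (pos + len > n) throw std::runtime_error("truncated field payload");
        const uint8_t *q = p + pos;
        pos += len;
        return q;
    }
};

uint64_t payload_varint(const uint8_t *q, size_t len) {
    size_t pos = 0;
    uint64_t v = get_varint(q, len, pos);
    if (pos != len) throw std::runtime_error("trailing bytes in varint field");
    return v;
}

SEXP payload_string(const uint8_t *q, size_t len) {
    return Rf_ScalarString(Rf_mkCharLenCE(reinterpret_cast<const char *>(q), len, CE_NATIVE));
}

SEXP payload_quals(const uint8_t *q, size_t len) {
    IntegerVector out(len);
    for (size_t i = 0; i < len; ++i) out[i] = q[i];
    return out;
}

List parse_variation(const uint8_t *q, size_t len) {
    List v = List::create(
        _["position"] = R_NilValue, _["read_index"] = R_NilValue,
        _["from"] = R_NilValue, _["to"] = R_NilValue, _["to_quality"] = R_NilValue);
    Cursor c(q, len);
    while (!c.done()) {
        uint64_t tag = c.varint();
        uint64_t flen = c.varint();
        const uint8_t *fp = c.take(flen);
        switch (tag) {
        case V_POSITION: v["position"] = static_cast<int>(payload_varint(fp, flen)); break;
        case V_READ_INDEX: v["read_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        case V_FROM: v["from"] = payload_string(fp, flen); break;
        case V_TO: v["to"] = payload_string(fp, flen); break;
        case V_TO_QUALITY: v["to_quality"] = payload_quals(fp, flen); break;
        default: throw std::runtime_error("unknown tag inside variation");
        }
    }
    return v;
}

List parse_link(const uint8_t *q, size_t len) {
    Cursor c(q, len);
    int pos = NA_INTEGER, ti = NA_INTEGER, fi = NA_INTEGER;
    bool have_delta = false;
    int64_t delta = 0;
    while (!c.done()) {
        uint64_t tag = c.varint();
        uint64_t flen = c.varint();
        const uint8_t *fp = c.take(flen);
        switch (tag) {
        case L_POSITION: pos = static_cast<int>(payload_varint(fp, flen)); break;
        case L_TARGET_INDEX: ti = static_cast<int>(payload_varint(fp, flen)); break;
        case L_FRAGMENT_INDEX: fi = static_cast<int>(payload_varint(fp, flen)); break;
        case L_DELTA: have_delta = true; delta = unzigzag(payload_varint(fp, flen)); break;
        default: throw std::runtime_error("unknown tag inside link");
        }
    }
    if (have_delta) return List::create(_["delta"] = static_cast<int>(delta));
    return List::create(_["position"] = pos, _["target_index"] = ti, _["fragment_index"] = fi);
}

const char *ENTRY_FIELDS[] = {
    "query_index", "target_index", "position", "fragment_index",
    "matching_reverse_strand", "query_length", "query_aligned_length",
    "target_aligned_length", "mapping_quality", "score",
    "sequence_variations", "pair_link", "splice_forward_link",
    "splice_backward_link", "softclip_left", "softclip_left_quality",
    "softclip_right", "softclip_right_quality", "to_quality",
    "read_origin_index", "unknown_fields"
};
const int N_ENTRY_FIELDS = 21;

List parse_entry(const uint8_t *q, size_t len) {
    List e(N_ENTRY_FIELDS);
    CharacterVector nm(N_ENTRY_FIELDS);
    for (int i = 0; i < N_ENTRY_FIELDS; ++i) nm[i] = ENTRY_FIELDS[i];
    e.attr("names") = nm;
    std::vector<List> vars;
    ByteVec unknown;
    Cursor c(q, len);
    while (!c.done()) {
        size_t field_start = c.pos;
        uint64_t tag = c.varint();
        uint64_t flen = c.varint();
        const uint8_t *fp = c.take(flen);
        switch (tag) {
        case T_QUERY_INDEX: e["query_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_TARGET_INDEX: e["target_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_POSITION: e["position"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_FRAGMENT_INDEX: e["fragment_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_REVERSE_STRAND: e["matching_reverse_strand"] = payload_varint(fp, flen) != 0; break;
        case T_QUERY_LENGTH: e["query_length"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_QUERY_ALIGNED: e["query_aligned_length"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_TARGET_ALIGNED: e["target_aligned_length"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_MAPPING_QUALITY: e["mapping_quality"] = static_cast<int>(payload_varint(fp, flen)); break;
        case T_SCORE: {
            if (flen != 4) throw std::runtime_error("score field must be 4 bytes");
            float f;
            std::memcpy(&f, fp, 4);
            e["score"] = static_cast<double>(f);
            break;
        }
        case T_VARIATION: vars.push_back(parse_variation(fp, flen)); break;
        case T_PAIR_LINK: e["pair_link"] = parse_link(fp, flen); break;
        case T_SPLICE_FWD: e["splice_forward_link"] = parse_link(fp, flen); break;
        case T_SPLICE_BWD: e["splice_backward_link"] = parse_link(fp, flen); break;
        case T_SOFTCLIP_LEFT: e["softclip_left"] = payload_string(fp, flen); break;
        case T_SOFTCLIP_LEFT_Q: e["softclip_left_quality"] = payload_quals(fp, flen); break;
        case T_SOFTCLIP_RIGHT: e["softclip_right"] = payload_string(fp, flen); break;
        case T_SOFTCLIP_RIGHT_Q: e["softclip_right_quality"] = payload_quals(fp, flen); break;
        case T_TO_QUALITY: e["to_quality"] = payload_quals(fp, flen); break;
        case T_READ_ORIGIN: e["read_origin_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        default:
            // unknown tag: keep the raw framed bytes for re-emission
            unknown.insert(unknown.end(), q + field_start, q + c.pos);
            break;
        }
    }
    List lv(vars.size());
    for (size_t i = 0; i < vars.size(); ++i) lv[i] = vars[i];
    e["sequence_variations"] = lv;
    RawVector u(unknown.size());
    std::copy(unknown.begin(), unknown.end(), u.begin());
    e["unknown_fields"] = u;
    return e;
}

} // namespace

// ---------------------------------------------------------------------------
// Exported collection (de)serializers: varint length prefix per record.

// [[Rcpp::export(name = ".serialize_entries")]]
RawVector serialize_entries_cpp(List entries) {
    ByteVec out;
    ByteVec body;
    for (R_xlen_t i = 0; i < entries.size(); ++i) {
        body.clear();
        serialize_entry_body(body, entries[i], true);
        put_varint(out, body.size());
        out.insert(out.end(), body.begin(), body.end());
    }
    RawVector rv(out.size());
    std::copy(out.begin(), out.end(), rv.begin());
    return rv;
}

// [[Rcpp::export(name = ".deserialize_entries")]]
List deserialize_entries_cpp(RawVector raw) {
    const uint8_t *p = RAW(raw);
    size_t n = raw.size();
    size_t pos = 0;
    std::vector<List> out;
    try {
        while (pos < n) {
            uint64_t len = get_varint(p, n, pos);
            if (pos + len > n) throw std::runtime_error("truncated record");
            out.push_back(parse_entry(p + pos, len));
            pos += len;
        }
    } catch (std::exception &ex) {
        stop("record decode error: %s", ex.what());
    }
    List res(out.size());
    for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
    return res;
}

// Run lengths of consecutive entries whose template (serialized body minus
// query index, position and to-quality) is byte-identical.
// [[Rcpp::export(name = ".template_runs")]]
IntegerVector template_runs_cpp(List entries) {
    std::vector<int> runs;
    ByteVec prev, cur;
    for (R_xlen_t i = 0; i < entries.size(); ++i) {
        cur.clear();
        serialize_entry_body(cur, entries[i], false);
        if (i > 0 && cur == prev) {
            runs.back() += 1;
        } else {
            runs.push_back(1);
        }
        std::swap(prev, cur);
    }
    return IntegerVector(runs.begin(), runs.end());
}

// ---------------------------------------------------------------------------
// Read (Tier I) schema.

namespace {

const char *READ_FIELDS[] = {
    "query_index", "identifier", "description", "sequence", "qualities",
    "pair_sequence", "pair_qualities", "metadata_index", "unknown_fields"
};
const int N_READ_FIELDS = 9;

void serialize_read_body(ByteVec &out, List r) {
    put_field_varint(out, R_QUERY_INDEX, get_int(r["query_index"], "query_index"));
    if (notnull(r["identifier"])) put_field_string(out, R_IDENTIFIER, r["identifier"]);
    if (notnull(r["description"])) put_field_string(out, R_DESCRIPTION, r["description"]);
    put_field_string(out, R_SEQUENCE, r["sequence"]);
    if (notnull(r["qualities"])) put_field_quals(out, R_QUALITIES, r["qualities"]);
    if (notnull(r["pair_sequence"])) put_field_string(out, R_PAIR_SEQUENCE, r["pair_sequence"]);
    if (notnull(r["pair_qualities"])) put_field_quals(out, R_PAIR_QUALITIES, r["pair_qualities"]);
    if (notnull(r["metadata_index"])) put_field_varint(out, R_METADATA, get_int(r["metadata_index"], "metadata_index"));
    if (notnull(r["unknown_fields"])) {
        RawVector u(r["unknown_fields"]);
        out.insert(out.end(), u.begin(), u.end());
    }
}

List parse_read(const uint8_t *q, size_t len) {
    List e(N_READ_FIELDS);
    CharacterVector nm(N_READ_FIELDS);
    for (int i = 0; i < N_READ_FIELDS; ++i) nm[i] = READ_FIELDS[i];
    e.attr("names") = nm;
    ByteVec unknown;
    Cursor c(q, len);
    while (!c.done()) {
        size_t field_start = c.pos;
        uint64_t tag = c.varint();
        uint64_t flen = c.varint();
        const uint8_t *fp = c.take(flen);
        switch (tag) {
        case R_QUERY_INDEX: e["query_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        case R_IDENTIFIER: e["identifier"] = payload_string(fp, flen); break;
        case R_DESCRIPTION: e["description"] = payload_string(fp, flen); break;
        case R_SEQUENCE: e["sequence"] = payload_string(fp, flen); break;
        case R_QUALITIES: e["qualities"] = payload_quals(fp, flen); break;
        case R_PAIR_SEQUENCE: e["pair_sequence"] = payload_string(fp, flen); break;
        case R_PAIR_QUALITIES: e["pair_qualities"] = payload_quals(fp, flen); break;
        case R_METADATA: e["metadata_index"] = static_cast<int>(payload_varint(fp, flen)); break;
        default:
            unknown.insert(unknown.end(), q + field_start, q + c.pos);
            break;
        }
    }
    RawVector u(unknown.size());
    std::copy(unknown.begin(), unknown.end(), u.begin());
    e["unknown_fields"] = u;
    return e;
}

} // namespace

// [[Rcpp::export(name = ".serialize_reads")]]
RawVector serialize_reads_cpp(List reads) {
    ByteVec out, body;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        body.clear();
        serialize_read_body(body, reads[i]);
        put_varint(out, body.size());
        out.insert(out.end(), body.begin(), body.end());
    }
    RawVector rv(out.size());
    std::copy(out.begin(), out.end(), rv.begin());
    return rv;
}

// [[Rcpp::export(name = ".deserialize_reads")]]
List deserialize_reads_cpp(RawVector raw) {
    const uint8_t *p = RAW(raw);
    size_t n = raw.size();
    size_t pos = 0;
    std::vector<List> out;
    try {
        while (pos < n) {
            uint64_t len = get_varint(p, n, pos);
            if (pos + len > n) throw std::runtime_error("truncated record");
            out.push_back(parse_read(p + pos, len));
            pos += len;
        }
    } catch (std::exception &ex) {
        stop("record decode error: %s", ex.what());
    }
    List res(out.size());
    for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
    return res;
}

// Validate that a byte payload parses as well-formed TLV whose tags are all
// outside the known alignment-entry tag range (used by set_unknown_field).
// [[Rcpp::export(name = ".check_unknown_payload")]]
bool check_unknown_payload_cpp(RawVector payload) {
    const uint8_t *p = RAW(payload);
    size_t n = payload.size();
    try {
        Cursor c(p, n);
        while (!c.done()) {
            uint64_t tag = c.varint();
            uint64_t flen = c.varint();
            c.take(flen);
            if (tag >= T_QUERY_INDEX && tag <= T_READ_ORIGIN) return false;
        }
    } catch (std::exception &) {
        return false;
    }
    return true;
}
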