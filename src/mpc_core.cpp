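#include <Rcpp.h>
#include <cstring>
#include "sha256.h"

using namespace Rcpp;

// Gate kinds shared with the R builder.
static const int G_AND = 1, G_XOR = 2, G_NOT = 3, G_CONST = 4;

// Wire convention: wires 0..n_inputs-1 are circuit inputs; gate g (0-based)
// drives wire n_inputs + g.  R passes 1-based wire ids.

static const int LABEL_LEN = 16;  // 128-bit wire labels
static const int TAG_LEN = 8;     // authentication tag per garbled row
static const int ROW_LEN = LABEL_LEN + TAG_LEN;

// ---------------------------------------------------------------------------
// Deterministic byte stream: block i = SHA256(seed32 || i).  Seeded from R so
// transcripts are reproducible; callers supply OS entropy for real runs.
struct Prg {
  uint8_t seed[32];
  uint64_t ctr;
  uint8_t buf[32];
  int avail;
  explicit Prg(const uint8_t *s) : ctr(0), avail(0) {
    std::memcpy(seed, s, 32);
  }
  void refill() {
    uint8_t in[40];
    std::memcpy(in, seed, 32);
    for (int i = 0; i < 8; i++) in[32 + i] = uint8_t(ctr >> (8 * i));
    sha256(in, 40, buf);
    ctr++;
    avail = 32;
  }
  void bytes(uint8_t *out, int n) {
    while (n > 0) {
      if (avail == 0) refill();
      int take = n < avail ? n : avail;
      std::memcpy(out, buf + (32 - avail), take);
      avail -= take;
      out += take;
      n -= take;
    }
  }
};

// [[Rcpp::export(name = ".prg_bytes_cpp")]]
RawVector prg_bytes_cpp(RawVector seed32, int n) {
  if (seed32.size() != 32) stop("PRG seed must be 32 bytes");
  Prg prg(RAW(seed32));
  RawVector out(n);
  prg.bytes(RAW(out), n);
  return out;
}

// [[Rcpp::export(name = ".sha256_cpp")]]
RawVector sha256_cpp(RawVector data) {
  RawVector out(32);
  sha256(RAW(data), data.size(), RAW(out));
  return out;
}

// ---------------------------------------------------------------------------
// Plain (cleartext) evaluation: the correctness oracle for the garbled path.

// [[Rcpp::export(name = ".eval_plain_cpp")]]
IntegerVector eval_plain_cpp(IntegerVector kind, IntegerVector in1,
                             IntegerVector in2, int n_inputs,
                             IntegerVector input_bits) {
  int n_gates = kind.size();
  if (input_bits.size() != n_inputs) stop("input bit count mismatch");
  int n_wires = n_inputs + n_gates;
  std::vector<uint8_t> val(n_wires);
  for (int i = 0; i < n_inputs; i++) {
    int b = input_bits[i];
    if (b != 0 && b != 1) stop("input bits must be 0/1");
    val[i] = uint8_t(b);
  }
  for (int g = 0; g < n_gates; g++) {
    int out = n_inputs + g;
    switch (kind[g]) {
      case G_AND:
        val[out] = val[in1[g] - 1] & val[in2[g] - 1];
        break;
      case G_XOR:
        val[out] = val[in1[g] - 1] ^ val[in2[g] - 1];
        break;
      case G_NOT:
        val[out] = 1 - val[in1[g] - 1];
        break;
      case G_CONST:
        val[out] = uint8_t(in1[g]);
        break;
      default:
        stop("unknown gate kind");
    }
  }
  IntegerVector res(n_wires);
  for (int i = 0; i < n_wires; i++) res[i] = val[i];
  return res;
}

// ---------------------------------------------------------------------------
// Garbling: classic four-row tables with point-and-permute.  Row key is
// SHA256(label_a || label_b || gate_index); the first 16 bytes mask the
// output label, the next 8 bytes are the authentication tag.  NOT gates are
// realised by swapping the input label pair (no table); CONST gates get a
// fresh label pair whose active label the generator discloses.

static inline int flag_of(const uint8_t *label) { return label[15] & 1; }

static void row_key(const uint8_t *la, const uint8_t *lb, uint32_t gid,
                    uint8_t out[32]) {
  uint8_t in[36];
  std::memcpy(in, la, 16);
  std::memcpy(in + 16, lb, 16);
  in[32] = uint8_t(gid);
  in[33] = uint8_t(gid >> 8);
  in[34] = uint8_t(gid >> 16);
  in[35] = uint8_t(gid >> 24);
  sha256(in, 36, out);
}

// [[Rcpp::export(name = ".garble_cpp")]]
List garble_cpp(IntegerVector kind, IntegerVector in1, IntegerVector in2,
                int n_inputs, RawVector seed32) {
  if (seed32.size() != 32) stop("garbling seed must be 32 bytes");
  int n_gates = kind.size();
  int n_wires = n_inputs + n_gates;
  Prg prg(RAW(seed32));

  RawVector lab0(n_wires * LABEL_LEN), lab1(n_wires * LABEL_LEN);
  uint8_t *L0 = RAW(lab0), *L1 = RAW(lab1);

  int n_tab = 0;
  for (int g = 0; g < n_gates; g++)
    if (kind[g] == G_AND || kind[g] == G_XOR) n_tab++;
  RawVector tables(size_t(n_tab) * 4 * ROW_LEN);
  uint8_t *T = RAW(tables);

  // fresh label pair with complementary permute flags
  auto fresh = [&](int w) {
    uint8_t *l0 = L0 + size_t(w) * LABEL_LEN;
    uint8_t *l1 = L1 + size_t(w) * LABEL_LEN;
    prg.bytes(l0, LABEL_LEN);
    prg.bytes(l1, LABEL_LEN);
    l1[15] = uint8_t((l1[15] & 0xFE) | (1 - (l0[15] & 1)));
  };

  for (int w = 0; w < n_inputs; w++) fresh(w);

  int tab_idx = 0;
  for (int g = 0; g < n_gates; g++) {
    int out = n_inputs + g;
    if (kind[g] == G_NOT) {
      int a = in1[g] - 1;
      std::memcpy(L0 + size_t(out) * LABEL_LEN, L1 + size_t(a) * LABEL_LEN,
                  LABEL_LEN);
      std::memcpy(L1 + size_t(out) * LABEL_LEN, L0 + size_t(a) * LABEL_LEN,
                  LABEL_LEN);
      continue;
    }
    if (kind[g] == G_CONST) {
      fresh(out);
      continue;
    }
    fresh(out);
    int a = in1[g] - 1, b = in2[g] - 1;
    uint8_t *rows = T + size_t(tab_idx) * 4 * ROW_LEN;
    for (int va = 0; va <= 1; va++) {
      const uint8_t *la =
          (va ? L1 : L0) + size_t(a) * LABEL_LEN;
      for (int vb = 0; vb <= 1; vb++) {
        const uint8_t *lb = (vb ? L1 : L0) + size_t(b) * LABEL_LEN;
        int ob = (kind[g] == G_AND) ? (va & vb) : (va ^ vb);
        const uint8_t *lo = (ob ? L1 : L0) + size_t(out) * LABEL_LEN;
        uint8_t key[32];
        row_key(la, lb, uint32_t(g), key);
        int pos = 2 * flag_of(la) + flag_of(lb);
        uint8_t *row = rows + size_t(pos) * ROW_LEN;
        for (int i = 0; i < LABEL_LEN; i++) row[i] = lo[i] ^ key[i];
        std::memcpy(row + LABEL_LEN, key + LABEL_LEN, TAG_LEN);
      }
    }
    tab_idx++;
  }
  return List::create(Named("tables") = tables, Named("label0") = lab0,
                      Named("label1") = lab1, Named("n_tables") = n_tab);
}

// Evaluate a garbled circuit.  `active` must carry the active label for every
// input wire and every CONST gate wire (slots identified by `prefilled`);
// remaining slots are computed gate by gate.  Any authentication failure
// aborts: the circuit or a label was corrupted.

// [[Rcpp::export(name = ".eval_garbled_cpp")]]
RawVector eval_garbled_cpp(IntegerVector kind, IntegerVector in1,
                           IntegerVector in2, int n_inputs, RawVector tables,
                           RawVector active_in) {
  int n_gates = kind.size();
  int n_wires = n_inputs + n_gates;
  if (active_in.size() != size_t(n_wires) * LABEL_LEN)
    stop("active label array has wrong size");
  RawVector active = clone(active_in);
  uint8_t *A = RAW(active);
  const uint8_t *T = RAW(tables);
  int tab_idx = 0;
  for (int g = 0; g < n_gates; g++) {
    int out = n_inputs + g;
    if (kind[g] == G_CONST) continue;  // prefilled by generator's message
    if (kind[g] == G_NOT) {
      std::memcpy(A + size_t(out) * LABEL_LEN,
                  A + size_t(in1[g] - 1) * LABEL_LEN, LABEL_LEN);
      continue;
    }
    const uint8_t *la = A + size_t(in1[g] - 1) * LABEL_LEN;
    const uint8_t *lb = A + size_t(in2[g] - 1) * LABEL_LEN;
    uint8_t key[32];
    row_key(la, lb, uint32_t(g), key);
    int pos = 2 * flag_of(la) + flag_of(lb);
    const uint8_t *row = T + (size_t(tab_idx) * 4 + pos) * ROW_LEN;
    if (std::memcmp(row + LABEL_LEN, key + LABEL_LEN, TAG_LEN) != 0)
      stop("garbled row failed authentication at gate %d: corrupted circuit",
           g + 1);
    uint8_t *lo = A + size_t(out) * LABEL_LEN;
    for (int i = 0; i < LABEL_LEN; i++) lo[i] = row[i] ^ key[i];
    tab_idx++;
  }
  return active;
}

// Map active labels back to bits using the generator's label pairs.

// [[Rcpp::export(name = ".decode_labels_cpp")]]
IntegerVector decode_labels_cpp(RawVector active, RawVector label0,
                                RawVector label1, IntegerVector wires) {
  int n = wires.size();
  IntegerVector bits(n);
  const uint8_t *A = RAW(active), *L0 = RAW(label0), *L1 = RAW(label1);
  for (int i = 0; i < n; i++) {
    size_t off = size_t(wires[i] - 1) * LABEL_LEN;
    if (std::memcmp(A + off, L0 + off, LABEL_LEN) == 0)
      bits[i] = 0;
    else if (std::memcmp(A + off, L1 + off, LABEL_LEN) == 0)
      bits[i] = 1;
    else
      stop("output label does not decode at wire %d", wires[i]);
  }
  return bits;
}

// Gather per-wire labels (used to build the generator/evaluator input-label
// messages): picks label0 or label1 per wire according to `bits`.

// [[Rcpp::export(name = ".select_labels_cpp")]]
RawVector select_labels_cpp(RawVector label0, RawVector label1,
                            IntegerVector wires, IntegerVector bits) {
  int n = wires.size();
  RawVector out(size_t(n) * LABEL_LEN);
  const uint8_t *L0 = RAW(label0), *L1 = RAW(label1);
  uint8_t *O = RAW(out);
  for (int i = 0; i < n; i++) {
    size_t off = size_t(wires[i] - 1) * LABEL_LEN;
    const uint8_t *src = bits[i] ? L1 + off : L0 + off;
    std::memcpy(O + size_t(i) * LABEL_LEN, src, LABEL_LEN);
  }
  return out;
}

// Scatter labels into a full-length active array at the given wires.

// [[Rcpp::export(name = ".scatter_labels_cpp")]]
RawVector scatter_labels_cpp(RawVector active, RawVector labels,
                             IntegerVector wires) {
  RawVector out = clone(active);
  uint8_t *O = RAW(out);
  const uint8_t *L = RAW(labels);
  int n = wires.size();
  for (int i = 0; i < n; i++)
    std::memcpy(O + size_t(wires[i] - 1) * LABEL_LEN,
                L + size_t(i) * LABEL_LEN, LABEL_LEN);
  return out;
}
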