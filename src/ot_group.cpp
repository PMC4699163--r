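#include <Rcpp.h>
#include <cstring>
#include "sha256.h"

using namespace Rcpp;

// Naor-Pinkas style semi-honest 1-out-of-2 oblivious transfer over the
// multiplicative group modulo the Mersenne prime p = 2^521 - 1.  The Mersenne
// form keeps modular reduction to a shift-and-add fold.  Elements are 17
// little-endian 32-bit limbs (68 bytes on the wire); exponents are 66-byte
// big-endian strings drawn from a seeded PRG.

static const int NLIMB = 17;
static const int ELEM_BYTES = NLIMB * 4;  // 68
static const int EXP_BYTES = 66;

typedef uint32_t fe[NLIMB];

// p = 2^521 - 1: limbs 0..15 all ones, limb 16 = 2^9 - 1
static const uint32_t P_TOP = 0x1FF;

static void fe_zero(fe r) { std::memset(r, 0, sizeof(fe)); }

static void fe_copy(fe r, const fe a) { std::memcpy(r, a, sizeof(fe)); }

static bool fe_is_ge_p(const fe a) {
  if (a[16] != P_TOP) return a[16] > P_TOP;
  for (int i = 15; i >= 0; i--)
    if (a[i] != 0xFFFFFFFFu) return false;
  return true;  // equal to p
}

// Fold a double-width value below 2^521 (x mod 2^521 + x >> 521 is congruent
// mod p because 2^521 = 1 mod p), then map the single leftover alias p -> 0.
static void fe_reduce(fe r, const uint32_t *t /* 2*NLIMB limbs */) {
  const int LIMBS = 2 * NLIMB + 1;
  uint32_t buf[2 * NLIMB + 1];
  std::memcpy(buf, t, 2 * NLIMB * 4);
  buf[2 * NLIMB] = 0;
  for (;;) {
    bool high = (buf[16] >> 9) != 0;
    for (int i = 17; i < LIMBS && !high; i++)
      if (buf[i]) high = true;
    if (!high) break;
    uint32_t hi[2 * NLIMB + 1];
    const int hn = LIMBS - 16;
    for (int i = 0; i < hn; i++) {
      uint32_t lo_part = buf[16 + i] >> 9;
      uint32_t hi_part = (17 + i < LIMBS) ? (buf[17 + i] << 23) : 0;
      hi[i] = lo_part | hi_part;
    }
    buf[16] &= P_TOP;
    for (int i = 17; i < LIMBS; i++) buf[i] = 0;
    uint64_t c = 0;
    for (int i = 0; i < LIMBS; i++) {
      uint64_t s = uint64_t(buf[i]) + (i < hn ? hi[i] : 0) + c;
      buf[i] = uint32_t(s);
      c = s >> 32;
    }
  }
  fe out;
  for (int i = 0; i < NLIMB; i++) out[i] = buf[i];
  if (fe_is_ge_p(out)) fe_zero(out);  // value < 2^521 and >= p means == p
  fe_copy(r, out);
}

static void fe_mul(fe r, const fe a, const fe b) {
  uint32_t t[2 * NLIMB];
  std::memset(t, 0, sizeof(t));
  for (int i = 0; i < NLIMB; i++) {
    uint64_t carry = 0;
    for (int j = 0; j < NLIMB; j++) {
      uint64_t s = uint64_t(t[i + j]) + uint64_t(a[i]) * b[j] + carry;
      t[i + j] = uint32_t(s);
      carry = s >> 32;
    }
    t[i + NLIMB] = uint32_t(carry);
  }
  fe_reduce(r, t);
}

static void fe_set_u32(fe r, uint32_t v) {
  fe_zero(r);
  r[0] = v;
}

// exponent: big-endian byte string
static void fe_pow(fe r, const fe base, const uint8_t *exp, int exp_len) {
  fe acc;
  fe_set_u32(acc, 1);
  for (int i = 0; i < exp_len; i++) {
    uint8_t byte = exp[i];
    for (int b = 7; b >= 0; b--) {
      fe_mul(acc, acc, acc);
      if ((byte >> b) & 1) fe_mul(acc, acc, base);
    }
  }
  fe_copy(r, acc);
}

static void fe_inv(fe r, const fe a) {
  // Fermat: a^(p-2); p - 2 = 2^521 - 3
  uint8_t exp[66];
  // big-endian bytes of 2^521 - 3: top byte 0x01, then 0xFF..., last 0xFD
  exp[0] = 0x01;
  for (int i = 1; i < 65; i++) exp[i] = 0xFF;
  exp[65] = 0xFD;
  fe_pow(r, a, exp, 66);
}

static void fe_from_raw(fe r, const uint8_t *b) {
  for (int i = 0; i < NLIMB; i++)
    r[i] = uint32_t(b[4 * i]) | (uint32_t(b[4 * i + 1]) << 8) |
           (uint32_t(b[4 * i + 2]) << 16) | (uint32_t(b[4 * i + 3]) << 24);
  if (fe_is_ge_p(r)) stop("malformed group element (not reduced)");
}

static void fe_to_raw(uint8_t *b, const fe a) {
  for (int i = 0; i < NLIMB; i++) {
    b[4 * i] = uint8_t(a[i]);
    b[4 * i + 1] = uint8_t(a[i] >> 8);
    b[4 * i + 2] = uint8_t(a[i] >> 16);
    b[4 * i + 3] = uint8_t(a[i] >> 24);
  }
}

static const uint32_t GEN = 7;  // fixed public group generator

// PRG for exponents (same construction as the garbling PRG)
struct ExpPrg {
  uint8_t seed[32];
  uint64_t ctr;
  explicit ExpPrg(const uint8_t *s) : ctr(0) { std::memcpy(seed, s, 32); }
  void next(uint8_t *out66) {
    uint8_t in[40], h[32];
    for (int blk = 0; blk < 3; blk++) {
      std::memcpy(in, seed, 32);
      uint64_t c = ctr++;
      for (int i = 0; i < 8; i++) in[32 + i] = uint8_t(c >> (8 * i));
      sha256(in, 40, h);
      int off = blk * 22;
      std::memcpy(out66 + off, h, (off + 22 <= 66) ? 22 : 66 - off);
    }
  }
};

// keystream block j for OT index i from group element S
static void ot_keystream(const fe S, uint32_t index, uint8_t *out, int len) {
  uint8_t in[ELEM_BYTES + 8], h[32];
  fe_to_raw(in, S);
  in[ELEM_BYTES] = uint8_t(index);
  in[ELEM_BYTES + 1] = uint8_t(index >> 8);
  in[ELEM_BYTES + 2] = uint8_t(index >> 16);
  in[ELEM_BYTES + 3] = uint8_t(index >> 24);
  int pos = 0;
  uint32_t blk = 0;
  while (pos < len) {
    in[ELEM_BYTES + 4] = uint8_t(blk);
    in[ELEM_BYTES + 5] = uint8_t(blk >> 8);
    in[ELEM_BYTES + 6] = uint8_t(blk >> 16);
    in[ELEM_BYTES + 7] = uint8_t(blk >> 24);
    sha256(in, ELEM_BYTES + 8, h);
    int take = (len - pos < 32) ? len - pos : 32;
    std::memcpy(out + pos, h, take);
    pos += take;
    blk++;
  }
}

// [[Rcpp::export(name = ".ot_sender_setup_cpp")]]
RawVector ot_sender_setup_cpp(RawVector seed32) {
  if (seed32.size() != 32) stop("seed must be 32 bytes");
  ExpPrg prg(RAW(seed32));
  uint8_t c_exp[EXP_BYTES];
  prg.next(c_exp);
  fe g, C;
  fe_set_u32(g, GEN);
  fe_pow(C, g, c_exp, EXP_BYTES);
  RawVector out(ELEM_BYTES);
  fe_to_raw(RAW(out), C);
  return out;
}

// [[Rcpp::export(name = ".ot_receiver_msg1_cpp")]]
List ot_receiver_msg1_cpp(IntegerVector choices, RawVector Craw,
                          RawVector seed32) {
  int n = choices.size();
  if (Craw.size() != ELEM_BYTES) stop("bad group element size");
  fe C, g;
  fe_from_raw(C, RAW(Craw));
  fe_set_u32(g, GEN);
  ExpPrg prg(RAW(seed32));
  RawVector pk0(size_t(n) * ELEM_BYTES), ks(size_t(n) * EXP_BYTES);
  for (int i = 0; i < n; i++) {
    uint8_t *k = RAW(ks) + size_t(i) * EXP_BYTES;
    prg.next(k);
    fe PKb, PK0;
    fe_pow(PKb, g, k, EXP_BYTES);
    int b = choices[i];
    if (b != 0 && b != 1) stop("choice bits must be 0/1");
    if (b == 0) {
      fe_copy(PK0, PKb);
    } else {
      fe inv;
      fe_inv(inv, PKb);
      fe_mul(PK0, C, inv);
    }
    fe_to_raw(RAW(pk0) + size_t(i) * ELEM_BYTES, PK0);
  }
  return List::create(Named("pk0") = pk0, Named("k") = ks);
}

// [[Rcpp::export(name = ".ot_sender_msg2_cpp")]]
List ot_sender_msg2_cpp(RawVector pk0s, RawVector m0, RawVector m1,
                        int msg_len, RawVector Craw, RawVector seed32) {
  int n = pk0s.size() / ELEM_BYTES;
  if (m0.size() != size_t(n) * msg_len || m1.size() != size_t(n) * msg_len)
    stop("message length mismatch");
  fe C, g;
  fe_from_raw(C, RAW(Craw));
  fe_set_u32(g, GEN);
  ExpPrg prg(RAW(seed32));
  RawVector gr(size_t(n) * ELEM_BYTES), e0(size_t(n) * msg_len),
      e1(size_t(n) * msg_len);
  std::vector<uint8_t> key(msg_len);
  for (int i = 0; i < n; i++) {
    uint8_t r_exp[EXP_BYTES];
    prg.next(r_exp);
    fe PK0, PK1, R, S0, S1, inv;
    fe_from_raw(PK0, RAW(pk0s) + size_t(i) * ELEM_BYTES);
    fe_inv(inv, PK0);
    fe_mul(PK1, C, inv);
    fe_pow(R, g, r_exp, EXP_BYTES);
    fe_pow(S0, PK0, r_exp, EXP_BYTES);
    fe_pow(S1, PK1, r_exp, EXP_BYTES);
    fe_to_raw(RAW(gr) + size_t(i) * ELEM_BYTES, R);
    ot_keystream(S0, uint32_t(i), key.data(), msg_len);
    for (int j = 0; j < msg_len; j++)
      RAW(e0)[size_t(i) * msg_len + j] =
          RAW(m0)[size_t(i) * msg_len + j] ^ key[j];
    ot_keystream(S1, uint32_t(i), key.data(), msg_len);
    for (int j = 0; j < msg_len; j++)
      RAW(e1)[size_t(i) * msg_len + j] =
          RAW(m1)[size_t(i) * msg_len + j] ^ key[j];
  }
  return List::create(Named("gr") = gr, Named("e0") = e0, Named("e1") = e1);
}

// [[Rcpp::export(name = ".ot_receiver_finish_cpp")]]
RawVector ot_receiver_finish_cpp(RawVector grs, RawVector e0, RawVector e1,
                                 int msg_len, IntegerVector choices,
                                 RawVector ks) {
  int n = choices.size();
  RawVector out(size_t(n) * msg_len);
  std::vector<uint8_t> key(msg_len);
  for (int i = 0; i < n; i++) {
    fe R, S;
    fe_from_raw(R, RAW(grs) + size_t(i) * ELEM_BYTES);
    fe_pow(S, R, RAW(ks) + size_t(i) * EXP_BYTES, EXP_BYTES);
    ot_keystream(S, uint32_t(i), key.data(), msg_len);
    const uint8_t *eb = (choices[i] ? RAW(e1) : RAW(e0));
    for (int j = 0; j < msg_len; j++)
      RAW(out)[size_t(i) * msg_len + j] =
          eb[size_t(i) * msg_len + j] ^ key[j];
  }
  return out;
}

// exposed for unit tests of the group arithmetic
// [[Rcpp::export(name = ".group_pow_cpp")]]
RawVector group_pow_cpp(RawVector base, RawVector exp_be) {
  fe b, r;
  if (base.size() == 0) {
    fe_set_u32(b, GEN);
  } else {
    fe_from_raw(b, RAW(base));
  }
  fe_pow(r, b, RAW(exp_be), exp_be.size());
  RawVector out(ELEM_BYTES);
  fe_to_raw(RAW(out), r);
  return out;
}

// [[Rcpp::export(name = ".group_mul_cpp")]]
RawVector group_mul_cpp(RawVector a, RawVector b) {
  fe x, y, r;
  fe_from_raw(x, RAW(a));
  fe_from_raw(y, RAW(b));
  fe_mul(r, x, y);
  RawVector out(ELEM_BYTES);
  fe_to_raw(RAW(out), r);
  return out;
}
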