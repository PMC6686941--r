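#include <Rcpp.h>
using namespace Rcpp;

// Packed bit-vector primitives. A strand over n loci is a RawVector of
// ceil(n/8) bytes; locus i lives at byte i/8, bit i%8 (LSB-first). Padding
// bits beyond n are kept at zero by every operation so whole-byte bitwise
// work never leaks state. Index convention: locus 0 = smallest map position.

static inline R_xlen_t n_bytes(const int nbits) {
  return (static_cast<R_xlen_t>(nbits) + 7) / 8;
}

static inline void clear_padding(RawVector &x, const int nbits) {
  const int rem = nbits % 8;
  if (rem != 0 && x.size() > 0)
    x[x.size() - 1] &= static_cast<Rbyte>((1u << rem) - 1u);
}

static inline void check_len(const RawVector &x, const int nbits,
                             const char *what) {
  if (x.size() != n_bytes(nbits))
    stop("%s: packed length %d does not match %d loci", what, (int)x.size(),
         nbits);
}

// [[Rcpp::export(name = ".bits_new")]]
RawVector bits_new(const int nbits, const bool ones) {
  RawVector out(n_bytes(nbits));
  if (ones) {
    std::fill(out.begin(), out.end(), static_cast<Rbyte>(0xFF));
    clear_padding(out, nbits);
  }
  return out;
}

// [[Rcpp::export(name = ".bits_pack")]]
RawVector bits_pack(const LogicalVector &bits) {
  const int nbits = bits.size();
  RawVector out(n_bytes(nbits));
  for (int i = 0; i < nbits; ++i) {
    if (bits[i] == NA_LOGICAL) stop("bits must not contain NA");
    if (bits[i]) out[i >> 3] |= static_cast<Rbyte>(1u << (i & 7));
  }
  return out;
}

// [[Rcpp::export(name = ".bits_unpack")]]
LogicalVector bits_unpack(const RawVector &x, const int nbits) {
  check_len(x, nbits, "unpack");
  LogicalVector out(nbits);
  for (int i = 0; i < nbits; ++i)
    out[i] = (x[i >> 3] >> (i & 7)) & 1u;
  return out;
}

// [[Rcpp::export(name = ".bits_not")]]
RawVector bits_not(const RawVector &x, const int nbits) {
  check_len(x, nbits, "not");
  RawVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = static_cast<Rbyte>(~x[i]);
  clear_padding(out, nbits);
  return out;
}

// [[Rcpp::export(name = ".bits_xor")]]
RawVector bits_xor(const RawVector &a, const RawVector &b) {
  if (a.size() != b.size()) stop("xor: operand lengths differ");
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = static_cast<Rbyte>(a[i] ^ b[i]);
  return out;
}

// [[Rcpp::export(name = ".bits_and")]]
RawVector bits_and(const RawVector &a, const RawVector &b) {
  if (a.size() != b.size()) stop("and: operand lengths differ");
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = static_cast<Rbyte>(a[i] & b[i]);
  return out;
}

// [[Rcpp::export(name = ".bits_or")]]
RawVector bits_or(const RawVector &a, const RawVector &b) {
  if (a.size() != b.size()) stop("or: operand lengths differ");
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = static_cast<Rbyte>(a[i] | b[i]);
  return out;
}

// ones >> k in locus-index space: clears indices 0..k-1, sets k..nbits-1.
static RawVector shift_ones(const int nbits, const int k) {
  RawVector out(n_bytes(nbits));
  if (k >= nbits) return out;
  const int kb = k >> 3, kr = k & 7;
  for (R_xlen_t i = kb; i < out.size(); ++i)
    out[i] = static_cast<Rbyte>(0xFF);
  out[kb] = static_cast<Rbyte>(0xFFu << kr);
  clear_padding(out, nbits);
  return out;
}

// [[Rcpp::export(name = ".bits_shift_ones")]]
RawVector bits_shift_ones(const int nbits, const int k) {
  if (k < 0) stop("shift must be non-negative");
  return shift_ones(nbits, k);
}

// XOR chain of right-shifted replete masks: one event per break index.
// Equivalent to bit j = parity of #{breaks <= j}.
// [[Rcpp::export(name = ".bits_xor_chain")]]
RawVector bits_xor_chain(const int nbits, const IntegerVector &breaks) {
  RawVector mask(n_bytes(nbits)); // zeros
  for (R_xlen_t e = 0; e < breaks.size(); ++e) {
    if (breaks[e] < 0) stop("break index must be non-negative");
    RawVector event = shift_ones(nbits, breaks[e]);
    for (R_xlen_t i = 0; i < mask.size(); ++i)
      mask[i] = static_cast<Rbyte>(mask[i] ^ event[i]);
  }
  return mask;
}

// Mosaic recombination: delta <- (gamma & alpha) | (~gamma & beta).
// [[Rcpp::export(name = ".bits_recombine")]]
RawVector bits_recombine(const RawVector &gamma, const RawVector &alpha,
                         const RawVector &beta, const int nbits) {
  check_len(gamma, nbits, "recombine gamma");
  check_len(alpha, nbits, "recombine alpha");
  check_len(beta, nbits, "recombine beta");
  RawVector out(alpha.size());
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = static_cast<Rbyte>((gamma[i] & alpha[i]) |
                                (static_cast<Rbyte>(~gamma[i]) & beta[i]));
  clear_padding(out, nbits);
  return out;
}

// Per-locus dosage of the "1" allele: alpha bit + beta bit, in {0,1,2}.
// [[Rcpp::export(name = ".bits_dosage")]]
IntegerVector bits_dosage(const RawVector &alpha, const RawVector &beta,
                          const int nbits) {
  check_len(alpha, nbits, "dosage alpha");
  check_len(beta, nbits, "dosage beta");
  IntegerVector out(nbits);
  for (int i = 0; i < nbits; ++i)
    out[i] = ((alpha[i >> 3] >> (i & 7)) & 1u) +
             ((beta[i >> 3] >> (i & 7)) & 1u);
  return out;
}

// [[Rcpp::export(name = ".bits_get")]]
IntegerVector bits_get(const RawVector &x, const int nbits,
                       const IntegerVector &idx0) {
  check_len(x, nbits, "get");
  IntegerVector out(idx0.size());
  for (R_xlen_t j = 0; j < idx0.size(); ++j) {
    const int i = idx0[j];
    if (i < 0 || i >= nbits) stop("locus index out of range");
    out[j] = (x[i >> 3] >> (i & 7)) & 1u;
  }
  return out;
}

// Toggle mask for point events (mutation / gene editing): each event at
// index i contributes (ones >> i) ^ (ones >> (i+1)), a single set bit;
// events are merged by the same XOR chain as crossover masks.
// [[Rcpp::export(name = ".bits_toggle")]]
RawVector bits_toggle(const RawVector &x, const int nbits,
                      const IntegerVector &idx0) {
  check_len(x, nbits, "toggle");
  RawVector mask(n_bytes(nbits));
  for (R_xlen_t j = 0; j < idx0.size(); ++j) {
    const int i = idx0[j];
    if (i < 0 || i >= nbits) stop("locus index out of range");
    RawVector lo = shift_ones(nbits, i);
    RawVector hi = shift_ones(nbits, i + 1);
    for (R_xlen_t b = 0; b < mask.size(); ++b)
      mask[b] = static_cast<Rbyte>(mask[b] ^ (lo[b] ^ hi[b]));
  }
  RawVector out(x.size());
  for (R_xlen_t b = 0; b < out.size(); ++b)
    out[b] = static_cast<Rbyte>(x[b] ^ mask[b]);
  return out;
}

// [[Rcpp::export(name = ".bits_popcount")]]
int bits_popcount(const RawVector &x) {
  int n = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    Rbyte b = x[i];
    while (b) { n += b & 1u; b >>= 1; }
  }
  return n;
}
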