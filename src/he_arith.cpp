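// 128-bit modular arithmetic core for the additively homomorphic layer.
//
// Big integers cross the R boundary as decimal strings; everything internal
// uses unsigned __int128. Supported range: modulus n < 2^64, so ciphertexts
// (residues mod n^2) fit in 128 bits. Multiplication mod a 128-bit modulus
// uses the shift-and-add ("peasant") method so no intermediate exceeds the
// type. Randomness is drawn from R's RNG so set.seed() governs encryption.

#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

typedef unsigned __int128 u128;
typedef __int128 i128;
typedef uint64_t u64;

static const u128 U128_MAX = ~(u128)0;

static u128 parse_dec(const std::string& s) {
  if (s.empty()) stop("empty big-integer string");
  u128 x = 0;
  for (size_t j = 0; j < s.size(); ++j) {
    char ch = s[j];
    if (ch < '0' || ch > '9')
      stop("invalid big-integer string '%s'", s.c_str());
    unsigned d = ch - '0';
    if (x > (U128_MAX - d) / 10)
      stop("big integer exceeds the supported 128-bit range: %s", s.c_str());
    x = x * 10 + d;
  }
  return x;
}

static std::string dec_str(u128 x) {
  if (x == 0) return "0";
  char buf[48];
  int p = 48;
  while (x > 0) { buf[--p] = '0' + (int)(x % 10); x /= 10; }
  return std::string(buf + p, 48 - p);
}

// (a + b) mod m, assuming a, b < m; safe against 128-bit overflow.
static inline u128 addmod(u128 a, u128 b, u128 m) {
  if (a >= m - b) return a - (m - b);
  return a + b;
}

// (a * b) mod m by shift-and-add; a, b < m < 2^128.
static u128 mulmod(u128 a, u128 b, u128 m) {
  if (m == 0) stop("zero modulus");
  a %= m; b %= m;
  // fast path: no overflow possible
  if (m <= (u128)0xFFFFFFFFFFFFFFFFULL) return (a * b) % m;
  u128 res = 0;
  while (b > 0) {
    if (b & 1) res = addmod(res, a, m);
    a = addmod(a, a, m);
    b >>= 1;
  }
  return res;
}

static u128 powmod(u128 base, u128 exp, u128 m) {
  u128 res = 1 % m;
  base %= m;
  while (exp > 0) {
    if (exp & 1) res = mulmod(res, base, m);
    base = mulmod(base, base, m);
    exp >>= 1;
  }
  return res;
}

static u128 gcd_u128(u128 a, u128 b) {
  while (b != 0) { u128 t = a % b; a = b; b = t; }
  return a;
}

// Deterministic Miller-Rabin, valid for all n < 2^64.
static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  static const u64 small[] = {2,3,5,7,11,13,17,19,23,29,31,37};
  for (u64 p : small) {
    if (n == p) return true;
    if (n % p == 0) return false;
  }
  u64 d = n - 1; int r = 0;
  while ((d & 1) == 0) { d >>= 1; ++r; }
  for (u64 a : small) {
    u128 x = powmod(a % n, d, n);
    if (x == 1 || x == n - 1) continue;
    bool composite = true;
    for (int j = 0; j < r - 1; ++j) {
      x = mulmod(x, x, n);
      if (x == n - 1) { composite = false; break; }
    }
    if (composite) return false;
  }
  return true;
}

// Extended Euclid: inverse of a mod m, or 0 if gcd(a, m) != 1. m < 2^64.
static u64 modinv_u64(u64 a, u64 m) {
  i128 t = 0, newt = 1;
  i128 r = (i128)m, newr = (i128)(a % m);
  while (newr != 0) {
    i128 q = r / newr;
    i128 tmp = t - q * newt; t = newt; newt = tmp;
    tmp = r - q * newr; r = newr; newr = tmp;
  }
  if (r != 1) return 0;
  if (t < 0) t += m;
  return (u64)t;
}

// 64-bit draw from R's RNG (two 32-bit halves). Not production crypto.
static u64 rng_u64() {
  u64 hi = (u64)(unif_rand() * 4294967296.0);
  u64 lo = (u64)(unif_rand() * 4294967296.0);
  if (hi > 0xFFFFFFFFULL) hi = 0xFFFFFFFFULL;
  if (lo > 0xFFFFFFFFULL) lo = 0xFFFFFFFFULL;
  return (hi << 32) | lo;
}

// [[Rcpp::export]]
bool cpp_is_prime(std::string x) {
  u128 v = parse_dec(x);
  if (v > (u128)0xFFFFFFFFFFFFFFFFULL)
    stop("primality test supports values < 2^64 only");
  return is_prime_u64((u64)v);
}

// [[Rcpp::export]]
std::string cpp_gen_prime(int bits) {
  if (bits < 4 || bits > 63) stop("prime bit length must be in [4, 63]");
  RNGScope scope;
  for (int tries = 0; tries < 100000; ++tries) {
    u64 cand = rng_u64();
    cand &= (bits == 63) ? 0x7FFFFFFFFFFFFFFFULL : ((1ULL << bits) - 1);
    cand |= (1ULL << (bits - 1)) | 1ULL;  // top bit and oddness
    // walk upward to the next prime within the bit range
    for (int step = 0; step < 20000; ++step) {
      if (is_prime_u64(cand)) return dec_str((u128)cand);
      cand += 2;
      if (bits < 63 && cand >= (1ULL << bits)) break;
    }
  }
  stop("prime generation failed");
}

// [[Rcpp::export]]
std::string cpp_gcd(std::string a, std::string b) {
  return dec_str(gcd_u128(parse_dec(a), parse_dec(b)));
}

// [[Rcpp::export]]
std::string cpp_modinv(std::string a, std::string m) {
  u128 av = parse_dec(a), mv = parse_dec(m);
  if (mv > (u128)0xFFFFFFFFFFFFFFFFULL)
    stop("modular inverse supports moduli < 2^64 only");
  u64 inv = modinv_u64((u64)(av % mv), (u64)mv);
  if (inv == 0 && !(mv == 1))
    return "";  // not invertible; caller reports the gcd
  return dec_str((u128)inv);
}

// [[Rcpp::export]]
std::string cpp_mod_mul(std::string a, std::string b, std::string m) {
  return dec_str(mulmod(parse_dec(a), parse_dec(b), parse_dec(m)));
}

// [[Rcpp::export]]
std::string cpp_mod_pow(std::string base, std::string exp, std::string m) {
  return dec_str(powmod(parse_dec(base), parse_dec(exp), parse_dec(m)));
}

// Encrypt plaintexts m (decimal strings, each < n) under modulus n:
// c = (1 + m*n) * r^n mod n^2 with r uniform in [1, n), gcd(r, n) = 1.
// [[Rcpp::export]]
CharacterVector cpp_he_encrypt(CharacterVector m, std::string n_str) {
  u128 n = parse_dec(n_str);
  if (n < 6 || n > (u128)0xFFFFFFFFFFFFFFFFULL)
    stop("modulus must satisfy 6 <= n < 2^64");
  u128 n2 = n * n;
  RNGScope scope;
  R_xlen_t len = m.size();
  CharacterVector out(len);
  for (R_xlen_t j = 0; j < len; ++j) {
    u128 mj = parse_dec(std::string(m[j]));
    if (mj >= n)
      stop("plaintext %s is outside the message space [0, n) with n = %s",
           std::string(m[j]).c_str(), n_str.c_str());
    u64 r = 0;
    for (int t = 0; t < 10000; ++t) {
      u64 cand = rng_u64() % (u64)n;
      if (cand >= 1 && gcd_u128((u128)cand, n) == 1) { r = cand; break; }
    }
    if (r == 0) stop("failed to draw an encryption nonce coprime to n");
    u128 c = mulmod(1 + mulmod(mj, n, n2), powmod((u128)r, n, n2), n2);
    out[j] = dec_str(c);
  }
  return out;
}

// CRT fast path: same ciphertext value as cpp_he_encrypt (for the same
// nonce r), but the exponentiation r^n runs modulo a^2 and b^2 (both
// < 2^64, so multiplication uses the single-instruction path) and the
// residues are CRT-combined mod n^2. Used when the key's factors are at
// hand, as with RSA-CRT private-key operations.
// [[Rcpp::export]]
CharacterVector cpp_he_encrypt_crt(CharacterVector m, std::string a_str,
                                   std::string b_str) {
  u128 a = parse_dec(a_str), b = parse_dec(b_str);
  u128 n = a * b;
  if (n < 6 || n > (u128)0xFFFFFFFFFFFFFFFFULL)
    stop("modulus must satisfy 6 <= n < 2^64");
  u128 n2 = n * n;
  u128 a2 = a * a, b2 = b * b;
  // reduce the exponent n modulo the group orders a(a-1), b(b-1)
  u128 ea = n % (a * (a - 1)), eb = n % (b * (b - 1));
  u64 a2_inv_b2 = modinv_u64((u64)(a2 % b2), (u64)b2);
  if (a2_inv_b2 == 0) stop("primes are not distinct");
  RNGScope scope;
  R_xlen_t len = m.size();
  CharacterVector out(len);
  for (R_xlen_t j = 0; j < len; ++j) {
    u128 mj = parse_dec(std::string(m[j]));
    if (mj >= n)
      stop("plaintext %s is outside the message space [0, n) with n = %s",
           std::string(m[j]).c_str(), dec_str(n).c_str());
    u64 r = 0;
    for (int t = 0; t < 10000; ++t) {
      u64 cand = rng_u64() % (u64)n;
      if (cand >= 1 && gcd_u128((u128)cand, n) == 1) { r = cand; break; }
    }
    if (r == 0) stop("failed to draw an encryption nonce coprime to n");
    u128 xa = mulmod((1 + mulmod(mj, n, a2)) % a2, powmod((u128)r, ea, a2), a2);
    u128 xb = mulmod((1 + mulmod(mj, n, b2)) % b2, powmod((u128)r, eb, b2), b2);
    u128 diff = (xb + b2 - (xa % b2)) % b2;
    u128 c = xa + a2 * mulmod(diff, (u128)a2_inv_b2, b2);
    if (c >= n2) c %= n2;
    out[j] = dec_str(c);
  }
  return out;
}

// CRT decryption: recovers m mod a and m mod b separately, then combines.
// Works for any pair of distinct odd primes (no gcd(n, omega) = 1 needed).
// [[Rcpp::export]]
CharacterVector cpp_he_decrypt(CharacterVector c, std::string a_str,
                               std::string b_str) {
  u128 a = parse_dec(a_str), b = parse_dec(b_str);
  u128 n = a * b, n2 = n * n;
  u128 a2 = a * a, b2 = b * b;
  u128 g = n + 1;
  // h_p = L_p(g^(p-1) mod p^2)^(-1) mod p, with L_p(u) = (u-1)/p
  u128 la = (powmod(g, a - 1, a2) - 1) / a;
  u128 lb = (powmod(g, b - 1, b2) - 1) / b;
  u64 ha = modinv_u64((u64)(la % a), (u64)a);
  u64 hb = modinv_u64((u64)(lb % b), (u64)b);
  if (ha == 0 || hb == 0) stop("degenerate key: decryption constant not invertible");
  u64 a_inv_b = modinv_u64((u64)(a % b), (u64)b);
  if (a_inv_b == 0) stop("primes are not distinct");
  R_xlen_t len = c.size();
  CharacterVector out(len);
  for (R_xlen_t j = 0; j < len; ++j) {
    u128 cj = parse_dec(std::string(c[j]));
    if (cj >= n2)
      stop("ciphertext outside the space [0, n^2): key mismatch?");
    u128 ua = (powmod(cj, a - 1, a2) - 1) / a;
    u128 ub = (powmod(cj, b - 1, b2) - 1) / b;
    u128 ma = mulmod(ua % a, (u128)ha, a);
    u128 mb = mulmod(ub % b, (u128)hb, b);
    // CRT: m = ma + a * ((mb - ma) * a^-1 mod b)
    u128 diff = (mb + b - (ma % b)) % b;
    u128 m = ma + a * mulmod(diff, (u128)a_inv_b, b);
    out[j] = dec_str(m);
  }
  return out;
}

// Homomorphic addition: ciphertext product mod n^2 (vectorized, recycled
// scalars are handled at the R level).
// [[Rcpp::export]]
CharacterVector cpp_he_add(CharacterVector c1, CharacterVector c2,
                           std::string n_str) {
  u128 n = parse_dec(n_str);
  u128 n2 = n * n;
  if (c1.size() != c2.size()) stop("ciphertext vectors differ in length");
  R_xlen_t len = c1.size();
  CharacterVector out(len);
  for (R_xlen_t j = 0; j < len; ++j) {
    u128 x = parse_dec(std::string(c1[j]));
    u128 y = parse_dec(std::string(c2[j]));
    if (x >= n2 || y >= n2) stop("ciphertext outside the space [0, n^2)");
    out[j] = dec_str(mulmod(x, y, n2));
  }
  return out;
}

// (m1 + m2) mod n on decimal strings; used by the R layer for key wrapping
// and headroom checks, not by tests (tests carry their own oracle).
// [[Rcpp::export]]
std::string cpp_mod_add(std::string a, std::string b, std::string m) {
  u128 mv = parse_dec(m);
  return dec_str(addmod(parse_dec(a) % mv, parse_dec(b) % mv, mv));
}
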