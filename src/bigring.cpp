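// Exact multiprecision integer and cyclotomic-ring arithmetic.
//
// Ciphertext moduli in the leveled scheme are products of word-size primes and
// exceed the 53-bit exact range of R doubles even for small rings, so all
// coefficient arithmetic is done here on sign-magnitude big integers
// (little-endian base-2^32 limbs).  Coefficients cross the R boundary as
// decimal strings in the centered representation (-q/2, q/2].

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

typedef std::vector<uint32_t> Mag; // little-endian, no trailing zero limbs

struct Big {
  int sign; // -1, 0, 1
  Mag mag;
  Big() : sign(0) {}
};

static void trim(Mag &m) {
  while (!m.empty() && m.back() == 0) m.pop_back();
}

static int cmpMag(const Mag &a, const Mag &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static Mag addMag(const Mag &a, const Mag &b) {
  const Mag &x = a.size() >= b.size() ? a : b;
  const Mag &y = a.size() >= b.size() ? b : a;
  Mag r(x.size() + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    uint64_t s = (uint64_t)x[i] + (i < y.size() ? y[i] : 0u) + carry;
    r[i] = (uint32_t)s;
    carry = s >> 32;
  }
  r[x.size()] = (uint32_t)carry;
  trim(r);
  return r;
}

// requires a >= b
static Mag subMag(const Mag &a, const Mag &b) {
  Mag r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t d = (int64_t)a[i] - (i < b.size() ? (int64_t)b[i] : 0) - borrow;
    if (d < 0) { d += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)d;
  }
  trim(r);
  return r;
}

static void mulMagInto(Mag &r, const Mag &a, const Mag &b) {
  r.assign(a.size() + b.size(), 0);
  if (a.empty() || b.empty()) { r.clear(); return; }
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    uint64_t ai = a[i];
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t s = ai * b[j] + r[i + j] + carry;
      r[i + j] = (uint32_t)s;
      carry = s >> 32;
    }
    r[i + b.size()] = (uint32_t)carry;
  }
  trim(r);
}

static Mag mulMag(const Mag &a, const Mag &b) {
  Mag r;
  mulMagInto(r, a, b);
  return r;
}

static Mag mulSmall(const Mag &a, uint32_t c) {
  if (c == 0 || a.empty()) return Mag();
  Mag r(a.size() + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = (uint64_t)a[i] * c + carry;
    r[i] = (uint32_t)s;
    carry = s >> 32;
  }
  r[a.size()] = (uint32_t)carry;
  trim(r);
  return r;
}

static Mag addSmall(const Mag &a, uint32_t c) {
  Mag b;
  if (c) b.push_back(c);
  return addMag(a, b);
}

// divide by a single limb, return remainder
static uint32_t divmodSmall(const Mag &a, uint32_t d, Mag &q) {
  q.assign(a.size(), 0);
  uint64_t rem = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = (rem << 32) | a[i];
    q[i] = (uint32_t)(cur / d);
    rem = cur % d;
  }
  trim(q);
  return (uint32_t)rem;
}

static int nlz32(uint32_t x) {
  int n = 0;
  if (x == 0) return 32;
  while (!(x & 0x80000000u)) { x <<= 1; ++n; }
  return n;
}

// Knuth Algorithm D (Hacker's Delight divmnu, 32-bit limbs)
static void divmodMag(const Mag &u0, const Mag &v0, Mag &q, Mag &r) {
  if (v0.empty()) stop("bigint: division by zero");
  if (cmpMag(u0, v0) < 0) { q.clear(); r = u0; return; }
  if (v0.size() == 1) {
    uint32_t rem = divmodSmall(u0, v0[0], q);
    r.clear();
    if (rem) r.push_back(rem);
    return;
  }
  const size_t n = v0.size();
  const size_t m = u0.size() - n;
  const int s = nlz32(v0[n - 1]);
  // normalized copies
  std::vector<uint32_t> vn(n), un(u0.size() + 1, 0);
  for (size_t i = n; i-- > 1;)
    vn[i] = (s ? (v0[i] << s) | (v0[i - 1] >> (32 - s)) : v0[i]);
  vn[0] = v0[0] << s;
  un[u0.size()] = s ? (u0[u0.size() - 1] >> (32 - s)) : 0;
  for (size_t i = u0.size(); i-- > 1;)
    un[i] = (s ? (u0[i] << s) | (u0[i - 1] >> (32 - s)) : u0[i]);
  un[0] = u0[0] << s;

  q.assign(m + 1, 0);
  const uint64_t b = ((uint64_t)1) << 32;
  for (size_t jj = m + 1; jj-- > 0;) {
    size_t j = jj;
    uint64_t num = ((uint64_t)un[j + n] << 32) | un[j + n - 1];
    uint64_t qhat = num / vn[n - 1];
    uint64_t rhat = num - qhat * vn[n - 1];
    while (qhat >= b ||
           qhat * vn[n - 2] > ((rhat << 32) | un[j + n - 2])) {
      qhat--;
      rhat += vn[n - 1];
      if (rhat >= b) break;
    }
    // multiply and subtract
    int64_t k = 0, t = 0;
    for (size_t i = 0; i < n; ++i) {
      uint64_t p = qhat * vn[i];
      t = (int64_t)un[i + j] - k - (int64_t)(p & 0xFFFFFFFFull);
      un[i + j] = (uint32_t)t;
      k = (int64_t)(p >> 32) - (t >> 32);
    }
    t = (int64_t)un[j + n] - k;
    un[j + n] = (uint32_t)t;
    q[j] = (uint32_t)qhat;
    if (t < 0) { // add back
      q[j]--;
      uint64_t carry = 0;
      for (size_t i = 0; i < n; ++i) {
        uint64_t s2 = (uint64_t)un[i + j] + vn[i] + carry;
        un[i + j] = (uint32_t)s2;
        carry = s2 >> 32;
      }
      un[j + n] = (uint32_t)((uint64_t)un[j + n] + carry);
    }
  }
  trim(q);
  r.assign(n, 0);
  for (size_t i = 0; i < n - 1; ++i)
    r[i] = s ? ((un[i] >> s) | ((uint64_t)un[i + 1] << (32 - s))) : un[i];
  r[n - 1] = un[n - 1] >> s;
  trim(r);
}

// ---- signed wrappers ----

static Big mk(int sign, Mag m) {
  Big b;
  trim(m);
  b.mag = std::move(m);
  b.sign = b.mag.empty() ? 0 : sign;
  return b;
}

static Big bigAdd(const Big &a, const Big &b) {
  if (a.sign == 0) return b;
  if (b.sign == 0) return a;
  if (a.sign == b.sign) return mk(a.sign, addMag(a.mag, b.mag));
  int c = cmpMag(a.mag, b.mag);
  if (c == 0) return Big();
  if (c > 0) return mk(a.sign, subMag(a.mag, b.mag));
  return mk(b.sign, subMag(b.mag, a.mag));
}

static Big bigNeg(const Big &a) { Big r = a; r.sign = -r.sign; return r; }

static Big bigSub(const Big &a, const Big &b) { return bigAdd(a, bigNeg(b)); }

static Big bigMul(const Big &a, const Big &b) {
  if (a.sign == 0 || b.sign == 0) return Big();
  return mk(a.sign * b.sign, mulMag(a.mag, b.mag));
}

static int bigCmp(const Big &a, const Big &b) {
  if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
  int c = cmpMag(a.mag, b.mag);
  return a.sign >= 0 ? c : -c;
}

// truncated division: q = trunc(a/b), r = a - q*b (r has sign of a)
static void bigDivmodTrunc(const Big &a, const Big &b, Big &q, Big &r) {
  Mag qm, rm;
  divmodMag(a.mag, b.mag, qm, rm);
  q = mk(a.sign * b.sign, qm);
  r = mk(a.sign, rm);
}

// euclidean remainder in [0, q) for q > 0
static Big bigModEuclid(const Big &a, const Big &q) {
  if (q.sign <= 0) stop("bigint: modulus must be positive");
  Big quo, rem;
  bigDivmodTrunc(a, q, quo, rem);
  if (rem.sign < 0) rem = bigAdd(rem, q);
  return rem;
}

// centered residue in (-q/2, q/2]
static Big bigModCenter(const Big &a, const Big &q) {
  Big r = bigModEuclid(a, q);
  // if 2r > q then r -= q
  Big twoR = mk(r.sign, mulSmall(r.mag, 2));
  if (bigCmp(twoR, q) > 0) r = bigSub(r, q);
  return r;
}

static Big bigFromU64(uint64_t v) {
  Big b;
  while (v) { b.mag.push_back((uint32_t)v); v >>= 32; }
  b.sign = b.mag.empty() ? 0 : 1;
  return b;
}

// ---- decimal I/O ----

static Big parseBig(const std::string &s) {
  size_t i = 0;
  int sign = 1;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) {
    if (s[i] == '-') sign = -1;
    ++i;
  }
  if (i >= s.size()) stop("bigint: empty numeral");
  Big b;
  while (i < s.size()) {
    uint32_t chunk = 0, mult = 1;
    int k = 0;
    while (i < s.size() && k < 9) {
      char c = s[i];
      if (c < '0' || c > '9') stop("bigint: invalid numeral '%s'", s.c_str());
      chunk = chunk * 10 + (uint32_t)(c - '0');
      mult *= 10;
      ++i;
      ++k;
    }
    b.mag = mulSmall(b.mag, mult);
    b.mag = addSmall(b.mag, chunk);
  }
  trim(b.mag);
  b.sign = b.mag.empty() ? 0 : sign;
  return b;
}

static std::string fmtBig(const Big &b) {
  if (b.sign == 0) return "0";
  Mag cur = b.mag;
  std::string digits;
  while (!cur.empty()) {
    Mag q;
    uint32_t rem = divmodSmall(cur, 1000000000u, q);
    cur = q;
    for (int k = 0; k < 9; ++k) {
      digits.push_back((char)('0' + rem % 10));
      rem /= 10;
    }
  }
  while (digits.size() > 1 && digits.back() == '0') digits.pop_back();
  std::string out;
  if (b.sign < 0) out.push_back('-');
  for (size_t i = digits.size(); i-- > 0;) out.push_back(digits[i]);
  return out;
}

static Big parseSexp(SEXP x) {
  if (TYPEOF(x) == STRSXP) return parseBig(as<std::string>(x));
  double v = as<double>(x);
  if (v != std::floor(v) || std::abs(v) > 9007199254740992.0)
    stop("bigint: non-integer numeric");
  int sign = v < 0 ? -1 : (v > 0 ? 1 : 0);
  Big b = bigFromU64((uint64_t)std::abs(v));
  b.sign = b.mag.empty() ? 0 : sign;
  return b;
}

static std::vector<Big> parseVec(const CharacterVector &x) {
  std::vector<Big> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = parseBig(as<std::string>(x[i]));
  return out;
}

static CharacterVector fmtVec(const std::vector<Big> &v) {
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = fmtBig(v[i]);
  return out;
}

// ---- scalar exports ----

// [[Rcpp::export]]
std::string gs_big_add(SEXP a, SEXP b) { return fmtBig(bigAdd(parseSexp(a), parseSexp(b))); }

// [[Rcpp::export]]
std::string gs_big_sub(SEXP a, SEXP b) { return fmtBig(bigSub(parseSexp(a), parseSexp(b))); }

// [[Rcpp::export]]
std::string gs_big_mul(SEXP a, SEXP b) { return fmtBig(bigMul(parseSexp(a), parseSexp(b))); }

// [[Rcpp::export]]
List gs_big_divmod(SEXP a, SEXP b) {
  Big q, r;
  bigDivmodTrunc(parseSexp(a), parseSexp(b), q, r);
  return List::create(_["q"] = fmtBig(q), _["r"] = fmtBig(r));
}

// [[Rcpp::export]]
std::string gs_big_mod(SEXP a, SEXP q) { return fmtBig(bigModEuclid(parseSexp(a), parseSexp(q))); }

// [[Rcpp::export]]
std::string gs_big_center(SEXP a, SEXP q) { return fmtBig(bigModCenter(parseSexp(a), parseSexp(q))); }

// [[Rcpp::export]]
int gs_big_cmp(SEXP a, SEXP b) { return bigCmp(parseSexp(a), parseSexp(b)); }

// [[Rcpp::export]]
double gs_big_mod_small(SEXP a, double m) {
  if (m < 1 || m > 4294967295.0) stop("modulus out of range");
  Big b = parseSexp(a);
  Mag q;
  uint32_t r = divmodSmall(b.mag, (uint32_t)m, q);
  double out = (double)r;
  if (b.sign < 0 && out != 0) out = m - out;
  return out;
}

// [[Rcpp::export]]
double gs_big_log2(SEXP a) {
  Big b = parseSexp(a);
  if (b.sign == 0) return R_NegInf;
  size_t n = b.mag.size();
  double top = (double)b.mag[n - 1];
  if (n >= 2) top += (double)b.mag[n - 2] / 4294967296.0;
  return (double)(n - 1) * 32.0 + std::log2(top);
}

static Big bigModExp(const Big &base, const Big &expo, const Big &mod) {
  Big result = bigFromU64(1);
  result = bigModEuclid(result, mod);
  Big b = bigModEuclid(base, mod);
  // iterate over bits of expo
  for (size_t limb = 0; limb < expo.mag.size(); ++limb) {
    uint32_t w = expo.mag[limb];
    for (int bit = 0; bit < 32; ++bit) {
      if (w & (1u << bit)) result = bigModEuclid(bigMul(result, b), mod);
      // skip squarings past the top bit
      if (limb == expo.mag.size() - 1 && (w >> (bit + 1)) == 0 &&
          bit == 31 - nlz32(w))
        break;
      b = bigModEuclid(bigMul(b, b), mod);
    }
  }
  return result;
}

// extended Euclid: inverse of a modulo q (q > 1), error if gcd != 1
static bool tryModInv(const Big &a0, const Big &q, Big &inv) {
  Big a = bigModEuclid(a0, q);
  if (a.sign == 0) return false;
  Big r0 = q, r1 = a;
  Big t0, t1 = bigFromU64(1);
  while (r1.sign != 0) {
    Big quo, rem;
    bigDivmodTrunc(r0, r1, quo, rem);
    Big t2 = bigSub(t0, bigMul(quo, t1));
    r0 = r1; r1 = rem;
    t0 = t1; t1 = t2;
  }
  Big one = bigFromU64(1);
  if (bigCmp(r0, one) != 0) return false;
  inv = bigModEuclid(t0, q);
  return true;
}

// [[Rcpp::export]]
std::string gs_big_modinv(SEXP a, SEXP q) {
  Big inv;
  if (!tryModInv(parseSexp(a), parseSexp(q), inv))
    stop("bigint: element not invertible");
  return fmtBig(inv);
}

// Miller-Rabin with the first 25 primes as bases (deterministic for our sizes
// in practice; probabilistic guarantee far below 2^-50 beyond).
// [[Rcpp::export]]
bool gs_is_prime(SEXP nstr) {
  Big n = parseSexp(nstr);
  if (n.sign <= 0) return false;
  static const uint32_t small[25] = {2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31,
                                     37, 41, 43, 47, 53, 59, 61, 67, 71, 73,
                                     79, 83, 89, 97};
  Big one = bigFromU64(1), two = bigFromU64(2);
  if (bigCmp(n, one) == 0) return false;
  for (int i = 0; i < 25; ++i) {
    Big p = bigFromU64(small[i]);
    if (bigCmp(n, p) == 0) return true;
    Mag q;
    if (divmodSmall(n.mag, small[i], q) == 0) return false;
  }
  Big nm1 = bigSub(n, one);
  Big d = nm1;
  int s = 0;
  while (!d.mag.empty() && (d.mag[0] & 1u) == 0) {
    Mag q;
    divmodSmall(d.mag, 2, q);
    d.mag = q;
    ++s;
  }
  for (int i = 0; i < 25; ++i) {
    Big a = bigFromU64(small[i]);
    Big x = bigModExp(a, d, n);
    if (bigCmp(x, one) == 0 || bigCmp(x, nm1) == 0) continue;
    bool witness = true;
    for (int r = 1; r < s; ++r) {
      x = bigModEuclid(bigMul(x, x), n);
      if (bigCmp(x, nm1) == 0) { witness = false; break; }
    }
    if (witness) return false;
  }
  return true;
}

// smallest prime p >= lo with p == res (mod m)
// [[Rcpp::export]]
std::string gs_next_prime_cong(SEXP lo, double m, double res) {
  Big p = parseSexp(lo);
  Big mm = bigFromU64((uint64_t)m);
  Big rr = bigFromU64((uint64_t)res);
  // align p to res mod m
  Big cur = bigModEuclid(p, mm);
  Big diff = bigSub(rr, cur);
  diff = bigModEuclid(diff, mm);
  p = bigAdd(p, diff);
  for (int iter = 0; iter < 2000000; ++iter) {
    CharacterVector tmp(1);
    if (gs_is_prime(wrap(fmtBig(p)))) return fmtBig(p);
    p = bigAdd(p, mm);
  }
  stop("prime search exhausted");
}

// ---- polynomial helpers ----

static std::vector<Big> centerVec(std::vector<Big> v, const Big &q) {
  for (size_t i = 0; i < v.size(); ++i) v[i] = bigModCenter(v[i], q);
  return v;
}

// [[Rcpp::export]]
CharacterVector gs_poly_center(CharacterVector a, SEXP q) {
  return fmtVec(centerVec(parseVec(a), parseSexp(q)));
}

// [[Rcpp::export]]
CharacterVector gs_poly_add(CharacterVector a, CharacterVector b, SEXP qs) {
  if (a.size() != b.size()) stop("length mismatch");
  Big q = parseSexp(qs);
  std::vector<Big> av = parseVec(a), bv = parseVec(b);
  for (size_t i = 0; i < av.size(); ++i)
    av[i] = bigModCenter(bigAdd(av[i], bv[i]), q);
  return fmtVec(av);
}

// [[Rcpp::export]]
CharacterVector gs_poly_sub(CharacterVector a, CharacterVector b, SEXP qs) {
  if (a.size() != b.size()) stop("length mismatch");
  Big q = parseSexp(qs);
  std::vector<Big> av = parseVec(a), bv = parseVec(b);
  for (size_t i = 0; i < av.size(); ++i)
    av[i] = bigModCenter(bigSub(av[i], bv[i]), q);
  return fmtVec(av);
}

// [[Rcpp::export]]
CharacterVector gs_poly_scalmul(CharacterVector a, SEXP c, SEXP qs) {
  Big q = parseSexp(qs), cc = parseSexp(c);
  std::vector<Big> av = parseVec(a);
  for (size_t i = 0; i < av.size(); ++i)
    av[i] = bigModCenter(bigMul(av[i], cc), q);
  return fmtVec(av);
}

// fixed-capacity in-place magnitude accumulation (no allocation in the hot
// loop); acc must have spare headroom limbs so the carry cannot overflow
static inline void addMagInto(Mag &acc, const Mag &x) {
  uint64_t carry = 0;
  size_t i = 0;
  for (; i < x.size(); ++i) {
    uint64_t s = (uint64_t)acc[i] + x[i] + carry;
    acc[i] = (uint32_t)s;
    carry = s >> 32;
  }
  for (; carry; ++i) {
    if (i >= acc.size()) {
      acc.push_back((uint32_t)carry);
      break;
    }
    uint64_t s = (uint64_t)acc[i] + carry;
    acc[i] = (uint32_t)s;
    carry = s >> 32;
  }
}

static inline void mulSmallInto(Mag &out, const Mag &a, uint32_t c) {
  out.resize(a.size() + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = (uint64_t)a[i] * c + carry;
    out[i] = (uint32_t)s;
    carry = s >> 32;
  }
  out[a.size()] = (uint32_t)carry;
  while (!out.empty() && out.back() == 0) out.pop_back();
}

static Big posNegDiff(Mag pos, const Mag &neg) {
  trim(pos);
  Mag n2 = neg;
  trim(n2);
  Big p = mk(1, std::move(pos));
  Big q = mk(1, std::move(n2));
  return bigSub(p, q);
}

// full integer convolution, then reduction mod the cyclotomic:
//  * negacyclic (m = 2n, Phi = x^n + 1): wrap with sign flip
//  * general odd m: fold mod x^m - 1, then reduce degrees n..m-1 with the
//    precomputed rows of x^k mod Phi_m (integer matrix redRows, row k-n)
// Signed values are carried as separate positive/negative magnitude
// accumulators so the hot loops never allocate.
static std::vector<Big> convReduce(const std::vector<Big> &a,
                                   const std::vector<Big> &b, int n,
                                   bool negacyclic, int m,
                                   const IntegerMatrix &redRows) {
  size_t la = 1, lb = 1;
  for (int i = 0; i < n; ++i) {
    if (a[i].mag.size() > la) la = a[i].mag.size();
    if (b[i].mag.size() > lb) lb = b[i].mag.size();
  }
  const size_t accL = la + lb + 3; // product limbs + headroom for n-term sums
  const int clen = 2 * n - 1;
  std::vector<Mag> pos(clen, Mag(accL, 0)), neg(clen, Mag(accL, 0));
  Mag scratch;
  for (int i = 0; i < n; ++i) {
    if (a[i].sign == 0) continue;
    for (int j = 0; j < n; ++j) {
      if (b[j].sign == 0) continue;
      mulMagInto(scratch, a[i].mag, b[j].mag);
      addMagInto(a[i].sign * b[j].sign > 0 ? pos[i + j] : neg[i + j], scratch);
    }
  }
  std::vector<Big> res(n);
  if (negacyclic) {
    for (int k = 0; k < n; ++k) {
      if (k + n <= 2 * n - 2) {
        addMagInto(pos[k], neg[k + n]); // res[k] = conv[k] - conv[k+n]
        addMagInto(neg[k], pos[k + n]);
      }
      res[k] = posNegDiff(std::move(pos[k]), neg[k]);
    }
    return res;
  }
  // fold mod x^m - 1 (conv degree is 2n-2 <= 2m-2)
  for (int k = m; k <= 2 * n - 2; ++k) {
    addMagInto(pos[k - m], pos[k]);
    addMagInto(neg[k - m], neg[k]);
  }
  Mag t1, t2;
  for (int k = n; k < m && k <= 2 * n - 2; ++k) {
    trim(pos[k]);
    trim(neg[k]);
    if (pos[k].empty() && neg[k].empty()) continue;
    const int row = k - n;
    for (int j = 0; j < n; ++j) {
      int c = redRows(row, j);
      if (c == 0) continue;
      uint32_t ac = (uint32_t)(c < 0 ? -c : c);
      if (ac == 1) {
        if (c > 0) {
          addMagInto(pos[j], pos[k]);
          addMagInto(neg[j], neg[k]);
        } else {
          addMagInto(pos[j], neg[k]);
          addMagInto(neg[j], pos[k]);
        }
      } else {
        mulSmallInto(t1, pos[k], ac);
        mulSmallInto(t2, neg[k], ac);
        if (c > 0) {
          addMagInto(pos[j], t1);
          addMagInto(neg[j], t2);
        } else {
          addMagInto(pos[j], t2);
          addMagInto(neg[j], t1);
        }
      }
    }
  }
  for (int j = 0; j < n; ++j) res[j] = posNegDiff(std::move(pos[j]), neg[j]);
  return res;
}

// [[Rcpp::export]]
CharacterVector gs_poly_mul(CharacterVector a, CharacterVector b, SEXP qs,
                            bool negacyclic, int m, IntegerMatrix redRows) {
  if (a.size() != b.size()) stop("length mismatch");
  const int n = (int)a.size();
  Big q = parseSexp(qs);
  std::vector<Big> res =
      convReduce(parseVec(a), parseVec(b), n, negacyclic, m, redRows);
  return fmtVec(centerVec(std::move(res), q));
}

// [[Rcpp::export]]
NumericVector gs_poly_mod_small(CharacterVector a, double t) {
  if (t < 2 || t > 4294967295.0) stop("plaintext modulus out of range");
  std::vector<Big> av = parseVec(a);
  NumericVector out(av.size());
  for (size_t i = 0; i < av.size(); ++i) {
    Mag q;
    uint32_t r = divmodSmall(av[i].mag, (uint32_t)t, q);
    double v = (double)r;
    if (av[i].sign < 0 && v != 0) v = t - v;
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
std::string gs_poly_linf(CharacterVector a) {
  std::vector<Big> av = parseVec(a);
  Big best;
  for (size_t i = 0; i < av.size(); ++i) {
    Big ab = av[i];
    ab.sign = ab.sign < 0 ? 1 : ab.sign;
    if (bigCmp(ab, best) > 0) best = ab;
  }
  return fmtBig(best);
}

// Modulus switch: rescale centered c mod q to modulus q/p, preserving the
// value mod t.  For each coefficient x we pick the small correction a with
// a == x (mod p), a == 0 (mod t); then x' = (x - a)/p.
// [[Rcpp::export]]
CharacterVector gs_bgv_modswitch(CharacterVector c, SEXP qs, SEXP ps, double t) {
  Big q = parseSexp(qs), p = parseSexp(ps);
  Big quo, rem;
  bigDivmodTrunc(q, p, quo, rem);
  if (rem.sign != 0) stop("modswitch: p must divide q");
  Big qprime = quo;
  uint32_t tt = (uint32_t)t;
  // p^{-1} mod t
  Mag tmp;
  uint32_t pmodt = divmodSmall(p.mag, tt, tmp);
  if (pmodt % tt != 1 % tt) {
    // general correction factor p^{-1} mod t must exist
    // (we only need gcd(p,t)=1; the R side arranges p == 1 mod t)
  }
  // compute p^{-1} mod t by brute force (t is small)
  uint32_t pinv = 0;
  for (uint32_t k = 1; k < tt; ++k)
    if ((uint64_t)k * pmodt % tt == 1) { pinv = k; break; }
  if (tt > 1 && pinv == 0) stop("modswitch: gcd(p, t) != 1");

  std::vector<Big> cv = parseVec(c);
  std::vector<Big> out(cv.size());
  for (size_t i = 0; i < cv.size(); ++i) {
    Big a0 = bigModCenter(cv[i], p);
    // residue of a0 mod t in [0, t)
    Mag dq;
    uint32_t r = divmodSmall(a0.mag, tt, dq);
    uint32_t rr = (a0.sign < 0 && r != 0) ? tt - r : r;
    Big a = a0;
    if (rr != 0) {
      int64_t bcorr = (int64_t)((uint64_t)rr * pinv % tt);
      if (2 * bcorr > (int64_t)tt) bcorr -= tt; // centered
      Big pb = bigMul(p, mk(bcorr < 0 ? -1 : 1,
                            bigFromU64((uint64_t)std::llabs(bcorr)).mag));
      a = bigSub(a0, pb);
    }
    Big num = bigSub(cv[i], a);
    Big qq, rm2;
    bigDivmodTrunc(num, p, qq, rm2);
    if (rm2.sign != 0) stop("modswitch: internal divisibility failure");
    out[i] = bigModCenter(qq, qprime);
  }
  return fmtVec(out);
}

// round(t * x / q) half away from zero, for centered x; result mod t in [0,t)
// [[Rcpp::export]]
NumericVector gs_yashe_round_dec(CharacterVector fc, SEXP qs, double t) {
  Big q = parseSexp(qs);
  uint32_t tt = (uint32_t)t;
  std::vector<Big> v = parseVec(fc);
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    Big num = bigMul(v[i], bigFromU64(tt));
    int sgn = num.sign;
    num.sign = std::abs(num.sign);
    // floor((2|num| + q) / (2q)) implements round-half-away for |num|
    Big twoNum = mk(1, mulSmall(num.mag, 2));
    Big numer = bigAdd(twoNum, q);
    Big den = mk(1, mulSmall(q.mag, 2));
    Big quo, rem;
    bigDivmodTrunc(numer, den, quo, rem);
    Mag dq;
    uint32_t r = divmodSmall(quo.mag, tt, dq);
    double val = (double)r;
    if (sgn < 0 && val != 0) val = t - val;
    out[i] = val;
  }
  return out;
}

// scale-invariant multiplication core: integer (centered) negacyclic product
// of c1, c2, then round(t * . / q), centered mod q
// [[Rcpp::export]]
CharacterVector gs_yashe_mult_core(CharacterVector c1, CharacterVector c2,
                                   SEXP qs, double t) {
  const int n = (int)c1.size();
  if ((int)c2.size() != n) stop("length mismatch");
  Big q = parseSexp(qs);
  IntegerMatrix dummy(0, 0);
  std::vector<Big> prod =
      convReduce(parseVec(c1), parseVec(c2), n, true, 2 * n, dummy);
  Big tb = bigFromU64((uint64_t)t);
  Big den = mk(1, mulSmall(q.mag, 2));
  std::vector<Big> out(n);
  for (int i = 0; i < n; ++i) {
    Big num = bigMul(prod[i], tb);
    int sgn = num.sign;
    num.sign = std::abs(num.sign);
    Big numer = bigAdd(mk(1, mulSmall(num.mag, 2)), q);
    Big quo, rem;
    bigDivmodTrunc(numer, den, quo, rem);
    quo.sign = quo.mag.empty() ? 0 : sgn;
    out[i] = bigModCenter(quo, q);
  }
  return fmtVec(out);
}

// balanced base-w decomposition of centered coefficients; lw digits, each in
// (-w/2, w/2]; digit matrix is lw x n
// [[Rcpp::export]]
CharacterMatrix gs_word_decompose(CharacterVector a, SEXP qs, SEXP ws, int lw) {
  Big w = parseSexp(ws);
  std::vector<Big> av = parseVec(a);
  const int n = (int)av.size();
  CharacterMatrix out(lw, n);
  for (int j = 0; j < n; ++j) {
    Big x = av[j];
    for (int i = 0; i < lw; ++i) {
      Big d = bigModCenter(x, w);
      out(i, j) = fmtBig(d);
      Big quo, rem;
      bigDivmodTrunc(bigSub(x, d), w, quo, rem);
      if (rem.sign != 0) stop("decompose: internal divisibility failure");
      x = quo;
    }
    if (x.sign != 0) stop("decompose: %d digits insufficient", lw);
  }
  return out;
}

// ---- polynomial inverse over GF(q)[x] / (x^n + 1), q prime ----

typedef std::vector<Big> Poly; // coefficients in [0, q), ascending

static int pdeg(const Poly &p) {
  for (int i = (int)p.size() - 1; i >= 0; --i)
    if (p[i].sign != 0) return i;
  return -1;
}

static void polyDivmodField(const Poly &a, const Poly &b, const Big &q,
                            Poly &quo, Poly &rem) {
  int db = pdeg(b);
  if (db < 0) stop("poly division by zero");
  rem = a;
  int da = pdeg(rem);
  quo.assign(std::max(0, da - db + 1), Big());
  Big lcInv;
  if (!tryModInv(b[db], q, lcInv)) stop("leading coefficient not invertible");
  while (da >= db) {
    Big c = bigModEuclid(bigMul(rem[da], lcInv), q);
    quo[da - db] = c;
    for (int i = 0; i <= db; ++i) {
      Big t = bigModEuclid(bigMul(c, b[i]), q);
      rem[da - db + i] = bigModEuclid(bigSub(rem[da - db + i], t), q);
    }
    da = pdeg(rem);
  }
}

static Poly polyMulModQ(const Poly &a, const Poly &b, const Big &q) {
  Poly r(std::max(0, pdeg(a) + pdeg(b) + 1), Big());
  if (r.empty()) return r;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i].sign == 0) continue;
    for (size_t j = 0; j < b.size(); ++j) {
      if (b[j].sign == 0) continue;
      r[i + j] = bigModEuclid(bigAdd(r[i + j], bigMul(a[i], b[j])), q);
    }
  }
  return r;
}

static Poly polySubModQ(const Poly &a, const Poly &b, const Big &q) {
  Poly r(std::max(a.size(), b.size()), Big());
  for (size_t i = 0; i < r.size(); ++i) {
    Big x = i < a.size() ? a[i] : Big();
    Big y = i < b.size() ? b[i] : Big();
    r[i] = bigModEuclid(bigSub(x, y), q);
  }
  return r;
}

// [[Rcpp::export]]
List gs_poly_inv_negacyclic(CharacterVector f, SEXP qs) {
  const int n = (int)f.size();
  Big q = parseSexp(qs);
  Poly r0(n + 1, Big()); // x^n + 1
  r0[0] = bigFromU64(1);
  r0[n] = bigFromU64(1);
  Poly r1(n, Big());
  {
    std::vector<Big> fv = parseVec(f);
    for (int i = 0; i < n; ++i) r1[i] = bigModEuclid(fv[i], q);
  }
  Poly t0(1, Big()), t1(1, Big());
  t1[0] = bigFromU64(1);
  while (pdeg(r1) > 0) {
    Poly quo, rem;
    polyDivmodField(r0, r1, q, quo, rem);
    Poly t2 = polySubModQ(t0, polyMulModQ(quo, t1, q), q);
    r0 = r1; r1 = rem;
    t0 = t1; t1 = t2;
  }
  if (pdeg(r1) < 0)
    return List::create(_["ok"] = false);
  Big cInv;
  if (!tryModInv(r1[0], q, cInv))
    return List::create(_["ok"] = false);
  // inv = t1 / r1[0]; reduce mod x^n + 1 (degree < n by construction, but be safe)
  Poly inv(n, Big());
  for (size_t i = 0; i < t1.size(); ++i) {
    if (t1[i].sign == 0) continue;
    Big v = bigModEuclid(bigMul(t1[i], cInv), q);
    size_t pos = i % (size_t)n;
    bool flip = ((i / (size_t)n) % 2) == 1; // x^n == -1
    if (flip) v = bigModEuclid(bigSub(Big(), v), q);
    inv[pos] = bigModEuclid(bigAdd(inv[pos], v), q);
  }
  std::vector<Big> out(n);
  for (int i = 0; i < n; ++i) out[i] = bigModCenter(inv[i], q);
  return List::create(_["ok"] = true, _["inv"] = fmtVec(out));
}

// uniform sampling of n coefficients mod q (centered), driven by R's RNG
// [[Rcpp::export]]
CharacterVector gs_sample_uniform(int n, SEXP qs) {
  Big q = parseSexp(qs);
  const size_t nl = q.mag.size();
  const uint32_t topMask =
      q.mag[nl - 1] >= 0x7FFFFFFFu
          ? 0xFFFFFFFFu
          : ((1u << (32 - nlz32(q.mag[nl - 1]))) - 1u);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    Big x;
    for (int guard = 0; guard < 10000; ++guard) {
      x.mag.assign(nl, 0);
      for (size_t l = 0; l < nl; ++l) {
        uint32_t hi = (uint32_t)(unif_rand() * 65536.0);
        uint32_t lo = (uint32_t)(unif_rand() * 65536.0);
        if (hi >= 65536u) hi = 65535u;
        if (lo >= 65536u) lo = 65535u;
        x.mag[l] = (hi << 16) | lo;
      }
      x.mag[nl - 1] &= topMask;
      trim(x.mag);
      x.sign = x.mag.empty() ? 0 : 1;
      if (cmpMag(x.mag, q.mag) < 0) break;
    }
    out[i] = fmtBig(bigModCenter(x, q));
  }
  return out;
}
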