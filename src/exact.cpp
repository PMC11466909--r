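// Exact computational kernel.
//
// Everything here works over arbitrary-precision rationals
// (boost::multiprecision::cpp_rational, header-only via BH), so that all
// feasibility and sign decisions reported to R are certified, not floating
// point.  Components:
//   * univariate polynomial arithmetic over Q, Sturm sequences, real-root
//     isolation on an interval;
//   * algebraic numbers as (squarefree polynomial, isolating interval) with
//     exact sign evaluation of further polynomials at them;
//   * the reduced Jacobian core M(alpha) = Gamma diag(h(alpha)) A of a planar
//     mass-action network on the kernel-cone cross-section, and the derived
//     decisions (zero eigenvalue, accompanying eigenvalue signs, purely
//     imaginary pair, double zero);
//   * focal values L1, L2, L3 of the Hopf point family, computed by the
//     Poincare-Lyapunov recursion in the quadratic extension Q(alpha)[omega],
//     omega^2 = det J(alpha), and their exact sign analysis over the
//     feasible domain;
//   * Bogdanov-Takens normal-form coefficients a20, b11, b20 and the sign
//     sigma = sign((a20+b11) b20) in the quadratic number field containing
//     the double-zero root, plus exact transversality ranks.

#include <Rcpp.h>
#include <boost/multiprecision/cpp_int.hpp>
#include <vector>
#include <string>
#include <sstream>

using namespace Rcpp;
using boost::multiprecision::cpp_int;
using boost::multiprecision::cpp_rational;

typedef cpp_rational Q;
typedef std::vector<Q> Poly;  // ascending coefficients

static int sgn(const Q& x) { return x == 0 ? 0 : (x > 0 ? 1 : -1); }

static Q q_from_double(double d) {
  if (d != std::floor(d) || std::fabs(d) > 4503599627370496.0)
    stop("non-integral coefficient passed to exact kernel");
  return Q(cpp_int(static_cast<long long>(d)));
}

static std::string q_str(const Q& x) {
  std::ostringstream os; os << x; return os.str();
}

static double q_dbl(const Q& x) {
  return static_cast<double>(numerator(x)) / static_cast<double>(denominator(x));
}

// ---------------------------------------------------------------- polynomials

static void p_trim(Poly& p) { while (!p.empty() && p.back() == 0) p.pop_back(); }
static bool p_zero(const Poly& p) { return p.empty(); }
static int p_deg(const Poly& p) { return (int)p.size() - 1; }

static Poly p_from(const NumericVector& v) {
  Poly p(v.size());
  for (int i = 0; i < v.size(); ++i) p[i] = q_from_double(v[i]);
  p_trim(p);
  return p;
}

static Poly p_const(const Q& c) { Poly p; if (c != 0) p.push_back(c); return p; }

static Poly p_add(const Poly& a, const Poly& b) {
  Poly r(std::max(a.size(), b.size()), Q(0));
  for (size_t i = 0; i < a.size(); ++i) r[i] += a[i];
  for (size_t i = 0; i < b.size(); ++i) r[i] += b[i];
  p_trim(r);
  return r;
}

static Poly p_neg(const Poly& a) {
  Poly r(a);
  for (auto& c : r) c = -c;
  return r;
}

static Poly p_sub(const Poly& a, const Poly& b) { return p_add(a, p_neg(b)); }

static Poly p_mul(const Poly& a, const Poly& b) {
  if (p_zero(a) || p_zero(b)) return Poly();
  Poly r(a.size() + b.size() - 1, Q(0));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      r[i + j] += a[i] * b[j];
  p_trim(r);
  return r;
}

static Poly p_scal(const Poly& a, const Q& c) {
  if (c == 0) return Poly();
  Poly r(a);
  for (auto& x : r) x *= c;
  return r;
}

static Q p_eval(const Poly& p, const Q& x) {
  Q r = 0;
  for (int i = p_deg(p); i >= 0; --i) r = r * x + p[i];
  return r;
}

static Poly p_deriv(const Poly& p) {
  if (p.size() <= 1) return Poly();
  Poly r(p.size() - 1);
  for (size_t i = 1; i < p.size(); ++i) r[i - 1] = p[i] * Q(cpp_int(i));
  return r;
}

// remainder of a by b (field division)
static Poly p_rem(Poly a, const Poly& b) {
  if (p_zero(b)) stop("polynomial division by zero");
  while (!p_zero(a) && p_deg(a) >= p_deg(b)) {
    Q f = a.back() / b.back();
    int shift = p_deg(a) - p_deg(b);
    for (size_t i = 0; i < b.size(); ++i) a[i + shift] -= f * b[i];
    a.pop_back();
    p_trim(a);
  }
  return a;
}

static Poly p_quot(Poly a, const Poly& b) {
  if (p_zero(b)) stop("polynomial division by zero");
  if (p_deg(a) < p_deg(b)) return Poly();
  Poly q(p_deg(a) - p_deg(b) + 1, Q(0));
  while (!p_zero(a) && p_deg(a) >= p_deg(b)) {
    Q f = a.back() / b.back();
    int shift = p_deg(a) - p_deg(b);
    q[shift] = f;
    for (size_t i = 0; i < b.size(); ++i) a[i + shift] -= f * b[i];
    a.pop_back();
    p_trim(a);
  }
  return q;
}

static Poly p_monic(Poly p) {
  if (p_zero(p)) return p;
  Q lead = p.back();
  for (auto& c : p) c /= lead;
  return p;
}

static Poly p_gcd(Poly a, Poly b) {
  while (!p_zero(b)) {
    Poly r = p_rem(a, b);
    a = b;
    b = r;
  }
  return p_monic(a);
}

static Poly p_squarefree(const Poly& p) {
  if (p_deg(p) <= 0) return p;
  Poly g = p_gcd(p, p_deriv(p));
  if (p_deg(g) <= 0) return p;
  return p_quot(p, g);
}

// ---------------------------------------------------------------- Sturm

static std::vector<Poly> sturm_chain(const Poly& p) {
  std::vector<Poly> ch;
  ch.push_back(p);
  ch.push_back(p_deriv(p));
  while (!p_zero(ch.back())) {
    Poly r = p_neg(p_rem(ch[ch.size() - 2], ch.back()));
    if (p_zero(r)) break;
    ch.push_back(r);
  }
  return ch;
}

static int sturm_var(const std::vector<Poly>& ch, const Q& x) {
  int v = 0, last = 0;
  for (const auto& p : ch) {
    int s = sgn(p_eval(p, x));
    if (s == 0) continue;
    if (last != 0 && s != last) ++v;
    last = s;
  }
  return v;
}

// number of distinct real roots in half-open (lo, hi]
static int sturm_count(const std::vector<Poly>& ch, const Q& lo, const Q& hi) {
  return sturm_var(ch, lo) - sturm_var(ch, hi);
}

// an algebraic real number: either exact rational, or the unique root of a
// squarefree polynomial in an open interval with a strict sign change
struct Alg {
  bool exact;
  Q val;         // if exact
  Poly p;        // defining squarefree polynomial (if !exact)
  Q lo, hi;      // isolating interval, p(lo) p(hi) < 0
};

static Alg alg_exact(const Q& v) { Alg a; a.exact = true; a.val = v; return a; }

static void alg_refine(Alg& a) {
  if (a.exact) return;
  Q mid = (a.lo + a.hi) / 2;
  Q pm = p_eval(a.p, mid);
  if (pm == 0) { a.exact = true; a.val = mid; return; }
  if (sgn(pm) == sgn(p_eval(a.p, a.lo))) a.lo = mid; else a.hi = mid;
}

static Q alg_lb(const Alg& a) { return a.exact ? a.val : a.lo; }
static Q alg_ub(const Alg& a) { return a.exact ? a.val : a.hi; }

// interval evaluation of g on [lo, hi] (Horner with interval arithmetic)
static void ieval(const Poly& g, const Q& lo, const Q& hi, Q& out_lo, Q& out_hi) {
  Q a = 0, b = 0; // running interval [a, b]
  bool first = true;
  for (int i = p_deg(g); i >= 0; --i) {
    if (first) { a = b = g[i]; first = false; continue; }
    // [a,b] * [lo,hi]
    Q c1 = a * lo, c2 = a * hi, c3 = b * lo, c4 = b * hi;
    Q mn = std::min(std::min(c1, c2), std::min(c3, c4));
    Q mx = std::max(std::max(c1, c2), std::max(c3, c4));
    a = mn + g[i];
    b = mx + g[i];
  }
  if (first) { a = b = 0; }
  out_lo = a; out_hi = b;
}

// exact sign of g at the algebraic number a
static int alg_sign(const Poly& g_in, Alg a) {
  Poly g = g_in;
  if (p_zero(g)) return 0;
  if (a.exact) return sgn(p_eval(g, a.val));
  // common root?
  Poly c = p_gcd(a.p, g);
  if (p_deg(c) >= 1) {
    if (sgn(p_eval(c, a.lo)) * sgn(p_eval(c, a.hi)) < 0) return 0;
    std::vector<Poly> ch = sturm_chain(c);
    if (sturm_count(ch, a.lo, a.hi) > 0) return 0;
  }
  for (int it = 0; it < 20000; ++it) {
    Q glo, ghi;
    ieval(g, a.lo, a.hi, glo, ghi);
    if (glo > 0) return 1;
    if (ghi < 0) return -1;
    alg_refine(a);
    if (a.exact) return sgn(p_eval(g, a.val));
  }
  stop("alg_sign failed to converge");
  return 0;
}

// isolate all distinct real roots of p in the OPEN interval (lo, hi)
static std::vector<Alg> isolate(const Poly& p_in, const Q& lo, const Q& hi) {
  std::vector<Alg> out;
  Poly p = p_squarefree(p_in);
  if (p_deg(p) <= 0) return out;
  std::vector<Poly> ch = sturm_chain(p);
  std::vector<std::pair<Q, Q>> stack;
  stack.push_back(std::make_pair(lo, hi));
  while (!stack.empty()) {
    Q a = stack.back().first, b = stack.back().second;
    stack.pop_back();
    // count roots in open (a, b): count (a, b] minus root at b
    int n = sturm_count(ch, a, b);
    if (p_eval(p, b) == 0) --n;
    if (n <= 0) continue;
    Q mid = (a + b) / 2;
    if (p_eval(p, mid) == 0) {
      out.push_back(alg_exact(mid));
      stack.push_back(std::make_pair(a, mid));
      stack.push_back(std::make_pair(mid, b));
      continue;
    }
    if (n == 1 && sgn(p_eval(p, a)) * sgn(p_eval(p, b)) < 0 &&
        p_eval(p, a) != 0) {
      Alg r; r.exact = false; r.p = p; r.lo = a; r.hi = b;
      out.push_back(r);
      continue;
    }
    stack.push_back(std::make_pair(a, mid));
    stack.push_back(std::make_pair(mid, b));
  }
  // sort by interval midpoint (intervals of a squarefree poly are disjoint)
  std::sort(out.begin(), out.end(), [](const Alg& x, const Alg& y) {
    return alg_lb(x) + alg_ub(x) < alg_lb(y) + alg_ub(y);
  });
  return out;
}

// sample rational points in the gaps of a sorted root list within (lo, hi)
static std::vector<Q> gap_samples(std::vector<Alg>& roots, const Q& lo, const Q& hi) {
  std::vector<Q> s;
  // make all roots pairwise separated and interior
  for (size_t i = 0; i < roots.size(); ++i) {
    while (!(alg_lb(roots[i]) > lo && alg_ub(roots[i]) < hi)) alg_refine(roots[i]);
  }
  for (size_t i = 0; i + 1 < roots.size(); ++i) {
    while (!(alg_ub(roots[i]) < alg_lb(roots[i + 1]))) {
      alg_refine(roots[i]);
      alg_refine(roots[i + 1]);
    }
  }
  if (roots.empty()) { s.push_back((lo + hi) / 2); return s; }
  s.push_back((lo + alg_lb(roots.front())) / 2);
  for (size_t i = 0; i + 1 < roots.size(); ++i)
    s.push_back((alg_ub(roots[i]) + alg_lb(roots[i + 1])) / 2);
  s.push_back((alg_ub(roots.back()) + hi) / 2);
  return s;
}

// ---------------------------------------------------------------- rational functions

struct RatF {
  Poly num, den; // den never zero; normalised with positive leading coeff
  RatF() { den = p_const(Q(1)); }
  RatF(const Poly& n, const Poly& d) : num(n), den(d) { normalise(); }
  explicit RatF(const Poly& n) : num(n) { den = p_const(Q(1)); }
  explicit RatF(const Q& c) { num = p_const(c); den = p_const(Q(1)); }
  void normalise() {
    if (p_zero(den)) stop("rational function with zero denominator");
    if (p_zero(num)) { den = p_const(Q(1)); return; }
    Poly g = p_gcd(num, den);
    if (p_deg(g) >= 1) { num = p_quot(num, g); den = p_quot(den, g); }
    Q lead = den.back();
    for (auto& c : num) c /= lead;
    for (auto& c : den) c /= lead;
  }
  bool is_zero() const { return p_zero(num); }
};

static RatF rf_add(const RatF& a, const RatF& b) {
  return RatF(p_add(p_mul(a.num, b.den), p_mul(b.num, a.den)), p_mul(a.den, b.den));
}
static RatF rf_sub(const RatF& a, const RatF& b) {
  return RatF(p_sub(p_mul(a.num, b.den), p_mul(b.num, a.den)), p_mul(a.den, b.den));
}
static RatF rf_mul(const RatF& a, const RatF& b) {
  return RatF(p_mul(a.num, b.num), p_mul(a.den, b.den));
}
static RatF rf_div(const RatF& a, const RatF& b) {
  if (b.is_zero()) stop("rational function division by zero");
  return RatF(p_mul(a.num, b.den), p_mul(a.den, b.num));
}
static RatF rf_neg(const RatF& a) { RatF r = a; r.num = p_neg(r.num); return r; }
static RatF rf_scal(const RatF& a, const Q& c) { return RatF(p_scal(a.num, c), a.den); }
static Q rf_eval(const RatF& a, const Q& x) {
  Q d = p_eval(a.den, x);
  if (d == 0) stop("rational function pole at sample point");
  return p_eval(a.num, x) / d;
}

// elements u + v*omega of Q(alpha)[omega], omega^2 = Delta(alpha)
struct FElem { RatF u, v; };

struct FCtx { RatF Delta; };

static FElem fe_zero() { FElem e; return e; }
static FElem fe_of(const RatF& u) { FElem e; e.u = u; return e; }
static FElem fe_omega() { FElem e; e.v = RatF(Q(1)); return e; }
static bool fe_is_zero(const FElem& a) { return a.u.is_zero() && a.v.is_zero(); }
static FElem fe_add(const FElem& a, const FElem& b) {
  FElem r; r.u = rf_add(a.u, b.u); r.v = rf_add(a.v, b.v); return r;
}
static FElem fe_sub(const FElem& a, const FElem& b) {
  FElem r; r.u = rf_sub(a.u, b.u); r.v = rf_sub(a.v, b.v); return r;
}
static FElem fe_neg(const FElem& a) { FElem r; r.u = rf_neg(a.u); r.v = rf_neg(a.v); return r; }
static FElem fe_mul(const FCtx& cx, const FElem& a, const FElem& b) {
  FElem r;
  r.u = rf_add(rf_mul(a.u, b.u), rf_mul(rf_mul(a.v, b.v), cx.Delta));
  r.v = rf_add(rf_mul(a.u, b.v), rf_mul(a.v, b.u));
  return r;
}
static FElem fe_scalq(const FElem& a, const Q& c) {
  FElem r; r.u = rf_scal(a.u, c); r.v = rf_scal(a.v, c); return r;
}
static FElem fe_scal(const FElem& a, const RatF& c) {
  FElem r; r.u = rf_mul(a.u, c); r.v = rf_mul(a.v, c); return r;
}
static FElem fe_inv(const FCtx& cx, const FElem& a) {
  // 1/(u + v w) = (u - v w) / (u^2 - v^2 Delta)
  RatF n = rf_sub(rf_mul(a.u, a.u), rf_mul(rf_mul(a.v, a.v), cx.Delta));
  if (n.is_zero()) stop("field inverse of zero-norm element");
  FElem r;
  r.u = rf_div(a.u, n);
  r.v = rf_div(rf_neg(a.v), n);
  return r;
}
static FElem fe_div(const FCtx& cx, const FElem& a, const FElem& b) {
  return fe_mul(cx, a, fe_inv(cx, b));
}

// exact sign of (u + v sqrt(d)) given rationals u, v and d > 0
static int sign_quadext(const Q& u, const Q& v, const Q& d) {
  if (v == 0) return sgn(u);
  if (u == 0) return sgn(v);
  if (sgn(u) == sgn(v)) return sgn(u);
  Q lhs = u * u, rhs = v * v * d;
  if (lhs == rhs) return 0;
  return (lhs > rhs) ? sgn(u) : sgn(v);
}

// sign of a field element at a rational point (Delta(x) must be >= 0)
static int fe_sign_at(const FCtx& cx, const FElem& a, const Q& x) {
  Q d = rf_eval(cx.Delta, x);
  if (d < 0) stop("omega^2 negative at sample point");
  return sign_quadext(rf_eval(a.u, x), rf_eval(a.v, x), d);
}

// ------------------------------------------------------- network core set-up

struct Core {
  // all polynomials in alpha
  Poly h[8];          // h_j(alpha), up to m = 8 reactions
  int m;
  Poly M11, M12, M21, M22, detM, trM_irrelevant;
  std::vector<std::vector<int>> G;  // gamma 2 x m
  std::vector<std::vector<int>> Aexp; // A m x 2 (reactant exponents)
};

static Core build_core(const IntegerMatrix& gamma, const IntegerMatrix& A,
                       const NumericVector& r1, const NumericVector& r2) {
  Core c;
  c.m = gamma.ncol();
  if (c.m > 8) stop("too many reactions");
  c.G.assign(2, std::vector<int>(c.m));
  c.Aexp.assign(c.m, std::vector<int>(2));
  for (int j = 0; j < c.m; ++j) {
    c.G[0][j] = gamma(0, j);
    c.G[1][j] = gamma(1, j);
    c.Aexp[j][0] = A(j, 0);
    c.Aexp[j][1] = A(j, 1);
  }
  for (int j = 0; j < c.m; ++j) {
    // h_j = alpha r1_j + (1 - alpha) r2_j = r2_j + alpha (r1_j - r2_j)
    Poly h;
    h.push_back(q_from_double(r2[j]));
    h.push_back(q_from_double(r1[j]) - q_from_double(r2[j]));
    p_trim(h);
    c.h[j] = h;
  }
  // M(alpha) = Gamma diag(h) A,  M_ik = sum_j Gamma_ij h_j A_jk
  Poly M[2][2];
  for (int i = 0; i < 2; ++i)
    for (int k = 0; k < 2; ++k) {
      Poly s;
      for (int j = 0; j < c.m; ++j) {
        Q gij(c.G[i][j]);
        Q ajk(c.Aexp[j][k]);
        if (gij == 0 || ajk == 0) continue;
        s = p_add(s, p_scal(c.h[j], gij * ajk));
      }
      M[i][k] = s;
    }
  c.M11 = M[0][0]; c.M12 = M[0][1]; c.M21 = M[1][0]; c.M22 = M[1][1];
  c.detM = p_sub(p_mul(c.M11, c.M22), p_mul(c.M12, c.M21));
  return c;
}

// -------------------------------------------- reduced-core decision analysis

// [[Rcpp::export]]
List core_analysis_cpp(IntegerMatrix gamma, IntegerMatrix A,
                       NumericVector r1, NumericVector r2) {
  Core c = build_core(gamma, A, r1, r2);
  Q lo(0), hi(1);
  bool detm_nonzero = !p_zero(c.detM);

  std::vector<Alg> droots = isolate(c.detM, lo, hi);
  bool zero_eig = !droots.empty();

  bool neg_possible = false, pos_possible = false, double_zero = false;
  bool forced_dz = zero_eig;  // all roots nilpotent so far
  List root_info;
  for (auto& r : droots) {
    int s11 = alg_sign(c.M11, r);
    int s22 = alg_sign(c.M22, r);
    if (s11 < 0 || s22 < 0) neg_possible = true;
    if (s11 > 0 || s22 > 0) pos_possible = true;
    if ((long)s11 * s22 < 0) double_zero = true;
    if (!(s11 == 0 && s22 == 0)) forced_dz = false;
    root_info.push_back(List::create(
      _["lo"] = q_dbl(alg_lb(r)), _["hi"] = q_dbl(alg_ub(r)),
      _["lo_str"] = q_str(alg_lb(r)), _["hi_str"] = q_str(alg_ub(r)),
      _["exact"] = r.exact,
      _["sign_M11"] = s11, _["sign_M22"] = s22));
  }
  if (!zero_eig) forced_dz = false;

  // purely imaginary pair: exists alpha in (0,1) with detM > 0, M11*M22 < 0
  bool hopf = false;
  {
    Poly prod = p_mul(c.detM, p_mul(c.M11, c.M22));
    std::vector<Alg> pts = isolate(prod, lo, hi);
    std::vector<Q> samples = gap_samples(pts, lo, hi);
    for (const Q& s : samples) {
      if (sgn(p_eval(c.detM, s)) > 0 &&
          sgn(p_eval(c.M11, s)) * sgn(p_eval(c.M22, s)) < 0) {
        hopf = true;
        break;
      }
    }
  }

  return List::create(
    _["detm_nonzero"] = detm_nonzero,
    _["zero_eigenvalue"] = zero_eig,
    _["n_det_roots"] = (int)droots.size(),
    _["neg_possible"] = neg_possible,
    _["pos_possible"] = pos_possible,
    _["double_zero"] = double_zero,
    _["forced_double_zero"] = forced_dz,
    _["hopf_feasible"] = hopf,
    _["roots"] = root_info);
}

// ------------------------------------------------------- generic root helpers

// [[Rcpp::export]]
List poly_roots_cpp(NumericVector coefs, double lo, double hi) {
  Poly p = p_from(coefs);
  // bounds are exchanged as dyadic rationals with denominator 4096
  Q L(cpp_int((long long)std::llround(lo * 4096)), cpp_int(4096));
  Q H(cpp_int((long long)std::llround(hi * 4096)), cpp_int(4096));
  std::vector<Alg> roots = isolate(p, L, H);
  int n = roots.size();
  NumericVector approx(n);
  CharacterVector los(n), his(n);
  for (int i = 0; i < n; ++i) {
    Alg r = roots[i];
    for (int k = 0; k < 30 && !r.exact; ++k) alg_refine(r);
    approx[i] = (q_dbl(alg_lb(r)) + q_dbl(alg_ub(r))) / 2;
    los[i] = q_str(alg_lb(roots[i]));
    his[i] = q_str(alg_ub(roots[i]));
  }
  return List::create(_["count"] = n, _["approx"] = approx,
                      _["lo"] = los, _["hi"] = his,
                      _["identically_zero"] = p_zero(p) && coefs.size() > 0);
}

// signs of each polynomial in `gs` at each root of `p` in (lo, hi)
// [[Rcpp::export]]
List signs_at_roots_cpp(NumericVector pcoefs, List gs, double lo, double hi) {
  Poly p = p_from(pcoefs);
  Q L(cpp_int((long long)std::llround(lo * 4096)), cpp_int(4096));
  Q H(cpp_int((long long)std::llround(hi * 4096)), cpp_int(4096));
  std::vector<Alg> roots = isolate(p, L, H);
  IntegerMatrix out(roots.size(), gs.size());
  for (size_t i = 0; i < roots.size(); ++i)
    for (int j = 0; j < gs.size(); ++j)
      out(i, j) = alg_sign(p_from(gs[j]), roots[i]);
  NumericVector approx(roots.size());
  for (size_t i = 0; i < roots.size(); ++i) {
    Alg r = roots[i];
    for (int k = 0; k < 30 && !r.exact; ++k) alg_refine(r);
    approx[i] = (q_dbl(alg_lb(r)) + q_dbl(alg_ub(r))) / 2;
  }
  return List::create(_["n_roots"] = (int)roots.size(), _["signs"] = out,
                      _["approx"] = approx);
}

// ------------------------------------------------------------- focal values

// homogeneous bivariate polynomial of degree k: coeffs[i] * x^(k-i) y^i
typedef std::vector<FElem> HPoly;

static HPoly h_zero(int k) { return HPoly(k + 1, fe_zero()); }

static HPoly h_mul(const FCtx& cx, const HPoly& a, const HPoly& b) {
  int ka = a.size() - 1, kb = b.size() - 1;
  HPoly r = h_zero(ka + kb);
  for (int i = 0; i <= ka; ++i)
    for (int j = 0; j <= kb; ++j)
      r[i + j] = fe_add(r[i + j], fe_mul(cx, a[i], b[j]));
  return r;
}

static HPoly h_dx(const HPoly& a) {
  // d/dx of degree-k homogeneous: term x^(k-i) y^i -> (k-i) x^(k-i-1) y^i
  int k = a.size() - 1;
  if (k == 0) return HPoly();
  HPoly r = h_zero(k - 1);
  for (int i = 0; i <= k - 1; ++i) r[i] = fe_scalq(a[i], Q(k - i));
  return r;
}

static HPoly h_dy(const HPoly& a) {
  int k = a.size() - 1;
  if (k == 0) return HPoly();
  HPoly r = h_zero(k - 1);
  for (int i = 1; i <= k; ++i) r[i - 1] = fe_scalq(a[i], Q(i));
  return r;
}

// Solve Rot(V) [+ eta m] = R for homogeneous degree k, where
// Rot(x^a y^b) = b x^(a+1) y^(b-1) - a x^(a-1) y^(b+1).
// For even k the kernel direction (x^2+y^2)^(k/2) is fixed to coefficient 0
// and eta is returned; for odd k eta is absent.
struct RotSolve { HPoly V; FElem eta; bool has_eta; };

static RotSolve rot_solve(const FCtx& cx, int k, const HPoly& R) {
  int n = k + 1;
  bool even = (k % 2 == 0);
  int ncol = n + (even ? 1 : 0);
  // build rational matrix: columns = images of basis monomials under Rot,
  // plus (even) the coefficients of (x^2+y^2)^(k/2)
  std::vector<std::vector<Q>> Mt(n, std::vector<Q>(ncol, Q(0)));
  for (int i = 0; i <= k; ++i) {
    int a = k - i, b = i;
    if (b > 0) Mt[i - 1][i] += Q(b);   // x∂y part: to row (i-1)
    if (a > 0) Mt[i + 1][i] -= Q(a);   // -y∂x part: to row (i+1)
  }
  if (even) {
    // (x^2+y^2)^(k/2): coefficient of x^(k-i) y^i is C(k/2, i/2) for even i
    int h = k / 2;
    std::vector<Q> binom(h + 1, Q(1));
    for (int i = 1; i <= h; ++i) binom[i] = binom[i - 1] * Q(h - i + 1) / Q(i);
    for (int i = 0; i <= k; i += 2) Mt[i][n] = binom[i / 2];
  }
  // Gaussian elimination on [Mt | R] with FElem RHS
  std::vector<FElem> rhs(R);
  std::vector<int> pivot_col;
  int row = 0;
  std::vector<int> col_of_row;
  for (int col = 0; col < ncol && row < n; ++col) {
    int pr = -1;
    for (int i = row; i < n; ++i) if (Mt[i][col] != 0) { pr = i; break; }
    if (pr < 0) continue;
    std::swap(Mt[pr], Mt[row]);
    std::swap(rhs[pr], rhs[row]);
    Q pv = Mt[row][col];
    for (int j = 0; j < ncol; ++j) Mt[row][j] /= pv;
    rhs[row] = fe_scalq(rhs[row], Q(1) / pv);
    for (int i = 0; i < n; ++i) {
      if (i == row) continue;
      Q f = Mt[i][col];
      if (f == 0) continue;
      for (int j = 0; j < ncol; ++j) Mt[i][j] -= f * Mt[row][j];
      rhs[i] = fe_sub(rhs[i], fe_scalq(rhs[row], f));
    }
    pivot_col.push_back(col);
    col_of_row.push_back(col);
    ++row;
  }
  // consistency: rows beyond pivots must have zero rhs
  for (int i = row; i < n; ++i)
    if (!fe_is_zero(rhs[i])) stop("rot_solve: inconsistent homological equation");
  RotSolve out;
  out.V = h_zero(k);
  out.eta = fe_zero();
  out.has_eta = even;
  for (int r2i = 0; r2i < row; ++r2i) {
    int col = col_of_row[r2i];
    if (col < n) out.V[col] = rhs[r2i];
    else out.eta = rhs[r2i];
  }
  return out;
}

struct Focal {
  FCtx cx;
  FElem eta2, eta3, eta4;  // ~ L1, L2, L3 up to positive factors
  bool valid;
};

// build the rotated, time-rescaled quadratic field and run the recursion.
// `s` is the x2 coordinate of the equilibrium (x1 = 1) as a function of the
// free variable: on the trace-zero curve s = -M22/M11; at a fixed
// cross-section point with M11 = M22 = 0 the variable IS x2 and s = id.
static Focal focal_values(const Core& c, const RatF& s, int maxk) {
  Focal F;
  F.valid = false;
  RatF M11((Poly)c.M11), M12((Poly)c.M12), M21((Poly)c.M21), M22((Poly)c.M22);
  RatF detM((Poly)c.detM);
  if (M12.is_zero()) return F;
  RatF a = M11;                                 // J11
  RatF b = rf_div(M12, s);                      // J12
  RatF Delta = rf_div(detM, s);                 // det J = omega^2
  F.cx.Delta = Delta;
  FCtx& cx = F.cx;

  // quadratic part of the field at the equilibrium (1, s):
  // c20_i, c11_i, c02_i with kappa_j = h_j / s^(a_j2)
  RatF c20[2], c11[2], c02[2];
  for (int i = 0; i < 2; ++i) { c20[i] = RatF(Q(0)); c11[i] = RatF(Q(0)); c02[i] = RatF(Q(0)); }
  for (int j = 0; j < c.m; ++j) {
    int a1 = c.Aexp[j][0], a2 = c.Aexp[j][1];
    if (a1 + a2 != 2) continue;
    RatF kap = RatF((Poly)c.h[j]);
    for (int t = 0; t < a2; ++t) kap = rf_div(kap, s);
    for (int i = 0; i < 2; ++i) {
      if (c.G[i][j] == 0) continue;
      RatF term = rf_scal(kap, Q(c.G[i][j]));
      if (a1 == 2) c20[i] = rf_add(c20[i], term);
      else if (a1 == 1) c11[i] = rf_add(c11[i], term);
      else c02[i] = rf_add(c02[i], term);
    }
  }

  // F_i(z1, z2) after u = P z with P = [[b, 0], [-a, omega]]:
  //   coefficient of z1^2 :  c20 b^2 - c11 a b + c02 a^2
  //   coefficient of z1z2 :  (c11 b - 2 c02 a) * omega
  //   coefficient of z2^2 :  c02 * omega^2 = c02 * Delta
  FElem Fz[2][3];
  for (int i = 0; i < 2; ++i) {
    RatF z1z1 = rf_add(rf_sub(rf_mul(c20[i], rf_mul(b, b)),
                              rf_mul(c11[i], rf_mul(a, b))),
                       rf_mul(c02[i], rf_mul(a, a)));
    RatF z1z2_coef = rf_sub(rf_mul(c11[i], b), rf_scal(rf_mul(c02[i], a), Q(2)));
    RatF z2z2 = rf_mul(c02[i], Delta);
    Fz[i][0] = fe_of(z1z1);
    Fz[i][1] = fe_mul(cx, fe_of(z1z2_coef), fe_omega());
    Fz[i][2] = fe_of(z2z2);
  }

  // g = P^{-1} F,  P^{-1} = (1/(b omega)) [[omega, 0], [a, b]]
  //   g1 = F1 / b
  //   g2 = (a F1 + b F2) / (b omega)
  FElem g1[3], g2[3];
  FElem inv_b = fe_inv(cx, fe_of(b));
  FElem inv_bw = fe_inv(cx, fe_mul(cx, fe_of(b), fe_omega()));
  for (int t = 0; t < 3; ++t) {
    g1[t] = fe_mul(cx, Fz[0][t], inv_b);
    FElem num = fe_add(fe_mul(cx, fe_of(a), Fz[0][t]), fe_mul(cx, fe_of(b), Fz[1][t]));
    g2[t] = fe_mul(cx, num, inv_bw);
  }

  // swap coordinates (x, y) = (z2, z1) and rescale time by omega:
  //   xdot = -y + p(x,y),  ydot = x + q(x,y)
  //   p = g2(z1=y, z2=x)/omega,  q = g1(z1=y, z2=x)/omega
  FElem inv_w = fe_inv(cx, fe_omega());
  HPoly p = h_zero(2), q = h_zero(2);
  // term z1^2 -> y^2 (index 2), z1z2 -> xy (index 1), z2^2 -> x^2 (index 0)
  p[2] = fe_mul(cx, g2[0], inv_w);
  p[1] = fe_mul(cx, g2[1], inv_w);
  p[0] = fe_mul(cx, g2[2], inv_w);
  q[2] = fe_mul(cx, g1[0], inv_w);
  q[1] = fe_mul(cx, g1[1], inv_w);
  q[0] = fe_mul(cx, g1[2], inv_w);

  // Poincare-Lyapunov recursion:
  // V2 = (x^2 + y^2)/2; for k >= 3:
  //   Rot(V_k) + dx(V_{k-1}) p + dy(V_{k-1}) q = [eta_{k/2} (x^2+y^2)^{k/2}]
  std::vector<HPoly> V(maxk + 1);
  V[2] = h_zero(2);
  V[2][0] = fe_of(RatF(Q(1) / Q(2)));
  V[2][2] = fe_of(RatF(Q(1) / Q(2)));
  for (int k = 3; k <= maxk; ++k) {
    HPoly R = h_zero(k);
    HPoly dxv = h_dx(V[k - 1]), dyv = h_dy(V[k - 1]);
    if (!dxv.empty()) {
      HPoly t1 = h_mul(cx, dxv, p);
      for (int i = 0; i <= k; ++i) R[i] = fe_add(R[i], t1[i]);
    }
    if (!dyv.empty()) {
      HPoly t2 = h_mul(cx, dyv, q);
      for (int i = 0; i <= k; ++i) R[i] = fe_add(R[i], t2[i]);
    }
    // Rot(V_k) = eta (x2+y2)^{k/2} - R
    HPoly Rm(k + 1);
    for (int i = 0; i <= k; ++i) Rm[i] = fe_neg(R[i]);
    RotSolve sol = rot_solve(cx, k, Rm);
    V[k] = sol.V;
    if (k == 4) F.eta2 = fe_neg(sol.eta);
    if (k == 6) F.eta3 = fe_neg(sol.eta);
    if (k == 8) F.eta4 = fe_neg(sol.eta);
  }
  F.valid = true;
  return F;
}
// note on signs: with Rot(V_k) + R_k = eta (x2+y2)^{k/2} we pass -R_k as the
// right-hand side of Rot(V_k) - eta (x2+y2)^{k/2} = -R_k; rot_solve returns
// that eta with a flipped sign, undone above (fe_neg), so eta_j is the
// coefficient in  dV/dt = sum_j eta_j (x^2+y^2)^j; eta < 0 means stable focus.

// evaluate a field element's sign at an algebraic point (needs Delta(pt) > 0)
static int fe_sign_at_alg(const FCtx& cx, const FElem& e, const Alg& pt) {
  // u + v omega, omega = sqrt(Delta):
  // decide via signs of u, v and of u^2 - v^2 Delta at pt
  Poly nu = p_mul(e.u.num, e.v.den); // u ~ nu / (du dv) with shared denominators
  Poly nv = p_mul(e.v.num, e.u.den);
  Poly shared_den = p_mul(e.u.den, e.v.den);
  int sden = alg_sign(shared_den, pt);
  if (sden == 0) stop("field element pole at algebraic point");
  int su = alg_sign(nu, pt) * sden;
  int sv = alg_sign(nv, pt) * sden;
  if (sv == 0) return su;
  if (su == 0) return sv;
  if (su == sv) return su;
  // compare u^2 vs v^2 Delta:  nu^2 * Dden  vs  nv^2 * Dnum  (times positive)
  Poly lhs = p_mul(p_mul(nu, nu), cx.Delta.den);
  Poly rhs = p_mul(p_mul(nv, nv), cx.Delta.num);
  int sd = alg_sign(cx.Delta.den, pt);
  if (sd == 0) stop("Delta pole at algebraic point");
  // u^2 - v^2 Delta  ~  (lhs - rhs) / (shared^2 * Dden); shared^2 > 0
  int scmp = alg_sign(p_sub(lhs, rhs), pt) * sd;
  if (scmp == 0) return 0;
  return (scmp > 0) ? su : sv;
}

// [[Rcpp::export]]
List hopf_classify_cpp(IntegerMatrix gamma, IntegerMatrix A,
                       NumericVector r1, NumericVector r2,
                       bool want_l2l3 = true) {
  Core c = build_core(gamma, A, r1, r2);
  Q lo(0), hi(1);

  // subdivision polynomials for the feasible region
  Poly region_prod = p_mul(c.detM, p_mul(c.M11, p_mul(c.M22, c.M12)));
  std::vector<Alg> bpts = isolate(region_prod, lo, hi);
  std::vector<Q> samples0 = gap_samples(bpts, lo, hi);
  std::vector<Q> region_samples;
  for (const Q& s : samples0)
    if (sgn(p_eval(c.detM, s)) > 0 &&
        sgn(p_eval(c.M11, s)) * sgn(p_eval(c.M22, s)) < 0)
      region_samples.push_back(s);
  if (region_samples.empty())
    return List::create(_["feasible"] = false);

  RatF M11r((Poly)c.M11), M22r((Poly)c.M22);
  if (M11r.is_zero() || M22r.is_zero())
    stop("identically vanishing diagonal entry: use the fixed-alpha pipeline");
  RatF s = rf_div(rf_neg(M22r), M11r);
  // L1 first; the degree-8 stages are only needed when L1 has zeros
  Focal F = focal_values(c, s, 4);
  if (!F.valid) stop("focal value construction failed");
  FCtx& cx = F.cx;

  bool l1_zero_fun = fe_is_zero(F.eta2);
  std::string cls;
  int l1_neg = 0, l1_pos = 0;
  List l1zero_info;

  if (l1_zero_fun) {
    F = focal_values(c, s, 8);
    bool l2z = fe_is_zero(F.eta3);
    bool l3z = fe_is_zero(F.eta4);
    cls = (l2z && l3z) ? "vertical" : "degenerate-unexpected";
    return List::create(
      _["feasible"] = true, _["classification"] = cls,
      _["l1_identically_zero"] = true,
      _["l2_identically_zero"] = l2z, _["l3_identically_zero"] = l3z);
  }

  // critical points: region boundary + zeros/poles of L1
  RatF Nrf = rf_sub(rf_mul(F.eta2.u, F.eta2.u),
                    rf_mul(rf_mul(F.eta2.v, F.eta2.v), cx.Delta));
  Poly crit = region_prod;
  if (!p_zero(Nrf.num)) crit = p_mul(crit, Nrf.num);
  crit = p_mul(crit, F.eta2.u.den);
  crit = p_mul(crit, F.eta2.v.den);
  std::vector<Alg> cpts = isolate(crit, lo, hi);
  std::vector<Q> samples = gap_samples(cpts, lo, hi);
  for (const Q& s : samples) {
    if (!(sgn(p_eval(c.detM, s)) > 0 &&
          sgn(p_eval(c.M11, s)) * sgn(p_eval(c.M22, s)) < 0)) continue;
    int sig = fe_sign_at(cx, F.eta2, s);
    if (sig < 0) ++l1_neg;
    if (sig > 0) ++l1_pos;
    if (sig == 0) stop("L1 exactly zero at a sample point");
  }

  // interior zeros of L1: critical points inside the open region with L1 = 0
  std::vector<Alg> l1_zero_pts;
  for (auto& ptc : cpts) {
    Alg pt = ptc;
    int sdet = alg_sign(c.detM, pt);
    if (sdet <= 0) continue;
    int s11 = alg_sign(c.M11, pt), s22 = alg_sign(c.M22, pt);
    if ((long)s11 * s22 >= 0) continue;
    if (fe_sign_at_alg(cx, F.eta2, pt) == 0) l1_zero_pts.push_back(pt);
  }
  int n_l1_zeros = (int)l1_zero_pts.size();
  bool all_l2_zero = true, all_l3_zero = true, all_l2_nonzero = true;
  int l2_sign_common = 0;
  if (n_l1_zeros > 0 && want_l2l3) {
    F = focal_values(c, s, 8);  // now need L2, L3
    for (auto& pt : l1_zero_pts) {
      int sl2 = fe_sign_at_alg(cx, F.eta3, pt);
      if (sl2 == 0) {
        all_l2_nonzero = false;
        if (fe_sign_at_alg(cx, F.eta4, pt) != 0) all_l3_zero = false;
      } else {
        all_l2_zero = false;
        if (l2_sign_common == 0) l2_sign_common = sl2;
        else if (l2_sign_common != sl2) l2_sign_common = 99;
      }
      l1zero_info.push_back(List::create(
        _["approx"] = (q_dbl(alg_lb(pt)) + q_dbl(alg_ub(pt))) / 2,
        _["l2_sign"] = sl2));
    }
  }

  if (n_l1_zeros == 0) {
    if (l1_neg > 0 && l1_pos == 0) cls = "supercritical";
    else if (l1_pos > 0 && l1_neg == 0) cls = "subcritical";
    else cls = "mixed-disconnected";
  } else {
    if (all_l2_zero && all_l3_zero) cls = "mixed";
    else if (all_l2_nonzero) cls = "bautin";
    else cls = "degenerate-unexpected";
  }

  return List::create(
    _["feasible"] = true,
    _["classification"] = cls,
    _["l1_identically_zero"] = false,
    _["l1_neg_samples"] = l1_neg, _["l1_pos_samples"] = l1_pos,
    _["n_l1_zeros"] = n_l1_zeros,
    _["l2_sign"] = l2_sign_common,
    _["l1_zeros"] = l1zero_info);
}

// L1 (eta2) components evaluated at a rational alpha: returns u, v, Delta
// as strings, for cross-checking against independent numerics.
// [[Rcpp::export]]
List l1_components_cpp(IntegerMatrix gamma, IntegerMatrix A,
                       NumericVector r1, NumericVector r2,
                       double alpha_num, double alpha_den) {
  Core c = build_core(gamma, A, r1, r2);
  RatF s = rf_div(rf_neg(RatF((Poly)c.M22)), RatF((Poly)c.M11));
  Focal F = focal_values(c, s, 4);
  if (!F.valid) stop("focal value construction failed");
  Q alpha = q_from_double(alpha_num) / q_from_double(alpha_den);
  Q u = rf_eval(F.eta2.u, alpha);
  Q v = rf_eval(F.eta2.v, alpha);
  Q D = rf_eval(F.cx.Delta, alpha);
  int sg_l1 = sign_quadext(u, v, D);
  return List::create(_["u"] = q_str(u), _["v"] = q_str(v),
                      _["Delta"] = q_str(D), _["sign"] = sg_l1,
                      _["value_num"] = q_dbl(u) + q_dbl(v) * std::sqrt(q_dbl(D)));
}

// Focal-value classification of the Hopf-point line at a fixed kernel-cone
// point where both diagonal entries of M vanish: the trace is then zero for
// every positive x, the free variable is x2 itself (x1 = 1), and the Hopf
// set is the whole ray x2 in (0, inf).  `hvec` is the (cleared-to-integer)
// kernel vector h(alpha*).
// [[Rcpp::export]]
List hopf_classify_fixed_cpp(IntegerMatrix gamma, IntegerMatrix A,
                             NumericVector hvec, bool want_l2l3 = true) {
  Core c = build_core(gamma, A, hvec, hvec);  // constant h
  if (!p_zero(c.M11) || !p_zero(c.M22))
    stop("fixed-alpha pipeline requires M11 = M22 = 0 at the point");
  Q det0 = p_zero(c.detM) ? Q(0) : c.detM[0];
  if (det0 <= 0) return List::create(_["feasible"] = false);

  Poly id; id.push_back(Q(0)); id.push_back(Q(1));  // s(t) = t = x2
  RatF s{id, p_const(Q(1))};
  Focal F = focal_values(c, s, 4);
  if (!F.valid) stop("focal value construction failed");
  FCtx& cx = F.cx;

  if (fe_is_zero(F.eta2)) {
    F = focal_values(c, s, 8);
    bool l2z = fe_is_zero(F.eta3), l3z = fe_is_zero(F.eta4);
    return List::create(
      _["feasible"] = true,
      _["classification"] = (l2z && l3z) ? std::string("vertical")
                                          : std::string("degenerate-unexpected"),
      _["l1_identically_zero"] = true,
      _["l2_identically_zero"] = l2z, _["l3_identically_zero"] = l3z);
  }

  RatF Nrf = rf_sub(rf_mul(F.eta2.u, F.eta2.u),
                    rf_mul(rf_mul(F.eta2.v, F.eta2.v), cx.Delta));
  Poly crit = p_mul(Nrf.num, p_mul(F.eta2.u.den, F.eta2.v.den));
  // root bound: 1 + max |a_i / a_d| over the critical polynomial
  Q B(2);
  if (!p_zero(crit)) {
    Q mx(0);
    for (size_t i = 0; i + 1 < crit.size(); ++i) {
      Q r = abs(crit[i] / crit.back());
      if (r > mx) mx = r;
    }
    B = mx + 2;
  }
  std::vector<Alg> cpts = isolate(crit, Q(0), B);
  std::vector<Q> samples = gap_samples(cpts, Q(0), B);
  int l1_neg = 0, l1_pos = 0;
  for (const Q& t : samples) {
    int sig = fe_sign_at(cx, F.eta2, t);
    if (sig < 0) ++l1_neg;
    if (sig > 0) ++l1_pos;
    if (sig == 0) stop("L1 exactly zero at a sample point");
  }
  std::vector<Alg> zero_pts;
  for (auto& pt : cpts)
    if (fe_sign_at_alg(cx, F.eta2, pt) == 0) zero_pts.push_back(pt);
  int n_l1_zeros = (int)zero_pts.size();
  bool all_l2_zero = true, all_l3_zero = true, all_l2_nonzero = true;
  int l2_sign_common = 0;
  if (n_l1_zeros > 0 && want_l2l3) {
    F = focal_values(c, s, 8);
    for (auto& pt : zero_pts) {
      int sl2 = fe_sign_at_alg(cx, F.eta3, pt);
      if (sl2 == 0) {
        all_l2_nonzero = false;
        if (fe_sign_at_alg(cx, F.eta4, pt) != 0) all_l3_zero = false;
      } else {
        all_l2_zero = false;
        if (l2_sign_common == 0) l2_sign_common = sl2;
        else if (l2_sign_common != sl2) l2_sign_common = 99;
      }
    }
  }
  std::string cls;
  if (n_l1_zeros == 0)
    cls = (l1_neg > 0 && l1_pos == 0) ? "supercritical"
        : (l1_pos > 0 && l1_neg == 0) ? "subcritical" : "mixed-disconnected";
  else if (all_l2_zero && all_l3_zero) cls = "mixed";
  else if (all_l2_nonzero) cls = "bautin";
  else cls = "degenerate-unexpected";
  return List::create(
    _["feasible"] = true, _["classification"] = cls,
    _["l1_identically_zero"] = false,
    _["l1_neg_samples"] = l1_neg, _["l1_pos_samples"] = l1_pos,
    _["n_l1_zeros"] = n_l1_zeros, _["l2_sign"] = l2_sign_common);
}

// -------------------------------------------- quadratic number field scalars

struct QF { Q a, b; };  // a + b sqrt(D)

struct QFCtx { Q D; };  // D >= 0 rational, not necessarily square-free

static QF qf_of(const Q& a) { QF x; x.a = a; x.b = 0; return x; }
static QF qf_add(const QF& x, const QF& y) { QF r; r.a = x.a + y.a; r.b = x.b + y.b; return r; }
static QF qf_sub(const QF& x, const QF& y) { QF r; r.a = x.a - y.a; r.b = x.b - y.b; return r; }
static QF qf_neg(const QF& x) { QF r; r.a = -x.a; r.b = -x.b; return r; }
static QF qf_mul(const QFCtx& c, const QF& x, const QF& y) {
  QF r; r.a = x.a * y.a + x.b * y.b * c.D; r.b = x.a * y.b + x.b * y.a; return r;
}
static int qf_sign(const QFCtx& c, const QF& x) { return sign_quadext(x.a, x.b, c.D); }
static bool qf_zero(const QFCtx& c, const QF& x) { return qf_sign(c, x) == 0; }
static QF qf_inv(const QFCtx& c, const QF& x) {
  Q n = x.a * x.a - x.b * x.b * c.D;
  if (n == 0) stop("quadratic-field inverse of zero (square discriminant not reduced?)");
  QF r; r.a = x.a / n; r.b = -x.b / n; return r;
}
static QF qf_div(const QFCtx& c, const QF& x, const QF& y) { return qf_mul(c, x, qf_inv(c, y)); }
static QF qf_eval_poly(const QFCtx& c, const Poly& p, const QF& x) {
  QF r = qf_of(Q(0));
  for (int i = p_deg(p); i >= 0; --i) r = qf_add(qf_mul(c, r, x), qf_of(p[i]));
  return r;
}

static bool is_square(const Q& x, Q& root) {
  if (x < 0) return false;
  cpp_int n = numerator(x), d = denominator(x);
  cpp_int sn = sqrt(n), sd = sqrt(d);
  if (sn * sn == n && sd * sd == d) { root = Q(sn, sd); return true; }
  return false;
}

// represent the det-roots in (0,1) exactly inside one quadratic field:
// returns per root a QF value plus the field context
struct DetRootsQF {
  QFCtx ctx;
  std::vector<QF> roots;
};

static DetRootsQF det_roots_qf(const Core& c) {
  DetRootsQF out;
  out.ctx.D = 0;
  const Poly& p = c.detM;
  int d = p_deg(p);
  std::vector<QF> cand;
  if (d == 1) {
    cand.push_back(qf_of(-p[0] / p[1]));
  } else if (d == 2) {
    Q A2 = p[2], B = p[1], C0 = p[0];
    Q disc = B * B - 4 * A2 * C0;
    if (disc < 0) return out;
    Q rt;
    if (is_square(disc, rt)) {
      cand.push_back(qf_of((-B + rt) / (2 * A2)));
      if (rt != 0) cand.push_back(qf_of((-B - rt) / (2 * A2)));
    } else {
      out.ctx.D = disc;
      QF r1; r1.a = -B / (2 * A2); r1.b = Q(1) / (2 * A2);
      QF r2; r2.a = -B / (2 * A2); r2.b = -Q(1) / (2 * A2);
      cand.push_back(r1);
      cand.push_back(r2);
    }
  }
  for (const QF& r : cand) {
    // keep roots in open (0,1)
    if (qf_sign(out.ctx, r) > 0 && qf_sign(out.ctx, qf_sub(qf_of(Q(1)), r)) > 0)
      out.roots.push_back(r);
  }
  return out;
}

// build all point data at a det-root: M entries, s, kappa, quadratic part
struct BTPoint {
  QFCtx ctx;
  QF M11, M12, M21, M22, s;
  std::vector<QF> kappa;  // all m rate constants
  QF c20[2], c11[2], c02[2];
  bool ok;
};

static BTPoint point_at_root(const Core& c, const QFCtx& ctx, const QF& alpha) {
  BTPoint P;
  P.ctx = ctx;
  P.M11 = qf_eval_poly(ctx, c.M11, alpha);
  P.M12 = qf_eval_poly(ctx, c.M12, alpha);
  P.M21 = qf_eval_poly(ctx, c.M21, alpha);
  P.M22 = qf_eval_poly(ctx, c.M22, alpha);
  P.ok = false;
  if (qf_zero(ctx, P.M11)) return P;  // needs M11 M22 < 0 anyway
  P.s = qf_div(ctx, qf_neg(P.M22), P.M11);
  if (qf_sign(ctx, P.s) <= 0) return P;
  P.kappa.resize(c.m);
  for (int j = 0; j < c.m; ++j) {
    QF h = qf_eval_poly(ctx, c.h[j], alpha);
    QF k = h;
    for (int t = 0; t < c.Aexp[j][1]; ++t) k = qf_div(ctx, k, P.s);
    P.kappa[j] = k;  // kappa_j = h_j / x^(A_j) with x = (1, s)
  }
  for (int i = 0; i < 2; ++i) {
    P.c20[i] = qf_of(Q(0)); P.c11[i] = qf_of(Q(0)); P.c02[i] = qf_of(Q(0));
  }
  for (int j = 0; j < c.m; ++j) {
    int a1 = c.Aexp[j][0], a2 = c.Aexp[j][1];
    if (a1 + a2 != 2) continue;
    for (int i = 0; i < 2; ++i) {
      if (c.G[i][j] == 0) continue;
      QF term = qf_mul(P.ctx, P.kappa[j], qf_of(Q(c.G[i][j])));
      if (a1 == 2) P.c20[i] = qf_add(P.c20[i], term);
      else if (a1 == 1) P.c11[i] = qf_add(P.c11[i], term);
      else P.c02[i] = qf_add(P.c02[i], term);
    }
  }
  P.ok = true;
  return P;
}

// bilinear form B(u, v)_i of the quadratic part
static void qf_bilinear(const BTPoint& P, const QF u[2], const QF v[2], QF out[2]) {
  for (int i = 0; i < 2; ++i) {
    QF t = qf_mul(P.ctx, qf_of(Q(2)), qf_mul(P.ctx, P.c20[i], qf_mul(P.ctx, u[0], v[0])));
    QF cross = qf_add(qf_mul(P.ctx, u[0], v[1]), qf_mul(P.ctx, u[1], v[0]));
    t = qf_add(t, qf_mul(P.ctx, P.c11[i], cross));
    t = qf_add(t, qf_mul(P.ctx, qf_of(Q(2)), qf_mul(P.ctx, P.c02[i], qf_mul(P.ctx, u[1], v[1]))));
    out[i] = t;
  }
}

// exact rank of a matrix over the quadratic field
static int qf_rank(const QFCtx& ctx, std::vector<std::vector<QF>> M) {
  int nr = M.size();
  if (nr == 0) return 0;
  int nc = M[0].size();
  int rank = 0;
  int row = 0;
  for (int col = 0; col < nc && row < nr; ++col) {
    int pr = -1;
    for (int i = row; i < nr; ++i) if (!qf_zero(ctx, M[i][col])) { pr = i; break; }
    if (pr < 0) continue;
    std::swap(M[pr], M[row]);
    QF inv = qf_inv(ctx, M[row][col]);
    for (int j = 0; j < nc; ++j) M[row][j] = qf_mul(ctx, M[row][j], inv);
    for (int i = 0; i < nr; ++i) {
      if (i == row || qf_zero(ctx, M[i][col])) continue;
      QF f = M[i][col];
      for (int j = 0; j < nc; ++j)
        M[i][j] = qf_sub(M[i][j], qf_mul(ctx, f, M[row][j]));
    }
    ++row; ++rank;
  }
  return rank;
}

// partial derivatives of f, trace and det of the Jacobian of the mass-action
// field at (x, kappa), all exact in the quadratic field.
// f_i = sum_j kappa_j gamma_ij x1^aj1 x2^aj2
struct FieldDerivs {
  QF J[2][2];
  QF fk[2][8];      // d f_i / d kappa_j
  QF dT_dx[2], dT_dk[8];
  QF dD_dx[2], dD_dk[8];
};

static QF qf_pow(const QFCtx& ctx, const QF& x, int e) {
  QF r = qf_of(Q(1));
  for (int i = 0; i < e; ++i) r = qf_mul(ctx, r, x);
  return r;
}

static FieldDerivs field_derivs(const Core& c, const BTPoint& P) {
  const QFCtx& ctx = P.ctx;
  QF x1 = qf_of(Q(1)), x2 = P.s;
  FieldDerivs D;
  for (int i = 0; i < 2; ++i) for (int k = 0; k < 2; ++k) D.J[i][k] = qf_of(Q(0));
  for (int i = 0; i < 2; ++i) { D.dT_dx[i] = qf_of(Q(0)); D.dD_dx[i] = qf_of(Q(0)); }
  for (int j = 0; j < 8; ++j) {
    for (int i = 0; i < 2; ++i) D.fk[i][j] = qf_of(Q(0));
    D.dT_dk[j] = qf_of(Q(0)); D.dD_dk[j] = qf_of(Q(0));
  }
  // monomial helper m(a1,a2) = x1^a1 x2^a2 at the point
  auto mono = [&](int a1, int a2) -> QF {
    if (a1 < 0 || a2 < 0) return qf_of(Q(0));
    return qf_mul(ctx, qf_pow(ctx, x1, a1), qf_pow(ctx, x2, a2));
  };
  // J and f_kappa
  for (int j = 0; j < c.m; ++j) {
    int a1 = c.Aexp[j][0], a2 = c.Aexp[j][1];
    QF mj = mono(a1, a2);
    QF d1 = qf_mul(ctx, qf_of(Q(a1)), mono(a1 - 1, a2));
    QF d2 = qf_mul(ctx, qf_of(Q(a2)), mono(a1, a2 - 1));
    for (int i = 0; i < 2; ++i) {
      QF g = qf_of(Q(c.G[i][j]));
      D.fk[i][j] = qf_mul(ctx, g, mj);
      QF kg = qf_mul(ctx, P.kappa[j], g);
      D.J[i][0] = qf_add(D.J[i][0], qf_mul(ctx, kg, d1));
      D.J[i][1] = qf_add(D.J[i][1], qf_mul(ctx, kg, d2));
    }
  }
  // trace T = J11 + J22 and det as functions of (x, kappa):
  // numeric differentiation is not acceptable; differentiate term-by-term.
  // J_ik(x,kappa) = sum_j kappa_j G_ij a_jk x^(a_j - e_k)
  // dJ_ik/dx_l = sum_j kappa_j G_ij a_jk (a_jl - [k==l]) x^(a_j - e_k - e_l)
  QF dJ_dx[2][2][2], dJ_dk[2][2][8];
  for (int i = 0; i < 2; ++i) for (int k = 0; k < 2; ++k) {
    for (int l = 0; l < 2; ++l) dJ_dx[i][k][l] = qf_of(Q(0));
    for (int j = 0; j < 8; ++j) dJ_dk[i][k][j] = qf_of(Q(0));
  }
  for (int j = 0; j < c.m; ++j) {
    int aj[2] = {c.Aexp[j][0], c.Aexp[j][1]};
    for (int i = 0; i < 2; ++i) {
      QF g = qf_of(Q(c.G[i][j]));
      for (int k = 0; k < 2; ++k) {
        if (aj[k] == 0) continue;
        QF base = qf_mul(ctx, g, qf_of(Q(aj[k])));
        int e[2] = {aj[0], aj[1]}; e[k] -= 1;
        dJ_dk[i][k][j] = qf_mul(ctx, base, mono(e[0], e[1]));
        for (int l = 0; l < 2; ++l) {
          int mult = e[l];
          if (mult == 0) continue;
          int e2[2] = {e[0], e[1]}; e2[l] -= 1;
          dJ_dx[i][k][l] = qf_add(dJ_dx[i][k][l],
            qf_mul(ctx, qf_mul(ctx, qf_mul(ctx, P.kappa[j], base), qf_of(Q(mult))),
                   mono(e2[0], e2[1])));
        }
      }
    }
  }
  for (int l = 0; l < 2; ++l)
    D.dT_dx[l] = qf_add(dJ_dx[0][0][l], dJ_dx[1][1][l]);
  for (int j = 0; j < c.m; ++j)
    D.dT_dk[j] = qf_add(dJ_dk[0][0][j], dJ_dk[1][1][j]);
  // det = J11 J22 - J12 J21; product rule
  for (int l = 0; l < 2; ++l) {
    QF t = qf_mul(ctx, dJ_dx[0][0][l], D.J[1][1]);
    t = qf_add(t, qf_mul(ctx, D.J[0][0], dJ_dx[1][1][l]));
    t = qf_sub(t, qf_mul(ctx, dJ_dx[0][1][l], D.J[1][0]));
    t = qf_sub(t, qf_mul(ctx, D.J[0][1], dJ_dx[1][0][l]));
    D.dD_dx[l] = t;
  }
  for (int j = 0; j < c.m; ++j) {
    QF t = qf_mul(ctx, dJ_dk[0][0][j], D.J[1][1]);
    t = qf_add(t, qf_mul(ctx, D.J[0][0], dJ_dk[1][1][j]));
    t = qf_sub(t, qf_mul(ctx, dJ_dk[0][1][j], D.J[1][0]));
    t = qf_sub(t, qf_mul(ctx, D.J[0][1], dJ_dk[1][0][j]));
    D.dD_dk[j] = t;
  }
  return D;
}

// Transversality certificate at a rational equilibrium witness:
// rank of the derivative of (f, trace J) or (f, det J) with respect to
// (x, kappa) at x = (1, x2), kappa_j = h_j / x^(A_j).  Full rank (3) means
// the spectral quantity is unfolded transversely by the rate constants
// while staying on the equilibrium manifold.
// [[Rcpp::export]]
List transversality_cpp(IntegerMatrix gamma, IntegerMatrix A,
                        NumericVector hvec, double x2num, double x2den,
                        std::string what) {
  Core c = build_core(gamma, A, hvec, hvec);
  BTPoint P;
  P.ctx.D = 0;
  P.s = qf_of(q_from_double(x2num) / q_from_double(x2den));
  if (qf_sign(P.ctx, P.s) <= 0) stop("witness x2 must be positive");
  P.kappa.resize(c.m);
  for (int j = 0; j < c.m; ++j) {
    QF k = qf_of(p_zero(c.h[j]) ? Q(0) : c.h[j][0]);
    for (int t = 0; t < c.Aexp[j][1]; ++t) k = qf_div(P.ctx, k, P.s);
    P.kappa[j] = k;
  }
  FieldDerivs Dv = field_derivs(c, P);
  std::vector<std::vector<QF>> Mx(3, std::vector<QF>(2 + c.m));
  for (int i = 0; i < 2; ++i) {
    Mx[i][0] = Dv.J[i][0]; Mx[i][1] = Dv.J[i][1];
    for (int j = 0; j < c.m; ++j) Mx[i][2 + j] = Dv.fk[i][j];
  }
  bool trace = (what == "trace");
  Mx[2][0] = trace ? Dv.dT_dx[0] : Dv.dD_dx[0];
  Mx[2][1] = trace ? Dv.dT_dx[1] : Dv.dD_dx[1];
  for (int j = 0; j < c.m; ++j)
    Mx[2][2 + j] = trace ? Dv.dT_dk[j] : Dv.dD_dk[j];
  int rank = qf_rank(P.ctx, Mx);
  return List::create(_["rank"] = rank, _["full_rank"] = (rank == 3));
}

// [[Rcpp::export]]
List bt_classify_cpp(IntegerMatrix gamma, IntegerMatrix A,
                     NumericVector r1, NumericVector r2) {
  Core c = build_core(gamma, A, r1, r2);
  DetRootsQF dr = det_roots_qf(c);
  List per_root;
  bool any_bt = false;
  for (const QF& alpha : dr.roots) {
    QFCtx ctx = dr.ctx;
    QF m11 = qf_eval_poly(ctx, c.M11, alpha);
    QF m22 = qf_eval_poly(ctx, c.M22, alpha);
    if ((long)qf_sign(ctx, m11) * qf_sign(ctx, m22) >= 0) continue;
    BTPoint P = point_at_root(c, ctx, alpha);
    if (!P.ok) continue;
    any_bt = true;
    // J at (1, s), trace zero by construction, J nilpotent of index two
    QF a = P.M11, b = qf_div(ctx, P.M12, P.s), cc = P.M21;
    // basis q0, q1 and dual p1, p0
    QF q0[2], q1[2], p1r[2], p0r[2];
    if (!qf_zero(ctx, b)) {
      q0[0] = b; q0[1] = qf_neg(a);
      q1[0] = qf_of(Q(0)); q1[1] = qf_of(Q(1));
    } else {
      q0[0] = qf_of(Q(0)); q0[1] = qf_of(Q(1));
      q1[0] = qf_inv(ctx, cc); q1[1] = qf_of(Q(0));
    }
    if (!qf_zero(ctx, cc)) {
      p1r[0] = cc; p1r[1] = qf_neg(a);
      // p0 raw solves p0 J = p1r: with J = [[a,b],[c,-a]]:
      // (x, y) J = (xa + yc, xb - ya) = (c, -a) -> try x = 0, y: yc = c -> y=1, check xb - ya = -a: ok (x=0,y=1)
      p0r[0] = qf_of(Q(0)); p0r[1] = qf_of(Q(1));
    } else {
      // c == 0 -> a == 0, J = [[0, b], [0, 0]]
      p1r[0] = qf_of(Q(0)); p1r[1] = qf_of(Q(1));
      p0r[0] = qf_inv(ctx, b); p0r[1] = qf_of(Q(0));
    }
    // normalise: p1 = p1r / <p1r, q1>; p0 = p0r/<p1r,q1> - <p0r/<p1r,q1>, q1> p1
    QF ip = qf_add(qf_mul(ctx, p1r[0], q1[0]), qf_mul(ctx, p1r[1], q1[1]));
    if (qf_zero(ctx, ip)) stop("degenerate BT basis normalisation");
    QF ipi = qf_inv(ctx, ip);
    QF p1[2] = {qf_mul(ctx, p1r[0], ipi), qf_mul(ctx, p1r[1], ipi)};
    QF p0s[2] = {qf_mul(ctx, p0r[0], ipi), qf_mul(ctx, p0r[1], ipi)};
    QF t = qf_add(qf_mul(ctx, p0s[0], q1[0]), qf_mul(ctx, p0s[1], q1[1]));
    QF p0[2] = {qf_sub(p0s[0], qf_mul(ctx, t, p1[0])),
                qf_sub(p0s[1], qf_mul(ctx, t, p1[1]))};
    // normal-form coefficients
    QF Bq0q0[2], Bq0q1[2];
    qf_bilinear(P, q0, q0, Bq0q0);
    qf_bilinear(P, q0, q1, Bq0q1);
    QF a20 = qf_add(qf_mul(ctx, p0[0], Bq0q0[0]), qf_mul(ctx, p0[1], Bq0q0[1]));
    QF b20 = qf_add(qf_mul(ctx, p1[0], Bq0q0[0]), qf_mul(ctx, p1[1], Bq0q0[1]));
    QF b11 = qf_add(qf_mul(ctx, p1[0], Bq0q1[0]), qf_mul(ctx, p1[1], Bq0q1[1]));
    QF sum = qf_add(a20, b11);
    int s_sum = qf_sign(ctx, sum), s_b20 = qf_sign(ctx, b20);
    int sigma = s_sum * s_b20;
    // transversality BT.3: rank of the 4 x 6 derivative of (f, trJ, detJ)
    FieldDerivs Dv = field_derivs(c, P);
    std::vector<std::vector<QF>> Mx(4, std::vector<QF>(2 + c.m));
    for (int i = 0; i < 2; ++i) {
      Mx[i][0] = Dv.J[i][0]; Mx[i][1] = Dv.J[i][1];
      for (int j = 0; j < c.m; ++j) Mx[i][2 + j] = Dv.fk[i][j];
    }
    Mx[2][0] = Dv.dT_dx[0]; Mx[2][1] = Dv.dT_dx[1];
    Mx[3][0] = Dv.dD_dx[0]; Mx[3][1] = Dv.dD_dx[1];
    for (int j = 0; j < c.m; ++j) {
      Mx[2][2 + j] = Dv.dT_dk[j];
      Mx[3][2 + j] = Dv.dD_dk[j];
    }
    int rank = qf_rank(ctx, Mx);
    per_root.push_back(List::create(
      _["vertical_bt"] = (s_sum == 0),
      _["b20_zero"] = (s_b20 == 0),
      _["sigma"] = sigma,
      _["sign_a20_plus_b11"] = s_sum,
      _["sign_b20"] = s_b20,
      _["transversal"] = (rank == 4)));
  }
  return List::create(_["double_zero_feasible"] = any_bt, _["points"] = per_root);
}

// fold nondegeneracy witness at det-roots where (M11, M22) != (0, 0):
// J = M(alpha*) diag(1/x) at x = (1, 1); quadratic coefficient <p, B(q,q)>
// and the transversal unfolding rank of (f, detJ) in (x, kappa).
// [[Rcpp::export]]
List fold_witness_cpp(IntegerMatrix gamma, IntegerMatrix A,
                      NumericVector r1, NumericVector r2) {
  Core c = build_core(gamma, A, r1, r2);
  DetRootsQF dr = det_roots_qf(c);
  bool any = false, all_nondeg = true;
  int n_checked = 0;
  for (const QF& alpha : dr.roots) {
    QFCtx ctx = dr.ctx;
    QF m11 = qf_eval_poly(ctx, c.M11, alpha);
    QF m22 = qf_eval_poly(ctx, c.M22, alpha);
    if (qf_zero(ctx, m11) && qf_zero(ctx, m22)) continue;  // forced double zero
    any = true; ++n_checked;
    // witness equilibrium x = (1, 1): kappa_j = h_j(alpha*), J = M(alpha*)
    BTPoint P;  // reuse struct with s = 1
    P.ctx = ctx;
    P.M11 = m11; P.M12 = qf_eval_poly(ctx, c.M12, alpha);
    P.M21 = qf_eval_poly(ctx, c.M21, alpha);
    P.M22 = m22; P.s = qf_of(Q(1));
    P.kappa.resize(c.m);
    for (int j = 0; j < c.m; ++j) P.kappa[j] = qf_eval_poly(ctx, c.h[j], alpha);
    for (int i = 0; i < 2; ++i) { P.c20[i] = qf_of(Q(0)); P.c11[i] = qf_of(Q(0)); P.c02[i] = qf_of(Q(0)); }
    for (int j = 0; j < c.m; ++j) {
      int a1 = c.Aexp[j][0], a2 = c.Aexp[j][1];
      if (a1 + a2 != 2) continue;
      for (int i = 0; i < 2; ++i) {
        if (c.G[i][j] == 0) continue;
        QF term = qf_mul(ctx, P.kappa[j], qf_of(Q(c.G[i][j])));
        if (a1 == 2) P.c20[i] = qf_add(P.c20[i], term);
        else if (a1 == 1) P.c11[i] = qf_add(P.c11[i], term);
        else P.c02[i] = qf_add(P.c02[i], term);
      }
    }
    // null vectors of J = [[M11, M12], [M21, M22]] (det = 0, J != 0)
    QF q[2], pv[2];
    if (!qf_zero(ctx, P.M12) || !qf_zero(ctx, P.M11)) {
      q[0] = qf_neg(P.M12); q[1] = P.M11;
      if (qf_zero(ctx, q[0]) && qf_zero(ctx, q[1])) { q[0] = qf_neg(P.M22); q[1] = P.M21; }
    } else { q[0] = qf_neg(P.M22); q[1] = P.M21; }
    if (qf_zero(ctx, q[0]) && qf_zero(ctx, q[1])) { q[0] = qf_of(Q(1)); q[1] = qf_of(Q(0)); }
    pv[0] = qf_neg(P.M21); pv[1] = P.M11;
    if (qf_zero(ctx, pv[0]) && qf_zero(ctx, pv[1])) { pv[0] = qf_neg(P.M22); pv[1] = P.M12; }
    if (qf_zero(ctx, pv[0]) && qf_zero(ctx, pv[1])) { pv[0] = qf_of(Q(1)); pv[1] = qf_of(Q(0)); }
    QF Bqq[2];
    qf_bilinear(P, q, q, Bqq);
    QF quad = qf_add(qf_mul(ctx, pv[0], Bqq[0]), qf_mul(ctx, pv[1], Bqq[1]));
    // unfolding: rank of 3 x (2 + m) derivative of (f, detJ)
    FieldDerivs Dv = field_derivs(c, P);
    std::vector<std::vector<QF>> Mx(3, std::vector<QF>(2 + c.m));
    for (int i = 0; i < 2; ++i) {
      Mx[i][0] = Dv.J[i][0]; Mx[i][1] = Dv.J[i][1];
      for (int j = 0; j < c.m; ++j) Mx[i][2 + j] = Dv.fk[i][j];
    }
    Mx[2][0] = Dv.dD_dx[0]; Mx[2][1] = Dv.dD_dx[1];
    for (int j = 0; j < c.m; ++j) Mx[2][2 + j] = Dv.dD_dk[j];
    int rank = qf_rank(ctx, Mx);
    if (qf_zero(ctx, quad) || rank != 3) all_nondeg = false;
  }
  return List::create(_["any_fold_root"] = any, _["n_checked"] = n_checked,
                      _["nondegenerate"] = any && all_nondeg);
}
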