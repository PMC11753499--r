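// Core molecular-dynamics kernels: pair forces for the bead-spring model
// (harmonic bonds, truncated-shifted r^-12 repulsion, quartic bending
// potential), a Verlet-buffer neighbor list, and the BAOAB Langevin stage
// loop with optional Berendsen isotropic pressure coupling or a deterministic
// box-compression schedule.
//
// All indices arriving from R are 0-based (converted in the R wrappers).
// Distances use the minimum-image convention in a cubic periodic box.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#ifdef __SSE2__
#include <emmintrin.h>
#endif

#if defined(__GNUC__) && !defined(__clang__)
// the pair loops below are the package's hot path; R's default -O2 leaves
// ~30% on the table here
#pragma GCC optimize("O3", "unroll-loops")
#endif

using namespace Rcpp;

namespace {

// Ziggurat sampler for standard normals (Marsaglia & Tsang, 128 layers) over
// a mt19937_64 stream: ~5x faster than std::normal_distribution, which
// dominates the cost of the O sub-step at ~3N draws per time step.
class ZigguratNormal {
 public:
  explicit ZigguratNormal(std::uint64_t seed) : rng_(seed), have_(false) {
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3, m1 = 2147483648.0;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = static_cast<std::uint32_t>((dn / q) * m1);
    kn_[1] = 0;
    wn_[0] = q / m1;
    wn_[127] = dn / m1;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = static_cast<std::uint32_t>((dn / tn) * m1);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m1;
    }
  }

  double operator()() {
    const std::int32_t hz = static_cast<std::int32_t>(next_u32());
    const std::uint32_t iz = hz & 127u;
    const std::uint32_t az =
        hz < 0 ? static_cast<std::uint32_t>(-static_cast<std::int64_t>(hz))
               : static_cast<std::uint32_t>(hz);
    return (az < kn_[iz]) ? hz * wn_[iz] : nfix(hz, iz);
  }

 private:
  std::uint32_t next_u32() {
    if (have_) {
      have_ = false;
      return static_cast<std::uint32_t>(buf_ >> 32);
    }
    buf_ = rng_();
    have_ = true;
    return static_cast<std::uint32_t>(buf_);
  }
  double uni() { return (next_u32() + 0.5) * 2.3283064365386963e-10; }

  double nfix(std::int32_t hz, std::uint32_t iz) {
    const double r = 3.442619855899;
    for (;;) {
      double x = hz * wn_[iz];
      if (iz == 0) { // base strip: sample the tail
        double y;
        do {
          x = -std::log(uni()) * 0.2904764515262606; // 1/r
          y = -std::log(uni());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (fn_[iz] + uni() * (fn_[iz - 1] - fn_[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      hz = static_cast<std::int32_t>(next_u32());
      iz = hz & 127u;
      const std::uint32_t az =
          hz < 0 ? static_cast<std::uint32_t>(-static_cast<std::int64_t>(hz))
                 : static_cast<std::uint32_t>(hz);
      if (az < kn_[iz]) return hz * wn_[iz];
    }
  }

  std::uint32_t kn_[128];
  double wn_[128], fn_[128];
  std::mt19937_64 rng_;
  std::uint64_t buf_;
  bool have_;
};

struct SimP {
  double kbond, eps, sigma, r, dcut, ktheta, cos0;
  double gam, m, kBT, dt, skin;
  bool flexible;
  double shift12; // (sigma/dcut)^12, subtracted so V_rep(dcut) = 0
};

SimP parse_params(const List& p, bool flexible) {
  SimP s;
  s.kbond = as<double>(p["K_bond"]);
  s.eps = as<double>(p["epsilon"]);
  s.sigma = as<double>(p["sigma"]);
  s.r = as<double>(p["r"]);
  s.dcut = as<double>(p["d_cutoff"]);
  s.ktheta = as<double>(p["K_theta"]);
  const double th0 = as<double>(p["theta0"]) * M_PI / 180.0;
  s.cos0 = std::cos(th0);
  s.gam = as<double>(p["gamma"]);
  s.m = as<double>(p["m"]);
  s.kBT = as<double>(p["kBT"]);
  s.dt = as<double>(p["dt"]);
  s.skin = as<double>(p["skin"]);
  s.flexible = flexible;
  const double sr = s.sigma / s.dcut;
  const double sr6 = sr * sr * sr * sr * sr * sr;
  s.shift12 = sr6 * sr6;
  return s;
}

// Branchless round-to-nearest-even via the 2^52 magic constant: exact for
// |y| < 2^51 and much faster than the libm nearbyint call on baseline
// x86-64 targets. Box counts in a simulation are tiny integers, far below
// the validity limit.
inline double round_nearest(double y) {
  const double magic = 6755399441055744.0; // 1.5 * 2^52
  return (y + magic) - magic;
}

inline void min_image(double* d, double box) {
  const double inv = 1.0 / box;
  for (int k = 0; k < 3; ++k) d[k] -= box * round_nearest(d[k] * inv);
}

inline void min_image_inv(double* d, double box, double inv) {
  for (int k = 0; k < 3; ++k) d[k] -= box * round_nearest(d[k] * inv);
}

struct EnergyOut {
  double e_bond = 0.0, e_rep = 0.0, e_angle = 0.0, e_xlink = 0.0;
  double virial = 0.0;
  double total() const { return e_bond + e_rep + e_angle + e_xlink; }
};

// Topology flattened into plain int vectors (0-based): avoids per-step Rcpp
// matrix accessor overhead in the force loop.
struct Topology {
  std::vector<int> bi, bj;         // chain bonds
  std::vector<int> xi, xj;         // crosslinks
  std::vector<int> ai, aj, ak;     // angle triads, vertex aj
};

Topology flatten_topology(const IntegerMatrix& bonds,
                          const IntegerMatrix& angles,
                          const IntegerMatrix& xlinks) {
  Topology t;
  t.bi.reserve(bonds.nrow());
  t.bj.reserve(bonds.nrow());
  for (int b = 0; b < bonds.nrow(); ++b) {
    t.bi.push_back(bonds(b, 0));
    t.bj.push_back(bonds(b, 1));
  }
  for (int b = 0; b < xlinks.nrow(); ++b) {
    t.xi.push_back(xlinks(b, 0));
    t.xj.push_back(xlinks(b, 1));
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    t.ai.push_back(angles(a, 0));
    t.aj.push_back(angles(a, 1));
    t.ak.push_back(angles(a, 2));
  }
  return t;
}

// Harmonic spring V = K (d - 2r)^2 / 2 acting on pair (i, j); used for both
// chain bonds and crosslinks. Returns energy, accumulates forces and virial.
inline double harmonic_pair(const std::vector<double>& x, int i, int j,
                            double box, double invbox, double k, double d0,
                            std::vector<double>& f, double& virial) {
  double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                 x[3 * i + 2] - x[3 * j + 2]};
  min_image_inv(d, box, invbox);
  const double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (d2 < 1e-24) stop("invalid geometry: coincident bonded beads");
  const double dist = std::sqrt(d2);
  const double dv = k * (dist - d0);       // dV/dd
  const double fs = -dv / dist;            // force on i along +d
  for (int c = 0; c < 3; ++c) {
    f[3 * i + c] += fs * d[c];
    f[3 * j + c] -= fs * d[c];
  }
  virial += fs * d2;
  return 0.5 * k * (dist - d0) * (dist - d0);
}

void compute_forces_core(const std::vector<double>& x, double box,
                         const Topology& topo,
                         const std::vector<int>& pi_, const std::vector<int>& pj_,
                         const SimP& p, std::vector<double>& f, EnergyOut& out) {
  std::fill(f.begin(), f.end(), 0.0);
  out = EnergyOut();
  const double invbox = 1.0 / box;

  // chain bonds, then crosslinks (same spring constant and equilibrium 2r)
  for (size_t b = 0; b < topo.bi.size(); ++b)
    out.e_bond += harmonic_pair(x, topo.bi[b], topo.bj[b], box, invbox,
                                p.kbond, 2.0 * p.r, f, out.virial);
  for (size_t b = 0; b < topo.xi.size(); ++b)
    out.e_xlink += harmonic_pair(x, topo.xi[b], topo.xj[b], box, invbox,
                                 p.kbond, 2.0 * p.r, f, out.virial);

  // steric repulsion: V = 4 eps [(sigma/d)^12 - (sigma/dcut)^12], d < dcut
  const double dcut2 = p.dcut * p.dcut;
  const double sig2 = p.sigma * p.sigma;
  const size_t npair = pi_.size();
  double e_rep = 0.0, w_rep = 0.0, min_d2 = 1.0;
  size_t q0 = 0;
#ifdef __SSE2__
  // two pairs per iteration: packed min-image, distance, masked r^-12 term;
  // gathers and force scatter stay scalar
  {
    const __m128d vbox = _mm_set1_pd(box);
    const __m128d vinv = _mm_set1_pd(invbox);
    const __m128d vmagic = _mm_set1_pd(6755399441055744.0);
    const __m128d vdcut2 = _mm_set1_pd(dcut2);
    const __m128d vsig2 = _mm_set1_pd(sig2);
    const __m128d vshift = _mm_set1_pd(p.shift12);
    const __m128d v48e = _mm_set1_pd(48.0 * p.eps);
    const __m128d vone = _mm_set1_pd(1.0);
    __m128d ve = _mm_setzero_pd(), vw = _mm_setzero_pd(), vmin = vone;
    alignas(16) double dxa[2], dya[2], dza[2], fsa[2];
    for (; q0 + 2 <= npair; q0 += 2) {
      const int i0 = pi_[q0], j0 = pj_[q0], i1 = pi_[q0 + 1], j1 = pj_[q0 + 1];
      __m128d dx = _mm_set_pd(x[3 * i1] - x[3 * j1], x[3 * i0] - x[3 * j0]);
      __m128d dy = _mm_set_pd(x[3 * i1 + 1] - x[3 * j1 + 1],
                              x[3 * i0 + 1] - x[3 * j0 + 1]);
      __m128d dz = _mm_set_pd(x[3 * i1 + 2] - x[3 * j1 + 2],
                              x[3 * i0 + 2] - x[3 * j0 + 2]);
      dx = _mm_sub_pd(dx, _mm_mul_pd(vbox,
             _mm_sub_pd(_mm_add_pd(_mm_mul_pd(dx, vinv), vmagic), vmagic)));
      dy = _mm_sub_pd(dy, _mm_mul_pd(vbox,
             _mm_sub_pd(_mm_add_pd(_mm_mul_pd(dy, vinv), vmagic), vmagic)));
      dz = _mm_sub_pd(dz, _mm_mul_pd(vbox,
             _mm_sub_pd(_mm_add_pd(_mm_mul_pd(dz, vinv), vmagic), vmagic)));
      const __m128d d2 = _mm_add_pd(_mm_mul_pd(dx, dx),
                         _mm_add_pd(_mm_mul_pd(dy, dy), _mm_mul_pd(dz, dz)));
      vmin = _mm_min_pd(vmin, d2);
      const __m128d mask = _mm_cmplt_pd(d2, vdcut2);
      const __m128d inv2 = _mm_div_pd(vone, d2);
      const __m128d s2 = _mm_mul_pd(vsig2, inv2);
      const __m128d s6 = _mm_mul_pd(s2, _mm_mul_pd(s2, s2));
      const __m128d s12 = _mm_mul_pd(s6, s6);
      ve = _mm_add_pd(ve, _mm_and_pd(mask, _mm_sub_pd(s12, vshift)));
      const __m128d fs =
          _mm_and_pd(mask, _mm_mul_pd(v48e, _mm_mul_pd(s12, inv2)));
      vw = _mm_add_pd(vw, _mm_mul_pd(fs, d2));
      _mm_store_pd(dxa, dx);
      _mm_store_pd(dya, dy);
      _mm_store_pd(dza, dz);
      _mm_store_pd(fsa, fs);
      f[3 * i0] += fsa[0] * dxa[0];
      f[3 * i0 + 1] += fsa[0] * dya[0];
      f[3 * i0 + 2] += fsa[0] * dza[0];
      f[3 * j0] -= fsa[0] * dxa[0];
      f[3 * j0 + 1] -= fsa[0] * dya[0];
      f[3 * j0 + 2] -= fsa[0] * dza[0];
      f[3 * i1] += fsa[1] * dxa[1];
      f[3 * i1 + 1] += fsa[1] * dya[1];
      f[3 * i1 + 2] += fsa[1] * dza[1];
      f[3 * j1] -= fsa[1] * dxa[1];
      f[3 * j1 + 1] -= fsa[1] * dya[1];
      f[3 * j1 + 2] -= fsa[1] * dza[1];
    }
    alignas(16) double acc[2];
    _mm_store_pd(acc, ve);
    e_rep += acc[0] + acc[1];
    _mm_store_pd(acc, vw);
    w_rep += acc[0] + acc[1];
    _mm_store_pd(acc, vmin);
    min_d2 = std::min(min_d2, std::min(acc[0], acc[1]));
  }
#endif
  for (size_t q = q0; q < npair; ++q) {
    const int i = pi_[q], j = pj_[q];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    dx -= box * round_nearest(dx * invbox);
    dy -= box * round_nearest(dy * invbox);
    dz -= box * round_nearest(dz * invbox);
    const double d2 = dx * dx + dy * dy + dz * dz;
    min_d2 = (d2 < min_d2) ? d2 : min_d2;
    // branchless: pairs beyond the cutoff contribute with weight 0
    const double w = (d2 < dcut2) ? 1.0 : 0.0;
    const double inv2 = 1.0 / d2;
    const double s2 = sig2 * inv2;
    const double s6 = s2 * s2 * s2;
    const double s12 = s6 * s6;
    e_rep += w * (s12 - p.shift12);
    const double fs = w * 48.0 * p.eps * s12 * inv2; // -dV/dd / d
    f[3 * i] += fs * dx;
    f[3 * i + 1] += fs * dy;
    f[3 * i + 2] += fs * dz;
    f[3 * j] -= fs * dx;
    f[3 * j + 1] -= fs * dy;
    f[3 * j + 2] -= fs * dz;
    w_rep += fs * d2;
  }
  if (min_d2 < 1e-24) stop("overlap error: beads at zero separation");
  out.e_rep = 4.0 * p.eps * e_rep;
  out.virial += w_rep;

  // bending: V = K_theta (cos th - cos th0)^2 / 2 on triads (i, j, k), vertex j
  if (!p.flexible && p.ktheta != 0.0) {
    for (size_t t = 0; t < topo.ai.size(); ++t) {
      const int i = topo.ai[t], j = topo.aj[t], k = topo.ak[t];
      double a[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      double b[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                     x[3 * k + 2] - x[3 * j + 2]};
      min_image_inv(a, box, invbox);
      min_image_inv(b, box, invbox);
      const double la2 = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
      const double lb2 = b[0] * b[0] + b[1] * b[1] + b[2] * b[2];
      if (la2 < 1e-24 || lb2 < 1e-24)
        stop("invalid geometry: coincident beads in angle triad");
      const double inv_ab = 1.0 / (la2 * lb2); // one division serves all three
      const double inv_lab = std::sqrt(inv_ab);
      double ct = (a[0] * b[0] + a[1] * b[1] + a[2] * b[2]) * inv_lab;
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      const double dv = p.ktheta * (ct - p.cos0); // dV/dcos(theta)
      out.e_angle += 0.5 * p.ktheta * (ct - p.cos0) * (ct - p.cos0);
      const double inv_la2 = lb2 * inv_ab, inv_lb2 = la2 * inv_ab;
      double fi[3], fk[3];
      for (int c = 0; c < 3; ++c) {
        fi[c] = -dv * (b[c] * inv_lab - ct * a[c] * inv_la2);
        fk[c] = -dv * (a[c] * inv_lab - ct * b[c] * inv_lb2);
        f[3 * i + c] += fi[c];
        f[3 * k + c] += fk[c];
        f[3 * j + c] -= fi[c] + fk[c];
      }
      out.virial += fi[0] * a[0] + fi[1] * a[1] + fi[2] * a[2] +
                    fk[0] * b[0] + fk[1] * b[1] + fk[2] * b[2];
    }
  }
}

// Refresh the inner pair list (within rlist) from an outer super-list built
// with a wider buffer: valid as long as no mutual approach has exceeded the
// outer buffer since the outer build.
void refine_pairs(const std::vector<double>& x, double box, double rlist,
                  const std::vector<int>& oi, const std::vector<int>& oj,
                  std::vector<int>& pi_, std::vector<int>& pj_) {
  pi_.clear();
  pj_.clear();
  const double rl2 = rlist * rlist;
  const double invbox = 1.0 / box;
  const size_t m = oi.size();
  for (size_t q = 0; q < m; ++q) {
    const int i = oi[q], j = oj[q];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    dx -= box * round_nearest(dx * invbox);
    dy -= box * round_nearest(dy * invbox);
    dz -= box * round_nearest(dz * invbox);
    if (dx * dx + dy * dy + dz * dz < rl2) {
      pi_.push_back(i);
      pj_.push_back(j);
    }
  }
}

// O(N^2) candidate-pair build; excludes directly (chain-)bonded neighbors,
// which by construction are consecutive indices of the same chain.
void build_pairs(const std::vector<double>& x, int n, double box, double rlist,
                 const IntegerVector& chain, std::vector<int>& pi_,
                 std::vector<int>& pj_) {
  pi_.clear();
  pj_.clear();
  const double rl2 = rlist * rlist;
  const double invbox = 1.0 / box;
  // structure-of-arrays copy so the distance scan vectorizes
  static thread_local std::vector<double> xs, ys, zs, d2s;
  xs.resize(n);
  ys.resize(n);
  zs.resize(n);
  d2s.resize(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[3 * i];
    ys[i] = x[3 * i + 1];
    zs[i] = x[3 * i + 2];
  }
  for (int i = 0; i < n; ++i) {
    const double xi = xs[i], yi = ys[i], zi = zs[i];
    const int chi = chain[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - xs[j];
      double dy = yi - ys[j];
      double dz = zi - zs[j];
      dx -= box * round_nearest(dx * invbox);
      dy -= box * round_nearest(dy * invbox);
      dz -= box * round_nearest(dz * invbox);
      d2s[j] = dx * dx + dy * dy + dz * dz;
    }
    for (int j = i + 1; j < n; ++j) {
      if (d2s[j] < rl2 && !(j - i == 1 && chi == chain[j])) {
        pi_.push_back(i);
        pj_.push_back(j);
      }
    }
  }
}

inline double wrap0(double v, double box) {
  v -= box * std::floor(v / box);
  if (v >= box) v -= box; // guard against floor rounding at the edge
  return v;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, double box, IntegerVector chain,
                IntegerMatrix bonds, IntegerMatrix angles,
                IntegerMatrix xlinks, List params, bool flexible) {
  const int n = pos.nrow();
  SimP p = parse_params(params, flexible);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  std::vector<int> pi_, pj_;
  build_pairs(x, n, box, p.dcut, chain, pi_, pj_);
  std::vector<double> f(3 * n);
  EnergyOut out;
  compute_forces_core(x, box, flatten_topology(bonds, angles, xlinks),
                      pi_, pj_, p, f, out);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) fm(i, c) = f[3 * i + c];
  return List::create(
      _["forces"] = fm, _["energy"] = out.total(), _["virial"] = out.virial,
      _["components"] = List::create(_["bond"] = out.e_bond, _["repulsive"] = out.e_rep,
                                     _["angle"] = out.e_angle, _["crosslink"] = out.e_xlink));
}

// [[Rcpp::export]]
IntegerMatrix cpp_brute_pairs(NumericMatrix pos, double box, double rmax,
                              IntegerVector chain) {
  const int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  std::vector<int> pi_, pj_;
  build_pairs(x, n, box, rmax, chain, pi_, pj_);
  IntegerMatrix out(static_cast<int>(pi_.size()), 2);
  for (size_t q = 0; q < pi_.size(); ++q) {
    out(q, 0) = pi_[q] + 1; // back to 1-based for R
    out(q, 1) = pj_[q] + 1;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix a, NumericMatrix b, double box) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double d[3] = {a(i, 0) - b(j, 0), a(i, 1) - b(j, 1), a(i, 2) - b(j, 2)};
      min_image(d, box);
      const double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// BAOAB Langevin stage loop.
//
// Per step: B (half kick) - A (half drift) - O (Ornstein-Uhlenbeck velocity
// refresh) - A (half drift) - force recomputation - B (half kick), then either
// the deterministic box schedule or the Berendsen rescale. The neighbor list
// is rebuilt whenever any bead has moved more than skin/2 since the last
// build; a single-step displacement above skin/2 aborts with a stability
// error (time step too large for the chosen buffer).
// [[Rcpp::export]]
List cpp_run_stage(NumericMatrix pos0, Nullable<NumericMatrix> vel0,
                   double box0, IntegerVector chain, IntegerMatrix bonds,
                   IntegerMatrix angles, IntegerMatrix xlinks, List params,
                   bool flexible, int n_steps, bool barostat, double p_target,
                   double tau_p, double kappa, double mu_lo, double mu_hi,
                   double sched_target, int sched_steps, int record_every,
                   int snapshot_every, double seed) {
  const int n = pos0.nrow();
  SimP p = parse_params(params, flexible);
  double box = box0;
  const double rlist = p.dcut + p.skin;
  const double half_skin2 = 0.25 * p.skin * p.skin;

  std::vector<double> x(3 * n), v(3 * n), f(3 * n), xref(3 * n), xprev(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);

  ZigguratNormal gauss(static_cast<std::uint64_t>(seed));

  if (vel0.isNotNull()) {
    NumericMatrix vm(vel0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] = vm(i, c);
  } else {
    const double sv = std::sqrt(p.kBT / p.m);
    for (int i = 0; i < 3 * n; ++i) v[i] = sv * gauss();
  }

  // OU coefficients for the O sub-step
  const double cexp = std::exp(-p.gam * p.dt);
  const double cnoise = std::sqrt(p.kBT / p.m * (1.0 - cexp * cexp));
  const double hdt = 0.5 * p.dt;

  const Topology topo = flatten_topology(bonds, angles, xlinks);
  // two-level Verlet list: the O(N^2) scan builds an outer super-list with a
  // wider buffer; the inner list used by the force loop is refreshed from it
  // at a fraction of the cost
  const double skin_outer = 4.0 * p.skin;
  const double rlist_outer = rlist + skin_outer;
  std::vector<int> oi_, oj_, pi_, pj_;
  std::vector<double> xref_out(3 * n);
  build_pairs(x, n, box, rlist_outer, chain, oi_, oj_);
  refine_pairs(x, box, rlist, oi_, oj_, pi_, pj_);
  xref = x;
  xref_out = x;
  int n_rebuilds = 0;
  EnergyOut eout;
  compute_forces_core(x, box, topo, pi_, pj_, p, f, eout);

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_step(n_rec), rec_vol(n_rec), rec_ke(n_rec), rec_press(n_rec);
  int irec = 0;
  bool mu_clamped = false;

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
    return 0.5 * p.m * ke;
  };
  auto pressure = [&]() {
    const double vol = box * box * box;
    return (n * p.kBT + eout.virial / 3.0) / vol;
  };
  auto record = [&](int step) {
    rec_step[irec] = step;
    rec_vol[irec] = box * box * box;
    rec_ke[irec] = kinetic();
    rec_press[irec] = pressure();
    ++irec;
  };
  record(0);

  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_box;
  std::vector<double> snap_step;
  // snapshots are stored unwrapped so chain-internal geometry (bond vectors,
  // tangent correlations) can be read off directly; re-wrapping happens when
  // a snapshot is turned back into a configuration
  auto snapshot = [&](int step) {
    NumericMatrix s(n, 3);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) s(i, c) = x[3 * i + c];
    snaps.push_back(s);
    snap_box.push_back(box);
    snap_step.push_back(step);
  };

  const double sched_from = box;
  // cumulative box scale since each list build: an affine shrink moves pairs
  // toward each other without any drift, so it consumes buffer too
  double s_in = 1.0, s_out = 1.0;

  const double kick = hdt / p.m;
  for (int step = 1; step <= n_steps; ++step) {
    xprev = x;
    // B: half kick, A: half drift
    for (int i = 0; i < 3 * n; ++i) {
      v[i] += kick * f[i];
      x[i] += hdt * v[i];
    }
    // O: velocity refresh, A: half drift
    for (int i = 0; i < 3 * n; ++i) {
      v[i] = cexp * v[i] + cnoise * gauss();
      x[i] += hdt * v[i];
    }

    // stability + rebuild bookkeeping; a list is stale once the two largest
    // drifts since its build can together bridge its buffer
    double max_step2 = 0.0, drift1 = 0.0, drift2 = 0.0, out1 = 0.0, out2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double s2 = 0.0, g2 = 0.0, h2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double ds = x[3 * i + c] - xprev[3 * i + c];
        const double dg = x[3 * i + c] - xref[3 * i + c];
        const double dh = x[3 * i + c] - xref_out[3 * i + c];
        s2 += ds * ds;
        g2 += dg * dg;
        h2 += dh * dh;
      }
      if (s2 > max_step2) max_step2 = s2;
      if (g2 > drift1) {
        drift2 = drift1;
        drift1 = g2;
      } else if (g2 > drift2) {
        drift2 = g2;
      }
      if (h2 > out1) {
        out2 = out1;
        out1 = h2;
      } else if (h2 > out2) {
        out2 = h2;
      }
    }
    if (max_step2 > half_skin2)
      stop("stability error: a bead moved more than skin/2 in one step; use a smaller dt");
    const double shrink_out = rlist_outer * std::max(0.0, 1.0 - s_out);
    const double shrink_in = rlist * std::max(0.0, 1.0 - s_in);
    if (std::sqrt(out1) + std::sqrt(out2) + shrink_out > skin_outer) {
      build_pairs(x, n, box, rlist_outer, chain, oi_, oj_);
      xref_out = x;
      s_out = 1.0;
      refine_pairs(x, box, rlist, oi_, oj_, pi_, pj_);
      xref = x;
      s_in = 1.0;
      ++n_rebuilds;
    } else if (std::sqrt(drift1) + std::sqrt(drift2) + shrink_in > p.skin) {
      refine_pairs(x, box, rlist, oi_, oj_, pi_, pj_);
      xref = x;
      s_in = 1.0;
      ++n_rebuilds;
    }

    compute_forces_core(x, box, topo, pi_, pj_, p, f, eout);
    // B: half kick with fresh forces
    for (int i = 0; i < 3 * n; ++i) v[i] += kick * f[i];

    if (sched_steps > 0 && step <= sched_steps) {
      // deterministic affine compression: linear interpolation of the edge
      const double new_edge =
          (step == sched_steps)
              ? sched_target
              : sched_from + (sched_target - sched_from) * (double(step) / sched_steps);
      const double scale = new_edge / box;
      for (int i = 0; i < 3 * n; ++i) {
        x[i] *= scale;
        xref[i] *= scale;
        xref_out[i] *= scale;
      }
      box = new_edge;
      s_in *= scale;
      s_out *= scale;
      if (rlist >= box / 2)
        stop("geometry error: box shrank below twice the interaction range");
    } else if (barostat) {
      const double pinst = pressure();
      double mu3 = 1.0 - kappa * (p.dt / tau_p) * (p_target - pinst);
      double mu = (mu3 > 0.0) ? std::cbrt(mu3) : mu_lo;
      if (mu < mu_lo) { mu = mu_lo; mu_clamped = true; }
      if (mu > mu_hi) { mu = mu_hi; mu_clamped = true; }
      if (mu != 1.0) {
        for (int i = 0; i < 3 * n; ++i) {
          x[i] *= mu;
          xref[i] *= mu;
          xref_out[i] *= mu;
        }
        box *= mu;
        s_in *= mu;
        s_out *= mu;
        if (rlist >= box / 2)
          stop("geometry error: box shrank below twice the interaction range");
      }
    }

    if (step % record_every == 0) record(step);
    if (snapshot_every > 0 && step % snapshot_every == 0) snapshot(step);
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos_out(i, c) = wrap0(x[3 * i + c], box);
      vel_out(i, c) = v[3 * i + c];
    }

  List snl(snaps.size());
  for (size_t q = 0; q < snaps.size(); ++q) snl[q] = snaps[q];

  return List::create(
      _["positions"] = pos_out, _["velocities"] = vel_out, _["box_edge"] = box,
      _["step"] = rec_step, _["volume"] = rec_vol, _["kinetic"] = rec_ke,
      _["pressure"] = rec_press, _["snapshots"] = snl,
      _["snapshot_box"] = NumericVector(snap_box.begin(), snap_box.end()),
      _["snapshot_step"] = NumericVector(snap_step.begin(), snap_step.end()),
      _["n_rebuilds"] = n_rebuilds, _["mu_clamped"] = mu_clamped,
      _["energy"] = eout.total(),
      _["energy_components"] = List::create(
          _["bond"] = eout.e_bond, _["repulsive"] = eout.e_rep,
          _["angle"] = eout.e_angle, _["crosslink"] = eout.e_xlink),
      _["virial"] = eout.virial);
}
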