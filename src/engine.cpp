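// Overdamped Brownian-dynamics engine for rigid filaments bridged by
// elastic crosslinkers with stochastic turnover.
//
// One step:
//   1. assemble deterministic forces/torques (crosslinker springs + steric
//      contacts), draw fluctuation-dissipation-compliant stochastic kicks,
//      solve the anisotropic mobility relations component-wise in the
//      filament frame, advance centers and frames (Rodrigues rotation with
//      re-orthonormalization), reflect centers at the box walls;
//   2. Poisson attachment trials per filament pair;
//   3. slip-bond detachment sweep over the crosslinkers that existed at the
//      start of the step.
//
// The RNG is a mt19937_64 whose full state round-trips through a text
// string, so runs can be snapshotted and resumed bit-for-bit. Normal draws
// use a cache-free Box-Muller and Poisson draws Knuth's product method, so
// no distribution-internal state exists outside the serialized generator.

#include <Rcpp.h>
#include <random>
#include <sstream>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline V3& operator+=(V3& a, const V3& b) { a.x += b.x; a.y += b.y; a.z += b.z; return a; }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 normalize(const V3& a) { double n = norm3(a); return (1.0 / n) * a; }

class Rng {
public:
  std::mt19937_64 gen;
  explicit Rng(int seed) : gen(static_cast<uint64_t>(seed)) {}
  void load(const std::string& s) { std::istringstream is(s); is >> gen; }
  std::string save() const { std::ostringstream os; os << gen; return os.str(); }
  // uniform in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  double normal() {
    double u1 = 1.0 - unif();  // (0, 1]
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int poisson(double lambda) {
    if (lambda <= 0) return 0;
    if (lambda > 30.0) return poisson(lambda / 2) + poisson(lambda / 2);
    double limit = std::exp(-lambda), prod = unif();
    int n = 0;
    while (prod > limit) { prod *= unif(); ++n; }
    return n;
  }
  int unif_int(int n) {  // 1..n
    int k = static_cast<int>(unif() * n) + 1;
    return k > n ? n : k;
  }
};

struct Par {
  double delta, b, l0, kext, ktor, kf, kb0, Ec_abs, rc, fst, kBT, eta,
      box, gmax, dt;
  bool steric_torque;
};

struct Fil {
  V3 C, N, M;
  int nmon;
  double len;  // subunit center-to-center span (nmon - 1) * delta
  double xi_par_t, xi_perp_t, xi_par_r, xi_perp_r;
  bool mobile;
};

static inline V3 sub_pos(const Fil& f, int i, double delta) {
  double s = (i - (f.nmon + 1) / 2.0) * delta;
  return f.C + s * f.N;
}

static inline V3 sub_orient(const Fil& f, int i) {
  double phi = (i - 1) * (14.0 * M_PI / 13.0);
  V3 nm = cross(f.N, f.M);
  return std::cos(phi) * f.M + std::sin(phi) * nm;
}

static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// theta/sin(theta), continuous at 0, zeroed at the degenerate antipode
static inline double sinc_ratio(double th) {
  double s = std::sin(th);
  if (th < 1e-8) return 1.0;
  if (s < 1e-12) return 0.0;
  return th / s;
}

struct XlForces {
  double E, E_ext, E_tor;
  V3 Fa, Ta, Fb, Tb;
};

// energy, force and torque of one crosslinker (analytic gradient)
static XlForces xl_eval(const Fil& fa, int i, const Fil& fb, int j,
                        const Par& par, bool need_force) {
  XlForces out;
  V3 pi = sub_pos(fa, i, par.delta), pj = sub_pos(fb, j, par.delta);
  V3 Oi = sub_orient(fa, i), Oj = sub_orient(fb, j);
  V3 d = pj - pi;
  double lc = norm3(d);
  V3 u = (1.0 / lc) * d;
  double ci = clamp1(dot(Oi, u)), thi = std::acos(ci);
  double cj = clamp1(-dot(Oj, u)), thj = std::acos(cj);
  out.E_ext = 0.5 * par.kext * (lc - par.l0) * (lc - par.l0);
  out.E_tor = 0.5 * par.ktor * (thi * thi + thj * thj);
  out.E = out.E_ext + out.E_tor;
  if (!need_force) return out;
  double si = sinc_ratio(thi), sj = sinc_ratio(thj);
  V3 dEdd = par.kext * (lc - par.l0) * u;
  dEdd += (-par.ktor * si / lc) * (Oi - ci * u);
  dEdd += (-par.ktor * sj / lc) * ((-1.0) * Oj - cj * u);
  V3 gi = (-par.ktor * si) * u;  // dE/dOi
  V3 gj = (par.ktor * sj) * u;   // dE/dOj
  V3 ri = pi - fa.C, rj = pj - fb.C;
  out.Fa = dEdd;
  out.Fb = (-1.0) * dEdd;
  out.Ta = cross(ri, dEdd) - cross(Oi, gi);
  out.Tb = (-1.0) * cross(rj, dEdd) - cross(Oj, gj);
  return out;
}

// closest points between two finite segments (clamped parameters)
static double seg_closest(const V3& C1, const V3& N1, double len1,
                          const V3& C2, const V3& N2, double len2,
                          V3& ca, V3& cb) {
  V3 p1 = C1 - (len1 / 2) * N1, q1 = C1 + (len1 / 2) * N1;
  V3 p2 = C2 - (len2 / 2) * N2, q2 = C2 + (len2 / 2) * N2;
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = dot(d1, d1), e = dot(d2, d2);
  double f = dot(d2, r), c = dot(d1, r), b = dot(d1, d2);
  double denom = a * e - b * b;
  double s = 0.0, t = 0.0;
  if (denom > 1e-14 * a * e) {
    s = (b * f - c * e) / denom;
    s = s < 0 ? 0 : (s > 1 ? 1 : s);
  }
  t = (b * s + f) / e;
  if (t < 0) {
    t = 0;
    s = -c / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
  } else if (t > 1) {
    t = 1;
    s = (b - c) / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
  }
  ca = p1 + s * d1;
  cb = p2 + t * d2;
  return norm3(ca - cb);
}

static void rotate_fil(Fil& f, const V3& omega) {
  double ang = norm3(omega);
  if (ang > 0) {
    V3 axis = (1.0 / ang) * omega;
    double ca = std::cos(ang), sa = std::sin(ang);
    V3 N = ca * f.N + sa * cross(axis, f.N) + (1 - ca) * dot(axis, f.N) * axis;
    V3 M = ca * f.M + sa * cross(axis, f.M) + (1 - ca) * dot(axis, f.M) * axis;
    f.N = N;
    f.M = M;
  }
  f.N = normalize(f.N);
  f.M = normalize(f.M - dot(f.M, f.N) * f.N);
}

// [[Rcpp::export(name = ".bd_run_cpp")]]
List bd_run_cpp(NumericMatrix C0, NumericMatrix N0, NumericMatrix M0,
                IntegerVector nmon, IntegerMatrix xl0, IntegerVector mobile,
                List par_list, double dt, int n_steps, int record_every,
                bool kinetics, bool thermal, bool steric_torque_on,
                std::string rng_state, int seed) {
  const int nf = C0.nrow();
  Par par;
  par.delta = as<double>(par_list["delta"]);
  par.b = as<double>(par_list["b"]);
  par.l0 = as<double>(par_list["l0"]);
  par.kext = as<double>(par_list["kappa_ext"]);
  par.ktor = as<double>(par_list["kappa_tor"]);
  par.kf = as<double>(par_list["kf"]);
  par.kb0 = as<double>(par_list["kb0"]);
  par.Ec_abs = as<double>(par_list["Ec_abs"]);
  par.rc = as<double>(par_list["rc"]);
  par.fst = as<double>(par_list["fst"]);
  par.kBT = as<double>(par_list["kBT"]);
  par.eta = as<double>(par_list["eta"]);
  par.box = as<double>(par_list["box_size"]);
  par.gmax = as<double>(par_list["g_max"]);
  par.dt = dt;
  par.steric_torque = steric_torque_on;

  std::vector<Fil> fil(nf);
  for (int k = 0; k < nf; ++k) {
    Fil& f = fil[k];
    f.C = V3(C0(k, 0), C0(k, 1), C0(k, 2));
    f.N = V3(N0(k, 0), N0(k, 1), N0(k, 2));
    f.M = V3(M0(k, 0), M0(k, 1), M0(k, 2));
    f.nmon = nmon[k];
    f.len = (f.nmon - 1) * par.delta;
    f.mobile = mobile[k] != 0;
    double L = f.nmon * par.delta, lg = std::log(L / par.b);
    if (lg <= 0.66) stop("slender-body friction requires log(L/b) > 0.66");
    f.xi_par_t = 2 * M_PI * par.eta * L / (lg - 0.2);
    f.xi_perp_t = 4 * M_PI * par.eta * L / (lg + 0.84);
    f.xi_par_r = M_PI * par.eta * par.b * par.b * L;
    f.xi_perp_r = M_PI * par.eta * L * L * L / (3 * (lg - 0.66));
  }

  std::vector<std::array<int, 4>> xl;  // fil_a, sub_i, fil_b, sub_j (1-based)
  std::vector<std::vector<char>> occ(nf);
  std::vector<int> occ_count(nf, 0), cap(nf);
  for (int k = 0; k < nf; ++k) {
    occ[k].assign(fil[k].nmon + 1, 0);
    cap[k] = static_cast<int>(std::floor(par.gmax * fil[k].nmon + 1e-9));
  }
  for (int r = 0; r < xl0.nrow(); ++r) {
    std::array<int, 4> row = {xl0(r, 0), xl0(r, 1), xl0(r, 2), xl0(r, 3)};
    xl.push_back(row);
    occ[row[0] - 1][row[1]] = 1; ++occ_count[row[0] - 1];
    occ[row[2] - 1][row[3]] = 1; ++occ_count[row[2] - 1];
  }

  Rng rng(seed);
  if (!rng_state.empty()) rng.load(rng_state);

  List records;
  std::vector<V3> Fe(nf), Te(nf);

  auto snapshot_xl = [&]() {
    IntegerMatrix m(static_cast<int>(xl.size()), 4);
    for (size_t r = 0; r < xl.size(); ++r)
      for (int c = 0; c < 4; ++c) m(static_cast<int>(r), c) = xl[r][c];
    colnames(m) = CharacterVector::create("fil_a", "sub_i", "fil_b", "sub_j");
    return m;
  };
  auto snapshot_mat = [&](int which) {
    NumericMatrix m(nf, 3);
    for (int k = 0; k < nf; ++k) {
      const V3& v = which == 0 ? fil[k].C : (which == 1 ? fil[k].N : fil[k].M);
      m(k, 0) = v.x; m(k, 1) = v.y; m(k, 2) = v.z;
    }
    return m;
  };

  for (int step = 1; step <= n_steps; ++step) {
    // --- deterministic forces and torques ---
    for (int k = 0; k < nf; ++k) { Fe[k] = V3(); Te[k] = V3(); }
    for (const auto& x : xl) {
      int a = x[0] - 1, b = x[2] - 1;
      XlForces ft = xl_eval(fil[a], x[1], fil[b], x[3], par, true);
      Fe[a] += ft.Fa; Te[a] += ft.Ta;
      Fe[b] += ft.Fb; Te[b] += ft.Tb;
    }
    for (int a = 0; a < nf - 1; ++a) {
      for (int b = a + 1; b < nf; ++b) {
        V3 ca, cb;
        double rmin = seg_closest(fil[a].C, fil[a].N, fil[a].len,
                                  fil[b].C, fil[b].N, fil[b].len, ca, cb);
        if (rmin >= par.b) continue;
        V3 n;
        if (rmin > 1e-12) {
          n = (1.0 / rmin) * (ca - cb);
        } else {
          n = cross(fil[a].N, fil[b].N);
          if (norm3(n) < 1e-9) {
            V3 ref = std::fabs(fil[a].N.x) < 0.9 ? V3(1, 0, 0) : V3(0, 1, 0);
            n = ref - dot(ref, fil[a].N) * fil[a].N;
          }
          n = normalize(n);
        }
        V3 F = par.fst * n;
        Fe[a] += F;
        Fe[b] += (-1.0) * F;
        if (par.steric_torque) {
          Te[a] += cross(ca - fil[a].C, F);
          Te[b] += cross(cb - fil[b].C, (-1.0) * F);
        }
      }
    }
    // --- stochastic kicks, mobility solve, update ---
    for (int k = 0; k < nf; ++k) {
      Fil& f = fil[k];
      if (!f.mobile) continue;
      V3 F = Fe[k], T = Te[k];
      if (thermal && par.kBT > 0) {
        V3 ref = std::fabs(f.N.x) < 0.9 ? V3(1, 0, 0) : V3(0, 1, 0);
        V3 e1 = normalize(ref - dot(ref, f.N) * f.N);
        V3 e2 = cross(f.N, e1);
        double pref = 2 * par.kBT / dt;
        F += std::sqrt(pref * f.xi_par_t) * rng.normal() * f.N;
        F += std::sqrt(pref * f.xi_perp_t) * rng.normal() * e1;
        F += std::sqrt(pref * f.xi_perp_t) * rng.normal() * e2;
        T += std::sqrt(pref * f.xi_par_r) * rng.normal() * f.N;
        T += std::sqrt(pref * f.xi_perp_r) * rng.normal() * e1;
        T += std::sqrt(pref * f.xi_perp_r) * rng.normal() * e2;
      }
      double Fpar = dot(F, f.N), Tpar = dot(T, f.N);
      V3 V = (Fpar / f.xi_par_t) * f.N +
             (1.0 / f.xi_perp_t) * (F - Fpar * f.N);
      V3 Om = (Tpar / f.xi_par_r) * f.N +
              (1.0 / f.xi_perp_r) * (T - Tpar * f.N);
      f.C += dt * V;
      rotate_fil(f, dt * Om);
      // reflecting walls on the center of mass
      double* coords[3] = {&f.C.x, &f.C.y, &f.C.z};
      for (int c = 0; c < 3; ++c) {
        double& v = *coords[c];
        if (v < -par.box || v > 2 * par.box || !std::isfinite(v))
          stop("filament %d escaped the box at step %d (coordinate %g)",
               k + 1, step, v);
        if (v < 0) v = -v;
        else if (v > par.box) v = 2 * par.box - v;
      }
    }
    if (kinetics) {
      // --- attachments ---
      size_t n_old = xl.size();
      if (par.kf > 0) {
        for (int a = 0; a < nf - 1; ++a) {
          for (int b = a + 1; b < nf; ++b) {
            double lambda =
                static_cast<double>(fil[a].nmon) * fil[b].nmon * par.kf * dt;
            int n_try = rng.poisson(lambda);
            for (int trial = 0; trial < n_try; ++trial) {
              int i = rng.unif_int(fil[a].nmon);
              int j = rng.unif_int(fil[b].nmon);
              if (occ[a][i] || occ[b][j]) continue;
              if (occ_count[a] + 1 > cap[a] || occ_count[b] + 1 > cap[b])
                continue;
              V3 d = sub_pos(fil[a], i, par.delta) -
                     sub_pos(fil[b], j, par.delta);
              if (norm3(d) >= par.rc) continue;
              std::array<int, 4> row = {a + 1, i, b + 1, j};
              xl.push_back(row);
              occ[a][i] = 1; ++occ_count[a];
              occ[b][j] = 1; ++occ_count[b];
            }
          }
        }
      }
      // --- detachments (bonds existing at the start of the step) ---
      if (par.kb0 > 0 && n_old > 0) {
        std::vector<char> gone(xl.size(), 0);
        for (size_t r = 0; r < n_old; ++r) {
          const auto& x = xl[r];
          XlForces ft =
              xl_eval(fil[x[0] - 1], x[1], fil[x[2] - 1], x[3], par, false);
          double kb = par.Ec_abs > 0
                          ? par.kb0 * std::exp(ft.E / par.Ec_abs)
                          : (ft.E > 0 ? INFINITY : par.kb0);
          if (rng.unif() < 1 - std::exp(-kb * dt)) gone[r] = 1;
        }
        std::vector<std::array<int, 4>> kept;
        kept.reserve(xl.size());
        for (size_t r = 0; r < xl.size(); ++r) {
          if (gone[r]) {
            const auto& x = xl[r];
            occ[x[0] - 1][x[1]] = 0; --occ_count[x[0] - 1];
            occ[x[2] - 1][x[3]] = 0; --occ_count[x[2] - 1];
          } else {
            kept.push_back(xl[r]);
          }
        }
        xl.swap(kept);
      }
    }
    if (record_every > 0 && step % record_every == 0) {
      records.push_back(List::create(
          _["step"] = step, _["C"] = snapshot_mat(0), _["N"] = snapshot_mat(1),
          _["M"] = snapshot_mat(2), _["xl"] = snapshot_xl()));
    }
    if (step % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  for (int k = 0; k < nf; ++k) {
    if (!std::isfinite(fil[k].C.x) || !std::isfinite(fil[k].N.x))
      stop("non-finite state after run (filament %d)", k + 1);
  }
  return List::create(_["C"] = snapshot_mat(0), _["N"] = snapshot_mat(1),
                      _["M"] = snapshot_mat(2), _["xl"] = snapshot_xl(),
                      _["rng_state"] = rng.save(), _["records"] = records);
}
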