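// Core numerical routines: torsion-space chain building, energy terms,
// TM-score search and the replica-exchange annealing loop.  Everything that
// sits inside the Monte Carlo inner loop lives here; the R layer owns the
// user-facing interfaces and all parameter defaults.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double DEG = M_PI / 180.0;

// ---------------------------------------------------------------------------
// Deterministic RNG (independent of R's RNG so that fold runs are
// bit-reproducible from an integer seed across platforms).
struct XRng {
  std::mt19937_64 g;
  bool has_cache;
  double cache;
  explicit XRng(uint64_t seed) : g(seed), has_cache(false), cache(0.0) {}
  double unif() {  // in [0, 1)
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
  int randint(int n) {  // in 0..n-1
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    double r = std::sqrt(-2.0 * std::log(u1));
    cache = r * std::sin(2.0 * M_PI * u2);
    has_cache = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// Geometry primitives

struct P3 { double x, y, z; };

static inline P3 p3sub(const P3& a, const P3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline P3 p3cross(const P3& a, const P3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline void p3unit(P3& v) {
  double n = std::sqrt(v.x * v.x + v.y * v.y + v.z * v.z);
  v.x /= n; v.y /= n; v.z /= n;
}

// Place atom D given A-B-C, bond length r (C-D), bond angle theta (B-C-D,
// degrees) and dihedral chi (A-B-C-D, degrees, IUPAC sign convention).
static inline P3 nerf_place(const P3& a, const P3& b, const P3& c, double r,
                            double theta_deg, double chi_deg) {
  double theta = theta_deg * DEG, chi = chi_deg * DEG;
  P3 bc = p3sub(c, b);
  p3unit(bc);
  P3 n = p3cross(p3sub(b, a), bc);
  p3unit(n);
  P3 m = p3cross(n, bc);
  double w0 = -r * std::cos(theta);
  double w1 = r * std::sin(theta) * std::cos(chi);
  double w2 = -r * std::sin(theta) * std::sin(chi);
  return {c.x + w0 * bc.x + w1 * m.x + w2 * n.x,
          c.y + w0 * bc.y + w1 * m.y + w2 * n.y,
          c.z + w0 * bc.z + w1 * m.z + w2 * n.z};
}

// Ideal backbone geometry (Engh-Huber-like averages)
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329,
                    B_C_O = 1.231;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7,
                    A_CA_C_O = 120.8;

// Build backbone N, CA, C, O, CB coordinates from per-residue torsions
// (degrees).  Row layout: residue i occupies rows 5i..5i+4 as N,CA,C,O,CB.
// phi[0] and omega[0] are ignored; psi[L-1] only positions the final O.
static mat build_chain_core(const vec& phi, const vec& psi, const vec& omega) {
  int L = phi.n_elem;
  std::vector<P3> at(5 * L);
  // first residue placed in a canonical frame
  at[0] = {0.0, 0.0, 0.0};
  at[1] = {B_N_CA, 0.0, 0.0};
  double th = A_N_CA_C * DEG;
  at[2] = {B_N_CA - B_CA_C * std::cos(th), B_CA_C * std::sin(th), 0.0};
  for (int i = 1; i < L; ++i) {
    const P3& Np = at[5 * (i - 1) + 0];
    const P3& CAp = at[5 * (i - 1) + 1];
    const P3& Cp = at[5 * (i - 1) + 2];
    P3 Ni = nerf_place(Np, CAp, Cp, B_C_N, A_CA_C_N, psi(i - 1));
    P3 CAi = nerf_place(CAp, Cp, Ni, B_N_CA, A_C_N_CA, omega(i));
    P3 Ci = nerf_place(Cp, Ni, CAi, B_CA_C, A_N_CA_C, phi(i));
    at[5 * i + 0] = Ni; at[5 * i + 1] = CAi; at[5 * i + 2] = Ci;
  }
  // carbonyl O and ideal CB for every residue
  for (int i = 0; i < L; ++i) {
    const P3& Ni = at[5 * i + 0];
    const P3& CAi = at[5 * i + 1];
    const P3& Ci = at[5 * i + 2];
    at[5 * i + 3] = nerf_place(Ni, CAi, Ci, B_C_O, A_CA_C_O, psi(i) + 180.0);
    P3 b = p3sub(CAi, Ni), c = p3sub(Ci, CAi);
    P3 a = p3cross(b, c);
    at[5 * i + 4] = {CAi.x - 0.58273431 * a.x + 0.56802827 * b.x -
                         0.54067466 * c.x,
                     CAi.y - 0.58273431 * a.y + 0.56802827 * b.y -
                         0.54067466 * c.y,
                     CAi.z - 0.58273431 * a.z + 0.56802827 * b.z -
                         0.54067466 * c.z};
  }
  mat X(5 * L, 3);
  for (int k = 0; k < 5 * L; ++k) {
    X(k, 0) = at[k].x; X(k, 1) = at[k].y; X(k, 2) = at[k].z;
  }
  return X;
}

// [[Rcpp::export(name = ".cpp_build_chain")]]
NumericMatrix cpp_build_chain(NumericVector phi, NumericVector psi,
                              NumericVector omega) {
  vec p(phi.begin(), phi.size()), s(psi.begin(), psi.size()),
      o(omega.begin(), omega.size());
  mat X = build_chain_core(p, s, o);
  return wrap(X);
}

// ---------------------------------------------------------------------------
// Energy model

struct EnergyParams {
  arma::cube pair_sr;   // 7 x 7 x nbin
  arma::cube pair_lr;   // 7 x 7 x nbin
  mat solv;             // 7 x (max_burial + 1)
  double pair_dmax, pair_bw;
  double solv_r;
  double d_con, decay;
  double rg_coef, rg_exp;
  vec radii;            // 5 atom radii: N CA C O CB
  int steric_minsep;    // minimum residue separation for steric pairs
};

static inline double wrap180(double x) {
  return x - 360.0 * std::floor((x + 180.0) / 360.0);
}

static inline int torsion_state(double phi, double psi) {
  phi = wrap180(phi);
  psi = wrap180(psi);
  if (phi > -120.0 && phi < -30.0 && psi > -80.0 && psi < -5.0) return 1;  // H
  if (phi >= -180.0 && phi < -90.0 && (psi > 90.0 || psi < -150.0)) return 2;  // E
  return 0;  // coil
}

// contact-bearing coordinate of residue i: CB, or CA for glycine
static inline rowvec contact_atom(const mat& X, const arma::ivec& isgly, int i) {
  return isgly(i) ? X.row(5 * i + 1) : X.row(5 * i + 4);
}

static inline double rrcon_one(double ppv, double d, double d_con,
                               double decay) {
  if (d <= d_con) return -ppv;
  return ppv * (1.0 - 2.0 * std::exp(-(d - d_con) / decay));
}

// The seven raw terms: SR, LR, SOLV, HB, COMPACT, STERIC, RR.
// Written against raw arrays: this is the Monte Carlo inner loop.
static vec eval_terms_core(const mat& X, const arma::ivec& cls,
                           const arma::ivec& isgly, const arma::ivec& ss,
                           const vec& phi, const vec& psi,
                           const arma::imat& con, const vec& ppv, int max_sep,
                           const EnergyParams& P) {
  int L = cls.n_elem;
  int nbin = P.pair_sr.n_slices;
  int maxbur = P.solv.n_cols - 1;
  vec out(7, arma::fill::zeros);
  // flat atom coordinates: X is (5L x 3) column-major
  const double* xc = X.colptr(0);
  const double* yc = X.colptr(1);
  const double* zc = X.colptr(2);
  std::vector<double> cx(L), cy(L), cz(L);  // contact atom (CB; CA for Gly)
  for (int i = 0; i < L; ++i) {
    int a = isgly(i) ? 5 * i + 1 : 5 * i + 4;
    cx[i] = xc[a]; cy[i] = yc[a]; cz[i] = zc[a];
  }
  std::vector<int> burial(L, 0);
  double solv_r2 = P.solv_r * P.solv_r;
  double dmax2 = P.pair_dmax * P.pair_dmax;
  const double* sr_tab = P.pair_sr.memptr();
  const double* lr_tab = P.pair_lr.memptr();
  double e_sr = 0.0, e_lr = 0.0;
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= solv_r2) { burial[i]++; burial[j]++; }
      int sep = j - i;
      if (sep < 5 || d2 >= dmax2) continue;
      int bin = (int)(std::sqrt(d2) / P.pair_bw);
      if (bin >= nbin) bin = nbin - 1;
      size_t idx = (size_t)cls(i) + 7 * (size_t)cls(j) + 49 * (size_t)bin;
      if (sep <= 10) e_sr += sr_tab[idx]; else e_lr += lr_tab[idx];
    }
  }
  out(0) = e_sr; out(1) = e_lr;
  for (int i = 0; i < L; ++i) {
    int b = burial[i] > maxbur ? maxbur : burial[i];
    out(2) += P.solv(cls(i), b);
  }
  // HB: reward residues whose backbone torsions realize the predicted H/E state
  int nmatch = 0;
  for (int i = 0; i < L; ++i) {
    if (ss(i) == 1 || ss(i) == 2) {
      if (torsion_state(phi(i), psi(i)) == ss(i)) nmatch++;
    }
  }
  out(3) = -(double)nmatch;
  // COMPACT: squared deviation of CA radius of gyration from globular target
  double mx = 0, my = 0, mz = 0;
  for (int i = 0; i < L; ++i) {
    int a = 5 * i + 1;
    mx += xc[a]; my += yc[a]; mz += zc[a];
  }
  mx /= L; my /= L; mz /= L;
  double rg2 = 0.0;
  for (int i = 0; i < L; ++i) {
    int a = 5 * i + 1;
    double dx = xc[a] - mx, dy = yc[a] - my, dz = zc[a] - mz;
    rg2 += dx * dx + dy * dy + dz * dz;
  }
  double rg = std::sqrt(rg2 / L);
  double rg_t = P.rg_coef * std::pow((double)L, P.rg_exp);
  out(4) = (rg - rg_t) * (rg - rg_t);
  // STERIC: soft-sphere overlap between atoms of residues >= minsep apart
  double rc2_tab[25], rc_tab[25];
  double reach = 0.0;
  for (int a = 0; a < 5; ++a) {
    reach = std::max(reach, P.radii(a));
    for (int b = 0; b < 5; ++b) {
      rc_tab[5 * a + b] = P.radii(a) + P.radii(b);
      rc2_tab[5 * a + b] = rc_tab[5 * a + b] * rc_tab[5 * a + b];
    }
  }
  double skip = 2.0 * reach + 2.0 * 2.5;
  double skip2 = skip * skip;
  double e_st = 0.0;
  for (int i = 0; i < L; ++i) {
    int ica = 5 * i + 1;
    int na_i = isgly(i) ? 4 : 5;
    for (int j = i + P.steric_minsep; j < L; ++j) {
      int jca = 5 * j + 1;
      double dxc = xc[ica] - xc[jca], dyc = yc[ica] - yc[jca],
             dzc = zc[ica] - zc[jca];
      if (dxc * dxc + dyc * dyc + dzc * dzc > skip2) continue;
      int na_j = isgly(j) ? 4 : 5;
      for (int a = 0; a < na_i; ++a) {
        int ia = 5 * i + a;
        for (int b = 0; b < na_j; ++b) {
          int jb = 5 * j + b;
          double dx = xc[ia] - xc[jb], dy = yc[ia] - yc[jb],
                 dz = zc[ia] - zc[jb];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < rc2_tab[5 * a + b]) {
            double diff = rc_tab[5 * a + b] - std::sqrt(d2);
            e_st += diff * diff;
          }
        }
      }
    }
  }
  out(5) = e_st;
  // RR: predicted-contact pseudo-energy over the active schedule window
  int nc = con.n_rows;
  for (int k = 0; k < nc; ++k) {
    int i = con(k, 0), j = con(k, 1);
    if (max_sep >= 0 && j - i > max_sep) continue;
    double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
    out(6) += rrcon_one(ppv(k), std::sqrt(dx * dx + dy * dy + dz * dz),
                        P.d_con, P.decay);
  }
  return out;
}

static EnergyParams params_from_list(List par) {
  EnergyParams P;
  NumericVector psr = par["pair_sr"], plr = par["pair_lr"];
  IntegerVector dim = par["pair_dim"];  // c(7, 7, nbin)
  P.pair_sr = arma::cube(psr.begin(), dim[0], dim[1], dim[2]);
  P.pair_lr = arma::cube(plr.begin(), dim[0], dim[1], dim[2]);
  NumericMatrix sv = par["solv"];
  P.solv = mat(sv.begin(), sv.nrow(), sv.ncol());
  P.pair_dmax = par["pair_dmax"]; P.pair_bw = par["pair_bw"];
  P.solv_r = par["solv_r"];
  P.d_con = par["d_con"]; P.decay = par["decay"];
  P.rg_coef = par["rg_coef"]; P.rg_exp = par["rg_exp"];
  NumericVector rr = par["radii"];
  P.radii = vec(rr.begin(), rr.size());
  P.steric_minsep = par["steric_minsep"];
  return P;
}

// [[Rcpp::export(name = ".cpp_eval_terms")]]
NumericVector cpp_eval_terms(NumericMatrix coords, IntegerVector cls,
                             IntegerVector isgly, IntegerVector ss,
                             NumericVector phi, NumericVector psi,
                             IntegerMatrix contacts, NumericVector ppv,
                             int max_sep, List par) {
  mat X(coords.begin(), coords.nrow(), coords.ncol());
  arma::ivec c(cls.size()), g(isgly.size()), s(ss.size());
  for (int i = 0; i < cls.size(); ++i) { c(i) = cls[i]; g(i) = isgly[i]; s(i) = ss[i]; }
  arma::imat con(contacts.nrow(), 2);
  for (int i = 0; i < contacts.nrow(); ++i) { con(i, 0) = contacts(i, 0); con(i, 1) = contacts(i, 1); }
  vec p(phi.begin(), phi.size()), q(psi.begin(), psi.size()),
      pv(ppv.begin(), ppv.size());
  EnergyParams P = params_from_list(par);
  vec t = eval_terms_core(X, c, g, s, p, q, con, pv, max_sep, P);
  NumericVector out = wrap(t);
  out.attr("names") =
      CharacterVector::create("SR", "LR", "SOLV", "HB", "COMPACT", "STERIC", "RR");
  return out;
}

// ---------------------------------------------------------------------------
// Superposition and TM-score

// Weighted Kabsch: returns R (3x3, det +1) and t so that A*R + t ~ B.
static double kabsch_fit(const mat& A, const mat& B, const vec& w, mat& R,
                         rowvec& t) {
  double W = arma::accu(w);
  rowvec ma = (w.t() * A) / W, mb = (w.t() * B) / W;
  mat Ac = A.each_row() - ma, Bc = B.each_row() - mb;
  mat H = Ac.t() * (Bc.each_col() % w);
  mat U, V;
  vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  t = mb - ma * R;
  mat diff = Ac * R - Bc;
  double ss = 0.0;
  for (arma::uword i = 0; i < diff.n_rows; ++i)
    ss += w(i) * arma::dot(diff.row(i), diff.row(i));
  return std::sqrt(ss / W);
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(NumericMatrix a, NumericMatrix b) {
  mat A(a.begin(), a.nrow(), 3), B(b.begin(), b.nrow(), 3);
  vec w(a.nrow(), arma::fill::ones);
  mat R; rowvec t;
  double rmsd = kabsch_fit(A, B, w, R, t);
  return List::create(_["rotation"] = wrap(R), _["translation"] = wrap(t),
                      _["rmsd"] = rmsd);
}

static double tm_of(const mat& Xs, const mat& Y, double d0) {
  int n = Y.n_rows;
  const double* xa = Xs.colptr(0); const double* xb = Xs.colptr(1);
  const double* xc = Xs.colptr(2);
  const double* ya = Y.colptr(0); const double* yb = Y.colptr(1);
  const double* yc = Y.colptr(2);
  double inv = 1.0 / (d0 * d0), s = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = xa[i] - ya[i], dy = xb[i] - yb[i], dz = xc[i] - yc[i];
    s += 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) * inv);
  }
  return s / n;
}

// TM-score of model X against reference Y (same length, same sequence).
// Deterministic search: seed superpositions from every contiguous window at a
// few window lengths, refine each by distance-cutoff reselection, then polish
// the best with TM-weighted iterations.
// [[Rcpp::export(name = ".cpp_tm_score")]]
double cpp_tm_score(NumericMatrix xm, NumericMatrix ym, double d0) {
  int L = xm.nrow();
  mat X(xm.begin(), L, 3), Y(ym.begin(), L, 3);
  double best = 0.0;
  std::vector<int> lens;
  for (int l : {L, L / 2, L / 4, 4}) {
    if (L > 40 && l == 4) continue;  // long chains: coarser seed schedule
    if (l >= 4 && std::find(lens.begin(), lens.end(), l) == lens.end())
      lens.push_back(l);
  }
  double dcut = std::max(d0, 4.5);
  int stride = L > 40 ? std::max(1, L / 16) : 1;
  mat R; rowvec t;

  // TM-weighted Kabsch polish (majorize-maximize on the TM objective)
  double inv_d02 = 1.0 / (d0 * d0);
  auto polish = [&](mat& Rb, rowvec& tb) {
    vec w(L);
    mat Xs = X * Rb;
    Xs.each_row() += tb;
    double prev = -1.0;
    for (int iter = 0; iter < 40; ++iter) {
      const double* xa = Xs.colptr(0); const double* xb = Xs.colptr(1);
      const double* xc = Xs.colptr(2);
      const double* ya = Y.colptr(0); const double* yb = Y.colptr(1);
      const double* yc = Y.colptr(2);
      for (int i = 0; i < L; ++i) {
        double dx = xa[i] - ya[i], dy = xb[i] - yb[i], dz = xc[i] - yc[i];
        double r2 = (dx * dx + dy * dy + dz * dz) * inv_d02;
        w(i) = 1.0 / ((1.0 + r2) * (1.0 + r2));
      }
      kabsch_fit(X, Y, w, R, t);
      Xs = X * R;
      Xs.each_row() += t;
      double tm = tm_of(Xs, Y, d0);
      if (tm > best) best = tm;
      if (tm - prev < 1e-8) break;
      prev = tm;
    }
  };

  // iterative distance-cutoff refinement from a starting superposition
  auto refine_from = [&](mat R0, rowvec t0, bool entry_polish) {
    mat Xs = X * R0;
    Xs.each_row() += t0;
    double tm0 = tm_of(Xs, Y, d0);
    if (tm0 > best) best = tm0;
    if (entry_polish) {
      mat Rp = R0; rowvec tp = t0;
      polish(Rp, tp);  // score-weighted ascent directly from the seed
    }
    mat Rl = R0; rowvec tl = t0;
    double local = tm0;
    std::vector<int> sub, prev_sub;
    double dcut2 = dcut * dcut;
    for (int iter = 0; iter < 30; ++iter) {
      sub.clear();
      const double* xa = Xs.colptr(0); const double* xb = Xs.colptr(1);
      const double* xc = Xs.colptr(2);
      const double* ya = Y.colptr(0); const double* yb = Y.colptr(1);
      const double* yc = Y.colptr(2);
      for (int i = 0; i < L; ++i) {
        double dx = xa[i] - ya[i], dy = xb[i] - yb[i], dz = xc[i] - yc[i];
        if (dx * dx + dy * dy + dz * dz < dcut2) sub.push_back(i);
      }
      if ((int)sub.size() < 3) {
        vec dists(L);
        for (int i = 0; i < L; ++i)
          dists(i) = arma::norm(Xs.row(i) - Y.row(i));
        arma::uvec ord = arma::sort_index(dists);
        sub = {(int)ord(0), (int)ord(1), (int)ord(2)};
        std::sort(sub.begin(), sub.end());
      }
      if (sub == prev_sub) break;
      prev_sub = sub;
      mat A(sub.size(), 3), B(sub.size(), 3);
      for (size_t i = 0; i < sub.size(); ++i) {
        A.row(i) = X.row(sub[i]);
        B.row(i) = Y.row(sub[i]);
      }
      vec w(sub.size(), arma::fill::ones);
      kabsch_fit(A, B, w, R, t);
      Xs = X * R;
      Xs.each_row() += t;
      double tm = tm_of(Xs, Y, d0);
      if (tm > local) { local = tm; Rl = R; tl = t; }
      if (tm > best) best = tm;
    }
    // polish only competitive candidates; the weighted ascent rarely gains
    // more than ~0.1 TM, so clearly hopeless seeds are skipped
    if (local > best - 0.15) polish(Rl, tl);
  };

  for (int wl : lens) {
    for (int st = 0; st + wl <= L; st += stride) {
      mat A(wl, 3), B(wl, 3);
      for (int i = 0; i < wl; ++i) {
        A.row(i) = X.row(st + i);
        B.row(i) = Y.row(st + i);
      }
      vec w(wl, arma::fill::ones);
      kabsch_fit(A, B, w, R, t);
      refine_from(R, t, false);
    }
  }

  // deterministic rotation seeds (centroid-aligned) to cover basins that
  // no contiguous-window alignment reaches; denser for short chains
  {
    int n_rot = L <= 40 ? 150 : 0;
    XRng rng(99991ULL);
    rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
    for (int k = 0; k < n_rot; ++k) {
      double q0 = rng.norm(), q1 = rng.norm(), q2 = rng.norm(),
             q3 = rng.norm();
      double qn = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
      q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
      mat R0(3, 3);
      R0(0, 0) = q0 * q0 + q1 * q1 - q2 * q2 - q3 * q3;
      R0(1, 0) = 2 * (q1 * q2 + q0 * q3);
      R0(2, 0) = 2 * (q1 * q3 - q0 * q2);
      R0(0, 1) = 2 * (q1 * q2 - q0 * q3);
      R0(1, 1) = q0 * q0 - q1 * q1 + q2 * q2 - q3 * q3;
      R0(2, 1) = 2 * (q2 * q3 + q0 * q1);
      R0(0, 2) = 2 * (q1 * q3 + q0 * q2);
      R0(1, 2) = 2 * (q2 * q3 - q0 * q1);
      R0(2, 2) = q0 * q0 - q1 * q1 - q2 * q2 + q3 * q3;
      rowvec t0 = cy - cx * R0;
      refine_from(R0, t0, true);
    }
    // random-subset alignment seeds: superpose on a few residues at a time
    int n_sub = L <= 40 ? 120 : 0;
    for (int k = 0; k < n_sub; ++k) {
      int m = 3 + (int)(rng.unif() * 4);  // subset of 3..6 residues
      mat A(m, 3), B(m, 3);
      for (int i = 0; i < m; ++i) {
        int idx = (int)(rng.unif() * L);
        if (idx >= L) idx = L - 1;
        A.row(i) = X.row(idx);
        B.row(i) = Y.row(idx);
      }
      vec w(m, arma::fill::ones);
      kabsch_fit(A, B, w, R, t);
      if (!R.has_nan()) refine_from(R, t, true);
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Replica-exchange simulated-annealing fragment assembly

struct Replica {
  vec phi, psi, omega;
  mat X;
  vec terms;
  double E;
};

// [[Rcpp::export(name = ".cpp_remc")]]
List cpp_remc(IntegerVector cls, IntegerVector isgly, IntegerVector ss,
              NumericVector phi0, NumericVector psi0, NumericVector omega0,
              List shortlists, IntegerMatrix contacts, NumericVector ppv,
              NumericVector weights, List par, List cfg) {
  int L = cls.size();
  arma::ivec C(L), G(L), S(L);
  for (int i = 0; i < L; ++i) { C(i) = cls[i]; G(i) = isgly[i]; S(i) = ss[i]; }
  arma::imat con(contacts.nrow(), 2);
  for (int i = 0; i < contacts.nrow(); ++i) { con(i, 0) = contacts(i, 0); con(i, 1) = contacts(i, 1); }
  vec pv(ppv.begin(), ppv.size());
  vec W(weights.begin(), weights.size());
  EnergyParams P = params_from_list(par);

  int steps = cfg["steps"];
  int n_rep = cfg["n_replicas"];
  double T_hi = cfg["t_high"], T_lo = cfg["t_low"];
  int exch = cfg["exchange_interval"];
  int n_cycles = cfg["n_cycles"];
  bool sequential = cfg["sequential"];
  int s0 = cfg["s0"];
  double p_frag = cfg["p_frag"], sigma = cfg["perturb_sigma"];
  uint64_t seed = (uint64_t)(double)cfg["seed"];
  XRng rng(seed * 2654435761ULL + 1ULL);

  // unpack fragment shortlists: per start position, a list of len x 3 matrices
  int npos = shortlists.size();
  std::vector<std::vector<mat> > frags(npos);
  std::vector<int> active_pos;
  for (int p = 0; p < npos; ++p) {
    List fl = shortlists[p];
    for (int k = 0; k < fl.size(); ++k) {
      NumericMatrix fm = fl[k];
      frags[p].push_back(mat(fm.begin(), fm.nrow(), 3));
    }
    if (fl.size() > 0) active_pos.push_back(p);
  }
  bool have_frags = !active_pos.empty();

  int steps_per_rep = n_rep > 0 ? steps / n_rep : 0;
  int cycle_len = std::max(1, n_cycles > 0 ? steps_per_rep / n_cycles : steps_per_rep);

  // geometric ladder, slot 0 coldest
  vec ladder(n_rep);
  for (int k = 0; k < n_rep; ++k)
    ladder(k) = n_rep == 1 ? T_hi
                           : T_lo * std::pow(T_hi / T_lo, (double)k / (n_rep - 1));
  double anneal_end = T_lo / T_hi;  // final multiplier of the ladder

  int max_sep_now = sequential ? s0 : -1;
  std::vector<Replica> reps(n_rep);
  for (int k = 0; k < n_rep; ++k) {
    reps[k].phi = vec(phi0.begin(), L);
    reps[k].psi = vec(psi0.begin(), L);
    reps[k].omega = vec(omega0.begin(), L);
    reps[k].X = build_chain_core(reps[k].phi, reps[k].psi, reps[k].omega);
    reps[k].terms = eval_terms_core(reps[k].X, C, G, S, reps[k].phi, reps[k].psi,
                                    con, pv, max_sep_now, P);
    reps[k].E = arma::dot(W, reps[k].terms);
  }

  Replica best = reps[0];
  double bestE = reps[0].E;
  std::vector<double> trace;
  arma::vec acc(n_rep, arma::fill::zeros), prop(n_rep, arma::fill::zeros);
  double ex_acc = 0, ex_try = 0;
  size_t max_k = 0;
  for (int p = 0; p < npos; ++p) max_k = std::max(max_k, frags[p].size());
  arma::imat frag_used(npos, std::max<size_t>(max_k, 1),
                       arma::fill::zeros);  // accepted insertions

  for (int step = 0; step < steps_per_rep; ++step) {
    int cycle = step / cycle_len;
    double frac = steps_per_rep > 1 ? (double)step / (steps_per_rep - 1) : 1.0;
    double mult = 1.0 + frac * (anneal_end - 1.0);
    if (sequential) {
      int T = std::max(1, n_cycles - 1);
      int ms = (int)std::floor(s0 + (L - 1.0 - s0) * std::min(cycle, T) / (double)T + 0.5);
      if (ms != max_sep_now) {
        max_sep_now = ms;
        for (int k = 0; k < n_rep; ++k) {
          reps[k].terms = eval_terms_core(reps[k].X, C, G, S, reps[k].phi,
                                          reps[k].psi, con, pv, max_sep_now, P);
          reps[k].E = arma::dot(W, reps[k].terms);
        }
      }
    }
    for (int k = 0; k < n_rep; ++k) {
      double T = ladder(k) * mult;
      Replica& r = reps[k];
      vec nphi = r.phi, npsi = r.psi, nomega = r.omega;
      bool do_frag = have_frags && rng.unif() < p_frag;
      int mv_p = -1, mv_f = -1;
      if (do_frag) {
        int p = active_pos[rng.randint(active_pos.size())];
        const std::vector<mat>& fl = frags[p];
        int fi = rng.randint(fl.size());
        mv_p = p; mv_f = fi;
        const mat& f = fl[fi];
        int fl_len = f.n_rows;
        for (int i = 0; i < fl_len && p + i < L; ++i) {
          nphi(p + i) = f(i, 0);
          npsi(p + i) = f(i, 1);
          nomega(p + i) = f(i, 2);
        }
      } else {
        int i = rng.randint(L);
        nphi(i) += sigma * rng.norm();
        npsi(i) += sigma * rng.norm();
      }
      mat nX = build_chain_core(nphi, npsi, nomega);
      vec nt = eval_terms_core(nX, C, G, S, nphi, npsi, con, pv, max_sep_now, P);
      double nE = arma::dot(W, nt);
      double dE = nE - r.E;
      prop(k) += 1;
      if (dE <= 0 || rng.unif() < std::exp(-dE / T)) {
        r.phi = nphi; r.psi = npsi; r.omega = nomega;
        r.X = nX; r.terms = nt; r.E = nE;
        acc(k) += 1;
        if (mv_p >= 0) frag_used(mv_p, mv_f) += 1;
      }
      if (k == 0 && r.E < bestE) { bestE = r.E; best = r; }
    }
    if (exch > 0 && (step + 1) % exch == 0 && n_rep > 1) {
      int par0 = ((step + 1) / exch) % 2;
      for (int k = par0; k + 1 < n_rep; k += 2) {
        double Ti = ladder(k) * mult, Tj = ladder(k + 1) * mult;
        double del = (1.0 / Ti - 1.0 / Tj) * (reps[k].E - reps[k + 1].E);
        ex_try += 1;
        if (del >= 0 || rng.unif() < std::exp(del)) {
          std::swap(reps[k], reps[k + 1]);
          ex_acc += 1;
          if (reps[0].E < bestE) { bestE = reps[0].E; best = reps[0]; }
        }
      }
    }
    if ((step + 1) % cycle_len == 0) trace.push_back(bestE);
  }

  mat tors(L, 3);
  tors.col(0) = best.phi; tors.col(1) = best.psi; tors.col(2) = best.omega;
  return List::create(
      _["torsions"] = wrap(tors), _["energy"] = bestE,
      _["terms"] = wrap(best.terms),
      _["accept_rate"] = wrap(prop.max() > 0 ? vec(acc / arma::clamp(prop, 1.0, arma::datum::inf)) : acc),
      _["exchange_rate"] = ex_try > 0 ? ex_acc / ex_try : NA_REAL,
      _["trace"] = wrap(trace), _["final_max_sep"] = max_sep_now,
      _["frag_used"] = wrap(frag_used));
}
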