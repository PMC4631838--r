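// Replica-exchange Gibbs sampling core.
//
// The R level compiles an assembly_system into flat vectors; this file
// runs the Monte Carlo sweeps with incremental score updates. All
// randomness goes through R's RNG, so runs are reproducible from
// set.seed() and a single-replica ladder consumes exactly the same
// stream as plain Metropolis sampling.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- forward model: P(|X-Y| <= L), X,Y uniform in spheres radius a,b,
// centers d apart. Exact piecewise-polynomial integrand; 16-point
// Gauss-Legendre per analytic piece is exact.

static const double GLX[16] = {
  -0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
  -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
  -0.2816035507792589, -0.0950125098376374,  0.0950125098376374,
   0.2816035507792589,  0.4580167776572274,  0.6178762444026438,
   0.7554044083550030,  0.8656312023878318,  0.9445750230732326,
   0.9894009349916499};
static const double GLW[16] = {
  0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
  0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
  0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
  0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
  0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
  0.0271524594117541};

static double lens_volume(double R, double r, double rho) {
  if (rho >= R + r) return 0.0;
  if (rho <= std::fabs(R - r)) {
    double m = std::min(R, r);
    return 4.0 / 3.0 * M_PI * m * m * m;
  }
  double s = R + r - rho;
  return M_PI * s * s *
         (rho * rho + 2.0 * rho * r - 3.0 * r * r + 2.0 * rho * R +
          6.0 * r * R - 3.0 * R * R) / (12.0 * rho);
}

static double fm_sphere(double d, double a, double b, double L) {
  if (d - a - b > L) return 0.0;
  if (d + a + b <= L) return 1.0;
  const double eps = 1e-9;
  double vb = 4.0 / 3.0 * M_PI * b * b * b;
  double t_lo, t_hi;
  bool central = (d < eps);
  if (central) { t_lo = 0.0; t_hi = a; }
  else { t_lo = std::max(0.0, d - a); t_hi = d + a; }
  std::vector<double> bp;
  bp.push_back(t_lo); bp.push_back(t_hi);
  if (!central && a > d) bp.push_back(a - d);
  double c1 = std::fabs(b - L), c2 = b + L;
  if (c1 > t_lo && c1 < t_hi) bp.push_back(c1);
  if (c2 > t_lo && c2 < t_hi) bp.push_back(c2);
  std::sort(bp.begin(), bp.end());
  double total = 0.0;
  for (size_t s = 0; s + 1 < bp.size(); ++s) {
    double lo = bp[s], hi = bp[s + 1];
    if (hi - lo < 1e-14) continue;
    double acc = 0.0;
    for (int k = 0; k < 16; ++k) {
      double t = 0.5 * (hi + lo) + 0.5 * (hi - lo) * GLX[k];
      double pt;
      if (central) pt = 3.0 * t * t / (a * a * a);
      else if (t < a - d) pt = 3.0 * t * t / (a * a * a);
      else pt = 3.0 * t * (a * a - (d - t) * (d - t)) / (4.0 * a * a * a * d);
      acc += GLW[k] * pt * lens_volume(b, L, t) / vb;
    }
    total += 0.5 * (hi - lo) * acc;
  }
  if (total < 0.0) total = 0.0;
  if (total > 1.0) total = 1.0;
  return total;
}

// [[Rcpp::export(name = "ia_forward_model_cpp")]]
NumericVector ia_forward_model_cpp(NumericVector d, double a, double b,
                                   double L) {
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = fm_sphere(d[i], a, b, L);
  return out;
}

// ---- 3x3 Gaussian pair overlap ---------------------------------------

static double pair_overlap(double w1, const double *m1, const double *S1,
                           double w2, const double *m2, const double *S2) {
  double S[9];
  for (int i = 0; i < 9; ++i) S[i] = S1[i] + S2[i];
  double det = S[0] * (S[4] * S[8] - S[5] * S[7]) -
               S[1] * (S[3] * S[8] - S[5] * S[6]) +
               S[2] * (S[3] * S[7] - S[4] * S[6]);
  if (det <= 0) return 0.0;
  double inv[9];
  inv[0] = (S[4] * S[8] - S[5] * S[7]) / det;
  inv[1] = (S[2] * S[7] - S[1] * S[8]) / det;
  inv[2] = (S[1] * S[5] - S[2] * S[4]) / det;
  inv[3] = inv[1];
  inv[4] = (S[0] * S[8] - S[2] * S[6]) / det;
  inv[5] = (S[2] * S[3] - S[0] * S[5]) / det;
  inv[6] = inv[2];
  inv[7] = inv[5];
  inv[8] = (S[0] * S[4] - S[1] * S[3]) / det;
  double dm[3] = {m1[0] - m2[0], m1[1] - m2[1], m1[2] - m2[2]};
  double q = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) q += dm[i] * inv[3 * i + j] * dm[j];
  const double c = 0.06349363593424097; // (2*pi)^(-3/2)
  return w1 * w2 * c / std::sqrt(det) * std::exp(-0.5 * q);
}

// ---- system / replica containers -------------------------------------

struct Sys {
  int n_beads;
  std::vector<double> radius;
  std::vector<int> is_coarse, rigid_id;
  std::vector<int> mobile_rigid, mobile_flex;
  int g_n, n_modules;
  std::vector<double> g_w;
  std::vector<int> g_rigid, g_bead, g_module;
  std::vector<double> d_w, d_means, d_covs;
  std::vector<int> d_module;
  std::vector<double> ovDD; // per module, constant
  int xl_n;
  std::vector<int> xl_b1, xl_b2, xl_class;
  std::vector<double> xl_w;
  std::vector<std::vector<int> > conn_i; // per pair: i, j; thr
  std::vector<double> conn_thr;
  std::vector<int> conn_a, conn_b;
  std::vector<int> teth_bead;
  std::vector<double> teth_x, teth_y, teth_z, teth_k;
  double l_xl, slope, em_scale, k_ev, k_conn, sigma_min, sigma_max;
  std::vector<int> coarse_idx;
  // per rigid id (1-based) member beads / gaussians; id 0 unused
  std::vector<std::vector<int> > rb_beads, rb_gauss;
  std::vector<std::vector<int> > bead_gauss; // per bead
  std::vector<std::vector<int> > bead_xl;    // links touching a bead
  std::vector<std::vector<int> > bead_conn;  // conn pairs touching a bead
  std::vector<std::vector<int> > bead_teth;
};

struct Rep {
  std::vector<double> x, y, z;     // bead coords
  std::vector<double> gm, gc;      // gaussian means (3*), covs (9*)
  double sigma, psi[2];
  std::vector<double> xl_d, xl_f;  // per-link caches
  double xl_total, linear_total, ev_total, conn_total, teth_total;
  std::vector<double> ovMD, ovMM;  // per module
};

static double em_term(const Sys &S, double ovMD, double ovMM, double ovDD) {
  double cc = 2.0 * ovMD / (ovMM + ovDD);
  if (cc < 1e-300) cc = 1e-300;
  return -S.em_scale * std::log(cc);
}

static double rep_total(const Sys &S, const Rep &r) {
  double t = r.xl_total + r.linear_total + r.ev_total + r.conn_total +
             r.teth_total;
  for (int m = 0; m < S.n_modules; ++m)
    t += em_term(S, r.ovMD[m], r.ovMM[m], S.ovDD[m]);
  return t;
}

static double dist3(const Rep &r, int i, int j) {
  double dx = r.x[i] - r.x[j], dy = r.y[i] - r.y[j], dz = r.z[i] - r.z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double xl_neglogp(const Sys &S, const Rep &r, int l, double f) {
  double psi = r.psi[S.xl_class[l] - 1];
  double p = psi * (1.0 - f) + f * (1.0 - psi);
  return -S.xl_w[l] * std::log(p);
}

// full (from-scratch) refresh of every cache
static void refresh(const Sys &S, Rep &r) {
  r.xl_total = 0.0; r.linear_total = 0.0;
  r.xl_d.assign(S.xl_n, 0.0); r.xl_f.assign(S.xl_n, 0.0);
  for (int l = 0; l < S.xl_n; ++l) {
    double d = dist3(r, S.xl_b1[l], S.xl_b2[l]);
    double f = fm_sphere(d, r.sigma, r.sigma, S.l_xl);
    r.xl_d[l] = d; r.xl_f[l] = f;
    r.xl_total += xl_neglogp(S, r, l, f);
    r.linear_total += S.slope * d;
  }
  r.ev_total = 0.0;
  for (size_t a = 0; a < S.coarse_idx.size(); ++a)
    for (size_t b = a + 1; b < S.coarse_idx.size(); ++b) {
      int i = S.coarse_idx[a], j = S.coarse_idx[b];
      if (S.rigid_id[i] != 0 && S.rigid_id[i] == S.rigid_id[j]) continue;
      double ov = S.radius[i] + S.radius[j] - dist3(r, i, j);
      if (ov > 0) r.ev_total += 0.5 * S.k_ev * ov * ov;
    }
  r.conn_total = 0.0;
  for (size_t p = 0; p < S.conn_a.size(); ++p) {
    double d = dist3(r, S.conn_a[p], S.conn_b[p]);
    double ex = d - S.conn_thr[p];
    if (ex > 0) r.conn_total += 0.5 * S.k_conn * ex * ex;
  }
  r.teth_total = 0.0;
  for (size_t t = 0; t < S.teth_bead.size(); ++t) {
    int i = S.teth_bead[t];
    double dx = r.x[i] - S.teth_x[t], dy = r.y[i] - S.teth_y[t],
           dz = r.z[i] - S.teth_z[t];
    r.teth_total += 0.5 * S.teth_k[t] * (dx * dx + dy * dy + dz * dz);
  }
  r.ovMD.assign(S.n_modules, 0.0);
  r.ovMM.assign(S.n_modules, 0.0);
  for (int g = 0; g < S.g_n; ++g) {
    int m = S.g_module[g] - 1;
    for (size_t j = 0; j < S.d_w.size(); ++j)
      if (S.d_module[j] - 1 == m)
        r.ovMD[m] += pair_overlap(S.g_w[g], &r.gm[3 * g], &r.gc[9 * g],
                                  S.d_w[j], &S.d_means[3 * j], &S.d_covs[9 * j]);
    for (int h = 0; h < S.g_n; ++h)
      if (S.g_module[h] - 1 == m)
        r.ovMM[m] += pair_overlap(S.g_w[g], &r.gm[3 * g], &r.gc[9 * g],
                                  S.g_w[h], &r.gm[3 * h], &r.gc[9 * h]);
  }
}

// ---- proposals (R RNG) ------------------------------------------------

static void runif_ball(double rmax, double *out) {
  for (;;) {
    double v[3];
    for (int i = 0; i < 3; ++i) v[i] = 2.0 * unif_rand() - 1.0;
    double n2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    if (n2 <= 1.0) {
      for (int i = 0; i < 3; ++i) out[i] = v[i] * rmax;
      return;
    }
  }
}

static void random_rotation(double amax, double *R) {
  double ax[3];
  for (int i = 0; i < 3; ++i) ax[i] = norm_rand();
  double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  for (int i = 0; i < 3; ++i) ax[i] /= n;
  double th = amax * (2.0 * unif_rand() - 1.0);
  double c = std::cos(th), s = std::sin(th), C = 1.0 - c;
  R[0] = c + ax[0] * ax[0] * C;
  R[1] = ax[0] * ax[1] * C - ax[2] * s;
  R[2] = ax[0] * ax[2] * C + ax[1] * s;
  R[3] = ax[1] * ax[0] * C + ax[2] * s;
  R[4] = c + ax[1] * ax[1] * C;
  R[5] = ax[1] * ax[2] * C - ax[0] * s;
  R[6] = ax[2] * ax[0] * C - ax[1] * s;
  R[7] = ax[2] * ax[1] * C + ax[0] * s;
  R[8] = c + ax[2] * ax[2] * C;
}

static bool mh_accept(double delta, double T) {
  if (delta <= 0) return true;
  return unif_rand() < std::exp(-delta / T);
}

// ---- coordinate move of a bead set -----------------------------------

// proposal buffers
struct Prop {
  std::vector<int> beads, gauss;
  std::vector<double> nx, ny, nz;     // new bead coords
  std::vector<double> ngm, ngc;       // new gaussian params (3*, 9*)
  std::vector<int> in_set;            // scratch: 0/1 per bead
};

static double coord_move_delta(const Sys &S, const Rep &r, Prop &P,
                               std::vector<double> &new_d,
                               std::vector<double> &new_f,
                               std::vector<int> &links,
                               std::vector<double> &dMD,
                               std::vector<double> &dMM) {
  double delta = 0.0;
  // cross-links and linear prior
  links.clear(); new_d.clear(); new_f.clear();
  std::vector<char> seen(S.xl_n, 0);
  for (size_t bi = 0; bi < P.beads.size(); ++bi) {
    const std::vector<int> &ls = S.bead_xl[P.beads[bi]];
    for (size_t k = 0; k < ls.size(); ++k) {
      int l = ls[k];
      if (seen[l]) continue;
      seen[l] = 1;
      int b1 = S.xl_b1[l], b2 = S.xl_b2[l];
      double x1, y1, z1, x2, y2, z2;
      int p1 = P.in_set[b1] - 1, p2 = P.in_set[b2] - 1;
      if (p1 >= 0) { x1 = P.nx[p1]; y1 = P.ny[p1]; z1 = P.nz[p1]; }
      else { x1 = r.x[b1]; y1 = r.y[b1]; z1 = r.z[b1]; }
      if (p2 >= 0) { x2 = P.nx[p2]; y2 = P.ny[p2]; z2 = P.nz[p2]; }
      else { x2 = r.x[b2]; y2 = r.y[b2]; z2 = r.z[b2]; }
      double dx = x1 - x2, dy = y1 - y2, dz = z1 - z2;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double f = fm_sphere(d, r.sigma, r.sigma, S.l_xl);
      links.push_back(l); new_d.push_back(d); new_f.push_back(f);
      delta += xl_neglogp(S, r, l, f) - xl_neglogp(S, r, l, r.xl_f[l]);
      delta += S.slope * (d - r.xl_d[l]);
    }
  }
  // EM restraint
  dMD.assign(S.n_modules, 0.0);
  dMM.assign(S.n_modules, 0.0);
  std::vector<char> gset(S.g_n, 0);
  for (size_t gi = 0; gi < P.gauss.size(); ++gi) gset[P.gauss[gi]] = 1;
  for (size_t gi = 0; gi < P.gauss.size(); ++gi) {
    int g = P.gauss[gi];
    int m = S.g_module[g] - 1;
    const double *nm = &P.ngm[3 * gi], *nc = &P.ngc[9 * gi];
    for (size_t j = 0; j < S.d_w.size(); ++j)
      if (S.d_module[j] - 1 == m)
        dMD[m] += pair_overlap(S.g_w[g], nm, nc, S.d_w[j], &S.d_means[3 * j],
                               &S.d_covs[9 * j]) -
                  pair_overlap(S.g_w[g], &r.gm[3 * g], &r.gc[9 * g], S.d_w[j],
                               &S.d_means[3 * j], &S.d_covs[9 * j]);
    for (int h = 0; h < S.g_n; ++h) {
      if (gset[h] || S.g_module[h] - 1 != m) continue;
      dMM[m] += 2.0 * (pair_overlap(S.g_w[g], nm, nc, S.g_w[h], &r.gm[3 * h],
                                    &r.gc[9 * h]) -
                       pair_overlap(S.g_w[g], &r.gm[3 * g], &r.gc[9 * g],
                                    S.g_w[h], &r.gm[3 * h], &r.gc[9 * h]));
    }
  }
  for (int m = 0; m < S.n_modules; ++m) {
    if (dMD[m] == 0.0 && dMM[m] == 0.0) continue;
    delta += em_term(S, r.ovMD[m] + dMD[m], r.ovMM[m] + dMM[m], S.ovDD[m]) -
             em_term(S, r.ovMD[m], r.ovMM[m], S.ovDD[m]);
  }
  return delta;
}

static void commit_coord_move(const Sys &S, Rep &r, const Prop &P,
                              const std::vector<double> &new_d,
                              const std::vector<double> &new_f,
                              const std::vector<int> &links,
                              const std::vector<double> &dMD,
                              const std::vector<double> &dMM) {
  for (size_t k = 0; k < links.size(); ++k) {
    int l = links[k];
    r.xl_total += xl_neglogp(S, r, l, new_f[k]) - xl_neglogp(S, r, l, r.xl_f[l]);
    r.linear_total += S.slope * (new_d[k] - r.xl_d[l]);
    r.xl_d[l] = new_d[k];
    r.xl_f[l] = new_f[k];
  }
  // ev/conn/teth totals: recompute the cheap way at refresh points; keep
  // exact running totals here by re-deriving the deltas is redundant --
  // instead fold them in via the same formulas used in the delta.
  // (handled by caller through stored partial deltas)
  for (int m = 0; m < S.n_modules; ++m) {
    r.ovMD[m] += dMD[m];
    r.ovMM[m] += dMM[m];
  }
  for (size_t bi = 0; bi < P.beads.size(); ++bi) {
    int i = P.beads[bi];
    r.x[i] = P.nx[bi]; r.y[i] = P.ny[bi]; r.z[i] = P.nz[bi];
  }
  for (size_t gi = 0; gi < P.gauss.size(); ++gi) {
    int g = P.gauss[gi];
    for (int c = 0; c < 3; ++c) r.gm[3 * g + c] = P.ngm[3 * gi + c];
    for (int c = 0; c < 9; ++c) r.gc[9 * g + c] = P.ngc[9 * gi + c];
  }
}

// split the delta of ev/conn/teth out so commit can update the totals
struct AuxDelta { double ev, conn, teth; };

static AuxDelta aux_delta(const Sys &S, const Rep &r, const Prop &P) {
  AuxDelta a; a.ev = 0; a.conn = 0; a.teth = 0;
  for (size_t bi = 0; bi < P.beads.size(); ++bi) {
    int i = P.beads[bi];
    if (!S.is_coarse[i]) continue;
    int pi = P.in_set[i] - 1;
    for (size_t cj = 0; cj < S.coarse_idx.size(); ++cj) {
      int j = S.coarse_idx[cj];
      if (P.in_set[j]) continue;
      if (S.rigid_id[i] != 0 && S.rigid_id[i] == S.rigid_id[j]) continue;
      double rs = S.radius[i] + S.radius[j];
      double d_old = dist3(r, i, j);
      double dxn = P.nx[pi] - r.x[j], dyn = P.ny[pi] - r.y[j],
             dzn = P.nz[pi] - r.z[j];
      double d_new = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn);
      double ovo = rs - d_old, ovn = rs - d_new;
      if (ovn > 0) a.ev += 0.5 * S.k_ev * ovn * ovn;
      if (ovo > 0) a.ev -= 0.5 * S.k_ev * ovo * ovo;
    }
  }
  std::vector<char> cseen(S.conn_a.size(), 0);
  for (size_t bi = 0; bi < P.beads.size(); ++bi) {
    const std::vector<int> &cs = S.bead_conn[P.beads[bi]];
    for (size_t k = 0; k < cs.size(); ++k) {
      int p = cs[k];
      if (cseen[p]) continue;
      cseen[p] = 1;
      int ia = S.conn_a[p], ib = S.conn_b[p];
      double xa, ya, za, xb, yb, zb;
      int pa = P.in_set[ia] - 1, pb = P.in_set[ib] - 1;
      if (pa >= 0) { xa = P.nx[pa]; ya = P.ny[pa]; za = P.nz[pa]; }
      else { xa = r.x[ia]; ya = r.y[ia]; za = r.z[ia]; }
      if (pb >= 0) { xb = P.nx[pb]; yb = P.ny[pb]; zb = P.nz[pb]; }
      else { xb = r.x[ib]; yb = r.y[ib]; zb = r.z[ib]; }
      double dn = std::sqrt((xa - xb) * (xa - xb) + (ya - yb) * (ya - yb) +
                            (za - zb) * (za - zb));
      double d0 = dist3(r, ia, ib);
      double exn = dn - S.conn_thr[p], exo = d0 - S.conn_thr[p];
      if (exn > 0) a.conn += 0.5 * S.k_conn * exn * exn;
      if (exo > 0) a.conn -= 0.5 * S.k_conn * exo * exo;
    }
  }
  for (size_t bi = 0; bi < P.beads.size(); ++bi) {
    const std::vector<int> &ts = S.bead_teth[P.beads[bi]];
    int pi = P.in_set[P.beads[bi]] - 1;
    for (size_t k = 0; k < ts.size(); ++k) {
      int t = ts[k];
      int i = S.teth_bead[t];
      double dxn = P.nx[pi] - S.teth_x[t], dyn = P.ny[pi] - S.teth_y[t],
             dzn = P.nz[pi] - S.teth_z[t];
      double dxo = r.x[i] - S.teth_x[t], dyo = r.y[i] - S.teth_y[t],
             dzo = r.z[i] - S.teth_z[t];
      a.teth += 0.5 * S.teth_k[t] *
                (dxn * dxn + dyn * dyn + dzn * dzn -
                 dxo * dxo - dyo * dyo - dzo * dzo);
    }
  }
  return a;
}

// matrix-vector helpers for the rigid move
static void rot_cov(const double *R, const double *C, double *out) {
  double T[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += R[3 * i + k] * C[3 * k + j];
      T[3 * i + j] = s;
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += T[3 * i + k] * R[3 * j + k];
      out[3 * i + j] = s;
    }
}

struct Mv {
  double rigid_trans, rigid_rot, flex_trans, sigma_step, psi_step,
         psi_min, psi_max, sigma_move_min;
};

// one Gibbs sweep of replica r at temperature T
static void gibbs_sweep(const Sys &S, Rep &r, double T, Prop &P,
                        const Mv &mv) {
  std::vector<double> new_d, new_f, dMD, dMM;
  std::vector<int> links;
  // rigid bodies
  for (size_t ri = 0; ri < S.mobile_rigid.size(); ++ri) {
    int id = S.mobile_rigid[ri];
    const std::vector<int> &mem = S.rb_beads[id];
    const std::vector<int> &gg = S.rb_gauss[id];
    double ctr[3] = {0, 0, 0};
    for (size_t k = 0; k < mem.size(); ++k) {
      ctr[0] += r.x[mem[k]]; ctr[1] += r.y[mem[k]]; ctr[2] += r.z[mem[k]];
    }
    for (int c = 0; c < 3; ++c) ctr[c] /= mem.size();
    double R[9], tr[3];
    random_rotation(mv.rigid_rot, R);
    runif_ball(mv.rigid_trans, tr);
    P.beads = mem; P.gauss = gg;
    P.nx.resize(mem.size()); P.ny.resize(mem.size()); P.nz.resize(mem.size());
    std::fill(P.in_set.begin(), P.in_set.end(), 0);
    for (size_t k = 0; k < mem.size(); ++k) {
      int i = mem[k];
      P.in_set[i] = (int)k + 1;
      double v[3] = {r.x[i] - ctr[0], r.y[i] - ctr[1], r.z[i] - ctr[2]};
      P.nx[k] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2] + ctr[0] + tr[0];
      P.ny[k] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2] + ctr[1] + tr[1];
      P.nz[k] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2] + ctr[2] + tr[2];
    }
    P.ngm.resize(3 * gg.size()); P.ngc.resize(9 * gg.size());
    for (size_t k = 0; k < gg.size(); ++k) {
      int g = gg[k];
      double v[3] = {r.gm[3 * g] - ctr[0], r.gm[3 * g + 1] - ctr[1],
                     r.gm[3 * g + 2] - ctr[2]};
      P.ngm[3 * k] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2] + ctr[0] + tr[0];
      P.ngm[3 * k + 1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2] + ctr[1] + tr[1];
      P.ngm[3 * k + 2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2] + ctr[2] + tr[2];
      rot_cov(R, &r.gc[9 * g], &P.ngc[9 * k]);
    }
    AuxDelta ad = aux_delta(S, r, P);
    double delta = coord_move_delta(S, r, P, new_d, new_f, links, dMD, dMM) +
                   ad.ev + ad.conn + ad.teth;
    if (mh_accept(delta, T)) {
      r.ev_total += ad.ev; r.conn_total += ad.conn; r.teth_total += ad.teth;
      commit_coord_move(S, r, P, new_d, new_f, links, dMD, dMM);
    }
  }
  // flexible beads
  for (size_t fi = 0; fi < S.mobile_flex.size(); ++fi) {
    int i = S.mobile_flex[fi];
    double tr[3];
    runif_ball(mv.flex_trans, tr);
    P.beads.assign(1, i);
    P.gauss = S.bead_gauss[i];
    P.nx.assign(1, r.x[i] + tr[0]);
    P.ny.assign(1, r.y[i] + tr[1]);
    P.nz.assign(1, r.z[i] + tr[2]);
    std::fill(P.in_set.begin(), P.in_set.end(), 0);
    P.in_set[i] = 1;
    P.ngm.resize(3 * P.gauss.size()); P.ngc.resize(9 * P.gauss.size());
    for (size_t k = 0; k < P.gauss.size(); ++k) {
      int g = P.gauss[k];
      P.ngm[3 * k] = r.gm[3 * g] + tr[0];
      P.ngm[3 * k + 1] = r.gm[3 * g + 1] + tr[1];
      P.ngm[3 * k + 2] = r.gm[3 * g + 2] + tr[2];
      for (int c = 0; c < 9; ++c) P.ngc[9 * k + c] = r.gc[9 * g + c];
    }
    AuxDelta ad = aux_delta(S, r, P);
    double delta = coord_move_delta(S, r, P, new_d, new_f, links, dMD, dMM) +
                   ad.ev + ad.conn + ad.teth;
    if (mh_accept(delta, T)) {
      r.ev_total += ad.ev; r.conn_total += ad.conn; r.teth_total += ad.teth;
      commit_coord_move(S, r, P, new_d, new_f, links, dMD, dMM);
    }
  }
  // sigma
  {
    double s_new = r.sigma + mv.sigma_step * (2.0 * unif_rand() - 1.0);
    if (s_new >= mv.sigma_move_min && s_new <= S.sigma_max) {
      double delta = 0.0;
      std::vector<double> fnew(S.xl_n);
      for (int l = 0; l < S.xl_n; ++l) {
        fnew[l] = fm_sphere(r.xl_d[l], s_new, s_new, S.l_xl);
        delta += xl_neglogp(S, r, l, fnew[l]) - xl_neglogp(S, r, l, r.xl_f[l]);
      }
      if (mh_accept(delta, T)) {
        for (int l = 0; l < S.xl_n; ++l) {
          r.xl_total += xl_neglogp(S, r, l, fnew[l]) -
                        xl_neglogp(S, r, l, r.xl_f[l]);
          r.xl_f[l] = fnew[l];
        }
        r.sigma = s_new;
      }
    }
  }
  // psi (one move per class)
  for (int c = 0; c < 2; ++c) {
    double p_new = r.psi[c] + mv.psi_step * (2.0 * unif_rand() - 1.0);
    if (p_new < mv.psi_min || p_new > mv.psi_max) continue;
    double delta = 0.0;
    for (int l = 0; l < S.xl_n; ++l) {
      if (S.xl_class[l] - 1 != c) continue;
      double f = r.xl_f[l];
      double po = r.psi[c] * (1.0 - f) + f * (1.0 - r.psi[c]);
      double pn = p_new * (1.0 - f) + f * (1.0 - p_new);
      delta += -S.xl_w[l] * (std::log(pn) - std::log(po));
    }
    if (mh_accept(delta, T)) {
      for (int l = 0; l < S.xl_n; ++l) {
        if (S.xl_class[l] - 1 != c) continue;
        double f = r.xl_f[l];
        double po = r.psi[c] * (1.0 - f) + f * (1.0 - r.psi[c]);
        double pn = p_new * (1.0 - f) + f * (1.0 - p_new);
        r.xl_total += -S.xl_w[l] * (std::log(pn) - std::log(po));
      }
      r.psi[c] = p_new;
    }
  }
}

// ---- driver -----------------------------------------------------------

static Sys build_sys(List cs) {
  Sys S;
  S.n_beads = as<int>(cs["n_beads"]);
  S.radius = as<std::vector<double> >(cs["radius"]);
  S.is_coarse = as<std::vector<int> >(cs["is_coarse"]);
  S.rigid_id = as<std::vector<int> >(cs["rigid_id"]);
  S.mobile_rigid = as<std::vector<int> >(cs["mobile_rigid"]);
  S.mobile_flex = as<std::vector<int> >(cs["mobile_flex"]);
  for (size_t i = 0; i < S.mobile_flex.size(); ++i) S.mobile_flex[i] -= 1;
  S.g_n = as<int>(cs["g_n"]);
  S.g_w = as<std::vector<double> >(cs["g_w"]);
  S.g_rigid = as<std::vector<int> >(cs["g_rigid"]);
  S.g_bead = as<std::vector<int> >(cs["g_bead"]);
  S.g_module = as<std::vector<int> >(cs["g_module"]);
  S.n_modules = as<int>(cs["n_modules"]);
  S.d_w = as<std::vector<double> >(cs["d_w"]);
  NumericMatrix dm = as<NumericMatrix>(cs["d_means"]);
  NumericMatrix dc = as<NumericMatrix>(cs["d_covs"]);
  S.d_means.resize(3 * dm.nrow());
  for (int i = 0; i < dm.nrow(); ++i)
    for (int j = 0; j < 3; ++j) S.d_means[3 * i + j] = dm(i, j);
  S.d_covs.resize(9 * dc.nrow());
  for (int i = 0; i < dc.nrow(); ++i)
    for (int j = 0; j < 9; ++j) S.d_covs[9 * i + j] = dc(i, j);
  S.d_module = as<std::vector<int> >(cs["d_module"]);
  S.xl_n = as<int>(cs["xl_n"]);
  S.xl_b1 = as<std::vector<int> >(cs["xl_b1"]);
  S.xl_b2 = as<std::vector<int> >(cs["xl_b2"]);
  for (int l = 0; l < S.xl_n; ++l) { S.xl_b1[l] -= 1; S.xl_b2[l] -= 1; }
  S.xl_w = as<std::vector<double> >(cs["xl_w"]);
  S.xl_class = as<std::vector<int> >(cs["xl_class"]);
  NumericMatrix cn = as<NumericMatrix>(cs["conn"]);
  for (int p = 0; p < cn.nrow(); ++p) {
    S.conn_a.push_back((int)cn(p, 0) - 1);
    S.conn_b.push_back((int)cn(p, 1) - 1);
    S.conn_thr.push_back(cn(p, 2));
  }
  NumericMatrix th = as<NumericMatrix>(cs["teth"]);
  for (int t = 0; t < th.nrow(); ++t) {
    S.teth_bead.push_back((int)th(t, 0) - 1);
    S.teth_x.push_back(th(t, 1));
    S.teth_y.push_back(th(t, 2));
    S.teth_z.push_back(th(t, 3));
    S.teth_k.push_back(th(t, 4));
  }
  S.l_xl = as<double>(cs["l_xl"]);
  S.slope = as<double>(cs["slope"]);
  S.em_scale = as<double>(cs["em_scale"]);
  S.k_ev = as<double>(cs["k_ev"]);
  S.k_conn = as<double>(cs["k_conn"]);
  S.sigma_min = as<double>(cs["sigma_min"]);
  S.sigma_max = as<double>(cs["sigma_max"]);
  for (int i = 0; i < S.n_beads; ++i)
    if (S.is_coarse[i]) S.coarse_idx.push_back(i);
  int max_rb = 0;
  for (int i = 0; i < S.n_beads; ++i) max_rb = std::max(max_rb, S.rigid_id[i]);
  S.rb_beads.assign(max_rb + 1, std::vector<int>());
  S.rb_gauss.assign(max_rb + 1, std::vector<int>());
  for (int i = 0; i < S.n_beads; ++i)
    if (S.rigid_id[i] > 0) S.rb_beads[S.rigid_id[i]].push_back(i);
  for (int g = 0; g < S.g_n; ++g)
    if (S.g_rigid[g] > 0 && S.g_rigid[g] <= max_rb)
      S.rb_gauss[S.g_rigid[g]].push_back(g);
  S.bead_gauss.assign(S.n_beads, std::vector<int>());
  for (int g = 0; g < S.g_n; ++g)
    if (S.g_bead[g] > 0) S.bead_gauss[S.g_bead[g] - 1].push_back(g);
  S.bead_xl.assign(S.n_beads, std::vector<int>());
  for (int l = 0; l < S.xl_n; ++l) {
    S.bead_xl[S.xl_b1[l]].push_back(l);
    if (S.xl_b2[l] != S.xl_b1[l]) S.bead_xl[S.xl_b2[l]].push_back(l);
  }
  S.bead_conn.assign(S.n_beads, std::vector<int>());
  for (size_t p = 0; p < S.conn_a.size(); ++p) {
    S.bead_conn[S.conn_a[p]].push_back((int)p);
    S.bead_conn[S.conn_b[p]].push_back((int)p);
  }
  S.bead_teth.assign(S.n_beads, std::vector<int>());
  for (size_t t = 0; t < S.teth_bead.size(); ++t)
    S.bead_teth[S.teth_bead[t]].push_back((int)t);
  // constant data-data overlaps per module
  S.ovDD.assign(std::max(S.n_modules, 1), 0.0);
  for (size_t i = 0; i < S.d_w.size(); ++i)
    for (size_t j = 0; j < S.d_w.size(); ++j)
      if (S.d_module[i] == S.d_module[j])
        S.ovDD[S.d_module[i] - 1] +=
            pair_overlap(S.d_w[i], &S.d_means[3 * i], &S.d_covs[9 * i],
                         S.d_w[j], &S.d_means[3 * j], &S.d_covs[9 * j]);
  return S;
}

static Rep build_rep(const Sys &S, List st) {
  Rep r;
  NumericMatrix co = as<NumericMatrix>(st["coords"]);
  r.x.resize(S.n_beads); r.y.resize(S.n_beads); r.z.resize(S.n_beads);
  for (int i = 0; i < S.n_beads; ++i) {
    r.x[i] = co(i, 0); r.y[i] = co(i, 1); r.z[i] = co(i, 2);
  }
  NumericMatrix gm = as<NumericMatrix>(st["gmeans"]);
  NumericMatrix gc = as<NumericMatrix>(st["gcovs"]);
  r.gm.resize(3 * S.g_n); r.gc.resize(9 * S.g_n);
  for (int g = 0; g < S.g_n; ++g) {
    for (int c = 0; c < 3; ++c) r.gm[3 * g + c] = gm(g, c);
    for (int c = 0; c < 9; ++c) r.gc[9 * g + c] = gc(g, c);
  }
  r.sigma = as<double>(st["sigma"]);
  NumericVector psi = as<NumericVector>(st["psi"]);
  r.psi[0] = psi[0]; r.psi[1] = psi[1];
  refresh(S, r);
  return r;
}

// [[Rcpp::export(name = "ia_run_re")]]
List ia_run_re(List cs, List states, NumericVector temps, int n_sweeps,
               int save_interval, NumericVector moves) {
  Sys S = build_sys(cs);
  int n_rep = temps.size();
  std::vector<Rep> reps;
  for (int i = 0; i < n_rep; ++i)
    reps.push_back(build_rep(S, as<List>(states[i])));
  Prop P;
  P.in_set.assign(S.n_beads, 0);
  Mv mv;
  mv.rigid_trans = moves["rigid_trans"]; mv.rigid_rot = moves["rigid_rot"];
  mv.flex_trans = moves["flex_trans"]; mv.sigma_step = moves["sigma_step"];
  mv.psi_step = moves["psi_step"]; mv.psi_min = moves["psi_min"];
  mv.psi_max = moves["psi_max"]; mv.sigma_move_min = moves["sigma_move_min"];
  List frames, scores, psis, gmeans_l, gcovs_l;
  std::vector<double> sigmas;
  int swap_att = 0, swap_acc = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < n_rep; ++i) gibbs_sweep(S, reps[i], temps[i], P, mv);
    if (n_rep > 1) {
      int start = (sweep % 2 == 1) ? 0 : 1;
      for (int i = start; i + 1 < n_rep; i += 2) {
        double Si = rep_total(S, reps[i]), Sj = rep_total(S, reps[i + 1]);
        double delta = (Si - Sj) * (1.0 / temps[i] - 1.0 / temps[i + 1]);
        bool acc = (delta >= 0) ? true : (unif_rand() < std::exp(delta));
        ++swap_att;
        if (acc) { std::swap(reps[i], reps[i + 1]); ++swap_acc; }
      }
    }
    if (sweep % save_interval == 0) {
      Rep &r0 = reps[0];
      refresh(S, r0); // also eliminates numerical drift of the caches
      NumericMatrix co(S.n_beads, 3);
      for (int i = 0; i < S.n_beads; ++i) {
        co(i, 0) = r0.x[i]; co(i, 1) = r0.y[i]; co(i, 2) = r0.z[i];
      }
      frames.push_back(co);
      NumericMatrix gm(S.g_n, 3), gc(S.g_n, 9);
      for (int g = 0; g < S.g_n; ++g) {
        for (int c = 0; c < 3; ++c) gm(g, c) = r0.gm[3 * g + c];
        for (int c = 0; c < 9; ++c) gc(g, c) = r0.gc[9 * g + c];
      }
      gmeans_l.push_back(gm);
      gcovs_l.push_back(gc);
      double em = 0.0;
      for (int m = 0; m < S.n_modules; ++m)
        em += em_term(S, r0.ovMD[m], r0.ovMM[m], S.ovDD[m]);
      NumericVector sc = NumericVector::create(
          _["crosslink"] = r0.xl_total, _["em"] = em,
          _["excluded_volume"] = r0.ev_total, _["connectivity"] = r0.conn_total,
          _["linear"] = r0.linear_total, _["tether"] = r0.teth_total,
          _["total"] = rep_total(S, r0));
      scores.push_back(sc);
      sigmas.push_back(r0.sigma);
      psis.push_back(NumericVector::create(r0.psi[0], r0.psi[1]));
    }
  }
  double srate = swap_att ? (double)swap_acc / swap_att : NA_REAL;
  return List::create(_["frames"] = frames, _["scores"] = scores,
                      _["sigma"] = wrap(sigmas), _["psi"] = psis,
                      _["gmeans"] = gmeans_l, _["gcovs"] = gcovs_l,
                      _["swap_rate"] = srate);
}
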