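#include <Rcpp.h>
using namespace Rcpp;

// Coarse-grained energies on a CA-level pentamer plus restraint potentials.
// These kernels are the single implementation used both when scoring finished
// models and inside the Monte Carlo sampler, so ranking and trace scores are
// identical by construction.

static inline double dist3(const double *x, int i, int j, int n) {
  double dx = x[i] - x[j];
  double dy = x[i + n] - x[j + n];
  double dz = x[i + 2 * n] - x[j + 2 * n];
  return sqrt(dx * dx + dy * dy + dz * dz);
}

// pseudo-dihedral of four consecutive CA positions, radians in (-pi, pi]
static double dihedral(const double *x, int a, int b, int c, int d, int n) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = x[b + k * n] - x[a + k * n];
    b2[k] = x[c + k * n] - x[b + k * n];
    b3[k] = x[d + k * n] - x[c + k * n];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb2 = sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m1[3] = {b2[0] / nb2, b2[1] / nb2, b2[2] / nb2};
  double xcomp = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double c1[3] = {n1[1] * n2[2] - n1[2] * n2[1], n1[2] * n2[0] - n1[0] * n2[2],
                  n1[0] * n2[1] - n1[1] * n2[0]};
  double ycomp = c1[0] * m1[0] + c1[1] * m1[1] + c1[2] * m1[2];
  return atan2(ycomp, xcomp);
}

// [[Rcpp::export]]
NumericVector cpp_cg_energy(NumericMatrix xyz, IntegerVector chain,
                            IntegerVector helix,
                            double k_bond, double b0,
                            double k_ang, double ang_lo, double ang_hi,
                            double k_rep, double r_rep,
                            double k_dih, double tau0) {
  int n = xyz.nrow();
  const double *x = xyz.begin();
  double e_bond = 0, e_ang = 0, e_rep = 0, e_dih = 0;
  for (int i = 0; i + 1 < n; ++i) {
    if (chain[i] != chain[i + 1]) continue;
    double d = dist3(x, i, i + 1, n);
    e_bond += k_bond * (d - b0) * (d - b0);
  }
  for (int i = 1; i + 1 < n; ++i) {
    if (chain[i - 1] != chain[i] || chain[i] != chain[i + 1]) continue;
    double ax = x[i - 1] - x[i], ay = x[i - 1 + n] - x[i + n],
           az = x[i - 1 + 2 * n] - x[i + 2 * n];
    double bx = x[i + 1] - x[i], by = x[i + 1 + n] - x[i + n],
           bz = x[i + 1 + 2 * n] - x[i + 2 * n];
    double ca = (ax * bx + ay * by + az * bz) /
                (sqrt(ax * ax + ay * ay + az * az) *
                 sqrt(bx * bx + by * by + bz * bz));
    if (ca > 1) ca = 1; if (ca < -1) ca = -1;
    double th = acos(ca);
    if (th < ang_lo) e_ang += k_ang * (ang_lo - th) * (ang_lo - th);
    else if (th > ang_hi) e_ang += k_ang * (th - ang_hi) * (th - ang_hi);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double d = dist3(x, i, j, n);
      if (d < r_rep) e_rep += k_rep * (r_rep - d) * (r_rep - d);
    }
    // skip only the directly bonded neighbour (i, i+1 same chain); the i+1
    // inter-chain pair is handled above by starting at i+2 unless the chain
    // differs, so treat that case explicitly
    if (i + 1 < n && chain[i] != chain[i + 1]) {
      double d = dist3(x, i, i + 1, n);
      if (d < r_rep) e_rep += k_rep * (r_rep - d) * (r_rep - d);
    }
  }
  for (int i = 0; i + 3 < n; ++i) {
    if (chain[i] != chain[i + 3]) continue;
    if (!(helix[i] && helix[i + 1] && helix[i + 2] && helix[i + 3])) continue;
    double tau = dihedral(x, i, i + 1, i + 2, i + 3, n);
    e_dih += k_dih * (1.0 - cos(tau - tau0));
  }
  return NumericVector::create(e_bond + e_ang + e_rep, e_dih);
}

// potential codes: 0 harmonic, 1 sigmoid, 2 flat-bottom
// kind codes:      0 NOE, 1 PRE, 2 DEER
// [[Rcpp::export]]
List cpp_restraint_energy(NumericMatrix xyz, IntegerVector ia, IntegerVector ib,
                          NumericVector d0, NumericVector lower,
                          NumericVector upper, IntegerVector pot,
                          NumericVector weight, IntegerVector kind,
                          double m) {
  int n = xyz.nrow(), nr = ia.size();
  const double *x = xyz.begin();
  double e_noe = 0, e_pre = 0, e_deer = 0;
  NumericVector dist(nr);
  for (int r = 0; r < nr; ++r) {
    double d = dist3(x, ia[r], ib[r], n);
    dist[r] = d;
    double e = 0;
    if (pot[r] == 0) {
      double dd = d - d0[r];
      e = dd * dd;
    } else if (pot[r] == 1) {
      bool has_lo = R_finite(lower[r]) && lower[r] > 0;
      bool has_hi = R_finite(upper[r]);
      if (has_lo) e += 1.0 / (1.0 + exp(m * (d - lower[r])));
      if (has_hi) e += 1.0 / (1.0 + exp(-m * (d - upper[r])));
    } else {
      if (d < lower[r]) { double v = lower[r] - d; e = v * v; }
      else if (d > upper[r]) { double v = d - upper[r]; e = v * v; }
    }
    e *= weight[r];
    if (kind[r] == 0) e_noe += e;
    else if (kind[r] == 1) e_pre += e;
    else e_deer += e;
  }
  return List::create(_["noe"] = e_noe, _["pre"] = e_pre, _["deer"] = e_deer,
                      _["dist"] = dist);
}

// ---- full Monte Carlo annealing loop -------------------------------------
//
// Samples the asymmetric unit with pivot/crankshaft moves on flexible
// residues and rigid-body moves of the whole subunit, scoring the C5
// pentamer at every step.  The coarse-grained energy exploits exact C5
// symmetry: intra-subunit terms and the chain1-chain2 / chain1-chain3
// interactions are computed once and multiplied by five, which equals the
// full-pentamer sum.  Uses R's RNG, so results are reproducible under
// set.seed().

static void rodrigues(const double axis[3], double angle, double R[9]) {
  double n = sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  double ux = axis[0] / n, uy = axis[1] / n, uz = axis[2] / n;
  double c = cos(angle), s = sin(angle), t = 1 - c;
  R[0] = c + ux * ux * t;      R[1] = ux * uy * t - uz * s; R[2] = ux * uz * t + uy * s;
  R[3] = uy * ux * t + uz * s; R[4] = c + uy * uy * t;      R[5] = uy * uz * t - ux * s;
  R[6] = uz * ux * t - uy * s; R[7] = uz * uy * t + ux * s; R[8] = uz * uz * t + uy * 0;
  R[8] = c + uz * uz * t;
}

static void random_axis(double ax[3]) {
  double n = 0;
  do {
    ax[0] = norm_rand(); ax[1] = norm_rand(); ax[2] = norm_rand();
    n = sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  } while (n < 1e-8);
}

// rotate rows [from, to] of coords (n x 3, column-major) about `point`
static void rotate_rows(std::vector<double> &x, int n, int from, int to,
                        const double point[3], const double R[9]) {
  for (int i = from; i <= to; ++i) {
    double px = x[i] - point[0], py = x[i + n] - point[1],
           pz = x[i + 2 * n] - point[2];
    x[i] = R[0] * px + R[1] * py + R[2] * pz + point[0];
    x[i + n] = R[3] * px + R[4] * py + R[5] * pz + point[1];
    x[i + 2 * n] = R[6] * px + R[7] * py + R[8] * pz + point[2];
  }
}

struct CgParams {
  double k_bond, b0, k_ang, ang_lo, ang_hi, k_rep, r_rep, k_dih, tau0;
  double w_phys, w_know, w_deer, w_pre, w_noe, sig_m;
};

// pairwise repulsion between coordinate blocks a and b (each n x 3 in one
// contiguous column-major array of length 3*stride)
static double block_rep(const double *xa, const double *xb, int n, int stride,
                        double k_rep, double r_rep) {
  double e = 0, r2 = r_rep * r_rep;
  for (int i = 0; i < n; ++i) {
    double ax = xa[i], ay = xa[i + stride], az = xa[i + 2 * stride];
    for (int j = 0; j < n; ++j) {
      double dx = ax - xb[j], dy = ay - xb[j + stride],
             dz = az - xb[j + 2 * stride];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < r2) {
        double d = sqrt(d2);
        e += k_rep * (r_rep - d) * (r_rep - d);
      }
    }
  }
  return e;
}

// symmetric-reduced coarse-grained energy of the C5 pentamer whose
// asymmetric unit is `sub` (n x 3); pent (5n x 3) must hold the replicated
// coordinates (chains in ring order).
static void sym_cg_energy(const std::vector<double> &pent, int n,
                          const int *helix, const CgParams &p,
                          double *e_phys, double *e_know) {
  int N = 5 * n;
  const double *x = pent.data();
  double e_bond = 0, e_ang = 0, e_rep = 0, e_dih = 0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[i] - x[i + 1], dy = x[i + N] - x[i + 1 + N],
           dz = x[i + 2 * N] - x[i + 1 + 2 * N];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    e_bond += p.k_bond * (d - p.b0) * (d - p.b0);
  }
  for (int i = 1; i + 1 < n; ++i) {
    double ax = x[i - 1] - x[i], ay = x[i - 1 + N] - x[i + N],
           az = x[i - 1 + 2 * N] - x[i + 2 * N];
    double bx = x[i + 1] - x[i], by = x[i + 1 + N] - x[i + N],
           bz = x[i + 1 + 2 * N] - x[i + 2 * N];
    double ca = (ax * bx + ay * by + az * bz) /
                (sqrt(ax * ax + ay * ay + az * az) *
                 sqrt(bx * bx + by * by + bz * bz));
    if (ca > 1) ca = 1; if (ca < -1) ca = -1;
    double th = acos(ca);
    if (th < p.ang_lo) e_ang += p.k_ang * (p.ang_lo - th) * (p.ang_lo - th);
    else if (th > p.ang_hi) e_ang += p.k_ang * (th - p.ang_hi) * (th - p.ang_hi);
  }
  // intra-subunit repulsion (|i-j| >= 2)
  double r2 = p.r_rep * p.r_rep;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[i] - x[j], dy = x[i + N] - x[j + N],
             dz = x[i + 2 * N] - x[j + 2 * N];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < r2) {
        double d = sqrt(d2);
        e_rep += p.k_rep * (p.r_rep - d) * (p.r_rep - d);
      }
    }
  }
  // chain1-chain2 (adjacent) and chain1-chain3 (diagonal) blocks
  e_rep += block_rep(x, x + n, n, N, p.k_rep, p.r_rep);
  e_rep += block_rep(x, x + 2 * n, n, N, p.k_rep, p.r_rep);
  for (int i = 0; i + 3 < n; ++i) {
    if (!(helix[i] && helix[i + 1] && helix[i + 2] && helix[i + 3])) continue;
    double tau = dihedral(x, i, i + 1, i + 2, i + 3, N);
    e_dih += p.k_dih * (1.0 - cos(tau - p.tau0));
  }
  *e_phys = 5.0 * (e_bond + e_ang + e_rep);
  *e_know = 5.0 * e_dih;
}

static double restraint_e(const std::vector<double> &pent, int N,
                          const std::vector<int> &ia, const std::vector<int> &ib,
                          const std::vector<double> &d0,
                          const std::vector<double> &lo,
                          const std::vector<double> &hi,
                          const std::vector<int> &pot,
                          const std::vector<double> &w,
                          const std::vector<int> &kind,
                          const CgParams &p,
                          double *e_noe, double *e_pre, double *e_deer) {
  *e_noe = 0; *e_pre = 0; *e_deer = 0;
  const double *x = pent.data();
  for (size_t r = 0; r < ia.size(); ++r) {
    double dx = x[ia[r]] - x[ib[r]], dy = x[ia[r] + N] - x[ib[r] + N],
           dz = x[ia[r] + 2 * N] - x[ib[r] + 2 * N];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    double e = 0;
    if (pot[r] == 0) { double dd = d - d0[r]; e = dd * dd; }
    else if (pot[r] == 1) {
      if (R_finite(lo[r]) && lo[r] > 0) e += 1.0 / (1.0 + exp(p.sig_m * (d - lo[r])));
      if (R_finite(hi[r])) e += 1.0 / (1.0 + exp(-p.sig_m * (d - hi[r])));
    } else {
      if (d < lo[r]) { double v = lo[r] - d; e = v * v; }
      else if (d > hi[r]) { double v = d - hi[r]; e = v * v; }
    }
    e *= w[r];
    if (kind[r] == 0) *e_noe += e; else if (kind[r] == 1) *e_pre += e;
    else *e_deer += e;
  }
  return *e_noe + *e_pre + *e_deer;
}

static void replicate5(std::vector<double> &pent, int n,
                       const double c72, const double s72) {
  int N = 5 * n;
  double c = c72, s = s72;
  for (int k = 1; k < 5; ++k) {
    for (int i = 0; i < n; ++i) {
      double px = pent[i], py = pent[i + N], pz = pent[i + 2 * N];
      pent[k * n + i] = c * px - s * py;
      pent[k * n + i + N] = s * px + c * py;
      pent[k * n + i + 2 * N] = pz;
    }
    double cn = c * c72 - s * s72, sn = s * c72 + c * s72;
    c = cn; s = sn;
  }
}

// [[Rcpp::export]]
List cpp_mc_fold(NumericMatrix xyz0, IntegerVector helix, IntegerVector flex,
                 IntegerVector ia, IntegerVector ib, NumericVector d0,
                 NumericVector lower, NumericVector upper, IntegerVector pot,
                 NumericVector weight, IntegerVector kind,
                 NumericVector cgpar, NumericVector temps, int moves_per_temp,
                 NumericVector sigma_rot, NumericVector sigma_tr,
                 NumericVector rep_ramp) {
  int n = xyz0.nrow(), N = 5 * n;
  CgParams P;
  P.k_bond = cgpar[0]; P.b0 = cgpar[1]; P.k_ang = cgpar[2];
  P.ang_lo = cgpar[3]; P.ang_hi = cgpar[4]; P.k_rep = cgpar[5];
  P.r_rep = cgpar[6]; P.k_dih = cgpar[7]; P.tau0 = cgpar[8];
  P.w_phys = cgpar[9]; P.w_know = cgpar[10]; P.w_deer = cgpar[11];
  P.w_pre = cgpar[12]; P.w_noe = cgpar[13]; P.sig_m = cgpar[14];
  std::vector<int> via(ia.begin(), ia.end()), vib(ib.begin(), ib.end()),
      vpot(pot.begin(), pot.end()), vkind(kind.begin(), kind.end());
  std::vector<double> vd0(d0.begin(), d0.end()), vlo(lower.begin(), lower.end()),
      vhi(upper.begin(), upper.end()), vw(weight.begin(), weight.end());
  std::vector<int> hx(helix.begin(), helix.end());
  std::vector<int> fx(flex.begin(), flex.end()); // 0-based flexible indices
  int nflex = fx.size();
  double c72 = cos(2 * M_PI / 5), s72 = sin(2 * M_PI / 5);

  std::vector<double> sub(3 * n), pent(3 * N), cand(3 * n);
  for (int i = 0; i < n; ++i) {
    sub[i] = xyz0(i, 0); sub[i + n] = xyz0(i, 1); sub[i + 2 * n] = xyz0(i, 2);
  }
  RNGScope scope;

  // energy evaluation closure
  double ephys, eknow, enoe, epre, edeer;
  auto energy = [&](const std::vector<double> &s) {
    for (int i = 0; i < n; ++i) {
      pent[i] = s[i]; pent[i + N] = s[i + n]; pent[i + 2 * N] = s[i + 2 * n];
    }
    replicate5(pent, n, c72, s72);
    sym_cg_energy(pent, n, hx.data(), P, &ephys, &eknow);
    restraint_e(pent, N, via, vib, vd0, vlo, vhi, vpot, vw, vkind, P,
                &enoe, &epre, &edeer);
    return P.w_phys * ephys + P.w_know * eknow + P.w_deer * edeer +
           P.w_pre * epre + P.w_noe * enoe;
  };

  double k_rep_full = P.k_rep;
  P.k_rep = k_rep_full * rep_ramp[0];
  double ecur = energy(sub);
  std::vector<double> best(sub);
  double ebest = R_PosInf; // tracked at full repulsion only (final rungs)
  int nsteps = temps.size() * moves_per_temp;
  NumericVector trace(nsteps);
  NumericVector acc(temps.size());
  int step = 0;
  for (int ti = 0; ti < temps.size(); ++ti) {
    double T = temps[ti];
    double s_rot = sigma_rot[ti], s_tr = sigma_tr[ti];
    P.k_rep = k_rep_full * rep_ramp[ti];
    bool full_rep = rep_ramp[ti] >= 1.0;
    ecur = energy(sub); // energy under this rung's repulsion scale
    int nacc = 0;
    for (int mv = 0; mv < moves_per_temp; ++mv) {
      cand = sub;
      double u = unif_rand();
      double axx[3], R[9], point[3];
      if (u < 0.4 && nflex > 0) { // pivot
        int p = fx[(int)(unif_rand() * nflex) % nflex];
        bool down = unif_rand() < 0.5;
        int from, to;
        if (down && p + 1 < n) { from = p + 1; to = n - 1; }
        else if (p > 0) { from = 0; to = p - 1; }
        else { from = 1; to = n - 1; }
        random_axis(axx);
        rodrigues(axx, norm_rand() * s_rot, R);
        point[0] = cand[p]; point[1] = cand[p + n]; point[2] = cand[p + 2 * n];
        rotate_rows(cand, n, from, to, point, R);
      } else if (u < 0.65 && nflex > 3) { // crankshaft
        for (int t = 0; t < 10; ++t) {
          int i = fx[(int)(unif_rand() * nflex) % nflex];
          int span = 3 + (int)(unif_rand() * 4) % 4;
          int j = i + span;
          if (j >= n) continue;
          bool ok = true;
          for (int q = i; q <= j; ++q) if (hx[q]) { ok = false; break; }
          if (!ok) continue;
          double ax2[3] = {cand[j] - cand[i], cand[j + n] - cand[i + n],
                           cand[j + 2 * n] - cand[i + 2 * n]};
          double nn = sqrt(ax2[0] * ax2[0] + ax2[1] * ax2[1] + ax2[2] * ax2[2]);
          if (nn < 1e-6) continue;
          rodrigues(ax2, norm_rand() * 2 * s_rot, R);
          point[0] = cand[i]; point[1] = cand[i + n]; point[2] = cand[i + 2 * n];
          rotate_rows(cand, n, i + 1, j - 1, point, R);
          break;
        }
      } else if (u < 0.825) { // rigid translation
        double tx = norm_rand() * s_tr, ty = norm_rand() * s_tr,
               tz = norm_rand() * s_tr;
        for (int i = 0; i < n; ++i) {
          cand[i] += tx; cand[i + n] += ty; cand[i + 2 * n] += tz;
        }
      } else { // rigid rotation about the centroid
        point[0] = point[1] = point[2] = 0;
        for (int i = 0; i < n; ++i) {
          point[0] += cand[i]; point[1] += cand[i + n]; point[2] += cand[i + 2 * n];
        }
        point[0] /= n; point[1] /= n; point[2] /= n;
        random_axis(axx);
        rodrigues(axx, norm_rand() * s_rot, R);
        rotate_rows(cand, n, 0, n - 1, point, R);
      }
      double ec = energy(cand);
      if (ec <= ecur || unif_rand() < exp(-(ec - ecur) / T)) {
        sub.swap(cand);
        ecur = ec;
        ++nacc;
        if (full_rep && ecur < ebest) { ebest = ecur; best = sub; }
      }
      trace[step++] = ecur;
    }
    acc[ti] = (double)nacc / moves_per_temp;
  }
  if (!R_finite(ebest)) { best = sub; ebest = ecur; }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = best[i]; out(i, 1) = best[i + n]; out(i, 2) = best[i + 2 * n];
  }
  return List::create(_["xyz"] = out, _["best_total"] = ebest,
                      _["trace"] = trace, _["acceptance"] = acc);
}
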