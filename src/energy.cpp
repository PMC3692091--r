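#include <Rcpp.h>
using namespace Rcpp;

// Coarse-grained energy core. A residue carries up to four interaction
// centers: Calpha (sampled), Cbeta, side-chain center and the Calpha-Calpha
// pseudo-bond midpoint. During Monte Carlo only Calpha positions move; the
// dependent centers are rederived from local Calpha geometry so that the
// energy is a pure function of the Calpha trace.

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline void unit3(double* v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n > 1e-12) { v[0] /= n; v[1] /= n; v[2] /= n; }
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Cbeta direction from the two chain neighbours: away from the neighbour
// bisector, tilted out of the neighbour plane. Deterministic and equivariant
// under proper rigid transforms.
static void cb_direction(const double* prev, const double* self,
                         const double* next, double* dir) {
  double u[3] = {prev[0] - self[0], prev[1] - self[1], prev[2] - self[2]};
  double v[3] = {next[0] - self[0], next[1] - self[1], next[2] - self[2]};
  unit3(u); unit3(v);
  double b[3] = {u[0] + v[0], u[1] + v[1], u[2] + v[2]};
  double n[3];
  cross3(u, v, n);
  double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nb < 1e-8 || nn < 1e-8) {
    // collinear neighbours: any perpendicular to u is acceptable
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(u[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
    cross3(u, ref, dir);
    unit3(dir);
    return;
  }
  for (int k = 0; k < 3; ++k) { b[k] /= nb; n[k] /= nn; }
  for (int k = 0; k < 3; ++k) dir[k] = -b[k] + 0.8 * n[k];
  unit3(dir);
}

static void derive_centers(const NumericMatrix& ca, const NumericVector& scdist,
                           std::vector<double>& cb, std::vector<double>& sc,
                           std::vector<double>& pep) {
  int n = ca.nrow();
  std::vector<double> C(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) C[3 * i + k] = ca(i, k);
  cb.assign(3 * n, 0.0);
  sc.assign(3 * n, 0.0);
  pep.assign(3 * (n > 1 ? n - 1 : 0), 0.0);
  const double CB_LEN = 1.53;
  for (int i = 0; i < n; ++i) {
    double dir[3] = {0.0, 0.0, 1.0};
    if (n >= 3) {
      const double* p = (i == 0) ? &C[3 * 1] : &C[3 * (i - 1)];
      const double* q = (i == 0) ? &C[3 * 2]
                      : (i == n - 1) ? &C[3 * (n - 3)] : &C[3 * (i + 1)];
      cb_direction(p, &C[3 * i], q, dir);
    }
    for (int k = 0; k < 3; ++k) {
      cb[3 * i + k] = C[3 * i + k] + CB_LEN * dir[k];
      sc[3 * i + k] = C[3 * i + k] + scdist[i] * dir[k];
    }
  }
  for (int i = 0; i + 1 < n; ++i)
    for (int k = 0; k < 3; ++k)
      pep[3 * i + k] = 0.5 * (C[3 * i + k] + C[3 * (i + 1) + k]);
}

// [[Rcpp::export]]
List cpp_rebuild_centers(NumericMatrix ca, NumericVector scdist) {
  int n = ca.nrow();
  std::vector<double> cb, sc, pep;
  derive_centers(ca, scdist, cb, sc, pep);
  NumericMatrix CB(n, 3), SC(n, 3), PEP(n > 1 ? n - 1 : 0, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { CB(i, k) = cb[3 * i + k]; SC(i, k) = sc[3 * i + k]; }
  for (int i = 0; i + 1 < n; ++i)
    for (int k = 0; k < 3; ++k) PEP(i, k) = pep[3 * i + k];
  return List::create(_["cb"] = CB, _["sc"] = SC, _["pep"] = PEP);
}

static inline double wrap_deg(double x) {
  while (x > 180.0) x -= 360.0;
  while (x <= -180.0) x += 360.0;
  return x;
}

static double pseudo_angle(const double* a, const double* b, const double* c) {
  double u[3] = {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
  double v[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
  unit3(u); unit3(v);
  double d = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  if (d > 1.0) d = 1.0;
  if (d < -1.0) d = -1.0;
  return std::acos(d) * 180.0 / M_PI;
}

static double pseudo_dihedral(const double* p1, const double* p2,
                              const double* p3, const double* p4) {
  double b1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double b2[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
  double b3[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
  double n1[3], n2[3], m[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  unit3(n1); unit3(n2);
  double b2u[3] = {b2[0], b2[1], b2[2]};
  unit3(b2u);
  cross3(n1, b2u, m);
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = m[0] * n2[0] + m[1] * n2[1] + m[2] * n2[2];
  // sign convention matches the standard polymer convention (right-handed
  // alpha-helix Calpha pseudo-dihedral is about +50 degrees)
  return -std::atan2(y, x) * 180.0 / M_PI;
}

static inline double flat_bottom(double x, double lo, double hi) {
  if (x < lo) return lo - x;
  if (x > hi) return x - hi;
  return 0.0;
}

static NumericVector energy_components(const std::vector<double>& C,
                                       const std::vector<double>& sc,
                                       const std::vector<double>& pep,
                                       const IntegerVector& ss,
                                       const IntegerVector& aa,
                                       const NumericMatrix& epsmat,
                                       const NumericMatrix& rest,
                                       const List& params) {
  int n = (int)C.size() / 3;
  double k_bond = as<double>(params["k_bond"]);
  double bond_ref = as<double>(params["bond_ref"]);
  double k_angle = as<double>(params["k_angle"]);
  double k_dih = as<double>(params["k_dih"]);
  NumericVector ang_lo = params["angle_lo"];  // indexed by ss code C/H/E
  NumericVector ang_hi = params["angle_hi"];
  NumericVector dih_ctr = params["dih_center"];
  NumericVector dih_hw = params["dih_halfwidth"];  // <0 disables the term
  double contact_radius = as<double>(params["contact_radius"]);
  double hb_dmin = as<double>(params["hb_dmin"]);
  double hb_dmax = as<double>(params["hb_dmax"]);
  double hb_align = as<double>(params["hb_align"]);
  double hb_eps = as<double>(params["hb_eps"]);
  int hb_minsep = as<int>(params["hb_minsep"]);
  double excl_ca = as<double>(params["excl_ca"]);
  double excl_sc = as<double>(params["excl_sc"]);
  double k_excl = as<double>(params["k_excl"]);
  int excl_minsep = as<int>(params["excl_minsep"]);

  double e_short = 0.0, e_pair = 0.0, e_hbond = 0.0, e_rest = 0.0, e_excl = 0.0;
  const double DEG = M_PI / 180.0;

  // short range: pseudo-bond, pseudo-angle, pseudo-dihedral
  for (int i = 0; i + 1 < n; ++i) {
    double d = dist3(&C[3 * i], &C[3 * (i + 1)]);
    e_short += k_bond * (d - bond_ref) * (d - bond_ref);
  }
  for (int i = 1; i + 1 < n; ++i) {
    double a = pseudo_angle(&C[3 * (i - 1)], &C[3 * i], &C[3 * (i + 1)]);
    int s = ss[i];
    double dev = flat_bottom(a, ang_lo[s], ang_hi[s]) * DEG;
    e_short += k_angle * dev * dev;
  }
  for (int i = 0; i + 3 < n; ++i) {
    int s = ss[i + 1];
    if (dih_hw[s] < 0) continue;
    double dh = pseudo_dihedral(&C[3 * i], &C[3 * (i + 1)], &C[3 * (i + 2)],
                                &C[3 * (i + 3)]);
    double dev = std::fabs(wrap_deg(dh - dih_ctr[s]));
    double excess = (dev > dih_hw[s]) ? (dev - dih_hw[s]) * DEG : 0.0;
    e_short += k_dih * excess * excess;
  }

  // side-chain contact wells
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double d = dist3(&sc[3 * i], &sc[3 * j]);
      if (d < contact_radius) e_pair += epsmat(aa[i] - 1, aa[j] - 1);
    }
  }

  // model hydrogen bonds on the Calpha trace: distance window plus alignment
  // of local chain directions taken between successive peptide centers
  if (n >= 4) {
    std::vector<double> vdir(3 * n, 0.0);
    std::vector<bool> has_dir(n, false);
    for (int i = 1; i + 1 < n; ++i) {  // pep[i-1] and pep[i] exist
      double v[3] = {pep[3 * i + 0] - pep[3 * (i - 1) + 0],
                     pep[3 * i + 1] - pep[3 * (i - 1) + 1],
                     pep[3 * i + 2] - pep[3 * (i - 1) + 2]};
      unit3(v);
      vdir[3 * i] = v[0]; vdir[3 * i + 1] = v[1]; vdir[3 * i + 2] = v[2];
      has_dir[i] = true;
    }
    for (int i = 0; i < n; ++i) {
      if (!has_dir[i]) continue;
      for (int j = i + hb_minsep; j < n; ++j) {
        if (!has_dir[j]) continue;
        double d = dist3(&C[3 * i], &C[3 * j]);
        if (d < hb_dmin || d > hb_dmax) continue;
        double dot = vdir[3 * i] * vdir[3 * j] + vdir[3 * i + 1] * vdir[3 * j + 1] +
                     vdir[3 * i + 2] * vdir[3 * j + 2];
        if (std::fabs(dot) >= hb_align) e_hbond -= hb_eps;
      }
    }
  }

  // flat-bottom harmonic restraints on Calpha distances
  for (int r = 0; r < rest.nrow(); ++r) {
    int i = (int)rest(r, 0) - 1, j = (int)rest(r, 1) - 1;
    double d = dist3(&C[3 * i], &C[3 * j]);
    double excess = std::fabs(d - rest(r, 2)) - rest(r, 3);
    if (excess > 0) e_rest += rest(r, 4) * excess * excess;
  }

  // excluded volume
  for (int i = 0; i < n; ++i) {
    for (int j = i + excl_minsep; j < n; ++j) {
      double d = dist3(&C[3 * i], &C[3 * j]);
      if (d < excl_ca) e_excl += k_excl * (excl_ca - d) * (excl_ca - d);
      double ds = dist3(&sc[3 * i], &sc[3 * j]);
      if (ds < excl_sc) e_excl += k_excl * (excl_sc - ds) * (excl_sc - ds);
    }
  }

  return NumericVector::create(_["short"] = e_short, _["pair"] = e_pair,
                               _["hbond"] = e_hbond, _["restraint"] = e_rest,
                               _["excluded"] = e_excl);
}

static std::vector<double> flatten(const NumericMatrix& m) {
  std::vector<double> out(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int k = 0; k < 3; ++k) out[3 * i + k] = m(i, k);
  return out;
}

// Energy of a bare Calpha trace; dependent centers derived internally.
// ss: 0 coil / 1 helix / 2 strand; aa: 1-based row of the pair-well matrix.
// rest: columns (i, j, d0, width, k) with 1-based residue indices.
// [[Rcpp::export]]
NumericVector cpp_energy_ca(NumericMatrix ca, NumericVector scdist,
                            IntegerVector ss, IntegerVector aa,
                            NumericMatrix epsmat, NumericMatrix rest,
                            List params) {
  std::vector<double> cb, sc, pep;
  derive_centers(ca, scdist, cb, sc, pep);
  return energy_components(flatten(ca), sc, pep, ss, aa, epsmat, rest, params);
}

// Energy of a frame with explicitly supplied side-chain and peptide centers.
// [[Rcpp::export]]
NumericVector cpp_energy_frame(NumericMatrix ca, NumericMatrix sc,
                               NumericMatrix pep, IntegerVector ss,
                               IntegerVector aa, NumericMatrix epsmat,
                               NumericMatrix rest, List params) {
  return energy_components(flatten(ca), flatten(sc), flatten(pep), ss, aa,
                           epsmat, rest, params);
}
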