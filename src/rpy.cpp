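// Rotne-Prager-Yamakawa grand mobility for spheres of unequal radii,
// with the overlap-regularized variant that stays positive-definite as the
// pair separation goes to zero.
//
// Layout: [V; Omega] = M [F; T] with V stacked first (3M rows), then Omega.
// All pair blocks use rhat = (x_receiver - x_source)/d. The coupling blocks
// are -g(d) [rhat]x acting on the source's torque (tr) or force (rf); the
// grand matrix is symmetric by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat33 crossmat(const vec3& a) {
  mat33 m;
  m(0, 0) = 0;     m(0, 1) = -a(2); m(0, 2) = a(1);
  m(1, 0) = a(2);  m(1, 1) = 0;     m(1, 2) = -a(0);
  m(2, 0) = -a(1); m(2, 1) = a(0);  m(2, 2) = 0;
  return m;
}

// The corrected (overlap) formulas take over only once the overlap exceeds a
// small relative margin: they agree with the standard far-field forms to
// O(overlap^2) there (~1e-8), and keeping exactly-touching spheres on the
// smooth far-field branch avoids parking the dynamics on the C1 kink of the
// formula switch (touching-sphere filaments hover at zero gap when straight).
static const double OVERLAP_MARGIN = 1e-4;

static inline bool deep_overlap(double d, double ai, double aj) {
  return d < (1.0 - OVERLAP_MARGIN) * (ai + aj);
}

// tt pair block coefficients (iso, rr) so that mu_tt = iso*I + rr*rhat rhat^T
static void tt_pair(double d, double ai, double aj, double eta, bool corrected,
                    double& iso, double& rr, bool& overlapped) {
  const double pi = datum::pi;
  overlapped = deep_overlap(d, ai, aj);
  if (!overlapped || !corrected) {
    double a2 = ai * ai + aj * aj;
    iso = (1.0 + a2 / (3.0 * d * d)) / (8.0 * pi * eta * d);
    rr  = (1.0 - a2 / (d * d)) / (8.0 * pi * eta * d);
  } else if (d > std::abs(ai - aj)) {
    double c = 1.0 / (6.0 * pi * eta * ai * aj);
    double dm = ai - aj;
    double t = dm * dm + 3.0 * d * d;
    iso = c * (16.0 * d * d * d * (ai + aj) - t * t) / (32.0 * d * d * d);
    double u = dm * dm - d * d;
    rr = c * 3.0 * u * u / (32.0 * d * d * d);
  } else {
    iso = 1.0 / (6.0 * pi * eta * std::max(ai, aj));
    rr = 0.0;
  }
}

static void rr_pair(double d, double ai, double aj, double eta, bool corrected,
                    double& iso, double& rr) {
  const double pi = datum::pi;
  if (!deep_overlap(d, ai, aj) || !corrected) {
    iso = -1.0 / (16.0 * pi * eta * d * d * d);
    rr  =  3.0 / (16.0 * pi * eta * d * d * d);
  } else if (d > std::abs(ai - aj)) {
    double c = 1.0 / (8.0 * pi * eta * std::pow(ai, 3) * std::pow(aj, 3));
    double d3 = d * d * d;
    double A = (5.0 * std::pow(d, 6) - 27.0 * std::pow(d, 4) * (ai * ai + aj * aj)
                + 32.0 * d3 * (std::pow(ai, 3) + std::pow(aj, 3))
                - 9.0 * d * d * std::pow(ai * ai - aj * aj, 2)
                - std::pow(ai - aj, 4) * (ai * ai + 4.0 * ai * aj + aj * aj)) / (64.0 * d3);
    double u = std::pow(ai - aj, 2) - d * d;
    double B = 3.0 * u * u * (ai * ai + 4.0 * ai * aj + aj * aj - d * d) / (64.0 * d3);
    iso = c * A;
    rr = c * B;
  } else {
    iso = 1.0 / (8.0 * pi * eta * std::pow(std::max(ai, aj), 3));
    rr = 0.0;
  }
}

// coefficient g so that v_i = -g [rhat]x T_j : a_t = radius of the
// translating (receiving) sphere, a_r = radius of the torqued (source) sphere
static double tr_pair(double d, double a_t, double a_r, double eta, bool corrected) {
  const double pi = datum::pi;
  if (!deep_overlap(d, a_t, a_r) || !corrected) {
    return 1.0 / (8.0 * pi * eta * d * d);
  }
  if (d > std::abs(a_t - a_r)) {
    double b = a_r - a_t + d;
    double num = b * b * (a_t * a_t + 2.0 * a_t * (a_r + d) - 3.0 * std::pow(a_r - d, 2));
    return num / (8.0 * d * d) / (16.0 * pi * eta * a_t * std::pow(a_r, 3));
  }
  // full overlap: the smaller sphere rides rigidly inside the larger
  if (a_r > a_t) return d / (8.0 * pi * eta * std::pow(a_r, 3));
  return 0.0;
}

// positions: M x 3, radii: length M, groups: length M integer component ids
// (pairs in different groups are hydrodynamically decoupled when mask_groups
// is true). Throws on overlap when corrected = false.
// [[Rcpp::export(name = ".rpy_mobility_cpp")]]
arma::mat rpy_mobility_cpp(const arma::mat& positions, const arma::vec& radii,
                           double eta, bool corrected,
                           const arma::ivec& groups, bool mask_groups) {
  const unsigned M = positions.n_rows;
  const double pi = datum::pi;
  mat MH(6 * M, 6 * M, fill::zeros);

  for (unsigned i = 0; i < M; ++i) {
    double a = radii(i);
    double mt = 1.0 / (6.0 * pi * eta * a);
    double mr = 1.0 / (8.0 * pi * eta * a * a * a);
    for (unsigned k = 0; k < 3; ++k) {
      MH(3 * i + k, 3 * i + k) = mt;
      MH(3 * M + 3 * i + k, 3 * M + 3 * i + k) = mr;
    }
  }

  for (unsigned i = 0; i < M; ++i) {
    for (unsigned j = i + 1; j < M; ++j) {
      if (mask_groups && groups(i) != groups(j)) continue;
      vec3 rij = positions.row(i).t() - positions.row(j).t(); // receiver i, source j
      double d = norm(rij);
      double ai = radii(i), aj = radii(j);
      if (d < 1e-14) Rcpp::stop("rpy_mobility: spheres %d and %d are coincident", i + 1, j + 1);
      bool overlapped;
      double iso, rrc;
      tt_pair(d, ai, aj, eta, corrected, iso, rrc, overlapped);
      if (overlapped && !corrected) {
        Rcpp::stop("rpy_mobility: spheres %d and %d overlap (separation %.6g < %.6g); "
                   "use overlap_corrected = TRUE", i + 1, j + 1, d, ai + aj);
      }
      vec3 rh = rij / d;
      mat33 P = rh * rh.t();
      mat33 tt = iso * eye(3, 3) + rrc * P;
      rr_pair(d, ai, aj, eta, corrected, iso, rrc);
      mat33 rrm = iso * eye(3, 3) + rrc * P;
      mat33 ch = crossmat(rh);
      // v_i from T_j (tr block, receiver i translates, source j torqued)
      mat33 tr_ij = -tr_pair(d, ai, aj, eta, corrected) * ch;
      // v_j from T_i: rhat flips sign
      mat33 tr_ji = tr_pair(d, aj, ai, eta, corrected) * ch;

      MH.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = tt;
      MH.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = tt.t();
      MH.submat(3 * M + 3 * i, 3 * M + 3 * j, 3 * M + 3 * i + 2, 3 * M + 3 * j + 2) = rrm;
      MH.submat(3 * M + 3 * j, 3 * M + 3 * i, 3 * M + 3 * j + 2, 3 * M + 3 * i + 2) = rrm.t();
      MH.submat(3 * i, 3 * M + 3 * j, 3 * i + 2, 3 * M + 3 * j + 2) = tr_ij;
      MH.submat(3 * j, 3 * M + 3 * i, 3 * j + 2, 3 * M + 3 * i + 2) = tr_ji;
      // rf blocks by grand-matrix symmetry
      MH.submat(3 * M + 3 * i, 3 * j, 3 * M + 3 * i + 2, 3 * j + 2) = tr_ji.t();
      MH.submat(3 * M + 3 * j, 3 * i, 3 * M + 3 * j + 2, 3 * i + 2) = tr_ij.t();
    }
  }
  return MH;
}

// One-way coupled velocities of force- and torque-free tracer spheres.
// forces/torques: M x 3 on the system spheres; tracers: P x 3.
// [[Rcpp::export(name = ".tracer_velocities_cpp")]]
arma::mat tracer_velocities_cpp(const arma::mat& positions, const arma::vec& radii,
                                const arma::mat& forces, const arma::mat& torques,
                                const arma::mat& tracers, double tracer_radius,
                                double eta, bool corrected) {
  const unsigned M = positions.n_rows, P = tracers.n_rows;
  mat V(P, 3, fill::zeros);
  for (unsigned p = 0; p < P; ++p) {
    vec3 v = zeros<vec>(3);
    for (unsigned k = 0; k < M; ++k) {
      vec3 rij = tracers.row(p).t() - positions.row(k).t();
      double d = norm(rij);
      double iso, rrc;
      bool overlapped;
      tt_pair(d, tracer_radius, radii(k), eta, corrected, iso, rrc, overlapped);
      if (overlapped && !corrected)
        Rcpp::stop("tracer_velocities: tracer %d overlaps sphere %d", p + 1, k + 1);
      vec3 rh = rij / d;
      vec3 F = forces.row(k).t();
      vec3 T = torques.row(k).t();
      v += iso * F + rrc * rh * dot(rh, F);
      v += -tr_pair(d, tracer_radius, radii(k), eta, corrected) * (crossmat(rh) * T);
    }
    V.row(p) = v.t();
  }
  return V;
}
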