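#include <Rcpp.h>
using namespace Rcpp;

// Ideal backbone geometry (Engh-Huber-style standard values)
static const double BL_N_CA = 1.458, BL_CA_C = 1.525, BL_C_N = 1.329,
                    BL_C_O = 1.231;
static const double ANG_N_CA_C = 111.2, ANG_CA_C_N = 116.2,
                    ANG_C_N_CA = 121.7, ANG_CA_C_O = 120.8;
static const double DEG = M_PI / 180.0;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 unit(const Vec3 &a) {
  double n = std::sqrt(dot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

// NeRF placement: position D given A-B-C, bond length C-D, bond angle
// B-C-D (deg) and dihedral A-B-C-D (deg, IUPAC sign convention).
static Vec3 place_atom(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                       double bl, double theta_deg, double chi_deg) {
  double theta = theta_deg * DEG, chi = chi_deg * DEG;
  Vec3 bc = unit(sub(C, B));
  Vec3 ab = sub(B, A);
  Vec3 n = unit(cross(ab, bc));
  Vec3 m = cross(n, bc);
  double d1 = -bl * std::cos(theta);
  double d2 = bl * std::sin(theta) * std::cos(chi);
  double d3 = -bl * std::sin(theta) * std::sin(chi);
  return {C.x + d1 * bc.x + d2 * m.x + d3 * n.x,
          C.y + d1 * bc.y + d2 * m.y + d3 * n.y,
          C.z + d1 * bc.z + d2 * m.z + d3 * n.z};
}

// Build N, CA, C, O coordinates for a chain from per-residue dihedrals.
// coords is filled with 4*L rows (N, CA, C, O per residue).
static void build_chain(const double *phi, const double *psi,
                        const double *omega, int L, std::vector<Vec3> &coords) {
  coords.resize(4 * (size_t)L);
  Vec3 N = {0.0, 0.0, 0.0};
  Vec3 CA = {BL_N_CA, 0.0, 0.0};
  Vec3 C = {CA.x - BL_CA_C * std::cos(ANG_N_CA_C * DEG),
            BL_CA_C * std::sin(ANG_N_CA_C * DEG), 0.0};
  coords[0] = N;
  coords[1] = CA;
  coords[2] = C;
  for (int i = 1; i < L; ++i) {
    Vec3 Np = coords[4 * (size_t)(i - 1) + 0];
    Vec3 CAp = coords[4 * (size_t)(i - 1) + 1];
    Vec3 Cp = coords[4 * (size_t)(i - 1) + 2];
    Vec3 Ni = place_atom(Np, CAp, Cp, BL_C_N, ANG_CA_C_N, psi[i - 1]);
    Vec3 CAi = place_atom(CAp, Cp, Ni, BL_N_CA, ANG_C_N_CA, omega[i]);
    Vec3 Ci = place_atom(Cp, Ni, CAi, BL_CA_C, ANG_N_CA_C, phi[i]);
    coords[4 * (size_t)i + 0] = Ni;
    coords[4 * (size_t)i + 1] = CAi;
    coords[4 * (size_t)i + 2] = Ci;
  }
  // carbonyl oxygens: trans to N across the CA-C bond (dihedral psi + 180)
  for (int i = 0; i < L; ++i) {
    Vec3 Ni = coords[4 * (size_t)i + 0];
    Vec3 CAi = coords[4 * (size_t)i + 1];
    Vec3 Ci = coords[4 * (size_t)i + 2];
    coords[4 * (size_t)i + 3] =
        place_atom(Ni, CAi, Ci, BL_C_O, ANG_CA_C_O, psi[i] + 180.0);
  }
}

// Reject iff any CA(i)-CA(j) with |i-j| >= min_sep lies below min_dist.
static bool clash_free(const std::vector<Vec3> &coords, int L,
                       double min_dist, int min_sep) {
  double d2min = min_dist * min_dist;
  for (int i = 0; i < L; ++i) {
    const Vec3 &a = coords[4 * (size_t)i + 1];
    for (int j = i + min_sep; j < L; ++j) {
      const Vec3 &b = coords[4 * (size_t)j + 1];
      double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
      if (dx * dx + dy * dy + dz * dz < d2min) return false;
    }
  }
  return true;
}

static double rgyr_of(const std::vector<Vec3> &coords) {
  size_t n = coords.size();
  double cx = 0, cy = 0, cz = 0;
  for (size_t i = 0; i < n; ++i) {
    cx += coords[i].x;
    cy += coords[i].y;
    cz += coords[i].z;
  }
  cx /= n;
  cy /= n;
  cz /= n;
  double s = 0;
  for (size_t i = 0; i < n; ++i) {
    double dx = coords[i].x - cx, dy = coords[i].y - cy,
           dz = coords[i].z - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / n);
}

static inline double wrap180(double a) {
  while (a > 180.0) a -= 360.0;
  while (a <= -180.0) a += 360.0;
  return a;
}

// Draw one chain's dihedrals.  weights: L x 3 (alpha, beta, coil);
// basins: 4 x 4 matrix rows (PPII, beta, alphaR, alphaL), cols
// (phi_center, psi_center, sigma_phi, sigma_psi); coil_mix: 4 probs over
// the basin rows for the coil state.  Proline phi is clamped near -65.
static int draw_dihedrals(const NumericMatrix &weights,
                          const NumericMatrix &basins,
                          const NumericVector &coil_mix,
                          const NumericVector &beta_rect,
                          const LogicalVector &is_pro, double pro_phi,
                          double pro_sigma, double cis_prob, double *phi,
                          double *psi, double *omega) {
  int L = weights.nrow();
  int cis_count = 0;
  for (int i = 0; i < L; ++i) {
    double u = R::runif(0.0, 1.0);
    int basin;
    if (u < weights(i, 0)) {
      basin = 2; // alpha state -> alpha_R basin
    } else if (u < weights(i, 0) + weights(i, 1)) {
      basin = 1; // beta state -> beta basin
    } else {
      double v = R::runif(0.0, 1.0);
      double acc = 0.0;
      basin = 0;
      for (int b = 0; b < 4; ++b) {
        acc += coil_mix[b];
        if (v < acc) {
          basin = b;
          break;
        }
      }
    }
    if (basin == 1) {
      phi[i] = R::runif(beta_rect[0], beta_rect[1]);
      psi[i] = R::runif(beta_rect[2], beta_rect[3]);
    } else {
      phi[i] = wrap180(R::rnorm(basins(basin, 0), basins(basin, 2)));
      psi[i] = wrap180(R::rnorm(basins(basin, 1), basins(basin, 3)));
    }
    if (is_pro[i]) phi[i] = wrap180(R::rnorm(pro_phi, pro_sigma));
    if (i > 0 && is_pro[i] && R::runif(0.0, 1.0) < cis_prob) {
      omega[i] = 0.0;
      ++cis_count;
    } else {
      omega[i] = 180.0;
    }
  }
  return cis_count;
}

// [[Rcpp::export]]
List cpp_sample_dihedrals(NumericMatrix weights, NumericMatrix basins,
                          NumericVector coil_mix, NumericVector beta_rect,
                          LogicalVector is_pro, double pro_phi,
                          double pro_sigma, double cis_prob, int max_cis) {
  int L = weights.nrow();
  NumericVector phi(L), psi(L), omega(L);
  int cis = 0;
  do {
    cis = draw_dihedrals(weights, basins, coil_mix, beta_rect, is_pro,
                         pro_phi, pro_sigma, cis_prob, phi.begin(),
                         psi.begin(), omega.begin());
  } while (cis > max_cis);
  return List::create(_["phi"] = phi, _["psi"] = psi, _["omega"] = omega,
                      _["cis_count"] = cis);
}

// [[Rcpp::export]]
NumericMatrix cpp_build_backbone(NumericVector phi, NumericVector psi,
                                 NumericVector omega) {
  int L = phi.size();
  std::vector<Vec3> coords;
  build_chain(phi.begin(), psi.begin(), omega.begin(), L, coords);
  NumericMatrix out(4 * L, 3);
  for (int i = 0; i < 4 * L; ++i) {
    out(i, 0) = coords[i].x;
    out(i, 1) = coords[i].y;
    out(i, 2) = coords[i].z;
  }
  return out;
}

// Draw one residue's (phi, psi) and the omega of its preceding peptide
// bond.  cis_count is only incremented when a cis draw is still allowed.
static void draw_residue(int i, const NumericMatrix &weights,
                         const NumericMatrix &basins,
                         const NumericVector &coil_mix,
                         const NumericVector &beta_rect,
                         const LogicalVector &is_pro, double pro_phi,
                         double pro_sigma, double cis_prob, int max_cis,
                         int &cis_count, double &phi, double &psi,
                         double &omega) {
  double u = R::runif(0.0, 1.0);
  int basin;
  if (u < weights(i, 0)) {
    basin = 2; // alpha state -> alpha_R basin
  } else if (u < weights(i, 0) + weights(i, 1)) {
    basin = 1; // beta state -> beta basin
  } else {
    double v = R::runif(0.0, 1.0);
    double acc = 0.0;
    basin = 0;
    for (int b = 0; b < 4; ++b) {
      acc += coil_mix[b];
      if (v < acc) {
        basin = b;
        break;
      }
    }
  }
  if (basin == 1) {
    // the beta basin is sampled uniformly over its classification
    // rectangle: beta-assigned dihedrals scatter across the whole upper-left
    // region rather than clustering at one strand geometry
    phi = R::runif(beta_rect[0], beta_rect[1]);
    psi = R::runif(beta_rect[2], beta_rect[3]);
  } else {
    phi = wrap180(R::rnorm(basins(basin, 0), basins(basin, 2)));
    psi = wrap180(R::rnorm(basins(basin, 1), basins(basin, 3)));
  }
  if (is_pro[i]) phi = wrap180(R::rnorm(pro_phi, pro_sigma));
  omega = 180.0;
  if (i > 0 && is_pro[i] && cis_count < max_cis &&
      R::runif(0.0, 1.0) < cis_prob) {
    omega = 0.0;
    ++cis_count;
  }
}

// Sequential chain growth with per-residue redraws and limited
// backtracking: each residue is placed and its CA tested against all CAs
// at sequence separation >= min_sep; on a clash the residue is redrawn up
// to `retries` times, then the chain steps back `backtrack` residues; a
// chain exceeding `max_backtracks` backtracks is restarted from scratch.
// [[Rcpp::export]]
List cpp_sample_ensemble(int n, NumericMatrix weights, NumericMatrix basins,
                         NumericVector coil_mix, NumericVector beta_rect,
                         LogicalVector is_pro, double pro_phi,
                         double pro_sigma, double cis_prob, int max_cis,
                         double min_dist, int min_sep, int max_restarts,
                         int retries = 50, int backtrack = 8,
                         int max_backtracks = 2000) {
  int L = weights.nrow();
  NumericMatrix phi(n, L), psi(n, L), omega(n, L);
  NumericVector rgyr(n);
  IntegerVector cis_counts(n);
  double d2min = min_dist * min_dist;
  std::vector<double> cphi(L), cpsi(L), comega(L);
  std::vector<Vec3> coords(4 * (size_t)L);
  std::vector<int> cis_before(L + 1);
  long long attempts = 0;

  for (int c = 0; c < n; ++c) {
    bool chain_done = false;
    for (int restart = 0; restart < max_restarts && !chain_done; ++restart) {
      ++attempts;
      int bt = 0;
      int i = 0;
      cis_before[0] = 0;
      bool failed = false;
      while (i < L) {
        bool placed = false;
        for (int r = 0; r <= retries; ++r) {
          int cis = cis_before[i];
          draw_residue(i, weights, basins, coil_mix, beta_rect, is_pro,
                       pro_phi, pro_sigma, cis_prob, max_cis, cis, cphi[i],
                       cpsi[i], comega[i]);
          // place this residue's backbone atoms
          Vec3 Ni, CAi, Ci;
          if (i == 0) {
            Ni = {0.0, 0.0, 0.0};
            CAi = {BL_N_CA, 0.0, 0.0};
            Ci = {CAi.x - BL_CA_C * std::cos(ANG_N_CA_C * DEG),
                  BL_CA_C * std::sin(ANG_N_CA_C * DEG), 0.0};
          } else {
            const Vec3 &Np = coords[4 * (size_t)(i - 1) + 0];
            const Vec3 &CAp = coords[4 * (size_t)(i - 1) + 1];
            const Vec3 &Cp = coords[4 * (size_t)(i - 1) + 2];
            Ni = place_atom(Np, CAp, Cp, BL_C_N, ANG_CA_C_N, cpsi[i - 1]);
            CAi = place_atom(CAp, Cp, Ni, BL_N_CA, ANG_C_N_CA, comega[i]);
            Ci = place_atom(Cp, Ni, CAi, BL_CA_C, ANG_N_CA_C, cphi[i]);
          }
          bool clash = false;
          for (int j = 0; j <= i - min_sep; ++j) {
            const Vec3 &b = coords[4 * (size_t)j + 1];
            double dx = CAi.x - b.x, dy = CAi.y - b.y, dz = CAi.z - b.z;
            if (dx * dx + dy * dy + dz * dz < d2min) {
              clash = true;
              break;
            }
          }
          if (!clash) {
            coords[4 * (size_t)i + 0] = Ni;
            coords[4 * (size_t)i + 1] = CAi;
            coords[4 * (size_t)i + 2] = Ci;
            cis_before[i + 1] = cis;
            placed = true;
            break;
          }
        }
        if (placed) {
          ++i;
        } else {
          ++bt;
          if (bt > max_backtracks) {
            failed = true;
            break;
          }
          i = std::max(0, i - backtrack);
        }
      }
      if (!failed) {
        // note: psi of the last residue never moved a placed atom, but is
        // part of the conformer (it orients the terminal carbonyl oxygen)
        for (int k = 0; k < L; ++k) {
          const Vec3 &Nk = coords[4 * (size_t)k + 0];
          const Vec3 &CAk = coords[4 * (size_t)k + 1];
          const Vec3 &Ck = coords[4 * (size_t)k + 2];
          coords[4 * (size_t)k + 3] =
              place_atom(Nk, CAk, Ck, BL_C_O, ANG_CA_C_O, cpsi[k] + 180.0);
        }
        chain_done = true;
      }
    }
    if (!chain_done) {
      stop("Conformer %d: no clash-free chain within %d restarts "
           "(acceptance rate too low).",
           c + 1, max_restarts);
    }
    for (int i = 0; i < L; ++i) {
      phi(c, i) = cphi[i];
      psi(c, i) = cpsi[i];
      omega(c, i) = comega[i];
    }
    rgyr[c] = rgyr_of(coords);
    cis_counts[c] = cis_before[L];
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["phi"] = phi, _["psi"] = psi, _["omega"] = omega,
                      _["rgyr"] = rgyr, _["cis_count"] = cis_counts,
                      _["attempts"] = (double)attempts);
}

// Independent all-pairs CA distance minimum (used for verification).
// [[Rcpp::export]]
double cpp_min_ca_separation(NumericMatrix coords, int min_sep) {
  // coords: 4L x 3 backbone rows; CA rows are 1, 5, 9, ...
  int L = coords.nrow() / 4;
  double best = R_PosInf;
  for (int i = 0; i < L; ++i) {
    for (int j = i + min_sep; j < L; ++j) {
      double dx = coords(4 * i + 1, 0) - coords(4 * j + 1, 0);
      double dy = coords(4 * i + 1, 1) - coords(4 * j + 1, 1);
      double dz = coords(4 * i + 1, 2) - coords(4 * j + 1, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  }
  return best;
}
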