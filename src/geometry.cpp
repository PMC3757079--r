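// Backbone geometry engine: NeRF chain construction from dihedrals,
// Kabsch-Sander H-bond scoring, dihedral refinement for hairpin closure,
// pairwise Kabsch RMSD matrices, and Shrake-Rupley SASA.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Standard backbone geometry (Angstrom / degrees)
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double B_C_O = 1.231, B_N_H = 1.01, B_CA_CB = 1.53;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.6, A_C_N_CA = 121.9;
static const double A_N_CA_CB = 110.4, T_C_N_CA_CB = -122.0;

// Place atom D given A-B-C with bond |C-D|, angle B-C-D and torsion A-B-C-D.
static arma::rowvec nerf(const arma::rowvec& A, const arma::rowvec& B,
                         const arma::rowvec& C, double bond, double angle_deg,
                         double torsion_deg) {
  double th = angle_deg * DEG, ta = torsion_deg * DEG;
  arma::rowvec bc = arma::normalise(C - B);
  arma::rowvec ab = B - A;
  arma::rowvec n = arma::normalise(arma::cross(ab, bc));
  arma::rowvec m = arma::cross(n, bc);
  arma::rowvec d2(3);
  d2(0) = -bond * std::cos(th);
  d2(1) = bond * std::sin(th) * std::cos(ta);
  d2(2) = bond * std::sin(th) * std::sin(ta);
  return C + d2(0) * bc + d2(1) * m + d2(2) * n;
}

// Build backbone (+H, +CB) for L residues.
// phi[0] is ignored; psi[L-1] is used only to orient the terminal carbonyl.
// Returns an L x 18 matrix: columns xyz for N, H, CA, C, O, CB (NA if absent).
// [[Rcpp::export(name = ".build_backbone_cpp")]]
NumericMatrix build_backbone_cpp(NumericVector phi, NumericVector psi,
                                 NumericVector omega, LogicalVector is_pro,
                                 LogicalVector is_gly) {
  int L = phi.size();
  arma::mat N(L, 3), CA(L, 3), C(L, 3), O(L, 3), H(L, 3), CB(L, 3);
  H.fill(NA_REAL);
  CB.fill(NA_REAL);

  N.row(0) = arma::rowvec({0.0, 0.0, 0.0});
  CA.row(0) = arma::rowvec({B_N_CA, 0.0, 0.0});
  double th = A_N_CA_C * DEG;
  C.row(0) = CA.row(0) +
    B_CA_C * arma::rowvec({-std::cos(th), std::sin(th), 0.0});

  for (int i = 1; i < L; ++i) {
    N.row(i) = nerf(N.row(i - 1), CA.row(i - 1), C.row(i - 1), B_C_N,
                    A_CA_C_N, psi[i - 1]);
    CA.row(i) = nerf(CA.row(i - 1), C.row(i - 1), N.row(i), B_N_CA,
                     A_C_N_CA, omega[i]);
    C.row(i) = nerf(C.row(i - 1), N.row(i), CA.row(i), B_CA_C,
                    A_N_CA_C, phi[i]);
    // carbonyl O of residue i-1: sp2, in the CA-C-N(i) plane
    arma::rowvec u1 = arma::normalise(CA.row(i - 1) - C.row(i - 1));
    arma::rowvec u2 = arma::normalise(N.row(i) - C.row(i - 1));
    O.row(i - 1) = C.row(i - 1) + B_C_O * arma::normalise(-(u1 + u2));
    // amide H of residue i: opposite the C(i-1)-N-CA bisector
    if (!is_pro[i]) {
      arma::rowvec v1 = arma::normalise(C.row(i - 1) - N.row(i));
      arma::rowvec v2 = arma::normalise(CA.row(i) - N.row(i));
      H.row(i) = N.row(i) + B_N_H * arma::normalise(-(v1 + v2));
    }
  }
  // terminal carbonyl: torsion N-CA-C-O = psi(L) + 180
  O.row(L - 1) = nerf(N.row(L - 1), CA.row(L - 1), C.row(L - 1), B_C_O,
                      120.5, psi[L - 1] + 180.0);
  for (int i = 0; i < L; ++i) {
    if (!is_gly[i])
      CB.row(i) = nerf(C.row(i), N.row(i), CA.row(i), B_CA_CB, A_N_CA_CB,
                       T_C_N_CA_CB);
  }

  NumericMatrix out(L, 18);
  for (int i = 0; i < L; ++i)
    for (int k = 0; k < 3; ++k) {
      out(i, k) = N(i, k);
      out(i, 3 + k) = H(i, k);
      out(i, 6 + k) = CA(i, k);
      out(i, 9 + k) = C(i, k);
      out(i, 12 + k) = O(i, k);
      out(i, 15 + k) = CB(i, k);
    }
  colnames(out) = CharacterVector({"N.x", "N.y", "N.z", "H.x", "H.y", "H.z",
                                   "CA.x", "CA.y", "CA.z", "C.x", "C.y",
                                   "C.z", "O.x", "O.y", "O.z", "CB.x",
                                   "CB.y", "CB.z"});
  return out;
}

// Kabsch-Sander electrostatic H-bond energy (kcal/mol); 0 beyond 7 A N...O.
static double ks_energy(const arma::rowvec& C, const arma::rowvec& O,
                        const arma::rowvec& N, const arma::rowvec& H) {
  double rON = arma::norm(O - N);
  if (rON > 7.0) return 0.0;
  double rCH = arma::norm(C - H), rOH = arma::norm(O - H),
         rCN = arma::norm(C - N);
  return 27.888 * (1.0 / rON + 1.0 / rCH - 1.0 / rOH - 1.0 / rCN);
}

struct ChainAtoms {
  arma::mat N, H, CA, C, O;
};

static ChainAtoms build_atoms(const std::vector<double>& phi,
                              const std::vector<double>& psi,
                              const std::vector<double>& omega,
                              const LogicalVector& is_pro) {
  int L = phi.size();
  ChainAtoms a;
  a.N.set_size(L, 3);
  a.H.set_size(L, 3);
  a.H.fill(arma::datum::nan);
  a.CA.set_size(L, 3);
  a.C.set_size(L, 3);
  a.O.set_size(L, 3);
  a.N.row(0) = arma::rowvec({0.0, 0.0, 0.0});
  a.CA.row(0) = arma::rowvec({B_N_CA, 0.0, 0.0});
  double th = A_N_CA_C * DEG;
  a.C.row(0) = a.CA.row(0) +
    B_CA_C * arma::rowvec({-std::cos(th), std::sin(th), 0.0});
  for (int i = 1; i < L; ++i) {
    a.N.row(i) = nerf(a.N.row(i - 1), a.CA.row(i - 1), a.C.row(i - 1), B_C_N,
                      A_CA_C_N, psi[i - 1]);
    a.CA.row(i) = nerf(a.CA.row(i - 1), a.C.row(i - 1), a.N.row(i), B_N_CA,
                       A_C_N_CA, omega[i]);
    a.C.row(i) = nerf(a.C.row(i - 1), a.N.row(i), a.CA.row(i), B_CA_C,
                      A_N_CA_C, phi[i]);
    arma::rowvec u1 = arma::normalise(a.CA.row(i - 1) - a.C.row(i - 1));
    arma::rowvec u2 = arma::normalise(a.N.row(i) - a.C.row(i - 1));
    a.O.row(i - 1) = a.C.row(i - 1) + B_C_O * arma::normalise(-(u1 + u2));
    if (!is_pro[i]) {
      arma::rowvec v1 = arma::normalise(a.C.row(i - 1) - a.N.row(i));
      arma::rowvec v2 = arma::normalise(a.CA.row(i) - a.N.row(i));
      a.H.row(i) = a.N.row(i) + B_N_H * arma::normalise(-(v1 + v2));
    }
  }
  a.O.row(phi.size() - 1) = nerf(a.N.row(phi.size() - 1),
                                 a.CA.row(phi.size() - 1),
                                 a.C.row(phi.size() - 1), B_C_O, 120.5,
                                 psi[phi.size() - 1] + 180.0);
  return a;
}

static double clash_penalty(const ChainAtoms& a);

// Objective over (acceptor, donor) pairs: the O...H distance deviation from
// the target guides long-range approach; the Kabsch-Sander energy (floored
// at -4 kcal/mol so bonds cannot collapse into contacts) enforces proper
// donor/acceptor geometry.
static double closure_objective(const ChainAtoms& a, const IntegerMatrix& pairs,
                                double target, double clash_weight) {
  double s = 0.0;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int ia = pairs(p, 0) - 1, id = pairs(p, 1) - 1;
    if (!a.H.row(id).is_finite()) continue;
    s += 0.5 * std::fabs(arma::norm(a.O.row(ia) - a.H.row(id)) - target);
    // drive each bond towards a healthy mid-range energy; penalising
    // over-deep bonds keeps the descent from tightening one direction of a
    // pair at the expense of its reverse
    double e = ks_energy(a.C.row(ia), a.O.row(ia), a.N.row(id), a.H.row(id));
    s += std::fabs(std::max(e, -6.0) + 2.5);
  }
  if (clash_weight > 0) s += clash_weight * clash_penalty(a);
  return s;
}

// Quadratic penalty on backbone heavy atoms (N, CA, C, O) of residues at
// least two apart that come closer than 2.2 A; keeps the descent from
// closing H-bonds through steric overlap.
static double clash_penalty(const ChainAtoms& a) {
  int L = a.N.n_rows;
  const double cut = 2.2, cut2 = cut * cut;
  double pen = 0.0;
  const arma::mat* mats[4] = {&a.N, &a.CA, &a.C, &a.O};
  for (int ri = 0; ri < L; ++ri) {
    for (int rj = ri + 2; rj < L; ++rj) {
      // residues whose CA atoms are far apart cannot clash
      double cx = a.CA(ri, 0) - a.CA(rj, 0), cy = a.CA(ri, 1) - a.CA(rj, 1),
             cz = a.CA(ri, 2) - a.CA(rj, 2);
      if (cx * cx + cy * cy + cz * cz > 49.0) continue;
      for (int ai = 0; ai < 4; ++ai) {
        const arma::rowvec& x = mats[ai]->row(ri);
        for (int aj = 0; aj < 4; ++aj) {
          const arma::rowvec& y = mats[aj]->row(rj);
          double dx = x(0) - y(0), dy = x(1) - y(1), dz = x(2) - y(2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < cut2) {
            double d = std::sqrt(d2);
            pen += (cut - d) * (cut - d);
          }
        }
      }
    }
  }
  return pen;
}

// Smallest backbone heavy-atom distance between residues >= 2 apart.
static double min_heavy_contact(const ChainAtoms& a) {
  int L = a.N.n_rows;
  double best = 1e9;
  const arma::mat* mats[4] = {&a.N, &a.CA, &a.C, &a.O};
  for (int ri = 0; ri < L; ++ri) {
    for (int rj = ri + 2; rj < L; ++rj) {
      double cx = a.CA(ri, 0) - a.CA(rj, 0), cy = a.CA(ri, 1) - a.CA(rj, 1),
             cz = a.CA(ri, 2) - a.CA(rj, 2);
      if (cx * cx + cy * cy + cz * cz > 49.0) continue;
      for (int ai = 0; ai < 4; ++ai)
        for (int aj = 0; aj < 4; ++aj) {
          double d = arma::norm(mats[ai]->row(ri) - mats[aj]->row(rj));
          if (d < best) best = d;
        }
    }
  }
  return best;
}

static bool pairs_bonded(const ChainAtoms& a, const IntegerMatrix& pairs,
                         double e_cut) {
  for (int p = 0; p < pairs.nrow(); ++p) {
    int ia = pairs(p, 0) - 1, id = pairs(p, 1) - 1;
    if (!a.H.row(id).is_finite()) continue;
    if (ks_energy(a.C.row(ia), a.O.row(ia), a.N.row(id), a.H.row(id)) >=
        e_cut)
      return false;
  }
  return true;
}

// Coordinate descent on phi/psi of the free residues to close a hairpin.
// One iteration = one single-dihedral update. Step size shrinks when a full
// sweep yields no improvement; stops early once every listed H-bond pair is
// below the energy cutoff.
// [[Rcpp::export(name = ".refine_closure_cpp")]]
List refine_closure_cpp(NumericVector phi, NumericVector psi,
                        NumericVector omega, LogicalVector is_pro,
                        IntegerVector free_res, IntegerMatrix pairs,
                        int max_iter = 500, double target = 1.95,
                        double e_cut = -0.5, double clash_weight = 10.0) {
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  std::vector<double> om = as<std::vector<double> >(omega);
  int L = ph.size();

  std::vector<std::pair<int, int> > dof;  // (residue idx 0-based, 0=phi 1=psi)
  for (int k = 0; k < free_res.size(); ++k) {
    int r = free_res[k] - 1;
    if (r > 0) dof.push_back(std::make_pair(r, 0));
    // psi of the last residue is a real degree of freedom: it orients the
    // terminal carbonyl oxygen
    dof.push_back(std::make_pair(r, 1));
  }

  bool need_clash_free = clash_weight > 0;
  const double contact_floor = 1.7;
  ChainAtoms a = build_atoms(ph, ps, om, is_pro);
  double best = closure_objective(a, pairs, target, clash_weight);
  bool conv = pairs_bonded(a, pairs, e_cut) &&
    (!need_clash_free || min_heavy_contact(a) >= contact_floor);
  int iter = 0;
  const double steps[] = {90.0, 45.0, 20.0, 10.0, 5.0, 2.0, 1.0};
  const int n_steps = 7;

  bool improved_cycle = true;
  while (!conv && iter < max_iter && improved_cycle) {
    improved_cycle = false;
    for (int si = 0; si < n_steps && !conv && iter < max_iter; ++si) {
      bool improved_sweep = true;
      while (improved_sweep && !conv && iter < max_iter) {
        improved_sweep = false;
        for (size_t d = 0; d < dof.size() && !conv && iter < max_iter; ++d) {
          ++iter;
          int r = dof[d].first, which = dof[d].second;
          double cur = which == 0 ? ph[r] : ps[r];
          double cand_best = best, ang_best = cur;
          for (int s = -1; s <= 1; s += 2) {
            double ang = cur + s * steps[si];
            if (which == 0) ph[r] = ang; else ps[r] = ang;
            ChainAtoms at = build_atoms(ph, ps, om, is_pro);
            double obj = closure_objective(at, pairs, target, clash_weight);
            if (obj < cand_best) {
              cand_best = obj;
              ang_best = ang;
            }
          }
          if (which == 0) ph[r] = ang_best; else ps[r] = ang_best;
          if (cand_best < best - 1e-12) {
            best = cand_best;
            improved_sweep = true;
            improved_cycle = true;
            ChainAtoms at = build_atoms(ph, ps, om, is_pro);
            conv = pairs_bonded(at, pairs, e_cut) &&
              (!need_clash_free || min_heavy_contact(at) >= contact_floor);
          }
        }
        // crankshaft moves (psi_r up, phi_{r+1} down) rotate the downstream
        // segment almost rigidly and resolve sheared registries that
        // single-dihedral moves cannot fix
        for (size_t d = 0; d + 1 < dof.size() && !conv && iter < max_iter;
             ++d) {
          if (dof[d].second != 1) continue;
          int r = dof[d].first;
          if (dof[d + 1].second != 0 || dof[d + 1].first != r + 1) continue;
          ++iter;
          double cur_ps = ps[r], cur_ph = ph[r + 1];
          double cand_best = best, best_ps = cur_ps, best_ph = cur_ph;
          for (int s = -1; s <= 1; s += 2) {
            ps[r] = cur_ps + s * steps[si];
            ph[r + 1] = cur_ph - s * steps[si];
            ChainAtoms at = build_atoms(ph, ps, om, is_pro);
            double obj = closure_objective(at, pairs, target, clash_weight);
            if (obj < cand_best) {
              cand_best = obj;
              best_ps = ps[r];
              best_ph = ph[r + 1];
            }
          }
          ps[r] = best_ps;
          ph[r + 1] = best_ph;
          if (cand_best < best - 1e-12) {
            best = cand_best;
            improved_sweep = true;
            improved_cycle = true;
            ChainAtoms at = build_atoms(ph, ps, om, is_pro);
            conv = pairs_bonded(at, pairs, e_cut) &&
              (!need_clash_free || min_heavy_contact(at) >= contact_floor);
          }
        }
      }
    }
  }

  return List::create(_["phi"] = NumericVector(ph.begin(), ph.end()),
                      _["psi"] = NumericVector(ps.begin(), ps.end()),
                      _["objective"] = best, _["converged"] = conv,
                      _["iterations"] = iter);
}

// Evaluate the closure objective and convergence state for given dihedrals
// (used by the simplex polish on the R side).
// [[Rcpp::export(name = ".closure_eval_cpp")]]
List closure_eval_cpp(NumericVector phi, NumericVector psi,
                      NumericVector omega, LogicalVector is_pro,
                      IntegerMatrix pairs, double target = 1.95,
                      double e_cut = -0.5, double clash_weight = 10.0,
                      bool check_conv = true) {
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  std::vector<double> om = as<std::vector<double> >(omega);
  ChainAtoms a = build_atoms(ph, ps, om, is_pro);
  bool conv = check_conv && pairs_bonded(a, pairs, e_cut) &&
    min_heavy_contact(a) >= 1.7;
  return List::create(_["objective"] = closure_objective(a, pairs, target,
                                                         clash_weight),
                      _["converged"] = conv);
}

// Pairwise Kabsch RMSD over pre-selected atoms.
// coords: k x 3 x n cube (k atoms per conformer).
// [[Rcpp::export(name = ".rmsd_matrix_cpp")]]
NumericMatrix rmsd_matrix_cpp(arma::cube coords) {
  int k = coords.n_rows, n = coords.n_slices;
  // center each conformer, cache squared norms
  std::vector<arma::mat> X(n);
  arma::vec ssq(n);
  for (int i = 0; i < n; ++i) {
    arma::mat M = coords.slice(i);
    M.each_row() -= arma::mean(M, 0);
    X[i] = M;
    ssq(i) = arma::accu(M % M);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      arma::mat Cov = X[i].t() * X[j];
      arma::vec s;
      arma::mat U, V;
      arma::svd(U, s, V, Cov);
      double d = arma::det(U) * arma::det(V) < 0 ? -1.0 : 1.0;
      double tr = s(0) + s(1) + d * s(2);
      double msd = (ssq(i) + ssq(j) - 2.0 * tr) / k;
      double r = msd > 0 ? std::sqrt(msd) : 0.0;
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// Shrake-Rupley accessible surface area with a Fibonacci sphere lattice.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe = 1.4, int n_points = 960) {
  int n = coords.nrow();
  arma::mat P(n_points, 3);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    double z = 1.0 - 2.0 * (p + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * p;
    P(p, 0) = r * std::cos(th);
    P(p, 1) = r * std::sin(th);
    P(p, 2) = z;
  }
  arma::mat X(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) X(i, k) = coords(i, k);
  arma::vec R(n);
  for (int i = 0; i < n; ++i) R(i) = radii[i] + probe;

  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (j != i && arma::norm(X.row(i) - X.row(j)) < R(i) + R(j))
        nb.push_back(j);
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      arma::rowvec pt = X.row(i) + R(i) * P.row(p);
      bool buried = false;
      for (size_t q = 0; q < nb.size() && !buried; ++q)
        if (arma::norm(pt - X.row(nb[q])) < R(nb[q])) buried = true;
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * R(i) * R(i) * acc / n_points;
  }
  return area;
}
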