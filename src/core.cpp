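// Coarse-grained dynamics core: double-basin elastic network forces,
// collective-variable values/gradients, overdamped Langevin integrator with
// time-dependent harmonic bias and exact work bookkeeping.
//
// Conventions: coordinates are N x 3 (rows = particles), reduced units
// (kT = 1 at temperature 1). All indices arriving from R are 1-based and
// converted here. Randomness comes from R's RNG so set.seed() governs runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double RAD2DEG = 57.29577951308232;

// ---------------------------------------------------------------------------
// energy model
// ---------------------------------------------------------------------------

struct EnergyTerms {
  double v_of, v_if, v_mix, v_excl, v_ion, total;
};

struct Enm {
  arma::umat pof, pif;   // M x 2, 0-based
  arma::vec r0of, r0if;
  double k_spring, beta, r_excl, k_excl, k_ion;
  int ion_row;           // -1 when apo
  arma::uvec site_rows;
  arma::vec ion_r0;
};

static Enm parse_enm(const List& enm) {
  Enm em;
  arma::imat pof = as<arma::imat>(enm["pairs_of"]);
  arma::imat pif = as<arma::imat>(enm["pairs_if"]);
  em.pof = arma::conv_to<arma::umat>::from(pof - 1);
  em.pif = arma::conv_to<arma::umat>::from(pif - 1);
  em.r0of = as<arma::vec>(enm["r0_of"]);
  em.r0if = as<arma::vec>(enm["r0_if"]);
  em.k_spring = as<double>(enm["k_spring"]);
  em.beta = as<double>(enm["beta_mix"]);
  em.r_excl = as<double>(enm["r_excl"]);
  em.k_excl = as<double>(enm["k_excl"]);
  em.k_ion = as<double>(enm["k_ion"]);
  em.ion_row = as<int>(enm["ion_row"]) - 1;  // 0 -> -1 (absent)
  if (em.ion_row >= 0) {
    arma::ivec sr = as<arma::ivec>(enm["site_rows"]);
    em.site_rows = arma::conv_to<arma::uvec>::from(sr - 1);
    em.ion_r0 = as<arma::vec>(enm["ion_r0"]);
  }
  return em;
}

static double basin_energy(const arma::mat& X, const arma::umat& P,
                           const arma::vec& r0, double k, arma::mat* G) {
  double V = 0.0;
  for (arma::uword m = 0; m < P.n_rows; ++m) {
    arma::uword i = P(m, 0), j = P(m, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    double dr = r - r0(m);
    V += 0.5 * k * dr * dr;
    if (G && r > 1e-12) {
      arma::rowvec g = (k * dr / r) * d;
      G->row(i) += g;
      G->row(j) -= g;
    }
  }
  return V;
}

// total potential; if G != nullptr it receives the full gradient dV/dX
static EnergyTerms model_energy(const arma::mat& X, const Enm& em, arma::mat* G) {
  EnergyTerms et;
  arma::mat Gof, Gif;
  if (G) { Gof.zeros(X.n_rows, 3); Gif.zeros(X.n_rows, 3); G->zeros(X.n_rows, 3); }
  et.v_of = basin_energy(X, em.pof, em.r0of, em.k_spring, G ? &Gof : nullptr);
  et.v_if = basin_energy(X, em.pif, em.r0if, em.k_spring, G ? &Gif : nullptr);

  // log-sum-exp mixing: V = -ln(exp(-b Vof) + exp(-b Vif)) / b
  double vmin = std::min(et.v_of, et.v_if);
  double e_of = std::exp(-em.beta * (et.v_of - vmin));
  double e_if = std::exp(-em.beta * (et.v_if - vmin));
  et.v_mix = vmin - std::log(e_of + e_if) / em.beta;
  if (G) {
    double w_of = e_of / (e_of + e_if);
    *G = w_of * Gof + (1.0 - w_of) * Gif;
  }

  // soft excluded volume over all pairs
  et.v_excl = 0.0;
  if (em.r_excl > 0) {
    for (arma::uword i = 0; i + 1 < X.n_rows; ++i) {
      for (arma::uword j = i + 1; j < X.n_rows; ++j) {
        arma::rowvec d = X.row(i) - X.row(j);
        double r = arma::norm(d);
        if (r < em.r_excl) {
          double pen = em.r_excl - r;
          et.v_excl += 0.5 * em.k_excl * pen * pen;
          if (G && r > 1e-12) {
            arma::rowvec g = (-em.k_excl * pen / r) * d;
            G->row(i) += g;
            G->row(j) -= g;
          }
        }
      }
    }
  }

  // five harmonic ion-site restraints (rest lengths from the OF reference)
  et.v_ion = 0.0;
  if (em.ion_row >= 0 && em.k_ion > 0) {
    for (arma::uword m = 0; m < em.site_rows.n_elem; ++m) {
      arma::rowvec d = X.row(em.ion_row) - X.row(em.site_rows(m));
      double r = arma::norm(d);
      double dr = r - em.ion_r0(m);
      et.v_ion += 0.5 * em.k_ion * dr * dr;
      if (G && r > 1e-12) {
        arma::rowvec g = (em.k_ion * dr / r) * d;
        G->row(em.ion_row) += g;
        G->row(em.site_rows(m)) -= g;
      }
    }
  }

  et.total = et.v_mix + et.v_excl + et.v_ion;
  return et;
}

// [[Rcpp::export]]
List cg_energy(NumericMatrix coords, List enm) {
  arma::mat X = as<arma::mat>(coords);
  Enm em = parse_enm(enm);
  EnergyTerms et = model_energy(X, em, nullptr);
  return List::create(_["total"] = et.total, _["of"] = et.v_of,
                      _["if"] = et.v_if, _["mix"] = et.v_mix,
                      _["excl"] = et.v_excl, _["ion"] = et.v_ion);
}

// [[Rcpp::export]]
NumericMatrix cg_gradient(NumericMatrix coords, List enm) {
  arma::mat X = as<arma::mat>(coords);
  Enm em = parse_enm(enm);
  arma::mat G;
  model_energy(X, em, &G);
  return wrap(G);
}

// ---------------------------------------------------------------------------
// collective variables
// ---------------------------------------------------------------------------

// kind codes (kept in step with R/colvars.R): 1 com_distance, 2 rg,
// 3 orientation_angle, 4 rmsd (superposed on its own group)
struct CvDef {
  int kind;
  arma::uvec ia, ib;
  arma::mat ref;  // group reference coordinates (orientation, rmsd)
};

static CvDef parse_cv(const List& cv) {
  CvDef c;
  c.kind = as<int>(cv["kind_code"]);
  arma::ivec ia = as<arma::ivec>(cv["idx"]);
  c.ia = arma::conv_to<arma::uvec>::from(ia - 1);
  if (cv.containsElementNamed("idx_b") && !Rf_isNull(cv["idx_b"])) {
    arma::ivec ib = as<arma::ivec>(cv["idx_b"]);
    c.ib = arma::conv_to<arma::uvec>::from(ib - 1);
  }
  if (cv.containsElementNamed("ref") && !Rf_isNull(cv["ref"]))
    c.ref = as<arma::mat>(cv["ref"]);
  return c;
}

static arma::mat centered(const arma::mat& Y) {
  arma::rowvec c = arma::mean(Y, 0);
  return Y.each_row() - c;
}

// quaternion key matrix of the correlation matrix S = Xc^T Yc
static arma::mat key_matrix(const arma::mat& S) {
  arma::mat K(4, 4);
  K(0, 0) = S(0, 0) + S(1, 1) + S(2, 2);
  K(0, 1) = K(1, 0) = S(1, 2) - S(2, 1);
  K(0, 2) = K(2, 0) = S(2, 0) - S(0, 2);
  K(0, 3) = K(3, 0) = S(0, 1) - S(1, 0);
  K(1, 1) = S(0, 0) - S(1, 1) - S(2, 2);
  K(1, 2) = K(2, 1) = S(0, 1) + S(1, 0);
  K(1, 3) = K(3, 1) = S(2, 0) + S(0, 2);
  K(2, 2) = -S(0, 0) + S(1, 1) - S(2, 2);
  K(2, 3) = K(3, 2) = S(1, 2) + S(2, 1);
  K(3, 3) = -S(0, 0) - S(1, 1) + S(2, 2);
  return K;
}

// orientation angle (degrees) of the optimal rotation taking the centered
// reference group onto the centered current group, via the quaternion
// 4x4 key-matrix eigenproblem
static double orientation_angle_group(const arma::mat& cur, const arma::mat& ref) {
  arma::mat Yc = centered(cur), Xc = centered(ref);
  arma::mat K = key_matrix(Xc.t() * Yc);
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, K);
  double w = std::fabs(eigvec(0, 3));  // largest eigenvalue is last
  if (w > 1.0) w = 1.0;
  return 2.0 * std::acos(w) * RAD2DEG;
}

// Kabsch proper rotation R (y ~ R x) for centered matrices
static arma::mat kabsch_rotation(const arma::mat& Xc, const arma::mat& Yc,
                                 arma::vec* sing = nullptr, double* dsign = nullptr) {
  arma::mat S = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, S);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  if (sing) *sing = s;
  if (dsign) *dsign = d;
  return V * D * U.t();
}

static double cv_value(const arma::mat& X, const CvDef& c) {
  switch (c.kind) {
    case 1: {  // com_distance
      arma::rowvec ca = arma::mean(X.rows(c.ia), 0);
      arma::rowvec cb = arma::mean(X.rows(c.ib), 0);
      return arma::norm(ca - cb);
    }
    case 2: {  // radius of gyration
      arma::mat Yc = centered(X.rows(c.ia));
      return std::sqrt(arma::accu(Yc % Yc) / Yc.n_rows);
    }
    case 3:  // orientation angle vs reference
      return orientation_angle_group(X.rows(c.ia), c.ref);
    case 4: {  // rmsd after superposition on its own group
      arma::mat Yc = centered(X.rows(c.ia));
      arma::mat Xc = centered(c.ref);
      arma::vec s;
      double d;
      kabsch_rotation(Xc, Yc, &s, &d);
      double msd = (arma::accu(Xc % Xc) + arma::accu(Yc % Yc) -
                    2.0 * (s(0) + s(1) + d * s(2))) / Yc.n_rows;
      return msd > 0 ? std::sqrt(msd) : 0.0;
    }
  }
  stop("unknown CV kind code");
}

// gradient of the CV with respect to all coordinates (N x 3); analytic for
// com_distance / rg / rmsd, central finite differences (h = 1e-5) through the
// quaternion eigenproblem for the orientation angle
static arma::mat cv_gradient(const arma::mat& X, const CvDef& c) {
  arma::mat G(X.n_rows, 3, arma::fill::zeros);
  switch (c.kind) {
    case 1: {
      arma::rowvec ca = arma::mean(X.rows(c.ia), 0);
      arma::rowvec cb = arma::mean(X.rows(c.ib), 0);
      arma::rowvec d = ca - cb;
      double r = arma::norm(d);
      if (r < 1e-12) return G;
      arma::rowvec u = d / r;
      for (arma::uword t = 0; t < c.ia.n_elem; ++t) G.row(c.ia(t)) += u / c.ia.n_elem;
      for (arma::uword t = 0; t < c.ib.n_elem; ++t) G.row(c.ib(t)) -= u / c.ib.n_elem;
      return G;
    }
    case 2: {
      arma::mat Y = X.rows(c.ia);
      arma::mat Yc = centered(Y);
      double rg = std::sqrt(arma::accu(Yc % Yc) / Yc.n_rows);
      if (rg < 1e-12) return G;
      for (arma::uword t = 0; t < c.ia.n_elem; ++t)
        G.row(c.ia(t)) = Yc.row(t) / (c.ia.n_elem * rg);
      return G;
    }
    case 3: {
      // analytic gradient through the eigenproblem: first-order eigenvector
      // perturbation dq = sum_{j != max} q_j (q_j^T dK q_max)/(l_max - l_j),
      // with dK assembled from dS = xc_i e_d^T (the centering term vanishes
      // because the centered reference sums to zero)
      arma::mat Yc = centered(X.rows(c.ia)), Xc = centered(c.ref);
      arma::mat K = key_matrix(Xc.t() * Yc);
      arma::vec eigval;
      arma::mat eigvec;
      arma::eig_sym(eigval, eigvec, K);
      arma::vec q = eigvec.col(3);
      double w = q(0);
      double s2 = 1.0 - w * w;
      if (s2 < 1e-14) return G;  // at 0 or 180 degrees the angle is non-smooth
      double pref = -2.0 * RAD2DEG * (w >= 0 ? 1.0 : -1.0) / std::sqrt(s2);
      arma::rowvec resp(4, arma::fill::zeros);  // row 0 of the response map
      for (int j = 0; j < 3; ++j) {
        double gap = eigval(3) - eigval(j);
        if (gap < 1e-9) gap = 1e-9;
        resp += (eigvec(0, j) / gap) * eigvec.col(j).t();
      }
      arma::mat dS(3, 3);
      for (arma::uword t = 0; t < c.ia.n_elem; ++t) {
        for (int dd = 0; dd < 3; ++dd) {
          dS.zeros();
          dS(0, dd) = Xc(t, 0);
          dS(1, dd) = Xc(t, 1);
          dS(2, dd) = Xc(t, 2);
          arma::vec u = key_matrix(dS) * q;
          G(c.ia(t), dd) = pref * arma::dot(resp, u);
        }
      }
      return G;
    }
    case 4: {
      arma::mat Yc = centered(X.rows(c.ia));
      arma::mat Xc = centered(c.ref);
      arma::mat R = kabsch_rotation(Xc, Yc);
      arma::mat fitted = Xc * R.t();  // rows: R x_i
      arma::mat resid = Yc - fitted;
      double rmsd = std::sqrt(arma::accu(resid % resid) / Yc.n_rows);
      if (rmsd < 1e-10) return G;
      for (arma::uword t = 0; t < c.ia.n_elem; ++t)
        G.row(c.ia(t)) = resid.row(t) / (c.ia.n_elem * rmsd);
      return G;
    }
  }
  stop("unknown CV kind code");
}

// [[Rcpp::export]]
double cg_cv_value(NumericMatrix coords, List cvdef) {
  return cv_value(as<arma::mat>(coords), parse_cv(cvdef));
}

// [[Rcpp::export]]
NumericMatrix cg_cv_gradient(NumericMatrix coords, List cvdef) {
  return wrap(cv_gradient(as<arma::mat>(coords), parse_cv(cvdef)));
}

// ---------------------------------------------------------------------------
// overdamped Langevin integrator with optional moving harmonic bias
// ---------------------------------------------------------------------------

// Work bookkeeping: at every steering step the bias centers move from c(t) to
// c(t+1) and the work increment is U_bias(x_t, c(t+1)) - U_bias(x_t, c(t)),
// an identity that is exact for stepwise schedules. Hold steps keep the bias
// at the final centers and add no work; relax steps run with the bias off.
// [[Rcpp::export]]
List cg_run(NumericMatrix coords0, List enm, List cvdefs,
            NumericVector c_start, NumericVector c_end, NumericVector k_cv,
            int steer_steps, int hold_steps, int relax_steps,
            double dt, double friction, double kT,
            int save_stride, double abort_energy) {
  arma::mat X = as<arma::mat>(coords0);
  const arma::uword N = X.n_rows;
  Enm em = parse_enm(enm);
  const int ncv = cvdefs.size();
  std::vector<CvDef> cvs(ncv);
  for (int q = 0; q < ncv; ++q) cvs[q] = parse_cv(cvdefs[q]);
  arma::vec cs = as<arma::vec>(c_start), ce = as<arma::vec>(c_end),
            kk = as<arma::vec>(k_cv);

  const int T = steer_steps + hold_steps + relax_steps;
  const int T_bias = steer_steps + hold_steps;
  if (T < 1) stop("total number of steps must be >= 1");
  const double mob = dt / friction;
  const double sigma = std::sqrt(2.0 * kT * dt / friction);

  // bias-center schedule, c(t) for t = 0..T (linear, then held)
  arma::mat centers(T + 1, std::max(ncv, 1), arma::fill::zeros);
  if (ncv > 0) {
    for (int t = 0; t <= T; ++t) {
      double f = steer_steps > 0 ? std::min(1.0, (double)t / steer_steps) : 1.0;
      centers.row(t) = (cs + f * (ce - cs)).t();
    }
  }

  int nsave = 1 + T / std::max(save_stride, 1);
  arma::cube frames(N, 3, nsave + 2, arma::fill::zeros);
  std::vector<int> frame_steps;
  arma::vec energy_saved(nsave + 2, arma::fill::zeros);
  int fi = 0;
  frames.slice(fi) = X;
  frame_steps.push_back(0);
  energy_saved(fi) = model_energy(X, em, nullptr).total;
  ++fi;

  arma::vec cumw(T + 1, arma::fill::zeros);
  arma::mat cvser(T + 1, std::max(ncv, 1), arma::fill::zeros);
  double W = 0.0;
  arma::mat G(N, 3), noise(N, 3);

  for (int t = 0; t < T; ++t) {
    EnergyTerms et = model_energy(X, em, &G);
    arma::mat F = -G;
    double ubias = 0.0;
    if (ncv > 0 && t < T_bias) {
      arma::vec v(ncv);
      for (int q = 0; q < ncv; ++q) v(q) = cv_value(X, cvs[q]);
      cvser.row(t) = v.t();
      // work increment at the center update, then force at the new centers
      const arma::rowvec c0 = centers.row(t), c1 = centers.row(t + 1);
      if (t < steer_steps) {
        for (int q = 0; q < ncv; ++q) {
          double d1 = v(q) - c1(q), d0 = v(q) - c0(q);
          W += 0.5 * kk(q) * (d1 * d1 - d0 * d0);
        }
      }
      for (int q = 0; q < ncv; ++q) {
        double dev = v(q) - c1(q);
        ubias += 0.5 * kk(q) * dev * dev;
        if (kk(q) != 0.0) F -= (kk(q) * dev) * cv_gradient(X, cvs[q]);
      }
    }
    cumw(t + 1) = W;

    double vtot = et.total + ubias;
    if (!std::isfinite(vtot) || vtot > abort_energy)
      stop("energy divergence at step %d (V = %g)", t, vtot);

    for (arma::uword i = 0; i < N; ++i)
      for (int dd = 0; dd < 3; ++dd) noise(i, dd) = R::norm_rand();
    X += mob * F + sigma * noise;

    if (((t + 1) % std::max(save_stride, 1) == 0) || t == T - 1) {
      if (fi < (int)frames.n_slices) {
        frames.slice(fi) = X;
        frame_steps.push_back(t + 1);
        energy_saved(fi) = model_energy(X, em, nullptr).total;
        ++fi;
      }
    }
  }
  if (ncv > 0) {
    arma::vec vf(ncv);
    for (int q = 0; q < ncv; ++q) vf(q) = cv_value(X, cvs[q]);
    cvser.row(T) = vf.t();
  }

  frames.resize(N, 3, fi);
  energy_saved.resize(fi);
  return List::create(
      _["frames"] = frames, _["frame_steps"] = wrap(frame_steps),
      _["work"] = cumw, _["cv_series"] = cvser, _["centers"] = centers,
      _["energy"] = energy_saved, _["final_coords"] = X);
}
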