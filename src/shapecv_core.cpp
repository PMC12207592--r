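#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Rotation matrix from a unit quaternion (q0, q1, q2, q3), acting on row
// vectors from the right via y * R^T (see optrot for the convention used).
static arma::mat33 quat_to_rot(const arma::vec4& q) {
  const double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  arma::mat33 R;
  R(0,0) = q0*q0+q1*q1-q2*q2-q3*q3; R(0,1) = 2*(q1*q2-q0*q3); R(0,2) = 2*(q1*q3+q0*q2);
  R(1,0) = 2*(q1*q2+q0*q3); R(1,1) = q0*q0-q1*q1+q2*q2-q3*q3; R(1,2) = 2*(q2*q3-q0*q1);
  R(2,0) = 2*(q1*q3-q0*q2); R(2,1) = 2*(q2*q3+q0*q1); R(2,2) = q0*q0-q1*q1-q2*q2+q3*q3;
  return R;
}

// Davenport 4x4 matrix: q' K(M) q == tr(R(q) M) for any unit quaternion q.
static arma::mat44 kmat(const arma::mat33& M) {
  const double tr = M(0,0) + M(1,1) + M(2,2);
  arma::mat44 K;
  K(0,0) = tr;
  K(0,1) = K(1,0) = M(1,2) - M(2,1);
  K(0,2) = K(2,0) = M(2,0) - M(0,2);
  K(0,3) = K(3,0) = M(0,1) - M(1,0);
  K(1,1) = 2*M(0,0) - tr;
  K(2,2) = 2*M(1,1) - tr;
  K(3,3) = 2*M(2,2) - tr;
  K(1,2) = K(2,1) = M(0,1) + M(1,0);
  K(1,3) = K(3,1) = M(0,2) + M(2,0);
  K(2,3) = K(3,2) = M(1,2) + M(2,1);
  return K;
}

// dR(q)/dq_m, m = 0..3
static arma::mat33 drot_dq(const arma::vec4& q, int m) {
  const double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  arma::mat33 J;
  switch (m) {
  case 0:
    J = { { q0, -q3,  q2}, { q3,  q0, -q1}, {-q2,  q1,  q0} }; break;
  case 1:
    J = { { q1,  q2,  q3}, { q2, -q1, -q0}, { q3,  q0, -q1} }; break;
  case 2:
    J = { {-q2,  q1,  q0}, { q1,  q2,  q3}, {-q0,  q3, -q2} }; break;
  default:
    J = { {-q3, -q0,  q1}, { q0, -q3,  q2}, { q1,  q2,  q3} }; break;
  }
  return 2.0 * J;
}

// Optimal rotation Rhat such that aligned = y * Rhat minimizes
// tr((y R - mu)' P (y R - mu)) over SO(3).  Because tr(R' y' P y R) is
// R-independent for orthogonal R, this is the Procrustes problem of
// maximizing tr(R' M) with M = y' P mu; the maximizer over proper rotations
// is Rhat = R(q)' with q the leading eigenvector of K(M).
static arma::mat33 optrot_core(const arma::mat& y, const arma::mat& mu,
                               const arma::mat& P, arma::vec4& q_out,
                               arma::vec4& eval_out, arma::mat44& evec_out) {
  arma::mat33 M = y.t() * P * mu;
  // parameterize Rhat = R(q)': tr(Rhat' M) = tr(R(q) M) = q' K(M) q
  arma::mat44 K = kmat(M);
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, arma::mat(K));
  arma::vec4 q = evec.col(3);
  q_out = q;
  eval_out = eval;
  evec_out = evec;
  return quat_to_rot(q).t();
}

// [[Rcpp::export]]
arma::mat optimal_rotation_cpp(const arma::mat& y, const arma::mat& mu,
                               const arma::mat& P) {
  arma::vec4 q; arma::vec4 ev; arma::mat44 evc;
  return optrot_core(y, mu, P, q, ev, evc);
}

static arma::rowvec colmeans(const arma::mat& x) {
  return arma::mean(x, 0);
}

// Value and analytic gradient of the linear-discriminant coordinate
//   l(x) = sum( v . ( y Rhat - mu ) ),  y = x - 1 mean(x)'
// with Rhat the Mahalanobis-optimal rotation against (mu, P).  The gradient
// includes the dependence of Rhat on x via first-order perturbation of the
// leading eigenvector of the Davenport matrix.
static double ld_eval_core(const arma::mat& x, const arma::mat& v,
                           const arma::mat& mu, const arma::mat& P,
                           bool align, bool want_grad, arma::mat& grad,
                           arma::mat33& rot_out) {
  const arma::uword N = x.n_rows;
  arma::mat y = x;
  y.each_row() -= colmeans(x);

  if (!align) {
    double l = arma::accu(v % (y - mu));
    if (want_grad) {
      grad = v;
      grad.each_row() -= colmeans(v);
    }
    rot_out.eye();
    return l;
  }

  // q' K(M) q = tr(R(q) M) = tr(Rhat' M) for Rhat = R(q)'
  arma::mat33 M = y.t() * P * mu;
  arma::mat44 K = kmat(M);
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, arma::mat(K));
  arma::vec4 q = evec.col(3);
  arma::mat33 R = quat_to_rot(q);      // Rhat = R'
  arma::mat33 Rhat = R.t();
  rot_out = Rhat;

  double l = arma::accu(v % (y * Rhat - mu));
  if (!want_grad) return l;

  // term 1: d l / d y at fixed R: <dy, v Rhat'> = <dy, v R>
  arma::mat G = v * R;

  // term 2: through the rotation.  g_m = <A, dR/dq_m>, A = v' y
  arma::mat33 A = v.t() * y;
  arma::vec4 g;
  for (int m = 0; m < 4; ++m) g(m) = arma::accu(A % drot_dq(q, m));

  // eigenvector perturbation: dq = sum_k u_k (u_k' dK q) / (l1 - l_k)
  // dl2 = <dK, Bs>, Bs = sym( sum_k c_k u_k q' ), c_k = (g . u_k)/(l1 - l_k)
  arma::mat44 B(arma::fill::zeros);
  const double l1 = eval(3);
  for (int k = 0; k < 3; ++k) {
    const double denom = l1 - eval(k);
    if (denom < 1e-12) continue;  // degenerate: drop (flagged upstream)
    arma::vec4 u = evec.col(k);
    const double ck = arma::dot(g, u) / denom;
    B += ck * (u * q.t());
  }
  arma::mat44 Bs = 0.5 * (B + B.t());

  // adjoint of M -> K(M') through 9 unit perturbations: Gm_ab = <K(E_ab'), Bs>
  arma::mat33 Gm;
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      arma::mat33 E(arma::fill::zeros);
      E(a, b) = 1.0;
      Gm(a, b) = arma::accu(kmat(E) % Bs);
    }
  }
  G += P * mu * Gm.t();

  // centering projection: y = (I - 11'/N) x
  G.each_row() -= colmeans(G);
  grad = G;
  (void)N;
  return l;
}

// [[Rcpp::export]]
List ld_eval_cpp(const arma::mat& x, const arma::mat& v, const arma::mat& mu,
                 const arma::mat& P, bool align, bool want_grad) {
  arma::mat grad;
  arma::mat33 rot;
  double l = ld_eval_core(x, v, mu, P, align, want_grad, grad, rot);
  if (want_grad)
    return List::create(_["value"] = l, _["grad"] = grad, _["rotation"] = rot);
  return List::create(_["value"] = l, _["rotation"] = rot);
}

// Batch alignment of M frames (R array M x N x 3, passed with its dim kept)
// to a fixed centered reference mu under precision P.  Returns the aligned
// array, per-frame squared Mahalanobis distance, rotations (3 x 3 x M) and
// removed translations.
// [[Rcpp::export]]
List align_frames_cpp(const NumericVector& coords, const arma::mat& mu,
                      const arma::mat& P) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  NumericVector out(coords.size());
  out.attr("dim") = dm;
  arma::vec maha(M);
  arma::cube rots(3, 3, M);
  arma::mat trans(M, 3);
  arma::mat y(N, 3);
  for (int i = 0; i < M; ++i) {
    for (int c = 0; c < 3; ++c)
      for (int n = 0; n < N; ++n)
        y(n, c) = coords[i + (long)M * (n + (long)N * c)];
    arma::rowvec t0 = arma::mean(y, 0);
    y.each_row() -= t0;
    arma::vec4 q; arma::vec4 ev; arma::mat44 evc;
    arma::mat33 R = optrot_core(y, mu, P, q, ev, evc);
    arma::mat a = y * R;
    arma::mat dev = a - mu;
    maha(i) = arma::accu(dev % (P * dev));
    rots.slice(i) = R;
    trans.row(i) = -t0 * R;
    for (int c = 0; c < 3; ++c)
      for (int n = 0; n < N; ++n)
        out[i + (long)M * (n + (long)N * c)] = a(n, c);
  }
  return List::create(_["aligned"] = out, _["mahalanobis"] = maha,
                      _["rotations"] = rots, _["translations"] = trans);
}

// Weighted Kronecker covariance factor of aligned frames about mu:
// (1/3) sum_i w_i (y_i - mu)(y_i - mu)' / sum_i w_i
// [[Rcpp::export]]
arma::mat weighted_cov_cpp(const NumericVector& coords, const arma::mat& mu,
                           const arma::vec& w) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  arma::mat S(N, N, arma::fill::zeros);
  arma::mat D(N, 3);
  double sw = 0.0;
  for (int i = 0; i < M; ++i) {
    if (w(i) == 0.0) continue;
    for (int c = 0; c < 3; ++c)
      for (int n = 0; n < N; ++n)
        D(n, c) = coords[i + (long)M * (n + (long)N * c)] - mu(n, c);
    S += w(i) * (D * D.t());
    sw += w(i);
  }
  return S / (3.0 * sw);
}

// Brute-force oracle: minimum of the Mahalanobis objective
// tr((yR - mu)' P (yR - mu)) over a ZYZ Euler-angle grid with the given
// step (degrees).  Evaluates the objective directly at every grid rotation;
// used only as an independent check of the closed-form rotation solvers.
// [[Rcpp::export]]
double euler_grid_min_cpp(const arma::mat& y, const arma::mat& mu,
                          const arma::mat& P, double step_deg) {
  const double step = step_deg * M_PI / 180.0;
  double best = arma::datum::inf;
  arma::mat Py = P * y;  // objective = accu((yR-mu) % (P yR - P mu))
  for (double a = 0.0; a < 2.0 * M_PI; a += step) {
    const double ca = std::cos(a), sa = std::sin(a);
    arma::mat33 Rz1 = { {ca, -sa, 0}, {sa, ca, 0}, {0, 0, 1} };
    for (double b = 0.0; b <= M_PI; b += step) {
      const double cb = std::cos(b), sb = std::sin(b);
      arma::mat33 Ry = { {cb, 0, sb}, {0, 1, 0}, {-sb, 0, cb} };
      arma::mat33 R1 = Rz1 * Ry;
      for (double c = 0.0; c < 2.0 * M_PI; c += step) {
        const double cc = std::cos(c), sc = std::sin(c);
        arma::mat33 Rz2 = { {cc, -sc, 0}, {sc, cc, 0}, {0, 0, 1} };
        arma::mat33 R = R1 * Rz2;
        arma::mat dev = y * R - mu;
        const double obj = arma::accu(dev % (P * dev));
        if (obj < best) best = obj;
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Bias bookkeeping shared by the engine

struct WTState {
  std::vector<double> center, height;
  double h0, sigma, dT;  // dT = (gamma - 1) * kT, energy units
  double eval(double s, double* dV) const {
    double V = 0.0, d = 0.0;
    const double s2 = sigma * sigma;
    for (size_t k = 0; k < center.size(); ++k) {
      const double x = s - center[k];
      const double e = height[k] * std::exp(-0.5 * x * x / s2);
      V += e;
      d += -e * x / s2;
    }
    if (dV) *dV = d;
    return V;
  }
  double deposit(double s) {
    const double h = h0 * std::exp(-eval(s, nullptr) / dT);
    center.push_back(s);
    height.push_back(h);
    return h;
  }
};

struct OPESState {
  std::vector<double> center, weight;  // weight = exp(V(center)/kT) at deposit
  double sigma, a, eps, kT, Z;         // a = kT (gamma-1)/gamma
  double prob(double s, double* dP) const {
    double p = 0.0, d = 0.0, sw = 0.0;
    const double s2 = sigma * sigma;
    const double nrm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
    for (size_t k = 0; k < center.size(); ++k) {
      const double x = s - center[k];
      const double g = weight[k] * nrm * std::exp(-0.5 * x * x / s2);
      p += g;
      d += -g * x / s2;
      sw += weight[k];
    }
    if (sw <= 0.0) sw = 1.0;
    if (dP) *dP = d / sw;
    return p / sw;
  }
  double eval(double s, double* dV) const {
    if (center.empty()) { if (dV) *dV = 0.0; return 0.0; }
    double dP;
    const double p = prob(s, &dP);
    const double arg = p / Z + eps;
    if (dV) *dV = a * (dP / Z) / arg;
    return a * std::log(arg);
  }
  void deposit(double s) {
    const double w = std::exp(eval(s, nullptr) / kT);  // V <= 0 so w <= 1
    center.push_back(s);
    weight.push_back(w);
    // Z: mean of the current probability estimate over kernel centers
    double z = 0.0;
    for (size_t k = 0; k < center.size(); ++k) z += prob(center[k], nullptr);
    Z = z / center.size();
    if (Z <= 0.0) Z = 1.0;
  }
};

static double wall_eval(double s, double lower, double upper, double kappa,
                        double* dV) {
  double V = 0.0, d = 0.0;
  if (kappa > 0.0) {
    if (s > upper) { const double x = s - upper; V = kappa * x * x; d = 2.0 * kappa * x; }
    else if (s < lower) { const double x = s - lower; V = kappa * x * x; d = 2.0 * kappa * x; }
  }
  if (dV) *dV = d;
  return V;
}

// ---------------------------------------------------------------------------
// Overdamped Langevin engine on a Gaussian-mixture potential
//   U(x) = -kT log sum_j phi_j N(x | mu_j, Sigma_Nj kron I3)
// optionally biased along a linear-discriminant coordinate with WT-MetaD (1)
// or OPES (2) deposits every `pace` steps, plus quadratic walls.
//
// means/precs: lists of N x 3 and N x N matrices; logdet: log det Sigma_Nj.
// Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List run_langevin_cpp(const arma::mat& x0, const List& means, const List& precs,
                      const arma::vec& logdet, const arma::vec& phi, double kT,
                      double friction, double dt, int steps, int save_every,
                      bool use_cv, const arma::mat& cv_v, const arma::mat& cv_mu,
                      const arma::mat& cv_prec, bool cv_align, int bias_scheme,
                      double h0, double hill_sigma, double gamma_bias, int pace,
                      double deltaE, double wall_lower, double wall_upper,
                      double wall_kappa, double bound, double kT_noise,
                      const arma::vec& init_centers,
                      const arma::vec& init_heights) {
  const int K = means.size();
  std::vector<arma::mat> mu(K), P(K);
  for (int j = 0; j < K; ++j) {
    mu[j] = as<arma::mat>(means[j]);
    P[j] = as<arma::mat>(precs[j]);
  }
  const arma::uword N = x0.n_rows;
  arma::vec logphi = arma::log(phi);

  WTState wt;
  wt.h0 = h0; wt.sigma = hill_sigma; wt.dT = (gamma_bias - 1.0) * kT;
  OPESState op;
  op.sigma = hill_sigma; op.kT = kT; op.a = kT * (gamma_bias - 1.0) / gamma_bias;
  op.eps = std::exp(-deltaE / op.a); op.Z = 1.0;

  // resume from an existing bias state (deposit history carried over)
  for (arma::uword k = 0; k < init_centers.n_elem; ++k) {
    if (bias_scheme == 1) {
      wt.center.push_back(init_centers(k));
      wt.height.push_back(init_heights(k));
    } else if (bias_scheme == 2) {
      op.center.push_back(init_centers(k));
      op.weight.push_back(init_heights(k));
    }
  }
  if (bias_scheme == 2 && !op.center.empty()) {
    double z = 0.0;
    for (size_t k = 0; k < op.center.size(); ++k)
      z += op.prob(op.center[k], nullptr);
    op.Z = z / op.center.size();
    if (op.Z <= 0.0) op.Z = 1.0;
  }

  const int nsave = steps / save_every;
  arma::cube frames(N, 3, nsave);
  arma::vec cv_out(nsave, arma::fill::zeros);
  arma::vec bias_out(nsave, arma::fill::zeros);
  std::vector<double> dep_step, dep_center, dep_height;

  arma::mat x = x0;
  const double amp = std::sqrt(2.0 * kT_noise * dt / friction);
  const double mob = dt / friction;
  int isave = 0;
  // Leimkuhler-Matthews noise averaging: using (eta_n + eta_{n+1})/2 gives
  // second-order accuracy in the sampled stationary distribution at the
  // cost of one stored noise matrix.
  arma::mat noise_prev(N, 3);
  for (arma::uword i = 0; i < N; ++i)
    for (int d3 = 0; d3 < 3; ++d3) noise_prev(i, d3) = R::norm_rand();

  for (int t = 1; t <= steps; ++t) {
    // mixture potential gradient: kT sum_j q_j P_j (x - mu_j)
    arma::vec logw(K);
    std::vector<arma::mat> dev(K);
    for (int j = 0; j < K; ++j) {
      dev[j] = x - mu[j];
      const double quad = arma::accu(dev[j] % (P[j] * dev[j]));
      logw(j) = logphi(j) - 0.5 * quad - 1.5 * logdet(j);
    }
    const double m = logw.max();
    arma::vec w = arma::exp(logw - m);
    w /= arma::accu(w);
    arma::mat force(N, 3, arma::fill::zeros);
    for (int j = 0; j < K; ++j) force -= kT * w(j) * (P[j] * dev[j]);

    double s = 0.0, Vtot = 0.0;
    if (use_cv) {
      arma::mat grad;
      arma::mat33 rot;
      s = ld_eval_core(x, cv_v, cv_mu, cv_prec, cv_align, true, grad, rot);
      double dV = 0.0, dVb = 0.0, dVw = 0.0;
      double Vb = 0.0;
      if (bias_scheme == 1) Vb = wt.eval(s, &dVb);
      else if (bias_scheme == 2) Vb = op.eval(s, &dVb);
      const double Vw = wall_eval(s, wall_lower, wall_upper, wall_kappa, &dVw);
      Vtot = Vb + Vw;
      dV = dVb + dVw;
      force -= dV * grad;

      if (bias_scheme == 1 && t % pace == 0) {
        const double h = wt.deposit(s);
        dep_step.push_back(t); dep_center.push_back(s); dep_height.push_back(h);
      } else if (bias_scheme == 2 && t % pace == 0) {
        op.deposit(s);
        dep_step.push_back(t); dep_center.push_back(s);
        dep_height.push_back(op.weight.back());
      }
    }

    for (arma::uword i = 0; i < N; ++i) {
      for (int d3 = 0; d3 < 3; ++d3) {
        const double eta = R::norm_rand();
        x(i, d3) += mob * force(i, d3) +
          amp * 0.5 * (noise_prev(i, d3) + eta);
        noise_prev(i, d3) = eta;
      }
    }

    if (!x.is_finite() || arma::abs(x).max() > bound)
      stop("Langevin integration blew up at step %d (|x| beyond %g)", t, bound);

    if (t % save_every == 0 && isave < nsave) {
      frames.slice(isave) = x;
      if (use_cv) {
        arma::mat g; arma::mat33 rot;
        s = ld_eval_core(x, cv_v, cv_mu, cv_prec, cv_align, false, g, rot);
        double Vb = 0.0;
        if (bias_scheme == 1) Vb = wt.eval(s, nullptr);
        else if (bias_scheme == 2) Vb = op.eval(s, nullptr);
        Vtot = Vb + wall_eval(s, wall_lower, wall_upper, wall_kappa, nullptr);
        cv_out(isave) = s;
        bias_out(isave) = Vtot;
      }
      ++isave;
    }
  }

  const size_t nd = dep_step.size();
  arma::mat deposits(nd, 4);
  for (size_t k = 0; k < nd; ++k) {
    deposits(k, 0) = dep_step[k];
    deposits(k, 1) = dep_center[k];
    deposits(k, 2) = dep_height[k];
    deposits(k, 3) = hill_sigma;
  }
  List out = List::create(
    _["frames"] = frames, _["cv"] = cv_out, _["bias"] = bias_out,
    _["deposits"] = deposits, _["final"] = x,
    _["opes_Z"] = op.Z, _["opes_eps"] = op.eps);
  return out;
}
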