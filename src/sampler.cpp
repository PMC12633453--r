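// Gibbs sampler core for spatial negative binomial regression with
// global-local shrinkage priors.
//
// Model: y_i ~ NB(psi_i, r), psi_i = logistic(eta_i), eta = X beta + phi + offset,
// phi ~ ICAR(nu Q + eps I) with sum-to-zero constraint per graph component.
// Polya-Gamma augmentation renders every beta/phi conditional Gaussian:
// omega_i ~ PG(y_i + r, eta_i), kappa_i = (y_i - r)/2, and the conditional
// log-likelihood in eta is kappa' eta - eta' Omega eta / 2.
//
// Half-Cauchy scales are sampled through the inverse-gamma parameter
// expansion: x ~ C+(0,1) iff x^2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1), giving
// inverse-gamma full conditionals throughout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "polyagamma.h"
using namespace Rcpp;

// family codes
enum Family { FAM_NORMAL = 0, FAM_HS = 1, FAM_SS = 2, FAM_GHS = 3, FAM_GSS = 4 };

static inline double rinvgamma(double shape, double rate) {
  // density prop. to x^{-shape-1} exp(-rate/x)
  double g = R::rgamma(shape, 1.0);
  if (g <= 0.0) g = DBL_MIN;
  return rate / g;
}

static inline double softplus(double x) {
  return (x > 30.0) ? x : std::log1p(std::exp(x));
}

// draw from N(P^{-1} rhs, P^{-1})
static arma::vec mvn_prec(const arma::mat& P, const arma::vec& rhs) {
  arma::mat R;
  if (!arma::chol(R, P))
    stop("Cholesky factorization failed: conditional precision not positive definite "
         "(dimension %d, max diag %g)", (int)P.n_rows, P.diag().max());
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), rhs));
  arma::vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

static void shuffle_order(arma::uvec& idx) {
  // Fisher-Yates using R's RNG for reproducibility
  for (int i = (int)idx.n_elem - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx(i), idx(j));
  }
}

static int crt_one(int y, double r) {
  // Chinese-restaurant-table count: sum_{t=1}^{y} Bernoulli(r / (r + t - 1)).
  // The first CRT_EXACT seatings are drawn exactly; beyond that the
  // occupation probabilities are tiny and the remaining sum is Poisson with
  // mean r * (digamma(r + y) - digamma(r + m)), which bounds the cost for
  // the huge counts heavy-tailed NB designs produce.
  const int CRT_EXACT = 1000;
  int m = std::min(y, CRT_EXACT);
  int l = 0;
  for (int t = 1; t <= m; ++t)
    if (unif_rand() < r / (r + t - 1.0)) ++l;
  if (y > m) {
    double tailMean = r * (R::digamma(r + y) - R::digamma(r + m));
    l += (int)R::rpois(tailMean);
  }
  return l;
}

struct Hyper {
  double a_omega, b_omega, a_slab, b_slab, a_nu, b_nu, a_r, b_r;
  double v_intercept, v_normal, nugget;
  double fix_omega, fix_slab, fix_zeta, fix_nu;
  arma::vec fix_tau;  // empty = free
};

static double list_num(const List& h, const char* name, double def) {
  if (!h.containsElementNamed(name)) return def;
  return as<double>(h[name]);
}

static Hyper read_hyper(const List& h) {
  Hyper hy;
  hy.a_omega = list_num(h, "a_omega", 1.0);
  hy.b_omega = list_num(h, "b_omega", 1.0);
  hy.a_slab = list_num(h, "a_slab", 0.5);
  hy.b_slab = list_num(h, "b_slab", 0.5);
  hy.a_nu = list_num(h, "a_nu", 0.1);
  hy.b_nu = list_num(h, "b_nu", 0.1);
  hy.a_r = list_num(h, "a_r", 1.0);
  hy.b_r = list_num(h, "b_r", 1.0);
  hy.v_intercept = list_num(h, "v_intercept", 100.0);
  hy.v_normal = list_num(h, "v_normal", 100.0);
  hy.nugget = list_num(h, "nugget", 1e-8);
  hy.fix_omega = list_num(h, "fix_omega", NA_REAL);
  hy.fix_slab = list_num(h, "fix_slab", NA_REAL);
  hy.fix_zeta = list_num(h, "fix_zeta", NA_REAL);
  hy.fix_nu = list_num(h, "fix_nu", NA_REAL);
  if (h.containsElementNamed("fix_tau") && !Rf_isNull(h["fix_tau"]))
    hy.fix_tau = as<arma::vec>(h["fix_tau"]);
  return hy;
}

struct State {
  arma::vec beta;            // length p (intercept first)
  arma::ivec delta;          // length m = p - 1 (SS families; all 1 otherwise)
  arma::vec lambda2, aux_l;  // per-feature local scales (HS families)
  double tau2, aux_t;        // HS global scale
  arma::vec tau2g, aux_tg;   // per-group scales (grouped families)
  double zeta2, aux_z;       // global-global scale (grouped families)
  double sigma2_slab;        // SS slab variance
  double omega;              // SS inclusion fraction
  arma::vec wg;              // grouped-SS inclusion fractions
  arma::vec phi;             // spatial field
  double nu, r;
};

static State init_state(int p, int n, int G, int family, const Hyper& hy, double r_init) {
  State s;
  int m = p - 1;
  s.beta = arma::zeros(p);
  s.delta.set_size(std::max(m, 0));
  for (int j = 0; j < m; ++j) s.delta(j) = (unif_rand() < 0.5) ? 1 : 0;
  if (family == FAM_NORMAL || family == FAM_HS || family == FAM_GHS)
    s.delta.fill(1);
  s.lambda2 = arma::ones(std::max(m, 0));
  s.aux_l = arma::ones(std::max(m, 0));
  s.tau2 = 1.0; s.aux_t = 1.0;
  s.tau2g = arma::ones(std::max(G, 0));
  s.aux_tg = arma::ones(std::max(G, 0));
  s.zeta2 = 1.0; s.aux_z = 1.0;
  s.sigma2_slab = 1.0;
  s.omega = 0.5;
  s.wg = arma::vec(std::max(G, 0), arma::fill::value(0.5));
  s.phi = arma::zeros(n);
  s.nu = 1.0;
  s.r = r_init;
  if (R_finite(hy.fix_omega)) {
    s.omega = hy.fix_omega;
    s.wg.fill(hy.fix_omega);
  }
  if (R_finite(hy.fix_slab)) s.sigma2_slab = hy.fix_slab;
  if (R_finite(hy.fix_zeta)) s.zeta2 = hy.fix_zeta * hy.fix_zeta;
  if (hy.fix_tau.n_elem > 0) s.tau2g = arma::square(hy.fix_tau);
  if (R_finite(hy.fix_nu)) s.nu = hy.fix_nu;
  return s;
}

static List state_to_list(const State& s) {
  return List::create(
      _["beta"] = s.beta, _["delta"] = s.delta, _["lambda2"] = s.lambda2,
      _["aux_l"] = s.aux_l, _["tau2"] = s.tau2, _["aux_t"] = s.aux_t,
      _["tau2g"] = s.tau2g, _["aux_tg"] = s.aux_tg, _["zeta2"] = s.zeta2,
      _["aux_z"] = s.aux_z, _["sigma2_slab"] = s.sigma2_slab,
      _["omega"] = s.omega, _["wg"] = s.wg, _["phi"] = s.phi,
      _["nu"] = s.nu, _["r"] = s.r);
}

static State state_from_list(const List& l) {
  State s;
  s.beta = as<arma::vec>(l["beta"]);
  s.delta = as<arma::ivec>(l["delta"]);
  s.lambda2 = as<arma::vec>(l["lambda2"]);
  s.aux_l = as<arma::vec>(l["aux_l"]);
  s.tau2 = as<double>(l["tau2"]);
  s.aux_t = as<double>(l["aux_t"]);
  s.tau2g = as<arma::vec>(l["tau2g"]);
  s.aux_tg = as<arma::vec>(l["aux_tg"]);
  s.zeta2 = as<double>(l["zeta2"]);
  s.aux_z = as<double>(l["aux_z"]);
  s.sigma2_slab = as<double>(l["sigma2_slab"]);
  s.omega = as<double>(l["omega"]);
  s.wg = as<arma::vec>(l["wg"]);
  s.phi = as<arma::vec>(l["phi"]);
  s.nu = as<double>(l["nu"]);
  s.r = as<double>(l["r"]);
  return s;
}

// marginal Gaussian prior variance each non-intercept coefficient sees
static arma::vec prior_variance_vec(const State& s, int family,
                                    const arma::ivec& group, const arma::ivec& gsize,
                                    const Hyper& hy) {
  int m = (int)s.lambda2.n_elem;
  arma::vec v(m);
  for (int j = 0; j < m; ++j) {
    switch (family) {
      case FAM_NORMAL: v(j) = hy.v_normal; break;
      case FAM_HS: v(j) = s.tau2 * s.lambda2(j); break;
      case FAM_SS: v(j) = s.sigma2_slab; break;
      case FAM_GHS: {
        int g = group(j);
        double l2 = (gsize(g) == 1) ? 1.0 : s.lambda2(j);
        v(j) = s.zeta2 * s.tau2g(g) * l2;
        break;
      }
      case FAM_GSS: {
        int g = group(j);
        double t2 = (gsize(g) == 1) ? 1.0 : s.tau2g(g);
        v(j) = s.zeta2 * t2;
        break;
      }
      default: stop("unknown prior family code %d", family);
    }
  }
  return v;
}

// ---- shrinkage-scale updates (shared by sampler and prior-only chain) ----

static void update_hs_scales(const arma::vec& bfeat, State& s) {
  int m = (int)bfeat.n_elem;
  for (int j = 0; j < m; ++j) {
    s.lambda2(j) = rinvgamma(1.0, 1.0 / s.aux_l(j) + bfeat(j) * bfeat(j) / (2.0 * s.tau2));
    s.aux_l(j) = rinvgamma(1.0, 1.0 + 1.0 / s.lambda2(j));
  }
  double q = 0.0;
  for (int j = 0; j < m; ++j) q += bfeat(j) * bfeat(j) / s.lambda2(j);
  s.tau2 = rinvgamma(0.5 * (m + 1.0), 1.0 / s.aux_t + 0.5 * q);
  s.aux_t = rinvgamma(1.0, 1.0 + 1.0 / s.tau2);
}

static void update_ghs_scales(const arma::vec& bfeat, const arma::ivec& group,
                              const arma::ivec& gsize, State& s) {
  int m = (int)bfeat.n_elem, G = (int)gsize.n_elem;
  // local-local scales; singleton groups pin lambda = 1
  for (int j = 0; j < m; ++j) {
    int g = group(j);
    if (gsize(g) == 1) { s.lambda2(j) = 1.0; continue; }
    s.lambda2(j) = rinvgamma(
        1.0, 1.0 / s.aux_l(j) + bfeat(j) * bfeat(j) / (2.0 * s.zeta2 * s.tau2g(g)));
    s.aux_l(j) = rinvgamma(1.0, 1.0 + 1.0 / s.lambda2(j));
  }
  // group scales
  arma::vec qg = arma::zeros(G);
  for (int j = 0; j < m; ++j) qg(group(j)) += bfeat(j) * bfeat(j) / s.lambda2(j);
  for (int g = 0; g < G; ++g) {
    s.tau2g(g) = rinvgamma(0.5 * (gsize(g) + 1.0),
                           1.0 / s.aux_tg(g) + qg(g) / (2.0 * s.zeta2));
    s.aux_tg(g) = rinvgamma(1.0, 1.0 + 1.0 / s.tau2g(g));
  }
  // global-global scale
  double q = 0.0;
  for (int j = 0; j < m; ++j)
    q += bfeat(j) * bfeat(j) / (s.tau2g(group(j)) * s.lambda2(j));
  s.zeta2 = rinvgamma(0.5 * (m + 1.0), 1.0 / s.aux_z + 0.5 * q);
  s.aux_z = rinvgamma(1.0, 1.0 + 1.0 / s.zeta2);
}

// grouped-SS group/global scales use currently included coefficients only;
// a group with no included members falls back to its hyperprior conditional
static void update_gss_scales(const arma::vec& bfeat, const arma::ivec& delta,
                              const arma::ivec& group, const arma::ivec& gsize,
                              const Hyper& hy, State& s) {
  int m = (int)bfeat.n_elem, G = (int)gsize.n_elem;
  arma::vec qg = arma::zeros(G);
  arma::ivec ng = arma::zeros<arma::ivec>(G);
  for (int j = 0; j < m; ++j)
    if (delta(j) == 1) { qg(group(j)) += bfeat(j) * bfeat(j); ng(group(j)) += 1; }
  bool tau_fixed = hy.fix_tau.n_elem > 0;
  for (int g = 0; g < G; ++g) {
    if (gsize(g) == 1) { s.tau2g(g) = 1.0; continue; }  // singleton: drop the level
    if (tau_fixed) continue;
    s.tau2g(g) = rinvgamma(0.5 * (ng(g) + 1.0),
                           1.0 / s.aux_tg(g) + qg(g) / (2.0 * s.zeta2));
    s.aux_tg(g) = rinvgamma(1.0, 1.0 + 1.0 / s.tau2g(g));
  }
  if (!R_finite(hy.fix_zeta)) {
    double q = 0.0;
    int S = 0;
    for (int j = 0; j < m; ++j)
      if (delta(j) == 1) {
        int g = group(j);
        double t2 = (gsize(g) == 1) ? 1.0 : s.tau2g(g);
        q += bfeat(j) * bfeat(j) / t2;
        ++S;
      }
    s.zeta2 = rinvgamma(0.5 * (S + 1.0), 1.0 / s.aux_z + 0.5 * q);
    s.aux_z = rinvgamma(1.0, 1.0 + 1.0 / s.zeta2);
  }
}

// ---- Gaussian conditionals ----

// joint draw of the coefficients flagged in `include` (intercept position 0
// included by the caller); excluded positions are returned as exact zeros
static arma::vec draw_beta_joint(const arma::mat& X, const arma::vec& w,
                                 const arma::vec& kappa, const arma::vec& cvec,
                                 const arma::vec& prior_var,
                                 const arma::uvec& include) {
  arma::uvec idx = arma::find(include == 1);
  arma::vec beta = arma::zeros(X.n_cols);
  if (idx.n_elem == 0) return beta;
  arma::mat Xs = X.cols(idx);
  arma::mat P = Xs.t() * (Xs.each_col() % w);
  P.diag() += 1.0 / prior_var.elem(idx);
  arma::vec rhs = Xs.t() * (kappa - w % cvec);
  beta.elem(idx) = mvn_prec(P, rhs);
  return beta;
}

static arma::vec draw_phi(const arma::mat& Q, double nugget, double nu,
                          const arma::vec& w, const arma::vec& kappa,
                          const arma::vec& cvec, const arma::ivec& comp) {
  int n = (int)Q.n_rows;
  arma::mat P = nu * Q;
  P.diag() += nugget + 1e-12;  // keep strictly PD even with tiny omegas
  P.diag() += w;
  arma::vec phi = mvn_prec(P, kappa - w % cvec);
  // recentre to sum zero within each graph component
  int ncomp = comp.max() + 1;
  arma::vec msum = arma::zeros(ncomp);
  arma::vec mcnt = arma::zeros(ncomp);
  for (int i = 0; i < n; ++i) { msum(comp(i)) += phi(i); mcnt(comp(i)) += 1.0; }
  for (int i = 0; i < n; ++i) phi(i) -= msum(comp(i)) / mcnt(comp(i));
  return phi;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_sample_beta")]]
arma::vec cpp_sample_beta(const arma::mat& X, const arma::vec& omega,
                          const arma::vec& kappa, const arma::vec& cvec,
                          const arma::vec& prior_var, const arma::uvec& include) {
  return draw_beta_joint(X, omega, kappa, cvec, prior_var, include);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_sample_phi")]]
arma::vec cpp_sample_phi(const arma::mat& Q, double nugget, double nu,
                         const arma::vec& omega, const arma::vec& kappa,
                         const arma::vec& cvec, const arma::ivec& comp) {
  return draw_phi(Q, nugget, nu, omega, kappa, cvec, comp);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_crt")]]
IntegerVector cpp_crt(IntegerVector y, double r) {
  int n = y.size();
  IntegerVector l(n);
  for (int i = 0; i < n; ++i) {
    if (y[i] < 0) stop("counts must be nonnegative");
    l[i] = crt_one(y[i], r);
  }
  return l;
}

// collapsed spike-and-slab sweep over features in randomized order:
// delta_j from the odds with beta_j integrated out of the PG-Gaussian
// likelihood, then beta_j from its conditional (or exact zero)
static void ss_coordinate_sweep(const arma::mat& X, const arma::vec& w,
                                const arma::vec& kappa, arma::vec& eta,
                                State& s, int family, const arma::ivec& group,
                                const arma::ivec& gsize) {
  int m = (int)X.n_cols - 1;
  arma::uvec order(m);
  for (int j = 0; j < m; ++j) order(j) = j;
  shuffle_order(order);
  for (int k = 0; k < m; ++k) {
    int j = (int)order(k);
    double v, pinc;
    if (family == FAM_SS) {
      v = s.sigma2_slab;
      pinc = s.omega;
    } else {
      int g = group(j);
      double t2 = (gsize(g) == 1) ? 1.0 : s.tau2g(g);
      v = s.zeta2 * t2;
      pinc = s.wg(g);
    }
    arma::vec col = X.col(j + 1);
    double bold = s.beta(j + 1);
    double a = arma::dot(w, col % col);
    double b = arma::dot(col, kappa - w % (eta - col * bold));
    double bnew;
    int dnew;
    if (pinc <= 0.0) { dnew = 0; bnew = 0.0; }
    else if (pinc >= 1.0) { dnew = 1; bnew = NA_REAL; }
    else {
      double lodds = std::log(pinc / (1.0 - pinc))
          - 0.5 * std::log1p(a * v) + 0.5 * b * b / (a + 1.0 / v);
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      dnew = (unif_rand() < p1) ? 1 : 0;
      bnew = dnew ? NA_REAL : 0.0;
    }
    if (dnew == 1) {
      double prec = a + 1.0 / v;
      bnew = b / prec + norm_rand() / std::sqrt(prec);
    }
    s.delta(j) = dnew;
    if (bnew != bold) {
      eta += col * (bnew - bold);
      s.beta(j + 1) = bnew;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_run_sampler")]]
List cpp_run_sampler(const arma::ivec& y, const arma::mat& X, const arma::vec& offset,
                     const arma::mat& Q, const arma::ivec& comp, bool spatial,
                     int family, const arma::ivec& group, const arma::ivec& gsize,
                     List hyper, int n_iter, int n_burn, int thin,
                     bool update_r, double r_init, Nullable<List> init,
                     bool verbose) {
  const int n = (int)X.n_rows, p = (int)X.n_cols, m = p - 1;
  const int G = (int)gsize.n_elem;
  const Hyper hy = read_hyper(hyper);
  const bool is_ss = (family == FAM_SS || family == FAM_GSS);
  const int ncomp = spatial ? (comp.max() + 1) : 0;

  State s = init.isNotNull() ? state_from_list(List(init))
                             : init_state(p, n, G, family, hy, r_init);

  arma::vec yv = arma::conv_to<arma::vec>::from(y);
  int S = (n_iter - n_burn) / thin;
  if (S < 1) stop("no retained draws: n_iter %d, burn-in %d, thin %d", n_iter, n_burn, thin);

  arma::mat beta_draws(S, p);
  arma::imat delta_draws(is_ss ? S : 0, is_ss ? m : 0);
  arma::mat phi_draws(spatial ? S : 0, spatial ? n : 0);
  arma::vec r_tr(S), nu_tr(spatial ? S : 0);
  arma::vec tau2_tr(family == FAM_HS ? S : 0);
  arma::vec zeta2_tr((family == FAM_GHS || family == FAM_GSS) ? S : 0);
  arma::vec slab_tr(family == FAM_SS ? S : 0);
  arma::vec omega_tr(family == FAM_SS ? S : 0);
  arma::mat wg_tr(family == FAM_GSS ? S : 0, family == FAM_GSS ? G : 0);
  arma::mat tau2g_tr((family == FAM_GHS || family == FAM_GSS) ? S : 0,
                     (family == FAM_GHS || family == FAM_GSS) ? G : 0);

  arma::vec w(n), kappa(n);
  int stored = 0;

  for (int t = 1; t <= n_iter; ++t) {
    // recompute from the exact state so a resumed chain is bit-identical
    arma::vec eta = X * s.beta + s.phi + offset;
    if (!eta.is_finite())
      stop("non-finite linear predictor entering sweep %d", t);

    // 1. Polya-Gamma latents
    for (int i = 0; i < n; ++i) {
      w(i) = rpg_one(yv(i) + s.r, eta(i));
      kappa(i) = (yv(i) - s.r) / 2.0;
    }

    // 2. coefficients (+ indicators / slab for SS families)
    arma::vec cvec = s.phi + offset;
    if (is_ss) {
      ss_coordinate_sweep(X, w, kappa, eta, s, family, group, gsize);
      // joint refresh of intercept + included coefficients (better mixing
      // under multicollinearity; indicators unchanged)
      arma::uvec incl(p, arma::fill::zeros);
      incl(0) = 1;
      arma::vec pv(p);
      pv(0) = hy.v_intercept;
      for (int j = 0; j < m; ++j) {
        if (s.delta(j) == 1) incl(j + 1) = 1;
        double v;
        if (family == FAM_SS) v = s.sigma2_slab;
        else {
          int g = group(j);
          v = s.zeta2 * ((gsize(g) == 1) ? 1.0 : s.tau2g(g));
        }
        pv(j + 1) = v;
      }
      s.beta = draw_beta_joint(X, w, kappa, cvec, pv, incl);
      eta = X * s.beta + cvec;
      // inclusion fractions and slab variance
      if (family == FAM_SS) {
        int sd = (int)arma::accu(s.delta);
        if (!R_finite(hy.fix_omega))
          s.omega = R::rbeta(hy.a_omega + sd, hy.b_omega + m - sd);
        if (!R_finite(hy.fix_slab)) {
          double q = 0.0;
          for (int j = 0; j < m; ++j)
            if (s.delta(j) == 1) q += s.beta(j + 1) * s.beta(j + 1);
          s.sigma2_slab = rinvgamma(hy.a_slab + 0.5 * sd, hy.b_slab + 0.5 * q);
        }
      } else {
        if (!R_finite(hy.fix_omega)) {
          arma::ivec sg = arma::zeros<arma::ivec>(G);
          for (int j = 0; j < m; ++j) if (s.delta(j) == 1) sg(group(j)) += 1;
          for (int g = 0; g < G; ++g)
            s.wg(g) = R::rbeta(hy.a_omega + sg(g), hy.b_omega + gsize(g) - sg(g));
        }
        if (m > 0)
          update_gss_scales(s.beta.subvec(1, p - 1), s.delta, group, gsize, hy, s);
      }
    } else {
      arma::uvec incl(p, arma::fill::ones);
      arma::vec pv(p);
      pv(0) = hy.v_intercept;
      if (m > 0) pv.subvec(1, p - 1) = prior_variance_vec(s, family, group, gsize, hy);
      s.beta = draw_beta_joint(X, w, kappa, cvec, pv, incl);
      eta = X * s.beta + cvec;
      // 3. shrinkage scales
      if (m > 0) {
        if (family == FAM_HS) update_hs_scales(s.beta.subvec(1, p - 1), s);
        else if (family == FAM_GHS) update_ghs_scales(s.beta.subvec(1, p - 1), group, gsize, s);
      }
    }

    // 4-5. spatial field and its precision
    if (spatial) {
      arma::vec cns = eta - s.phi;  // non-spatial part of eta
      s.phi = draw_phi(Q, hy.nugget, s.nu, w, kappa, cns, comp);
      eta = cns + s.phi;
      if (!R_finite(hy.fix_nu)) {
        double quad = arma::as_scalar(s.phi.t() * Q * s.phi);
        s.nu = R::rgamma(hy.a_nu + 0.5 * (n - ncomp), 1.0 / (hy.b_nu + 0.5 * quad));
      }
    }

    // 6. dispersion via CRT-gamma augmentation
    if (update_r) {
      int l = 0;
      double rate = hy.b_r;
      for (int i = 0; i < n; ++i) {
        l += crt_one(y(i), s.r);
        rate += softplus(eta(i));
      }
      s.r = R::rgamma(hy.a_r + l, 1.0 / rate);
      if (s.r < 1e-8) s.r = 1e-8;
    }

    // store
    if (t > n_burn && (t - n_burn) % thin == 0 && stored < S) {
      beta_draws.row(stored) = s.beta.t();
      if (is_ss)
        delta_draws.row(stored) = arma::conv_to<arma::irowvec>::from(s.delta);
      if (spatial) {
        phi_draws.row(stored) = s.phi.t();
        nu_tr(stored) = s.nu;
      }
      r_tr(stored) = s.r;
      if (family == FAM_HS) tau2_tr(stored) = s.tau2;
      if (family == FAM_GHS || family == FAM_GSS) {
        zeta2_tr(stored) = s.zeta2;
        tau2g_tr.row(stored) = s.tau2g.t();
      }
      if (family == FAM_SS) {
        slab_tr(stored) = s.sigma2_slab;
        omega_tr(stored) = s.omega;
      }
      if (family == FAM_GSS) wg_tr.row(stored) = s.wg.t();
      ++stored;
    }

    if (t % 500 == 0) {
      checkUserInterrupt();
      if (verbose) Rcout << "sweep " << t << "/" << n_iter << "\n";
    }
  }

  return List::create(
      _["beta"] = beta_draws,
      _["delta"] = is_ss ? wrap(delta_draws) : R_NilValue,
      _["phi"] = spatial ? wrap(phi_draws) : R_NilValue,
      _["r"] = r_tr,
      _["nu"] = spatial ? wrap(nu_tr) : R_NilValue,
      _["tau2"] = family == FAM_HS ? wrap(tau2_tr) : R_NilValue,
      _["zeta2"] = (family == FAM_GHS || family == FAM_GSS) ? wrap(zeta2_tr) : R_NilValue,
      _["sigma2_slab"] = family == FAM_SS ? wrap(slab_tr) : R_NilValue,
      _["omega"] = family == FAM_SS ? wrap(omega_tr) : R_NilValue,
      _["wg"] = family == FAM_GSS ? wrap(wg_tr) : R_NilValue,
      _["tau2g"] = (family == FAM_GHS || family == FAM_GSS) ? wrap(tau2g_tr) : R_NilValue,
      _["state"] = state_to_list(s));
}

// likelihood-free Gibbs chain on the prior: alternates coefficient draws
// beta | scales with the same scale/indicator updates the sampler uses, so
// its stationary law is the joint prior of the chosen family
//' @noRd
// [[Rcpp::export(name = ".cpp_prior_chain")]]
List cpp_prior_chain(int family, int m, const arma::ivec& group,
                     const arma::ivec& gsize, List hyper, int n_sweeps, int thin) {
  const Hyper hy = read_hyper(hyper);
  const int G = (int)gsize.n_elem;
  State s = init_state(m + 1, 0, G, family, hy, 1.0);
  int S = n_sweeps / thin;
  arma::mat beta_draws(S, m);
  arma::imat delta_draws(S, m);
  arma::vec tau2_tr(S), zeta2_tr(S), lam2_tr(S), omega_tr(S), slab_tr(S);
  arma::mat tau2g_tr(S, std::max(G, 1));
  arma::mat wg_tr(S, std::max(G, 1));
  int stored = 0;

  for (int t = 1; t <= n_sweeps; ++t) {
    // indicators and coefficients from their conditional priors
    arma::vec v = prior_variance_vec(s, family, group, gsize, hy);
    arma::vec bfeat(m);
    for (int j = 0; j < m; ++j) {
      int d = 1;
      if (family == FAM_SS) d = (unif_rand() < s.omega) ? 1 : 0;
      else if (family == FAM_GSS) d = (unif_rand() < s.wg(group(j))) ? 1 : 0;
      s.delta(j) = d;
      bfeat(j) = d ? norm_rand() * std::sqrt(v(j)) : 0.0;
    }
    s.beta.subvec(1, m) = bfeat;
    // hyperparameters given (delta, beta)
    if (family == FAM_HS) update_hs_scales(bfeat, s);
    else if (family == FAM_GHS) update_ghs_scales(bfeat, group, gsize, s);
    else if (family == FAM_SS) {
      int sd = (int)arma::accu(s.delta);
      if (!R_finite(hy.fix_omega))
        s.omega = R::rbeta(hy.a_omega + sd, hy.b_omega + m - sd);
      if (!R_finite(hy.fix_slab)) {
        double q = arma::dot(bfeat, bfeat);
        s.sigma2_slab = rinvgamma(hy.a_slab + 0.5 * sd, hy.b_slab + 0.5 * q);
      }
    } else if (family == FAM_GSS) {
      if (!R_finite(hy.fix_omega)) {
        arma::ivec sg = arma::zeros<arma::ivec>(G);
        for (int j = 0; j < m; ++j) if (s.delta(j) == 1) sg(group(j)) += 1;
        for (int g = 0; g < G; ++g)
          s.wg(g) = R::rbeta(hy.a_omega + sg(g), hy.b_omega + gsize(g) - sg(g));
      }
      update_gss_scales(bfeat, s.delta, group, gsize, hy, s);
    }

    if (t % thin == 0 && stored < S) {
      beta_draws.row(stored) = bfeat.t();
      delta_draws.row(stored) = arma::conv_to<arma::irowvec>::from(s.delta);
      tau2_tr(stored) = s.tau2;
      zeta2_tr(stored) = s.zeta2;
      lam2_tr(stored) = m > 0 ? s.lambda2(0) : NA_REAL;
      omega_tr(stored) = s.omega;
      slab_tr(stored) = s.sigma2_slab;
      if (G > 0) {
        tau2g_tr.row(stored) = s.tau2g.t();
        wg_tr.row(stored) = s.wg.t();
      }
      ++stored;
    }
    if (t % 10000 == 0) checkUserInterrupt();
  }

  return List::create(
      _["beta"] = beta_draws, _["delta"] = delta_draws, _["tau2"] = tau2_tr,
      _["zeta2"] = zeta2_tr, _["lambda2_1"] = lam2_tr, _["omega"] = omega_tr,
      _["sigma2_slab"] = slab_tr, _["tau2g"] = tau2g_tr, _["wg"] = wg_tr);
}
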