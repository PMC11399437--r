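// Gradient-based posterior sampling for the package's three model classes:
//  - the hierarchical prospect-theory choice model (non-centered),
//  - hierarchical logistic regression with participant intercepts,
//  - hierarchical cumulative ordered-logit regression.
// All are sampled with a multinomial No-U-Turn sampler with dual-averaging
// step-size adaptation and diagonal mass-matrix estimation during warmup.
// Randomness comes from R's RNG so set.seed() controls reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <memory>

using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 18.0) return x + std::exp(-x);
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// ---------------------------------------------------------------------------
// model interface
// ---------------------------------------------------------------------------

struct Model {
  virtual int dim() const = 0;
  virtual double logp_grad(const std::vector<double>& th,
                           std::vector<double>& grad) const = 0;
  virtual ~Model() {}
};

// ---------------------------------------------------------------------------
// hierarchical prospect-theory model
//
// Unconstrained parameter layout (dim = 15 + 3N):
//   0: beta (group decision bias)
//   1-4: beta_j (contrast coefficients)
//   5: lambda_probit, 6: gamma_probit
//   7: alpha_raw (alpha = exp), 8: phi_probit (phi = Phi)
//   9: log sigma_beta, 10-11: logit sigma_lambda, logit sigma_gamma
//   12-14: y1-y3, tanh-parameterized canonical partial correlations of the
//          Cholesky factor of the displacement correlation matrix
//   15 + 3i + {0,1,2}: standard-normal displacement innovations z_i
// The density equals the centered specification (MVN displacements,
// LKJ(5) correlation prior, gamma(2,1) and truncated-N(0.5,0.13) scale
// priors) plus the exact transform jacobians.
// ---------------------------------------------------------------------------

struct PTModel : Model {
  int N;                       // participants
  int T;                       // trials
  std::vector<int> part;       // trial -> participant (0-based, sorted)
  std::vector<int> y;          // accept (0/1)
  std::vector<double> X;       // T x 4, row-major
  std::vector<int> off;        // T+1 outcome offsets
  std::vector<double> m;       // |rating| per non-ignored outcome
  std::vector<int> is_se;      // side effect?
  std::vector<int> has_p;      // probability inspected (Prelec) vs fixed 0.5
  std::vector<double> tneg;    // -log(p) (clamped), where has_p
  std::vector<double> log_m, log_tneg;  // precomputed logs
  std::vector<int> pstart;     // participant -> first trial index (N+1)
  double lkj_eta;

  explicit PTModel(const List& d) {
    N = as<int>(d["N"]);
    IntegerVector pr = d["part"], yy = d["y"], offv = d["off"],
      sev = d["is_se"], hpv = d["has_p"];
    NumericMatrix Xm = d["X"];
    NumericVector mv = d["m"], tv = d["tneg"];
    lkj_eta = d.containsElementNamed("lkj_eta") ? as<double>(d["lkj_eta"]) : 5.0;
    T = pr.size();
    part.assign(pr.begin(), pr.end());
    y.assign(yy.begin(), yy.end());
    off.assign(offv.begin(), offv.end());
    m.assign(mv.begin(), mv.end());
    is_se.assign(sev.begin(), sev.end());
    has_p.assign(hpv.begin(), hpv.end());
    tneg.assign(tv.begin(), tv.end());
    X.resize((size_t)T * 4);
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < 4; ++j) X[(size_t)t * 4 + j] = Xm(t, j);
    log_m.resize(m.size());
    log_tneg.resize(m.size());
    for (size_t o = 0; o < m.size(); ++o) {
      log_m[o] = std::log(m[o]);
      log_tneg[o] = has_p[o] ? std::log(tneg[o]) : 0.0;
    }
    pstart.assign(N + 1, 0);
    for (int t = 0; t < T; ++t) {
      if (part[t] < 0 || part[t] >= N) stop("participant index out of range");
      if (t > 0 && part[t] < part[t - 1]) stop("trials must be sorted by participant");
    }
    // offsets per participant
    for (int i = 0, t = 0; i <= N; ++i) {
      while (t < T && part[t] < i) ++t;
      pstart[i] = t;
    }
    pstart[N] = T;
  }

  int dim() const { return 15 + 3 * N; }

  double logp_grad(const std::vector<double>& th,
                   std::vector<double>& grad) const {
    const double LOG2PI = 1.8378770664093453;
    std::fill(grad.begin(), grad.end(), 0.0);
    const double beta = th[0];
    const double* bj = &th[1];
    const double lP = th[5], gP = th[6], araw = th[7], phP = th[8];
    const double usb = th[9], usl = th[10], usg = th[11];
    const double y1 = th[12], y2 = th[13], y3 = th[14];

    const double c1 = std::tanh(y1), c2 = std::tanh(y2), c3 = std::tanh(y3);
    const double s1sq = 1.0 - c1 * c1, s2sq = 1.0 - c2 * c2, s3sq = 1.0 - c3 * c3;
    const double s1 = std::sqrt(s1sq), s2 = std::sqrt(s2sq), s3 = std::sqrt(s3sq);
    const double L21 = c1, L22 = s1, L31 = c2, L32 = c3 * s2, L33 = s2 * s3;

    const double sb = std::exp(usb);
    const double sl = inv_logit(usl), sg = inv_logit(usg);
    const double alpha = std::exp(araw);
    const double phi = R::pnorm(phP, 0.0, 1.0, 1, 0);
    const double phid = R::dnorm(phP, 0.0, 1.0, 0);

    double lp = 0.0;

    // --- priors on group-level parameters (with transform jacobians) ---
    // standard normals: beta, beta_j, lambda_probit, gamma_probit, phi_probit
    {
      double ss = beta * beta + lP * lP + gP * gP + phP * phP;
      for (int j = 0; j < 4; ++j) ss += bj[j] * bj[j];
      lp += -0.5 * ss - 8.0 * 0.5 * LOG2PI;
      grad[0] += -beta;
      for (int j = 0; j < 4; ++j) grad[1 + j] += -bj[j];
      grad[5] += -lP; grad[6] += -gP; grad[8] += -phP;
    }
    // alpha_raw ~ N(0, 0.5)
    lp += -0.5 * araw * araw / 0.25 - 0.5 * LOG2PI - std::log(0.5);
    grad[7] += -araw / 0.25;
    // sigma_beta ~ gamma(2,1), sigma_beta = exp(usb), + jacobian
    lp += 2.0 * usb - sb;
    grad[9] += 2.0 - sb;
    // sigma_lambda, sigma_gamma ~ N(0.5, 0.13) truncated to (0,1), logit xf
    {
      const double sdl = 0.13;
      const double trunc_const = std::log(R::pnorm(1.0, 0.5, sdl, 1, 0) -
                                          R::pnorm(0.0, 0.5, sdl, 1, 0));
      const double svals[2] = { sl, sg };
      const int idx[2] = { 10, 11 };
      for (int k = 0; k < 2; ++k) {
        double s = svals[k];
        lp += R::dnorm(s, 0.5, sdl, 1) - trunc_const + std::log(s * (1.0 - s));
        grad[idx[k]] += -(s - 0.5) / (sdl * sdl) * s * (1.0 - s) + (1.0 - 2.0 * s);
      }
    }
    // LKJ(eta) on the correlation matrix + full transform jacobian:
    // (eta-1) log det R + log|dR/dy| collapses to the log-s terms below.
    {
      double a = 2.0 * (lkj_eta - 1.0) + 3.0;  // 11 at eta = 5
      double b = 2.0 * (lkj_eta - 1.0) + 2.0;  // 10 at eta = 5
      lp += 0.5 * a * std::log(s1sq) + 0.5 * a * std::log(s2sq) +
            0.5 * b * std::log(s3sq);
      grad[12] += -a * c1;
      grad[13] += -a * c2;
      grad[14] += -b * c3;
    }

    double gL21 = 0, gL22 = 0, gL31 = 0, gL32 = 0, gL33 = 0;

    // --- likelihood + z priors, per participant ---
    for (int i = 0; i < N; ++i) {
      const double z1 = th[15 + 3 * i], z2 = th[16 + 3 * i], z3 = th[17 + 3 * i];
      lp += -0.5 * (z1 * z1 + z2 * z2 + z3 * z3) - 1.5 * LOG2PI;
      grad[15 + 3 * i] += -z1;
      grad[16 + 3 * i] += -z2;
      grad[17 + 3 * i] += -z3;

      const double e1 = z1;
      const double e2 = L21 * z1 + L22 * z2;
      const double e3 = L31 * z1 + L32 * z2 + L33 * z3;
      const double beta_i = beta + sb * e1;
      const double ql = lP + sl * e2;
      const double qg = gP + sg * e3;
      const double lam = R::pnorm(ql, 0.0, 1.0, 1, 0);
      const double gam = R::pnorm(qg, 0.0, 1.0, 1, 0);
      const double dql = R::dnorm(ql, 0.0, 1.0, 0);
      const double dqg = R::dnorm(qg, 0.0, 1.0, 0);

      double Gb = 0, Gl = 0, Gg = 0;

      for (int t = pstart[i]; t < pstart[i + 1]; ++t) {
        double V = 0, dVdl = 0, dVdg = 0, dVda = 0;
        for (int o = off[t]; o < off[t + 1]; ++o) {
          const double ma = std::exp(alpha * log_m[o]);
          double w, dwdg = 0;
          if (has_p[o]) {
            const double tg = std::exp(gam * log_tneg[o]);
            w = std::exp(-tg);
            dwdg = -tg * log_tneg[o] * w;
          } else {
            w = 0.5;
          }
          const double mult = is_se[o] ? -lam : (1.0 - lam);
          const double c = mult * ma * w;
          V += c;
          dVdl += -ma * w;                       // d mult / d lambda = -1 both
          dVda += c * log_m[o];
          if (has_p[o]) dVdg += mult * ma * dwdg;
        }
        double eta = beta_i + phi * V;
        const double* xr = &X[(size_t)t * 4];
        for (int j = 0; j < 4; ++j) eta += xr[j] * bj[j];
        const double g = (double)y[t] - inv_logit(eta);
        lp += (y[t] ? eta : 0.0) - log1pexp_(eta);
        Gb += g;
        for (int j = 0; j < 4; ++j) grad[1 + j] += g * xr[j];
        grad[8] += g * V * phid;                 // phi_probit
        const double gV = g * phi;
        Gl += gV * dVdl;
        Gg += gV * dVdg;
        grad[7] += gV * dVda * alpha;            // alpha_raw
      }

      // flush participant-level chain rules
      grad[0] += Gb;
      grad[9] += Gb * e1 * sb;
      grad[15 + 3 * i] += Gb * sb;
      const double gql = Gl * dql;
      grad[5] += gql;
      grad[10] += gql * e2 * sl * (1.0 - sl);
      const double ge2 = gql * sl;
      grad[15 + 3 * i] += ge2 * L21;
      grad[16 + 3 * i] += ge2 * L22;
      gL21 += ge2 * z1; gL22 += ge2 * z2;
      const double gqg = Gg * dqg;
      grad[6] += gqg;
      grad[11] += gqg * e3 * sg * (1.0 - sg);
      const double ge3 = gqg * sg;
      grad[15 + 3 * i] += ge3 * L31;
      grad[16 + 3 * i] += ge3 * L32;
      grad[17 + 3 * i] += ge3 * L33;
      gL31 += ge3 * z1; gL32 += ge3 * z2; gL33 += ge3 * z3;
    }

    // Cholesky-factor gradients back to the tanh parameters
    grad[12] += gL21 * s1sq + gL22 * (-c1 * s1);
    grad[13] += gL31 * s2sq + gL32 * (-c2 * c3 * s2) + gL33 * (-c2 * s2 * s3);
    grad[14] += gL32 * (s2 * s3sq) + gL33 * (-c3 * s2 * s3);

    return lp;
  }
};

// ---------------------------------------------------------------------------
// hierarchical logistic regression
// theta = [b (K incl. design columns), log sigma_u, u_raw (P)]
// eta_n = X_n b + sigma_u * u_raw[part_n]
// priors: b ~ t(3, 0, 2.5); sigma_u ~ half-t(3, 0, 2.5); u_raw ~ N(0,1)
// ---------------------------------------------------------------------------

static inline double t3_lpdf(double x, double s) {
  // Student-t, nu = 3: lgamma(2) - lgamma(1.5) - 0.5 log(3 pi s^2)
  const double c = -std::lgamma(1.5) - 0.5 * std::log(3.0 * M_PI * s * s);
  return c - 2.0 * std::log1p(x * x / (3.0 * s * s));
}
static inline double t3_grad(double x, double s) {
  return -4.0 * x / (3.0 * s * s + x * x);
}

struct LogisticModel : Model {
  int n, K, P;
  std::vector<int> y, part;
  std::vector<double> X;  // n x K row-major
  double prior_scale;

  explicit LogisticModel(const List& d) {
    IntegerVector yy = d["y"], pp = d["part"];
    NumericMatrix Xm = d["X"];
    P = as<int>(d["P"]);
    prior_scale = d.containsElementNamed("prior_scale")
      ? as<double>(d["prior_scale"]) : 2.5;
    n = yy.size(); K = Xm.ncol();
    y.assign(yy.begin(), yy.end());
    part.assign(pp.begin(), pp.end());
    X.resize((size_t)n * K);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < K; ++j) X[(size_t)i * K + j] = Xm(i, j);
  }

  int dim() const { return K + 1 + P; }

  double logp_grad(const std::vector<double>& th,
                   std::vector<double>& grad) const {
    std::fill(grad.begin(), grad.end(), 0.0);
    const double* b = &th[0];
    const double lsu = th[K];
    const double su = std::exp(lsu);
    const double* u = &th[K + 1];
    double lp = 0.0;
    for (int j = 0; j < K; ++j) {
      lp += t3_lpdf(b[j], prior_scale);
      grad[j] += t3_grad(b[j], prior_scale);
    }
    // half-t prior on sigma_u with log transform jacobian
    lp += std::log(2.0) + t3_lpdf(su, prior_scale) + lsu;
    grad[K] += t3_grad(su, prior_scale) * su + 1.0;
    double gsu = 0.0;
    for (int p = 0; p < P; ++p) {
      lp += -0.5 * u[p] * u[p] - 0.5 * 1.8378770664093453;
      grad[K + 1 + p] += -u[p];
    }
    for (int i = 0; i < n; ++i) {
      const double* xr = &X[(size_t)i * K];
      double eta = su * u[part[i]];
      for (int j = 0; j < K; ++j) eta += xr[j] * b[j];
      const double g = (double)y[i] - inv_logit(eta);
      lp += (y[i] ? eta : 0.0) - log1pexp_(eta);
      for (int j = 0; j < K; ++j) grad[j] += g * xr[j];
      grad[K + 1 + part[i]] += g * su;
      gsu += g * u[part[i]];
    }
    grad[K] += gsu * su;
    return lp;
  }
};

// ---------------------------------------------------------------------------
// hierarchical cumulative ordered-logit regression
// theta = [b (J), cut raw t (K-1), log sigma_u, u_raw (P)]
// c_1 = t_1; c_k = c_{k-1} + exp(t_k)  (ordered cutpoints)
// P(y = k) = logit^{-1}(c_k - eta) - logit^{-1}(c_{k-1} - eta)
// priors: b, c_k ~ t(3, 0, 2.5); sigma_u ~ half-t(3, 0, 2.5); u ~ N(0,1)
// ---------------------------------------------------------------------------

struct OrderedModel : Model {
  int n, J, P, K;
  std::vector<int> y, part;
  std::vector<double> X;  // n x J
  double prior_scale;

  explicit OrderedModel(const List& d) {
    IntegerVector yy = d["y"], pp = d["part"];
    NumericMatrix Xm = d["X"];
    P = as<int>(d["P"]);
    K = as<int>(d["K"]);
    prior_scale = d.containsElementNamed("prior_scale")
      ? as<double>(d["prior_scale"]) : 2.5;
    n = yy.size(); J = Xm.ncol();
    y.assign(yy.begin(), yy.end());
    part.assign(pp.begin(), pp.end());
    X.resize((size_t)n * J);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < J; ++j) X[(size_t)i * J + j] = Xm(i, j);
    if (K < 3) stop("ordered outcome needs >= 3 levels");
  }

  int dim() const { return J + (K - 1) + 1 + P; }

  double logp_grad(const std::vector<double>& th,
                   std::vector<double>& grad) const {
    std::fill(grad.begin(), grad.end(), 0.0);
    const int nc = K - 1;
    const double* b = &th[0];
    const double* tc = &th[J];
    const double lsu = th[J + nc];
    const double su = std::exp(lsu);
    const double* u = &th[J + nc + 1];
    std::vector<double> cut(nc), gcut(nc, 0.0);
    cut[0] = tc[0];
    for (int k = 1; k < nc; ++k) cut[k] = cut[k - 1] + std::exp(tc[k]);

    double lp = 0.0;
    for (int j = 0; j < J; ++j) {
      lp += t3_lpdf(b[j], prior_scale);
      grad[j] += t3_grad(b[j], prior_scale);
    }
    for (int k = 0; k < nc; ++k) {
      lp += t3_lpdf(cut[k], prior_scale);
      gcut[k] += t3_grad(cut[k], prior_scale);
      if (k > 0) { lp += tc[k]; grad[J + k] += 1.0; }  // ordered-transform jacobian
    }
    lp += std::log(2.0) + t3_lpdf(su, prior_scale) + lsu;
    grad[J + nc] += t3_grad(su, prior_scale) * su + 1.0;
    for (int p = 0; p < P; ++p) {
      lp += -0.5 * u[p] * u[p] - 0.5 * 1.8378770664093453;
      grad[J + nc + 1 + p] += -u[p];
    }

    double gsu = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xr = &X[(size_t)i * J];
      double eta = su * u[part[i]];
      for (int j = 0; j < J; ++j) eta += xr[j] * b[j];
      const int k = y[i];  // 1..K
      double A = 1.0, dA = 0.0, B = 0.0, dB = 0.0;
      if (k < K) { A = inv_logit(cut[k - 1] - eta); dA = A * (1.0 - A); }
      if (k > 1) { B = inv_logit(cut[k - 2] - eta); dB = B * (1.0 - B); }
      double pr = A - B;
      if (pr < 1e-300) pr = 1e-300;
      lp += std::log(pr);
      const double geta = -(dA - dB) / pr;
      for (int j = 0; j < J; ++j) grad[j] += geta * xr[j];
      grad[J + nc + 1 + part[i]] += geta * su;
      gsu += geta * u[part[i]];
      if (k < K) gcut[k - 1] += dA / pr;
      if (k > 1) gcut[k - 2] += -dB / pr;
    }
    grad[J + nc] += gsu * su;

    // cutpoint gradients back to the raw scale: dc_m/dt_0 = 1;
    // dc_m/dt_k = exp(t_k) for k <= m
    double tail = 0.0;
    for (int k = nc - 1; k >= 1; --k) {
      tail += gcut[k];
      grad[J + k] += tail * std::exp(tc[k]);
      if (k == 1) grad[J] += tail + gcut[0];
    }
    if (nc == 1) grad[J] += gcut[0];
    return lp;
  }
};

static std::unique_ptr<Model> make_model(const List& spec) {
  std::string type = as<std::string>(spec["type"]);
  List data = spec["data"];
  if (type == "pt") return std::unique_ptr<Model>(new PTModel(data));
  if (type == "logistic") return std::unique_ptr<Model>(new LogisticModel(data));
  if (type == "ordered") return std::unique_ptr<Model>(new OrderedModel(data));
  stop("unknown model type: " + type);
}

// [[Rcpp::export]]
List model_logp_grad_cpp(List model_spec, NumericVector theta) {
  std::unique_ptr<Model> mod = make_model(model_spec);
  if ((int)theta.size() != mod->dim())
    stop("theta has length %d, model dimension is %d", theta.size(), mod->dim());
  std::vector<double> th(theta.begin(), theta.end()), grad(mod->dim());
  double lp = mod->logp_grad(th, grad);
  return List::create(_["logp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
int model_dim_cpp(List model_spec) {
  return make_model(model_spec)->dim();
}

// Per-draw acceptance probabilities of the prospect-theory model
// (trials x draws); draws are rows of unconstrained parameter vectors.
// [[Rcpp::export]]
NumericMatrix pt_acceptance_probs_cpp(List data, NumericMatrix draws) {
  PTModel mod(data);
  const int S = draws.nrow();
  if (draws.ncol() != mod.dim()) stop("draws do not match the model dimension");
  NumericMatrix P(mod.T, S);
  for (int s = 0; s < S; ++s) {
    const double beta = draws(s, 0);
    double bj[4];
    for (int j = 0; j < 4; ++j) bj[j] = draws(s, 1 + j);
    const double lP = draws(s, 5), gP = draws(s, 6);
    const double alpha = std::exp(draws(s, 7));
    const double phi = R::pnorm(draws(s, 8), 0.0, 1.0, 1, 0);
    const double sb = std::exp(draws(s, 9));
    const double sl = inv_logit(draws(s, 10)), sg = inv_logit(draws(s, 11));
    const double c1 = std::tanh(draws(s, 12)), c2 = std::tanh(draws(s, 13)),
      c3 = std::tanh(draws(s, 14));
    const double s1 = std::sqrt(1 - c1 * c1), s2 = std::sqrt(1 - c2 * c2),
      s3 = std::sqrt(1 - c3 * c3);
    const double L21 = c1, L22 = s1, L31 = c2, L32 = c3 * s2, L33 = s2 * s3;
    for (int i = 0; i < mod.N; ++i) {
      const double z1 = draws(s, 15 + 3 * i), z2 = draws(s, 16 + 3 * i),
        z3 = draws(s, 17 + 3 * i);
      const double beta_i = beta + sb * z1;
      const double lam = R::pnorm(lP + sl * (L21 * z1 + L22 * z2), 0, 1, 1, 0);
      const double gam = R::pnorm(gP + sg * (L31 * z1 + L32 * z2 + L33 * z3),
                                  0, 1, 1, 0);
      for (int t = mod.pstart[i]; t < mod.pstart[i + 1]; ++t) {
        double V = 0;
        for (int o = mod.off[t]; o < mod.off[t + 1]; ++o) {
          const double ma = std::exp(alpha * mod.log_m[o]);
          const double w = mod.has_p[o]
            ? std::exp(-std::exp(gam * mod.log_tneg[o])) : 0.5;
          V += (mod.is_se[o] ? -lam : (1.0 - lam)) * ma * w;
        }
        double eta = beta_i + phi * V;
        const double* xr = &mod.X[(size_t)t * 4];
        for (int j = 0; j < 4; ++j) eta += xr[j] * bj[j];
        P(t, s) = inv_logit(eta);
      }
    }
  }
  return P;
}

// Linear predictors of the hierarchical logistic model (obs x draws)
// [[Rcpp::export]]
NumericMatrix logistic_linpred_cpp(List data, NumericMatrix draws) {
  LogisticModel mod(data);
  const int S = draws.nrow();
  if (draws.ncol() != mod.dim()) stop("draws do not match the model dimension");
  NumericMatrix E(mod.n, S);
  for (int s = 0; s < S; ++s) {
    const double su = std::exp(draws(s, mod.K));
    for (int i = 0; i < mod.n; ++i) {
      double eta = su * draws(s, mod.K + 1 + mod.part[i]);
      const double* xr = &mod.X[(size_t)i * mod.K];
      for (int j = 0; j < mod.K; ++j) eta += xr[j] * draws(s, j);
      E(i, s) = eta;
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// multinomial NUTS with dual averaging + diagonal mass adaptation
// ---------------------------------------------------------------------------

struct PSPoint {
  std::vector<double> q, p, grad;
  double logp;
};

struct Hamiltonian {
  const Model* mod;
  std::vector<double> minv;  // diagonal inverse mass

  double H(const PSPoint& z) const {
    double ke = 0.0;
    for (size_t k = 0; k < z.p.size(); ++k) ke += z.p[k] * z.p[k] * minv[k];
    return -z.logp + 0.5 * ke;
  }
  void leapfrog(PSPoint& z, double eps) const {
    const int d = (int)z.q.size();
    for (int k = 0; k < d; ++k) z.p[k] += 0.5 * eps * z.grad[k];
    for (int k = 0; k < d; ++k) z.q[k] += eps * minv[k] * z.p[k];
    z.logp = mod->logp_grad(z.q, z.grad);
    for (int k = 0; k < d; ++k) z.p[k] += 0.5 * eps * z.grad[k];
  }
};

struct TreeState {
  PSPoint zp;           // multinomial proposal from the subtree
  PSPoint z_lo, z_hi;   // backward-most / forward-most points of the subtree
  double log_sum_w;     // log multinomial weight of subtree
  double sum_accept;    // accept-stat accumulator
  int n_leapfrog;
  bool divergent, ok;   // ok = no divergence and no u-turn inside
};

struct NutsSampler {
  Hamiltonian ham;
  int max_depth;
  double H0;

  // a = backward extreme, b = forward extreme (trajectory order)
  bool uturn(const PSPoint& a, const PSPoint& b) const {
    const int d = (int)a.q.size();
    double s1 = 0.0, s2 = 0.0;
    for (int k = 0; k < d; ++k) {
      const double dq = b.q[k] - a.q[k];
      s1 += dq * ham.minv[k] * a.p[k];
      s2 += dq * ham.minv[k] * b.p[k];
    }
    return (s1 < 0.0) || (s2 < 0.0);
  }

  TreeState build_tree(const PSPoint& edge, int depth, double eps, int dir) {
    TreeState ts;
    if (depth == 0) {
      PSPoint z = edge;
      ham.leapfrog(z, dir * eps);
      double h = ham.H(z);
      if (!std::isfinite(h)) h = 1e300;
      ts.zp = z;
      ts.z_lo = z;
      ts.z_hi = z;
      ts.log_sum_w = H0 - h;
      double a = std::exp(H0 - h);
      ts.sum_accept = (a > 1.0) ? 1.0 : a;
      ts.n_leapfrog = 1;
      ts.divergent = (h - H0) > 1000.0;
      ts.ok = !ts.divergent;
      return ts;
    }
    TreeState first = build_tree(edge, depth - 1, eps, dir);
    if (!first.ok) return first;
    const PSPoint& inner_edge = (dir < 0) ? first.z_lo : first.z_hi;
    TreeState second = build_tree(inner_edge, depth - 1, eps, dir);
    TreeState out;
    out.n_leapfrog = first.n_leapfrog + second.n_leapfrog;
    out.sum_accept = first.sum_accept + second.sum_accept;
    out.divergent = first.divergent || second.divergent;
    if (dir < 0) { out.z_lo = second.z_lo; out.z_hi = first.z_hi; }
    else { out.z_lo = first.z_lo; out.z_hi = second.z_hi; }
    if (!second.ok) {
      out.ok = false;
      out.zp = first.zp;
      out.log_sum_w = first.log_sum_w;
      return out;
    }
    double hi = std::max(first.log_sum_w, second.log_sum_w);
    out.log_sum_w = hi + std::log(std::exp(first.log_sum_w - hi) +
                                  std::exp(second.log_sum_w - hi));
    double pr = std::exp(second.log_sum_w - out.log_sum_w);
    out.zp = (R::unif_rand() < pr) ? second.zp : first.zp;
    out.ok = !uturn(out.z_lo, out.z_hi);
    return out;
  }

  // one NUTS transition; returns average accept statistic
  double transition(PSPoint& z, double eps, int& n_div, int& treedepth) {
    const int d = (int)z.q.size();
    for (int k = 0; k < d; ++k)
      z.p[k] = R::norm_rand() / std::sqrt(ham.minv[k]);
    H0 = ham.H(z);
    PSPoint zminus = z, zplus = z, sample = z;
    double log_sum_w = 0.0;  // weight of the initial point: exp(H0 - H0) = 1
    double sum_a = 0.0; int n_lf = 0;
    int depth = 0;
    bool ok = true;
    while (ok && depth < max_depth) {
      int dir = (R::unif_rand() < 0.5) ? -1 : 1;
      const PSPoint& edge = (dir < 0) ? zminus : zplus;
      TreeState ts = build_tree(edge, depth, eps, dir);
      sum_a += ts.sum_accept; n_lf += ts.n_leapfrog;
      if (ts.divergent) ++n_div;
      if (!ts.ok) break;
      if (dir < 0) zminus = ts.z_lo; else zplus = ts.z_hi;
      // progressive multinomial: take subtree proposal with prob w'/w_total
      double hi = std::max(log_sum_w, ts.log_sum_w);
      double new_total = hi + std::log(std::exp(log_sum_w - hi) +
                                       std::exp(ts.log_sum_w - hi));
      if (R::unif_rand() < std::exp(ts.log_sum_w - new_total)) sample = ts.zp;
      log_sum_w = new_total;
      ok = !uturn(zminus, zplus);
      ++depth;
    }
    treedepth = depth;
    z = sample;
    return (n_lf > 0) ? sum_a / n_lf : 1.0;
  }
};

// dual averaging state
struct DualAverage {
  double mu, log_eps, log_eps_bar, h_bar;
  int counter;
  double gamma, t0, kappa, delta;
  void init(double eps0, double delta_) {
    mu = std::log(10.0 * eps0);
    log_eps = std::log(eps0);
    log_eps_bar = 0.0;
    h_bar = 0.0;
    counter = 0;
    gamma = 0.05; t0 = 10.0; kappa = 0.75; delta = delta_;
  }
  void update(double accept) {
    ++counter;
    double eta = 1.0 / (counter + t0);
    h_bar = (1.0 - eta) * h_bar + eta * (delta - accept);
    log_eps = mu - std::sqrt((double)counter) / gamma * h_bar;
    double w = std::pow((double)counter, -kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
  }
};

static double find_initial_stepsize(const Hamiltonian& ham, PSPoint z) {
  const int d = (int)z.q.size();
  for (int k = 0; k < d; ++k)
    z.p[k] = R::norm_rand() / std::sqrt(ham.minv[k]);
  double eps = 1.0;
  double h0 = ham.H(z);
  PSPoint z1 = z;
  ham.leapfrog(z1, eps);
  double h1 = ham.H(z1);
  if (!std::isfinite(h1)) h1 = 1e300;
  double dH = h0 - h1;
  int dir = (dH > std::log(0.5)) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    eps = (dir == 1) ? 2.0 * eps : 0.5 * eps;
    z1 = z;
    ham.leapfrog(z1, eps);
    h1 = ham.H(z1);
    if (!std::isfinite(h1)) h1 = 1e300;
    dH = h0 - h1;
    if (dir == 1 && dH <= std::log(0.5)) break;
    if (dir == -1 && dH >= std::log(0.5)) break;
  }
  return eps;
}

// [[Rcpp::export]]
List nuts_sample_cpp(List model_spec, NumericMatrix inits,
                     int n_warmup, int n_iter, int thin,
                     int max_treedepth = 10, double delta = 0.8) {
  std::unique_ptr<Model> mod = make_model(model_spec);
  const int d = mod->dim();
  const int n_chains = inits.nrow();
  if (inits.ncol() != d) stop("inits have %d columns, model dimension is %d",
                              inits.ncol(), d);
  const int n_keep = n_iter / thin;

  List chains(n_chains);
  IntegerVector divergences(n_chains);
  NumericVector stepsizes(n_chains), accept_stats(n_chains);
  IntegerVector max_depth_hits(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    Hamiltonian ham;
    ham.mod = mod.get();
    ham.minv.assign(d, 1.0);
    NutsSampler sampler;
    sampler.ham = ham;
    sampler.max_depth = max_treedepth;

    PSPoint z;
    z.q.assign(d, 0.0);
    z.p.assign(d, 0.0);
    z.grad.assign(d, 0.0);
    for (int k = 0; k < d; ++k) z.q[k] = inits(c, k);
    z.logp = mod->logp_grad(z.q, z.grad);
    if (!std::isfinite(z.logp)) stop("non-finite log density at initialization");

    double eps = find_initial_stepsize(sampler.ham, z);
    DualAverage da;
    da.init(eps, delta);

    // warmup windows (Stan-like): step-size-only head/tail, doubling
    // variance-estimation windows in between
    int init_buf = 75, term_buf = 50, base_win = 25;
    if (n_warmup < 150) {
      init_buf = (int)std::floor(0.15 * n_warmup);
      term_buf = (int)std::floor(0.10 * n_warmup);
      base_win = n_warmup - init_buf - term_buf;
      if (base_win < 1) { init_buf = 0; term_buf = 0; base_win = n_warmup; }
    }
    std::vector<int> win_ends;
    {
      int start = init_buf, w = base_win;
      while (start < n_warmup - term_buf) {
        int end = start + w;
        if (end * 2 > n_warmup - term_buf) end = n_warmup - term_buf;
        win_ends.push_back(end);
        start = end;
        w *= 2;
      }
    }
    std::vector<double> wsum(d, 0.0), wsum2(d, 0.0);
    int wn = 0;
    size_t win_idx = 0;

    int n_div = 0, n_maxdepth = 0;
    double acc_sum = 0.0;

    for (int it = 0; it < n_warmup; ++it) {
      int depth = 0;
      sampler.ham.minv = ham.minv;
      double a = sampler.transition(z, std::exp(da.log_eps), n_div, depth);
      da.update(a);
      bool in_window = (it >= init_buf) && (it < n_warmup - term_buf);
      if (in_window) {
        ++wn;
        for (int k = 0; k < d; ++k) {
          wsum[k] += z.q[k];
          wsum2[k] += z.q[k] * z.q[k];
        }
        if (win_idx < win_ends.size() && it + 1 == win_ends[win_idx]) {
          if (wn > 1) {
            for (int k = 0; k < d; ++k) {
              double mean = wsum[k] / wn;
              double var = (wsum2[k] - wn * mean * mean) / (wn - 1);
              // regularize toward unit metric as Stan does
              double v = (wn / (wn + 5.0)) * var + 1e-3 * (5.0 / (wn + 5.0));
              ham.minv[k] = std::max(v, 1e-10);
            }
          }
          std::fill(wsum.begin(), wsum.end(), 0.0);
          std::fill(wsum2.begin(), wsum2.end(), 0.0);
          wn = 0;
          ++win_idx;
          // re-initialize step-size search for the new metric
          sampler.ham.minv = ham.minv;
          double eps_new = find_initial_stepsize(sampler.ham, z);
          da.init(eps_new, delta);
        }
      }
    }
    double eps_final = std::exp(da.log_eps_bar);
    if (!std::isfinite(eps_final) || eps_final <= 0) eps_final = std::exp(da.log_eps);
    n_div = 0;  // report post-warmup divergences only

    NumericMatrix draws(n_keep, d);
    sampler.ham.minv = ham.minv;
    int kept = 0;
    for (int it = 0; it < n_iter; ++it) {
      int depth = 0;
      double a = sampler.transition(z, eps_final, n_div, depth);
      acc_sum += a;
      if (depth >= max_treedepth) ++n_maxdepth;
      if ((it + 1) % thin == 0 && kept < n_keep) {
        for (int k = 0; k < d; ++k) draws(kept, k) = z.q[k];
        ++kept;
      }
    }
    chains[c] = draws;
    divergences[c] = n_div;
    stepsizes[c] = eps_final;
    accept_stats[c] = acc_sum / n_iter;
    max_depth_hits[c] = n_maxdepth;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["chains"] = chains,
                      _["divergences"] = divergences,
                      _["stepsize"] = stepsizes,
                      _["accept_stat"] = accept_stats,
                      _["max_depth_hits"] = max_depth_hits);
}
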