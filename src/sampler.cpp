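// Reversible-jump MCMC for the spatial normal mixture over copy-number
// classes. Components are permanently identified with their class slot
// (uniform support interval), so the state never needs label-switching
// bookkeeping: `active[j]` says whether class j currently carries a
// component. All acceptance probabilities are computed in log space.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;
// class count is small (default 7); fixed buffers avoid per-SNP allocation
#define KBUF 64

struct Ctx {
  int n, kmax, nb;
  std::vector<double> y, lower, upper, gev;
  std::vector<int> deg;
  double lambda, ig_shape, ig_scale, h_max, phi;
  NumericMatrix V; // eigenvectors of the graph Laplacian (n x n)
  bool prior_only;
};

static Ctx make_ctx(const List& c) {
  Ctx x;
  x.n = as<int>(c["n"]);
  x.kmax = as<int>(c["kmax"]);
  x.nb = as<int>(c["nb"]);
  x.y = as< std::vector<double> >(c["y"]);
  x.lower = as< std::vector<double> >(c["lower"]);
  x.upper = as< std::vector<double> >(c["upper"]);
  x.gev = as< std::vector<double> >(c["eigenvalues"]);
  x.deg = as< std::vector<int> >(c["degree"]);
  x.lambda = as<double>(c["poisson_mean"]);
  x.ig_shape = as<double>(c["ig_shape"]);
  x.ig_scale = as<double>(c["ig_scale"]);
  x.h_max = as<double>(c["h_max"]);
  x.phi = as<double>(c["phi"]);
  x.V = as<NumericMatrix>(c["eigenvectors"]);
  x.prior_only = as<bool>(c["prior_only"]);
  if (x.kmax > KBUF) stop("too many classes");
  return x;
}

struct State {
  std::vector<int> active;        // 0/1 per class slot
  std::vector<double> mu, sigma2; // per class slot
  NumericMatrix x;                // n x kmax field matrix
  std::vector<int> z;             // 0-based class allocation per SNP
  double h;
};

static State state_from_list(const List& s) {
  State st;
  st.active = as< std::vector<int> >(s["active"]);
  st.mu = as< std::vector<double> >(s["mu"]);
  st.sigma2 = as< std::vector<double> >(s["sigma2"]);
  st.x = clone(as<NumericMatrix>(s["x"]));
  IntegerVector z1 = s["z"]; // 1-based from R
  st.z.resize(z1.size());
  for (int i = 0; i < z1.size(); i++) st.z[i] = z1[i] - 1;
  st.h = as<double>(s["h"]);
  return st;
}

static List state_to_list(const State& s) {
  IntegerVector z1(s.z.size());
  for (size_t i = 0; i < s.z.size(); i++) z1[i] = s.z[i] + 1;
  return List::create(
    _["active"] = wrap(s.active), _["mu"] = wrap(s.mu),
    _["sigma2"] = wrap(s.sigma2), _["x"] = s.x, _["z"] = z1,
    _["h"] = s.h);
}

static inline int active_list(const State& s, int kmax, int* idx) {
  int k = 0;
  for (int j = 0; j < kmax; j++) if (s.active[j]) idx[k++] = j;
  return k;
}

static inline double birth_prob(int k, int kmax) {
  if (k <= 1) return 1.0;
  if (k >= kmax) return 0.0;
  return 0.5;
}

// unnormalized truncated-Poisson log mass; normalization cancels in ratios
static inline double log_pois_un(int k, double lam) {
  return k * std::log(lam) - std::lgamma(k + 1.0);
}

// log softmax of xv/phi into lw (max-subtraction for overflow safety)
static inline void log_softmax(const double* xv, int k, double phi, double* lw) {
  double m = xv[0];
  for (int l = 1; l < k; l++) if (xv[l] > m) m = xv[l];
  double s = 0.0;
  for (int l = 0; l < k; l++) { lw[l] = (xv[l] - m) / phi; s += std::exp(lw[l]); }
  double ls = std::log(s);
  for (int l = 0; l < k; l++) lw[l] -= ls;
}

static inline double logsumexp(const double* t, int k) {
  double m = t[0];
  for (int l = 1; l < k; l++) if (t[l] > m) m = t[l];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int l = 0; l < k; l++) s += std::exp(t[l] - m);
  return m + std::log(s);
}

// per-component Gaussian log-density pieces, precomputed once per sweep
static inline void comp_consts(const Ctx& c, const State& s, const int* idx,
                               int k, double* cst, double* i2, double* muv) {
  for (int l = 0; l < k; l++) {
    int j = idx[l];
    cst[l] = -0.5 * (LOG2PI + std::log(s.sigma2[j]));
    i2[l] = 0.5 / s.sigma2[j];
    muv[l] = s.mu[j];
  }
}

static inline double log_mix_at(const Ctx& c, int i, const double* lw,
                                const double* cst, const double* i2,
                                const double* muv, int k) {
  double t[KBUF];
  if (c.prior_only) {
    for (int l = 0; l < k; l++) t[l] = lw[l];
  } else {
    double yi = c.y[i];
    for (int l = 0; l < k; l++) {
      double d = yi - muv[l];
      t[l] = lw[l] + cst[l] - i2[l] * d * d;
    }
  }
  return logsumexp(t, k);
}

static inline double nb_sum(const NumericMatrix& x, int i, int j, int n, int nb) {
  double s = 0.0;
  int lo = i - nb; if (lo < 0) lo = 0;
  int hi = i + nb; if (hi > n - 1) hi = n - 1;
  for (int t = lo; t <= hi; t++) if (t != i) s += x(t, j);
  return s;
}

// draw one field column from the GMRF prior N(0, (I + hQ)^{-1})
static void gmrf_draw(const Ctx& c, double h, double* out) {
  int n = c.n;
  std::vector<double> zc(n);
  for (int q = 0; q < n; q++)
    zc[q] = R::norm_rand() / std::sqrt(1.0 + h * c.gev[q]);
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int q = 0; q < n; q++) s += c.V(i, q) * zc[q];
    out[i] = s;
  }
}

static inline double rinvgamma(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// ---- trans-dimensional moves -------------------------------------------

static double birth_log_alpha_impl(const Ctx& c, const State& s, int cnew,
                                   double mu_s, double s2_s, const double* xs) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double la =
    std::log(1.0 - birth_prob(k + 1, c.kmax)) - std::log((double)(k + 1)) +
    log_pois_un(k + 1, c.lambda) -
    std::log(birth_prob(k, c.kmax)) + std::log((double)(c.kmax - k)) -
    log_pois_un(k, c.lambda);
  double cst[KBUF], i2[KBUF], muv[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  cst[k] = -0.5 * (LOG2PI + std::log(s2_s));
  i2[k] = 0.5 / s2_s;
  muv[k] = mu_s;
  double xv[KBUF], lw[KBUF];
  for (int i = 0; i < c.n; i++) {
    for (int l = 0; l < k; l++) xv[l] = s.x(i, idx[l]);
    log_softmax(xv, k, c.phi, lw);
    double lo = log_mix_at(c, i, lw, cst, i2, muv, k);
    xv[k] = xs[i];
    log_softmax(xv, k + 1, c.phi, lw);
    double ln = log_mix_at(c, i, lw, cst, i2, muv, k + 1);
    la += ln - lo;
  }
  return la;
}

static double death_log_alpha_impl(const Ctx& c, const State& s, int cdel) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double la =
    std::log(birth_prob(k - 1, c.kmax)) - std::log((double)(c.kmax - (k - 1))) +
    log_pois_un(k - 1, c.lambda) -
    std::log(1.0 - birth_prob(k, c.kmax)) + std::log((double)k) -
    log_pois_un(k, c.lambda);
  double cst[KBUF], i2[KBUF], muv[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  // reduced component set (drop cdel), order preserved
  int ridx[KBUF];
  double rcst[KBUF], ri2[KBUF], rmuv[KBUF];
  int kr = 0;
  for (int l = 0; l < k; l++) {
    if (idx[l] == cdel) continue;
    ridx[kr] = idx[l]; rcst[kr] = cst[l]; ri2[kr] = i2[l]; rmuv[kr] = muv[l];
    kr++;
  }
  double xv[KBUF], lw[KBUF];
  for (int i = 0; i < c.n; i++) {
    for (int l = 0; l < k; l++) xv[l] = s.x(i, idx[l]);
    log_softmax(xv, k, c.phi, lw);
    double lo = log_mix_at(c, i, lw, cst, i2, muv, k);
    for (int l = 0; l < kr; l++) xv[l] = s.x(i, ridx[l]);
    log_softmax(xv, kr, c.phi, lw);
    double ln = log_mix_at(c, i, lw, rcst, ri2, rmuv, kr);
    la += ln - lo;
  }
  return la;
}

static void update_k(const Ctx& c, State& s, std::vector<double>& buf,
                     int* prop_b, int* acc_b, int* prop_d, int* acc_d) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double bk = birth_prob(k, c.kmax);
  if (R::unif_rand() < bk) {
    (*prop_b)++;
    int inact[KBUF], m = 0;
    for (int j = 0; j < c.kmax; j++) if (!s.active[j]) inact[m++] = j;
    int pick = (int)(R::unif_rand() * m); if (pick >= m) pick = m - 1;
    int cnew = inact[pick];
    double mu_s = R::runif(c.lower[cnew], c.upper[cnew]);
    double s2_s = rinvgamma(c.ig_shape, c.ig_scale);
    gmrf_draw(c, s.h, buf.data());
    double la = birth_log_alpha_impl(c, s, cnew, mu_s, s2_s, buf.data());
    if (std::log(R::unif_rand()) < la) {
      (*acc_b)++;
      s.active[cnew] = 1; s.mu[cnew] = mu_s; s.sigma2[cnew] = s2_s;
      for (int i = 0; i < c.n; i++) s.x(i, cnew) = buf[i];
    }
  } else {
    (*prop_d)++;
    int pick = (int)(R::unif_rand() * k); if (pick >= k) pick = k - 1;
    int cdel = idx[pick];
    double la = death_log_alpha_impl(c, s, cdel);
    if (std::log(R::unif_rand()) < la) {
      (*acc_d)++;
      s.active[cdel] = 0;
      // allocations pointing at cdel stay until the next Gibbs sweep;
      // nothing between here and that sweep reads z
    }
  }
}

// ---- within-model moves -------------------------------------------------

static void field_sweep(const Ctx& c, State& s, long* prop, long* acc) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double cst[KBUF], i2[KBUF], muv[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  double xv[KBUF], xn[KBUF], lw[KBUF];
  for (int i = 0; i < c.n; i++) {
    double v = 1.0 / (1.0 + s.h * c.deg[i]);
    double sdv = std::sqrt(v);
    for (int l = 0; l < k; l++) {
      int j = idx[l];
      xv[l] = s.x(i, j);
      double m = s.h * nb_sum(s.x, i, j, c.n, c.nb) * v;
      xn[l] = m + sdv * R::norm_rand();
    }
    log_softmax(xv, k, c.phi, lw);
    double lo = log_mix_at(c, i, lw, cst, i2, muv, k);
    log_softmax(xn, k, c.phi, lw);
    double ln = log_mix_at(c, i, lw, cst, i2, muv, k);
    (*prop)++;
    if (std::log(R::unif_rand()) < ln - lo) {
      (*acc)++;
      for (int l = 0; l < k; l++) s.x(i, idx[l]) = xn[l];
    }
  }
}

static double pair_sq_sum(const Ctx& c, const State& s) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double S = 0.0;
  for (int l = 0; l < k; l++) {
    int j = idx[l];
    for (int i = 0; i < c.n - 1; i++) {
      int hi = i + c.nb; if (hi > c.n - 1) hi = c.n - 1;
      double xi = s.x(i, j);
      for (int t = i + 1; t <= hi; t++) {
        double d = xi - s.x(t, j);
        S += d * d;
      }
    }
  }
  return S;
}

static double h_log_alpha_impl(const Ctx& c, const State& s, double hp,
                               double sigma_h) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double h = s.h;
  double la = 0.0;
  for (int i = 0; i < c.n; i++)
    la += 0.5 * k * (std::log1p(hp * c.gev[i]) - std::log1p(h * c.gev[i]));
  la += -0.5 * (hp - h) * pair_sq_sum(c, s);
  double num = R::pnorm((c.h_max - h) / sigma_h, 0, 1, 1, 0) -
               R::pnorm((0.0 - h) / sigma_h, 0, 1, 1, 0);
  double den = R::pnorm((c.h_max - hp) / sigma_h, 0, 1, 1, 0) -
               R::pnorm((0.0 - hp) / sigma_h, 0, 1, 1, 0);
  la += std::log(num) - std::log(den);
  return la;
}

static void update_h(const Ctx& c, State& s, double sigma_h,
                     int* prop, int* acc) {
  double h = s.h;
  double pa = R::pnorm((0.0 - h) / sigma_h, 0, 1, 1, 0);
  double pb = R::pnorm((c.h_max - h) / sigma_h, 0, 1, 1, 0);
  double hp;
  if (pb - pa < 1e-14) {
    hp = h; // proposal numerically degenerate; keep current value
  } else {
    double u = R::runif(pa, pb);
    hp = h + sigma_h * R::qnorm(u, 0, 1, 1, 0);
    if (hp < 0) hp = 0;
    if (hp > c.h_max) hp = c.h_max;
  }
  double la = h_log_alpha_impl(c, s, hp, sigma_h);
  (*prop)++;
  if (std::log(R::unif_rand()) < la) {
    (*acc)++;
    s.h = hp;
  }
}

static void alloc_logprobs_row(const Ctx& c, const State& s, const int* idx,
                               int k, const double* cst, const double* i2,
                               const double* muv, int i, double* t) {
  double xv[KBUF], lw[KBUF];
  for (int l = 0; l < k; l++) xv[l] = s.x(i, idx[l]);
  log_softmax(xv, k, c.phi, lw);
  if (c.prior_only) {
    for (int l = 0; l < k; l++) t[l] = lw[l];
  } else {
    double yi = c.y[i];
    for (int l = 0; l < k; l++) {
      double d = yi - muv[l];
      t[l] = lw[l] + cst[l] - i2[l] * d * d;
    }
  }
}

static void update_alloc(const Ctx& c, State& s) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double cst[KBUF], i2[KBUF], muv[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  double t[KBUF], p[KBUF];
  for (int i = 0; i < c.n; i++) {
    alloc_logprobs_row(c, s, idx, k, cst, i2, muv, i, t);
    double m = t[0];
    for (int l = 1; l < k; l++) if (t[l] > m) m = t[l];
    double tot = 0.0;
    for (int l = 0; l < k; l++) { p[l] = std::exp(t[l] - m); tot += p[l]; }
    double u = R::unif_rand() * tot, cum = 0.0;
    int sel = k - 1;
    for (int l = 0; l < k; l++) { cum += p[l]; if (u <= cum) { sel = l; break; } }
    s.z[i] = idx[sel];
  }
}

// ---- mean/variance update with interval migration and merges ------------

static void interval_select(const Ctx& c, double m, double sd, int* best,
                            double* masses) {
  double bm = -1.0;
  *best = 0;
  for (int t = 0; t < c.kmax; t++) {
    double pa = R::pnorm(c.lower[t], m, sd, 1, 0);
    double pb = R::pnorm(c.upper[t], m, sd, 1, 0);
    double mass = pb - pa;
    masses[t] = mass;
    if (mass > bm) { bm = mass; *best = t; } // ties: lowest index wins
  }
  if (bm <= 0.0) { // every interval mass underflowed: nearest midpoint
    double bd = R_PosInf;
    for (int t = 0; t < c.kmax; t++) {
      double d = std::fabs(0.5 * (c.lower[t] + c.upper[t]) - m);
      if (d < bd) { bd = d; *best = t; }
    }
  }
}

static double rtruncnorm(double m, double sd, double a, double b) {
  double pa = R::pnorm(a, m, sd, 1, 0);
  double pb = R::pnorm(b, m, sd, 1, 0);
  if (pb - pa < 1e-14) { // deep in a tail: clamp the mean into the interval
    double eps = 1e-8 * (b - a);
    if (m < a) return a + eps;
    if (m > b) return b - eps;
    return m;
  }
  double r = R::qnorm(R::runif(pa, pb), m, sd, 1, 0);
  if (r < a) r = a;
  if (r > b) r = b;
  return r;
}

// deterministic merge step: components (slots idx[l]) move to target[l] with
// freshly sampled means mut[l]; collisions merge by allocation-count weights
static int resolve_merges(const Ctx& c, State& s, const int* idx, int k,
                          const int* target, const double* mut,
                          const double* cnt, NumericMatrix& xtmp) {
  std::vector<int> newactive(c.kmax, 0);
  std::vector<double> newmu(c.kmax, 0.0), newsig(c.kmax, 0.0);
  std::vector<int> zmap(c.kmax);
  for (int j = 0; j < c.kmax; j++) zmap[j] = j;
  for (int t = 0; t < c.kmax; t++) {
    double W = 0.0;
    int m = 0;
    for (int l = 0; l < k; l++) if (target[l] == t) { W += cnt[l]; m++; }
    if (m == 0) continue;
    newactive[t] = 1;
    for (int i = 0; i < c.n; i++) xtmp(i, t) = 0.0;
    double muacc = 0.0, sigacc = 0.0;
    for (int l = 0; l < k; l++) {
      if (target[l] != t) continue;
      double wl = (W > 0) ? cnt[l] / W : 1.0 / m;
      muacc += wl * mut[l];
      sigacc += wl * std::sqrt(s.sigma2[idx[l]]);
      for (int i = 0; i < c.n; i++) xtmp(i, t) += wl * s.x(i, idx[l]);
      zmap[idx[l]] = t;
    }
    newmu[t] = muacc;
    newsig[t] = sigacc * sigacc;
  }
  for (int j = 0; j < c.kmax; j++) {
    s.active[j] = newactive[j];
    if (newactive[j]) {
      s.mu[j] = newmu[j];
      s.sigma2[j] = newsig[j];
      for (int i = 0; i < c.n; i++) s.x(i, j) = xtmp(i, j);
    }
  }
  for (int i = 0; i < c.n; i++) s.z[i] = zmap[s.z[i]];
  int k2 = 0;
  for (int j = 0; j < c.kmax; j++) if (s.active[j]) k2++;
  return k - k2; // components removed by merging
}

static int update_mu_sigma(const Ctx& c, State& s, NumericMatrix& xtmp,
                           bool allow_migration) {
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  int slot[KBUF];
  for (int j = 0; j < c.kmax; j++) slot[j] = -1;
  for (int l = 0; l < k; l++) slot[idx[l]] = l;
  double cnt[KBUF] = {0}, sum[KBUF] = {0};
  for (int i = 0; i < c.n; i++) {
    int l = slot[s.z[i]];
    if (l >= 0) { cnt[l] += 1.0; sum[l] += c.y[i]; }
  }
  int target[KBUF];
  double mut[KBUF], masses[KBUF];
  for (int l = 0; l < k; l++) {
    int j = idx[l];
    if (c.prior_only || cnt[l] == 0) { // no data: draw from the class prior
      target[l] = j;
      mut[l] = R::runif(c.lower[j], c.upper[j]);
    } else {
      double m = sum[l] / cnt[l];
      double sd = std::sqrt(s.sigma2[j] / cnt[l]);
      int best = j;
      if (allow_migration) interval_select(c, m, sd, &best, masses);
      target[l] = best;
      mut[l] = rtruncnorm(m, sd, c.lower[best], c.upper[best]);
    }
  }
  int merged = resolve_merges(c, s, idx, k, target, mut, cnt, xtmp);
  // variances from their inverse-gamma full conditionals under the new state
  k = active_list(s, c.kmax, idx);
  for (int j = 0; j < c.kmax; j++) slot[j] = -1;
  for (int l = 0; l < k; l++) slot[idx[l]] = l;
  double n2[KBUF] = {0}, ssq[KBUF] = {0};
  if (!c.prior_only) {
    for (int i = 0; i < c.n; i++) {
      int l = slot[s.z[i]];
      if (l < 0) continue;
      double d = c.y[i] - s.mu[s.z[i]];
      n2[l] += 1.0;
      ssq[l] += d * d;
    }
  }
  for (int l = 0; l < k; l++) {
    int j = idx[l];
    if (c.prior_only || n2[l] == 0) {
      s.sigma2[j] = rinvgamma(c.ig_shape, c.ig_scale);
    } else {
      s.sigma2[j] = rinvgamma(0.5 * n2[l] + c.ig_shape,
                              0.5 * ssq[l] + c.ig_scale);
    }
  }
  return merged;
}

// ---- one full iteration and the chain driver ----------------------------

struct Counters {
  int prop_b = 0, acc_b = 0, prop_d = 0, acc_d = 0;
  long prop_f = 0, acc_f = 0;
  int prop_h = 0, acc_h = 0;
  int merges = 0;
};

static void one_iteration(const Ctx& c, State& s, double sigma_h,
                          std::vector<double>& buf, NumericMatrix& xtmp,
                          Counters& ct, bool with_k) {
  if (with_k)
    update_k(c, s, buf, &ct.prop_b, &ct.acc_b, &ct.prop_d, &ct.acc_d);
  field_sweep(c, s, &ct.prop_f, &ct.acc_f);
  update_h(c, s, sigma_h, &ct.prop_h, &ct.acc_h);
  update_alloc(c, s);
  // interval migration (and hence merging) is frozen together with the
  // birth/death move during warm-up: while sigma^2 is still settling from its
  // vague prior scale, a single large variance draw can hand a component's
  // full-conditional mass to a wider neighboring interval and silently merge
  // a data-supported component away
  ct.merges += update_mu_sigma(c, s, xtmp, with_k);
}

// [[Rcpp::export]]
List cpp_run_chain(List ctxl, List initl, int burnin, int samples,
                   double sigma_h0, int adapt_every, bool store_mu,
                   int k_warmup) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(initl);
  double sigma_h = sigma_h0;
  int total = burnin + samples;
  NumericMatrix omega(c.n, c.kmax);
  IntegerVector ktr(total);
  IntegerVector atr(total); // active classes as a bitmask, for diagnostics
  NumericVector htr(total);
  NumericMatrix mutr = store_mu ? NumericMatrix(samples, c.kmax)
                                : NumericMatrix(0, 0);
  Counters ct;
  int h_prop_win = 0, h_acc_win = 0, h_prop_prev = 0, h_acc_prev = 0;
  std::vector<double> buf(c.n);
  NumericMatrix xtmp(c.n, c.kmax);
  int idx[KBUF];
  double xv[KBUF], lw[KBUF];
  if (k_warmup > burnin) k_warmup = burnin;
  for (int it = 0; it < total; it++) {
    // hold the trans-dimensional move during early burn-in so the fields can
    // sharpen around the initial components before any is considered for death
    one_iteration(c, s, sigma_h, buf, xtmp, ct, it >= k_warmup);
    // sigma_h adaptation from the h-acceptance in the last window,
    // frozen after burn-in so the sampling phase is a fixed kernel
    if (it < burnin && adapt_every > 0 && (it + 1) % adapt_every == 0) {
      h_prop_win = ct.prop_h - h_prop_prev;
      h_acc_win = ct.acc_h - h_acc_prev;
      double r = h_prop_win > 0 ? (double)h_acc_win / h_prop_win : 0.5;
      if (r > 0.70) sigma_h *= 1.25;
      else if (r < 0.40) sigma_h *= 0.8;
      if (sigma_h > c.h_max) sigma_h = c.h_max;
      if (sigma_h < 1e-8) sigma_h = 1e-8;
      h_prop_prev = ct.prop_h;
      h_acc_prev = ct.acc_h;
    }
    int k = active_list(s, c.kmax, idx);
    ktr[it] = k;
    htr[it] = s.h;
    int mask = 0;
    for (int l = 0; l < k; l++) mask |= (1 << idx[l]);
    atr[it] = mask;
    if (it >= burnin) {
      for (int i = 0; i < c.n; i++) {
        for (int l = 0; l < k; l++) xv[l] = s.x(i, idx[l]);
        log_softmax(xv, k, c.phi, lw);
        for (int l = 0; l < k; l++) omega(i, idx[l]) += std::exp(lw[l]);
      }
      if (store_mu) {
        int r = it - burnin;
        for (int j = 0; j < c.kmax; j++)
          mutr(r, j) = s.active[j] ? s.mu[j] : NA_REAL;
      }
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < c.n; i++)
    for (int j = 0; j < c.kmax; j++) omega(i, j) /= samples;
  List accept = List::create(
    _["birth_proposed"] = ct.prop_b, _["birth_accepted"] = ct.acc_b,
    _["death_proposed"] = ct.prop_d, _["death_accepted"] = ct.acc_d,
    _["field_proposed"] = (double)ct.prop_f, _["field_accepted"] = (double)ct.acc_f,
    _["h_proposed"] = ct.prop_h, _["h_accepted"] = ct.acc_h,
    _["merges"] = ct.merges);
  return List::create(
    _["omega_bar"] = omega, _["k_trace"] = ktr, _["h_trace"] = htr,
    _["active_trace"] = atr, _["mu_trace"] = mutr, _["accept"] = accept,
    _["sigma_h"] = sigma_h, _["state"] = state_to_list(s));
}

// ---- exposures for unit tests -------------------------------------------

// [[Rcpp::export]]
List cpp_step_iteration(List ctxl, List statel, double sigma_h) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  Counters ct;
  std::vector<double> buf(c.n);
  NumericMatrix xtmp(c.n, c.kmax);
  one_iteration(c, s, sigma_h, buf, xtmp, ct, true);
  return state_to_list(s);
}

// [[Rcpp::export]]
double cpp_birth_log_alpha(List ctxl, List statel, int cnew, double mu_s,
                           double s2_s, NumericVector xcol) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  if (cnew < 1 || cnew > c.kmax || s.active[cnew - 1])
    stop("`cnew` must be an inactive class");
  return birth_log_alpha_impl(c, s, cnew - 1, mu_s, s2_s, REAL(xcol));
}

// [[Rcpp::export]]
double cpp_death_log_alpha(List ctxl, List statel, int cdel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  if (cdel < 1 || cdel > c.kmax || !s.active[cdel - 1])
    stop("`cdel` must be an active class");
  return death_log_alpha_impl(c, s, cdel - 1);
}

// [[Rcpp::export]]
double cpp_h_log_alpha(List ctxl, List statel, double h_new, double sigma_h) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  return h_log_alpha_impl(c, s, h_new, sigma_h);
}

// [[Rcpp::export]]
NumericVector cpp_log_mix(List ctxl, List statel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double cst[KBUF], i2[KBUF], muv[KBUF], xv[KBUF], lw[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  NumericVector out(c.n);
  for (int i = 0; i < c.n; i++) {
    for (int l = 0; l < k; l++) xv[l] = s.x(i, idx[l]);
    log_softmax(xv, k, c.phi, lw);
    out[i] = log_mix_at(c, i, lw, cst, i2, muv, k);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_allocation_probs(List ctxl, List statel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  double cst[KBUF], i2[KBUF], muv[KBUF], t[KBUF];
  comp_consts(c, s, idx, k, cst, i2, muv);
  NumericMatrix out(c.n, c.kmax);
  for (int i = 0; i < c.n; i++) {
    alloc_logprobs_row(c, s, idx, k, cst, i2, muv, i, t);
    double m = t[0];
    for (int l = 1; l < k; l++) if (t[l] > m) m = t[l];
    double tot = 0.0;
    for (int l = 0; l < k; l++) tot += std::exp(t[l] - m);
    for (int l = 0; l < k; l++)
      out(i, idx[l]) = std::exp(t[l] - m) / tot;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_update_allocations(List ctxl, List statel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  update_alloc(c, s);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_field_sweep(List ctxl, List statel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  long prop = 0, acc = 0;
  field_sweep(c, s, &prop, &acc);
  return List::create(_["state"] = state_to_list(s),
                      _["proposed"] = (double)prop,
                      _["accepted"] = (double)acc);
}

// [[Rcpp::export]]
List cpp_update_mu_sigma(List ctxl, List statel) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  NumericMatrix xtmp(c.n, c.kmax);
  update_mu_sigma(c, s, xtmp, true);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_resolve_merges(List ctxl, List statel, IntegerVector targets,
                        NumericVector mut) {
  Ctx c = make_ctx(ctxl);
  State s = state_from_list(statel);
  int idx[KBUF];
  int k = active_list(s, c.kmax, idx);
  if (targets.size() != k || mut.size() != k)
    stop("`targets` and `mut` must have one entry per active component");
  int tg[KBUF];
  double mt[KBUF], cnt[KBUF] = {0};
  int slot[KBUF];
  for (int j = 0; j < c.kmax; j++) slot[j] = -1;
  for (int l = 0; l < k; l++) slot[idx[l]] = l;
  for (int i = 0; i < c.n; i++) {
    int l = slot[s.z[i]];
    if (l >= 0) cnt[l] += 1.0;
  }
  for (int l = 0; l < k; l++) { tg[l] = targets[l] - 1; mt[l] = mut[l]; }
  NumericMatrix xtmp(c.n, c.kmax);
  resolve_merges(c, s, idx, k, tg, mt, cnt, xtmp);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_interval_select(double m, double sd, NumericVector lower,
                         NumericVector upper) {
  Ctx c;
  c.kmax = lower.size();
  c.lower = as< std::vector<double> >(lower);
  c.upper = as< std::vector<double> >(upper);
  int best;
  double masses[KBUF];
  interval_select(c, m, sd, &best, masses);
  return List::create(_["index"] = best + 1,
                      _["masses"] = NumericVector(masses, masses + c.kmax));
}

// [[Rcpp::export]]
NumericVector cpp_gmrf_draw(List ctxl, double h) {
  Ctx c = make_ctx(ctxl);
  NumericVector out(c.n);
  gmrf_draw(c, h, REAL(out));
  return out;
}
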