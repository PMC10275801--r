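// Adaptive Metropolis-within-Gibbs samplers for AE twin models with
// gene-environment interaction, in sum-score and item-level (GRM) forms.
//
// Conventions shared by all samplers:
//  * genetic structure: MZ co-twins share one family value g_f ~ N(0, v);
//    DZ twins have A = sqrt(.5) * (g_f + s_t) with g_f, s_t ~ N(0, v),
//    giving marginal variance v and co-twin covariance v/2;
//  * proposal scales adapt by Robbins-Monro during burn-in only;
//  * a joint rescaling move on (genetic latents, genetic variance) breaks
//    the random-walk coupling between a variance and its latents;
//  * R's RNG is used throughout, so seeding happens from R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

static inline double ldnorm(double x, double m, double sd) {
  if (!(sd > 0.0) || !R_finite(sd)) return R_NegInf;
  double z = (x - m) / sd;
  return -0.5 * LOG2PI - std::log(sd) - 0.5 * z * z;
}

static inline double plogis_(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// GRM log-probability of code y (1..K) at theta; thr has K-1 entries
static inline double grm_logp(int y, double theta, double alpha,
                              const std::vector<double>& thr) {
  int K = (int)thr.size() + 1;
  double hi = (y == 1) ? 1.0 : plogis_(alpha * (theta - thr[y - 2]));
  double lo = (y == K) ? 0.0 : plogis_(alpha * (theta - thr[y - 1]));
  double p = hi - lo;
  return std::log(p > 1e-300 ? p : 1e-300);
}

// Robbins-Monro tuning of a log proposal scale
static inline void tune(double& ls, bool acc, double tgt, int t) {
  double g = 1.0 / std::pow((double)t + 1.0, 0.6);
  ls += g * ((acc ? 1.0 : 0.0) - tgt);
  if (ls < -12.0) ls = -12.0;
  if (ls > 6.0) ls = 6.0;
}

static inline bool mh_accept(double logratio) {
  if (!R_finite(logratio)) return false;
  return std::log(unif_rand()) < logratio;
}

// half-normal (sd 2.5) prior on a standard-deviation-like parameter
// sampled on the log-variance scale: x = log v, sigma = exp(x/2); the
// Jacobian into x-space is included.  Weakly informative for phenotypes on
// a standardized scale; a wider prior (e.g. half-normal sd 10) leaves the
// weakly identified latent scale of item-level fits prior-dominated.
static inline double prior_logvar(double x) {
  return -std::exp(x) / 12.5 + 0.5 * x;
}
// N(0, 10^2) prior on an unconstrained coefficient
static inline double prior_coef(double b) { return -b * b / 200.0; }
// half-normal (sd 5) on a discrimination / Cholesky diagonal sampled on
// the log scale (Jacobian included)
static inline double prior_logalpha(double la) {
  double a = std::exp(la);
  return -a * a / 50.0 + la;
}

struct ItemBankState {
  int J;
  std::vector<double> alpha;               // alpha[0] fixed at 1 when fixed_first
  std::vector<std::vector<double> > thr;   // per item, ordered
  std::vector<int> ncat;
  bool fixed_first;

  void init(IntegerVector ncat_, List thr_init, NumericVector alpha_init,
            bool fixed_first_) {
    J = ncat_.size();
    fixed_first = fixed_first_;
    ncat.assign(ncat_.begin(), ncat_.end());
    alpha.assign(alpha_init.begin(), alpha_init.end());
    thr.resize(J);
    for (int j = 0; j < J; ++j) {
      NumericVector tj = thr_init[j];
      thr[j].assign(tj.begin(), tj.end());
    }
  }
};

// log-likelihood of one twin's responses on one item bank
static inline double bank_ll_row(const IntegerMatrix& Y, int t,
                                 const ItemBankState& B, double theta) {
  double ll = 0.0;
  for (int j = 0; j < B.J; ++j) {
    int y = Y(t, j);
    if (y > 0) ll += grm_logp(y, theta, B.alpha[j], B.thr[j]);
  }
  return ll;
}

// item-parameter updates for one bank given current thetas; returns nothing
// but mutates bank state and its tuning scales.  ll_item(t, j, alpha, thr)
// is evaluated over all twins with an observed response on item j.
struct BankSampler {
  ItemBankState B;
  std::vector<double> ls_thr, ls_alpha;
  std::vector<std::vector<int> > obs;   // twins with observed response per item
  const IntegerMatrix* Y;

  void setup(const IntegerMatrix& Ym, IntegerVector ncat_, List thr_init,
             NumericVector alpha_init, bool fixed_first) {
    Y = &Ym;
    B.init(ncat_, thr_init, alpha_init, fixed_first);
    ls_thr.assign(B.J, std::log(0.05));
    ls_alpha.assign(B.J, std::log(0.05));
    obs.resize(B.J);
    for (int j = 0; j < B.J; ++j)
      for (int t = 0; t < Ym.nrow(); ++t)
        if (Ym(t, j) > 0) obs[j].push_back(t);
  }

  double item_ll(int j, double alpha, const std::vector<double>& thr,
                 const std::vector<double>& theta) const {
    double ll = 0.0;
    const IntegerMatrix& Ym = *Y;
    for (size_t i = 0; i < obs[j].size(); ++i) {
      int t = obs[j][i];
      ll += grm_logp(Ym(t, j), theta[t], alpha, thr);
    }
    return ll;
  }

  // pieces for the joint latent-scale move: log-likelihood change of the
  // first (fixed-discrimination) item when theta and its thresholds are
  // both scaled by exp(eps) -- all other items are kept invariant by
  // scaling their thresholds and dividing their discriminations
  double ll0_scaled_diff(const std::vector<double>& theta, double c) const {
    std::vector<double> thrs = B.thr[0];
    for (size_t k = 0; k < thrs.size(); ++k) thrs[k] *= c;
    double d = 0.0;
    const IntegerMatrix& Ym = *Y;
    for (size_t i = 0; i < obs[0].size(); ++i) {
      int t = obs[0][i];
      d += grm_logp(Ym(t, 0), c * theta[t], B.alpha[0], thrs) -
           grm_logp(Ym(t, 0), theta[t], B.alpha[0], B.thr[0]);
    }
    return d;
  }
  // prior change from scaling all thresholds by exp(eps) and shifting all
  // free log-discriminations by -eps; n_thr counts the scaled coordinates
  double scale_prior_diff(double eps, int& n_thr) const {
    double c = std::exp(eps), d = 0.0;
    n_thr = 0;
    for (int j = 0; j < B.J; ++j)
      for (size_t k = 0; k < B.thr[j].size(); ++k) {
        d += prior_coef(c * B.thr[j][k]) - prior_coef(B.thr[j][k]);
        ++n_thr;
      }
    for (int j = 0; j < B.J; ++j) {
      if (B.fixed_first && j == 0) continue;
      double la = std::log(B.alpha[j]);
      d += prior_logalpha(la - eps) - prior_logalpha(la);
    }
    return d;
  }
  void apply_scale(double eps) {
    double c = std::exp(eps);
    for (int j = 0; j < B.J; ++j) {
      for (size_t k = 0; k < B.thr[j].size(); ++k) B.thr[j][k] *= c;
      if (!(B.fixed_first && j == 0)) B.alpha[j] *= std::exp(-eps);
    }
  }

  void update(const std::vector<double>& theta, bool adapt, int it) {
    for (int j = 0; j < B.J; ++j) {
      // thresholds jointly
      std::vector<double> prop = B.thr[j];
      double sc = std::exp(ls_thr[j]);
      bool ok = true;
      double dprior = 0.0;
      for (size_t k = 0; k < prop.size(); ++k) {
        double nw = prop[k] + sc * norm_rand();
        dprior += prior_coef(nw) - prior_coef(prop[k]);
        prop[k] = nw;
        if (k > 0 && prop[k] <= prop[k - 1]) ok = false;
      }
      bool acc = false;
      if (ok) {
        double d = item_ll(j, B.alpha[j], prop, theta) -
                   item_ll(j, B.alpha[j], B.thr[j], theta) + dprior;
        if (mh_accept(d)) { B.thr[j] = prop; acc = true; }
      }
      if (adapt) tune(ls_thr[j], acc, 0.234, it);

      // discrimination (first item fixed when identified)
      if (!(B.fixed_first && j == 0)) {
        double la = std::log(B.alpha[j]);
        double lap = la + std::exp(ls_alpha[j]) * norm_rand();
        double d = item_ll(j, std::exp(lap), B.thr[j], theta) -
                   item_ll(j, B.alpha[j], B.thr[j], theta) +
                   prior_logalpha(lap) - prior_logalpha(la);
        bool acc2 = mh_accept(d);
        if (acc2) B.alpha[j] = std::exp(lap);
        if (adapt) tune(ls_alpha[j], acc2, 0.44, it);
      }
    }
  }
};

// family bookkeeping shared by samplers
struct Families {
  int n, n_fam;
  std::vector<int> fam, zyg, cotwin;          // per twin
  std::vector<int> fzyg;                      // per family
  std::vector<std::vector<int> > members;     // twins per family
  void setup(IntegerVector fam_, IntegerVector zyg_, IntegerVector cotwin_) {
    n = fam_.size();
    fam.assign(fam_.begin(), fam_.end());
    zyg.assign(zyg_.begin(), zyg_.end());
    cotwin.assign(cotwin_.begin(), cotwin_.end());
    n_fam = 0;
    for (int t = 0; t < n; ++t) n_fam = std::max(n_fam, fam[t] + 1);
    members.assign(n_fam, std::vector<int>());
    fzyg.assign(n_fam, 0);
    for (int t = 0; t < n; ++t) {
      members[fam[t]].push_back(t);
      fzyg[fam[t]] = zyg[t];
    }
  }
};

static const double R5 = 0.70710678118654752;

// =====================================================================
// univariate (unmeasured GxE) sampler, sum-score or item-level form
// =====================================================================

// [[Rcpp::export]]
List mcmc_univariate_cpp(List dat, List opts) {
  Families F;
  F.setup(dat["fam"], dat["zyg"], dat["cotwin"]);
  int n = F.n;
  NumericVector sex = dat["sex"], age = dat["age"];
  LogicalVector age_miss = dat["age_miss"];
  bool item_level = as<bool>(dat["item_level"]);
  bool gxe = as<bool>(opts["gxe"]);
  int n_burn = as<int>(opts["n_burn"]), n_iter = as<int>(opts["n_iter"]);
  int thin = as<int>(opts["thin"]);

  NumericVector ysum;
  IntegerMatrix Y;
  BankSampler bank;
  if (item_level) {
    Y = as<IntegerMatrix>(dat["Y"]);
    bank.setup(Y, dat["ncat"], opts["thr_init"], opts["alpha_init"], true);
  } else {
    ysum = dat["ysum"];
  }

  // state
  List init = opts["init"];
  double bsex = as<double>(init["beta_sex"]), bage = as<double>(init["beta_age"]);
  double lsa = as<double>(init["log_var_a"]);
  double b0 = as<double>(init["beta0"]), b1 = as<double>(init["beta1"]);
  std::vector<double> th(n, 0.0);
  if (item_level) {
    NumericVector th0 = init["theta"];
    th.assign(th0.begin(), th0.end());
  } else {
    for (int t = 0; t < n; ++t) th[t] = ysum[t];
  }
  std::vector<double> g(F.n_fam, 0.0), s(n, 0.0);   // genetic primitives
  std::vector<double> agev(age.begin(), age.end());
  std::vector<int> miss_idx;
  for (int t = 0; t < n; ++t) if (age_miss[t]) { agev[t] = 0.0; miss_idx.push_back(t); }

  double vA = std::exp(lsa), sdA = std::sqrt(vA);

  // tuning
  std::vector<double> ls_th(n, std::log(0.5)), ls_g(F.n_fam, std::log(0.5)),
      ls_s(n, std::log(0.5));
  double ls_bsex = std::log(0.1), ls_bage = std::log(0.1), ls_b0 = std::log(0.1),
      ls_b1 = std::log(0.1), ls_lsa = std::log(0.3), ls_scale = std::log(0.1),
      ls_agem = std::log(0.5), ls_gsc = std::log(0.05);

  int n_s_lat = 0;
  for (int t = 0; t < n; ++t) if (F.zyg[t] == 1) ++n_s_lat;

  // A value of twin t
  #define A_OF(t) (F.zyg[t] == 0 ? g[F.fam[t]] : R5 * (g[F.fam[t]] + s[t]))

  // phenotype-layer term of twin t with genetic value a and phenotype value p
  #define STRUCT(t, p, a) \
    ldnorm((p), bsex * sex[t] + bage * agev[t] + (a), \
           std::sqrt(std::exp(b0 + b1 * (a))))

  int n_keep = n_iter / thin;
  int npar = 6;                          // bsex bage var_a b0 b1 deviance
  std::vector<std::string> nm = {"beta_sex", "beta_age", "var_a", "beta0",
                                 "beta1", "deviance"};
  if (item_level) {
    for (int j = 1; j < bank.B.J; ++j)
      nm.push_back("alpha" + std::to_string(j + 1));
    for (int j = 0; j < bank.B.J; ++j)
      for (int k = 0; k + 1 < bank.B.ncat[j]; ++k)
        nm.push_back("thr" + std::to_string(j + 1) + "_" + std::to_string(k + 1));
    npar = (int)nm.size();
  }
  NumericMatrix draws(n_keep, npar);

  // accumulators for the plug-in deviance
  std::vector<double> sum_th(n, 0.0), sum_A(n, 0.0);
  double sum_bsex = 0, sum_bage = 0, sum_b0 = 0, sum_b1 = 0;
  std::vector<double> sum_age(n, 0.0);
  std::vector<double> sum_alpha, sum_thr_flat;
  if (item_level) {
    sum_alpha.assign(bank.B.J, 0.0);
    int tot = 0; for (int j = 0; j < bank.B.J; ++j) tot += bank.B.ncat[j] - 1;
    sum_thr_flat.assign(tot, 0.0);
  }

  int total_it = n_burn + n_iter;
  int kept = 0;
  for (int it = 0; it < total_it; ++it) {
    bool adapt = it < n_burn;

    // latent phenotypes
    if (item_level) {
      for (int t = 0; t < n; ++t) {
        double a = A_OF(t);
        double prop = th[t] + std::exp(ls_th[t]) * norm_rand();
        double d = bank_ll_row(Y, t, bank.B, prop) - bank_ll_row(Y, t, bank.B, th[t]) +
                   STRUCT(t, prop, a) - STRUCT(t, th[t], a);
        bool acc = mh_accept(d);
        if (acc) th[t] = prop;
        if (adapt) tune(ls_th[t], acc, 0.44, it);
      }
    }

    // family-common genetic values
    for (int f = 0; f < F.n_fam; ++f) {
      double prop = g[f] + std::exp(ls_g[f]) * norm_rand();
      double d = ldnorm(prop, 0, sdA) - ldnorm(g[f], 0, sdA);
      for (size_t i = 0; i < F.members[f].size(); ++i) {
        int t = F.members[f][i];
        double a_new = (F.fzyg[f] == 0) ? prop : R5 * (prop + s[t]);
        d += STRUCT(t, th[t], a_new) - STRUCT(t, th[t], A_OF(t));
      }
      bool acc = mh_accept(d);
      if (acc) g[f] = prop;
      if (adapt) tune(ls_g[f], acc, 0.44, it);
    }

    // DZ twin-specific genetic values
    for (int t = 0; t < n; ++t) {
      if (F.zyg[t] != 1) continue;
      double prop = s[t] + std::exp(ls_s[t]) * norm_rand();
      double a_new = R5 * (g[F.fam[t]] + prop);
      double d = ldnorm(prop, 0, sdA) - ldnorm(s[t], 0, sdA) +
                 STRUCT(t, th[t], a_new) - STRUCT(t, th[t], A_OF(t));
      bool acc = mh_accept(d);
      if (acc) s[t] = prop;
      if (adapt) tune(ls_s[t], acc, 0.44, it);
    }

    // joint rescale of (g, s, sigma_A): Jacobian cancels against the
    // N(0, sigma_A) prior terms, leaving the structural and lsa-prior parts
    {
      double eps = std::exp(ls_scale) * norm_rand();
      double c = std::exp(eps);
      double d = prior_logvar(lsa + 2 * eps) - prior_logvar(lsa);
      for (int t = 0; t < n; ++t) {
        double a_new = c * A_OF(t);
        d += STRUCT(t, th[t], a_new) - STRUCT(t, th[t], A_OF(t));
      }
      bool acc = mh_accept(d);
      if (acc) {
        for (int f = 0; f < F.n_fam; ++f) g[f] *= c;
        for (int t = 0; t < n; ++t) s[t] *= c;
        lsa += 2 * eps; vA = std::exp(lsa); sdA = std::sqrt(vA);
      }
      if (adapt) tune(ls_scale, acc, 0.44, it);
    }

    // genetic variance given latents
    {
      double prop = lsa + std::exp(ls_lsa) * norm_rand();
      double sdp = std::sqrt(std::exp(prop));
      double d = prior_logvar(prop) - prior_logvar(lsa);
      for (int f = 0; f < F.n_fam; ++f)
        d += ldnorm(g[f], 0, sdp) - ldnorm(g[f], 0, sdA);
      for (int t = 0; t < n; ++t)
        if (F.zyg[t] == 1) d += ldnorm(s[t], 0, sdp) - ldnorm(s[t], 0, sdA);
      bool acc = mh_accept(d);
      if (acc) { lsa = prop; vA = std::exp(lsa); sdA = std::sqrt(vA); }
      if (adapt) tune(ls_lsa, acc, 0.44, it);
    }

    // structural coefficients
    struct Prop { double* par; double* ls; };
    double* pars[4] = {&bsex, &bage, &b0, &b1};
    double* lss[4] = {&ls_bsex, &ls_bage, &ls_b0, &ls_b1};
    int nupd = gxe ? 4 : 3;
    for (int u = 0; u < nupd; ++u) {
      double old = *pars[u];
      double prop = old + std::exp(*lss[u]) * norm_rand();
      double d = prior_coef(prop) - prior_coef(old);
      double base = 0.0;
      for (int t = 0; t < n; ++t) base += STRUCT(t, th[t], A_OF(t));
      *pars[u] = prop;
      double nw = 0.0;
      for (int t = 0; t < n; ++t) nw += STRUCT(t, th[t], A_OF(t));
      double dd = d + nw - base;
      bool acc = mh_accept(dd);
      if (!acc) *pars[u] = old;
      if (adapt) tune(*lss[u], acc, 0.44, it);
    }

    // item parameters
    if (item_level) bank.update(th, adapt, it);

    // joint latent-scale move: rescale (theta, A, thresholds, covariate
    // effects, variances) while dividing free discriminations, leaving all
    // likelihood terms invariant except the first (identifying) item; the
    // theta and genetic-latent Jacobians cancel against the structural and
    // genetic prior changes, which are therefore omitted on both sides
    if (item_level) {
      double eps = std::exp(ls_gsc) * norm_rand();
      double c = std::exp(eps);
      int n_thr = 0;
      double d = bank.ll0_scaled_diff(th, c) + bank.scale_prior_diff(eps, n_thr);
      d += prior_coef(c * bsex) - prior_coef(bsex) +
           prior_coef(c * bage) - prior_coef(bage) +
           prior_coef(b0 + 2 * eps) - prior_coef(b0) +
           prior_logvar(lsa + 2 * eps) - prior_logvar(lsa);
      double njac = n_thr + 2;
      if (gxe) { d += prior_coef(b1 / c) - prior_coef(b1); njac -= 1; }
      d += njac * eps;
      bool acc = mh_accept(d);
      if (acc) {
        bank.apply_scale(eps);
        for (int t = 0; t < n; ++t) th[t] *= c;
        for (int f = 0; f < F.n_fam; ++f) g[f] *= c;
        for (int t = 0; t < n; ++t) s[t] *= c;
        bsex *= c; bage *= c; b0 += 2 * eps;
        if (gxe) b1 /= c;
        lsa += 2 * eps; vA = std::exp(lsa); sdA = std::sqrt(vA);
      }
      if (adapt) tune(ls_gsc, acc, 0.44, it);
    }

    // missing ages, N(0, 10) prior (variance 10)
    for (size_t i = 0; i < miss_idx.size(); ++i) {
      int t = miss_idx[i];
      double prop = agev[t] + std::exp(ls_agem) * norm_rand();
      double old = agev[t];
      double d = ldnorm(prop, 0, std::sqrt(10.0)) - ldnorm(old, 0, std::sqrt(10.0));
      double a = A_OF(t);
      double base = STRUCT(t, th[t], a);
      agev[t] = prop;
      d += STRUCT(t, th[t], a) - base;
      bool acc = mh_accept(d);
      if (!acc) agev[t] = old;
      if (adapt && i == 0) tune(ls_agem, acc, 0.44, it);
    }

    // record
    if (!adapt && ((it - n_burn) % thin == 0) && kept < n_keep) {
      // observed-data deviance: item responses given theta (item form),
      // standardized sums given A and structure (sum form)
      double dev = 0.0;
      for (int t = 0; t < n; ++t) {
        if (item_level) dev += bank_ll_row(Y, t, bank.B, th[t]);
        else dev += STRUCT(t, th[t], A_OF(t));
      }
      dev *= -2.0;
      draws(kept, 0) = bsex; draws(kept, 1) = bage; draws(kept, 2) = vA;
      draws(kept, 3) = b0; draws(kept, 4) = b1; draws(kept, 5) = dev;
      if (item_level) {
        int c = 6;
        for (int j = 1; j < bank.B.J; ++j) draws(kept, c++) = bank.B.alpha[j];
        for (int j = 0; j < bank.B.J; ++j)
          for (int k = 0; k + 1 < bank.B.ncat[j]; ++k)
            draws(kept, c++) = bank.B.thr[j][k];
      }
      sum_bsex += bsex; sum_bage += bage; sum_b0 += b0; sum_b1 += b1;
      for (int t = 0; t < n; ++t) {
        sum_th[t] += th[t]; sum_A[t] += A_OF(t); sum_age[t] += agev[t];
      }
      if (item_level) {
        int c = 0;
        for (int j = 0; j < bank.B.J; ++j) sum_alpha[j] += bank.B.alpha[j];
        for (int j = 0; j < bank.B.J; ++j)
          for (int k = 0; k + 1 < bank.B.ncat[j]; ++k)
            sum_thr_flat[c++] += bank.B.thr[j][k];
      }
      ++kept;
    }
  }

  // plug-in deviance at posterior means
  double m = (double)kept;
  double pb_sex = sum_bsex / m, pb_age = sum_bage / m, pb0 = sum_b0 / m,
      pb1 = sum_b1 / m;
  std::vector<double> pth(n), pA(n), page(n);
  for (int t = 0; t < n; ++t) {
    pth[t] = sum_th[t] / m; pA[t] = sum_A[t] / m; page[t] = sum_age[t] / m;
  }
  ItemBankState pB = bank.B;
  if (item_level) {
    int c = 0;
    for (int j = 0; j < pB.J; ++j) pB.alpha[j] = sum_alpha[j] / m;
    for (int j = 0; j < pB.J; ++j)
      for (int k = 0; k + 1 < pB.ncat[j]; ++k) pB.thr[j][k] = sum_thr_flat[c++] / m;
  }
  double dhat = 0.0;
  for (int t = 0; t < n; ++t) {
    if (item_level) {
      dhat += bank_ll_row(Y, t, pB, pth[t]);
    } else {
      double mu = pb_sex * sex[t] + pb_age * page[t] + pA[t];
      double sd = std::sqrt(std::exp(pb0 + pb1 * pA[t]));
      dhat += ldnorm(ysum[t], mu, sd);
    }
  }
  dhat *= -2.0;

  List post_mean = List::create(
      _["beta_sex"] = pb_sex, _["beta_age"] = pb_age, _["beta0"] = pb0,
      _["beta1"] = pb1, _["theta"] = NumericVector(pth.begin(), pth.end()),
      _["A"] = NumericVector(pA.begin(), pA.end()),
      _["age"] = NumericVector(page.begin(), page.end()));
  if (item_level) {
    post_mean["alpha"] = NumericVector(pB.alpha.begin(), pB.alpha.end());
    List thl(pB.J);
    for (int j = 0; j < pB.J; ++j)
      thl[j] = NumericVector(pB.thr[j].begin(), pB.thr[j].end());
    post_mean["thresholds"] = thl;
  }

  colnames(draws) = wrap(nm);
  return List::create(_["draws"] = draws, _["dhat"] = dhat,
                      _["post_mean"] = post_mean);
  #undef A_OF
  #undef STRUCT
}

// =====================================================================
// measured-moderator GxE sampler, sum-score or item-level form
// =====================================================================

// [[Rcpp::export]]
List mcmc_measured_cpp(List dat, List opts) {
  Families F;
  F.setup(dat["fam"], dat["zyg"], dat["cotwin"]);
  int n = F.n;
  NumericVector sex = dat["sex"], age = dat["age"];
  LogicalVector age_miss = dat["age_miss"];
  bool item_level = as<bool>(dat["item_level"]);
  bool gxe = as<bool>(opts["gxe"]);
  int n_burn = as<int>(opts["n_burn"]), n_iter = as<int>(opts["n_iter"]);
  int thin = as<int>(opts["thin"]);

  NumericVector ysum, msum;
  LogicalVector m_miss;
  IntegerMatrix Yt, Ym;
  BankSampler bank_t, bank_m;
  if (item_level) {
    Yt = as<IntegerMatrix>(dat["Y"]);
    Ym = as<IntegerMatrix>(dat["Ym"]);
    bank_t.setup(Yt, dat["ncat"], opts["thr_init"], opts["alpha_init"], true);
    bank_m.setup(Ym, dat["ncat_m"], opts["thr_init_m"], opts["alpha_init_m"], true);
  } else {
    ysum = dat["ysum"];
    msum = dat["msum"];
    m_miss = dat["m_miss"];
  }

  List init = opts["init"];
  double bsex = as<double>(init["beta_sex"]), bage = as<double>(init["beta_age"]);
  double b1mz = as<double>(init["beta1_mz"]), b2mz = as<double>(init["beta2_mz"]);
  double b1dz = as<double>(init["beta1_dz"]), b2dz = as<double>(init["beta2_dz"]);
  double b0a = as<double>(init["beta0a"]), b1a = as<double>(init["beta1a"]);
  double b0e = as<double>(init["beta0e"]), b1e = as<double>(init["beta1e"]);
  double lsam = as<double>(init["log_var_a_mod"]);
  double lsem = as<double>(init["log_var_e_mod"]);

  std::vector<double> th(n, 0.0), M(n, 0.0);
  if (item_level) {
    NumericVector th0 = init["theta"], M0 = init["M"];
    th.assign(th0.begin(), th0.end());
    M.assign(M0.begin(), M0.end());
  } else {
    for (int t = 0; t < n; ++t) {
      th[t] = ysum[t];
      M[t] = m_miss[t] ? 0.0 : msum[t];
    }
  }
  std::vector<double> ug(F.n_fam, 0.0), us(n, 0.0);   // standard-normal trait A
  std::vector<double> gm(F.n_fam, 0.0), sm(n, 0.0);   // moderator A primitives
  std::vector<double> agev(age.begin(), age.end());
  std::vector<int> miss_idx, mmiss_idx;
  for (int t = 0; t < n; ++t) if (age_miss[t]) { agev[t] = 0.0; miss_idx.push_back(t); }
  if (!item_level)
    for (int t = 0; t < n; ++t) if (m_miss[t]) mmiss_idx.push_back(t);

  double vAm = std::exp(lsam), sdAm = std::sqrt(vAm);
  double sdEm = std::sqrt(std::exp(lsem));

  std::vector<double> ls_th(n, std::log(0.5)), ls_M(n, std::log(0.5)),
      ls_ug(F.n_fam, std::log(0.5)), ls_us(n, std::log(0.5)),
      ls_gm(F.n_fam, std::log(0.5)), ls_sm(n, std::log(0.5));
  double ls_sc[12];
  for (int i = 0; i < 12; ++i) ls_sc[i] = std::log(0.1);
  double ls_lsam = std::log(0.3), ls_lsem = std::log(0.3),
      ls_scalem = std::log(0.1), ls_iw = std::log(0.1),
      ls_agem = std::log(0.5), ls_mmiss = std::log(0.5),
      ls_gsct = std::log(0.05), ls_gscm = std::log(0.05);

  int n_u = F.n_fam;               // count of ug coords
  for (int t = 0; t < n; ++t) if (F.zyg[t] == 1) ++n_u;   // plus us coords

  #define ASTD(t) (F.zyg[t] == 0 ? ug[F.fam[t]] : R5 * (ug[F.fam[t]] + us[t]))
  #define AMOD(t) (F.zyg[t] == 0 ? gm[F.fam[t]] : R5 * (gm[F.fam[t]] + sm[t]))

  // trait phenotype-layer term for twin t given its own moderator value mv,
  // co-twin moderator mcv (ignored for singletons), standard genetic u
  auto tstruct = [&](int t, double phen, double mv, double mcv, double u) {
    double b1 = (F.zyg[t] == 0) ? b1mz : b1dz;
    double b2 = (F.zyg[t] == 0) ? b2mz : b2dz;
    double mu = bsex * sex[t] + bage * agev[t] + b1 * mv;
    if (F.cotwin[t] >= 0) mu += b2 * mcv;
    mu += std::sqrt(std::exp(b0a + b1a * mv)) * u;
    double sd = std::sqrt(std::exp(b0e + b1e * mv));
    return ldnorm(phen, mu, sd);
  };
  auto phen_of = [&](int t) { return item_level ? th[t] : (double)ysum[t]; };
  auto mco_of = [&](int t) { return F.cotwin[t] >= 0 ? M[F.cotwin[t]] : 0.0; };
  auto tstruct_cur = [&](int t) {
    return tstruct(t, phen_of(t), M[t], mco_of(t), ASTD(t));
  };
  // moderator phenotype-layer term (item form only)
  auto mstruct = [&](int t, double mv, double am) {
    return ldnorm(mv, am, sdEm);
  };

  int total_it = n_burn + n_iter;
  int n_keep = n_iter / thin;
  std::vector<std::string> nm = {"beta_sex", "beta_age", "beta1_mz", "beta2_mz",
                                 "beta1_dz", "beta2_dz", "beta0a", "beta1a",
                                 "beta0e", "beta1e", "var_a_mod", "var_e_mod",
                                 "deviance"};
  if (item_level) {
    for (int j = 1; j < bank_t.B.J; ++j)
      nm.push_back("y_alpha" + std::to_string(j + 1));
    for (int j = 0; j < bank_t.B.J; ++j)
      for (int k = 0; k + 1 < bank_t.B.ncat[j]; ++k)
        nm.push_back("y_thr" + std::to_string(j + 1) + "_" + std::to_string(k + 1));
    for (int j = 1; j < bank_m.B.J; ++j)
      nm.push_back("m_alpha" + std::to_string(j + 1));
    for (int j = 0; j < bank_m.B.J; ++j)
      for (int k = 0; k + 1 < bank_m.B.ncat[j]; ++k)
        nm.push_back("m_thr" + std::to_string(j + 1) + "_" + std::to_string(k + 1));
  }
  NumericMatrix draws(n_keep, (int)nm.size());

  // plug-in accumulators
  double s_bsex = 0, s_bage = 0, s_b1mz = 0, s_b2mz = 0, s_b1dz = 0, s_b2dz = 0,
      s_b0a = 0, s_b1a = 0, s_b0e = 0, s_b1e = 0, s_lsem = 0;
  std::vector<double> s_th(n, 0), s_M(n, 0), s_u(n, 0), s_am(n, 0), s_age(n, 0);
  std::vector<double> s_alpha_t, s_thr_t, s_alpha_m, s_thr_m;
  if (item_level) {
    s_alpha_t.assign(bank_t.B.J, 0);
    int tot = 0; for (int j = 0; j < bank_t.B.J; ++j) tot += bank_t.B.ncat[j] - 1;
    s_thr_t.assign(tot, 0);
    s_alpha_m.assign(bank_m.B.J, 0);
    tot = 0; for (int j = 0; j < bank_m.B.J; ++j) tot += bank_m.B.ncat[j] - 1;
    s_thr_m.assign(tot, 0);
  }

  int kept = 0;
  for (int it = 0; it < total_it; ++it) {
    bool adapt = it < n_burn;

    if (item_level) {
      // trait latents
      for (int t = 0; t < n; ++t) {
        double prop = th[t] + std::exp(ls_th[t]) * norm_rand();
        double d = bank_ll_row(Yt, t, bank_t.B, prop) -
                   bank_ll_row(Yt, t, bank_t.B, th[t]) +
                   tstruct(t, prop, M[t], mco_of(t), ASTD(t)) - tstruct_cur(t);
        bool acc = mh_accept(d);
        if (acc) th[t] = prop;
        if (adapt) tune(ls_th[t], acc, 0.44, it);
      }
      // moderator latents: own items + own structure + own trait layer +
      // co-twin trait layer (through the cross-twin mean effect)
      for (int t = 0; t < n; ++t) {
        double prop = M[t] + std::exp(ls_M[t]) * norm_rand();
        int c = F.cotwin[t];
        double d = bank_ll_row(Ym, t, bank_m.B, prop) -
                   bank_ll_row(Ym, t, bank_m.B, M[t]) +
                   mstruct(t, prop, AMOD(t)) - mstruct(t, M[t], AMOD(t)) +
                   tstruct(t, phen_of(t), prop, mco_of(t), ASTD(t)) -
                   tstruct_cur(t);
        if (c >= 0)
          d += tstruct(c, phen_of(c), M[c], prop, ASTD(c)) - tstruct_cur(c);
        bool acc = mh_accept(d);
        if (acc) M[t] = prop;
        if (adapt) tune(ls_M[t], acc, 0.44, it);
      }
      // moderator genetic primitives
      for (int f = 0; f < F.n_fam; ++f) {
        double prop = gm[f] + std::exp(ls_gm[f]) * norm_rand();
        double d = ldnorm(prop, 0, sdAm) - ldnorm(gm[f], 0, sdAm);
        for (size_t i = 0; i < F.members[f].size(); ++i) {
          int t = F.members[f][i];
          double am_new = (F.fzyg[f] == 0) ? prop : R5 * (prop + sm[t]);
          d += mstruct(t, M[t], am_new) - mstruct(t, M[t], AMOD(t));
        }
        bool acc = mh_accept(d);
        if (acc) gm[f] = prop;
        if (adapt) tune(ls_gm[f], acc, 0.44, it);
      }
      for (int t = 0; t < n; ++t) {
        if (F.zyg[t] != 1) continue;
        double prop = sm[t] + std::exp(ls_sm[t]) * norm_rand();
        double am_new = R5 * (gm[F.fam[t]] + prop);
        double d = ldnorm(prop, 0, sdAm) - ldnorm(sm[t], 0, sdAm) +
                   mstruct(t, M[t], am_new) - mstruct(t, M[t], AMOD(t));
        bool acc = mh_accept(d);
        if (acc) sm[t] = prop;
        if (adapt) tune(ls_sm[t], acc, 0.44, it);
      }
      // rescale (gm, sm, sigma_Am)
      {
        double eps = std::exp(ls_scalem) * norm_rand();
        double c = std::exp(eps);
        double d = prior_logvar(lsam + 2 * eps) - prior_logvar(lsam);
        for (int t = 0; t < n; ++t)
          d += mstruct(t, M[t], c * AMOD(t)) - mstruct(t, M[t], AMOD(t));
        bool acc = mh_accept(d);
        if (acc) {
          for (int f = 0; f < F.n_fam; ++f) gm[f] *= c;
          for (int t = 0; t < n; ++t) sm[t] *= c;
          lsam += 2 * eps; vAm = std::exp(lsam); sdAm = std::sqrt(vAm);
        }
        if (adapt) tune(ls_scalem, acc, 0.44, it);
      }
      // moderator variances
      {
        double prop = lsam + std::exp(ls_lsam) * norm_rand();
        double sdp = std::sqrt(std::exp(prop));
        double d = prior_logvar(prop) - prior_logvar(lsam);
        for (int f = 0; f < F.n_fam; ++f)
          d += ldnorm(gm[f], 0, sdp) - ldnorm(gm[f], 0, sdAm);
        for (int t = 0; t < n; ++t)
          if (F.zyg[t] == 1) d += ldnorm(sm[t], 0, sdp) - ldnorm(sm[t], 0, sdAm);
        bool acc = mh_accept(d);
        if (acc) { lsam = prop; vAm = std::exp(lsam); sdAm = std::sqrt(vAm); }
        if (adapt) tune(ls_lsam, acc, 0.44, it);
      }
      {
        double prop = lsem + std::exp(ls_lsem) * norm_rand();
        double sdp = std::sqrt(std::exp(prop));
        double d = prior_logvar(prop) - prior_logvar(lsem);
        for (int t = 0; t < n; ++t)
          d += ldnorm(M[t], AMOD(t), sdp) - ldnorm(M[t], AMOD(t), sdEm);
        bool acc = mh_accept(d);
        if (acc) { lsem = prop; sdEm = std::sqrt(std::exp(lsem)); }
        if (adapt) tune(ls_lsem, acc, 0.44, it);
      }
    } else {
      // sum form: impute missing moderator values, N(0, 10) prior
      for (size_t i = 0; i < mmiss_idx.size(); ++i) {
        int t = mmiss_idx[i];
        int c = F.cotwin[t];
        double old = M[t];
        double prop = old + std::exp(ls_mmiss) * norm_rand();
        double d = ldnorm(prop, 0, std::sqrt(10.0)) -
                   ldnorm(old, 0, std::sqrt(10.0)) +
                   tstruct(t, phen_of(t), prop, mco_of(t), ASTD(t)) -
                   tstruct_cur(t);
        if (c >= 0)
          d += tstruct(c, phen_of(c), M[c], prop, ASTD(c)) - tstruct_cur(c);
        bool acc = mh_accept(d);
        if (acc) M[t] = prop;
        if (adapt && i == 0) tune(ls_mmiss, acc, 0.44, it);
      }
    }

    // trait standard genetic latents
    for (int f = 0; f < F.n_fam; ++f) {
      double prop = ug[f] + std::exp(ls_ug[f]) * norm_rand();
      double d = ldnorm(prop, 0, 1) - ldnorm(ug[f], 0, 1);
      for (size_t i = 0; i < F.members[f].size(); ++i) {
        int t = F.members[f][i];
        double u_new = (F.fzyg[f] == 0) ? prop : R5 * (prop + us[t]);
        d += tstruct(t, phen_of(t), M[t], mco_of(t), u_new) - tstruct_cur(t);
      }
      bool acc = mh_accept(d);
      if (acc) ug[f] = prop;
      if (adapt) tune(ls_ug[f], acc, 0.44, it);
    }
    for (int t = 0; t < n; ++t) {
      if (F.zyg[t] != 1) continue;
      double prop = us[t] + std::exp(ls_us[t]) * norm_rand();
      double u_new = R5 * (ug[F.fam[t]] + prop);
      double d = ldnorm(prop, 0, 1) - ldnorm(us[t], 0, 1) +
                 tstruct(t, phen_of(t), M[t], mco_of(t), u_new) - tstruct_cur(t);
      bool acc = mh_accept(d);
      if (acc) us[t] = prop;
      if (adapt) tune(ls_us[t], acc, 0.44, it);
    }

    // interweaving move: rescale standard genetic latents against beta0a,
    // leaving every genetic contribution sqrt(exp(b0a + b1a M)) * u invariant
    {
      double eps = std::exp(ls_iw) * norm_rand();
      double c = std::exp(eps);
      double d = prior_coef(b0a - 2 * eps) - prior_coef(b0a) + n_u * eps;
      for (int f = 0; f < F.n_fam; ++f)
        d += ldnorm(c * ug[f], 0, 1) - ldnorm(ug[f], 0, 1);
      for (int t = 0; t < n; ++t)
        if (F.zyg[t] == 1) d += ldnorm(c * us[t], 0, 1) - ldnorm(us[t], 0, 1);
      bool acc = mh_accept(d);
      if (acc) {
        for (int f = 0; f < F.n_fam; ++f) ug[f] *= c;
        for (int t = 0; t < n; ++t) us[t] *= c;
        b0a -= 2 * eps;
      }
      if (adapt) tune(ls_iw, acc, 0.44, it);
    }

    // structural coefficients
    {
      double* pars[10] = {&bsex, &bage, &b1mz, &b2mz, &b1dz, &b2dz,
                          &b0a, &b1a, &b0e, &b1e};
      for (int u = 0; u < 10; ++u) {
        if (!gxe && (u == 7 || u == 9)) continue;   // b1a, b1e fixed at 0
        double old = *pars[u];
        double prop = old + std::exp(ls_sc[u]) * norm_rand();
        double base = 0.0;
        for (int t = 0; t < n; ++t) base += tstruct_cur(t);
        *pars[u] = prop;
        double nw = 0.0;
        for (int t = 0; t < n; ++t) nw += tstruct_cur(t);
        double d = prior_coef(prop) - prior_coef(old) + nw - base;
        bool acc = mh_accept(d);
        if (!acc) *pars[u] = old;
        if (adapt) tune(ls_sc[u], acc, 0.44, it);
      }
    }

    if (item_level) {
      bank_t.update(th, adapt, it);
      bank_m.update(M, adapt, it);

      // joint trait-scale move (see the univariate sampler): only the
      // first trait item resists the rescaling
      {
        double eps = std::exp(ls_gsct) * norm_rand();
        double c = std::exp(eps);
        int n_thr = 0;
        double d = bank_t.ll0_scaled_diff(th, c) +
                   bank_t.scale_prior_diff(eps, n_thr);
        double* sc6[6] = {&bsex, &bage, &b1mz, &b2mz, &b1dz, &b2dz};
        for (int u = 0; u < 6; ++u)
          d += prior_coef(c * *sc6[u]) - prior_coef(*sc6[u]);
        d += prior_coef(b0a + 2 * eps) - prior_coef(b0a) +
             prior_coef(b0e + 2 * eps) - prior_coef(b0e);
        d += (n_thr + 6) * eps;
        bool acc = mh_accept(d);
        if (acc) {
          bank_t.apply_scale(eps);
          for (int t = 0; t < n; ++t) th[t] *= c;
          for (int u = 0; u < 6; ++u) *sc6[u] *= c;
          b0a += 2 * eps; b0e += 2 * eps;
        }
        if (adapt) tune(ls_gsct, acc, 0.44, it);
      }
      // joint moderator-scale move: moderator latents and bank rescale,
      // moderator main effects and moderation slopes divide to keep the
      // trait layer invariant
      {
        double eps = std::exp(ls_gscm) * norm_rand();
        double c = std::exp(eps);
        int n_thr = 0;
        double d = bank_m.ll0_scaled_diff(M, c) +
                   bank_m.scale_prior_diff(eps, n_thr);
        double* dv4[4] = {&b1mz, &b2mz, &b1dz, &b2dz};
        for (int u = 0; u < 4; ++u)
          d += prior_coef(*dv4[u] / c) - prior_coef(*dv4[u]);
        d += prior_logvar(lsam + 2 * eps) - prior_logvar(lsam) +
             prior_logvar(lsem + 2 * eps) - prior_logvar(lsem);
        double njac = n_thr - 4;
        if (gxe) {
          d += prior_coef(b1a / c) - prior_coef(b1a) +
               prior_coef(b1e / c) - prior_coef(b1e);
          njac -= 2;
        }
        d += njac * eps;
        bool acc = mh_accept(d);
        if (acc) {
          bank_m.apply_scale(eps);
          for (int t = 0; t < n; ++t) M[t] *= c;
          for (int f = 0; f < F.n_fam; ++f) gm[f] *= c;
          for (int t = 0; t < n; ++t) sm[t] *= c;
          for (int u = 0; u < 4; ++u) *dv4[u] /= c;
          if (gxe) { b1a /= c; b1e /= c; }
          lsam += 2 * eps; vAm = std::exp(lsam); sdAm = std::sqrt(vAm);
          lsem += 2 * eps; sdEm = std::sqrt(std::exp(lsem));
        }
        if (adapt) tune(ls_gscm, acc, 0.44, it);
      }
    }

    // missing ages
    for (size_t i = 0; i < miss_idx.size(); ++i) {
      int t = miss_idx[i];
      double old = agev[t];
      double prop = old + std::exp(ls_agem) * norm_rand();
      double d = ldnorm(prop, 0, std::sqrt(10.0)) - ldnorm(old, 0, std::sqrt(10.0));
      double base = tstruct_cur(t);
      agev[t] = prop;
      d += tstruct_cur(t) - base;
      bool acc = mh_accept(d);
      if (!acc) agev[t] = old;
      if (adapt && i == 0) tune(ls_agem, acc, 0.44, it);
    }

    if (!adapt && ((it - n_burn) % thin == 0) && kept < n_keep) {
      // observed-data deviance: both banks' responses (item form), the
      // standardized trait sums given structure (sum form)
      double dev = 0.0;
      for (int t = 0; t < n; ++t) {
        if (item_level) {
          dev += bank_ll_row(Yt, t, bank_t.B, th[t]);
          dev += bank_ll_row(Ym, t, bank_m.B, M[t]);
        } else {
          dev += tstruct_cur(t);
        }
      }
      dev *= -2.0;
      double vals[13] = {bsex, bage, b1mz, b2mz, b1dz, b2dz, b0a, b1a, b0e,
                         b1e, vAm, std::exp(lsem), dev};
      for (int c = 0; c < 13; ++c) draws(kept, c) = vals[c];
      if (item_level) {
        int c = 13;
        for (int j = 1; j < bank_t.B.J; ++j) draws(kept, c++) = bank_t.B.alpha[j];
        for (int j = 0; j < bank_t.B.J; ++j)
          for (int k = 0; k + 1 < bank_t.B.ncat[j]; ++k)
            draws(kept, c++) = bank_t.B.thr[j][k];
        for (int j = 1; j < bank_m.B.J; ++j) draws(kept, c++) = bank_m.B.alpha[j];
        for (int j = 0; j < bank_m.B.J; ++j)
          for (int k = 0; k + 1 < bank_m.B.ncat[j]; ++k)
            draws(kept, c++) = bank_m.B.thr[j][k];
      }
      s_bsex += bsex; s_bage += bage; s_b1mz += b1mz; s_b2mz += b2mz;
      s_b1dz += b1dz; s_b2dz += b2dz; s_b0a += b0a; s_b1a += b1a;
      s_b0e += b0e; s_b1e += b1e; s_lsem += lsem;
      for (int t = 0; t < n; ++t) {
        s_th[t] += th[t]; s_M[t] += M[t]; s_u[t] += ASTD(t);
        s_am[t] += AMOD(t); s_age[t] += agev[t];
      }
      if (item_level) {
        int c = 0;
        for (int j = 0; j < bank_t.B.J; ++j) s_alpha_t[j] += bank_t.B.alpha[j];
        for (int j = 0; j < bank_t.B.J; ++j)
          for (int k = 0; k + 1 < bank_t.B.ncat[j]; ++k)
            s_thr_t[c++] += bank_t.B.thr[j][k];
        c = 0;
        for (int j = 0; j < bank_m.B.J; ++j) s_alpha_m[j] += bank_m.B.alpha[j];
        for (int j = 0; j < bank_m.B.J; ++j)
          for (int k = 0; k + 1 < bank_m.B.ncat[j]; ++k)
            s_thr_m[c++] += bank_m.B.thr[j][k];
      }
      ++kept;
    }
  }

  // plug-in deviance at posterior means
  double m = (double)kept;
  double p_bsex = s_bsex / m, p_bage = s_bage / m, p_b1mz = s_b1mz / m,
      p_b2mz = s_b2mz / m, p_b1dz = s_b1dz / m, p_b2dz = s_b2dz / m,
      p_b0a = s_b0a / m, p_b1a = s_b1a / m, p_b0e = s_b0e / m,
      p_b1e = s_b1e / m, p_sdEm = std::sqrt(std::exp(s_lsem / m));
  ItemBankState pBt = bank_t.B, pBm = bank_m.B;
  if (item_level) {
    int c = 0;
    for (int j = 0; j < pBt.J; ++j) pBt.alpha[j] = s_alpha_t[j] / m;
    for (int j = 0; j < pBt.J; ++j)
      for (int k = 0; k + 1 < pBt.ncat[j]; ++k) pBt.thr[j][k] = s_thr_t[c++] / m;
    c = 0;
    for (int j = 0; j < pBm.J; ++j) pBm.alpha[j] = s_alpha_m[j] / m;
    for (int j = 0; j < pBm.J; ++j)
      for (int k = 0; k + 1 < pBm.ncat[j]; ++k) pBm.thr[j][k] = s_thr_m[c++] / m;
  }
  double dhat = 0.0;
  for (int t = 0; t < n; ++t) {
    double mv = s_M[t] / m;
    double mcv = F.cotwin[t] >= 0 ? s_M[F.cotwin[t]] / m : 0.0;
    double b1 = (F.zyg[t] == 0) ? p_b1mz : p_b1dz;
    double b2 = (F.zyg[t] == 0) ? p_b2mz : p_b2dz;
    double mu = p_bsex * sex[t] + p_bage * (s_age[t] / m) + b1 * mv;
    if (F.cotwin[t] >= 0) mu += b2 * mcv;
    mu += std::sqrt(std::exp(p_b0a + p_b1a * mv)) * (s_u[t] / m);
    double sd = std::sqrt(std::exp(p_b0e + p_b1e * mv));
    if (item_level) {
      dhat += bank_ll_row(Yt, t, pBt, s_th[t] / m);
      dhat += bank_ll_row(Ym, t, pBm, mv);
    } else {
      dhat += ldnorm(ysum[t], mu, sd);
    }
  }
  dhat *= -2.0;

  List post_mean = List::create(
      _["theta"] = NumericVector(s_th.begin(), s_th.end()),
      _["M"] = NumericVector(s_M.begin(), s_M.end()),
      _["A_std"] = NumericVector(s_u.begin(), s_u.end()),
      _["A_mod"] = NumericVector(s_am.begin(), s_am.end()));
  for (int t = 0; t < n; ++t) {
    // convert sums to means in place
  }
  NumericVector pm_th = post_mean["theta"], pm_M = post_mean["M"],
      pm_u = post_mean["A_std"], pm_am = post_mean["A_mod"];
  for (int t = 0; t < n; ++t) {
    pm_th[t] /= m; pm_M[t] /= m; pm_u[t] /= m; pm_am[t] /= m;
  }

  colnames(draws) = wrap(nm);
  return List::create(_["draws"] = draws, _["dhat"] = dhat,
                      _["post_mean"] = post_mean);
  #undef ASTD
  #undef AMOD
}

// =====================================================================
// bivariate AE sampler, sum-score or item-level form
// =====================================================================

struct Chol2 {
  double l11, l21, l22;   // lower-triangular factor
  double s11() const { return l11 * l11; }
  double s21() const { return l11 * l21; }
  double s22() const { return l21 * l21 + l22 * l22; }
  // log density of N2(0, L L') at (x1, x2), optionally scaled by v (Sigma*v)
  double ld(double x1, double x2, double v = 1.0) const {
    double sv = std::sqrt(v);
    double a = l11 * sv, b = l21 * sv, c = l22 * sv;
    if (!(a > 0) || !(c > 0)) return R_NegInf;
    double z1 = x1 / a;
    double z2 = (x2 - b * z1) / c;
    return -LOG2PI - std::log(a) - std::log(c) - 0.5 * (z1 * z1 + z2 * z2);
  }
};

// [[Rcpp::export]]
List mcmc_bivariate_cpp(List dat, List opts) {
  Families F;
  F.setup(dat["fam"], dat["zyg"], dat["cotwin"]);
  int n = F.n;
  NumericVector sex = dat["sex"], age = dat["age"];
  LogicalVector age_miss = dat["age_miss"];
  bool item_level = as<bool>(dat["item_level"]);
  int n_burn = as<int>(opts["n_burn"]), n_iter = as<int>(opts["n_iter"]);
  int thin = as<int>(opts["thin"]);

  NumericVector y1, y2;
  IntegerMatrix Y1, Y2;
  BankSampler bank1, bank2;
  if (item_level) {
    Y1 = as<IntegerMatrix>(dat["Y"]);
    Y2 = as<IntegerMatrix>(dat["Ym"]);
    bank1.setup(Y1, dat["ncat"], opts["thr_init"], opts["alpha_init"], true);
    bank2.setup(Y2, dat["ncat_m"], opts["thr_init_m"], opts["alpha_init_m"], true);
  } else {
    y1 = dat["ysum"];
    y2 = dat["msum"];
  }

  List init = opts["init"];
  double bsex1 = as<double>(init["beta_sex1"]), bage1 = as<double>(init["beta_age1"]);
  double bsex2 = as<double>(init["beta_sex2"]), bage2 = as<double>(init["beta_age2"]);
  Chol2 La, Le;
  La.l11 = as<double>(init["la11"]); La.l21 = as<double>(init["la21"]);
  La.l22 = as<double>(init["la22"]);
  Le.l11 = as<double>(init["le11"]); Le.l21 = as<double>(init["le21"]);
  Le.l22 = as<double>(init["le22"]);

  std::vector<double> th1(n, 0.0), th2(n, 0.0);
  if (item_level) {
    NumericVector a = init["theta1"], b = init["theta2"];
    th1.assign(a.begin(), a.end());
    th2.assign(b.begin(), b.end());
  } else {
    for (int t = 0; t < n; ++t) { th1[t] = y1[t]; th2[t] = y2[t]; }
  }
  // genetic primitives: per family 2-vector g, per DZ twin 2-vector s
  std::vector<double> g1(F.n_fam, 0), g2(F.n_fam, 0), s1v(n, 0), s2v(n, 0);
  std::vector<double> agev(age.begin(), age.end());
  std::vector<int> miss_idx;
  for (int t = 0; t < n; ++t) if (age_miss[t]) { agev[t] = 0.0; miss_idx.push_back(t); }

  std::vector<double> ls_th1(n, std::log(0.5)), ls_th2(n, std::log(0.5)),
      ls_g(F.n_fam, std::log(0.5)), ls_s(n, std::log(0.5));
  double ls_b[4] = {std::log(0.1), std::log(0.1), std::log(0.1), std::log(0.1)};
  double ls_la[3] = {std::log(0.1), std::log(0.1), std::log(0.1)};
  double ls_le[3] = {std::log(0.1), std::log(0.1), std::log(0.1)};
  double ls_scale1 = std::log(0.1), ls_scale2 = std::log(0.1),
      ls_agem = std::log(0.5), ls_gsc1 = std::log(0.05),
      ls_gsc2 = std::log(0.05);

  #define A1(t) (F.zyg[t] == 0 ? g1[F.fam[t]] : R5 * (g1[F.fam[t]] + s1v[t]))
  #define A2(t) (F.zyg[t] == 0 ? g2[F.fam[t]] : R5 * (g2[F.fam[t]] + s2v[t]))

  auto mu1 = [&](int t) { return bsex1 * sex[t] + bage1 * agev[t]; };
  auto mu2 = [&](int t) { return bsex2 * sex[t] + bage2 * agev[t]; };
  // E-layer term of twin t at phenotype pair (p1, p2), genetic pair (a1, a2)
  auto estruct = [&](int t, double p1, double p2, double a1, double a2) {
    return Le.ld(p1 - mu1(t) - a1, p2 - mu2(t) - a2);
  };
  auto estruct_cur = [&](int t) {
    return estruct(t, th1[t], th2[t], A1(t), A2(t));
  };
  // genetic prior of the stored primitives: every g and (DZ) s 2-vector is
  // N2(0, Sigma_A)
  auto gprior_all = [&]() {
    double ll = 0.0;
    for (int f = 0; f < F.n_fam; ++f) ll += La.ld(g1[f], g2[f]);
    for (int t = 0; t < n; ++t)
      if (F.zyg[t] == 1) ll += La.ld(s1v[t], s2v[t]);
    return ll;
  };

  int total_it = n_burn + n_iter;
  int n_keep = n_iter / thin;
  std::vector<std::string> nm = {"beta_sex1", "beta_age1", "beta_sex2",
                                 "beta_age2", "a11", "a21", "a22", "e11",
                                 "e21", "e22", "deviance"};
  if (item_level) {
    for (int j = 1; j < bank1.B.J; ++j)
      nm.push_back("y_alpha" + std::to_string(j + 1));
    for (int j = 0; j < bank1.B.J; ++j)
      for (int k = 0; k + 1 < bank1.B.ncat[j]; ++k)
        nm.push_back("y_thr" + std::to_string(j + 1) + "_" + std::to_string(k + 1));
    for (int j = 1; j < bank2.B.J; ++j)
      nm.push_back("m_alpha" + std::to_string(j + 1));
    for (int j = 0; j < bank2.B.J; ++j)
      for (int k = 0; k + 1 < bank2.B.ncat[j]; ++k)
        nm.push_back("m_thr" + std::to_string(j + 1) + "_" + std::to_string(k + 1));
  }
  NumericMatrix draws(n_keep, (int)nm.size());

  double s_bsex1 = 0, s_bage1 = 0, s_bsex2 = 0, s_bage2 = 0;
  double s_le11 = 0, s_le21 = 0, s_le22 = 0;
  std::vector<double> s_th1(n, 0), s_th2(n, 0), s_A1(n, 0), s_A2(n, 0),
      s_age(n, 0);
  std::vector<double> s_alpha1, s_thr1, s_alpha2, s_thr2;
  if (item_level) {
    s_alpha1.assign(bank1.B.J, 0);
    int tot = 0; for (int j = 0; j < bank1.B.J; ++j) tot += bank1.B.ncat[j] - 1;
    s_thr1.assign(tot, 0);
    s_alpha2.assign(bank2.B.J, 0);
    tot = 0; for (int j = 0; j < bank2.B.J; ++j) tot += bank2.B.ncat[j] - 1;
    s_thr2.assign(tot, 0);
  }

  int kept = 0;
  for (int it = 0; it < total_it; ++it) {
    bool adapt = it < n_burn;

    if (item_level) {
      for (int t = 0; t < n; ++t) {
        double prop = th1[t] + std::exp(ls_th1[t]) * norm_rand();
        double d = bank_ll_row(Y1, t, bank1.B, prop) -
                   bank_ll_row(Y1, t, bank1.B, th1[t]) +
                   estruct(t, prop, th2[t], A1(t), A2(t)) - estruct_cur(t);
        bool acc = mh_accept(d);
        if (acc) th1[t] = prop;
        if (adapt) tune(ls_th1[t], acc, 0.44, it);
      }
      for (int t = 0; t < n; ++t) {
        double prop = th2[t] + std::exp(ls_th2[t]) * norm_rand();
        double d = bank_ll_row(Y2, t, bank2.B, prop) -
                   bank_ll_row(Y2, t, bank2.B, th2[t]) +
                   estruct(t, th1[t], prop, A1(t), A2(t)) - estruct_cur(t);
        bool acc = mh_accept(d);
        if (acc) th2[t] = prop;
        if (adapt) tune(ls_th2[t], acc, 0.44, it);
      }
    }

    // family-common genetic 2-vectors
    for (int f = 0; f < F.n_fam; ++f) {
      double sc = std::exp(ls_g[f]);
      double p1 = g1[f] + sc * norm_rand(), p2 = g2[f] + sc * norm_rand();
      double d = La.ld(p1, p2) - La.ld(g1[f], g2[f]);
      for (size_t i = 0; i < F.members[f].size(); ++i) {
        int t = F.members[f][i];
        double a1n, a2n;
        if (F.fzyg[f] == 0) { a1n = p1; a2n = p2; }
        else { a1n = R5 * (p1 + s1v[t]); a2n = R5 * (p2 + s2v[t]); }
        d += estruct(t, th1[t], th2[t], a1n, a2n) - estruct_cur(t);
      }
      bool acc = mh_accept(d);
      if (acc) { g1[f] = p1; g2[f] = p2; }
      if (adapt) tune(ls_g[f], acc, 0.234, it);
    }
    // DZ specific genetic 2-vectors
    for (int t = 0; t < n; ++t) {
      if (F.zyg[t] != 1) continue;
      double sc = std::exp(ls_s[t]);
      double p1 = s1v[t] + sc * norm_rand(), p2 = s2v[t] + sc * norm_rand();
      double a1n = R5 * (g1[F.fam[t]] + p1), a2n = R5 * (g2[F.fam[t]] + p2);
      double d = La.ld(p1, p2) - La.ld(s1v[t], s2v[t]) +
                 estruct(t, th1[t], th2[t], a1n, a2n) - estruct_cur(t);
      bool acc = mh_accept(d);
      if (acc) { s1v[t] = p1; s2v[t] = p2; }
      if (adapt) tune(ls_s[t], acc, 0.234, it);
    }

    // genetic Cholesky entries: diagonal on log scale (half-normal prior
    // with Jacobian), off-diagonal unconstrained
    for (int u = 0; u < 3; ++u) {
      Chol2 prop = La;
      double d = 0.0;
      if (u == 0) {
        double lx = std::log(La.l11) + std::exp(ls_la[0]) * norm_rand();
        prop.l11 = std::exp(lx);
        d += prior_logalpha(lx) - prior_logalpha(std::log(La.l11));
      } else if (u == 1) {
        prop.l21 = La.l21 + std::exp(ls_la[1]) * norm_rand();
        d += prior_coef(prop.l21) - prior_coef(La.l21);
      } else {
        double lx = std::log(La.l22) + std::exp(ls_la[2]) * norm_rand();
        prop.l22 = std::exp(lx);
        d += prior_logalpha(lx) - prior_logalpha(std::log(La.l22));
      }
      double base = gprior_all();
      Chol2 keep = La; La = prop;
      d += gprior_all() - base;
      bool acc = mh_accept(d);
      if (!acc) La = keep;
      if (adapt) tune(ls_la[u], acc, 0.44, it);
    }
    // environmental Cholesky entries
    for (int u = 0; u < 3; ++u) {
      Chol2 prop = Le;
      double d = 0.0;
      if (u == 0) {
        double lx = std::log(Le.l11) + std::exp(ls_le[0]) * norm_rand();
        prop.l11 = std::exp(lx);
        d += prior_logalpha(lx) - prior_logalpha(std::log(Le.l11));
      } else if (u == 1) {
        prop.l21 = Le.l21 + std::exp(ls_le[1]) * norm_rand();
        d += prior_coef(prop.l21) - prior_coef(Le.l21);
      } else {
        double lx = std::log(Le.l22) + std::exp(ls_le[2]) * norm_rand();
        prop.l22 = std::exp(lx);
        d += prior_logalpha(lx) - prior_logalpha(std::log(Le.l22));
      }
      double base = 0.0;
      for (int t = 0; t < n; ++t) base += estruct_cur(t);
      Chol2 keep = Le; Le = prop;
      double nw = 0.0;
      for (int t = 0; t < n; ++t) nw += estruct_cur(t);
      d += nw - base;
      bool acc = mh_accept(d);
      if (!acc) Le = keep;
      if (adapt) tune(ls_le[u], acc, 0.44, it);
    }

    // per-trait rescale of genetic latents together with the Cholesky row;
    // the genetic prior is invariant, the Jacobian is (n_lat + row entries
    // below the diagonal) * eps minus the same from the log-diagonal shift
    for (int trait = 0; trait < 2; ++trait) {
      double& ls_sc = trait == 0 ? ls_scale1 : ls_scale2;
      double eps = std::exp(ls_sc) * norm_rand();
      double c = std::exp(eps);
      Chol2 prop = La;
      double d = 0.0;
      if (trait == 0) {
        prop.l11 = La.l11 * c;
        d += prior_logalpha(std::log(prop.l11)) - prior_logalpha(std::log(La.l11));
      } else {
        prop.l21 = La.l21 * c; prop.l22 = La.l22 * c;
        d += prior_coef(prop.l21) - prior_coef(La.l21) + eps +
             prior_logalpha(std::log(prop.l22)) - prior_logalpha(std::log(La.l22));
      }
      // E-layer change from scaling the trait's genetic values
      for (int t = 0; t < n; ++t) {
        double a1n = trait == 0 ? c * A1(t) : A1(t);
        double a2n = trait == 1 ? c * A2(t) : A2(t);
        d += estruct(t, th1[t], th2[t], a1n, a2n) - estruct_cur(t);
      }
      bool acc = mh_accept(d);
      if (acc) {
        if (trait == 0) {
          for (int f = 0; f < F.n_fam; ++f) g1[f] *= c;
          for (int t = 0; t < n; ++t) s1v[t] *= c;
        } else {
          for (int f = 0; f < F.n_fam; ++f) g2[f] *= c;
          for (int t = 0; t < n; ++t) s2v[t] *= c;
        }
        La = prop;
      }
      if (adapt) tune(ls_sc, acc, 0.44, it);
    }

    // covariate coefficients
    {
      double* pars[4] = {&bsex1, &bage1, &bsex2, &bage2};
      for (int u = 0; u < 4; ++u) {
        double old = *pars[u];
        double prop = old + std::exp(ls_b[u]) * norm_rand();
        double base = 0.0;
        for (int t = 0; t < n; ++t) base += estruct_cur(t);
        *pars[u] = prop;
        double nw = 0.0;
        for (int t = 0; t < n; ++t) nw += estruct_cur(t);
        double d = prior_coef(prop) - prior_coef(old) + nw - base;
        bool acc = mh_accept(d);
        if (!acc) *pars[u] = old;
        if (adapt) tune(ls_b[u], acc, 0.44, it);
      }
    }

    if (item_level) {
      bank1.update(th1, adapt, it);
      bank2.update(th2, adapt, it);

      // joint latent-scale move per trait: rescale the trait's latents,
      // thresholds, covariate effects and its rows of both Cholesky
      // factors; only the trait's first item opposes the move
      for (int trait = 0; trait < 2; ++trait) {
        double& ls_gs = trait == 0 ? ls_gsc1 : ls_gsc2;
        double eps = std::exp(ls_gs) * norm_rand();
        double c = std::exp(eps);
        BankSampler& bk = trait == 0 ? bank1 : bank2;
        std::vector<double>& thx = trait == 0 ? th1 : th2;
        int n_thr = 0;
        double d = bk.ll0_scaled_diff(thx, c) + bk.scale_prior_diff(eps, n_thr);
        double* bsx = trait == 0 ? &bsex1 : &bsex2;
        double* bag = trait == 0 ? &bage1 : &bage2;
        d += prior_coef(c * *bsx) - prior_coef(*bsx) +
             prior_coef(c * *bag) - prior_coef(*bag);
        double njac = n_thr + 2;
        if (trait == 0) {
          d += prior_logalpha(std::log(La.l11) + eps) -
               prior_logalpha(std::log(La.l11)) +
               prior_logalpha(std::log(Le.l11) + eps) -
               prior_logalpha(std::log(Le.l11));
        } else {
          d += prior_coef(c * La.l21) - prior_coef(La.l21) +
               prior_coef(c * Le.l21) - prior_coef(Le.l21) +
               prior_logalpha(std::log(La.l22) + eps) -
               prior_logalpha(std::log(La.l22)) +
               prior_logalpha(std::log(Le.l22) + eps) -
               prior_logalpha(std::log(Le.l22));
          njac += 2;
        }
        d += njac * eps;
        bool acc = mh_accept(d);
        if (acc) {
          bk.apply_scale(eps);
          for (int t = 0; t < n; ++t) thx[t] *= c;
          *bsx *= c; *bag *= c;
          if (trait == 0) {
            for (int f = 0; f < F.n_fam; ++f) g1[f] *= c;
            for (int t = 0; t < n; ++t) s1v[t] *= c;
            La.l11 *= c; Le.l11 *= c;
          } else {
            for (int f = 0; f < F.n_fam; ++f) g2[f] *= c;
            for (int t = 0; t < n; ++t) s2v[t] *= c;
            La.l21 *= c; La.l22 *= c; Le.l21 *= c; Le.l22 *= c;
          }
        }
        if (adapt) tune(ls_gs, acc, 0.44, it);
      }
    }

    for (size_t i = 0; i < miss_idx.size(); ++i) {
      int t = miss_idx[i];
      double old = agev[t];
      double prop = old + std::exp(ls_agem) * norm_rand();
      double d = ldnorm(prop, 0, std::sqrt(10.0)) - ldnorm(old, 0, std::sqrt(10.0));
      double base = estruct_cur(t);
      agev[t] = prop;
      d += estruct_cur(t) - base;
      bool acc = mh_accept(d);
      if (!acc) agev[t] = old;
      if (adapt && i == 0) tune(ls_agem, acc, 0.44, it);
    }

    if (!adapt && ((it - n_burn) % thin == 0) && kept < n_keep) {
      // observed-data deviance (items in item form, score pairs in sum form)
      double dev = 0.0;
      for (int t = 0; t < n; ++t) {
        if (item_level) {
          dev += bank_ll_row(Y1, t, bank1.B, th1[t]);
          dev += bank_ll_row(Y2, t, bank2.B, th2[t]);
        } else {
          dev += estruct_cur(t);
        }
      }
      dev *= -2.0;
      double vals[11] = {bsex1, bage1, bsex2, bage2, La.s11(), La.s21(),
                         La.s22(), Le.s11(), Le.s21(), Le.s22(), dev};
      for (int c = 0; c < 11; ++c) draws(kept, c) = vals[c];
      if (item_level) {
        int c = 11;
        for (int j = 1; j < bank1.B.J; ++j) draws(kept, c++) = bank1.B.alpha[j];
        for (int j = 0; j < bank1.B.J; ++j)
          for (int k = 0; k + 1 < bank1.B.ncat[j]; ++k)
            draws(kept, c++) = bank1.B.thr[j][k];
        for (int j = 1; j < bank2.B.J; ++j) draws(kept, c++) = bank2.B.alpha[j];
        for (int j = 0; j < bank2.B.J; ++j)
          for (int k = 0; k + 1 < bank2.B.ncat[j]; ++k)
            draws(kept, c++) = bank2.B.thr[j][k];
      }
      s_bsex1 += bsex1; s_bage1 += bage1; s_bsex2 += bsex2; s_bage2 += bage2;
      s_le11 += Le.l11; s_le21 += Le.l21; s_le22 += Le.l22;
      for (int t = 0; t < n; ++t) {
        s_th1[t] += th1[t]; s_th2[t] += th2[t];
        s_A1[t] += A1(t); s_A2[t] += A2(t); s_age[t] += agev[t];
      }
      if (item_level) {
        int c = 0;
        for (int j = 0; j < bank1.B.J; ++j) s_alpha1[j] += bank1.B.alpha[j];
        for (int j = 0; j < bank1.B.J; ++j)
          for (int k = 0; k + 1 < bank1.B.ncat[j]; ++k)
            s_thr1[c++] += bank1.B.thr[j][k];
        c = 0;
        for (int j = 0; j < bank2.B.J; ++j) s_alpha2[j] += bank2.B.alpha[j];
        for (int j = 0; j < bank2.B.J; ++j)
          for (int k = 0; k + 1 < bank2.B.ncat[j]; ++k)
            s_thr2[c++] += bank2.B.thr[j][k];
      }
      ++kept;
    }
  }

  double m = (double)kept;
  Chol2 pLe;
  pLe.l11 = s_le11 / m; pLe.l21 = s_le21 / m; pLe.l22 = s_le22 / m;
  ItemBankState pB1 = bank1.B, pB2 = bank2.B;
  if (item_level) {
    int c = 0;
    for (int j = 0; j < pB1.J; ++j) pB1.alpha[j] = s_alpha1[j] / m;
    for (int j = 0; j < pB1.J; ++j)
      for (int k = 0; k + 1 < pB1.ncat[j]; ++k) pB1.thr[j][k] = s_thr1[c++] / m;
    c = 0;
    for (int j = 0; j < pB2.J; ++j) pB2.alpha[j] = s_alpha2[j] / m;
    for (int j = 0; j < pB2.J; ++j)
      for (int k = 0; k + 1 < pB2.ncat[j]; ++k) pB2.thr[j][k] = s_thr2[c++] / m;
  }
  double p_bsex1 = s_bsex1 / m, p_bage1 = s_bage1 / m, p_bsex2 = s_bsex2 / m,
      p_bage2 = s_bage2 / m;
  double dhat = 0.0;
  for (int t = 0; t < n; ++t) {
    double m1 = p_bsex1 * sex[t] + p_bage1 * (s_age[t] / m);
    double m2 = p_bsex2 * sex[t] + p_bage2 * (s_age[t] / m);
    if (item_level) {
      dhat += bank_ll_row(Y1, t, pB1, s_th1[t] / m);
      dhat += bank_ll_row(Y2, t, pB2, s_th2[t] / m);
    } else {
      dhat += pLe.ld(y1[t] - m1 - s_A1[t] / m, y2[t] - m2 - s_A2[t] / m);
    }
  }
  dhat *= -2.0;

  NumericVector pm_th1(n), pm_th2(n), pm_A1(n), pm_A2(n);
  for (int t = 0; t < n; ++t) {
    pm_th1[t] = s_th1[t] / m; pm_th2[t] = s_th2[t] / m;
    pm_A1[t] = s_A1[t] / m; pm_A2[t] = s_A2[t] / m;
  }
  List post_mean = List::create(_["theta1"] = pm_th1, _["theta2"] = pm_th2,
                                _["A1"] = pm_A1, _["A2"] = pm_A2);

  colnames(draws) = wrap(nm);
  return List::create(_["draws"] = draws, _["dhat"] = dhat,
                      _["post_mean"] = post_mean);
  #undef A1
  #undef A2
}
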