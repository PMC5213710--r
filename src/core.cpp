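#include <Rcpp.h>
using namespace Rcpp;

// Trial-sequential core for the reward/effort learning models.
//
// Encoding shared by all entry points (learning trials only, in task order;
// attention trials carry no feedback and must be removed upstream):
//   prob_a, prob_b   displayed reward probabilities
//   rm_a..em_b       outcome magnitudes, raw units (pence / circles)
//   fixed_opt        0 = both options drifting, 1 = side A is the fixed
//                    special option this trial, 2 = side B is
//   new_block        1 at the first trial of a session: predictions reset
//   choice           1 = A, 2 = B
// Predictions live on the normalised scale (reward / max_rm, effort /
// max_em).  On special-option trials the fixed side's value is known
// exactly (learned pre-scan), so its prediction is pinned to the displayed
// magnitudes and it triggers no update; the hidden drifting option on that
// side is not updated either (its outcome is not shown).

struct ModelDef {
  double alpha_r, alpha_e, gamma, lambda, beta;
  bool multiplicative;   // M4-M6 utility
  bool external_pred;    // M3/M6: predictions supplied, no RW update
};

static inline double utility(const ModelDef &m, double p, double rhat, double ehat) {
  if (m.multiplicative)
    return (1.0 - m.lambda) * p * rhat - m.lambda * ehat;
  return (1.0 - m.gamma) * p + m.gamma * (m.lambda * rhat - (1.0 - m.lambda) * ehat);
}

// P(choose A), numerically stable softmax on two utilities
static inline double p_choose_a(double ua, double ub, double beta) {
  double d = beta * (ua - ub);
  if (d > 0) return 1.0 / (1.0 + std::exp(-d));
  double e = std::exp(d);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector par, int utility_type, int use_external_pred,
                  NumericVector prob_a, NumericVector prob_b,
                  NumericVector rm_a, NumericVector rm_b,
                  NumericVector em_a, NumericVector em_b,
                  IntegerVector fixed_opt, IntegerVector new_block,
                  IntegerVector choice,
                  double max_rm, double max_em, double init_pred,
                  NumericMatrix ext_pred) {
  ModelDef m;
  m.alpha_r = par[0]; m.alpha_e = par[1]; m.gamma = par[2];
  m.lambda = par[3]; m.beta = par[4];
  m.multiplicative = utility_type == 1;
  m.external_pred = use_external_pred == 1;

  int n = prob_a.size();
  double ra = init_pred, rb = init_pred, ea = init_pred, eb = init_pred;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (new_block[t] == 1) { ra = rb = ea = eb = init_pred; }
    double pra = ra, prb = rb, pea = ea, peb = eb;
    if (m.external_pred) {
      pra = ext_pred(t, 0); prb = ext_pred(t, 1);
      pea = ext_pred(t, 2); peb = ext_pred(t, 3);
    }
    // pinned known values for the fixed special option
    if (fixed_opt[t] == 1) { pra = rm_a[t] / max_rm; pea = em_a[t] / max_em; }
    if (fixed_opt[t] == 2) { prb = rm_b[t] / max_rm; peb = em_b[t] / max_em; }

    double ua = utility(m, prob_a[t], pra, pea);
    double ub = utility(m, prob_b[t], prb, peb);
    double pa = p_choose_a(ua, ub, m.beta);
    double pc = (choice[t] == 1) ? pa : (1.0 - pa);
    if (pc < 1e-300) pc = 1e-300;
    ll += std::log(pc);

    if (!m.external_pred) {
      if (fixed_opt[t] != 1) {
        ra += m.alpha_r * (rm_a[t] / max_rm - ra);
        ea += m.alpha_e * (em_a[t] / max_em - ea);
      }
      if (fixed_opt[t] != 2) {
        rb += m.alpha_r * (rm_b[t] / max_rm - rb);
        eb += m.alpha_e * (em_b[t] / max_em - eb);
      }
    }
  }
  return ll;
}

// Log-likelihood for a cohort: one parameter row per participant, trials
// stacked with 0-based participant index `part`.  Used by the samplers so a
// whole Gibbs sweep costs a single .Call.
// [[Rcpp::export]]
NumericVector cpp_loglik_matrix(NumericMatrix par, int utility_type,
                                int use_external_pred,
                                IntegerVector part,
                                NumericVector prob_a, NumericVector prob_b,
                                NumericVector rm_a, NumericVector rm_b,
                                NumericVector em_a, NumericVector em_b,
                                IntegerVector fixed_opt, IntegerVector new_block,
                                IntegerVector choice,
                                double max_rm, double max_em, double init_pred,
                                NumericMatrix ext_pred) {
  int npart = par.nrow();
  NumericVector out(npart);
  int n = prob_a.size();
  std::vector<ModelDef> mods(npart);
  for (int i = 0; i < npart; ++i) {
    mods[i].alpha_r = par(i, 0); mods[i].alpha_e = par(i, 1);
    mods[i].gamma = par(i, 2); mods[i].lambda = par(i, 3);
    mods[i].beta = par(i, 4);
    mods[i].multiplicative = utility_type == 1;
    mods[i].external_pred = use_external_pred == 1;
  }
  std::vector<double> ra(npart), rb(npart), ea(npart), eb(npart);

  for (int t = 0; t < n; ++t) {
    int i = part[t];
    const ModelDef &m = mods[i];
    if (new_block[t] == 1) { ra[i] = rb[i] = ea[i] = eb[i] = init_pred; }
    double pra = ra[i], prb = rb[i], pea = ea[i], peb = eb[i];
    if (m.external_pred) {
      pra = ext_pred(t, 0); prb = ext_pred(t, 1);
      pea = ext_pred(t, 2); peb = ext_pred(t, 3);
    }
    if (fixed_opt[t] == 1) { pra = rm_a[t] / max_rm; pea = em_a[t] / max_em; }
    if (fixed_opt[t] == 2) { prb = rm_b[t] / max_rm; peb = em_b[t] / max_em; }

    double ua = utility(m, prob_a[t], pra, pea);
    double ub = utility(m, prob_b[t], prb, peb);
    double pa = p_choose_a(ua, ub, m.beta);
    double pc = (choice[t] == 1) ? pa : (1.0 - pa);
    if (pc < 1e-300) pc = 1e-300;
    out[i] += std::log(pc);

    if (!m.external_pred) {
      if (fixed_opt[t] != 1) {
        ra[i] += m.alpha_r * (rm_a[t] / max_rm - ra[i]);
        ea[i] += m.alpha_e * (em_a[t] / max_em - ea[i]);
      }
      if (fixed_opt[t] != 2) {
        rb[i] += m.alpha_r * (rm_b[t] / max_rm - rb[i]);
        eb[i] += m.alpha_e * (em_b[t] / max_em - eb[i]);
      }
    }
  }
  return out;
}

// Log-likelihood of ONE participant's trials under many candidate
// parameter vectors (rows of `par`); used by grid searches.
// [[Rcpp::export]]
NumericVector cpp_loglik_grid(NumericMatrix par, int utility_type,
                              int use_external_pred,
                              NumericVector prob_a, NumericVector prob_b,
                              NumericVector rm_a, NumericVector rm_b,
                              NumericVector em_a, NumericVector em_b,
                              IntegerVector fixed_opt, IntegerVector new_block,
                              IntegerVector choice,
                              double max_rm, double max_em, double init_pred,
                              NumericMatrix ext_pred) {
  int ncand = par.nrow();
  NumericVector out(ncand);
  for (int i = 0; i < ncand; ++i) {
    NumericVector p = par(i, _);
    out[i] = cpp_loglik(p, utility_type, use_external_pred, prob_a, prob_b,
                        rm_a, rm_b, em_a, em_b, fixed_opt, new_block,
                        choice, max_rm, max_em, init_pred, ext_pred);
  }
  return out;
}

// Simulate one agent's choices on a schedule.  Uses R's RNG so that
// set.seed() in R gives bit-reproducible choices.  Returns choices (1/2),
// reward_real (0/1) and the per-trial model probability of choosing A.
// [[Rcpp::export]]
List cpp_simulate(NumericVector par, int utility_type, int use_external_pred,
                  NumericVector prob_a, NumericVector prob_b,
                  NumericVector rm_a, NumericVector rm_b,
                  NumericVector em_a, NumericVector em_b,
                  IntegerVector fixed_opt, IntegerVector new_block,
                  double max_rm, double max_em, double init_pred,
                  NumericMatrix ext_pred) {
  ModelDef m;
  m.alpha_r = par[0]; m.alpha_e = par[1]; m.gamma = par[2];
  m.lambda = par[3]; m.beta = par[4];
  m.multiplicative = utility_type == 1;
  m.external_pred = use_external_pred == 1;

  int n = prob_a.size();
  IntegerVector choice(n);
  IntegerVector reward_real(n);
  NumericVector p_a(n);
  double ra = init_pred, rb = init_pred, ea = init_pred, eb = init_pred;

  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    if (new_block[t] == 1) { ra = rb = ea = eb = init_pred; }
    double pra = ra, prb = rb, pea = ea, peb = eb;
    if (m.external_pred) {
      pra = ext_pred(t, 0); prb = ext_pred(t, 1);
      pea = ext_pred(t, 2); peb = ext_pred(t, 3);
    }
    if (fixed_opt[t] == 1) { pra = rm_a[t] / max_rm; pea = em_a[t] / max_em; }
    if (fixed_opt[t] == 2) { prb = rm_b[t] / max_rm; peb = em_b[t] / max_em; }

    double ua = utility(m, prob_a[t], pra, pea);
    double ub = utility(m, prob_b[t], prb, peb);
    double pa = p_choose_a(ua, ub, m.beta);
    p_a[t] = pa;
    int c = (unif_rand() < pa) ? 1 : 2;
    choice[t] = c;
    double pc_rew = (c == 1) ? prob_a[t] : prob_b[t];
    reward_real[t] = (unif_rand() < pc_rew) ? 1 : 0;

    if (!m.external_pred) {
      if (fixed_opt[t] != 1) {
        ra += m.alpha_r * (rm_a[t] / max_rm - ra);
        ea += m.alpha_e * (em_a[t] / max_em - ea);
      }
      if (fixed_opt[t] != 2) {
        rb += m.alpha_r * (rm_b[t] / max_rm - rb);
        eb += m.alpha_e * (em_b[t] / max_em - eb);
      }
    }
  }
  return List::create(_["choice"] = choice, _["reward_real"] = reward_real,
                      _["p_choose_a"] = p_a);
}

// Per-trial prior (pre-update) RW predictions on the normalised scale,
// for regressor construction and binned choice curves.
// [[Rcpp::export]]
NumericMatrix cpp_rw_predictions(NumericVector par,
                                 NumericVector rm_a, NumericVector rm_b,
                                 NumericVector em_a, NumericVector em_b,
                                 IntegerVector fixed_opt, IntegerVector new_block,
                                 double max_rm, double max_em, double init_pred) {
  int n = rm_a.size();
  NumericMatrix out(n, 4);
  double ar = par[0], ae = par[1];
  double ra = init_pred, rb = init_pred, ea = init_pred, eb = init_pred;
  for (int t = 0; t < n; ++t) {
    if (new_block[t] == 1) { ra = rb = ea = eb = init_pred; }
    out(t, 0) = ra; out(t, 1) = rb; out(t, 2) = ea; out(t, 3) = eb;
    if (fixed_opt[t] != 1) {
      ra += ar * (rm_a[t] / max_rm - ra);
      ea += ae * (em_a[t] / max_em - ea);
    }
    if (fixed_opt[t] != 2) {
      rb += ar * (rm_b[t] / max_rm - rb);
      eb += ae * (em_b[t] / max_em - eb);
    }
  }
  return out;
}
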