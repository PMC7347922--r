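#include <Rcpp.h>
using namespace Rcpp;

// Deterministic likelihood replay of one subject's trial log.
// choice codes: 0 = reject, 1 = accept, 2 = missed.
// Reward-free updates multiply rho by (1 - alpha_neg) once per elapsed
// second; the final handling second of an accepted option is a reward-free
// update followed by a reward update with alpha_pos. The choice likelihood
// is evaluated with the rate estimate after the encounter seconds' updates.
// [[Rcpp::export]]
List replay_core(NumericVector r_i, NumericVector t_i,
                 IntegerVector choice, LogicalVector include,
                 double alpha_pos, double alpha_neg,
                 double beta0, double beta1,
                 double rho0, double enc_seconds, double timeout_seconds) {
  int n = r_i.size();
  NumericVector ll(n, NA_REAL);
  double rho = rho0;
  double total = 0.0;
  double dn = 1.0 - alpha_neg;
  double dec_enc = std::pow(dn, enc_seconds);

  for (int k = 0; k < n; ++k) {
    rho *= dec_enc;
    if (include[k]) {
      double x = beta1 * (r_i[k] - rho * t_i[k]) - beta0;
      // stable log(p) / log(1-p)
      double lp = (x > 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
      double lq = (-x > 0) ? -std::log1p(std::exp(x)) : -x - std::log1p(std::exp(-x));
      double v = (choice[k] == 1) ? lp : lq;
      ll[k] = v;
      total += v;
    }
    if (choice[k] == 1) {            // accept: handling then reward second
      rho *= std::pow(dn, t_i[k]);   // t_i - 1 delay seconds + delay half of the final second
      rho += alpha_pos * (r_i[k] - rho);
    } else if (choice[k] == 2) {     // missed: timeout seconds
      rho *= std::pow(dn, timeout_seconds);
    }
  }
  return List::create(_["loglik"] = total, _["trial_loglik"] = ll,
                      _["rho_final"] = rho);
}

// Forward simulation of one subject's choices over a pre-built offer plan,
// consuming R's global RNG (one uniform per free trial) so that results are
// reproducible under set.seed and identical to the R reference simulator.
// forced_dir codes: 1 = accept, 0 = reject, NA for free trials.
// [[Rcpp::export]]
List simulate_core(NumericVector r_i, NumericVector t_i,
                   LogicalVector forced, IntegerVector forced_dir,
                   NumericVector block_end, IntegerVector block_of,
                   double alpha_pos, double alpha_neg,
                   double beta0, double beta1,
                   double rho0, double enc_seconds) {
  int n_off = r_i.size();
  IntegerVector used(n_off);
  IntegerVector acc(n_off);
  NumericVector ts(n_off), te(n_off);
  double rho = rho0;
  double dn = 1.0 - alpha_neg;
  double dec_enc = std::pow(dn, enc_seconds);
  double t_clock = 0.0;
  int n_trials = 0;

  for (int k = 0; k < n_off; ++k) {
    if (t_clock >= block_end[block_of[k] - 1]) continue; // block over: skip remaining offers
    rho *= dec_enc;
    double p;
    int choice;
    if (forced[k]) {
      choice = forced_dir[k];
    } else {
      double x = beta1 * (r_i[k] - rho * t_i[k]) - beta0;
      p = 1.0 / (1.0 + std::exp(-x));
      choice = (unif_rand() < p) ? 1 : 0;
    }
    double t_start = t_clock;
    if (choice == 1) {
      rho *= std::pow(dn, t_i[k]);
      rho += alpha_pos * (r_i[k] - rho);
      t_clock = t_start + enc_seconds + t_i[k];
    } else {
      t_clock = t_start + enc_seconds;
    }
    used[k] = 1;
    acc[k] = choice;
    ts[k] = t_start;
    te[k] = t_clock;
    ++n_trials;
  }
  return List::create(_["used"] = used, _["accept"] = acc,
                      _["t_start"] = ts, _["t_end"] = te,
                      _["rho_final"] = rho, _["n_trials"] = n_trials);
}

// Replay log-likelihood together with its analytic gradient in natural
// parameter space (alpha_pos, alpha_neg, beta0, beta1), via forward
// sensitivities of rho with respect to the two learning rates.
// [[Rcpp::export]]
List replay_grad_core(NumericVector r_i, NumericVector t_i,
                      IntegerVector choice, LogicalVector include,
                      double alpha_pos, double alpha_neg,
                      double beta0, double beta1,
                      double rho0, double enc_seconds, double timeout_seconds) {
  int n = r_i.size();
  double rho = rho0, g_ap = 0.0, g_an = 0.0;
  double total = 0.0;
  double d_ap = 0.0, d_an = 0.0, d_b0 = 0.0, d_b1 = 0.0;
  double dn = 1.0 - alpha_neg;

  // decay rho by k reward-free seconds, propagating sensitivities
  auto decay = [&](double k) {
    double D = std::pow(dn, k);
    double dD = -k * std::pow(dn, k - 1.0); // dD/d(alpha_neg)
    g_ap *= D;
    g_an = g_an * D + rho * dD;
    rho *= D;
  };

  for (int k = 0; k < n; ++k) {
    decay(enc_seconds);
    if (include[k]) {
      double x = beta1 * (r_i[k] - rho * t_i[k]) - beta0;
      double p = 1.0 / (1.0 + std::exp(-x));
      double lp = (x > 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
      double lq = (-x > 0) ? -std::log1p(std::exp(x)) : -x - std::log1p(std::exp(-x));
      double w = (choice[k] == 1) ? (1.0 - p) : (-p); // dll/dx
      total += (choice[k] == 1) ? lp : lq;
      double dx_drho = -beta1 * t_i[k];
      d_ap += w * dx_drho * g_ap;
      d_an += w * dx_drho * g_an;
      d_b0 += -w;
      d_b1 += w * (r_i[k] - rho * t_i[k]);
    }
    if (choice[k] == 1) {
      decay(t_i[k]);
      // rho' = rho + alpha_pos * (r - rho)
      g_ap = (1.0 - alpha_pos) * g_ap + (r_i[k] - rho);
      g_an = (1.0 - alpha_pos) * g_an;
      rho += alpha_pos * (r_i[k] - rho);
    } else if (choice[k] == 2) {
      decay(timeout_seconds);
    }
  }
  return List::create(
    _["loglik"] = total,
    _["grad"] = NumericVector::create(d_ap, d_an, d_b0, d_b1));
}
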