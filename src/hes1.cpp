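#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Gamma hazard psi(t) / (1 - F(t)) in log space via the regularized upper
// incomplete gamma (numerically stable for large rate * t).
static inline double gamma_hazard(double t, double shape, double rate) {
  if (t <= 0.0) return shape > 1.0 ? 0.0 : (shape == 1.0 ? rate : R_PosInf);
  double scale = 1.0 / rate;
  double ld = R::dgamma(t, shape, scale, 1);
  double ls = R::pgamma(t, shape, scale, 0, 1); // upper tail, log
  return std::exp(ld - ls);
}

static inline double hill_repression(double np, double beta, double h) {
  return 1.0 / (1.0 + std::pow(np / beta, h));
}

// Thinning simulation of the Hes1 delayed negative-feedback circuit.
// Channels: initiation (zeroth order, rate beta * G(N_P)), per-molecule
// Gamma elongation (shape alpha_elong, rate alpha_elong * lambda0 with
// lambda0 state-dependent when gamma > 0), translation, and two
// exponential degradations.  Markovian channels are proposed at their
// exact current propensity (piecewise constant between events) and never
// reject; only the elongation channel thins against its analytic bound
// alpha_elong * lambda0.
// [[Rcpp::export]]
List hes1_mosaic_cpp(double beta, double gamma_res, double t_end,
                     double record_dt, double hill_h, double lambda_trans,
                     double lambda_degM, double lambda_degP, double tau0,
                     double alpha_elong, bool strict_bound,
                     double lambda_mult) {
  std::vector<double> clocks; // initiation times of nascent RNAs
  clocks.reserve(1024);
  long NM = 0, NP = 0;
  double T = 0.0;

  int n_rec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector rec_t(n_rec);
  IntegerVector rec_N(n_rec), rec_M(n_rec), rec_P(n_rec);
  int irec = 0;
  double next_rec = 0.0;

  long long proposals = 0, accepted = 0, rejected = 0;
  long long acc_init = 0, acc_elong = 0, acc_trans = 0, acc_degM = 0,
            acc_degP = 0;

  while (true) {
    long NN = (long)clocks.size();
    double lam0 = (1.0 / tau0) / (1.0 + gamma_res * (double)(NN + NM) / beta);
    double b_el = alpha_elong * lam0 * lambda_mult;
    if (strict_bound) {
      long nproc = NN + NM + NP;
      if (nproc < 1) nproc = 1;
      double floor_b = 20.0 * lam0 / (double)nproc;
      if (b_el < floor_b) b_el = floor_b;
    }
    double lam_init = beta * hill_repression((double)NP, beta, hill_h);
    double w_el = (double)NN * b_el;
    double w_tr = (double)NM * lambda_trans;
    double w_dm = (double)NM * lambda_degM;
    double w_dp = (double)NP * lambda_degP;
    double rtot = lam_init + w_el + w_tr + w_dm + w_dp;
    if (rtot <= 0.0) break;

    T += R::exp_rand() / rtot;
    while (irec < n_rec && next_rec <= T && next_rec <= t_end) {
      rec_t[irec] = next_rec;
      rec_N[irec] = (int)NN; rec_M[irec] = (int)NM; rec_P[irec] = (int)NP;
      irec++; next_rec += record_dt;
    }
    if (T > t_end) break;
    proposals++;

    double u = unif_rand() * rtot;
    if (u < lam_init) {
      clocks.push_back(T);
      accepted++; acc_init++;
    } else if ((u -= lam_init) < w_el) {
      int idx = (int)(unif_rand() * NN);
      if (idx >= NN) idx = (int)NN - 1;
      double lam = gamma_hazard(T - clocks[idx], alpha_elong,
                                alpha_elong * lam0);
      if (unif_rand() < lam / b_el) {
        clocks[idx] = clocks.back();
        clocks.pop_back();
        NM++;
        accepted++; acc_elong++;
      } else {
        rejected++;
      }
    } else if ((u -= w_el) < w_tr) {
      NP++;
      accepted++; acc_trans++;
    } else if ((u -= w_tr) < w_dm) {
      NM--;
      accepted++; acc_degM++;
    } else {
      NP--;
      accepted++; acc_degP++;
    }
  }
  // fill any remaining grid points with the final state
  while (irec < n_rec) {
    rec_t[irec] = next_rec;
    rec_N[irec] = (int)clocks.size(); rec_M[irec] = (int)NM;
    rec_P[irec] = (int)NP;
    irec++; next_rec += record_dt;
  }

  return List::create(
    _["trajectory"] = DataFrame::create(
      _["time"] = rec_t, _["N_N"] = rec_N, _["N_M"] = rec_M,
      _["N_P"] = rec_P),
    _["counters"] = List::create(
      _["candidates"] = (double)proposals, _["accepted"] = (double)accepted,
      _["rejected"] = (double)rejected, _["clipped"] = 0.0,
      _["accepted_by_channel"] = NumericVector::create(
        _["initiation"] = (double)acc_init,
        _["elongation"] = (double)acc_elong,
        _["translation"] = (double)acc_trans,
        _["degradation_M"] = (double)acc_degM,
        _["degradation_P"] = (double)acc_degP)),
    _["t_final"] = std::min(T, t_end),
    _["mean_dt"] = proposals > 0 ? std::min(T, t_end) / (double)proposals
                                 : NA_REAL);
}

// Delay-queue SSA for the same circuit with gamma = 0: elongation
// completion times are drawn from the Gamma distribution at initiation and
// executed through a min-ordered queue.  Exact for state-independent
// delays.
// [[Rcpp::export]]
List hes1_delay_ssa_cpp(double beta, double t_end, double record_dt,
                        double hill_h, double lambda_trans,
                        double lambda_degM, double lambda_degP, double tau0,
                        double alpha_elong) {
  std::priority_queue<double, std::vector<double>,
                      std::greater<double> > q;
  long NN = 0, NM = 0, NP = 0;
  double T = 0.0;
  double lam0 = 1.0 / tau0;

  int n_rec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector rec_t(n_rec);
  IntegerVector rec_N(n_rec), rec_M(n_rec), rec_P(n_rec);
  int irec = 0;
  double next_rec = 0.0;

  long long n_events = 0;
  double delay_sum = 0.0;
  long long delay_n = 0;

  while (true) {
    double lam_init = beta * hill_repression((double)NP, beta, hill_h);
    double rexp_tot = lam_init + (double)NM * (lambda_trans + lambda_degM) +
                      (double)NP * lambda_degP;
    double t_next;
    bool completion = false;
    if (rexp_tot > 0.0) {
      t_next = T + R::exp_rand() / rexp_tot;
    } else {
      t_next = R_PosInf;
    }
    if (!q.empty() && q.top() < t_next) {
      t_next = q.top();
      completion = true;
    }
    if (!R_FINITE(t_next)) break;

    while (irec < n_rec && next_rec <= t_next && next_rec <= t_end) {
      rec_t[irec] = next_rec;
      rec_N[irec] = (int)NN; rec_M[irec] = (int)NM; rec_P[irec] = (int)NP;
      irec++; next_rec += record_dt;
    }
    if (t_next > t_end) break;
    T = t_next;
    n_events++;

    if (completion) {
      q.pop();
      NN--; NM++;
      continue;
    }
    double u = unif_rand() * rexp_tot;
    if (u < lam_init) {
      double d = R::rgamma(alpha_elong, 1.0 / (alpha_elong * lam0));
      delay_sum += d; delay_n++;
      q.push(T + d);
      NN++;
    } else if ((u -= lam_init) < (double)NM * lambda_trans) {
      NP++;
    } else if ((u -= (double)NM * lambda_trans) < (double)NM * lambda_degM) {
      NM--;
    } else {
      NP--;
    }
  }
  while (irec < n_rec) {
    rec_t[irec] = next_rec;
    rec_N[irec] = (int)NN; rec_M[irec] = (int)NM; rec_P[irec] = (int)NP;
    irec++; next_rec += record_dt;
  }

  return List::create(
    _["trajectory"] = DataFrame::create(
      _["time"] = rec_t, _["N_N"] = rec_N, _["N_M"] = rec_M,
      _["N_P"] = rec_P),
    _["n_events"] = (double)n_events,
    _["mean_scheduled_delay"] = delay_n > 0 ? delay_sum / (double)delay_n
                                            : NA_REAL,
    _["t_final"] = std::min(T, t_end));
}
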