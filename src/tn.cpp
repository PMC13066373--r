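#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Node-driven non-Markovian temporal network.  Each node carries a clock
// t_i (time since its last interaction); pair-formation events are thinned
// against the constant global bound
//   Lambda_max = lambda_max^2 / ((N_A - 1) lambda_A),  lambda_max = alpha_A / t_min,
// valid for the whole run because the Pareto hazard alpha/t decreases
// monotonically beyond t_min.  Active edges carry their own termination
// clock (elapsed since formation) with a Pareto hazard bounded by
// alpha_0 / t_min_0.  Formation and termination channels share one clock:
// the proposal rate is N_form * Lambda_max + n_edges * lambda_max_term,
// with N_form the number of admissible (currently inactive) pairs.
//
// Partner selection: uniform over inactive pairs (variant A); with
// history weight w > 1, once node i is drawn its previous partners are w
// times more likely to be proposed (variant B, a model change with
// unchanged acceptance).  A third mode routes the same preference through
// the kernel under uniform proposals with bound w * Lambda_max; it targets
// the same dynamics as variant B but pays ~w times more rejections, and at
// w = 1 it reduces exactly to variant A (debug cross-check).
//
// activity_family / term_family: 0 = Pareto, 1 = exponential (constant
// hazard; with both exponential the node-driven process coincides with an
// edge-driven Markovian simulation).
// [[Rcpp::export]]
List tn_mosaic_cpp(int n_a, double t_end, double alpha_a, double lambda_a,
                   double alpha_e, double lambda_e, double w, int mode,
                   int activity_family, int term_family) {
  // mode: 0 = uniform proposal (variant A), 1 = history-biased proposal
  // (variant B), 2 = kernel-weighted uniform proposal (debug)
  double tmin_a, lmax_a;
  if (activity_family == 0) {
    tmin_a = std::pow(2.0, -1.0 / alpha_a) / lambda_a;
    lmax_a = alpha_a / tmin_a;
  } else {
    tmin_a = 0.0;
    lmax_a = lambda_a;
  }
  double tmin_e, lmax_e;
  if (term_family == 0) {
    tmin_e = std::pow(2.0, -1.0 / alpha_e) / lambda_e;
    lmax_e = alpha_e / tmin_e;
  } else {
    tmin_e = 0.0;
    lmax_e = lambda_e;
  }
  double Lmax = lmax_a * lmax_a / ((double)(n_a - 1) * lambda_a);
  double bound_form = (mode == 2) ? w * Lmax : Lmax;

  auto node_hazard = [&](double t) -> double {
    if (activity_family == 0) return t >= tmin_a ? alpha_a / t : 0.0;
    return lambda_a;
  };
  auto term_hazard = [&](double t) -> double {
    if (term_family == 0) return t >= tmin_e ? alpha_e / t : 0.0;
    return lambda_e;
  };

  std::vector<double> tau(n_a, 0.0);      // last interaction time per node
  std::vector<char> active((size_t)n_a * n_a, 0);
  std::vector<char> prior((size_t)n_a * n_a, 0);
  std::vector<int> prior_count(n_a, 0), active_deg(n_a, 0);
  std::vector<int> ei, ej;
  std::vector<double> estart;

  std::vector<double> c_start, c_end;
  std::vector<int> c_i, c_j;
  std::vector<int> c_cens;

  double T = 0.0;
  long long proposals = 0, acc_form = 0, acc_term = 0, rejected = 0;
  double max_ratio = 0.0;
  double n_pairs = (double)n_a * (n_a - 1) / 2.0;

  while (true) {
    double n_e = (double)ei.size();
    double n_form = n_pairs - n_e;
    double r_form = n_form * bound_form;
    double r_term = n_e * lmax_e;
    double rtot = r_form + r_term;
    if (rtot <= 0.0) break;
    T += R::exp_rand() / rtot;
    if (T > t_end) break;
    proposals++;

    if (unif_rand() * rtot < r_form) {
      int i = -1, j = -1;
      double wij = 1.0;
      if (mode == 1 && w != 1.0) {
        i = (int)(unif_rand() * n_a);
        if (i >= n_a) i = n_a - 1;
        // previous partners of i are `prior`; every active partner is also
        // prior (set at formation), so the inactive-prior count is
        // prior_count - active_deg
        double n_pa = (double)(prior_count[i] - active_deg[i]);
        double n_new = (double)(n_a - 1 - prior_count[i]);
        double W = w * n_pa + n_new;
        if (W <= 0.0) { rejected++; continue; }
        bool pick_prior = unif_rand() * W < w * n_pa;
        int target = pick_prior
          ? (int)(unif_rand() * n_pa) : (int)(unif_rand() * n_new);
        int seen = 0;
        for (int k = 0; k < n_a; ++k) {
          if (k == i) continue;
          bool is_pa = prior[(size_t)i * n_a + k] &&
                       !active[(size_t)i * n_a + k];
          bool is_new = !prior[(size_t)i * n_a + k];
          if ((pick_prior && is_pa) || (!pick_prior && is_new)) {
            if (seen == target) { j = k; break; }
            seen++;
          }
        }
        if (j < 0) { rejected++; continue; }
      } else {
        // uniform over inactive pairs by redraw
        do {
          i = (int)(unif_rand() * n_a);
          j = (int)(unif_rand() * n_a);
          if (i >= n_a) i = n_a - 1;
          if (j >= n_a) j = n_a - 1;
        } while (i == j || active[(size_t)i * n_a + j]);
        if (mode == 2) {
          wij = prior[(size_t)i * n_a + j] ? w : 1.0;
        }
      }
      double li = node_hazard(T - tau[i]);
      double lj = node_hazard(T - tau[j]);
      double lam = wij * li * lj / ((double)(n_a - 1) * lambda_a);
      double ratio = lam / bound_form;
      if (ratio > max_ratio) max_ratio = ratio;
      if (ratio > 1.0 + 1e-9) {
        stop("pairwise rate %g exceeds the bound %g", lam, bound_form);
      }
      if (unif_rand() < ratio) {
        tau[i] = T; tau[j] = T;       // both node clocks reset on formation
        active[(size_t)i * n_a + j] = active[(size_t)j * n_a + i] = 1;
        active_deg[i]++; active_deg[j]++;
        if (!prior[(size_t)i * n_a + j]) {
          prior[(size_t)i * n_a + j] = prior[(size_t)j * n_a + i] = 1;
          prior_count[i]++; prior_count[j]++;
        }
        ei.push_back(std::min(i, j)); ej.push_back(std::max(i, j));
        estart.push_back(T);
        acc_form++;
      } else {
        rejected++;
      }
    } else {
      int idx = (int)(unif_rand() * n_e);
      if (idx >= (int)n_e) idx = (int)n_e - 1;
      double lam = term_hazard(T - estart[idx]);
      double ratio = lam / lmax_e;
      if (ratio > max_ratio) max_ratio = ratio;
      if (unif_rand() < ratio) {
        int i = ei[idx], j = ej[idx];
        c_start.push_back(estart[idx]); c_end.push_back(T);
        c_i.push_back(i); c_j.push_back(j); c_cens.push_back(0);
        active[(size_t)i * n_a + j] = active[(size_t)j * n_a + i] = 0;
        active_deg[i]--; active_deg[j]--;
        ei[idx] = ei.back(); ej[idx] = ej.back(); estart[idx] = estart.back();
        ei.pop_back(); ej.pop_back(); estart.pop_back();
        acc_term++;
      } else {
        rejected++;
      }
    }
  }
  // edges still open at the horizon are censored there
  for (size_t k = 0; k < ei.size(); ++k) {
    c_start.push_back(estart[k]); c_end.push_back(t_end);
    c_i.push_back(ei[k]); c_j.push_back(ej[k]); c_cens.push_back(1);
  }

  int nc = (int)c_start.size();
  NumericVector t0(nc), t1(nc);
  IntegerVector ii(nc), jj(nc), cc(nc);
  for (int k = 0; k < nc; ++k) {
    t0[k] = c_start[k]; t1[k] = c_end[k];
    ii[k] = c_i[k] + 1; jj[k] = c_j[k] + 1; cc[k] = c_cens[k];
  }

  return List::create(
    _["contacts"] = DataFrame::create(
      _["t_start"] = t0, _["t_end"] = t1, _["i"] = ii, _["j"] = jj,
      _["censored"] = cc),
    _["counters"] = List::create(
      _["candidates"] = (double)proposals,
      _["accepted"] = (double)(acc_form + acc_term),
      _["accepted_formation"] = (double)acc_form,
      _["accepted_termination"] = (double)acc_term,
      _["rejected"] = (double)rejected),
    _["max_acceptance_ratio"] = max_ratio,
    _["lambda_max"] = lmax_a,
    _["Lambda_max"] = Lmax,
    _["t_final"] = std::min(T, t_end));
}
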