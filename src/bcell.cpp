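#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Germinal-center affinity-maturation model: five channels over an agent
// population of B cells with per-cell receptor affinities.
//
//   (i)   binding        B + T -> [BT]            rate lambda_BT per (free B, free T) pair
//   (ii)  competition    [B1 T] + B2 -> [B2 T] + B1, rate lambda_BT per
//         (bound pair, free B) pair, accepted only when the challenger's
//         affinity is strictly higher (rejection implements the
//         individual-property dependence; the bound is lambda_BT, fixed)
//   (iii) apoptosis      B -> 0                   rate lambda_apop per free B
//   (iv)  unbinding      [BT] -> B_div + T        rate lambda_unbind per pair
//   (v)   division       B_div -> B + B           rate lambda_div per cell
//
// Pairwise channels are never enumerated: a candidate pair is drawn
// uniformly (bound pair x free challenger) and thinned, giving O(1) work
// per candidate iteration regardless of population size.  Membership lists
// use swap-and-pop so uniform sampling is over the live registry.
//
// Division replaces the parent by two free daughters; each daughter
// receives an independent affinity update a + (u - a) / beta, which keeps
// affinities in [0, 1].  Clones are indexed by founder cell.
// [[Rcpp::export]]
List bcell_mosaic_cpp(int n_b, int n_t, double t_end, double lambda_bt,
                      double lambda_unbind, double lambda_apop,
                      double lambda_div, double beta, bool competition,
                      double record_dt) {
  std::vector<double> aff;     // affinity per cell
  std::vector<int> clone;      // founder index per cell
  std::vector<int> loc;        // 0 free, 1 bound, 2 division-ready, -1 dead
  std::vector<int> pos;        // index within its membership list
  std::vector<int> free_l, bound_l, div_l;
  std::vector<long> clone_count(n_b, 0);

  aff.reserve(2 * n_b); clone.reserve(2 * n_b);
  loc.reserve(2 * n_b); pos.reserve(2 * n_b);
  for (int i = 0; i < n_b; ++i) {
    aff.push_back(0.0);          // affinities start at 0
    clone.push_back(i);
    loc.push_back(0);
    pos.push_back((int)free_l.size());
    free_l.push_back(i);
    clone_count[i] = 1;
  }
  long alive = n_b;

  // move cell c from its current list into list `to`
  std::vector<int>* lists[3] = { &free_l, &bound_l, &div_l };
  auto detach = [&](int c) {
    std::vector<int>& L = *lists[loc[c]];
    int p = pos[c];
    int last = L.back();
    L[p] = last; pos[last] = p;
    L.pop_back();
  };
  auto attach = [&](int c, int to) {
    std::vector<int>& L = *lists[to];
    loc[c] = to; pos[c] = (int)L.size();
    L.push_back(c);
  };

  double T = 0.0;
  int n_rec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector rec_t(n_rec), rec_aff(n_rec), rec_dom(n_rec);
  IntegerVector rec_free(n_rec), rec_bound(n_rec), rec_div(n_rec),
      rec_total(n_rec);
  int irec = 0;
  double next_rec = 0.0;
  auto record_state = [&]() {
    rec_t[irec] = next_rec;
    rec_free[irec] = (int)free_l.size();
    rec_bound[irec] = (int)bound_l.size();
    rec_div[irec] = (int)div_l.size();
    rec_total[irec] = (int)alive;
    if (alive > 0) {
      double s = 0.0;
      for (size_t k = 0; k < aff.size(); ++k)
        if (loc[k] >= 0) s += aff[k];
      rec_aff[irec] = s / (double)alive;
      long mx = 0;
      for (int k = 0; k < n_b; ++k)
        if (clone_count[k] > mx) mx = clone_count[k];
      rec_dom[irec] = (double)mx / (double)alive;
    } else {
      rec_aff[irec] = NA_REAL;
      rec_dom[irec] = NA_REAL;
    }
    irec++; next_rec += record_dt;
  };

  long long proposals = 0, accepted = 0, rejected = 0;
  long long acc_bind = 0, acc_comp = 0, acc_apop = 0, acc_unbind = 0,
            acc_div = 0;
  bool extinct = false;

  while (true) {
    double n_f = (double)free_l.size();
    double n_bd = (double)bound_l.size();
    double n_d = (double)div_l.size();
    double n_tf = (double)(n_t - (int)bound_l.size());
    double w_bind = n_f * n_tf * lambda_bt;
    double w_comp = competition ? n_bd * n_f * lambda_bt : 0.0;
    double w_apop = n_f * lambda_apop;
    double w_unb = n_bd * lambda_unbind;
    double w_div = n_d * lambda_div;
    double rtot = w_bind + w_comp + w_apop + w_unb + w_div;
    if (alive == 0) { extinct = true; break; }
    if (rtot <= 0.0) break;

    T += R::exp_rand() / rtot;
    while (irec < n_rec && next_rec <= T && next_rec <= t_end) record_state();
    if (T > t_end) break;
    proposals++;

    double u = unif_rand() * rtot;
    if (u < w_bind) {
      int c = free_l[(int)(unif_rand() * n_f)];
      detach(c); attach(c, 1);
      accepted++; acc_bind++;
    } else if ((u -= w_bind) < w_comp) {
      int b = bound_l[(int)(unif_rand() * n_bd)];
      int f = free_l[(int)(unif_rand() * n_f)];
      if (aff[f] > aff[b]) {       // strict: equal affinities are rejected
        detach(b); detach(f);
        attach(f, 1); attach(b, 0); // displaced cell returns to the free pool
        accepted++; acc_comp++;
      } else {
        rejected++;
      }
    } else if ((u -= w_comp) < w_apop) {
      int c = free_l[(int)(unif_rand() * n_f)];
      detach(c); loc[c] = -1;
      clone_count[clone[c]]--;
      alive--;
      accepted++; acc_apop++;
    } else if ((u -= w_apop) < w_unb) {
      int c = bound_l[(int)(unif_rand() * n_bd)];
      detach(c); attach(c, 2);
      accepted++; acc_unbind++;
    } else {
      int c = div_l[(int)(unif_rand() * n_d)];
      double a = aff[c];
      double a1 = a + (unif_rand() - a) / beta;
      double a2 = a + (unif_rand() - a) / beta;
      detach(c);
      aff[c] = a1; attach(c, 0);
      aff.push_back(a2);
      clone.push_back(clone[c]);
      loc.push_back(-2); pos.push_back(-1); // placeholders, set by attach
      attach((int)aff.size() - 1, 0);
      clone_count[clone[c]]++;
      alive++;
      accepted++; acc_div++;
    }
  }
  while (irec < n_rec) record_state();

  int n_cells = (int)aff.size();
  NumericVector out_aff(n_cells);
  IntegerVector out_clone(n_cells), out_status(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    out_aff[i] = aff[i]; out_clone[i] = clone[i] + 1; out_status[i] = loc[i];
  }

  return List::create(
    _["trajectory"] = DataFrame::create(
      _["time"] = rec_t, _["n_free"] = rec_free, _["n_bound"] = rec_bound,
      _["n_div"] = rec_div, _["n_total"] = rec_total,
      _["mean_affinity"] = rec_aff, _["dominance"] = rec_dom),
    _["cells"] = DataFrame::create(
      _["affinity"] = out_aff, _["clone"] = out_clone,
      _["status"] = out_status),
    _["counters"] = List::create(
      _["candidates"] = (double)proposals, _["accepted"] = (double)accepted,
      _["rejected"] = (double)rejected,
      _["accepted_by_channel"] = NumericVector::create(
        _["binding"] = (double)acc_bind,
        _["competition"] = (double)acc_comp,
        _["apoptosis"] = (double)acc_apop,
        _["unbinding"] = (double)acc_unbind,
        _["division"] = (double)acc_div)),
    _["extinct"] = extinct,
    _["t_final"] = std::min(T, t_end));
}
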