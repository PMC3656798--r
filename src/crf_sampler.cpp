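// Compiled engine for the collapsed Chinese-restaurant-franchise Gibbs
// sampler. Semantics mirror the R reference implementation in R/sampler.R:
// per-customer table resampling (direct categorical or one M-H step with a
// uniform proposal over the finite support), per-table dish resampling,
// optional concentration redraws from the Gamma prior, canonical relabeling
// of each recorded snapshot. Uses R's RNG so set.seed() governs the run.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <utility>

using namespace Rcpp;

namespace {

struct Table {
  int dish;
  int n;
  double sum, sumsq;
};

struct Dish {
  int ntab;  // tables serving this dish, summed over rows
  int n;
  double sum, sumsq;
};

struct Model {
  double s2, m0, s02;
};

// log marginal likelihood of a block with sufficient stats (n, s, ss)
double lml(int n, double s, double ss, const Model& mod) {
  if (n == 0) return 0.0;
  if (mod.s02 == 0.0) {
    return -0.5 * n * std::log(2.0 * M_PI * mod.s2) -
           (ss - 2.0 * mod.m0 * s + n * mod.m0 * mod.m0) / (2.0 * mod.s2);
  }
  double tau = 1.0 / mod.s2, tau0 = 1.0 / mod.s02;
  double A = n * tau + tau0;
  double B = tau * s + tau0 * mod.m0;
  return -0.5 * n * std::log(2.0 * M_PI * mod.s2) - tau * ss / 2.0 -
         0.5 * std::log(2.0 * M_PI * mod.s02) - tau0 * mod.m0 * mod.m0 / 2.0 +
         0.5 * std::log(2.0 * M_PI / A) + B * B / (2.0 * A);
}

double log_pred(double g, const Dish& d, const Model& mod) {
  return lml(d.n + 1, d.sum + g, d.sumsq + g * g, mod) - lml(d.n, d.sum, d.sumsq, mod);
}

int sample_log(const std::vector<double>& lw) {
  double m = lw[0];
  for (double v : lw) if (v > m) m = v;
  double tot = 0.0;
  std::vector<double> p(lw.size());
  for (size_t i = 0; i < lw.size(); ++i) { p[i] = std::exp(lw[i] - m); tot += p[i]; }
  double u = unif_rand() * tot, c = 0.0;
  for (size_t i = 0; i < lw.size(); ++i) { c += p[i]; if (u <= c) return (int)i; }
  return (int)lw.size() - 1;
}

struct State {
  int M, N;
  IntegerMatrix phi;                 // M x N table labels (R indexing kept)
  std::vector<std::map<int, Table> > rows;
  std::map<int, Dish> dishes;
  std::vector<int> next_table;
  int next_dish;

  void dish_detach(int k, int n, double s, double ss) {
    Dish& d = dishes[k];
    d.ntab -= 1; d.n -= n; d.sum -= s; d.sumsq -= ss;
    if (d.ntab == 0) dishes.erase(k);
  }
  void dish_attach(int k, int n, double s, double ss) {
    Dish& d = dishes[k];  // creates if absent (ntab 0)
    d.ntab += 1; d.n += n; d.sum += s; d.sumsq += ss;
  }
};

}  // namespace

// [[Rcpp::export]]
List crf_run_chain(NumericMatrix g,        // M x N (experiments x genes)
                   IntegerMatrix phi0,     // M x N initial table labels
                   IntegerMatrix z0,       // M x N initial dish labels
                   double obs_var, double prior_mean, double prior_var,
                   double alpha0, double alpha1,
                   double gamma_shape, double gamma_rate,
                   bool resample_conc,
                   int burnin, int L, int thin,
                   bool mh, bool verbose) {
  const int M = g.nrow(), N = g.ncol();
  Model mod{obs_var, prior_mean, prior_var};
  State st;
  st.M = M; st.N = N;
  st.phi = clone(phi0);
  st.rows.resize(M);
  st.next_table.assign(M, 1);
  st.next_dish = 1;

  // rebuild tables and dishes from (phi0, z0)
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < N; ++i) {
      int t = phi0(j, i), k = z0(j, i);
      double v = g(j, i);
      std::map<int, Table>::iterator it = st.rows[j].find(t);
      if (it == st.rows[j].end()) {
        Table tb; tb.dish = k; tb.n = 1; tb.sum = v; tb.sumsq = v * v;
        st.rows[j][t] = tb;
        Dish& d = st.dishes[k];
        d.ntab += 1;
      } else {
        if (it->second.dish != k) stop("inconsistent initial dish labels at table");
        it->second.n += 1; it->second.sum += v; it->second.sumsq += v * v;
      }
      Dish& d = st.dishes[k];
      d.n += 1; d.sum += v; d.sumsq += v * v;
      if (t >= st.next_table[j]) st.next_table[j] = t + 1;
      if (k >= st.next_dish) st.next_dish = k + 1;
    }
  }

  RNGScope scope;
  const int total = burnin + L * thin;
  IntegerVector Zout(M * N * L), Tout(M * N * L);
  NumericVector a0out(L), a1out(L);
  IntegerVector Kout(L);
  double a0 = alpha0, a1 = alpha1;
  int rec = 0;

  std::vector<int> dish_labs;
  std::vector<double> logf, lw;

  for (int l = 1; l <= total; ++l) {
    // ---- table step ----
    for (int j = 0; j < M; ++j) {
      for (int i = 0; i < N; ++i) {
        double v = g(j, i);
        int prev_t = st.phi(j, i);
        // unseat
        {
          Table& tb = st.rows[j][prev_t];
          int k = tb.dish;
          tb.n -= 1; tb.sum -= v; tb.sumsq -= v * v;
          Dish& d = st.dishes[k];
          d.n -= 1; d.sum -= v; d.sumsq -= v * v;
          if (tb.n == 0) {
            st.rows[j].erase(prev_t);
            d.ntab -= 1;
            if (d.ntab == 0) st.dishes.erase(k);
          }
        }
        // per-dish log predictives of v
        dish_labs.clear(); logf.clear();
        double totd = 0.0;
        for (std::map<int, Dish>::const_iterator it = st.dishes.begin();
             it != st.dishes.end(); ++it) {
          dish_labs.push_back(it->first);
          logf.push_back(log_pred(v, it->second, mod));
          totd += it->second.ntab;
        }
        double lp0 = lml(1, v, v * v, mod);
        // new-table weight: alpha0 * mixture over dishes + fresh dish
        double mix;
        {
          std::vector<double> parts;
          size_t di = 0;
          for (std::map<int, Dish>::const_iterator it = st.dishes.begin();
               it != st.dishes.end(); ++it, ++di)
            parts.push_back(std::log((double)it->second.ntab) + logf[di]);
          parts.push_back(std::log(a1) + lp0);
          double m = parts[0];
          for (double x : parts) if (x > m) m = x;
          double s = 0.0;
          for (double x : parts) s += std::exp(x - m);
          mix = m + std::log(s);
        }
        double log_new = std::log(a0) + mix - std::log(totd + a1);
        // occupied-table weights
        std::vector<int> tab_labs;
        lw.clear();
        for (std::map<int, Table>::const_iterator it = st.rows[j].begin();
             it != st.rows[j].end(); ++it) {
          tab_labs.push_back(it->first);
          size_t di = 0;
          double f = 0.0;
          for (; di < dish_labs.size(); ++di)
            if (dish_labs[di] == it->second.dish) { f = logf[di]; break; }
          lw.push_back(std::log((double)it->second.n) + f);
        }
        lw.push_back(log_new);
        int n_opt = (int)lw.size();
        int idx;
        if (!mh) {
          idx = sample_log(lw);
        } else {
          int cur = n_opt - 1;
          for (size_t ti = 0; ti < tab_labs.size(); ++ti)
            if (tab_labs[ti] == prev_t) { cur = (int)ti; break; }
          int cand = (int)std::floor(unif_rand() * n_opt);
          if (cand >= n_opt) cand = n_opt - 1;
          double beta = std::exp(lw[cand] - lw[cur]);
          idx = (cand == cur || unif_rand() < beta) ? cand : cur;
        }
        if (idx < (int)tab_labs.size()) {
          int t = tab_labs[idx];
          Table& tb = st.rows[j][t];
          tb.n += 1; tb.sum += v; tb.sumsq += v * v;
          Dish& d = st.dishes[tb.dish];
          d.n += 1; d.sum += v; d.sumsq += v * v;
          st.phi(j, i) = t;
        } else {
          // new table: draw its dish from dish-level CRP weights
          std::vector<double> ld;
          size_t di = 0;
          for (std::map<int, Dish>::const_iterator it = st.dishes.begin();
               it != st.dishes.end(); ++it, ++di)
            ld.push_back(std::log((double)it->second.ntab) + logf[di]);
          ld.push_back(std::log(a1) + lp0);
          int kidx = sample_log(ld);
          int k;
          if (kidx < (int)dish_labs.size()) k = dish_labs[kidx];
          else k = st.next_dish++;
          int t = st.next_table[j]++;
          Table tb; tb.dish = k; tb.n = 1; tb.sum = v; tb.sumsq = v * v;
          st.rows[j][t] = tb;
          st.dish_attach(k, 1, v, v * v);
          st.phi(j, i) = t;
        }
      }
    }
    // ---- dish step ----
    for (int j = 0; j < M; ++j) {
      std::vector<int> labs;
      for (std::map<int, Table>::const_iterator it = st.rows[j].begin();
           it != st.rows[j].end(); ++it)
        labs.push_back(it->first);
      for (int t : labs) {
        std::map<int, Table>::iterator ti = st.rows[j].find(t);
        if (ti == st.rows[j].end()) continue;
        Table& tb = ti->second;
        int prev_k = tb.dish;
        st.dish_detach(prev_k, tb.n, tb.sum, tb.sumsq);
        tb.dish = -1;
        double block = lml(tb.n, tb.sum, tb.sumsq, mod);
        dish_labs.clear(); lw.clear();
        for (std::map<int, Dish>::const_iterator it = st.dishes.begin();
             it != st.dishes.end(); ++it) {
          dish_labs.push_back(it->first);
          const Dish& d = it->second;
          lw.push_back(std::log((double)d.ntab) +
                       lml(d.n + tb.n, d.sum + tb.sum, d.sumsq + tb.sumsq, mod) -
                       lml(d.n, d.sum, d.sumsq, mod));
        }
        lw.push_back(std::log(a1) + block);
        int n_opt = (int)lw.size();
        int idx;
        if (!mh) {
          idx = sample_log(lw);
        } else {
          int cur = n_opt - 1;
          for (size_t di = 0; di < dish_labs.size(); ++di)
            if (dish_labs[di] == prev_k) { cur = (int)di; break; }
          int cand = (int)std::floor(unif_rand() * n_opt);
          if (cand >= n_opt) cand = n_opt - 1;
          double beta = std::exp(lw[cand] - lw[cur]);
          idx = (cand == cur || unif_rand() < beta) ? cand : cur;
        }
        int k;
        if (idx < (int)dish_labs.size()) k = dish_labs[idx];
        else k = st.next_dish++;
        tb.dish = k;
        st.dish_attach(k, tb.n, tb.sum, tb.sumsq);
      }
    }
    // ---- concentrations ----
    if (resample_conc) {
      a0 = R::rgamma(gamma_shape, 1.0 / gamma_rate);
      a1 = R::rgamma(gamma_shape, 1.0 / gamma_rate);
    }
    // ---- record ----
    if (l > burnin && (l - burnin) % thin == 0) {
      // canonical dish labels: rank dishes by increasing mean of their data
      std::vector<std::pair<double, int> > by_mean;
      for (std::map<int, Dish>::const_iterator it = st.dishes.begin();
           it != st.dishes.end(); ++it)
        by_mean.push_back(std::make_pair(it->second.sum / it->second.n, it->first));
      std::sort(by_mean.begin(), by_mean.end());
      std::map<int, int> dmap;
      for (size_t r = 0; r < by_mean.size(); ++r)
        dmap[by_mean[r].second] = (int)r + 1;
      for (int j = 0; j < M; ++j) {
        std::map<int, int> tmap;
        int tnext = 1;
        for (int i = 0; i < N; ++i) {
          int t = st.phi(j, i);
          int k = st.rows[j][t].dish;
          if (tmap.find(t) == tmap.end()) tmap[t] = tnext++;
          Zout[rec * M * N + (size_t)i * M + j] = dmap[k];
          Tout[rec * M * N + (size_t)i * M + j] = tmap[t];
        }
      }
      a0out[rec] = a0; a1out[rec] = a1;
      Kout[rec] = (int)st.dishes.size();
      ++rec;
    }
    if (verbose && l % 100 == 0)
      Rprintf("sweep %d/%d: %d dishes\n", l, total, (int)st.dishes.size());
    if (l % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["z"] = Zout, _["tab"] = Tout,
                      _["alpha0"] = a0out, _["alpha1"] = a1out,
                      _["K"] = Kout);
}
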