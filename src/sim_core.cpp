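// Exact continuous-time (Gillespie) simulation of island assembly for a
// single mainland species.  Mainland species are independent, so whole-island
// simulations are assembled from independent per-species trajectories.
//
// Uses R's RNG throughout so that set.seed() from R gives reproducible,
// platform-portable results.

#include <Rcpp.h>
using namespace Rcpp;

static inline double ddr(double base, double n, double K) {
  if (!std::isfinite(K)) return base;
  double r = base * (1.0 - n / K);
  return r > 0.0 ? r : 0.0;
}

// Event codes in the event log.
enum EvCode { EV_IMM = 1, EV_REIMM = 2, EV_CLADO = 3, EV_ANA = 4, EV_EXT = 5 };

struct LineageSim {
  // per-species genealogy; indices are 0-based, parents always precede
  // children, so single sweeps resolve roots and survivor counts
  std::vector<int> parent, endemic, origin, child1, child2;
  std::vector<double> t_birth, t_col, t_death; // t_death < 0 means extant
  std::vector<double> ev_t;
  std::vector<int> ev_code, ev_delta;
  int pop; // index of the non-endemic (mainland-conspecific) population, -1 if absent

  void reset() {
    parent.clear(); endemic.clear(); origin.clear();
    child1.clear(); child2.clear();
    t_birth.clear(); t_col.clear(); t_death.clear();
    ev_t.clear(); ev_code.clear(); ev_delta.clear();
    pop = -1;
  }

  int add_species(int par, double tb, double tc, int end, int orig) {
    parent.push_back(par); t_birth.push_back(tb); t_col.push_back(tc);
    t_death.push_back(-1.0); endemic.push_back(end); origin.push_back(orig);
    child1.push_back(-1); child2.push_back(-1);
    return (int)parent.size() - 1;
  }

  void log_event(double t, int code, int delta) {
    ev_t.push_back(t); ev_code.push_back(code); ev_delta.push_back(delta);
  }

  // Simulate one mainland species over [0, age].  Rules: immigration at
  // clade-diversity-dependent rate gamma_N (a re-immigration onto a
  // non-diverged population resets its colonisation time); per-species
  // extinction mu and cladogenesis lambda^c_N; anagenesis lambda^a converts
  // the non-endemic population into an endemic species and is a no-op for
  // species that are already endemic.
  void run(double gamma, double lac, double laa, double mu, double K,
           double age, double t_start = 0.0, bool start_with_pop = false) {
    reset();
    std::vector<int> alive;
    double t = t_start;
    if (start_with_pop) {
      pop = add_species(-1, t_start, t_start, 0, 0);
      alive.push_back(pop);
      log_event(t_start, EV_IMM, +1);
    }
    for (;;) {
      const int N = (int)alive.size();
      const double g = ddr(gamma, N, K);
      const double lc = ddr(lac, N, K);
      const double tot = g + N * (mu + lc) + (pop >= 0 ? laa : 0.0);
      if (tot <= 0.0) break;
      t += R::rexp(1.0 / tot);
      if (t >= age) break;
      double u = R::runif(0.0, tot);
      if (u < g) {
        if (pop >= 0) {          // replacement: divergence time resets
          t_col[pop] = t;
          log_event(t, EV_REIMM, 0);
        } else {                 // (re)colonisation founds a population
          pop = add_species(-1, t, t, 0, 0);
          alive.push_back(pop);
          log_event(t, EV_IMM, +1);
        }
        continue;
      }
      u -= g;
      if (u < N * mu) {          // extinction of a uniformly chosen species
        int vi = (int)(R::unif_rand() * N); if (vi >= N) vi = N - 1;
        int v = alive[vi];
        t_death[v] = t;
        alive.erase(alive.begin() + vi);
        if (v == pop) pop = -1;
        log_event(t, EV_EXT, -1);
        continue;
      }
      u -= N * mu;
      if (u < N * lc) {          // cladogenesis: parent replaced by 2 endemics
        int pi = (int)(R::unif_rand() * N); if (pi >= N) pi = N - 1;
        int p = alive[pi];
        int a = add_species(p, t, t, 1, 1);
        int b = add_species(p, t, t, 1, 1);
        child1[p] = a; child2[p] = b; t_death[p] = t;
        alive[pi] = a; alive.push_back(b);
        if (p == pop) pop = -1;
        log_event(t, EV_CLADO, +1);
        continue;
      }
      // anagenesis of the non-endemic population (divergence time kept)
      endemic[pop] = 1; origin[pop] = 2; pop = -1;
      log_event(t, EV_ANA, 0);
    }
  }

  int n_species() const { return (int)parent.size(); }
};

static List pack_lineage(const LineageSim& s, int mainland_id) {
  const int n = s.n_species();
  IntegerVector parent(n), endemic(n), origin(n), child1(n), child2(n);
  NumericVector tb(n), tc(n), td(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = s.parent[i] < 0 ? NA_INTEGER : s.parent[i] + 1;
    endemic[i] = s.endemic[i]; origin[i] = s.origin[i];
    child1[i] = s.child1[i] < 0 ? NA_INTEGER : s.child1[i] + 1;
    child2[i] = s.child2[i] < 0 ? NA_INTEGER : s.child2[i] + 1;
    tb[i] = s.t_birth[i]; tc[i] = s.t_col[i];
    td[i] = s.t_death[i] < 0 ? NA_REAL : s.t_death[i];
  }
  // plain vector lists (not DataFrames): cheap to create and sufficient
  // for $-style column access on the R side
  return List::create(
      _["mainland_id"] = mainland_id,
      _["species"] = List::create(
          _["parent"] = parent, _["t_birth"] = tb, _["t_col"] = tc,
          _["t_death"] = td, _["endemic"] = endemic, _["origin"] = origin,
          _["child1"] = child1, _["child2"] = child2),
      _["events"] = List::create(
          _["t"] = NumericVector(s.ev_t.begin(), s.ev_t.end()),
          _["code"] = IntegerVector(s.ev_code.begin(), s.ev_code.end()),
          _["delta"] = IntegerVector(s.ev_delta.begin(), s.ev_delta.end())));
}

// Simulate M independent mainland species of one lineage class; only species
// with at least one event are returned (the rest never interacted with the
// island).
// [[Rcpp::export(name = ".cpp_sim_class")]]
List cpp_sim_class(double gamma, double lac, double laa, double mu, double K,
                   double age, int M) {
  LineageSim s;
  List out;
  for (int m = 0; m < M; ++m) {
    // first event, if any, is an immigration at rate gamma
    if (gamma <= 0.0) break;
    double t0 = R::rexp(1.0 / gamma);
    if (t0 >= age) continue;
    // replay from the injected first arrival (the process is memoryless)
    s.run(gamma, lac, laa, mu, K, age, t0, true);
    out.push_back(pack_lineage(s, m + 1));
  }
  return out;
}

// Terminal category of one mainland species, replicated nreps times:
// columns are (population present 0/1, number of extant endemic species,
// colonisation time of the population if present else -1).
// [[Rcpp::export(name = ".cpp_sim_categories")]]
NumericMatrix cpp_sim_categories(double gamma, double lac, double laa,
                                 double mu, double K, double age, int nreps) {
  NumericMatrix out(nreps, 3);
  LineageSim s;
  for (int r = 0; r < nreps; ++r) {
    s.run(gamma, lac, laa, mu, K, age);
    int nend = 0;
    for (int i = 0; i < s.n_species(); ++i)
      if (s.t_death[i] < 0 && s.endemic[i]) ++nend;
    out(r, 0) = s.pop >= 0 ? 1.0 : 0.0;
    out(r, 1) = nend;
    out(r, 2) = s.pop >= 0 ? s.t_col[s.pop] : -1.0;
  }
  return out;
}

// Replicated per-species simulations summarised at the clade level, for
// Monte-Carlo validation of the timed likelihood densities.  Columns:
//  1 population present (0/1)
//  2 total extant endemic species
//  3 number of surviving endemic clades (distinct colonisation roots)
//  4 colonisation (stem) time of the primary clade (oldest root), -1 if none
//  5 oldest reconstructed branching time within the primary clade, -1 if none
//  6 extant endemic species in the primary clade
//  7 second-oldest reconstructed branching time in the primary clade, -1
//  8 stem time of the second-oldest surviving endemic clade, -1
// [[Rcpp::export(name = ".cpp_sim_clade_pattern")]]
NumericMatrix cpp_sim_clade_pattern(double gamma, double lac, double laa,
                                    double mu, double K, double age,
                                    int nreps) {
  NumericMatrix out(nreps, 8);
  LineageSim s;
  std::vector<int> cnt, root;
  for (int r = 0; r < nreps; ++r) {
    s.run(gamma, lac, laa, mu, K, age);
    const int n = s.n_species();
    cnt.assign(n, 0); root.assign(n, -1);
    int nend = 0;
    for (int i = 0; i < n; ++i) {
      if (s.t_death[i] < 0 && s.endemic[i]) { cnt[i] = 1; ++nend; }
      root[i] = s.parent[i] < 0 ? i : root[s.parent[i]];
    }
    for (int i = n - 1; i >= 0; --i)
      if (s.parent[i] >= 0) cnt[s.parent[i]] += cnt[i];
    // roots with surviving endemic descendants
    int primary = -1, nclades = 0;
    for (int i = 0; i < n; ++i) {
      if (s.parent[i] < 0 && cnt[i] > 0) {
        ++nclades;
        if (primary < 0 || s.t_col[i] < s.t_col[primary]) primary = i;
      }
    }
    double crown = -1.0, node2 = -1.0, stem2 = -1.0;
    int nprim = 0;
    if (primary >= 0) {
      for (int i = 0; i < n; ++i) {
        if (s.parent[i] < 0 && cnt[i] > 0 && i != primary)
          if (stem2 < 0 || s.t_col[i] < stem2) stem2 = s.t_col[i];
        if (root[i] != primary) continue;
        if (s.t_death[i] < 0 && s.endemic[i]) ++nprim;
        if (s.child1[i] >= 0 && cnt[s.child1[i]] > 0 &&
            cnt[s.child2[i]] > 0) {
          double tn = s.t_death[i];
          if (crown < 0 || tn < crown) { node2 = crown; crown = tn; }
          else if (node2 < 0 || tn < node2) node2 = tn;
        }
      }
    }
    out(r, 0) = s.pop >= 0 ? 1.0 : 0.0;
    out(r, 1) = nend;
    out(r, 2) = nclades;
    out(r, 3) = primary >= 0 ? s.t_col[primary] : -1.0;
    out(r, 4) = crown;
    out(r, 5) = nprim;
    out(r, 6) = node2;
    out(r, 7) = stem2;
  }
  return out;
}
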