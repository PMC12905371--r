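#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct SearchState {
  int nc, ns, nl;
  const double *mass;   // nc x nc pairwise leak mass (total objective)
  const double *sim;    // nc x nc inter-cluster similarity (max objective)
  const double *w;      // cluster weights
  const int *labcnt;    // nc x nl per-cluster label counts (may be null)
  std::vector<double> lo, hi;       // per-split weight windows
  std::vector<double> gshare;       // global label shares
  double strat_tol;
  int objective;                    // 0 = total, 1 = max
  double W;
  std::vector<int> assign, best_assign;
  std::vector<double> wsum;
  std::vector<std::vector<double>> lsum;  // ns x nl assigned label counts
  std::vector<double> lcluster_tot;       // per-cluster total label count
  std::vector<double> ltot;               // per-split total label count
  double best;
  bool found;
  std::vector<double> suffix_w;     // remaining weight after cluster i
};

bool leaf_ok(SearchState &st) {
  for (int s = 0; s < st.ns; ++s)
    if (st.wsum[s] < st.lo[s] - 1e-9) return false;
  if (st.labcnt) {
    for (int s = 0; s < st.ns; ++s) {
      if (st.ltot[s] <= 0) continue;
      for (int l = 0; l < st.nl; ++l) {
        double share = st.lsum[s][l] / st.ltot[s];
        if (std::abs(share - st.gshare[l]) > st.strat_tol + 1e-9) return false;
      }
    }
  }
  return true;
}

void dfs(SearchState &st, int i, double obj) {
  if (obj >= st.best) return;  // strict improvement keeps lexicographic first
  if (i == st.nc) {
    if (leaf_ok(st)) { st.best = obj; st.best_assign = st.assign; st.found = true; }
    return;
  }
  double rem = st.suffix_w[i];
  for (int s = 0; s < st.ns; ++s) {
    if (st.wsum[s] + st.w[i] > st.hi[s] + 1e-9) continue;
    // remaining weight must be able to fill every split's lower bound
    double deficit = 0.0;
    for (int t = 0; t < st.ns; ++t) {
      double ws = st.wsum[t] + (t == s ? st.w[i] : 0.0);
      if (ws < st.lo[t]) deficit += st.lo[t] - ws;
    }
    if (deficit > rem - st.w[i] + 1e-9) continue;
    double add = 0.0, newmax = obj;
    for (int j = 0; j < i; ++j) {
      if (st.assign[j] == s) continue;
      if (st.objective == 0) add += st.mass[j + (size_t)st.nc * i];
      else {
        double v = st.sim[j + (size_t)st.nc * i];
        if (v > newmax) newmax = v;
      }
    }
    double nobj = st.objective == 0 ? obj + add : newmax;
    st.assign[i] = s;
    st.wsum[s] += st.w[i];
    if (st.labcnt) {
      for (int l = 0; l < st.nl; ++l) st.lsum[s][l] += st.labcnt[i + (size_t)st.nc * l];
      st.ltot[s] += st.lcluster_tot[i];
    }
    dfs(st, i + 1, nobj);
    st.wsum[s] -= st.w[i];
    if (st.labcnt) {
      for (int l = 0; l < st.nl; ++l) st.lsum[s][l] -= st.labcnt[i + (size_t)st.nc * l];
      st.ltot[s] -= st.lcluster_tot[i];
    }
  }
  st.assign[i] = -1;
}

} // namespace

// Exact branch-and-bound over cluster-to-split assignments.
// Clusters are taken in input order and splits in input order, so with
// strict-improvement updates the reported optimum is the lexicographically
// first among ties. labcnt may be a 0-column matrix to disable
// stratification.
// [[Rcpp::export(name = ".s1_exact_cpp")]]
List s1_exact_cpp(NumericMatrix mass, NumericMatrix sim, NumericVector w,
                  NumericVector fractions, double epsilon, int objective,
                  IntegerMatrix labcnt, double strat_tol) {
  SearchState st;
  st.nc = w.size();
  st.ns = fractions.size();
  st.nl = labcnt.ncol();
  st.mass = REAL(mass);
  st.sim = REAL(sim);
  st.w = REAL(w);
  st.labcnt = st.nl > 0 ? INTEGER(labcnt) : nullptr;
  st.objective = objective;
  st.strat_tol = strat_tol;
  st.W = 0.0;
  for (int i = 0; i < st.nc; ++i) st.W += st.w[i];
  st.lo.resize(st.ns); st.hi.resize(st.ns);
  for (int s = 0; s < st.ns; ++s) {
    st.lo[s] = std::max(0.0, (fractions[s] - epsilon)) * st.W;
    st.hi[s] = (fractions[s] + epsilon) * st.W;
  }
  if (st.labcnt) {
    st.gshare.assign(st.nl, 0.0);
    st.lcluster_tot.assign(st.nc, 0.0);
    double tot = 0.0;
    for (int l = 0; l < st.nl; ++l)
      for (int i = 0; i < st.nc; ++i) {
        double v = st.labcnt[i + (size_t)st.nc * l];
        st.gshare[l] += v; st.lcluster_tot[i] += v; tot += v;
      }
    if (tot > 0) for (int l = 0; l < st.nl; ++l) st.gshare[l] /= tot;
  }
  st.assign.assign(st.nc, -1);
  st.best_assign.assign(st.nc, -1);
  st.wsum.assign(st.ns, 0.0);
  st.lsum.assign(st.ns, std::vector<double>(std::max(st.nl, 1), 0.0));
  st.ltot.assign(st.ns, 0.0);
  st.best = R_PosInf;
  st.found = false;
  st.suffix_w.assign(st.nc + 1, 0.0);
  for (int i = st.nc - 1; i >= 0; --i) st.suffix_w[i] = st.suffix_w[i + 1] + st.w[i];

  dfs(st, 0, 0.0);

  return List::create(
    _["found"] = st.found,
    _["objective"] = st.found ? st.best : NA_REAL,
    _["assignment"] = st.found ? IntegerVector(st.best_assign.begin(), st.best_assign.end())
                               : IntegerVector(0));
}
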