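#include <Rcpp.h>
#include <vector>
#include <map>
#include <unordered_map>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Backward-time deme size: N(t) = ne0 * exp(-r * min(t, anchor)).
// With r > 0 the population shrinks backward in time (exponential growth
// forward) down to the anchored ancestral size, constant earlier; r = 0 is a
// constant-size deme.

// Absolute time of the next coalescence among j lineages of a deme, starting
// from t0, by inversion of the cumulative hazard; E is a fresh Exp(1) draw.
static double coal_wait(double t0, double ne0, double r, double anchor,
                        long double cjk, double E) {
  if (cjk <= 0) return R_PosInf;
  if (r != 0.0 && t0 < anchor) {
    // exponential phase on [t0, anchor]: hazard cjk * exp(r t) / ne0
    long double lam_anchor =
      (long double)cjk / (ne0 * r) * (std::exp(r * anchor) - std::exp(r * t0));
    if (E <= lam_anchor) {
      return std::log(std::exp(r * t0) + E * ne0 * r / cjk) / r;
    }
    double ne_anc = ne0 * std::exp(-r * anchor);
    return anchor + (double)((E - lam_anchor) * ne_anc / cjk);
  }
  double ne = ne0 * std::exp(-r * std::min(t0, anchor));
  return t0 + E * ne / cjk;
}

// [[Rcpp::export]]
List cpp_simulate_genealogy(NumericVector tip_age, IntegerVector tip_deme,
                            NumericVector ne0, NumericVector growth,
                            NumericVector anchor, NumericVector ev_time,
                            IntegerVector ev_type, IntegerVector ev_from,
                            IntegerVector ev_to, NumericVector ev_prob) {
  const int n = tip_age.size();
  const int nd = ne0.size();
  const int ne = ev_time.size();
  if (n < 1) stop("at least one tip is required");
  for (int d = 0; d < nd; ++d) {
    if (!(ne0[d] > 0)) stop("non-positive deme size");
  }

  // tips sorted by sampling age for entry into the process
  std::vector<int> tip_order(n);
  for (int i = 0; i < n; ++i) tip_order[i] = i;
  std::stable_sort(tip_order.begin(), tip_order.end(),
                   [&](int a, int b) { return tip_age[a] < tip_age[b]; });

  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes);
  for (int i = 0; i < n; ++i) node_time[i] = tip_age[i];

  std::vector<std::vector<int>> active(nd);
  std::vector<bool> deme_gone(nd, false);  // merged away demes accept nothing

  double t = 0.0;
  int ti = 0;      // next tip (in tip_order) to enter
  int ei = 0;      // next demographic event
  int next_node = n;
  int n_active = 0;

  long safety = 50L * n + 50L * (ne + 1);
  while (ti < n || n_active > 1) {
    if (--safety < 0) stop("coalescent simulation failed to converge");

    double t_tip = (ti < n) ? tip_age[tip_order[ti]] : R_PosInf;
    double t_ev = (ei < ne) ? ev_time[ei] : R_PosInf;
    double t_disc = std::min(t_tip, t_ev);

    // candidate coalescence, competing across demes
    double t_coal = R_PosInf;
    int coal_deme = -1;
    for (int d = 0; d < nd; ++d) {
      int j = active[d].size();
      if (j < 2) continue;
      long double cjk = (long double)j * (j - 1) / 2.0L;
      double tc = coal_wait(t, ne0[d], growth[d], anchor[d], cjk, exp_rand());
      if (tc < t_coal) { t_coal = tc; coal_deme = d; }
    }

    if (t_coal < t_disc) {
      // coalesce a uniform pair in coal_deme
      std::vector<int>& A = active[coal_deme];
      int j = A.size();
      int i1 = (int)(unif_rand() * j); if (i1 == j) i1--;
      int l1 = A[i1]; A[i1] = A[j - 1]; A.pop_back();
      int i2 = (int)(unif_rand() * (j - 1)); if (i2 == j - 1) i2--;
      int l2 = A[i2];
      int anc = next_node++;
      parent[l1] = anc;
      parent[l2] = anc;
      node_time[anc] = t_coal;
      A[i2] = anc;
      n_active -= 1;
      t = t_coal;
      continue;
    }

    if (!R_finite(t_disc)) {
      stop("lineages remain in disconnected demes with no further events");
    }
    t = t_disc;
    if (t_tip <= t_ev) {
      int tip = tip_order[ti++];
      int d = tip_deme[tip];
      if (d < 0 || d >= nd) stop("tip assigned to unknown deme");
      if (deme_gone[d]) stop("sample scheduled after its deme diverged away");
      active[d].push_back(tip);
      n_active += 1;
    } else {
      int from = ev_from[ei], to = ev_to[ei];
      if (from < 0 || from >= nd || to < 0 || to >= nd || from == to)
        stop("invalid event deme indices");
      if (ev_type[ei] == 0) {
        // migration pulse: each `from`-deme lineage moves independently
        std::vector<int> stay;
        for (int lin : active[from]) {
          if (unif_rand() < ev_prob[ei]) active[to].push_back(lin);
          else stay.push_back(lin);
        }
        active[from].swap(stay);
      } else {
        // divergence: all lineages of `from` join `to`; `from` disappears
        for (int lin : active[from]) active[to].push_back(lin);
        active[from].clear();
        deme_gone[from] = true;
      }
      ei++;
    }
  }

  return List::create(_["parent"] = parent, _["node_time"] = node_time,
                      _["n_tip"] = n);
}

// [[Rcpp::export]]
List cpp_mutate_tree(IntegerVector parent, NumericVector node_time, int n_tip,
                     IntegerVector root_seq, NumericVector site_rate,
                     double mu, double titv, bool return_seq) {
  const int n_nodes = parent.size();
  const int L = root_seq.size();
  if ((int)site_rate.size() != L) stop("site_rate length mismatch");

  // children lists and the root
  std::vector<std::vector<int>> child(n_nodes);
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] < 0) { root = i; continue; }
    child[parent[i]].push_back(i);
  }
  if (root < 0) stop("no root in genealogy");

  std::vector<double> cum(L);
  double tot = 0.0;
  for (int s = 0; s < L; ++s) { tot += site_rate[s]; cum[s] = tot; }
  if (tot <= 0) stop("site rates sum to zero");
  const double rate_total = mu * tot;
  const double p_ti = titv / (1.0 + titv);

  // pass 1: draw the mutation events of every branch (site and type only;
  // the realised base depends on the current state and is resolved in the
  // DFS below), and collect the set of sites hit anywhere on the tree.
  // CSR layout: branch i owns entries [off[i], off[i+1])
  std::vector<int> off(n_nodes + 1, 0);
  for (int i = 0; i < n_nodes; ++i) {
    int nm = 0;
    if (parent[i] >= 0) {
      double len = node_time[parent[i]] - node_time[i];
      if (len < 0) stop("negative branch length");
      if (len > 0 && rate_total > 0) nm = (int)R::rpois(len * rate_total);
    }
    off[i + 1] = off[i] + nm;
  }
  const int n_mut_total = off[n_nodes];
  std::vector<int> mut_site(n_mut_total);
  std::vector<uint8_t> mut_kind(n_mut_total);  // 0 ti, 1/2 tv target index
  std::vector<uint8_t> mut_old(n_mut_total);   // filled during the DFS
  std::vector<bool> hit(L, false);
  long n_mut = n_mut_total, n_ti = 0, n_tv = 0;
  for (int m = 0; m < n_mut_total; ++m) {
    double u = unif_rand() * tot;
    int site = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                     cum.begin());
    if (site >= L) site = L - 1;
    if (unif_rand() < p_ti) { mut_kind[m] = 0; n_ti++; }
    else { mut_kind[m] = (unif_rand() < 0.5) ? 1 : 2; n_tv++; }
    mut_site[m] = site;
    hit[site] = true;
  }
  std::vector<int> hit_sites;
  for (int s = 0; s < L; ++s) if (hit[s]) hit_sites.push_back(s);
  const int nh = (int)hit_sites.size();

  // pass 2: depth-first traversal with one working sequence and undo lists;
  // tip haplotype keys are read off over the hit sites only
  std::vector<uint8_t> seq(L);
  for (int s = 0; s < L; ++s) seq[s] = (uint8_t)root_seq[s];
  static const uint8_t tv[4][2] = {{1, 3}, {0, 2}, {1, 3}, {0, 2}};

  IntegerVector hap_id(n_tip);
  std::unordered_map<std::string, int> seen;
  seen.reserve(2 * n_tip);
  IntegerMatrix tip_seq;
  if (return_seq) tip_seq = IntegerMatrix(n_tip, L);

  // stack frames: node entering (apply) or leaving (undo)
  struct Frame { int node; bool leaving; };
  std::vector<Frame> stack;
  stack.reserve(n_nodes + 1);
  stack.push_back({root, false});
  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    if (f.leaving) {
      for (int m = off[f.node + 1] - 1; m >= off[f.node]; --m) {
        seq[mut_site[m]] = mut_old[m];
      }
      continue;
    }
    if (f.node != root) {
      for (int m = off[f.node]; m < off[f.node + 1]; ++m) {
        uint8_t& b = seq[mut_site[m]];
        mut_old[m] = b;
        b = (mut_kind[m] == 0) ? (uint8_t)((b + 2) % 4)
                               : tv[b][mut_kind[m] - 1];
      }
      if (off[f.node + 1] > off[f.node]) stack.push_back({f.node, true});
    }
    if (f.node < n_tip) {
      std::string key(nh, '\0');
      for (int s = 0; s < nh; ++s) key[s] = (char)seq[hit_sites[s]];
      auto it = seen.find(key);
      if (it == seen.end()) {
        int id = (int)seen.size() + 1;
        seen.emplace(std::move(key), id);
        hap_id[f.node] = id;
      } else {
        hap_id[f.node] = it->second;
      }
      if (return_seq) {
        for (int s = 0; s < L; ++s) tip_seq(f.node, s) = seq[s];
      }
    }
    for (int c : child[f.node]) stack.push_back({c, false});
  }

  // sequences of the unique haplotypes over the hit sites (dense id order),
  // for pairwise-difference statistics
  const int n_uniq = (int)seen.size();
  IntegerMatrix hap_seq(n_uniq, nh);
  for (const auto& kv : seen) {
    for (int s = 0; s < nh; ++s) {
      hap_seq(kv.second - 1, s) = (int)(uint8_t)kv.first[s];
    }
  }

  List out = List::create(_["hap_id"] = hap_id, _["hap_seq"] = hap_seq,
                          _["n_mutations"] = (double)n_mut,
                          _["n_transitions"] = (double)n_ti,
                          _["n_transversions"] = (double)n_tv);
  if (return_seq) out["tip_seq"] = tip_seq;
  return out;
}

// per-site base counts of a population: counts[h] copies of unique haplotype
// h (rows of hap_seq, bases coded 0..3) -> sites x 4 count matrix
// [[Rcpp::export]]
NumericMatrix cpp_base_counts(IntegerMatrix hap_seq, NumericVector counts) {
  const int n_uniq = hap_seq.nrow();
  const int nh = hap_seq.ncol();
  if ((int)counts.size() != n_uniq) stop("counts length mismatch");
  NumericMatrix F(nh, 4);
  for (int h = 0; h < n_uniq; ++h) {
    double c = counts[h];
    if (c == 0) continue;
    for (int s = 0; s < nh; ++s) F(s, hap_seq(h, s)) += c;
  }
  return F;
}
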