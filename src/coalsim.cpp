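// Structured-coalescent engine with serial sampling, piecewise-constant
// migration matrices, founder bottlenecks and a terminal refugium merge.
// Backward time, continuous-time exponential waiting times; rates are
// re-drawn at every deterministic boundary (epoch change, founding event,
// tip activation, colonization).
//
// Node layout: indices 0..T-1 are sampled allele copies (tips) in plan
// order; internal nodes are appended as coalescences happen. `parent` is
// -1 for the root, `age` is in generations before present. Founder
// bottlenecks can produce multifurcations (several lineages drawn into one
// parental copy in a single generation).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <map>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Independent, reproducible stream per locus regardless of how many draws
// other loci consume.
static inline std::mt19937_64 locus_engine(uint64_t seed, uint64_t locus) {
  uint64_t s = splitmix64(seed ^ (0xA3C59AC2ULL + locus * 0x9E3779B97f4A7C15ULL));
  return std::mt19937_64(s);
}

struct Model {
  int D;
  std::vector<double> ne;        // size while the deme exists pre-colonization
  std::vector<double> ft;       // founding time (gen BP); R_PosInf = primordial
  std::vector<int> src;         // 0-based source deme, -1 if none
  std::vector<double> founder;  // founder bottleneck (diploids), <=0 = none
  double colonization_time;
  double refugium_ne;
  int refugium;                 // 0-based
  std::vector<double> epoch_start;           // ascending, first 0
  std::vector<NumericMatrix> mats;           // backward rates m[i][j]
};

static Model parse_model(const List& m) {
  Model mod;
  mod.D = as<int>(m["n_demes"]);
  mod.ne = as<std::vector<double>>(m["ne"]);
  mod.ft = as<std::vector<double>>(m["founding_time"]);
  mod.src = as<std::vector<int>>(m["source"]);
  mod.founder = as<std::vector<double>>(m["founder_size"]);
  mod.colonization_time = as<double>(m["colonization_time"]);
  mod.refugium_ne = as<double>(m["refugium_ne"]);
  mod.refugium = as<int>(m["refugium"]);
  mod.epoch_start = as<std::vector<double>>(m["epoch_start"]);
  List ml = m["epoch_mats"];
  for (int i = 0; i < ml.size(); ++i)
    mod.mats.push_back(as<NumericMatrix>(ml[i]));
  return mod;
}

struct Genealogy {
  int ntip;
  std::vector<int> parent;   // -1 root
  std::vector<double> age;
};

// One locus of the structured coalescent.
static Genealogy sim_locus(const Model& mod,
                           const std::vector<int>& tip_deme,
                           const std::vector<double>& tip_time,
                           std::mt19937_64& eng) {
  const int T = (int)tip_time.size();
  const int D = mod.D;
  Genealogy g;
  g.ntip = T;
  g.parent.assign(2 * T, -1);
  g.age.assign(2 * T, 0.0);
  for (int i = 0; i < T; ++i) g.age[i] = tip_time[i];
  int next_node = T;

  // deterministic boundaries
  std::vector<double> bounds;
  bounds.push_back(0.0);
  for (int i = 0; i < T; ++i) bounds.push_back(tip_time[i]);
  for (int d = 0; d < D; ++d)
    if (R_finite(mod.ft[d])) bounds.push_back(mod.ft[d]);
  bounds.push_back(mod.colonization_time);
  for (size_t e = 1; e < mod.epoch_start.size(); ++e)
    bounds.push_back(mod.epoch_start[e]);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  std::vector<std::vector<int>> demes(D);  // active lineage node ids per deme
  std::vector<double> ne = mod.ne;
  int n_active = 0, n_pending = T;

  // tips sorted by activation time
  std::vector<int> tip_order(T);
  for (int i = 0; i < T; ++i) tip_order[i] = i;
  std::stable_sort(tip_order.begin(), tip_order.end(),
                   [&](int a, int b) { return tip_time[a] < tip_time[b]; });
  size_t tip_ptr = 0;

  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double t = 0.0;
  size_t b_ptr = 0;

  auto activate_tips = [&](double at) {
    while (tip_ptr < tip_order.size() && tip_time[tip_order[tip_ptr]] <= at) {
      int tip = tip_order[tip_ptr++];
      demes[tip_deme[tip]].push_back(tip);
      ++n_active;
      --n_pending;
    }
  };

  auto do_founding = [&](double at) {
    for (int d = 0; d < D; ++d) {
      if (!R_finite(mod.ft[d]) || mod.ft[d] != at) continue;
      std::vector<int>& lin = demes[d];
      if (lin.size() > 1 && mod.founder[d] > 0) {
        // one Wright-Fisher generation with 2*founder parental copies
        int copies = (int)(2.0 * mod.founder[d]);
        std::uniform_int_distribution<int> pick(0, copies - 1);
        std::map<int, std::vector<int>> bucket;
        for (int id : lin) bucket[pick(eng)].push_back(id);
        std::vector<int> out;
        for (auto& kv : bucket) {
          std::vector<int>& b = kv.second;
          if (b.size() == 1) { out.push_back(b[0]); continue; }
          int nn = next_node++;
          g.age[nn] = at;
          for (int id : b) g.parent[id] = nn;
          out.push_back(nn);
          n_active -= (int)b.size() - 1;
        }
        lin = out;
      }
      if (!lin.empty()) {
        int s = mod.src[d];
        for (int id : lin) demes[s].push_back(id);
        lin.clear();
      }
    }
  };

  while (true) {
    double tb = (b_ptr < bounds.size()) ? bounds[b_ptr] : R_PosInf;
    if (b_ptr < bounds.size() && tb <= t) {  // process boundary at t
      ++b_ptr;
      activate_tips(tb);
      do_founding(tb);
      if (tb == mod.colonization_time) ne[mod.refugium] = mod.refugium_ne;
      continue;
    }
    if (n_active + n_pending <= 1) break;

    // constant-rate interval (t, tb)
    int epoch = 0;
    for (size_t e = 0; e < mod.epoch_start.size(); ++e)
      if (mod.epoch_start[e] <= t) epoch = (int)e;
    const NumericMatrix& M = mod.mats[epoch];
    // deme j exists throughout (t, tb) iff ft[j] >= tb
    std::vector<bool> exists(D);
    for (int d = 0; d < D; ++d)
      exists[d] = !(R_finite(mod.ft[d]) && mod.ft[d] < tb) || mod.ft[d] >= tb;
    std::vector<double> row_rate(D, 0.0);
    for (int d = 0; d < D; ++d) {
      if (!exists[d]) continue;
      double r = 0.0;
      for (int j = 0; j < D; ++j)
        if (j != d && exists[j]) r += M(d, j);
      row_rate[d] = r;
    }

    bool hit_boundary = false;
    while (true) {
      double coal_tot = 0.0, mig_tot = 0.0;
      for (int d = 0; d < D; ++d) {
        double k = (double)demes[d].size();
        if (k >= 2.0) coal_tot += k * (k - 1.0) / (4.0 * ne[d]);
        if (k >= 1.0) mig_tot += k * row_rate[d];
      }
      double tot = coal_tot + mig_tot;
      if (tot <= 0.0) { hit_boundary = true; break; }
      double dt = -std::log(1.0 - unif(eng)) / tot;
      if (t + dt >= tb) { hit_boundary = true; break; }
      t += dt;
      double u = unif(eng) * tot;
      if (u < coal_tot) {
        // coalescence: pick deme, then an unordered pair
        int d = -1;
        double acc = 0.0;
        for (int j = 0; j < D; ++j) {
          double k = (double)demes[j].size();
          if (k >= 2.0) acc += k * (k - 1.0) / (4.0 * ne[j]);
          if (u < acc) { d = j; break; }
        }
        if (d < 0) d = D - 1;
        std::vector<int>& lin = demes[d];
        int k = (int)lin.size();
        std::uniform_int_distribution<int> pi(0, k - 1);
        int a = pi(eng), b = pi(eng);
        while (b == a) b = pi(eng);
        int nn = next_node++;
        g.age[nn] = t;
        g.parent[lin[a]] = nn;
        g.parent[lin[b]] = nn;
        int hi = std::max(a, b), lo = std::min(a, b);
        lin[lo] = nn;
        lin.erase(lin.begin() + hi);
        --n_active;
        if (n_active + n_pending <= 1) break;
      } else {
        // migration: pick source deme, lineage, destination
        double v = u - coal_tot;
        int d = -1;
        double acc = 0.0;
        for (int j = 0; j < D; ++j) {
          acc += (double)demes[j].size() * row_rate[j];
          if (v < acc) { d = j; break; }
        }
        if (d < 0) d = D - 1;
        std::vector<int>& lin = demes[d];
        std::uniform_int_distribution<int> pi(0, (int)lin.size() - 1);
        int which = pi(eng);
        int id = lin[which];
        double w = unif(eng) * row_rate[d];
        int dest = -1;
        double acc2 = 0.0;
        for (int j = 0; j < D; ++j) {
          if (j == d || !exists[j]) continue;
          acc2 += M(d, j);
          if (w < acc2) { dest = j; break; }
        }
        if (dest < 0) continue;  // numerical slack: no move
        lin.erase(lin.begin() + which);
        demes[dest].push_back(id);
      }
    }
    if (n_active + n_pending <= 1) break;
    if (hit_boundary) {
      if (b_ptr >= bounds.size())
        stop("coalescent failed to terminate (no rates, no boundaries)");
      t = tb;
    }
  }

  g.parent.resize(next_node);
  g.age.resize(next_node);
  return g;
}

struct VariantSet {
  std::vector<int> pos;                      // 1-based site, sorted
  std::vector<std::vector<int>> derived;     // 1-based tip indices
};

// Poisson mutations along branches; uniform site in 1..L; any site hit more
// than once is discarded (strict infinite-sites surrogate).
static VariantSet place_mutations(const Genealogy& g, double mu, int L,
                                  std::mt19937_64& eng) {
  VariantSet vs;
  int n = (int)g.parent.size();
  std::vector<double> blen(n, 0.0);
  double tot = 0.0;
  for (int v = 0; v < n; ++v) {
    if (g.parent[v] < 0) continue;
    blen[v] = g.age[g.parent[v]] - g.age[v];
    tot += blen[v];
  }
  if (mu <= 0.0 || tot <= 0.0) return vs;
  std::poisson_distribution<int> pois(mu * (double)L * tot);
  int nmut = pois(eng);
  if (nmut == 0) return vs;
  std::vector<double> cum(n, 0.0);
  double acc = 0.0;
  for (int v = 0; v < n; ++v) { acc += blen[v]; cum[v] = acc; }
  std::uniform_real_distribution<double> unif(0.0, acc);
  std::uniform_int_distribution<int> usite(1, L);
  std::vector<int> mut_branch(nmut), mut_site(nmut);
  std::vector<int> site_count(L + 1, 0);
  for (int k = 0; k < nmut; ++k) {
    double x = unif(eng);
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), x) - cum.begin());
    if (v >= n) v = n - 1;
    mut_branch[k] = v;
    mut_site[k] = usite(eng);
    ++site_count[mut_site[k]];
  }
  // children adjacency for subtree extraction
  std::vector<std::vector<int>> kids(n);
  for (int v = 0; v < n; ++v)
    if (g.parent[v] >= 0) kids[g.parent[v]].push_back(v);
  std::vector<std::pair<int, int>> keep;  // (site, branch)
  for (int k = 0; k < nmut; ++k)
    if (site_count[mut_site[k]] == 1) keep.emplace_back(mut_site[k], mut_branch[k]);
  std::sort(keep.begin(), keep.end());
  for (auto& m : keep) {
    std::vector<int> tips;
    std::vector<int> stack{m.second};
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < g.ntip) tips.push_back(v + 1);
      for (int c : kids[v]) stack.push_back(c);
    }
    if (tips.empty() || (int)tips.size() == g.ntip) continue;  // not a proper subset
    std::sort(tips.begin(), tips.end());
    vs.pos.push_back(m.first);
    vs.derived.push_back(std::move(tips));
  }
  return vs;
}

static List genealogy_to_list(const Genealogy& g) {
  IntegerVector p(g.parent.size());
  NumericVector a(g.age.size());
  for (size_t i = 0; i < g.parent.size(); ++i) {
    p[i] = g.parent[i] < 0 ? NA_INTEGER : g.parent[i] + 1;  // 1-based, NA root
    a[i] = g.age[i];
  }
  return List::create(_["ntip"] = g.ntip, _["parent"] = p, _["age"] = a);
}

static List variants_to_list(const VariantSet& vs) {
  IntegerVector pos(vs.pos.begin(), vs.pos.end());
  List der(vs.derived.size());
  for (size_t i = 0; i < vs.derived.size(); ++i)
    der[i] = IntegerVector(vs.derived[i].begin(), vs.derived[i].end());
  return List::create(_["pos"] = pos, _["derived"] = der);
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List model, IntegerVector tip_deme, NumericVector tip_time,
                  int n_loci, double seed, double mu, int locus_length,
                  bool return_trees, bool return_variants) {
  Model mod = parse_model(model);
  std::vector<int> td(tip_deme.begin(), tip_deme.end());
  std::vector<double> tt(tip_time.begin(), tip_time.end());
  uint64_t us = (uint64_t)(int64_t)seed;
  List trees(return_trees ? n_loci : 0);
  List vars(return_variants ? n_loci : 0);
  for (int l = 0; l < n_loci; ++l) {
    if (l % 256 == 0) Rcpp::checkUserInterrupt();
    std::mt19937_64 eng = locus_engine(us, (uint64_t)l);
    Genealogy g = sim_locus(mod, td, tt, eng);
    if (return_trees) trees[l] = genealogy_to_list(g);
    if (return_variants) {
      VariantSet vs = place_mutations(g, mu, locus_length, eng);
      vars[l] = variants_to_list(vs);
    }
  }
  return List::create(_["trees"] = trees, _["variants"] = vars);
}

// [[Rcpp::export(name = ".cpp_mutate")]]
List cpp_mutate(List genealogy, double mu, int locus_length, double seed) {
  Genealogy g;
  g.ntip = as<int>(genealogy["ntip"]);
  IntegerVector p = genealogy["parent"];
  NumericVector a = genealogy["age"];
  for (int i = 0; i < p.size(); ++i) {
    g.parent.push_back(p[i] == NA_INTEGER ? -1 : p[i] - 1);
    g.age.push_back(a[i]);
  }
  std::mt19937_64 eng = locus_engine((uint64_t)(int64_t)seed, 0);
  return variants_to_list(place_mutations(g, mu, locus_length, eng));
}
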