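// Per-locus structured coalescent on a circular stepping-stone migration
// matrix (Hudson-style continuous-time event simulation), with optional
// fully isolated outlier demes that join the ring ancestrally at a split
// time.  Each locus is conditioned on exactly one segregating site: a
// single mutation is placed uniformly at random along the total branch
// length of the realized genealogy (infinite-sites with one site kept).
//
// Scaling: time is measured in units of 4N generations (N = diploid deme
// size).  The coalescence rate for each pair of lineages within a deme is
// then 2, and the migration rate per lineage to EACH adjacent ring deme is
// mig_rate = 4 N m, where m is the per-generation fraction of a deme made
// up of migrants from that neighbor.
//
// Genotypes are returned directly: haplotypes are paired within demes
// (leaves within a deme are exchangeable, so consecutive pairing is
// equivalent to random pairing) and coded 0 / 0.5 / 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct RingSim {
  int n_ring, n_out, D, hpd, H, n_nodes;
  double mig_rate, t_split;

  // per-node tree bookkeeping
  std::vector<int> parent, child1, child2;
  std::vector<double> ntime;
  // active-lineage bookkeeping
  std::vector<std::vector<int>> members; // nodes per deme
  std::vector<int> mem_pos;              // position of node in its deme list
  std::vector<int> deme_of;              // current deme of an active node
  std::vector<int> pool;                 // active nodes eligible to migrate
  std::vector<int> pool_pos;             // position in pool, -1 if absent
  std::vector<int> attach;               // ring deme each outlier joins
  double total_coal;                     // sum over demes of 2*C(k,2) * ... see below

  RingSim(int n_ring_, int n_out_, int hpd_, double mig_rate_, double t_split_)
      : n_ring(n_ring_), n_out(n_out_), D(n_ring_ + n_out_), hpd(hpd_),
        H(D * hpd_), n_nodes(2 * D * hpd_ - 1), mig_rate(mig_rate_),
        t_split(t_split_) {
    parent.resize(n_nodes);
    child1.resize(n_nodes);
    child2.resize(n_nodes);
    ntime.resize(n_nodes);
    members.resize(D);
    mem_pos.resize(n_nodes);
    deme_of.resize(n_nodes);
    pool_pos.resize(n_nodes);
    attach.resize(n_out);
    for (int o = 0; o < n_out; ++o)
      attach[o] = (int)((long long)o * n_ring / std::max(1, n_out));
  }

  inline double coal_weight(int k) const { return 2.0 * 0.5 * k * (k - 1); }

  void add_to_deme(int node, int d) {
    total_coal -= coal_weight((int)members[d].size());
    deme_of[node] = d;
    mem_pos[node] = (int)members[d].size();
    members[d].push_back(node);
    total_coal += coal_weight((int)members[d].size());
  }

  void remove_from_deme(int node) {
    int d = deme_of[node];
    total_coal -= coal_weight((int)members[d].size());
    int p = mem_pos[node];
    int last = members[d].back();
    members[d][p] = last;
    mem_pos[last] = p;
    members[d].pop_back();
    total_coal += coal_weight((int)members[d].size());
  }

  void pool_add(int node) {
    pool_pos[node] = (int)pool.size();
    pool.push_back(node);
  }

  void pool_remove(int node) {
    int p = pool_pos[node];
    if (p < 0) return;
    int last = pool.back();
    pool[p] = last;
    pool_pos[last] = p;
    pool.pop_back();
    pool_pos[node] = -1;
  }

  // Simulates one genealogy; fills parent/child/time.  Returns root node.
  int simulate_tree() {
    for (int d = 0; d < D; ++d) members[d].clear();
    pool.clear();
    total_coal = 0.0;
    std::fill(pool_pos.begin(), pool_pos.end(), -1);
    std::fill(parent.begin(), parent.end(), -1);
    std::fill(child1.begin(), child1.end(), -1);
    std::fill(child2.begin(), child2.end(), -1);

    for (int d = 0; d < D; ++d)
      for (int h = 0; h < hpd; ++h) {
        int node = d * hpd + h;
        ntime[node] = 0.0;
        add_to_deme(node, d);
        if (d < n_ring) pool_add(node);
      }

    double t = 0.0;
    bool split_done = (n_out == 0);
    int next_node = H;
    int n_active = H;

    while (n_active > 1) {
      double total_mig = (double)pool.size() * 2.0 * mig_rate;
      double total_rate = total_coal + total_mig;
      double dt;
      if (total_rate <= 0.0) {
        dt = R_PosInf;
      } else {
        dt = R::exp_rand() / total_rate;
      }
      if (!split_done && t + dt >= t_split) {
        // outlier demes join the ring: move every remaining outlier lineage
        // to its attachment deme and make it migration-eligible
        t = t_split;
        for (int o = 0; o < n_out; ++o) {
          int d = n_ring + o;
          while (!members[d].empty()) {
            int node = members[d].back();
            remove_from_deme(node);
            add_to_deme(node, attach[o]);
            pool_add(node);
          }
        }
        split_done = true;
        continue;
      }
      t += dt;
      double u = unif_rand() * total_rate;
      if (u < total_coal) {
        // coalescence: pick deme proportional to its pair weight
        double acc = 0.0;
        int d = -1;
        for (int dd = 0; dd < D; ++dd) {
          int k = (int)members[dd].size();
          if (k < 2) continue;
          acc += coal_weight(k);
          if (u < acc) { d = dd; break; }
        }
        if (d < 0) {
          for (int dd = D - 1; dd >= 0; --dd)
            if ((int)members[dd].size() >= 2) { d = dd; break; }
        }
        int k = (int)members[d].size();
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int a = members[d][i], b = members[d][j];
        int p = next_node++;
        ntime[p] = t;
        parent[a] = p; parent[b] = p;
        child1[p] = a; child2[p] = b;
        remove_from_deme(a); remove_from_deme(b);
        pool_remove(a); pool_remove(b);
        add_to_deme(p, d);
        if (split_done || d < n_ring) pool_add(p);
        --n_active;
      } else {
        // migration: uniform over eligible lineages, then a random neighbor
        int np = (int)pool.size();
        int i = (int)(unif_rand() * np); if (i >= np) i = np - 1;
        int node = pool[i];
        int d = deme_of[node];
        int d2 = (unif_rand() < 0.5) ? (d + 1) % n_ring : (d - 1 + n_ring) % n_ring;
        remove_from_deme(node);
        add_to_deme(node, d2);
      }
    }
    return next_node - 1; // root
  }

  // Places one mutation uniformly on the branches and writes 0/1 carrier
  // status per leaf into `hap`.  Returns number of carriers.
  int drop_mutation(int root, std::vector<int>& hap) {
    double total_len = 0.0;
    for (int v = 0; v < n_nodes; ++v)
      if (v != root && parent[v] >= 0) total_len += ntime[parent[v]] - ntime[v];
    double s = unif_rand() * total_len;
    int chosen = -1;
    double acc = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      if (v == root || parent[v] < 0) continue;
      acc += ntime[parent[v]] - ntime[v];
      if (s < acc) { chosen = v; break; }
    }
    if (chosen < 0) chosen = root == n_nodes - 1 ? n_nodes - 2 : n_nodes - 1;
    std::fill(hap.begin(), hap.end(), 0);
    // mark leaves below `chosen`
    std::vector<int> stack;
    stack.push_back(chosen);
    int carriers = 0;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < H) {
        hap[v] = 1;
        ++carriers;
      } else {
        stack.push_back(child1[v]);
        stack.push_back(child2[v]);
      }
    }
    return carriers;
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix simulate_ring_loci_cpp(int n_ring, int n_outlier, int haps_per_deme,
                                     int n_loci, double mig_rate, double t_split,
                                     int max_retries) {
  if (haps_per_deme % 2 != 0) stop("haps_per_deme must be even");
  RingSim sim(n_ring, n_outlier, haps_per_deme, mig_rate, t_split);
  const int n_ind = sim.H / 2;
  NumericMatrix G(n_ind, n_loci);
  std::vector<int> hap(sim.H);
  for (int l = 0; l < n_loci; ++l) {
    if (l % 64 == 0) Rcpp::checkUserInterrupt();
    int carriers = 0;
    int tries = 0;
    while (true) {
      int root = sim.simulate_tree();
      carriers = sim.drop_mutation(root, hap);
      if (carriers > 0 && carriers < sim.H) break;
      if (++tries > max_retries)
        stop("locus failed to segregate after %d attempts", max_retries);
    }
    for (int i = 0; i < n_ind; ++i)
      G(i, l) = 0.5 * (hap[2 * i] + hap[2 * i + 1]);
  }
  return G;
}
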