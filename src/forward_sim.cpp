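// Forward-time diploid Wright-Fisher island-model simulator with
// background selection.
//
// Genome layout: [flank A: L_sel/2 selected sites][neutral block][flank B].
// The neutral block is internally non-recombining, so all neutral sites
// share one genealogy; each haplotype carries an immutable block id into a
// persistent mutation-chain table (copy-on-write), and site alleles are
// resolved only at measurement time. Selected sites are explicit biallelic
// arrays when the map length M > 0; when M = 0 the whole genome is a single
// non-recombining unit and only the per-haplotype deleterious count is
// tracked.
//
// Event order per generation (load-bearing for the F_ST theory):
// reproduction (selection + recombination + mutation, drift) first, then
// migration, then measurement.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

namespace {

struct BlockTable {
  // node 0 is the ancestral block (all sites allele 0)
  std::vector<int> parent, site, label;
  int next_label = 0;

  BlockTable() {
    parent.push_back(-1);
    site.push_back(-1);
    label.push_back(0);
  }

  int add_mutation(int from, int at_site) {
    parent.push_back(from);
    site.push_back(at_site);
    label.push_back(++next_label);
    return (int)parent.size() - 1;
  }

  // nearest mutation above the leaf wins at each site
  void resolve(int leaf, int *out, std::vector<signed char> &seen) const {
    std::fill(seen.begin(), seen.end(), 0);
    int filled = 0, L = (int)seen.size();
    for (int cur = leaf; cur > 0 && filled < L; cur = parent[cur]) {
      int s = site[cur];
      if (!seen[s]) {
        seen[s] = 1;
        out[s] = label[cur];
        ++filled;
      }
    }
    for (int s = 0; s < L; ++s)
      if (!seen[s]) out[s] = 0;
  }
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One deme's haplotypes. Individual i owns haplotypes 2i and 2i+1.
struct Deme {
  int N, Lsel;
  bool arrays; // explicit selected-site arrays (M > 0 path)
  std::vector<int> block;           // 2N block ids
  std::vector<int> kcount;          // 2N deleterious counts per haplotype
  std::vector<unsigned char> sel;   // 2N * Lsel alleles (arrays path only)

  void init(int N_, int Lsel_, bool arrays_) {
    N = N_; Lsel = Lsel_; arrays = arrays_;
    block.assign(2 * N, 0);
    kcount.assign(2 * N, 0);
    if (arrays) sel.assign((size_t)2 * N * Lsel, 0);
  }
  unsigned char *hap(int h) { return sel.data() + (size_t)h * Lsel; }
};

// pick parent index proportional to cumulative weights
inline int pick_parent(const std::vector<double> &cumw, int N) {
  if (cumw.empty()) return runif_int(N);
  double u = unif_rand() * cumw[N - 1];
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// Transmit one gamete from parent `p` of deme `src` into haplotype slot
// `dst_h` of deme `dst`.
void make_gamete(Deme &dst, int dst_h, Deme &src, int p,
                 double U, double M_map, double mu_block,
                 int L_neutral, BlockTable &blocks,
                 std::vector<double> &bp /* scratch */) {
  int h0 = 2 * p + (unif_rand() < 0.5 ? 1 : 0);
  int h1 = 2 * p + ((h0 & 1) ^ 1);
  int Lsel = src.Lsel, Lh = Lsel / 2;

  int blk;
  int k;
  if (!dst.arrays) {
    // fully linked genome: gamete is a faithful copy of one haplotype
    blk = src.block[h0];
    k = src.kcount[h0];
    if (U > 0) {
      int nmut = (int)R::rpois(U);
      k += nmut; // site identity irrelevant for fitness when fully linked
    }
  } else {
    int nx = (M_map > 0) ? (int)R::rpois(M_map) : 0;
    unsigned char *g = dst.hap(dst_h);
    if (nx == 0) {
      std::memcpy(g, src.hap(h0), Lsel);
      blk = src.block[h0];
      k = src.kcount[h0];
    } else {
      // breakpoints in map units of selected sites; the block sits at
      // position Lh between the flanks and is indivisible
      bp.clear();
      for (int i = 0; i < nx; ++i) bp.push_back(unif_rand() * Lsel);
      std::sort(bp.begin(), bp.end());
      const unsigned char *src0 = src.hap(h0), *src1 = src.hap(h1);
      int cur = 0; // 0 -> h0, 1 -> h1
      size_t b = 0;
      k = 0;
      for (int s = 0; s < Lsel; ++s) {
        // selected site s at map position s + 0.5; the indivisible block
        // occupies the unit gap centred at position Lh
        double pos = s + 0.5;
        while (b < bp.size() && bp[b] < pos) { cur ^= 1; ++b; }
        g[s] = cur ? src1[s] : src0[s];
        k += g[s];
      }
      // block source: haplotype state at map position Lh
      int sw = 0;
      for (size_t j = 0; j < bp.size(); ++j) if (bp[j] < Lh) ++sw;
      blk = (sw & 1) ? src.block[h1] : src.block[h0];
    }
    if (U > 0) {
      int nmut = (int)R::rpois(U);
      for (int i = 0; i < nmut; ++i) {
        int s = runif_int(Lsel);
        if (!g[s]) { g[s] = 1; ++k; } // irreversible; repeat hits are no-ops
      }
    }
  }

  if (mu_block > 0) {
    int nmut = (int)R::rpois(mu_block);
    for (int i = 0; i < nmut; ++i)
      blk = blocks.add_mutation(blk, runif_int(L_neutral));
  }
  dst.block[dst_h] = blk;
  dst.kcount[dst_h] = k;
}

// Symmetric pairwise exchange migration: for each deme pair, a
// Binomial(N, m/(d-1)) number of whole individuals swap demes. Conserves
// deme sizes and metapopulation allele counts exactly; each individual
// emigrates with probability ~m.
struct Swap { int di, ii, dj, ij; };

void plan_exchange(int d, int N, double m, std::vector<Swap> &plan,
                   std::vector<std::vector<int>> &pool,
                   std::vector<int> &used) {
  plan.clear();
  if (d < 2 || m <= 0) return;
  double pr = m / (d - 1);
  for (int i = 0; i < d; ++i) used[i] = 0;
  for (int i = 0; i < d; ++i) {
    for (int j = i + 1; j < d; ++j) {
      int k = (int)R::rbinom(N, pr);
      for (int s = 0; s < k; ++s) {
        if (used[i] >= N || used[j] >= N) break;
        // draw distinct not-yet-moved individuals from each deme
        int ai = used[i] + runif_int(N - used[i]);
        std::swap(pool[i][used[i]], pool[i][ai]);
        int aj = used[j] + runif_int(N - used[j]);
        std::swap(pool[j][used[j]], pool[j][aj]);
        plan.push_back({i, pool[i][used[i]], j, pool[j][used[j]]});
        ++used[i]; ++used[j];
      }
    }
  }
}

void apply_swap(std::vector<Deme> &pop, const Swap &sw) {
  Deme &A = pop[sw.di], &B = pop[sw.dj];
  for (int h = 0; h < 2; ++h) {
    int ha = 2 * sw.ii + h, hb = 2 * sw.ij + h;
    std::swap(A.block[ha], B.block[hb]);
    std::swap(A.kcount[ha], B.kcount[hb]);
    if (A.arrays) {
      unsigned char *pa = A.hap(ha), *pb = B.hap(hb);
      for (int s = 0; s < A.Lsel; ++s) std::swap(pa[s], pb[s]);
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".run_forward_sim")]]
List run_forward_sim_cpp(int d, int N_local, double m, double t, double U,
                         double mu_neutral, int L_selected, int L_neutral,
                         double M_map, int generations) {
  if (d < 1 || N_local < 1 || generations < 1)
    stop("invalid simulation dimensions");
  if (m < 0 || m >= 1) stop("'m' must lie in [0, 1)");
  if (d == 1 && m > 0) stop("d = 1 forces m = 0");
  if (L_selected % 2 != 0) stop("'L_selected' must be even (two flanks)");

  bool has_sel = (U > 0);
  bool arrays = has_sel && M_map > 0;
  double mu_block = mu_neutral * L_neutral;

  BlockTable blocks;
  std::vector<Deme> cur(d), nxt(d);
  for (int i = 0; i < d; ++i) {
    cur[i].init(N_local, L_selected, arrays);
    nxt[i].init(N_local, L_selected, arrays);
  }

  std::vector<double> cumw(N_local), bp;
  std::vector<Swap> plan;
  std::vector<std::vector<int>> pool(d);
  std::vector<int> used(d);
  for (int i = 0; i < d; ++i) {
    pool[i].resize(N_local);
    for (int j = 0; j < N_local; ++j) pool[i][j] = j;
  }

  double log1mt = (t > 0) ? std::log1p(-t) : 0.0;

  for (int gen = 0; gen < generations; ++gen) {
    for (int dm = 0; dm < d; ++dm) {
      Deme &P = cur[dm], &O = nxt[dm];
      bool uniform = true;
      if (has_sel && t > 0) {
        // fitness w = (1-t)^k, normalised by the deme minimum so that
        // fixed deleterious alleles generate no variance in sampling
        int kmin = INT_MAX, kmax = 0;
        std::vector<int> ktot(N_local);
        for (int i = 0; i < N_local; ++i) {
          int k = P.kcount[2 * i] + P.kcount[2 * i + 1];
          ktot[i] = k;
          if (k < kmin) kmin = k;
          if (k > kmax) kmax = k;
        }
        if (kmax > kmin) {
          uniform = false;
          double acc = 0;
          for (int i = 0; i < N_local; ++i) {
            acc += std::exp(log1mt * (ktot[i] - kmin));
            cumw[i] = acc;
          }
        }
      }
      for (int off = 0; off < N_local; ++off) {
        int p1 = uniform ? runif_int(N_local) : pick_parent(cumw, N_local);
        int p2 = uniform ? runif_int(N_local) : pick_parent(cumw, N_local);
        make_gamete(O, 2 * off, P, p1, U, M_map, mu_block,
                    L_neutral, blocks, bp);
        make_gamete(O, 2 * off + 1, P, p2, U, M_map, mu_block,
                    L_neutral, blocks, bp);
      }
    }
    if (d > 1 && m > 0) {
      plan_exchange(d, N_local, m, plan, pool, used);
      for (const Swap &sw : plan) apply_swap(nxt, sw);
    }
    std::swap(cur, nxt);
  }

  // measurement: resolve neutral block alleles per haplotype
  List neutral(d);
  std::vector<signed char> seen(L_neutral);
  for (int dm = 0; dm < d; ++dm) {
    IntegerMatrix mat(2 * N_local, L_neutral);
    std::vector<int> row(L_neutral);
    for (int h = 0; h < 2 * N_local; ++h) {
      blocks.resolve(cur[dm].block[h], row.data(), seen);
      for (int s = 0; s < L_neutral; ++s) mat(h, s) = row[s];
    }
    neutral[dm] = mat;
  }

  IntegerMatrix kmat(N_local, d);
  for (int dm = 0; dm < d; ++dm)
    for (int i = 0; i < N_local; ++i)
      kmat(i, dm) = cur[dm].kcount[2 * i] + cur[dm].kcount[2 * i + 1];

  int fixed_del = NA_INTEGER;
  if (arrays) {
    fixed_del = 0;
    for (int s = 0; s < L_selected; ++s) {
      bool fixed = true;
      for (int dm = 0; dm < d && fixed; ++dm)
        for (int h = 0; h < 2 * N_local; ++h)
          if (!cur[dm].hap(h)[s]) { fixed = false; break; }
      if (fixed) ++fixed_del;
    }
  }

  return List::create(
    _["neutral"] = neutral,
    _["k"] = kmat,
    _["fixed_deleterious"] = fixed_del,
    _["n_block_nodes"] = (int)blocks.parent.size()
  );
}

//' @noRd
// [[Rcpp::export(name = ".migrate_exchange")]]
List migrate_exchange_cpp(List demes, double m) {
  int d = demes.size();
  if (d < 1) stop("empty state");
  if (m < 0 || m >= 1) stop("'m' must lie in [0, 1)");
  List out(d);
  std::vector<IntegerMatrix> mats(d);
  int nhap = -1;
  for (int i = 0; i < d; ++i) {
    IntegerMatrix mi = as<IntegerMatrix>(demes[i]);
    if (nhap < 0) nhap = mi.nrow();
    if (mi.nrow() != nhap || nhap % 2 != 0)
      stop("each deme needs the same even number of haplotype rows");
    mats[i] = clone(mi);
  }
  int N = nhap / 2;
  if (d > 1 && m > 0) {
    std::vector<Swap> plan;
    std::vector<std::vector<int>> pool(d);
    std::vector<int> used(d);
    for (int i = 0; i < d; ++i) {
      pool[i].resize(N);
      for (int j = 0; j < N; ++j) pool[i][j] = j;
    }
    plan_exchange(d, N, m, plan, pool, used);
    int L = mats[0].ncol();
    for (const Swap &sw : plan) {
      for (int h = 0; h < 2; ++h) {
        int ra = 2 * sw.ii + h, rb = 2 * sw.ij + h;
        for (int c = 0; c < L; ++c)
          std::swap(mats[sw.di](ra, c), mats[sw.dj](rb, c));
      }
    }
  }
  for (int i = 0; i < d; ++i) out[i] = mats[i];
  return out;
}
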