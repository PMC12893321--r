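// Individual-based non-Wright-Fisher forward simulator of gibbon demography
// and deleterious-mutation dynamics.
//
// Genome model: n_genes gene blocks of gene_length bp distributed over
// n_chromosomes chromosomes, separated by intergenic_length bp. Mutations
// arise only in genes (infinite-sites: every event is a new mutation id);
// recombination occurs only between adjacent genes (probability `xover` per
// interval per meiosis), chromosomes assort freely, and no crossover ever
// falls inside a gene. Each haplotype carries (a) a sorted vector of
// mutation ids and (b) a per-gene founder-ancestry label used for exact
// autozygosity (ROH) tracking: an ROH is a maximal run of genes where both
// haplotypes carry the same founder label.
//
// Life cycle (one calendar year): pair maintenance -> reproduction ->
// viability selection -> ageing. Breeding males (>= breeding_age) hold up to
// two fixed female mates and sire at most one offspring per year with the
// mate who has waited longest (>= breeding_interval years since her last
// birth); widowed males re-pair, and new bonds prefer females who did not
// breed the previous year. Survival probability is
//   exp(log genetic fitness) * age factor * min(1, K/N),
// where the age factor is (1 - mortality[age]) in the default mortality
// reading of the age table, or the raw table value in the literal
// "survival" reading. Individuals beyond max_age die.
//
// All randomness comes from R's RNG (RNGScope), so R-level set.seed()
// makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <climits>
#include <cmath>
using namespace Rcpp;

static const int N_CLS = 5; // 0 neutral, 1 weak, 2 moderate, 3 strong, 4 very strong

struct MutEffect { int gene; double s; double h; int cls; };

struct Params {
  int n_chromosomes, n_genes, gene_length;
  double intergenic_length;
  double mut_rate;        // per coding site per meiosis
  double xover;           // per inter-gene interval per meiosis
  double neutral_prop, gamma_shape, gamma_mean; // gamma_mean < 0
  double s_scale;         // fitness-effect rescaling 1/q (desk scaling)
  int breeding_age, breeding_interval, max_age;
  bool mortality_mode;    // age table read as mortality (default)
  double fecundity;
  double density_release_max; // upper bound on the K/N survival boost
  std::vector<int> chrom_first; // first gene index per chromosome + sentinel
  double span;            // bp per gene block incl. intergenic spacer
  double u_genome;        // mut_rate * gene_length * n_genes
};

struct Ind {
  int id, sex, age, subpop, last_bred; // sex: 0 female, 1 male
  double admix;                        // lineage-A ancestry fraction (-1 pre-split)
  double logw;                         // log fitness from segregating mutations
  int mate1, mate2;                    // males: female mate ids (-1 none)
  int mate_of;                         // females: id of bonded male (-1)
  std::vector<int> h1, h2;             // mutation ids sorted by (gene, id)
  std::vector<int> a1, a2;             // ancestry labels per gene, layer 0
  std::vector<int> b1, b2;             // ancestry labels per gene, layer 1
};

// Autozygosity is tracked with two staggered layers of per-gene ancestry
// labels. Each layer is periodically refreshed with unique labels (every
// roh_window years, the layers offset by half a window); F_ROH is always
// measured on the layer whose labels are at least half a window old. IBD
// older than that contributes negligibly to tracts above the ROH length
// thresholds (recombination shortens tracts as e^{-2 g r L}), so the rolling
// labels measure threshold-passing autozygosity without the saturation that
// fixed founder labels suffer once the population coalesces.
struct Pop {
  std::vector<Ind> inds;
  std::vector<MutEffect> muts;
  double fixed_logw = 0.0;
  int fixed_cnt[N_CLS] = {0, 0, 0, 0, 0};
  int next_id = 0;
  int year = 0;
  int label_next = 0;
  int last_relabel[2] = {0, 0};
};

// ---- age-specific mortality (per the gibbon life table) ------------------
static double age_mortality(int age) {
  if (age == 0) return 0.10;
  if (age <= 2) return 0.05;
  if (age <= 6) return 0.03;
  if (age == 7) return 0.10;
  if (age <= 30) return 0.05;
  if (age <= 35) return 0.25;
  if (age <= 40) return 0.50;
  return 1.0;
}

// ---- mutation effects -----------------------------------------------------
static double h_from_s(double s) {
  // printed map; boundary s = -0.1 (unassigned by the strict inequalities)
  // goes to the more recessive neighbour
  if (s <= -0.1) return 0.0;
  if (s < -0.01) return 0.01;
  if (s < -0.001) return 0.1;
  return 0.4;
}

static int class_from_s(double s) {
  if (s == 0.0) return 0;
  if (s <= -0.1) return 4;
  if (s < -0.01) return 3;
  if (s < -0.001) return 2;
  return 1;
}

// Draws the nominal selection coefficient from the DFE; dominance and the
// class label follow the nominal s, while the fitness effect applied in the
// simulation is the desk-rescaled s * (1/q), truncated at -1.
static MutEffect draw_effect(const Params& P, int gene) {
  MutEffect m; m.gene = gene;
  if (unif_rand() < P.neutral_prop) {
    m.s = 0.0; m.h = 0.5; m.cls = 0;
  } else {
    double scale = -P.gamma_mean / P.gamma_shape;
    double s = -R::rgamma(P.gamma_shape, scale);
    if (s < -1.0) s = -1.0;
    m.h = h_from_s(s); m.cls = class_from_s(s);
    m.s = std::max(-1.0, s * P.s_scale);
  }
  return m;
}

// ordering key for haplotype mutation vectors: (gene, id)
struct KeyLess {
  const std::vector<MutEffect>& muts;
  KeyLess(const std::vector<MutEffect>& m) : muts(m) {}
  bool operator()(int a, int b) const {
    int ga = muts[a].gene, gb = muts[b].gene;
    if (ga != gb) return ga < gb;
    return a < b;
  }
};

// ---- meiosis --------------------------------------------------------------
// Chooses a per-gene source haplotype by free chromosome assortment plus
// Bernoulli(xover) switches between adjacent genes, then copies mutations
// and ancestry labels; new mutations are Poisson(u_genome) per gamete.
static void make_gamete(const Ind& par, const Params& P,
                        std::vector<MutEffect>& muts,
                        std::vector<int>& out_h, std::vector<int>& out_a,
                        std::vector<int>& out_b, std::vector<int>& src_buf) {
  const int G = P.n_genes;
  src_buf.resize(G);
  // per chromosome: free assortment of the starting haplotype, then a
  // binomial number of crossovers at uniformly chosen distinct intervals
  // (equivalent to an independent Bernoulli(xover) per interval)
  for (int c = 0; c < P.n_chromosomes; ++c) {
    int g0 = P.chrom_first[c], g1 = P.chrom_first[c + 1];
    int cur = unif_rand() < 0.5 ? 0 : 1;
    int n_int = g1 - g0 - 1;
    int k = n_int > 0 ? (int) R::rbinom(n_int, P.xover) : 0;
    if (k == 0) {
      std::fill(src_buf.begin() + g0, src_buf.begin() + g1, cur);
      continue;
    }
    // k distinct crossover intervals (k is almost always tiny)
    int pos[64];
    if (k > 64) k = 64;
    for (int i = 0; i < k; ++i) {
      bool fresh;
      do {
        pos[i] = (int) std::floor(unif_rand() * n_int);
        if (pos[i] >= n_int) pos[i] = n_int - 1;
        fresh = true;
        for (int j = 0; j < i; ++j) if (pos[j] == pos[i]) { fresh = false; break; }
      } while (!fresh);
    }
    std::sort(pos, pos + k);
    int at = g0;
    for (int i = 0; i < k; ++i) {
      int brk = g0 + pos[i] + 1; // crossover between genes brk-1 and brk
      std::fill(src_buf.begin() + at, src_buf.begin() + brk, cur);
      cur = 1 - cur;
      at = brk;
    }
    std::fill(src_buf.begin() + at, src_buf.begin() + g1, cur);
  }
  out_h.clear();
  {
    // merge the two filtered, already-sorted parental vectors
    size_t i = 0, j = 0;
    const std::vector<int>& A = par.h1;
    const std::vector<int>& B = par.h2;
    while (i < A.size() || j < B.size()) {
      bool takeA;
      if (i >= A.size()) takeA = false;
      else if (j >= B.size()) takeA = true;
      else {
        int ga = muts[A[i]].gene, gb = muts[B[j]].gene;
        takeA = (ga < gb) || (ga == gb && A[i] < B[j]);
      }
      if (takeA) {
        if (src_buf[muts[A[i]].gene] == 0) out_h.push_back(A[i]);
        ++i;
      } else {
        if (src_buf[muts[B[j]].gene] == 1) out_h.push_back(B[j]);
        ++j;
      }
    }
  }
  out_a.resize(G);
  out_b.resize(G);
  for (int g = 0; g < G; ) {
    int cur = src_buf[g];
    int h = g + 1;
    while (h < G && src_buf[h] == cur) ++h;
    const std::vector<int>& pa = cur == 0 ? par.a1 : par.a2;
    const std::vector<int>& pb = cur == 0 ? par.b1 : par.b2;
    std::copy(pa.begin() + g, pa.begin() + h, out_a.begin() + g);
    std::copy(pb.begin() + g, pb.begin() + h, out_b.begin() + g);
    g = h;
  }
  // new mutations
  int n_new = (int) R::rpois(P.u_genome);
  for (int k = 0; k < n_new; ++k) {
    int gene = (int) std::floor(unif_rand() * G);
    if (gene >= G) gene = G - 1;
    MutEffect m = draw_effect(P, gene);
    int id = (int) muts.size();
    muts.push_back(m);
    KeyLess less(muts);
    out_h.insert(std::upper_bound(out_h.begin(), out_h.end(), id, less), id);
  }
}

// ---- fitness and load -----------------------------------------------------
// multiplicative: (1+s) per homozygous mutation, (1+h s) per heterozygous
static double log_fitness(const std::vector<int>& h1, const std::vector<int>& h2,
                          const std::vector<MutEffect>& muts) {
  double lw = 0.0;
  size_t i = 0, j = 0;
  while (i < h1.size() || j < h2.size()) {
    int which; // 0 hom, 1 het from h1, 2 het from h2
    if (i >= h1.size()) which = 2;
    else if (j >= h2.size()) which = 1;
    else if (h1[i] == h2[j]) which = 0;
    else {
      int ga = muts[h1[i]].gene, gb = muts[h2[j]].gene;
      which = ((ga < gb) || (ga == gb && h1[i] < h2[j])) ? 1 : 2;
    }
    double f;
    if (which == 0) { f = 1.0 + muts[h1[i]].s; ++i; ++j; }
    else if (which == 1) { const MutEffect& m = muts[h1[i]]; f = 1.0 + m.h * m.s; ++i; }
    else { const MutEffect& m = muts[h2[j]]; f = 1.0 + m.h * m.s; ++j; }
    if (f <= 0.0) return -1e30;
    lw += std::log(f);
  }
  return lw;
}

static void load_counts(const Ind& ind, const std::vector<MutEffect>& muts,
                        int* hom, int* het) {
  for (int c = 0; c < N_CLS; ++c) { hom[c] = 0; het[c] = 0; }
  size_t i = 0, j = 0;
  const std::vector<int>& h1 = ind.h1;
  const std::vector<int>& h2 = ind.h2;
  while (i < h1.size() || j < h2.size()) {
    int which;
    if (i >= h1.size()) which = 2;
    else if (j >= h2.size()) which = 1;
    else if (h1[i] == h2[j]) which = 0;
    else {
      int ga = muts[h1[i]].gene, gb = muts[h2[j]].gene;
      which = ((ga < gb) || (ga == gb && h1[i] < h2[j])) ? 1 : 2;
    }
    if (which == 0) { hom[muts[h1[i]].cls]++; ++i; ++j; }
    else if (which == 1) { het[muts[h1[i]].cls]++; ++i; }
    else { het[muts[h2[j]].cls]++; ++j; }
  }
}

// ---- ROH ------------------------------------------------------------------
// F_ROH = summed length of autozygous runs >= threshold / genome length,
// runs measured in whole gene blocks (span bp each) within chromosomes.
static double froh_of(const Ind& ind, const Params& P, double thresh_bp,
                      int layer) {
  const std::vector<int>& x1 = layer == 0 ? ind.a1 : ind.b1;
  const std::vector<int>& x2 = layer == 0 ? ind.a2 : ind.b2;
  double kept = 0.0;
  for (int c = 0; c < P.n_chromosomes; ++c) {
    int run = 0;
    for (int g = P.chrom_first[c]; g < P.chrom_first[c + 1]; ++g) {
      if (x1[g] == x2[g]) { run++; }
      else {
        double len = run * P.span;
        if (len >= thresh_bp) kept += len;
        run = 0;
      }
    }
    double len = run * P.span;
    if (len >= thresh_bp) kept += len;
  }
  return kept / (P.span * P.n_genes);
}

// ---- RNG helpers ----------------------------------------------------------
static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = (int) std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// ---- mating constraints ---------------------------------------------------
// inter-lineage pair: not both pure members of the same lineage; admixed
// individuals (0 < a < 1) count as inter-lineage partners for anyone
static bool inter_lineage(const Ind& m, const Ind& f) {
  if (m.admix < 0 || f.admix < 0) return false; // lineages undefined
  bool pureA = m.admix == 1.0 && f.admix == 1.0;
  bool pureB = m.admix == 0.0 && f.admix == 0.0;
  return !(pureA || pureB);
}

// mode: 0 unconstrained/random, 1 all_cross, 2 half_cross
static bool bond_allowed(int mode, const Ind& m, const Ind& f) {
  if (mode == 0) return true;
  if (mode == 1) return inter_lineage(m, f);
  // half_cross: each pairing is constrained inter-lineage with prob 0.5
  if (unif_rand() < 0.5) return inter_lineage(m, f);
  return true;
}

// ---- one year of the life cycle ------------------------------------------
// K_sub: carrying capacity per subpopulation (index by subpop id)
static void year_step(Pop& pop, const Params& P,
                      const std::vector<double>& K_sub, int mate_mode) {
  std::vector<Ind>& inds = pop.inds;
  // id -> index
  std::unordered_map<int, int> at;
  at.reserve(inds.size() * 2);
  for (size_t i = 0; i < inds.size(); ++i) at[inds[i].id] = (int) i;

  // validate bonds (drop links to dead or moved individuals)
  for (auto& ind : inds) {
    if (ind.sex == 1) {
      for (int* m : {&ind.mate1, &ind.mate2}) {
        if (*m >= 0) {
          auto it = at.find(*m);
          if (it == at.end() || inds[it->second].subpop != ind.subpop ||
              inds[it->second].mate_of != ind.id)
            *m = -1;
        }
      }
    } else if (ind.mate_of >= 0) {
      auto it = at.find(ind.mate_of);
      if (it == at.end() || inds[it->second].subpop != ind.subpop)
        ind.mate_of = -1;
      else {
        const Ind& male = inds[it->second];
        if (male.mate1 != ind.id && male.mate2 != ind.id) ind.mate_of = -1;
      }
    }
  }

  // pair maintenance: breeding males fill mate vacancies
  std::vector<int> males, females;
  for (size_t i = 0; i < inds.size(); ++i) {
    if (inds[i].age >= P.breeding_age) {
      if (inds[i].sex == 1) males.push_back((int) i);
      else if (inds[i].mate_of < 0) females.push_back((int) i);
    }
  }
  shuffle_idx(males);
  shuffle_idx(females);
  for (int mi : males) {
    Ind& male = inds[mi];
    int vac = (male.mate1 < 0) + (male.mate2 < 0);
    if (vac == 0) continue;
    for (size_t fi = 0; fi < females.size() && vac > 0; ) {
      Ind& fem = inds[females[fi]];
      if (fem.mate_of >= 0 || fem.subpop != male.subpop ||
          fem.last_bred == pop.year - 1 ||
          !bond_allowed(mate_mode, male, fem)) { ++fi; continue; }
      fem.mate_of = male.id;
      if (male.mate1 < 0) male.mate1 = fem.id; else male.mate2 = fem.id;
      --vac;
      females[fi] = females.back(); females.pop_back();
    }
  }

  // reproduction: one offspring per male per year, with the eligible mate
  // who has waited longest since her last birth
  size_t n_before = inds.size();
  std::vector<int> src_buf;
  for (size_t mi = 0; mi < n_before; ++mi) {
    if (inds[mi].sex != 1 || inds[mi].age < P.breeding_age) continue;
    int best = -1, best_bred = INT_MAX;
    for (int mid : {inds[mi].mate1, inds[mi].mate2}) {
      if (mid < 0) continue;
      auto it = at.find(mid);
      if (it == at.end()) continue;
      const Ind& fem = inds[it->second];
      if (fem.age < P.breeding_age) continue;
      if (fem.last_bred > pop.year - P.breeding_interval) continue;
      if (fem.last_bred < best_bred) { best_bred = fem.last_bred; best = it->second; }
    }
    if (best < 0) continue;
    if (P.fecundity < 1.0 && unif_rand() >= P.fecundity) continue;
    Ind child;
    child.id = pop.next_id++;
    child.sex = unif_rand() < 0.5 ? 0 : 1;
    child.age = 0;
    child.subpop = inds[mi].subpop;
    child.last_bred = -1000;
    child.mate1 = child.mate2 = child.mate_of = -1;
    // gametes may reallocate inds via push_back, so build before pushing
    make_gamete(inds[mi], P, pop.muts, child.h1, child.a1, child.b1, src_buf);
    make_gamete(inds[best], P, pop.muts, child.h2, child.a2, child.b2, src_buf);
    child.admix = (inds[mi].admix < 0 || inds[best].admix < 0) ? -1.0
      : 0.5 * (inds[mi].admix + inds[best].admix);
    child.logw = log_fitness(child.h1, child.h2, pop.muts);
    inds[best].last_bred = pop.year;
    inds.push_back(std::move(child));
  }

  // viability selection with density dependence per subpopulation
  std::vector<double> n_sub(K_sub.size(), 0.0);
  for (const auto& ind : inds)
    if (ind.subpop >= 0 && ind.subpop < (int) n_sub.size()) n_sub[ind.subpop]++;
  std::vector<Ind> survivors;
  survivors.reserve(inds.size());
  for (auto& ind : inds) {
    if (ind.age > P.max_age) continue;
    // density regulation: survival scaled by K/N; below K the release is
    // bounded (vital rates can rise at most density_release_max-fold), so
    // sparse populations are demographically compensated without rescuing
    // genetically inviable individuals
    double dens = 1.0;
    if (ind.subpop >= 0 && ind.subpop < (int) K_sub.size() &&
        n_sub[ind.subpop] > 0)
      dens = std::min(K_sub[ind.subpop] / n_sub[ind.subpop],
                      P.density_release_max);
    double agef = P.mortality_mode ? (1.0 - age_mortality(ind.age))
                                   : age_mortality(ind.age);
    double w = std::exp(ind.logw + pop.fixed_logw);
    double p = std::min(1.0, w * agef * dens);
    if (p > 0 && unif_rand() < p) {
      ind.age++;
      survivors.push_back(std::move(ind));
    }
  }
  inds.swap(survivors);
  pop.year++;
}

// ---- fixed-mutation purging ----------------------------------------------
// Mutations carried by every haplotype of every living individual are
// converted to substitutions: their fitness effect moves into fixed_logw,
// their class counts into fixed_cnt, and they leave the per-individual lists.
static void purge_fixed(Pop& pop) {
  if (pop.inds.empty() || pop.muts.empty()) return;
  std::vector<int> cnt(pop.muts.size(), 0);
  int n_hap = 0;
  for (const auto& ind : pop.inds) {
    n_hap += 2;
    for (int id : ind.h1) cnt[id]++;
    for (int id : ind.h2) cnt[id]++;
  }
  std::vector<char> fixed(pop.muts.size(), 0);
  bool any = false;
  for (size_t id = 0; id < cnt.size(); ++id)
    if (cnt[id] == n_hap) { fixed[id] = 1; any = true; }
  if (!any) return;
  for (size_t id = 0; id < fixed.size(); ++id) {
    if (!fixed[id]) continue;
    pop.fixed_cnt[pop.muts[id].cls]++;
    double f = 1.0 + pop.muts[id].s;
    pop.fixed_logw += std::log(std::max(f, 1e-300));
  }
  for (auto& ind : pop.inds) {
    for (std::vector<int>* h : {&ind.h1, &ind.h2}) {
      size_t k = 0;
      for (size_t i = 0; i < h->size(); ++i)
        if (!fixed[(*h)[i]]) (*h)[k++] = (*h)[i];
      h->resize(k);
    }
  }
}

// ---- ancestry-label maintenance ------------------------------------------
static void relabel_layer(Pop& pop, const Params& P, int layer) {
  for (auto& ind : pop.inds) {
    std::vector<int>& x1 = layer == 0 ? ind.a1 : ind.b1;
    std::vector<int>& x2 = layer == 0 ? ind.a2 : ind.b2;
    x1.assign(P.n_genes, pop.label_next++);
    x2.assign(P.n_genes, pop.label_next++);
  }
  pop.last_relabel[layer] = pop.year;
}

static void maintain_labels(Pop& pop, const Params& P, int roh_window) {
  for (int l = 0; l < 2; ++l)
    if (pop.year >= pop.last_relabel[l] + roh_window)
      relabel_layer(pop, P, l);
}

// layer whose labels are oldest (>= half a window at steady state)
static int roh_layer(const Pop& pop) {
  return pop.last_relabel[0] <= pop.last_relabel[1] ? 0 : 1;
}

// ---- trajectory recording -------------------------------------------------
struct Recorder {
  std::vector<int> year, N;
  std::vector<double> froh500, froh1m, het_mean, fitness;
  std::vector<double> realized[N_CLS], masked[N_CLS];
};

static void record(Recorder& rec, const Pop& pop, const Params& P,
                   int roh_subsample) {
  int layer = roh_layer(pop);
  rec.year.push_back(pop.year);
  rec.N.push_back((int) pop.inds.size());
  int n = (int) pop.inds.size();
  if (n == 0) {
    rec.froh500.push_back(NA_REAL); rec.froh1m.push_back(NA_REAL);
    rec.het_mean.push_back(NA_REAL); rec.fitness.push_back(NA_REAL);
    for (int c = 0; c < N_CLS; ++c) {
      rec.realized[c].push_back(NA_REAL); rec.masked[c].push_back(NA_REAL);
    }
    return;
  }
  // subsample individuals for the per-individual statistics
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  if (roh_subsample > 0 && n > roh_subsample) {
    shuffle_idx(idx);
    idx.resize(roh_subsample);
  }
  double f5 = 0, f10 = 0, hetm = 0, wsum = 0;
  double rsum[N_CLS] = {0}, msum[N_CLS] = {0};
  int rn[N_CLS] = {0};
  int hom[N_CLS], het[N_CLS];
  for (int i : idx) {
    const Ind& ind = pop.inds[i];
    f5 += froh_of(ind, P, 5e5, layer);
    f10 += froh_of(ind, P, 1e6, layer);
    wsum += std::exp(ind.logw + pop.fixed_logw);
    load_counts(ind, pop.muts, hom, het);
    int tot_het = 0;
    for (int c = 0; c < N_CLS; ++c) {
      tot_het += het[c];
      int homc = hom[c] + pop.fixed_cnt[c];
      double denom = 2.0 * homc + het[c];
      if (denom > 0) {
        rsum[c] += 2.0 * homc / denom;
        msum[c] += het[c] / denom;
        rn[c]++;
      }
    }
    hetm += tot_het;
  }
  double m = (double) idx.size();
  rec.froh500.push_back(f5 / m);
  rec.froh1m.push_back(f10 / m);
  rec.het_mean.push_back(hetm / m);
  rec.fitness.push_back(wsum / m);
  for (int c = 0; c < N_CLS; ++c) {
    rec.realized[c].push_back(rn[c] ? rsum[c] / rn[c] : 0.0);
    rec.masked[c].push_back(rn[c] ? msum[c] / rn[c] : 0.0);
  }
}

static DataFrame rec_to_df(const Recorder& rec) {
  return DataFrame::create(
    _["year"] = rec.year, _["N"] = rec.N,
    _["froh500"] = rec.froh500, _["froh1mb"] = rec.froh1m,
    _["het_sites"] = rec.het_mean,
    _["mean_fitness"] = rec.fitness,
    _["realized_weak"] = rec.realized[1],
    _["realized_moderate"] = rec.realized[2],
    _["realized_strong"] = rec.realized[3],
    _["realized_vstrong"] = rec.realized[4],
    _["masked_weak"] = rec.masked[1],
    _["masked_moderate"] = rec.masked[2],
    _["masked_strong"] = rec.masked[3],
    _["masked_vstrong"] = rec.masked[4]);
}

// ---- parameter/state marshalling -----------------------------------------
static Params params_from(List layout, List dfe, List life) {
  Params P;
  P.n_chromosomes = as<int>(layout["n_chromosomes"]);
  P.n_genes = as<int>(layout["n_genes"]);
  P.gene_length = as<int>(layout["gene_length"]);
  P.intergenic_length = as<double>(layout["intergenic_length"]);
  P.mut_rate = as<double>(layout["mutation_rate"]);
  P.xover = as<double>(layout["intergene_crossover_prob"]);
  P.neutral_prop = as<double>(dfe["neutral_prop"]);
  P.gamma_shape = as<double>(dfe["gamma_shape"]);
  P.gamma_mean = as<double>(dfe["gamma_mean"]);
  P.s_scale = layout.containsElementNamed("scale_factor")
    ? 1.0 / as<double>(layout["scale_factor"]) : 1.0;
  P.breeding_age = as<int>(life["breeding_age"]);
  P.breeding_interval = as<int>(life["breeding_interval"]);
  P.max_age = as<int>(life["max_age"]);
  P.mortality_mode = as<std::string>(life["age_factor_mode"]) == "mortality";
  P.fecundity = as<double>(life["fecundity"]);
  P.density_release_max = life.containsElementNamed("density_release_max")
    ? as<double>(life["density_release_max"]) : 2.0;
  P.span = P.gene_length + P.intergenic_length;
  P.u_genome = P.mut_rate * P.gene_length * P.n_genes;
  // distribute genes over chromosomes as evenly as possible
  P.chrom_first.resize(P.n_chromosomes + 1);
  int base = P.n_genes / P.n_chromosomes, extra = P.n_genes % P.n_chromosomes;
  P.chrom_first[0] = 0;
  for (int c = 0; c < P.n_chromosomes; ++c)
    P.chrom_first[c + 1] = P.chrom_first[c] + base + (c < extra ? 1 : 0);
  return P;
}

static List pop_to_list(const Pop& pop) {
  int n = (int) pop.inds.size();
  IntegerVector id(n), sex(n), age(n), subpop(n), last_bred(n);
  NumericVector admix(n), logw(n);
  List h1(n), h2(n), a1(n), a2(n), b1(n), b2(n);
  for (int i = 0; i < n; ++i) {
    const Ind& d = pop.inds[i];
    id[i] = d.id; sex[i] = d.sex; age[i] = d.age; subpop[i] = d.subpop;
    last_bred[i] = d.last_bred; admix[i] = d.admix; logw[i] = d.logw;
    h1[i] = IntegerVector(d.h1.begin(), d.h1.end());
    h2[i] = IntegerVector(d.h2.begin(), d.h2.end());
    a1[i] = IntegerVector(d.a1.begin(), d.a1.end());
    a2[i] = IntegerVector(d.a2.begin(), d.a2.end());
    b1[i] = IntegerVector(d.b1.begin(), d.b1.end());
    b2[i] = IntegerVector(d.b2.begin(), d.b2.end());
  }
  int nm = (int) pop.muts.size();
  IntegerVector mg(nm), mc(nm);
  NumericVector ms(nm), mh(nm);
  for (int i = 0; i < nm; ++i) {
    mg[i] = pop.muts[i].gene; ms[i] = pop.muts[i].s;
    mh[i] = pop.muts[i].h; mc[i] = pop.muts[i].cls;
  }
  return List::create(
    _["id"] = id, _["sex"] = sex, _["age"] = age, _["subpop"] = subpop,
    _["last_bred"] = last_bred, _["admix"] = admix, _["logw"] = logw,
    _["h1"] = h1, _["h2"] = h2, _["a1"] = a1, _["a2"] = a2,
    _["b1"] = b1, _["b2"] = b2,
    _["mut_gene"] = mg, _["mut_s"] = ms, _["mut_h"] = mh, _["mut_cls"] = mc,
    _["fixed_logw"] = pop.fixed_logw,
    _["fixed_cnt"] = IntegerVector(pop.fixed_cnt, pop.fixed_cnt + N_CLS),
    _["next_id"] = pop.next_id, _["year"] = pop.year,
    _["label_next"] = pop.label_next,
    _["last_relabel"] = IntegerVector(pop.last_relabel,
                                      pop.last_relabel + 2));
}

static Pop pop_from_list(List st) {
  Pop pop;
  IntegerVector id = st["id"], sex = st["sex"], age = st["age"],
    subpop = st["subpop"], last_bred = st["last_bred"];
  NumericVector admix = st["admix"], logw = st["logw"];
  List h1 = st["h1"], h2 = st["h2"], a1 = st["a1"], a2 = st["a2"],
    b1 = st["b1"], b2 = st["b2"];
  int n = id.size();
  pop.inds.resize(n);
  for (int i = 0; i < n; ++i) {
    Ind& d = pop.inds[i];
    d.id = id[i]; d.sex = sex[i]; d.age = age[i]; d.subpop = subpop[i];
    d.last_bred = last_bred[i]; d.admix = admix[i]; d.logw = logw[i];
    d.mate1 = d.mate2 = d.mate_of = -1; // bonds re-form on the first year
    IntegerVector v;
    v = h1[i]; d.h1.assign(v.begin(), v.end());
    v = h2[i]; d.h2.assign(v.begin(), v.end());
    v = a1[i]; d.a1.assign(v.begin(), v.end());
    v = a2[i]; d.a2.assign(v.begin(), v.end());
    v = b1[i]; d.b1.assign(v.begin(), v.end());
    v = b2[i]; d.b2.assign(v.begin(), v.end());
  }
  IntegerVector mg = st["mut_gene"], mc = st["mut_cls"];
  NumericVector ms = st["mut_s"], mh = st["mut_h"];
  pop.muts.resize(mg.size());
  for (int i = 0; i < mg.size(); ++i) {
    pop.muts[i].gene = mg[i]; pop.muts[i].s = ms[i];
    pop.muts[i].h = mh[i]; pop.muts[i].cls = mc[i];
  }
  pop.fixed_logw = as<double>(st["fixed_logw"]);
  IntegerVector fc = st["fixed_cnt"];
  for (int c = 0; c < N_CLS; ++c) pop.fixed_cnt[c] = fc[c];
  pop.next_id = as<int>(st["next_id"]);
  pop.year = as<int>(st["year"]);
  pop.label_next = as<int>(st["label_next"]);
  IntegerVector lr = st["last_relabel"];
  pop.last_relabel[0] = lr[0]; pop.last_relabel[1] = lr[1];
  return pop;
}

static void init_founders(Pop& pop, const Params& P, int n0, int roh_window) {
  pop.inds.clear();
  pop.inds.reserve(n0);
  for (int i = 0; i < n0; ++i) {
    Ind d;
    d.id = pop.next_id++;
    d.sex = i % 2;
    d.age = (int) std::floor(unif_rand() * 15.0);
    d.subpop = 0; d.last_bred = -1000; d.admix = -1.0; d.logw = 0.0;
    d.mate1 = d.mate2 = d.mate_of = -1;
    d.a1.assign(P.n_genes, pop.label_next++);
    d.a2.assign(P.n_genes, pop.label_next++);
    d.b1.assign(P.n_genes, pop.label_next++);
    d.b2.assign(P.n_genes, pop.label_next++);
    pop.inds.push_back(std::move(d));
  }
  // stagger the layers by half a window
  pop.last_relabel[0] = 0;
  pop.last_relabel[1] = -roh_window / 2;
}

// ---- exported drivers -----------------------------------------------------

// Demographic scenario: epochs of (duration, K ramping K0 -> K1), then an
// optional split period with lineages A and B at K_A / K_B.
// [[Rcpp::export]]
List cpp_run_scenario(List layout, List dfe, List life, List scenario,
                      int record_every, int roh_subsample, int roh_window) {
  RNGScope rng;
  Params P = params_from(layout, dfe, life);
  IntegerVector dur = scenario["durations"];
  NumericVector K0 = scenario["K0"], K1 = scenario["K1"];
  int split_dur = as<int>(scenario["split_duration"]);
  double K_A = as<double>(scenario["K_A"]), K_B = as<double>(scenario["K_B"]);
  double K_A0 = as<double>(scenario["K_A_start"]);
  double K_B0 = as<double>(scenario["K_B_start"]);

  Pop pop;
  init_founders(pop, P, (int) K0[0], roh_window);
  Recorder rec;
  bool extinct = false;
  int ext_year = NA_INTEGER;
  List presplit = R_NilValue;
  std::vector<int> epoch_end;
  for (int e = 0; e < dur.size() && !extinct; ++e) {
    for (int t = 0; t < dur[e]; ++t) {
      double K = K0[e] + (K1[e] - K0[e]) * (t + 1.0) / dur[e];
      std::vector<double> Ks(1, K);
      year_step(pop, P, Ks, 0);
      maintain_labels(pop, P, roh_window);
      if (pop.year % 50 == 0) purge_fixed(pop);
      if (pop.year % record_every == 0) record(rec, pop, P, roh_subsample);
      if (pop.inds.empty()) { extinct = true; ext_year = pop.year; break; }
    }
    epoch_end.push_back(pop.year);
  }
  if (!extinct && split_dur > 0) {
    presplit = pop_to_list(pop);
    // partition the population into lineages A and B
    double pA = K_A0 / (K_A0 + K_B0);
    for (auto& ind : pop.inds) {
      bool toA = unif_rand() < pA;
      ind.subpop = toA ? 0 : 1;
      ind.admix = toA ? 1.0 : 0.0;
      ind.mate1 = ind.mate2 = ind.mate_of = -1;
    }
    for (int t = 0; t < split_dur; ++t) {
      double f = (t + 1.0) / split_dur;
      std::vector<double> Ks = {K_A0 + (K_A - K_A0) * f,
                                K_B0 + (K_B - K_B0) * f};
      year_step(pop, P, Ks, 0);
      maintain_labels(pop, P, roh_window);
      if (pop.year % 50 == 0) purge_fixed(pop);
      if (pop.year % record_every == 0) record(rec, pop, P, roh_subsample);
      if (pop.inds.empty()) { extinct = true; ext_year = pop.year; break; }
    }
    epoch_end.push_back(pop.year);
  }
  record(rec, pop, P, roh_subsample);
  return List::create(
    _["trajectory"] = rec_to_df(rec),
    _["population"] = pop_to_list(pop),
    _["population_presplit"] = presplit,
    _["extinct"] = extinct,
    _["extinction_year"] = ext_year,
    _["epoch_end_years"] = IntegerVector(epoch_end.begin(), epoch_end.end()));
}

// Continue a saved population under constant K and a mating mode
// ("random", "all_cross", "half_cross"); used for the PVA and for drift
// checks. With K2 < 0 all individuals are merged into one habitat at
// capacity K; with K2 >= 0 the existing subpopulations 0 and 1 are kept
// separate at capacities K and K2 (mating stays within subpopulation).
// [[Rcpp::export]]
List cpp_run_forward(List pop_state, List layout, List dfe, List life,
                     std::string mating_mode, double K, double K2, int years,
                     int record_every, int roh_subsample, int roh_window,
                     bool return_population) {
  RNGScope rng;
  Params P = params_from(layout, dfe, life);
  Pop pop = pop_from_list(pop_state);
  int mode = mating_mode == "all_cross" ? 1 :
             mating_mode == "half_cross" ? 2 : 0;
  if (K2 < 0) for (auto& ind : pop.inds) ind.subpop = 0;
  int year0 = pop.year;
  Recorder rec;
  record(rec, pop, P, roh_subsample);
  bool extinct = pop.inds.empty();
  int ext_year = extinct ? 0 : NA_INTEGER;
  std::vector<double> Ks(1, K);
  if (K2 >= 0) Ks.push_back(K2);
  for (int t = 0; t < years && !extinct; ++t) {
    year_step(pop, P, Ks, mode);
    maintain_labels(pop, P, roh_window);
    if (pop.year % 50 == 0) purge_fixed(pop);
    if ((pop.year - year0) % record_every == 0)
      record(rec, pop, P, roh_subsample);
    if (pop.inds.empty()) { extinct = true; ext_year = pop.year - year0; }
  }
  List out = List::create(
    _["trajectory"] = rec_to_df(rec),
    _["extinct"] = extinct,
    _["extinction_year"] = ext_year);
  if (return_population) out["population"] = pop_to_list(pop);
  return out;
}

// Meiosis test harness: parental haplotypes given as gene indices of their
// mutations; returns per-gamete source haplotypes per gene and the inherited
// mutation ids (ids < n1 come from haplotype 1).
// [[Rcpp::export]]
List cpp_test_gametes(int n_genes, int n_chromosomes, double xover,
                      IntegerVector genes_h1, IntegerVector genes_h2,
                      int n_gametes, double mut_rate) {
  RNGScope rng;
  List layout = List::create(
    _["n_chromosomes"] = n_chromosomes, _["n_genes"] = n_genes,
    _["gene_length"] = 1458, _["intergenic_length"] = 1e5,
    _["mutation_rate"] = mut_rate, _["intergene_crossover_prob"] = xover);
  List dfe = List::create(_["neutral_prop"] = 1.0, _["gamma_shape"] = 0.186,
                          _["gamma_mean"] = -0.01314833);
  List life = List::create(_["breeding_age"] = 7, _["breeding_interval"] = 2,
                           _["max_age"] = 40,
                           _["age_factor_mode"] = "mortality",
                           _["fecundity"] = 1.0);
  Params P = params_from(layout, dfe, life);
  Pop pop;
  Ind par;
  par.id = 0; par.sex = 1; par.age = 10; par.subpop = 0;
  par.last_bred = -1000; par.admix = -1; par.logw = 0;
  par.mate1 = par.mate2 = par.mate_of = -1;
  for (int i = 0; i < genes_h1.size(); ++i) {
    pop.muts.push_back({genes_h1[i], 0.0, 0.5, 0});
    par.h1.push_back(i);
  }
  for (int i = 0; i < genes_h2.size(); ++i) {
    pop.muts.push_back({genes_h2[i], 0.0, 0.5, 0});
    par.h2.push_back((int) genes_h1.size() + i);
  }
  KeyLess less(pop.muts);
  std::sort(par.h1.begin(), par.h1.end(), less);
  std::sort(par.h2.begin(), par.h2.end(), less);
  par.a1.assign(n_genes, 0);
  par.a2.assign(n_genes, 1);
  par.b1.assign(n_genes, 0);
  par.b2.assign(n_genes, 1);
  IntegerMatrix sources(n_gametes, n_genes);
  List gametes(n_gametes);
  std::vector<int> h, a, b, buf;
  for (int g = 0; g < n_gametes; ++g) {
    make_gamete(par, P, pop.muts, h, a, b, buf);
    for (int j = 0; j < n_genes; ++j) sources(g, j) = a[j];
    gametes[g] = IntegerVector(h.begin(), h.end());
  }
  return List::create(_["sources"] = sources, _["gametes"] = gametes,
                      _["n_h1"] = (int) genes_h1.size());
}

// Dominance coefficient implied by a selection coefficient (the printed
// s -> h step map used inside the simulator).
// [[Rcpp::export]]
NumericVector cpp_h_from_s(NumericVector s) {
  NumericVector out(s.size());
  for (int i = 0; i < s.size(); ++i)
    out[i] = s[i] == 0.0 ? 0.5 : h_from_s(s[i]);
  return out;
}

// Deleterious-class label index for a selection coefficient
// (0 neutral, 1 weak, 2 moderate, 3 strong, 4 very strong).
// [[Rcpp::export]]
IntegerVector cpp_class_from_s(NumericVector s) {
  IntegerVector out(s.size());
  for (int i = 0; i < s.size(); ++i) out[i] = class_from_s(s[i]);
  return out;
}

// Age factor entering the survival probability: 1 - mortality[age] under the
// default mortality reading, the raw table value under the literal survival
// reading; 0 beyond max age 40.
// [[Rcpp::export]]
NumericVector cpp_age_factor(IntegerVector age, std::string mode) {
  bool mort = mode == "mortality";
  NumericVector out(age.size());
  for (int i = 0; i < age.size(); ++i) {
    if (age[i] > 40) { out[i] = 0.0; continue; }
    double m = age_mortality(age[i]);
    out[i] = mort ? 1.0 - m : m;
  }
  return out;
}

// Direct access to the effect-draw machinery for distribution tests.
// [[Rcpp::export]]
List cpp_draw_effects(int n, double neutral_prop, double gamma_shape,
                      double gamma_mean) {
  RNGScope rng;
  Params P;
  P.neutral_prop = neutral_prop;
  P.gamma_shape = gamma_shape;
  P.gamma_mean = gamma_mean;
  P.s_scale = 1.0;
  NumericVector s(n), h(n);
  IntegerVector cls(n);
  for (int i = 0; i < n; ++i) {
    MutEffect m = draw_effect(P, 0);
    s[i] = m.s; h[i] = m.h; cls[i] = m.cls;
  }
  return List::create(_["s"] = s, _["h"] = h, _["cls"] = cls);
}
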