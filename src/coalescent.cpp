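// Three-deme structured coalescent for a songbird isolation/IM model family.
//
// Demes: 0 = Sonoran (S), 1 = Chihuahuan (C), 2 = outgroup lineage (O).
// Backward in time: within-deme coalescence at rate k(k-1)/2 / N (haploid N,
// time in generations); migration as per-lineage exponential events while the
// model's migration window is open (mS moves a lineage from C to S, i.e.
// forward S->C gene flow; mC the reverse); at T_D the S and C demes merge
// into the ancestral-desert deme of size N_D; at T_A everything merges into
// the root deme of size N_A.
//
// Expectations are Rao-Blackwellized over branch lengths: a lineage's
// subtended sample counts never change during its lifetime, so its whole
// exposure is credited to one SFS cell at death.  Because the cell index is
// affine in the (i, j, k) counts, a parent's cell index is simply the sum of
// its children's — the event loop is O(1) per event apart from the per-deme
// index lists.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  bool flip;   // antithetic partner: u -> 1 - u
  Rng(uint64_t seed, uint64_t stream, bool flip_ = false) : flip(flip_) {
    uint64_t x = seed;
    s = splitmix64(x) ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    uint64_t y = s;
    splitmix64(y);
    s = y;
  }
  double unif() {
    double u = (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
    return flip ? 1.0 - u : u;
  }
  double expo(double rate) {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u) / rate;
  }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Model {
  double NS, NC, NO, ND, NA_;
  double TD, TA, TSC;
  double mS, mC;      // backward per-lineage rates: mS C->S, mC S->C
  int migWindow;      // 0 none, 1 [0,TD), 2 [0,TSC)
};

// One genealogy.  `onDeath(slot, t)` fires when a lineage is removed by
// coalescence; `onCoal(child1, child2, parentSlot, t)` after the parent is
// created.  Slot state lives in the caller-provided arrays.
struct Sim {
  const Model &mod;
  Rng &rng;
  std::vector<int> cell;      // per-slot SFS cell index (additive)
  std::vector<double> birth;  // per-slot birth time
  std::vector<int> deme;      // per-slot deme
  std::vector<int> pos;       // per-slot position in its deme list
  std::vector<int> list[3];   // per-deme slot lists
  double t;

  Sim(const Model &m, Rng &r) : mod(m), rng(r), t(0.0) {}

  void addTo(int d, int slot) {
    deme[slot] = d;
    pos[slot] = (int)list[d].size();
    list[d].push_back(slot);
  }
  void removeFrom(int d, int slot) {
    int p = pos[slot];
    int last = list[d].back();
    list[d][p] = last;
    pos[last] = p;
    list[d].pop_back();
  }

  template <typename DeathFn, typename CoalFn>
  double run(const int ns[3], int d1mult, int d2mult,
             DeathFn onDeath, CoalFn onCoal) {
    int ntot = ns[0] + ns[1] + ns[2];
    cell.resize(ntot); birth.resize(ntot); deme.resize(ntot);
    pos.resize(ntot);
    for (int d = 0; d < 3; ++d) list[d].clear();
    int slot = 0;
    for (int d = 0; d < 3; ++d) {
      int unit = (d == 0) ? 1 : (d == 1) ? d1mult : d1mult * d2mult;
      for (int i = 0; i < ns[d]; ++i) {
        cell[slot] = unit;
        birth[slot] = 0.0;
        addTo(d, slot);
        ++slot;
      }
    }

    double N[3] = {mod.NS, mod.NC, mod.NO};
    double btime[3]; int bcode[3]; int nb = 0;
    if (mod.migWindow == 2) { btime[nb] = mod.TSC; bcode[nb++] = 1; }
    else if (mod.migWindow == 1) { btime[nb] = mod.TD; bcode[nb++] = 1; }
    btime[nb] = mod.TD; bcode[nb++] = 2;
    btime[nb] = mod.TA; bcode[nb++] = 3;
    for (int i = 1; i < nb; ++i)
      for (int j = i; j > 0 && btime[j] < btime[j - 1]; --j) {
        std::swap(btime[j], btime[j - 1]);
        std::swap(bcode[j], bcode[j - 1]);
      }

    bool migOn = mod.migWindow != 0;
    t = 0.0;
    int bi = 0;
    int alive = ntot;

    while (alive > 1) {
      int k0 = (int)list[0].size(), k1 = (int)list[1].size(),
          k2 = (int)list[2].size();
      double rc0 = (k0 > 1) ? 0.5 * k0 * (k0 - 1) / N[0] : 0.0;
      double rc1 = (k1 > 1) ? 0.5 * k1 * (k1 - 1) / N[1] : 0.0;
      double rc2 = (k2 > 1) ? 0.5 * k2 * (k2 - 1) / N[2] : 0.0;
      double rCS = migOn ? k1 * mod.mS : 0.0;
      double rSC = migOn ? k0 * mod.mC : 0.0;
      double R = rc0 + rc1 + rc2 + rCS + rSC;

      double tev = (R > 0.0) ? t + rng.expo(R) : R_PosInf;
      if (bi < nb && tev >= btime[bi]) {
        t = btime[bi];
        int code = bcode[bi++];
        if (code == 1) migOn = false;
        else if (code == 2) {
          for (size_t i = 0; i < list[1].size(); ++i)
            addTo(0, list[1][i]);
          list[1].clear();
          N[0] = mod.ND;
        } else {
          for (size_t i = 0; i < list[2].size(); ++i)
            addTo(0, list[2][i]);
          list[2].clear();
          N[0] = mod.NA_;
        }
        continue;
      }
      t = tev;

      double u = rng.unif() * R;
      int d;
      if (u < rc0) d = 0;
      else if (u < rc0 + rc1) d = 1;
      else if (u < rc0 + rc1 + rc2) d = 2;
      else {
        // migration
        int from = (u < rc0 + rc1 + rc2 + rCS) ? 1 : 0;
        int to = 1 - from;
        int r = rng.below((int)list[from].size());
        int sl = list[from][r];
        removeFrom(from, sl);
        addTo(to, sl);
        continue;
      }
      int kk = (int)list[d].size();
      int r1 = rng.below(kk), r2 = rng.below(kk - 1);
      if (r2 >= r1) ++r2;
      int s1 = list[d][r1], s2 = list[d][r2];
      onDeath(s1, t);
      onDeath(s2, t);
      removeFrom(d, s1);
      removeFrom(d, s2);
      int parent = (int)cell.size();
      cell.push_back(cell[s1] + cell[s2]);
      birth.push_back(t);
      deme.push_back(d);
      pos.push_back(0);
      addTo(d, parent);
      onCoal(s1, s2, parent, t);
      --alive;
    }
    return t;
  }
};

static Model build_model(NumericVector sizes, double TD, double TA,
                         double TSC, double mS, double mC, int migWindow) {
  Model m;
  m.NS = sizes[0]; m.NC = sizes[1]; m.NO = sizes[2];
  m.ND = sizes[3]; m.NA_ = sizes[4];
  m.TD = TD; m.TA = TA; m.TSC = TSC; m.mS = mS; m.mC = mC;
  m.migWindow = migWindow;
  return m;
}

// Accumulated branch-length SFS with per-replicate squared totals for
// Monte-Carlo standard errors.  Entry (i,j,k), column-major with dims
// ns + 1, is total branch length (generations) subtending (i,j,k) samples.
// With `antithetic`, replicates come in pairs sharing one uniform stream,
// the partner seeing u -> 1-u; exponential waiting times anticorrelate and
// the variance of the mean drops.  `sumsq` then holds squared pair means
// and `nEff` the number of independent units.
// [[Rcpp::export(name = ".coalExpectedSfs")]]
List coal_expected_sfs(IntegerVector nsamp, NumericVector sizes,
                       double TD, double TA, double TSC,
                       double mS, double mC, int migWindow,
                       int nReps, double seed, bool antithetic = false) {
  int ns[3] = {nsamp[0], nsamp[1], nsamp[2]};
  int d1 = ns[0] + 1, d2 = ns[1] + 1, d3 = ns[2] + 1;
  int len = d1 * d2 * d3;
  std::vector<double> sum(len, 0.0), sumsq(len, 0.0), local(len, 0.0),
      unit(len, 0.0);
  Model mod = build_model(sizes, TD, TA, TSC, mS, mC, migWindow);
  uint64_t baseSeed = (uint64_t)seed;
  if (antithetic && (nReps % 2)) ++nReps;   // whole pairs
  int perUnit = antithetic ? 2 : 1;
  int nEff = nReps / perUnit;

  for (int u = 0; u < nEff; ++u) {
    std::fill(unit.begin(), unit.end(), 0.0);
    for (int half = 0; half < perUnit; ++half) {
      std::fill(local.begin(), local.end(), 0.0);
      Rng rng(baseSeed, (uint64_t)u, antithetic && half == 1);
      Sim sim(mod, rng);
      sim.run(ns, d1, d2,
              [&](int sl, double t) {
                local[sim.cell[sl]] += t - sim.birth[sl];
              },
              [](int, int, int, double) {});
      for (int i = 0; i < len; ++i) unit[i] += local[i];
    }
    for (int i = 0; i < len; ++i) {
      double m = unit[i] / perUnit;
      sum[i] += unit[i];
      sumsq[i] += m * m;
    }
  }
  return List::create(_["sum"] = NumericVector(sum.begin(), sum.end()),
                      _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
                      _["nReps"] = nReps, _["nEff"] = nEff);
}

// Per-branch records (subtended counts per deme, length in generations)
// and the TMRCA of each replicate genealogy.
// [[Rcpp::export(name = ".coalBranchTable")]]
List coal_branch_table(IntegerVector nsamp, NumericVector sizes,
                       double TD, double TA, double TSC,
                       double mS, double mC, int migWindow,
                       int nReps, double seed) {
  int ns[3] = {nsamp[0], nsamp[1], nsamp[2]};
  int d1 = ns[0] + 1, d2 = ns[1] + 1;
  Model mod = build_model(sizes, TD, TA, TSC, mS, mC, migWindow);
  std::vector<int> repv, av, bv, cv;
  std::vector<double> lenv, tmrca;
  uint64_t baseSeed = (uint64_t)seed;
  for (int rep = 0; rep < nReps; ++rep) {
    Rng rng(baseSeed, (uint64_t)rep);
    Sim sim(mod, rng);
    double tm = sim.run(ns, d1, d2,
        [&](int sl, double t) {
          int c = sim.cell[sl];
          repv.push_back(rep + 1);
          av.push_back(c % d1);
          bv.push_back((c / d1) % d2);
          cv.push_back(c / (d1 * d2));
          lenv.push_back(t - sim.birth[sl]);
        },
        [](int, int, int, double) {});
    tmrca.push_back(tm);
  }
  return List::create(
      _["branches"] = DataFrame::create(
          _["rep"] = IntegerVector(repv.begin(), repv.end()),
          _["nS"] = IntegerVector(av.begin(), av.end()),
          _["nC"] = IntegerVector(bv.begin(), bv.end()),
          _["nO"] = IntegerVector(cv.begin(), cv.end()),
          _["length"] = NumericVector(lenv.begin(), lenv.end())),
      _["tmrca"] = NumericVector(tmrca.begin(), tmrca.end()));
}

// One segregating site per genealogy: the mutated branch is chosen with
// probability proportional to its length; haploid samples below it carry
// the derived allele.  Returns an nSnps x (total haploids) 0/1 matrix;
// columns ordered S block, C block, O block.
// [[Rcpp::export(name = ".coalSampleSnps")]]
IntegerMatrix coal_sample_snps(IntegerVector nsamp, NumericVector sizes,
                               double TD, double TA, double TSC,
                               double mS, double mC, int migWindow,
                               int nSnps, double seed) {
  int ns[3] = {nsamp[0], nsamp[1], nsamp[2]};
  int ntot = ns[0] + ns[1] + ns[2];
  Model mod = build_model(sizes, TD, TA, TSC, mS, mC, migWindow);
  IntegerMatrix out(nSnps, ntot);
  uint64_t baseSeed = (uint64_t)seed;
  int W = (ntot + 63) / 64;

  std::vector<uint64_t> masks;
  std::vector<int> brSlot;
  std::vector<double> brLen;

  for (int s = 0; s < nSnps; ++s) {
    Rng rng(baseSeed, 0x53AE0000ULL + (uint64_t)s);
    Sim sim(mod, rng);
    masks.assign((size_t)W * (size_t)(2 * ntot), 0ULL);
    for (int i = 0; i < ntot; ++i)
      masks[(size_t)W * i + (i / 64)] |= (1ULL << (i % 64));
    brSlot.clear();
    brLen.clear();
    sim.run(ns, ns[0] + 1, ns[1] + 1,
            [&](int sl, double t) {
              brSlot.push_back(sl);
              brLen.push_back(t - sim.birth[sl]);
            },
            [&](int c1, int c2, int par, double) {
              if ((size_t)W * (par + 1) > masks.size())
                masks.resize((size_t)W * (par + 1), 0ULL);
              for (int w = 0; w < W; ++w)
                masks[(size_t)W * par + w] =
                    masks[(size_t)W * c1 + w] | masks[(size_t)W * c2 + w];
            });
    double total = 0.0;
    for (size_t i = 0; i < brLen.size(); ++i) total += brLen[i];
    double u = rng.unif() * total;
    size_t pick = 0;
    for (; pick + 1 < brLen.size(); ++pick) {
      if (u < brLen[pick]) break;
      u -= brLen[pick];
    }
    int sl = brSlot[pick];
    for (int i = 0; i < ntot; ++i)
      out(s, i) = (masks[(size_t)W * sl + (i / 64)] >> (i % 64)) & 1ULL;
  }
  return out;
}
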