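// Metropolis Monte Carlo kernel for coarse-grained toy systems.
//
// Samples either the physical potential (canonical ensemble at temperature
// T) or a modified energy E_mc(E) at T_mc (multicanonical ensemble). The
// modified-energy mapping is supplied as a fine grid with linear
// interpolation and linear extensions beyond the grid, matching the R-side
// bias_value() exactly. Randomness comes from a self-contained xoshiro256+
// generator seeded from two 32-bit integers, so trajectories are bitwise
// reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double GAS_R = 1.98720425864083e-3; // kcal/mol/K

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() { // Box-Muller, one value per call (cache the second)
    if (have_) { have_ = false; return cached_; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached_ = r * std::sin(2.0 * M_PI * u2);
    have_ = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  bool have_ = false;
  double cached_ = 0.0;
};

struct Bias {
  std::vector<double> E, Emc;
  bool identity;
  double value(double e) const {
    if (identity) return e;
    size_t n = E.size();
    if (e <= E[0])
      return Emc[0] + (Emc[1] - Emc[0]) / (E[1] - E[0]) * (e - E[0]);
    if (e >= E[n - 1])
      return Emc[n - 1] +
             (Emc[n - 1] - Emc[n - 2]) / (E[n - 1] - E[n - 2]) * (e - E[n - 1]);
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (E[mid] <= e) lo = mid; else hi = mid;
    }
    double f = (e - E[lo]) / (E[hi] - E[lo]);
    return Emc[lo] + f * (Emc[hi] - Emc[lo]);
  }
};

struct ComTerm {
  std::vector<int> idx;     // 0-based
  std::vector<double> mfrac; // mass / total mass
  int axis;                  // 0..2
  double lo, hi, k;
};

inline double fb_pen(double v, double lo, double hi, double k) {
  if (v < lo) { double d = lo - v; return k * d * d; }
  if (v > hi) { double d = v - hi; return k * d * d; }
  return 0.0;
}

struct System {
  int n;
  std::vector<double> x; // 3n coordinates
  NumericMatrix bonds, pairs, dwells, harm, fbs;
  std::vector<ComTerm> coms;
  std::vector<double> comval; // current COM along axis per term
  // term lists touching each particle: encoded type*big + row
  std::vector<std::vector<std::pair<int, int> > > touch;

  double dist(int i, int j) const {
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double term_energy(int type, int row) const {
    switch (type) {
    case 0: { // bond
      double d = dist((int)bonds(row, 0) - 1, (int)bonds(row, 1) - 1) -
                 bonds(row, 3);
      return bonds(row, 2) * d * d;
    }
    case 1: { // gaussian pair
      double r = dist((int)pairs(row, 0) - 1, (int)pairs(row, 1) - 1);
      double s = pairs(row, 3);
      return pairs(row, 2) * std::exp(-r * r / (2.0 * s * s));
    }
    case 2: { // coordinate double-well
      int i = (int)dwells(row, 0) - 1, ax = (int)dwells(row, 1) - 1;
      double s = x[3 * i + ax] - dwells(row, 3);
      double w2 = dwells(row, 4) * dwells(row, 4);
      double q = (s * s - w2) / w2;
      return dwells(row, 2) * q * q + dwells(row, 5) * s;
    }
    case 3: { // coordinate harmonic
      int i = (int)harm(row, 0) - 1, ax = (int)harm(row, 1) - 1;
      double d = x[3 * i + ax] - harm(row, 3);
      return harm(row, 2) * d * d;
    }
    case 4: { // flat-bottom distance restraint
      double r = dist((int)fbs(row, 0) - 1, (int)fbs(row, 1) - 1);
      return fb_pen(r, fbs(row, 2), fbs(row, 3), fbs(row, 4));
    }
    default: { // COM axis box (row indexes coms; uses cached comval)
      const ComTerm &c = coms[row];
      return fb_pen(comval[row], c.lo, c.hi, c.k);
    }
    }
  }
  double particle_energy(int p) const {
    double e = 0.0;
    for (size_t t = 0; t < touch[p].size(); ++t)
      e += term_energy(touch[p][t].first, touch[p][t].second);
    return e;
  }
  double full_energy() {
    double e = 0.0;
    for (size_t r = 0; r < coms.size(); ++r) { // refresh COM caches
      const ComTerm &c = coms[r];
      double v = 0.0;
      for (size_t a = 0; a < c.idx.size(); ++a)
        v += c.mfrac[a] * x[3 * c.idx[a] + c.axis];
      comval[r] = v;
    }
    for (int r = 0; r < bonds.nrow(); ++r) e += term_energy(0, r);
    for (int r = 0; r < pairs.nrow(); ++r) e += term_energy(1, r);
    for (int r = 0; r < dwells.nrow(); ++r) e += term_energy(2, r);
    for (int r = 0; r < harm.nrow(); ++r) e += term_energy(3, r);
    for (int r = 0; r < fbs.nrow(); ++r) e += term_energy(4, r);
    for (size_t r = 0; r < coms.size(); ++r) e += term_energy(5, (int)r);
    return e;
  }
};

} // namespace

// [[Rcpp::export(name = ".mc_sample_cpp")]]
List mc_sample_cpp(NumericMatrix coords0, NumericMatrix mobile,
                   NumericVector masses,
                   NumericMatrix bonds, NumericMatrix pairs,
                   NumericMatrix dwells, NumericMatrix harm,
                   NumericMatrix fbs, List combox,
                   NumericVector biasE, NumericVector biasEmc,
                   double T_mc, int n_sweeps, int save_every,
                   double step, double seed, bool quench) {
  System S;
  S.n = coords0.nrow();
  S.x.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) S.x[3 * i + a] = coords0(i, a);
  S.bonds = bonds; S.pairs = pairs; S.dwells = dwells; S.harm = harm;
  S.fbs = fbs;
  for (int r = 0; r < combox.size(); ++r) {
    List cb = combox[r];
    ComTerm c;
    IntegerVector idx = cb["group"];
    double M = 0.0;
    for (int a = 0; a < idx.size(); ++a) M += masses[idx[a] - 1];
    for (int a = 0; a < idx.size(); ++a) {
      c.idx.push_back(idx[a] - 1);
      c.mfrac.push_back(masses[idx[a] - 1] / M);
    }
    c.axis = (int)as<double>(cb["axis"]) - 1;
    c.lo = as<double>(cb["lo"]); c.hi = as<double>(cb["hi"]);
    c.k = as<double>(cb["k"]);
    S.coms.push_back(c);
  }
  S.comval.resize(S.coms.size(), 0.0);

  S.touch.resize(S.n);
  for (int r = 0; r < bonds.nrow(); ++r) {
    S.touch[(int)bonds(r, 0) - 1].push_back(std::make_pair(0, r));
    S.touch[(int)bonds(r, 1) - 1].push_back(std::make_pair(0, r));
  }
  for (int r = 0; r < pairs.nrow(); ++r) {
    S.touch[(int)pairs(r, 0) - 1].push_back(std::make_pair(1, r));
    S.touch[(int)pairs(r, 1) - 1].push_back(std::make_pair(1, r));
  }
  for (int r = 0; r < dwells.nrow(); ++r)
    S.touch[(int)dwells(r, 0) - 1].push_back(std::make_pair(2, r));
  for (int r = 0; r < harm.nrow(); ++r)
    S.touch[(int)harm(r, 0) - 1].push_back(std::make_pair(3, r));
  for (int r = 0; r < fbs.nrow(); ++r) {
    S.touch[(int)fbs(r, 0) - 1].push_back(std::make_pair(4, r));
    S.touch[(int)fbs(r, 1) - 1].push_back(std::make_pair(4, r));
  }
  for (size_t r = 0; r < S.coms.size(); ++r)
    for (size_t a = 0; a < S.coms[r].idx.size(); ++a)
      S.touch[S.coms[r].idx[a]].push_back(std::make_pair(5, (int)r));

  Bias B;
  B.identity = (biasE.size() < 2);
  if (!B.identity) {
    B.E.assign(biasE.begin(), biasE.end());
    B.Emc.assign(biasEmc.begin(), biasEmc.end());
  }

  std::vector<int> movers;
  for (int i = 0; i < S.n; ++i) {
    bool any = false;
    for (int a = 0; a < 3; ++a) if (mobile(i, a) != 0) any = true;
    if (any) movers.push_back(i);
  }
  if (movers.empty()) stop("system has no mobile coordinates");

  Xoshiro rng((uint64_t)(seed < 0 ? -seed + 0.5 : seed + 0.5) + 0x5DEECE66DULL);
  double beta = (T_mc > 0) ? 1.0 / (GAS_R * T_mc) : 0.0;

  double E = S.full_energy();
  if (!std::isfinite(E)) stop("non-finite energy at the initial configuration");

  int n_save = n_sweeps / save_every;
  NumericMatrix out_coords(n_save, 3 * S.n);
  NumericVector out_energy(n_save);
  long accepted = 0, attempted = 0;
  int isave = 0;

  std::vector<double> newcom(S.coms.size());
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (size_t mi = 0; mi < movers.size(); ++mi) {
      int p = movers[mi];
      double old_xyz[3];
      double d[3] = {0, 0, 0};
      for (int a = 0; a < 3; ++a) {
        old_xyz[a] = S.x[3 * p + a];
        if (mobile(p, a) != 0) d[a] = step * rng.gauss();
      }
      double e_old = S.particle_energy(p);
      // COM caches for terms touching p must be updated for the trial
      for (size_t t = 0; t < S.touch[p].size(); ++t) {
        if (S.touch[p][t].first == 5) {
          int r = S.touch[p][t].second;
          const ComTerm &c = S.coms[r];
          double mf = 0.0;
          for (size_t a = 0; a < c.idx.size(); ++a)
            if (c.idx[a] == p) mf = c.mfrac[a];
          newcom[r] = S.comval[r] + mf * d[c.axis];
        }
      }
      for (int a = 0; a < 3; ++a) S.x[3 * p + a] = old_xyz[a] + d[a];
      std::vector<double> savedcom;
      for (size_t t = 0; t < S.touch[p].size(); ++t) {
        if (S.touch[p][t].first == 5) {
          int r = S.touch[p][t].second;
          savedcom.push_back(S.comval[r]);
          S.comval[r] = newcom[r];
        }
      }
      double e_new = S.particle_energy(p);
      double dE = e_new - e_old;
      double dB = quench ? dE : (B.value(E + dE) - B.value(E));
      ++attempted;
      bool accept;
      if (quench) accept = (dB <= 0.0);
      else accept = (dB <= 0.0) || (rng.unif() < std::exp(-beta * dB));
      if (accept) {
        E += dE;
        ++accepted;
      } else {
        for (int a = 0; a < 3; ++a) S.x[3 * p + a] = old_xyz[a];
        size_t ci = 0;
        for (size_t t = 0; t < S.touch[p].size(); ++t)
          if (S.touch[p][t].first == 5)
            S.comval[S.touch[p][t].second] = savedcom[ci++];
      }
    }
    if (sweep % save_every == 0 && isave < n_save) {
      E = S.full_energy(); // exact refresh, avoids drift
      for (int i = 0; i < 3 * S.n; ++i) out_coords(isave, i) = S.x[i];
      out_energy[isave] = E;
      ++isave;
    }
  }

  return List::create(_["coords"] = out_coords, _["energy"] = out_energy,
                      _["acceptance"] = (double)accepted / (double)attempted);
}
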