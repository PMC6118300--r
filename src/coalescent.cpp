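// Coalescent-with-recombination engine (Hudson algorithm) plus two small
// Wright-Fisher simulators used as independent oracles by the test suite.
//
// Conventions (ms-compatible):
//   * time is measured in units of 4*N0 generations;
//   * a pair of lineages in deme k (relative size x_k) coalesces at rate 2/x_k;
//   * a lineage in deme i migrates (backwards in time) to deme j at rate
//     M[i][j], where M = 4*N0*m as set by -m / the trailing -I rate;
//   * crossovers occur on a lineage at rate rho * span, where span is the
//     extent of its ancestral material (trapped non-ancestral material
//     included, as in ms) and positions live on [0, 1);
//   * mutations fall on a branch at rate theta per unit time per unit of
//     carried ancestral length (infinite sites), so E[S] = theta * sum(1/i).
//
// RNG: xoshiro256++ seeded through splitmix64. Each replicate gets its own
// stream derived from (root seed, replicate index), so replicates are
// individually reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double expo(double rate) { return -std::log(unif_pos()) / rate; }
  int unif_int(int n) {  // uniform on 0..n-1
    return static_cast<int>(unif() * n) % n;
  }
  int pois_small(double lambda) {  // Knuth, lambda <= ~30
    if (lambda <= 0.0) return 0;
    const double limit = std::exp(-lambda);
    double p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif_pos();
    } while (p > limit);
    return k - 1;
  }
  int pois(double lambda) {
    int total = 0;
    while (lambda > 30.0) {  // sum of independent Poissons
      total += pois_small(30.0);
      lambda -= 30.0;
    }
    return total + pois_small(lambda);
  }
  double norm() {  // Box-Muller
    const double u1 = unif_pos(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  // Binomial(n, p): exact inversion for small mean, normal approximation
  // otherwise (used only by the forward Wright-Fisher oracle).
  int binom(int n, double p) {
    if (p <= 0.0) return 0;
    if (p >= 1.0) return n;
    bool flip = p > 0.5;
    double q = flip ? 1.0 - p : p;
    double mean = n * q;
    int k;
    if (mean < 30.0) {
      // inversion via geometric skips
      const double lq = std::log(1.0 - q);
      k = 0;
      int pos = 0;
      while (true) {
        pos += 1 + static_cast<int>(std::log(unif_pos()) / lq);
        if (pos > n) break;
        ++k;
      }
    } else {
      const double sd = std::sqrt(n * q * (1.0 - q));
      double draw = std::floor(mean + sd * norm() + 0.5);
      if (draw < 0.0) draw = 0.0;
      if (draw > n) draw = n;
      k = static_cast<int>(draw);
    }
    return flip ? n - k : k;
  }
};

uint64_t replicate_seed(double root_seed, int rep_index) {
  uint64_t base = static_cast<uint64_t>(root_seed);
  return base * 0x9e3779b97f4a7c15ULL + static_cast<uint64_t>(rep_index) + 1ULL;
}

typedef std::vector<uint64_t> Mask;

struct Seg {
  double l, r;
  Mask mask;
};

struct Lin {
  double birth;
  int deme;
  std::vector<Seg> segs;
  double span() const { return segs.back().r - segs.front().l; }
};

struct Mut {
  double pos;
  Mask mask;
};

inline bool mask_full(const Mask& m, const Mask& all) {
  for (size_t w = 0; w < m.size(); ++w)
    if (m[w] != all[w]) return false;
  return true;
}

inline bool mask_equal(const Mask& a, const Mask& b) {
  for (size_t w = 0; w < a.size(); ++w)
    if (a[w] != b[w]) return false;
  return true;
}

void push_seg(std::vector<Seg>& out, double l, double r, const Mask& mask) {
  if (r <= l) return;
  if (!out.empty() && out.back().r == l && mask_equal(out.back().mask, mask)) {
    out.back().r = r;  // coalesce adjacent equal-mask pieces
    return;
  }
  Seg s;
  s.l = l;
  s.r = r;
  s.mask = mask;
  out.push_back(s);
}

// Merge the ancestral material of two coalescing lineages; intervals where
// the union covers the whole sample have reached their MRCA and are dropped.
std::vector<Seg> merge_segs(std::vector<Seg> a, std::vector<Seg> b,
                            const Mask& all) {
  std::vector<Seg> out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    Seg& sa = a[i];
    Seg& sb = b[j];
    if (sa.r <= sb.l) {
      push_seg(out, sa.l, sa.r, sa.mask);
      ++i;
    } else if (sb.r <= sa.l) {
      push_seg(out, sb.l, sb.r, sb.mask);
      ++j;
    } else if (sa.l < sb.l) {
      push_seg(out, sa.l, sb.l, sa.mask);
      sa.l = sb.l;
    } else if (sb.l < sa.l) {
      push_seg(out, sb.l, sa.l, sb.mask);
      sb.l = sa.l;
    } else {
      const double e = std::min(sa.r, sb.r);
      Mask u(sa.mask.size());
      for (size_t w = 0; w < u.size(); ++w) u[w] = sa.mask[w] | sb.mask[w];
      if (!mask_full(u, all)) push_seg(out, sa.l, e, u);
      const bool adv_a = (sa.r == e), adv_b = (sb.r == e);
      if (adv_a) ++i; else sa.l = e;
      if (adv_b) ++j; else sb.l = e;
    }
  }
  for (; i < a.size(); ++i) push_seg(out, a[i].l, a[i].r, a[i].mask);
  for (; j < b.size(); ++j) push_seg(out, b[j].l, b[j].r, b[j].mask);
  return out;
}

void emit_mutations(const Lin& lin, double t_death, double theta, Rng& rng,
                    std::vector<Mut>& muts) {
  const double dt = t_death - lin.birth;
  if (dt <= 0.0 || theta <= 0.0) return;
  for (const Seg& s : lin.segs) {
    const int k = rng.pois(theta * dt * (s.r - s.l));
    for (int m = 0; m < k; ++m) {
      Mut mu;
      mu.pos = s.l + rng.unif() * (s.r - s.l);
      mu.mask = s.mask;
      muts.push_back(mu);
    }
  }
}

struct DemEvent {
  double time;
  int type;  // 0 = -en (size change), 1 = -ej (deme join)
  int deme;  // 0-based
  double x;  // new size (en) or destination deme as double (ej)
};

}  // namespace

// Simulate one replicate. Returns list(positions, alleles) with positions in
// [0, 1) sorted increasing and alleles an integer matrix (haplotype x site,
// 1 = derived). Demes are assigned in sample order: the first n1 haplotypes
// belong to deme 1, the next n2 to deme 2, and so on.
// [[Rcpp::export]]
List sim_replicate_cpp(IntegerVector deme_sizes, double theta, double rho,
                       NumericMatrix mig, NumericMatrix events,
                       NumericVector sizes_now, double root_seed,
                       int rep_index, double max_events) {
  const int npop = deme_sizes.size();
  int n_sam = 0;
  for (int k = 0; k < npop; ++k) n_sam += deme_sizes[k];
  if (n_sam < 2) stop("need at least two sampled haplotypes");
  const int words = (n_sam + 63) / 64;

  Mask all(words, 0ULL);
  for (int i = 0; i < n_sam; ++i) all[i / 64] |= (1ULL << (i % 64));

  Rng rng(replicate_seed(root_seed, rep_index));

  // demography state
  std::vector<double> x(npop);
  for (int k = 0; k < npop; ++k) x[k] = sizes_now[k];
  std::vector<std::vector<double> > M(npop, std::vector<double>(npop, 0.0));
  for (int i = 0; i < npop; ++i)
    for (int j = 0; j < npop; ++j) M[i][j] = mig(i, j);

  std::vector<DemEvent> evs;
  for (int e = 0; e < events.nrow(); ++e) {
    DemEvent de;
    de.time = events(e, 0);
    de.type = static_cast<int>(events(e, 1));
    de.deme = static_cast<int>(events(e, 2));
    de.x = events(e, 3);
    evs.push_back(de);
  }
  std::sort(evs.begin(), evs.end(),
            [](const DemEvent& a, const DemEvent& b) { return a.time < b.time; });

  // lineages
  std::vector<Lin> lins;
  lins.reserve(2 * n_sam);
  std::vector<int> n_deme(npop, 0);
  int sample_index = 0;
  for (int k = 0; k < npop; ++k) {
    for (int c = 0; c < deme_sizes[k]; ++c) {
      Lin ln;
      ln.birth = 0.0;
      ln.deme = k;
      Seg s;
      s.l = 0.0;
      s.r = 1.0;
      s.mask.assign(words, 0ULL);
      s.mask[sample_index / 64] |= (1ULL << (sample_index % 64));
      ln.segs.push_back(s);
      lins.push_back(ln);
      ++n_deme[k];
      ++sample_index;
    }
  }

  double total_span = static_cast<double>(n_sam);
  std::vector<Mut> muts;
  double t = 0.0;
  size_t next_ev = 0;
  double n_events = 0.0;

  auto destroy = [&](int idx, double at) {
    emit_mutations(lins[idx], at, theta, rng, muts);
    --n_deme[lins[idx].deme];
    total_span -= lins[idx].span();
    lins[idx] = lins.back();
    lins.pop_back();
  };

  while (!lins.empty()) {
    if (++n_events > max_events)
      stop("event budget exceeded (%.0f events): model may not coalesce",
           max_events);
    if ((static_cast<long long>(n_events) & 0xFFF) == 0) {
      // refresh the running span sum to cancel floating-point drift
      total_span = 0.0;
      for (const Lin& ln : lins) total_span += ln.span();
    }

    double coal_rate = 0.0;
    for (int k = 0; k < npop; ++k)
      if (n_deme[k] > 1) coal_rate += n_deme[k] * (n_deme[k] - 1.0) / x[k];
    double rec_rate = rho > 0.0 ? rho * total_span : 0.0;
    double mig_rate = 0.0;
    std::vector<double> mig_out(npop, 0.0);
    for (int i = 0; i < npop; ++i) {
      for (int j = 0; j < npop; ++j) mig_out[i] += M[i][j];
      mig_rate += n_deme[i] * mig_out[i];
    }
    const double total_rate = coal_rate + rec_rate + mig_rate;

    double t_next;
    if (total_rate > 0.0) {
      t_next = t + rng.expo(total_rate);
    } else if (next_ev < evs.size()) {
      t_next = evs[next_ev].time + 1.0;  // jump to the event
    } else {
      stop("no possible events but %d lineages remain (isolated demes?)",
           static_cast<int>(lins.size()));
    }

    if (next_ev < evs.size() && evs[next_ev].time <= t_next) {
      t = evs[next_ev].time;
      const DemEvent& de = evs[next_ev];
      if (de.type == 0) {
        x[de.deme] = de.x;
      } else {
        const int dest = static_cast<int>(de.x);
        for (Lin& ln : lins) {
          if (ln.deme == de.deme) {
            ln.deme = dest;
            --n_deme[de.deme];
            ++n_deme[dest];
          }
        }
        // the joined deme no longer exists further back in time
        for (int k = 0; k < npop; ++k) {
          M[k][de.deme] = 0.0;
          M[de.deme][k] = 0.0;
        }
      }
      ++next_ev;
      continue;
    }
    t = t_next;

    double u = rng.unif() * total_rate;
    if (u < coal_rate) {
      // pick the deme, then an unordered pair within it
      int deme = -1, last_valid = -1;
      double acc = 0.0;
      for (int k = 0; k < npop; ++k) {
        if (n_deme[k] > 1) {
          acc += n_deme[k] * (n_deme[k] - 1.0) / x[k];
          last_valid = k;
        }
        if (u < acc) { deme = k; break; }
      }
      if (deme < 0) deme = last_valid;
      int ia, ib;
      do { ia = rng.unif_int(lins.size()); } while (lins[ia].deme != deme);
      do { ib = rng.unif_int(lins.size()); } while (ib == ia || lins[ib].deme != deme);
      std::vector<Seg> merged = merge_segs(lins[ia].segs, lins[ib].segs, all);
      const double birth = t;
      // destroy the higher index first so swap-removal keeps the other valid
      const int hi = std::max(ia, ib), lo = std::min(ia, ib);
      destroy(hi, t);
      destroy(lo, t);
      if (!merged.empty()) {
        Lin child;
        child.birth = birth;
        child.deme = deme;
        child.segs = std::move(merged);
        total_span += child.span();
        ++n_deme[deme];
        lins.push_back(std::move(child));
      }
    } else if (u < coal_rate + rec_rate) {
      // rejection-sample a lineage with probability proportional to span
      int idx;
      do {
        idx = rng.unif_int(lins.size());
      } while (rng.unif() >= lins[idx].span());
      const Lin& parent = lins[idx];
      const double b =
          parent.segs.front().l + rng.unif() * parent.span();
      Lin left, right;
      left.birth = right.birth = t;
      left.deme = right.deme = parent.deme;
      for (const Seg& s : parent.segs) {
        if (s.r <= b) {
          left.segs.push_back(s);
        } else if (s.l >= b) {
          right.segs.push_back(s);
        } else {
          Seg sl = s, sr = s;
          sl.r = b;
          sr.l = b;
          left.segs.push_back(sl);
          right.segs.push_back(sr);
        }
      }
      if (left.segs.empty() || right.segs.empty()) continue;  // no-op split
      const int deme = parent.deme;
      destroy(idx, t);
      total_span += left.span() + right.span();
      n_deme[deme] += 2;
      lins.push_back(std::move(left));
      lins.push_back(std::move(right));
    } else {
      // migration: pick source deme, then destination
      u -= coal_rate + rec_rate;
      int src = -1;
      double acc = 0.0;
      for (int i = 0; i < npop; ++i) {
        acc += n_deme[i] * mig_out[i];
        if (u < acc) { src = i; break; }
      }
      if (src < 0 || n_deme[src] == 0) continue;
      double v = rng.unif() * mig_out[src];
      int dst = -1;
      double acc2 = 0.0;
      for (int j = 0; j < npop; ++j) {
        acc2 += M[src][j];
        if (v < acc2) { dst = j; break; }
      }
      if (dst < 0) continue;
      int idx;
      do { idx = rng.unif_int(lins.size()); } while (lins[idx].deme != src);
      lins[idx].deme = dst;
      --n_deme[src];
      ++n_deme[dst];
    }
  }

  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  const int S = static_cast<int>(muts.size());
  NumericVector positions(S);
  IntegerMatrix alleles(n_sam, S);
  for (int s = 0; s < S; ++s) {
    positions[s] = muts[s].pos;
    const Mask& m = muts[s].mask;
    for (int i = 0; i < n_sam; ++i)
      if (m[i / 64] & (1ULL << (i % 64))) alleles(i, s) = 1;
  }
  return List::create(_["positions"] = positions, _["alleles"] = alleles);
}

// Discrete-generation Wright-Fisher oracle for the segregating-site count:
// genealogy of n genes in a population of 2N genes, one pair coalescing per
// generation with probability choose(k,2)/(2N) (geometric waiting times),
// mutations Poisson(total branch generations * theta/(4N)). Used by tests as
// an implementation-independent check of the coalescent engine.
// [[Rcpp::export]]
IntegerVector wf_seg_sites_cpp(int n, double theta, int N, int n_reps,
                               double root_seed) {
  IntegerVector out(n_reps);
  const double mu = theta / (4.0 * N);
  for (int rep = 0; rep < n_reps; ++rep) {
    Rng rng(replicate_seed(root_seed, rep));
    double total_gens = 0.0;
    int k = n;
    while (k > 1) {
      const double p = k * (k - 1.0) / 2.0 / (2.0 * N);
      // geometric number of generations until this pair coalesces
      const int gens = 1 + static_cast<int>(std::log(rng.unif_pos()) /
                                            std::log(1.0 - p));
      total_gens += static_cast<double>(k) * gens;
      --k;
    }
    out[rep] = rng.pois(mu * total_gens);
  }
  return out;
}

// Forward Wright-Fisher age-at-frequency oracle: a single copy in a
// population of 2N genes drifts under binomial resampling; every generation
// the allele is observed at one of the target counts contributes one visit
// with the allele's current age. The per-target mean visit age estimates
// E[age | current count = j], the quantity the Kimura-Ohta expected-age
// formula describes.
// [[Rcpp::export]]
List wf_age_at_count_cpp(int N, IntegerVector targets, double n_attempts,
                         double root_seed) {
  const int two_n = 2 * N;
  const int k = targets.size();
  std::vector<double> sum_age(k, 0.0), n_visit(k, 0.0);
  for (double a = 0; a < n_attempts; a += 1.0) {
    Rng rng(replicate_seed(root_seed, static_cast<int>(a)));
    int j = 1;
    double gens = 0.0;
    while (j > 0 && j < two_n) {
      j = rng.binom(two_n, static_cast<double>(j) / two_n);
      gens += 1.0;
      if (j > 0 && j < two_n) {
        for (int t = 0; t < k; ++t) {
          if (j == targets[t]) {
            sum_age[t] += gens;
            n_visit[t] += 1.0;
          }
        }
      }
      if (gens > 400.0 * N) break;
    }
  }
  return List::create(_["sum_age"] = wrap(sum_age),
                      _["n_visits"] = wrap(n_visit));
}

// Forward Wright-Fisher conditional first-passage oracle: a single copy in a
// population of 2N genes drifts under binomial resampling; returns the number
// of generations to first reach frequency >= x for trajectories that do.
// Trajectories are attempted until n_success successes or max_attempts.
// [[Rcpp::export]]
NumericVector wf_first_passage_cpp(int N, double x_target, int n_success,
                                   double max_attempts, double root_seed) {
  std::vector<double> times;
  const int two_n = 2 * N;
  const int target = static_cast<int>(std::ceil(x_target * two_n));
  double attempts = 0.0;
  uint64_t stream = 0;
  while (static_cast<int>(times.size()) < n_success && attempts < max_attempts) {
    attempts += 1.0;
    Rng rng(replicate_seed(root_seed, static_cast<int>(stream++)));
    int j = 1;
    double gens = 0.0;
    while (j > 0 && j < target) {
      j = rng.binom(two_n, static_cast<double>(j) / two_n);
      gens += 1.0;
      if (gens > 400.0 * N) break;  // pathological wander guard
    }
    if (j >= target) times.push_back(gens);
  }
  return wrap(times);
}
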