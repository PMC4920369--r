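// Forward-time individual-based engine for the two-habitat life cycle:
// public-goods game -> fecundity-proportional offspring -> migration ->
// random mating with cue-modifier recombination in the dispersal pool ->
// group founding to capacity -> one asexual generation.
//
// Haploid individuals carry one cue allele (0/1) and a vector of real-valued
// modifier alleles. Locus roles encode the genotype-phenotype map:
//   0 ag additive            1 a0 additive (raw)
//   2 a0 positive-expression 3 a0 negative-expression (expression = max(v,0))
//   4 threshold on the positive set   5 threshold on the negative set
// All randomness comes from R's RNG, so set.seed() governs trajectories.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  // per habitat: cue[ind], genome[ind*L + l]
  std::vector<int> cue[2];
  std::vector<double> genome[2];
};

inline double sigmoid(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

inline int sample_weighted(const std::vector<double> &cum, double total) {
  double r = unif_rand() * total;
  return std::upper_bound(cum.begin(), cum.end(), r) - cum.begin();
}

} // namespace

// [[Rcpp::export(name = ".ibm_run")]]
List ibm_run(IntegerVector N, IntegerVector cap,
             NumericVector W, NumericVector b, NumericVector cc,
             NumericMatrix M, int cycles, int record_every,
             IntegerVector locus_role, NumericVector rec,
             NumericVector mut_rate, NumericVector mut_sd,
             double a0_fixed, double cue_flip, NumericVector xval,
             IntegerVector init_cue1, IntegerVector init_cue2,
             NumericMatrix init_genome1, NumericMatrix init_genome2) {
  RNGScope scope;
  const int L = locus_role.size();
  const bool has_thr_pos = std::find(locus_role.begin(), locus_role.end(), 4) != locus_role.end();
  const bool has_thr_neg = std::find(locus_role.begin(), locus_role.end(), 5) != locus_role.end();

  Pop pop, next;
  for (int h = 0; h < 2; ++h) {
    if (cap[h] % N[h] != 0) stop("capacity not divisible by group size");
    pop.cue[h].resize(cap[h]);
    pop.genome[h].resize((size_t)cap[h] * L);
    next.cue[h].resize(cap[h]);
    next.genome[h].resize((size_t)cap[h] * L);
  }
  for (int i = 0; i < cap[0]; ++i) pop.cue[0][i] = init_cue1[i];
  for (int i = 0; i < cap[1]; ++i) pop.cue[1][i] = init_cue2[i];
  for (int i = 0; i < cap[0]; ++i)
    for (int l = 0; l < L; ++l) pop.genome[0][(size_t)i * L + l] = init_genome1(l, i);
  for (int i = 0; i < cap[1]; ++i)
    for (int l = 0; l < L; ++l) pop.genome[1][(size_t)i * L + l] = init_genome2(l, i);

  // scratch
  std::vector<double> z[2], liab[2], a0v[2], agv[2], fec[2];
  for (int h = 0; h < 2; ++h) {
    z[h].resize(cap[h]); liab[h].resize(cap[h]);
    a0v[h].resize(cap[h]); agv[h].resize(cap[h]); fec[h].resize(cap[h]);
  }
  const int ntot = cap[0] + cap[1];
  std::vector<double> cum(ntot);
  std::vector<int> fndr_cue(std::max(N[0], N[1]));
  std::vector<double> fndr_gen((size_t)std::max(N[0], N[1]) * L);

  auto phenotypes = [&](const Pop &p) {
    for (int h = 0; h < 2; ++h) {
      for (int i = 0; i < cap[h]; ++i) {
        const double *g = &p.genome[h][(size_t)i * L];
        double a0 = a0_fixed, ag = 0.0, sp = 0.0, sn = 0.0, tp = 0.0, tn = 0.0;
        for (int l = 0; l < L; ++l) {
          switch (locus_role[l]) {
          case 0: ag += g[l]; break;
          case 1: a0 += g[l]; break;
          case 2: sp += std::max(g[l], 0.0); break;
          case 3: sn += std::max(g[l], 0.0); break;
          case 4: tp += g[l]; break;
          case 5: tn += g[l]; break;
          }
        }
        if (has_thr_pos) sp = std::min(sp, std::max(tp, 0.0));
        if (has_thr_neg) sn = std::min(sn, std::max(tn, 0.0));
        a0 += sp - sn;
        a0v[h][i] = a0; agv[h][i] = ag;
        liab[h][i] = a0 + ag * xval[p.cue[h][i]];
        z[h][i] = sigmoid(liab[h][i]);
      }
    }
  };

  // trajectory: cycle, f1_h1, f1_h2, mz[h][k] (4), mz_x1, mz_x2,
  //             mean_a0, sd_a0, mean_ag, sd_ag, mean_z, sd_z
  const int NSTAT = 15;
  std::vector<double> traj;
  auto record = [&](int cycle) {
    double cnt[2][2] = {{0, 0}, {0, 0}}, sz[2][2] = {{0, 0}, {0, 0}};
    double sa0 = 0, sa02 = 0, sag = 0, sag2 = 0, szz = 0, szz2 = 0;
    for (int h = 0; h < 2; ++h)
      for (int i = 0; i < cap[h]; ++i) {
        int k = pop.cue[h][i];
        cnt[h][k] += 1; sz[h][k] += z[h][i];
        sa0 += a0v[h][i]; sa02 += a0v[h][i] * a0v[h][i];
        sag += agv[h][i]; sag2 += agv[h][i] * agv[h][i];
        szz += z[h][i];   szz2 += z[h][i] * z[h][i];
      }
    traj.push_back(cycle);
    traj.push_back(cnt[0][0] / cap[0]);
    traj.push_back(cnt[1][0] / cap[1]);
    for (int h = 0; h < 2; ++h)
      for (int k = 0; k < 2; ++k)
        traj.push_back(cnt[h][k] > 0 ? sz[h][k] / cnt[h][k] : NA_REAL);
    for (int k = 0; k < 2; ++k) {
      double n = cnt[0][k] + cnt[1][k];
      traj.push_back(n > 0 ? (sz[0][k] + sz[1][k]) / n : NA_REAL);
    }
    double mn = sa0 / ntot;
    traj.push_back(mn);
    traj.push_back(std::sqrt(std::max(sa02 / ntot - mn * mn, 0.0)));
    mn = sag / ntot;
    traj.push_back(mn);
    traj.push_back(std::sqrt(std::max(sag2 / ntot - mn * mn, 0.0)));
    mn = szz / ntot;
    traj.push_back(mn);
    traj.push_back(std::sqrt(std::max(szz2 / ntot - mn * mn, 0.0)));
  };

  phenotypes(pop);
  record(0);

  for (int t = 1; t <= cycles; ++t) {
    // (i) game: fecundity proportional to clamped payoff
    for (int h = 0; h < 2; ++h) {
      int ng = cap[h] / N[h];
      for (int g = 0; g < ng; ++g) {
        double zbar = 0.0;
        for (int i = 0; i < N[h]; ++i) zbar += z[h][g * N[h] + i];
        zbar /= N[h];
        for (int i = 0; i < N[h]; ++i) {
          int idx = g * N[h] + i;
          double w = W[h] + b[h] * zbar - cc[h] * z[h][idx] * z[h][idx];
          fec[h][idx] = std::max(w, 0.0);
        }
      }
    }
    // (ii)-(iv) per destination habitat: weighted parents -> mating with
    // recombination and mutation -> founders -> asexual offspring
    for (int j = 0; j < 2; ++j) {
      double total = 0.0;
      int pos = 0;
      for (int i = 0; i < 2; ++i) {
        double mji = M(j, i);
        for (int ind = 0; ind < cap[i]; ++ind) {
          total += mji * fec[i][ind];
          cum[pos++] = total;
        }
      }
      if (total <= 0.0) stop("dispersal pool extinct in habitat %d", j + 1);
      int ng = cap[j] / N[j];
      int out = 0;
      for (int g = 0; g < ng; ++g) {
        for (int f = 0; f < N[j]; ++f) {
          int p1 = sample_weighted(cum, total);
          int p2 = sample_weighted(cum, total);
          int h1 = p1 < cap[0] ? 0 : 1, i1 = p1 < cap[0] ? p1 : p1 - cap[0];
          int h2 = p2 < cap[0] ? 0 : 1, i2 = p2 < cap[0] ? p2 : p2 - cap[0];
          // cue donor, then per-locus recombination relative to the cue
          bool first = unif_rand() < 0.5;
          int ch = first ? h1 : h2, ci = first ? i1 : i2;
          int oh = first ? h2 : h1, oi = first ? i2 : i1;
          int cueallele = pop.cue[ch][ci];
          if (cue_flip > 0 && unif_rand() < cue_flip) cueallele = 1 - cueallele;
          fndr_cue[f] = cueallele;
          const double *gc = &pop.genome[ch][(size_t)ci * L];
          const double *go = &pop.genome[oh][(size_t)oi * L];
          double *gf = &fndr_gen[(size_t)f * L];
          for (int l = 0; l < L; ++l) {
            double v = (rec[l] > 0 && unif_rand() < rec[l]) ? go[l] : gc[l];
            if (mut_rate[l] > 0 && unif_rand() < mut_rate[l])
              v += norm_rand() * mut_sd[l];
            gf[l] = v;
          }
        }
        // one asexual generation: each offspring copies a uniform founder
        for (int o = 0; o < N[j]; ++o) {
          int f = (int)(unif_rand() * N[j]);
          if (f == N[j]) f = N[j] - 1;
          next.cue[j][out] = fndr_cue[f];
          std::copy(&fndr_gen[(size_t)f * L], &fndr_gen[(size_t)f * L] + L,
                    &next.genome[j][(size_t)out * L]);
          ++out;
        }
      }
    }
    std::swap(pop.cue[0], next.cue[0]);
    std::swap(pop.cue[1], next.cue[1]);
    std::swap(pop.genome[0], next.genome[0]);
    std::swap(pop.genome[1], next.genome[1]);
    phenotypes(pop);
    if (t % record_every == 0 || t == cycles) record(t);
  }

  int nrec = traj.size() / NSTAT;
  NumericMatrix tm(nrec, NSTAT);
  for (int r = 0; r < nrec; ++r)
    for (int s = 0; s < NSTAT; ++s) tm(r, s) = traj[(size_t)r * NSTAT + s];

  List fin(2);
  for (int h = 0; h < 2; ++h) {
    NumericMatrix G(L, cap[h]);
    for (int i = 0; i < cap[h]; ++i)
      for (int l = 0; l < L; ++l) G(l, i) = pop.genome[h][(size_t)i * L + l];
    fin[h] = List::create(
      _["cue"] = IntegerVector(pop.cue[h].begin(), pop.cue[h].end()),
      _["genome"] = G,
      _["z"] = NumericVector(z[h].begin(), z[h].end()),
      _["liability"] = NumericVector(liab[h].begin(), liab[h].end()),
      _["a0"] = NumericVector(a0v[h].begin(), a0v[h].end()),
      _["ag"] = NumericVector(agv[h].begin(), agv[h].end()));
  }
  return List::create(_["trajectory"] = tm, _["final"] = fin);
}
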