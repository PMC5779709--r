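// Simulation-based estimator of the site likelihood: gene trees are drawn
// under the multispecies network coalescent and, for each, the probability
// of the observed pattern under the two-state mutation model is computed
// (by exact pruning when one lineage is sampled per species, otherwise by
// simulating the mutations).  Entirely independent of the exact
// labeled-partial-likelihood engine; used to validate it.

#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

struct GeneNode {
  double time;
  int c1 = -1, c2 = -1;   // children (-1 for a sampled lineage)
  int species = -1;       // leaf species index
};

// [[Rcpp::export]]
List cpp_site_lik_mc(IntegerVector kind,
                     IntegerVector eparent, IntegerVector echild,
                     NumericVector etheta, NumericVector egamma,
                     NumericVector heights, int root, double root_theta,
                     IntegerVector order_ascending,     // nodes, leaves first
                     IntegerVector leaf_species,        // per node, -1 if not leaf
                     IntegerVector n_per_species,
                     IntegerVector r_per_species,
                     double u, double v,
                     int ntrees, double seed) {
  const int nN = kind.size();
  const int nE = eparent.size();
  const int nsp = n_per_species.size();
  std::vector<std::vector<int>> out_e(nN), in_e(nN);
  for (int e = 0; e < nE; ++e) {
    out_e[eparent[e] - 1].push_back(e);
    in_e[echild[e] - 1].push_back(e);
  }
  bool prune_exact = true;
  for (int s = 0; s < nsp; ++s) if (n_per_species[s] != 1) prune_exact = false;

  const double piR = v / (u + v), piG = u / (u + v), q = u + v;
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::exponential_distribution<double> E1(1.0);

  double sum = 0.0, sumsq = 0.0;
  std::vector<GeneNode> gn;
  std::vector<std::vector<int>> surv(nE);    // survivors at the top of each edge

  for (int it = 0; it < ntrees; ++it) {
    gn.clear();
    for (int e = 0; e < nE; ++e) surv[e].clear();
    int groot = -1;

    auto coalesce = [&](std::vector<int> &L, double t0, double t1, double theta) {
      double t = t0;
      while ((int)L.size() >= 2) {
        const double s = (double)L.size();
        const double rate = s * (s - 1.0) / theta;   // pairwise rate 2/theta
        t += E1(rng) / rate;
        if (t > t1) break;
        int i = (int)(U(rng) * L.size()); if (i >= (int)L.size()) i = L.size() - 1;
        int j = (int)(U(rng) * (L.size() - 1)); if (j >= (int)L.size() - 1) j = L.size() - 2;
        if (j >= i) ++j;
        GeneNode w; w.time = t; w.c1 = L[i]; w.c2 = L[j];
        gn.push_back(w);
        const int id = gn.size() - 1;
        if (i > j) std::swap(i, j);
        L.erase(L.begin() + j); L.erase(L.begin() + i);
        L.push_back(id);
      }
    };

    for (int oi = 0; oi < nN; ++oi) {
      const int vtx = order_ascending[oi] - 1;
      std::vector<int> entering;
      if (kind[vtx] == 0) {                       // leaf: sample lineages
        const int sp = leaf_species[vtx];
        for (int i = 0; i < n_per_species[sp]; ++i) {
          GeneNode g; g.time = 0.0; g.species = sp;
          gn.push_back(g);
          entering.push_back(gn.size() - 1);
        }
      } else {
        for (int e : out_e[vtx])
          for (int id : surv[e]) entering.push_back(id);
      }
      if ((vtx + 1) == root) {
        coalesce(entering, heights[vtx], R_PosInf, root_theta);
        groot = entering[0];
      } else if (kind[vtx] == 2) {                // reticulation: route lineages
        const int e1 = in_e[vtx][0], e2 = in_e[vtx][1];
        const double g = egamma[e1];
        std::vector<int> L1, L2;
        for (int id : entering) (U(rng) < g ? L1 : L2).push_back(id);
        coalesce(L1, heights[vtx], heights[eparent[e1] - 1], etheta[e1]);
        coalesce(L2, heights[vtx], heights[eparent[e2] - 1], etheta[e2]);
        surv[e1] = L1; surv[e2] = L2;
      } else {
        const int e = in_e[vtx][0];
        coalesce(entering, heights[vtx], heights[eparent[e] - 1], etheta[e]);
        surv[e] = entering;
      }
    }

    double p;
    if (prune_exact) {
      // Felsenstein pruning with two states on the realized gene tree;
      // gene nodes were created children-before-parents.
      std::vector<double> LR(gn.size()), LG(gn.size());
      for (size_t i = 0; i < gn.size(); ++i) {
        if (gn[i].c1 < 0) {
          const int red = r_per_species[gn[i].species];
          LR[i] = red ? 1.0 : 0.0;
          LG[i] = red ? 0.0 : 1.0;
        } else {
          double mR = 1.0, mG = 1.0;
          for (int c : {gn[i].c1, gn[i].c2}) {
            const double t = gn[i].time - gn[c].time;
            const double e = std::exp(-q * t);
            const double pRR = piR + piG * e, pRG = piG * (1.0 - e);
            const double pGG = piG + piR * e, pGR = piR * (1.0 - e);
            mR *= pRR * LR[c] + pRG * LG[c];
            mG *= pGR * LR[c] + pGG * LG[c];
          }
          LR[i] = mR; LG[i] = mG;
        }
      }
      p = piR * LR[groot] + piG * LG[groot];
    } else {
      // simulate the mutations once and score the count event
      std::vector<int> state(gn.size());
      for (int i = (int)gn.size() - 1; i >= 0; --i) {
        if (i == groot) state[i] = (U(rng) < piR) ? 1 : 0;
      }
      // propagate from the root down (children have smaller indices)
      std::vector<int> parent(gn.size(), -1);
      for (size_t i = 0; i < gn.size(); ++i)
        if (gn[i].c1 >= 0) { parent[gn[i].c1] = i; parent[gn[i].c2] = i; }
      for (int i = (int)gn.size() - 1; i >= 0; --i) {
        if (i == groot) continue;
        const int pa = parent[i];
        const double t = gn[pa].time - gn[i].time;
        const double e = std::exp(-q * t);
        if (state[pa] == 1) state[i] = (U(rng) < piG * (1.0 - e)) ? 0 : 1;
        else state[i] = (U(rng) < piR * (1.0 - e)) ? 1 : 0;
      }
      std::vector<int> reds(nsp, 0);
      for (size_t i = 0; i < gn.size(); ++i)
        if (gn[i].c1 < 0 && state[i] == 1) reds[gn[i].species] += 1;
      bool match = true;
      for (int s = 0; s < nsp; ++s) if (reds[s] != r_per_species[s]) match = false;
      p = match ? 1.0 : 0.0;
    }
    sum += p; sumsq += p * p;
  }
  const double mean = sum / ntrees;
  const double var = std::max(0.0, sumsq / ntrees - mean * mean);
  return List::create(_["estimate"] = mean,
                      _["se"] = std::sqrt(var / ntrees),
                      _["n_trees"] = ntrees);
}
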