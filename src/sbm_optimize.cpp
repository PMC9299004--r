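// Minimum-description-length optimisation of type-pure block partitions on
// bipartite graphs.  Two objective kinds share one search engine:
//
//  kind A (base level): microcanonical degree-corrected likelihood of the
//    simple bipartite graph, plus degree-sequence and partition priors and
//    a flat edge-matrix closure;
//
//  kind B (upper level): grouping of the previous level's blocks, where
//    the block multigraph's edge counts are described given the grouping
//    (multiset coefficients), plus partition priors and closure.
//
// The search is agglomerative (start from singletons, greedily merge by
// best candidate delta, shrinking the number of blocks by a factor sigma
// per stage) interleaved with single-node Metropolis sweeps at a schedule
// of inverse temperatures; the best state seen anywhere along the
// trajectory is kept.  Randomness comes from R's RNG stream so set.seed()
// fixes the whole search.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double lf(double x) { return std::lgamma(x + 1.0); }
static inline double lms(double n, double m) {
  if (m <= 0.0 || n <= 0.0) return 0.0;
  return ::Rf_lchoose(n + m - 1.0, m);
}
static inline int runif_int(int k) {          // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

struct Engine {
  // problem ------------------------------------------------------------
  int nL, nR, n;
  bool kindA, priorL, priorR, frozenL;
  double npL, npR;        // partition-prior universe size per side
  long long E;
  std::vector<int> ptr, nb;
  std::vector<long long> w;
  std::vector<long long> deg;
  double sigma; int nsweeps; std::vector<double> betas; int ncand;
  double constTerm;

  // state --------------------------------------------------------------
  int BcapL, BcapR, Bcap;
  std::vector<int> b;                 // block id per node (global ids)
  std::vector<long long> ers;         // dense BcapL x BcapR
  std::vector<long long> er;          // block degree sums
  std::vector<int> nr;                // block sizes
  int BL, BR;
  std::vector<std::vector<int>> members;
  std::vector<int> posInBlock;
  std::vector<int> activeL, activeR;  // nonempty blocks per side
  std::vector<int> activePos;
  double dl;

  // scratch
  std::vector<long long> wt;
  std::vector<int> stamp;
  int stampCur = 0;

  // best ---------------------------------------------------------------
  std::vector<int> best_b;
  double best_dl;

  inline long long &ERS(int r, int s) { return ers[(size_t)r * BcapR + (s - BcapL)]; }
  inline int sideOf(int blk) const { return blk < BcapL ? 0 : 1; }

  double blkVal(int side, int nrv, long long erv) const {
    if (nrv <= 0) return 0.0;
    double v = 0.0;
    if (kindA) v += lf((double)erv) + lms((double)nrv, (double)erv);
    if (side == 0 ? priorL : priorR) v -= lf((double)nrv);
    return v;
  }
  double pairVal(int nrl, int nrr, long long e) const {
    if (e <= 0) return 0.0;
    if (kindA) return -lf((double)e);
    return lms((double)nrl * (double)nrr, (double)e);
  }
  double globalVal(int bl, int br) const {
    double v = lms((double)bl * (double)br, (double)E);
    if (priorL) v += ::Rf_lchoose(npL - 1.0, bl - 1.0);
    if (priorR) v += ::Rf_lchoose(npR - 1.0, br - 1.0);
    return v;
  }

  double fullDL() const {
    double v = constTerm + globalVal(BL, BR);
    for (int r = 0; r < BcapL; ++r)
      if (nr[r] > 0) v += blkVal(0, nr[r], er[r]);
    for (int s = BcapL; s < Bcap; ++s)
      if (nr[s] > 0) v += blkVal(1, nr[s], er[s]);
    for (int r = 0; r < BcapL; ++r) {
      if (nr[r] == 0) continue;
      const long long *row = &ers[(size_t)r * BcapR];
      for (int sc = 0; sc < BcapR; ++sc)
        if (row[sc] > 0) v += pairVal(nr[r], nr[BcapL + sc], row[sc]);
    }
    return v;
  }

  void initFrom(const std::vector<int> &b0) {
    b = b0;
    ers.assign((size_t)BcapL * BcapR, 0);
    er.assign(Bcap, 0);
    nr.assign(Bcap, 0);
    members.assign(Bcap, {});
    posInBlock.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      nr[b[i]]++;
      posInBlock[i] = (int)members[b[i]].size();
      members[b[i]].push_back(i);
      er[b[i]] += deg[i];
    }
    for (int i = 0; i < nL; ++i)
      for (int p = ptr[i]; p < ptr[i + 1]; ++p)
        ERS(b[i], b[nb[p]]) += w[p];
    activeL.clear(); activeR.clear();
    activePos.assign(Bcap, -1);
    BL = BR = 0;
    for (int r = 0; r < Bcap; ++r) {
      if (nr[r] == 0) continue;
      if (r < BcapL) { activePos[r] = (int)activeL.size(); activeL.push_back(r); BL++; }
      else           { activePos[r] = (int)activeR.size(); activeR.push_back(r); BR++; }
    }
    dl = fullDL();
  }

  void deactivate(int blk) {
    std::vector<int> &act = sideOf(blk) == 0 ? activeL : activeR;
    int p = activePos[blk];
    int last = act.back();
    act[p] = last; activePos[last] = p;
    act.pop_back(); activePos[blk] = -1;
    if (sideOf(blk) == 0) BL--; else BR--;
  }

  // gather opposite blocks touched by moving node i between r and s;
  // wt[t] holds i's edge weight into t.  For kind B, size changes make
  // every nonzero pair of r and s relevant too.
  std::vector<int> touchedFor(int i, int r, int s) {
    stampCur++;
    std::vector<int> touched;
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      int t = b[nb[p]];
      if (stamp[t] != stampCur) { stamp[t] = stampCur; wt[t] = 0; touched.push_back(t); }
      wt[t] += w[p];
    }
    if (!kindA) {
      const std::vector<int> &opp = (r < BcapL) ? activeR : activeL;
      for (int t : opp) {
        long long e1 = (r < BcapL) ? ERS(r, t) : ERS(t, r);
        long long e2 = (s < BcapL) ? ERS(s, t) : ERS(t, s);
        if ((e1 > 0 || e2 > 0) && stamp[t] != stampCur) {
          stamp[t] = stampCur; wt[t] = 0; touched.push_back(t);
        }
      }
    }
    return touched;
  }

  inline long long ersPair(int a, int t) { return a < BcapL ? ERS(a, t) : ERS(t, a); }

  double deltaMove(int i, int s, const std::vector<int> &touched) {
    int r = b[i];
    int side = sideOf(r);
    long long k = deg[i];
    double d = 0.0;
    d -= blkVal(side, nr[r], er[r]) + blkVal(side, nr[s], er[s]);
    int nr2 = nr[r] - 1, ns2 = nr[s] + 1;
    d += blkVal(side, nr2, er[r] - k) + blkVal(side, ns2, er[s] + k);
    for (int t : touched) {
      long long ert = ersPair(r, t), est = ersPair(s, t);
      d -= pairVal(nr[r], nr[t], ert) + pairVal(nr[s], nr[t], est);
      d += pairVal(nr2, nr[t], ert - wt[t]) + pairVal(ns2, nr[t], est + wt[t]);
    }
    if (nr2 == 0) {
      if (side == 0) d += globalVal(BL - 1, BR) - globalVal(BL, BR);
      else           d += globalVal(BL, BR - 1) - globalVal(BL, BR);
    }
    return d;
  }

  void applyMove(int i, int s, const std::vector<int> &touched) {
    int r = b[i];
    for (int t : touched) {
      if (wt[t] == 0) continue;
      if (r < BcapL) { ERS(r, t) -= wt[t]; ERS(s, t) += wt[t]; }
      else           { ERS(t, r) -= wt[t]; ERS(t, s) += wt[t]; }
    }
    er[r] -= deg[i]; er[s] += deg[i];
    nr[r]--; nr[s]++;
    // members bookkeeping (swap-pop)
    std::vector<int> &mr = members[r];
    int p = posInBlock[i], last = mr.back();
    mr[p] = last; posInBlock[last] = p; mr.pop_back();
    posInBlock[i] = (int)members[s].size();
    members[s].push_back(i);
    b[i] = s;
    if (nr[r] == 0) deactivate(r);
  }

  double deltaMerge(int r, int s, std::vector<int> &touched) {
    // merge r into s, same side
    int side = sideOf(r);
    touched.clear();
    const std::vector<int> &opp = side == 0 ? activeR : activeL;
    for (int t : opp)
      if (ersPair(r, t) > 0 || ersPair(s, t) > 0) touched.push_back(t);
    double d = -blkVal(side, nr[r], er[r]) - blkVal(side, nr[s], er[s])
             + blkVal(side, nr[r] + nr[s], er[r] + er[s]);
    for (int t : touched) {
      long long ert = ersPair(r, t), est = ersPair(s, t);
      d -= pairVal(nr[r], nr[t], ert) + pairVal(nr[s], nr[t], est);
      d += pairVal(nr[r] + nr[s], nr[t], ert + est);
    }
    if (side == 0) d += globalVal(BL - 1, BR) - globalVal(BL, BR);
    else           d += globalVal(BL, BR - 1) - globalVal(BL, BR);
    return d;
  }

  void applyMerge(int r, int s) {
    int side = sideOf(r);
    const std::vector<int> &opp = side == 0 ? activeR : activeL;
    for (int t : opp) {
      long long e = ersPair(r, t);
      if (e > 0) {
        if (r < BcapL) { ERS(r, t) = 0; ERS(s, t) += e; }
        else           { ERS(t, r) = 0; ERS(t, s) += e; }
      }
    }
    er[s] += er[r]; er[r] = 0;
    nr[s] += nr[r]; nr[r] = 0;
    for (int i : members[r]) {
      b[i] = s;
      posInBlock[i] = (int)members[s].size();
      members[s].push_back(i);
    }
    members[r].clear();
    deactivate(r);
  }

  void maybeRecord() {
    if (dl < best_dl - 1e-10) { best_dl = dl; best_b = b; }
  }

  int proposeTarget(int i) {
    int side = i < nL ? 0 : 1;
    const std::vector<int> &act = side == 0 ? activeL : activeR;
    if (act.size() < 2) return -1;
    if (unif_rand() < 0.1) return act[runif_int((int)act.size())];
    // neighbour-of-neighbour informed proposal
    int di = ptr[i + 1] - ptr[i];
    if (di == 0) return -1;
    int j = nb[ptr[i] + runif_int(di)];
    int dj = ptr[j + 1] - ptr[j];
    int i2 = nb[ptr[j] + runif_int(dj)];
    return b[i2];
  }

  void sweep(double beta) {
    // random permutation of movable nodes
    std::vector<int> order;
    order.reserve(n);
    for (int i = frozenL ? nL : 0; i < n; ++i) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i)
      std::swap(order[i], order[runif_int(i + 1)]);
    for (int i : order) {
      int s = proposeTarget(i);
      if (s < 0 || s == b[i]) continue;
      std::vector<int> touched = touchedFor(i, b[i], s);
      double d = deltaMove(i, s, touched);
      bool acc = d < -1e-12;
      if (!acc && R_finite(beta)) acc = unif_rand() < std::exp(-beta * d);
      if (acc) { applyMove(i, s, touched); dl += d; }
    }
    maybeRecord();
  }

  void mergeStage(int side) {
    int B = side == 0 ? BL : BR;
    if (B <= 1) return;
    int Bnext = std::max(1, (int)std::floor(B / sigma));
    if (Bnext == B) Bnext = B - 1;
    int nm = B - Bnext;
    const std::vector<int> &act = side == 0 ? activeL : activeR;
    std::vector<int> blocks(act);
    struct Cand { double d; int r, s; };
    std::vector<Cand> cands;
    std::vector<int> touched;
    for (int r : blocks) {
      double bestd = R_PosInf; int bests = -1;
      for (int c = 0; c < ncand; ++c) {
        int s = -1;
        // sample a partner via a random 2-step walk from a node of r
        const std::vector<int> &mr = members[r];
        if (!mr.empty()) {
          int i = mr[runif_int((int)mr.size())];
          int di = ptr[i + 1] - ptr[i];
          if (di > 0) {
            int j = nb[ptr[i] + runif_int(di)];
            int dj = ptr[j + 1] - ptr[j];
            int i2 = nb[ptr[j] + runif_int(dj)];
            s = b[i2];
          }
        }
        if (s == r || s < 0) {
          const std::vector<int> &a2 = side == 0 ? activeL : activeR;
          if (a2.size() < 2) continue;
          s = a2[runif_int((int)a2.size())];
          if (s == r) continue;
        }
        double d = deltaMerge(r, s, touched);
        if (d < bestd) { bestd = d; bests = s; }
      }
      if (bests >= 0) cands.push_back({bestd, r, bests});
    }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand &a, const Cand &b) { return a.d < b.d; });
    int done = 0;
    for (const Cand &c : cands) {
      if (done >= nm) break;
      if (nr[c.r] == 0 || nr[c.s] == 0 || c.r == c.s) continue;
      double d = deltaMerge(c.r, c.s, touched);   // refresh (earlier merges)
      applyMerge(c.r, c.s);
      dl += d;
      done++;
      maybeRecord();
    }
  }

  bool finished() const {
    bool leftDone = frozenL || BL == 1;
    return leftDone && BR == 1;
  }

  void run(bool agglomerate) {
    best_dl = dl; best_b = b;
    if (agglomerate) {
      int guard = 0;
      while (!finished() && guard++ < 10000) {
        for (double beta : betas)
          for (int t = 0; t < nsweeps; ++t) sweep(beta);
        dl = fullDL();            // guard against numeric drift
        maybeRecord();
        if (!frozenL) mergeStage(0);
        mergeStage(1);
      }
      dl = fullDL();
      maybeRecord();
    } else {
      for (double beta : betas)
        for (int t = 0; t < nsweeps; ++t) sweep(beta);
    }
    // polish: restore best, then greedy sweeps to a local optimum
    initFrom(best_b);
    for (int it = 0; it < 100; ++it) {
      double before = dl;
      sweep(R_PosInf);
      if (dl >= before - 1e-10) break;
    }
    dl = fullDL();
    maybeRecord();
  }
};

// [[Rcpp::export]]
List cpp_fit_level(IntegerMatrix edges, NumericVector weights,
                   int nL, int nR,
                   bool kindA, bool priorL, bool priorR,
                   IntegerVector frozen_left,
                   double npL, double npR,
                   double sigma, int nsweeps, NumericVector betas,
                   int ncand,
                   IntegerVector init_left, IntegerVector init_right,
                   bool agglomerate) {
  Engine eng;
  eng.nL = nL; eng.nR = nR; eng.n = nL + nR;
  eng.kindA = kindA; eng.priorL = priorL; eng.priorR = priorR;
  eng.frozenL = frozen_left.size() > 0;
  eng.npL = npL; eng.npR = npR;
  eng.sigma = sigma; eng.nsweeps = nsweeps; eng.ncand = ncand;
  eng.betas.assign(betas.begin(), betas.end());

  // adjacency (both directions) ---------------------------------------
  int m = edges.nrow();
  std::vector<int> degcnt(eng.n, 0);
  for (int e = 0; e < m; ++e) {
    degcnt[edges(e, 0) - 1]++;
    degcnt[nL + edges(e, 1) - 1]++;
  }
  eng.ptr.assign(eng.n + 1, 0);
  for (int i = 0; i < eng.n; ++i) eng.ptr[i + 1] = eng.ptr[i] + degcnt[i];
  eng.nb.assign(2 * (size_t)m, 0);
  eng.w.assign(2 * (size_t)m, 0);
  std::vector<int> fill(eng.n, 0);
  eng.deg.assign(eng.n, 0);
  eng.E = 0;
  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0) - 1, j = nL + edges(e, 1) - 1;
    long long we = (long long)weights[e];
    eng.nb[eng.ptr[i] + fill[i]] = j; eng.w[eng.ptr[i] + fill[i]] = we; fill[i]++;
    eng.nb[eng.ptr[j] + fill[j]] = i; eng.w[eng.ptr[j] + fill[j]] = we; fill[j]++;
    eng.deg[i] += we; eng.deg[j] += we;
    eng.E += we;
  }

  eng.BcapL = eng.frozenL ? max(frozen_left) : nL;
  if (init_left.size() > 0) eng.BcapL = nL;
  eng.BcapR = nR;
  eng.Bcap = eng.BcapL + eng.BcapR;
  eng.wt.assign(eng.Bcap, 0);
  eng.stamp.assign(eng.Bcap, 0);

  // constants so that the objective equals the full description length
  eng.constTerm = 0.0;
  if (kindA)
    for (int i = 0; i < eng.n; ++i) eng.constTerm -= lf((double)eng.deg[i]);
  if (priorL) eng.constTerm += lf(npL);
  if (priorR) eng.constTerm += lf(npR);

  std::vector<int> b0(eng.n);
  for (int i = 0; i < nL; ++i) {
    if (eng.frozenL) b0[i] = frozen_left[i] - 1;
    else if (init_left.size() > 0) b0[i] = init_left[i] - 1;
    else b0[i] = i;
  }
  for (int i = 0; i < nR; ++i) {
    if (init_right.size() > 0) b0[nL + i] = eng.BcapL + init_right[i] - 1;
    else b0[nL + i] = eng.BcapL + i;
  }
  eng.initFrom(b0);
  eng.run(agglomerate);

  IntegerVector outL(nL), outR(nR);
  for (int i = 0; i < nL; ++i) outL[i] = eng.best_b[i] + 1;
  for (int i = 0; i < nR; ++i) outR[i] = eng.best_b[nL + i] - eng.BcapL + 1;
  return List::create(_["left"] = outL, _["right"] = outR,
                      _["dl"] = eng.best_dl);
}
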