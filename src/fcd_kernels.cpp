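// Inner loops of the FCD graph construction: the supra-threshold scan of
// correlation-matrix blocks and the per-seed cluster growing (BFS over
// the spatial adjacency restricted to the seed's supra-threshold
// partners).

#include <Rcpp.h>
using namespace Rcpp;

// Scan a block of correlation rows for entries strictly above the
// threshold. Returns per-row partner lists (1-based mask indices, the
// self column excluded) and their lengths. rowOffset is the 0-based
// mask index of the block's first row.
// [[Rcpp::export(name = ".supraScan")]]
List supraScan(NumericMatrix C, double threshold, int rowOffset) {
  const int nr = C.nrow(), nc = C.ncol();
  std::vector< std::vector<int> > rows(nr);
  for (int c = 0; c < nc; ++c) {
    const double *col = &C(0, c);
    for (int r = 0; r < nr; ++r) {
      if (col[r] > threshold && (rowOffset + r) != c)
        rows[r].push_back(c + 1);
    }
  }
  IntegerVector counts(nr);
  List cands(nr);
  for (int r = 0; r < nr; ++r) {
    counts[r] = (int) rows[r].size();
    cands[r] = IntegerVector(rows[r].begin(), rows[r].end());
  }
  return List::create(_["counts"] = counts, _["cands"] = cands);
}

// Cluster growing per seed: starting from seed i, repeatedly add any
// voxel that is a supra-threshold partner of i AND neighborhood-adjacent
// to a voxel already in the cluster. cand holds the per-seed partner
// lists (1-based); nbr is the V x K neighbor matrix (0 = none). Returns
// cluster size - 1 per seed (the edge-count convention).
// [[Rcpp::export(name = ".lfcdCounts")]]
IntegerVector lfcdCounts(List cand, IntegerMatrix nbr) {
  const int V = cand.size(), K = nbr.ncol();
  std::vector<char> inCand(V + 1, 0), inClus(V + 1, 0);
  std::vector<int> stack, members;
  stack.reserve(512); members.reserve(512);
  IntegerVector out(V);
  for (int i = 0; i < V; ++i) {
    IntegerVector cv = cand[i];
    const int m = cv.size();
    if (m == 0) { out[i] = 0; continue; }
    for (int k = 0; k < m; ++k) inCand[cv[k]] = 1;
    stack.clear(); members.clear();
    stack.push_back(i + 1);
    members.push_back(i + 1);
    inClus[i + 1] = 1;
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      for (int k = 0; k < K; ++k) {
        const int nb = nbr(v - 1, k);
        if (nb > 0 && inCand[nb] && !inClus[nb]) {
          inClus[nb] = 1;
          stack.push_back(nb);
          members.push_back(nb);
        }
      }
    }
    out[i] = (int) members.size() - 1;
    for (int k = 0; k < m; ++k) inCand[cv[k]] = 0;
    for (size_t k = 0; k < members.size(); ++k) inClus[members[k]] = 0;
  }
  return out;
}
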