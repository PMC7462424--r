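#include <Rcpp.h>
using namespace Rcpp;

// Two-phase greedy Louvain on a dense (generalized) modularity matrix B.
// The quality of a partition M is sum_{ij : M_i == M_j} B_ij, which covers
// the signed Q* quality function once B is assembled in R with the
// asymmetric negative-weight null model. Node order is a fresh seeded
// random permutation each pass (R RNG, so set.seed() controls it); ties in
// the move gain are broken by the first strictly improving community
// encountered in scan order.
// [[Rcpp::export]]
IntegerVector louvain_dense(NumericMatrix B0, double tol = 1e-10) {
  const int n0 = B0.nrow();
  std::vector<int> node2comm(n0);
  for (int i = 0; i < n0; ++i) node2comm[i] = i;
  NumericMatrix B = clone(B0);

  for (;;) {
    const int n = B.nrow();
    std::vector<int> M(n);
    for (int i = 0; i < n; ++i) M[i] = i;

    bool any_move = false;
    bool improved = true;
    while (improved) {
      improved = false;
      IntegerVector ord = sample(n, n, false);
      for (int oi = 0; oi < n; ++oi) {
        const int i = ord[oi] - 1;
        const int cu = M[i];
        // S[c] = sum over j != i with M_j == c of B(i, j)
        std::vector<double> S(n, 0.0);
        for (int j = 0; j < n; ++j) {
          if (j != i) S[M[j]] += B(i, j);
        }
        double best_gain = tol;
        int best_c = -1;
        for (int c = 0; c < n; ++c) {
          if (c == cu) continue;
          const double gain = 2.0 * (S[c] - S[cu]);
          if (gain > best_gain) {
            best_gain = gain;
            best_c = c;
          }
        }
        if (best_c >= 0) {
          M[i] = best_c;
          improved = true;
          any_move = true;
        }
      }
    }

    // renumber communities consecutively by first appearance
    std::vector<int> remap(n, -1);
    int k = 0;
    for (int i = 0; i < n; ++i) {
      if (remap[M[i]] < 0) remap[M[i]] = k++;
      M[i] = remap[M[i]];
    }
    for (int v = 0; v < n0; ++v) node2comm[v] = M[node2comm[v]];

    if (!any_move || k == n) break;

    // aggregate: one node per community, weights summed
    NumericMatrix B2(k, k);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        B2(M[i], M[j]) += B(i, j);
    B = B2;
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = node2comm[i] + 1;
  return out;
}
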