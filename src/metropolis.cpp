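#include <Rcpp.h>
using namespace Rcpp;

// flat index of the unordered state pair {a,b} (0-based, a<=b) in the
// row-major upper-triangular ordering (0,0),(0,1),...,(0,Q-1),(1,1),...
static inline int tri_index(int a, int b, int Q) {
  if (a > b) { int t = a; a = b; b = t; }
  return a * Q - a * (a - 1) / 2 + (b - a);
}

// Count-space observables: per configuration, Q state counts followed by
// the unordered near-neighbour pair counts of each edge class.
// [[Rcpp::export]]
NumericMatrix cpp_count_observables(IntegerMatrix states, int Q,
                                    IntegerMatrix edges, IntegerVector cls,
                                    int nclass) {
  const int nconf = states.nrow();
  const int m = edges.nrow();
  const int ntri = Q * (Q + 1) / 2;
  const int M = Q + nclass * ntri;
  NumericMatrix Y(nconf, M);
  for (int r = 0; r < nconf; ++r) {
    for (int k = 0; k < states.ncol(); ++k) Y(r, states(r, k)) += 1.0;
    for (int e = 0; e < m; ++e) {
      int a = states(r, edges(e, 0));
      int b = states(r, edges(e, 1));
      int col = Q + (cls[e] - 1) * ntri + tri_index(a, b, Q);
      Y(r, col) += 1.0;
    }
  }
  return Y;
}

// Single-site Metropolis sampler for the Potts model with per-class
// couplings.  Boltzmann exponent is the extensive energy
//   E = sum_k h[s_k] + sum_edges J_class[s_i, s_j].
// Proposal: uniform free node, uniform allowed state different from the
// current one; acceptance min(1, exp(-dE)).  One sweep = n_free proposals.
// Uses R's RNG, so set.seed() makes runs reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_metropolis(IntegerVector init, NumericVector h,
                             NumericVector Jcube, int Q, int nclass,
                             IntegerVector ptr, IntegerVector idx,
                             IntegerVector cls, IntegerVector free_nodes,
                             IntegerVector allow_ptr, IntegerVector allow_val,
                             int n_keep, int burn_in, int stride) {
  const int N = init.size();
  const int n_free = free_nodes.size();
  if (n_free == 0) stop("all nodes are clamped");
  std::vector<int> s(init.begin(), init.end());
  IntegerMatrix kept(n_keep, N);
  const int QQ = Q * Q;

  auto sweep = [&]() {
    for (int t = 0; t < n_free; ++t) {
      int k = free_nodes[(int)(unif_rand() * n_free) % n_free];
      int a = s[k];
      int a0 = allow_ptr[k], a1 = allow_ptr[k + 1];
      int n_allowed = a1 - a0;
      if (n_allowed <= 1) continue;
      // uniform among allowed states excluding the current one
      int r = (int)(unif_rand() * (n_allowed - 1)) % (n_allowed - 1);
      int b = -1;
      for (int q = a0; q < a1; ++q) {
        if (allow_val[q] == a) continue;
        if (r-- == 0) { b = allow_val[q]; break; }
      }
      if (b < 0) continue;
      double d = h[b] - h[a];
      for (int q = ptr[k]; q < ptr[k + 1]; ++q) {
        int sn = s[idx[q]];
        const double *J = &Jcube[(cls[q] - 1) * QQ];
        d += J[b + Q * sn] - J[a + Q * sn];
      }
      if (d <= 0.0 || unif_rand() < std::exp(-d)) s[k] = b;
    }
  };

  for (int t = 0; t < burn_in; ++t) sweep();
  for (int r = 0; r < n_keep; ++r) {
    if (r > 0) for (int t = 0; t < stride; ++t) sweep();
    for (int k = 0; k < N; ++k) kept(r, k) = s[k];
  }
  return kept;
}
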