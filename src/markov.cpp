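#include <Rcpp.h>
using namespace Rcpp;

// Generate an order-3 Markov DNA sequence of length n.
// trans: 64 x 4 row-stochastic matrix; rows index the previous trimer in
// lexicographic A<C<G<T order, columns the next base.  Draws come from R's
// RNG so set.seed() governs the output.
// [[Rcpp::export]]
std::string markov_generate_cpp(int n, NumericMatrix trans) {
  if (trans.nrow() != 64 || trans.ncol() != 4)
    stop("trans must be a 64 x 4 matrix");
  static const char bases[] = "ACGT";
  std::string out(n > 0 ? n : 0, 'A');
  RNGScope scope;
  int ctx = 0;
  int warm = n < 3 ? n : 3;
  for (int i = 0; i < warm; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out[i] = bases[b];
    ctx = (ctx % 16) * 4 + b;
  }
  for (int i = 3; i < n; ++i) {
    double u = unif_rand();
    double acc = 0.0;
    int b = 0;
    for (; b < 3; ++b) {
      acc += trans(ctx, b);
      if (u < acc) break;
    }
    out[i] = bases[b];
    ctx = (ctx % 16) * 4 + b;
  }
  return out;
}
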