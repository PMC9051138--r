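#include <Rcpp.h>
using namespace Rcpp;

// Sample a base sequence from an order-2 Markov chain over {A,C,G,T}.
// cum_trans: 16 x 4 row-wise cumulative transition probabilities, rows
// indexed by state 4*prev2 + prev1 (0-based). Uses R's RNG so results are
// reproducible under set.seed(). Returns 0-based base codes.
// [[Rcpp::export]]
IntegerVector cpp_markov_order2(NumericMatrix cum_trans, int len,
                                int s0, int s1) {
  if (len < 2) stop("sequence length must be >= 2");
  if (cum_trans.nrow() != 16 || cum_trans.ncol() != 4)
    stop("cum_trans must be 16 x 4");
  IntegerVector out(len);
  out[0] = s0;
  out[1] = s1;
  int a = s0, b = s1;
  for (int i = 2; i < len; ++i) {
    int state = 4 * a + b;
    double u = unif_rand();
    int c = 0;
    while (c < 3 && u > cum_trans(state, c)) ++c;
    out[i] = c;
    a = b;
    b = c;
  }
  return out;
}
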