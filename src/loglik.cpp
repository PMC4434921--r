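#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of a choice sequence under the Q-learning/softmax model.
// Q values are replayed from q_init separately for each deck pair and
// carried across block transitions. pair_idx and choice_idx are 1-based;
// choice_idx indexes the deck within its pair.
// [[Rcpp::export(name = ".ll_qlearn_cpp")]]
double ll_qlearn_cpp(IntegerVector pair_idx, IntegerVector choice_idx,
                     IntegerVector reward, double alpha, double beta,
                     double q_init, int n_pairs) {
  int n = pair_idx.size();
  std::vector<double> q(2 * n_pairs, q_init);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int p = pair_idx[t] - 1;
    int c = choice_idx[t] - 1;
    double qc = q[2 * p + c];
    double qu = q[2 * p + (1 - c)];
    // log P(chosen) = -log(1 + exp(-beta * (qc - qu))), stable form
    double x = beta * (qc - qu);
    ll += (x > 0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
    q[2 * p + c] = qc + alpha * (reward[t] - qc);
  }
  return ll;
}
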