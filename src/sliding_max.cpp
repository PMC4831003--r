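#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window maximum with symmetric half-width, clipped at the ends:
// out[i] = max(values[max(0, i-half) .. min(n-1, i+half)]).
// Monotonic deque, O(n) regardless of window size.
// [[Rcpp::export(name = ".sliding_max_cpp")]]
NumericVector sliding_max_cpp(NumericVector values, int half) {
  const int n = values.size();
  NumericVector out(n);
  std::deque<int> dq;
  for (int j = 0; j < n + half; ++j) {
    if (j < n) {
      while (!dq.empty() && values[dq.back()] <= values[j]) dq.pop_back();
      dq.push_back(j);
    }
    int i = j - half;
    if (i >= 0) {
      while (dq.front() < i - half) dq.pop_front();
      out[i] = values[dq.front()];
    }
  }
  return out;
}
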