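#include <Rcpp.h>
using namespace Rcpp;

// Time-multiplexed FIR engine.
//
// Emulates the embedded datapath: a single coefficient memory shared by all
// channels and a delay-line bank with one state per channel. For every sample
// period the channels are visited round-robin; symmetric coefficients let the
// datapath add the two delay-line entries that share a coefficient before one
// multiplication (the reuse scheme that halves the multiplier count).
//
// x: samples x channels, taps: FIR coefficients.
// Output equals direct causal convolution with zero initial state.
// [[Rcpp::export]]
NumericMatrix mux_fir(NumericMatrix x, NumericVector taps) {
  const int n = x.nrow();
  const int nc = x.ncol();
  const int nt = taps.size();
  const int half = nt / 2;
  const bool odd = (nt % 2) == 1;

  bool symmetric = true;
  for (int i = 0; i < half; ++i) {
    if (taps[i] != taps[nt - 1 - i]) { symmetric = false; break; }
  }

  NumericMatrix y(n, nc);
  // delay-line bank: nt rows (newest first) per channel
  std::vector<double> dl((size_t)nt * nc, 0.0);
  std::vector<int> head(nc, 0); // circular head per channel

  for (int t = 0; t < n; ++t) {
    for (int ch = 0; ch < nc; ++ch) { // round-robin channel visit
      double *line = &dl[(size_t)nt * ch];
      int h = head[ch];
      h = (h + nt - 1) % nt; // advance: new sample displaces the oldest
      line[h] = x(t, ch);
      head[ch] = h;
      double acc = 0.0;
      if (symmetric) {
        // reuse: taps[i] == taps[nt-1-i], add before the single multiply
        for (int i = 0; i < half; ++i) {
          double a = line[(h + i) % nt];          // x[t - i]
          double b = line[(h + nt - 1 - i) % nt]; // x[t - (nt-1-i)]
          acc += taps[i] * (a + b);
        }
        if (odd) acc += taps[half] * line[(h + half) % nt];
      } else {
        for (int i = 0; i < nt; ++i) acc += taps[i] * line[(h + i) % nt];
      }
      y(t, ch) = acc;
    }
  }
  return y;
}
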