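#include <Rcpp.h>
using namespace Rcpp;

// Non-paralyzable pulse processing. An accepted pulse opens a fixed dead
// window of tau seconds; arrivals inside the window are lost. When pile-up is
// enabled their (analog) amplitudes are summed into the pending pulse instead,
// emulating coincidence summation in the analog peak detector. Times must be
// non-decreasing.
// [[Rcpp::export]]
List process_pulse_train(NumericVector time, NumericVector amplitude,
                         double tau, bool pileup) {
  const R_xlen_t n = time.size();
  if (amplitude.size() != n) stop("time and amplitude lengths differ");
  std::vector<double> acc_t;   acc_t.reserve(n);
  std::vector<double> acc_a;   acc_a.reserve(n);
  std::vector<int>    acc_i;   acc_i.reserve(n);
  int dropped = 0;
  double window_end = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (time[i] < window_end) {
      ++dropped;
      if (pileup) acc_a.back() += amplitude[i];
    } else {
      acc_t.push_back(time[i]);
      acc_a.push_back(amplitude[i]);
      acc_i.push_back(static_cast<int>(i) + 1);
      window_end = time[i] + tau;
    }
  }
  return List::create(_["time"] = acc_t, _["amplitude"] = acc_a,
                      _["index"] = acc_i, _["dropped"] = dropped);
}
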