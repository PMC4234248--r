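#include <Rcpp.h>
using namespace Rcpp;

// Five cascaded divisive adaptation loops (nonlinear feedback), applied
// independently to each channel of a time x channel envelope matrix.
// Each loop divides the input by a lowpass-filtered copy of its own
// output; stationary inputs are mapped approximately logarithmically
// (steady state: x^(1/32) for five loops) while onsets pass through
// before the divisor charges, producing overshoot.
//
// The input is floored at 'floor_amp' (the absolute hearing threshold in
// full-scale amplitude units) and the loop states are initialised to the
// steady-state response to the floor, so silence maps to a fixed resting
// output that the caller subtracts when rescaling to model units.
//
// Onset overshoot is bounded per loop by the usual broken-stick limiter:
// outputs above 1 (the stationary response to a full-scale input) are
// compressed to at most 'limit' times it,
//   y -> limit - (limit - 1) * exp(-(y - 1)/(limit - 1)),  y > 1.
// limit <= 1 disables the limiter.
// [[Rcpp::export(name = ".adaptation_loops_cpp")]]
NumericMatrix adaptation_loops_cpp(NumericMatrix env, double fs,
                                   NumericVector tau_s, double floor_amp,
                                   double limit) {
  const int n = env.nrow(), nch = env.ncol(), nl = tau_s.size();
  NumericMatrix out(n, nch);
  std::vector<double> alpha(nl), q0(nl);
  for (int i = 0; i < nl; ++i)
    alpha[i] = std::exp(-1.0 / (tau_s[i] * fs));
  // resting states: steady-state chain response to the floor amplitude
  double v = floor_amp;
  for (int i = 0; i < nl; ++i) {
    v = std::sqrt(v);
    q0[i] = v;
  }
  std::vector<double> q(nl);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < nl; ++i) q[i] = q0[i];
    for (int t = 0; t < n; ++t) {
      double y = env(t, c);
      if (y < floor_amp) y = floor_amp;
      for (int i = 0; i < nl; ++i) {
        y = y / q[i];
        if (limit > 1.0 && y > 1.0)
          y = limit - (limit - 1.0) * std::exp(-(y - 1.0) / (limit - 1.0));
        q[i] = alpha[i] * q[i] + (1.0 - alpha[i]) * y;
      }
      out(t, c) = y;
    }
  }
  return out;
}
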