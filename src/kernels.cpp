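#include <Rcpp.h>
using namespace Rcpp;

// Sequential thinning of a candidate event stream by a sigmoid recovery
// function of the time since the last accepted event. Candidate times and
// the recovery parameters share one time unit (seconds). u holds one uniform
// draw per candidate so the R side owns the RNG stream.
// [[Rcpp::export]]
NumericVector thin_train_cpp(NumericVector cand, NumericVector u,
                             double center, double width, double floor_) {
  int n = cand.size();
  std::vector<double> out;
  out.reserve(n);
  double last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double dt = cand[i] - last;
    double w;
    if (dt < floor_) {
      w = 0.0;
    } else {
      w = 1.0 / (1.0 + std::exp(-(dt - center) / width));
    }
    if (u[i] < w) {
      out.push_back(cand[i]);
      last = cand[i];
    }
  }
  return wrap(out);
}

// Accumulate waveforms into a trace: for event e, pool column id[e] is added
// with its trigger row `trig` landing on sample time[e] (1-based). Events
// whose window would cross the trace boundary are skipped; the number of
// skipped events is returned via attribute "n_skipped".
// [[Rcpp::export]]
NumericVector render_events_cpp(NumericVector trace, IntegerVector times,
                                IntegerVector ids, NumericMatrix pool,
                                int trig) {
  NumericVector out = clone(trace);
  int n = out.size(), L = pool.nrow(), nev = times.size(), skipped = 0;
  for (int e = 0; e < nev; ++e) {
    int start = times[e] - trig;        // 0-based index of waveform sample 1
    if (start < 0 || start + L > n) { ++skipped; continue; }
    int k = ids[e] - 1;
    for (int j = 0; j < L; ++j) out[start + j] += pool(j, k);
  }
  out.attr("n_skipped") = skipped;
  return out;
}

// One direct-form-II-transposed IIR pass; z holds the initial state and is
// scaled by the caller (steady-state conditions for the first sample).
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x, std::vector<double> z) {
  size_t nb = b.size(), na = a.size();
  size_t nz = std::max(nb, na) - 1;
  z.resize(nz, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (size_t j = 1; j <= nz; ++j) {
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      double znext = (j < nz) ? z[j] : 0.0;
      z[j - 1] = bj * xi - aj * yi + znext;
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with reflective edge padding
// and steady-state initial conditions (zi scaled by the first sample of each
// pass), so constant inputs produce no startup transient.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a, NumericVector x,
                           NumericVector zi, int npad) {
  int n = x.size();
  if (npad > n - 1) npad = n - 1;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  std::vector<double> y(n + 2 * npad);
  // odd (point-reflected) extension, as is standard for zero-phase filtering
  for (int i = 0; i < npad; ++i) y[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) y[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) y[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  std::vector<double> z0(zi.begin(), zi.end());
  std::vector<double> z(z0);
  for (size_t j = 0; j < z.size(); ++j) z[j] *= y[0];
  iir_pass(bb, aa, y, z);
  std::reverse(y.begin(), y.end());
  z = z0;
  for (size_t j = 0; j < z.size(); ++j) z[j] *= y[0];
  iir_pass(bb, aa, y, z);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[npad + i];
  return out;
}
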