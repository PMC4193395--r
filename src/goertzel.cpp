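#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Goertzel evaluation of the DFT of each windowed frame at arbitrary
// (non-grid) frequencies.  Frame k covers samples [k*step, k*step + L).
// Returns an nfreq x nframes complex matrix with entries
//   S(i, k) = sum_{n=0}^{L-1} x[k*step + n] * w[n] * exp(-2*pi*1i*f_i*n/fs).
// [[Rcpp::export]]
ComplexMatrix goertzel_stft_cpp(NumericVector x, NumericVector window,
                                NumericVector freqs, double fs, int step) {
  const int L = window.size();
  const int n = x.size();
  const int nframes = (n >= L) ? (n - L) / step + 1 : 0;
  const int nf = freqs.size();
  ComplexMatrix out(nf, nframes);
  std::vector<double> v(L);
  for (int k = 0; k < nframes; ++k) {
    const int off = k * step;
    for (int j = 0; j < L; ++j) v[j] = x[off + j] * window[j];
    for (int i = 0; i < nf; ++i) {
      const double w = 2.0 * M_PI * freqs[i] / fs;
      const double coeff = 2.0 * std::cos(w);
      double s1 = 0.0, s2 = 0.0;
      for (int j = 0; j < L; ++j) {
        const double s0 = v[j] + coeff * s1 - s2;
        s2 = s1;
        s1 = s0;
      }
      // s1 = s[L-1], s2 = s[L-2]; X = (s1 - exp(-iw)*s2) * exp(-iw*(L-1))
      const double re1 = s1 - std::cos(w) * s2;
      const double im1 = std::sin(w) * s2;
      const double ph = -w * (L - 1);
      const double cp = std::cos(ph), sp = std::sin(ph);
      Rcomplex z;
      z.r = re1 * cp - im1 * sp;
      z.i = re1 * sp + im1 * cp;
      out(i, k) = z;
    }
  }
  return out;
}

// Event extraction and quality-parameter computation swept over thresholds.
// An event is an upward threshold crossing: a run of supra-threshold frames
// preceded by a sub-threshold frame, collapsed to its maximal frame (a run
// already in progress at the first frame has no identifiable peak and is
// skipped).  The event is a true positive when its frame lies inside a
// ground-truth interval (erd_id > 0); d counts distinct intervals containing
// >= 1 TP.  Returns an nthr x 3 matrix with columns (p, d, qp in percent).
// [[Rcpp::export]]
NumericMatrix sweep_qp_cpp(NumericVector trace, IntegerVector erd_id,
                           int n_erd, NumericVector thresholds) {
  const int n = trace.size();
  const int nthr = thresholds.size();
  NumericMatrix out(nthr, 3);
  std::vector<char> hit(n_erd + 1);
  for (int t = 0; t < nthr; ++t) {
    const double thr = thresholds[t];
    std::fill(hit.begin(), hit.end(), 0);
    int tp = 0, fp = 0;
    int i = 0;
    while (i < n) {
      if (trace[i] > thr) {
        const bool crossed = (i > 0);
        int best = i;
        int j = i;
        while (j < n && trace[j] > thr) {
          if (trace[j] > trace[best]) best = j;
          ++j;
        }
        if (crossed) {
          if (erd_id[best] > 0) {
            ++tp;
            hit[erd_id[best]] = 1;
          } else {
            ++fp;
          }
        }
        i = j;
      } else {
        ++i;
      }
    }
    int ndet = 0;
    for (int k = 1; k <= n_erd; ++k) ndet += hit[k];
    const double p = (tp + fp > 0) ? (double)tp / (tp + fp) : 0.0;
    const double d = (n_erd > 0) ? (double)ndet / n_erd : 0.0;
    out(t, 0) = p;
    out(t, 1) = d;
    out(t, 2) = 100.0 * std::sqrt(p * d);
  }
  return out;
}
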