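#include <Rcpp.h>
using namespace Rcpp;

// Noiseless model prediction over a fit window in the adjusted
// (adaptation-positive) convention, initial state 0.
// fb_code: 0 = veridical (r = 0 rotation step), 1 = clamp, 2 = no feedback.
// Across a step flagged post_break the retention factor becomes A^d.
// [[Rcpp::export]]
NumericVector predict_window_cpp(double A, double b, double d,
                                 IntegerVector fb_code,
                                 LogicalVector post_break,
                                 NumericVector engagement,
                                 double clamp_deg) {
  int K = fb_code.size();
  NumericVector p(K);
  double pn = 0.0;
  double Ad = std::pow(A, d);
  for (int i = 0; i < K; ++i) {
    p[i] = pn;
    if (i < K - 1) {
      double a = post_break[i + 1] ? Ad : A;
      switch (fb_code[i]) {
      case 1:  // clamp
        pn = a * pn + b * engagement[i] * clamp_deg;
        break;
      case 2:  // no feedback
        pn = a * pn;
        break;
      default: // veridical, r = 0
        pn = (a + b * engagement[i]) * pn;
      }
    }
  }
  return p;
}

// Mean-squared error of the window prediction against an observed series
// (NA observations omitted from the mean).
// [[Rcpp::export]]
double window_mse_cpp(double A, double b, double d,
                      IntegerVector fb_code, LogicalVector post_break,
                      NumericVector engagement, double clamp_deg,
                      NumericVector observed) {
  int K = fb_code.size();
  double pn = 0.0, sse = 0.0;
  int n = 0;
  double Ad = std::pow(A, d);
  for (int i = 0; i < K; ++i) {
    if (!NumericVector::is_na(observed[i])) {
      double r = observed[i] - pn;
      sse += r * r;
      ++n;
    }
    if (i < K - 1) {
      double a = post_break[i + 1] ? Ad : A;
      switch (fb_code[i]) {
      case 1:
        pn = a * pn + b * engagement[i] * clamp_deg;
        break;
      case 2:
        pn = a * pn;
        break;
      default:
        pn = (a + b * engagement[i]) * pn;
      }
    }
  }
  return n > 0 ? sse / n : NA_REAL;
}
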