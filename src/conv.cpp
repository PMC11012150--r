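#include <Rcpp.h>
using namespace Rcpp;

// Poisson shot noise plus Gaussian read noise, clipped at zero. Uses R's RNG
// stream so scene generation stays reproducible under set.seed().
// [[Rcpp::export]]
NumericVector noise_cpp(NumericVector lambda, double read_sd) {
  const R_xlen_t n = lambda.size();
  NumericVector out(n);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = R::rpois(lambda[i]);
    if (read_sd > 0) v += read_sd * norm_rand();
    out[i] = v < 0 ? 0.0 : v;
  }
  PutRNGstate();
  return out;
}

// Convolve a 2D/3D array along one axis with reflective boundary handling.
// Shared by the simulator PSF and pre-segmentation smoothing; a compiled
// kernel keeps Monte-Carlo simulation runs cheap.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dim, int axis,
                            NumericVector kernel) {
  const int nd = dim.size();
  if (axis < 1 || axis > nd) stop("axis out of range");
  const int L = dim[axis - 1];
  R_xlen_t stride = 1;
  for (int a = 0; a < axis - 1; ++a) stride *= dim[a];
  R_xlen_t outer = 1;
  for (int a = axis; a < nd; ++a) outer *= dim[a];
  const int K = kernel.size();
  const int r = (K - 1) / 2;

  NumericVector out(x.size());
  std::vector<double> line(L);
  const double* xs = REAL(x);
  double* os = REAL(out);
  const double* k = REAL(kernel);

  for (R_xlen_t o = 0; o < outer; ++o) {
    for (R_xlen_t inner = 0; inner < stride; ++inner) {
      const R_xlen_t base = o * stride * L + inner;
      for (int i = 0; i < L; ++i) line[i] = xs[base + (R_xlen_t)i * stride];
      const int lo = std::min(r, L);
      const int hi = std::max(L - r, lo);
      for (int i = 0; i < lo; ++i) {            // left boundary (reflect)
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = i + t;
          if (p < 0) p = -p - 1;
          else if (p >= L) p = 2 * L - p - 1;
          acc += k[t + r] * line[p];
        }
        os[base + (R_xlen_t)i * stride] = acc;
      }
      for (int i = lo; i < hi; ++i) {           // interior, branch-free
        double acc = 0.0;
        const double* lp = &line[i - r];
        for (int t = 0; t < K; ++t) acc += k[t] * lp[t];
        os[base + (R_xlen_t)i * stride] = acc;
      }
      for (int i = hi; i < L; ++i) {            // right boundary (reflect)
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = i + t;
          if (p < 0) p = -p - 1;
          else if (p >= L) p = 2 * L - p - 1;
          acc += k[t + r] * line[p];
        }
        os[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}
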