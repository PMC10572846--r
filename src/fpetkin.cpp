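#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Segment kernels for integrating a linear function against exp(-lam*(h-s))
// over s in [0,h]:
//   g1 = int_0^h exp(-lam*(h-s)) ds          = (1 - exp(-lam*h))/lam
//   g2 = int_0^h s * exp(-lam*(h-s)) ds      = (h - g1)/lam
// Series expansions take over when lam*h is tiny (cancellation).
static inline void seg_kernels(double lam, double h, double &E, double &g1,
                               double &g2) {
  double x = lam * h;
  if (x < 1e-6) {
    E = std::exp(-x);
    g1 = h * (1.0 - x / 2.0 + x * x / 6.0);
    g2 = h * h * (0.5 - x / 6.0 + x * x / 24.0);
  } else {
    E = std::exp(-x);
    g1 = (1.0 - E) / lam;
    g2 = (h - g1) / lam;
  }
}

// Running convolution F(t_j) = int_{t_i0}^{t_j} exp(-lam*(t_j-u)) ca(u) du
// for every grid point, treating ca as piecewise linear between grid points.
// Exact for the piecewise-linear representation (no quadrature error).
// F[j] = 0 for j <= i0.
// [[Rcpp::export]]
NumericVector cpp_exp_conv(NumericVector time, NumericVector ca, double lam,
                           int i0) {
  int n = time.size();
  NumericVector F(n);
  if (lam < 0) stop("lam must be >= 0");
  double E = 1.0, g1 = 0.0, g2 = 0.0, h_prev = -1.0;
  double acc = 0.0;
  for (int i = i0; i < n - 1; ++i) {
    double h = time[i + 1] - time[i];
    if (h <= 0) stop("time grid must be strictly increasing");
    if (h != h_prev) {  // kernels depend on lam and h only: cache per spacing
      seg_kernels(lam, h, E, g1, g2);
      h_prev = h;
    }
    double m = (ca[i + 1] - ca[i]) / h;
    acc = E * acc + ca[i] * g1 + m * g2;
    F[i + 1] = acc;
  }
  return F;
}

// Running trapezoid integral of y over time (exact for piecewise-linear y).
// [[Rcpp::export]]
NumericVector cpp_cumtrapz(NumericVector time, NumericVector y) {
  int n = time.size();
  NumericVector out(n);
  double acc = 0.0;
  for (int i = 1; i < n; ++i) {
    acc += 0.5 * (y[i] + y[i - 1]) * (time[i] - time[i - 1]);
    out[i] = acc;
  }
  return out;
}

// Free + trapped compartment curves for the baseline session on [0, end of
// grid]: cf = K1 * conv(lam), cm = K1*k3/lam * (int ca - conv(lam)),
// lam = k2 + k3. Degenerate lam = 0 (=> k3 = 0): cf = K1 * int ca, cm = 0.
static void baseline_curves(const NumericVector &time, const NumericVector &ca,
                            const NumericVector &cumca, double k1, double k2,
                            double k3, std::vector<double> &cf,
                            std::vector<double> &cm) {
  int n = time.size();
  double lam = k2 + k3;
  cf.assign(n, 0.0);
  cm.assign(n, 0.0);
  if (lam <= 0) {
    for (int i = 0; i < n; ++i) cf[i] = k1 * cumca[i];
    return;
  }
  NumericVector F = cpp_exp_conv(time, ca, lam, 0);
  double w = k1 * k3 / lam;
  for (int i = 0; i < n; ++i) {
    cf[i] = k1 * F[i];
    cm[i] = w * (cumca[i] - F[i]);
  }
}

// Activation-session update in place over [i_t2, end]. The baseline terminal
// state (cf2, cm2) is carried over: cf gains cf2*exp(-lam*(t-t2)); cm gains
// cm2 plus the continued trapping of the boundary free tracer,
// (k3a/lam)*cf2*(1-exp(-lam*(t-t2))), which the session-2 convolution alone
// does not cover. Both terms follow from integrating the model ODEs across
// the boundary; omitting the second breaks continuity of the piecewise
// solution.
static void activation_update(const NumericVector &time,
                              const NumericVector &ca,
                              const NumericVector &cumca, double k1a,
                              double k2a, double k3a, int i_t2,
                              std::vector<double> &cf, std::vector<double> &cm) {
  int n = time.size();
  double cf2 = cf[i_t2], cm2 = cm[i_t2];
  double lam = k2a + k3a;
  double t2 = time[i_t2];
  NumericVector G;
  if (lam > 0) G = cpp_exp_conv(time, ca, lam, i_t2);
  double w = (lam > 0) ? k1a * k3a / lam : 0.0;
  double wb = (lam > 0) ? k3a / lam : 0.0;
  for (int i = i_t2; i < n; ++i) {
    if (lam > 0) {
      double E = std::exp(-lam * (time[i] - t2));
      cf[i] = k1a * G[i] + E * cf2;
      cm[i] = w * ((cumca[i] - cumca[i_t2]) - G[i]) + cm2 +
        wb * cf2 * (1.0 - E);
    } else {
      cf[i] = k1a * (cumca[i] - cumca[i_t2]) + cf2;
      cm[i] = cm2;
    }
  }
}

// Piecewise two-session solution. Baseline parameters (k1b,k2b,k3b) apply on
// [0, t2], activation parameters (k1a,k2a,k3a) on [t2, end] with the baseline
// terminal state carried over. i_t2 is the 0-based index of t2 on the grid
// (t2 must be a grid point). two_session = false solves baseline over the
// whole grid. Returns cf, cm, ct with ct = cf + cm + v0*ca.
// [[Rcpp::export]]
List cpp_solve_two_session(NumericVector time, NumericVector ca,
                           NumericVector cumca, double k1b, double k2b,
                           double k3b, double k1a, double k2a, double k3a,
                           double v0, int i_t2, bool two_session) {
  int n = time.size();
  std::vector<double> cf, cm;
  baseline_curves(time, ca, cumca, k1b, k2b, k3b, cf, cm);
  if (two_session)
    activation_update(time, ca, cumca, k1a, k2a, k3a, i_t2, cf, cm);
  NumericVector cfv(cf.begin(), cf.end());
  NumericVector cmv(cm.begin(), cm.end());
  NumericVector ct(n);
  for (int i = 0; i < n; ++i) ct[i] = cf[i] + cm[i] + v0 * ca[i];
  return List::create(_["cf"] = cfv, _["cm"] = cmv, _["ct"] = ct);
}

// Trapezoid mean of y over index ranges [i_start[f], i_end[f]] (0-based,
// inclusive). Frame boundaries must be grid points.
// [[Rcpp::export]]
NumericVector cpp_frame_avg(NumericVector time, NumericVector y,
                            IntegerVector i_start, IntegerVector i_end) {
  int nf = i_start.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    int a = i_start[f], b = i_end[f];
    double area = 0.0;
    for (int i = a; i < b; ++i)
      area += 0.5 * (y[i] + y[i + 1]) * (time[i + 1] - time[i]);
    out[f] = area / (time[b] - time[a]);
  }
  return out;
}

// One-shot model evaluation for the fitting loop: two-session (or baseline
// only) total-activity curve, frame-averaged. Avoids intermediate R objects.
// [[Rcpp::export]]
NumericVector cpp_predict_frames(NumericVector time, NumericVector ca,
                                 NumericVector cumca, double k1b, double k2b,
                                 double k3b, double k1a, double k2a,
                                 double k3a, double v0, int i_t2,
                                 bool two_session, IntegerVector i_start,
                                 IntegerVector i_end) {
  int n = time.size();
  std::vector<double> cf, cm;
  baseline_curves(time, ca, cumca, k1b, k2b, k3b, cf, cm);
  if (two_session)
    activation_update(time, ca, cumca, k1a, k2a, k3a, i_t2, cf, cm);
  std::vector<double> ct(n);
  for (int i = 0; i < n; ++i) ct[i] = cf[i] + cm[i] + v0 * ca[i];
  int nf = i_start.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    int a = i_start[f], b = i_end[f];
    double area = 0.0;
    for (int i = a; i < b; ++i)
      area += 0.5 * (ct[i] + ct[i + 1]) * (time[i + 1] - time[i]);
    out[f] = area / (time[b] - time[a]);
  }
  return out;
}

// Separable truncated-Gaussian 3D smoothing (zero padding, normalized
// kernel). sigma in voxel units per axis; radius 4*sigma. Totals are
// preserved except for mass smoothed past the array boundary.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      ksum += k[j + r];
    }
    for (double &v : k) v /= ksum;
    int st = strides[ax], len = sizes[ax];
    int nline = (int)a.size() / len;
    for (int line = 0; line < nline; ++line) {
      // base index of this line: decompose line over the two other axes
      int rem = line, base = 0;
      for (int other = 0; other < 3; ++other) {
        if (other == ax) continue;
        int idx = rem % sizes[other];
        rem /= sizes[other];
        base += idx * strides[other];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += a[base + j * st] * k[j - i + r];
        b[base + i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// 6-connectivity connected components of a logical 3D mask.
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int w = X + nx * (Y + ny * Z);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
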