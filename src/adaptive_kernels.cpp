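#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All kernels share the transversal-filter conventions:
//   x_vec(n) = [x(n), x(n-1), ..., x(n-M+1)]   (zero history for n < M)
//   y(n) = w(n-1)' x_vec(n)                    (a priori prediction)
//   e(n) = d(n) - y(n)                         (a priori error = fECG_est)
// Weights start at zero.  All updates use the a priori error.

static inline void shift_in(std::vector<double>& xb, double xn) {
  for (int j = (int)xb.size() - 1; j > 0; --j) xb[j] = xb[j - 1];
  xb[0] = xn;
}

// LMS family.  sign_error switches to the sign(e) update (sign(0) = 0);
// with_bias appends a constant-1 regressor (ADALINE bias weight).
static List lms_family(const NumericVector& d, const NumericVector& x,
                       int M, double mu, bool sign_error, bool with_bias) {
  const int n = d.size();
  const int L = with_bias ? M + 1 : M;
  std::vector<double> xb(L, 0.0);
  if (with_bias) xb[M] = 1.0;  // bias input is always 1
  std::vector<double> w(L, 0.0);
  NumericVector e(n), y(n);
  for (int i = 0; i < n; ++i) {
    // shift the M delay taps only (index M, when present, is the bias input)
    for (int j = M - 1; j > 0; --j) xb[j] = xb[j - 1];
    xb[0] = x[i];
    double yi = 0.0;
    for (int j = 0; j < L; ++j) yi += w[j] * xb[j];
    double ei = d[i] - yi;
    if (!std::isfinite(ei))
      stop("adaptive filter diverged at sample %d (non-finite error)", i + 1);
    double g = ei;
    if (sign_error) g = (ei > 0.0) - (ei < 0.0);
    for (int j = 0; j < L; ++j) {
      w[j] += mu * g * xb[j];
      if (!std::isfinite(w[j]))
        stop("adaptive filter diverged at sample %d (non-finite weight)", i + 1);
    }
    e[i] = ei;
    y[i] = yi;
  }
  return List::create(_["e"] = e, _["y"] = y,
                      _["w"] = NumericVector(w.begin(), w.end()));
}

// [[Rcpp::export]]
List cpp_lms(NumericVector d, NumericVector x, int M, double mu,
             bool sign_error) {
  return lms_family(d, x, M, mu, sign_error, false);
}

// [[Rcpp::export]]
List cpp_adaline(NumericVector d, NumericVector x, int p, double eta,
                 bool bias) {
  // bias off is structurally identical to LMS(M = p, mu = eta)
  return lms_family(d, x, p, eta, false, bias);
}

// Exponentially weighted RLS with a priori error.
// P(0) = (1/delta) * diag(1, lam, ..., lam^(M-1)): the lambda-tapered prior
// is shift-consistent, making the FTF recursions below its exact O(M)
// counterpart; at lam = 1 it is the classic (1/delta) I.
// [[Rcpp::export]]
List cpp_rls(NumericVector d, NumericVector x, int M, double lam,
             double delta) {
  const int n = d.size();
  std::vector<double> xb(M, 0.0), w(M, 0.0), Px(M), k(M);
  std::vector<double> P(M * M, 0.0);
  double taper = 1.0;
  for (int j = 0; j < M; ++j) { P[j * M + j] = taper / delta; taper *= lam; }
  NumericVector e(n), y(n);
  for (int i = 0; i < n; ++i) {
    shift_in(xb, x[i]);
    double xPx = 0.0;
    for (int r = 0; r < M; ++r) {
      double s = 0.0;
      for (int c = 0; c < M; ++c) s += P[r * M + c] * xb[c];
      Px[r] = s;
      xPx += s * xb[r];
    }
    double denom = lam + xPx;
    double yi = 0.0;
    for (int j = 0; j < M; ++j) yi += w[j] * xb[j];
    double ei = d[i] - yi;
    if (!std::isfinite(ei))
      stop("RLS diverged at sample %d (non-finite error)", i + 1);
    for (int j = 0; j < M; ++j) {
      k[j] = Px[j] / denom;
      w[j] += k[j] * ei;
      if (!std::isfinite(w[j]))
        stop("RLS diverged at sample %d (non-finite weight)", i + 1);
    }
    // P <- (P - k x'P) / lam, keeping symmetry
    for (int r = 0; r < M; ++r)
      for (int c = 0; c < M; ++c)
        P[r * M + c] = (P[r * M + c] - k[r] * Px[c]) / lam;
    for (int r = 0; r < M; ++r)
      for (int c = r + 1; c < M; ++c) {
        double s = 0.5 * (P[r * M + c] + P[c * M + r]);
        P[r * M + c] = s; P[c * M + r] = s;
      }
    e[i] = ei;
    y[i] = yi;
  }
  return List::create(_["e"] = e, _["y"] = y,
                      _["w"] = NumericVector(w.begin(), w.end()));
}

// Fast transversal filter: O(M) exact RLS via forward/backward prediction
// recursions and the conversion factor gamma.  State: forward predictor a,
// backward predictor b, gain k (a posteriori convention k(n) = P(n) x_vec(n)),
// gamma, forward/backward error energies F and B.  A rescue re-initializes
// the prediction state (keeping the joint-process weights) whenever gamma
// leaves (0, 1] or any state variable goes non-finite.
// [[Rcpp::export]]
List cpp_ftf(NumericVector d, NumericVector x, int M, double lam,
             double delta, int rescue_budget) {
  const int n = d.size();
  std::vector<double> a(M, 0.0), b(M, 0.0), k(M, 0.0), w(M, 0.0);
  std::vector<double> xb(M, 0.0), xb_prev(M, 0.0), k1(M + 1);
  const double B0 = delta * std::pow(lam, -M);
  double gam = 1.0, Fe = delta, Be = B0;
  NumericVector e(n), y(n), gam_trace(n);
  IntegerVector rescue_at;
  int rescues = 0;
  for (int i = 0; i < n; ++i) {
    xb_prev = xb;
    shift_in(xb, x[i]);
    // forward prediction
    double ef = x[i];
    for (int j = 0; j < M; ++j) ef -= a[j] * xb_prev[j];
    double epsf = gam * ef;
    double Fn = lam * Fe + ef * epsf;
    for (int j = 0; j < M; ++j) a[j] += k[j] * ef;
    // order-up gain and conversion factor
    k1[0] = epsf / Fn;
    for (int j = 1; j <= M; ++j)
      k1[j] = k[j - 1] - (epsf / Fn) * a[j - 1];
    double gam1 = gam * lam * Fe / Fn;
    Fe = Fn;
    // order-down via backward prediction.  The backward a priori error is
    // available both from the fast recursion and directly from the
    // backward predictor; the direct form is used (it is the same
    // quantity in exact arithmetic and numerically better behaved) and
    // the divergence of the two is the classic instability symptom that
    // triggers a rescue below.
    double m = k1[M];
    double eb_fast = lam * Be * m / gam1;
    double eb = xb_prev[M - 1];
    for (int j = 0; j < M; ++j) eb -= b[j] * xb[j];
    double gamN = gam1 / (1.0 - lam * Be * m * m / gam1);
    double epsb = gamN * eb;
    Be = lam * Be + eb * epsb;
    double denomb = 1.0 - m * eb;
    for (int j = 0; j < M; ++j) k[j] = (k1[j] + m * b[j]) / denomb;
    for (int j = 0; j < M; ++j) b[j] += k[j] * eb;
    gam = gamN;
    // joint process
    double yi = 0.0;
    for (int j = 0; j < M; ++j) yi += w[j] * xb[j];
    double ei = d[i] - yi;
    for (int j = 0; j < M; ++j) w[j] += k[j] * ei;
    e[i] = ei;
    y[i] = yi;
    gam_trace[i] = gam;
    // stability supervision
    double ebmag = std::fabs(eb) + std::fabs(eb_fast);
    bool drift = ebmag > 1e-12 &&
      std::fabs(eb - eb_fast) / ebmag > 1e-3;
    bool bad = drift || !(gam > 0.0 && gam <= 1.0 + 1e-9) ||
      !std::isfinite(gam) || !std::isfinite(Fe) || !std::isfinite(Be) ||
      Fe <= 0.0 || Be <= 0.0 || !std::isfinite(ei);
    if (!bad)
      for (int j = 0; j < M; ++j)
        if (!std::isfinite(k[j]) || !std::isfinite(a[j]) ||
            !std::isfinite(b[j]) || !std::isfinite(w[j])) { bad = true; break; }
    if (bad) {
      ++rescues;
      rescue_at.push_back(i + 1);
      if (rescues > rescue_budget)
        stop("FTF instability: rescue budget (%d) exceeded at sample %d",
             rescue_budget, i + 1);
      std::fill(a.begin(), a.end(), 0.0);
      std::fill(b.begin(), b.end(), 0.0);
      std::fill(k.begin(), k.end(), 0.0);
      // prewindowed restart: the prediction recursions resume from empty
      // history (the joint-process weights and their taps are kept)
      std::fill(xb.begin(), xb.end(), 0.0);
      gam = 1.0; Fe = delta; Be = B0;
      for (int j = 0; j < M; ++j)
        if (!std::isfinite(w[j])) w[j] = 0.0;
      if (!std::isfinite(e[i])) e[i] = d[i];
      gam_trace[i] = gam;
    }
  }
  return List::create(_["e"] = e, _["y"] = y,
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["rescues"] = rescues, _["rescue_at"] = rescue_at,
                      _["gamma"] = gam_trace);
}
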