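// Reaction-diffusion model of pheromone-induced Cdc42 polarization on a
// circular membrane: 10 diffusing membrane fields + activated Cla4 (no
// diffusion) + two cytoplasmic pools recovered from conservation.
// Time stepping: Crank-Nicolson for diffusion (periodic second-order
// finite differences), semi-implicit trapezoidal for reactions (linear
// decay implicit with frozen coefficients, production explicit, one
// fixed-point correction).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum Field { iR = 0, iRL, iG, iGa, iGbg, iGd, iC24m, iC42, iC42a, iB1m,
             iCla4a, NFIELD };

struct Pars {
  double D[10];
  double kRL, kRLm, kRd0, kRd1, kRs, kGa, kGd, kG1;
  double k42d, k42a, k24cm0, k24cm1, k24mc, kB1mc, kB1cm, kCla4a, kCla4d,
      k24d;
  double q, h, C24t, B1t, Rt, Gt, C42t;
};

static double getp(const NumericVector &v, const char *nm) {
  CharacterVector nms = v.names();
  for (int i = 0; i < v.size(); ++i)
    if (std::strcmp(nms[i], nm) == 0) return v[i];
  stop("missing parameter '%s'", nm);
  return NA_REAL;
}

static Pars read_pars(const NumericVector &v) {
  Pars p;
  const char *dn[10] = {"DR", "DRL", "DG", "DGa", "DGbg", "DGd",
                        "DC24m", "DC42", "DC42a", "DB1m"};
  for (int f = 0; f < 10; ++f) p.D[f] = getp(v, dn[f]);
  p.kRL = getp(v, "kRL");     p.kRLm = getp(v, "kRLm");
  p.kRd0 = getp(v, "kRd0");   p.kRd1 = getp(v, "kRd1");
  p.kRs = getp(v, "kRs");     p.kGa = getp(v, "kGa");
  p.kGd = getp(v, "kGd");     p.kG1 = getp(v, "kG1");
  p.k42d = getp(v, "k42d");   p.k42a = getp(v, "k42a");
  p.k24cm0 = getp(v, "k24cm0"); p.k24cm1 = getp(v, "k24cm1");
  p.k24mc = getp(v, "k24mc"); p.kB1mc = getp(v, "kB1mc");
  p.kB1cm = getp(v, "kB1cm"); p.kCla4a = getp(v, "kCla4a");
  p.kCla4d = getp(v, "kCla4d"); p.k24d = getp(v, "k24d");
  p.q = getp(v, "q");         p.h = getp(v, "h");
  p.C24t = getp(v, "C24t");   p.B1t = getp(v, "B1t");
  p.Rt = getp(v, "Rt");       p.Gt = getp(v, "Gt");
  p.C42t = getp(v, "C42t");
  return p;
}

// increasing Hill switch u -> 1/(1 + u^-q), guarded against over/underflow
static inline double hill_up(double u, double q) {
  if (u < 1e-12) u = 1e-12;
  double t = -q * std::log(u);
  if (t > 700.0) return 0.0;
  double out = 1.0 / (1.0 + std::exp(t));
  return out < 0.0 ? 0.0 : (out > 1.0 ? 1.0 : out);
}

// Thomas solve, constant off-diagonals `off`, varying diagonal bb
static void tridiag(int N, double off, const double *bb, const double *rhs,
                    double *x, double *cp) {
  cp[0] = off / bb[0];
  x[0] = rhs[0] / bb[0];
  for (int i = 1; i < N; ++i) {
    double m = bb[i] - off * cp[i - 1];
    cp[i] = off / m;
    x[i] = (rhs[i] - off * x[i - 1]) / m;
  }
  for (int i = N - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
}

// Cyclic tridiagonal solve (Sherman-Morrison), diag b, off-diagonals and
// corner entries `off`
static void cyclic_solve(int N, const double *b, double off,
                         const double *rhs, double *x, double *work) {
  if (off == 0.0) {
    for (int i = 0; i < N; ++i) x[i] = rhs[i] / b[i];
    return;
  }
  double *bb = work, *u = work + N, *z = work + 2 * N, *cp = work + 3 * N;
  double gamma = -b[0];
  for (int i = 0; i < N; ++i) bb[i] = b[i];
  bb[0] = b[0] - gamma;
  bb[N - 1] = b[N - 1] - off * off / gamma;
  tridiag(N, off, bb, rhs, x, cp);
  for (int i = 0; i < N; ++i) u[i] = 0.0;
  u[0] = gamma;
  u[N - 1] = off;
  tridiag(N, off, bb, u, z, cp);
  double fact = (x[0] + off * x[N - 1] / gamma) /
                (1.0 + z[0] + off * z[N - 1] / gamma);
  for (int i = 0; i < N; ++i) x[i] -= fact * z[i];
}

// reaction terms split as rate = prod - dec * W (dec >= 0), with the
// nonlocal coefficients and cytoplasmic pools evaluated on W
static void reactions(int N, const std::vector<double> &W, const double *L,
                      const Pars &p, double ds, double SA, double V,
                      std::vector<double> &prod, std::vector<double> &dec,
                      double *min_pool) {
  const double *R = &W[(size_t)iR * N], *RL = &W[(size_t)iRL * N],
               *G = &W[(size_t)iG * N], *Ga = &W[(size_t)iGa * N],
               *Gbg = &W[(size_t)iGbg * N], *Gd = &W[(size_t)iGd * N],
               *C24m = &W[(size_t)iC24m * N], *C42 = &W[(size_t)iC42 * N],
               *C42a = &W[(size_t)iC42a * N], *B1m = &W[(size_t)iB1m * N],
               *Cla4a = &W[(size_t)iCla4a * N];
  double sC24m = 0, sB1m = 0, sGbg = 0, sC42a = 0;
  for (int i = 0; i < N; ++i) {
    sC24m += C24m[i];
    sB1m += B1m[i];
    sGbg += Gbg[i];
    sC42a += C42a[i];
  }
  double C24c = (p.C24t - sC24m * ds) / V;
  double B1c = (p.B1t - sB1m * ds) / V;
  if (C24c < *min_pool) *min_pool = C24c;
  if (B1c < *min_pool) *min_pool = B1c;
  if (C24c < 0) C24c = 0;
  if (B1c < 0) B1c = 0;

  double G0 = p.Gt / SA;
  double IG = (sGbg / G0) * ds;               // integral of Gbgn
  double delta = IG > 0 ? SA / IG : 0.0;
  double IB = sB1m * ds;
  double B1t_star = IB / SA;
  double gamma = IB > 0 ? SA / (2.0 * IB) : 0.0;
  double C42at_star = sC42a * ds / SA;

  for (int i = 0; i < N; ++i) {
    double Gbgn_star =
        IG > 0 ? hill_up(delta * Gbg[i] / G0, p.q) : 0.0;
    double B1star =
        IB > 0 ? B1t_star * hill_up(gamma * Gbgn_star * B1m[i], p.h) : 0.0;
    double ps = C42at_star > 0 ? C42a[i] / C42at_star : 1.0;

    prod[(size_t)iR * N + i] = p.kRLm * RL[i] + ps * p.kRs;
    dec[(size_t)iR * N + i] = p.kRL * L[i] + p.kRd0;

    prod[(size_t)iRL * N + i] = p.kRL * L[i] * R[i];
    dec[(size_t)iRL * N + i] = p.kRLm + p.kRd1;

    prod[(size_t)iG * N + i] = p.kG1 * Gd[i] * Gbg[i];
    dec[(size_t)iG * N + i] = p.kGa * RL[i];

    prod[(size_t)iGa * N + i] = p.kGa * RL[i] * G[i];
    dec[(size_t)iGa * N + i] = p.kGd;

    prod[(size_t)iGbg * N + i] = p.kGa * RL[i] * G[i];
    dec[(size_t)iGbg * N + i] = p.kG1 * Gd[i];

    prod[(size_t)iGd * N + i] = p.kGd * Ga[i];
    dec[(size_t)iGd * N + i] = p.kG1 * Gbg[i];

    prod[(size_t)iC24m * N + i] =
        (p.k24cm0 * Gbgn_star + p.k24cm1 * B1star) * C24c;
    dec[(size_t)iC24m * N + i] = p.k24mc + p.k24d * Cla4a[i];

    prod[(size_t)iC42 * N + i] = p.k42d * C42a[i];
    dec[(size_t)iC42 * N + i] = p.k42a * C24m[i];

    prod[(size_t)iC42a * N + i] = p.k42a * C24m[i] * C42[i];
    dec[(size_t)iC42a * N + i] = p.k42d;

    prod[(size_t)iB1m * N + i] = p.kB1cm * C42a[i] * B1c;
    dec[(size_t)iB1m * N + i] = p.kB1mc;

    prod[(size_t)iCla4a * N + i] = p.kCla4a * C42at_star;
    dec[(size_t)iCla4a * N + i] = p.kCla4d;
  }
}

// explicit half of the CN diffusion operator: (I + beta T) W, periodic
static void explicit_diff(int N, double beta, const double *W, double *out) {
  for (int i = 0; i < N; ++i) {
    int l = i == 0 ? N - 1 : i - 1, r = i == N - 1 ? 0 : i + 1;
    out[i] = W[i] + beta * (W[l] - 2.0 * W[i] + W[r]);
  }
}

// [[Rcpp::export]]
List polar_simulate_cpp(NumericMatrix fields0, NumericVector L,
                        NumericVector pars, double radius, double dt,
                        int nsteps, int steady_window) {
  int N = fields0.nrow();
  if (fields0.ncol() != NFIELD) stop("expected %d field columns", NFIELD);
  if (L.size() != N) stop("ligand field length does not match mesh");
  Pars p = read_pars(pars);
  double SA = 2.0 * M_PI * radius, V = M_PI * radius * radius;
  double ds = SA / N;

  std::vector<double> W((size_t)NFIELD * N), Ws((size_t)NFIELD * N),
      Wn((size_t)NFIELD * N);
  for (int f = 0; f < NFIELD; ++f)
    for (int i = 0; i < N; ++i) W[(size_t)f * N + i] = fields0(i, f);

  std::vector<double> P1((size_t)NFIELD * N), D1((size_t)NFIELD * N),
      P2((size_t)NFIELD * N), D2((size_t)NFIELD * N);
  std::vector<double> rhs(N), ex(N), diag(N), work(4 * N);
  std::vector<double> beta(10);
  for (int f = 0; f < 10; ++f) beta[f] = p.D[f] * dt / (2.0 * ds * ds);

  std::vector<double> Wold;
  int save_at = nsteps - steady_window;
  double min_field = 0.0, min_pool = 1e300;

  for (int s = 0; s < nsteps; ++s) {
    if (s == save_at && steady_window > 0) Wold = W;
    reactions(N, W, &L[0], p, ds, SA, V, P1, D1, &min_pool);
    // predictor: implicit Euler in the frozen decay, CN diffusion
    for (int f = 0; f < NFIELD; ++f) {
      double *w = &W[(size_t)f * N];
      double *ws = &Ws[(size_t)f * N];
      if (f < 10) {
        explicit_diff(N, beta[f], w, ex.data());
        for (int i = 0; i < N; ++i) {
          rhs[i] = ex[i] + dt * P1[(size_t)f * N + i];
          diag[i] = 1.0 + 2.0 * beta[f] + dt * D1[(size_t)f * N + i];
        }
        cyclic_solve(N, diag.data(), -beta[f], rhs.data(), ws, work.data());
      } else {
        for (int i = 0; i < N; ++i)
          ws[i] = (w[i] + dt * P1[(size_t)f * N + i]) /
                  (1.0 + dt * D1[(size_t)f * N + i]);
      }
    }
    reactions(N, Ws, &L[0], p, ds, SA, V, P2, D2, &min_pool);
    // trapezoidal corrector with the corrected decay coefficient implicit
    for (int f = 0; f < NFIELD; ++f) {
      double *w = &W[(size_t)f * N];
      double *wn = &Wn[(size_t)f * N];
      if (f < 10) {
        explicit_diff(N, beta[f], w, ex.data());
        for (int i = 0; i < N; ++i) {
          size_t k = (size_t)f * N + i;
          rhs[i] = ex[i] + 0.5 * dt * (P1[k] + P2[k]) - 0.5 * dt * D1[k] * w[i];
          diag[i] = 1.0 + 2.0 * beta[f] + 0.5 * dt * D2[k];
        }
        cyclic_solve(N, diag.data(), -beta[f], rhs.data(), wn, work.data());
      } else {
        for (int i = 0; i < N; ++i) {
          size_t k = (size_t)f * N + i;
          wn[i] = (w[i] + 0.5 * dt * (P1[k] + P2[k]) -
                   0.5 * dt * D1[k] * w[i]) /
                  (1.0 + 0.5 * dt * D2[k]);
        }
      }
    }
    W.swap(Wn);
    if ((s & 63) == 0) {
      for (size_t k = 0; k < W.size(); ++k)
        if (!R_finite(W[k]))
          stop("PDE integration produced a non-finite value at step %d "
               "(t = %g s); reduce dt", s + 1, (s + 1) * dt);
    }
  }
  for (size_t k = 0; k < W.size(); ++k)
    if (!R_finite(W[k]))
      stop("PDE integration produced a non-finite value at the final step");

  for (size_t k = 0; k < W.size(); ++k)
    if (W[k] < min_field) min_field = W[k];

  double rel_change = NA_REAL;
  if (steady_window > 0 && !Wold.empty()) {
    double num = 0, den = 0;
    for (size_t k = 0; k < W.size(); ++k) {
      double d = std::fabs(W[k] - Wold[k]);
      if (d > num) num = d;
      double a = std::fabs(W[k]);
      if (a > den) den = a;
    }
    rel_change = num / (den + 1e-300);
  }

  NumericMatrix fields(N, NFIELD);
  for (int f = 0; f < NFIELD; ++f)
    for (int i = 0; i < N; ++i) fields(i, f) = W[(size_t)f * N + i];
  return List::create(
      _["fields"] = fields,
      _["diagnostics"] = List::create(
          _["rel_change_10s"] = rel_change, _["min_field"] = min_field,
          _["min_pool"] = min_pool, _["steps"] = nsteps, _["dt"] = dt));
}
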