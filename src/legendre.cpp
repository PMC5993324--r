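#include <Rcpp.h>
using namespace Rcpp;

// Enumerate all multi-indices with total degree <= d in n variables,
// graded lexicographic (by degree, then lex with dimension 1 most
// significant, larger exponent first).
static void compositions(int pos, int n, int rem, std::vector<int> &cur,
                         std::vector<int> &out) {
  if (pos == n - 1) {
    cur[pos] = rem;
    out.insert(out.end(), cur.begin(), cur.end());
    return;
  }
  for (int k = rem; k >= 0; --k) {
    cur[pos] = k;
    compositions(pos + 1, n, rem - k, cur, out);
  }
}

// [[Rcpp::export]]
IntegerMatrix multi_indices_cpp(int n, int d) {
  if (n < 1 || d < 0) stop("need n >= 1, d >= 0");
  double cnt = Rf_choose(n + d, n);
  if (cnt > 2e7) stop("basis too large to enumerate (%.0f terms)", cnt);
  std::vector<int> out;
  out.reserve((size_t)cnt * n);
  std::vector<int> cur(n);
  for (int g = 0; g <= d; ++g) compositions(0, n, g, cur, out);
  int nb = out.size() / n;
  IntegerMatrix idx(nb, n);
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < n; ++k) idx(j, k) = out[(size_t)j * n + k];
  return idx;
}

// Legendre recurrence table P_0..P_dmax at x, written into p (length dmax+1)
static inline void leg_table(double x, int dmax, double *p) {
  p[0] = 1.0;
  if (dmax >= 1) p[1] = x;
  for (int k = 2; k <= dmax; ++k)
    p[k] = ((2.0 * k - 1.0) * x * p[k - 1] - (k - 1.0) * p[k - 2]) / k;
}

// [[Rcpp::export]]
NumericMatrix design_matrix_cpp(NumericMatrix Y, IntegerMatrix idx) {
  int m = Y.nrow(), n = Y.ncol(), nb = idx.nrow();
  if (idx.ncol() != n) stop("basis dimension does not match samples");
  int dmax = 0;
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < n; ++k) if (idx(j, k) > dmax) dmax = idx(j, k);
  NumericMatrix A(m, nb);
  std::vector<double> P((size_t)n * (dmax + 1));
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < n; ++k) leg_table(Y(i, k), dmax, &P[(size_t)k * (dmax + 1)]);
    for (int j = 0; j < nb; ++j) {
      double v = 1.0;
      for (int k = 0; k < n; ++k) {
        int dg = idx(j, k);
        if (dg) v *= P[(size_t)k * (dmax + 1) + dg];
      }
      A(i, j) = v;
    }
  }
  return A;
}

// Metropolis-Hastings random walk on the cube with a Gaussian data
// likelihood evaluated through the Legendre surrogate(s).
// [[Rcpp::export]]
List mh_chain_cpp(NumericVector y0, IntegerMatrix idx, NumericMatrix C,
                  NumericVector data_mean, NumericVector data_sd,
                  NumericVector prop_sd, int steps, int burn, int thin) {
  RNGScope scope;
  int n = y0.size(), nb = idx.nrow(), nr = C.ncol();
  if (idx.ncol() != n) stop("surrogate dimension does not match start point");
  if (C.nrow() != nb) stop("coefficient rows do not match basis");
  if (data_mean.size() != nr || data_sd.size() != nr)
    stop("need one data point per surrogate response");
  int dmax = 0;
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < n; ++k) if (idx(j, k) > dmax) dmax = idx(j, k);
  std::vector<double> P((size_t)n * (dmax + 1)), z(nr);
  std::vector<double> w(nr);
  for (int r = 0; r < nr; ++r) w[r] = 1.0 / (2.0 * data_sd[r] * data_sd[r]);

  auto loglik = [&](const double *y) {
    for (int k = 0; k < n; ++k) leg_table(y[k], dmax, &P[(size_t)k * (dmax + 1)]);
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < nb; ++j) {
      double phi = 1.0;
      for (int k = 0; k < n; ++k) {
        int dg = idx(j, k);
        if (dg) phi *= P[(size_t)k * (dmax + 1) + dg];
      }
      for (int r = 0; r < nr; ++r) z[r] += phi * C(j, r);
    }
    double ll = 0.0;
    for (int r = 0; r < nr; ++r) {
      double e = z[r] - data_mean[r];
      ll -= e * e * w[r];
    }
    return ll;
  };

  std::vector<double> y(y0.begin(), y0.end()), prop(n);
  double lp = loglik(y.data());
  int keep = (steps - burn) / thin;
  NumericMatrix samples(keep, n);
  NumericVector log_post(keep);
  long acc = 0;
  int since_acc = 0, kk = 0;
  for (int i = 1; i <= steps; ++i) {
    bool inside = true;
    for (int k = 0; k < n; ++k) {
      prop[k] = y[k] + R::rnorm(0.0, prop_sd[k]);
      if (prop[k] < -1.0 || prop[k] > 1.0) inside = false;
    }
    bool accept = false;
    if (inside) {
      double lpp = loglik(prop.data());
      if (R_finite(lpp) && std::log(unif_rand()) < lpp - lp) {
        y = prop;
        lp = lpp;
        accept = true;
      }
    }
    if (accept) {
      ++acc;
      since_acc = 0;
    } else if (++since_acc >= 10000) {
      stop("MCMC stalled: no acceptance over 10000 consecutive steps");
    }
    if (i > burn && (i - burn) % thin == 0 && kk < keep) {
      for (int k = 0; k < n; ++k) samples(kk, k) = y[k];
      log_post[kk] = lp;
      ++kk;
    }
  }
  return List::create(_["samples"] = samples, _["log_post"] = log_post,
                      _["acceptance_rate"] = (double)acc / steps);
}
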