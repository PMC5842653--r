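// Transfer-matrix computations for the inhomogeneous 1D Ising chain
//
//   P(x) = (1/Z) exp{ sum_n a_n (2x_n - 1) + sum_{n>=2} c_n (2x_n-1)(2x_{n-1}-1) }
//
// All chain recursions rescale per step; logs of the scales are accumulated
// so that partition functions and marginal likelihoods remain finite for
// chains of hundreds of sites with large |a|, |c|.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double spin(int x) { return 2.0 * x - 1.0; }

// Forward/backward messages for a chain with fields a[0..R-1] and couplings
// c[1..R-1] (c[0] ignored).  fn[n][x] is the normalized forward message
// (sums to 1 over x); logF[n] its log scale, so the unnormalized forward
// message is fn[n][x] * exp(logF[n]) and log Z = logF[R-1].
// bn[n][x] is the normalized backward message with log scale logB[n]
// (unnormalized b*[R-1][x] = 1).
struct Messages {
  int R;
  std::vector<double> fn, bn, logF, logB;
  double logZ;
};

Messages compute_messages(const NumericVector& a, const NumericVector& c) {
  int R = a.size();
  Messages M;
  M.R = R;
  M.fn.assign(2 * R, 0.0);
  M.bn.assign(2 * R, 0.0);
  M.logF.assign(R, 0.0);
  M.logB.assign(R, 0.0);

  // forward
  double f0 = std::exp(-a[0]), f1 = std::exp(a[0]);
  double s = f0 + f1;
  M.fn[0] = f0 / s; M.fn[1] = f1 / s;
  M.logF[0] = std::log(s);
  for (int n = 1; n < R; ++n) {
    double g[2];
    for (int x = 0; x < 2; ++x) {
      double acc = 0.0;
      for (int xp = 0; xp < 2; ++xp)
        acc += M.fn[2 * (n - 1) + xp] * std::exp(c[n] * spin(x) * spin(xp));
      g[x] = std::exp(a[n] * spin(x)) * acc;
    }
    s = g[0] + g[1];
    M.fn[2 * n] = g[0] / s; M.fn[2 * n + 1] = g[1] / s;
    M.logF[n] = M.logF[n - 1] + std::log(s);
  }
  M.logZ = M.logF[R - 1];

  // backward
  M.bn[2 * (R - 1)] = 0.5; M.bn[2 * (R - 1) + 1] = 0.5;
  M.logB[R - 1] = std::log(2.0);
  for (int n = R - 2; n >= 0; --n) {
    double g[2];
    for (int x = 0; x < 2; ++x) {
      double acc = 0.0;
      for (int xn = 0; xn < 2; ++xn)
        acc += std::exp(c[n + 1] * spin(x) * spin(xn) + a[n + 1] * spin(xn)) *
               M.bn[2 * (n + 1) + xn];
      g[x] = acc;
    }
    s = g[0] + g[1];
    M.bn[2 * n] = g[0] / s; M.bn[2 * n + 1] = g[1] / s;
    M.logB[n] = M.logB[n + 1] + std::log(s);
  }
  return M;
}

// log marginal probability of one contiguous block of fixed states
// sites i..j (0-based), states st[0..j-i].
double block_logmarg(const Messages& M, const NumericVector& a,
                     const NumericVector& c, int i, int j, const int* st) {
  double logg;
  int s0 = st[0];
  if (i == 0) {
    logg = a[0] * spin(s0);
  } else {
    double acc = 0.0;
    for (int xp = 0; xp < 2; ++xp)
      acc += M.fn[2 * (i - 1) + xp] * std::exp(c[i] * spin(s0) * spin(xp));
    logg = M.logF[i - 1] + a[i] * spin(s0) + std::log(acc);
  }
  for (int n = i + 1; n <= j; ++n) {
    logg += c[n] * spin(st[n - i]) * spin(st[n - i - 1]) + a[n] * spin(st[n - i]);
  }
  int sj = st[j - i];
  if (j < M.R - 1) {
    logg += M.logB[j] + std::log(M.bn[2 * j + sj]);
  }
  return logg - M.logZ;
}

} // namespace

// [[Rcpp::export]]
double cpp_ising_logZ(NumericVector a, NumericVector c) {
  return compute_messages(a, c).logZ;
}

// [[Rcpp::export]]
NumericVector cpp_ising_site_marginals(NumericVector a, NumericVector c) {
  Messages M = compute_messages(a, c);
  int R = a.size();
  NumericVector p(R);
  for (int n = 0; n < R; ++n) {
    double q0 = M.fn[2 * n] * M.bn[2 * n];
    double q1 = M.fn[2 * n + 1] * M.bn[2 * n + 1];
    p[n] = q1 / (q0 + q1);
  }
  return p;
}

// Per-read log marginal likelihoods.  Reads are passed in CSR layout:
// read m covers entries ptr[m] .. ptr[m+1]-1 of `sites` (1-based CpG index
// within the region, sorted ascending per read) and `states` (0/1).
// Non-contiguous reads are split into maximal contiguous runs and the
// product of the run marginals is returned (log-sum).
// [[Rcpp::export]]
NumericVector cpp_ising_read_logliks(NumericVector a, NumericVector c,
                                     IntegerVector ptr, IntegerVector sites,
                                     IntegerVector states) {
  Messages M = compute_messages(a, c);
  int nread = ptr.size() - 1;
  NumericVector out(nread);
  std::vector<int> st;
  for (int m = 0; m < nread; ++m) {
    int lo = ptr[m], hi = ptr[m + 1]; // half-open, 0-based into sites
    double ll = 0.0;
    int runstart = lo;
    for (int k = lo + 1; k <= hi; ++k) {
      if (k == hi || sites[k] != sites[k - 1] + 1) {
        int i = sites[runstart] - 1, j = sites[k - 1] - 1;
        st.assign(states.begin() + runstart, states.begin() + k);
        ll += block_logmarg(M, a, c, i, j, st.data());
        runstart = k;
      }
    }
    out[m] = ll;
  }
  return out;
}

// PMF of the methylation level L = (1/K) sum X over GU sites gu_lo..gu_hi
// (1-based, contiguous), marginalizing all flanking sites of the region.
// Returns probabilities for counts 0..K.
// [[Rcpp::export]]
NumericVector cpp_ising_level_pmf(NumericVector a, NumericVector c,
                                  int gu_lo, int gu_hi) {
  Messages M = compute_messages(a, c);
  int i = gu_lo - 1, j = gu_hi - 1;
  int K = j - i + 1;
  // d[x][k]: restricted forward over the GU with k methylated so far
  std::vector<double> d(2 * (K + 1), 0.0), dn(2 * (K + 1), 0.0);
  double logD = 0.0;
  for (int x = 0; x < 2; ++x) {
    double base;
    if (i == 0) {
      base = std::exp(a[0] * spin(x));
    } else {
      double acc = 0.0;
      for (int xp = 0; xp < 2; ++xp)
        acc += M.fn[2 * (i - 1) + xp] * std::exp(c[i] * spin(x) * spin(xp));
      base = std::exp(a[i] * spin(x)) * acc;
    }
    d[x * (K + 1) + x] = base;
  }
  if (i > 0) logD = M.logF[i - 1];
  for (int n = i + 1; n <= j; ++n) {
    std::fill(dn.begin(), dn.end(), 0.0);
    int kmax = n - i + 1; // sites seen so far bound the methylated count
    for (int x = 0; x < 2; ++x) {
      double wx = std::exp(a[n] * spin(x));
      for (int k = x; k <= kmax; ++k) {
        double acc = 0.0;
        for (int xp = 0; xp < 2; ++xp)
          acc += std::exp(c[n] * spin(x) * spin(xp)) * d[xp * (K + 1) + (k - x)];
        dn[x * (K + 1) + k] = wx * acc;
      }
    }
    double mx = 0.0;
    for (size_t q = 0; q < dn.size(); ++q) if (dn[q] > mx) mx = dn[q];
    for (size_t q = 0; q < dn.size(); ++q) dn[q] /= mx;
    logD += std::log(mx);
    d.swap(dn);
  }
  NumericVector p(K + 1);
  double logTail = (j < M.R - 1) ? M.logB[j] : 0.0;
  for (int k = 0; k <= K; ++k) {
    double acc = 0.0;
    for (int x = 0; x < 2; ++x) {
      double tail = (j < M.R - 1) ? M.bn[2 * j + x] : 1.0;
      acc += d[x * (K + 1) + k] * tail;
    }
    p[k] = (acc > 0) ? std::exp(std::log(acc) + logD + logTail - M.logZ) : 0.0;
  }
  double s = sum(p);
  for (int k = 0; k <= K; ++k) p[k] /= s;
  return p;
}

// Exact forward sampling: X_1 from its marginal, then X_n | X_{n-1} from the
// exact chain conditionals built from backward messages.  Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_ising_sample(NumericVector a, NumericVector c, int nsamp) {
  Messages M = compute_messages(a, c);
  int R = a.size();
  IntegerMatrix out(nsamp, R);
  // first-site marginal
  double q0 = std::exp(-a[0]) * M.bn[0];
  double q1 = std::exp(a[0]) * M.bn[1];
  double p1first = q1 / (q0 + q1);
  // conditional P(x_n = 1 | x_{n-1}) for n >= 1
  std::vector<double> cond(2 * R, 0.0);
  for (int n = 1; n < R; ++n) {
    for (int xp = 0; xp < 2; ++xp) {
      double g0 = std::exp(c[n] * spin(xp) * -1.0 - a[n]) * M.bn[2 * n];
      double g1 = std::exp(c[n] * spin(xp) * 1.0 + a[n]) * M.bn[2 * n + 1];
      cond[2 * n + xp] = g1 / (g0 + g1);
    }
  }
  GetRNGstate();
  for (int m = 0; m < nsamp; ++m) {
    int x = (unif_rand() < p1first) ? 1 : 0;
    out(m, 0) = x;
    for (int n = 1; n < R; ++n) {
      x = (unif_rand() < cond[2 * n + x]) ? 1 : 0;
      out(m, n) = x;
    }
  }
  PutRNGstate();
  return out;
}
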