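#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Compiled per-generation cycle: decay -> mutant creation -> selection ->
// (drift) -> extinction pruning.  Draws come from R's RNG in exactly the
// order the pure-R engine consumes them, so the two paths are comparable
// realization by realization under a common seed.

namespace {

// column-major flat symmetric matrix, size n*n
inline double &at(std::vector<double> &w, int n, int i, int j) {
  return w[i + static_cast<size_t>(j) * n];
}

double wbar_of(const std::vector<double> &w, const std::vector<double> &p,
               int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int j = 0; j < n; ++j)
      m += w[i + static_cast<size_t>(j) * n] * p[j];
    s += p[i] * m;
  }
  return s;
}

int nc_of(const std::vector<double> &p, double common_threshold) {
  int c = 0;
  for (double q : p)
    if (q > common_threshold) ++c;
  return c;
}

} // namespace

// [[Rcpp::export]]
List run_sim_cpp(bool infinite, double N, bool gendom, double alpha,
                 int decay_kind, double d, double mu, double sigma,
                 int generations, int census_at, double p0,
                 double extinct_threshold, double common_threshold,
                 bool record_trajectory, bool verbose) {
  int n = 1;
  std::vector<double> w, X, p;
  std::vector<int> labels;
  std::vector<char> seen;
  int next_label = 2, turnover = 0;

  if (gendom) {
    double X1 = R::runif(0, 1);
    double Y11 = R::runif(0, 1);
    X.assign(1, X1);
    w.assign(1, 2 * alpha * X1 + (1 - 2 * alpha) * Y11);
  } else {
    w.assign(1, 0.5);
  }
  p.assign(1, 1.0);
  labels.assign(1, 1);
  seen.assign(1, 0);
  if (p[0] > common_threshold) {
    seen[0] = 1;
    ++turnover;
  }

  NumericMatrix traj;
  if (record_trajectory) {
    traj = NumericMatrix(generations + 1, 3);
    traj(0, 0) = n;
    traj(0, 1) = nc_of(p, common_threshold);
    traj(0, 2) = wbar_of(w, p, n);
  }

  // census snapshot
  std::vector<double> cw = w, cX = X, cp = p;
  std::vector<int> clab = labels;
  double cwb = wbar_of(w, p, n);
  int cn = n, cturn = turnover;

  std::vector<int> counts;
  std::vector<double> mfit;
  const int size2N = infinite ? 0 : static_cast<int>(std::lround(2.0 * N));

  for (int t = 1; t <= generations; ++t) {
    // 1. environmental decay
    if (decay_kind == 1) {
      for (double &v : w) v *= d;
      if (gendom)
        for (double &v : X) v *= d;
    } else if (decay_kind == 2) {
      for (int j = 0; j < n; ++j)
        for (int i = 0; i <= j; ++i) {
          double dij = R::rnorm(mu, sigma);
          double v = at(w, n, i, j) * dij;
          if (v < 0) v = 0;
          if (v > 1) v = 1;
          at(w, n, i, j) = v;
          at(w, n, j, i) = v;
        }
    }
    // 2. one novel mutant: fresh viabilities, introduction at p0
    {
      const int m = n + 1;
      std::vector<double> w2(static_cast<size_t>(m) * m);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          w2[i + static_cast<size_t>(j) * m] =
              w[i + static_cast<size_t>(j) * n];
      if (!gendom) {
        for (int i = 0; i < m; ++i) {
          double u = R::runif(0, 1);
          w2[i + static_cast<size_t>(n) * m] = u;
          w2[n + static_cast<size_t>(i) * m] = u;
        }
      } else {
        double Xn = R::runif(0, 1);
        for (int i = 0; i < m; ++i) {
          double Y = R::runif(0, 1);
          double Xi = (i < n) ? X[i] : Xn;
          double v = alpha * (Xi + Xn) + (1 - 2 * alpha) * Y;
          w2[i + static_cast<size_t>(n) * m] = v;
          w2[n + static_cast<size_t>(i) * m] = v;
        }
        X.push_back(Xn);
      }
      w.swap(w2);
      for (double &q : p) q *= (1.0 - p0);
      p.push_back(p0);
      labels.push_back(next_label++);
      seen.push_back(0);
      n = m;
    }
    // 3. deterministic viability selection
    {
      mfit.assign(n, 0.0);
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.0;
        for (int j = 0; j < n; ++j)
          m += w[i + static_cast<size_t>(j) * n] * p[j];
        mfit[i] = m;
        s += p[i] * m;
      }
      if (!(s > 0))
        stop("degenerate population: mean fitness is zero");
      for (int i = 0; i < n; ++i) p[i] = p[i] * mfit[i] / s;
    }
    // shared subset-and-renormalize step for both extinction rules
    auto compact = [&](bool below_cut) {
      std::vector<int> keep;
      keep.reserve(n);
      for (int i = 0; i < n; ++i) {
        bool k = below_cut ? (p[i] >= extinct_threshold) : (p[i] > 0);
        if (k) keep.push_back(i);
      }
      if (keep.empty())
        stop("impossible state: all alleles would be extinct");
      if (static_cast<int>(keep.size()) < n) {
        const int m = static_cast<int>(keep.size());
        std::vector<double> w2(static_cast<size_t>(m) * m), p2(m);
        std::vector<int> lab2(m);
        std::vector<char> seen2(m);
        for (int a = 0; a < m; ++a) {
          p2[a] = p[keep[a]];
          lab2[a] = labels[keep[a]];
          seen2[a] = seen[keep[a]];
          for (int b = 0; b < m; ++b)
            w2[a + static_cast<size_t>(b) * m] =
                w[keep[a] + static_cast<size_t>(keep[b]) * n];
        }
        if (gendom) {
          std::vector<double> X2(m);
          for (int a = 0; a < m; ++a) X2[a] = X[keep[a]];
          X.swap(X2);
        }
        w.swap(w2);
        p.swap(p2);
        labels.swap(lab2);
        seen.swap(seen2);
        n = m;
      }
      double s = 0.0;
      for (double q : p) s += q;
      for (double &q : p) q /= s;
    };
    // 4. Wright-Fisher multinomial drift; alleles sampled to zero copies are
    //    extinct immediately
    if (!infinite) {
      counts.assign(n, 0);
      rmultinom(size2N, p.data(), n, counts.data());
      for (int i = 0; i < n; ++i) p[i] = counts[i] / (2.0 * N);
      compact(false);
    }
    // bookkeeping on the extant (p > 0) state: newly common alleles,
    // trajectory, census snapshot.  The infinite-mode sub-threshold sweep is
    // applied after recording, i.e. it is the first thing that acts on these
    // frequencies going into the next generation.
    for (int i = 0; i < n; ++i)
      if (!seen[i] && p[i] > common_threshold) {
        seen[i] = 1;
        ++turnover;
      }
    if (record_trajectory) {
      traj(t, 0) = n;
      traj(t, 1) = nc_of(p, common_threshold);
      traj(t, 2) = wbar_of(w, p, n);
    }
    if (t == census_at) {
      cw = w;
      cX = X;
      cp = p;
      clab = labels;
      cwb = wbar_of(w, p, n);
      cn = n;
      cturn = turnover;
    }
    // 5. infinite-mode extinction: frequencies strictly below the threshold
    //    are rounded to zero and the alleles removed
    if (infinite) compact(true);
    if (verbose && t % 1000 == 0)
      Rcerr << "generation " << t << ": n=" << n
            << " n_c=" << nc_of(p, common_threshold)
            << " wbar=" << wbar_of(w, p, n) << "\n";
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix cwm(cn, cn);
  for (int j = 0; j < cn; ++j)
    for (int i = 0; i < cn; ++i)
      cwm(i, j) = cw[i + static_cast<size_t>(j) * cn];
  SEXP Xout = R_NilValue;
  if (gendom) Xout = NumericVector(cX.begin(), cX.end());
  List census = List::create(
      _["p"] = NumericVector(cp.begin(), cp.end()),
      _["labels"] = IntegerVector(clab.begin(), clab.end()),
      _["w"] = cwm, _["X"] = Xout, _["n"] = cn,
      _["n_c"] = nc_of(cp, common_threshold), _["mean_fitness"] = cwb,
      _["turnover"] = cturn);
  return List::create(_["census"] = census,
                      _["trajectory"] =
                          record_trajectory ? SEXP(traj) : R_NilValue);
}
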