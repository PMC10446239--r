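#include <RcppArmadillo.h>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::chrono::steady_clock sclock;

static inline double seconds_since(const sclock::time_point& t0) {
  return std::chrono::duration<double>(sclock::now() - t0).count();
}

// One coordinate hit-and-run chord: feasible step range along coordinate k.
// slacks s = b - A x (all >= 0), column = A.col(k).
// dplus = min over c_j >  zeroTol of s_j / c_j
// dminus = max over c_j < -zeroTol of s_j / c_j
static inline bool chord_bounds(const arma::vec& col, const arma::vec& s,
                                double zeroTol, double& dminus, double& dplus) {
  dminus = -arma::datum::inf;
  dplus = arma::datum::inf;
  const arma::uword n = col.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    const double c = col[j];
    if (c > zeroTol) {
      const double r = s[j] / c;
      if (r < dplus) dplus = r;
    } else if (c < -zeroTol) {
      const double r = s[j] / c;
      if (r > dminus) dminus = r;
    }
  }
  return std::isfinite(dminus) && std::isfinite(dplus);
}

// Coordinate hit-and-run with thinning on a rounded polytope {x : A x < b}.
// Stores a sample after every tau-th update (first store at update tau); each
// stored rounded state is back-transformed to flux space at storage time via
// nu = M x + cvec. Uses R's RNG stream: two uniform draws per update
// (coordinate index, step size). Returns per-phase wall-clock times.
// [[Rcpp::export(name = ".cpp_chrrt_chain")]]
List cpp_chrrt_chain(const arma::mat& A, const arma::vec& b,
                     const arma::vec& x0, const int N, const double tau,
                     const arma::mat& M, const arma::vec& cvec,
                     const bool storeRounded, const double zeroTol,
                     const int warmup) {
  const arma::uword d = A.n_cols;
  const arma::uword D = M.n_rows;
  if (x0.n_elem != d) stop("start vector has wrong dimension");
  if (M.n_cols != d) stop("back-transform operator has wrong dimension");
  if (N < 1) stop("N must be >= 1");
  if (tau < 1) stop("tau must be >= 1");

  arma::vec x = x0;
  arma::vec s = b - A * x;
  if (s.min() < -1e-9) stop("starting state is not feasible in the rounded polytope");
  s.transform([](double v) { return v < 0.0 ? 0.0 : v; });

  arma::mat orig(N, D);
  arma::mat rnd(storeRounded ? N : 0, storeRounded ? d : 0);

  double dminus, dplus;
  long long i = 0;
  int stored = 0;
  double tTransform = 0.0;
  const long long tauL = (long long)tau;

  const sclock::time_point tStart = sclock::now();

  for (int w = 0; w < warmup; ++w) {
    const double u1 = unif_rand();
    arma::uword k = (arma::uword)(u1 * d);
    if (k >= d) k = d - 1;
    if (!chord_bounds(A.col(k), s, zeroTol, dminus, dplus))
      stop("unbounded chord along coordinate %d: polytope contract violated",
           (int)k + 1);
    const double lam = dminus + unif_rand() * (dplus - dminus);
    x[k] += lam;
    s -= lam * A.col(k);
    if (s.min() < 0) s.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  }

  while (stored < N) {
    const double u1 = unif_rand();
    arma::uword k = (arma::uword)(u1 * d);
    if (k >= d) k = d - 1;
    if (!chord_bounds(A.col(k), s, zeroTol, dminus, dplus))
      stop("unbounded chord along coordinate %d: polytope contract violated",
           (int)k + 1);
    const double lam = dminus + unif_rand() * (dplus - dminus);
    x[k] += lam;
    s -= lam * A.col(k);
    if (s.min() < 0) s.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    ++i;
    if ((i & 4095LL) == 0LL) s = b - A * x;  // periodic exact refresh

    if (i % tauL == 0LL) {
      const sclock::time_point t1 = sclock::now();
      orig.row(stored) = (M * x + cvec).t();
      tTransform += seconds_since(t1);
      if (storeRounded) rnd.row(stored) = x.t();
      ++stored;
    }
  }

  const double tTotal = seconds_since(tStart);
  return List::create(
    _["original"] = orig,
    _["rounded"] = rnd,
    _["nUpdates"] = (double)i,
    _["updateTime"] = tTotal - tTransform,
    _["transformTime"] = tTransform);
}

// Timing probe: n back-transforms of the same vector (reported per call).
// [[Rcpp::export(name = ".cpp_time_transforms")]]
double cpp_time_transforms(const arma::mat& M, const arma::vec& cvec,
                           const arma::vec& x, const int n) {
  arma::vec acc(M.n_rows, arma::fill::zeros);
  const sclock::time_point t0 = sclock::now();
  for (int j = 0; j < n; ++j) acc += M * x + cvec;
  const double t = seconds_since(t0);
  if (acc.n_elem > 0 && !std::isfinite(acc[0])) stop("overflow in timing probe");
  return t / n;
}
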