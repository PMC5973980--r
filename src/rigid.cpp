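#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Closed-form least-squares rigid transform (Kabsch / Procrustes via SVD of
// the cross-covariance), mapping `moving` onto `fixed`; reflections excluded
// by flipping the sign of the smallest singular direction.
static void kabsch(const arma::mat &moving, const arma::mat &fixed,
                   arma::mat33 &R, arma::vec3 &t) {
  arma::rowvec cm = arma::mean(moving, 0), cf = arma::mean(fixed, 0);
  arma::mat H = (moving.each_row() - cm).t() * (fixed.each_row() - cf);
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cf.t() - R * cm.t();
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(NumericMatrix moving, NumericMatrix fixed) {
  arma::mat M(moving.begin(), moving.nrow(), 3, false);
  arma::mat F(fixed.begin(), fixed.nrow(), 3, false);
  arma::mat33 R;
  arma::vec3 t;
  kabsch(M, F, R, t);
  return List::create(_["rotation"] = wrap(arma::mat(R)), _["translation"] = wrap(arma::vec(t)));
}

// index (0-based) of the cloud point nearest to p; ties -> lowest index
static int nearest_idx(const arma::mat &cloud, const arma::rowvec &p, double &best) {
  best = arma::datum::inf;
  int bi = 0;
  for (arma::uword i = 0; i < cloud.n_rows; ++i) {
    double dx = cloud(i, 0) - p[0], dy = cloud(i, 1) - p[1], dz = cloud(i, 2) - p[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d < best) {
      best = d;
      bi = (int)i;
    }
  }
  return bi;
}

// [[Rcpp::export(name = ".closest_point_cpp")]]
List closest_point_cpp(NumericVector p, NumericMatrix cloud) {
  arma::mat C(cloud.begin(), cloud.nrow(), 3, false);
  arma::rowvec q = {p[0], p[1], p[2]};
  double d2;
  int i = nearest_idx(C, q, d2);
  return List::create(_["index"] = i + 1, _["distance"] = std::sqrt(d2));
}

static int runif_int(int n) {
  int j = (int)std::floor(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

// Stochastic correspondence seed for one start. Three anchor landmarks (the
// ones with the smallest clouds, i.e. the most localising structures) each
// draw a random point of their corresponding structure, rejecting draws
// whose pairwise distances are inconsistent with the landmarks' own
// (rigid-invariant) pairwise distances by more than `tau`. Several such
// triples are drawn per start and the one whose fitted pose best explains
// *all* landmarks wins; every landmark is then assigned its nearest point
// under that pose. Falls back to fully uniform draws if rejection fails.
static void seed_correspondences(const arma::mat &L, const IntegerVector &cloud_of,
                                 const std::vector<arma::mat> &C, double tau,
                                 int start, int n_starts, arma::mat &corr) {
  const int m = (int)L.n_rows;
  // anchors: three landmarks with the smallest corresponding clouds
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    return C[cloud_of[i]].n_rows < C[cloud_of[j]].n_rows;
  });
  const int a = ord[0], b = ord[1], c = ord[2];
  const double dab = arma::norm(L.row(a) - L.row(b));
  const double dac = arma::norm(L.row(a) - L.row(c));
  const double dbc = arma::norm(L.row(b) - L.row(c));
  const arma::mat &A = C[cloud_of[a]];
  const arma::mat &B = C[cloud_of[b]];
  const arma::mat &Cc = C[cloud_of[c]];

  double bestScore = arma::datum::inf;
  arma::mat33 bestR0;
  arma::vec3 bestT0;
  bool seeded = false;
  std::vector<int> cand;
  arma::mat anchorsL(3, 3), anchorsC(3, 3);
  anchorsL.row(0) = L.row(a);
  anchorsL.row(1) = L.row(b);
  anchorsL.row(2) = L.row(c);
  for (int attempt = 0; attempt < 15; ++attempt) {
    // first half of the attempts anchor on a stratified point of the
    // smallest cloud (starts jointly sweep it), the rest draw uniformly
    int ia;
    if (attempt < 8 && n_starts > 1) {
      double u = (start + unif_rand()) / n_starts;
      ia = (int)std::floor(u * A.n_rows);
      if (ia >= (int)A.n_rows) ia = (int)A.n_rows - 1;
    } else {
      ia = runif_int((int)A.n_rows);
    }
    arma::rowvec ca = A.row(ia);
    cand.clear();
    for (arma::uword i = 0; i < B.n_rows; ++i) {
      double dx = B(i, 0) - ca[0], dy = B(i, 1) - ca[1], dz = B(i, 2) - ca[2];
      if (std::abs(std::sqrt(dx * dx + dy * dy + dz * dz) - dab) <= tau)
        cand.push_back((int)i);
    }
    if (cand.empty()) continue;
    arma::rowvec cb = B.row(cand[runif_int((int)cand.size())]);
    cand.clear();
    for (arma::uword i = 0; i < Cc.n_rows; ++i) {
      double ax = Cc(i, 0) - ca[0], ay = Cc(i, 1) - ca[1], az = Cc(i, 2) - ca[2];
      if (std::abs(std::sqrt(ax * ax + ay * ay + az * az) - dac) > tau) continue;
      double bx = Cc(i, 0) - cb[0], by = Cc(i, 1) - cb[1], bz = Cc(i, 2) - cb[2];
      if (std::abs(std::sqrt(bx * bx + by * by + bz * bz) - dbc) <= tau)
        cand.push_back((int)i);
    }
    if (cand.empty()) continue;
    arma::rowvec cc = Cc.row(cand[runif_int((int)cand.size())]);
    anchorsC.row(0) = ca;
    anchorsC.row(1) = cb;
    anchorsC.row(2) = cc;
    arma::mat33 R0;
    arma::vec3 t0;
    kabsch(anchorsL, anchorsC, R0, t0);
    arma::mat Lt = L * R0.t();
    Lt.each_row() += t0.t();
    double ss = 0.0;
    for (int i = 0; i < m; ++i) {
      double d2;
      nearest_idx(C[cloud_of[i]], Lt.row(i), d2);
      ss += d2;
    }
    if (ss < bestScore) {
      bestScore = ss;
      bestR0 = R0;
      bestT0 = t0;
      seeded = true;
    }
  }
  if (seeded) {
    arma::mat Lt = L * bestR0.t();
    Lt.each_row() += bestT0.t();
    for (int i = 0; i < m; ++i) {
      double d2;
      int j = nearest_idx(C[cloud_of[i]], Lt.row(i), d2);
      corr.row(i) = C[cloud_of[i]].row(j);
    }
  } else {
    for (int i = 0; i < m; ++i) {
      const arma::mat &ci = C[cloud_of[i]];
      corr.row(i) = ci.row(runif_int((int)ci.n_rows));
    }
  }
}

// nearest-correspondence RMS of the pose fitted to `corr` (also updates
// `corr` to the nearest points under that pose)
static double fit_and_rms(const arma::mat &L, const IntegerVector &cloud_of,
                          const std::vector<arma::mat> &C, arma::mat &corr,
                          arma::mat33 &R, arma::vec3 &t) {
  kabsch(L, corr, R, t);
  arma::mat Lt = L * R.t();
  Lt.each_row() += t.t();
  double ss = 0.0;
  const int m = (int)L.n_rows;
  for (int i = 0; i < m; ++i) {
    double d2;
    int j = nearest_idx(C[cloud_of[i]], Lt.row(i), d2);
    corr.row(i) = C[cloud_of[i]].row(j);
    ss += d2;
  }
  return std::sqrt(ss / m);
}

// Discrete polish around a converged ICP state: nearest-point assignment is
// greedy per landmark, so converged states one cloud point away from the
// optimum are stable. Try the few nearest alternative correspondences for
// each landmark in turn and re-fit, keeping strict improvements.
static double polish_correspondences(const arma::mat &L, const IntegerVector &cloud_of,
                                     const std::vector<arma::mat> &C, arma::mat &corr,
                                     arma::mat33 &R, arma::vec3 &t, double rms) {
  const int m = (int)L.n_rows;
  const int K = 3;
  for (int sweep = 0; sweep < 5; ++sweep) {
    bool improved = false;
    arma::mat Lt = L * R.t();
    Lt.each_row() += t.t();
    for (int i = 0; i < m; ++i) {
      const arma::mat &ci = C[cloud_of[i]];
      // K nearest candidates for landmark i under the current pose
      // (single pass, ties keep the lower index)
      int k = std::min<int>(K, (int)ci.n_rows);
      double bd[3] = {arma::datum::inf, arma::datum::inf, arma::datum::inf};
      int bi[3] = {0, 0, 0};
      const double px = Lt(i, 0), py = Lt(i, 1), pz = Lt(i, 2);
      for (arma::uword j = 0; j < ci.n_rows; ++j) {
        double dx = ci(j, 0) - px, dy = ci(j, 1) - py, dz = ci(j, 2) - pz;
        double d = dx * dx + dy * dy + dz * dz;
        if (d < bd[k - 1]) {
          int pos = k - 1;
          while (pos > 0 && d < bd[pos - 1]) {
            bd[pos] = bd[pos - 1];
            bi[pos] = bi[pos - 1];
            --pos;
          }
          bd[pos] = d;
          bi[pos] = (int)j;
        }
      }
      for (int cidx = 0; cidx < k; ++cidx) {
        arma::mat corr2 = corr;
        corr2.row(i) = ci.row(bi[cidx]);
        arma::mat33 R2;
        arma::vec3 t2;
        double rms2 = fit_and_rms(L, cloud_of, C, corr2, R2, t2);
        if (rms2 < rms - 1e-12) {
          rms = rms2;
          corr = corr2;
          R = R2;
          t = t2;
          Lt = L * R.t();
          Lt.each_row() += t.t();
          improved = true;
        }
      }
    }
    if (!improved) break;
  }
  return rms;
}

// Landmark-to-structure ICP with stochastic correspondence initialisation.
// Each landmark is constrained to its own structure's point cloud at every
// iteration. Random draws come from R's RNG so set.seed() governs them.
// [[Rcpp::export(name = ".icp_register_cpp")]]
List icp_register_cpp(NumericMatrix landmarks, IntegerVector cloud_of, List clouds,
                      int n_starts, int max_iter, double tol, double init_tol) {
  const int m = landmarks.nrow();
  arma::mat L(landmarks.begin(), m, 3, false);
  std::vector<arma::mat> C;
  for (int k = 0; k < clouds.size(); ++k) {
    NumericMatrix ck = clouds[k];
    C.emplace_back(ck.begin(), ck.nrow(), 3, true);
  }
  RNGScope scope;

  arma::mat33 bestR = arma::eye(3, 3);
  arma::vec3 bestT = arma::zeros(3);
  double bestRms = arma::datum::inf;
  int bestIter = 0;
  bool bestConv = false;
  std::vector<double> bestTrace;

  arma::mat corr(m, 3);
  for (int s = 0; s < n_starts; ++s) {
    seed_correspondences(L, cloud_of, C, init_tol, s, n_starts, corr);
    arma::mat33 R;
    arma::vec3 t;
    double prev = arma::datum::inf, rms = arma::datum::inf;
    int it = 0;
    bool conv = false;
    std::vector<double> trace;
    for (it = 1; it <= max_iter; ++it) {
      kabsch(L, corr, R, t);
      arma::mat Lt = L * R.t();
      Lt.each_row() += t.t();
      double ss = 0.0;
      for (int i = 0; i < m; ++i) {
        double d2;
        int j = nearest_idx(C[cloud_of[i]], Lt.row(i), d2);
        corr.row(i) = C[cloud_of[i]].row(j);
        ss += d2;
      }
      rms = std::sqrt(ss / m);
      trace.push_back(rms);
      if (std::abs(prev - rms) < tol) {
        conv = true;
        break;
      }
      prev = rms;
    }
    rms = polish_correspondences(L, cloud_of, C, corr, R, t, rms);
    if (trace.empty() || rms < trace.back()) trace.push_back(rms);
    if (rms < bestRms) {
      bestRms = rms;
      bestR = R;
      bestT = t;
      bestIter = std::min(it, max_iter);
      bestConv = conv;
      bestTrace = trace;
    }
  }
  return List::create(_["rotation"] = wrap(arma::mat(bestR)),
                      _["translation"] = wrap(arma::vec(bestT)),
                      _["rms_mm"] = bestRms, _["iterations"] = bestIter,
                      _["converged"] = bestConv,
                      _["trace"] = NumericVector(bestTrace.begin(), bestTrace.end()));
}
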