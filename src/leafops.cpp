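// Per-point surface operators used by leaf-centre detection and leaf
// modelling: constrained plane fits, robust (iteratively reweighted) normals,
// the 40-cell angular uniformity statistic, and MLS smoothing.
#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec3 prow(const arma::mat& P, int i) {
  return arma::vec3{P(i, 0), P(i, 1), P(i, 2)};
}

// smallest-eigenvalue eigenvector of a symmetric 3x3 matrix
static arma::vec3 smallest_evec(const arma::mat33& M) {
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, arma::mat(M));
  return arma::vec3{evec(0, 0), evec(1, 0), evec(2, 0)};
}

// sign convention: z >= 0, ties broken by y >= 0 then x >= 0
static arma::vec3 fix_sign(arma::vec3 v) {
  double tol = 0.0;
  if (v[2] < tol || (v[2] == 0 && (v[1] < 0 || (v[1] == 0 && v[0] < 0)))) v = -v;
  return v;
}

// plane through the centre point: normal = smallest eigenvector of sum w w^T
static void plane_through_point(const arma::mat& W, arma::vec3& nrm, double& meanDist,
                                double& lam1) {
  arma::mat33 S(arma::fill::zeros);
  for (arma::uword j = 0; j < W.n_rows; ++j) {
    arma::vec3 w = prow(W, j);
    S += w * w.t();
  }
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, arma::mat(S));
  lam1 = eval(2);
  nrm = fix_sign(arma::vec3{evec(0, 0), evec(1, 0), evec(2, 0)});
  double s = 0;
  for (arma::uword j = 0; j < W.n_rows; ++j) s += std::fabs(arma::dot(prow(W, j), nrm));
  meanDist = W.n_rows ? s / W.n_rows : 0.0;
}

// iteratively reweighted robust normal (Gaussian weights on plane offsets)
static arma::vec3 irls_normal(const arma::mat& W, int maxIter, double angTol) {
  arma::vec3 n0; double md, lam1;
  plane_through_point(W, n0, md, lam1);
  arma::vec res(W.n_rows);
  for (arma::uword j = 0; j < W.n_rows; ++j) res(j) = std::fabs(arma::dot(prow(W, j), n0));
  double h = arma::median(res);
  if (!(h > 0)) return n0;  // exactly planar: weights are irrelevant
  arma::vec3 nrm = n0;
  for (int it = 0; it < maxIter; ++it) {
    arma::mat33 S(arma::fill::zeros);
    for (arma::uword j = 0; j < W.n_rows; ++j) {
      arma::vec3 w = prow(W, j);
      double r = arma::dot(w, nrm);
      double om = std::exp(-(r * r) / (h * h));
      S += om * (w * w.t());
    }
    arma::vec3 nn = fix_sign(smallest_evec(S));
    double ca = std::min(1.0, std::fabs(arma::dot(nn, nrm)));
    double ang = std::acos(ca);
    nrm = nn;
    if (ang < angTol) break;
  }
  return nrm;
}

// deterministic in-plane orthonormal basis for a unit normal
static void plane_basis(const arma::vec3& n, arma::vec3& u, arma::vec3& v) {
  arma::vec3 e{0, 0, 0};
  arma::vec3 an = arma::abs(n);
  if (an[0] <= an[1] && an[0] <= an[2]) e[0] = 1;
  else if (an[1] <= an[2]) e[1] = 1;
  else e[2] = 1;
  u = arma::normalise(arma::cross(n, e));
  v = arma::cross(n, u);
}

// index-of-dispersion over 8 sectors x 5 equal-area annuli
static double sigma_prime(const arma::mat& Q, const arma::vec3& centre,
                          const arma::vec3& nrm, double R) {
  arma::vec3 u, v;
  plane_basis(nrm, u, v);
  int counts[40] = {0};
  int kept = 0;
  for (arma::uword j = 0; j < Q.n_rows; ++j) {
    arma::vec3 w = prow(Q, j) - centre;
    double x = arma::dot(w, u), y = arma::dot(w, v);
    double r2 = x * x + y * y;
    if (r2 > R * R) continue;
    int d = (r2 <= 0) ? 1 : (int)std::ceil(5.0 * r2 / (R * R));
    if (d < 1) d = 1;
    if (d > 5) d = 5;
    double phi = std::atan2(y, x);
    if (phi < 0) phi += 2.0 * M_PI;
    int s = (int)std::floor(phi / (M_PI / 4.0));
    if (s > 7) s = 7;
    counts[(d - 1) * 8 + s]++;
    kept++;
  }
  double mu = kept / 40.0;
  if (!(mu > 0)) return R_PosInf;
  double ss = 0;
  for (int c = 0; c < 40; ++c) { double dd = counts[c] - mu; ss += dd * dd; }
  return ss / 40.0 / mu;
}

// [[Rcpp::export(name = ".planeThroughPointCpp")]]
List planeThroughPointCpp(const arma::mat& offsets) {
  arma::vec3 nrm; double md, lam1;
  plane_through_point(offsets, nrm, md, lam1);
  return List::create(_["normal"] = NumericVector::create(nrm[0], nrm[1], nrm[2]),
                      _["meanDistance"] = md, _["lambda1"] = lam1);
}

// [[Rcpp::export(name = ".irlsNormalCpp")]]
NumericVector irlsNormalCpp(const arma::mat& offsets, int maxIter, double angTol) {
  arma::vec3 nrm = irls_normal(offsets, maxIter, angTol);
  return NumericVector::create(nrm[0], nrm[1], nrm[2]);
}

// [[Rcpp::export(name = ".sigmaPrimeCpp")]]
double sigmaPrimeCpp(const arma::mat& pts, const arma::vec& centre, const arma::vec& nrm,
                     double R) {
  return sigma_prime(pts, arma::vec3{centre[0], centre[1], centre[2]},
                     arma::vec3{nrm[0], nrm[1], nrm[2]}, R);
}

// Batch leaf-centre statistics. Neighbour lists in flattened 1-based form.
// Returns per point: mean plane distance, robust normal, plane normal,
// neighbour count; second pass (consistency + uniformity) done here too.
// [[Rcpp::export(name = ".centreStatsCpp")]]
List centreStatsCpp(const arma::mat& P, const IntegerVector& nbrFlat,
                    const IntegerVector& nbrOff, double radius, double threshold1,
                    double threshold2, int minNeighbors) {
  const int n = P.n_rows;
  NumericVector meanDist(n, NA_REAL), meanAngle(n, NA_REAL), sigma(n, NA_REAL);
  IntegerVector nNbr(n);
  arma::mat normals(n, 3, arma::fill::zeros);
  arma::mat planeN(n, 3, arma::fill::zeros);
  LogicalVector okPlane(n, false);

  for (int i = 0; i < n; ++i) {
    int lo = nbrOff[i], hi = nbrOff[i + 1];
    int m = hi - lo;
    nNbr[i] = m;
    if (m < 3) continue;
    arma::mat W(m, 3);
    for (int t = 0; t < m; ++t) {
      int j = nbrFlat[lo + t] - 1;
      W(t, 0) = P(j, 0) - P(i, 0);
      W(t, 1) = P(j, 1) - P(i, 1);
      W(t, 2) = P(j, 2) - P(i, 2);
    }
    arma::vec3 pn; double md, lam1;
    plane_through_point(W, pn, md, lam1);
    if (!(lam1 > 0)) continue;
    meanDist[i] = md;
    planeN.row(i) = pn.t();
    arma::vec3 rn = irls_normal(W, 20, 1e-4);
    normals.row(i) = rn.t();
    okPlane[i] = true;
  }

  // normal-consistency + uniformity for candidates passing the distance test
  for (int i = 0; i < n; ++i) {
    if (!okPlane[i] || nNbr[i] < minNeighbors) continue;
    if (!(meanDist[i] < threshold1)) continue;
    int lo = nbrOff[i], hi = nbrOff[i + 1];
    int m = hi - lo;
    double s = 0;
    arma::vec3 ni{normals(i, 0), normals(i, 1), normals(i, 2)};
    for (int t = 0; t < m; ++t) {
      int j = nbrFlat[lo + t] - 1;
      arma::vec3 nj{normals(j, 0), normals(j, 1), normals(j, 2)};
      double ca = std::fabs(arma::dot(ni, nj));
      if (ca > 1) ca = 1;
      s += std::acos(ca);
    }
    meanAngle[i] = s / m;
    if (!(meanAngle[i] < threshold2)) continue;
    // project neighbours onto the great-circle plane through p_i, then sigma'
    arma::vec3 pn{planeN(i, 0), planeN(i, 1), planeN(i, 2)};
    arma::vec3 pi = prow(P, i);
    double D = arma::dot(pn, pi);
    arma::mat Q(m, 3);
    for (int t = 0; t < m; ++t) {
      int j = nbrFlat[lo + t] - 1;
      arma::vec3 pj = prow(P, j);
      arma::vec3 q = pj - (arma::dot(pn, pj) - D) * pn;
      Q.row(t) = q.t();
    }
    sigma[i] = sigma_prime(Q, pi, pn, radius);
  }

  return List::create(_["meanDistance"] = meanDist, _["meanAngle"] = meanAngle,
                      _["sigma"] = sigma, _["nNeighbors"] = nNbr,
                      _["normal"] = wrap(normals), _["planeNormal"] = wrap(planeN));
}

// Moving-least-squares smoothing: project each point onto a locally weighted
// polynomial surface fitted in the local tangent frame.
// [[Rcpp::export(name = ".mlsSmoothCpp")]]
arma::mat mlsSmoothCpp(const arma::mat& P, const IntegerVector& nbrFlat,
                       const IntegerVector& nbrOff, double bandwidth, int degree) {
  const int n = P.n_rows;
  arma::mat out = P;
  const double bw2 = 2.0 * bandwidth * bandwidth;
  for (int i = 0; i < n; ++i) {
    int lo = nbrOff[i], hi = nbrOff[i + 1];
    int m = hi - lo;  // neighbour list includes the point itself
    if (m < 3) continue;
    arma::mat X(m, 3);
    arma::vec wgt(m);
    arma::vec3 pi = prow(P, i);
    for (int t = 0; t < m; ++t) {
      int j = nbrFlat[lo + t] - 1;
      X.row(t) = P.row(j);
      arma::vec3 d = prow(P, j) - pi;
      wgt(t) = std::exp(-arma::dot(d, d) / bw2);
    }
    // weighted centroid + tangent frame from the weighted covariance
    arma::rowvec mu = (wgt.t() * X) / arma::accu(wgt);
    arma::mat Xc = X.each_row() - mu;
    arma::mat33 S(arma::fill::zeros);
    for (int t = 0; t < m; ++t)
      S += wgt(t) * (Xc.row(t).t() * Xc.row(t));
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, arma::mat(S));
    arma::vec3 e3{evec(0, 0), evec(1, 0), evec(2, 0)};
    arma::vec3 e1{evec(0, 2), evec(1, 2), evec(2, 2)};
    arma::vec3 e2{evec(0, 1), evec(1, 1), evec(2, 1)};
    arma::vec u(m), v(m), z(m);
    for (int t = 0; t < m; ++t) {
      arma::vec3 d{Xc(t, 0), Xc(t, 1), Xc(t, 2)};
      u(t) = arma::dot(d, e1); v(t) = arma::dot(d, e2); z(t) = arma::dot(d, e3);
    }
    int deg = degree;
    if (deg == 2 && m < 6) deg = 1;
    int q = (deg == 2) ? 6 : 3;
    arma::mat B(m, q);
    for (int t = 0; t < m; ++t) {
      B(t, 0) = 1; B(t, 1) = u(t); B(t, 2) = v(t);
      if (q == 6) { B(t, 3) = u(t) * u(t); B(t, 4) = u(t) * v(t); B(t, 5) = v(t) * v(t); }
    }
    arma::mat BW = B.each_col() % wgt;
    arma::mat A = BW.t() * B;
    arma::vec rhs = BW.t() * z;
    arma::vec coef;
    if (!arma::solve(coef, A, rhs, arma::solve_opts::no_approx)) {
      if (q == 6) {  // fall back to a plane for this point
        arma::mat B1 = B.cols(0, 2);
        arma::mat BW1 = BW.cols(0, 2);
        if (!arma::solve(coef, BW1.t() * B1, BW1.t() * z, arma::solve_opts::no_approx))
          continue;
        q = 3;
      } else continue;
    }
    arma::vec3 d0 = pi - arma::vec3{mu(0), mu(1), mu(2)};
    double u0 = arma::dot(d0, e1), v0 = arma::dot(d0, e2);
    double z0 = coef(0) + coef(1) * u0 + coef(2) * v0;
    if (q == 6) z0 += coef(3) * u0 * u0 + coef(4) * u0 * v0 + coef(5) * v0 * v0;
    arma::vec3 np = arma::vec3{mu(0), mu(1), mu(2)} + u0 * e1 + v0 * e2 + z0 * e3;
    out.row(i) = np.t();
  }
  return out;
}

// covariance eigen-features of neighbourhoods (linearity/planarity/scattering)
// [[Rcpp::export(name = ".eigenFeaturesBatchCpp")]]
List eigenFeaturesBatchCpp(const arma::mat& P, const IntegerVector& nbrFlat,
                           const IntegerVector& nbrOff) {
  const int n = nbrOff.size() - 1;
  NumericVector lin(n, NA_REAL), pla(n, NA_REAL), sca(n, NA_REAL);
  arma::mat lam(n, 3, arma::fill::value(NA_REAL));
  for (int i = 0; i < n; ++i) {
    int lo = nbrOff[i], hi = nbrOff[i + 1];
    int m = hi - lo;
    if (m < 3) continue;
    arma::mat X(m, 3);
    for (int t = 0; t < m; ++t) X.row(t) = P.row(nbrFlat[lo + t] - 1);
    arma::rowvec mu = arma::mean(X, 0);
    arma::mat Xc = X.each_row() - mu;
    arma::mat33 S = arma::mat33(Xc.t() * Xc) / m;
    arma::vec eval;
    arma::eig_sym(eval, arma::mat(S));
    double l3 = std::max(0.0, eval(0)), l2 = std::max(0.0, eval(1)),
           l1 = std::max(0.0, eval(2));
    lam(i, 0) = l1; lam(i, 1) = l2; lam(i, 2) = l3;
    if (l1 > 0) {
      lin[i] = (l1 - l2) / l1;
      pla[i] = (l2 - l3) / l1;
      sca[i] = l3 / l1;
    } else { lin[i] = 0; pla[i] = 0; sca[i] = 1; }
  }
  return List::create(_["linearity"] = lin, _["planarity"] = pla,
                      _["scattering"] = sca, _["eigenvalues"] = wrap(lam));
}

// batch principal direction (largest-eigenvalue eigenvector) of local
// neighbourhoods; used for direction-aware branch decomposition
// [[Rcpp::export(name = ".principalDirectionsCpp")]]
arma::mat principalDirectionsCpp(const arma::mat& P, const IntegerVector& nbrFlat,
                                 const IntegerVector& nbrOff) {
  const int n = nbrOff.size() - 1;
  arma::mat out(n, 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int lo = nbrOff[i], hi = nbrOff[i + 1];
    int m = hi - lo;
    if (m < 3) continue;
    arma::mat X(m, 3);
    for (int t = 0; t < m; ++t) X.row(t) = P.row(nbrFlat[lo + t] - 1);
    arma::rowvec mu = arma::mean(X, 0);
    arma::mat Xc = X.each_row() - mu;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, arma::mat33(Xc.t() * Xc));
    out(i, 0) = evec(0, 2); out(i, 1) = evec(1, 2); out(i, 2) = evec(2, 2);
  }
  return out;
}
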