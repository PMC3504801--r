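// Kabsch superposition RMSD kernels.
//
// These sit in the inner loop of the within-generation clustering, which
// needs all pairwise superposed C-alpha RMSDs of the expanded population
// (quadratic in pool size), so they are compiled.
//
// Flat layout convention: one model per row, length 3*m, atom-major
// (x1, y1, z1, x2, y2, z2, ...).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Minimized MSD between centered coordinate sets A, B (m x 3) with
// precomputed squared norms. d = +1 rotation branch of the Kabsch solution.
static double kabsch_msd(const arma::mat& A, const arma::mat& B,
                         double ssqA, double ssqB) {
  const arma::uword m = A.n_rows;
  arma::mat H = A.t() * B;          // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in Kabsch superposition");
  double d = arma::det(V * U.t());
  double tr = s(0) + s(1) + (d < 0 ? -s(2) : s(2));
  double msd = (ssqA + ssqB - 2.0 * tr) / static_cast<double>(m);
  return msd > 0 ? msd : 0.0;
}

static void center_rows(arma::mat& X) {
  arma::rowvec c = arma::mean(X, 0);
  X.each_row() -= c;
}

// Unflatten row i of `flat` into an m x 3 matrix.
static arma::mat row_coords(const arma::mat& flat, arma::uword i, arma::uword m) {
  arma::mat X(m, 3);
  for (arma::uword a = 0; a < m; ++a) {
    X(a, 0) = flat(i, 3 * a);
    X(a, 1) = flat(i, 3 * a + 1);
    X(a, 2) = flat(i, 3 * a + 2);
  }
  return X;
}

//' @noRd
// [[Rcpp::export(name = ".cppKabschRmsd")]]
double cppKabschRmsd(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    Rcpp::stop("coordinate sets must be n x 3 with equal atom counts");
  arma::mat Ac = A, Bc = B;
  center_rows(Ac);
  center_rows(Bc);
  // explicit-rotation residual: free of the catastrophic cancellation of
  // the trace formula near zero, so identical structures give ~0 exactly
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in Kabsch superposition");
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0) D(2, 2) = -1.0;
  arma::mat R = U * D * V.t();  // minimizes || Ac R - Bc ||_F
  arma::mat res = Ac * R - Bc;
  return std::sqrt(arma::accu(res % res) / Ac.n_rows);
}

// Sum of singular values of a 3x3 matrix H with the smallest one negated
// when det(H) < 0 (the optimal-rotation trace of the Kabsch solution),
// via closed-form eigenvalues of the symmetric matrix H'H. Avoids a LAPACK
// call per pair in the quadratic clustering loop.
static double kabsch_trace_analytic(const double H[9]) {
  // B = H'H (columns of H are H[0..2], H[3..5], H[6..8])
  double B[6]; // b11 b22 b33 b12 b13 b23
  B[0] = H[0]*H[0] + H[1]*H[1] + H[2]*H[2];
  B[1] = H[3]*H[3] + H[4]*H[4] + H[5]*H[5];
  B[2] = H[6]*H[6] + H[7]*H[7] + H[8]*H[8];
  B[3] = H[0]*H[3] + H[1]*H[4] + H[2]*H[5];
  B[4] = H[0]*H[6] + H[1]*H[7] + H[2]*H[8];
  B[5] = H[3]*H[6] + H[4]*H[7] + H[5]*H[8];
  double q = (B[0] + B[1] + B[2]) / 3.0;
  double p1 = B[3]*B[3] + B[4]*B[4] + B[5]*B[5];
  double e1, e2, e3;
  if (p1 < 1e-300) {
    e1 = B[0]; e2 = B[1]; e3 = B[2];
  } else {
    double p2 = (B[0]-q)*(B[0]-q) + (B[1]-q)*(B[1]-q) + (B[2]-q)*(B[2]-q)
      + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B - qI) / (2 p^3)
    double c11 = (B[0]-q)/p, c22 = (B[1]-q)/p, c33 = (B[2]-q)/p;
    double c12 = B[3]/p, c13 = B[4]/p, c23 = B[5]/p;
    double detC = c11*(c22*c33 - c23*c23) - c12*(c12*c33 - c23*c13)
      + c13*(c12*c23 - c22*c13);
    double r = detC / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    e1 = q + 2.0 * p * std::cos(phi);
    e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e2 = 3.0 * q - e1 - e3;
  }
  double s1 = std::sqrt(std::max(e1, 0.0));
  double s2 = std::sqrt(std::max(e2, 0.0));
  double s3 = std::sqrt(std::max(e3, 0.0));
  // order so s3 is the smallest
  double smin = std::min(s1, std::min(s2, s3));
  double ssum = s1 + s2 + s3;
  double detH = H[0]*(H[4]*H[8] - H[5]*H[7]) - H[3]*(H[1]*H[8] - H[2]*H[7])
    + H[6]*(H[1]*H[5] - H[2]*H[4]);
  return detH < 0 ? ssum - 2.0 * smin : ssum;
}

//' @noRd
// [[Rcpp::export(name = ".cppPairwiseKabschRmsd")]]
arma::mat cppPairwiseKabschRmsd(const arma::mat& flat, int natoms) {
  const arma::uword n = flat.n_rows;
  const arma::uword m = static_cast<arma::uword>(natoms);
  if (flat.n_cols != 3 * m) Rcpp::stop("flat width must be 3 * natoms");
  std::vector<arma::mat> coords(n);
  arma::vec ssq(n);
  for (arma::uword i = 0; i < n; ++i) {
    coords[i] = row_coords(flat, i, m);
    center_rows(coords[i]);
    ssq(i) = arma::accu(coords[i] % coords[i]);
  }
  arma::mat D(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < n; ++i) {
    const double* A = coords[i].memptr();  // column-major m x 3
    for (arma::uword j = i + 1; j < n; ++j) {
      const double* B = coords[j].memptr();
      double H[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (arma::uword a = 0; a < m; ++a) {
        const double ax = A[a], ay = A[a + m], az = A[a + 2 * m];
        const double bx = B[a], by = B[a + m], bz = B[a + 2 * m];
        H[0] += ax * bx; H[1] += ay * bx; H[2] += az * bx;
        H[3] += ax * by; H[4] += ay * by; H[5] += az * by;
        H[6] += ax * bz; H[7] += ay * bz; H[8] += az * bz;
      }
      double tr = kabsch_trace_analytic(H);
      double msd = (ssq(i) + ssq(j) - 2.0 * tr) / static_cast<double>(m);
      double r = std::sqrt(msd > 0 ? msd : 0.0);
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

//' @noRd
// [[Rcpp::export(name = ".cppKabschRmsdToRef")]]
arma::vec cppKabschRmsdToRef(const arma::mat& flat, const arma::mat& ref) {
  const arma::uword m = ref.n_rows;
  if (flat.n_cols != 3 * m) Rcpp::stop("flat width must be 3 * nrow(ref)");
  arma::mat R = ref;
  center_rows(R);
  double ssqR = arma::accu(R % R);
  const arma::uword n = flat.n_rows;
  arma::vec out(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat X = row_coords(flat, i, m);
    center_rows(X);
    out(i) = std::sqrt(kabsch_msd(X, R, arma::accu(X % X), ssqR));
  }
  return out;
}
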