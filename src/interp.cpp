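// Trilinear interpolation kernels: volume rotation and real-space projection.
// Conventions (used package-wide):
//   * cubic N^3 volumes, 0-based voxel coordinates, rotation centre at c = floor(N/2)
//   * a rotation operator R acts on the map as (R.V)(v) = V(R^-1 v)
//   * samples outside the box read as 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double tri_sample(const cube& V, double x, double y, double z) {
  const int N0 = V.n_rows, N1 = V.n_cols, N2 = V.n_slices;
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > N0 - 1.0 || y > N1 - 1.0 || z > N2 - 1.0) return 0.0;
  int x0 = (int)std::floor(x); if (x0 > N0 - 2) x0 = N0 - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > N1 - 2) y0 = N1 - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > N2 - 2) z0 = N2 - 2; if (z0 < 0) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const double c00 = V(x0, y0, z0) * (1 - fx) + V(x0 + 1, y0, z0) * fx;
  const double c10 = V(x0, y0 + 1, z0) * (1 - fx) + V(x0 + 1, y0 + 1, z0) * fx;
  const double c01 = V(x0, y0, z0 + 1) * (1 - fx) + V(x0 + 1, y0, z0 + 1) * fx;
  const double c11 = V(x0, y0 + 1, z0 + 1) * (1 - fx) + V(x0 + 1, y0 + 1, z0 + 1) * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// In-plane (2D) rotation of a square image about the box centre, bilinear,
// zero outside. out(x) = img(R2(psi) x): the projection at in-plane angle
// psi of a map equals the psi=0 projection composed with this rotation.
// [[Rcpp::export]]
arma::mat rotate_image_cpp(const arma::mat& img, double psi_deg) {
  const int N = img.n_rows;
  const double c = std::floor(N / 2.0);
  const double a = psi_deg * datum::pi / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  mat out(N, N, fill::zeros);
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      const double x = ca * (i - c) - sa * (j - c) + c;
      const double y = sa * (i - c) + ca * (j - c) + c;
      if (x < 0 || y < 0 || x > N - 1 || y > N - 1) continue;
      int x0 = (int)x; if (x0 > N - 2) x0 = N - 2;
      int y0 = (int)y; if (y0 > N - 2) y0 = N - 2;
      const double fx = x - x0, fy = y - y0;
      out(i, j) = img(x0, y0) * (1 - fx) * (1 - fy) +
                  img(x0 + 1, y0) * fx * (1 - fy) +
                  img(x0, y0 + 1) * (1 - fx) * fy +
                  img(x0 + 1, y0 + 1) * fx * fy;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube rotate_map_cpp(const arma::cube& V, const arma::mat& R) {
  const int N = V.n_rows;
  const double c = std::floor(N / 2.0);
  cube out(N, N, N, fill::zeros);
  const mat Rt = R.t();  // inverse rotation
  for (int k = 0; k < N; ++k) {
    for (int j = 0; j < N; ++j) {
      // u = Rt * (i - c, j - c, k - c) + c, incremental in i
      double ux = Rt(0, 1) * (j - c) + Rt(0, 2) * (k - c) + Rt(0, 0) * (0 - c) + c;
      double uy = Rt(1, 1) * (j - c) + Rt(1, 2) * (k - c) + Rt(1, 0) * (0 - c) + c;
      double uz = Rt(2, 1) * (j - c) + Rt(2, 2) * (k - c) + Rt(2, 0) * (0 - c) + c;
      for (int i = 0; i < N; ++i) {
        out(i, j, k) = tri_sample(V, ux, uy, uz);
        ux += Rt(0, 0); uy += Rt(1, 0); uz += Rt(2, 0);
      }
    }
  }
  return out;
}

// Projection at Euler matrix R: img(i,j) = sum_k V(R (i,j,k)), i.e. the map
// is sampled along rays rotated by R. With this convention a map with Cn
// symmetry about z gives identical projections at phi and phi + 360/n.
// [[Rcpp::export]]
arma::mat project_cpp(const arma::cube& V, const arma::mat& R) {
  const int N = V.n_rows;
  const double c = std::floor(N / 2.0);
  mat img(N, N, fill::zeros);
  const mat& Rt = R;  // sample at R v directly
  const double R2 = c * c;  // rays only intersect the inscribed sphere
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      const double d2 = (i - c) * (i - c) + (j - c) * (j - c);
      if (d2 > R2) continue;
      const double half = std::sqrt(R2 - d2);
      const int k0 = std::max(0, (int)std::floor(c - half));
      const int k1 = std::min(N - 1, (int)std::ceil(c + half));
      double ux = Rt(0, 0) * (i - c) + Rt(0, 1) * (j - c) + Rt(0, 2) * (k0 - c) + c;
      double uy = Rt(1, 0) * (i - c) + Rt(1, 1) * (j - c) + Rt(1, 2) * (k0 - c) + c;
      double uz = Rt(2, 0) * (i - c) + Rt(2, 1) * (j - c) + Rt(2, 2) * (k0 - c) + c;
      double acc = 0.0;
      for (int k = k0; k <= k1; ++k) {
        acc += tri_sample(V, ux, uy, uz);
        ux += Rt(0, 2); uy += Rt(1, 2); uz += Rt(2, 2);
      }
      img(i, j) = acc;
    }
  }
  return img;
}
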