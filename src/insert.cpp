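// Direct Fourier inversion, accumulation step: each particle image contributes
// a central slice of the 3D transform. The slice of image p with orientation R
// lives at 3D frequencies h3 = R (h1, h2, 0) (centred integer frequencies,
// h in [-c, c)), because project() samples the map at R v.
// Values are spread with trilinear gridding into a complex accumulator plus a
// weight volume; division and the inverse 3D FFT happen on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List insert_slices_cpp(const arma::cube& images, const arma::cube& rots,
                             const arma::mat& shifts) {
  const int N = images.n_rows;
  const int np = images.n_slices;
  const int c = N / 2;
  const int lo = -c, hi = N - c - 1;  // centred frequency range
  cx_cube A(N, N, N, fill::zeros);
  cube W(N, N, N, fill::zeros);
  const double twopi = 2.0 * datum::pi;

  for (int p = 0; p < np; ++p) {
    const cx_mat F = fft2(images.slice(p));
    const mat& Rt = rots.slice(p);     // slice plane basis
    const double dx = shifts(p, 0), dy = shifts(p, 1);
    for (int h2 = lo; h2 <= hi; ++h2) {
      const int i2 = (h2 + N) % N;
      for (int h1 = lo; h1 <= hi; ++h1) {
        const int i1 = (h1 + N) % N;
        // centring phase (object centre at voxel c) and shift removal
        const double ph = twopi * ((h1 + h2) * (double)c + h1 * dx + h2 * dy) / N;
        const cx_double v = F(i1, i2) * cx_double(std::cos(ph), std::sin(ph));
        const double px = Rt(0, 0) * h1 + Rt(0, 1) * h2;
        const double py = Rt(1, 0) * h1 + Rt(1, 1) * h2;
        const double pz = Rt(2, 0) * h1 + Rt(2, 1) * h2;
        if (px < lo || px > hi - 1 || py < lo || py > hi - 1 || pz < lo || pz > hi - 1)
          continue;
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                  z0 = (int)std::floor(pz);
        const double fx = px - x0, fy = py - y0, fz = pz - z0;
        for (int oz = 0; oz <= 1; ++oz) {
          const double wz = oz ? fz : 1 - fz;
          for (int oy = 0; oy <= 1; ++oy) {
            const double wy = oy ? fy : 1 - fy;
            for (int ox = 0; ox <= 1; ++ox) {
              const double w = (ox ? fx : 1 - fx) * wy * wz;
              if (w <= 0) continue;
              A(x0 + ox + c, y0 + oy + c, z0 + oz + c) += v * w;
              W(x0 + ox + c, y0 + oy + c, z0 + oz + c) += w;
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("W") = W);
}
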