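// Exhaustive template matching: normalized cross-correlation over a template
// bank and integer in-plane shifts.
// Templates are assumed mean-zero and unit-norm (enforced by the bank
// builder). The correlation is evaluated in Fourier space, restricted to the
// centred band |k| <= kmax where the (smooth) reference carries its power --
// a matched filter on the occupied band. For each shift e,
//   NCC(e) = <T, shift_e(P)>_band / ||P||_band,
// computed separably as Px^T (conj(F_T) o F_P) Py, so scores stay in [-1, 1]
// (Cauchy-Schwarz within the band; the DC term is zeroed, which removes the
// particle mean).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List assign_cpp(const arma::cube& particles, const arma::cube& templates,
                      int shift_range, const Rcpp::List& candidates,
                      int kmax) {
  const int N = particles.n_rows;
  const int np = particles.n_slices;
  const int nt = templates.n_slices;
  const bool restrict_cand = candidates.size() > 0;
  if (kmax < 1 || 2 * kmax + 1 > N) kmax = N / 4;
  const int B = 2 * kmax + 1;
  const int S = 2 * shift_range + 1;
  const double twopi = 2.0 * datum::pi;

  // centred band index -> DFT index
  uvec bidx(B);
  for (int i = 0; i < B; ++i) bidx[i] = ((i - kmax) + N) % N;

  // shift phase tables: px(k, e) = exp(+2 pi i k e / N)
  cx_mat Px(B, S), Py(B, S);
  for (int e = 0; e < S; ++e)
    for (int i = 0; i < B; ++i) {
      const double ph = twopi * (i - kmax) * (e - shift_range) / N;
      Px(i, e) = Py(i, e) = cx_double(std::cos(ph), std::sin(ph));
    }

  // template band spectra (conjugated)
  std::vector<cx_mat> FT(nt);
  for (int t = 0; t < nt; ++t) {
    cx_mat F = fft2(templates.slice(t));
    FT[t] = conj(F.submat(bidx, bidx));
  }

  Rcpp::IntegerVector best_t(np), best_dx(np), best_dy(np);
  Rcpp::NumericVector best_score(np);
  cx_mat Q(B, B), M(B, S), Rm(S, S);

  for (int p = 0; p < np; ++p) {
    cx_mat F = fft2(particles.slice(p));
    cx_mat FP = F.submat(bidx, bidx);
    FP(kmax, kmax) = 0.0;                       // remove the mean
    const double pnorm = std::sqrt(accu(square(abs(FP)))) / N;
    double best = -datum::inf;
    int bt = 0, bx = 0, by = 0;

    Rcpp::IntegerVector cand;
    int ncand = nt;
    if (restrict_cand) { cand = candidates[p]; ncand = cand.size(); }
    for (int ci = 0; ci < ncand; ++ci) {
      const int t = restrict_cand ? (cand[ci] - 1) : ci;
      Q = FT[t] % FP;
      M = Q * Py;
      Rm = Px.st() * M;
      for (int ey = 0; ey < S; ++ey)
        for (int ex = 0; ex < S; ++ex) {
          const double v = Rm(ex, ey).real();
          if (v > best) { best = v; bt = t; bx = ex - shift_range;
                          by = ey - shift_range; }
        }
    }
    best_t[p] = bt + 1;
    best_dx[p] = bx;
    best_dy[p] = by;
    best_score[p] = (pnorm > 0) ? best / (N * (double)N) / pnorm : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("template") = best_t,
                            Rcpp::Named("dx") = best_dx,
                            Rcpp::Named("dy") = best_dy,
                            Rcpp::Named("score") = best_score);
}

// Candidate template lists for local / symmetry-relaxed search: templates
// whose orientation lies within max_deg (geodesic angle on SO(3)) of
// sym_s * prev_i for any operator s (left action: orientations equivalent
// under a map symmetry differ by a left factor). Always includes the
// globally nearest template.
// [[Rcpp::export]]
Rcpp::List candidates_cpp(const arma::cube& bank_R, const arma::cube& prev_R,
                          const arma::cube& sym_R, double max_deg) {
  const int nt = bank_R.n_slices, np = prev_R.n_slices, ns = sym_R.n_slices;
  const double cmin = std::cos(max_deg * datum::pi / 180.0);
  Rcpp::List out(np);
  std::vector<int> idx;
  idx.reserve(nt);
  for (int p = 0; p < np; ++p) {
    std::vector<mat> C(ns);
    for (int s = 0; s < ns; ++s) C[s] = sym_R.slice(s) * prev_R.slice(p);
    idx.clear();
    double best = -2.0;
    int best_t = 0;
    for (int t = 0; t < nt; ++t) {
      const mat& B = bank_R.slice(t);
      double cmax = -2.0;
      for (int s = 0; s < ns; ++s) {
        const double ctr = (accu(B % C[s]) - 1.0) / 2.0;  // cos of rel. angle
        if (ctr > cmax) cmax = ctr;
      }
      if (cmax >= cmin) idx.push_back(t + 1);
      if (cmax > best) { best = cmax; best_t = t + 1; }
    }
    if (idx.empty()) idx.push_back(best_t);
    out[p] = Rcpp::IntegerVector(idx.begin(), idx.end());
  }
  return out;
}
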