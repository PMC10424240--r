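// Exact resonance-field solver for one electron spin (S = 1/2) coupled to a
// single I = 1 nucleus under collinear g- and A-tensors, plus a windowed
// Gaussian line accumulator used by the powder integrator.
//
// Units at the interface: magnetic field in mT, frequencies/couplings in MHz
// (microwave frequency passed in MHz), g dimensionless.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Bohr magneton over Planck constant, MHz per mT (CODATA 2018:
// mu_B = 9.2740100783e-24 J/T, h = 6.62607015e-34 J s).
static const double MHZ_PER_MT = 9.2740100783e-24 / 6.62607015e-34 * 1e-9;

namespace {

struct SpinOps {
  cx_mat Sx, Sy, Sz;  // 6x6, electron operators (x) identity on nucleus
  cx_mat SIx, SIy, SIz;  // Sx*Ix etc., 6x6
};

SpinOps make_ops() {
  cx_double i1(0.0, 1.0);
  cx_mat sx(2, 2, fill::zeros), sy(2, 2, fill::zeros), sz(2, 2, fill::zeros);
  sx(0, 1) = 0.5; sx(1, 0) = 0.5;
  sy(0, 1) = -0.5 * i1; sy(1, 0) = 0.5 * i1;
  sz(0, 0) = 0.5; sz(1, 1) = -0.5;

  // I = 1 operators in the |+1,0,-1> basis
  double s2 = std::sqrt(2.0) / 2.0;  // <m|Ix|m'> elements = 1/sqrt(2)
  cx_mat ix(3, 3, fill::zeros), iy(3, 3, fill::zeros), iz(3, 3, fill::zeros);
  ix(0, 1) = s2; ix(1, 0) = s2; ix(1, 2) = s2; ix(2, 1) = s2;
  iy(0, 1) = -s2 * i1; iy(1, 0) = s2 * i1;
  iy(1, 2) = -s2 * i1; iy(2, 1) = s2 * i1;
  iz(0, 0) = 1.0; iz(2, 2) = -1.0;

  cx_mat e2 = eye<cx_mat>(2, 2), e3 = eye<cx_mat>(3, 3);
  SpinOps ops;
  ops.Sx = kron(sx, e3); ops.Sy = kron(sy, e3); ops.Sz = kron(sz, e3);
  ops.SIx = kron(sx, ix); ops.SIy = kron(sy, iy); ops.SIz = kron(sz, iz);
  return ops;
}

// Three Delta mS = +-1, Delta mI = 0 transition frequencies (MHz), sorted
// ascending, plus their relative transition probabilities.
void transition_freqs(const SpinOps& ops, const vec& g, const vec& A,
                      const vec& n, double B_mT, vec& freqs, vec& amps) {
  cx_mat H = MHZ_PER_MT * B_mT *
                 (g(0) * n(0) * ops.Sx + g(1) * n(1) * ops.Sy +
                  g(2) * n(2) * ops.Sz) +
             A(0) * ops.SIx + A(1) * ops.SIy + A(2) * ops.SIz;
  vec eval;
  cx_mat evec;
  eig_sym(eval, evec, H);  // ascending

  // perpendicular direction for the transition moment operator
  vec p;
  if (std::abs(n(2)) < 0.9) p = cross(n, vec{0.0, 0.0, 1.0});
  else p = cross(n, vec{1.0, 0.0, 0.0});
  p /= norm(p);
  cx_mat Sp = p(0) * ops.Sx + p(1) * ops.Sy + p(2) * ops.Sz;

  // lower manifold = eigenvalues 0..2, upper = 3..5 (electron Zeeman
  // dominant at all fields searched)
  mat amp(3, 3);
  mat frq(3, 3);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      cx_double m = cdot(evec.col(3 + j), Sp * evec.col(i));
      amp(i, j) = std::norm(m);
      frq(i, j) = eval(3 + j) - eval(i);
    }
  }
  // greedy assignment of each lower level to its Delta mI = 0 partner
  freqs.set_size(3);
  amps.set_size(3);
  bool used_i[3] = {false, false, false}, used_j[3] = {false, false, false};
  for (int k = 0; k < 3; ++k) {
    int bi = -1, bj = -1;
    double best = -1.0;
    for (int i = 0; i < 3; ++i) {
      if (used_i[i]) continue;
      for (int j = 0; j < 3; ++j) {
        if (used_j[j]) continue;
        if (amp(i, j) > best) { best = amp(i, j); bi = i; bj = j; }
      }
    }
    used_i[bi] = true; used_j[bj] = true;
    freqs(k) = frq(bi, bj);
    amps(k) = amp(bi, bj);
  }
  uvec ord = sort_index(freqs);
  freqs = freqs(ord);
  amps = amps(ord);
}

}  // namespace

// Resonance fields (mT) by bisection on the k-th sorted transition frequency.
// orientations: n x 3 matrix of unit direction cosines; returns an n x 3
// field matrix (columns = sorted transition branches, low to high frequency
// at fixed field, i.e. high to low field) and an n x 3 amplitude matrix.
// [[Rcpp::export(name = ".resfields_exact")]]
Rcpp::List resfields_exact(Rcpp::NumericVector g_in, Rcpp::NumericVector A_in,
                           Rcpp::NumericMatrix orient, double freq_MHz,
                           double B_lo, double B_hi, double tol_mT) {
  SpinOps ops = make_ops();
  vec g(g_in.begin(), 3), A(A_in.begin(), 3);
  int nor = orient.nrow();
  mat fields(nor, 3), amps(nor, 3);
  vec fr_lo(3), fr_hi(3), fr(3), am(3);

  for (int o = 0; o < nor; ++o) {
    vec n = {orient(o, 0), orient(o, 1), orient(o, 2)};
    transition_freqs(ops, g, A, n, B_lo, fr_lo, am);
    transition_freqs(ops, g, A, n, B_hi, fr_hi, am);
    for (int k = 0; k < 3; ++k) {
      if ((fr_lo(k) - freq_MHz) * (fr_hi(k) - freq_MHz) > 0.0) {
        Rcpp::stop("resonance of transition branch %d (orientation %d) lies "
                   "outside the search window [%.3f, %.3f] mT",
                   k + 1, o + 1, B_lo, B_hi);
      }
      double lo = B_lo, hi = B_hi;
      while (hi - lo > tol_mT) {
        double mid = 0.5 * (lo + hi);
        transition_freqs(ops, g, A, n, mid, fr, am);
        if (fr(k) < freq_MHz) lo = mid; else hi = mid;
      }
      double B = 0.5 * (lo + hi);
      transition_freqs(ops, g, A, n, B, fr, am);
      fields(o, k) = B;
      amps(o, k) = am(k);
    }
  }
  return Rcpp::List::create(Rcpp::Named("fields") = fields,
                            Rcpp::Named("amplitudes") = amps);
}

// Transition frequencies (MHz) and amplitudes at a fixed field, one row per
// orientation, columns sorted ascending in frequency.
// [[Rcpp::export(name = ".transition_freqs")]]
Rcpp::List transition_freqs_at(Rcpp::NumericVector g_in,
                               Rcpp::NumericVector A_in,
                               Rcpp::NumericMatrix orient, double B_mT) {
  SpinOps ops = make_ops();
  vec g(g_in.begin(), 3), A(A_in.begin(), 3);
  int nor = orient.nrow();
  mat freqs(nor, 3), amps(nor, 3);
  vec fr(3), am(3);
  for (int o = 0; o < nor; ++o) {
    vec n = {orient(o, 0), orient(o, 1), orient(o, 2)};
    transition_freqs(ops, g, A, n, B_mT, fr, am);
    freqs.row(o) = fr.t();
    amps.row(o) = am.t();
  }
  return Rcpp::List::create(Rcpp::Named("freqs") = freqs,
                            Rcpp::Named("amplitudes") = amps);
}

// Accumulate weighted Gaussian absorption lines on a uniform axis.
// Evaluation is windowed to +-8 sigma around each centre.
// [[Rcpp::export(name = ".gaussian_lines")]]
Rcpp::NumericVector gaussian_lines(Rcpp::NumericVector axis,
                                   Rcpp::NumericVector centers,
                                   Rcpp::NumericVector sigma,
                                   Rcpp::NumericVector weights) {
  int np = axis.size(), nl = centers.size();
  Rcpp::NumericVector out(np);
  double x0 = axis[0];
  double dx = np > 1 ? (axis[np - 1] - x0) / (np - 1) : 1.0;
  for (int l = 0; l < nl; ++l) {
    double s = sigma[l], c = centers[l], w = weights[l];
    if (s <= 0.0) continue;
    double norm = w / (s * std::sqrt(2.0 * M_PI));
    int i0 = std::max(0, (int)std::floor((c - 8.0 * s - x0) / dx));
    int i1 = std::min(np - 1, (int)std::ceil((c + 8.0 * s - x0) / dx));
    double inv2s2 = 1.0 / (2.0 * s * s);
    for (int i = i0; i <= i1; ++i) {
      double d = axis[i] - c;
      out[i] += norm * std::exp(-d * d * inv2s2);
    }
  }
  return out;
}

// Area-preserving accumulation of stick intensities into per-width-class
// histograms: each line's weight is split linearly between the two
// neighbouring axis bins and between the two bracketing sigma classes.
// Returns an (n_classes x n_points) matrix.
// [[Rcpp::export(name = ".class_sticks")]]
Rcpp::NumericMatrix class_sticks(Rcpp::NumericVector axis,
                                 Rcpp::NumericVector centers,
                                 Rcpp::NumericVector sigma,
                                 Rcpp::NumericVector weights,
                                 Rcpp::NumericVector class_sigma) {
  int np = axis.size(), nl = centers.size(), nc = class_sigma.size();
  Rcpp::NumericMatrix out(nc, np);
  double x0 = axis[0];
  double dx = np > 1 ? (axis[np - 1] - x0) / (np - 1) : 1.0;
  for (int l = 0; l < nl; ++l) {
    double pos = (centers[l] - x0) / dx;
    int i = (int)std::floor(pos);
    if (i < 0 || i >= np - 1) continue;  // caller guarantees bracketing
    double tx = pos - i;
    // locate sigma class (class_sigma ascending)
    int j = nc - 2;
    double ts = 1.0;
    if (nc == 1) { j = 0; ts = 0.0; }
    else {
      if (sigma[l] <= class_sigma[0]) { j = 0; ts = 0.0; }
      else if (sigma[l] >= class_sigma[nc - 1]) { j = nc - 2; ts = 1.0; }
      else {
        j = (int)std::floor((sigma[l] - class_sigma[0]) /
                            (class_sigma[1] - class_sigma[0]));
        if (j > nc - 2) j = nc - 2;
        ts = (sigma[l] - class_sigma[j]) /
             (class_sigma[j + 1] - class_sigma[j]);
      }
    }
    double w = weights[l];
    out(j, i) += w * (1 - tx) * (1 - ts);
    out(j, i + 1) += w * tx * (1 - ts);
    if (nc > 1) {
      out(j + 1, i) += w * (1 - tx) * ts;
      out(j + 1, i + 1) += w * tx * ts;
    }
  }
  return out;
}
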