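// Ensemble-averaged wave-packet (NISE) propagation over a fluctuating
// exciton Hamiltonian. The per-step propagator is the exact
// eigen-exponential of the frame Hamiltonian (unconditionally norm
// conserving); the Hamiltonian is held piecewise-constant within a frame.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static cx_mat frame_propagator(const rowvec& energies, const mat& couplings,
                               double dt_over_hbar) {
  mat H = couplings;
  H.diag() += energies.t();
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, H))
    Rcpp::stop("eigendecomposition of frame Hamiltonian failed");
  cx_vec phases = exp(cx_double(0.0, -dt_over_hbar) *
                      conv_to<cx_vec>::from(eval));
  cx_mat V = conv_to<cx_mat>::from(evec);
  return V * diagmat(phases) * V.t();
}

// Propagate initial states psi0 (n x k) through every frame, recording the
// site populations after each of `substeps` sub-steps per frame.
// Returns a cube (nframes*substeps + 1) x n x k.
// [[Rcpp::export]]
arma::cube nise_propagate_cpp(const arma::mat& energies,
                              const arma::mat& couplings,
                              double dt, int substeps,
                              const arma::cx_mat& psi0, double hbar) {
  if (!energies.is_finite() || !couplings.is_finite())
    Rcpp::stop("non-finite Hamiltonian entries");
  const uword nframes = energies.n_rows;
  const uword n = couplings.n_rows;
  const uword k = psi0.n_cols;
  const double dtp = dt / substeps;
  cube P(nframes * substeps + 1, n, k);
  cx_mat psi = psi0;
  for (uword j = 0; j < k; ++j)
    P.slice(j).row(0) = trans(square(abs(psi.col(j))));
  uword row = 1;
  for (uword f = 0; f < nframes; ++f) {
    cx_mat U = frame_propagator(energies.row(f), couplings, dtp / hbar);
    for (int s = 0; s < substeps; ++s) {
      psi = U * psi;
      for (uword j = 0; j < k; ++j)
        P.slice(j).row(row) = trans(square(abs(psi.col(j))));
      ++row;
    }
  }
  return P;
}

// Ensemble average over overlapping windows: per-frame propagators are
// precomputed once and reused by every window. offsets are 0-based frame
// indices; each window runs `nsteps` frames. Returns the mean population
// cube (nsteps + 1) x n x k for initial states psi0 (n x k).
// [[Rcpp::export]]
arma::cube nise_ensemble_cpp(const arma::mat& energies,
                             const arma::mat& couplings,
                             double dt, const arma::uvec& offsets,
                             int nsteps, const arma::cx_mat& psi0,
                             double hbar) {
  if (!energies.is_finite() || !couplings.is_finite())
    Rcpp::stop("non-finite Hamiltonian entries");
  const uword n = couplings.n_rows;
  const uword k = psi0.n_cols;
  const uword needed = offsets.max() + (uword)nsteps;
  if (needed > energies.n_rows)
    Rcpp::stop("window extends past the end of the trajectory");
  cx_cube U(n, n, needed);
  for (uword f = 0; f < needed; ++f)
    U.slice(f) = frame_propagator(energies.row(f), couplings, dt / hbar);
  cube P(nsteps + 1, n, k, fill::zeros);
  for (uword w = 0; w < offsets.n_elem; ++w) {
    cx_mat psi = psi0;
    for (uword j = 0; j < k; ++j)
      P.slice(j).row(0) += trans(square(abs(psi.col(j))));
    for (int s = 0; s < nsteps; ++s) {
      psi = U.slice(offsets(w) + s) * psi;
      for (uword j = 0; j < k; ++j)
        P.slice(j).row(s + 1) += trans(square(abs(psi.col(j))));
    }
  }
  P /= (double)offsets.n_elem;
  return P;
}
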