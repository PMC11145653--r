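#' @keywords internal
#' Half-Fourier lineshape profile D(omega) for one state
#'
#' D(omega) = (1/pi) Re int_0^tmax (dt/hbar)
#'   exp(i (omega - center) t / hbar) f(t),
#' with f(t) the complex time-domain response, by trapezoid quadrature.
.half_fourier <- function(omega, center, tgrid, f) {
  wt <- c(diff(tgrid) / 2, 0) + c(0, diff(tgrid) / 2)
  phase <- exp(1i * outer(omega - center, tgrid) / .HBAR)
  drop(Re(phase %*% (f * wt))) / (pi * .HBAR)
}

.spectrum_obj <- function(omega, intensity, kind, shift_eV, normalize) {
  intensity <- pmax(intensity, 0)         # numerical floor
  if (normalize && max(intensity) > 0) intensity <- intensity / max(intensity)
  structure(list(omega = omega, intensity = intensity, kind = kind,
                 shift_applied_eV = shift_eV, normalized = normalize),
            class = "exciton_spectrum")
}

#' @export
print.exciton_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, peak at %.1f cm^-1%s\n",
              x$kind, length(x$omega), x$omega[which.max(x$intensity)],
              if (x$shift_applied_eV != 0)
                sprintf(" (rigid shift %.3f eV applied)", x$shift_applied_eV)
              else ""))
  invisible(x)
}

# shared assembly for absorption-type spectra; tau broadening optional
.absorption_spectrum <- function(basis, ex, tau, grid, normalize, shift_eV,
                                 extra_damping_fs, kind) {
  stopifnot(inherits(basis, "exciton_basis"))
  if (is.null(basis$dipoles)) stop("attach dipoles first (exciton_dipoles)")
  n_ex <- length(basis$energies)
  if (length(tau) == 1) tau <- rep(tau, n_ex)
  d2 <- dipole_strengths(basis)
  shift_cm <- convert_units(shift_eV, "eV", "cm-1")
  omega_eval <- grid + shift_cm           # red shift: features move down
  total <- numeric(length(grid))
  for (mu in seq_len(n_ex)) {
    center <- basis$energies[mu] - ex$lambda[mu]
    f <- exp(-ex$g$g[, mu] - ex$g$tgrid / (2 * tau[mu]) -
               ex$g$tgrid / (2 * extra_damping_fs))
    total <- total + d2[mu] * .half_fourier(omega_eval, center, ex$g$tgrid, f)
  }
  # the omega prefactor acts at the physical (unshifted) frequency so that
  # a rigid shift is a pure translation of the spectrum
  .spectrum_obj(grid, omega_eval * total, kind, shift_eV, normalize)
}

#' Absorption spectrum within the secular Redfield approximation
#'
#' alpha(omega) proportional to omega sum_mu |d_mu|^2 D_mu(omega), where
#' D_mu is the half-Fourier transform of
#' exp(-i (E_mu - lambda_mu) t / hbar - g_mu(t) - t / (2 tau_mu)): the
#' second-order cumulant lineshape with lifetime broadening from the
#' Redfield depopulation rates. Rigid red shifts are presentation-only
#' parameters and are never applied silently (`shift_eV = 0` default).
#'
#' @param basis an `exciton_basis` with dipoles attached.
#' @param ex exciton lineshapes from [exciton_g_and_lambda()].
#' @param tau exciton lifetimes, fs (vector or scalar; `Inf` disables
#'   lifetime broadening), from [lifetimes()].
#' @param grid output frequency grid, cm^-1.
#' @param normalize scale the peak maximum to 1?
#' @param shift_eV rigid shift toward lower energies, eV.
#' @param extra_damping_fs optional additional Lorentzian damping time
#'   constant for delta-like lines (default `Inf` = none).
#' @return An `exciton_spectrum` (intensity floored at 0).
#' @export
absorption_redfield <- function(basis, ex, tau, grid, normalize = TRUE,
                                shift_eV = 0, extra_damping_fs = Inf) {
  .absorption_spectrum(basis, ex, tau, grid, normalize, shift_eV,
                       extra_damping_fs, "absorption")
}

#' Absorption spectrum from the exact second-order cumulant
#'
#' Identical construction to [absorption_redfield()] but without the
#' lifetime broadening term: the lineshape of every state is the pure
#' second-order cumulant exp(-g_mu(t)). Coincides with the Redfield
#' spectrum in the limit tau -> Inf.
#'
#' @inheritParams absorption_redfield
#' @return An `exciton_spectrum`.
#' @export
absorption_cumulant <- function(basis, ex, grid, normalize = TRUE,
                                shift_eV = 0, extra_damping_fs = Inf) {
  .absorption_spectrum(basis, ex, rep(Inf, length(basis$energies)), grid,
                       normalize, shift_eV, extra_damping_fs, "absorption")
}

#' Fluorescence spectrum within the secular Redfield approximation
#'
#' I(omega) proportional to omega^3 sum_mu P_mu |d_mu|^2 D~_mu(omega),
#' with P_mu the Boltzmann population of state mu and D~_mu the emission
#' lineshape: the absorption profile mirrored about E_mu - 2 lambda_mu,
#' realized as the half-Fourier transform of
#' exp(-i (E_mu - 3 lambda_mu) t / hbar - conj(g_mu(t)) - t / (2 tau_mu)).
#' For a monomer with a smooth slow bath this reproduces the classical
#' Stokes shift of 2 lambda between absorption and emission maxima.
#'
#' @inheritParams absorption_redfield
#' @param temperature temperature for the Boltzmann factors, K.
#' @return An `exciton_spectrum` of kind `"fluorescence"`.
#' @export
fluorescence_redfield <- function(basis, ex, tau, grid, temperature = 300,
                                  normalize = TRUE, shift_eV = 0,
                                  extra_damping_fs = Inf) {
  stopifnot(inherits(basis, "exciton_basis"))
  if (is.null(basis$dipoles)) stop("attach dipoles first (exciton_dipoles)")
  n_ex <- length(basis$energies)
  if (length(tau) == 1) tau <- rep(tau, n_ex)
  d2 <- dipole_strengths(basis)
  P <- boltzmann_populations(basis$energies, temperature)
  shift_cm <- convert_units(shift_eV, "eV", "cm-1")
  omega_eval <- grid + shift_cm
  total <- numeric(length(grid))
  for (mu in seq_len(n_ex)) {
    center <- basis$energies[mu] - 3 * ex$lambda[mu]
    f <- exp(-Conj(ex$g$g[, mu]) - ex$g$tgrid / (2 * tau[mu]) -
               ex$g$tgrid / (2 * extra_damping_fs))
    total <- total + P[mu] * d2[mu] *
      .half_fourier(omega_eval, center, ex$g$tgrid, f)
  }
  .spectrum_obj(grid, omega_eval^3 * total, "fluorescence", shift_eV, normalize)
}

#' Write a spectrum as two-column text plus a JSON sidecar
#'
#' @param spec an `exciton_spectrum`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_spectrum <- function(spec, file) {
  write.table(data.frame(omega_cm1 = spec$omega, intensity = spec$intensity),
              file, row.names = FALSE, quote = FALSE, sep = "\t")
  jsonlite::write_json(
    list(kind = spec$kind, shift_applied_eV = spec$shift_applied_eV,
         normalized = spec$normalized),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
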