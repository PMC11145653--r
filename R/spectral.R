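#' Construct a site-energy trajectory
#'
#' Regularly sampled site-energy time series, one column per pigment,
#' energies in cm^-1 and the sampling interval `dt` in fs. These stand in
#' for vertical-excitation-energy (energy gap) trajectories from excited
#' state QM/MM calculations.
#'
#' @param values numeric matrix (frames x pigments) or vector, cm^-1.
#' @param dt sampling interval, fs (> 0).
#' @param labels pigment labels (default column names or `site1..siteN`).
#' @return Object of class `site_trajectory`.
#' @export
site_trajectory <- function(values, dt, labels = NULL) {
  v <- as.matrix(values)
  if (dt <= 0) stop("dt must be > 0")
  if (nrow(v) < 2) stop("need at least 2 frames")
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite site energies")
  if (is.null(labels)) {
    labels <- colnames(v)
    if (is.null(labels)) labels <- paste0("site", seq_len(ncol(v)))
  }
  colnames(v) <- labels
  structure(list(values = v, dt = dt, labels = labels),
            class = "site_trajectory")
}

#' Read a columnar site-energy trajectory
#'
#' Expects whitespace- or tab-separated text with a `time_fs` column
#' followed by one column per pigment (cm^-1 by default, eV accepted).
#'
#' @param file path to the trajectory table.
#' @param units `"cm-1"` (default) or `"eV"`.
#' @return A [site_trajectory()].
#' @export
read_site_trajectory <- function(file, units = c("cm-1", "eV")) {
  units <- match.arg(units)
  tab <- read.table(file, header = TRUE, check.names = FALSE)
  t_fs <- tab[[1]]
  dt <- stats::median(diff(t_fs))
  v <- as.matrix(tab[, -1, drop = FALSE])
  if (units == "eV") v <- convert_units(v, "eV", "cm-1")
  site_trajectory(v, dt, colnames(v))
}

#' Unbiased site-energy autocorrelation function
#'
#' C(tau) = <dE(t) dE(t + tau)> with dE = E - <E>, computed via FFT and
#' normalized by (N - lag) (unbiased), so that C(0) equals the sample
#' variance.
#'
#' @param traj a [site_trajectory()].
#' @param max_lag maximum lag, fs; must not exceed `(N - 1) * dt`.
#' @return List with `lags` (fs, from 0) and `C` (matrix, lag x pigment,
#'   cm^-2). A constant (zero-variance) series yields zero C with a
#'   warning.
#' @export
autocorrelation <- function(traj, max_lag = 2000) {
  stopifnot(inherits(traj, "site_trajectory"))
  n <- nrow(traj$values)
  nlag <- floor(max_lag / traj$dt)
  if (nlag > n - 1) stop("max_lag exceeds trajectory length")
  lags <- (0:nlag) * traj$dt
  C <- matrix(0, nlag + 1, ncol(traj$values),
              dimnames = list(NULL, traj$labels))
  npad <- stats::nextn(2L * n, 2)
  for (j in seq_len(ncol(traj$values))) {
    x <- traj$values[, j] - mean(traj$values[, j])
    if (all(x == 0)) {
      warning(sprintf("constant series for %s; autocorrelation is zero",
                      traj$labels[j]))
      next
    }
    f <- fft(c(x, numeric(npad - n)))
    acov <- Re(fft(f * Conj(f), inverse = TRUE))[1:(nlag + 1)] / npad
    C[, j] <- acov / (n - 0:nlag)
  }
  list(lags = lags, C = C)
}

#' Construct a spectral density on a frequency grid
#'
#' @param omega ascending uniform grid starting at 0, cm^-1.
#' @param J values J(omega), cm^-1; vector or matrix (one column per
#'   pigment).
#' @param temperature temperature in K associated with the estimate.
#' @param provenance free-text provenance.
#' @return Object of class `spectral_density`.
#' @export
new_spectral_density <- function(omega, J, temperature = 300,
                                 provenance = "") {
  J <- if (is.matrix(J)) J else matrix(J, ncol = 1)
  if (length(omega) != nrow(J)) stop("omega/J length mismatch")
  if (omega[1] != 0) stop("frequency grid must start at 0")
  d <- diff(omega)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * d[1])
    stop("frequency grid must be uniform and ascending")
  structure(list(omega = omega, J = J, temperature = temperature,
                 provenance = provenance),
            class = "spectral_density")
}

#' Spectral density from a site-energy trajectory
#'
#' Cosine transform of the (tapered) classical autocorrelation with a
#' harmonic quantum-correction prefactor:
#' J(w) = (beta w / (pi hbar)) * int_0^tmax C(tau) cos(w tau / hbar) dtau,
#' beta = 1/(kB T). This convention round-trips with the reorganization
#' energy lambda = (1/pi) int J(w)/w dw: an Ornstein-Uhlenbeck bath with
#' marginal variance sigma^2 and correlation time tau_c yields exactly the
#' Drude-Lorentz form J(w) = 2 lambda gamma w / (w^2 + gamma^2) with
#' lambda = beta sigma^2 / (2 pi) and gamma = hbar / tau_c. Negative lobes
#' introduced by windowing are clamped to zero; the clamped fraction of
#' grid points is recorded in attribute `"clamp_fraction"`.
#'
#' @param traj a [site_trajectory()].
#' @param temperature temperature in K (> 0).
#' @param window taper applied to C before the transform: `"hann"`
#'   (default), `"exp"` (decay to 1/e^2 at `max_lag`) or `"none"`.
#' @param max_lag transform upper limit t_max, fs (default 2000).
#' @param omega frequency grid, cm^-1 (uniform, from 0).
#' @return A [new_spectral_density()] with one column of J per pigment.
#' @export
spectral_density <- function(traj, temperature = 300,
                             window = c("hann", "exp", "none"),
                             max_lag = 2000,
                             omega = seq(0, 2500, by = 10)) {
  window <- match.arg(window)
  if (temperature <= 0) stop("temperature must be > 0")
  ac <- autocorrelation(traj, max_lag = max_lag)
  tau <- ac$lags
  w_tap <- switch(window,
    none = rep(1, length(tau)),
    hann = 0.5 * (1 + cos(pi * tau / max(tau))),
    exp  = exp(-2 * tau / max(tau))
  )
  beta <- 1 / (.KB * temperature)
  # trapezoid weights on the lag grid
  wt <- rep(traj$dt, length(tau))
  wt[c(1, length(tau))] <- traj$dt / 2
  # cosine kernel: n_omega x n_lag
  kern <- cos(outer(omega, tau) / .HBAR)
  J <- kern %*% (ac$C * (w_tap * wt))
  J <- J * (beta * omega / (pi * .HBAR))
  clamp <- colMeans(J < 0)
  J[J < 0] <- 0
  sd_obj <- new_spectral_density(omega, J, temperature,
                                 provenance = sprintf("estimated (%s window, t_max = %g fs)",
                                                      window, max_lag))
  colnames(sd_obj$J) <- traj$labels
  attr(sd_obj, "clamp_fraction") <- clamp
  sd_obj
}

#' Reorganization energy of a spectral density
#'
#' lambda = (1/pi) int_0^inf J(w)/w dw, trapezoid on the stored grid with
#' the w = 0 integrand replaced by its linear-slope limit.
#'
#' @param sd a [new_spectral_density()].
#' @return Named numeric vector of lambda (cm^-1), one per J column.
#' @export
reorganization_energy <- function(sd) {
  stopifnot(inherits(sd, "spectral_density"))
  omega <- sd$omega
  apply(sd$J, 2, function(j) {
    integrand <- j / omega
    integrand[1] <- if (length(omega) > 1) j[2] / omega[2] else 0
    sum(diff(omega) * (integrand[-1] + integrand[-length(omega)]) / 2) / pi
  })
}

#' Parametric spectral densities (Drude-Lorentz + Brownian oscillators)
#'
#' Sum of standard overdamped Drude-Lorentz terms
#' J(w) = 2 lambda gamma w / (w^2 + gamma^2) and underdamped Brownian
#' oscillator terms
#' J(w) = 2 lambda w0^2 gamma0 w / ((w0^2 - w^2)^2 + gamma0^2 w^2),
#' each parameterized directly by its reorganization-energy contribution
#' `lambda`.
#'
#' @param modes list of mode descriptions: `list(type = "overdamped",
#'   lambda =, gamma =)` or `list(type = "underdamped", lambda =,
#'   omega0 =, gamma0 =)`, all parameters in cm^-1 and positive.
#' @param omega frequency grid, cm^-1.
#' @param temperature stored temperature, K.
#' @return A single-column [new_spectral_density()].
#' @export
parametric_sd <- function(modes, omega = seq(0, 2500, by = 10),
                          temperature = 300) {
  J <- numeric(length(omega))
  for (m in modes) {
    pars <- unlist(m[names(m) != "type"])
    if (any(pars < 0)) stop("negative spectral-density parameters")
    J <- J + switch(match.arg(m$type, c("overdamped", "underdamped")),
      overdamped = 2 * m$lambda * m$gamma * omega / (omega^2 + m$gamma^2),
      underdamped = 2 * m$lambda * m$omega0^2 * m$gamma0 * omega /
        ((m$omega0^2 - omega^2)^2 + m$gamma0^2 * omega^2)
    )
  }
  new_spectral_density(omega, J, temperature, provenance = "parametric")
}

#' Pointwise average of spectral densities
#'
#' @param sds either a list of [new_spectral_density()] objects on
#'   identical grids, or a single multi-column object.
#' @return A single-column `spectral_density` with the pointwise mean.
#' @export
average_sd <- function(sds) {
  if (inherits(sds, "spectral_density")) sds <- list(sds)
  omega <- sds[[1]]$omega
  for (s in sds) {
    if (!identical(length(s$omega), length(omega)) ||
        max(abs(s$omega - omega)) > 0)
      stop("spectral densities are on different grids")
  }
  Jall <- do.call(cbind, lapply(sds, function(s) s$J))
  new_spectral_density(omega, rowMeans(Jall), sds[[1]]$temperature,
                       provenance = "average")
}

#' Write a spectral density as two-column text plus a JSON sidecar
#'
#' @param sd a [new_spectral_density()] (single column).
#' @param file output path; a sidecar `<file>.json` records temperature,
#'   provenance and grid step.
#' @return `file`, invisibly.
#' @export
write_spectral_density <- function(sd, file) {
  write.table(data.frame(omega_cm1 = sd$omega, J_cm1 = sd$J[, 1]),
              file, row.names = FALSE, quote = FALSE, sep = "\t")
  jsonlite::write_json(
    list(temperature_K = sd$temperature, provenance = sd$provenance,
         domega_cm1 = diff(sd$omega[1:2])),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
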