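#' Secular Redfield rates between exciton states
#'
#' For a downhill transition (omega_mu_nu = (E_mu - E_nu) > 0) the rate is
#' k(nu <- mu) = (2 pi / hbar) sum_m |c_m^mu|^2 |c_m^nu|^2 J_m(omega_mu_nu)
#' (n(omega_mu_nu) + 1), with n the Bose-Einstein occupation at the given
#' temperature. Uphill rates follow from detailed balance,
#' k(up) = k(down) exp(-beta hbar |omega|), which therefore holds exactly
#' by construction. J is interpolated linearly on its grid; transition
#' energies outside the grid raise an error.
#'
#' @param basis an `exciton_basis` from [diagonalize()].
#' @param J a [new_spectral_density()] with either one shared column or
#'   one column per site.
#' @param temperature temperature, K.
#' @return Object of class `rate_matrix`: list with `k` (matrix, fs^-1,
#'   `k[nu, mu]` = rate from state mu to state nu, zero diagonal) and
#'   `temperature`.
#' @export
redfield_rates <- function(basis, J, temperature = 300) {
  stopifnot(inherits(basis, "exciton_basis"), inherits(J, "spectral_density"))
  C2 <- basis$coefficients^2
  n_site <- nrow(C2)
  n_ex <- ncol(C2)
  Jm <- J$J
  if (ncol(Jm) == 1) Jm <- Jm[, rep(1, n_site), drop = FALSE]
  if (ncol(Jm) != n_site) stop("need one spectral density per site (or one shared)")
  beta <- 1 / (.KB * temperature)
  k <- matrix(0, n_ex, n_ex)
  for (mu in seq_len(n_ex)) for (nu in seq_len(n_ex)) {
    dE <- basis$energies[mu] - basis$energies[nu]
    if (dE <= 0) next                      # downhill pairs only; uphill below
    if (dE > max(J$omega))
      stop("transition energy outside the spectral-density grid")
    Jval <- vapply(seq_len(n_site), function(m)
      approx(J$omega, Jm[, m], xout = dE)$y, 1)
    nocc <- 1 / (exp(beta * dE) - 1)
    overlap <- sum(C2[, mu] * C2[, nu] * Jval)
    kdown <- (2 * pi / .HBAR) * overlap * (nocc + 1)
    k[nu, mu] <- kdown
    k[mu, nu] <- kdown * exp(-beta * dE)   # detailed balance
  }
  structure(list(k = k, temperature = temperature), class = "rate_matrix")
}

#' Exciton state lifetimes from a rate matrix
#'
#' tau_mu = 1 / sum_{nu != mu} k(nu <- mu); a state with no depopulation
#' channel has infinite lifetime.
#'
#' @param rates a `rate_matrix` from [redfield_rates()].
#' @return Numeric vector of lifetimes in fs (possibly `Inf`).
#' @export
lifetimes <- function(rates) {
  stopifnot(inherits(rates, "rate_matrix"))
  total <- colSums(rates$k)
  ifelse(total > 0, 1 / total, Inf)
}

#' Second-order cumulant lineshape function g(t)
#'
#' g(t) = (1/pi) int_0^inf dw J(w)/w^2 [coth(beta w / 2) (1 - cos(w t /
#' hbar)) + i (sin(w t / hbar) - w t / hbar)], evaluated by trapezoid
#' quadrature on the spectral-density grid (the w -> 0 integrand is
#' replaced by its finite limit). g(0) = 0 and Im g(t) approaches the
#' classical drift -lambda t / hbar at long times.
#'
#' @param J a [new_spectral_density()] (one column per site accepted).
#' @param temperature temperature, K.
#' @param tgrid time grid starting at 0, fs.
#' @return Object of class `lineshape_function`: list with `tgrid` and
#'   complex matrix `g` (time x site).
#' @export
lineshape_g <- function(J, temperature = 300, tgrid = seq(0, 2000, by = 2)) {
  stopifnot(inherits(J, "spectral_density"))
  if (tgrid[1] != 0) stop("time grid must start at 0")
  omega <- J$omega
  beta <- 1 / (.KB * temperature)
  wt <- c(diff(omega) / 2, 0) + c(0, diff(omega) / 2)   # trapezoid weights
  phase <- outer(tgrid, omega) / .HBAR                  # nt x nw
  g <- matrix(0 + 0i, length(tgrid), ncol(J$J))
  for (m in seq_len(ncol(J$J))) {
    j <- J$J[, m]
    re_w <- j / omega^2 / tanh(beta * omega / 2)
    im_w <- j / omega^2
    # replace the singular w = 0 integrand by its finite limit:
    # Re -> slope * t^2 / (beta hbar^2) with slope = J'(0); Im -> 0
    slope <- if (length(omega) > 1 && omega[2] > 0) j[2] / omega[2] else 0
    re_w[1] <- 0
    im_w[1] <- 0
    re_part <- (1 - cos(phase)) %*% (re_w * wt) +
      slope * (tgrid / .HBAR)^2 / beta * wt[1]
    im_part <- (sin(phase) - phase) %*% (im_w * wt)
    g[, m] <- (re_part + 1i * im_part) / pi
  }
  structure(list(tgrid = tgrid, g = g), class = "lineshape_function")
}

#' Transform lineshape functions and reorganization energies to excitons
#'
#' Participation-ratio weighting: g_mu(t) = sum_m |c_m^mu|^4 g_m(t) and
#' lambda_mu = sum_m |c_m^mu|^4 lambda_m. A fully localized exciton keeps
#' its site values; a delocalized state is motionally narrowed by the
#' inverse participation ratio.
#'
#' @param g a `lineshape_function` from [lineshape_g()] (one column per
#'   site, or one shared column).
#' @param lambda numeric vector of site reorganization energies, cm^-1
#'   (recycled if length 1).
#' @param coefficients orthonormal site x exciton coefficient matrix.
#' @return List with `g` (a `lineshape_function` per exciton) and
#'   `lambda` (cm^-1 per exciton).
#' @export
exciton_g_and_lambda <- function(g, lambda, coefficients) {
  stopifnot(inherits(g, "lineshape_function"))
  n_site <- nrow(coefficients)
  gm <- g$g
  if (ncol(gm) == 1) gm <- gm[, rep(1, n_site), drop = FALSE]
  if (ncol(gm) != n_site) stop("lineshape/coefficient shape mismatch")
  if (length(lambda) == 1) lambda <- rep(lambda, n_site)
  if (length(lambda) != n_site) stop("lambda/coefficient shape mismatch")
  W <- coefficients^4                     # site x exciton weights
  structure(
    list(g = structure(list(tgrid = g$tgrid, g = gm %*% W),
                       class = "lineshape_function"),
         lambda = drop(crossprod(W, lambda))),
    class = "exciton_lineshapes"
  )
}

#' Boltzmann populations of exciton states
#'
#' P_mu = exp(-beta E_mu) / sum_nu exp(-beta E_nu).
#'
#' @param energies exciton energies, cm^-1.
#' @param temperature temperature, K.
#' @return Numeric vector summing to 1.
#' @export
boltzmann_populations <- function(energies, temperature = 300) {
  beta <- 1 / (.KB * temperature)
  w <- exp(-beta * (energies - min(energies)))
  w / sum(w)
}
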