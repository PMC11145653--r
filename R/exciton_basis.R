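#' Diagonalize an exciton Hamiltonian into the exciton basis
#'
#' The excitonic states |mu> are linear combinations of the site-localized
#' states, |mu> = sum_i c_i^mu |i>, obtained from the dense symmetric
#' eigenproblem H c = E c. Eigenvalues are returned in ascending order with
#' a deterministic sign convention: the largest-magnitude coefficient of
#' each eigenvector is made positive (ties broken by the lowest site
#' index). Within a degenerate eigenvalue group, states are ordered by the
#' index of their dominant site.
#'
#' @param h an [exciton_hamiltonian()].
#' @return An object of class `exciton_basis`: list with `energies`
#'   (ascending, cm^-1), `coefficients` (sites x excitons, orthonormal
#'   columns), `labels`, and `dipoles` (`NULL` until site dipoles are
#'   supplied via [exciton_dipoles()]).
#' @export
diagonalize <- function(h) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  e <- eigen(h$matrix, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  n <- length(vals)
  dominant <- integer(n)
  for (mu in seq_len(n)) {
    v <- vecs[, mu]
    i_max <- which.max(abs(v))            # which.max takes the first on ties
    if (v[i_max] < 0) v <- -v
    vecs[, mu] <- v
    dominant[mu] <- i_max
  }
  # deterministic order inside degenerate groups: by dominant-site index
  if (n > 1) {
    grp <- cumsum(c(TRUE, diff(vals) > 1e-8 * pmax(1, abs(vals[-n]))))
    ord2 <- order(grp, dominant)
    vals <- vals[ord2]
    vecs <- vecs[, ord2, drop = FALSE]
  }
  rownames(vecs) <- h$labels
  colnames(vecs) <- paste0("ex", seq_len(n))
  structure(
    list(energies = vals, coefficients = vecs, labels = h$labels,
         dipoles = NULL),
    class = "exciton_basis"
  )
}

#' @export
print.exciton_basis <- function(x, ...) {
  cat(sprintf("Exciton basis: %d states, %.1f - %.1f cm^-1\n",
              length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Transform site transition dipoles into the exciton basis
#'
#' d_mu = sum_i c_i^mu d_i. Because the coefficient matrix is orthonormal,
#' the dipole-strength sum rule sum_mu |d_mu|^2 = sum_i |d_i|^2 holds
#' exactly.
#'
#' @param basis an `exciton_basis` from [diagonalize()].
#' @param site_dipoles numeric matrix (n_sites x 3) of transition dipole
#'   vectors in Debye, one row per site in Hamiltonian order.
#' @return The `exciton_basis` with element `dipoles` filled in
#'   (n_excitons x 3 matrix, Debye).
#' @export
exciton_dipoles <- function(basis, site_dipoles) {
  stopifnot(inherits(basis, "exciton_basis"))
  d <- as.matrix(site_dipoles)
  if (ncol(d) != 3) stop("site dipoles must be 3-vectors (rows)")
  if (nrow(d) != nrow(basis$coefficients))
    stop("need one dipole per site")
  basis$dipoles <- t(basis$coefficients) %*% d
  rownames(basis$dipoles) <- colnames(basis$coefficients)
  basis
}

#' Exciton dipole strengths |d_mu|^2
#'
#' @param basis an `exciton_basis` with dipoles attached.
#' @return numeric vector of squared dipole magnitudes (D^2) per exciton.
#' @export
dipole_strengths <- function(basis) {
  if (is.null(basis$dipoles)) stop("no dipoles attached; see exciton_dipoles()")
  rowSums(basis$dipoles^2)
}
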