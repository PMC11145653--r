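#' Construct a transition-charge set
#'
#' Atomic point charges representing a pigment's transition density
#' (TrEsp): positions in Angstrom and transition charges in units of the
#' elementary charge. The set's transition dipole is
#' d = sum_I q_I r_I (converted to Debye with 1 e Angstrom = 4.80320 D).
#'
#' @param positions numeric matrix (n_atoms x 3), Angstrom.
#' @param charges numeric vector of transition charges, e.
#' @param atom_names optional character vector of atom names.
#' @param pigment_type `"chl-a"`, `"chl-b"` or `"other"`; controls the
#'   default rescaling target (5.7 D for Chl-a, 4.6 D for Chl-b).
#' @return Object of class `transition_charge_set`.
#' @export
transition_charge_set <- function(positions, charges, atom_names = NULL,
                                  pigment_type = c("other", "chl-a", "chl-b")) {
  pigment_type <- match.arg(pigment_type)
  pos <- as.matrix(positions)
  if (ncol(pos) != 3) stop("positions must be an n x 3 matrix (Angstrom)")
  if (nrow(pos) != length(charges))
    stop("positions and charges must have the same length")
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(nrow(pos)))
  structure(
    list(atom_names = as.character(atom_names), positions = pos,
         charges = as.numeric(charges), pigment_type = pigment_type),
    class = "transition_charge_set"
  )
}

#' Transition dipole vector of a charge set
#'
#' @param cs a [transition_charge_set()].
#' @return Length-3 numeric vector in Debye.
#' @export
transition_dipole <- function(cs) {
  drop(crossprod(cs$positions, cs$charges)) * .DEBYE_PER_EA
}

#' Read a transition-charge table and (optionally) PDB coordinates
#'
#' The charge table is columnar text with columns
#' `atom_name x y z q` (Angstrom, e). When `pdb` is given, coordinates are
#' taken from its ATOM/HETATM records (via the bio3d package) and joined to
#' the table by atom name; the table then only needs `atom_name` and `q`.
#'
#' @param file path to the charge table.
#' @param pdb optional path to a PDB file supplying coordinates.
#' @param pigment_type forwarded to [transition_charge_set()].
#' @return A [transition_charge_set()].
#' @export
read_charge_set <- function(file, pdb = NULL,
                            pigment_type = c("other", "chl-a", "chl-b")) {
  pigment_type <- match.arg(pigment_type)
  tab <- read.table(file, header = TRUE)
  if (!is.null(pdb)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB coordinates requires the bio3d package")
    p <- bio3d::read.pdb(pdb)
    at <- p$atom
    idx <- match(tab$atom_name, at$elety)
    if (anyNA(idx)) stop("atom names in charge table not found in PDB")
    pos <- cbind(at$x[idx], at$y[idx], at$z[idx])
  } else {
    pos <- as.matrix(tab[, c("x", "y", "z")])
  }
  transition_charge_set(pos, tab$q, tab$atom_name, pigment_type)
}

#' Rescale transition charges to a target dipole magnitude
#'
#' All charges are multiplied by one scalar so that the transition dipole
#' magnitude equals `target_debye`. The convention follows the common TrEsp
#' practice of rescaling computed transition charges to the experimental
#' transition dipole moments, 5.7 D for Chl-a and 4.6 D for Chl-b.
#'
#' @param cs a [transition_charge_set()].
#' @param target_debye target dipole magnitude in Debye; defaults to 5.7
#'   for `pigment_type == "chl-a"` and 4.6 for `"chl-b"`.
#' @return The rescaled `transition_charge_set`, with the applied scalar in
#'   attribute `"scale_factor"`.
#' @export
rescale_charges <- function(cs, target_debye = NULL) {
  stopifnot(inherits(cs, "transition_charge_set"))
  if (is.null(target_debye)) {
    target_debye <- switch(cs$pigment_type,
                           "chl-a" = 5.7, "chl-b" = 4.6,
                           stop("no default dipole for pigment_type 'other'"))
  }
  raw <- sqrt(sum(transition_dipole(cs)^2))
  if (raw == 0) stop("raw transition dipole is zero; cannot rescale")
  s <- target_debye / raw
  cs$charges <- cs$charges * s
  attr(cs, "scale_factor") <- s
  cs
}

#' Distance-dependent dielectric screening factor
#'
#' f(R) = A exp(-B R) + f0 with the empirical parameters A = 2.68,
#' B = 0.27 1/Angstrom, f0 = 0.54. It multiplies the vacuum Coulomb
#' coupling: at large separations the environment attenuates the coupling
#' to f0 times its vacuum value, at contact the effective factor is
#' A + f0.
#'
#' @param R_mn intermolecular center-center distance(s), Angstrom (>= 0).
#' @param A,B,f0 screening parameters (dimensionless, 1/Angstrom,
#'   dimensionless).
#' @return Dimensionless screening factor(s).
#' @examples
#' screening_factor(10)    # ~0.7203
#' screening_factor(0)     # 3.22
#' @export
screening_factor <- function(R_mn, A = 2.68, B = 0.27, f0 = 0.54) {
  if (any(R_mn < 0)) stop("distance must be non-negative")
  if (f0 <= 0 || B < 0) stop("invalid screening parameters: need f0 > 0, B >= 0")
  A * exp(-B * R_mn) + f0
}

#' Geometric center of the charge-bearing atoms
#' @param cs a [transition_charge_set()].
#' @return Length-3 numeric vector, Angstrom.
#' @export
charge_center <- function(cs) colMeans(cs$positions)

#' TrEsp excitonic coupling between two pigments
#'
#' Vacuum coupling as the Coulomb sum over transition charges,
#' V = C sum_IJ q_I q_J / r_IJ with C = e^2/(4 pi eps0) = 1.16146e5
#' cm^-1 Angstrom, optionally multiplied by the distance-dependent
#' screening factor f(R_mn) evaluated at the center-center distance. By
#' default the molecular center is the geometric center of the
#' charge-bearing atoms; explicit centers (e.g. Mg positions) can be
#' supplied instead.
#'
#' @param donor,acceptor [transition_charge_set()] objects.
#' @param screen logical; apply [screening_factor()]?
#' @param A,B,f0 screening parameters, see [screening_factor()].
#' @param centers optional 2 x 3 matrix of molecular centers (donor row
#'   first) overriding the geometric charge centers.
#' @param min_distance minimum allowed interatomic distance in Angstrom;
#'   closer contacts are treated as an atom clash error.
#' @return Coupling in cm^-1.
#' @export
tresp_coupling <- function(donor, acceptor, screen = TRUE,
                           A = 2.68, B = 0.27, f0 = 0.54,
                           centers = NULL, min_distance = 0.1) {
  stopifnot(inherits(donor, "transition_charge_set"),
            inherits(acceptor, "transition_charge_set"))
  # pairwise distances r_IJ
  d2 <- outer(rowSums(donor$positions^2), rowSums(acceptor$positions^2), "+") -
    2 * donor$positions %*% t(acceptor$positions)
  r <- sqrt(pmax(d2, 0))
  if (min(r) < min_distance)
    stop(sprintf("atom clash: minimum interatomic distance %.3g Angstrom", min(r)))
  v <- .COULOMB_CM1_A * sum((donor$charges %o% acceptor$charges) / r)
  if (screen) {
    if (is.null(centers))
      centers <- rbind(charge_center(donor), charge_center(acceptor))
    R_mn <- sqrt(sum((centers[1, ] - centers[2, ])^2))
    v <- v * screening_factor(R_mn, A, B, f0)
  }
  v
}

#' Assemble an exciton Hamiltonian from site energies and charge sets
#'
#' Site energies go on the diagonal; every off-diagonal element is the
#' pairwise [tresp_coupling()].
#'
#' @param site_energies numeric vector, cm^-1.
#' @param charge_sets list of [transition_charge_set()], one per pigment.
#' @param labels pigment labels (default `names(site_energies)` or
#'   `site1..siteN`).
#' @param screen,A,B,f0 forwarded to [tresp_coupling()].
#' @return An [exciton_hamiltonian()].
#' @export
build_hamiltonian <- function(site_energies, charge_sets, labels = NULL,
                              screen = TRUE, A = 2.68, B = 0.27, f0 = 0.54) {
  n <- length(site_energies)
  if (length(charge_sets) != n)
    stop("need one charge set per pigment")
  if (is.null(labels))
    labels <- if (!is.null(names(site_energies))) names(site_energies)
              else paste0("site", seq_len(n))
  m <- diag(as.numeric(site_energies), n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- tresp_coupling(charge_sets[[i]], charge_sets[[j]], screen = screen,
                          A = A, B = B, f0 = f0)
      m[i, j] <- m[j, i] <- v
    }
  }
  exciton_hamiltonian(m, labels, metadata = list(source = "tresp"))
}
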