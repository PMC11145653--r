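#' Time-dependent exciton Hamiltonian
#'
#' Couplings are held fixed at their (time-averaged) values while the site
#' energies fluctuate frame by frame, matching the common construction in
#' which couplings come from a long classical trajectory and site energies
#' from excited-state QM/MM calculations.
#'
#' @param energies matrix (frames x sites) of site energies, cm^-1.
#' @param couplings symmetric coupling matrix with zero diagonal, cm^-1.
#' @param dt frame spacing, fs.
#' @param labels pigment labels.
#' @return Object of class `td_hamiltonian`.
#' @export
td_hamiltonian <- function(energies, couplings, dt, labels = NULL) {
  e <- as.matrix(energies)
  v <- as.matrix(couplings)
  if (nrow(e) < 2) stop("need at least 2 frames")
  if (ncol(e) != nrow(v) || nrow(v) != ncol(v))
    stop("energies and couplings are inconsistent")
  if (max(abs(v - t(v))) > 1e-9) stop("coupling block must be symmetric")
  if (is.null(labels)) {
    labels <- colnames(e)
    if (is.null(labels)) labels <- paste0("site", seq_len(ncol(e)))
  }
  diag(v) <- 0
  structure(list(energies = e, couplings = v, dt = dt, labels = labels),
            class = "td_hamiltonian")
}

#' Overlapping-window realizations of a site-energy trajectory
#'
#' Splits one long trajectory into `n` windows of length `window_len`
#' whose start offsets are evenly spaced over `[0, T - window_len]`
#' (T = n_frames * dt) and rounded down to frame boundaries. This is the
#' windowing scheme that turns a single 40 ps trajectory into 1000
#' overlapping 6 ps realizations for ensemble averaging; realizations are
#' therefore not fully independent, but to a good approximation.
#'
#' @param traj a [site_trajectory()].
#' @param window_len window length, fs.
#' @param n number of windows.
#' @return Object of class `window_set`: list with `offsets_fs` (frame-
#'   aligned start times), `offset_frames` (0-based), `window_len`,
#'   `nsteps` (propagation steps per window) and the trajectory.
#' @export
window_realizations <- function(traj, window_len, n) {
  stopifnot(inherits(traj, "site_trajectory"), n >= 1)
  total <- nrow(traj$values) * traj$dt
  if (window_len > total) stop("window longer than trajectory")
  exact <- if (n == 1) 0 else (0:(n - 1)) * (total - window_len) / (n - 1)
  frames <- floor(exact / traj$dt)
  structure(list(offsets_fs = frames * traj$dt, offset_frames = frames,
                 window_len = window_len,
                 nsteps = round(window_len / traj$dt), traj = traj),
            class = "window_set")
}

#' Materialize one window as a time-dependent Hamiltonian
#'
#' @param ws a `window_set` from [window_realizations()].
#' @param i window index (1-based).
#' @param couplings static coupling matrix, cm^-1.
#' @return A [td_hamiltonian()] covering that window.
#' @export
window_segment <- function(ws, i, couplings) {
  stopifnot(inherits(ws, "window_set"))
  o <- ws$offset_frames[i]
  rows <- (o + 1):(o + ws$nsteps)
  td_hamiltonian(ws$traj$values[rows, , drop = FALSE], couplings,
                 ws$traj$dt, ws$traj$labels)
}

.site_index <- function(labels, site) {
  if (is.character(site)) {
    i <- match(site, labels)
    if (is.na(i)) stop(sprintf("unknown site '%s'", site))
    i
  } else as.integer(site)
}

.trace_obj <- function(tgrid, P, labels, n_realizations, initial_site) {
  colnames(P) <- labels
  structure(list(tgrid = tgrid, P = P, n_realizations = n_realizations,
                 initial_site = initial_site),
            class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  cat(sprintf(
    "Population trace: start %s, %d sites, %.0f fs, %d realization(s)\n",
    x$initial_site, ncol(x$P), max(x$tgrid), x$n_realizations))
  invisible(x)
}

#' Propagate a single wave-packet realization
#'
#' Numerically integrates the time-dependent Schroedinger equation for one
#' realization: within each stored frame the Hamiltonian is constant and
#' the wave function advances by the exact eigen-exponential
#' psi <- exp(-i H dt_prop / hbar) psi. Populations are P_m = |<m|psi>|^2;
#' the propagation is exactly unitary, so the norm is conserved to
#' numerical precision.
#'
#' @param tdh a [td_hamiltonian()].
#' @param initial_site label or index of the initially excited pigment.
#' @param dt_prop propagation time step, fs; must divide the frame spacing
#'   (default: the frame spacing itself).
#' @return A `population_trace` with populations at every propagation
#'   step.
#' @export
propagate <- function(tdh, initial_site, dt_prop = NULL) {
  stopifnot(inherits(tdh, "td_hamiltonian"))
  if (is.null(dt_prop)) dt_prop <- tdh$dt
  if (dt_prop > tdh$dt) stop("dt_prop must not exceed the frame spacing")
  substeps <- tdh$dt / dt_prop
  if (abs(substeps - round(substeps)) > 1e-9)
    stop("dt_prop must divide the frame spacing")
  substeps <- as.integer(round(substeps))
  n <- ncol(tdh$energies)
  i0 <- .site_index(tdh$labels, initial_site)
  psi0 <- matrix(0 + 0i, n, 1)
  psi0[i0, 1] <- 1 + 0i
  P <- nise_propagate_cpp(tdh$energies, tdh$couplings, tdh$dt, substeps,
                          psi0, .HBAR)[, , 1]
  tgrid <- seq(0, by = dt_prop, length.out = nrow(P))
  .trace_obj(tgrid, P, tdh$labels, 1L, tdh$labels[i0])
}

#' Ensemble-averaged exciton population dynamics (NISE)
#'
#' Propagates every overlapping-window realization from the same initial
#' pigment(s) and averages the site populations. Window offsets are
#' deterministic (evenly spaced), so the result is fully determined by the
#' trajectory and the parameters; only the synthetic-noise generator
#' consumes random seeds. Note that ensemble-averaged wave-packet dynamics
#' does not thermalize: at long times it approaches equal populations of
#' the coupled sites rather than a Boltzmann distribution.
#'
#' @param traj a [site_trajectory()] of site energies, cm^-1.
#' @param couplings static symmetric coupling matrix, cm^-1.
#' @param initial_sites labels (or indices) of initially excited pigments;
#'   default all.
#' @param window_len realization length, fs (default 6000).
#' @param n number of overlapping windows (default 1000).
#' @return A single `population_trace` if one initial site was requested,
#'   otherwise a named list of traces.
#' @export
ensemble_dynamics <- function(traj, couplings, initial_sites = traj$labels,
                              window_len = 6000, n = 1000) {
  stopifnot(inherits(traj, "site_trajectory"))
  ws <- window_realizations(traj, window_len, n)
  nsite <- ncol(traj$values)
  idx <- vapply(initial_sites, .site_index, labels = traj$labels, 1L)
  psi0 <- matrix(0 + 0i, nsite, length(idx))
  psi0[cbind(idx, seq_along(idx))] <- 1 + 0i
  P <- nise_ensemble_cpp(traj$values, as.matrix(couplings), traj$dt,
                         as.integer(ws$offset_frames), ws$nsteps, psi0, .HBAR)
  tgrid <- seq(0, by = traj$dt, length.out = dim(P)[1])
  traces <- lapply(seq_along(idx), function(j)
    .trace_obj(tgrid, P[, , j], traj$labels, n, traj$labels[idx[j]]))
  names(traces) <- traj$labels[idx]
  if (length(traces) == 1) traces[[1]] else traces
}

#' 1/e relaxation time of the initial-site population
#'
#' The long-time plateau of ensemble-averaged wave-packet dynamics inside
#' an N-site coupling cluster is the equal population P_inf = 1/N. The
#' relaxation time is the first time at which the initial-site population
#' falls below P_inf + (1 - P_inf)/e; `Inf` if it never does within the
#' trace.
#'
#' @param trace a `population_trace`.
#' @param initial_site pigment whose decay is followed (default the
#'   trace's initial site).
#' @param cluster_size number of pigments in the coupling cluster
#'   containing the initial site (see [coupling_clusters()]).
#' @return Relaxation time in fs, or `Inf`.
#' @export
relaxation_time <- function(trace, initial_site = trace$initial_site,
                            cluster_size) {
  stopifnot(inherits(trace, "population_trace"))
  i0 <- .site_index(colnames(trace$P), initial_site)
  p_inf <- 1 / cluster_size
  thr <- p_inf + (1 - p_inf) / exp(1)
  below <- which(trace$P[, i0] < thr)
  if (length(below) == 0) return(Inf)
  trace$tgrid[below[1]]
}

#' Population transferred between two pigment groups
#'
#' Maximum total population found on the pigments of `group` over the
#' trace; with the initial excitation outside `group` this measures
#' inter-cluster exciton crossing.
#'
#' @param trace a `population_trace`.
#' @param group character vector of pigment labels.
#' @return Maximum summed population on `group` over time.
#' @export
max_population_on <- function(trace, group) {
  idx <- vapply(group, .site_index, labels = colnames(trace$P), 1L)
  max(rowSums(trace$P[, idx, drop = FALSE]))
}

#' Write a population trace as columnar text
#'
#' @param trace a `population_trace`.
#' @param file output path (`t_fs` column followed by one `P_<label>`
#'   column per pigment).
#' @return `file`, invisibly.
#' @export
write_population_trace <- function(trace, file) {
  df <- data.frame(t_fs = trace$tgrid, trace$P, check.names = FALSE)
  names(df)[-1] <- paste0("P_", colnames(trace$P))
  write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}
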