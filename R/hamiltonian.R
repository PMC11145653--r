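#' Construct an exciton Hamiltonian
#'
#' An `exciton_hamiltonian` holds the site (diagonal) energies E_i and the
#' excitonic couplings V_ij of a Frenkel tight-binding Hamiltonian
#' H = sum_i E_i |i><i| + sum_{i != j} V_ij |i><j|, all in cm^-1, together
#' with pigment labels (e.g. `"b601"`, `"a612"`).
#'
#' Invariants enforced on construction: the coupling block is symmetric to
#' within 1e-9 cm^-1, diagonal energies are strictly positive, labels are
#' unique and match the matrix dimension.
#'
#' @param matrix square numeric matrix in cm^-1 (diagonal = site energies).
#' @param labels character vector of pigment labels; defaults to the
#'   matrix dimnames.
#' @param metadata free-text provenance, carried along unmodified.
#' @return An object of class `exciton_hamiltonian` with elements
#'   `labels`, `energies`, `couplings` (full symmetric matrix with zero
#'   diagonal), `matrix` (the full Hamiltonian) and `metadata`.
#' @export
exciton_hamiltonian <- function(matrix, labels = rownames(matrix),
                                metadata = list()) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("Hamiltonian matrix must be square")
  n <- nrow(m)
  if (is.null(labels)) labels <- paste0("site", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("label count does not match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate pigment labels")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite Hamiltonian entries")
  if (max(abs(m - t(m))) > 1e-9)
    stop("Hamiltonian not symmetric to within 1e-9 cm^-1")
  if (any(diag(m) <= 0)) stop("site energies must be strictly positive")
  dimnames(m) <- list(labels, labels)
  couplings <- m
  diag(couplings) <- 0
  structure(
    list(labels = labels, energies = setNames(diag(m), labels),
         couplings = couplings, matrix = m, metadata = metadata),
    class = "exciton_hamiltonian"
  )
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  n <- length(x$labels)
  offd <- abs(x$couplings)
  vmax <- max(offd)
  idx <- which(offd == vmax, arr.ind = TRUE)[1, ]
  cat(sprintf("Exciton Hamiltonian: %d sites (%s)\n", n,
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  site energies: %.1f - %.1f cm^-1\n",
              min(x$energies), max(x$energies)))
  if (n > 1)
    cat(sprintf("  max |coupling|: %.1f cm^-1 (%s, %s)\n", vmax,
                x$labels[idx[1]], x$labels[idx[2]]))
  invisible(x)
}

#' @export
as.matrix.exciton_hamiltonian <- function(x, ...) x$matrix

#' @export
dim.exciton_hamiltonian <- function(x) dim(x$matrix)

#' Parse a labelled Hamiltonian matrix from text
#'
#' Reads a square labelled matrix (first row: pigment labels; each further
#' row: label followed by N numbers, whitespace- or comma-separated) or the
#' JSON form `{"labels": [...], "matrix": [[...]], "units": "cm-1"}`.
#' Printed tables are often rounded, so an asymmetry of up to `tolerance`
#' (default 0.05 cm^-1) is accepted and removed by averaging `V` and
#' `t(V)`; larger asymmetries are an error. The maximum asymmetry found is
#' recorded in `metadata$max_asymmetry_cm1`.
#'
#' @param file path to the matrix file (text or `.json`).
#' @param units input units, `"cm-1"` (default) or `"eV"`; the stored
#'   Hamiltonian is always in cm^-1.
#' @param tolerance maximum accepted asymmetry in cm^-1 before
#'   symmetrization.
#' @return An [exciton_hamiltonian()].
#' @examples
#' h <- parse_hamiltonian(system.file("extdata",
#'   "cp24_table2_hamiltonian.csv", package = "excitonkit"))
#' h$energies[["a610"]]  # 16397.1
#' @export
parse_hamiltonian <- function(file, units = c("cm-1", "eV"), tolerance = 0.05) {
  units <- match.arg(units)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(file)
    labels <- as.character(obj$labels)
    m <- if (is.matrix(obj$matrix)) obj$matrix
         else matrix(unlist(obj$matrix), nrow = length(labels), byrow = TRUE)
    if (!is.null(obj$units)) units <- match.arg(obj$units, c("cm-1", "eV"))
  } else {
    first <- readLines(file, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
    tab <- read.table(file, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, strip.white = TRUE)
    m <- as.matrix(tab)
    labels <- rownames(tab)
    # header may carry a leading corner label; align on row labels
    if (!identical(colnames(tab), labels) && ncol(m) == length(labels))
      colnames(m) <- labels
  }
  if (nrow(m) != ncol(m)) stop("Hamiltonian block is not square")
  if (anyNA(m)) stop("NaN/NA entries in Hamiltonian")
  if (anyDuplicated(labels)) stop("duplicate pigment labels")
  if (units == "eV") {
    m <- convert_units(m, "eV", "cm-1")
    tolerance <- convert_units(tolerance, "eV", "cm-1")
  }
  asym <- max(abs(m - t(m)))
  if (asym > tolerance)
    stop(sprintf("asymmetry %.4g cm^-1 exceeds tolerance %.4g cm^-1",
                 asym, tolerance))
  m <- (m + t(m)) / 2
  exciton_hamiltonian(m, labels,
                      metadata = list(source = file, input_units = units,
                                      max_asymmetry_cm1 = asym))
}

#' Write an exciton Hamiltonian as labelled text
#'
#' @param h an [exciton_hamiltonian()].
#' @param file output path; comma-separated with a `label` corner column.
#' @return `file`, invisibly.
#' @export
write_hamiltonian <- function(h, file) {
  df <- data.frame(label = h$labels, h$matrix, check.names = FALSE)
  write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
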