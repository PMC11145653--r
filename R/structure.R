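#' Construct a pigment structure
#'
#' Minimal chlorophyll-like geometry record for coordination analysis:
#' atom names and positions, the central Mg atom, the porphyrin-plane atom
#' subset (at least three, so the ring plane is definable) and the first
#' phytyl-chain atom used as the tail-side reference.
#'
#' @param atom_names character vector.
#' @param positions numeric matrix (n x 3), Angstrom.
#' @param mg_atom name (or index) of the single Mg atom.
#' @param ring_atoms names (or indices) of the porphyrin-plane atoms.
#' @param tail_atom name (or index) of the first phytyl-chain atom.
#' @param label pigment label.
#' @return Object of class `pigment_structure`.
#' @export
pigment_structure <- function(atom_names, positions, mg_atom = "MG",
                              ring_atoms, tail_atom, label = "pigment") {
  pos <- as.matrix(positions)
  if (ncol(pos) != 3 || nrow(pos) != length(atom_names))
    stop("positions must be n x 3 with one row per atom name")
  to_idx <- function(x) if (is.character(x)) match(x, atom_names) else as.integer(x)
  mg <- to_idx(mg_atom)
  ring <- to_idx(ring_atoms)
  tail <- to_idx(tail_atom)
  if (length(mg) != 1 || is.na(mg)) stop("need exactly one Mg atom")
  if (length(ring) < 3 || anyNA(ring)) stop("need >= 3 ring atoms")
  if (length(tail) != 1 || is.na(tail)) stop("need one tail reference atom")
  structure(list(atom_names = atom_names, positions = pos, mg_index = mg,
                 ring_index = ring, tail_index = tail, label = label),
            class = "pigment_structure")
}

#' Mg position of a pigment structure
#' @param struct a [pigment_structure()].
#' @return Length-3 vector, Angstrom.
#' @export
mg_position <- function(struct) struct$positions[struct$mg_index, ]

# least-squares ring plane: centroid + unit normal (smallest right singular
# vector of the centered ring coordinates)
.ring_plane <- function(struct) {
  ring <- struct$positions[struct$ring_index, , drop = FALSE]
  centroid <- colMeans(ring)
  sv <- svd(sweep(ring, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Classify an axial water as cis (Wc) or trans (Wt) to the phytyl tail
#'
#' The porphyrin plane is the least-squares plane of the designated ring
#' atoms. The signed plane distance of the water oxygen is compared with
#' that of the first phytyl-chain atom: same side of the plane as the tail
#' is `"Wc"` (cis-like), the opposite side is `"Wt"` (trans-like). A water
#' essentially in the plane (|signed distance| < 0.1 Angstrom) is flagged
#' `"ambiguous"`.
#'
#' @param struct a [pigment_structure()].
#' @param water_O_position length-3 position of the water oxygen,
#'   Angstrom.
#' @return `"Wc"`, `"Wt"` or `"ambiguous"`.
#' @export
classify_water_side <- function(struct, water_O_position) {
  pl <- .ring_plane(struct)
  d_water <- sum((water_O_position - pl$centroid) * pl$normal)
  d_tail <- sum((struct$positions[struct$tail_index, ] - pl$centroid) * pl$normal)
  if (abs(d_water) < 0.1) return("ambiguous")
  if (sign(d_water) == sign(d_tail)) "Wc" else "Wt"
}

#' Mg coordination analysis
#'
#' Records every candidate ligand atom within `cutoff` of the Mg atom of
#' each pigment (the standard 2.5 Angstrom criterion; water distances are
#' measured Mg to water oxygen). The four porphyrin nitrogens are counted
#' implicitly, so the coordination number is 4 plus the number of axial
#' ligands found — matching the usual five-/six-coordinated language for
#' chlorophylls. Waters are additionally classified Wc/Wt via
#' [classify_water_side()].
#'
#' @param structs a [pigment_structure()] or list of them.
#' @param ligands data frame of candidate ligand atoms with columns
#'   `resname`, `atom`, `x`, `y`, `z` (water oxygens plus side-chain O/N).
#' @param cutoff Mg-ligand distance cutoff, Angstrom.
#' @param water_resnames residue names treated as water.
#' @return List of `coordination_record` objects: `pigment`, `ligands`
#'   (data frame with `resname`, `atom`, `distance`, `side`) and
#'   `coordination_number`.
#' @export
mg_coordination <- function(structs, ligands, cutoff = 2.5,
                            water_resnames = c("HOH", "SOL", "WAT")) {
  if (inherits(structs, "pigment_structure")) structs <- list(structs)
  lig_pos <- as.matrix(ligands[, c("x", "y", "z")])
  lapply(structs, function(st) {
    mg <- mg_position(st)
    d <- sqrt(rowSums(sweep(lig_pos, 2, mg)^2))
    keep <- which(d <= cutoff)
    side <- character(length(keep))
    for (i in seq_along(keep)) {
      side[i] <- if (ligands$resname[keep[i]] %in% water_resnames)
        classify_water_side(st, lig_pos[keep[i], ])
      else "n/a"
    }
    structure(
      list(pigment = st$label,
           ligands = data.frame(resname = ligands$resname[keep],
                                atom = ligands$atom[keep],
                                distance = d[keep], side = side,
                                stringsAsFactors = FALSE),
           coordination_number = 4L + length(keep)),
      class = "coordination_record")
  })
}

#' @export
print.coordination_record <- function(x, ...) {
  cat(sprintf("%s: coordination %d (4 ring N + %d axial)\n", x$pigment,
              x$coordination_number, nrow(x$ligands)))
  if (nrow(x$ligands))
    for (i in seq_len(nrow(x$ligands)))
      cat(sprintf("  %s %s at %.2f Angstrom [%s]\n", x$ligands$resname[i],
                  x$ligands$atom[i], x$ligands$distance[i], x$ligands$side[i]))
  invisible(x)
}

#' Mg-Mg distance matrix of a pigment set
#'
#' @param structs list of [pigment_structure()] objects.
#' @return Symmetric matrix of Mg-Mg distances in Angstrom, zero diagonal,
#'   labelled by pigment.
#' @export
mg_distance_matrix <- function(structs) {
  if (length(structs) < 2) stop("need at least 2 pigments")
  mg <- t(vapply(structs, mg_position, numeric(3)))
  labels <- vapply(structs, function(s) s$label, "")
  d <- as.matrix(stats::dist(mg))
  dimnames(d) <- list(labels, labels)
  d
}

# Kabsch optimal rotation R such that x %*% R best matches y (both centered)
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square fluctuations of selected atoms
#'
#' RMSF_i = sqrt(< |x_i(t) - <x_i>|^2 >) after optimal rigid-body
#' superposition of every frame onto the mean structure (Kabsch, iterated
#' once so the mean is self-consistent).
#'
#' @param coords numeric array (frames x atoms x 3), Angstrom.
#' @param select atom indices to fit and report (default all).
#' @param align superpose frames before computing fluctuations?
#' @return Numeric vector of per-atom RMSF values, Angstrom.
#' @export
rmsf <- function(coords, select = NULL, align = TRUE) {
  if (length(dim(coords)) != 3) stop("coords must be frames x atoms x 3")
  if (dim(coords)[1] < 2) stop("need at least 2 frames")
  if (!is.null(select)) coords <- coords[, select, , drop = FALSE]
  nf <- dim(coords)[1]
  if (align) {
    for (pass in 1:2) {
      ref <- apply(coords, c(2, 3), mean)
      ref_c <- sweep(ref, 2, colMeans(ref))
      for (f in seq_len(nf)) {
        x <- coords[f, , ]
        xc <- sweep(x, 2, colMeans(x))
        coords[f, , ] <- sweep(xc %*% .kabsch(xc, ref_c), 2,
                               -colMeans(ref))
      }
    }
  }
  mean_pos <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_pos)^2
  sqrt(apply(dev2, 2, mean) * 3)
}

#' Select representative frames by PCA + K-means on Mg positions
#'
#' Flattened Mg coordinates are projected onto the leading principal
#' components explaining at least `var_explained` of the variance and
#' clustered with K-means (`nstart` seeded random restarts). The returned
#' frames are those nearest each cluster centroid, sorted by time. The RNG
#' state is restored afterwards.
#'
#' @param mg_positions numeric array (frames x n_mg x 3) or matrix
#'   (frames x 3 n_mg).
#' @param k number of representatives (default 5).
#' @param seed RNG seed for the K-means restarts.
#' @param var_explained cumulative variance threshold for retained PCs.
#' @param nstart number of K-means restarts.
#' @return Integer vector of `k` frame indices, ascending.
#' @export
select_frames <- function(mg_positions, k = 5, seed = 1,
                          var_explained = 0.9, nstart = 50) {
  x <- if (length(dim(mg_positions)) == 3)
    matrix(mg_positions, nrow = dim(mg_positions)[1]) else as.matrix(mg_positions)
  if (k > nrow(x)) stop("k exceeds the number of frames")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  ncomp <- max(1, which(cum >= var_explained)[1], na.rm = TRUE)
  scores <- p$x[, seq_len(ncomp), drop = FALSE]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    d2 <- rowSums(sweep(scores[members, , drop = FALSE], 2,
                        km$centers[cl, ])^2)
    members[which.min(d2)]
  }, 1L)
  sort(reps)
}

#' Read pigment structures from a PDB file
#'
#' Extracts one [pigment_structure()] per chlorophyll-like residue from
#' the ATOM/HETATM records of a PDB file (requires the bio3d package).
#'
#' @param file PDB path.
#' @param resnames residue names treated as pigments.
#' @param mg_name,tail_name atom names of the Mg and of the first phytyl
#'   carbon.
#' @param ring_names atom names spanning the porphyrin plane (default:
#'   the four ring nitrogens).
#' @return Named list of `pigment_structure` objects.
#' @export
read_pigment_structures <- function(file, resnames = c("CLA", "CHL"),
                                    mg_name = "MG", tail_name = "C1",
                                    ring_names = c("NA", "NB", "NC", "ND")) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  sel <- at$resid %in% resnames
  if (!any(sel)) stop("no pigment residues found")
  keys <- unique(paste(at$resid[sel], at$chain[sel], at$resno[sel]))
  out <- lapply(keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    rows <- which(at$resid == parts[1] &
                    (is.na(at$chain) | at$chain == parts[2]) &
                    at$resno == as.integer(parts[3]))
    pigment_structure(at$elety[rows],
                      cbind(at$x[rows], at$y[rows], at$z[rows]),
                      mg_atom = mg_name, ring_atoms = ring_names,
                      tail_atom = tail_name,
                      label = paste0(parts[1], parts[3]))
  })
  names(out) <- vapply(out, function(s) s$label, "")
  out
}
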