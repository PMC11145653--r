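#' Identify coupling clusters of pigments
#'
#' Builds the graph whose vertices are the pigments and whose edges connect
#' pairs with |V_ij| strictly greater than `threshold`, and returns its
#' connected components. Pigments without any above-threshold coupling are
#' reported as singletons. In CP24 a 30 cm^-1 threshold separates the
#' complex into three strongly coupled clusters plus one isolated
#' chlorophyll-b.
#'
#' @param h an [exciton_hamiltonian()].
#' @param threshold coupling magnitude threshold in cm^-1 (must be > 0).
#' @return An object of class `cluster_partition`: list with `clusters`
#'   (list of character vectors of pigment labels, in first-appearance
#'   order), `singletons` (labels of size-1 clusters) and `threshold`.
#' @examples
#' h <- table2_fixture()
#' coupling_clusters(h, threshold = 30)
#' @export
coupling_clusters <- function(h, threshold = 30) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  if (threshold <= 0) stop("threshold must be > 0")
  adj <- (abs(h$couplings) > threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  clusters <- split(h$labels, comp$membership)
  # order clusters by the position of their first member in the label list
  first <- vapply(clusters, function(cl) min(match(cl, h$labels)), 1)
  clusters <- unname(clusters[order(first)])
  clusters <- lapply(clusters, function(cl) cl[order(match(cl, h$labels))])
  sizes <- lengths(clusters)
  structure(
    list(clusters = clusters,
         singletons = unlist(clusters[sizes == 1], use.names = FALSE),
         threshold = threshold),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Coupling clusters at |V| > %g cm^-1:\n", x$threshold))
  for (cl in x$clusters)
    cat("  {", paste(cl, collapse = ", "), "}\n")
  if (length(x$singletons))
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster containing a given pigment
#'
#' @param partition a `cluster_partition`.
#' @param label pigment label.
#' @return Character vector of labels of the cluster containing `label`.
#' @export
cluster_of <- function(partition, label) {
  for (cl in partition$clusters) if (label %in% cl) return(cl)
  stop(sprintf("label '%s' not in partition", label))
}
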