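# Structural summaries: the constraint set that the null-model ladder
# reproduces (degree distribution, joint degree distribution, clustering,
# degree-dependent clustering) plus the k-core index and epidemic threshold.

local_clustering <- function(graph) {
  # local clustering coefficient; nodes of degree < 2 are defined as 0
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  cc
}

degree_dist <- function(deg) {
  tab <- table(factor(deg, levels = sort(unique(deg))))
  p <- as.numeric(tab) / length(deg)
  names(p) <- names(tab)
  p
}

#' Joint degree distribution
#'
#' Probability that a uniformly random (ordered) edge endpoint pair has
#' degrees `(k1, k2)`. The ordered-pair convention makes the matrix
#' symmetric and its entries sum to 1.
#'
#' @param graph A network.
#' @return A symmetric matrix indexed by the degrees present in the graph.
#' @export
joint_degree_dist <- function(graph) {
  graph <- as_network(graph)
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  ks <- sort(unique(deg))
  m <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  if (nrow(el) > 0) {
    i1 <- match(deg[el[, 1]], ks)
    i2 <- match(deg[el[, 2]], ks)
    for (e in seq_len(nrow(el))) {
      m[i1[e], i2[e]] <- m[i1[e], i2[e]] + 1
      m[i2[e], i1[e]] <- m[i2[e], i1[e]] + 1
    }
    m <- m / (2 * nrow(el))
  }
  m
}

#' Degree-dependent mean clustering
#'
#' Mean local clustering coefficient of the nodes in each degree class.
#'
#' @param graph A network.
#' @return A named numeric vector indexed by degree.
#' @export
clustering_by_degree <- function(graph) {
  graph <- as_network(graph)
  deg <- igraph::degree(graph)
  cc <- local_clustering(graph)
  out <- tapply(cc, factor(deg, levels = sort(unique(deg))), mean)
  structure(as.numeric(out), names = names(out))
}

#' Epidemic threshold
#'
#' The degree-based mean-field epidemic threshold
#' \eqn{\beta_{th} = \langle k\rangle / \langle k^2\rangle}, the infection
#' probability at which an SIR outbreak transitions from dying out to
#' spreading. On any k-regular graph this equals `1/k`.
#'
#' @param graph A network with at least 2 nodes and one edge.
#' @return A number in (0, 1].
#' @export
epidemic_threshold <- function(graph) {
  graph <- as_network(graph)
  if (igraph::vcount(graph) < 2L || igraph::ecount(graph) < 1L) {
    stop("epidemic threshold is undefined for an edgeless graph", call. = FALSE)
  }
  deg <- igraph::degree(graph)
  mean(deg) / mean(deg^2)
}

#' Structural summary of a network
#'
#' Computes the constraint set used by the null-model ladder and the
#' epidemic quantities: node/edge counts, true mean degree (2E/N), degree
#' distribution, joint degree distribution, mean local clustering,
#' degree-dependent clustering, maximum k-core index and the epidemic
#' threshold. Local clustering of degree-<2 nodes is defined as 0.
#'
#' The printed report also shows the doubled-count convention
#' (ordered-pair edge count 2E and degree sum / N) used by some published
#' network tables; all internal computation uses undirected counts.
#'
#' @param graph A network.
#' @return An object of class `"network_summary"`.
#' @export
network_summary <- function(graph) {
  graph <- as_network(graph)
  deg <- igraph::degree(graph)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  out <- list(
    n_nodes = n,
    n_edges_undirected = m,
    mean_degree = 2 * m / n,
    degree_distribution = degree_dist(deg),
    joint_degree_distribution = joint_degree_dist(graph),
    mean_clustering = mean(local_clustering(graph)),
    clustering_by_degree = clustering_by_degree(graph),
    max_kshell = if (m > 0) max(igraph::coreness(graph)) else 0L,
    epidemic_threshold = if (m > 0) epidemic_threshold(graph) else NA_real_
  )
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, digits = 3, ...) {
  cat("Network summary\n")
  cat(sprintf("  nodes N:              %d\n", x$n_nodes))
  cat(sprintf("  edges (undirected):   %d   [ordered-pair count: %d]\n",
              x$n_edges_undirected, 2L * x$n_edges_undirected))
  cat(sprintf("  mean degree 2E/N:     %.*f   [doubled convention: %.*f]\n",
              digits, x$mean_degree, digits, 2 * x$mean_degree))
  cat(sprintf("  mean clustering:      %.*f\n", digits, x$mean_clustering))
  cat(sprintf("  max k-shell:          %d\n", x$max_kshell))
  if (!is.na(x$epidemic_threshold)) {
    cat(sprintf("  epidemic threshold:   %.*f\n", digits, x$epidemic_threshold))
  }
  invisible(x)
}
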