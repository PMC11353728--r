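# Ego-subnetwork decomposition: one fixed-size subnetwork per node (the
# centre plus its highest-degree neighbours, padded to length L), with six
# classical centralities computed on the induced subgraph as spatial
# features. PAD positions are structural zeros (NA member ids), never a
# real node.

round_half_up <- function(x) floor(x + 0.5)

#' Subnetwork size L
#'
#' The common ego-subnetwork size: the rounded mean degree of the top 10%
#' highest-degree nodes (at least one node; degree ties broken by ascending
#' node id; round-half-up). On any k-regular graph this is k. On the
#' karate club it is 15.
#'
#' @param graph A network.
#' @return An integer L >= 1.
#' @export
subnet_size <- function(graph) {
  graph <- as_network(graph)
  deg <- igraph::degree(graph)
  m <- max(1L, floor(igraph::vcount(graph) / 10))
  top <- order(-deg, seq_along(deg))[seq_len(m)]
  max(1L, as.integer(round_half_up(mean(deg[top]))))
}

#' Subnetwork membership of a node
#'
#' The ordered member list of the ego-subnetwork centred at `v`: the centre
#' first, then its neighbours in decreasing degree order (ties by ascending
#' node id), truncated to `L - 1` neighbours or padded with `NA` (PAD) when
#' the centre has fewer. Only 1-hop neighbours are ever included.
#'
#' @param graph A network.
#' @param v Centre node id.
#' @param L Subnetwork size (default [subnet_size()]).
#' @return An integer vector of length `L`; trailing `NA`s are PAD slots.
#' @export
subnet_members <- function(graph, v, L = NULL) {
  graph <- as_network(graph)
  n <- igraph::vcount(graph)
  if (length(v) != 1L || is.na(v) || v < 1L || v > n) {
    stop("invalid centre node id", call. = FALSE)
  }
  if (is.null(L)) L <- subnet_size(graph)
  stopifnot(L >= 1)
  deg <- igraph::degree(graph)
  nb <- as.integer(igraph::neighbors(graph, v))
  nb <- nb[order(-deg[nb], nb)]
  keep <- nb[seq_len(min(length(nb), L - 1L))]
  c(as.integer(v), keep, rep(NA_integer_, L - 1L - length(keep)))
}

# power iteration for eigenvector-type centralities on a nonnegative matrix;
# returns NULL on non-convergence or a zero matrix
.power_iteration <- function(M, tol = 1e-8, maxit = 1000L) {
  n <- nrow(M)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(maxit)) {
    y <- as.numeric(M %*% x)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(NULL)
    y <- y / nrm
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  NULL
}

# component-scaled closeness: (r/s) * (r/(n-1)) with r = reachable nodes
# (excluding self) and s = sum of distances to them; isolated nodes get 0
.closeness_scaled <- function(sub) {
  n <- igraph::vcount(sub)
  if (n == 1L) return(0)
  d <- igraph::distances(sub)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- is.finite(di)
    r <- sum(fin)
    if (r == 0) return(0)
    (r / sum(di[fin])) * (r / (n - 1))
  }, 1)
}

.minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Spatial feature matrix of a subnetwork
#'
#' Computes, on the induced subgraph of the non-PAD members only, the six
#' centrality columns in fixed order: degree (DC), eigenvector (EC), HITS
#' authority, closeness (CC, component-scaled for disconnected subgraphs),
#' betweenness (BC) and k-core index (Ks). Each column is min-max scaled to
#' `[0, 1]` within the subnetwork (constant columns map to 0); PAD rows are
#' all-zero. EC and HITS use power iteration (tolerance 1e-8, 1000
#' iterations) with a degree-proportional fallback on non-convergence.
#'
#' @param graph A network.
#' @param members Member vector from [subnet_members()] (length L, `NA` pads).
#' @return An `L x 6` matrix with columns `DC, EC, HITS, CC, BC, Ks`.
#' @export
spatial_features <- function(graph, members) {
  graph <- as_network(graph)
  L <- length(members)
  real <- members[!is.na(members)]
  out <- matrix(0, L, 6, dimnames = list(NULL, c("DC", "EC", "HITS", "CC", "BC", "Ks")))
  if (length(real) == 0L) return(out)
  sub <- igraph::induced_subgraph(graph, real)
  a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  deg <- igraph::degree(sub)
  ec <- .power_iteration(a)
  if (is.null(ec)) ec <- deg
  hits <- .power_iteration(a %*% a)
  if (is.null(hits)) hits <- deg
  f <- cbind(
    DC = deg,
    EC = ec,
    HITS = hits,
    CC = .closeness_scaled(sub),
    BC = igraph::betweenness(sub),
    Ks = igraph::coreness(sub)
  )
  out[seq_along(real), ] <- apply(f, 2, .minmax01)
  out
}

#' Build the stacked subnetwork dataset
#'
#' Assembles the per-node tensors the scorer consumes: an `N x L x 6`
#' feature array, an `N x L x L` adjacency array (induced subgraph
#' adjacency embedded in zeros, following member order), an `N x L x 1`
#' label array (network-wide min-max-normalised influence labels of the
#' members, PAD slots 0) and the `N x L` member table. Subnetworks are
#' evaluated in ascending node-id order.
#'
#' @param graph A network.
#' @param labels Influence labels over the same node set (numeric length N).
#' @param L Subnetwork size (default [subnet_size()]).
#' @return An object of class `"subnet_dataset"`.
#' @export
build_subnet_dataset <- function(graph, labels, L = NULL) {
  graph <- as_network(graph)
  n <- igraph::vcount(graph)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") does not match node count (", n, ")",
         call. = FALSE)
  }
  if (is.null(L)) L <- subnet_size(graph)
  lab01 <- .minmax01(as.numeric(labels))
  features <- array(0, c(n, L, 6))
  adjacency <- array(0, c(n, L, L))
  labarr <- array(0, c(n, L, 1))
  members <- matrix(NA_integer_, n, L)
  for (v in seq_len(n)) {
    mem <- subnet_members(graph, v, L)
    members[v, ] <- mem
    real <- mem[!is.na(mem)]
    features[v, , ] <- spatial_features(graph, mem)
    sub <- igraph::induced_subgraph(graph, real)
    a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    adjacency[v, seq_along(real), seq_along(real)] <- a
    labarr[v, seq_along(real), 1] <- lab01[real]
  }
  out <- list(features = features, adjacency = adjacency, labels = labarr,
              members = members, L = L, n = n, labels01 = lab01)
  class(out) <- "subnet_dataset"
  out
}

#' @export
print.subnet_dataset <- function(x, ...) {
  cat(sprintf("Subnetwork dataset: N = %d, L = %d\n", x$n, x$L))
  cat(sprintf("  features %d x %d x 6, adjacency %d x %d x %d, labels %d x %d x 1\n",
              x$n, x$L, x$n, x$L, x$L, x$n, x$L))
  invisible(x)
}

#' Save or load a subnetwork dataset
#'
#' Single-file archive (compressed RDS) holding the named arrays and the
#' member table.
#'
#' @param dataset A `subnet_dataset`.
#' @param path File path.
#' @return Invisibly `path` (writer) or the dataset (reader).
#' @export
write_subnet_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "subnet_dataset"))
  saveRDS(dataset, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_subnet_dataset
#' @export
read_subnet_dataset <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "subnet_dataset"))
  x
}
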