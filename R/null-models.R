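# dk-series null models: training networks that copy an empirical network's
# structure at increasing fidelity.
#
#   0k    same N and edge count (uniform simple G(N,M))
#   1k    same degree sequence (degree-preserving double-edge swaps)
#   2k    same joint degree distribution (swaps restricted to degree-matched
#         endpoints)
#   2.25k 2k constraints + mean clustering within tolerance
#   2.5k  2k constraints + degree-dependent clustering within tolerance
#
# Clustering-targeting uses greedy accept-if-closer rewiring with a small
# probability of accepting worsening swaps to escape local minima.

# -- internal mutable edge structure ----------------------------------------

.nm_state <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  deg <- vapply(adj, length, 1L)
  # per-node triangle counts for incremental clustering
  tri <- integer(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) >= 2) {
      cnt <- 0L
      for (j in nb) cnt <- cnt + sum(adj[[j]] %in% nb)
      tri[i] <- cnt %/% 2L
    }
  }
  list(n = n, el = el, adj = adj, deg = deg, tri = tri)
}

.nm_has_edge <- function(st, a, b) b %in% st$adj[[a]]

.nm_remove_edge <- function(st, a, b) {
  common <- intersect(st$adj[[a]], st$adj[[b]])
  nc <- length(common)
  if (nc > 0) {
    st$tri[a] <- st$tri[a] - nc
    st$tri[b] <- st$tri[b] - nc
    st$tri[common] <- st$tri[common] - 1L
  }
  st$adj[[a]] <- st$adj[[a]][st$adj[[a]] != b]
  st$adj[[b]] <- st$adj[[b]][st$adj[[b]] != a]
  st
}

.nm_add_edge <- function(st, a, b) {
  common <- intersect(st$adj[[a]], st$adj[[b]])
  nc <- length(common)
  if (nc > 0) {
    st$tri[a] <- st$tri[a] + nc
    st$tri[b] <- st$tri[b] + nc
    st$tri[common] <- st$tri[common] + 1L
  }
  st$adj[[a]] <- c(st$adj[[a]], b)
  st$adj[[b]] <- c(st$adj[[b]], a)
  st
}

# apply swap: edges (u,v),(x,y) -> (u,y),(x,v); caller guarantees validity
.nm_apply_swap <- function(st, e1, e2, u, v, x, y) {
  st <- .nm_remove_edge(st, u, v)
  st <- .nm_remove_edge(st, x, y)
  st <- .nm_add_edge(st, u, y)
  st <- .nm_add_edge(st, x, v)
  st$el[e1, ] <- c(min(u, y), max(u, y))
  st$el[e2, ] <- c(min(x, v), max(x, v))
  st
}

# Propose a double-edge swap. Returns NULL if invalid, else the endpoint
# assignment (u,v,x,y) meaning (u,v),(x,y) -> (u,y),(x,v). `match_degree`
# enforces the joint-degree-preserving restriction deg(v)==deg(y) (or the
# symmetric deg(u)==deg(x), reached via random orientation).
.nm_propose <- function(st, match_degree) {
  m <- nrow(st$el)
  e <- sample.int(m, 2L)
  u <- st$el[e[1], 1]; v <- st$el[e[1], 2]
  x <- st$el[e[2], 1]; y <- st$el[e[2], 2]
  if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
  if (stats::runif(1) < 0.5) { tmp <- u; u <- v; v <- tmp }
  if (length(unique(c(u, v, x, y))) < 4L) return(NULL)
  if (match_degree && st$deg[v] != st$deg[y] && st$deg[u] != st$deg[x]) {
    return(NULL)
  }
  if (match_degree && st$deg[v] != st$deg[y]) {
    # realise the symmetric case deg(u)==deg(x) as (v,u),(y,x) -> (v,x),(y,u)
    tmp <- u; u <- v; v <- tmp
    tmp <- x; x <- y; y <- tmp
  }
  if (.nm_has_edge(st, u, y) || .nm_has_edge(st, x, v)) return(NULL)
  list(e1 = e[1], e2 = e[2], u = u, v = v, x = x, y = y)
}

.nm_local_cc <- function(st) {
  denom <- st$deg * (st$deg - 1) / 2
  ifelse(denom > 0, st$tri / denom, 0)
}

# clustering objective: scalar distance to target
.nm_objective <- function(st, order, target) {
  cc <- .nm_local_cc(st)
  if (order == "2.25k") {
    abs(mean(cc) - target$cbar)
  } else {
    ck <- tapply(cc, target$deg_class, mean)
    mean(abs(ck - target$ck))
  }
}

.nm_graph <- function(st, labels) {
  g <- igraph::graph_from_edgelist(st$el, directed = FALSE)
  g <- igraph::add_vertices(g, st$n - igraph::vcount(g))
  igraph::V(g)$label <- labels
  g
}

#' Generate a structure-matched null-model network
#'
#' Produces a randomised copy of `graph` preserving its structure at the
#' requested order of the dk-series ladder (see Details). Orders `"2.25k"`
#' and `"2.5k"` target the original's clustering by constraint-preserving
#' rewiring: after an equilibration phase of joint-degree-preserving swaps,
#' swaps that reduce the distance to the clustering target are accepted
#' greedily, worsening swaps with probability `p_accept_worse`. If the
#' tolerance is not reached within `max_swap_attempts` the best-found
#' network is returned with `converged = FALSE` in the report (no error).
#'
#' @details
#' * `"0k"` — uniform random simple graph with the same N and edge count;
#' * `"1k"` — exact same degree sequence;
#' * `"2k"` — exact same joint degree distribution;
#' * `"2.25k"` — 2k constraints plus `|mean clustering - target| <= tol`;
#' * `"2.5k"` — 2k constraints plus mean over degree classes of
#'   `|C(k) - C_target(k)| <= tol`.
#'
#' @param graph A network with at least 2 edges.
#' @param order One of `"0k"`, `"1k"`, `"2k"`, `"2.25k"`, `"2.5k"`.
#' @param tol Clustering tolerance for orders 2.25k/2.5k (default 0.05).
#' @param max_swap_attempts Proposal budget for the targeting phase
#'   (default `200 *` edge count).
#' @param equilibration_swaps Proposals in the randomising phase
#'   (default `10 *` edge count).
#' @param p_accept_worse Probability of accepting a worsening swap during
#'   targeting (default 0.01).
#' @param seed Optional integer seed; fixes the output exactly.
#' @return An object of class `"null_model"`: a list with `graph` (the
#'   generated igraph), `order`, `converged`, `objective`, `tol`,
#'   `attempts`, `accepted` and `report` (a [constraint_report()] against
#'   the original).
#' @export
generate_null <- function(graph,
                          order = c("2.5k", "0k", "1k", "2k", "2.25k"),
                          tol = 0.05,
                          max_swap_attempts = NULL,
                          equilibration_swaps = NULL,
                          p_accept_worse = 0.01,
                          seed = NULL) {
  order <- match.arg(order)
  graph <- as_network(graph)
  m <- igraph::ecount(graph)
  if (m < 2) stop("null models need a graph with at least 2 edges", call. = FALSE)
  if (order %in% c("2.25k", "2.5k") && tol <= 0) {
    stop("clustering orders require tol > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- igraph::V(graph)$label
  n <- igraph::vcount(graph)
  if (is.null(equilibration_swaps)) equilibration_swaps <- 10L * m
  if (is.null(max_swap_attempts)) max_swap_attempts <- 200L * m

  if (order == "0k") {
    g0 <- igraph::sample_gnm(n, m)
    igraph::V(g0)$label <- labels
    out <- list(graph = g0, order = order, converged = TRUE,
                objective = 0, tol = NA_real_, attempts = 0L, accepted = 0L,
                report = constraint_report(graph, g0))
    class(out) <- "null_model"
    return(out)
  }

  st <- .nm_state(graph)
  match_degree <- order != "1k"
  accepted <- 0L
  for (i in seq_len(equilibration_swaps)) {
    p <- .nm_propose(st, match_degree)
    if (!is.null(p)) {
      st <- .nm_apply_swap(st, p$e1, p$e2, p$u, p$v, p$x, p$y)
      accepted <- accepted + 1L
    }
  }

  converged <- TRUE
  objective <- 0
  attempts <- 0L
  if (order %in% c("2.25k", "2.5k")) {
    cc0 <- local_clustering(graph)
    deg0 <- igraph::degree(graph)
    deg_class <- factor(deg0, levels = sort(unique(deg0)))
    target <- list(cbar = mean(cc0), deg_class = deg_class,
                   ck = tapply(cc0, deg_class, mean))
    cur <- .nm_objective(st, order, target)
    best <- st; best_obj <- cur
    while (attempts < max_swap_attempts && cur > tol) {
      attempts <- attempts + 1L
      p <- .nm_propose(st, TRUE)
      if (is.null(p)) next
      cand <- .nm_apply_swap(st, p$e1, p$e2, p$u, p$v, p$x, p$y)
      obj <- .nm_objective(cand, order, target)
      if (obj < cur || stats::runif(1) < p_accept_worse) {
        st <- cand
        cur <- obj
        accepted <- accepted + 1L
        if (obj < best_obj) { best <- st; best_obj <- obj }
      }
    }
    if (best_obj < cur) { st <- best; cur <- best_obj }
    objective <- cur
    converged <- cur <= tol
  }

  g1 <- .nm_graph(st, labels)
  out <- list(graph = g1, order = order, converged = converged,
              objective = objective,
              tol = if (order %in% c("2.25k", "2.5k")) tol else NA_real_,
              attempts = attempts, accepted = accepted,
              report = constraint_report(graph, g1))
  class(out) <- "null_model"
  out
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Null model (order %s): %d nodes, %d edges\n", x$order,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (!is.na(x$tol)) {
    cat(sprintf("  clustering objective %.4f (tol %.3g) -- %s after %d targeting proposals\n",
                x$objective, x$tol,
                if (x$converged) "converged" else "NOT converged", x$attempts))
  }
  print(x$report)
  invisible(x)
}

#' Constraint deviation report between two networks
#'
#' Measures how far a generated (null-model) network deviates from the
#' original on each constraint of the dk-series ladder: node and edge
#' counts, L1 distance between degree distributions and between joint
#' degree distributions, absolute difference of mean clustering, and the
#' per-degree absolute deviations of degree-dependent clustering.
#'
#' @param original,null Two non-empty networks.
#' @return An object of class `"constraint_report"` (a list).
#' @export
constraint_report <- function(original, null) {
  original <- as_network(original); null <- as_network(null)
  d1 <- igraph::degree(original); d2 <- igraph::degree(null)
  ks <- sort(unique(c(d1, d2)))
  p1 <- p2 <- structure(numeric(length(ks)), names = ks)
  p1[names(degree_dist(d1))] <- degree_dist(d1)
  p2[names(degree_dist(d2))] <- degree_dist(d2)
  j1 <- joint_degree_dist(original); j2 <- joint_degree_dist(null)
  jfull1 <- jfull2 <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  jfull1[rownames(j1), colnames(j1)] <- j1
  jfull2[rownames(j2), colnames(j2)] <- j2
  c1 <- clustering_by_degree(original); c2 <- clustering_by_degree(null)
  common <- intersect(names(c1), names(c2))
  ck_dev <- abs(c1[common] - c2[common])
  out <- list(
    delta_n = igraph::vcount(null) - igraph::vcount(original),
    delta_edges = igraph::ecount(null) - igraph::ecount(original),
    degree_l1 = sum(abs(p1 - p2)),
    joint_degree_l1 = sum(abs(jfull1 - jfull2)),
    delta_mean_clustering = abs(mean(local_clustering(null)) -
                                  mean(local_clustering(original))),
    clustering_by_degree_dev = ck_dev,
    mean_ck_dev = if (length(ck_dev)) mean(ck_dev) else NA_real_,
    max_ck_dev = if (length(ck_dev)) max(ck_dev) else NA_real_
  )
  class(out) <- "constraint_report"
  out
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("Constraint deviations (null vs original):\n")
  cat(sprintf("  dN = %d, dE = %d\n", x$delta_n, x$delta_edges))
  cat(sprintf("  degree distribution L1:       %.4f\n", x$degree_l1))
  cat(sprintf("  joint degree distribution L1: %.4f\n", x$joint_degree_l1))
  cat(sprintf("  |d mean clustering|:          %.4f\n", x$delta_mean_clustering))
  cat(sprintf("  |d C(k)| mean / max:          %.4f / %.4f\n",
              x$mean_ck_dev, x$max_ck_dev))
  invisible(x)
}
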