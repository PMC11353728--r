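# Synthetic training-network generators matched to an empirical network's
# node count and mean degree: Erdos-Renyi G(N,M), Barabasi-Albert
# preferential attachment, Watts-Strogatz small world and the Holme-Kim
# power-law-cluster model. BA and PLC grow from an m-clique so the edge
# count is exactly m*(N-m) + choose(m,2).

.grow_pa <- function(n, m, triangle_p = 0) {
  # preferential-attachment growth, optionally with a triad-formation step
  # taken with probability triangle_p after each preferential link
  deg <- numeric(n)
  edges <- matrix(0L, nrow = m * (n - m) + m * (m - 1) / 2, ncol = 2)
  k <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j) { k <- k + 1L; edges[k, ] <- c(i, j); deg[c(i, j)] <- deg[c(i, j)] + 1 }
    }
  }
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(k)) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (v in seq((m + 1), n)) {
    existing <- seq_len(v - 1L)
    chosen <- integer(0)
    prev <- NA_integer_
    while (length(chosen) < m) {
      cand <- NA_integer_
      if (!is.na(prev) && stats::runif(1) < triangle_p) {
        nb <- setdiff(adj[[prev]], c(chosen, v))
        if (length(nb) > 0) cand <- nb[sample.int(length(nb), 1L)]
      }
      if (is.na(cand)) {
        pool <- setdiff(existing, chosen)
        w <- deg[pool] + 1e-12
        cand <- pool[sample.int(length(pool), 1L, prob = w)]
      }
      chosen <- c(chosen, cand)
      prev <- cand
    }
    for (u in chosen) {
      k <- k + 1L
      edges[k, ] <- c(u, v)
      deg[c(u, v)] <- deg[c(u, v)] + 1
      adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    }
  }
  g <- igraph::graph_from_edgelist(edges[seq_len(k), , drop = FALSE],
                                   directed = FALSE)
  igraph::V(g)$label <- as.character(seq_len(n))
  g
}

#' Generate a classic synthetic network
#'
#' Families parameterised by node count and target mean degree, matching
#' the ablation protocol:
#' * `"er"` — G(N, M) with `M = round(N * k / 2)` (mean degree exact);
#' * `"ba"` — preferential attachment with `m = round(k / 2)` links per
#'   node, grown from an m-clique (`m*(N-m) + choose(m,2)` edges);
#' * `"ws"` — ring lattice of even degree (odd targets rounded to the
#'   nearest even value with a message) rewired with probability
#'   `rewire_p`;
#' * `"plc"` — Holme-Kim power-law cluster model: preferential attachment
#'   with a triad-formation step taken with probability `triangle_p`.
#'
#' @param family `"er"`, `"ba"`, `"ws"` or `"plc"`.
#' @param n_nodes Number of nodes (>= 2).
#' @param mean_degree Target mean degree (< `n_nodes`).
#' @param rewire_p WS rewiring probability (default 0.1).
#' @param triangle_p PLC triad-formation probability (default 0.5).
#' @param seed Optional integer seed.
#' @return A simple undirected igraph object with exactly `n_nodes` nodes.
#' @export
generate_classic <- function(family = c("er", "ba", "ws", "plc"),
                             n_nodes, mean_degree,
                             rewire_p = 0.1, triangle_p = 0.5, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n_nodes >= 2, mean_degree > 0)
  if (mean_degree >= n_nodes) {
    stop("mean degree must be below the node count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- switch(family,
    er = igraph::sample_gnm(n_nodes, round(n_nodes * mean_degree / 2)),
    ba = {
      m <- max(1L, round(mean_degree / 2))
      if (m >= n_nodes) stop("infeasible BA parameter m >= N", call. = FALSE)
      .grow_pa(n_nodes, m, triangle_p = 0)
    },
    ws = {
      ke <- 2L * max(1L, round(mean_degree / 2))
      if (ke != round(mean_degree)) {
        message("generate_classic: WS ring degree rounded to even value ", ke)
      }
      igraph::sample_smallworld(1, n_nodes, ke %/% 2L, rewire_p)
    },
    plc = {
      m <- max(1L, round(mean_degree / 2))
      if (m >= n_nodes) stop("infeasible PLC parameter m >= N", call. = FALSE)
      .grow_pa(n_nodes, m, triangle_p = triangle_p)
    }
  )
  igraph::V(g)$label <- as.character(seq_len(igraph::vcount(g)))
  as_network(g)
}

#' Demonstration toy network
#'
#' A fixed, seeded 26-node connected network with heterogeneous degrees
#' (a synthetic stand-in built with the power-law-cluster generator) used
#' by the small-network demonstration pipeline: rank by every method, take
#' the top-5 spreaders, run the spreading experiment.
#'
#' @param seed Integer seed of the fixture (default 2024; the default is
#'   the versioned fixture and is identical across runs).
#' @return A connected 26-node igraph object.
#' @export
toy_network <- function(seed = 2024L) {
  for (i in 0:99) {
    g <- generate_classic("plc", 26, 4, triangle_p = 0.5, seed = seed + i)
    if (igraph::is_connected(g)) return(g)
  }
  stop("could not generate a connected toy network", call. = FALSE)
}
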