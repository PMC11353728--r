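# SIR Monte-Carlo influence labelling.
#
# Node influence (spreading ability) is the expected final outbreak size of a
# discrete-time SIR epidemic seeded at that node, with recovery probability 1:
# a newly infected node is infectious for exactly one step, infects each
# susceptible neighbour independently with probability beta, then recovers.

adj_list0 <- function(graph) {
  lapply(igraph::as_adj_list(graph), function(v) as.integer(v) - 1L)
}

#' Monte-Carlo iteration schedule
#'
#' The number of SIR repetitions per source node as a function of the
#' undirected edge count E: fewer than 100 edges get 100,000 repetitions,
#' 100 to 9,999 edges get 10,000 and larger networks get 1,000 (the E =
#' 10,000 boundary falls in the cheaper tier).
#'
#' @param n_edges Undirected edge count (>= 0).
#' @return An integer repetition count.
#' @export
iteration_schedule <- function(n_edges) {
  stopifnot(n_edges >= 0)
  if (n_edges < 100) 100000L else if (n_edges < 10000) 10000L else 1000L
}

#' Single SIR outbreak
#'
#' Runs one discrete-time SIR epidemic from `source` and returns the final
#' recovered count.
#'
#' @param graph A network.
#' @param source Seed node id (1..N).
#' @param beta Infection probability in `[0, 1]`.
#' @param include_seed Count the seed in the outbreak size (default TRUE).
#' @return An integer outbreak size.
#' @export
sir_outbreak <- function(graph, source, beta, include_seed = TRUE) {
  graph <- as_network(graph)
  n <- igraph::vcount(graph)
  if (length(source) != 1L || is.na(source) || source < 1L || source > n) {
    stop("invalid source node id", call. = FALSE)
  }
  stopifnot(beta >= 0, beta <= 1)
  sz <- sir_spread_engine(adj_list0(graph), as.integer(source) - 1L, beta, 1L)
  as.integer(sz) - if (include_seed) 0L else 1L
}

#' SIR influence labels
#'
#' Mean SIR outbreak size per source node, the ground-truth node influence
#' score used as the training target and evaluation reference. `beta`
#' defaults to the network's [epidemic_threshold()] (the critical infection
#' rate); `reps` defaults to [iteration_schedule()] of the edge count.
#'
#' @inheritParams sir_outbreak
#' @param beta Infection probability; `NULL` for the epidemic threshold.
#' @param reps Repetitions per source node; `NULL` for the schedule value.
#' @param seed Optional integer seed for reproducibility.
#' @return A numeric vector of length N of class `"influence_labels"`, with
#'   attributes `beta` and `reps`.
#' @export
sir_labels <- function(graph, beta = NULL, reps = NULL, seed = NULL,
                       include_seed = TRUE) {
  graph <- as_network(graph)
  if (is.null(beta)) beta <- epidemic_threshold(graph)
  stopifnot(beta >= 0, beta <= 1)
  if (is.null(reps)) reps <- iteration_schedule(igraph::ecount(graph))
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  scores <- sir_label_engine(adj_list0(graph), beta, as.integer(reps))
  if (!include_seed) scores <- scores - 1
  structure(scores, beta = beta, reps = as.integer(reps),
            include_seed = include_seed, class = "influence_labels")
}

#' @export
print.influence_labels <- function(x, ...) {
  cat(sprintf("SIR influence labels: %d nodes, beta = %.4g, %d reps/node\n",
              length(x), attr(x, "beta"), attr(x, "reps")))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Multi-source SIR spreading
#'
#' Final recovered counts of `reps` epidemics in which all `sources` start
#' infected; the engine behind the maximum-influence spreading experiment.
#'
#' @inheritParams sir_outbreak
#' @param sources Vector of seed node ids.
#' @param reps Number of repetitions.
#' @param seed Optional integer seed.
#' @return A numeric vector of length `reps` of final recovered counts.
#' @export
sir_spread <- function(graph, sources, beta, reps = 1000L, seed = NULL) {
  graph <- as_network(graph)
  n <- igraph::vcount(graph)
  sources <- unique(as.integer(sources))
  if (length(sources) == 0L || anyNA(sources) || any(sources < 1L | sources > n)) {
    stop("invalid source node ids", call. = FALSE)
  }
  stopifnot(beta >= 0, beta <= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  sir_spread_engine(adj_list0(graph), sources - 1L, beta, as.integer(reps))
}

#' Read/write influence labels as CSV
#'
#' Two-column CSV (`node`, `score`) with node ids as original labels.
#'
#' @param labels An `influence_labels` vector (or plain numeric).
#' @param graph The network the labels belong to (for its labels).
#' @param path Output path.
#' @return Invisibly, `path` (writer) or a numeric vector (reader).
#' @export
write_labels <- function(labels, graph, path) {
  graph <- as_network(graph)
  utils::write.csv(
    data.frame(node = igraph::V(graph)$label, score = as.numeric(labels)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  structure(as.numeric(df$score), names = as.character(df$node))
}
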