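# Independent oracles and small builders used across the suite.

# brute-force Kendall tau-a by explicit pair enumeration
kendall_bruteforce <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- s + sign(a[i] - a[j]) * sign(b[i] - b[j])
    }
  }
  s / (n * (n - 1) / 2)
}

# central finite differences of a scalar function over a flat vector
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 1)
}

# refill a nested list skeleton from a flat vector (same order as unlist)
unflatten <- function(flat, skel) {
  i <- 0
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    v <- flat[i + seq_along(s)]
    i <<- i + length(s)
    if (is.null(dim(s))) {
      if (length(s) == 1L) v else v
    } else {
      array(v, dim(s))
    }
  }
  walk(skel)
}

make_star_net <- function(leaves) igraph::make_star(leaves + 1, mode = "undirected")
make_path_net <- function(n) igraph::make_ring(n, circular = FALSE)
make_ring_net <- function(n) igraph::make_ring(n)

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(L, p = 0.5) {
  a <- matrix(0, L, L)
  a[upper.tri(a)] <- as.numeric(stats::runif(L * (L - 1) / 2) < p)
  a + t(a)
}
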