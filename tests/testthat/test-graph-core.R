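test_that("edge-list parsing handles the basic dialect", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "1 2", "2,3", ""), f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  # path graph: degrees 1,2,1 in label order 1,2,3
  expect_equal(unname(igraph::degree(g)), c(1, 2, 1))
})

test_that("duplicate edges and self-loops are dropped with a message", {
  f <- withr::local_tempfile()
  writeLines(c("1 2", "1 2", "3 3", "2 3"), f)
  expect_message(g <- read_network(f), "dropped")
  expect_equal(igraph::ecount(g), 2)
})

test_that("unreadable or empty files raise errors", {
  expect_error(read_network(file.path(tempdir(), "no-such-file.edgelist")),
               "cannot read")
  f <- withr::local_tempfile()
  writeLines("# only comments", f)
  expect_error(read_network(f), "no edges")
})

test_that("edge-list and GML round-trips preserve the edge set", {
  g <- karate_club()
  edge_key <- function(x) {
    el <- igraph::as_edgelist(x, names = FALSE)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  f1 <- withr::local_tempfile(fileext = ".edgelist")
  write_edgelist(g, f1)
  expect_identical(edge_key(read_network(f1)), edge_key(g))
  f2 <- withr::local_tempfile(fileext = ".gml")
  write_gml(g, f2)
  expect_identical(edge_key(read_network(f2)), edge_key(g))
})

test_that("karate club matches its published statistics", {
  g <- karate_club()
  expect_equal(igraph::vcount(g), 34)
  expect_equal(igraph::ecount(g), 78)
  s <- network_summary(g)
  expect_equal(round(s$mean_clustering, 2), 0.57)
  expect_equal(round(s$epidemic_threshold, 2), 0.13)
})

test_that("adjacency matrices are binary, symmetric, zero-diagonal", {
  g3 <- igraph::make_empty_graph(3, directed = FALSE)
  g3 <- igraph::add_edges(g3, c(1, 2))
  a <- adjacency_binary(g3)
  expect_equal(a, t(a))
  expect_equal(sum(a), 2)
  expect_equal(a[1, 2], 1)
  expect_true(all(diag(adjacency_binary(karate_club())) == 0))
  tri <- adjacency_binary(igraph::make_full_graph(3))
  expect_equal(tri, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
})

test_that("summary statistics on canonical small graphs", {
  k4 <- network_summary(igraph::make_full_graph(4))
  expect_equal(k4$mean_clustering, 1.0)
  expect_equal(k4$max_kshell, 3)
  star <- network_summary(make_star_net(5))
  expect_equal(star$mean_clustering, 0)
  expect_equal(star$max_kshell, 1)
})

test_that("degree distributions are normalised and consistent with edges", {
  set.seed(11)
  for (i in 1:5) {
    g <- igraph::sample_gnm(20, 35)
    s <- network_summary(g)
    expect_equal(sum(s$degree_distribution), 1, tolerance = 1e-9)
    expect_equal(sum(s$joint_degree_distribution), 1, tolerance = 1e-9)
    expect_equal(s$joint_degree_distribution, t(s$joint_degree_distribution))
    expect_equal(sum(igraph::degree(g)), 2 * s$n_edges_undirected)
    # mean clustering is the degree-class-weighted combination of C(k)
    w <- s$degree_distribution
    expect_equal(sum(w * s$clustering_by_degree[names(w)]),
                 s$mean_clustering, tolerance = 1e-12)
  }
})

test_that("epidemic threshold follows the degree-based mean-field formula", {
  expect_equal(epidemic_threshold(make_ring_net(8)), 0.5)   # 1/k for 2-regular
  expect_equal(epidemic_threshold(make_star_net(4)), 1.6 / 4)
  expect_error(epidemic_threshold(igraph::make_empty_graph(3, directed = FALSE)),
               "undefined")
  # regular graph: single-atom degree distribution, threshold 1/k
  s <- network_summary(igraph::make_lattice(c(4, 4), periodic = TRUE))
  expect_equal(length(s$degree_distribution), 1)
  expect_equal(s$epidemic_threshold, 1 / 4)
})
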