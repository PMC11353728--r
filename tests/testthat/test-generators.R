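test_that("generators hit the node count exactly and the mean degree closely", {
  for (fam in c("er", "ba", "ws", "plc")) {
    g <- generate_classic(fam, 100, 6, seed = 1)
    expect_equal(igraph::vcount(g), 100, info = fam)
    expect_true(igraph::is_simple(g), info = fam)
    kbar <- 2 * igraph::ecount(g) / 100
    expect_lt(abs(kbar - 6) / 6, 0.10, label = paste(fam, "mean degree"))
  }
  expect_equal(igraph::ecount(generate_classic("er", 100, 6, seed = 2)), 300)
  # m-clique start: m*(N-m) + choose(m,2) edges
  expect_equal(igraph::ecount(generate_classic("ba", 100, 6, seed = 3)), 294)
  expect_error(generate_classic("ba", 5, 20, seed = 1))
})

test_that("unrewired small-world graphs are exact ring lattices", {
  g <- generate_classic("ws", 30, 4, rewire_p = 0, seed = 1)
  expect_equal(unname(igraph::degree(g)), rep(4, 30))
  expect_equal(igraph::transitivity(g), 0.5)  # 2-neighbour ring lattice
  expect_message(generate_classic("ws", 30, 5, seed = 1), "even")
})

test_that("generation is reproducible under a seed", {
  for (fam in c("er", "ba", "ws", "plc")) {
    a <- generate_classic(fam, 50, 4, seed = 9)
    b <- generate_classic(fam, 50, 4, seed = 9)
    expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b), info = fam)
  }
})

test_that("the demonstration network is a fixed connected 26-node fixture", {
  g <- toy_network()
  expect_equal(igraph::vcount(g), 26)
  expect_true(igraph::is_connected(g))
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(toy_network()))
  expect_gt(max(igraph::degree(g)) - min(igraph::degree(g)), 2)  # heterogeneous
})

test_that("the pipeline writes every stage artifact and a stable manifest", {
  net_file <- withr::local_tempfile(fileext = ".edgelist")
  write_edgelist(karate_club(), net_file)
  out1 <- withr::local_tempdir()
  cfg <- list(input = net_file, out_dir = out1, null_order = "1k",
              reps = 150, epochs = 1, local_steps = 1, seed = 3)
  man <- run_pipeline(cfg)
  expect_setequal(man$stages, c("load", "label", "nullmodel", "train",
                                "dataset", "rank", "evaluate"))
  for (f in c("network.edgelist", "labels.csv", "trainnet.edgelist",
              "dataset.rds", "model.rds", "scores.csv", "metrics.json",
              "manifest.json")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
  }
  # rerun with the same config: identical hash and identical text artifacts
  out2 <- withr::local_tempdir()
  cfg2 <- cfg; cfg2$out_dir <- out2
  man2 <- run_pipeline(cfg2)
  expect_identical(man$config_hash, man2$config_hash)
  for (f in c("labels.csv", "trainnet.edgelist", "scores.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("pipeline configuration is validated before any stage runs", {
  expect_error(run_pipeline(list(out_dir = tempdir())), "config error")
  expect_error(run_pipeline(list(input = "missing.edgelist",
                                 out_dir = tempdir())), "not found")
  expect_error(run_pipeline(list(input = "x.edgelist")), "out_dir")
})

test_that("a YAML pipeline config is accepted", {
  net_file <- withr::local_tempfile(fileext = ".edgelist")
  write_edgelist(make_star_net(8), net_file)
  out <- withr::local_tempdir()
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(input = net_file, out_dir = out, null_order = "none",
                        reps = 100, epochs = 1, local_steps = 1, seed = 1),
                   yml)
  man <- run_pipeline(yml)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_equal(man$seed, 1)
})
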