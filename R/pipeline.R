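# End-to-end pipeline: label -> null model -> dataset -> train -> rank ->
# evaluate, with every intermediate written to disk and a deterministic
# manifest.

.pipeline_defaults <- list(
  null_order = "2.5k", beta = "auto", reps = "auto",
  epochs = 5L, local_steps = 5L, seed = 1L
)

.config_hash <- function(config) {
  config$out_dir <- NULL  # hash the run configuration, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full influence-ranking pipeline
#'
#' Executes, in order: network loading (or generation), SIR labelling of
#' the input network, null-model training-network construction, dataset
#' construction and model training, ranking of the input network, and
#' Kendall evaluation. Every stage writes its artifact into `out_dir`
#' together with a deterministic `manifest.json` (config, config hash,
#' seed, stage outputs with checksums of the text artifacts). A stage
#' failure aborts with the stage name; artifacts of completed stages are
#' kept.
#'
#' @param config A configuration list, or the path of a YAML/JSON file.
#'   Recognised fields: `input` (edge-list/GML path) *or* `generator`
#'   (list with `family`, `n_nodes`, `mean_degree`, ...), `out_dir`
#'   (required), `null_order` (`"0k"`..`"2.5k"` or `"none"`, default
#'   `"2.5k"`), `beta` (`"auto"` = epidemic threshold), `reps` (`"auto"` =
#'   schedule), `epochs` (default 5), `local_steps` (default 5), `seed`
#'   (default 1).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  for (nm in names(.pipeline_defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- .pipeline_defaults[[nm]]
  }
  # validate before any stage runs
  if (is.null(config$out_dir)) stop("config error: `out_dir` is required", call. = FALSE)
  if (is.null(config$input) && is.null(config$generator)) {
    stop("config error: provide `input` (a network file) or `generator`", call. = FALSE)
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop("config error: input file not found: ", config$input, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- res
    res
  }

  seed <- as.integer(config$seed)
  graph <- run_stage("load", {
    g <- if (!is.null(config$input)) {
      read_network(config$input)
    } else {
      gen <- config$generator
      generate_classic(gen$family, gen$n_nodes, gen$mean_degree,
                       rewire_p = gen$rewire_p %||% 0.1,
                       triangle_p = gen$triangle_p %||% 0.5,
                       seed = seed)
    }
    write_edgelist(g, out("network.edgelist"))
    g
  })
  beta <- if (identical(config$beta, "auto")) epidemic_threshold(graph) else as.numeric(config$beta)
  reps <- if (identical(config$reps, "auto")) iteration_schedule(igraph::ecount(graph)) else as.integer(config$reps)

  labels <- run_stage("label", {
    lab <- sir_labels(graph, beta = beta, reps = reps, seed = seed)
    write_labels(lab, graph, out("labels.csv"))
    lab
  })
  train_net <- run_stage("nullmodel", {
    tn <- if (identical(config$null_order, "none")) graph else {
      generate_null(graph, order = config$null_order, seed = seed)$graph
    }
    write_edgelist(tn, out("trainnet.edgelist"))
    tn
  })
  fit <- run_stage("train", {
    f <- spreadrank(train_net, beta = beta, reps = reps,
                    epochs = as.integer(config$epochs),
                    local_steps = as.integer(config$local_steps), seed = seed)
    save_model(f, out("model.rds"))
    f
  })
  run_stage("dataset", {
    write_subnet_dataset(build_subnet_dataset(train_net, fit$labels, L = fit$L),
                         out("dataset.rds"))
    TRUE
  })
  scores <- run_stage("rank", {
    s <- predict(fit, graph)
    utils::write.csv(data.frame(node = igraph::V(graph)$label,
                                score = as.numeric(s)),
                     out("scores.csv"), row.names = FALSE)
    s
  })
  metrics <- run_stage("evaluate", {
    m <- list(kendall = kendall_tau(scores, labels),
              train_kendall = kendall_tau(fit$scores, fit$labels),
              beta = beta, reps = reps)
    jsonlite::write_json(m, out("metrics.json"), auto_unbox = TRUE, digits = NA)
    m
  })

  text_artifacts <- c("network.edgelist", "labels.csv", "trainnet.edgelist",
                      "scores.csv", "metrics.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("spreadrank")),
    seed = seed,
    config = config[order(names(config))],
    config_hash = .config_hash(config),
    stages = names(stages),
    artifacts = as.list(tools::md5sum(vapply(text_artifacts, out, "")))
  )
  names(manifest$artifacts) <- text_artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
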