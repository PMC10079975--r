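# Pipeline runner behind the command-line front end. Every subcommand
# reads a flat YAML config (CLI flags override seed/output), writes its
# artifacts into the output directory, and records a manifest with the
# config echo, seed and content hashes of the inputs.

run_allowed_keys <- list(
  simulate = c("n_proteins", "n_pos", "n_neg", "embed_dim", "separation",
               "noise_sd", "seq_len_min", "seq_len_max"),
  `build-graph` = c("records", "fasta", "min_len", "drop_unknown",
                    "graphml"),
  featurize = c("records", "store"),
  train = c("records", "store", "test_fraction", "learning_rate",
            "max_epochs", "patience", "validation_fraction", "batch_size",
            "d_h", "k", "n_layers", "heads", "hidden_dropout",
            "attention_dropout", "alpha", "max_hop", "readout"),
  evaluate = c("records", "store", "checkpoint", "split"),
  cv = c("records", "store", "folds", "learning_rate", "max_epochs",
         "patience", "validation_fraction", "batch_size", "d_h", "k",
         "n_layers", "heads", "hidden_dropout", "attention_dropout",
         "alpha", "max_hop", "readout")
)

check_config <- function(subcommand, config) {
  allowed <- c(run_allowed_keys[[subcommand]], "seed", "out_dir")
  extra <- setdiff(names(config), allowed)
  if (length(extra) > 0L) {
    gb_stop("gb_config", "unknown config keys for %s: %s", subcommand,
            paste(extra, collapse = ", "))
  }
  config
}

require_inputs <- function(config, keys) {
  for (k in keys) {
    p <- config[[k]]
    if (is.null(p)) gb_stop("gb_config", "config key '%s' is required", k)
    if (!file.exists(p)) {
      gb_stop("gb_config", "input path for '%s' does not exist: %s", k, p)
    }
  }
}

write_manifest <- function(out_dir, subcommand, config, inputs = character(0)) {
  hashes <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    structure(list(), names = character(0))
  }
  jsonlite::write_json(
    list(subcommand = subcommand, config = config,
         seed = config$seed %||% NA,
         input_md5 = hashes,
         package_version = as.character(utils::packageVersion("pairGBERT"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
}

metrics_as_list <- function(r) {
  r[c("tp", "fp", "tn", "fn", "accuracy", "sensitivity", "specificity",
      "precision", "f_score", "mcc", "degenerate")]
}

load_graph_and_features <- function(config) {
  require_inputs(config, c("records", "store"))
  records <- read_interactions(config$records)
  graph <- build_pair_graph(records)
  store <- read_embedding_store(config$store)
  list(graph = graph, X = build_node_features(graph, store))
}

config_to_train <- function(config, seed) {
  train_config(
    learning_rate = config$learning_rate %||% 0.001,
    max_epochs = as.integer(config$max_epochs %||% 200L),
    patience = as.integer(config$patience %||% 20L),
    validation_fraction = config$validation_fraction %||% 0.1,
    batch_size = as.integer(config$batch_size %||% 64L),
    seed = seed,
    d_h = as.integer(config$d_h %||% 32L),
    k = as.integer(config$k %||% 7L),
    n_layers = as.integer(config$n_layers %||% 2L),
    heads = as.integer(config$heads %||% 2L),
    hidden_dropout = config$hidden_dropout %||% 0.5,
    attention_dropout = config$attention_dropout %||% 0.3,
    alpha = config$alpha %||% 0.15,
    max_hop = as.integer(config$max_hop %||% 20L),
    readout = config$readout %||% "target")
}

#' Run a pipeline subcommand
#'
#' The programmatic core of the `ppigbert` command-line tool. Config is a
#' flat named list (typically parsed from YAML); `seed` and `out_dir`
#' arguments override the config. Artifacts land in the output directory
#' together with a `manifest.json` (config echo, seed, input hashes).
#'
#' Subcommands: `simulate` writes synthetic interactions.tsv /
#' proteins.fasta / embeddings.tsv; `build-graph` writes node and edge
#' tables (optionally GraphML); `featurize` writes the node feature
#' matrix; `train` writes checkpoint.json, history.csv and split.json;
#' `evaluate` writes metrics.json for the held-out split; `cv` writes a
#' k-fold report with per-fold metrics plus mean and standard deviation.
#'
#' @param subcommand One of simulate, build-graph, featurize, train,
#'   evaluate, cv.
#' @param config Named list of settings (see the package vignette), or a
#'   path to a YAML file.
#' @param seed Optional integer overriding `config$seed`.
#' @param out_dir Optional output directory overriding `config$out_dir`.
#' @return Invisibly, a list of the main artifact paths.
#' @export
ppi_run <- function(subcommand, config = list(), seed = NULL,
                    out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      gb_stop("gb_config", "config file not found: %s", config)
    }
    config <- yaml::read_yaml(config) %||% list()
  }
  subcommand <- match.arg(subcommand, names(run_allowed_keys))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  check_config(subcommand, config)
  out <- config$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  paths <- switch(
    subcommand,
    simulate = {
      spec <- synthetic_spec(
        n_proteins = as.integer(config$n_proteins %||% 60L),
        n_pos = as.integer(config$n_pos %||% 250L),
        n_neg = as.integer(config$n_neg %||% 250L),
        embed_dim = as.integer(config$embed_dim %||% 32L),
        separation = config$separation %||% 6,
        noise_sd = config$noise_sd %||% 1,
        seed = seed,
        seq_len_range = c(as.integer(config$seq_len_min %||% 50L),
                          as.integer(config$seq_len_max %||% 400L)))
      records <- generate_interactions(spec)
      store <- generate_planted_embeddings(records, spec)
      seqs <- generate_sequences(synthetic_protein_ids(spec$n_proteins),
                                 spec)
      p1 <- write_interactions(records, file.path(out, "interactions.tsv"))
      p2 <- write_fasta(seqs, file.path(out, "proteins.fasta"))
      p3 <- write_embedding_store(store, file.path(out, "embeddings.tsv"))
      write_manifest(out, subcommand, config)
      c(p1, p2, p3)
    },
    `build-graph` = {
      require_inputs(config, "records")
      records <- read_interactions(config$records)
      inputs <- config$records
      if (!is.null(config$fasta)) {
        require_inputs(config, "fasta")
        seqs <- read_fasta(config$fasta)
        records <- filter_records(records, seqs,
                                  min_len = config$min_len %||% 50,
                                  drop_unknown =
                                    config$drop_unknown %||% TRUE)
        inputs <- c(inputs, config$fasta)
      }
      graph <- build_pair_graph(records)
      p <- write_pair_graph(graph, out,
                            graphml = isTRUE(config$graphml))
      write_manifest(out, subcommand, config, inputs)
      p
    },
    featurize = {
      gx <- load_graph_and_features(config)
      p <- file.path(out, "features.tsv")
      utils::write.table(
        format(gx$X, digits = 17, scientific = TRUE, trim = TRUE),
        p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      write_manifest(out, subcommand, config,
                     c(config$records, config$store))
      p
    },
    train = {
      gx <- load_graph_and_features(config)
      split <- split_train_test(gx$graph$n,
                                test_fraction =
                                  config$test_fraction %||% 0.2,
                                seed = seed,
                                labels = gx$graph$nodes$label)
      fit <- train(gx$graph, gx$X, split$train,
                   config_to_train(config, seed))
      p1 <- save_checkpoint(fit$params, file.path(out, "checkpoint.json"))
      p2 <- file.path(out, "history.csv")
      utils::write.csv(fit$history, p2, row.names = FALSE)
      p3 <- file.path(out, "split.json")
      jsonlite::write_json(split, p3)
      write_manifest(out, subcommand, config,
                     c(config$records, config$store))
      c(p1, p2, p3)
    },
    evaluate = {
      require_inputs(config, c("records", "store", "checkpoint", "split"))
      gx <- load_graph_and_features(config)
      params <- load_checkpoint(config$checkpoint)
      split <- jsonlite::read_json(config$split, simplifyVector = TRUE)
      rpt <- evaluate(params, gx$graph, gx$X, as.integer(split$test))
      p <- file.path(out, "metrics.json")
      jsonlite::write_json(
        list(metrics = metrics_as_list(rpt), seed = seed,
             config = config),
        p, auto_unbox = TRUE, digits = NA)
      write_manifest(out, subcommand, config,
                     c(config$records, config$store, config$checkpoint))
      p
    },
    cv = {
      gx <- load_graph_and_features(config)
      k <- as.integer(config$folds %||% 5L)
      res <- cross_validate(gx$graph, gx$X, config_to_train(config, seed),
                            k = k)
      p <- file.path(out, "cv_metrics.json")
      jsonlite::write_json(
        list(folds = lapply(res$folds, metrics_as_list),
             mean = as.list(res$mean), sd = as.list(res$sd),
             k = k, seed = seed, config = config),
        p, auto_unbox = TRUE, digits = NA)
      write_manifest(out, subcommand, config,
                     c(config$records, config$store))
      p
    })
  invisible(paths)
}
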