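#' Read a pipeline run configuration
#'
#' Loads a YAML configuration and merges it over the documented defaults
#' (`fraction = 0.01`, `percentile = 95`, `n_perm = 1e6`, `seed = 1`).
#' See [run_pipeline()] for the recognised fields.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list of configuration fields.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(fraction = 0.01, percentile = 95, n_perm = 1e6,
                   seed = 1L, core = NULL, distances = NULL,
                   ranking = NULL, known_list = NULL, expression = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$core)) stop_input("config must name the core gene")
  if (cfg$fraction <= 0 || cfg$fraction > 1)
    stop_input("fraction must lie in (0, 1]")
  if (cfg$percentile <= 0 || cfg$percentile >= 100)
    stop_input("percentile must lie in (0, 100)")
  if (cfg$n_perm < 1) stop_input("n_perm must be >= 1")
  structure(cfg, class = c("run_config", "list"))
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    cat(sprintf("stage %s: FAILED (%s)\n", name, conditionMessage(e)),
        file = log, append = TRUE)
    stop(errorCondition(
      sprintf("stage %s failed: %s", name, conditionMessage(e)),
      class = c("bat_stage_error", class(e)[1L], "bat_error")))
  })
  cat(sprintf("stage %s: ok\n", name), file = log, append = TRUE)
  res
}

#' Run the full candidate-prediction pipeline
#'
#' Executes the five analysis stages over one configuration: connectome
#' extraction from the core ranking, known/candidate partitioning, the
#' within-group and cross-group closeness permutation tests, the
#' neighbour-joining functional-genomic-alignment tree, and (when
#' expression studies are configured) the top-percentile expression
#' enrichment test. All randomness derives from the single root `seed`, so
#' re-running an identical configuration reproduces every artifact
#' byte-for-byte.
#'
#' Configuration fields:
#' \describe{
#'   \item{core}{Core gene symbol (required).}
#'   \item{seed, fraction, percentile, n_perm}{Scalars; see
#'     [read_run_config()] for defaults.}
#'   \item{distances}{Either `list(path=, dialect=)` pointing at a TSV
#'     matrix, or `list(synthetic = list(...))` with
#'     [distance_sim_spec()] arguments (the core and a derived seed are
#'     filled in).}
#'   \item{ranking}{Optional `list(path=)` with a gene/distance/p_value
#'     TSV; when absent the ranking is derived from the distance matrix
#'     via [ranking_from_matrix()].}
#'   \item{known_list}{Either a path to a plain-text gene list, or
#'     `list(module_head = k)` to label the first `k` planted module genes
#'     as "known" (synthetic runs only).}
#'   \item{expression}{Optional. Either a list of
#'     `list(values=, map=, id=)` study file triples, or
#'     `list(synthetic = list(n_studies =, ...))` with
#'     [expression_sim_spec()] arguments; synthetic studies reuse the
#'     distance-matrix gene names and plant the module genes.}
#' }
#'
#' @param config A `run_config` (from [read_run_config()] /
#'   [as_run_config()]) or a bare named list.
#' @param out_dir Output directory, created if needed. Artifacts:
#'   `log.txt`, `connectome.txt`, `known.txt`, `candidates.txt`,
#'   `within_test.json`, `cross_test.json`, `tree.nwk`,
#'   `tree_annotation.tsv` and, with expression configured,
#'   `expression_enrichment.json`.
#' @return Invisibly, a list with the partition, test results, tree and
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "log.txt")
  cat(sprintf("batconnectome %s | %s\n",
              as.character(utils::packageVersion("batconnectome")),
              R.version.string),
      file = log)
  cat("config:\n", yaml::as.yaml(unclass(config)), file = log,
      append = TRUE, sep = "")
  seed <- as.integer(config$seed)
  module <- NULL

  dist_in <- run_stage("distances", log, {
    dc <- config$distances
    if (is.null(dc)) stop_input("no distance matrix configured")
    if (!is.null(dc$synthetic)) {
      args <- dc$synthetic
      args$core <- config$core
      if (is.null(args$seed)) args$seed <- seed
      do.call(simulate_distance_matrix, list(do.call(distance_sim_spec,
                                                     args)))
    } else {
      if (!file.exists(dc$path %||% ""))
        stop_input("distance file not found: %s", dc$path %||% "<missing>")
      list(D = read_distance_matrix(dc$path,
                                    dialect = dc$dialect %||% "square"),
           module = NULL)
    }
  })
  D <- dist_in$D
  module <- dist_in$module

  ranking <- run_stage("ranking", log, {
    if (!is.null(config$ranking$path))
      read_core_ranking(config$ranking$path, config$core)
    else
      ranking_from_matrix(D, config$core)
  })

  connectome <- run_stage("extract", log,
    extract_connectome(ranking, config$fraction))

  partition <- run_stage("partition", log, {
    kl <- config$known_list
    known <- if (is.character(kl)) {
      if (!file.exists(kl)) stop_input("known list not found: %s", kl)
      match_genes(read_gene_list(kl), genes(D), "known list")
    } else if (!is.null(kl$module_head)) {
      if (is.null(module))
        stop_input("module_head known list needs a synthetic matrix")
      utils::head(module, kl$module_head)
    } else {
      stop_input("no known list configured")
    }
    partition_connectome(connectome, known, config$core)
  })

  within_res <- run_stage("test-within", log,
    within_group_closeness_test(D, partition$known,
                                n_perm = config$n_perm, seed = seed + 1L,
                                core = config$core))

  cross_res <- run_stage("test-cross", log,
    cross_group_closeness_test(D, partition$candidates, partition$known,
                               outside = setdiff(genes(D), connectome),
                               n_perm = config$n_perm, seed = seed + 2L,
                               core = config$core))

  tree <- run_stage("tree", log,
    nj_tree(symmetrize(D), tree_genes = connectome))

  expr_res <- NULL
  if (!is.null(config$expression)) {
    expr_res <- run_stage("expression", log, {
      ec <- config$expression
      studies <- if (!is.null(ec$synthetic)) {
        args <- ec$synthetic
        n_studies <- args$n_studies %||% 2L
        args$n_studies <- NULL
        lapply(seq_len(n_studies), function(k) {
          a <- args
          a$gene_names <- genes(D)
          a$n_genes <- length(genes(D))
          if (is.null(a$planted_genes))
            a$planted_genes <- c(partition$known, partition$candidates)
          a$study_id <- sprintf("sim_study_%d", k)
          a$seed <- seed + 10L + k
          simulate_expression_study(do.call(expression_sim_spec, a))$study
        })
      } else {
        lapply(ec, function(s)
          read_expression_study(s$values, s$map, s$id %||% s$values))
      }
      tops <- make_top_sets(lapply(studies, collapse_probes),
                            percentile = config$percentile)
      query <- match_genes(setdiff(connectome, config$core),
                           tops$universe, "connectome query")
      expression_enrichment_test(query, tops, n_perm = config$n_perm,
                                 seed = seed + 3L)
    })
  }

  run_stage("write", log, {
    writeLines(connectome, file.path(out_dir, "connectome.txt"))
    writeLines(partition$known, file.path(out_dir, "known.txt"))
    writeLines(partition$candidates, file.path(out_dir, "candidates.txt"))
    permutation_result_json(within_res,
                            file.path(out_dir, "within_test.json"),
                            test = "within_group_closeness")
    permutation_result_json(cross_res,
                            file.path(out_dir, "cross_test.json"),
                            test = "cross_group_closeness")
    write_fga_tree(tree, file.path(out_dir, "tree.nwk"))
    fga_annotation(partition, file.path(out_dir, "tree_annotation.tsv"))
    if (!is.null(expr_res))
      permutation_result_json(expr_res,
                              file.path(out_dir,
                                        "expression_enrichment.json"),
                              test = "expression_enrichment")
    NULL
  })

  invisible(list(out_dir = out_dir, connectome = connectome,
                 partition = partition, within = within_res,
                 cross = cross_res, tree = tree, expression = expr_res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
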