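# One-command end-to-end run: curation -> weights -> similarity -> network ->
# requested analyses, with a reproducibility manifest. Outputs carry no
# timestamps, so identical config + input give byte-identical bundles.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate input with [generate_dataset()]) or
#'   `"hmdd-tsv"` (read an association TSV and a class-map TSV).
#' @param input association TSV path (`hmdd-tsv` mode).
#' @param classes class-map TSV path (`hmdd-tsv` mode; required whenever a
#'   class-based analysis is enabled).
#' @param generator named list of [generator_config()] arguments
#'   (`synthetic` mode).
#' @param threshold similarity threshold.
#' @param log_base weight-penalty logarithm base.
#' @param analyses named list of toggles: `distances`, `contingency`
#'   (logicals), `coherence` = list(`enabled`, `reps`, `seed`), `neighbors` =
#'   list(`enabled`, `focal`, `target_class`, `reps`, `seed`,
#'   `swaps_per_edge`), `neighborhood` = list(`enabled`, `focal`, `k`).
#' @param out_dir output directory (created if missing).
#' @return a list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "hmdd-tsv"), input = NULL,
                       classes = NULL, generator = list(), threshold = 0.05,
                       log_base = exp(1), analyses = list(),
                       out_dir = "mirdisnet-run") {
  mode <- match.arg(mode)
  defaults <- list(
    distances = TRUE,
    contingency = TRUE,
    coherence = list(enabled = FALSE, reps = 200L, seed = 1L),
    neighbors = list(enabled = FALSE, focal = NULL, target_class = NULL,
                     reps = 99L, seed = 1L, swaps_per_edge = 10L),
    neighborhood = list(enabled = FALSE, focal = NULL, k = 10L)
  )
  for (nm in names(analyses)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]][names(analyses[[nm]])] <- analyses[[nm]]
    } else {
      defaults[[nm]] <- analyses[[nm]]
    }
  }
  cfg <- list(mode = mode, input = input, classes = classes,
              generator = generator, threshold = threshold,
              log_base = log_base, analyses = defaults, out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the arguments of [run_config()]; the parsed configuration
#' round-trips through serialization unchanged.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  an <- config$analyses
  if (config$mode == "hmdd-tsv") {
    if (is.null(config$input) || !file.exists(config$input)) {
      stop("config error: association input file missing (input = ",
           config$input %||% "NULL", ")")
    }
    needs_classes <- isTRUE(an$distances) || isTRUE(an$contingency) ||
      isTRUE(an$neighbors$enabled)
    if (needs_classes &&
        (is.null(config$classes) || !file.exists(config$classes))) {
      stop("config error: a class map is required for the enabled analyses ",
           "but none was given or the file does not exist")
    }
  }
  if (config$threshold <= 0) stop("config error: threshold must be positive")
  if (isTRUE(an$neighbors$enabled) &&
      (is.null(an$neighbors$focal) || is.null(an$neighbors$target_class))) {
    stop("config error: neighbors analysis needs 'focal' and 'target_class'")
  }
  if (isTRUE(an$neighborhood$enabled) && is.null(an$neighborhood$focal)) {
    stop("config error: neighborhood report needs 'focal'")
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Validates the configuration (failing fast before any computation), loads
#' or generates the association data, builds the weight matrix, similarity
#' matrix and signed network, runs the enabled analyses, and writes every
#' result plus a manifest (configuration, package version, seeds, input
#' checksums and stage counts) to the output directory. Given identical
#' configuration and input, the output bundle is byte-identical.
#'
#' @param config a `run_config` or a path to a YAML/JSON config file.
#' @return invisibly, a list with the in-memory results (`dataset`,
#'   `classes`, `weights`, `similarity`, `network`, `analyses`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  checksums <- list()
  if (config$mode == "synthetic") {
    gen <- do.call(generator_config, config$generator)
    sy <- generate_dataset(gen)
    dataset <- sy$dataset
    classes <- sy$classes
    write_hmdd_like_tsv(dataset, file.path(out, "associations.tsv"))
    write_class_map(classes, file.path(out, "classes.tsv"))
    say("generated synthetic dataset (seed %d)", gen$seed)
  } else {
    parsed <- parse_hmdd_tsv(config$input)
    say("parsed %d records from %s (%d curatable)", nrow(parsed),
        config$input, sum(parsed$curatable))
    dataset <- curate(parsed)
    classes <- if (!is.null(config$classes)) read_class_map(config$classes)
    checksums$input <- unname(tools::md5sum(config$input))
    if (!is.null(config$classes)) {
      checksums$classes <- unname(tools::md5sum(config$classes))
    }
  }
  up <- unique_pair_counts(dataset)
  say("curated dataset: %d records, %d diseases, %d miRNAs",
      nrow(dataset$records), dataset$N, dataset$M)
  say("unique pairs: %d (%d up, %d down)", up["total"], up["up"], up["down"])

  weights <- build_weight_matrix(dataset, config$log_base)
  write_matrix_tsv(weights$values, file.path(out, "weight_matrix.tsv"))
  sim <- pairwise_similarity(weights)
  write_matrix_tsv(sim$values, file.path(out, "similarity_matrix.tsv"))
  net <- build_network(sim, config$threshold)
  export_network(net, file.path(out, "network_edges.tsv"), "edge-tsv")
  export_network(net, file.path(out, "network.graphml"), "graphml",
                 classes = classes)
  comp <- connected_components(net)
  deg <- degree_summary(net)
  say("network: %d nodes, %d edges (%d positive, %d negative), %d isolated",
      length(net$nodes), nrow(net$edges), sum(net$edges$sign == 1L),
      sum(net$edges$sign == -1L), comp$n_isolated)

  an <- config$analyses
  results <- list()
  if (!is.null(classes)) {
    summ <- dataset_summary(dataset, classes)
    utils::write.table(summ$class_counts, file.path(out, "class_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$top_diseases, file.path(out, "top_diseases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$top_mirnas, file.path(out, "top_mirnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(an$distances)) {
    dist <- shortest_path_distances(net)
    results$distance_test <- intra_inter_distance_test(dist, classes)
    say("distance test: mean intra %.3f vs inter %.3f (p = %.3g; %d pairs unreachable)",
        results$distance_test$mean_intra, results$distance_test$mean_inter,
        results$distance_test$p, dist$n_unreachable_pairs)
  }
  if (isTRUE(an$contingency)) {
    tab <- link_sign_contingency(net, classes)
    fish <- fisher_exact_2x2(tab)
    results$contingency <- list(table = tab, fisher = fish)
    say("link-sign contingency Fisher p = %.3g (odds ratio %.3f)",
        fish$p, fish$odds_ratio)
  }
  if (isTRUE(an$coherence$enabled)) {
    results$coherence <- coherence_ratio_test(
      dataset, config$threshold, n_reps = an$coherence$reps,
      seed = an$coherence$seed, log_base = config$log_base)
    say("coherence test: observed %.3f, empirical p = %.3g (%d reps, seed %d)",
        results$coherence$observed, results$coherence$empirical_p,
        an$coherence$reps, an$coherence$seed)
  }
  if (isTRUE(an$neighbors$enabled)) {
    results$neighbors <- neighbor_enrichment_test(
      net, classes, an$neighbors$focal, an$neighbors$target_class,
      n_reps = an$neighbors$reps, seed = an$neighbors$seed,
      swaps_per_edge = an$neighbors$swaps_per_edge)
  }
  if (isTRUE(an$neighborhood$enabled)) {
    results$neighborhood <- disease_neighborhood_report(
      net, sim, an$neighborhood$focal, k = an$neighborhood$k,
      dataset = dataset)
  }

  stats_json <- list(
    counts = list(records = nrow(dataset$records), diseases = dataset$N,
                  mirnas = dataset$M,
                  unique_pairs = as.list(stats::setNames(as.integer(up),
                                                         names(up))),
                  edges = nrow(net$edges),
                  positive_edges = sum(net$edges$sign == 1L),
                  negative_edges = sum(net$edges$sign == -1L),
                  isolated_nodes = comp$n_isolated),
    mean_degree = unname(deg$means["degree"]),
    mean_pos_degree = unname(deg$means["pos_degree"]),
    mean_neg_degree = unname(deg$means["neg_degree"]),
    pos_neg_degree_correlation = pos_neg_degree_correlation(net),
    analyses = serialize_results(results)
  )
  jsonlite::write_json(stats_json, file.path(out, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  # the manifest records the run's content, not its location: out_dir is
  # deliberately omitted so identical runs hash identically wherever written
  manifest_config <- unclass(config)
  manifest_config$out_dir <- NULL
  manifest <- list(
    package = "mirdisnet",
    version = as.character(utils::packageVersion("mirdisnet")),
    config = manifest_config,
    input_checksums = checksums,
    counts = stats_json$counts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(list(dataset = dataset, classes = classes, weights = weights,
                 similarity = sim, network = net, analyses = results,
                 manifest = manifest))
}

# JSON-friendly view of analysis results (drops bulky replicate vectors into
# summaries, keeps seeds and reps so every number is reproducible).
serialize_results <- function(results) {
  out <- list()
  if (!is.null(results$distance_test)) out$distance_test <- results$distance_test
  if (!is.null(results$contingency)) {
    out$contingency <- list(
      table = as.list(stats::setNames(as.integer(results$contingency$table),
                                      c("pos_intra", "neg_intra",
                                        "pos_inter", "neg_inter"))),
      fisher_p = results$contingency$fisher$p,
      odds_ratio = results$contingency$fisher$odds_ratio)
  }
  for (nm in c("coherence", "neighbors")) {
    nd <- results[[nm]]
    if (is.null(nd)) next
    if (inherits(nd, "null_distribution")) {
      out[[nm]] <- list(statistic = nd$statistic, observed = nd$observed,
                        null_mean = mean(nd$replicates, na.rm = TRUE),
                        empirical_p = nd$empirical_p, n_reps = nd$n_reps,
                        seed = nd$seed)
    } else {
      out[[nm]] <- nd
    }
  }
  if (!is.null(results$neighborhood)) {
    nb <- results$neighborhood
    out$neighborhood <- list(focal = nb$focal,
                             top_similar = nb$top_similar,
                             top_opposite = nb$top_opposite,
                             subnetwork_nodes = length(nb$subnetwork$nodes),
                             subnetwork_edges = nrow(nb$subnetwork$edges))
  }
  out
}
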