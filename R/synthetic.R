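# Synthetic HMDD-style association data with planted disease-class structure.
# The generator exists so the whole pipeline - curation, weighting, similarity,
# network construction and every statistical test - can be exercised end to end
# on data whose ground truth is known.

#' Configuration for the synthetic association generator
#'
#' The planted model: each disease class owns a reference pool of miRNAs, each
#' pool miRNA carrying a reference regulation direction. A disease draws its
#' miRNAs from its class pool with probability `within_class_share` (otherwise
#' uniformly from all miRNAs), and a pool miRNA keeps the class's reference
#' direction with probability `sign_concordance` (otherwise it is flipped);
#' off-pool miRNAs get a uniform random direction. Per retained (disease,
#' miRNA) pair the number of literature records is drawn with mean
#' `record_multiplicity_mean` (minimum 1). High `within_class_share` and
#' `sign_concordance` therefore plant exactly the structure the downstream
#' tests look for: diseases of a class share miRNAs with concordant signs.
#'
#' @param n_classes number of disease classes (>= 1).
#' @param diseases_per_class diseases per class (>= 1).
#' @param n_mirnas total number of miRNAs.
#' @param class_pool_size miRNAs in each class's reference pool; pools are
#'   drawn independently per class and may overlap (pan-disease miRNAs exist
#'   in real data). Must not exceed `n_mirnas`.
#' @param mean_mirnas_per_disease mean number of miRNA draws per disease; the
#'   per-disease count is 1 + Geometric, a heavy-tailed shape mimicking the
#'   skew of real per-disease miRNA counts.
#' @param within_class_share probability a draw comes from the class pool.
#' @param sign_concordance probability a pool miRNA keeps the reference sign.
#' @param record_multiplicity_mean mean records per retained pair (>= 1);
#'   counts are 1 + Poisson(mean - 1).
#' @param seed integer seed; identical config (including seed) gives
#'   byte-identical output.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_classes = 3L, diseases_per_class = 20L,
                             n_mirnas = 150L, class_pool_size = 40L,
                             mean_mirnas_per_disease = 8,
                             within_class_share = 0.9,
                             sign_concordance = 0.9,
                             record_multiplicity_mean = 1.5,
                             seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              diseases_per_class = as.integer(diseases_per_class),
              n_mirnas = as.integer(n_mirnas),
              class_pool_size = as.integer(class_pool_size),
              mean_mirnas_per_disease = mean_mirnas_per_disease,
              within_class_share = within_class_share,
              sign_concordance = sign_concordance,
              record_multiplicity_mean = record_multiplicity_mean,
              seed = as.integer(seed))
  if (cfg$n_classes < 1L || cfg$diseases_per_class < 1L || cfg$n_mirnas < 1L) {
    stop("counts in the generator config must be positive")
  }
  if (cfg$class_pool_size < 1L || cfg$class_pool_size > cfg$n_mirnas) {
    stop("class_pool_size must be between 1 and n_mirnas (",
         cfg$n_mirnas, ")")
  }
  for (p in c("within_class_share", "sign_concordance")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$mean_mirnas_per_disease < 1) {
    stop("mean_mirnas_per_disease must be >= 1")
  }
  if (cfg$record_multiplicity_mean < 1) {
    stop("record_multiplicity_mean must be >= 1")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic HMDD-like dataset
#'
#' Draws association records under the planted-class model described in
#' [generator_config()] and curates them. All randomness comes from a single
#' seeded stream local to this call; the global RNG state is untouched.
#'
#' @param config a [generator_config()].
#' @return a list with components `dataset` (a `curated_dataset`), `classes`
#'   (a `class_map`), `truth` (a list with the per-class `pools` data frame of
#'   planted pool memberships and reference directions, and the per-pair
#'   `assignments` data frame with each planted direction and whether the
#'   miRNA came from the class pool), and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_dis <- config$n_classes * config$diseases_per_class
    mirnas <- sprintf("hsa-mir-%04d", seq_len(config$n_mirnas))
    class_labels <- sprintf("Class %02d", seq_len(config$n_classes))
    diseases <- sprintf("Disease %02d-%02d",
                        rep(seq_len(config$n_classes),
                            each = config$diseases_per_class),
                        rep(seq_len(config$diseases_per_class),
                            config$n_classes))
    disease_class <- rep(class_labels, each = config$diseases_per_class)

    # per-class reference pools with reference directions
    pools <- vector("list", config$n_classes)
    for (c in seq_len(config$n_classes)) {
      idx <- sample.int(config$n_mirnas, config$class_pool_size)
      pools[[c]] <- data.frame(
        class = class_labels[c],
        mirna = mirnas[idx],
        ref_direction = sample(c(1L, -1L), config$class_pool_size,
                               replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    pool_df <- do.call(rbind, pools)

    assign_rows <- vector("list", n_dis)
    for (d in seq_len(n_dis)) {
      cls_i <- (d - 1L) %/% config$diseases_per_class + 1L
      pool <- pools[[cls_i]]
      n_draw <- 1L + stats::rgeom(1L, prob = 1 / config$mean_mirnas_per_disease)
      from_pool <- stats::runif(n_draw) < config$within_class_share
      drawn <- character(n_draw)
      n_pool_draws <- sum(from_pool)
      if (n_pool_draws > 0L) {
        drawn[from_pool] <- sample(pool$mirna, n_pool_draws, replace = TRUE)
      }
      if (n_pool_draws < n_draw) {
        drawn[!from_pool] <- sample(mirnas, n_draw - n_pool_draws,
                                    replace = TRUE)
      }
      dup <- duplicated(drawn)
      drawn <- drawn[!dup]
      # direction depends on pool *membership*, not on the arm of the draw
      in_pool <- drawn %in% pool$mirna
      dir <- integer(length(drawn))
      if (any(in_pool)) {
        ref <- pool$ref_direction[match(drawn[in_pool], pool$mirna)]
        keep <- stats::runif(sum(in_pool)) < config$sign_concordance
        dir[in_pool] <- ifelse(keep, ref, -ref)
      }
      if (any(!in_pool)) {
        dir[!in_pool] <- sample(c(1L, -1L), sum(!in_pool), replace = TRUE)
      }
      assign_rows[[d]] <- data.frame(
        disease = diseases[d], class = class_labels[cls_i], mirna = drawn,
        direction = dir, from_pool = in_pool, stringsAsFactors = FALSE
      )
    }
    assignments <- do.call(rbind, assign_rows)
    rownames(assignments) <- NULL

    n_rec <- 1L + stats::rpois(nrow(assignments),
                               lambda = config$record_multiplicity_mean - 1)
    rec <- assignments[rep(seq_len(nrow(assignments)), n_rec), , drop = FALSE]
    records <- data.frame(
      mirna_id = rec$mirna,
      disease_name = rec$disease,
      evidence_code = ifelse(rec$direction == 1L, EVIDENCE_UP, EVIDENCE_DOWN),
      direction = rec$direction,
      reference_id = sprintf("SYN%06d", seq_len(nrow(rec))),
      stringsAsFactors = FALSE
    )

    list(dataset = curate(records),
         classes = class_map(diseases, disease_class),
         truth = list(pools = pool_df, assignments = assignments),
         config = config)
  })
}

#' Write a curated dataset as an HMDD-style TSV
#'
#' Emits one row per record with the default dialect's columns, so that
#' `curate(parse_hmdd_tsv(path))` round-trips the dataset exactly.
#'
#' @param dataset a `curated_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hmdd_like_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (length(dataset$diseases) == 0L) stop("dataset has no diseases")
  rec <- dataset$records
  df <- data.frame(category = rec$evidence_code,
                   mir = rec$mirna,
                   disease = rec$disease,
                   pmid = rec$reference_id,
                   description = "",
                   stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
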