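# The statistics suite: network distances and class clustering, link-sign
# contingency with exact Fisher tests, signed-triangle coherence with a
# record-shuffle null, and degree-preserving neighbor-class enrichment.

#' Run curation output through weights, similarity and network in one step
#'
#' @param dataset a `curated_dataset`.
#' @param threshold similarity threshold for [build_network()].
#' @param log_base penalty logarithm base for [build_weight_matrix()].
#' @return a `disease_network`.
#' @export
network_from_dataset <- function(dataset, threshold = 0.05,
                                 log_base = exp(1)) {
  build_network(pairwise_similarity(build_weight_matrix(dataset, log_base)),
                threshold)
}

#' All-pairs shortest-path distances
#'
#' Unweighted breadth-first distances on the unsigned skeleton. Pairs in
#' different components are unreachable and omitted from the table (counted,
#' never encoded as a number).
#'
#' @param net a `disease_network`.
#' @return a list with `distances` (data frame `from`, `to`, `distance` for
#'   every reachable unordered pair, `from < to`) and `n_unreachable_pairs`.
#' @export
shortest_path_distances <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- as_igraph(net)
  D <- igraph::distances(g, weights = NA)
  nm <- igraph::V(g)$name
  dimnames(D) <- list(nm, nm)
  ord <- order(nm, method = "radix")
  D <- D[ord, ord]
  idx <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
  df <- data.frame(from = rownames(D)[idx[, 1]], to = colnames(D)[idx[, 2]],
                   distance = as.integer(D[idx]), stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to, method = "radix"), ]
  rownames(df) <- NULL
  n_pairs <- length(net$nodes) * (length(net$nodes) - 1L) / 2L
  list(distances = df, n_unreachable_pairs = n_pairs - nrow(df))
}

#' Compare intra-class and inter-class network distances
#'
#' Partitions the finite pairwise distances into pairs whose endpoints share
#' a disease class (intra) and pairs that do not (inter), and compares the
#' two groups with a classic pooled-variance two-sample Student's t-test.
#' If the pooled variance is zero the degenerate rule applies: equal means
#' give t = 0, p = 1, unequal means give t = +/-Inf, p = 0.
#'
#' @param distances result of [shortest_path_distances()].
#' @param classes a `class_map` total on the nodes that appear in the table.
#' @return a list with `mean_intra`, `mean_inter`, `t`, `p`, `df`,
#'   `n_intra`, `n_inter`, `n_unreachable_excluded`, and `testable` (`FALSE`
#'   with everything else `NA` if either group has fewer than 2 distances).
#' @export
intra_inter_distance_test <- function(distances, classes) {
  df <- distances$distances
  cf <- disease_classes(classes, df$from)
  ct <- disease_classes(classes, df$to)
  intra <- df$distance[cf == ct]
  inter <- df$distance[cf != ct]
  if (length(intra) < 2L || length(inter) < 2L) {
    return(list(mean_intra = NA_real_, mean_inter = NA_real_, t = NA_real_,
                p = NA_real_, df = NA_real_, n_intra = length(intra),
                n_inter = length(inter),
                n_unreachable_excluded = distances$n_unreachable_pairs,
                testable = FALSE))
  }
  n1 <- length(intra); n2 <- length(inter)
  m1 <- mean(intra); m2 <- mean(inter)
  dof <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(intra) + (n2 - 1) * stats::var(inter)) / dof
  if (sp2 == 0) {
    tt <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    pp <- if (m1 == m2) 1 else 0
  } else {
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    pp <- 2 * stats::pt(-abs(tt), df = dof)
  }
  list(mean_intra = m1, mean_inter = m2, t = tt, p = pp, df = dof,
       n_intra = n1, n_inter = n2,
       n_unreachable_excluded = distances$n_unreachable_pairs,
       testable = TRUE)
}

#' Link-sign by link-locality contingency table
#'
#' Counts every edge of the network exactly once into a 2x2 table: rows are
#' the edge sign (positive / negative), columns are whether the endpoints
#' share a class (intra) or not (inter).
#'
#' @param net a `disease_network`.
#' @param classes a `class_map` total on the network's nodes.
#' @return a 2x2 integer matrix with dimnames
#'   `list(sign = c("positive", "negative"), links = c("intra", "inter"))`.
#' @export
link_sign_contingency <- function(net, classes) {
  stopifnot(inherits(net, "disease_network"))
  cf <- disease_classes(classes, net$edges$from)
  ct <- disease_classes(classes, net$edges$to)
  intra <- cf == ct
  pos <- net$edges$sign == 1L
  tab <- matrix(c(sum(pos & intra), sum(!pos & intra),
                  sum(pos & !intra), sum(!pos & !intra)),
                nrow = 2,
                dimnames = list(sign = c("positive", "negative"),
                                links = c("intra", "inter")))
  storage.mode(tab) <- "integer"
  tab
}

#' Sign-by-locality contingency restricted to one pair of classes
#'
#' Considers only edges whose two endpoints both lie in `class_a` or
#' `class_b`. The intra column counts edges inside either class; the inter
#' column counts edges bridging the two classes; edges touching any other
#' class are ignored.
#'
#' @param net a `disease_network`.
#' @param classes a `class_map` total on the network's nodes.
#' @param class_a,class_b the two class labels to compare.
#' @return a 2x2 integer matrix, layout as in [link_sign_contingency()].
#' @export
class_pair_contingency <- function(net, classes, class_a, class_b) {
  stopifnot(inherits(net, "disease_network"))
  known <- unique(unname(classes$map))
  for (cl in c(class_a, class_b)) {
    if (!cl %in% known) stop("unknown class label: ", cl)
  }
  cf <- disease_classes(classes, net$edges$from)
  ct <- disease_classes(classes, net$edges$to)
  in_ab <- cf %in% c(class_a, class_b) & ct %in% c(class_a, class_b)
  intra <- in_ab & cf == ct
  inter <- in_ab & cf != ct
  pos <- net$edges$sign == 1L
  tab <- matrix(c(sum(pos & intra), sum(!pos & intra),
                  sum(pos & inter), sum(!pos & inter)),
                nrow = 2,
                dimnames = list(sign = c("positive", "negative"),
                                links = c("intra", "inter")))
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test by the point-probability convention: conditioning on the table
#' margins, the p-value is the sum of hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed table.
#' The odds ratio is the sample ratio ad/bc (`Inf` when bc = 0 with ad > 0,
#' `NaN` when both products are 0). A table with a zero margin admits only
#' one configuration and is degenerate: p = 1.
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return a list with `p`, `odds_ratio`, and `degenerate`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  or <- (a * d) / (b * c)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(p = 1, odds_ratio = or, degenerate = TRUE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  # relative tolerance guards against ties lost to floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), odds_ratio = or, degenerate = FALSE)
}

#' Enumerate and classify the signed triangles of a network
#'
#' Lists each 3-clique of the unsigned skeleton once and classifies it by its
#' number of negative edges: a triangle is coherent iff that number is even
#' (0 or 2), the structural-balance notion of a consistent disease loop. All
#' four sign-multiset counts (+++, ++-, +--, ---) are reported.
#'
#' @param net a `disease_network`.
#' @return a list with `triangles` (data frame `a`, `b`, `c`, `n_negative`,
#'   `coherent`; vertices sorted within and across rows), `type_counts`
#'   (named by number of negative edges: `"0"`..`"3"`), `coherent`,
#'   `incoherent` and `total`.
#' @export
enumerate_triangles <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- as_igraph(net)
  tri <- igraph::triangles(g)
  sign_of <- net$edges$sign
  names(sign_of) <- paste(net$edges$from, net$edges$to, sep = "\r")
  edge_sign <- function(u, v) {
    key <- ifelse(u < v, paste(u, v, sep = "\r"), paste(v, u, sep = "\r"))
    unname(sign_of[key])
  }
  if (length(tri) == 0L) {
    df <- data.frame(a = character(), b = character(), c = character(),
                     n_negative = integer(), coherent = logical(),
                     stringsAsFactors = FALSE)
  } else {
    m <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
    m <- t(apply(m, 1L, sort, method = "radix"))
    neg <- (edge_sign(m[, 1], m[, 2]) == -1L) +
      (edge_sign(m[, 1], m[, 3]) == -1L) +
      (edge_sign(m[, 2], m[, 3]) == -1L)
    df <- data.frame(a = m[, 1], b = m[, 2], c = m[, 3],
                     n_negative = as.integer(neg),
                     coherent = neg %% 2L == 0L, stringsAsFactors = FALSE)
    df <- df[order(df$a, df$b, df$c, method = "radix"), ]
    rownames(df) <- NULL
  }
  type_counts <- vapply(0:3, function(k) sum(df$n_negative == k), integer(1))
  names(type_counts) <- as.character(0:3)
  list(triangles = df, type_counts = type_counts,
       coherent = sum(df$coherent), incoherent = sum(!df$coherent),
       total = nrow(df))
}

new_null_distribution <- function(statistic, observed, replicates, n_reps,
                                  seed, extra = list()) {
  exceed <- sum(!is.na(replicates) & replicates >= observed - 1e-12)
  obj <- c(list(statistic = statistic, observed = observed,
                replicates = replicates, n_reps = n_reps, seed = seed,
                empirical_p = (1 + exceed) / (1 + n_reps)), extra)
  structure(obj, class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Randomization test of %s\n", x$statistic))
  cat(sprintf("  observed = %.4f; null mean = %.4f over %d replicates (seed %d)\n",
              x$observed, mean(x$replicates, na.rm = TRUE), x$n_reps, x$seed))
  cat(sprintf("  empirical p = %.4g (one-sided, add-one corrected)\n",
              x$empirical_p))
  invisible(x)
}

# Permute the miRNA field across curated records, leaving diseases and
# directions fixed. Preserves per-disease record counts exactly and the
# per-miRNA record-count multiset (the labels are merely permuted); the
# miRNA-to-disease wiring, and hence each miRNA's disease spectrum width,
# is randomized.
shuffle_records <- function(records) {
  out <- records
  out$mirna <- records$mirna[sample.int(nrow(records))]
  stopifnot(identical(table(out$disease), table(records$disease)),
            identical(sort(out$mirna), sort(records$mirna)))
  out
}

#' Randomization test of triangle coherence
#'
#' The observed statistic is the ratio of coherent to incoherent triangles in
#' the network built from the dataset. Each null replicate permutes the miRNA
#' labels across the curated records (per-disease and per-miRNA record counts
#' are conserved and asserted), then recomputes weights, similarities, the
#' network and the triangle census from scratch. The empirical p-value is
#' add-one corrected: (1 + #\{replicate >= observed\}) / (1 + n_reps).
#'
#' If the observed network or any replicate has zero incoherent triangles the
#' raw ratio is undefined or infinite, so the comparison falls back to the
#' coherent *share* (coherent / total) for every replicate; replicates with
#' no triangles at all count as less extreme than any observed value.
#'
#' @param dataset a `curated_dataset`.
#' @param threshold similarity threshold.
#' @param n_reps number of null replicates (>= 1).
#' @param seed RNG seed for the replicate stream.
#' @param log_base penalty logarithm base.
#' @return a `null_distribution` with extra fields `observed_ratio`,
#'   `observed_share`, `observed_counts`, and `replicate_shares`.
#' @export
coherence_ratio_test <- function(dataset, threshold = 0.05, n_reps = 200L,
                                 seed = 1L, log_base = exp(1)) {
  stopifnot(inherits(dataset, "curated_dataset"), n_reps >= 1L)
  obs <- enumerate_triangles(network_from_dataset(dataset, threshold,
                                                  log_base))
  obs_ratio <- if (obs$incoherent > 0L) obs$coherent / obs$incoherent else
    if (obs$coherent > 0L) Inf else NA_real_
  obs_share <- if (obs$total > 0L) obs$coherent / obs$total else NA_real_

  rep_ratio <- rep(NA_real_, n_reps)
  rep_share <- rep(NA_real_, n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      shuf <- curate(shuffle_records(dataset$records))
      cnt <- enumerate_triangles(network_from_dataset(shuf, threshold,
                                                      log_base))
      rep_ratio[r] <- if (cnt$incoherent > 0L) cnt$coherent / cnt$incoherent
        else if (cnt$coherent > 0L) Inf else NA_real_
      rep_share[r] <- if (cnt$total > 0L) cnt$coherent / cnt$total
        else NA_real_
    }
  })

  use_share <- !is.finite(obs_ratio) || any(!is.finite(rep_ratio))
  if (use_share) {
    stat_name <- "coherent share of triangles"
    observed <- obs_share
    reps <- rep_share
  } else {
    stat_name <- "coherent/incoherent triangle ratio"
    observed <- obs_ratio
    reps <- rep_ratio
  }
  new_null_distribution(stat_name, observed, reps, n_reps, seed,
                        extra = list(observed_ratio = obs_ratio,
                                     observed_share = obs_share,
                                     observed_counts = obs$type_counts,
                                     replicate_shares = rep_share))
}

#' Class composition of each node's first neighbors
#'
#' @param net a `disease_network`.
#' @param classes a `class_map` total on the network's nodes.
#' @return a list with `histograms` (named list, per node, of class-count
#'   tables summing to the node's degree) and `summary` (data frame
#'   `disease`, `degree`, `modal_class` - lexicographically smallest among
#'   tied maxima, `NA` for isolated nodes -, `modal_count`, `tied_classes`
#'   - comma-separated when the maximum is tied).
#' @export
neighbor_class_composition <- function(net, classes) {
  stopifnot(inherits(net, "disease_network"))
  node_class <- disease_classes(classes, net$nodes)
  nbrs <- split(c(net$edges$to, net$edges$from),
                c(net$edges$from, net$edges$to))
  histograms <- lapply(net$nodes, function(v) {
    nb <- nbrs[[v]]
    if (is.null(nb)) return(integer(0))
    tab <- table(node_class[nb])
    tab[order(names(tab), method = "radix")]
  })
  names(histograms) <- net$nodes
  rows <- lapply(net$nodes, function(v) {
    h <- histograms[[v]]
    if (length(h) == 0L) {
      return(data.frame(disease = v, degree = 0L, modal_class = NA_character_,
                        modal_count = 0L, tied_classes = NA_character_,
                        stringsAsFactors = FALSE))
    }
    top <- names(h)[h == max(h)]
    data.frame(disease = v, degree = sum(h),
               modal_class = sort(top, method = "radix")[1L],
               modal_count = as.integer(max(h)),
               tied_classes = if (length(top) > 1L)
                 paste(sort(top, method = "radix"), collapse = ",")
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  list(histograms = histograms, summary = do.call(rbind, rows))
}

# One degree-preserving rewiring of the signed edge list: n_attempts double
# edge swaps (a,b)+(c,d) -> (a,d)+(c,b), rejecting self-loops and
# multi-edges; each edge's sign and similarity travel with it.
double_edge_swap <- function(edges, n_attempts) {
  m <- nrow(edges)
  if (m < 2L) return(edges)
  from <- edges$from
  to <- edges$to
  key <- function(u, v) ifelse(u < v, paste(u, v, sep = "\r"),
                               paste(v, u, sep = "\r"))
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(from, to)) assign(k, TRUE, envir = present)
  picks <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2)
  flips <- stats::runif(n_attempts) < 0.5
  for (s in seq_len(n_attempts)) {
    i <- picks[s, 1]; j <- picks[s, 2]
    if (i == j) next
    a <- from[i]; b <- to[i]; c <- from[j]; d <- to[j]
    if (flips[s]) { tmp <- c; c <- d; d <- tmp }
    # proposal: (a,d) and (c,b)
    if (a == d || c == b) next
    k1 <- key(a, d); k2 <- key(c, b)
    if (k1 == k2) next
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(a, b), key(c, d)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    from[i] <- a; to[i] <- d
    from[j] <- c; to[j] <- b
  }
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  out <- edges
  out$from <- from
  out$to <- to
  out
}

#' Degree-preserving test of neighbor-class enrichment
#'
#' The statistic is the number of the focal disease's first neighbors that
#' belong to `target_class`. The null rewires the network by attempted
#' double edge swaps (`swaps_per_edge` x |E| attempts per replicate, each
#' replicate restarted from the observed network), which preserve every
#' node's total degree exactly (asserted per replicate) while signs travel
#' with their edges; class labels stay fixed. Empirical p is add-one
#' corrected as in [coherence_ratio_test()].
#'
#' @param net a `disease_network`.
#' @param classes a `class_map` total on the network's nodes.
#' @param focal focal disease name (must be a network node).
#' @param target_class class whose neighbor count is tested.
#' @param n_reps number of rewired replicates.
#' @param seed RNG seed.
#' @param swaps_per_edge attempted swaps per edge per replicate (default 10).
#' @return a `null_distribution`, or a list with `testable = FALSE` if the
#'   focal disease is isolated.
#' @export
neighbor_enrichment_test <- function(net, classes, focal, target_class,
                                     n_reps = 99L, seed = 1L,
                                     swaps_per_edge = 10L) {
  stopifnot(inherits(net, "disease_network"), n_reps >= 1L)
  focal <- match_node(net, focal)
  node_class <- disease_classes(classes, net$nodes)
  count_target <- function(edges) {
    nb <- c(edges$to[edges$from == focal], edges$from[edges$to == focal])
    sum(node_class[nb] == target_class)
  }
  deg_of <- function(edges) {
    table(factor(c(edges$from, edges$to), levels = net$nodes))
  }
  if (sum(net$edges$from == focal | net$edges$to == focal) == 0L) {
    return(list(testable = FALSE,
                reason = sprintf("'%s' is isolated in the network", focal)))
  }
  observed <- count_target(net$edges)
  deg0 <- deg_of(net$edges)
  n_attempts <- as.integer(swaps_per_edge * nrow(net$edges))
  reps <- rep(NA_real_, n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      rewired <- double_edge_swap(net$edges, n_attempts)
      stopifnot(identical(deg_of(rewired), deg0))
      reps[r] <- count_target(rewired)
    }
  })
  new_null_distribution(
    sprintf("neighbors of '%s' in class '%s'", focal, target_class),
    observed, reps, n_reps, seed,
    extra = list(focal = focal, target_class = target_class,
                 swaps_per_edge = swaps_per_edge))
}

match_node <- function(net, name) {
  if (name %in% net$nodes) return(name)
  hit <- net$nodes[norm_disease_key(net$nodes) == norm_disease_key(name)]
  if (length(hit) == 1L) return(hit)
  stop("disease '", name, "' is not a node of the network")
}

#' Neighborhood report for a focal disease
#'
#' Ranks the focal disease's first neighbors by signed similarity (most
#' similar descending, most opposite ascending), extracts the induced
#' subnetwork on the focal disease plus its neighbors, and - when the
#' curated dataset is supplied - lists the miRNAs shared between the focal
#' disease and each neighbor.
#'
#' @param net a `disease_network`.
#' @param sim the `similarity_matrix` the network was built from.
#' @param focal focal disease name.
#' @param k number of top entries per ranking (no padding when the degree is
#'   smaller).
#' @param dataset optional `curated_dataset` for shared-miRNA reporting.
#' @return a list with `focal`, `neighbors` (data frame `disease`,
#'   `similarity`, `sign`, and `shared_mirnas` comma-separated when
#'   available), `top_similar`, `top_opposite`, and `subnetwork` (a
#'   `disease_network` induced on the focal disease and its neighbors).
#' @export
disease_neighborhood_report <- function(net, sim, focal, k = 10L,
                                        dataset = NULL) {
  stopifnot(inherits(net, "disease_network"),
            inherits(sim, "similarity_matrix"), k >= 1L)
  focal <- match_node(net, focal)
  e <- net$edges
  touch <- e$from == focal | e$to == focal
  nb <- ifelse(e$from[touch] == focal, e$to[touch], e$from[touch])
  df <- data.frame(disease = nb, similarity = e$similarity[touch],
                   sign = e$sign[touch], stringsAsFactors = FALSE)
  if (!is.null(dataset)) {
    pc <- dataset$pair_counts
    support <- split(pc$mirna, pc$disease)
    focal_m <- support[[focal]] %||% character(0)
    df$shared_mirnas <- vapply(df$disease, function(d) {
      paste(sort(intersect(focal_m, support[[d]] %||% character(0))),
            collapse = ",")
    }, character(1))
  }
  df <- df[order(-df$similarity, df$disease, method = "radix"), ]
  rownames(df) <- NULL
  top_similar <- utils::head(df[df$similarity > 0, , drop = FALSE], k)
  opp <- df[df$similarity < 0, , drop = FALSE]
  top_opposite <- utils::head(opp[order(opp$similarity, opp$disease,
                                        method = "radix"), , drop = FALSE], k)
  rownames(top_similar) <- rownames(top_opposite) <- NULL
  members <- c(focal, df$disease)
  sub_edges <- e[e$from %in% members & e$to %in% members, , drop = FALSE]
  subnet <- disease_network(members, sub_edges, net$threshold)
  list(focal = focal, neighbors = df, top_similar = top_similar,
       top_opposite = top_opposite, subnetwork = subnet)
}
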