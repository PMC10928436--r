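# The signed disease network: thresholded similarity edges over all curated
# diseases, plus basic topology. igraph backs the graph algorithms; the
# network object itself stays a plain edge list so outputs are byte-stable.

#' Construct a disease network object from parts
#'
#' Low-level constructor used by [build_network()] and the importers; also
#' handy for building fixture networks directly. Edge endpoints are stored
#' with `from < to` lexicographically and edges sorted, so identical networks
#' serialize identically.
#'
#' @param nodes character vector of all node names (isolated nodes included).
#' @param edges data frame with columns `from`, `to`, `similarity`; `sign` is
#'   derived from the sign of `similarity` if absent.
#' @param threshold the similarity threshold the network was built at.
#' @return an object of class `disease_network` with components `nodes`,
#'   `edges` (`from`, `to`, `similarity`, `sign`) and `threshold`.
#' @export
disease_network <- function(nodes, edges, threshold) {
  stopifnot(is.character(nodes), is.data.frame(edges), threshold > 0)
  nodes <- sort(unique(nodes), method = "radix")
  if (nrow(edges) > 0L) {
    stopifnot(all(c("from", "to", "similarity") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      stop("duplicate edges are not allowed")
    }
    if (!all(edges$from %in% nodes & edges$to %in% nodes)) {
      stop("edge endpoints must be drawn from the node set")
    }
    if (!"sign" %in% names(edges)) edges$sign <- ifelse(edges$similarity > 0, 1L, -1L)
    edges <- edges[order(edges$from, edges$to, method = "radix"),
                   c("from", "to", "similarity", "sign")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        similarity = double(), sign = integer(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "disease_network")
}

#' Build the signed disease network from a similarity matrix
#'
#' Two diseases are connected iff the absolute value of their similarity
#' strictly exceeds `threshold`; the edge sign is the sign of the similarity.
#' Ties at exactly the threshold are excluded. Every disease of the
#' similarity matrix is a node, so diseases with no supra-threshold partner
#' (or no information at all) appear as isolated nodes.
#'
#' @param sim a `similarity_matrix`.
#' @param threshold positive similarity cutoff (default 0.05).
#' @return a `disease_network`.
#' @export
build_network <- function(sim, threshold = 0.05) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  S <- sim$values
  idx <- which(upper.tri(S) & !is.na(S) & abs(S) > threshold, arr.ind = TRUE)
  edges <- data.frame(from = sim$ids[idx[, 1]], to = sim$ids[idx[, 2]],
                      similarity = S[idx], stringsAsFactors = FALSE)
  disease_network(sim$ids, edges, threshold)
}

#' @export
print.disease_network <- function(x, ...) {
  np <- sum(x$edges$sign == 1L)
  nn <- sum(x$edges$sign == -1L)
  cat(sprintf(paste0("Signed disease network: %d nodes, %d edges ",
                     "(%d positive, %d negative), threshold %g\n"),
              length(x$nodes), nrow(x$edges), np, nn, x$threshold))
  invisible(x)
}

# igraph view of the unsigned skeleton (sign/similarity kept as attributes).
as_igraph <- function(net, classes = NULL) {
  stopifnot(inherits(net, "disease_network"))
  vertices <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    vertices$class <- unname(disease_classes(classes, net$nodes))
  }
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Per-node signed degree and clustering summary
#'
#' @param net a `disease_network`.
#' @return a list with `nodes` (data frame: `disease`, `pos_degree`,
#'   `neg_degree`, `degree`, `clustering` - local clustering coefficient of
#'   the unsigned skeleton, `NaN` for nodes of degree < 2) and `means`
#'   (`degree` = 2|E|/N, `pos_degree`, `neg_degree`).
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  nodes <- net$nodes
  ends <- c(net$edges$from, net$edges$to)
  signs <- rep(net$edges$sign, 2L)
  pos <- table(factor(ends[signs == 1L], levels = nodes))
  neg <- table(factor(ends[signs == -1L], levels = nodes))
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  names(cc) <- igraph::V(g)$name
  df <- data.frame(disease = nodes,
                   pos_degree = as.integer(pos),
                   neg_degree = as.integer(neg),
                   stringsAsFactors = FALSE)
  df$degree <- df$pos_degree + df$neg_degree
  df$clustering <- unname(cc[nodes])
  n <- length(nodes)
  list(nodes = df,
       means = c(degree = 2 * nrow(net$edges) / n,
                 pos_degree = 2 * sum(net$edges$sign == 1L) / n,
                 neg_degree = 2 * sum(net$edges$sign == -1L) / n))
}

#' Correlation between positive and negative degree
#'
#' Pearson product-moment correlation between each node's number of positive
#' and negative edges, over all nodes of the network, with the usual
#' two-sided t-transform p-value.
#'
#' @param net a `disease_network`.
#' @return a list with `r`, `p`, `n` and `defined`; if either degree sequence
#'   has zero variance the result is the distinguished undefined value
#'   (`defined = FALSE`, `r` and `p` `NA`).
#' @export
pos_neg_degree_correlation <- function(net) {
  ds <- degree_summary(net)$nodes
  x <- ds$pos_degree
  y <- ds$neg_degree
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Connected components of the unsigned skeleton
#'
#' @param net a `disease_network`.
#' @return a list with `components` (list of node-name vectors, ordered by
#'   decreasing size then by lexicographically smallest member; members
#'   sorted), `sizes`, and `n_isolated` (number of size-1 components).
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- lapply(groups, sort, method = "radix")
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1L), method = "radix")
  groups <- unname(groups[ord])
  sizes <- vapply(groups, length, integer(1))
  list(components = groups, sizes = sizes, n_isolated = sum(sizes == 1L))
}

#' Export a disease network to file
#'
#' `edge-tsv` writes the edge list (`source`, `target`, `similarity`, `sign`)
#' at full precision; `graphml` writes the whole network including isolated
#' nodes, with `similarity` and `sign` as edge attributes and, when a class
#' map is supplied, `class` as a node attribute.
#'
#' @param net a `disease_network`.
#' @param path output file path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @param classes optional `class_map` for the GraphML node attribute.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge-tsv", "graphml"),
                           classes = NULL) {
  stopifnot(inherits(net, "disease_network"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    df <- data.frame(source = net$edges$from, target = net$edges$to,
                     similarity = fmt_num(net$edges$similarity),
                     sign = net$edges$sign, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net, classes = classes)
    g <- igraph::set_graph_attr(g, "threshold", net$threshold)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a disease network from file
#'
#' Inverse of [export_network()]. The edge-TSV carries no isolated nodes, so
#' its round trip restores the edge set; GraphML round-trips the full
#' network.
#'
#' @param path file path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @param threshold threshold to record when importing edge-TSV (GraphML
#'   carries it as a graph attribute).
#' @return a `disease_network`.
#' @export
import_network <- function(path, format = c("edge-tsv", "graphml"),
                           threshold = 0.05) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    edges <- data.frame(from = df$source, to = df$target,
                        similarity = as.numeric(df$similarity),
                        sign = as.integer(df$sign), stringsAsFactors = FALSE)
    disease_network(unique(c(edges$from, edges$to)), edges, threshold)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ea <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = ea$from, to = ea$to,
                        similarity = as.numeric(ea$similarity),
                        sign = as.integer(ea$sign), stringsAsFactors = FALSE)
    thr <- igraph::graph_attr(g, "threshold")
    disease_network(igraph::V(g)$name, edges,
                    if (is.null(thr)) threshold else as.numeric(thr))
  }
}
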