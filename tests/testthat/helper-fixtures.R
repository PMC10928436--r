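# Fixture builders and independent brute-force oracles. The oracles
# deliberately share no code with the implementation paths they check.

make_records <- function(disease, mirna, direction,
                         reference = NULL) {
  n <- length(disease)
  data.frame(
    mirna_id = mirna,
    disease_name = disease,
    evidence_code = ifelse(direction == 1L, "tissue_expression_up",
                           "tissue_expression_down"),
    direction = as.integer(direction),
    reference_id = reference %||% sprintf("PM%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_assoc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random signed network over n nodes; each pair gets an edge with prob
# p_edge, negative with prob p_neg; similarities placed strictly beyond the
# threshold
random_signed_network <- function(n, p_edge = 0.4, p_neg = 0.3, seed = 1,
                                  threshold = 0.05) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  m <- sum(keep)
  sgn <- ifelse(runif(m) < p_neg, -1, 1)
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      similarity = sgn * runif(m, threshold + 0.01, 1),
                      stringsAsFactors = FALSE)
  disease_network(nodes, edges, threshold)
}

random_weight_matrix <- function(n_mirna, n_disease, seed = 1,
                                 sparsity = 0.4) {
  set.seed(seed)
  W <- matrix(rnorm(n_mirna * n_disease), n_mirna, n_disease,
              dimnames = list(sprintf("m%02d", seq_len(n_mirna)),
                              sprintf("d%02d", seq_len(n_disease))))
  W[runif(length(W)) < sparsity] <- 0
  structure(list(values = W, log_base = exp(1)), class = "weight_matrix")
}

# --- oracles ---------------------------------------------------------------

# Tanimoto per the defining formula, pair by pair
oracle_tanimoto_matrix <- function(W) {
  n <- ncol(W)
  S <- matrix(NA_real_, n, n, dimnames = list(colnames(W), colnames(W)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- W[, i]; y <- W[, j]
    if (all(x == 0) || all(y == 0)) next
    dot <- sum(x * y)
    S[i, j] <- dot / (sum(x^2) + sum(y^2) - dot)
  }
  S
}

# cubic triple loop over node triples
oracle_triangles <- function(net) {
  nodes <- sort(net$nodes)
  sgn <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(net$edges))) {
    assign(paste(net$edges$from[r], net$edges$to[r]), net$edges$sign[r],
           envir = sgn)
  }
  look <- function(u, v) {
    k <- if (u < v) paste(u, v) else paste(v, u)
    if (exists(k, envir = sgn, inherits = FALSE)) get(k, envir = sgn) else NA
  }
  out <- list()
  n <- length(nodes)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    s1 <- look(nodes[i], nodes[j]); s2 <- look(nodes[i], nodes[k])
    s3 <- look(nodes[j], nodes[k])
    if (anyNA(c(s1, s2, s3))) next
    neg <- sum(c(s1, s2, s3) == -1)
    out[[length(out) + 1L]] <- data.frame(
      a = nodes[i], b = nodes[j], c = nodes[k], n_negative = neg,
      coherent = neg %% 2 == 0, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(a = character(), b = character(), c = character(),
                      n_negative = integer(), coherent = logical()))
  }
  do.call(rbind, out)
}

# Fisher two-sided p by direct enumeration with binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  av <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, av) * choose(r2, c1 - av) / choose(n, c1)
  p_obs <- probs[av == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# flood fill on an adjacency list
oracle_components <- function(net) {
  adj <- lapply(setNames(net$nodes, net$nodes), function(v) {
    c(net$edges$to[net$edges$from == v], net$edges$from[net$edges$to == v])
  })
  seen <- character(0)
  comps <- list()
  for (v in net$nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps[order(-lengths(comps), vapply(comps, `[`, character(1), 1))]
}

# exhaustive BFS distances, one source at a time
oracle_distances <- function(net) {
  nodes <- sort(net$nodes)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(net$edges$to[net$edges$from == v], net$edges$from[net$edges$to == v])
  })
  for (s in nodes) {
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- depth
      frontier <- nxt
    }
  }
  D
}
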