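path_net <- function() {
  disease_network(c("a", "b", "c"),
                  data.frame(from = c("a", "b"), to = c("b", "c"),
                             similarity = c(0.2, 0.3)), 0.05)
}

test_that("shortest-path distances are BFS on the unsigned skeleton", {
  d <- shortest_path_distances(path_net())
  expect_equal(d$distances$distance[d$distances$from == "a" &
                                      d$distances$to == "c"], 2L)
  expect_equal(d$n_unreachable_pairs, 0L)

  two_comp <- disease_network(c("a", "b", "c", "d"),
                              data.frame(from = c("a", "c"), to = c("b", "d"),
                                         similarity = c(0.2, 0.2)), 0.05)
  d2 <- shortest_path_distances(two_comp)
  expect_equal(nrow(d2$distances), 2L)
  expect_equal(d2$n_unreachable_pairs, 4L)

  for (seed in 1:4) {
    net <- random_signed_network(12, p_edge = 0.15, seed = seed + 50)
    got <- shortest_path_distances(net)
    D <- oracle_distances(net)
    idx <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
    expect_equal(nrow(got$distances), nrow(idx))
    for (r in seq_len(nrow(got$distances))) {
      expect_equal(got$distances$distance[r],
                   unname(D[got$distances$from[r], got$distances$to[r]]))
    }
  }
})

test_that("intra/inter distance test follows the pooled-variance Student's t", {
  fake <- list(distances = data.frame(from = c("a1", "b1", "a1", "a2"),
                                      to = c("a2", "b2", "b1", "b2"),
                                      distance = c(2L, 2L, 2L, 2L)),
               n_unreachable_pairs = 0L)
  cm <- class_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  res <- intra_inter_distance_test(fake, cm)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  fake2 <- fake
  fake2$distances$distance <- c(1L, 1L, 3L, 3L)  # intra {1,1}, inter {3,3}
  res2 <- intra_inter_distance_test(fake2, cm)
  expect_lt(res2$mean_intra, res2$mean_inter)
  expect_equal(res2$p, 0)          # degenerate zero-variance rule
  expect_equal(res2$t, -Inf)

  # against stats::t.test with var.equal on a non-degenerate fixture
  set.seed(2)
  fake3 <- list(distances = data.frame(
    from = c(rep("a1", 4), rep("b1", 4)),
    to = rep(c("a2", "b2"), 4),
    distance = sample(1:4, 8, TRUE)), n_unreachable_pairs = 0L)
  res3 <- intra_inter_distance_test(fake3, cm)
  cls_f <- c(rep("A", 4), rep("B", 4))
  cls_t <- rep(c("A", "B"), 4)
  intra <- fake3$distances$distance[cls_f == cls_t]
  inter <- fake3$distances$distance[cls_f != cls_t]
  ref <- t.test(intra, inter, var.equal = TRUE)
  expect_equal(res3$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res3$p, ref$p.value, tolerance = 1e-12)
})

test_that("link-sign contingency counts every edge once", {
  tri <- disease_network(c("a", "b", "c"),
                         data.frame(from = c("a", "a", "b"),
                                    to = c("b", "c", "c"),
                                    similarity = c(0.2, 0.3, 0.4)), 0.05)
  cm <- class_map(c("a", "b", "c"), c("X", "X", "X"))
  tab <- link_sign_contingency(tri, cm)
  expect_equal(unname(tab), matrix(c(3L, 0L, 0L, 0L), 2))

  mixed <- disease_network(c("a", "b", "c", "d"),
                           data.frame(from = c("a", "a", "c"),
                                      to = c("b", "c", "d"),
                                      similarity = c(0.2, 0.3, -0.4)), 0.05)
  cm2 <- class_map(c("a", "b", "c", "d"), c("X", "X", "X", "Y"))
  tab2 <- link_sign_contingency(mixed, cm2)
  expect_equal(unname(tab2), matrix(c(2L, 0L, 0L, 1L), 2))

  for (seed in 1:3) {
    net <- random_signed_network(10, seed = seed)
    cmr <- class_map(net$nodes, sample(c("A", "B", "C"), 10, TRUE))
    expect_equal(sum(link_sign_contingency(net, cmr)), nrow(net$edges))
  }
})

test_that("class-pair contingency ignores edges outside the two classes", {
  net <- disease_network(c("a1", "a2", "b1", "c1"),
                         data.frame(from = c("a1", "a1", "b1"),
                                    to = c("a2", "b1", "c1"),
                                    similarity = c(0.2, -0.3, 0.5)), 0.05)
  cm <- class_map(c("a1", "a2", "b1", "c1"), c("A", "A", "B", "C"))
  tab <- class_pair_contingency(net, cm, "A", "B")
  expect_equal(unname(tab), matrix(c(1L, 0L, 0L, 1L), 2))
  # no cross links between A and C -> inter column all zero
  tabAC <- class_pair_contingency(net, cm, "A", "C")
  expect_equal(unname(tabAC[, "inter"]), c(0L, 0L))
  expect_error(class_pair_contingency(net, cm, "A", "Z"), "unknown class")

  # brute-force edge classification on a random fixture
  rnet <- random_signed_network(12, seed = 5)
  rcm <- class_map(rnet$nodes,
                   rep(c("A", "B", "C"), length.out = 12))
  got <- class_pair_contingency(rnet, rcm, "A", "B")
  cls <- disease_classes(rcm, rnet$nodes)
  ref <- matrix(0L, 2, 2)
  for (r in seq_len(nrow(rnet$edges))) {
    cf <- cls[rnet$edges$from[r]]; ct <- cls[rnet$edges$to[r]]
    if (!all(c(cf, ct) %in% c("A", "B"))) next
    row <- if (rnet$edges$sign[r] == 1L) 1L else 2L
    col <- if (cf == ct) 1L else 2L
    ref[row, col] <- ref[row, col] + 1L
  }
  expect_equal(unname(got), ref)
})

test_that("fisher test matches enumeration, the R reference, and worked
           examples", {
  expect_equal(fisher_exact_2x2(matrix(c(1L, 0L, 0L, 1L), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(2L, 0L, 0L, 2L), 2))$p, 1 / 3)
  expect_true(fisher_exact_2x2(matrix(c(0L, 0L, 3L, 2L), 2))$degenerate)
  expect_equal(fisher_exact_2x2(matrix(c(0L, 0L, 3L, 2L), 2))$p, 1)

  set.seed(9)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    got <- fisher_exact_2x2(tab)$p
    expect_equal(got, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                      tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(got, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # odds-ratio conventions
  expect_equal(fisher_exact_2x2(matrix(c(2L, 1L, 1L, 2L), 2))$odds_ratio, 4)
  expect_identical(fisher_exact_2x2(matrix(c(2L, 0L, 1L, 2L), 2))$odds_ratio,
                   Inf)
})

test_that("triangle census classifies sign multisets by the even-negative
           rule", {
  mk <- function(s1, s2, s3) {
    disease_network(c("a", "b", "c"),
                    data.frame(from = c("a", "a", "b"),
                               to = c("b", "c", "c"),
                               similarity = 0.2 * c(s1, s2, s3)), 0.05)
  }
  expect_true(enumerate_triangles(mk(1, 1, 1))$triangles$coherent)
  expect_false(enumerate_triangles(mk(1, 1, -1))$triangles$coherent)
  expect_true(enumerate_triangles(mk(1, -1, -1))$triangles$coherent)
  expect_false(enumerate_triangles(mk(-1, -1, -1))$triangles$coherent)

  # all-positive K4: choose(4,3) coherent triangles
  k4pairs <- t(combn(c("a", "b", "c", "d"), 2))
  k4 <- disease_network(c("a", "b", "c", "d"),
                        data.frame(from = k4pairs[, 1], to = k4pairs[, 2],
                                   similarity = 0.3), 0.05)
  cen <- enumerate_triangles(k4)
  expect_equal(cen$coherent, 4L)
  expect_equal(cen$incoherent, 0L)

  for (seed in 1:6) {
    net <- random_signed_network(12, p_edge = 0.4, seed = seed + 100)
    got <- enumerate_triangles(net)
    ref <- oracle_triangles(net)
    expect_equal(got$total, nrow(ref))
    expect_equal(got$coherent + got$incoherent, got$total)
    if (nrow(ref) > 0) {
      ref <- ref[order(ref$a, ref$b, ref$c), ]
      rownames(ref) <- NULL
      expect_equal(got$triangles, ref)
    }
    expect_equal(unname(got$type_counts),
                 vapply(0:3, function(k) sum(ref$n_negative == k), integer(1)))
  }
})

test_that("coherence randomization is deterministic and respects the
           empirical-p floor", {
  sy <- generate_dataset(generator_config(n_classes = 2, diseases_per_class = 8,
                                          n_mirnas = 60, class_pool_size = 20,
                                          seed = 17))
  a <- coherence_ratio_test(sy$dataset, n_reps = 5, seed = 11)
  b <- coherence_ratio_test(sy$dataset, n_reps = 5, seed = 11)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_gte(a$empirical_p, 1 / 6)
})

test_that("fully planted concordance drives coherent share to 1 with floor p", {
  sy <- generate_dataset(generator_config(
    n_classes = 3, diseases_per_class = 10, n_mirnas = 200,
    class_pool_size = 30, within_class_share = 1, sign_concordance = 1,
    seed = 7))
  res <- coherence_ratio_test(sy$dataset, n_reps = 99, seed = 7)
  expect_equal(res$observed_share, 1)
  expect_equal(res$empirical_p, 1 / 100)
})

test_that("neighbor class composition histograms sum to the degree", {
  net <- disease_network(c("f", "x", "y", "z"),
                         data.frame(from = c("f", "f", "f"),
                                    to = c("x", "y", "z"),
                                    similarity = c(0.2, 0.3, -0.4)), 0.05)
  cm <- class_map(c("f", "x", "y", "z"), c("C", "A", "A", "B"))
  comp <- neighbor_class_composition(net, cm)
  f <- comp$summary[comp$summary$disease == "f", ]
  expect_equal(f$modal_class, "A")
  expect_equal(as.integer(comp$histograms$f), c(2L, 1L))

  iso <- disease_network(c("f", "x", "lonely"),
                         data.frame(from = "f", to = "x", similarity = 0.2),
                         0.05)
  cmi <- class_map(c("f", "x", "lonely"), c("A", "A", "B"))
  comp2 <- neighbor_class_composition(iso, cmi)
  lone <- comp2$summary[comp2$summary$disease == "lonely", ]
  expect_true(is.na(lone$modal_class))
  expect_equal(length(comp2$histograms$lonely), 0L)

  rnet <- random_signed_network(12, seed = 13)
  rcm <- class_map(rnet$nodes, rep(c("A", "B", "C"), length.out = 12))
  comp3 <- neighbor_class_composition(rnet, rcm)
  deg <- degree_summary(rnet)$nodes
  expect_equal(comp3$summary$degree,
               deg$degree[match(comp3$summary$disease, deg$disease)])
})

test_that("degree-preserving rewiring flags a planted neighbor enrichment", {
  set.seed(1)
  nodes <- c("focal", sprintf("t%02d", 1:5), sprintf("x%02d", 1:34))
  cls <- class_map(nodes, c("Other", rep("Target", 5), rep("Other", 34)))
  others <- sprintf("x%02d", 1:34)
  pairs <- t(combn(others, 2))
  keep <- sample(nrow(pairs), 120)
  edges <- data.frame(from = c(rep("focal", 5), pairs[keep, 1]),
                      to = c(sprintf("t%02d", 1:5), pairs[keep, 2]),
                      similarity = runif(125, 0.06, 0.9) *
                        sample(c(1, -1), 125, TRUE))
  net <- disease_network(nodes, edges, 0.05)
  res <- neighbor_enrichment_test(net, cls, "focal", "Target",
                                  n_reps = 99, seed = 7)
  expect_equal(res$observed, 5)
  expect_equal(res$empirical_p, 1 / 100)   # at the add-one floor

  # absent target class: statistic 0, p = 1 under any null
  cls2 <- class_map(nodes, rep("Other", 40))
  res2 <- neighbor_enrichment_test(net, cls2, "focal", "Ghost",
                                   n_reps = 9, seed = 1)
  expect_equal(res2$observed, 0)
  expect_equal(res2$empirical_p, 1)

  iso_net <- disease_network(c(nodes, "isolated"), edges, 0.05)
  cls3 <- class_map(c(nodes, "isolated"), c(rep("Other", 40), "Other"))
  res3 <- neighbor_enrichment_test(iso_net, cls3, "isolated", "Other",
                                   n_reps = 5, seed = 1)
  expect_false(res3$testable)
})

test_that("double edge swaps preserve the degree sequence", {
  for (seed in 1:3) {
    net <- random_signed_network(15, p_edge = 0.3, seed = seed + 40)
    deg_before <- table(factor(c(net$edges$from, net$edges$to),
                               levels = net$nodes))
    set.seed(seed)
    rewired <- mirdisnet:::double_edge_swap(net$edges, 10L * nrow(net$edges))
    deg_after <- table(factor(c(rewired$from, rewired$to),
                              levels = net$nodes))
    expect_identical(deg_before, deg_after)
    # still a simple graph
    keys <- paste(rewired$from, rewired$to)
    expect_false(any(duplicated(keys)))
    expect_false(any(rewired$from == rewired$to))
    # sign multiset travels with the edges
    expect_equal(sort(rewired$sign), sort(net$edges$sign))
  }
})

test_that("neighborhood report ranks by signed similarity and induces the
           focal subnetwork", {
  net <- random_signed_network(12, p_edge = 0.5, seed = 77)
  ids <- net$nodes
  S <- diag(length(ids))
  dimnames(S) <- list(ids, ids)
  for (r in seq_len(nrow(net$edges))) {
    S[net$edges$from[r], net$edges$to[r]] <- net$edges$similarity[r]
    S[net$edges$to[r], net$edges$from[r]] <- net$edges$similarity[r]
  }
  sim <- structure(list(values = S, ids = ids), class = "similarity_matrix")
  focal <- ids[which.max(degree_summary(net)$nodes$degree)]
  rep_ <- disease_neighborhood_report(net, sim, focal, k = 3)
  expect_lte(nrow(rep_$top_similar), 3L)
  expect_equal(rep_$neighbors$similarity, sort(rep_$neighbors$similarity,
                                               decreasing = TRUE))
  sims <- rep_$top_similar$similarity
  expect_true(all(sims > 0))
  opps <- rep_$top_opposite$similarity
  expect_true(all(opps < 0))
  expect_equal(opps, sort(opps))

  # induced subgraph against a brute-force filter
  members <- c(rep_$focal, rep_$neighbors$disease)
  brute <- net$edges[net$edges$from %in% members & net$edges$to %in% members, ]
  brute <- brute[order(brute$from, brute$to), ]
  rownames(brute) <- NULL
  expect_equal(rep_$subnetwork$edges, brute)

  # focal with 3 neighbors and k = 10: no padding
  small <- disease_network(c("f", "p", "q", "r"),
                           data.frame(from = c("f", "f", "f"),
                                      to = c("p", "q", "r"),
                                      similarity = c(0.5, 0.2, -0.3)), 0.05)
  Ss <- diag(4); dimnames(Ss) <- list(c("f", "p", "q", "r"),
                                      c("f", "p", "q", "r"))
  sms <- structure(list(values = Ss, ids = colnames(Ss)),
                   class = "similarity_matrix")
  rp <- disease_neighborhood_report(small, sms, "f", k = 10)
  expect_equal(nrow(rp$neighbors), 3L)
  expect_error(disease_neighborhood_report(small, sms, "ghost"), "not a node")
})
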