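test_that("contact graph matches the exhaustive all-pairs oracle", {
  # A and B 3 Angstrom apart, C isolated
  topo <- toy_topology(rep("CA", 3), rep("C", 3), 0:2)
  fr <- aggtraj_frame(rbind(c(0, 0, 0), c(3, 0, 0), c(50, 50, 50)),
                      c(200, 200, 200), 0)
  g <- build_contact_graph(fr, topo, 4.0)
  expect_equal(g$edges, rbind(c(0L, 1L)), ignore_attr = TRUE)
  g0 <- build_contact_graph(fr, topo, 0.1)
  expect_equal(nrow(g0$edges), 0L)

  for (seed in 1:6) {
    sys <- random_chain_frame(20, atoms_per_chain = 3L,
                              box = c(25, 25, 25), seed = seed)
    g <- build_contact_graph(sys$frame, sys$topology, 4.0)
    expect_equal(g$edges, bf_contact_edges(sys$frame, sys$topology, 4.0),
                 ignore_attr = TRUE)
  }
})

test_that("head-and-list equals union-find components on random graphs", {
  g_empty <- structure(list(n_chains = 3L,
                            edges = matrix(integer(0), ncol = 2)),
                       class = "aggtraj_contact_graph")
  expect_equal(head_and_list_clusters(g_empty)$clusters,
               list(0L, 1L, 2L))
  g_path <- structure(list(n_chains = 3L,
                           edges = rbind(c(0L, 1L), c(1L, 2L))),
                      class = "aggtraj_contact_graph")
  cl <- head_and_list_clusters(g_path)
  expect_equal(cl$clusters, list(0:2))
  expect_equal(cl$sizes, 3L)

  set.seed(99)
  for (k in 1:200) {
    n <- 20L
    p <- runif(1, 0.02, 0.3)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
    keep <- runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    g <- structure(list(n_chains = n, edges = edges),
                   class = "aggtraj_contact_graph")
    got <- head_and_list_clusters(g)
    expect_equal(got$clusters, union_find_components(n, edges))
    expect_equal(sum(got$sizes), n)
    expect_equal(sort(unlist(got$clusters)), 0:(n - 1L))
  }
})

test_that("head-and-list agrees with igraph components", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (k in 1:20) {
    n <- 15L
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
    edges <- pairs[runif(nrow(pairs)) < 0.1, , drop = FALSE]
    g <- structure(list(n_chains = n, edges = edges),
                   class = "aggtraj_contact_graph")
    got <- head_and_list_clusters(g)
    ig <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges) > 0) {
      ig <- igraph::add_edges(ig, as.vector(t(edges + 1L)))
    }
    comp <- igraph::components(ig)$membership
    ref <- unname(lapply(split(seq_len(n) - 1L, comp), sort))
    ref <- ref[order(vapply(ref, min, integer(1)))]
    expect_equal(lapply(got$clusters, as.integer), ref)
  }
})

test_that("cluster time series ranks sizes with deterministic ties", {
  iso <- fake_assignment(as.list(0:19))
  fused <- fake_assignment(list(0:19))
  expect_equal(cluster_timeseries(list(iso, iso), rank = 1), c(1L, 1L))
  expect_equal(cluster_timeseries(list(iso, iso), rank = 2), c(1L, 1L))
  expect_equal(cluster_timeseries(list(fused), rank = 1), 20L)
  expect_equal(cluster_timeseries(list(fused), rank = 2), 0L)
})

test_that("running average is a trailing mean preserving length", {
  expect_equal(running_average(rep(4, 7), 10), rep(4, 7))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(running_average(x, 1), x)
  step <- c(rep(0, 5), rep(10, 5))
  expect_equal(running_average(step, 5),
               c(0, 0, 0, 0, 0, 2, 4, 6, 8, 10))
  expect_error(running_average(numeric(0), 5), "nonempty")
  expect_error(running_average(1:3, 0), ">= 1")
})

test_that("size distribution counts clusters and conserves chains", {
  iso3 <- fake_assignment(as.list(0:2))
  d <- size_distribution(list(iso3, iso3))
  expect_equal(d, data.frame(size = 1L, count = 6L), ignore_attr = TRUE)
  mix <- fake_assignment(list(c(0L, 1L), 2L))
  d2 <- size_distribution(list(mix))
  expect_equal(d2$count[d2$size == 1], 1L)
  expect_equal(d2$count[d2$size == 2], 1L)
  # conservation on a scripted trajectory
  sc <- demo_aggregation_scripts()$competition
  out <- scripted_aggregation_trajectory(sc)
  ass <- cluster_frames(out$trajectory)
  d3 <- size_distribution(ass)
  expect_equal(sum(d3$size * d3$count), sc$n_chains * sc$n_frames)
  # pooling over runs adds frames
  d4 <- size_distribution(list(ass, ass))
  expect_equal(attr(d4, "n_frames"), 2L * length(ass))
  expect_equal(sum(d4$size * d4$count), 2L * sc$n_chains * sc$n_frames)
})

test_that("transition tracking counts overlap events and skips self-events", {
  # {1},{1} -> {2}: two events 1 -> 2
  a <- fake_assignment(list(0L, 1L))
  b <- fake_assignment(list(c(0L, 1L)))
  net <- track_transitions(list(a, b))
  expect_equal(net$edges, data.frame(from = 1L, to = 2L, count = 2L))
  expect_equal(net$nodes$weight[net$nodes$size == 1], 2L)
  expect_equal(net$nodes$weight[net$nodes$size == 2], 2L)

  # {3} -> {2},{1}: events 3->2 and 3->1
  c3 <- fake_assignment(list(0:2))
  s21 <- fake_assignment(list(c(0L, 1L), 2L))
  net2 <- track_transitions(list(c3, s21))
  expect_equal(net2$edges,
               data.frame(from = c(3L, 3L), to = c(1L, 2L),
                          count = c(1L, 1L)))

  # static partitions produce no events
  net3 <- track_transitions(rep(list(s21), 100))
  expect_equal(nrow(net3$edges), 0L)

  # same-size exchange counts (membership changed), conservation holds
  x1 <- fake_assignment(list(c(0L, 1L), c(2L, 3L)))
  x2 <- fake_assignment(list(c(0L, 2L), c(1L, 3L)))
  net4 <- track_transitions(list(x1, x2))
  expect_equal(net4$edges, data.frame(from = 2L, to = 2L, count = 4L))
  expect_error(track_transitions(list(x1)), "at least 2")
})

test_that("top-k edge pruning is deterministic under ties", {
  ed <- data.frame(from = c(1L, 1L, 2L, 3L), to = c(2L, 3L, 3L, 1L),
                   count = c(5L, 2L, 2L, 7L))
  net <- aggtraj:::new_transition_network(aggtraj:::node_weights(ed), ed)
  expect_identical(top_k_edges(net, 40), net)
  pruned <- top_k_edges(net, 3)
  expect_equal(nrow(pruned$edges), 3L)
  # tie between (1,3) and (2,3) at count 2 resolves to (1,3)
  expect_true(any(pruned$edges$from == 1 & pruned$edges$to == 3))
  expect_false(any(pruned$edges$from == 2 & pruned$edges$to == 3))
  # node weights recomputed on kept edges only
  expect_equal(pruned$nodes$weight[pruned$nodes$size == 2],
               sum(pruned$edges$count[pruned$edges$from == 2 |
                                        pruned$edges$to == 2]))
})
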