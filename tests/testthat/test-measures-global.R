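edgeless_sin <- function(n = 30) {
  ev <- data.frame(fly_a = character(), fly_b = character(),
                   duration_s = numeric())
  build_sin(ev, roster = sprintf("f%02d", seq_len(n)))
}

test_that("path-length measures match hand values and component rule", {
  p3 <- graph_fixture("path3")
  expect_equal(avg_shortest_path(p3), 4 / 3, tolerance = 1e-12)
  expect_equal(net_diameter(p3), 2)
  expect_equal(global_efficiency(p3), 5 / 6, tolerance = 1e-12)
  expect_equal(avg_shortest_path(graph_fixture("k5")), 1)
  expect_equal(net_diameter(graph_fixture("cycle6")), 3)
  expect_equal(net_diameter(graph_fixture("k5")), 1)
  # two disjoint triangles: largest component only
  expect_equal(avg_shortest_path(graph_fixture("two_triangles")), 1)
  expect_true(is.na(avg_shortest_path(edgeless_sin())))
  expect_true(is.na(net_diameter(edgeless_sin())))
})

test_that("clustering, transitivity and density match hand values", {
  k3 <- graph_fixture("k3")
  expect_equal(avg_clustering(k3), 1)
  expect_equal(net_transitivity(k3), 1)
  p3 <- graph_fixture("path3")
  expect_equal(avg_clustering(p3), 0)
  expect_equal(net_transitivity(p3), 0)
  expect_equal(net_transitivity(graph_fixture("star5")), 0)
  expect_equal(net_density(graph_fixture("k5")), 1)
  expect_equal(net_density(edgeless_sin()), 0)
  expect_equal(net_density(graph_fixture("star5")), 0.4)
})

test_that("heterogeneity and assortativity match closed forms", {
  expect_equal(degree_heterogeneity(graph_fixture("star5")), 0.75,
               tolerance = 1e-12)
  expect_equal(degree_heterogeneity(graph_fixture("k5")), 0)
  expect_equal(degree_heterogeneity(graph_fixture("cycle6")), 0)
  expect_true(is.na(degree_heterogeneity(edgeless_sin())))
  # single edge + isolated node, by the direct formula
  ev <- data.frame(fly_a = "a", fly_b = "b", duration_s = 1)
  s <- build_sin(ev, roster = c("a", "b", "c"))
  expect_equal(degree_heterogeneity(s),
               bf_heterogeneity(sin_adjacency(s)), tolerance = 1e-12)
  expect_equal(net_assortativity(graph_fixture("star5")), -1,
               tolerance = 1e-9)
  expect_true(is.na(net_assortativity(graph_fixture("cycle6"))))
  expect_true(is.na(net_assortativity(edgeless_sin())))
})

test_that("global measures equal brute-force oracles on random graphs", {
  for (i in 1:40) {
    s <- graph_fixture("random", n = sample(4:8, 1), p = stats::runif(1, .2, .8),
                       seed = 8000 + i)
    A <- sin_adjacency(s)
    comp <- bf_largest_component(A)
    expect_equal(net_density(s), sum(A > 0) / (nrow(A) * (nrow(A) - 1)),
                 tolerance = 1e-12)
    expect_equal(net_transitivity(s), bf_transitivity(A), tolerance = 1e-9)
    if (length(comp) >= 2) {
      Ac <- A[comp, comp]
      expect_equal(avg_shortest_path(s), bf_avg_path(Ac), tolerance = 1e-9)
      expect_equal(net_diameter(s), max(bf_distances(Ac)), tolerance = 1e-9)
      expect_equal(global_efficiency(s), bf_efficiency(Ac), tolerance = 1e-9)
    }
    r <- net_assortativity(s)
    r_want <- if (sum(A) > 0) bf_assortativity(A) else NA_real_
    if (is.na(r_want)) expect_true(is.na(r))
    else expect_equal(r, r_want, tolerance = 1e-9)
  }
})

test_that("efficiency and path length hit 1 exactly on complete components", {
  expect_equal(global_efficiency(graph_fixture("k5")), 1)
  expect_equal(avg_shortest_path(graph_fixture("two_triangles")), 1)
  s <- graph_fixture("random", n = 7, p = 0.5, seed = 3)
  if (!is.na(avg_shortest_path(s)) && avg_shortest_path(s) > 1)
    expect_lt(global_efficiency(s), 1)
})

test_that("adding an edge inside the largest component never increases L", {
  for (i in 1:10) {
    s <- graph_fixture("random", n = 7, p = 0.35, seed = 8100 + i)
    A <- sin_adjacency(s)
    comp <- bf_largest_component(A)
    if (length(comp) < 3) next
    ids <- rownames(A)[comp]
    free <- Filter(function(p) A[p[1], p[2]] == 0,
                   utils::combn(ids, 2, simplify = FALSE))
    if (!length(free)) next
    e <- sin_edges(s)
    ev <- rbind(data.frame(fly_a = e$fly_a, fly_b = e$fly_b,
                           duration_s = e$w_duration),
                data.frame(fly_a = free[[1]][1], fly_b = free[[1]][2],
                           duration_s = 1))
    s2 <- build_sin(ev, roster = sin_nodes(s))
    expect_lte(avg_shortest_path(s2), avg_shortest_path(s) + 1e-12)
  }
})

test_that("the global summary row is complete and internally consistent", {
  ev <- data.frame(fly_a = c("A", "A"), fly_b = c("B", "C"),
                   duration_s = c(3, 0.6))
  s <- build_sin(ev, roster = c("A", "B", "C", "D"))
  g <- global_summary(s)
  expect_equal(g$N, 4)
  expect_equal(g$K, 2)
  expect_equal(g$avg_degree, 1)
  expect_equal(g$avg_links_per_node, 0.5)
  expect_equal(g$density, 1 / 3, tolerance = 1e-12)
  expect_equal(g$avg_strength_duration, 2 * sum(ev$duration_s) / 4)
  empty <- global_summary(edgeless_sin())
  expect_equal(empty$density, 0)
  expect_true(is.na(empty$L))
  k3 <- global_summary(graph_fixture("k3"))
  expect_equal(k3$transitivity, 1)
  expect_equal(k3$E_glob, 1)
  expect_equal(k3$avg_clustering, 1)
})
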