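test_that("degree centrality matches hand values on canonical graphs", {
  star <- graph_fixture("star5")
  dc <- degree_centrality(star)
  expect_equal(unname(dc["H"]), 1)
  expect_equal(unname(dc[c("L1", "L2", "L3", "L4")]), rep(0.25, 4))
  expect_equal(unname(degree_centrality(graph_fixture("k3"))), rep(1, 3))
  iso <- build_sin(structure(data.frame(fly_a = character(),
                                        fly_b = character(),
                                        duration_s = numeric()), fps = 24),
                   roster = sprintf("f%d", 1:30))
  expect_equal(unname(degree_centrality(iso)), rep(0, 30))
})

test_that("node strength sums the chosen weight", {
  ev <- data.frame(fly_a = c("A", "A", "A"), fly_b = c("B", "B", "C"),
                   start_frame = c(0L, 50L, 0L), end_frame = c(24L, 98L, 14L),
                   duration_s = c(1.5, 2.5, 0.6))
  attr(ev, "fps") <- 24
  s <- build_sin(ev, roster = c("A", "B", "C", "D"))
  expect_equal(unname(node_strength(s, "duration")["A"]), 4.6)
  expect_equal(unname(node_strength(s, "count")["A"]), 3)
  expect_equal(unname(node_strength(s, "duration")["D"]), 0)
  expect_error(node_strength(s, "frames"))
})

test_that("closeness matches hand values and the component convention", {
  cc <- closeness_centrality(graph_fixture("path3"))
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3))
  expect_equal(unname(closeness_centrality(graph_fixture("k5"))), rep(1, 5))
  cc2 <- closeness_centrality(graph_fixture("k5_plus_isolates"))
  expect_equal(unname(cc2[LETTERS[1:5]]), rep(1, 5))
  expect_equal(unname(cc2[paste0("iso", 1:5)]), rep(0, 5))
})

test_that("betweenness matches hand values and the path-count oracle", {
  bc <- betweenness_centrality(graph_fixture("path3"))
  expect_equal(unname(bc), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(graph_fixture("k5"))), rep(0, 5))
  # two triangles sharing a vertex: oracle value for the cut vertex
  ev <- data.frame(
    fly_a = c("a", "a", "b", "v", "v", "c"),
    fly_b = c("b", "v", "v", "c", "d", "d"),
    duration_s = 1)
  s <- build_sin(ev, roster = c("a", "b", "c", "d", "v"))
  A <- sin_adjacency(s)
  expect_equal(unname(betweenness_centrality(s)[rownames(A)]),
               bf_betweenness(A), tolerance = 1e-9)
})

test_that("eigenvector centrality is the unit-norm principal vector", {
  ec <- eigenvector_centrality(graph_fixture("k3"))
  expect_equal(unname(ec), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  ec_star <- eigenvector_centrality(graph_fixture("star5"))
  expect_gt(ec_star[["H"]], ec_star[["L1"]])
  expect_equal(stats::sd(ec_star[c("L1", "L2", "L3", "L4")]), 0)
  expect_equal(sum(ec_star^2), 1, tolerance = 1e-8)
  ec2 <- eigenvector_centrality(graph_fixture("k5_plus_isolates"))
  expect_equal(unname(ec2[paste0("iso", 1:5)]), rep(0, 5))
})

test_that("information centrality matches the effective-resistance oracle", {
  ic <- information_centrality(graph_fixture("k3"))
  expect_equal(unname(ic), rep(0.75, 3), tolerance = 1e-9)
  star <- graph_fixture("star5")
  A <- sin_adjacency(star)
  want <- vapply(seq_len(nrow(A)), function(i)
    1 / sum(vapply(setdiff(seq_len(nrow(A)), i), function(j)
      bf_effective_resistance(A, i, j), numeric(1))), numeric(1))
  expect_equal(unname(information_centrality(star)[rownames(A)]), want,
               tolerance = 1e-9)
  expect_gt(ic_h <- information_centrality(star)[["H"]],
            information_centrality(star)[["L1"]])
  mixed <- graph_fixture("k5_plus_isolates")
  expect_equal(unname(information_centrality(mixed)[paste0("iso", 1:5)]),
               rep(0, 5))
})

test_that("local clustering handles triangles, paths, hubs and weights", {
  expect_equal(unname(local_clustering(graph_fixture("k3"))), rep(1, 3))
  expect_equal(unname(local_clustering(graph_fixture("path3"))["B"]), 0)
  expect_equal(unname(local_clustering(graph_fixture("star5"))["H"]), 0)
  # unit weights: weighted variants coincide with the unweighted value
  tt <- graph_fixture("two_triangles")
  expect_equal(local_clustering(tt, "duration"), local_clustering(tt, "none"),
               tolerance = 1e-12)
})

test_that("local measures equal brute-force oracles on random graphs", {
  for (i in 1:40) {
    s <- graph_fixture("random", n = sample(4:8, 1), p = stats::runif(1, .2, .7),
                       seed = 5000 + i)
    A <- sin_adjacency(s)
    comp <- bf_largest_component(A)
    if (length(comp) < 3) next
    Ac <- A[comp, comp]
    ids <- rownames(A)
    got_cc <- closeness_centrality(s)[ids]
    got_bc <- betweenness_centrality(s)[ids]
    want_cc <- want_bc <- stats::setNames(rep(0, nrow(A)), ids)
    want_cc[comp] <- bf_closeness(Ac)
    want_bc[comp] <- bf_betweenness(Ac)
    expect_equal(unname(got_cc), unname(want_cc), tolerance = 1e-9)
    expect_equal(unname(got_bc), unname(want_bc), tolerance = 1e-9)
    expect_equal(unname(degree_centrality(s)[ids]),
                 unname(rowSums(A > 0) / (nrow(A) - 1)), tolerance = 1e-12)
    expect_equal(unname(local_clustering(s)[ids]), bf_local_clustering(A),
                 tolerance = 1e-9)
  }
})

test_that("distance measures are invariant under node relabeling", {
  s <- graph_fixture("random", n = 7, p = 0.4, seed = 99)
  perm_ids <- rev(sin_nodes(s))
  e <- sin_edges(s)
  relabel <- stats::setNames(perm_ids, sin_nodes(s))
  ev <- data.frame(fly_a = unname(relabel[e$fly_a]),
                   fly_b = unname(relabel[e$fly_b]), duration_s = e$w_duration)
  s2 <- build_sin(ev, roster = perm_ids)
  for (fn in list(closeness_centrality, betweenness_centrality)) {
    v1 <- fn(s)
    v2 <- fn(s2)
    expect_equal(unname(v2[unname(relabel[names(v1)])]), unname(v1),
                 tolerance = 1e-9)
  }
})

test_that("adding an edge never decreases degree centrality", {
  for (i in 1:10) {
    s <- graph_fixture("random", n = 6, p = 0.3, seed = 6000 + i)
    e <- sin_edges(s)
    ids <- sin_nodes(s)
    all_pairs <- utils::combn(ids, 2, simplify = FALSE)
    present <- paste(e$fly_a, e$fly_b)
    free <- Filter(function(p) !paste(p[1], p[2]) %in% present, all_pairs)
    if (!length(free)) next
    add <- free[[1]]
    ev <- rbind(data.frame(fly_a = e$fly_a, fly_b = e$fly_b,
                           duration_s = e$w_duration),
                data.frame(fly_a = add[1], fly_b = add[2], duration_s = 1))
    s2 <- build_sin(ev, roster = ids)
    expect_true(all(degree_centrality(s2)[ids] >= degree_centrality(s)[ids]))
  }
})

test_that("vertex-transitive graphs give constant measures", {
  for (name in c("k5", "cycle6")) {
    s <- graph_fixture(name)
    for (fn in list(degree_centrality, closeness_centrality,
                    betweenness_centrality, eigenvector_centrality,
                    information_centrality, local_clustering)) {
      v <- fn(s)
      expect_lt(max(v) - min(v), 1e-8)
    }
  }
})

test_that("the local measure table is total and carries summaries", {
  s <- graph_fixture("k3")
  lt <- local_measure_table(s)
  expect_identical(names(lt$per_node),
                   c("fly_id", "dc", "s_count", "s_duration", "cc", "bc",
                     "ec", "ic", "C", "C_wcount", "C_wduration"))
  expect_equal(lt$per_node$dc, rep(1, 3))
  expect_equal(lt$per_node$C, rep(1, 3))
  expect_equal(unname(lt$median["cc"]), 1)
  s_rand <- graph_fixture("random", n = 8, p = 0.3, seed = 7)
  expect_equal(nrow(local_measure_table(s_rand)$per_node), 8L)
})
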