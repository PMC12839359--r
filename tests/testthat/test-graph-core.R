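test_that("network construction collapses self-loops and duplicates, keeps provenance union", {
  expect_message(
    net <- ppi_network(data.frame(id_a = c("A", "B", "A", "C"),
                                  id_b = c("B", "A", "A", "D"),
                                  provenance = c("intact", "biogrid", "x", "string"))),
    "collapsed 1 self-loop\\(s\\) and 1 duplicate edge\\(s\\)")
  expect_equal(n_nodes(net), 4)
  expect_equal(n_edges(net), 2)
  ab <- net$edges[net$edges$id_a == "A" & net$edges$id_b == "B", ]
  expect_equal(ab$provenance, "biogrid;intact")
  expect_error(ppi_network(data.frame(id_a = "", id_b = "B")), "non-empty")
})

test_that("connected components partition the nodes", {
  expect_equal(connected_components(path_net(c("A", "B", "C")))$sizes, 3L)

  edgeless <- ppi_network(nodes = c("A", "B"))
  cc <- connected_components(edgeless)
  expect_equal(cc$sizes, c(1L, 1L))

  # two triangles plus an isolated node -> 3 components, sizes 3, 3, 1
  tri2 <- ppi_network(rbind(
    data.frame(id_a = c("A1", "A1", "A2"), id_b = c("A2", "A3", "A3")),
    data.frame(id_a = c("B1", "B1", "B2"), id_b = c("B2", "B3", "B3"))
  ), nodes = "Z")
  cc <- connected_components(tri2)
  expect_equal(sort(cc$sizes, decreasing = TRUE), c(3L, 3L, 1L))
  expect_equal(sum(cc$sizes), n_nodes(tri2))
  # membership: two nodes share a component iff connected
  expect_equal(cc$membership[["A1"]], cc$membership[["A3"]])
  expect_false(cc$membership[["A1"]] == cc$membership[["B1"]])

  expect_equal(length(connected_components(ppi_network())$sizes), 0)
})

test_that("betweenness matches hand-computed toy values", {
  expect_equal(betweenness_centrality(path_net(c("A", "B", "C"))),
               c(A = 0, B = 1, C = 0))
  expect_equal(betweenness_centrality(star_net("X", c("L1", "L2", "L3")))[["X"]], 3)
  # 4-cycle: each opposite pair has 2 shortest paths, each intermediate carries 1/2
  cyc <- ppi_network(data.frame(id_a = c("A", "B", "C", "D"),
                                id_b = c("B", "C", "D", "A")), quiet = TRUE)
  expect_equal(unname(betweenness_centrality(cyc)), rep(0.5, 4))
})

test_that("closeness follows the component-restricted formula", {
  p3 <- path_net(c("A", "B", "C"))
  expect_equal(closeness_centrality(p3, "B"), c(B = 1.0))
  expect_equal(closeness_centrality(p3, "A"), c(A = 2 / 3))
  # complete graph: closeness 1 everywhere
  k4 <- ppi_network(data.frame(id_a = c("A", "A", "A", "B", "B", "C"),
                               id_b = c("B", "C", "D", "C", "D", "D")),
                    quiet = TRUE)
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  # isolated node -> 0, and the sum never leaves the component
  two <- ppi_network(data.frame(id_a = "A", id_b = "B"), nodes = "Z")
  expect_equal(closeness_centrality(two, "Z"), c(Z = 0))
  expect_equal(closeness_centrality(two, "A"), c(A = 1))
  expect_error(closeness_centrality(two, "missing"), "unknown node")
})

test_that("closeness on a 6-node star-plus-pendant-chain tree matches brute force", {
  # star X-(A,B,C) with chain X-D-E
  tr <- ppi_network(data.frame(id_a = c("X", "X", "X", "X", "D"),
                               id_b = c("A", "B", "C", "D", "E")), quiet = TRUE)
  for (v in tr$nodes) {
    expect_equal(closeness_centrality(tr, v)[[v]], brute_closeness(tr, v),
                 tolerance = 1e-12, label = paste("closeness", v))
  }
  # X: distances 1,1,1,1,2 -> 5/6
  expect_equal(closeness_centrality(tr, "X")[["X"]], 5 / 6)
})

test_that("topology summary averages over connected pairs only", {
  s <- topology_summary(path_net(c("A", "B", "C")))
  expect_equal(s$avg_path_length, 4 / 3)
  expect_equal(s[, c("n_nodes", "n_edges", "n_components", "lcc_size")],
               data.frame(n_nodes = 3L, n_edges = 2L, n_components = 1L,
                          lcc_size = 3L))
  # two disjoint edges: the two cross pairs are excluded
  de <- ppi_network(data.frame(id_a = c("A", "C"), id_b = c("B", "D")))
  expect_equal(topology_summary(de)$avg_path_length, 1.0)
  # no connected pair -> undefined, never 0
  expect_true(is.na(topology_summary(ppi_network(nodes = c("A", "B")))$avg_path_length))
  expect_true(is.na(topology_summary(ppi_network())$avg_path_length))
})

test_that("efficient metrics agree with brute force and igraph on random graphs", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    net <- random_net(n, stats::runif(1, 0.15, 0.7))
    bt <- betweenness_centrality(net)
    expect_equal(bt, brute_betweenness(net), tolerance = 1e-9)
    s <- topology_summary(net)
    bs <- brute_summary(net)
    expect_equal(s$n_components, bs$n_components)
    expect_equal(s$lcc_size, bs$lcc_size)
    expect_equal(s$avg_path_length, bs$avg_path_length, tolerance = 1e-9)
  }
  # cross-check against an independent library implementation
  set.seed(72)
  for (rep in 1:5) {
    net <- random_net(10, 0.35)
    g <- as_igraph(net)
    expect_equal(unname(betweenness_centrality(net)[igraph::V(g)$name]),
                 unname(igraph::betweenness(g, directed = FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("tree betweenness equals the crossing-pair count from subtree sizes", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- random_tree(sample(5:12, 1))
    bt <- betweenness_centrality(tr)
    n <- n_nodes(tr)
    for (v in tr$nodes) {
      # unique paths: Cb(v) = pairs of nodes in different branches around v
      branches <- connected_components(remove_node(tr, v))$sizes
      crossing <- (sum(branches)^2 - sum(branches^2)) / 2
      expect_equal(bt[[v]], crossing, label = paste("tree Cb", v))
    }
  }
})

test_that("total betweenness equals the sum of (path length - 1) over connected pairs", {
  set.seed(9)
  for (rep in 1:15) {
    net <- random_net(sample(5:11, 1), stats::runif(1, 0.2, 0.6))
    D <- brute_distances(net)
    off <- is.finite(D) & upper.tri(D)
    expect_equal(sum(betweenness_centrality(net)), sum(D[off] - 1),
                 tolerance = 1e-9)
  }
})

test_that("normalized closeness attains 1 exactly at the argmax nodes", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_net(sample(5:12, 1), 0.4)
    rep_df <- centrality_report(net)
    expect_equal(max(rep_df$closeness_norm), 1)
    argmax <- rep_df$closeness_raw == max(rep_df$closeness_raw)
    expect_equal(rep_df$closeness_norm == 1, argmax)
  }
})

test_that("centrality report is deterministic, sorted and degree-consistent", {
  net <- barbell_net()
  r1 <- centrality_report(net)
  expect_equal(r1$node, sort(net$nodes))
  expect_identical(r1, centrality_report(net))
  expect_equal(r1$degree, unname(node_degree(net)[r1$node]))
  expect_true(all(r1$betweenness[r1$degree <= 1] == 0))
})

test_that("ego networks label rings and induce the right subgraph", {
  p5 <- path_net(c("A", "B", "C", "D", "E"))
  e0 <- ego_network(p5, "C", 0)
  expect_equal(e0$nodes, "C")
  expect_equal(e0$node_attrs$ring, 0L)

  st <- star_net("X", c("L1", "L2", "L3"))
  e1 <- ego_network(st, "X", 1)
  expect_equal(sort(e1$nodes), sort(st$nodes))
  expect_equal(e1$node_attrs[c("L1", "L2", "L3"), "ring"], rep(1L, 3))

  e2 <- ego_network(p5, "A", 2)
  expect_equal(e2$nodes, c("A", "B", "C"))
  expect_equal(e2$node_attrs[c("A", "B", "C"), "ring"], 0:2)
  expect_equal(n_edges(e2), 2)   # C-D is outside the induced subgraph
  expect_error(ego_network(p5, "nope"), "unknown node")
})

test_that("ego network at radius >= diameter returns the whole component", {
  set.seed(21)
  for (rep in 1:8) {
    net <- random_net(sample(6:12, 1), 0.3)
    cc <- connected_components(net)
    v <- net$nodes[1]
    comp <- cc$components[[cc$membership[[v]]]]
    D <- brute_distances(net)
    diam <- max(D[v, is.finite(D[v, ])])
    expect_equal(sort(ego_network(net, v, diam)$nodes), sort(comp))
  }
})

test_that("graphml round-trips through igraph with attributes", {
  net <- ego_network(path_net(c("A", "B", "C", "D")), "A", 2)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_true("ring" %in% igraph::vertex_attr_names(g))
})
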