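test_that("edge-list reading simplifies duplicates, reversals and self-loops", {
  f <- withr::local_tempfile(lines = c("# comment", "A\tB", "B\tC"))
  net <- read_edge_list(f)
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)

  f2 <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tB"))
  net2 <- read_edge_list(f2)
  expect_equal(n_nodes(net2), 2L)
  expect_equal(n_edges(net2), 1L)

  # 100 random lines incl. self-loops: edge count = distinct non-loop pairs
  withr::with_seed(7, {
    a <- sample(LETTERS[1:8], 100, replace = TRUE)
    b <- sample(LETTERS[1:8], 100, replace = TRUE)
    loop <- sample(100, 10)
    b[loop] <- a[loop]
  })
  f3 <- withr::local_tempfile(lines = paste(a, b, sep = "\t"))
  expect_message(net3 <- read_edge_list(f3), "self-loop")
  keys <- unique(ifelse(a < b, paste(a, b), paste(b, a))[a != b])
  expect_equal(n_edges(net3), length(keys))
  expect_setequal(paste(net3$edges[, 1], net3$edges[, 2]), keys)
})

test_that("edge-list errors: malformed lines and empty input", {
  f <- withr::local_tempfile(lines = c("A\tB", "C"))
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile(lines = c("# only a comment"))
  expect_error(read_edge_list(f2), "empty")
})

test_that("write -> read round-trips to an identical network", {
  g <- random_graph(12, 0.3, seed = 5)
  net <- int_edges_to_net(g$n, g$edges)
  f <- withr::local_tempfile()
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes, sort(unique(as.character(net$edges))))
})

test_that("node topology on hand-checked graphs", {
  path3 <- network_new(rbind(c("A", "B"), c("B", "C")))
  tp <- node_topology(path3)
  expect_equal(tp$avg_shortest_path[tp$node == "A"], 1.5)
  expect_equal(tp$betweenness[tp$node == "B"], 1.0)
  expect_equal(tp$betweenness[tp$node == "A"], 0)

  star <- network_new(cbind("c", paste0("l", 1:5)))
  ts <- node_topology(star)
  expect_equal(ts$avg_shortest_path[ts$node == "c"], 1.0)
  expect_equal(ts$betweenness[ts$node == "c"], 1.0)
  expect_equal(ts$betweenness[ts$node != "c"], rep(0, 5))
  expect_equal(ts$avg_shortest_path[ts$node != "c"], rep(1.8, 5))
})

test_that("betweenness and path lengths match the exhaustive oracle on random graphs", {
  sizes <- rep(c(5, 8, 12, 16, 20, 25), 5)
  for (i in 1:30) {
    g <- random_graph(n = sizes[i], p_edge = 0.2, seed = 1000 + i)
    net <- int_edges_to_net(g$n, g$edges)
    tp <- node_topology(net)
    ids <- sprintf("n%02d", seq_len(g$n))
    tp <- tp[match(ids, tp$node), ]
    expect_equal(tp$betweenness, oracle_betweenness(g$n, g$edges),
                 tolerance = 1e-12)
    expect_equal(tp$avg_shortest_path, oracle_avg_path(g$n, g$edges),
                 tolerance = 1e-12)
  }
})

test_that("tree betweenness sums to the enumerated interior pair count", {
  # random tree on 12 nodes
  withr::with_seed(42, {
    parent <- c(NA, vapply(2:12, function(v) sample(v - 1, 1), integer(1)))
  })
  edges <- cbind(2:12, parent[2:12])
  net <- int_edges_to_net(12, edges)
  tp <- node_topology(net)
  raw_sum <- sum(tp$betweenness) * (12 - 1) * (12 - 2) / 2
  # enumeration: in a tree every pair has one path; count interior memberships
  adj <- oracle_adj(12, edges)
  dist <- vapply(1:12, function(s) oracle_bfs(adj, s, 12)$dist, numeric(12))
  cnt <- 0
  for (s in 1:11) for (t in (s + 1):12) for (v in 1:12) {
    if (v != s && v != t && dist[v, s] + dist[t, v] == dist[t, s]) cnt <- cnt + 1
  }
  expect_equal(raw_sum, cnt)
})

test_that("topology is invariant under node relabeling", {
  g <- random_graph(15, 0.25, seed = 77)
  ids <- sprintf("n%02d", seq_len(g$n))
  withr::with_seed(8, perm <- sample(g$n))
  relabeled <- sprintf("m%02d", perm)
  net1 <- int_edges_to_net(g$n, g$edges)
  net2 <- network_new(cbind(relabeled[g$edges[, 1]], relabeled[g$edges[, 2]]),
                      nodes = relabeled)
  t1 <- node_topology(net1)
  t2 <- node_topology(net2)
  m <- match(relabeled, t2$node)
  expect_equal(t2$avg_shortest_path[m], t1$avg_shortest_path[match(ids, t1$node)])
  expect_equal(t2$betweenness[m], t1$betweenness[match(ids, t1$node)])
})

test_that("average degree follows 2E/N and k-regularity", {
  expect_error(average_degree(network_new()), "empty")
  path3 <- network_new(rbind(c("A", "B"), c("B", "C")))
  expect_equal(average_degree(path3), 4 / 3)
  # 3-regular: complete graph K4
  k4 <- network_new(t(combn(LETTERS[1:4], 2)))
  expect_equal(average_degree(k4), 3)
})

test_that("tripartite assembly equals the set-union oracle and tags roles", {
  ct <- list(matrine = c("CASP3", "MMP2", "MYC"),
             oxymatrine = c("MMP2", "REG1A"),
             sophoridine = c("MMP2", "REG1A"),
             `N-methylcytisine` = "MMP2")
  gm <- list(ARG1 = c("arginine", "ornithine"), CTH = "cystathionine")
  ppi <- network_new(rbind(c("CASP3", "TP53X"), c("MMP2", "TIMP2X")))
  tri <- build_tripartite(ct, ppi, gm)
  expect_equal(degree_to_role(tri, "matrine", "target"), 3L)
  expect_equal(unname(tri$node_role["matrine"]), "compound")
  expect_equal(unname(tri$node_role["arginine"]), "metabolite")
  expect_equal(unname(tri$node_role["TP53X"]), "protein")
  # set-union oracle on random 3-layer maps
  withr::with_seed(21, {
    rct <- lapply(setNames(1:4, paste0("c", 1:4)),
                  function(i) sample(paste0("t", 1:6), 3))
    rgm <- lapply(setNames(1:3, paste0("g", 1:3)),
                  function(i) sample(paste0("m", 1:5), 2))
  })
  tri2 <- build_tripartite(rct, NULL, rgm)
  expected <- unique(c(
    unlist(lapply(names(rct), function(p) paste(pmin(p, rct[[p]]), pmax(p, rct[[p]])))),
    unlist(lapply(names(rgm), function(p) paste(pmin(p, rgm[[p]]), pmax(p, rgm[[p]]))))))
  expect_setequal(paste(tri2$edges[, 1], tri2$edges[, 2]), expected)

  # empty gene->metabolite map: bipartite compound-target graph only
  tri3 <- build_tripartite(ct, NULL, list())
  expect_setequal(unique(unname(tri3$node_role)), c("compound", "target"))
})
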