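# Seed expansion and network merging.

test_that("seed expansion returns the induced first-neighbour subnetwork with roles", {
  bg <- make_named_graph(c("S", "A", "A", "B"))  # path S-A-B
  net <- expand_seed_network("S", bg)
  expect_setequal(igraph::V(net)$name, c("S", "A"))
  expect_equal(igraph::ecount(net), 1L)
  roles <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_equal(roles[["S"]], "seed")
  expect_equal(roles[["A"]], "neighbor")

  # neighbour-neighbour edges are retained (induced, not star-like)
  tri <- make_named_graph(c("S", "A", "A", "C", "S", "C"))
  net2 <- expand_seed_network("S", tri)
  expect_setequal(igraph::V(net2)$name, c("S", "A", "C"))
  expect_equal(igraph::ecount(net2), 3L)
})

test_that("expanding from all nodes reproduces the background", {
  withr::local_seed(5)
  bg <- random_test_graph(15, 0.3)
  net <- expand_seed_network(igraph::V(bg)$name, bg)
  expect_setequal(igraph::V(net)$name, igraph::V(bg)$name)
  expect_setequal(edge_keys_of(net), edge_keys_of(bg))
  expect_true(all(igraph::V(net)$role == "seed"))
})

test_that("seeds absent from the background are excluded, all-absent errors", {
  bg <- make_named_graph(c("A", "B"))
  expect_message(net <- expand_seed_network(c("A", "ZZZ"), bg), "absent")
  expect_false("ZZZ" %in% igraph::V(net)$name)
  expect_error(expand_seed_network("ZZZ", bg),
               class = "netpharm_empty_result_error")
  expect_error(expand_seed_network(character(0), bg),
               class = "netpharm_validation_error")
})

test_that("expansion equals the brute-force induced subgraph on random graphs", {
  withr::local_seed(99)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    bg <- random_test_graph(n)
    seeds <- sample(igraph::V(bg)$name, sample(1:3, 1))
    net <- tryCatch(suppressMessages(expand_seed_network(seeds, bg)),
                    error = function(e) NULL)
    # oracle: seeds plus BFS-distance-1 nodes, then every background edge
    # with both endpoints inside
    adj <- adj_list(bg)
    idx <- match(seeds, igraph::V(bg)$name)
    nbrs <- unique(unlist(lapply(idx, function(i) adj[[i]])))
    nodes <- unique(c(igraph::V(bg)$name[idx], igraph::V(bg)$name[nbrs]))
    el <- igraph::as_edgelist(bg)
    inside <- el[, 1] %in% nodes & el[, 2] %in% nodes
    expected_edges <- paste(pmin(el[inside, 1], el[inside, 2]),
                            pmax(el[inside, 1], el[inside, 2]))
    expect_setequal(igraph::V(net)$name, nodes)
    expect_setequal(edge_keys_of(net), expected_edges)
    # always a subgraph of the background
    expect_true(all(edge_keys_of(net) %in% edge_keys_of(bg)))
  }
})

test_that("intersection merge keeps shared nodes and shared edges", {
  a <- make_named_graph(c("X", "Y", "Y", "Z"))
  b <- make_named_graph(c("Y", "Z", "Z", "W"))
  m <- intersect_networks(a, b)
  expect_setequal(igraph::V(m)$name, c("Y", "Z"))
  expect_equal(edge_keys_of(m), "Y Z")

  disjoint <- intersect_networks(make_named_graph(c("A", "B")),
                                 make_named_graph(c("C", "D")))
  expect_equal(igraph::vcount(disjoint), 0L)
})

test_that("merging is idempotent, commutative and bounded in size", {
  withr::local_seed(17)
  for (rep in 1:10) {
    a <- random_test_graph(sample(5:25, 1))
    b <- random_test_graph(sample(5:25, 1))
    # overlap the name spaces partially
    igraph::V(b)$name <- sprintf("N%02d", sample(1:35, igraph::vcount(b)))
    b <- igraph::simplify(b)
    ab <- intersect_networks(a, b)
    ba <- intersect_networks(b, a)
    expect_setequal(igraph::V(ab)$name, igraph::V(ba)$name)
    expect_setequal(edge_keys_of(ab), edge_keys_of(ba))
    expect_lte(igraph::vcount(ab), min(igraph::vcount(a), igraph::vcount(b)))
    # simple-graph invariants on the result
    expect_false(igraph::any_multiple(ab) || any(igraph::which_loop(ab)))

    aa <- intersect_networks(a, a)
    expect_setequal(igraph::V(aa)$name, igraph::V(a)$name)
    expect_setequal(edge_keys_of(aa), edge_keys_of(a))
  }
})

test_that("induced-union merge keeps shared nodes with either parent's edges", {
  a <- make_named_graph(c("X", "Y", "Y", "Z"))
  b <- make_named_graph(c("X", "Z", "Y", "Z"))
  mi <- intersect_networks(a, b, mode = "intersection")
  mu <- intersect_networks(a, b, mode = "induced-union")
  expect_setequal(igraph::V(mu)$name, c("X", "Y", "Z"))
  expect_setequal(edge_keys_of(mu), c("X Y", "X Z", "Y Z"))
  expect_true(all(edge_keys_of(mi) %in% edge_keys_of(mu)))
})

test_that("merged roles mark a node as seed if either parent deems it one", {
  bg <- make_named_graph(c("S", "A", "A", "T", "T", "S"))
  a <- expand_seed_network("S", bg)
  b <- expand_seed_network("T", bg)
  m <- intersect_networks(a, b)
  roles <- setNames(igraph::V(m)$role, igraph::V(m)$name)
  expect_equal(roles[["S"]], "seed")
  expect_equal(roles[["T"]], "seed")
  expect_equal(roles[["A"]], "neighbor")
})
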