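# Reference values for the 8-airport example were frozen from the
# brute-force oracle (oracle_centrality) at full precision.

test_that("ego subgraphs are induced on the focal node and all its neighbours", {
  net <- toy_network()
  sub_b <- ego_subgraph(net, "B")
  expect_equal(sub_b$nodes, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(network_edges(sub_b)), 14L) # neighbour-neighbour edges included
  expect_equal(attr(sub_b, "focal"), "B")

  sub_h <- ego_subgraph(net, "H")
  expect_equal(sub_h$nodes, c("C", "G", "H"))
  expect_setequal(
    paste(network_edges(sub_h)$from, network_edges(sub_h)$to),
    c("C H", "H C", "G H", "H G")
  )

  iso <- weighted_network(data.frame(from = "X", to = "Y", weight = 1),
                          nodes = "Z")
  sub_z <- ego_subgraph(iso, "Z")
  expect_equal(sub_z$nodes, "Z")
  expect_equal(nrow(network_edges(sub_z)), 0L)
})

test_that("subgraph degree centrality counts within-subgraph degrees", {
  sdc <- subgraph_degrees(ego_subgraph(toy_network(), "B"))
  expect_equal(setNames(sdc$sdc, sdc$node),
               c(A = 4L, B = 8L, C = 4L, D = 6L, E = 6L))

  one_way <- weighted_network(data.frame(from = "X", to = "Y", weight = 3))
  sdc <- subgraph_degrees(ego_subgraph(one_way, "X"))
  expect_equal(sdc$sdc[sdc$node == "X"], 1L) # pure out-degree
})

test_that("entropies match the worked example and closed forms", {
  net <- toy_network()
  expect_equal(structural_entropy(net, "B")$structural_entropy, 0.6836,
               tolerance = 1e-4)
  expect_equal(frequency_entropy(net, "B")$frequency_entropy, 0.5898,
               tolerance = 1e-4)

  # equal subgraph degrees maximise structural entropy at log10(M + 1)
  tri <- weighted_network(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"), weight = 1),
    directed = FALSE
  )
  expect_equal(structural_entropy(tri, "a")$structural_entropy, log10(3),
               tolerance = 1e-12)

  # single out-edge: zero frequency entropy; M equal weights: log10(M)
  star <- weighted_network(data.frame(
    from = c("c", "c", "c", "x"), to = c("l1", "l2", "l3", "c"),
    weight = c(2, 2, 2, 9)
  ))
  expect_equal(frequency_entropy(star, "x")$frequency_entropy, 0)
  expect_equal(frequency_entropy(star, "c")$frequency_entropy, log10(3),
               tolerance = 1e-12)
})

test_that("local influence combines the entropies with the default coefficients", {
  net <- toy_network()
  li <- local_influence(net, c("B", "E"))
  expect_equal(li$local_influence, c(0.6273, 0.6956), tolerance = 1e-4)

  iso <- weighted_network(data.frame(from = "X", to = "Y", weight = 1),
                          nodes = "Z")
  expect_equal(local_influence(iso, "Z")$local_influence, 0)
})

test_that("two-hop neighbourhoods follow edge direction and skip one-hop targets", {
  net <- toy_network()
  th <- two_hop_neighbors(net, "B")
  expect_equal(th$target, c("F", "G", "H"))
  expect_equal(th$intermediates,
               list(c("A", "E"), "E", "C"))

  expect_equal(two_hop_neighbors(net, "E")$target, c("A", "H"))

  path <- weighted_network(data.frame(from = "X", to = "Y", weight = 1))
  expect_equal(nrow(two_hop_neighbors(path, "X")), 0L)
})

test_that("indirect influence averages intermediate products per target, then over targets", {
  net <- toy_network()
  li <- local_influence(net)
  li_vec <- setNames(li$local_influence, li$node)

  expect_equal(indirect_influence_on(net, "B", "F", local = li),
               mean(li_vec["B"] * li_vec[c("A", "E")]), tolerance = 1e-12)
  expect_equal(indirect_influence_on(net, "B", "H", local = li),
               unname(li_vec["B"] * li_vec["C"]), tolerance = 1e-12)
  expect_error(indirect_influence_on(net, "B", "A"), "two-hop")

  ii <- indirect_influence(net)
  expect_equal(setNames(ii$indirect_influence, ii$node)[c("A", "B")],
               c(A = 0.2625073940, B = 0.3721289216), tolerance = 1e-8)

  path <- weighted_network(data.frame(from = "X", to = "Y", weight = 1))
  expect_equal(indirect_influence(path, "X")$indirect_influence, 0)
})

test_that("total influence ranks the airline example as expected", {
  tab <- entropy_centrality(toy_network())
  expect_s3_class(tab, "entropy_centrality")
  expect_equal(tab$total_influence[tab$node == "B"], 0.5252347,
               tolerance = 1e-6)
  expect_equal(tab$node[order(tab$rank)],
               c("E", "B", "D", "C", "G", "F", "A", "H"))
  expect_false(any(tab$tied))

  # edgeless network: all influences zero, every node tied
  empty <- weighted_network(
    data.frame(from = character(), to = character(), weight = numeric()),
    nodes = c("u", "v", "w")
  )
  tab0 <- entropy_centrality(empty)
  expect_equal(tab0$total_influence, rep(0, 3))
  expect_true(all(tab0$tied))
  expect_equal(sort(tab0$rank), 1:3)
})

test_that("coefficients are validated", {
  net <- toy_network()
  expect_error(entropy_centrality(net, omega1 = 0.5, omega2 = 0.6), "equal 1")
  expect_error(entropy_centrality(net, theta1 = -0.2, theta2 = 1.2), "nonnegative")
  expect_error(entropy_centrality(net, log_base = 1), "log_base")
  expect_error(structural_entropy(net, log_base = -2), "log_base")
})

test_that("every pipeline quantity matches the brute-force oracle on random graphs", {
  graphs <- random_test_graphs(50, seed = 404)
  for (net in graphs) {
    e <- as.data.frame(network_edges(net, canonical = TRUE))
    want <- oracle_centrality(e, directed = net$directed)
    got <- entropy_centrality(net)
    got <- got[match(want$node, got$node), ]
    expect_equal(got$structural_entropy, want$Is, tolerance = 1e-12)
    expect_equal(got$frequency_entropy, want$If, tolerance = 1e-12)
    expect_equal(got$local_influence, want$LI, tolerance = 1e-12)
    expect_equal(got$indirect_influence, want$II, tolerance = 1e-12)
    expect_equal(got$total_influence, want$total, tolerance = 1e-12)

    v <- sample(network_nodes(net), 1)
    th <- two_hop_neighbors(net, v)
    want_th <- oracle_two_hop(oracle_prepare(e, net$directed), v)
    expect_equal(th$target,
                 if (length(want_th)) names(want_th) else character(0))
    expect_equal(th$intermediates, unname(want_th), ignore_attr = TRUE)
  }
})

test_that("entropy bounds hold on every property-test graph", {
  for (net in random_test_graphs(20, seed = 77)) {
    tab <- entropy_centrality(net)
    for (r in seq_len(nrow(tab))) {
      M <- length(all_neighbors(net, tab$node[r]))
      expect_lte(tab$structural_entropy[r], log10(M + 1) + 1e-12)
      expect_gte(tab$structural_entropy[r], 0)
      expect_lte(tab$frequency_entropy[r], log10(max(M, 1)) + 1e-12)
      expect_gte(tab$frequency_entropy[r], 0)
    }
  }
})

test_that("scores are equivariant under node relabelling", {
  for (net in random_test_graphs(6, seed = 99)) {
    tab <- entropy_centrality(net)
    tab2 <- entropy_centrality(relabelled_copy(net))
    m <- match(paste0("zz_", tab$node), tab2$node)
    expect_equal(tab2$total_influence[m], tab$total_influence, tolerance = 1e-12)
    expect_equal(tab2$rank[m], tab$rank) # prefix relabelling preserves id order
  }
})

test_that("scores are invariant under global weight rescaling", {
  for (net in random_test_graphs(6, seed = 123)) {
    e <- network_edges(net, canonical = TRUE)
    e$weight <- e$weight * 37.5
    scaled <- weighted_network(as.data.frame(e), directed = net$directed,
                               nodes = network_nodes(net))
    expect_equal(entropy_centrality(scaled)$total_influence,
                 entropy_centrality(net)$total_influence, tolerance = 1e-12)
  }
})

test_that("with theta2 = 0 the ranking reduces to local influence", {
  for (net in random_test_graphs(4, seed = 7)) {
    tab <- entropy_centrality(net, theta1 = 1, theta2 = 0)
    li_order <- order(-tab$local_influence, tab$node)
    expect_equal(tab$rank[li_order], seq_len(nrow(tab)))
  }
  li_first <- entropy_centrality(toy_network(), theta1 = 1, theta2 = 0)
  expect_equal(li_first$node[order(li_first$rank)][1:2], c("E", "B"))
})

test_that("centrality tables export with the fixed schema", {
  tab <- entropy_centrality(toy_network())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_centrality(tab, csv)
  expect_equal(names(utils::read.csv(csv)),
               c("node", "Is", "If", "LI", "II", "total", "rank"))

  js <- withr::local_tempfile(fileext = ".json")
  write_centrality(tab, js, format = "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$node[parsed$rank == 1], "E")
})
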