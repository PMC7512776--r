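# Shared graph fixtures, built in code.

toy_edges <- function() network_edges(toy_network())

# a batch of small random weighted networks spanning the conventions the
# 8-airport example cannot discriminate: non-reciprocal arcs, undirected
# graphs, fractional weights
random_test_graphs <- function(n_graphs, seed = 20260919) {
  set.seed(seed)
  lapply(seq_len(n_graphs), function(i) {
    n <- sample(4:12, 1)
    directed <- runif(1) < 0.7
    reciprocity <- sample(c(0, 0.5, 1), 1)
    wdist <- sample(c("uniform", "geometric", "lognormal"), 1)
    random_network(
      n, mean_out_degree = runif(1, 1.5, min(6, n - 1)),
      reciprocity = if (directed) reciprocity else 0,
      weights = wdist, directed = directed,
      seed = sample.int(1e6, 1)
    )
  })
}

# X -> Y chain used for the closed-form SI check
chain_network <- function(w = 1) {
  weighted_network(data.frame(from = "X", to = "Y", weight = w),
                   directed = TRUE)
}

relabelled_copy <- function(net, prefix = "zz_") {
  e <- network_edges(net, canonical = TRUE)
  map <- setNames(paste0(prefix, network_nodes(net)), network_nodes(net))
  weighted_network(
    data.frame(from = unname(map[e$from]), to = unname(map[e$to]),
               weight = e$weight),
    directed = net$directed,
    nodes = unname(map[network_nodes(net)])
  )
}
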