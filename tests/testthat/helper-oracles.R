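# Independent brute-force oracles. Everything here works directly on a raw
# edge data frame (from, to, weight) with literal loops and no calls into the
# package's computational code, so it can serve as a reference for the
# entropy-centrality pipeline and for the weighted shortest-path baselines.

# symmetrise an undirected edge list so that all oracles can treat adjacency
# uniformly as "follow the arrows"
oracle_prepare <- function(edges, directed) {
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      weight = as.numeric(edges$weight))
  if (!directed) {
    edges <- rbind(edges, data.frame(from = edges$to, to = edges$from,
                                     weight = edges$weight))
    edges <- unique(edges)
  }
  edges
}

oracle_entropy <- function(w, base = 10) {
  w <- w[w > 0]
  if (length(w) == 0) return(0)
  p <- w / sum(w)
  -sum(p * log(p, base))
}

oracle_neighbors <- function(edges, i) {
  sort(unique(c(edges$to[edges$from == i], edges$from[edges$to == i])))
}

oracle_ego_sdc <- function(edges, i, directed) {
  members <- sort(unique(c(i, oracle_neighbors(edges, i))))
  sdc <- sapply(members, function(v) {
    outd <- length(unique(edges$to[edges$from == v & edges$to %in% members]))
    ind <- length(unique(edges$from[edges$to == v & edges$from %in% members]))
    if (directed) outd + ind else outd
  })
  names(sdc) <- members
  sdc
}

oracle_two_hop <- function(edges, i) {
  one_hop <- unique(edges$to[edges$from == i])
  targets <- list()
  for (j in one_hop) {
    for (p in unique(edges$to[edges$from == j])) {
      if (p != i && !(p %in% one_hop)) {
        targets[[p]] <- sort(unique(c(targets[[p]], j)))
      }
    }
  }
  if (length(targets)) targets[order(names(targets))] else targets
}

# full entropy-centrality table computed by literal enumeration
oracle_centrality <- function(edges, directed = TRUE,
                              w1 = 0.4, w2 = 0.6, t1 = 0.6, t2 = 0.4,
                              base = 10) {
  edges <- oracle_prepare(edges, directed)
  nodes <- sort(unique(c(edges$from, edges$to)))
  Is <- If <- LI <- II <- setNames(numeric(length(nodes)), nodes)
  for (i in nodes) {
    Is[i] <- oracle_entropy(oracle_ego_sdc(edges, i, directed), base)
    If[i] <- oracle_entropy(edges$weight[edges$from == i], base)
    LI[i] <- w1 * Is[i] + w2 * If[i]
  }
  for (i in nodes) {
    th <- oracle_two_hop(edges, i)
    if (length(th) == 0) next
    per_target <- sapply(th, function(js) mean(LI[i] * LI[js]))
    II[i] <- mean(per_target)
  }
  data.frame(node = nodes, Is = Is, If = If, LI = LI, II = II,
             total = t1 * LI + t2 * II, row.names = NULL)
}

# all-pairs shortest-path distances (Floyd-Warshall) on distances 1/weight
oracle_distances <- function(edges, directed, weighted = TRUE) {
  edges <- oracle_prepare(edges, directed)
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    len <- if (weighted) 1 / edges$weight[r] else 1
    d[edges$from[r], edges$to[r]] <- min(d[edges$from[r], edges$to[r]], len)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_harmonic_closeness <- function(edges, directed, weighted = TRUE,
                                      n_nodes = NULL) {
  d <- oracle_distances(edges, directed, weighted)
  # isolated nodes never appear in the edge list but still count towards the
  # 1/(n - 1) normalisation (they contribute distance infinity, i.e. 0)
  n <- if (is.null(n_nodes)) nrow(d) else n_nodes
  sapply(rownames(d), function(i) {
    inv <- 1 / d[i, setdiff(rownames(d), i)]
    sum(inv[is.finite(inv)]) / (n - 1)
  })
}

# betweenness by exhaustive simple-path enumeration (feasible for n <= 8)
oracle_betweenness <- function(edges, directed, weighted = TRUE) {
  edges <- oracle_prepare(edges, directed)
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    rows <- edges$from == v
    data.frame(to = edges$to[rows],
               len = if (weighted) 1 / edges$weight[rows] else rep(1, sum(rows)))
  })
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, path, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return()
      }
      nb <- adj[[v]]
      for (r in seq_len(nrow(nb))) {
        if (!(nb$to[r] %in% path)) {
          walk(nb$to[r], c(path, nb$to[r]), len + nb$len[r])
        }
      }
    }
    walk(s, s, 0)
    paths
  }
  bc <- setNames(numeric(length(nodes)), nodes)
  pair_set <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pair_set <- pair_set[pair_set$s != pair_set$t, ]
  if (!directed) pair_set <- pair_set[pair_set$s < pair_set$t, ]
  for (r in seq_len(nrow(pair_set))) {
    ps <- all_paths(pair_set$s[r], pair_set$t[r])
    if (length(ps) == 0) next
    lens <- sapply(ps, `[[`, "len")
    geo <- ps[lens <= min(lens) + 1e-9]
    for (g in geo) {
      interior <- setdiff(g$path, c(pair_set$s[r], pair_set$t[r]))
      for (v in interior) bc[v] <- bc[v] + 1 / length(geo)
    }
  }
  bc
}

# dominant eigenvector of a symmetric weighted adjacency via dense eigen()
oracle_eigenvector_sym <- function(edges, weighted = TRUE) {
  edges <- oracle_prepare(edges, directed = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- if (weighted) edges$weight[r] else 1
  }
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  setNames(v / sqrt(sum(v^2)), nodes)
}
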