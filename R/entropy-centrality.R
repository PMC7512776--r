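#' Entropy-based centrality
#'
#' Ranks the nodes of a weighted network by an entropy-based influence score.
#' Each node's *local influence* is a convex combination of two Shannon
#' entropies computed on its ego subgraph: the **structural entropy** of the
#' subgraph-degree distribution over the subgraph's members (how active and
#' popular the node's immediate world is) and the **frequency entropy** of the
#' node's own interaction weights (how evenly its attention is spread over its
#' ties). Influence reaching two-hop neighbours through common intermediates
#' supplies the *indirect influence*, and the total influence is a convex
#' combination of the two. Nodes are ranked by descending total influence.
#'
#' For a node \eqn{i} with ego subgraph \eqn{G_i} (the induced subgraph on
#' \eqn{i} and all of its in- and out-neighbours), each member's subgraph
#' degree centrality (SDC) is its in-degree plus out-degree within \eqn{G_i}
#' (for undirected networks, the number of adjacent members). With
#' \eqn{p_v = SDC_v / \sum_u SDC_u},
#' \deqn{I_i^s = -\sum_v p_v \log_b p_v,}
#' and with \eqn{q_j = C_{ij} / \sum_k C_{ik}} over the out-edge weights of
#' \eqn{i} (incident weights when undirected),
#' \deqn{I_i^f = -\sum_j q_j \log_b q_j,}
#' \deqn{LI_i = \omega_1 I_i^s + \omega_2 I_i^f.}
#' For each two-hop neighbour \eqn{p} of \eqn{i} (reachable along a directed
#' path \eqn{i \to j \to p} but not a one-hop out-neighbour), the per-target
#' influence averages \eqn{LI_i \cdot LI_j} over the \eqn{N_{ip}} common
#' intermediates \eqn{j}, and the indirect influence \eqn{II_i} averages those
#' terms over the \eqn{M_i} two-hop neighbours. Finally
#' \eqn{I_i = \theta_1 LI_i + \theta_2 II_i}.
#'
#' Degenerate distributions contribute zero entropy (`0 log 0 := 0`; a node
#' with no edges, or a single out-edge, scores 0 on the corresponding term).
#' All scores are invariant under a global rescaling of the weights.
#'
#' @param x A `weighted_network` or an edge data frame (coerced with
#'   [as_weighted_network()] and the `directed` flag).
#' @param omega1,omega2 Nonnegative weights of the structural and frequency
#'   entropies in the local influence; must sum to 1. Defaults 0.4 and 0.6.
#' @param theta1,theta2 Nonnegative weights of the local and indirect
#'   influence in the total influence; must sum to 1. Defaults 0.6 and 0.4.
#' @param log_base Base of the logarithm used in both entropies (default 10).
#' @param directed Logical, used only when `x` is an edge data frame.
#'
#' @return A tibble of class `entropy_centrality` (also `centrality_ranking`)
#'   with one row per node and columns `node`, `structural_entropy`,
#'   `frequency_entropy`, `local_influence`, `indirect_influence`,
#'   `total_influence`, `rank` and `tied`. Ranks are 1..n by descending total
#'   influence; ties are broken by ascending node identifier and flagged in
#'   `tied`.
#'
#' @examples
#' entropy_centrality(toy_network())
#' @export
entropy_centrality <- function(x, omega1 = 0.4, omega2 = 0.6,
                               theta1 = 0.6, theta2 = 0.4,
                               log_base = 10, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  check_coeff_pair(omega1, omega2, c("omega1", "omega2"))
  check_coeff_pair(theta1, theta2, c("theta1", "theta2"))
  check_log_base(log_base)
  if (length(x$nodes) == 0L) abort("Cannot rank an empty network.")

  adj <- adjacency_index(x)
  li <- local_influence_impl(x, adj, omega1, omega2, log_base)
  li_vec <- setNames(li$local_influence, li$node)
  ii_vec <- indirect_influence_impl(adj, li_vec)

  out <- li |>
    mutate(
      indirect_influence = unname(ii_vec[.data$node]),
      total_influence = theta1 * .data$local_influence +
        theta2 * .data$indirect_influence
    )
  out <- add_ranks(out, "total_influence")
  structure(
    out,
    class = c("entropy_centrality", "centrality_ranking", class(out)),
    method = "entropy",
    coefficients = list(omega1 = omega1, omega2 = omega2,
                        theta1 = theta1, theta2 = theta2, log_base = log_base),
    conventions = paste(
      "ego subgraph = induced subgraph on focal node and union of in/out-neighbours;",
      "frequency entropy over out-edge weights (incident weights if undirected);",
      "two-hop traversal follows edge direction at both hops, excluding the",
      "focal node and its one-hop out-neighbours;",
      "indirect influence averages over distinct two-hop neighbours;",
      "ties broken by ascending node identifier"
    )
  )
}

check_coeff_pair <- function(a, b, nm) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || a < 0 || b < 0) {
    abort(sprintf("`%s` and `%s` must be single nonnegative numbers.", nm[1], nm[2]))
  }
  if (abs(a + b - 1) > 1e-8) {
    abort(sprintf("`%s` + `%s` must equal 1 (got %g).", nm[1], nm[2], a + b))
  }
  invisible(TRUE)
}

check_log_base <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0 || b == 1) {
    abort("`log_base` must be a positive number different from 1.")
  }
  invisible(TRUE)
}

# Shannon entropy of an unnormalised weight vector; 0 log 0 := 0, empty := 0
shannon <- function(w, base) {
  w <- w[w > 0]
  s <- sum(w)
  if (length(w) == 0L || s <= 0) return(0)
  p <- w / s
  -sum(p * log(p, base = base))
}

ego_members <- function(adj, node) {
  sort(unique(c(node, adj$out[[node]], adj$`in`[[node]])))
}

# in-degree + out-degree of each member within the induced subgraph
# (adjacency count for undirected networks, whose edge map is symmetric)
induced_sdc <- function(adj, members, directed) {
  vapply(members, function(v) {
    if (directed) {
      sum(unique(adj$out[[v]]) %in% members) + sum(unique(adj$`in`[[v]]) %in% members)
    } else {
      sum(unique(adj$out[[v]]) %in% members)
    }
  }, numeric(1))
}

#' Ego subgraph of a node
#'
#' The induced subgraph on a focal node and the union of its in- and
#' out-neighbours: every edge of the network between two members — including
#' edges among the neighbours themselves — is retained.
#'
#' @inheritParams entropy_centrality
#' @param node A node identifier.
#' @return A `weighted_network` (subclass `ego_subgraph`) whose `focal`
#'   attribute records the focal node.
#' @examples
#' ego_subgraph(toy_network(), "B")
#' @export
ego_subgraph <- function(x, node, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  node <- check_node(x, node)
  adj <- adjacency_index(x)
  members <- ego_members(adj, node)
  e <- filter(x$edges, .data$from %in% members & .data$to %in% members)
  sub <- structure(
    list(edges = e, nodes = members, directed = x$directed),
    class = c("ego_subgraph", "weighted_network")
  )
  attr(sub, "focal") <- node
  sub
}

#' Subgraph degree centrality within an ego subgraph
#'
#' For each member of an ego subgraph, the in-degree plus out-degree counted
#' within the subgraph only (directed networks), or the number of adjacent
#' members (undirected networks).
#'
#' @param sub An `ego_subgraph` (or any `weighted_network`, in which case the
#'   whole network is the subgraph).
#' @return A tibble with columns `node`, `in_degree`, `out_degree`, `sdc`.
#' @examples
#' subgraph_degrees(ego_subgraph(toy_network(), "B"))
#' @export
subgraph_degrees <- function(sub) {
  if (!is_weighted_network(sub)) abort("`sub` must be a weighted_network / ego_subgraph.")
  adj <- adjacency_index(sub)
  members <- sub$nodes
  ind <- vapply(members, function(v) length(unique(adj$`in`[[v]])), numeric(1))
  outd <- vapply(members, function(v) length(unique(adj$out[[v]])), numeric(1))
  tibble(
    node = members,
    in_degree = as.integer(ind),
    out_degree = as.integer(outd),
    sdc = as.integer(if (sub$directed) ind + outd else outd)
  )
}

#' Structural and frequency entropies
#'
#' `structural_entropy()` is the Shannon entropy of the subgraph-degree
#' distribution over a node's ego subgraph; `frequency_entropy()` is the
#' Shannon entropy of the node's out-edge weight distribution (incident
#' weights for undirected networks). Both return 0 for degenerate cases (no
#' edges; a single out-edge).
#'
#' @inheritParams entropy_centrality
#' @param nodes Nodes to score; defaults to every node.
#' @return A tibble with columns `node` and `structural_entropy` (resp.
#'   `frequency_entropy`).
#' @examples
#' structural_entropy(toy_network(), "B") # 0.6836
#' frequency_entropy(toy_network(), "B") # 0.5898
#' @export
structural_entropy <- function(x, nodes = NULL, log_base = 10, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  check_log_base(log_base)
  nodes <- resolve_nodes(x, nodes)
  adj <- adjacency_index(x)
  vals <- vapply(nodes, function(i) {
    members <- ego_members(adj, i)
    shannon(induced_sdc(adj, members, x$directed), log_base)
  }, numeric(1))
  tibble(node = nodes, structural_entropy = unname(vals))
}

#' @rdname structural_entropy
#' @export
frequency_entropy <- function(x, nodes = NULL, log_base = 10, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  check_log_base(log_base)
  nodes <- resolve_nodes(x, nodes)
  adj <- adjacency_index(x)
  vals <- vapply(nodes, function(i) shannon(adj$out_w[[i]], log_base), numeric(1))
  tibble(node = nodes, frequency_entropy = unname(vals))
}

resolve_nodes <- function(x, nodes) {
  if (is.null(nodes)) return(x$nodes)
  vapply(as.character(nodes), function(n) check_node(x, n), character(1),
         USE.NAMES = FALSE)
}

#' Local influence
#'
#' The convex combination `omega1 * structural_entropy + omega2 *
#' frequency_entropy` for each requested node.
#'
#' @inheritParams structural_entropy
#' @inheritParams entropy_centrality
#' @return A tibble with columns `node`, `structural_entropy`,
#'   `frequency_entropy`, `local_influence`.
#' @examples
#' local_influence(toy_network(), "B") # 0.6273
#' @export
local_influence <- function(x, nodes = NULL, omega1 = 0.4, omega2 = 0.6,
                            log_base = 10, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  check_coeff_pair(omega1, omega2, c("omega1", "omega2"))
  check_log_base(log_base)
  nodes <- resolve_nodes(x, nodes)
  adj <- adjacency_index(x)
  local_influence_impl(x, adj, omega1, omega2, log_base, nodes)
}

local_influence_impl <- function(x, adj, omega1, omega2, log_base,
                                 nodes = x$nodes) {
  s <- vapply(nodes, function(i) {
    members <- ego_members(adj, i)
    shannon(induced_sdc(adj, members, x$directed), log_base)
  }, numeric(1))
  f <- vapply(nodes, function(i) shannon(adj$out_w[[i]], log_base), numeric(1))
  tibble(
    node = nodes,
    structural_entropy = unname(s),
    frequency_entropy = unname(f),
    local_influence = omega1 * unname(s) + omega2 * unname(f)
  )
}

#' Two-hop neighbours and their common intermediates
#'
#' Nodes reachable from `node` along a directed path of length exactly two
#' (following edge direction at both hops; undirected adjacency for
#' undirected networks) that are neither `node` itself nor one of its one-hop
#' out-neighbours. Each target is returned with the set of intermediates —
#' the common neighbours through which influence reaches it.
#'
#' @inheritParams ego_subgraph
#' @return A tibble with columns `target`, `intermediates` (list-column of
#'   character vectors) and `n_intermediates`; zero rows if the node has no
#'   two-hop neighbours.
#' @examples
#' two_hop_neighbors(toy_network(), "B")
#' @export
two_hop_neighbors <- function(x, node, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  node <- check_node(x, node)
  adj <- adjacency_index(x)
  th <- two_hop_targets(adj, node)
  tibble(
    target = if (length(th)) names(th) else character(0),
    intermediates = unname(th),
    n_intermediates = lengths(th)
  )
}

# named list target -> character vector of intermediates
two_hop_targets <- function(adj, i) {
  one_hop <- unique(adj$out[[i]])
  targets <- list()
  for (j in one_hop) {
    for (p in unique(adj$out[[j]])) {
      if (p != i && !(p %in% one_hop)) {
        targets[[p]] <- c(targets[[p]], j)
      }
    }
  }
  if (length(targets) == 0L) return(targets)
  targets <- lapply(targets, function(v) sort(unique(v)))
  targets[order(names(targets))]
}

#' Indirect (two-hop) influence
#'
#' `indirect_influence_on()` gives the influence of `from` on a single
#' two-hop neighbour `to`: the mean of `LI[from] * LI[j]` over the common
#' intermediates `j`. `indirect_influence()` averages these per-target values
#' over all two-hop neighbours of each node (0 for nodes with none).
#'
#' @inheritParams entropy_centrality
#' @param from,to Node identifiers; `to` must be a two-hop neighbour of
#'   `from`.
#' @param local Optional precomputed local influences: either the tibble
#'   returned by [local_influence()] for all nodes or a named numeric vector.
#'   Computed from `x` with the given coefficients when omitted.
#' @return `indirect_influence_on()`: a single nonnegative number.
#'   `indirect_influence()`: a tibble with columns `node`,
#'   `indirect_influence`.
#' @examples
#' indirect_influence(toy_network(), nodes = "B") # 0.3721
#' @export
indirect_influence <- function(x, nodes = NULL, local = NULL,
                               omega1 = 0.4, omega2 = 0.6, log_base = 10,
                               directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  nodes <- resolve_nodes(x, nodes)
  adj <- adjacency_index(x)
  li_vec <- resolve_local(x, adj, local, omega1, omega2, log_base)
  ii <- indirect_influence_impl(adj, li_vec, nodes)
  tibble(node = nodes, indirect_influence = unname(ii[nodes]))
}

#' @rdname indirect_influence
#' @export
indirect_influence_on <- function(x, from, to, local = NULL,
                                  omega1 = 0.4, omega2 = 0.6, log_base = 10,
                                  directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  from <- check_node(x, from)
  to <- check_node(x, to)
  adj <- adjacency_index(x)
  th <- two_hop_targets(adj, from)
  if (!to %in% names(th)) {
    abort(sprintf("'%s' is not a two-hop neighbour of '%s'.", to, from))
  }
  li_vec <- resolve_local(x, adj, local, omega1, omega2, log_base)
  mean(li_vec[from] * li_vec[th[[to]]])
}

resolve_local <- function(x, adj, local, omega1, omega2, log_base) {
  if (is.null(local)) {
    li <- local_influence_impl(x, adj, omega1, omega2, log_base)
    return(setNames(li$local_influence, li$node))
  }
  if (is.data.frame(local)) {
    if (!all(c("node", "local_influence") %in% names(local))) {
      abort("`local` must have columns `node` and `local_influence`.")
    }
    local <- setNames(local$local_influence, local$node)
  }
  if (!is.numeric(local) || is.null(names(local))) {
    abort("`local` must be a named numeric vector or a local_influence() tibble.")
  }
  missing <- setdiff(x$nodes, names(local))
  if (length(missing) > 0L) {
    abort(sprintf("`local` lacks values for node(s): %s.",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  local
}

indirect_influence_impl <- function(adj, li_vec, nodes = adj$nodes) {
  vapply(setNames(nodes, nodes), function(i) {
    th <- two_hop_targets(adj, i)
    if (length(th) == 0L) return(0)
    per_target <- vapply(th, function(js) mean(li_vec[i] * li_vec[js]), numeric(1))
    mean(per_target)
  }, numeric(1))
}

# descending score, ties broken by ascending node id; tied values flagged
add_ranks <- function(tbl, score_col) {
  ord <- order(-tbl[[score_col]], tbl$node)
  rk <- integer(nrow(tbl))
  rk[ord] <- seq_len(nrow(tbl))
  tbl$rank <- rk
  tbl$tied <- duplicated(tbl[[score_col]]) | duplicated(tbl[[score_col]], fromLast = TRUE)
  arrange(tbl, .data$rank)
}

#' Write a centrality table to CSV or JSON
#'
#' Entropy-centrality tables are written with the fixed column header
#' `node, Is, If, LI, II, total, rank`; baseline tables with
#' `node, score, rank`.
#'
#' @param scores A `centrality_ranking` tibble.
#' @param path Destination file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the path written.
#' @export
write_centrality <- function(scores, path, format = c("csv", "json")) {
  format <- arg_match(format)
  if (!inherits(scores, "centrality_ranking")) {
    abort("`scores` must be a centrality table.")
  }
  out <- if (inherits(scores, "entropy_centrality")) {
    tibble(
      node = scores$node, Is = scores$structural_entropy,
      If = scores$frequency_entropy, LI = scores$local_influence,
      II = scores$indirect_influence, total = scores$total_influence,
      rank = scores$rank
    )
  } else {
    tibble(node = scores$node, score = scores$score, rank = scores$rank)
  }
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
tidy.centrality_ranking <- function(x, ...) {
  as_tibble(unclass_ranking(x))
}

#' @export
glance.centrality_ranking <- function(x, ...) {
  co <- attr(x, "coefficients")
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_nodes = nrow(x),
    top_node = x$node[x$rank == 1L][1L],
    n_tied = sum(x$tied),
    coefficients = list(co)
  )
}

unclass_ranking <- function(x) {
  class(x) <- setdiff(class(x), c("entropy_centrality", "centrality_ranking"))
  x
}
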