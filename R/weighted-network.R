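#' Build a weighted network from an edge table
#'
#' Constructs a validated weighted network from a data frame of edges. The
#' first three columns are interpreted as source, target and weight (columns
#' named `from`/`to`/`weight` or `source`/`target`/`weight` are used by name
#' when present). Weights are interaction frequencies — flight counts, message
#' counts, collaboration strengths — and must be strictly positive.
#'
#' Duplicate rows for the same ordered pair are aggregated by summing their
#' weights. Self-loops are dropped with a warning. For undirected networks the
#' edge map is stored symmetrically, so every edge is visible in both
#' orientations; use `network_edges(x, canonical = TRUE)` to see each edge
#' once.
#'
#' @param edges A data frame (or tibble) of edges; at least three columns.
#' @param directed Logical; is the network directed? Undirectedness is an
#'   explicit flag, never inferred from the data.
#' @param nodes Optional character vector of node identifiers to include in
#'   addition to all edge endpoints (allows isolated nodes).
#'
#' @return An object of class `weighted_network`: a list with elements
#'   `edges` (tibble `from`, `to`, `weight`), `nodes` (sorted character
#'   vector) and `directed`.
#'
#' @examples
#' net <- weighted_network(
#'   data.frame(from = c("A", "A", "B"), to = c("B", "B", "A"), weight = c(2, 3, 4))
#' )
#' network_edges(net) # A->B aggregated to weight 5
#' @export
weighted_network <- function(edges, directed = TRUE, nodes = NULL) {
  stopifnot(is.logical(directed), length(directed) == 1L, !is.na(directed))
  edges <- normalise_edge_cols(edges)
  if (nrow(edges) == 0L && is.null(nodes)) {
    abort("Cannot build a weighted network from an empty edge list.")
  }
  validate_edge_rows(edges)
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))

  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop edge(s) (e.g. row %d: %s -> %s).",
                 sum(loops), which(loops)[1L],
                 edges$from[which(loops)[1L]], edges$to[which(loops)[1L]]))
    edges <- edges[!loops, , drop = FALSE]
  }

  if (length(all_nodes) == 0L) {
    abort("Cannot build a weighted network with no nodes.")
  }

  if (!directed && nrow(edges) > 0L) {
    # collapse to unordered pairs before aggregating, then symmetrise
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  if (nrow(edges) > 0L) {
    edges <- edges |>
      group_by(.data$from, .data$to) |>
      summarise(weight = sum(.data$weight), .groups = "drop")
  }
  if (!directed && nrow(edges) > 0L) {
    edges <- bind_rows(edges, tibble(from = edges$to, to = edges$from,
                                     weight = edges$weight))
  }
  edges <- arrange(edges, .data$from, .data$to)

  structure(
    list(edges = edges, nodes = all_nodes, directed = directed),
    class = "weighted_network"
  )
}

normalise_edge_cols <- function(edges) {
  if (inherits(edges, "weighted_network")) {
    abort("`edges` is already a weighted_network; use as_weighted_network().")
  }
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame with columns source, target, weight.")
  }
  nm <- tolower(names(edges))
  pick <- function(cands, fallback) {
    hit <- which(nm %in% cands)
    if (length(hit) >= 1L) hit[1L] else fallback
  }
  i_from <- pick(c("from", "source"), 1L)
  i_to <- pick(c("to", "target"), 2L)
  i_w <- pick(c("weight", "w"), 3L)
  if (ncol(edges) < max(i_from, i_to, i_w)) {
    abort("`edges` must have at least three columns: source, target, weight.")
  }
  tibble(
    from = as.character(edges[[i_from]]),
    to = as.character(edges[[i_to]]),
    weight = edges[[i_w]]
  )
}

validate_edge_rows <- function(edges) {
  w <- suppressWarnings(as.numeric(edges$weight))
  bad <- which(is.na(w) | !is.finite(w) | w <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Edge weights must be finite and strictly positive; offending row(s): %s (first: %s -> %s, weight = %s).",
      paste(head(bad, 5L), collapse = ", "),
      edges$from[bad[1L]], edges$to[bad[1L]], format(edges$weight[bad[1L]])
    ))
  }
  if (any(is.na(edges$from) | is.na(edges$to) | edges$from == "" | edges$to == "")) {
    abort("Edge endpoints must be non-missing, non-empty identifiers.")
  }
  invisible(edges)
}

#' Coerce to a weighted network
#'
#' Data frames are passed through [weighted_network()]; existing
#' `weighted_network` objects are returned unchanged (the `directed` argument
#' is then ignored).
#'
#' @inheritParams weighted_network
#' @param x A `weighted_network` or an edge data frame.
#' @return A `weighted_network`.
#' @export
as_weighted_network <- function(x, directed = TRUE, nodes = NULL) {
  if (is_weighted_network(x)) return(x)
  weighted_network(x, directed = directed, nodes = nodes)
}

#' @rdname as_weighted_network
#' @export
is_weighted_network <- function(x) inherits(x, "weighted_network")

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network: %d nodes, %d %s edges>\n",
              length(x$nodes), n_edges(x),
              if (x$directed) "directed" else "undirected"))
  print(network_edges(x, canonical = TRUE), n = 6)
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the sorted node identifiers; `network_edges()`
#' returns the edge tibble (`from`, `to`, `weight`). For undirected networks
#' the internal edge map is symmetric; `canonical = TRUE` returns each edge
#' once with `from <= to`.
#'
#' @param x A `weighted_network` (or edge data frame, coerced with defaults).
#' @param canonical Logical; list each undirected edge once. Ignored for
#'   directed networks.
#' @return A character vector (`network_nodes`) or tibble (`network_edges`).
#' @export
network_nodes <- function(x) {
  x <- as_weighted_network(x)
  x$nodes
}

#' @rdname network_nodes
#' @export
network_edges <- function(x, canonical = FALSE) {
  x <- as_weighted_network(x)
  e <- x$edges
  if (!x$directed && canonical) e <- filter(e, .data$from <= .data$to)
  e
}

n_edges <- function(x) {
  if (x$directed) nrow(x$edges) else nrow(x$edges) %/% 2L
}

check_node <- function(x, node) {
  if (length(node) != 1L || is.na(node)) abort("`node` must be a single identifier.")
  node <- as.character(node)
  if (!node %in% x$nodes) {
    abort(sprintf("Unknown node '%s'.", node))
  }
  node
}

#' Neighbourhoods of a node
#'
#' `out_neighbors()` returns the nodes reachable along a single edge from
#' `node` (for undirected networks, all adjacent nodes); `in_neighbors()` the
#' nodes with an edge pointing at `node`; `all_neighbors()` their union,
#' excluding `node` itself. The union neighbourhood defines ego-subgraph
#' membership for the entropy centrality.
#'
#' @param x A `weighted_network` or edge data frame.
#' @param node A node identifier present in the network.
#' @return A character vector of node identifiers (sorted).
#' @examples
#' out_neighbors(toy_network(), "B")
#' @export
out_neighbors <- function(x, node) {
  x <- as_weighted_network(x)
  node <- check_node(x, node)
  sort(unique(x$edges$to[x$edges$from == node]))
}

#' @rdname out_neighbors
#' @export
in_neighbors <- function(x, node) {
  x <- as_weighted_network(x)
  node <- check_node(x, node)
  sort(unique(x$edges$from[x$edges$to == node]))
}

#' @rdname out_neighbors
#' @export
all_neighbors <- function(x, node) {
  x <- as_weighted_network(x)
  node <- check_node(x, node)
  sort(unique(c(
    x$edges$to[x$edges$from == node],
    x$edges$from[x$edges$to == node]
  )))
}

#' Summary statistics of a network
#'
#' Returns a one-row tibble with the node count `n`, edge count `m` (arcs for
#' directed networks, unordered edges for undirected), the global clustering
#' coefficient computed on the undirected, unweighted skeleton, and the
#' average degree. The average-degree convention is the mean total degree
#' `2m/n` (for directed networks an arc contributes to both endpoints'
#' degrees); the conventions used are recorded in the `clustering_on` and
#' `degree_convention` columns so results are auditable.
#'
#' @param x A `weighted_network` or edge data frame.
#' @return A tibble with columns `n`, `m`, `clustering`, `average_degree`,
#'   `directed`, `clustering_on`, `degree_convention`.
#' @examples
#' network_summary(toy_network())
#' @export
network_summary <- function(x) {
  x <- as_weighted_network(x)
  if (length(x$nodes) == 0L) abort("Cannot summarise an empty network.")
  g <- as_igraph(x)
  skel <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(skel, type = "global")
  m <- n_edges(x)
  n <- length(x$nodes)
  tibble(
    n = n,
    m = m,
    clustering = if (is.nan(cc)) 0 else cc,
    average_degree = 2 * m / n,
    directed = x$directed,
    clustering_on = "undirected unweighted skeleton, global transitivity",
    degree_convention = "mean total degree 2m/n"
  )
}

#' @export
#' @rdname network_summary
#' @param ... Unused.
glance.weighted_network <- function(x, ...) network_summary(x)

# igraph view of the network; canonical edges so undirected edges are not doubled
as_igraph <- function(x) {
  e <- network_edges(x, canonical = TRUE)
  igraph::graph_from_data_frame(
    as.data.frame(e), directed = x$directed,
    vertices = data.frame(name = x$nodes)
  )
}

# fast adjacency index used by the entropy centrality and the SI model
adjacency_index <- function(x) {
  e <- x$edges
  out_n <- split(e$to, factor(e$from, levels = x$nodes))
  in_n <- split(e$from, factor(e$to, levels = x$nodes))
  out_w <- split(e$weight, factor(e$from, levels = x$nodes))
  list(out = out_n, `in` = in_n, out_w = out_w, nodes = x$nodes)
}
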