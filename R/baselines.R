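#' Baseline centralities
#'
#' The four classical centralities used as comparison baselines for the
#' entropy ranking, with explicit weighted/directed conventions recorded in
#' the result's `convention` attribute:
#'
#' * `degree_centrality()` — total (in + out) degree, unweighted by default;
#'   `weighted = TRUE` uses node strength (sum of incident weights).
#' * `betweenness_centrality()` — exact shortest-path betweenness (Brandes,
#'   via igraph) on the directed graph; with `weighted = TRUE` (default)
#'   distances are `1/weight`, so strong ties are short.
#' * `closeness_centrality()` — harmonic closeness by default (the mean of
#'   inverse distances to all other nodes, which handles disconnected
#'   components gracefully: unreachable nodes contribute 0); the
#'   `"reachable"` variant is classic closeness normalised over the reachable
#'   component. Distances are `1/weight` when `weighted = TRUE`.
#' * `eigenvector_centrality()` — principal eigenvector of the (weighted)
#'   adjacency matrix, computed by power iteration with a diagonal shift
#'   (which leaves the eigenvector unchanged but guarantees a unique dominant
#'   eigenvalue on bipartite-like spectra), L2-normalised. For directed
#'   networks a node's score is fed by its in-edges.
#'
#' @param x A `weighted_network` or edge data frame.
#' @param weighted Logical; use edge weights under the conventions above.
#' @param variant For closeness, `"harmonic"` (default) or `"reachable"`.
#' @param tol,max_iter Convergence tolerance (L2 change per iteration,
#'   default 1e-8) and iteration cap (default 1000) for the eigenvector power
#'   iteration; non-convergence is an error naming the cap.
#' @param directed Logical, used only when `x` is an edge data frame.
#'
#' @return A tibble of class `centrality_ranking` with columns `node`,
#'   `score`, `rank`, `tied`; attributes `method` and `convention` record the
#'   method and the exact convention used.
#'
#' @examples
#' degree_centrality(toy_network())
#' @name baselines
NULL

new_baseline <- function(tbl, method, convention) {
  tbl <- add_ranks(tbl, "score")
  structure(
    tbl,
    class = c("centrality_ranking", class(tbl)),
    method = method,
    convention = convention
  )
}

#' @rdname baselines
#' @export
degree_centrality <- function(x, weighted = FALSE, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  g <- as_igraph(x)
  sc <- if (weighted) {
    igraph::strength(g, mode = "all")
  } else {
    igraph::degree(g, mode = "all")
  }
  new_baseline(
    tibble(node = x$nodes, score = unname(sc[x$nodes])),
    "degree",
    if (weighted) "total strength (sum of in- and out-weights)"
    else "total degree (in + out, unweighted)"
  )
}

edge_distances <- function(x, weighted) {
  if (!weighted) return(NULL)
  1 / network_edges(x, canonical = TRUE)$weight
}

#' @rdname baselines
#' @export
betweenness_centrality <- function(x, weighted = TRUE, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  g <- as_igraph(x)
  sc <- igraph::betweenness(g, directed = x$directed,
                            weights = edge_distances(x, weighted))
  new_baseline(
    tibble(node = x$nodes, score = unname(sc[x$nodes])),
    "betweenness",
    sprintf("exact shortest-path betweenness, %s, distances = %s",
            if (x$directed) "directed" else "undirected",
            if (weighted) "1/weight" else "1")
  )
}

#' @rdname baselines
#' @export
closeness_centrality <- function(x, weighted = TRUE,
                                 variant = c("harmonic", "reachable"),
                                 directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  variant <- arg_match(variant)
  g <- as_igraph(x)
  w <- edge_distances(x, weighted)
  if (variant == "harmonic") {
    sc <- igraph::harmonic_centrality(g, mode = "out", weights = w,
                                      normalized = TRUE)
  } else {
    sc <- suppressWarnings(
      igraph::closeness(g, mode = "out", weights = w, normalized = TRUE)
    )
    sc[is.na(sc)] <- 0
  }
  new_baseline(
    tibble(node = x$nodes, score = unname(sc[x$nodes])),
    "closeness",
    sprintf("%s closeness, outward distances = %s",
            variant, if (weighted) "1/weight" else "1")
  )
}

#' @rdname baselines
#' @export
eigenvector_centrality <- function(x, weighted = TRUE, tol = 1e-8,
                                   max_iter = 1000L, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  if (nrow(x$edges) == 0L) abort("Eigenvector centrality needs at least one edge.")
  nodes <- x$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- x$edges
  A[cbind(match(e$from, nodes), match(e$to, nodes))] <-
    if (weighted) e$weight else 1

  # score fed by in-edges: v = A^T v / lambda; the diagonal shift sigma keeps
  # the dominant eigenvalue unique (spectra of bipartite graphs are symmetric)
  # without changing the eigenvector
  sigma <- max(A)
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v_new <- drop(crossprod(A, v)) + sigma * v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) abort("Power iteration collapsed to the zero vector.")
    v_new <- v_new / nrm
    if (sqrt(sum((v_new - v)^2)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  if (!converged) {
    abort(sprintf("Eigenvector power iteration did not converge within %d iterations (tol %g).",
                  max_iter, tol))
  }
  v <- abs(v) # Perron vector of a nonnegative matrix is nonnegative
  new_baseline(
    tibble(node = nodes, score = unname(v)),
    "eigenvector",
    sprintf("power iteration on %s adjacency (in-edge fed), L2-normalised, tol %g",
            if (weighted) "weighted" else "binary", tol)
  )
}
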