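#' The 8-airport example network
#'
#' A small directed, weighted network of 8 airports (nodes `A`-`H`) and 26
#' airline connections; each weight is the number of flights on that
#' connection in the given direction. Used throughout the documentation and
#' tests as a fully worked example of the entropy centrality.
#'
#' @return A directed `weighted_network` with 8 nodes and 26 edges.
#' @examples
#' toy_network()
#' @export
toy_network <- function() {
  edges <- tibble(
    from = c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C", "D", "D", "D",
             "E", "E", "E", "E", "E", "F", "F", "F", "G", "G", "G", "H", "H"),
    to = c("B", "D", "F", "A", "C", "D", "E", "B", "E", "H", "A", "B", "E",
           "B", "C", "D", "F", "G", "A", "G", "E", "E", "F", "H", "C", "G"),
    weight = c(5, 1, 3, 4, 2, 3, 3, 4, 2, 5, 2, 5, 4,
               3, 3, 4, 2, 1, 1, 3, 2, 1, 1, 2, 1, 4)
  )
  weighted_network(edges, directed = TRUE)
}

#' Generate a random weighted network
#'
#' G(n, p)-style arc sampling with optional reciprocity augmentation and
#' i.i.d. positive weights. For directed networks each ordered pair gains an
#' arc with probability `p` (derived from `mean_out_degree / (n - 1)` or
#' given directly as `density`); each sampled arc then gains its reverse arc
#' with probability `reciprocity` (with an independently drawn weight) unless
#' the reverse was already sampled. Undirected networks sample unordered
#' pairs. If no edge is sampled, one arc between a uniformly chosen pair is
#' added so the network is never empty.
#'
#' @param n Number of nodes (labelled `n001`, `n002`, ...).
#' @param mean_out_degree Target mean out-degree (directed) or mean degree
#'   (undirected); mutually exclusive with `density`.
#' @param density Arc/edge probability `p` in (0, 1]; mutually exclusive with
#'   `mean_out_degree`.
#' @param reciprocity Probability in `[0, 1]` that a sampled arc gains its
#'   reverse (directed networks only; the example airline network is fully
#'   reciprocal, while most real directed networks are not).
#' @param weights Weight distribution: `"uniform"` (integers 1..`w_max`),
#'   `"geometric"` (1 + rgeom(`prob`)) or `"lognormal"`
#'   (rlnorm(`meanlog`, `sdlog`), continuous).
#' @param w_max,prob,meanlog,sdlog Parameters of the weight distributions.
#' @param directed Logical.
#' @param seed Optional integer seed; identical seeds give identical networks.
#' @return A `weighted_network` with `n` nodes and at least one edge.
#' @examples
#' random_network(20, mean_out_degree = 3, seed = 1)
#' @export
random_network <- function(n, mean_out_degree = NULL, density = NULL,
                           reciprocity = 0,
                           weights = c("uniform", "geometric", "lognormal"),
                           w_max = 10L, prob = 0.5, meanlog = 0, sdlog = 1,
                           directed = TRUE, seed = NULL) {
  weights <- arg_match(weights)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort("`n` must be an integer >= 2.")
  if (is.null(density) == is.null(mean_out_degree)) {
    abort("Supply exactly one of `mean_out_degree` or `density`.")
  }
  p <- if (!is.null(density)) density else mean_out_degree / (n - 1)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    abort("Edge probability must lie in (0, 1]; increase the density or mean out-degree.")
  }
  if (!is.numeric(reciprocity) || length(reciprocity) != 1L ||
      is.na(reciprocity) || reciprocity < 0 || reciprocity > 1) {
    abort("`reciprocity` must be a probability in [0, 1].")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  nodes <- sprintf("n%03d", seq_len(n))
  if (directed) {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  } else {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    pairs <- data.frame(from = idx[, "row"], to = idx[, "col"])
  }
  keep <- runif(nrow(pairs)) < p
  from <- pairs$from[keep]
  to <- pairs$to[keep]

  if (directed && reciprocity > 0 && length(from) > 0L) {
    key <- paste(from, to)
    rev_new <- runif(length(from)) < reciprocity & !(paste(to, from) %in% key)
    from <- c(from, to[rev_new])
    to <- c(to, pairs$from[keep][rev_new])
  }

  if (length(from) == 0L) {
    # guarantee at least one edge: resample a single uniformly chosen pair
    i <- sample.int(nrow(pairs), 1L)
    from <- pairs$from[i]
    to <- pairs$to[i]
  }

  w <- switch(weights,
    uniform = sample.int(as.integer(w_max), length(from), replace = TRUE),
    geometric = 1L + stats::rgeom(length(from), prob = prob),
    lognormal = stats::rlnorm(length(from), meanlog = meanlog, sdlog = sdlog)
  )
  weighted_network(
    tibble(from = nodes[from], to = nodes[to], weight = as.numeric(w)),
    directed = directed, nodes = nodes
  )
}
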