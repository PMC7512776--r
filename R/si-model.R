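#' SI spreading-model configuration
#'
#' Parameters of the discrete-time susceptible-infectious process used to
#' score seed sets. Two published weighted infection-probability forms are
#' supported: the Wang form, where a susceptible node is infected across an
#' edge of weight `w` with per-step probability `1 - (1 - beta)^w` (the
#' weight acts as a number of independent contacts), and the Yan form
#' `(w / w_max)^alpha`.
#'
#' @param beta Per-contact infection probability in `[0, 1]` (Wang form);
#'   `beta = 0` yields a degenerate process with no transmission.
#' @param model `"wang"` (default) or `"yan"`.
#' @param alpha Positive exponent of the Yan form (ignored for `"wang"`).
#' @param t_max Number of time steps to simulate (default 30).
#' @param replicates Number of Monte-Carlo replicates (default 1000).
#' @param seed Optional integer seed; when supplied, results are bit-for-bit
#'   reproducible (replicate r uses seed + r, so identical seeds give
#'   identical noise across methods and seed sets).
#' @return A list of class `si_config`.
#' @examples
#' si_config(beta = 0.1, t_max = 20, replicates = 100, seed = 1)
#' @export
si_config <- function(beta, model = c("wang", "yan"), alpha = 1,
                      t_max = 30L, replicates = 1000L, seed = NULL) {
  model <- arg_match(model)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    abort("`beta` must be a single probability in [0, 1].")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  t_max <- as.integer(t_max)
  replicates <- as.integer(replicates)
  if (is.na(t_max) || t_max < 1L) abort("`t_max` must be a positive integer.")
  if (is.na(replicates) || replicates < 1L) abort("`replicates` must be a positive integer.")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) abort("`seed` must be an integer.")
  }
  structure(
    list(beta = beta, model = model, alpha = alpha, t_max = t_max,
         replicates = replicates, seed = seed),
    class = "si_config"
  )
}

#' Per-edge infection probability
#'
#' Wang form: `1 - (1 - beta)^w`. Yan form: `(w / w_max)^alpha`. Vectorised
#' over `w`.
#'
#' @param config An [si_config()].
#' @param w Positive edge weight(s).
#' @param w_max Largest weight in the network (required by the Yan form;
#'   defaults to `max(w)`).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' infection_probability(si_config(beta = 0.1), w = 2) # 0.19
#' @export
infection_probability <- function(config, w, w_max = max(w)) {
  if (!inherits(config, "si_config")) abort("`config` must be an si_config.")
  if (any(w <= 0)) abort("Edge weights must be positive.")
  switch(config$model,
    wang = 1 - (1 - config$beta)^w,
    yan = {
      if (any(w > w_max)) abort("`w_max` must be at least max(w).")
      (w / w_max)^config$alpha
    }
  )
}

#' Run the weighted SI spreading process
#'
#' Discrete-time synchronous dynamics: at every step each susceptible node is
#' challenged once by each currently infected in-neighbour `j` along the edge
#' `j -> i`, independently with probability [infection_probability()] of that
#' edge's weight; infections take effect at the end of the step, and infected
#' nodes stay infected. Undirected networks transmit along both orientations
#' with the single edge weight.
#'
#' @param x A `weighted_network` or edge data frame.
#' @param seeds Character vector of initially infected nodes (non-empty).
#' @param config An [si_config()].
#' @param directed Logical, used only when `x` is an edge data frame.
#' @return An object of class `si_result`: list with `trajectory` (tibble
#'   `t`, `mean_infected`, `sd_infected` for t = 0..t_max), `counts` (integer
#'   matrix, replicates x time points), `seeds` and `config`. The mean curve
#'   is non-decreasing and starts at `length(seeds)`.
#' @examples
#' run_si(toy_network(), seeds = c("E", "B"),
#'        config = si_config(beta = 0.2, t_max = 5, replicates = 50, seed = 1))
#' @export
run_si <- function(x, seeds, config, directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  if (!inherits(config, "si_config")) abort("`config` must be an si_config.")
  if (length(seeds) == 0L) abort("`seeds` must contain at least one node.")
  seeds <- unique(as.character(seeds))
  unknown <- setdiff(seeds, x$nodes)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown seed node(s): %s.", paste(head(unknown, 5L), collapse = ", ")))
  }

  n <- length(x$nodes)
  src <- match(x$edges$from, x$nodes)
  dst <- match(x$edges$to, x$nodes)
  w_max <- if (nrow(x$edges) > 0L) max(x$edges$weight) else 1
  p_edge <- if (nrow(x$edges) > 0L) {
    infection_probability(config, x$edges$weight, w_max)
  } else {
    numeric(0)
  }
  seed_idx <- match(seeds, x$nodes)

  counts <- matrix(0L, nrow = config$replicates, ncol = config$t_max + 1L)
  for (r in seq_len(config$replicates)) {
    if (!is.null(config$seed)) {
      set.seed((config$seed + r) %% .Machine$integer.max)
    }
    infected <- logical(n)
    infected[seed_idx] <- TRUE
    counts[r, 1L] <- sum(infected)
    for (t in seq_len(config$t_max)) {
      if (all(infected) || length(p_edge) == 0L) {
        counts[r, (t + 1L):(config$t_max + 1L)] <- sum(infected)
        break
      }
      live <- which(infected[src] & !infected[dst])
      if (length(live) > 0L) {
        hit <- live[runif(length(live)) < p_edge[live]]
        infected[dst[hit]] <- TRUE
      }
      counts[r, t + 1L] <- sum(infected)
    }
  }

  trajectory <- tibble(
    t = 0:config$t_max,
    mean_infected = colMeans(counts),
    sd_infected = apply(counts, 2L, sd)
  )
  structure(
    list(trajectory = trajectory, counts = counts, seeds = seeds,
         config = config),
    class = "si_result"
  )
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result: %s model, beta = %g, %d seed(s), %d replicates, t_max = %d>\n",
              x$config$model, x$config$beta, length(x$seeds),
              x$config$replicates, x$config$t_max))
  cat(sprintf("  final mean infected: %.2f\n",
              x$trajectory$mean_infected[nrow(x$trajectory)]))
  invisible(x)
}

#' @export
tidy.si_result <- function(x, ...) x$trajectory

#' @export
glance.si_result <- function(x, ...) {
  tibble(
    model = x$config$model, beta = x$config$beta,
    n_seeds = length(x$seeds), replicates = x$config$replicates,
    t_max = x$config$t_max,
    final_mean_infected = x$trajectory$mean_infected[nrow(x$trajectory)]
  )
}

#' Select the top-k seed nodes from a ranking
#'
#' @param scores A `centrality_ranking` tibble (from [entropy_centrality()]
#'   or a baseline).
#' @param k Number of seeds, `1 <= k <= n`.
#' @return Character vector of the k highest-ranked nodes, in rank order
#'   (deterministic under the ranking's tie-breaking).
#' @examples
#' top_k_seeds(entropy_centrality(toy_network()), 2) # "E" "B"
#' @export
top_k_seeds <- function(scores, k) {
  if (!inherits(scores, "centrality_ranking")) {
    abort("`scores` must be a centrality table.")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  if (k > nrow(scores)) {
    abort(sprintf("k = %d exceeds the number of nodes (%d).", k, nrow(scores)))
  }
  scores$node[order(scores$rank)][seq_len(k)]
}

#' Compare ranking methods by simulated influence spread
#'
#' For every method and every seed-set size `k`, selects the top-k nodes
#' under that method's ranking and runs the SI process. All method/k
#' combinations reuse the same per-replicate random substreams (derived from
#' `config$seed`), so every method faces identical noise and results are
#' deterministic given the configuration.
#'
#' @param x A `weighted_network` or edge data frame.
#' @param methods Character vector among `"entropy"`, `"degree"`,
#'   `"betweenness"`, `"closeness"`, `"eigenvector"`.
#' @param k Integer vector of seed-set sizes (default `c(10, 20, 30, 40, 50)`).
#' @param config An [si_config()].
#' @param omega1,omega2,theta1,theta2,log_base Coefficients passed to
#'   [entropy_centrality()] when `"entropy"` is among the methods.
#' @param directed Logical, used only when `x` is an edge data frame.
#' @return A tibble of class `si_comparison` in tidy long format with columns
#'   `method`, `k`, `t`, `mean_infected`, `sd_infected`.
#' @export
compare_methods <- function(x,
                            methods = c("entropy", "degree", "betweenness",
                                        "closeness", "eigenvector"),
                            k = c(10L, 20L, 30L, 40L, 50L),
                            config = si_config(beta = 0.05),
                            omega1 = 0.4, omega2 = 0.6,
                            theta1 = 0.6, theta2 = 0.4, log_base = 10,
                            directed = TRUE) {
  x <- as_weighted_network(x, directed = directed)
  methods <- unique(match.arg(methods, c("entropy", "degree", "betweenness",
                                         "closeness", "eigenvector"),
                              several.ok = TRUE))
  k <- as.integer(k)
  if (any(is.na(k) | k < 1L)) abort("`k` must contain positive integers.")
  bad_k <- k[k > length(x$nodes)]
  if (length(bad_k) > 0L) {
    abort(sprintf("k = %d exceeds the number of nodes (%d).",
                  bad_k[1L], length(x$nodes)))
  }

  rankings <- lapply(setNames(methods, methods), function(m) {
    switch(m,
      entropy = entropy_centrality(x, omega1 = omega1, omega2 = omega2,
                                   theta1 = theta1, theta2 = theta2,
                                   log_base = log_base),
      degree = degree_centrality(x),
      betweenness = betweenness_centrality(x),
      closeness = closeness_centrality(x),
      eigenvector = eigenvector_centrality(x)
    )
  })

  rows <- list()
  for (m in methods) {
    for (kk in sort(k)) {
      seeds <- top_k_seeds(rankings[[m]], kk)
      res <- run_si(x, seeds, config)
      rows[[length(rows) + 1L]] <- mutate(res$trajectory, method = m, k = kk)
    }
  }
  out <- bind_rows(rows) |>
    select("method", "k", "t", "mean_infected", "sd_infected")
  structure(out,
            class = c("si_comparison", class(out)),
            config = config)
}
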