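#' Read a weighted edge list from a delimited file
#'
#' Reads `source <sep> target <sep> weight` records. The separator (tab,
#' comma, or whitespace) is detected from the first data line. Lines starting
#' with `%` or `#` are treated as comments and skipped, which accommodates
#' KONECT-style headers. A header line is not expected; a first line whose
#' third field is not numeric is skipped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; interpret edges as directed. This is an explicit
#'   flag, never inferred from the file.
#' @return A [weighted_network()].
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) abort(sprintf("Edge-list file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[%#]", lines)]
  if (length(lines) == 0L) abort(sprintf("No edge records in '%s'.", path))

  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
  fields <- strsplit(lines, sep)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("Line %d of '%s' has fewer than 3 fields.", which(nf < 3L)[1L], path))
  }
  tab <- tibble(
    from = trimws(vapply(fields, `[[`, "", 1L)),
    to = trimws(vapply(fields, `[[`, "", 2L)),
    weight = trimws(vapply(fields, `[[`, "", 3L))
  )
  w1 <- suppressWarnings(as.numeric(tab$weight[[1L]]))
  if (is.na(w1) && nrow(tab) > 1L) {
    warn("First line does not have a numeric weight; treating it as a header and skipping it.")
    tab <- tab[-1L, , drop = FALSE]
  }
  tab$weight <- suppressWarnings(as.numeric(tab$weight))
  weighted_network(tab, directed = directed)
}

#' Write a network as a tab-separated edge list
#'
#' Writes `source<TAB>target<TAB>weight` lines with no header. Undirected
#' edges are written once (canonical orientation). The output round-trips
#' through [read_edge_list()] to an identical network.
#'
#' @param x A `weighted_network` or edge data frame.
#' @param path Destination file path.
#' @return Invisibly, the path written.
#' @export
write_edge_list <- function(x, path) {
  x <- as_weighted_network(x)
  if (length(x$nodes) == 0L) abort("Refusing to write a network with no nodes.")
  e <- network_edges(x, canonical = TRUE)
  lines <- sprintf("%s\t%s\t%s", e$from, e$to,
                   format(e$weight, trim = TRUE, scientific = FALSE, digits = 15))
  writeLines(lines, path)
  invisible(path)
}
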