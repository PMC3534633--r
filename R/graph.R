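#' Similarity graphs of protein structures
#'
#' A `tern_graph` holds the undirected graph G = (O, E) of items (protein
#' domains) and significant pairwise similarities. Each edge carries its
#' alignment mapping, which the ternary constraint machinery consumes later.
#' Internally it is a list with `items` (character vector of vertex ids) and
#' `edges` (a mappings tibble, one row per edge, plus an `edge` key column).
#'
#' @param items Character vector of vertex ids.
#' @param edges A mappings tibble ([as_mappings()]); every endpoint must be in
#'   `items`.
#' @return A `tern_graph`.
#' @export
tern_graph <- function(items, edges) {
  items <- sort(unique(as.character(items)))
  stopifnot(is.data.frame(edges))
  endpoints <- union(edges$item_a, edges$item_b)
  if (!all(endpoints %in% items)) {
    rlang::abort(paste0(
      "edge endpoints outside the item set: ",
      paste(setdiff(endpoints, items), collapse = ", ")
    ))
  }
  edges <- tibble::as_tibble(edges)
  edges$edge <- edge_key(edges$item_a, edges$item_b)
  edges <- dplyr::relocate(edges, "edge")
  structure(list(items = items, edges = edges), class = "tern_graph")
}

edge_key <- function(a, b) paste(a, b, sep = "--")

#' @export
print.tern_graph <- function(x, ...) {
  cat(sprintf(
    "<tern_graph> %d items, %d edges\n", length(x$items), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of items / edges of a similarity graph
#' @param graph A `tern_graph`.
#' @return An integer.
#' @export
n_items <- function(graph) length(graph$items)

#' @rdname n_items
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Pairwise similarity predicate
#'
#' Decides whether an alignment counts as a significant similarity. Two
#' criteria are supported: `"score"` keeps alignments whose aligner score
#' (e.g. a YAKUSA z-score) is at least `t_o` — the criterion used with
#' t_o = 7.0 in the reference experiment — and `"count"` keeps alignments with
#' at least `t_o` mapped part pairs. Both comparisons are inclusive.
#'
#' @param mappings A mappings tibble (one or more rows).
#' @param t_o Pairwise threshold.
#' @param criterion `"score"` or `"count"`.
#' @return Logical vector, one element per mapping row.
#' @export
sim_o <- function(mappings, t_o = 7, criterion = c("score", "count")) {
  criterion <- rlang::arg_match(criterion)
  stopifnot(is.numeric(t_o), length(t_o) == 1, is.finite(t_o))
  switch(criterion,
    score = mappings$score >= t_o,
    count = purrr::map_int(mappings$pairs, nrow) >= t_o
  )
}

#' Build the similarity graph from alignment mappings
#'
#' Vertices are every item named by any mapping; edges are exactly the
#' mappings passing [sim_o()] at threshold `t_o`. Items whose every alignment
#' fell below the threshold remain as isolated vertices until
#' [drop_isolated()].
#'
#' @param mappings A mappings tibble or long-form data frame accepted by
#'   [as_mappings()]. Duplicate unordered pairs are an error.
#' @inheritParams sim_o
#' @return A `tern_graph`.
#' @examples
#' m <- as_mappings(data.frame(
#'   item_a = c("A", "B"), item_b = c("B", "C"),
#'   score = c(7.5, 6.0), pos_a = 1L, pos_b = 1L
#' ))
#' build_graph(m, t_o = 7, criterion = "score")
#' @export
build_graph <- function(mappings, t_o = 7, criterion = c("score", "count")) {
  criterion <- rlang::arg_match(criterion)
  mappings <- as_mappings(mappings)
  keep <- sim_o(mappings, t_o = t_o, criterion = criterion)
  tern_graph(
    items = union(mappings$item_a, mappings$item_b),
    edges = mappings[keep, , drop = FALSE]
  )
}

#' Remove isolated items from a similarity graph
#'
#' Items similar to nothing (degree 0) carry no information for a
#' connectivity-based clustering and are removed before processing. The
#' dropped ids are attached as attribute `"dropped"`.
#'
#' @param graph A `tern_graph`.
#' @return A `tern_graph` without degree-0 vertices.
#' @export
drop_isolated <- function(graph) {
  linked <- union(graph$edges$item_a, graph$edges$item_b)
  dropped <- setdiff(graph$items, linked)
  out <- tern_graph(items = linked, edges = graph$edges)
  attr(out, "dropped") <- sort(dropped)
  out
}

#' Item degrees
#' @param graph A `tern_graph`.
#' @return A tibble with columns `item`, `degree` covering every item.
#' @export
graph_degrees <- function(graph) {
  tibble::tibble(item = c(graph$edges$item_a, graph$edges$item_b)) |>
    dplyr::count(.data$item, name = "degree") |>
    dplyr::right_join(tibble::tibble(item = graph$items), by = "item") |>
    tidyr::replace_na(list(degree = 0L)) |>
    dplyr::arrange(.data$item)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges[, c("item_a", "item_b")],
    directed = FALSE,
    vertices = data.frame(name = graph$items)
  )
}

#' Independent connected components (ICCs)
#'
#' Splits a similarity graph into its connected components, the coarse
#' pre-partition the reduction refines. Components are ordered by decreasing
#' vertex count, ties broken by smallest member id.
#'
#' @param graph A `tern_graph`.
#' @return A list of `tern_graph`s, vertex- and edge-disjoint, exhausting the
#'   input.
#' @export
graph_components <- function(graph) {
  if (length(graph$items) == 0) return(list())
  comp <- igraph::components(as_igraph(graph))
  member <- split(names(comp$membership), comp$membership)
  ord <- order(
    -purrr::map_int(member, length),
    purrr::map_chr(member, min)
  )
  member <- member[ord]
  purrr::map(member, function(ids) {
    tern_graph(
      items = ids,
      edges = graph$edges[graph$edges$item_a %in% ids, , drop = FALSE]
    )
  }) |> unname()
}

#' Summary statistics of a graph's components
#' @param graph A `tern_graph`.
#' @return One-row tibble: `n_items`, `n_edges`, `n_icc`, `largest_icc`,
#'   `mean_icc`.
#' @export
component_stats <- function(graph) {
  comps <- graph_components(graph)
  sizes <- purrr::map_int(comps, n_items)
  tibble::tibble(
    n_items = n_items(graph),
    n_edges = n_edges(graph),
    n_icc = length(comps),
    largest_icc = if (length(sizes)) max(sizes) else 0L,
    mean_icc = if (length(sizes)) mean(sizes) else NA_real_
  )
}

#' Serialize a similarity graph to JSON and back
#'
#' The JSON document lists `items`, then `edges` with per-edge mapped pairs
#' (`pos_a`, `pos_b` arrays), in stable key order, so graphs can move between
#' CLI stages.
#'
#' @param graph A `tern_graph`.
#' @param path File path.
#' @return `write_graph_json()` returns `path` invisibly; `read_graph_json()`
#'   returns a `tern_graph`.
#' @export
write_graph_json <- function(graph, path) {
  edges <- purrr::pmap(
    graph$edges[, c("item_a", "item_b", "score", "pairs")],
    function(item_a, item_b, score, pairs) {
      list(
        item_a = item_a, item_b = item_b, score = score,
        pos_a = pairs$pos_a, pos_b = pairs$pos_b
      )
    }
  )
  doc <- list(items = graph$items, edges = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- purrr::map_chr(doc$items, identity)
  if (length(doc$edges) == 0) {
    edges <- tibble::tibble(
      item_a = character(), item_b = character(),
      score = numeric(), pairs = list()
    )
  } else {
    edges <- purrr::map_dfr(doc$edges, function(e) {
      tibble::tibble(
        item_a = e$item_a, item_b = e$item_b, score = e$score,
        pairs = list(tibble::tibble(
          pos_a = as.integer(unlist(e$pos_a)),
          pos_b = as.integer(unlist(e$pos_b))
        ))
      )
    })
    edges <- as_mappings(edges)
  }
  tern_graph(items = items, edges = edges)
}
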