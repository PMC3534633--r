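#' Labeled line-graph transformation
#'
#' The line graph L(G) = (E, F) has one vertex per edge of G and joins two
#' vertices whenever the corresponding G-edges share an endpoint. Because G
#' has no parallel edges, two adjacent edges share exactly one item — the
#' *center* — which is recorded on every line edge. With vertex labels kept
#' (each line vertex is the pair of item ids it came from) the transformation
#' is invertible, which is what lets edge-removal decisions made on L(G) be
#' carried back to G.
#'
#' A `tern_line_graph` is a list with `vertices` (the source graph's edge
#' tibble, keyed by `edge`) and `edges` (tibble `edge_1`, `edge_2`, `center`,
#' `satisfied`; flags start `TRUE` and are set by [mark_line_graph()]).
#'
#' @param graph A `tern_graph` (no self-loops or parallel edges by
#'   construction).
#' @return A `tern_line_graph`.
#' @examples
#' m <- as_mappings(data.frame(
#'   item_a = c("a", "b"), item_b = c("b", "c"),
#'   score = 9, pos_a = 1L, pos_b = 1L
#' ))
#' line_graph(build_graph(m, t_o = 7))
#' @export
line_graph <- function(graph) {
  stopifnot(inherits(graph, "tern_graph"))
  incidence <- tibble::tibble(
    edge = rep(graph$edges$edge, 2),
    item = c(graph$edges$item_a, graph$edges$item_b)
  )
  by_item <- split(incidence$edge, incidence$item)
  ledges <- purrr::imap(by_item, function(edges, center) {
    if (length(edges) < 2) return(NULL)
    edges <- sort(edges)
    idx <- utils::combn(length(edges), 2)
    tibble::tibble(
      edge_1 = edges[idx[1, ]],
      edge_2 = edges[idx[2, ]],
      center = center
    )
  })
  ledges <- dplyr::bind_rows(ledges)
  if (nrow(ledges) == 0) {
    ledges <- tibble::tibble(
      edge_1 = character(), edge_2 = character(), center = character()
    )
  } else {
    # no parallel G-edges, so each adjacent pair has a unique center
    key <- paste(ledges$edge_1, ledges$edge_2, sep = "\r")
    stopifnot(!anyDuplicated(key))
    ledges <- dplyr::arrange(ledges, .data$edge_1, .data$edge_2)
  }
  ledges$satisfied <- rep(TRUE, nrow(ledges))
  structure(
    list(vertices = graph$edges, edges = ledges),
    class = "tern_line_graph"
  )
}

#' @export
print.tern_line_graph <- function(x, ...) {
  cat(sprintf(
    "<tern_line_graph> %d vertices (G-edges), %d edges (%d marked)\n",
    nrow(x$vertices), nrow(x$edges), sum(!x$edges$satisfied)
  ))
  invisible(x)
}

#' Invert a labeled line graph back to an item graph
#'
#' Each line vertex is a labeled G-edge, so the inverse transformation simply
#' reassembles the graph whose edge set is the current line-vertex set
#' (removing a line vertex removes the corresponding G-edge). Items of
#' `item_universe` left with no incident edge are excluded from the result and
#' reported in attribute `"absent"`.
#'
#' @param line A `tern_line_graph`.
#' @param item_universe Character vector of the source graph's item ids; line
#'   vertex labels outside it are an error.
#' @return A `tern_graph` with attribute `"absent"`.
#' @export
from_line_graph <- function(line, item_universe) {
  stopifnot(inherits(line, "tern_line_graph"))
  endpoints <- union(line$vertices$item_a, line$vertices$item_b)
  stray <- setdiff(endpoints, item_universe)
  if (length(stray) > 0) {
    rlang::abort(paste0(
      "line vertices name items outside the universe: ",
      paste(stray, collapse = ", ")
    ))
  }
  out <- tern_graph(items = endpoints, edges = line$vertices)
  attr(out, "absent") <- sort(setdiff(item_universe, endpoints))
  out
}

#' Component correspondence between a graph and its line graph
#'
#' On a graph without isolated vertices, connected components of G and of
#' L(G) are in one-to-one correspondence: a G-component's edges form exactly
#' one L-component. The bijection is computed by locating, for each
#' G-component, the L-component containing its edges, and verified to be
#' one-to-one.
#'
#' @param graph A `tern_graph` with no isolated vertices.
#' @param line Its line graph, `line_graph(graph)`.
#' @return A tibble `g_component`, `l_component` (integer indices into
#'   [graph_components()] ordering and an analogous line-graph component
#'   ordering), one row per component.
#' @export
component_bijection <- function(graph, line) {
  deg0 <- setdiff(graph$items, union(graph$edges$item_a, graph$edges$item_b))
  if (length(deg0) > 0) {
    rlang::abort("graph has isolated vertices; drop them first")
  }
  g_comps <- graph_components(graph)
  l_comps <- line_components(line)
  g_edge_sets <- purrr::map(g_comps, function(g) sort(g$edges$edge))
  pairing <- purrr::imap_int(g_edge_sets, function(edges, i) {
    hit <- which(purrr::map_lgl(l_comps, function(vs) all(edges %in% vs)))
    if (length(hit) != 1 || !setequal(l_comps[[hit]], edges)) {
      rlang::abort("component bijection violated: malformed line graph")
    }
    hit
  })
  if (anyDuplicated(pairing) || length(pairing) != length(l_comps)) {
    rlang::abort("component bijection violated: counts differ")
  }
  tibble::tibble(
    g_component = seq_along(g_comps),
    l_component = as.integer(pairing)
  )
}

# connected components of the line graph, as lists of line-vertex keys,
# ordered by decreasing size then smallest member
line_components <- function(line) {
  if (nrow(line$vertices) == 0) return(list())
  ig <- igraph::graph_from_data_frame(
    d = line$edges[, c("edge_1", "edge_2")],
    directed = FALSE,
    vertices = data.frame(name = line$vertices$edge)
  )
  comp <- igraph::components(ig)
  member <- split(names(comp$membership), comp$membership)
  ord <- order(
    -purrr::map_int(member, length),
    purrr::map_chr(member, min)
  )
  purrr::map(member[ord], sort) |> unname()
}
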