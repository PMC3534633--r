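#' Parts of the central item mapped in both of its alignments
#'
#' For two alignments that share an item (the center), returns the positions
#' of the center that appear in both mappings — the substructure of the center
#' that its two neighbors both align to.
#'
#' @param mapping_left,mapping_right One-row mapping tibbles (rows of a graph's
#'   edge table), both involving `center`.
#' @param center Item id shared by the two mappings.
#' @return Sorted integer vector of center positions mapped in both
#'   alignments.
#' @export
central_overlap <- function(mapping_left, mapping_right, center) {
  sort(intersect(
    center_positions(mapping_left, center),
    center_positions(mapping_right, center)
  ))
}

center_positions <- function(mapping, center) {
  stopifnot(nrow(mapping) == 1)
  p <- mapping$pairs[[1]]
  if (mapping$item_a == center) {
    p$pos_a
  } else if (mapping$item_b == center) {
    p$pos_b
  } else {
    rlang::abort(paste0(
      "item ", center, " is not part of the mapping (",
      mapping$item_a, ",", mapping$item_b, ")"
    ))
  }
}

#' Centered ternary similarity of three items
#'
#' Three items o', o, o'' linked by alignments (o', o) and (o, o'') share a
#' common substructure when the parts of the central item o mapped in *both*
#' alignments make up at least a fraction `t` of the smaller alignment:
#' `|overlap| >= t * min(|M(o,o')|, |M(o,o'')|)`, inclusive. This is the
#' constraint the graph reduction enforces on every pair of adjacent edges.
#'
#' @inheritParams central_overlap
#' @param t Ternary similarity threshold in \[0, 1\].
#' @return A one-row tibble: `center`, `left`, `right`, `overlap_count`,
#'   `min_alignment`, `fraction`, `satisfied`.
#' @examples
#' # two alignments of 3 and 4 mapped pairs overlapping in 2 center positions
#' m <- as_mappings(data.frame(
#'   item_a = c(rep("b", 3), rep("b", 4)),
#'   item_b = c(rep("a", 3), rep("c", 4)),
#'   score = 9,
#'   pos_a = c(1L, 2L, 3L, 2L, 3L, 4L, 5L),
#'   pos_b = c(1L, 2L, 3L, 1L, 2L, 3L, 4L)
#' ))
#' sim3(m[1, ], m[2, ], center = "b", t = 0.65)
#' @export
sim3 <- function(mapping_left, mapping_right, center, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t > 1) {
    rlang::abort("ternary threshold t must be a number in [0, 1]")
  }
  ov <- central_overlap(mapping_left, mapping_right, center)
  n_left <- nrow(mapping_left$pairs[[1]])
  n_right <- nrow(mapping_right$pairs[[1]])
  other <- function(m) if (m$item_a == center) m$item_b else m$item_a
  overlap_count <- length(ov)
  min_alignment <- min(n_left, n_right)
  tibble::tibble(
    center = center,
    left = other(mapping_left),
    right = other(mapping_right),
    overlap_count = overlap_count,
    min_alignment = min_alignment,
    fraction = overlap_count / min_alignment,
    satisfied = overlap_count >= t * min_alignment
  )
}

#' Mark line-graph edges violating the ternary constraint
#'
#' Every line edge joins two alignments sharing a center item, so the ternary
#' test applies to each. Edges failing it are *marked* (`satisfied = FALSE`);
#' the satisfied set F_T and marked set F-bar_T partition the line edges.
#'
#' @param line A `tern_line_graph`.
#' @param t Ternary threshold in \[0, 1\].
#' @return The line graph with per-edge `overlap_count`, `min_alignment`,
#'   `fraction`, `satisfied` filled in, and attributes `n_satisfied`,
#'   `n_marked`, `t`.
#' @export
mark_line_graph <- function(line, t) {
  stopifnot(inherits(line, "tern_line_graph"))
  v <- line$vertices
  le <- line$edges
  if (nrow(le) > 0) {
    i1 <- match(le$edge_1, v$edge)
    i2 <- match(le$edge_2, v$edge)
    checks <- purrr::pmap_dfr(
      list(i1, i2, le$center),
      function(a, b, ctr) sim3(v[a, ], v[b, ], ctr, t)
    )
    le$overlap_count <- checks$overlap_count
    le$min_alignment <- checks$min_alignment
    le$fraction <- checks$fraction
    le$satisfied <- checks$satisfied
  } else {
    le$overlap_count <- integer()
    le$min_alignment <- integer()
    le$fraction <- numeric()
  }
  out <- structure(list(vertices = v, edges = le), class = "tern_line_graph")
  attr(out, "t") <- t
  attr(out, "n_satisfied") <- sum(le$satisfied)
  attr(out, "n_marked") <- sum(!le$satisfied)
  out
}

#' Greedy removal of line vertices until no marked edge remains
#'
#' Let N be the subgraph of the line graph induced by the marked edges. While
#' N still has edges: find the maximum degree Delta(N) over its vertices,
#' remove *all* vertices attaining it in one batch, and accumulate them into
#' the removal set E_T. Removing a line vertex removes the corresponding edge
#' of G, so the surviving line graph inverts to the reduced graph G_T, which
#' satisfies every ternary constraint. Removing highest-degree vertices first
#' maximizes marked edges cleared per vertex spent, keeping E_T small (it is
#' a vertex cover of N, not necessarily minimum).
#'
#' @param line A *marked* `tern_line_graph` (see [mark_line_graph()]).
#' @param item_universe Item ids of the source graph; defaults to the
#'   endpoints named by the line vertices.
#' @param one_at_a_time If `TRUE`, remove a single max-degree vertex
#'   (smallest label) per iteration instead of the whole batch.
#' @return A `tern_reduction`: list with `removed` (tibble of removed G-edges),
#'   `graph` (the reduced `tern_graph` G_T, attribute `"absent"` listing items
#'   that lost all their edges), `trace` (tibble `iteration`, `delta`,
#'   `n_removed`, `n_marked_remaining`) and `t` (threshold used for marking,
#'   `NA` if the line graph was never marked).
#' @export
heuristic_reduce <- function(line, item_universe = NULL, one_at_a_time = FALSE) {
  stopifnot(inherits(line, "tern_line_graph"))
  if (is.null(item_universe)) {
    item_universe <- union(line$vertices$item_a, line$vertices$item_b)
  }
  marked <- line$edges[!line$edges$satisfied, c("edge_1", "edge_2")]
  removed <- character()
  trace <- list()
  iter <- 0L
  while (nrow(marked) > 0) {
    iter <- iter + 1L
    deg <- table(c(marked$edge_1, marked$edge_2))
    delta <- max(deg)
    batch <- sort(names(deg)[deg == delta])
    if (one_at_a_time) batch <- batch[1]
    removed <- c(removed, batch)
    marked <- marked[!(marked$edge_1 %in% batch | marked$edge_2 %in% batch), ]
    trace[[iter]] <- tibble::tibble(
      iteration = iter,
      delta = as.integer(delta),
      n_removed = length(batch),
      n_marked_remaining = nrow(marked)
    )
  }
  keep_v <- !(line$vertices$edge %in% removed)
  keep_e <- line$edges$edge_1 %in% line$vertices$edge[keep_v] &
    line$edges$edge_2 %in% line$vertices$edge[keep_v]
  pruned <- structure(
    list(
      vertices = line$vertices[keep_v, , drop = FALSE],
      edges = line$edges[keep_e, , drop = FALSE]
    ),
    class = "tern_line_graph"
  )
  g_t <- from_line_graph(pruned, item_universe)
  structure(
    list(
      removed = line$vertices[!keep_v, , drop = FALSE],
      graph = g_t,
      trace = if (iter > 0) dplyr::bind_rows(trace) else tibble::tibble(
        iteration = integer(), delta = integer(),
        n_removed = integer(), n_marked_remaining = integer()
      ),
      t = attr(line, "t") %||% NA_real_
    ),
    class = "tern_reduction"
  )
}

#' Reduce a similarity graph to satisfy all ternary constraints
#'
#' Convenience pipeline: line graph, mark at threshold `t`, greedy reduction,
#' and an exhaustive re-check that the reduced graph violates no ternary
#' constraint (an internal error otherwise).
#'
#' @param graph A `tern_graph`.
#' @inheritParams mark_line_graph
#' @inheritParams heuristic_reduce
#' @return A `tern_reduction` (see [heuristic_reduce()]).
#' @export
reduce_graph <- function(graph, t, one_at_a_time = FALSE) {
  marked <- mark_line_graph(line_graph(graph), t)
  res <- heuristic_reduce(
    marked,
    item_universe = graph$items,
    one_at_a_time = one_at_a_time
  )
  leftover <- verify_ternary(res$graph, t)
  if (nrow(leftover) > 0) {
    rlang::abort("internal error: reduced graph still violates ternary constraints")
  }
  res
}

#' @export
print.tern_reduction <- function(x, ...) {
  cat(sprintf(
    "<tern_reduction> t = %s: removed %d edges in %d iterations; G_T has %d items, %d edges (%d items absent)\n",
    format(x$t), nrow(x$removed), nrow(x$trace),
    n_items(x$graph), n_edges(x$graph), length(attr(x$graph, "absent"))
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration trace of a graph reduction
#' @param x A `tern_reduction`.
#' @param ... Unused.
#' @return The trace tibble: `iteration`, `delta`, `n_removed`,
#'   `n_marked_remaining`.
#' @export
tidy.tern_reduction <- function(x, ...) x$trace

#' One-row summary of a graph reduction
#' @param x A `tern_reduction`.
#' @param ... Unused.
#' @return Tibble: `t`, `n_removed_edges`, `n_iterations`, `n_items`,
#'   `n_edges`, `n_absent_items`.
#' @export
glance.tern_reduction <- function(x, ...) {
  tibble::tibble(
    t = x$t,
    n_removed_edges = nrow(x$removed),
    n_iterations = nrow(x$trace),
    n_items = n_items(x$graph),
    n_edges = n_edges(x$graph),
    n_absent_items = length(attr(x$graph, "absent"))
  )
}

#' Exhaustively check every ternary constraint of a graph
#'
#' Enumerates every length-2 path o'–o–o'' (every pair of adjacent edges) and
#' evaluates the centered ternary similarity at threshold `t`. An empty result
#' certifies the graph: every linked triple shares a common substructure at
#' level `t`.
#'
#' @param graph A `tern_graph`.
#' @param t Ternary threshold in \[0, 1\].
#' @return Tibble of violating checks (columns as [sim3()]), zero rows if the
#'   graph satisfies all constraints.
#' @export
verify_ternary <- function(graph, t) {
  line <- mark_line_graph(line_graph(graph), t)
  le <- line$edges[!line$edges$satisfied, , drop = FALSE]
  if (nrow(le) == 0) {
    return(tibble::tibble(
      center = character(), left = character(), right = character(),
      overlap_count = integer(), min_alignment = integer(),
      fraction = numeric(), satisfied = logical()
    ))
  }
  v <- line$vertices
  other <- function(keys) {
    i <- match(keys, v$edge)
    ifelse(v$item_a[i] == le$center, v$item_b[i], v$item_a[i])
  }
  tibble::tibble(
    center = le$center,
    left = other(le$edge_1),
    right = other(le$edge_2),
    overlap_count = as.integer(le$overlap_count),
    min_alignment = as.integer(le$min_alignment),
    fraction = le$fraction,
    satisfied = le$satisfied
  )
}
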