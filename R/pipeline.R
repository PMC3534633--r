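#' Default parameter grids for the T-by-I experiment
#'
#' Ternary thresholds 0.05 to 0.95 in steps of 0.05; MCL inflation 1.2 to 2.0
#' in steps of 0.1 plus 2.0 to 3.0 in steps of 0.2.
#'
#' @return Numeric vector.
#' @export
default_t_grid <- function() seq(0.05, 0.95, by = 0.05)

#' @rdname default_t_grid
#' @export
default_inflation_grid <- function() {
  sort(unique(round(c(seq(1.2, 2, by = 0.1), seq(2, 3, by = 0.2)), 10)))
}

# one row per (t, inflation): reduction stats + clustering stats (+ metrics)
grid_runs <- function(graph, t_grid, inflation_grid, reference = NULL,
                      universe = graph$items, one_at_a_time = FALSE,
                      weighted = FALSE, ...) {
  ts <- c(NA_real_, t_grid) # NA = baseline, no reduction
  purrr::map_dfr(ts, function(t) {
    g_t <- if (is.na(t)) graph else reduce_graph(graph, t, one_at_a_time)$graph
    stats <- component_stats(g_t)
    purrr::map_dfr(inflation_grid, function(i) {
      part <- mcl_cluster(g_t, inflation = i, weighted = weighted, ...)
      part_full <- complete_partition(part, universe)
      sizes <- dplyr::count(tibble::as_tibble(part_full), .data$cluster)$n
      row <- dplyr::bind_cols(
        tibble::tibble(t = t, inflation = i),
        stats,
        tibble::tibble(
          n_clusters = length(sizes),
          max_cluster_size = max(sizes),
          mean_cluster_size = mean(sizes)
        )
      )
      if (!is.null(reference)) {
        ref <- reference[reference$item %in% universe, , drop = FALSE]
        metrics <- partition_metrics(ref, part_full) |>
          dplyr::select("tp", "fn", "fp", "recall", "precision", "jaccard")
        row <- dplyr::bind_cols(row, metrics)
      }
      row
    })
  })
}

#' Clustering granularity across ternary and inflation grids
#'
#' Runs the reduction for each ternary threshold `t` (plus a baseline with no
#' reduction, reported as `t = NA`) and MCL at each inflation value,
#' tabulating cluster counts and sizes — how the two granularity controls
#' interact.
#'
#' @param graph A `tern_graph` (isolated items already dropped).
#' @param inflation_grid,t_grid Numeric grids; an empty `t_grid` gives
#'   baseline-only rows.
#' @param one_at_a_time Passed to [heuristic_reduce()].
#' @param ... Further arguments to [mcl_cluster()].
#' @return Tibble: `t`, `inflation`, `n_clusters`, `max_cluster_size`,
#'   `mean_cluster_size`.
#' @export
granularity_profile <- function(graph,
                                inflation_grid = default_inflation_grid(),
                                t_grid = default_t_grid(),
                                one_at_a_time = FALSE, ...) {
  stopifnot(length(inflation_grid) > 0)
  grid_runs(
    graph,
    t_grid = t_grid, inflation_grid = inflation_grid,
    one_at_a_time = one_at_a_time, ...
  ) |>
    dplyr::select(
      "t", "inflation", "n_clusters", "max_cluster_size", "mean_cluster_size"
    )
}

#' Run the full classification pipeline over a parameter grid
#'
#' End-to-end driver: build the similarity graph from alignment mappings,
#' drop isolated items, then for the baseline and every ternary threshold in
#' `t_grid`, reduce the graph, cluster with MCL at every inflation in
#' `inflation_grid`, and (when a reference classification is supplied) score
#' the partition with pair-counting metrics. Items losing all edges during a
#' reduction re-enter the evaluated partition as singletons, so every row is
#' scored over the same item universe (the graph's items after isolated-item
#' removal). Every reduced graph is certified by an exhaustive ternary
#' re-check before clustering.
#'
#' @param mappings Mappings tibble (or long data frame) of aligner output.
#' @param reference Optional reference partition; must cover the graph's
#'   items.
#' @param t_o,criterion Pairwise significance threshold and criterion for
#'   [build_graph()].
#' @param t_grid,inflation_grid Parameter grids; `t = NA` rows are the
#'   no-reduction baseline.
#' @param weighted Use scores as MCL edge weights.
#' @param one_at_a_time Passed to [heuristic_reduce()].
#' @param ... Further arguments to [mcl_cluster()].
#' @return A report tibble, one row per (t, inflation): reduced-graph
#'   statistics (`n_items`, `n_edges`, `n_icc`, `largest_icc`, `mean_icc`),
#'   clustering statistics, and metrics columns when a reference is given.
#'   Attributes: `config` (resolved parameters), `dropped` (isolated items).
#' @export
run_pipeline <- function(mappings,
                         reference = NULL,
                         t_o = 7,
                         criterion = c("score", "count"),
                         t_grid = default_t_grid(),
                         inflation_grid = default_inflation_grid(),
                         weighted = FALSE,
                         one_at_a_time = FALSE,
                         ...) {
  criterion <- rlang::arg_match(criterion)
  stopifnot(length(inflation_grid) > 0)
  graph <- drop_isolated(build_graph(mappings, t_o = t_o, criterion = criterion))
  if (!is.null(reference)) {
    reference <- as_partition(reference)
    uncovered <- setdiff(graph$items, reference$item)
    if (length(uncovered) > 0) {
      rlang::abort(paste0(
        "reference does not cover graph items: ",
        paste(utils::head(uncovered, 5), collapse = ", ")
      ))
    }
  }
  report <- grid_runs(
    graph,
    t_grid = t_grid, inflation_grid = inflation_grid,
    reference = reference, universe = graph$items,
    one_at_a_time = one_at_a_time, weighted = weighted, ...
  )
  attr(report, "config") <- list(
    t_o = t_o, criterion = criterion, t_grid = t_grid,
    inflation_grid = inflation_grid, weighted = weighted,
    one_at_a_time = one_at_a_time
  )
  attr(report, "dropped") <- attr(graph, "dropped")
  report
}
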