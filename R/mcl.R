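#' Markov Cluster (MCL) algorithm on a similarity graph
#'
#' Flow-based graph clustering: random walks are simulated on the graph by
#' alternating *expansion* (matrix power, spreading flow) and *inflation*
#' (entrywise power then column renormalization, strengthening strong flows
#' and weakening weak ones) until the flow matrix converges. Regions where
#' flow concentrates become the clusters. The inflation parameter is the main
#' granularity control: larger values give finer clusters.
#'
#' Operates on the column-stochastic matrix of the graph with self-loops
#' added (weight `self_loop_weight`). Adjacency is binary by default;
#' `weighted = TRUE` uses alignment scores as edge weights. Entries below
#' `prune_threshold` are dropped (and columns renormalized) after each
#' inflation to keep the matrix sparse.
#'
#' Attractors (nodes holding flow on their own column at convergence) label
#' the clusters; a node attracted by several attractors is assigned to the
#' cluster of its lexicographically smallest attractor, so the output is a
#' deterministic partition. Clusters never span connected components.
#'
#' @param graph A nonempty `tern_graph`.
#' @param inflation Inflation parameter I > 1.
#' @param expansion Expansion power (integer >= 2).
#' @param self_loop_weight Weight of the self-loops added before
#'   normalization.
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @param max_iterations Iteration cap; non-convergence warns and returns the
#'   current interpretation.
#' @param convergence_tol Maximum absolute change between successive flow
#'   matrices at which iteration stops.
#' @param weighted Use alignment scores as edge weights.
#' @return A `tern_partition`: tibble `item`, `cluster` covering exactly the
#'   graph's items, with attributes `inflation`, `iterations`, `converged`.
#' @examples
#' m <- as_mappings(data.frame(
#'   item_a = c("a", "b", "a", "x", "y", "x"),
#'   item_b = c("b", "c", "c", "y", "z", "z"),
#'   score = 9, pos_a = 1L, pos_b = 1L
#' ))
#' mcl_cluster(build_graph(m), inflation = 2)
#' @export
mcl_cluster <- function(graph,
                        inflation = 2,
                        expansion = 2L,
                        self_loop_weight = 1,
                        prune_threshold = 1e-5,
                        max_iterations = 200L,
                        convergence_tol = 1e-8,
                        weighted = FALSE) {
  stopifnot(inherits(graph, "tern_graph"))
  if (length(graph$items) == 0) rlang::abort("cannot cluster an empty graph")
  if (inflation <= 1) rlang::abort("inflation must be > 1")
  stopifnot(expansion >= 2, prune_threshold >= 0, self_loop_weight > 0)

  items <- graph$items
  n <- length(items)
  ia <- match(graph$edges$item_a, items)
  ib <- match(graph$edges$item_b, items)
  w <- if (weighted) graph$edges$score else rep(1, length(ia))
  m <- Matrix::sparseMatrix(
    i = c(ia, ib, seq_len(n)),
    j = c(ib, ia, seq_len(n)),
    x = c(w, w, rep(self_loop_weight, n)),
    dims = c(n, n)
  )
  m <- normalize_columns(m)

  converged <- FALSE
  iterations <- 0L
  for (iter in seq_len(max_iterations)) {
    iterations <- iter
    m_new <- m
    for (k in seq_len(expansion - 1L)) m_new <- m_new %*% m
    m_new <- inflate(m_new, inflation, prune_threshold)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf(
      "MCL did not converge in %d iterations (inflation %.2f); interpreting current matrix",
      max_iterations, inflation
    ))
  }

  part <- interpret_mcl(m, items, tau = max(prune_threshold, 1e-9))
  out <- relabel_partition(part)
  class(out) <- c("tern_partition", class(out))
  attr(out, "inflation") <- inflation
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

inflate <- function(m, inflation, prune_threshold) {
  m <- as(m, "CsparseMatrix")
  m@x <- m@x^inflation
  m <- Matrix::drop0(m)
  if (prune_threshold > 0) {
    m@x[m@x < prune_threshold] <- 0
    m <- Matrix::drop0(m)
  }
  normalize_columns(m)
}

# assign every item to the cluster of its smallest attractor
interpret_mcl <- function(m, items, tau) {
  m <- as(m, "TsparseMatrix")
  keep <- m@x > tau
  ri <- m@i[keep] + 1L
  ci <- m@j[keep] + 1L
  attractors <- sort(unique(ri[ri == ci]))
  lab <- rep(NA_character_, length(items))
  sup <- ri %in% attractors
  if (any(sup)) {
    support <- split(items[ri[sup]], ci[sup])
    idx <- as.integer(names(support))
    lab[idx] <- purrr::map_chr(support, min)
  }
  # columns with no attractor support (unconverged corner): singleton
  lab[is.na(lab)] <- items[is.na(lab)]
  tibble::tibble(item = items, cluster = lab)
}

# stable cluster ids ordered by decreasing size, ties by smallest member
relabel_partition <- function(part) {
  sizes <- part |>
    dplyr::count(.data$cluster, name = "size") |>
    dplyr::left_join(
      part |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(min_item = min(.data$item), .groups = "drop"),
      by = "cluster"
    ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_item)
  width <- max(2L, nchar(nrow(sizes)))
  new_ids <- stats::setNames(
    sprintf("c%0*d", width, seq_len(nrow(sizes))),
    sizes$cluster
  )
  part |>
    dplyr::mutate(cluster = unname(new_ids[.data$cluster])) |>
    dplyr::arrange(.data$item)
}

#' @export
print.tern_partition <- function(x, ...) {
  cat(sprintf(
    "<tern_partition> %d items in %d clusters (inflation %s, %s)\n",
    nrow(x), dplyr::n_distinct(x$cluster),
    format(attr(x, "inflation")),
    if (isTRUE(attr(x, "converged"))) "converged" else "not converged"
  ))
  NextMethod()
}

#' One-row summary of an MCL partition
#' @param x A `tern_partition`.
#' @param ... Unused.
#' @return Tibble: `inflation`, `iterations`, `converged`, `n_items`,
#'   `n_clusters`, `max_cluster_size`, `mean_cluster_size`.
#' @export
glance.tern_partition <- function(x, ...) {
  sizes <- dplyr::count(tibble::as_tibble(x), .data$cluster)$n
  tibble::tibble(
    inflation = attr(x, "inflation") %||% NA_real_,
    iterations = attr(x, "iterations") %||% NA_integer_,
    converged = attr(x, "converged") %||% NA,
    n_items = nrow(x),
    n_clusters = length(sizes),
    max_cluster_size = max(sizes),
    mean_cluster_size = mean(sizes)
  )
}
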