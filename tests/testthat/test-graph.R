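make_mappings <- function(a, b, score, n_pairs = 1L) {
  tibble::tibble(
    item_a = a, item_b = b, score = score,
    pairs = purrr::map(n_pairs, function(k) {
      tibble::tibble(pos_a = seq_len(k), pos_b = seq_len(k))
    })
  )
}

test_that("sim_o applies inclusive thresholds under both criteria", {
  m <- as_mappings(make_mappings("a", "b", score = 7.0, n_pairs = 1L))
  expect_true(sim_o(m, t_o = 7.0, criterion = "score"))
  expect_false(sim_o(m, t_o = 7.01, criterion = "score"))
  expect_true(sim_o(m, t_o = 1, criterion = "count"))
  expect_false(sim_o(m, t_o = 2, criterion = "count"))
  expect_error(sim_o(m, t_o = 7, criterion = "zscore"))
})

test_that("threshold filtering matches a brute-force scan on random mappings", {
  set.seed(41)
  n <- 200
  idx <- utils::combn(30, 2)[, sample(choose(30, 2), n)]
  m <- as_mappings(make_mappings(
    sprintf("i%02d", idx[1, ]), sprintf("i%02d", idx[2, ]),
    score = stats::runif(n, 0, 14),
    n_pairs = sample.int(20, n, replace = TRUE)
  ))
  for (t_o in c(3, 7, 11)) {
    g <- build_graph(m, t_o = t_o, criterion = "score")
    keep <- m$score >= t_o
    expect_setequal(
      paste(g$edges$item_a, g$edges$item_b),
      paste(m$item_a[keep], m$item_b[keep])
    )
    g2 <- build_graph(m, t_o = 10, criterion = "count")
    keep2 <- vapply(m$pairs, nrow, integer(1)) >= 10
    expect_setequal(
      paste(g2$edges$item_a, g2$edges$item_b),
      paste(m$item_a[keep2], m$item_b[keep2])
    )
  }
})

test_that("build_graph keeps sub-threshold items as isolated vertices", {
  m <- as_mappings(make_mappings(c("A", "B"), c("B", "C"), score = c(7.5, 6.0)))
  g <- build_graph(m, t_o = 7.0, criterion = "score")
  expect_setequal(g$items, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$item_a, "A")
  expect_equal(g$edges$item_b, "B")

  empty <- build_graph(m[0, ], t_o = 7)
  expect_equal(n_items(empty), 0L)
  expect_equal(n_edges(empty), 0L)
})

test_that("raising the pairwise threshold never adds edges and refiltering is idempotent", {
  set.seed(42)
  m <- random_topology_mappings(15, 0.4)
  m$score <- stats::runif(nrow(m), 0, 14)
  grid <- sort(stats::runif(6, 0, 14))
  prev <- NULL
  for (t_o in grid) {
    g <- build_graph(m, t_o = t_o)
    if (!is.null(prev)) expect_true(all(g$edges$edge %in% prev))
    prev <- g$edges$edge
    refiltered <- build_graph(g$edges[, c("item_a", "item_b", "score", "pairs")],
                              t_o = t_o)
    expect_setequal(refiltered$edges$edge, g$edges$edge)
  }
})

test_that("drop_isolated removes exactly the degree-0 items", {
  m <- as_mappings(make_mappings("A", "B", 9))
  g <- tern_graph(items = c("A", "B", "C"), edges = m)
  g2 <- drop_isolated(g)
  expect_setequal(g2$items, c("A", "B"))
  expect_equal(attr(g2, "dropped"), "C")

  edgeless <- tern_graph(items = c("X", "Y"), edges = m[0, ])
  g3 <- drop_isolated(edgeless)
  expect_equal(n_items(g3), 0L)
  expect_setequal(attr(g3, "dropped"), c("X", "Y"))

  set.seed(7)
  mm <- random_topology_mappings(20, 0.08)
  gg <- build_graph(mm, t_o = 7)
  deg <- graph_degrees(gg)
  expect_setequal(
    attr(drop_isolated(gg), "dropped"),
    deg$item[deg$degree == 0]
  )
})

test_that("connected components match an independent igraph oracle", {
  tri2 <- as_mappings(make_mappings(
    c("a", "b", "a", "x", "y", "x"),
    c("b", "c", "c", "y", "z", "z"),
    score = 9
  ))
  comps <- graph_components(build_graph(tri2))
  expect_length(comps, 2)
  expect_equal(purrr::map_int(comps, n_items), c(3L, 3L))
  expect_equal(comps[[1]]$items, c("a", "b", "c")) # tie broken by smallest id

  path <- build_graph(as_mappings(make_mappings(c("a", "b"), c("b", "c"), 9)))
  expect_length(graph_components(path), 1)

  set.seed(11)
  for (rep in 1:10) {
    m <- random_topology_mappings(18, 0.07)
    if (is.null(m)) next
    g <- build_graph(m)
    ig <- igraph::graph_from_data_frame(
      m[, c("item_a", "item_b")], directed = FALSE,
      vertices = data.frame(name = g$items)
    )
    oracle <- igraph::components(ig)
    comps <- graph_components(g)
    expect_length(comps, oracle$no)
    expect_equal(
      sort(purrr::map_int(comps, n_items)),
      sort(unname(oracle$csize))
    )
    # vertex-disjoint and exhaustive
    all_items <- unlist(purrr::map(comps, "items"))
    expect_setequal(all_items, g$items)
    expect_equal(anyDuplicated(all_items), 0L)
    expect_equal(sum(purrr::map_int(comps, n_edges)), n_edges(g))
  }
})

test_that("graph JSON serialization round-trips", {
  fx <- case_fixture("case1")
  g <- build_graph(fx$mappings, t_o = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  back <- read_graph_json(path)
  expect_equal(back$items, g$items)
  expect_equal(back$edges, g$edges)
})
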