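clique_mappings <- function(members_list) {
  rows <- purrr::map_dfr(members_list, function(members) {
    idx <- utils::combn(length(members), 2)
    tibble::tibble(
      item_a = members[idx[1, ]], item_b = members[idx[2, ]], score = 9,
      pairs = replicate(ncol(idx), tibble::tibble(pos_a = 1L, pos_b = 1L),
                        simplify = FALSE)
    )
  })
  as_mappings(rows)
}

test_that("MCL recovers disjoint cliques exactly", {
  g <- build_graph(clique_mappings(list(
    c("a1", "a2", "a3"), c("b1", "b2", "b3"), c("c1", "c2", "c3", "c4")
  )))
  part <- mcl_cluster(g, inflation = 2)
  expect_equal(
    partition_as_sets(part),
    list(c("a1", "a2", "a3"), c("b1", "b2", "b3"), c("c1", "c2", "c3", "c4"))
  )
  expect_true(attr(part, "converged"))

  single <- mcl_cluster(build_graph(clique_mappings(list(c("a", "b")))), inflation = 2)
  expect_equal(partition_as_sets(single), list(c("a", "b")))
})

test_that("a planted two-clique graph with one bridge splits into the cliques", {
  m <- clique_mappings(list(paste0("a", 1:6), paste0("b", 1:6)))
  bridge <- as_mappings(tibble::tibble(
    item_a = "a1", item_b = "b1", score = 9,
    pairs = list(tibble::tibble(pos_a = 1L, pos_b = 1L))
  ))
  g <- build_graph(dplyr::bind_rows(m, bridge))
  part <- mcl_cluster(g, inflation = 2)
  expect_equal(
    partition_as_sets(part),
    list(paste0("a", 1:6), paste0("b", 1:6))
  )
  oracle <- mcl_dense_oracle(g, inflation = 2)
  expect_equal(partition_as_sets(part), cluster_sets(names(oracle), oracle))
})

test_that("sparse MCL agrees with an independent dense implementation", {
  set.seed(606)
  done <- 0
  while (done < 20) {
    m <- random_topology_mappings(sample(6:14, 1), stats::runif(1, 0.2, 0.6))
    if (is.null(m)) next
    done <- done + 1
    g <- drop_isolated(build_graph(m))
    for (inflation in c(1.5, 2)) {
      part <- suppressWarnings(mcl_cluster(g, inflation = inflation))
      oracle <- mcl_dense_oracle(g, inflation = inflation)
      expect_equal(
        partition_as_sets(part),
        cluster_sets(names(oracle), oracle)
      )
    }
  }
})

test_that("the flow matrix stays column-stochastic through the iteration", {
  set.seed(707)
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 4, 1), j = c(2, 1, 4, 3, 3), x = 1, dims = c(4, 4)
  )
  m <- m + Matrix::t(m) + Matrix::Diagonal(4)
  flow <- ternclust:::normalize_columns(m)
  for (k in 1:10) {
    expect_equal(max(abs(Matrix::colSums(flow) - 1)), 0, tolerance = 1e-12)
    flow <- ternclust:::inflate(flow %*% flow, 2, 1e-5)
  }
  expect_equal(max(abs(Matrix::colSums(flow) - 1)), 0, tolerance = 1e-12)
})

test_that("clusters never span connected components and cover every item", {
  set.seed(808)
  for (rep in 1:8) {
    m <- random_topology_mappings(14, 0.12)
    if (is.null(m)) next
    g <- drop_isolated(build_graph(m))
    part <- suppressWarnings(mcl_cluster(g, inflation = 1.8))
    expect_setequal(part$item, g$items)
    expect_equal(anyDuplicated(part$item), 0L)
    comp_of <- purrr::imap(graph_components(g), function(cg, i) {
      stats::setNames(rep(i, n_items(cg)), cg$items)
    })
    comp_of <- unlist(comp_of)
    by_cluster <- split(part$item, part$cluster)
    for (members in by_cluster) {
      expect_equal(dplyr::n_distinct(comp_of[members]), 1L)
    }
  }
})

test_that("inflation controls granularity on a simple fixture", {
  m <- clique_mappings(list(paste0("a", 1:5), paste0("b", 1:5)))
  bridge <- as_mappings(tibble::tibble(
    item_a = "a1", item_b = "b1", score = 9,
    pairs = list(tibble::tibble(pos_a = 1L, pos_b = 1L))
  ))
  g <- build_graph(dplyr::bind_rows(m, bridge))
  n_low <- dplyr::n_distinct(mcl_cluster(g, inflation = 1.2)$cluster)
  n_high <- dplyr::n_distinct(mcl_cluster(g, inflation = 3)$cluster)
  expect_lte(n_low, n_high)

  expect_error(mcl_cluster(g, inflation = 1), "inflation")
  empty <- tern_graph(character(), build_graph(m)$edges[0, c("item_a", "item_b", "score", "pairs")])
  expect_error(mcl_cluster(empty), "empty")
})
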