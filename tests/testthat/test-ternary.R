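# brute-force recomputation of every centered check of a graph, by direct
# set intersection of position projections (independent of sim3 internals)
brute_violations <- function(graph, t) {
  edges <- graph$edges
  out <- list()
  for (center in graph$items) {
    inc <- which(edges$item_a == center | edges$item_b == center)
    if (length(inc) < 2) next
    for (ii in seq_len(length(inc) - 1)) {
      for (jj in seq(ii + 1, length(inc))) {
        e1 <- edges[inc[ii], ]
        e2 <- edges[inc[jj], ]
        proj <- function(e) {
          if (e$item_a == center) e$pairs[[1]]$pos_a else e$pairs[[1]]$pos_b
        }
        ov <- length(intersect(proj(e1), proj(e2)))
        mn <- min(nrow(e1$pairs[[1]]), nrow(e2$pairs[[1]]))
        if (ov < t * mn) {
          out[[length(out) + 1]] <- sort(c(e1$edge, e2$edge))
        }
      }
    }
  }
  out
}

test_that("central overlap is the intersection of the center's projections", {
  set.seed(9)
  for (rep in 1:20) {
    pa <- sort(sample.int(60, 25))
    pb <- sort(sample.int(60, 30))
    m <- as_mappings(tibble::tibble(
      item_a = c("ctr", "ctr"), item_b = c("nb1", "nb2"), score = 9,
      pairs = list(
        tibble::tibble(pos_a = pa, pos_b = seq_along(pa)),
        tibble::tibble(pos_a = pb, pos_b = seq_along(pb))
      )
    ))
    ov <- central_overlap(m[1, ], m[2, ], "ctr")
    expect_equal(ov, sort(intersect(pa, pb)))
  }
  m <- case_fixture("figure6")$mappings
  expect_error(central_overlap(m[1, ], m[2, ], "nobody"), "not part of the mapping")
})

test_that("sim3 reproduces the worked 73/75/35 example and its boundaries", {
  fx <- case_fixture("figure6")
  g <- build_graph(fx$mappings, t_o = 7)
  e <- g$edges
  left <- e[e$item_b == "d1w0pa2" | e$item_a == "d1w0pa2", ]
  right <- e[e$item_b == "d1j1ta_" | e$item_a == "d1j1ta_", ]
  chk <- sim3(left, right, center = "d1uaia_", t = 0.65)
  expect_equal(chk$overlap_count, 35L)
  expect_equal(chk$min_alignment, 73L)
  expect_equal(chk$fraction, 35 / 73)
  expect_equal(round(chk$fraction * 100), 48)
  expect_false(chk$satisfied)
  # inclusive comparison: exactly at the bound satisfies
  at_bound <- sim3(left, right, center = "d1uaia_", t = 35 / 73)
  expect_true(at_bound$satisfied)

  ident <- sim3(left, left, center = "d1uaia_", t = 1)
  expect_equal(ident$fraction, 1)
  expect_true(ident$satisfied)

  expect_error(sim3(left, right, "d1uaia_", t = 1.2), "\\[0, 1\\]")
  expect_error(sim3(left, right, "d1uaia_", t = -0.1), "\\[0, 1\\]")
})

test_that("a clique through pairwise-distinct parts violates every centered check", {
  fx <- case_fixture("property1")
  g <- build_graph(fx$mappings, t_o = 1, criterion = "count")
  expect_equal(n_edges(g), 3L)
  for (t in c(0.05, 0.3, 0.65, 1)) {
    viol <- verify_ternary(g, t)
    expect_equal(nrow(viol), 3L)
    expect_setequal(viol$center, c("o", "op", "opp"))
  }
  # at t = 0 every check passes vacuously
  expect_equal(nrow(verify_ternary(g, 0)), 0L)
})

test_that("marking agrees with an exhaustive per-triple scan on random graphs", {
  set.seed(55)
  for (rep in 1:8) {
    inst <- random_part_mappings(sample(7:10, 1))
    if (is.null(inst)) next
    g <- drop_isolated(build_graph(inst$mappings, t_o = 1, criterion = "count"))
    for (t in c(0.3, 0.65, 0.9)) {
      marked <- mark_line_graph(line_graph(g), t)
      got <- marked$edges[!marked$edges$satisfied, c("edge_1", "edge_2")]
      got_keys <- purrr::map2_chr(got$edge_1, got$edge_2,
                                  ~ paste(sort(c(.x, .y)), collapse = "+"))
      want <- purrr::map_chr(brute_violations(g, t), paste, collapse = "+")
      expect_setequal(got_keys, want)
    }
  }
})

test_that("the marked set grows monotonically with the ternary threshold", {
  set.seed(77)
  for (rep in 1:5) {
    inst <- random_part_mappings(9)
    if (is.null(inst)) next
    g <- drop_isolated(build_graph(inst$mappings, t_o = 1, criterion = "count"))
    lg <- line_graph(g)
    prev <- character()
    for (t in seq(0.05, 0.95, by = 0.15)) {
      marked <- mark_line_graph(lg, t)
      cur <- with(
        marked$edges[!marked$edges$satisfied, ],
        paste(edge_1, edge_2)
      )
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("greedy reduction removes max-degree batches and leaves no marked edge", {
  # nothing marked: reduction is the identity
  fx <- case_fixture("case1")
  g <- build_graph(fx$mappings, t_o = 7)
  lg <- mark_line_graph(line_graph(g), 0)
  res <- heuristic_reduce(lg, g$items)
  expect_equal(nrow(res$removed), 0L)
  expect_equal(res$graph$edges, g$edges)
  expect_equal(nrow(res$trace), 0L)

  # a single marked edge between two degree-1 line vertices: the batch rule
  # removes both at once
  pg <- build_graph(as_mappings(tibble::tibble(
    item_a = c("a", "b"), item_b = c("b", "c"), score = 9,
    pairs = list(tibble::tibble(pos_a = 1L, pos_b = 1L),
                 tibble::tibble(pos_a = 2L, pos_b = 1L))
  )))
  res2 <- reduce_graph(pg, t = 0.5)
  expect_equal(nrow(res2$removed), 2L)
  expect_equal(res2$trace$delta, 1L)
  expect_equal(res2$trace$n_removed, 2L)
  expect_setequal(attr(res2$graph, "absent"), c("a", "b", "c"))

  # one-at-a-time variant removes a single vertex and stops: the other
  # endpoint of the marked edge survives
  lg2 <- mark_line_graph(line_graph(pg), 0.5)
  res3 <- heuristic_reduce(lg2, pg$items, one_at_a_time = TRUE)
  expect_equal(nrow(res3$removed), 1L)
  expect_equal(res3$removed$edge, "a--b") # smallest label among ties
  expect_equal(n_edges(res3$graph), 1L)
})

test_that("the removal set is a vertex cover of the marked graph", {
  set.seed(88)
  for (rep in 1:6) {
    inst <- random_part_mappings(sample(7:10, 1))
    if (is.null(inst)) next
    g <- drop_isolated(build_graph(inst$mappings, t_o = 1, criterion = "count"))
    for (t in c(0.4, 0.8)) {
      lg <- mark_line_graph(line_graph(g), t)
      marked <- lg$edges[!lg$edges$satisfied, ]
      res <- heuristic_reduce(lg, g$items)
      covered <- marked$edge_1 %in% res$removed$edge |
        marked$edge_2 %in% res$removed$edge
      expect_true(all(covered))
      # only vertices of the marked subgraph are ever removed
      expect_true(all(
        res$removed$edge %in% c(marked$edge_1, marked$edge_2)
      ))
      expect_equal(nrow(verify_ternary(res$graph, t)), 0L)
    }
  }
})

test_that("greedy cover is at least the exhaustive minimum on tiny instances", {
  set.seed(99)
  done <- 0
  while (done < 8) {
    inst <- random_part_mappings(sample(5:7, 1), pool_size = 8)
    if (is.null(inst)) next
    g <- drop_isolated(build_graph(inst$mappings, t_o = 1, criterion = "count"))
    if (n_edges(g) > 10) next
    lg <- mark_line_graph(line_graph(g), 0.7)
    marked <- lg$edges[!lg$edges$satisfied, c("edge_1", "edge_2")]
    if (nrow(marked) == 0) next
    done <- done + 1
    res <- heuristic_reduce(lg, g$items)
    opt <- min_vertex_cover_size(marked)
    expect_gte(nrow(res$removed), opt)
    expect_equal(nrow(verify_ternary(res$graph, 0.7)), 0L)
  }
})

test_that("reduction severs linker paths between unrelated families", {
  fx <- case_fixture("case1")
  g <- build_graph(fx$mappings, t_o = 7)
  class1_only <- setdiff(fx$expected$class1, fx$expected$linker)
  class2_only <- setdiff(fx$expected$class2, fx$expected$linker)
  for (t in c(0.05, 0.5, 0.95)) {
    g_t <- reduce_graph(g, t)$graph
    keys <- g_t$edges$edge
    for (x in class1_only) {
      for (y in class2_only) {
        both <- ternclust:::edge_key(min(x, "o5"), max(x, "o5")) %in% keys &&
          ternclust:::edge_key(min(y, "o5"), max(y, "o5")) %in% keys
        expect_false(both)
      }
    }
  }
})
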