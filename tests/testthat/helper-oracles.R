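# Independent oracles and random-instance generators used across the suite.
# Everything here is deliberately written the naive way (brute force, dense
# matrices, exhaustive enumeration) and never calls the package code path it
# is used to check.

# random simple graph topology as a mappings table (trivial 1-pair alignments)
random_topology_mappings <- function(n_items, p_edge) {
  items <- sprintf("v%02d", seq_len(n_items))
  idx <- utils::combn(n_items, 2)
  keep <- stats::runif(ncol(idx)) < p_edge
  idx <- idx[, keep, drop = FALSE]
  if (ncol(idx) == 0) return(NULL)
  as_mappings(tibble::tibble(
    item_a = items[idx[1, ]],
    item_b = items[idx[2, ]],
    score = 9,
    pairs = replicate(ncol(idx), tibble::tibble(pos_a = 1L, pos_b = 1L),
                      simplify = FALSE)
  ))
}

# items with random part subsets from a shared pool; mappings on shared parts,
# giving line graphs with a realistic mix of satisfied/violated triples
random_part_mappings <- function(n_items, pool_size = 12, parts_min = 3,
                                 parts_max = 7) {
  items <- sprintf("v%02d", seq_len(n_items))
  pool <- sprintf("p%02d", seq_len(pool_size))
  parts <- lapply(seq_len(n_items), function(i) {
    sample(pool, sample(parts_min:parts_max, 1))
  })
  rows <- list()
  for (i in seq_len(n_items - 1)) {
    for (j in seq(i + 1, n_items)) {
      shared <- intersect(parts[[i]], parts[[j]])
      if (length(shared) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        item_a = items[i], item_b = items[j], score = 9,
        pairs = list(tibble::tibble(
          pos_a = as.integer(match(shared, parts[[i]])),
          pos_b = as.integer(match(shared, parts[[j]]))
        ))
      )
    }
  }
  if (length(rows) == 0) return(NULL)
  list(
    items = items, parts = stats::setNames(parts, items),
    mappings = as_mappings(dplyr::bind_rows(rows))
  )
}

# brute-force pair counting by explicit enumeration of all unordered pairs
brute_pair_counts <- function(reference, predicted) {
  items <- sort(reference$item)
  ref <- stats::setNames(reference$cluster, reference$item)
  pred <- stats::setNames(predicted$cluster, predicted$item)
  tp <- fn <- fp <- 0L
  n <- length(items)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      in_ref <- ref[items[i]] == ref[items[j]]
      in_pred <- pred[items[i]] == pred[items[j]]
      if (in_ref && in_pred) tp <- tp + 1L
      if (in_ref && !in_pred) fn <- fn + 1L
      if (!in_ref && in_pred) fp <- fp + 1L
    }
  }
  list(tp = tp, fn = fn, fp = fp)
}

# random partition of n items into up to k labels
random_partition <- function(items, k) {
  as_partition(tibble::tibble(
    item = items,
    cluster = as.character(sample.int(k, length(items), replace = TRUE))
  ))
}

# exhaustive minimum vertex cover size of the graph given as an edge list
# (two-column data frame of vertex labels); feasible for <= ~12 vertices
min_vertex_cover_size <- function(edges) {
  vs <- sort(unique(c(edges[[1]], edges[[2]])))
  if (nrow(edges) == 0) return(0L)
  for (k in 0:length(vs)) {
    if (k == 0) next
    combos <- utils::combn(vs, k, simplify = FALSE)
    for (cover in combos) {
      if (all(edges[[1]] %in% cover | edges[[2]] %in% cover)) return(k)
    }
  }
  length(vs)
}

# textbook dense MCL, independent of the package's sparse implementation
mcl_dense_oracle <- function(graph, inflation, expansion = 2,
                             self_loop_weight = 1, prune = 1e-5,
                             max_iter = 200, tol = 1e-8) {
  items <- graph$items
  n <- length(items)
  adj <- matrix(0, n, n, dimnames = list(items, items))
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges$item_a[r]
    b <- graph$edges$item_b[r]
    adj[a, b] <- adj[b, a] <- 1
  }
  diag(adj) <- self_loop_weight
  colnorm <- function(m) sweep(m, 2, pmax(colSums(m), 1e-300), "/")
  m <- colnorm(adj)
  for (it in seq_len(max_iter)) {
    m2 <- m
    for (k in seq_len(expansion - 1)) m2 <- m2 %*% m
    m2 <- m2^inflation
    m2[m2 < prune] <- 0
    m2 <- colnorm(m2)
    if (max(abs(m2 - m)) < tol) {
      m <- m2
      break
    }
    m <- m2
  }
  tau <- max(prune, 1e-9)
  attractors <- which(diag(m) > tau)
  lab <- vapply(seq_len(n), function(j) {
    sup <- intersect(which(m[, j] > tau), attractors)
    if (length(sup) == 0) items[j] else min(items[sup])
  }, character(1))
  stats::setNames(lab, items)
}

# canonical set-of-sets view of a partition, for implementation-independent
# comparison of clusterings
cluster_sets <- function(items, labels) {
  sets <- lapply(split(items, labels), sort)
  unname(sets[order(vapply(sets, min, character(1)))])
}

partition_as_sets <- function(partition) {
  cluster_sets(partition$item, partition$cluster)
}
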