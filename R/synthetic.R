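#' Specification of a synthetic planted-family benchmark
#'
#' The generator emulates the situation the ternary constraint corrects:
#' structural families whose members all share a family motif, plus *linker*
#' (modular) items carrying the motifs of two families. A structural aligner
#' run over such a set reports, for each similar pair, the mapped motif
#' positions and a significance score; linkers connect the families in the
#' similarity graph even though members of different families share nothing.
#'
#' @param n_families Number of planted families.
#' @param parts_per_motif Mapped-pair count of each family motif (the length,
#'   in parts, of the shared substructure; plays the role of an alignment
#'   length in residues/blocks).
#' @param items_per_family Non-linker items per family.
#' @param n_linkers Items carrying the motifs of two families (assigned round
#'   robin over family pairs).
#' @param extra_parts Item-specific parts appended after the motif(s), giving
#'   items individual, unaligned structure.
#' @param noise_pair_rate Probability that a pair of motif-unrelated items
#'   gets a spurious low-score alignment over a few random positions.
#' @param score_signal,score_noise Means of the aligner score for true and
#'   spurious similarities (normal, sd 1, truncated at 0), placed on either
#'   side of the usual z-score cutoff of 7.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `tern_synth_spec` list.
#' @export
synthetic_spec <- function(n_families = 2,
                           parts_per_motif = 40,
                           items_per_family = 5,
                           n_linkers = 2,
                           extra_parts = 8,
                           noise_pair_rate = 0.05,
                           score_signal = 9,
                           score_noise = 5,
                           seed = 101) {
  spec <- list(
    n_families = as.integer(n_families),
    parts_per_motif = as.integer(parts_per_motif),
    items_per_family = as.integer(items_per_family),
    n_linkers = as.integer(n_linkers),
    extra_parts = as.integer(extra_parts),
    noise_pair_rate = noise_pair_rate,
    score_signal = score_signal,
    score_noise = score_noise,
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(
      n_families >= 1, parts_per_motif >= 1, items_per_family >= 0,
      n_linkers >= 0, extra_parts >= 0,
      noise_pair_rate >= 0, noise_pair_rate <= 1,
      score_signal >= 0, score_noise >= 0
    )
  })
  if (spec$n_linkers > 0 && spec$n_families < 2) {
    rlang::abort("linkers need at least two families to straddle")
  }
  structure(spec, class = "tern_synth_spec")
}

rtrunc_norm <- function(n, mean) pmax(stats::rnorm(n, mean = mean, sd = 1), 0)

#' Generate a synthetic benchmark with planted families and linkers
#'
#' Produces items (as part lists), simulated aligner output (one mapping per
#' similar or spuriously-aligned pair), and the ground truth. Members of a
#' family share its motif; any two items sharing a motif get an alignment
#' mapping the full shared motif(s) with score around `score_signal`.
#' Motif-unrelated pairs get, with probability `noise_pair_rate`, a spurious
#' alignment over a handful of random positions with score around
#' `score_noise`. In the reference partition each linker belongs to its
#' first-listed family (a flat reference assigns every domain one family).
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `items` (tibble `item`, `family`, `parts` list-column),
#'   `mappings` (nested mappings tibble), `truth` (list with `partition` and
#'   `linker_ids`).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "tern_synth_spec"))
  set.seed(spec$seed)
  k <- spec$parts_per_motif

  motifs <- purrr::map(seq_len(spec$n_families), function(f) {
    paste0("m", f, "_", seq_len(k))
  })
  fam_label <- function(f) sprintf("fam%02d", f)

  items <- list()
  extra_id <- 0L
  new_extras <- function(n) {
    if (n == 0) return(character())
    ids <- paste0("x", extra_id + seq_len(n))
    extra_id <<- extra_id + n
    ids
  }
  for (f in seq_len(spec$n_families)) {
    for (j in seq_len(spec$items_per_family)) {
      items[[length(items) + 1L]] <- tibble::tibble(
        item = sprintf("F%d_%02d", f, j),
        family = fam_label(f),
        motif_families = list(f),
        parts = list(c(motifs[[f]], new_extras(spec$extra_parts)))
      )
    }
  }
  if (spec$n_linkers > 0) {
    fam_pairs <- utils::combn(spec$n_families, 2)
    for (l in seq_len(spec$n_linkers)) {
      fp <- fam_pairs[, ((l - 1L) %% ncol(fam_pairs)) + 1L]
      items[[length(items) + 1L]] <- tibble::tibble(
        item = sprintf("L%02d", l),
        family = fam_label(fp[1]),
        motif_families = list(fp),
        parts = list(c(
          motifs[[fp[1]]], motifs[[fp[2]]], new_extras(spec$extra_parts)
        ))
      )
    }
  }
  items <- dplyr::bind_rows(items)

  pos_of <- function(i, labels) match(labels, items$parts[[i]])
  rows <- list()
  if (nrow(items) >= 2) {
    for (i in seq_len(nrow(items) - 1L)) {
      for (j in seq(i + 1L, nrow(items))) {
        shared_f <- intersect(
          items$motif_families[[i]], items$motif_families[[j]]
        )
        if (length(shared_f) > 0) {
          labels <- unlist(motifs[shared_f], use.names = FALSE)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            item_a = items$item[i],
            item_b = items$item[j],
            score = rtrunc_norm(1, spec$score_signal),
            pairs = list(tibble::tibble(
              pos_a = as.integer(pos_of(i, labels)),
              pos_b = as.integer(pos_of(j, labels))
            ))
          )
        } else if (stats::runif(1) < spec$noise_pair_rate) {
          s <- sample(3:8, 1)
          na <- length(items$parts[[i]])
          nb <- length(items$parts[[j]])
          s <- min(s, na, nb)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            item_a = items$item[i],
            item_b = items$item[j],
            score = rtrunc_norm(1, spec$score_noise),
            pairs = list(tibble::tibble(
              pos_a = sort(sample.int(na, s)),
              pos_b = sample.int(nb, s)
            ))
          )
        }
      }
    }
  }
  mappings <- as_mappings(dplyr::bind_rows(rows))

  truth <- list(
    partition = as_partition(items[, c("item", "family")]),
    linker_ids = items$item[purrr::map_int(items$motif_families, length) > 1]
  )
  list(
    items = items[, c("item", "family", "parts")],
    mappings = mappings,
    truth = truth
  )
}

#' Write a generated benchmark to disk
#'
#' Writes `<prefix>mappings.tsv` (alignment TSV), `<prefix>reference.tsv`
#' (item_id / class_id) and `<prefix>truth.json` (planted partition and
#' linker ids).
#'
#' @param bench Output of [generate_benchmark()].
#' @param out_prefix Path prefix for the three files.
#' @return The three paths, invisibly.
#' @export
write_benchmark <- function(bench, out_prefix) {
  p_map <- paste0(out_prefix, "mappings.tsv")
  p_ref <- paste0(out_prefix, "reference.tsv")
  p_truth <- paste0(out_prefix, "truth.json")
  write_mappings(bench$mappings, p_map)
  readr::write_tsv(
    tibble::tibble(
      item_id = bench$truth$partition$item,
      class_id = bench$truth$partition$cluster
    ),
    p_ref
  )
  jsonlite::write_json(
    list(
      partition = bench$truth$partition,
      linker_ids = bench$truth$linker_ids
    ),
    p_truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(p_map, p_ref, p_truth))
}

#' Exact toy fixtures for the method's worked examples
#'
#' Small hand-built item sets that exercise the cases motivating the ternary
#' constraint. Each fixture returns the items (with their parts), the
#' alignment mappings a part-identity aligner would report, and the expected
#' structural facts.
#'
#' * `case1`: a linker item (`o5 = {p1, p2}`) bridges a family of p1-items
#'   and a family of p2-items; no part is shared across the bridge.
#' * `case2`: three items pairwise similar through three *different* parts —
#'   a 3-clique in G with no part common to all three.
#' * `case3`: items `{p1 p2 p3}`, `{p1 p2 p3 p4}`, `{p3 p4}` under a
#'   more-than-half-of-the-shorter-item rule (with these sizes, at least two
#'   mapped pairs, i.e. `criterion = "count"`, `t_o = 2`): edges (o1,o2) and
#'   (o2,o3) but not (o1,o3), even though p3 is common to all three.
#' * `property1`: the minimal 3-clique on single-part alignments in which
#'   every centered ternary check fails for any threshold above zero.
#' * `figure6`: three pseudo-domains reproducing a real triple where the two
#'   alignments map 73 and 75 amino acids but share only 35 positions on the
#'   central domain — 48% of the smaller alignment, below a 65% threshold.
#'
#' @param name One of `"case1"`, `"case2"`, `"case3"`, `"property1"`,
#'   `"figure6"`.
#' @return A list: `items` (tibble `item`, `parts` list-column), `mappings`,
#'   `expected` (fixture-specific named list), and for `case3` the
#'   recommended `criterion`/`t_o`.
#' @export
case_fixture <- function(name = c("case1", "case2", "case3", "property1", "figure6")) {
  name <- rlang::arg_match(name)
  shared_part_mappings <- function(items, score = 9) {
    rows <- list()
    for (i in seq_len(nrow(items) - 1L)) {
      for (j in seq(i + 1L, nrow(items))) {
        shared <- intersect(items$parts[[i]], items$parts[[j]])
        if (length(shared) == 0) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          item_a = items$item[i],
          item_b = items$item[j],
          score = score,
          pairs = list(tibble::tibble(
            pos_a = as.integer(match(shared, items$parts[[i]])),
            pos_b = as.integer(match(shared, items$parts[[j]]))
          ))
        )
      }
    }
    as_mappings(dplyr::bind_rows(rows))
  }

  if (name == "case1") {
    items <- tibble::tibble(
      item = paste0("o", 1:8),
      parts = c(
        rep(list("p1"), 4), list(c("p1", "p2")), rep(list("p2"), 3)
      )
    )
    mappings <- shared_part_mappings(items)
    expected <- list(
      class1 = paste0("o", 1:5),
      class2 = paste0("o", 5:8),
      linker = "o5",
      n_edges = choose(5, 2) + choose(4, 2)
    )
    return(list(items = items, mappings = mappings, expected = expected))
  }
  if (name == "case2") {
    items <- tibble::tibble(
      item = paste0("o", 1:3),
      parts = list(c("p1", "p3"), c("p1", "p2"), c("p2", "p3"))
    )
    mappings <- shared_part_mappings(items)
    expected <- list(
      edges = list(c("o1", "o2"), c("o1", "o3"), c("o2", "o3")),
      common_part_all_three = character()
    )
    return(list(items = items, mappings = mappings, expected = expected))
  }
  if (name == "case3") {
    items <- tibble::tibble(
      item = paste0("o", 1:3),
      parts = list(c("p1", "p2", "p3"), c("p1", "p2", "p3", "p4"), c("p3", "p4"))
    )
    mappings <- shared_part_mappings(items)
    expected <- list(
      edges = list(c("o1", "o2"), c("o2", "o3")),
      absent_edges = list(c("o1", "o3")),
      common_part_all_three = "p3"
    )
    return(list(
      items = items, mappings = mappings, expected = expected,
      criterion = "count", t_o = 2
    ))
  }
  if (name == "property1") {
    items <- tibble::tibble(
      item = c("o", "op", "opp"),
      parts = list(c("pi", "pj"), c("pi", "pk"), c("pj", "pk"))
    )
    mappings <- shared_part_mappings(items)
    expected <- list(
      clique = c("o", "op", "opp"),
      all_ternary_checks_fail_above = 0
    )
    return(list(items = items, mappings = mappings, expected = expected))
  }
  # figure6: pseudo-domains with the in-paper alignment cardinalities;
  # synthetic stand-in for the real structures (only the mapped-pair counts
  # and the 35-position central overlap matter)
  center <- "d1uaia_"
  items <- tibble::tibble(
    item = c("d1j1ta_", "d1uaia_", "d1w0pa2"),
    parts = list(
      as.character(1:75),
      as.character(1:113),
      as.character(1:73)
    )
  )
  mappings <- as_mappings(dplyr::bind_rows(
    tibble::tibble(
      item_a = center, item_b = "d1w0pa2", score = 9,
      pairs = list(tibble::tibble(pos_a = 1:73, pos_b = 1:73))
    ),
    tibble::tibble(
      item_a = center, item_b = "d1j1ta_", score = 9,
      pairs = list(tibble::tibble(pos_a = 39:113, pos_b = 1:75))
    )
  ))
  expected <- list(
    center = center,
    n_left = 73L, n_right = 75L, overlap = 35L,
    fraction = 35 / 73, percent = 48,
    t = 0.65, satisfied = FALSE
  )
  list(items = items, mappings = mappings, expected = expected)
}
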