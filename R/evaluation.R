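#' Pair-counting comparison of two partitions
#'
#' Two items are co-classified by a partition when they fall in the same
#' cluster. Comparing a predicted partition against a reference over all
#' unordered item pairs gives: TP, pairs co-classified in both; FN,
#' co-classified in the reference only; FP, co-classified in the prediction
#' only. Computed from the cluster contingency table:
#' `TP = sum choose(n_ij, 2)`, with FN and FP from the marginal pair counts.
#' True negatives are deliberately not counted — they dominate on sparse
#' classifications and would mask differences.
#'
#' @param reference,predicted Partition tibbles ([as_partition()]) over the
#'   same item set.
#' @param strict Error on item-set mismatch (default). With `strict = FALSE`
#'   the comparison silently restricts to the common items.
#' @return One-row tibble: `tp`, `fn`, `fp`.
#' @examples
#' ref <- as_partition(data.frame(
#'   item = c("a", "b", "c", "d"), cluster = c(1, 1, 1, 2)
#' ))
#' pred <- as_partition(data.frame(
#'   item = c("a", "b", "c", "d"), cluster = c(1, 1, 2, 2)
#' ))
#' pair_counts(ref, pred) # tp 1, fn 2, fp 1
#' @export
pair_counts <- function(reference, predicted, strict = TRUE) {
  reference <- as_partition(reference)
  predicted <- as_partition(predicted)
  if (!setequal(reference$item, predicted$item)) {
    if (strict) {
      extra_ref <- setdiff(reference$item, predicted$item)
      extra_pred <- setdiff(predicted$item, reference$item)
      rlang::abort(paste0(
        "partitions cover different item sets; only in reference: {",
        paste(utils::head(extra_ref, 5), collapse = ", "),
        "}, only in predicted: {",
        paste(utils::head(extra_pred, 5), collapse = ", "), "}"
      ))
    }
    common <- intersect(reference$item, predicted$item)
    reference <- reference[reference$item %in% common, ]
    predicted <- predicted[predicted$item %in% common, ]
  }
  joint <- dplyr::inner_join(
    reference, predicted,
    by = "item", suffix = c("_ref", "_pred")
  )
  tp <- joint |>
    dplyr::count(.data$cluster_ref, .data$cluster_pred) |>
    dplyr::summarise(tp = sum(choose(.data$n, 2))) |>
    dplyr::pull(.data$tp)
  ref_pairs <- sum(choose(dplyr::count(reference, .data$cluster)$n, 2))
  pred_pairs <- sum(choose(dplyr::count(predicted, .data$cluster)$n, 2))
  tibble::tibble(
    tp = as.integer(tp),
    fn = as.integer(ref_pairs - tp),
    fp = as.integer(pred_pairs - tp)
  )
}

# 0/0 convention: 1 when both partitions have zero co-classified pairs
# (perfect agreement on all-singletons), else 0
safe_ratio <- function(num, den, both_zero) {
  dplyr::if_else(den == 0, dplyr::if_else(both_zero, 1, 0), num / den)
}

#' Recall, Precision and Jaccard from pair counts
#'
#' `recall = TP / (TP + FN)` (ability to retrieve the reference's
#' co-classified pairs), `precision = TP / (TP + FP)` (correctness of the
#' predicted co-classifications), `jaccard = TP / (TP + FN + FP)` (overall
#' concordance, insensitive to the over-represented true negatives). When a
#' denominator is zero the value is 1 if both partitions have zero
#' co-classified pairs (perfect agreement between all-singleton partitions),
#' otherwise 0.
#'
#' @param counts A pair-count tibble from [pair_counts()] (columns `tp`,
#'   `fn`, `fp`; vectorized over rows).
#' @return Numeric vector in \[0, 1\].
#' @export
recall <- function(counts) {
  safe_ratio(counts$tp, counts$tp + counts$fn, counts$fn + counts$fp == 0)
}

#' @rdname recall
#' @export
precision <- function(counts) {
  safe_ratio(counts$tp, counts$tp + counts$fp, counts$fn + counts$fp == 0)
}

#' @rdname recall
#' @export
jaccard <- function(counts) {
  safe_ratio(
    counts$tp, counts$tp + counts$fn + counts$fp,
    counts$fn + counts$fp == 0
  )
}

#' All pair-counting metrics of one comparison
#'
#' @inheritParams pair_counts
#' @return One-row tibble: `tp`, `fn`, `fp`, `recall`, `precision`,
#'   `jaccard`, `n_items`, `n_clusters`.
#' @export
partition_metrics <- function(reference, predicted, strict = TRUE) {
  predicted <- as_partition(predicted)
  counts <- pair_counts(reference, predicted, strict = strict)
  counts |>
    dplyr::mutate(
      recall = recall(counts),
      precision = precision(counts),
      jaccard = jaccard(counts),
      n_items = nrow(predicted),
      n_clusters = dplyr::n_distinct(predicted$cluster)
    )
}

#' Metrics across a family of partitions (PR-curve table)
#'
#' Evaluates each partition of a parameterized family (e.g. MCL runs across
#' an inflation grid) against the same reference, yielding the table behind a
#' Precision/Recall curve.
#'
#' @param reference Reference partition.
#' @param partitions Named list of partitions; names are the parameter values.
#' @param parameter Name for the parameter column.
#' @return Tibble with `parameter` (numeric if possible), `recall`,
#'   `precision`, `jaccard`, `n_clusters`, one row per partition, sorted by
#'   parameter.
#' @export
pr_curve <- function(reference, partitions, parameter = "parameter") {
  if (length(partitions) == 0) {
    out <- tibble::tibble(
      parameter = numeric(), recall = numeric(), precision = numeric(),
      jaccard = numeric(), n_clusters = integer()
    )
    names(out)[1] <- parameter
    return(out)
  }
  vals <- names(partitions) %||% as.character(seq_along(partitions))
  out <- purrr::map2_dfr(partitions, vals, function(p, v) {
    partition_metrics(reference, p) |>
      dplyr::transmute(
        parameter = v, .data$recall, .data$precision, .data$jaccard,
        .data$n_clusters
      )
  })
  suppressWarnings({
    num <- as.numeric(out$parameter)
    if (!anyNA(num)) out$parameter <- num
  })
  out <- dplyr::arrange(out, .data$parameter)
  names(out)[1] <- parameter
  out
}

#' Complete a partition with singleton clusters for missing items
#'
#' Items removed by the reduction (absent from G_T) still belong to the
#' evaluation universe; they re-enter the predicted partition as singleton
#' clusters, which adds no false-positive pairs and keeps both partitions on
#' the same item set.
#'
#' @param partition A partition tibble.
#' @param universe Character vector of all item ids to cover.
#' @return A partition covering `universe`.
#' @export
complete_partition <- function(partition, universe) {
  partition <- as_partition(partition)
  missing <- setdiff(universe, partition$item)
  if (length(missing) == 0) return(partition)
  singles <- tibble::tibble(
    item = missing,
    cluster = paste0("singleton_", missing)
  )
  as_partition(dplyr::bind_rows(tibble::as_tibble(partition), singles))
}
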