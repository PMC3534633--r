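#' Build a validated table of pairwise alignment mappings
#'
#' An alignment mapping records the output of one pairwise structural
#' alignment: the two domain identifiers, the aligner's significance score
#' (e.g. a z-score), and the one-to-one correspondence of aligned parts
#' (residue or block positions). `as_mappings()` accepts either a long table
#' with one mapped pair per row (columns `item_a`, `item_b`, `score`, `pos_a`,
#' `pos_b`, the on-disk TSV layout) or an already-nested table with a `pairs`
#' list-column, and returns the nested canonical form.
#'
#' Each unordered item pair is stored once, oriented so that `item_a` sorts
#' before `item_b`; positions are swapped alongside. [mapping_pairs()] recovers
#' either orientation.
#'
#' @param x A data frame, long or nested (see Details).
#' @return A tibble with columns `item_a`, `item_b`, `score` and a `pairs`
#'   list-column of tibbles with integer columns `pos_a`, `pos_b`.
#' @examples
#' long <- data.frame(
#'   item_a = "d2", item_b = "d1", score = 8.1,
#'   pos_a = 1:3, pos_b = 11:13
#' )
#' as_mappings(long)
#' @export
as_mappings <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!"pairs" %in% names(x)) {
    req <- c("item_a", "item_b", "score", "pos_a", "pos_b")
    missing <- setdiff(req, names(x))
    if (length(missing) > 0) {
      rlang::abort(paste0(
        "long-form mappings need columns: ", paste(missing, collapse = ", ")
      ))
    }
    x <- x |>
      dplyr::mutate(
        item_a = as.character(.data$item_a),
        item_b = as.character(.data$item_b),
        pos_a = as.integer(.data$pos_a),
        pos_b = as.integer(.data$pos_b)
      ) |>
      tidyr::nest(pairs = c("pos_a", "pos_b")) |>
      dplyr::relocate("item_a", "item_b", "score", "pairs")
  }
  x <- dplyr::mutate(
    x,
    item_a = as.character(.data$item_a),
    item_b = as.character(.data$item_b),
    score = as.numeric(.data$score)
  )
  # canonical orientation: lexicographically smaller id on the left
  swap <- x$item_a > x$item_b
  if (any(swap)) {
    tmp <- x$item_a[swap]
    x$item_a[swap] <- x$item_b[swap]
    x$item_b[swap] <- tmp
    x$pairs[swap] <- purrr::map(x$pairs[swap], function(p) {
      tibble::tibble(pos_a = as.integer(p$pos_b), pos_b = as.integer(p$pos_a))
    })
  }
  x$pairs <- purrr::map(x$pairs, function(p) {
    tibble::tibble(pos_a = as.integer(p$pos_a), pos_b = as.integer(p$pos_b))
  })
  validate_mappings(x)
  dplyr::arrange(x, .data$item_a, .data$item_b)
}

validate_mappings <- function(x) {
  if (any(!nzchar(x$item_a)) || any(!nzchar(x$item_b))) {
    rlang::abort("item identifiers must be nonempty strings")
  }
  if (any(x$item_a == x$item_b)) {
    bad <- unique(x$item_a[x$item_a == x$item_b])
    rlang::abort(paste0("self-alignment not allowed: ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(x$score))) rlang::abort("scores must be finite")
  key <- paste(x$item_a, x$item_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), c("item_a", "item_b")]
    rlang::abort(paste0(
      "duplicate mapping for pair(s): ",
      paste(paste0("(", dup$item_a, ",", dup$item_b, ")"), collapse = " ")
    ))
  }
  ok <- purrr::map_lgl(x$pairs, function(p) {
    nrow(p) > 0 &&
      !anyNA(p$pos_a) && !anyNA(p$pos_b) &&
      !anyDuplicated(p$pos_a) && !anyDuplicated(p$pos_b)
  })
  if (!all(ok)) {
    bad <- x[!ok, c("item_a", "item_b")]
    rlang::abort(paste0(
      "mappings must be nonempty one-to-one correspondences; offending pair(s): ",
      paste(paste0("(", bad$item_a, ",", bad$item_b, ")"), collapse = " ")
    ))
  }
  invisible(x)
}

#' Retrieve the mapped position pairs of one alignment, from either side
#'
#' @param mappings A mappings tibble from [as_mappings()].
#' @param from,to Item identifiers of the alignment to look up.
#' @return A tibble with columns `pos_from`, `pos_to`: the mapped positions of
#'   `from` and the corresponding positions of `to`. Errors if the pair has no
#'   mapping.
#' @export
mapping_pairs <- function(mappings, from, to) {
  a <- min(from, to)
  b <- max(from, to)
  i <- which(mappings$item_a == a & mappings$item_b == b)
  if (length(i) != 1) {
    rlang::abort(paste0("no mapping stored for pair (", from, ",", to, ")"))
  }
  p <- mappings$pairs[[i]]
  if (from == a) {
    tibble::tibble(pos_from = p$pos_a, pos_to = p$pos_b)
  } else {
    tibble::tibble(pos_from = p$pos_b, pos_to = p$pos_a)
  }
}

#' Read and write alignment mappings as TSV
#'
#' The TSV dialect has one mapped pair per row, header line
#' `item_a item_b score pos_a pos_b`, tab-separated, `#` comment lines
#' allowed — the layout a wrapper around a structural aligner would emit.
#'
#' @param path File path.
#' @return `read_mappings()` returns the nested mappings tibble;
#'   `write_mappings()` returns `path` invisibly.
#' @export
read_mappings <- function(path) {
  x <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      item_a = readr::col_character(),
      item_b = readr::col_character(),
      score = readr::col_double(),
      pos_a = readr::col_integer(),
      pos_b = readr::col_integer()
    )
  )
  as_mappings(x)
}

#' @param mappings A mappings tibble.
#' @rdname read_mappings
#' @export
write_mappings <- function(mappings, path) {
  long <- tidyr::unnest(mappings, "pairs")
  readr::write_tsv(long, path)
  invisible(path)
}

#' Partitions of a set of items
#'
#' A partition (a flat clustering, or a reference classification such as
#' SCOP Family labels) is a two-column tibble: `item`, `cluster`. Every item
#' appears exactly once; clusters are the equivalence classes of the `cluster`
#' column.
#'
#' @param x A data frame whose first two columns are item and cluster labels
#'   (any column names; `item_id`/`class_id` and `item_id`/`cluster_id` TSVs
#'   are accepted as-is).
#' @return A validated partition tibble with columns `item`, `cluster`.
#' @export
as_partition <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  p <- tibble::tibble(
    item = as.character(x[[1]]),
    cluster = as.character(x[[2]])
  )
  if (anyNA(p$item) || anyNA(p$cluster) || any(!nzchar(p$item))) {
    rlang::abort("partition rows must have nonempty item and cluster labels")
  }
  if (anyDuplicated(p$item)) {
    dup <- unique(p$item[duplicated(p$item)])
    rlang::abort(paste0(
      "clusters must be disjoint; item(s) assigned twice: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  dplyr::arrange(p, .data$item)
}

#' @rdname as_partition
#' @param path File path of a two-column tab-separated file with a header.
#' @export
read_partition <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()))
  as_partition(x)
}

#' @rdname as_partition
#' @param partition A partition tibble.
#' @export
write_partition <- function(partition, path) {
  out <- tibble::tibble(item_id = partition$item, cluster_id = partition$cluster)
  readr::write_tsv(out, path)
  invisible(path)
}
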