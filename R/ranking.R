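#' Rank miRNAs by abundance within one sample
#'
#' Tags with at least `min_count` reads are sorted by descending count, ties
#' broken lexicographically by name. When the table carries a `mirna`
#' annotation it is used as the ranked name, otherwise the tag sequence is.
#'
#' @param counts Long count tibble (annotated or not).
#' @param sample_id Sample to rank.
#' @param min_count Minimum count to retain (default 32, the adaptive
#'   threshold used throughout).
#' @return A `ranked_list` tibble: `rank`, `name`, `count`, with the sample
#'   id kept in `attr(, "sample")`.
#' @export
rank_mirnas <- function(counts, sample_id, min_count = 32L) {
  validate_counts(counts)
  if (!sample_id %in% counts$sample) {
    abort(paste0("sample '", sample_id, "' not present in the count table"))
  }
  if (min_count < 1L) abort("`min_count` must be >= 1")
  out <- counts %>%
    filter(.data$sample == sample_id, .data$count >= min_count) %>%
    mutate(name = if ("mirna" %in% names(counts)) .data$mirna
           else .data$sequence) %>%
    arrange(desc(.data$count), .data$name) %>%
    mutate(rank = row_number()) %>%
    select("rank", "name", "count")
  if (anyDuplicated(out$name)) {
    warn("ranked names are not unique; distinct tags share an annotation")
  }
  attr(out, "sample") <- sample_id
  class(out) <- c("ranked_list", class(out))
  out
}

#' Overlap and kappa agreement of two top-N ranked lists
#'
#' Compares the name sets of the top `n` entries of two ranked lists;
#' agreement is chance-corrected with [cohens_kappa()] over a universe that
#' defaults to the union of all names in the two full lists. A list shorter
#' than `n` is truncated to its length with a warning.
#'
#' @param list_a,list_b `ranked_list` tibbles from [rank_mirnas()] (any
#'   tibble with `name` ordered by rank works).
#' @param n Depth of the comparison.
#' @param universe Universe for the kappa computation.
#' @return One-row tibble: `n_a`, `n_b`, `overlap`, `kappa`.
#' @export
top_n_overlap <- function(list_a, list_b, n, universe = NULL) {
  for (l in list(list_a, list_b)) {
    if (!"name" %in% names(l)) abort("ranked lists need a `name` column")
  }
  if (is.null(universe)) universe <- union(list_a$name, list_b$name)
  if (length(universe) == 0L) abort("empty universe")
  if (n > nrow(list_a) || n > nrow(list_b)) {
    warn("`n` exceeds a list length; comparing full list(s)")
  }
  top_a <- head(list_a$name, n)
  top_b <- head(list_b$name, n)
  tibble(
    n_a = length(top_a),
    n_b = length(top_b),
    overlap = length(intersect(top_a, top_b)),
    kappa = cohens_kappa(top_a, top_b, universe)
  )
}

#' Summarise a miRNA family within a ranked list
#'
#' Counts the entries whose name starts with `family_prefix` and sums their
#' abundances; used e.g. to quantify the dominance of the let-7 family in the
#' top rankings.
#'
#' @inheritParams top_n_overlap
#' @param list A `ranked_list` tibble.
#' @param family_prefix Name prefix defining the family
#'   (e.g. `"hsa-let-7"`).
#' @return One-row tibble: `family_prefix`, `members`, `total_count`.
#' @export
family_summary <- function(list, family_prefix) {
  if (!all(c("name", "count") %in% names(list))) {
    abort("`list` needs columns name and count")
  }
  hit <- startsWith(list$name, family_prefix)
  tibble(family_prefix = family_prefix,
         members = sum(hit),
         total_count = sum(list$count[hit]))
}

#' Plot a ranked abundance list
#'
#' @param object A `ranked_list` tibble.
#' @param n_top How many entries to show (default 20).
#' @param ... Unused.
#' @export
autoplot.ranked_list <- function(object, n_top = 20, ...) {
  d <- head(as_tibble(object), n_top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$name, .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "read count",
                  title = paste0("Top ", nrow(d), " miRNAs: ",
                                 attr(object, "sample") %||% ""))
}
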