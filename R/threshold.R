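#' Per-sample count distribution
#'
#' Extracts the multiset of per-tag counts for one sample and attaches its
#' empirical cumulative distribution function built on log2 counts. The KS
#' distance is invariant under the monotone log transform, so the log scale
#' only affects plotting.
#'
#' @param counts Long count tibble.
#' @param sample_id Sample to extract.
#' @return An object of class `count_dist`: list with `sample`, `counts`
#'   (sorted integer vector) and `ecdf` (on log2 counts).
#' @export
count_distribution <- function(counts, sample_id) {
  validate_counts(counts)
  if (!sample_id %in% counts$sample && nrow(counts) > 0L) {
    abort(paste0("sample '", sample_id, "' not present in the count table"))
  }
  x <- sort(counts$count[counts$sample == sample_id])
  structure(
    list(sample = sample_id, counts = x,
         ecdf = if (length(x) > 0L) stats::ecdf(log2(x)) else NULL),
    class = "count_dist"
  )
}

#' @export
print.count_dist <- function(x, ...) {
  cat("<count_dist> sample '", x$sample, "': ", length(x$counts),
      " tags", if (length(x$counts) > 0L)
        paste0(", counts ", min(x$counts), "-", max(x$counts)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.count_dist <- function(x, ...) {
  tibble(count = x$counts, log2_count = log2(x$counts),
         ecdf = if (length(x$counts)) x$ecdf(log2(x$counts)) else numeric())
}

#' Exact two-sample Kolmogorov-Smirnov distance
#'
#' Computes D = sup_x |F_a(x) - F_b(x)| exactly over the merged step points
#' of the two empirical CDFs. Ties and heavily discrete data (integer counts)
#' are handled exactly; no p-value is computed, the statistic is used as a
#' distance between replicate count distributions.
#'
#' @param a,b Numeric vectors of counts, or `count_dist` objects.
#' @return D in \[0, 1\].
#' @export
ks_two_sample <- function(a, b) {
  a <- as_count_vector(a)
  b <- as_count_vector(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("both samples must be non-empty")
  }
  ks_distance_sorted(sort(a), sort(b))
}

as_count_vector <- function(x) {
  if (inherits(x, "count_dist")) return(x$counts)
  if (!is.numeric(x)) abort("expected a numeric vector or count_dist")
  x
}

# core statistic on pre-sorted vectors
ks_distance_sorted <- function(a_sorted, b_sorted) {
  xs <- sort(unique(c(a_sorted, b_sorted)))
  fa <- findInterval(xs, a_sorted) / length(a_sorted)
  fb <- findInterval(xs, b_sorted) / length(b_sorted)
  max(abs(fa - fb))
}

#' Adaptive count threshold by an iterative two-sample KS sweep
#'
#' For each integer threshold t the tags with count >= t are retained in each
#' replicate and the exact two-sample KS distance D(t) between the retained
#' count distributions is recorded. D(t) acts as a cost: it is large while
#' poorly reproducible low-count noise dominates and falls as the threshold
#' climbs out of the noise, converging once only the shared high-abundance
#' component remains. The selected threshold is the first instance of a
#' minimum point of D: the smallest t that is an interior local minimum
#' (plateau runs of equal D resolve to their smallest t); when no interior
#' local minimum exists (e.g. a monotone curve), the smallest t attaining the
#' global minimum is returned.
#'
#' The sweep runs over every integer in `[t_min, t_max]` but stops early at
#' the largest t where both replicates still retain at least 2 tags. D(t) is
#' only recomputed where the retained sets change, so the cost is governed by
#' the number of distinct counts, not by `t_max`.
#'
#' @param counts Long count tibble holding both replicates.
#' @param sample_a,sample_b Replicate sample identifiers.
#' @param t_min Smallest threshold (default 1).
#' @param t_max Largest threshold; default the 99th percentile of the pooled
#'   counts.
#' @param normalize Scale each replicate to counts per million before the
#'   sweep (default `FALSE`; the KS statistic is already insensitive to any
#'   common monotone rescaling, this only matters for very unequal library
#'   sizes).
#' @return A `ks_sweep` object; see [tidy.ks_sweep()], [glance.ks_sweep()],
#'   [autoplot.ks_sweep()]. The selected threshold is in
#'   `$selected_threshold`.
#' @export
adaptive_threshold <- function(counts, sample_a, sample_b,
                               t_min = 1L, t_max = NULL, normalize = FALSE) {
  a <- count_distribution(counts, sample_a)$counts
  b <- count_distribution(counts, sample_b)$counts
  if (t_min < 1L) abort("`t_min` must be >= 1")
  if (normalize) {
    # cpm scaling applied to both; thresholds remain on the raw-count grid
    a_scaled <- a / sum(a) * 1e6
    b_scaled <- b / sum(b) * 1e6
  }
  if (is.null(t_max)) {
    t_max <- as.integer(floor(quantile(c(a, b), 0.99, names = FALSE)))
  }
  if (t_max < t_min) abort("`t_max` must be >= `t_min`")
  if (sum(a >= t_min) < 2L || sum(b >= t_min) < 2L) {
    abort("fewer than 2 tags retained at `t_min` in at least one replicate")
  }

  a_sorted <- sort(a)
  b_sorted <- sort(b)
  na <- length(a_sorted); nb <- length(b_sorted)
  # largest t keeping >= 2 tags in both replicates
  t_stop <- min(t_max, a_sorted[na - 1L], b_sorted[nb - 1L])
  ts <- t_min:t_stop

  # D(t) changes only where some count crosses the threshold
  seg_starts <- sort(unique(c(t_min, unique(c(a_sorted, b_sorted)) + 1L)))
  seg_starts <- seg_starts[seg_starts >= t_min & seg_starts <= t_stop]
  seg <- purrr::map(seg_starts, function(t) {
    A <- if (normalize) a_scaled[a >= t] else a_sorted[a_sorted >= t]
    B <- if (normalize) b_scaled[b >= t] else b_sorted[b_sorted >= t]
    list(D = ks_distance_sorted(sort(A), sort(B)),
         n_a = length(A), n_b = length(B))
  })
  take <- findInterval(ts, seg_starts)
  sweep_tbl <- tibble(
    t = ts,
    D = vapply(seg, `[[`, numeric(1), "D")[take],
    n_a = vapply(seg, `[[`, integer(1), "n_a")[take],
    n_b = vapply(seg, `[[`, integer(1), "n_b")[take]
  )

  structure(
    list(sweep = sweep_tbl,
         selected_threshold = select_first_minimum(sweep_tbl$t, sweep_tbl$D),
         samples = c(sample_a, sample_b),
         t_range = c(t_min, t_stop)),
    class = "ks_sweep"
  )
}

# First instance of a minimum point of the D(t) curve: first interior
# local-minimum run (plateaus resolve to their smallest t); fallback to the
# first t attaining the global minimum when no interior local minimum exists.
select_first_minimum <- function(ts, D) {
  r <- rle(D)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  k <- length(r$values)
  if (k >= 3L) {
    for (i in 2:(k - 1L)) {
      if (r$values[i] < r$values[i - 1L] && r$values[i] < r$values[i + 1L]) {
        return(ts[starts[i]])
      }
    }
  }
  ts[which.min(D)]
}

#' @export
print.ks_sweep <- function(x, ...) {
  cat("<ks_sweep> replicates ", paste(x$samples, collapse = " vs "),
      "; t in [", x$t_range[1], ", ", x$t_range[2], "]\n", sep = "")
  cat("selected threshold: ", x$selected_threshold,
      " (D = ", signif(x$sweep$D[x$sweep$t == x$selected_threshold], 3),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy a KS threshold sweep
#'
#' @param x A `ks_sweep` object.
#' @param ... Unused.
#' @return One row per threshold: `t`, `D`, retained tag counts `n_a`, `n_b`.
#' @export
tidy.ks_sweep <- function(x, ...) x$sweep

#' One-row summary of a KS threshold sweep
#'
#' @inheritParams tidy.ks_sweep
#' @export
glance.ks_sweep <- function(x, ...) {
  tibble(
    selected_threshold = x$selected_threshold,
    D_at_selected = x$sweep$D[match(x$selected_threshold, x$sweep$t)],
    D_min = min(x$sweep$D),
    t_min = x$t_range[1],
    t_stop = x$t_range[2],
    n_thresholds = nrow(x$sweep)
  )
}

#' Plot the KS cost curve of a threshold sweep
#'
#' @inheritParams tidy.ks_sweep
#' @param object A `ks_sweep` object.
#' @export
autoplot.ks_sweep <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$t, y = .data$D)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$selected_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "count threshold t",
      y = "two-sample KS distance D(t)",
      title = paste0("Adaptive threshold: ",
                     paste(object$samples, collapse = " vs ")),
      subtitle = paste0("selected t = ", object$selected_threshold)
    )
}

#' Plot a per-sample count distribution
#'
#' Frequency polygon of log2 counts, the shape used to judge the
#' noise/signal mixture by eye.
#'
#' @param object A `count_dist` object.
#' @param ... Unused.
#' @export
autoplot.count_dist <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$log2_count)) +
    ggplot2::geom_freqpoly(bins = 40) +
    ggplot2::labs(x = "log2 count", y = "tags",
                  title = paste0("Count distribution: ", object$sample))
}
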