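#' Partition counts into Low / Mid / High abundance tiers
#'
#' Every stored (tag, sample) count receives exactly one tier:
#' Low when `count < low_upper`, Mid when `low_upper <= count <= high_lower`,
#' High when `count > high_lower`. The defaults (32 and 10,000) are the
#' boundaries used throughout the package: 32 is the adaptive KS threshold
#' separating noise from reproducible expression, and 10,000 marks the
#' sporadic very-high-abundance regime. Both the Mid lower and upper bounds
#' are inclusive.
#'
#' @param counts Long count tibble.
#' @param low_upper Boundary below which a count is Low (default 32).
#' @param high_lower Boundary above which a count is High (default 10000).
#' @return A `mir_tiers` tibble: the input rows plus an ordered `tier`
#'   factor, with the boundaries kept in `attr(, "boundaries")`.
#' @export
assign_tiers <- function(counts, low_upper = 32L, high_lower = 10000L) {
  validate_counts(counts)
  if (!(low_upper < high_lower)) abort("need low_upper < high_lower")
  out <- counts %>%
    mutate(tier = factor(
      case_when(
        .data$count < low_upper ~ "Low",
        .data$count > high_lower ~ "High",
        TRUE ~ "Mid"
      ),
      levels = c("Low", "Mid", "High"), ordered = TRUE
    ))
  attr(out, "boundaries") <- c(low_upper = low_upper, high_lower = high_lower)
  class(out) <- c("mir_tiers", class(out))
  out
}

#' Replicate overlap of one abundance tier
#'
#' Venn-style set arithmetic on the tags holding a given tier in each of two
#' samples.
#'
#' @param tiers A `mir_tiers` tibble from [assign_tiers()].
#' @param sample_a,sample_b Sample identifiers.
#' @param tier One of `"Low"`, `"Mid"`, `"High"`.
#' @return One-row tibble: `tier`, `set_a_size`, `set_b_size`,
#'   `intersection_size`, `union_size`.
#' @export
tier_venn <- function(tiers, sample_a, sample_b, tier) {
  if (!"tier" %in% names(tiers)) abort("`tiers` must come from assign_tiers()")
  if (!tier %in% c("Low", "Mid", "High")) {
    abort("`tier` must be one of 'Low', 'Mid', 'High'")
  }
  for (s in c(sample_a, sample_b)) {
    if (!s %in% tiers$sample) abort(paste0("sample '", s, "' not present"))
  }
  set_a <- tiers$sequence[tiers$sample == sample_a & tiers$tier == tier]
  set_b <- tiers$sequence[tiers$sample == sample_b & tiers$tier == tier]
  tibble(
    tier = tier,
    set_a_size = length(set_a),
    set_b_size = length(set_b),
    intersection_size = length(intersect(set_a, set_b)),
    union_size = length(union(set_a, set_b))
  )
}

#' Cohen's kappa agreement between two sets over a universe
#'
#' Treats membership of each set as a binary rating of every element of the
#' universe and returns the chance-corrected agreement
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement
#' p_o = (|A n B| + |A' n B'|) / |U| and expected agreement p_e from the
#' marginal membership frequencies. When both raters are degenerate
#' (p_e = 1) and agree perfectly, kappa is 1 by convention; a degenerate
#' disagreement yields `NA` with a warning.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Non-empty character vector of all considered elements.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(universe) == 0L) abort("`universe` must be non-empty")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be contained in the universe")
  }
  n <- length(universe)
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(set_a) - n11
  n01 <- length(set_b) - n11
  n00 <- n - n11 - n10 - n01
  p_o <- (n11 + n00) / n
  p_a <- length(set_a) / n
  p_b <- length(set_b) / n
  p_e <- p_a * p_b + (1 - p_a) * (1 - p_b)
  if (p_e == 1) {
    if (p_o == 1) return(1)
    warn("degenerate marginals with imperfect agreement; kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Three-phase summary of a count distribution
#'
#' Splits one sample's tags into the three phases of the global count
#' distribution - the low-count noise cloud (`count < threshold`), the
#' mid-range steady-state phase (`threshold <= count <= high_boundary`) and
#' the sporadic high-abundance phase (`count > high_boundary`) - and reports
#' each phase's tag count and share of the total read mass.
#'
#' @param counts Long count tibble.
#' @param sample_id Sample to summarise.
#' @param threshold Noise/signal boundary (default 32).
#' @param high_boundary Mid/High boundary (default 10000).
#' @return Tibble with one row per phase: `phase`, `n_tags`, `read_mass`,
#'   `mass_fraction` (fractions sum to 1 when the sample is non-empty).
#' @export
three_phase_summary <- function(counts, sample_id, threshold = 32L,
                                high_boundary = 10000L) {
  if (!(threshold < high_boundary)) abort("need threshold < high_boundary")
  x <- count_distribution(counts, sample_id)$counts
  phase <- factor(
    case_when(
      x < threshold ~ "noise",
      x > high_boundary ~ "high",
      TRUE ~ "mid"
    ),
    levels = c("noise", "mid", "high")
  )
  total <- sum(x)
  phase_levels <- levels(phase)
  phase_mass <- vapply(phase_levels, function(p) sum(x[phase == p]),
                       numeric(1))
  phase_tags <- as.integer(table(phase))
  tibble(
    phase = phase_levels,
    n_tags = phase_tags,
    read_mass = as.numeric(phase_mass),
    mass_fraction = if (total > 0) as.numeric(phase_mass) / total
                    else rep(0, length(phase_levels))
  )
}

#' Plot tier occupancy per sample
#'
#' @param object A `mir_tiers` tibble.
#' @param ... Unused.
#' @export
autoplot.mir_tiers <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sample, fill = .data$tier)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "tags", fill = "tier",
                  title = "Abundance-tier occupancy")
}
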