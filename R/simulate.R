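#' Specification of the two-component count mixture
#'
#' Describes the synthetic replicate pair used to exercise the adaptive
#' threshold machinery. The marginal count distribution of each replicate is
#' a mixture of:
#'
#' * a **noise** component confined to counts `1 .. boundary - 1`: a shared
#'   shape built from a singleton-rich spike (geometric, `spike_prob`) and a
#'   shallow exponential tail decaying by `tail_efolds` e-folds across the
#'   noise range, so that every count level below the boundary carries mass.
#'   Replicate discordance is encoded by abundance (the two replicates carry
#'   `n_noise_tags[1]` and `n_noise_tags[2]` noise tags, 4:1 by default) and
#'   by identity (a noise tag recurs in the other replicate with probability
#'   `noise_cooccur` only);
#' * a **signal** component of `n_signal_tags` tags shared by both
#'   replicates: per-tag means are log-normal on the log2 scale
#'   (`signal_meanlog2`, `signal_sdlog2`), counts are re-sampled per
#'   replicate from a Poisson around the shared mean and floored at
#'   `boundary`.
#'
#' With these defaults the replicate KS cost curve D(t) declines strictly
#' while the threshold climbs through the noise range and flattens at the
#' shared-signal floor exactly at `boundary`, which is what makes the
#' boundary recoverable by [adaptive_threshold()].
#'
#' @param n_noise_tags Integer pair: noise tags per replicate
#'   (default `c(8000, 2000)`, i.e. 5000 on average).
#' @param n_signal_tags Shared signal tags (default 2000, must be >= 2).
#' @param boundary Noise/signal boundary count (default 32, must be >= 2).
#' @param spike_weight Weight of the singleton spike in the noise shape
#'   (default 0.75).
#' @param spike_prob Geometric success probability of the spike
#'   (default 0.95; ~95% of spike tags are singletons).
#' @param tail_efolds Exponential decay, in e-folds across
#'   `[1, boundary - 1]`, of the shallow noise tail (default 1).
#' @param signal_meanlog2,signal_sdlog2 Location and scale of the log-normal
#'   signal means on the log2 scale (defaults `log2(1000)` and 1.5, placing
#'   >99% of signal mass at or above the default boundary before flooring).
#' @param noise_cooccur Probability that a noise tag identity recurs in the
#'   second replicate (default 0.3).
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(n_noise_tags = c(8000L, 2000L),
                         n_signal_tags = 2000L,
                         boundary = 32L,
                         spike_weight = 0.75,
                         spike_prob = 0.95,
                         tail_efolds = 1,
                         signal_meanlog2 = log2(1000),
                         signal_sdlog2 = 1.5,
                         noise_cooccur = 0.3) {
  if (length(n_noise_tags) == 1L) n_noise_tags <- rep(n_noise_tags, 2L)
  if (boundary < 2L) abort("`boundary` must be >= 2")
  if (n_signal_tags < 2L) abort("`n_signal_tags` must be >= 2")
  if (spike_prob <= 0 || spike_prob >= 1) abort("`spike_prob` must be in (0,1)")
  if (spike_weight < 0 || spike_weight > 1) abort("`spike_weight` in [0,1]")
  if (noise_cooccur < 0 || noise_cooccur > 1) abort("`noise_cooccur` in [0,1]")
  structure(
    list(n_noise_tags = as.integer(n_noise_tags),
         n_signal_tags = as.integer(n_signal_tags),
         boundary = as.integer(boundary),
         spike_weight = spike_weight, spike_prob = spike_prob,
         tail_efolds = tail_efolds,
         signal_meanlog2 = signal_meanlog2, signal_sdlog2 = signal_sdlog2,
         noise_cooccur = noise_cooccur),
    class = "mixture_spec"
  )
}

# noise pmf on 1..boundary-1: spike + shallow tail, truncated and normalised
noise_pmf <- function(spec) {
  k <- seq_len(spec$boundary - 1L)
  spike <- spec$spike_prob * (1 - spec$spike_prob)^(k - 1)
  spike <- spike / sum(spike)
  lam <- spec$tail_efolds / max(spec$boundary - 1L, 1L)
  tail_ <- exp(-lam * (k - 1))
  tail_ <- tail_ / sum(tail_)
  spec$spike_weight * spike + (1 - spec$spike_weight) * tail_
}

random_tags <- function(n, width = 22L) {
  if (n == 0L) return(character())
  tags <- character(0)
  while (length(tags) < n) {
    fresh <- vapply(seq_len(n - length(tags)), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, "")
    tags <- unique(c(tags, fresh))
  }
  tags[seq_len(n)]
}

#' Simulate a two-replicate count table from the noise/signal mixture
#'
#' Draws the replicate pair described by a [mixture_spec()]. Signal tags are
#' shared between the replicates with per-replicate Poisson resampling of
#' their common mean (floored at the boundary); noise tags are drawn
#' independently per replicate from the shared sub-boundary noise shape,
#' with tag identities co-occurring across replicates only with the spec's
#' co-occurrence probability. All counts are >= 1.
#'
#' @param spec A [mixture_spec()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(spec, seed)`.
#' @param sample_ids Names of the two replicate samples.
#' @return A long count tibble with the generator truth attached as
#'   `attr(, "truth")`: a tibble of `sequence`, `class` (`"noise"` /
#'   `"signal"`) and `mu` (shared signal mean, `NA` for noise).
#' @export
simulate_count_replicates <- function(spec = mixture_spec(), seed = 1L,
                                      sample_ids = c("rep1", "rep2")) {
  stopifnot(inherits(spec, "mixture_spec"), length(sample_ids) == 2L)
  set.seed(seed)

  n1 <- spec$n_noise_tags[1]
  n2 <- spec$n_noise_tags[2]
  ns <- spec$n_signal_tags

  sig_tags <- random_tags(ns)
  mu <- 2^rnorm(ns, spec$signal_meanlog2, spec$signal_sdlog2)
  sig_a <- pmax(rpois(ns, mu), spec$boundary)
  sig_b <- pmax(rpois(ns, mu), spec$boundary)

  pmf <- noise_pmf(spec)
  noise_a_tags <- random_tags(n1)
  n_shared <- if (n1 > 0L) rbinom(1L, n2, spec$noise_cooccur) else 0L
  n_shared <- min(n_shared, n1)
  noise_b_tags <- c(
    if (n_shared > 0L) sample(noise_a_tags, n_shared) else character(),
    random_tags(n2 - n_shared)
  )
  noise_a <- if (n1 > 0L) sample.int(spec$boundary - 1L, n1, TRUE, pmf) else integer()
  noise_b <- if (n2 > 0L) sample.int(spec$boundary - 1L, n2, TRUE, pmf) else integer()

  counts <- bind_rows(
    tibble(sequence = c(sig_tags, noise_a_tags), sample = sample_ids[1],
           count = as.integer(c(sig_a, noise_a))),
    tibble(sequence = c(sig_tags, noise_b_tags), sample = sample_ids[2],
           count = as.integer(c(sig_b, noise_b)))
  )
  attr(counts, "truth") <- tibble(
    sequence = c(sig_tags, noise_a_tags,
                 setdiff(noise_b_tags, noise_a_tags)),
    class = c(rep("signal", ns),
              rep("noise", n1 + length(setdiff(noise_b_tags, noise_a_tags)))),
    mu = c(mu, rep(NA_real_, n1 + length(setdiff(noise_b_tags, noise_a_tags))))
  )
  attr(counts, "mixture_spec") <- spec
  counts
}

#' Simulate FASTQ reads realising a count table
#'
#' Emits, for every sample of the table, `count` copies of each tag with the
#' adapter appended, as a 4-line FASTQ file with constant base quality.
#' Substitution errors are applied to the insert (the tag) at `error_rate`
#' per base; the adapter is written intact so that exact-overlap trimming
#' remains applicable - the error model emulates biological/RT variation of
#' the insert, not sequencer miscalls in the adapter.
#'
#' @param counts Long count tibble.
#' @param reference Optional [mirna_reference()]; with `strict = TRUE` every
#'   tag must equal one of its mature sequences.
#' @param adapter 3' adapter appended to every read.
#' @param error_rate Per-base substitution probability on the insert
#'   (0 to 0.05).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param strict Enforce that all tags exist in the reference.
#' @return Invisibly, a named character vector of written FASTQ paths.
#' @export
simulate_reads <- function(counts, reference = NULL, adapter = "TCGTATGCC",
                           error_rate = 0, seed = 1L,
                           out_dir = tempfile("reads"), strict = !is.null(reference)) {
  validate_counts(counts)
  if (error_rate < 0 || error_rate > 0.05) {
    abort("`error_rate` must be in [0, 0.05]")
  }
  if (strict) {
    if (is.null(reference)) abort("`strict = TRUE` needs a reference")
    missing_tags <- setdiff(unique(counts$sequence), reference$seqs$sequence)
    if (length(missing_tags) > 0L) {
      abort(paste0(length(missing_tags),
                   " tag(s) absent from the reference in strict mode"))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character()
  for (s in unique(counts$sample)) {
    tab <- counts[counts$sample == s, ]
    seqs <- rep(tab$sequence, tab$count)
    if (error_rate > 0 && length(seqs) > 0L) {
      seqs <- vapply(seqs, mutate_sequence, "", error_rate = error_rate,
                     USE.NAMES = FALSE)
    }
    reads <- paste0(seqs, adapter)
    path <- file.path(out_dir, paste0(s, ".fastq"))
    if (length(reads) == 0L) {
      writeLines(character(), path)
    } else {
      ids <- paste0("@", s, "_", seq_along(reads))
      writeLines(as.vector(rbind(ids, reads, "+",
                                 strrep("I", nchar(reads)))), path)
    }
    paths[s] <- path
  }
  invisible(paths)
}

mutate_sequence <- function(seq, error_rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < error_rate)
  if (length(hit) == 0L) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate a pair of interaction networks with designated shared hubs
#'
#' Both networks contain the hub nodes, each wired to `degree` private spoke
#' nodes; spoke and private neighbourhoods are disjoint between the two
#' networks, so the node-set intersection is exactly the hub set.
#'
#' @param n_shared_hubs Number of shared hub nodes.
#' @param n_private Extra private (non-hub) nodes per network, chained
#'   among themselves.
#' @param degree Spokes per hub.
#' @param seed Integer seed.
#' @param hub_names Optional hub names (default `HUB1`, `HUB2`, ...).
#' @return List of two [interaction_network()] objects `net_a`, `net_b`.
#' @export
simulate_networks <- function(n_shared_hubs = 1L, n_private = 10L,
                              degree = 5L, seed = 1L, hub_names = NULL) {
  stopifnot(n_shared_hubs >= 0L, n_private >= 0L, degree >= 0L)
  set.seed(seed)
  hubs <- hub_names %||%
    if (n_shared_hubs > 0L) paste0("HUB", seq_len(n_shared_hubs)) else character()
  if (length(hubs) != n_shared_hubs) {
    abort("`hub_names` must have length `n_shared_hubs`")
  }
  one_side <- function(side) {
    edges <- list()
    for (h in seq_along(hubs)) {
      if (degree > 0L) {
        spokes <- paste0(side, "_", hubs[h], "_S", seq_len(degree))
        edges[[length(edges) + 1L]] <- tibble(from = hubs[h], to = spokes)
      }
    }
    if (n_private >= 2L) {
      priv <- paste0(side, "_P", seq_len(n_private))
      edges[[length(edges) + 1L]] <- tibble(from = priv[-n_private],
                                            to = priv[-1L])
    }
    edge_tbl <- if (length(edges) > 0L) bind_rows(edges) else
      tibble(from = character(), to = character())
    interaction_network(edge_tbl, label = side)
  }
  list(net_a = one_side("NETA"), net_b = one_side("NETB"))
}

#' Simulate a grouped expression matrix with per-gene fold changes
#'
#' Generates a long expression table for two groups of samples. Each gene
#' has a random base level; its mean in the first (numerator) group is the
#' base level times its fold change, in the second group the base level.
#' Values carry multiplicative log-normal noise with coefficient of
#' variation `noise_cv` (exact at 0). The housekeeping gene is constant up
#' to the same noise, so ratios computed by [normalized_group_ratio()]
#' recover the fold changes.
#'
#' @param genes Character vector of gene symbols.
#' @param fold_change Per-gene fold change for the first group: a single
#'   value or a vector named by gene (default 1).
#' @param group_labels Two group labels, numerator first
#'   (default `c("HEPG2", "hES_MSC")`).
#' @param group_sizes Samples per group (default `c(2, 12)`).
#' @param noise_cv Multiplicative noise CV (default 0).
#' @param housekeeping Housekeeping gene symbol added to the matrix.
#' @param seed Integer seed.
#' @return An [expression_data()] tibble.
#' @export
simulate_expression <- function(genes, fold_change = 1,
                                group_labels = c("HEPG2", "hES_MSC"),
                                group_sizes = c(2L, 12L),
                                noise_cv = 0, housekeeping = "GAPDH",
                                seed = 1L) {
  stopifnot(length(group_labels) == 2L, length(group_sizes) == 2L,
            noise_cv >= 0)
  if (housekeeping %in% genes) {
    abort("`genes` must not contain the housekeeping gene")
  }
  set.seed(seed)
  fc <- if (length(fold_change) == 1L) {
    setNames(rep(fold_change, length(genes)), genes)
  } else {
    if (!all(genes %in% names(fold_change))) {
      abort("`fold_change` must be named by gene")
    }
    fold_change[genes]
  }
  base <- setNames(2^runif(length(genes), 5, 12), genes)
  samples <- tibble(
    sample = c(paste0(group_labels[1], "_", seq_len(group_sizes[1])),
               paste0(group_labels[2], "_", seq_len(group_sizes[2]))),
    group = rep(group_labels, group_sizes)
  )
  grid <- tidyr::expand_grid(gene = c(genes, housekeeping),
                             sample = samples$sample) %>%
    inner_join(samples, by = "sample") %>%
    mutate(
      mean = dplyr::if_else(
        .data$gene == housekeeping, 1000,
        base[.data$gene] *
          dplyr::if_else(.data$group == group_labels[1],
                         fc[.data$gene], 1)),
      value = .data$mean * exp(rnorm(dplyr::n(), 0, noise_cv))
    ) %>%
    select("gene", "sample", "group", "value")
  expression_data(grid, housekeeping)
}
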