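# Independent brute-force oracles, deliberately written in the most naive
# style possible so they share no code path with the package internals.

ex_path <- function(f) system.file("extdata", f, package = "mirsieve")

# sup over merged support of |F_a - F_b|, elementwise means
oracle_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Cohen's kappa via the generic categorical contingency-table form
oracle_kappa <- function(set_a, set_b, universe) {
  ra <- factor(universe %in% set_a, levels = c(FALSE, TRUE))
  rb <- factor(universe %in% set_b, levels = c(FALSE, TRUE))
  tab <- table(ra, rb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

# exhaustive all-offset, all-reference Hamming scan for one tag
oracle_best_hits <- function(tag, ref_names, ref_seqs, max_mismatches) {
  best <- Inf
  rows <- data.frame(mirna = character(), mismatches = integer(),
                     offset = integer())
  tchars <- strsplit(tag, "")[[1]]
  for (j in seq_along(ref_seqs)) {
    rchars <- strsplit(ref_seqs[j], "")[[1]]
    m <- length(tchars); L <- length(rchars)
    if (m > L) next
    for (off in 0:(L - m)) {
      mm <- sum(tchars != rchars[(off + 1):(off + m)] | tchars == "N")
      if (mm < best) {
        best <- mm
        rows <- data.frame(mirna = ref_names[j], mismatches = mm, offset = off)
      } else if (mm == best) {
        rows <- rbind(rows, data.frame(mirna = ref_names[j], mismatches = mm,
                                       offset = off))
      }
    }
  }
  if (!is.finite(best) || best > max_mismatches) {
    return(rows[0, ])
  }
  rows
}

random_seq <- function(n, width = 22) {
  width <- rep(width, length.out = n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

reads_tbl <- function(seqs, quality = NA_character_) {
  tibble::tibble(read_id = paste0("r", seq_along(seqs)), sequence = seqs,
                 quality = quality)
}

random_count_table <- function(n_tags = 20, samples = c("s1", "s2"),
                               max_count = 500) {
  tags <- random_seq(n_tags)
  do.call(rbind, lapply(samples, function(s) {
    keep <- sample(c(TRUE, FALSE), n_tags, replace = TRUE, prob = c(0.8, 0.2))
    tibble::tibble(sequence = tags[keep], sample = s,
                   count = sample.int(max_count, sum(keep), replace = TRUE))
  }))
}
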