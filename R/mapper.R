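#' Map unique tags to mature miRNA sequences with bounded mismatches
#'
#' Every unique tag in the count table is aligned, ungapped, against every
#' mature sequence at every offset, and scored by Hamming distance. For each
#' tag the minimum attainable mismatch count m* is found; all (miRNA, offset)
#' hits achieving m* are reported, provided m* does not exceed
#' `max_mismatches`. An `N` in a tag counts as a mismatch at every position.
#' Tags longer than a mature sequence produce no hit against it.
#'
#' The default bound of 3 mismatches follows common practice for aligning
#' ~22 nt small-RNA tags, where the mapped fraction is stable up to 3
#' mismatches and degrades beyond.
#'
#' @param counts Long count tibble (`sequence`, `sample`, `count`).
#' @param reference A [mirna_reference()].
#' @param max_mismatches Maximum allowed mismatches (default 3).
#' @return Tibble with one row per equal-best hit: `sequence`, `mirna`,
#'   `mismatches`, `offset` (0-based start of the tag within the mature
#'   sequence).
#' @export
map_tags <- function(counts, reference, max_mismatches = 3L) {
  validate_counts(counts)
  if (!inherits(reference, "mirna_reference")) {
    abort("`reference` must be a mirna_reference")
  }
  if (max_mismatches < 0L) abort("`max_mismatches` must be >= 0")

  tags <- unique(counts$sequence)
  ref_int <- lapply(reference$seqs$sequence, utf8ToInt)
  ref_len <- lengths(ref_int)
  ref_nm <- reference$seqs$mirna

  hit_list <- lapply(tags, function(tag) {
    tv <- utf8ToInt(tag)
    m <- length(tv)
    best <- Inf
    rows <- list()
    for (j in seq_along(ref_int)) {
      L <- ref_len[j]
      if (m > L) next
      rv <- ref_int[[j]]
      for (off in 0:(L - m)) {
        mm <- sum(tv != rv[(off + 1L):(off + m)])
        if (mm < best) {
          best <- mm
          rows <- list(c(j, mm, off))
        } else if (mm == best) {
          rows[[length(rows) + 1L]] <- c(j, mm, off)
        }
      }
    }
    if (!is.finite(best) || best > max_mismatches) return(NULL)
    mat <- do.call(rbind, rows)
    tibble(sequence = tag, mirna = ref_nm[mat[, 1]],
           mismatches = as.integer(mat[, 2]), offset = as.integer(mat[, 3]))
  })
  out <- bind_rows(hit_list)
  if (nrow(out) == 0L) {
    out <- tibble(sequence = character(), mirna = character(),
                  mismatches = integer(), offset = integer())
  }
  out
}

#' Annotate a count table with its best miRNA hits
#'
#' Each tag gains the name of its unique best-hit miRNA. Tags whose equal-best
#' hits span several miRNAs receive a concatenated annotation
#' (`"name1;name2"`, lexicographic) and are flagged `ambiguous`. Tags without
#' any hit are dropped: only reference-aligned sequences are retained.
#'
#' @inheritParams map_tags
#' @param hits Hit tibble from [map_tags()] run on the same table.
#' @return The annotated count tibble with `mirna` and `ambiguous` columns.
#' @export
annotate_counts <- function(counts, hits) {
  validate_counts(counts)
  ann <- hits %>%
    distinct(.data$sequence, .data$mirna) %>%
    group_by(.data$sequence) %>%
    summarise(mirna = paste(sort(.data$mirna), collapse = ";"),
              ambiguous = dplyr::n() > 1L, .groups = "drop")
  counts %>%
    select(-dplyr::any_of(c("mirna", "ambiguous"))) %>%
    inner_join(ann, by = "sequence")
}

#' Project annotated counts onto a genomic peak track
#'
#' Counts of each unambiguously annotated tag are added to the genomic locus
#' of its miRNA for one sample; loci that overlap are merged into a single
#' interval whose height is the sum (via [GenomicRanges::reduce()]). The
#' resulting track conserves mass: the summed heights equal the summed counts
#' of the uniquely annotated, locus-bearing tags of the sample.
#'
#' @inheritParams annotate_counts
#' @param reference A [mirna_reference()] carrying loci.
#' @param sample_id Which sample's counts to project.
#' @return A peak-track tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `height`, sorted by (chrom, start).
#' @export
build_peak_track <- function(counts, hits, reference, sample_id) {
  if (is.null(reference$loci)) abort("reference carries no loci")
  if (!sample_id %in% counts$sample) {
    abort(paste0("sample '", sample_id, "' not present in the count table"))
  }
  ann <- annotate_counts(counts, hits) %>%
    filter(!.data$ambiguous, .data$sample == sample_id)
  per_mirna <- ann %>%
    group_by(.data$mirna) %>%
    summarise(height = sum(.data$count), .groups = "drop")
  no_locus <- setdiff(per_mirna$mirna, reference$loci$mirna)
  if (length(no_locus) > 0L) {
    warn(paste0("no locus for ", length(no_locus), " annotated miRNA(s), ",
                "their tags are skipped: ",
                paste(head(no_locus, 5), collapse = ", ")))
  }
  located <- per_mirna %>% inner_join(reference$loci, by = "mirna")
  if (nrow(located) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  height = integer()))
  }
  gr <- GenomicRanges::GRanges(
    located$chrom,
    IRanges::IRanges(start = located$start + 1L, end = located$end)
  )
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, ignore.strand = TRUE)
  height <- vapply(S4Vectors::mcols(red)$revmap,
                   function(i) sum(located$height[i]), numeric(1))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    height = as.integer(height)
  ) %>%
    arrange(.data$chrom, .data$start)
}

#' Histogram of peak heights in log space
#'
#' Bins the log-transformed peak heights into left-closed bins of fixed width
#' starting at 0, covering the full range of observed log-heights. Frequencies
#' sum to the number of intervals.
#'
#' @param track Peak-track tibble from [build_peak_track()].
#' @param log_base Base of the log transform (default 10).
#' @param bin_width Bin width on the log scale (default 1).
#' @return Tibble with `bin_start`, `bin_end` (log units) and frequency `n`.
#' @export
peak_histogram <- function(track, log_base = 10, bin_width = 1) {
  validate_track(track)
  if (log_base <= 1) abort("`log_base` must be > 1")
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  if (nrow(track) == 0L) {
    return(tibble(bin_start = numeric(), bin_end = numeric(), n = integer()))
  }
  if (any(track$height < 1)) abort("cannot take log of a zero-height interval")
  x <- log(track$height, base = log_base)
  n_bins <- floor(max(x) / bin_width) + 1L
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- findInterval(x, breaks)
  tibble(
    bin_start = breaks[seq_len(n_bins)],
    bin_end = breaks[seq_len(n_bins) + 1L],
    n = tabulate(idx, nbins = n_bins)
  )
}

#' Write a peak track as BED5 or variableStep wiggle
#'
#' BED output is 0-based half-open with the peak height in column 5; wiggle
#' output is 1-based `variableStep` with the height repeated across each
#' interval via a per-interval span. Both start with a browser `track` line.
#'
#' @inheritParams peak_histogram
#' @param path Output file path.
#' @param name Track name for the header line.
#' @export
write_bed <- function(track, path, name = "peaks") {
  validate_track(track)
  lines <- paste0("track name=\"", name, "\" type=bed")
  if (nrow(track) > 0L) {
    lines <- c(lines, paste(track$chrom, track$start, track$end,
                            paste0("peak", seq_len(nrow(track))),
                            track$height, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_wiggle <- function(track, path, name = "peaks") {
  validate_track(track)
  lines <- paste0("track type=wiggle_0 name=\"", name, "\"")
  for (i in seq_len(nrow(track))) {
    lines <- c(lines,
               paste0("variableStep chrom=", track$chrom[i],
                      " span=", track$end[i] - track$start[i]),
               paste(track$start[i] + 1L, track$height[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED5 peak track written by [write_bed()]
#'
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                   nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  height = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    height = as.integer(vapply(parts, `[`, "", 5L))
  )
}

validate_track <- function(track) {
  need <- c("chrom", "start", "end", "height")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    abort("a peak track needs columns chrom, start, end, height")
  }
  if (nrow(track) > 0L) {
    if (any(track$end <= track$start)) abort("track intervals need end > start")
    if (any(track$height < 0)) abort("track heights must be >= 0")
  }
  invisible(track)
}
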