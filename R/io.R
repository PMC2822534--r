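#' Read small-RNA reads from FASTA or FASTQ
#'
#' Parses a (optionally gzipped) FASTA or 4-line FASTQ file into a tibble of
#' reads. Sequences are uppercased; the alphabet is restricted to A, C, G, T
#' and N. Parsing is delegated to [Biostrings::readDNAStringSet()]; when the
#' file is malformed, the file is rescanned line by line so the error names
#' the offending line.
#'
#' @param path Path to the reads file.
#' @param format `"auto"` (default; decided from the file extension),
#'   `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id`, `sequence` and `quality`
#'   (`NA` for FASTA input), one row per input record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "tgaggtagtagattgtatagtt", ">r2", "ACGT"), fa)
#' read_smallrna(fa)
#' @export
read_smallrna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("reads file not found: ", path))
  }
  if (format == "auto") {
    format <- guess_reads_format(path)
  }

  first <- readLines(path, n = 1L)
  if (length(first) == 0L || all(!nzchar(trimws(first)))) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }

  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) diagnose_fasta(path, conditionMessage(e))
    )
    out <- tibble(
      read_id  = names(set),
      sequence = unname(toupper(as.character(set))),
      quality  = NA_character_
    )
  } else {
    validate_fastq_lines(path) # line-numbered structural checks first
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) abort(paste0("FASTQ parse error: ",
                                       conditionMessage(e)))
    )
    out <- tibble(
      read_id  = names(set),
      sequence = unname(toupper(as.character(set))),
      quality  = unname(as.character(S4Vectors::mcols(set)$qualities))
    )
  }

  bad <- which(!grepl("^[ACGTN]+$", out$sequence))
  if (length(bad) > 0L) {
    abort(paste0("parse error: record ", bad[1], " ('", out$read_id[bad[1]],
                 "') contains characters outside {A,C,G,T,N}"))
  }
  out
}

guess_reads_format <- function(path) {
  base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
  if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) return("fasta")
  abort(paste0("cannot guess reads format from extension of '", path,
               "'; pass format = \"fasta\" or \"fastq\""))
}

# Structural validation of a 4-line FASTQ with line-numbered errors; run
# before the real parser so malformed files fail with a useful location.
validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  n <- length(lines)
  if (n %% 4L != 0L) {
    abort(paste0("FASTQ parse error: file has ", n,
                 " lines, not a multiple of 4 (truncated record at line ",
                 4L * (n %/% 4L) + 1L, ")"))
  }
  for (i in seq_len(n %/% 4L)) {
    l <- (i - 1L) * 4L
    if (!startsWith(lines[l + 1L], "@")) {
      abort(paste0("FASTQ parse error at line ", l + 1L,
                   ": expected header starting with '@'"))
    }
    if (!startsWith(lines[l + 3L], "+")) {
      abort(paste0("FASTQ parse error at line ", l + 3L,
                   ": expected separator starting with '+'"))
    }
    if (nchar(lines[l + 4L]) != nchar(lines[l + 2L])) {
      abort(paste0("FASTQ parse error at line ", l + 4L,
                   ": quality length differs from sequence length"))
    }
  }
  invisible(TRUE)
}

diagnose_fasta <- function(path, parent_msg) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0L && !startsWith(trimws(lines[1]), ">")) {
    abort("FASTA parse error at line 1: expected header starting with '>'")
  }
  abort(paste0("FASTA parse error: ", parent_msg))
}

#' Trim a 3' adapter from reads
#'
#' Removes from each read the longest suffix that exactly matches a prefix of
#' the adapter, provided the overlap is at least `min_overlap` nucleotides.
#' Reads without a qualifying overlap pass through unchanged; reads trimmed to
#' zero length (adapter dimers) are dropped. Matching is exact; `N` never
#' matches.
#'
#' @param reads Tibble of reads as returned by [read_smallrna()].
#' @param adapter Adapter sequence (non-empty, A/C/G/T).
#' @param min_overlap Minimum suffix/prefix overlap to trim (default 6).
#' @return The reads tibble with trimmed `sequence` (and `quality`, when
#'   present) columns; dimer reads removed.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  validate_reads(reads)
  adapter <- toupper(adapter)
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    abort("`adapter` must be a single non-empty sequence")
  }
  if (min_overlap < 1L) abort("`min_overlap` must be >= 1")

  seq_len_v <- nchar(reads$sequence)
  keep_len <- seq_len_v # length of read after trimming
  matched <- rep(FALSE, nrow(reads))
  for (k in seq(min(nchar(adapter), max(seq_len_v, 0L)), min_overlap)) {
    if (k < min_overlap) break
    idx <- which(!matched & seq_len_v >= k)
    if (length(idx) == 0L) next
    suffix <- substr(reads$sequence[idx], seq_len_v[idx] - k + 1L, seq_len_v[idx])
    hit <- suffix == substr(adapter, 1L, k)
    keep_len[idx[hit]] <- seq_len_v[idx[hit]] - k
    matched[idx[hit]] <- TRUE
  }

  out <- reads
  out$sequence <- substr(out$sequence, 1L, keep_len)
  if ("quality" %in% names(out)) {
    out$quality <- ifelse(is.na(out$quality), out$quality,
                          substr(out$quality, 1L, keep_len))
  }
  out[keep_len > 0L, , drop = FALSE]
}

#' Filter reads by length window
#'
#' Keeps reads whose length lies in `[min_len, max_len]` (both inclusive),
#' the computational analogue of the 18-35 nt gel-purification window used
#' for intracellular small-RNA libraries. Order is preserved and the filter
#' is idempotent.
#'
#' @inheritParams trim_adapter
#' @param min_len,max_len Inclusive length bounds in nucleotides
#'   (defaults 18 and 35).
#' @export
filter_length <- function(reads, min_len = 18L, max_len = 35L) {
  validate_reads(reads)
  if (!(min_len >= 1L && min_len <= max_len)) {
    abort("need 1 <= min_len <= max_len")
  }
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Collapse identical reads into a unique-tag count table
#'
#' Identical sequences are counted and collapsed, producing the long count
#' table used throughout the package: one row per (sequence, sample) with the
#' sequencing multiplicity as `count`. The total count equals the number of
#' input reads.
#'
#' @inheritParams trim_adapter
#' @param sample_id Sample identifier for the resulting column (non-empty).
#' @return A count tibble with columns `sequence`, `sample`, `count`.
#' @export
collapse_reads <- function(reads, sample_id) {
  validate_reads(reads)
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    abort("`sample_id` must be a single non-empty string")
  }
  if (nrow(reads) == 0L) {
    return(tibble(sequence = character(), sample = character(),
                  count = integer()))
  }
  reads %>%
    count(.data$sequence, name = "count") %>%
    mutate(sample = sample_id, .after = "sequence") %>%
    arrange(desc(.data$count), .data$sequence)
}

#' Merge per-sample count tables
#'
#' Binds count tables row-wise. Sample identifiers must be pairwise distinct
#' across the inputs; (tag, sample) pairs absent from every input stay absent.
#'
#' @param ... Count tibbles, or a single list of count tibbles.
#' @export
merge_counts <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  purrr::walk(tables, validate_counts)
  samples <- purrr::map(tables, ~ unique(.x$sample))
  all_samples <- unlist(samples)
  if (anyDuplicated(all_samples)) {
    dup <- unique(all_samples[duplicated(all_samples)])
    abort(paste0("duplicate sample id(s) across tables: ",
                 paste(dup, collapse = ", ")))
  }
  bind_rows(tables)
}

#' Read / write wide count-table TSV files
#'
#' The on-disk shape mirrors published per-sample count tables: a `sequence`
#' column, one integer column per sample, and an optional `mirna` (or
#' `annotation`) column. Lines starting with `#` are ignored. Zero cells are
#' treated as absent (the long table stores only positive counts). On write,
#' rows are ordered by descending count of the first sample and absent pairs
#' are written as 0, so write-then-read is the identity on canonical tables.
#'
#' @param path TSV file path.
#' @return `read_count_table()` returns a long count tibble (`sequence`,
#'   `sample`, `count`, and `mirna` when an annotation column is present).
#' @export
read_count_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sequence" %in% names(raw)) {
    abort("count table must have a 'sequence' column")
  }
  names(raw)[names(raw) == "annotation"] <- "mirna"
  sample_cols <- setdiff(names(raw), c("sequence", "mirna"))
  if (length(sample_cols) == 0L) {
    abort("count table has no sample columns")
  }
  for (sc in sample_cols) {
    cells <- raw[[sc]]
    bad <- which(!grepl("^[0-9]+$", cells))
    if (length(bad) > 0L) {
      abort(paste0("count table parse error in column '", sc, "', row ",
                   bad[1], ": '", cells[bad[1]],
                   "' is not a non-negative integer"))
    }
  }
  long <- raw %>%
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample",
                        values_to = "count") %>%
    mutate(count = as.integer(.data$count)) %>%
    filter(.data$count > 0L)
  cols <- c("sequence", "sample", "count",
            if ("mirna" %in% names(long)) "mirna")
  long <- long[, cols]
  validate_counts(long)
  long
}

#' @param table Long count tibble.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  validate_counts(table)
  samples <- unique(table$sample)
  wide <- table %>%
    tidyr::pivot_wider(id_cols = dplyr::any_of(c("sequence", "mirna")),
                       names_from = "sample", values_from = "count",
                       values_fill = 0L)
  first <- samples[1]
  wide <- wide %>% arrange(desc(.data[[first]]), .data$sequence)
  ord <- c("sequence", samples, if ("mirna" %in% names(wide)) "mirna")
  readr::write_tsv(wide[, ord], path, progress = FALSE)
  invisible(path)
}

validate_reads <- function(reads) {
  if (!is.data.frame(reads) || !all(c("read_id", "sequence") %in% names(reads))) {
    abort("`reads` must be a data frame with columns read_id and sequence")
  }
  invisible(reads)
}

validate_counts <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("sequence", "sample", "count") %in% names(table))) {
    abort("a count table needs columns sequence, sample and count")
  }
  if (nrow(table) > 0L) {
    if (any(table$count < 1L)) abort("stored counts must be >= 1")
    if (anyDuplicated(table[, c("sequence", "sample")])) {
      abort("duplicate (sequence, sample) rows in count table")
    }
  }
  invisible(table)
}
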