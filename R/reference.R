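#' Construct a mature-miRNA reference
#'
#' A reference is a named set of mature miRNA sequences, optionally with one
#' genomic locus per miRNA (0-based half-open coordinates, as in BED). Mature
#' sequences must be at least 15 nt of plain A/C/G/T; names must be unique.
#'
#' @param mirna Character vector of miRNA names.
#' @param sequence Character vector of mature sequences (same length).
#' @param loci Optional tibble with columns `mirna`, `chrom`, `start`, `end`,
#'   `strand` giving one interval per miRNA (`end > start`).
#' @return An object of class `mirna_reference`: a list with elements
#'   `seqs` (tibble `mirna`, `sequence`) and `loci` (tibble or `NULL`).
#' @export
mirna_reference <- function(mirna, sequence, loci = NULL) {
  sequence <- toupper(sequence)
  if (length(mirna) != length(sequence)) {
    abort("`mirna` and `sequence` must have the same length")
  }
  if (length(mirna) == 0L) abort("empty reference")
  if (anyDuplicated(mirna)) abort("miRNA names must be unique")
  if (any(!grepl("^[ACGT]+$", sequence))) {
    abort("mature sequences must be plain A/C/G/T")
  }
  if (any(nchar(sequence) < 15L)) {
    abort("mature sequences must be at least 15 nt")
  }
  if (!is.null(loci)) {
    need <- c("mirna", "chrom", "start", "end", "strand")
    if (!is.data.frame(loci) || !all(need %in% names(loci))) {
      abort("`loci` needs columns mirna, chrom, start, end, strand")
    }
    if (any(loci$end <= loci$start)) abort("loci must satisfy end > start")
    if (!all(loci$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
    if (anyDuplicated(loci$mirna)) abort("one locus per miRNA")
    loci <- as_tibble(loci)[, need]
  }
  structure(list(seqs = tibble(mirna = mirna, sequence = sequence),
                 loci = loci),
            class = "mirna_reference")
}

#' Read a mature-miRNA reference from FASTA (and optional BED6 loci)
#'
#' FASTA headers are taken as miRNA names (first whitespace-delimited token);
#' `U` is converted to `T` so miRBase-style RNA sequences are accepted. The
#' optional BED6 file supplies one genomic interval per miRNA via its name
#' column.
#'
#' @param fasta_path Mature-sequence FASTA file.
#' @param bed_path Optional BED6 file of per-miRNA loci.
#' @return A [mirna_reference()] object.
#' @export
read_mirna_reference <- function(fasta_path, bed_path = NULL) {
  set <- Biostrings::readBStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- chartr("Uu", "Tt", as.character(set))
  loci <- NULL
  if (!is.null(bed_path)) {
    bed <- readr::read_tsv(bed_path, comment = "#",
                           col_names = c("chrom", "start", "end", "mirna",
                                         "score", "strand"),
                           col_types = "ciicnc", progress = FALSE)
    loci <- bed[, c("mirna", "chrom", "start", "end", "strand")]
    unknown <- setdiff(loci$mirna, nm)
    if (length(unknown) > 0L) {
      warn(paste0("loci for miRNAs absent from the FASTA are ignored: ",
                  paste(head(unknown, 5), collapse = ", ")))
      loci <- loci[loci$mirna %in% nm, ]
    }
  }
  mirna_reference(nm, seqs, loci)
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("<mirna_reference> ", nrow(x$seqs), " mature sequences",
      if (!is.null(x$loci)) paste0(", ", nrow(x$loci), " loci"), "\n", sep = "")
  invisible(x)
}
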