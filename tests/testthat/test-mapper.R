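ref_small <- function() {
  mirna_reference(
    c("mirA", "mirB", "mirC"),
    c("TGAGGTAGTAGATTGTATAGTT",   # hsa-let-7f mature sequence
      "TGAGGTAGTAGGTTGTATAGTT",   # 2 mismatches from mirA
      "ACAGTAGTCTGCACATTGGTTAGG")
  )
}

test_that("exact tags map with zero mismatches at offset zero", {
  tab <- tibble::tibble(sequence = "TGAGGTAGTAGATTGTATAGTT",
                        sample = "s", count = 10L)
  hits <- map_tags(tab, ref_small(), 3)
  expect_equal(hits$mirna, "mirA")
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$offset, 0L)
})

test_that("tags beyond the mismatch bound yield no hit", {
  tag <- "TGAGGTAGTAGATTGTATAGTT"
  substr(tag, 1, 1) <- "C"; substr(tag, 3, 3) <- "C"
  substr(tag, 5, 5) <- "A"; substr(tag, 7, 7) <- "C" # 4 mismatches vs mirA
  tab <- tibble::tibble(sequence = tag, sample = "s", count = 1L)
  expect_equal(nrow(map_tags(tab, ref_small(), 3)), 0L)
  expect_gt(nrow(map_tags(tab, ref_small(), 6)), 0L)
})

test_that("equidistant best hits are all reported", {
  # one mismatch from both mirA and mirB (position 12 sits between them)
  tag <- "TGAGGTAGTAGCTTGTATAGTT"
  tab <- tibble::tibble(sequence = tag, sample = "s", count = 1L)
  hits <- map_tags(tab, ref_small(), 3)
  expect_setequal(hits$mirna, c("mirA", "mirB"))
  expect_true(all(hits$mismatches == 1L))
})

test_that("map_tags agrees with the exhaustive Hamming-scan oracle", {
  set.seed(101)
  ref_names <- paste0("m", 1:12)
  ref_seqs <- random_seq(12, width = sample(18:26, 12, replace = TRUE))
  reference <- mirna_reference(ref_names, ref_seqs)
  # mix of exact copies, mutated copies, truncations and random tags
  tags <- unique(c(
    ref_seqs[1:4],
    vapply(ref_seqs[5:8], function(s) {
      p <- sample(nchar(s), 2)
      for (i in p) substr(s, i, i) <- sample(setdiff(c("A","C","G","T"),
                                                     substr(s, i, i)), 1)
      s
    }, character(1), USE.NAMES = FALSE),
    substr(ref_seqs[9:10], 3, 20),
    random_seq(10, width = 22),
    gsub("^(.)", "N", ref_seqs[11])
  ))
  tab <- tibble::tibble(sequence = tags, sample = "s",
                        count = seq_along(tags))
  hits <- map_tags(tab, reference, 3)
  for (tag in tags) {
    got <- hits[hits$sequence == tag, c("mirna", "mismatches", "offset")]
    want <- oracle_best_hits(tag, ref_names, ref_seqs, 3)
    expect_equal(nrow(got), nrow(want), info = tag)
    if (nrow(want) > 0) {
      expect_setequal(paste(got$mirna, got$mismatches, got$offset),
                      paste(want$mirna, want$mismatches, want$offset))
    }
  }
})

test_that("raising the mismatch bound never removes a hit; 0 mm = substring", {
  set.seed(7)
  reference <- mirna_reference(paste0("m", 1:6), random_seq(6, 24))
  tab <- tibble::tibble(sequence = c(random_seq(20, 22),
                                     substr(reference$seqs$sequence[1], 2, 23)),
                        sample = "s", count = 1L)
  h1 <- map_tags(tab, reference, 1)
  h3 <- map_tags(tab, reference, 3)
  key <- function(h) paste(h$sequence, h$mirna, h$offset)
  expect_true(all(key(h1) %in% key(h3)))

  h0 <- map_tags(tab, reference, 0)
  if (nrow(h0) > 0) {
    ok <- vapply(seq_len(nrow(h0)), function(i) {
      grepl(h0$sequence[i],
            reference$seqs$sequence[reference$seqs$mirna == h0$mirna[i]],
            fixed = TRUE)
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("annotation reproduces the printed miRNA names and drops orphans", {
  t1 <- read_count_table(ex_path("table1_intracellular.tsv"))
  reference <- read_mirna_reference(ex_path("mature_mirnas.fasta"))
  hits <- map_tags(dplyr::select(t1, -mirna), reference, 3)
  ann <- annotate_counts(dplyr::select(t1, -mirna), hits)
  joined <- dplyr::inner_join(t1, dplyr::select(ann, sequence, sample,
                                                got = mirna),
                              by = c("sequence", "sample"))
  expect_equal(nrow(joined), nrow(t1))
  expect_equal(joined$got, joined$mirna)

  with_orphan <- dplyr::bind_rows(
    t1, tibble::tibble(sequence = "CCCCCCCCCCCCCCCCCCCCCC",
                       sample = "intracellular_1", count = 5L,
                       mirna = NA_character_))
  hits2 <- map_tags(with_orphan, reference, 3)
  ann2 <- annotate_counts(with_orphan, hits2)
  expect_false("CCCCCCCCCCCCCCCCCCCCCC" %in% ann2$sequence)
  expect_equal(nrow(annotate_counts(t1, hits[0, ])), 0L)
})

test_that("peak tracks conserve mass and merge overlapping loci", {
  reference <- mirna_reference(
    c("mirA", "mirB", "mirC"),
    c("TGAGGTAGTAGATTGTATAGTT", "TGAGGTAGTAGGTTGTATAGTT",
      "ACAGTAGTCTGCACATTGGTTA"),
    loci = tibble::tibble(
      mirna = c("mirA", "mirB", "mirC"),
      chrom = c("chr1", "chr1", "chr2"),
      start = c(100L, 110L, 500L),
      end = c(122L, 132L, 522L),
      strand = "+"
    )
  )
  tab <- tibble::tibble(
    sequence = reference$seqs$sequence,
    sample = "s",
    count = c(30L, 70L, 100L)
  )
  hits <- map_tags(tab, reference, 0)
  track <- build_peak_track(tab, hits, reference, "s")
  expect_equal(nrow(track), 2L) # chr1 loci overlap and merge
  expect_equal(track$height[track$chrom == "chr1"], 100L)
  expect_equal(sum(track$height), sum(tab$count))

  # a miRNA without a locus warns and is skipped
  ref2 <- mirna_reference(reference$seqs$mirna, reference$seqs$sequence,
                          loci = reference$loci[-3, ])
  expect_warning(track2 <- build_peak_track(tab, hits, ref2, "s"),
                 "no locus")
  expect_equal(sum(track2$height), 100L)
})

test_that("peak-track mass equals the sample total for the printed table", {
  t1 <- read_count_table(ex_path("table1_intracellular.tsv"))
  reference <- read_mirna_reference(ex_path("mature_mirnas.fasta"),
                                    ex_path("mirna_loci_synthetic.bed"))
  hits <- map_tags(t1, reference, 3)
  for (s in unique(t1$sample)) {
    track <- build_peak_track(t1, hits, reference, s)
    expect_equal(sum(track$height), sum(t1$count[t1$sample == s]))
  }
})

test_that("peak histograms bin log-heights as hand-computed", {
  track <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L),
                          end = c(10L, 110L, 210L),
                          height = c(10L, 10L, 1000L))
  h <- peak_histogram(track, log_base = 10, bin_width = 1)
  expect_equal(h$n[h$bin_start == 1], 2L)
  expect_equal(h$n[h$bin_start == 3], 1L)
  expect_equal(sum(h$n), 3L)

  single <- peak_histogram(tibble::tibble(chrom = "c", start = 0L, end = 1L,
                                          height = 7L))
  expect_equal(sum(single$n), 1L)
  expect_equal(nrow(peak_histogram(track[0, ])), 0L)
  expect_error(peak_histogram(dplyr::mutate(track, height = c(0L, 10L, 10L))),
               "zero-height")
})

test_that("BED and wiggle emitters produce the documented formats", {
  track <- tibble::tibble(chrom = "chr9", start = 94175957L, end = 94175979L,
                          height = 667868L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(track, bed)
  expect_equal(readLines(bed)[2],
               "chr9\t94175957\t94175979\tpeak1\t667868")
  expect_equal(read_bed(bed), track, ignore_attr = TRUE)

  wig <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(track, wig)
  lines <- readLines(wig)
  expect_match(lines[2], "variableStep chrom=chr9 span=22")
  expect_equal(lines[3], "94175958 667868") # 1-based start

  empty <- withr::local_tempfile(fileext = ".bed")
  write_bed(track[0, ], empty)
  expect_length(readLines(empty), 1L) # header only
  expect_equal(nrow(read_bed(empty)), 0L)
})
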