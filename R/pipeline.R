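#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with the package
#' defaults: 3 mapping mismatches, an 18-35 nt length window applied to
#' intracellular samples only, tier boundaries 32 and 10,000, and top-list
#' depths of 100 (intracellular) / 50 (extracellular).
#'
#' @param samples Data frame with columns `id`, `path`, `compartment`
#'   (`"intracellular"` or `"extracellular"`); `path` may be `NA` when
#'   `counts_tsv` supplies a precomputed count table.
#' @param counts_tsv Optional wide count-table TSV replacing read ingestion.
#' @param reference_fasta,loci_bed Optional mature-miRNA reference inputs.
#' @param adapter Optional 3' adapter to trim.
#' @param min_overlap Minimum adapter overlap (default 6).
#' @param max_mismatches Mapping mismatch bound (default 3).
#' @param length_window Length filter in nt (default `c(18, 35)`), applied
#'   to intracellular samples only.
#' @param tier_boundaries Low/Mid and Mid/High boundaries
#'   (default `c(32, 10000)`).
#' @param sweep_t_min,sweep_t_max Threshold sweep range (defaults 1 and the
#'   data-driven 99th percentile).
#' @param top_n Named depths for top-list comparisons
#'   (default `c(intracellular = 100, extracellular = 50)`).
#' @param network_a,network_b Optional edge-list TSV paths.
#' @param expression_tsv,expression_groups_tsv,housekeeping Optional
#'   expression matrix inputs.
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(samples,
                            counts_tsv = NULL,
                            reference_fasta = NULL, loci_bed = NULL,
                            adapter = NULL, min_overlap = 6L,
                            max_mismatches = 3L,
                            length_window = c(18L, 35L),
                            tier_boundaries = c(32L, 10000L),
                            sweep_t_min = 1L, sweep_t_max = NULL,
                            top_n = c(intracellular = 100L,
                                      extracellular = 50L),
                            network_a = NULL, network_b = NULL,
                            expression_tsv = NULL,
                            expression_groups_tsv = NULL,
                            housekeeping = "GAPDH",
                            seed = 1L) {
  samples <- as_tibble(samples)
  need <- c("id", "compartment")
  if (!all(need %in% names(samples))) {
    abort("`samples` needs columns id and compartment (and usually path)")
  }
  if (!"path" %in% names(samples)) samples$path <- NA_character_
  if (anyDuplicated(samples$id)) abort("sample ids must be unique")
  if (!all(samples$compartment %in% c("intracellular", "extracellular"))) {
    abort("compartment must be 'intracellular' or 'extracellular'")
  }
  if (is.null(counts_tsv) && any(is.na(samples$path))) {
    abort("either per-sample read paths or `counts_tsv` must be given")
  }
  structure(
    list(samples = samples, counts_tsv = counts_tsv,
         reference_fasta = reference_fasta, loci_bed = loci_bed,
         adapter = adapter, min_overlap = as.integer(min_overlap),
         max_mismatches = as.integer(max_mismatches),
         length_window = as.integer(length_window),
         tier_boundaries = as.integer(tier_boundaries),
         sweep_t_min = as.integer(sweep_t_min),
         sweep_t_max = if (!is.null(sweep_t_max)) as.integer(sweep_t_max),
         top_n = top_n,
         network_a = network_a, network_b = network_b,
         expression_tsv = expression_tsv,
         expression_groups_tsv = expression_groups_tsv,
         housekeeping = housekeeping,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (`samples` as a list of `id`/`path`/`compartment`
#'   records).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$samples)) {
    y$samples <- bind_rows(lapply(y$samples, as_tibble))
  }
  if (!is.null(y$top_n)) y$top_n <- unlist(y$top_n)
  do.call(pipeline_config, y)
}

#' Run the full small-RNA workflow
#'
#' Executes, in order: read ingestion (trim, length-filter, collapse) or
#' count-table loading; miRNA mapping and annotation; peak tracks (BED +
#' wiggle) when loci are available; per-sample count-distribution TSVs; the
#' replicate KS threshold sweep per compartment; tier partitions with
#' replicate Venn/kappa agreement; ranked lists with top-N comparisons; and,
#' when the inputs are supplied, network common-node sieving and
#' housekeeping-normalised expression ratios. Optional stages without inputs
#' are skipped with a notice; a `manifest.yaml` records parameters, seeds,
#' stage status and warning counts. Outputs are pure functions of (inputs,
#' config), so reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(
    package = "mirsieve",
    version = as.character(utils::packageVersion("mirsieve")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      adapter = config$adapter, min_overlap = config$min_overlap,
      max_mismatches = config$max_mismatches,
      length_window = config$length_window,
      tier_boundaries = config$tier_boundaries,
      top_n = as.list(config$top_n)
    ),
    stages = list(), warnings = 0L
  )
  note_warning <- function() manifest$warnings <<- manifest$warnings + 1L

  comp_of <- setNames(config$samples$compartment, config$samples$id)
  if (!any(table(config$samples$compartment) >= 2L)) {
    abort(paste0("the KS threshold sweep needs at least two replicates of ",
                 "one compartment; got ",
                 nrow(config$samples), " sample(s), all singletons"))
  }

  # -- ingestion ------------------------------------------------------------
  if (!is.null(config$counts_tsv)) {
    counts <- read_count_table(config$counts_tsv)
    manifest$stages$ingest <- "loaded precomputed count table"
  } else {
    tables <- purrr::pmap(config$samples, function(id, path, compartment, ...) {
      reads <- read_smallrna(path)
      if (!is.null(config$adapter)) {
        reads <- trim_adapter(reads, config$adapter, config$min_overlap)
      }
      if (compartment == "intracellular") {
        reads <- filter_length(reads, config$length_window[1],
                               config$length_window[2])
      }
      collapse_reads(reads, id)
    })
    counts <- merge_counts(tables)
    manifest$stages$ingest <- paste0("collapsed ", length(tables), " sample(s)")
  }
  say("ingested ", dplyr::n_distinct(counts$sample), " sample(s), ",
      dplyr::n_distinct(counts$sequence), " unique tags")

  # -- mapping / annotation -------------------------------------------------
  reference <- NULL
  if (!is.null(config$reference_fasta)) {
    reference <- read_mirna_reference(config$reference_fasta, config$loci_bed)
    hits <- map_tags(counts, reference, config$max_mismatches)
    counts <- annotate_counts(counts, hits)
    write_count_table(counts %>% select(-"ambiguous"),
                      file.path(out_dir, "annotated_counts.tsv"))
    manifest$stages$map <- paste0(dplyr::n_distinct(counts$sequence),
                                  " tags annotated")
    if (!is.null(reference$loci)) {
      for (s in unique(counts$sample)) {
        track <- withCallingHandlers(
          build_peak_track(counts, hits, reference, s),
          warning = function(w) { note_warning(); invokeRestart("muffleWarning") }
        )
        write_bed(track, file.path(out_dir, paste0("peaks_", s, ".bed")))
        write_wiggle(track, file.path(out_dir, paste0("peaks_", s, ".wig")))
      }
      manifest$stages$peaks <- "written"
    } else {
      manifest$stages$peaks <- "skipped: no loci"
    }
  } else {
    manifest$stages$map <- "skipped: no reference"
    say("no reference supplied; tags kept unannotated")
  }

  # -- distributions --------------------------------------------------------
  dist_tbl <- purrr::map_dfr(unique(counts$sample), function(s) {
    tidy(count_distribution(counts, s)) %>% mutate(sample = s, .before = 1)
  })
  readr::write_tsv(dist_tbl, file.path(out_dir, "count_distributions.tsv"),
                   progress = FALSE)

  # -- KS threshold sweep ---------------------------------------------------
  thresholds <- list()
  for (comp in unique(config$samples$compartment)) {
    ids <- config$samples$id[config$samples$compartment == comp]
    ids <- intersect(ids, unique(counts$sample))
    if (length(ids) < 2L) {
      manifest$stages[[paste0("sweep_", comp)]] <-
        "skipped: fewer than 2 replicates"
      next
    }
    sw <- adaptive_threshold(counts, ids[1], ids[2],
                             t_min = config$sweep_t_min,
                             t_max = config$sweep_t_max)
    readr::write_tsv(tidy(sw),
                     file.path(out_dir, paste0("ks_sweep_", comp, ".tsv")),
                     progress = FALSE)
    writeLines(paste0("selected_threshold\t", sw$selected_threshold),
               file.path(out_dir, paste0("threshold_", comp, ".tsv")))
    thresholds[[comp]] <- sw$selected_threshold
    manifest$stages[[paste0("sweep_", comp)]] <-
      paste0("selected threshold ", sw$selected_threshold)
    say("compartment ", comp, ": selected threshold ", sw$selected_threshold)
  }

  # -- tiers and agreement --------------------------------------------------
  tiers <- assign_tiers(counts, config$tier_boundaries[1],
                        config$tier_boundaries[2])
  readr::write_tsv(as_tibble(tiers)[, c("sequence", "sample", "count", "tier")],
                   file.path(out_dir, "tiers.tsv"), progress = FALSE)
  universe <- unique(counts$sequence)
  agreement <- purrr::map_dfr(unique(config$samples$compartment), function(comp) {
    ids <- intersect(config$samples$id[config$samples$compartment == comp],
                     unique(counts$sample))
    if (length(ids) < 2L) return(NULL)
    purrr::map_dfr(c("Low", "Mid", "High"), function(tr) {
      v <- tier_venn(tiers, ids[1], ids[2], tr)
      a <- tiers$sequence[tiers$sample == ids[1] & tiers$tier == tr]
      b <- tiers$sequence[tiers$sample == ids[2] & tiers$tier == tr]
      v %>% mutate(compartment = comp, .before = 1) %>%
        mutate(kappa = cohens_kappa(a, b, universe))
    })
  })
  readr::write_tsv(agreement, file.path(out_dir, "tier_agreement.tsv"),
                   progress = FALSE)
  manifest$stages$tiers <- "written"

  # -- ranking --------------------------------------------------------------
  ranked <- list()
  for (s in unique(counts$sample)) {
    mc <- thresholds[[comp_of[[s]]]] %||% config$tier_boundaries[1]
    ranked[[s]] <- rank_mirnas(counts, s, min_count = mc)
    readr::write_tsv(as_tibble(ranked[[s]]),
                     file.path(out_dir, paste0("ranked_", s, ".tsv")),
                     progress = FALSE)
  }
  topn <- purrr::map_dfr(unique(config$samples$compartment), function(comp) {
    ids <- intersect(config$samples$id[config$samples$compartment == comp],
                     names(ranked))
    if (length(ids) < 2L) return(NULL)
    n <- unname(config$top_n[comp])
    top_n_overlap(ranked[[ids[1]]], ranked[[ids[2]]],
                  n = min(n, nrow(ranked[[ids[1]]]), nrow(ranked[[ids[2]]]))) %>%
      mutate(compartment = comp, .before = 1)
  })
  readr::write_tsv(topn, file.path(out_dir, "topn_overlap.tsv"),
                   progress = FALSE)
  manifest$stages$ranking <- "written"

  # -- networks -------------------------------------------------------------
  if (!is.null(config$network_a) && !is.null(config$network_b)) {
    hubs <- common_nodes(read_edge_list(config$network_a, "network_a"),
                         read_edge_list(config$network_b, "network_b"))
    readr::write_tsv(hubs, file.path(out_dir, "common_hubs.tsv"),
                     progress = FALSE)
    manifest$stages$networks <- paste0(nrow(hubs), " common node(s)")
  } else {
    manifest$stages$networks <- "skipped: no network inputs"
    say("network inputs absent; skipping common-node sieve")
  }

  # -- expression ratios ----------------------------------------------------
  if (!is.null(config$expression_tsv) &&
      !is.null(config$expression_groups_tsv)) {
    expr <- read_expression_matrix(config$expression_tsv,
                                   config$expression_groups_tsv,
                                   config$housekeeping)
    grp <- unique(expr$group)
    ratios <- normalized_group_ratio(expr, group_num = grp[1],
                                     group_den = grp[2])
    readr::write_tsv(ratios, file.path(out_dir, "expression_ratios.tsv"),
                     progress = FALSE)
    manifest$stages$expression <- paste0(
      nrow(ratios), " gene ratios (", grp[1], "/", grp[2], "); concordance >1: ",
      round(direction_concordance(ratios, ">1"), 3))
  } else {
    manifest$stages$expression <- "skipped: no expression inputs"
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
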