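#' Read an undirected gene-interaction network from an edge-list TSV
#'
#' Consumes two-column symbol pairs as exported by target-prediction or
#' pathway tools. Symbols are uppercased and whitespace-trimmed; duplicate
#' and reversed-duplicate edges are collapsed; self-loops are dropped with a
#' warning. A header row is recognised when its first field is one of
#' `from`, `source`, `node1`, `gene1` (case-insensitive).
#'
#' @param path Edge-list TSV path.
#' @param label Free-text label for the network (e.g.
#'   `"alignment-derived"`).
#' @return An `interaction_network` tibble of edges (`from`, `to`,
#'   `from < to` lexicographically) with the label in `attr(, "label")`.
#' @export
read_edge_list <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) > 0L) {
    first_field <- tolower(trimws(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1]))
    if (first_field %in% c("from", "source", "node1", "gene1")) {
      lines <- lines[-1]
    }
  }
  if (length(lines) == 0L) {
    return(new_interaction_network(
      tibble(from = character(), to = character()), label))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L |
                 vapply(parts, function(p) any(!nzchar(trimws(p[1:2]))), TRUE))
  if (length(bad) > 0L) {
    abort(paste0("edge list parse error at row ", bad[1],
                 ": need two non-empty tab-separated symbols"))
  }
  edges <- tibble(
    from = toupper(trimws(vapply(parts, `[`, "", 1L))),
    to = toupper(trimws(vapply(parts, `[`, "", 2L)))
  )
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop(s)"))
    edges <- edges[!loops, ]
  }
  edges <- edges %>%
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) %>%
    distinct(.data$a, .data$b) %>%
    rename(from = "a", to = "b")
  new_interaction_network(edges, label)
}

new_interaction_network <- function(edges, label) {
  attr(edges, "label") <- label
  class(edges) <- c("interaction_network", class(edges))
  edges
}

#' Build an interaction network from an edge data frame
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param label Network label.
#' @export
interaction_network <- function(edges, label = "network") {
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` needs columns from and to")
  }
  edges <- as_tibble(edges) %>%
    mutate(from = toupper(trimws(.data$from)),
           to = toupper(trimws(.data$to))) %>%
    filter(.data$from != .data$to) %>%
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) %>%
    distinct(.data$a, .data$b) %>%
    rename(from = "a", to = "b")
  new_interaction_network(edges, label)
}

network_nodes <- function(net) sort(unique(c(net$from, net$to)))

network_degrees <- function(net) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0L) {
    return(setNames(integer(), character()))
  }
  g <- igraph::graph_from_data_frame(as_tibble(net)[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodes)
  deg <- igraph::degree(g)
  deg[nodes]
}

#' Sieve two interaction networks for common nodes and shared hubs
#'
#' Intersects the node sets of two networks and annotates every common node
#' with its degree in each network. Shared hubs are ordered by descending
#' `min(degree_a, degree_b)` - rewarding genes that are well connected in
#' both networks, which is the point of the sieve - with lexicographic tie
#' breaks. A gene at the head of this report is a candidate downstream
#' target supported by both network sources.
#'
#' @param net_a,net_b `interaction_network` objects (any edge tibble with
#'   `from`/`to` works).
#' @return Tibble of common nodes: `node`, `degree_a`, `degree_b`,
#'   `min_degree`, sorted as described.
#' @export
common_nodes <- function(net_a, net_b) {
  deg_a <- network_degrees(net_a)
  deg_b <- network_degrees(net_b)
  shared <- intersect(names(deg_a), names(deg_b))
  tibble(
    node = shared,
    degree_a = as.integer(deg_a[shared]),
    degree_b = as.integer(deg_b[shared])
  ) %>%
    mutate(min_degree = pmin(.data$degree_a, .data$degree_b)) %>%
    arrange(desc(.data$min_degree), .data$node)
}

#' Read a gene-by-sample expression matrix with a group map
#'
#' The matrix TSV has a `gene` column and one numeric column per sample; the
#' group TSV maps `sample` to `group`. The housekeeping gene must be present
#' with a positive value in every sample.
#'
#' @param path Expression matrix TSV.
#' @param group_path Two-column (`sample`, `group`) TSV.
#' @param housekeeping Housekeeping gene symbol (default `"GAPDH"`).
#' @return A long `expression_data` tibble: `gene`, `sample`, `group`,
#'   `value`, with the housekeeping symbol in `attr(, "housekeeping")`.
#' @export
read_expression_matrix <- function(path, group_path, housekeeping = "GAPDH") {
  mat <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(gene = readr::col_character(),
                                                 .default = readr::col_double()))
  groups <- readr::read_tsv(group_path, comment = "#", progress = FALSE,
                            col_types = "cc")
  if (!"gene" %in% names(mat)) abort("expression matrix needs a 'gene' column")
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("group map needs columns sample and group")
  }
  long <- mat %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    inner_join(groups, by = "sample") %>%
    select("gene", "sample", "group", "value")
  expression_data(long, housekeeping)
}

#' Construct expression data from a long tibble
#'
#' @param long Tibble with columns `gene`, `sample`, `group`, `value`.
#' @param housekeeping Housekeeping gene symbol.
#' @export
expression_data <- function(long, housekeeping = "GAPDH") {
  need <- c("gene", "sample", "group", "value")
  if (!all(need %in% names(long))) {
    abort("expression data needs columns gene, sample, group, value")
  }
  hk <- long %>% filter(.data$gene == housekeeping)
  missing_in <- setdiff(unique(long$sample), hk$sample)
  if (length(missing_in) > 0L || any(hk$value <= 0)) {
    abort(paste0("housekeeping gene '", housekeeping,
                 "' must be present with value > 0 in every sample"))
  }
  out <- as_tibble(long)[, need]
  attr(out, "housekeeping") <- housekeeping
  class(out) <- c("expression_data", class(out))
  out
}

#' Group-wise housekeeping-normalised expression ratios
#'
#' Within each sample, every gene's expression is divided by the
#' housekeeping gene's expression; the normalised values are averaged within
#' each of two groups and the ratio of group means (numerator over
#' denominator) is reported per gene. Gene-sample pairs absent from the
#' matrix are excluded from that gene's mean (not imputed as zero); genes
#' absent altogether are reported and skipped; genes with a zero denominator
#' mean are flagged undefined and excluded, with a warning.
#'
#' @param expr An `expression_data` tibble (see [expression_data()]).
#' @param genes Genes to report; default all genes except the housekeeping
#'   gene.
#' @param group_num,group_den Group labels for the numerator and denominator
#'   means.
#' @param housekeeping Housekeeping symbol; defaults to the attribute
#'   attached by [expression_data()].
#' @return Tibble: `gene`, `mean_num`, `mean_den`, `ratio`.
#' @export
normalized_group_ratio <- function(expr, genes = NULL, group_num, group_den,
                                   housekeeping = NULL) {
  housekeeping <- housekeeping %||% attr(expr, "housekeeping") %||% "GAPDH"
  for (g in c(group_num, group_den)) {
    if (!g %in% expr$group) abort(paste0("group '", g, "' not present"))
  }
  if (is.null(genes)) genes <- setdiff(unique(expr$gene), housekeeping)
  absent <- setdiff(genes, expr$gene)
  if (length(absent) > 0L) {
    warn(paste0(length(absent), " gene(s) absent from the matrix, skipped: ",
                paste(head(absent, 5), collapse = ", ")))
    genes <- setdiff(genes, absent)
  }
  hk <- expr %>%
    filter(.data$gene == housekeeping) %>%
    select("sample", hk_value = "value")
  norm <- expr %>%
    filter(.data$gene %in% genes,
           .data$group %in% c(group_num, group_den)) %>%
    inner_join(hk, by = "sample") %>%
    mutate(norm = .data$value / .data$hk_value)
  means <- norm %>%
    group_by(.data$gene, .data$group) %>%
    summarise(m = mean(.data$norm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "m")
  for (g in c(group_num, group_den)) {
    if (!g %in% names(means)) means[[g]] <- NA_real_
  }
  out <- means %>%
    mutate(mean_num = .data[[group_num]], mean_den = .data[[group_den]]) %>%
    select("gene", "mean_num", "mean_den")
  undef <- !is.na(out$mean_den) & out$mean_den == 0
  if (any(undef)) {
    warn(paste0(sum(undef), " gene(s) with zero denominator mean excluded: ",
                paste(head(out$gene[undef], 5), collapse = ", ")))
    out <- out[!undef, ]
  }
  out %>%
    filter(!is.na(.data$mean_num), !is.na(.data$mean_den)) %>%
    mutate(ratio = .data$mean_num / .data$mean_den) %>%
    arrange(desc(.data$ratio))
}

#' Fraction of genes whose expression ratio lies on an expected side of 1
#'
#' @param ratios Tibble from [normalized_group_ratio()] (or a numeric vector
#'   of ratios).
#' @param expected_direction `">1"` (up in the numerator group) or `"<1"`.
#' @return Fraction of concordant genes; a ratio of exactly 1 counts as
#'   discordant.
#' @export
direction_concordance <- function(ratios, expected_direction = c(">1", "<1")) {
  expected_direction <- match.arg(expected_direction)
  r <- if (is.data.frame(ratios)) ratios$ratio else ratios
  if (length(r) == 0L) abort("empty ratio set")
  if (expected_direction == ">1") mean(r > 1) else mean(r < 1)
}

#' Write a hub report or ratio table as TSV
#'
#' @param x Tibble.
#' @param path Output path.
#' @export
write_report_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
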