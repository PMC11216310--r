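# Candidate regions: strand-specific single-linkage chaining of HSPs per
# query gene, margin extension clipped to contig bounds, isoform retention,
# and the similarity summary carried forward as filter features.

#' Group HSPs into margin-extended candidate regions
#'
#' HSPs are partitioned by (gene_id, contig, strand); within a partition,
#' coordinate-sorted HSPs whose end-to-start gap is smaller than
#' `config$merge_gap` are chained into one region (overlapping HSPs always
#' merge). Each merged span is extended by `config$margin` on both sides and
#' clipped to `[0, contig length)`.
#'
#' @param hsps HSP tibble (see [parse_blast_tab()]).
#' @param config A [gs_config()].
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @return Candidate-region tibble sorted by (contig, start): `region_id`,
#'   `gene_id`, `contig`, `strand`, `start`, `end`, list-column `hsps`
#'   (member HSPs), and similarity summary columns `sim_pident`,
#'   `sim_gene_cov` (maxima over members).
#' @export
#' @examples
#' hsps <- tibble::tibble(gene_id = "g", isoform_id = "g", contig = "c1",
#'   strand = "+", start = c(10000L, 100000L), end = c(12000L, 105000L),
#'   pident = 95, aln_len = 500L, query_cov = 0.9, evalue = 0, bits = 200)
#' group_and_extend(hsps, gs_config(), c(c1 = 200000L))
group_and_extend <- function(hsps, config = gs_config(), contig_lengths) {
  unknown <- setdiff(unique(hsps$contig), names(contig_lengths))
  if (length(unknown)) {
    abort(paste("HSP references unknown contig(s):", paste(unknown, collapse = ", ")))
  }
  if (nrow(hsps) == 0L) return(empty_regions())
  chained <- hsps |>
    arrange(.data$gene_id, .data$contig, .data$strand, .data$start, .data$end) |>
    group_by(.data$gene_id, .data$contig, .data$strand) |>
    mutate(chain = cumsum(is.na(lag(cummax(.data$end))) |
                            .data$start - lag(cummax(.data$end)) >= config$merge_gap)) |>
    ungroup() |>
    mutate(.key = paste(.data$gene_id, .data$contig, .data$strand, .data$chain,
                        sep = "\r"))

  regions <- chained |>
    group_by(.data$gene_id, .data$contig, .data$strand, .data$.key) |>
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop") |>
    mutate(start = pmax(0L, .data$span_start - config$margin),
           end = pmin(unname(contig_lengths[.data$contig]),
                      .data$span_end + config$margin))
  members <- split(select(chained, -"chain", -".key"),
                   factor(chained$.key, levels = regions$.key))
  regions$hsps <- unname(map(members, as_tibble))

  regions |>
    arrange(.data$contig, .data$start, .data$gene_id, .data$strand) |>
    mutate(region_id = sprintf("region%04d", row_number()),
           sim_pident = map_dbl(.data$hsps, ~max(.x$pident)),
           sim_gene_cov = map_dbl(.data$hsps, ~max(.x$query_cov))) |>
    select("region_id", "gene_id", "contig", "strand", "start", "end",
           "hsps", "sim_pident", "sim_gene_cov")
}

empty_regions <- function() {
  tibble(region_id = character(), gene_id = character(), contig = character(),
         strand = character(), start = integer(), end = integer(),
         hsps = list(), sim_pident = double(), sim_gene_cov = double())
}

#' Retain the top query isoforms per identical alignment location
#'
#' Within each region, member HSPs sharing an exactly identical location
#' (contig, start, end, strand) are ranked by bit score (descending, ties by
#' isoform id ascending) and only the first `top_k` are kept. Adds a
#' `queries` list-column with the retained (isoform_id, bits) pairs, one row
#' per isoform (best bits).
#'
#' @param regions Candidate-region tibble from [group_and_extend()].
#' @param top_k Maximum isoforms kept per identical location.
#' @return The region tibble with filtered `hsps` and a `queries` list-column.
#' @export
retain_top_queries <- function(regions, top_k = 5L) {
  regions$hsps <- map(regions$hsps, function(h) {
    h |>
      group_by(.data$contig, .data$start, .data$end, .data$strand) |>
      arrange(desc(.data$bits), .data$isoform_id, .by_group = TRUE) |>
      slice(seq_len(top_k)) |>
      ungroup() |>
      arrange(.data$start, .data$end, desc(.data$bits), .data$isoform_id)
  })
  regions$queries <- map(regions$hsps, function(h) {
    h |>
      group_by(.data$isoform_id) |>
      summarise(bits = max(.data$bits), .groups = "drop") |>
      arrange(desc(.data$bits), .data$isoform_id)
  })
  regions
}

#' Similarity summary of a candidate region
#'
#' The per-region similarity features handed to the result filter: the best
#' percent identity and the best query coverage over member HSPs.
#'
#' @param region One row of a candidate-region tibble.
#' @return Named numeric vector `c(sim_pident =, sim_gene_cov =)`.
#' @export
region_similarity_summary <- function(region) {
  h <- region$hsps[[1]]
  if (is.null(h) || nrow(h) == 0L) abort("region has no member HSPs")
  c(sim_pident = max(h$pident), sim_gene_cov = max(h$query_cov))
}
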