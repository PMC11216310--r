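# Reduction of scored candidates to the final report: overlap deduplication,
# isoform reduction, per-gene near-tie retention, then the calibrated
# probability threshold. Rules are applied in this order and all ties break
# on identifiers, so runs are reproducible.

# Assign overlap-cluster ids to intervals on one (contig, strand): two
# candidates conflict when their CDS spans overlap by >= 1 bp; clusters are
# the transitive closure (single pass over start-sorted rows with a running
# max end).
overlap_clusters <- function(df) {
  df <- arrange(df, .data$contig, .data$strand, .data$start, .data$end)
  df |>
    group_by(.data$contig, .data$strand) |>
    mutate(cluster = cumsum(is.na(lag(cummax(.data$end))) |
                              .data$start >= lag(cummax(.data$end)))) |>
    ungroup()
}

#' Deduplicate candidates that share a genomic region
#'
#' Among candidates whose CDS spans overlap by at least 1 bp on the same
#' strand (transitively), only the highest-probability one survives; ties
#' break on (gene_id, model_id) ascending.
#'
#' @param candidates Scored candidate tibble (needs `contig`, `strand`,
#'   `start`, `end`, `probability`, `gene_id`, `model_id`).
#' @return Filtered tibble.
#' @export
dedup_by_region <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates |>
    overlap_clusters() |>
    group_by(.data$contig, .data$strand, .data$cluster) |>
    arrange(desc(.data$probability), .data$gene_id, .data$model_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"cluster") |>
    arrange(.data$contig, .data$start)
}

#' Reduce same-gene same-locus models from different isoforms
#'
#' When several models of one gene at one locus derive from different
#' validated isoforms, only the highest-probability model is reported
#' (equal probabilities: smallest model_id). Loci are same-strand overlap
#' clusters, so this is subsumed by [dedup_by_region()] when loci overlap.
#'
#' @param candidates Scored candidate tibble.
#' @return Filtered tibble.
#' @export
pick_isoform_model <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates |>
    overlap_clusters() |>
    group_by(.data$gene_id, .data$contig, .data$strand, .data$cluster) |>
    arrange(desc(.data$probability), .data$model_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"cluster") |>
    arrange(.data$contig, .data$start)
}

#' Per-gene deduplication with near-tie retention
#'
#' For each gene, keeps every candidate whose probability is strictly greater
#' than `tie_ratio` times the gene's best probability; the best candidate
#' always survives.
#'
#' @param candidates Scored candidate tibble.
#' @param tie_ratio Near-tie factor (default 0.95).
#' @return Filtered tibble.
#' @export
dedup_by_gene <- function(candidates, tie_ratio = 0.95) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates |>
    group_by(.data$gene_id) |>
    filter(.data$probability > tie_ratio * max(.data$probability) |
             .data$probability == max(.data$probability)) |>
    ungroup() |>
    arrange(.data$contig, .data$start)
}

#' Apply the calibrated probability threshold
#'
#' Keeps candidates with probability greater than or equal to the threshold,
#' sorted by (contig, start).
#'
#' @param candidates Scored candidate tibble.
#' @param threshold Calibrated decision threshold.
#' @return The final report tibble.
#' @export
apply_threshold <- function(candidates, threshold) {
  candidates |>
    filter(.data$probability >= threshold) |>
    arrange(.data$contig, .data$start)
}

#' Full selection chain
#'
#' Region-level deduplication, isoform reduction, per-gene near-tie
#' deduplication, then the probability threshold. Idempotent.
#'
#' @inheritParams dedup_by_region
#' @inheritParams dedup_by_gene
#' @inheritParams apply_threshold
#' @return The final report tibble.
#' @export
select_candidates <- function(candidates, threshold, tie_ratio = 0.95) {
  candidates |>
    dedup_by_region() |>
    pick_isoform_model() |>
    dedup_by_gene(tie_ratio = tie_ratio) |>
    apply_threshold(threshold)
}
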