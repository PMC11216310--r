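# Orthology-aware evaluation of a final report against a truth annotation.
# Negatives are defined by ortholog absence: a query gene can be truly
# absent from the searched genome, and finding nothing for it is a true
# negative. A gene is the region from its start codon through its stop codon.

span_overlaps <- function(start1, end1, start2, end2) {
  pmax(start1, start2) < pmin(end1, end2)
}

#' Confusion matrix over query genes
#'
#' TP: a present query gene with at least one reported locus overlapping
#' (>= 1 bp, same contig) its truth gene region. FN: a present query gene
#' with no such locus. TN: an absent query gene with no reported locus.
#' FP: every reported locus that does not overlap its own gene's truth
#' region (all loci of absent genes count).
#'
#' @param report Final report tibble (`gene_id`, `contig`, `start`, `end`).
#' @param truth Annotation tibble from [read_gff3_genes()].
#' @param orthologs Ortholog-presence tibble (`gene_id`, `present`).
#' @return List with counts `tp`, `fp`, `fn`, `tn` and per-gene / per-locus
#'   assignment tibbles.
#' @export
gs_confusion <- function(report, truth, orthologs) {
  genes <- unique(c(orthologs$gene_id, report$gene_id))
  missing <- setdiff(genes, orthologs$gene_id)
  if (length(missing)) {
    abort(paste("query gene(s) missing from ortholog table:",
                paste(missing, collapse = ", ")))
  }
  hit <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    tr <- truth[truth$gene_id == r$gene_id & truth$contig == r$contig, , drop = FALSE]
    nrow(tr) > 0L && any(span_overlaps(r$start, r$end, tr$start, tr$end))
  }, logical(1))
  per_gene <- orthologs |>
    mutate(reported = .data$gene_id %in% report$gene_id,
           found_at_locus = .data$gene_id %in% report$gene_id[hit],
           cell = dplyr::case_when(
             .data$present & .data$found_at_locus ~ "TP",
             .data$present & !.data$found_at_locus ~ "FN",
             !.data$present & !.data$reported ~ "TN",
             TRUE ~ "FP_gene"))
  list(tp = sum(per_gene$cell == "TP"),
       fp = sum(!hit),
       fn = sum(per_gene$cell == "FN"),
       tn = sum(per_gene$cell == "TN"),
       per_gene = per_gene,
       per_locus = mutate(report, overlaps_truth = hit))
}

#' Confusion-derived rates
#'
#' Sensitivity, specificity, positive and negative predictive value. A zero
#' denominator yields `NA` (undefined), never a silent `0/0`.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return One-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' gs_metrics(9, 1, 1, 9)
gs_metrics <- function(tp, fp, fn, tn) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp),
         npv = rate(tn, tn + fn))
}

#' Coverage of a truth gene by a predicted model
#'
#' Gene coverage: overlap of the predicted gene span with the truth gene
#' region, divided by the truth region length. Exon coverage: truth CDS
#' bases covered by predicted CDS intervals, divided by total truth CDS
#' bases.
#'
#' @param pred One row of a report tibble (with `cds` list-column).
#' @param truth_gene One row of a truth annotation tibble.
#' @return Named numeric vector `c(gene_cov =, exon_cov =)`.
#' @export
gs_coverage <- function(pred, truth_gene) {
  glen <- truth_gene$end - truth_gene$start
  if (glen <= 0L) abort("zero-length truth gene region")
  ov <- max(0L, min(pred$end, truth_gene$end) - max(pred$start, truth_gene$start))
  tcds <- truth_gene$cds[[1]]
  exon_cov <- NA_real_
  if (nrow(tcds) > 0L) {
    t_ir <- IRanges::reduce(IRanges::IRanges(tcds$start + 1L, tcds$end))
    pcds <- pred$cds[[1]]
    p_ir <- IRanges::reduce(IRanges::IRanges(pcds$start + 1L, pcds$end))
    exon_cov <- sum(IRanges::width(IRanges::intersect(t_ir, p_ir))) /
      sum(IRanges::width(t_ir))
  }
  c(gene_cov = ov / glen, exon_cov = exon_cov)
}

#' Categorize a reported locus against the annotation
#'
#' Five-way categorisation with fixed precedence: `correct` (overlaps its own
#' query gene's region) > `paralog` (overlaps an annotated paralog of the
#' query gene) > `other_gene` (overlaps any other non-pseudogene annotation)
#' > `pseudogene` > `intergenic`. Overlap is >= 1 bp, strand-agnostic.
#'
#' @param pred One row of a report tibble.
#' @param truth Annotation tibble.
#' @param paralogs Paralog map tibble (`gene_id`, `paralog_id`) or `NULL`.
#' @return Category string.
#' @export
gs_categorize <- function(pred, truth, paralogs = NULL) {
  on_contig <- truth[truth$contig == pred$contig, , drop = FALSE]
  ov <- on_contig[span_overlaps(pred$start, pred$end, on_contig$start,
                                on_contig$end), , drop = FALSE]
  if (any(ov$gene_id == pred$gene_id)) return("correct")
  pids <- if (is.null(paralogs)) character() else
    paralogs$paralog_id[paralogs$gene_id == pred$gene_id]
  if (any(ov$gene_id %in% pids)) return("paralog")
  if (any(ov$biotype != "pseudogene")) return("other_gene")
  if (any(ov$biotype == "pseudogene")) return("pseudogene")
  "intergenic"
}

#' Evaluate a final report against a truth annotation
#'
#' Computes the orthology-aware confusion matrix and rates, per-true-positive
#' gene and exon coverage, and the five-way categorisation of every reported
#' locus. `mode = "presence"` scores presence/absence only (a gene found
#' anywhere counts as TP), the evaluation used for fragmented assemblies
#' where locations are not comparable.
#'
#' @param report Final report tibble.
#' @param truth Annotation tibble from [read_gff3_genes()].
#' @param orthologs Ortholog-presence tibble.
#' @param paralogs Optional paralog map tibble.
#' @param mode `"overlap"` (default) or `"presence"`.
#' @return A `gs_eval` object: counts, `metrics` tibble, `coverage` tibble
#'   (one row per true-positive locus), `categories` tibble, mode.
#' @export
gs_evaluate <- function(report, truth, orthologs, paralogs = NULL,
                        mode = c("overlap", "presence")) {
  mode <- match.arg(mode)
  conf <- gs_confusion(report, truth, orthologs)
  if (mode == "presence") {
    per_gene <- orthologs |>
      mutate(reported = .data$gene_id %in% report$gene_id,
             cell = dplyr::case_when(
               .data$present & .data$reported ~ "TP",
               .data$present & !.data$reported ~ "FN",
               !.data$present & !.data$reported ~ "TN",
               TRUE ~ "FP"))
    counts <- list(tp = sum(per_gene$cell == "TP"),
                   fp = sum(per_gene$cell == "FP"),
                   fn = sum(per_gene$cell == "FN"),
                   tn = sum(per_gene$cell == "TN"))
  } else {
    counts <- conf[c("tp", "fp", "fn", "tn")]
  }
  cov <- list()
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    tr <- truth[truth$gene_id == r$gene_id & truth$contig == r$contig, , drop = FALSE]
    tr <- tr[span_overlaps(r$start, r$end, tr$start, tr$end), , drop = FALSE]
    if (nrow(tr) == 0L) next
    cc <- gs_coverage(r, tr[1, ])
    cov[[length(cov) + 1L]] <- tibble(gene_id = r$gene_id,
                                      gene_cov = cc[["gene_cov"]],
                                      exon_cov = cc[["exon_cov"]])
  }
  cats <- if (nrow(report)) {
    tibble(gene_id = report$gene_id,
           category = vapply(seq_len(nrow(report)), function(i) {
             gs_categorize(report[i, ], truth, paralogs)
           }, character(1)))
  } else {
    tibble(gene_id = character(), category = character())
  }
  structure(list(
    counts = counts,
    metrics = gs_metrics(counts$tp, counts$fp, counts$fn, counts$tn),
    coverage = if (length(cov)) bind_rows(cov) else
      tibble(gene_id = character(), gene_cov = double(), exon_cov = double()),
    categories = cats,
    category_counts = table(factor(cats$category,
                                   levels = c("correct", "paralog", "other_gene",
                                              "pseudogene", "intergenic"))),
    per_gene = conf$per_gene,
    mode = mode
  ), class = "gs_eval")
}

#' @export
print.gs_eval <- function(x, ...) {
  cat("<gs_eval> mode:", x$mode, "\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  m <- x$metrics
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  if (nrow(x$coverage)) {
    cat(sprintf("  mean gene coverage %.3f  mean exon coverage %.3f (%d TP loci)\n",
                mean(x$coverage$gene_cov), mean(x$coverage$exon_cov, na.rm = TRUE),
                nrow(x$coverage)))
  }
  invisible(x)
}

#' @describeIn gs_evaluate Long tibble of evaluation statistics.
#' @param x A `gs_eval`.
#' @param ... Unused.
#' @export
tidy.gs_eval <- function(x, ...) {
  tibble(statistic = c("tp", "fp", "fn", "tn", "sensitivity", "specificity",
                       "ppv", "npv"),
         value = c(x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn,
                   x$metrics$sensitivity, x$metrics$specificity,
                   x$metrics$ppv, x$metrics$npv))
}

#' @describeIn gs_evaluate One-row summary with counts, rates, and mean
#'   coverages.
#' @export
glance.gs_eval <- function(x, ...) {
  tibble(tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn, tn = x$counts$tn,
         sensitivity = x$metrics$sensitivity, specificity = x$metrics$specificity,
         ppv = x$metrics$ppv, npv = x$metrics$npv,
         mean_gene_cov = if (nrow(x$coverage)) mean(x$coverage$gene_cov) else NA_real_,
         mean_exon_cov = if (nrow(x$coverage)) mean(x$coverage$exon_cov, na.rm = TRUE) else NA_real_,
         mode = x$mode)
}

#' @describeIn gs_evaluate Bar chart of the five-way locus categorisation.
#' @param object A `gs_eval`.
#' @export
autoplot.gs_eval <- function(object, ...) {
  df <- as_tibble(object$category_counts)
  names(df) <- c("category", "n")
  df$category <- factor(df$category, levels = c("correct", "paralog",
                                                "other_gene", "pseudogene",
                                                "intergenic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reported loci",
                  title = "Reported locus categorisation") +
    ggplot2::theme_minimal()
}
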