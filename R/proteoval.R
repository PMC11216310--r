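# Validation of predicted proteins: best ungapped alignment of each query
# isoform against the predicted protein, over all relative offsets. The
# alignment at an offset is the full overlap window (no internal gaps), so
# statistics are defined on contiguous columns. X and stop codons score 0
# and are never counted as similar.

gs_valmat <- function() {
  if (is.null(gs_env$valmat)) {
    m <- gs_blosum62()
    m["X", ] <- 0; m[, "X"] <- 0
    m["*", ] <- 0; m[, "*"] <- 0
    gs_env$valmat <- m
  }
  gs_env$valmat
}

#' Ungapped validation alignment
#'
#' Slides the query across the predicted protein over every relative offset,
#' scores each full overlap window under BLOSUM62 (X and `*` score 0), and
#' reports statistics at the best-scoring offset (ties: smallest offset).
#'
#' @param query Query amino-acid string.
#' @param predicted Predicted amino-acid string.
#' @return A one-row tibble: `aln_pident` (percent identical columns),
#'   `aln_psim` (percent columns with positive substitution score),
#'   `aln_gene_cov` (overlap length / query length), `score` (raw BLOSUM62
#'   sum), `offset` (position of query start relative to predicted start).
#' @export
#' @examples
#' align_validate("MKLV", "AAAAMKLVAAAA")
align_validate <- function(query, predicted) {
  if (!nzchar(predicted %||% "")) abort("nothing to validate: empty predicted protein")
  if (!nzchar(query %||% "")) abort("empty query protein")
  mat <- gs_valmat()
  q <- aa_encode(query, mat)
  p <- aa_encode(predicted, mat)
  lq <- length(q); lp <- length(p)
  best <- NULL
  for (off in (-(lq - 1L)):(lp - 1L)) {
    qs <- max(1L, 1L - off)          # first query position in the window
    qe <- min(lq, lp - off)
    if (qe < qs) next
    qi <- q[qs:qe]
    pi <- p[(qs + off):(qe + off)]
    sc <- sum(mat[cbind(qi, pi)])
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, offset = off, qi = qi, pi = pi)
    }
  }
  wlen <- length(best$qi)
  ident <- best$qi == best$pi
  tibble(
    aln_pident = 100 * sum(ident) / wlen,
    # identical columns count as similar even when the residue (X, *) scores 0,
    # so psim >= pident always holds
    aln_psim = 100 * sum(gs_valmat()[cbind(best$qi, best$pi)] > 0 | ident) / wlen,
    aln_gene_cov = wlen / lq,
    score = best$score,
    offset = best$offset
  )
}

#' Best query isoform for a predicted protein
#'
#' Validates the predicted protein against every retained isoform of the
#' region's gene and returns the one with the highest raw alignment score
#' (ties broken by isoform id, ascending).
#'
#' @param predicted Predicted amino-acid string.
#' @param queries_of_gene Tibble with `isoform_id`, `seq` (>= 1 row).
#' @return One-row tibble: `isoform_id` plus the [align_validate()] columns.
#' @export
best_query_for_model <- function(predicted, queries_of_gene) {
  stopifnot(nrow(queries_of_gene) >= 1L)
  stats <- map(queries_of_gene$seq, align_validate, predicted = predicted)
  stats <- bind_rows(stats)
  stats$isoform_id <- queries_of_gene$isoform_id
  stats <- arrange(stats, desc(.data$score), .data$isoform_id)
  relocate(stats[1, ], "isoform_id")
}
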