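mk_truth <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r$id, contig = r$contig %||% "c1",
                   strand = r$strand %||% "+", start = r$start, end = r$end,
                   biotype = r$biotype %||% "protein_coding",
                   cds = list(r$cds %||% tibble::tibble(start = r$start,
                                                        end = r$end)))
  }))
}

mk_report <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r$id, model_id = r$model %||% paste0(r$id, ".m"),
                   contig = r$contig %||% "c1", strand = r$strand %||% "+",
                   start = r$start, end = r$end, probability = r$prob %||% 0.9,
                   cds = list(r$cds %||% tibble::tibble(start = r$start,
                                                        end = r$end)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

orth3 <- tibble::tibble(gene_id = c("A", "B", "C"),
                        present = c(TRUE, TRUE, FALSE))
truth3 <- mk_truth(list(id = "A", start = 1000L, end = 2000L),
                   list(id = "B", start = 5000L, end = 6000L))

test_that("confusion cells follow the orthology-aware definitions", {
  # A found at its locus; B and C not reported
  conf <- gs_confusion(mk_report(list(id = "A", start = 1100L, end = 1900L)),
                       truth3, orth3)
  expect_equal(unlist(conf[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 1L, tn = 1L))

  # A reported at a non-overlapping locus: FP and FN simultaneously
  conf2 <- gs_confusion(mk_report(list(id = "A", start = 8000L, end = 8500L)),
                        truth3, orth3)
  expect_equal(unlist(conf2[c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 1L, fn = 2L, tn = 1L))

  # absent gene C claimed: FP, and C no longer a TN
  conf3 <- gs_confusion(mk_report(list(id = "C", start = 3000L, end = 3400L)),
                        truth3, orth3)
  expect_equal(conf3$fp, 1L)
  expect_equal(conf3$tn, 0L)

  expect_error(gs_confusion(mk_report(list(id = "Z", start = 1L, end = 10L)),
                            truth3, orth3), "missing from ortholog")
})

test_that("rates handle zero denominators as undefined", {
  expect_equal(as.numeric(gs_metrics(9, 1, 1, 9)), rep(0.9, 4))
  m <- gs_metrics(0, 0, 5, 5)
  expect_equal(m$sensitivity, 0)
  expect_true(is.na(m$ppv))
  expect_equal(m$npv, 0.5)
  expect_equal(as.numeric(gs_metrics(1, 0, 1, 1)), c(0.5, 1.0, 1.0, 0.5))
})

test_that("gene and exon coverage are proportions of the truth structures", {
  truth_g <- mk_truth(list(id = "A", start = 100L, end = 200L))[1, ]
  pred <- mk_report(list(id = "A", start = 150L, end = 250L))[1, ]
  expect_equal(unname(gs_coverage(pred, truth_g)["gene_cov"]), 0.5)

  truth_cds <- mk_truth(list(id = "A", start = 100L, end = 200L,
                             cds = tibble::tibble(start = c(100L, 180L),
                                                  end = c(160L, 200L))))[1, ]
  pred_cds <- mk_report(list(id = "A", start = 100L, end = 160L,
                             cds = tibble::tibble(start = 100L, end = 160L)))[1, ]
  cc <- gs_coverage(pred_cds, truth_cds)
  expect_equal(unname(cc["exon_cov"]), 0.75)   # 60 of 80 CDS bases

  same <- gs_coverage(mk_report(list(id = "A", start = 100L, end = 200L,
                                     cds = tibble::tibble(start = c(100L, 180L),
                                                          end = c(160L, 200L))))[1, ],
                      truth_cds)
  expect_equal(unname(same), c(1, 1))

  zero <- mk_truth(list(id = "A", start = 100L, end = 100L))[1, ]
  expect_error(gs_coverage(pred, zero), "zero-length")
})

test_that("coverage matches a per-base brute-force counter", {
  set.seed(55)
  for (rep in 1:25) {
    n_t <- sample(1:6, 1)
    bounds <- sort(sample.int(2000, 2 * n_t))
    tcds <- tibble::tibble(start = bounds[seq(1, 2 * n_t, 2)],
                           end = bounds[seq(2, 2 * n_t, 2)])
    n_p <- sample(1:6, 1)
    pb <- sort(sample.int(2000, 2 * n_p))
    pcds <- tibble::tibble(start = pb[seq(1, 2 * n_p, 2)],
                           end = pb[seq(2, 2 * n_p, 2)])
    truth_g <- tibble::tibble(gene_id = "A", contig = "c1", strand = "+",
                              start = min(tcds$start), end = max(tcds$end),
                              biotype = "protein_coding", cds = list(tcds))
    pred <- tibble::tibble(gene_id = "A", contig = "c1", strand = "+",
                           start = min(pcds$start), end = max(pcds$end),
                           probability = 1, cds = list(pcds))
    got <- gs_coverage(pred[1, ], truth_g[1, ])
    # brute force over individual bases
    tbase <- unique(unlist(Map(seq, tcds$start, tcds$end - 1L)))
    pbase <- unique(unlist(Map(seq, pcds$start, pcds$end - 1L)))
    gspan <- seq(truth_g$start, truth_g$end - 1L)
    pspan <- seq(pred$start, pred$end - 1L)
    expect_equal(unname(got["gene_cov"]), length(intersect(gspan, pspan)) / length(gspan))
    expect_equal(unname(got["exon_cov"]), length(intersect(tbase, pbase)) / length(tbase))
  }
})

test_that("locus categorisation follows the fixed precedence", {
  ann <- mk_truth(list(id = "A", start = 1000L, end = 2000L),
                  list(id = "P1", start = 4000L, end = 5000L),
                  list(id = "other", start = 7000L, end = 8000L),
                  list(id = "ps", start = 9000L, end = 9500L,
                       biotype = "pseudogene",
                       cds = tibble::tibble(start = integer(), end = integer())))
  par_map <- tibble::tibble(gene_id = "A", paralog_id = "P1")
  at <- function(s, e) mk_report(list(id = "A", start = s, end = e))[1, ]
  expect_equal(gs_categorize(at(1500L, 2500L), ann, par_map), "correct")
  expect_equal(gs_categorize(at(4100L, 4300L), ann, par_map), "paralog")
  expect_equal(gs_categorize(at(7100L, 7300L), ann, par_map), "other_gene")
  expect_equal(gs_categorize(at(9100L, 9200L), ann, par_map), "pseudogene")
  expect_equal(gs_categorize(at(20000L, 20300L), ann, par_map), "intergenic")
  # adding a lower-precedence overlap never changes the category
  expect_equal(gs_categorize(at(1500L, 9200L), ann, par_map), "correct")
})

test_that("presence mode credits relocated genes that overlap mode penalises", {
  moved <- mk_report(list(id = "A", start = 8000L, end = 8500L))
  ov <- gs_evaluate(moved, truth3, orth3, mode = "overlap")
  expect_equal(ov$counts$tp, 0L)
  expect_equal(ov$counts$fp, 1L)
  pr <- gs_evaluate(moved, truth3, orth3, mode = "presence")
  expect_equal(pr$counts$tp, 1L)
  expect_equal(pr$counts$fp, 0L)

  # identical report and truth: perfect scores, all correct
  perfect <- mk_report(list(id = "A", start = 1000L, end = 2000L),
                       list(id = "B", start = 5000L, end = 6000L))
  ev <- gs_evaluate(perfect, truth3, orth3)
  expect_equal(ev$metrics$sensitivity, 1.0)
  expect_equal(unname(ev$category_counts["correct"]), 2L)
  expect_equal(ev$coverage$gene_cov, c(1, 1))
  expect_equal(glance(ev)$mean_exon_cov, 1)
  expect_equal(nrow(tidy(ev)), 8L)
})
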