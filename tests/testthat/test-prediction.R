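mk_region <- function(start, end, contig = "c1", gene = "g", strand = "+",
                      queries = NULL) {
  tibble::tibble(region_id = "regionT", gene_id = gene, contig = contig,
                 strand = strand, start = start, end = end,
                 hsps = list(tibble::tibble()),
                 queries = list(if (is.null(queries))
                   tibble::tibble(isoform_id = "i1", bits = 100) else queries),
                 sim_pident = 90, sim_gene_cov = 1)
}

test_that("hints reproduce matched blocks, including opposite-strand matches", {
  set.seed(7)
  prot <- paste(c("M", sample(genescout:::GS_AA20, 99, TRUE)), collapse = "")
  orf <- genescout:::encode_protein(prot)
  pad <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  rseq <- paste0(pad(500), orf, pad(500))
  region <- mk_region(0L, nchar(rseq))
  qs <- tibble::tibble(gene_id = "g", isoform_id = "i1", seq = prot)
  h <- build_hints(region, rseq, qs)
  expect_gte(nrow(h), 1L)
  best <- h[which.max(h$score), ]
  expect_equal(best$kind, "CDSpart")
  expect_equal(best$strand, "+")
  expect_equal(c(best$start, best$end), c(500L, 800L))

  h_rc <- build_hints(region, revcomp(rseq), qs)
  expect_equal(h_rc$strand[which.max(h_rc$score)], "-")

  none <- build_hints(region, pad(600), qs)
  expect_equal(nrow(none), 0L)
})

test_that("builtin predictor finds complete ORFs and scores hint support", {
  set.seed(9)
  prot <- paste(c("M", sample(genescout:::GS_AA20, 99, TRUE)), collapse = "")
  orf <- genescout:::encode_protein(prot)
  pad <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  # in-frame stops right before the ORF pin the predicted start to its ATG
  rseq <- paste0(pad(492), "TAATAATAA", orf, pad(501))
  region <- mk_region(10000L, 10000L + nchar(rseq))

  full_hint <- tibble::tibble(start = 501L, end = 501L + 303L, strand = "+",
                              kind = "CDSpart", src = "P", score = 100, grp = "i1")
  m <- predict_genes(region, rseq, full_hint)
  mine <- m[m$protein == prot, ]
  expect_equal(nrow(mine), 1L)
  expect_equal(mine$hint_support, 100)
  expect_equal(mine$start, 10501L)
  expect_equal(mine$end, 10501L + 303L)
  expect_true(all(m$has_start & m$has_stop))

  # partial hints: 150 of 303 CDS bases
  part <- dplyr::mutate(full_hint, end = start + 150L)
  m2 <- predict_genes(region, rseq, part)
  expect_equal(m2$hint_support[m2$protein == prot], 100 * 150 / 303)

  # hint fragmentation leaves the metric unchanged
  frag <- dplyr::bind_rows(dplyr::mutate(part, end = start + 70L),
                           dplyr::mutate(part, start = start + 70L))
  m3 <- predict_genes(region, rseq, frag)
  expect_equal(m3$hint_support[m3$protein == prot], 100 * 150 / 303)
})

test_that("regions without a qualifying ORF yield no models", {
  # independent oracle: a sequence of pure stop codons in every frame offset
  # cannot contain an ATG..stop ORF
  rseq <- strrep("TAATAGTGA", 100)
  region <- mk_region(0L, nchar(rseq))
  expect_equal(nrow(predict_genes(region, rseq, genescout:::empty_hints())), 0L)
  # below the minimum region length
  expect_equal(nrow(predict_genes(mk_region(0L, 100L), strrep("A", 100),
                                  genescout:::empty_hints())), 0L)
})

test_that("model proteins equal the translation of their lifted CDS", {
  fx <- fx_eval()
  qs <- qc_queries(fx$queries)
  hsps <- search_translated(qs, fx$genome)
  regions <- retain_top_queries(
    group_and_extend(hsps, gs_config(), setNames(nchar(fx$genome), names(fx$genome))), 5)
  checked <- 0L
  for (i in seq_len(min(3, nrow(regions)))) {
    region <- regions[i, ]
    rseq <- region_sequence(fx$genome, region)
    m <- predict_genes(region, rseq, genescout:::empty_hints())
    for (j in seq_len(nrow(m))) {
      p <- genescout:::translate_model_cds(fx$genome[[m$contig[j]]],
                                           m$cds[[j]], m$strand[j])
      expect_equal(p, paste0(m$protein[j], "*"))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)
})

test_that("lifting maps local to genomic coordinates on both strands", {
  region <- mk_region(1000L, 5000L)
  plus <- tibble::tibble(start = 100L, end = 400L, strand = "+", protein = "M")
  expect_equal(lift_to_genome(plus, region)$start, 1100L)
  expect_equal(lift_to_genome(plus, region)$end, 1400L)

  # coordinates measured on the reverse complement of a 4000 bp region
  rc <- lift_to_genome(plus, region, from_revcomp = TRUE)
  expect_equal(rc$start, 1000L + 4000L - 400L)
  expect_equal(rc$end, 1000L + 4000L - 100L)
  expect_equal(rc$strand, "-")

  oob <- tibble::tibble(start = 3900L, end = 4100L, strand = "+", protein = "M")
  expect_error(lift_to_genome(oob, region), "bounds")
})

test_that("revcomp lifting round-trips through re-translation", {
  set.seed(13)
  prot <- paste(c("M", sample(genescout:::GS_AA20, 69, TRUE)), collapse = "")
  orf <- genescout:::encode_protein(prot)
  pad <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  rseq <- paste0(pad(200), revcomp(orf), pad(200))
  genome <- c(c1 = paste0(pad(1000), rseq, pad(1000)))
  region <- mk_region(1000L, 1000L + nchar(rseq))
  # the ORF lies at [200, 413) of the reverse complement of the region
  local <- tibble::tibble(start = 200L, end = 200L + nchar(orf), strand = "+",
                          protein = prot)
  lifted <- lift_to_genome(local, region, from_revcomp = TRUE)
  expect_equal(lifted$strand, "-")
  p <- genescout:::translate_model_cds(genome[["c1"]], lifted$cds[[1]], lifted$strand)
  expect_equal(p, paste0(prot, "*"))
})
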