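test_that("six-frame translation follows the standard code", {
  expect_equal(translate_dna("ATGAAATAA"), "MK*")
  fr <- translate_six_frames("ATGAAATAA")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(fr[["-1"]], "LFH")   # revcomp TTATTTCAT
  expect_true(all(translate_six_frames("AT") == ""))
  expect_equal(translate_dna("ATNAAA"), "XK")
  expect_error(translate_dna("ATR"), "outside")
})

test_that("an exact ORF match seeds and extends to full coverage", {
  set.seed(42)
  prot <- paste(c("M", sample(genescout:::GS_AA20, 99, TRUE)), collapse = "")
  orf <- genescout:::encode_protein(prot)
  pad <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  genome <- c(chr = paste0(pad(500), orf, pad(500)))
  q <- tibble::tibble(gene_id = "g", isoform_id = "i1", seq = prot)
  h <- search_translated(q, genome)
  expect_gte(nrow(h), 1L)
  top <- h[which.max(h$bits), ]
  expect_equal(top$pident, 100)
  expect_equal(top$query_cov, 1.0)
  expect_equal(top$strand, "+")
  expect_equal(top$start, 500L)
  expect_equal(top$end, 500L + 300L)   # 100 codons, stop codon outside the alignment

  # same ORF planted on the reverse strand
  genome_rc <- c(chr = paste0(pad(500), revcomp(orf), pad(500)))
  hr <- search_translated(q, genome_rc)
  top_r <- hr[which.max(hr$bits), ]
  expect_equal(top_r$strand, "-")
  expect_equal(top_r$pident, 100)
  expect_equal(top_r$query_cov, 1.0)
  expect_equal(top_r$start, 500L + 3L)  # stop codon at the 5' end of the minus ORF
  expect_equal(top_r$end, 500L + 303L)
})

test_that("no shared 5-mer means no HSP", {
  genome <- c(chr = strrep("ACGT", 300))
  q <- tibble::tibble(gene_id = "g", isoform_id = "i1", seq = strrep("W", 60))
  expect_equal(nrow(search_translated(q, genome)), 0L)
})

test_that("frame-to-genome mapping is invertible on reported HSPs", {
  fx <- fx_eval()
  qs <- qc_queries(fx$queries)
  h <- search_translated(qs, fx$genome)
  h <- h[h$pident > 85, ]   # near-exact hits admit direct sequence comparison
  expect_gt(nrow(h), 0L)
  for (i in seq_len(nrow(h))) {
    r <- h[i, ]
    nt <- substring(fx$genome[[r$contig]], r$start + 1L, r$end)
    if (r$strand == "-") nt <- revcomp(nt)
    aa <- translate_dna(nt)
    q <- qs$seq[qs$gene_id == r$gene_id & qs$isoform_id == r$isoform_id]
    # the re-translated interval aligns to a query substring of equal length
    expect_equal(nchar(aa), r$aln_len)
    best <- align_validate(aa, q)
    expect_gte(best$aln_pident, r$pident - 1e-9)
  }
})

test_that("contigs shorter than 3 nt are skipped with a warning", {
  q <- tibble::tibble(gene_id = "g", isoform_id = "i1", seq = strrep("MKLV", 20))
  genome <- c(ok = strrep("ACGT", 100), tiny = "AC")
  expect_warning(search_translated(q, genome), "shorter than 3 nt")
})

test_that("external backend errors name the missing tool", {
  q <- tibble::tibble(gene_id = "g", isoform_id = "i1", seq = "MKLVMKLV")
  expect_error(
    search_translated(q, c(c1 = "ACGTACGT"), backend = "external",
                      command = "no_such_aligner {queries} {genome} {out}"),
    "no_such_aligner")
})

test_that("builtin search agrees with Smith-Waterman per frame", {
  # full SW (Biostrings) of each query against each frame translation; every
  # gap-free oracle optimum above the bit floor with an exact 5-mer seed must
  # be reported with identical coordinates
  b62 <- genescout:::gs_blosum62()
  cfg <- gs_config()
  n_checked <- 0L
  for (seed in 1:6) {
    fx <- generate_fixture(sim_config(seed = seed, contig_length = 4000,
                                      n_genes = 2, gene_len_range = c(60, 90),
                                      n_paralogs = 0, n_pseudogenes = 0,
                                      n_absent = 0, min_spacing = 300))
    qs <- qc_queries(fx$queries)
    h <- search_translated(qs, fx$genome, config = cfg)
    clen <- nchar(fx$genome[[1]])
    frames <- translate_six_frames(fx$genome[[1]])
    for (qi in seq_len(nrow(qs))) {
      for (fr in names(frames)) {
        if (nchar(frames[[fr]]) < 5) next
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(qs$seq[qi]), Biostrings::AAString(frames[[fr]]),
          type = "local", substitutionMatrix = b62,
          gapOpening = 11, gapExtension = 1)
        bits <- genescout:::raw_to_bits(Biostrings::score(pa))
        if (bits < cfg$min_bits) next
        if (Biostrings::nindel(pa)@insertion[2] + Biostrings::nindel(pa)@deletion[2] > 0) next
        al_q <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
        al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
        runs <- rle(al_q == al_s)
        if (!any(runs$values) || max(runs$lengths[runs$values]) < cfg$seed_k) next
        g <- genescout:::frame_to_genome(
          fr,
          Biostrings::start(Biostrings::subject(pa)) - 1L,
          Biostrings::end(Biostrings::subject(pa)), clen)
        hit <- h[h$isoform_id == qs$isoform_id[qi] & h$gene_id == qs$gene_id[qi] &
                   h$strand == g$strand & h$start == g$start & h$end == g$end, ]
        expect_equal(nrow(hit), 1L)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 10L)
})
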