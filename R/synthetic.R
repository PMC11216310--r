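# Planted-gene genome simulator. Generates a multi-contig genome with
# complete intronless ORFs at recorded loci, query proteins that are
# controlled-divergence orthologs of the planted genes, paralog and
# frameshifted-pseudogene decoys, absent queries with no planted source, and
# the matching truth GFF3 / ortholog / paralog tables. Everything is
# deterministic given the seed. Divergence is substitution-only, so the
# ungapped validation aligner remains a faithful stage on fixtures.

#' Simulation configuration
#'
#' @param seed RNG seed (required; the whole fixture is deterministic in it).
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (bp).
#' @param n_genes Planted ortholog-target genes.
#' @param gene_len_range Protein length range (codons, excluding stop).
#' @param intronless Plant single-exon genes (the builtin predictor's world).
#'   Multi-exon planting is not implemented; the flag is validated.
#' @param divergence Fraction of residues substituted in each ortholog query.
#' @param n_isoforms Query isoforms per gene (independently mutated).
#' @param n_paralogs Planted paralog decoys (diverged copies of planted genes).
#' @param paralog_divergence Divergence of paralog copies.
#' @param n_pseudogenes Planted pseudogene decoys (frameshifted copies).
#' @param n_absent Query genes with no planted counterpart.
#' @param gc Intergenic GC fraction.
#' @param min_spacing Minimum gap (bp) between planted loci.
#' @return A list of class `gs_sim_config`.
#' @export
sim_config <- function(seed, n_contigs = 1L, contig_length = 100000L,
                       n_genes = 5L, gene_len_range = c(80L, 150L),
                       intronless = TRUE, divergence = 0.1, n_isoforms = 1L,
                       n_paralogs = 2L, paralog_divergence = 0.3,
                       n_pseudogenes = 2L, n_absent = 2L, gc = 0.4,
                       min_spacing = 5000L) {
  stopifnot(divergence >= 0, divergence < 1,
            paralog_divergence >= 0, paralog_divergence < 1,
            n_genes >= 1, isTRUE(intronless))
  structure(as.list(environment()), class = "gs_sim_config")
}

#' Substitute a fixed fraction of residues
#'
#' Exactly `round(divergence * nchar(seq))` positions are substituted, each
#' to a different residue drawn from the 20 standard amino acids (never to an
#' ambiguity code). Deterministic given `seed`.
#'
#' @param seq Amino-acid string.
#' @param divergence Fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return Mutated sequence.
#' @export
#' @examples
#' mutate_protein("MKLVNP", 0.5, seed = 1)
mutate_protein <- function(seq, divergence, seed) {
  L <- nchar(seq)
  if (L == 0L) abort("cannot mutate an empty sequence")
  stopifnot(divergence >= 0, divergence < 1)
  n <- round(divergence * L)
  if (n == 0L) return(seq)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(L, n)
  for (p in pos) {
    choices <- setdiff(GS_AA20, ch[p])
    ch[p] <- choices[sample.int(length(choices), 1L)]
  }
  paste(ch, collapse = "")
}

# aa -> codons reverse table of the standard genetic code
gs_codons_for <- function() {
  if (is.null(gs_env$codon_rev)) {
    gc <- Biostrings::GENETIC_CODE
    gs_env$codon_rev <- split(names(gc), unname(gc))
  }
  gs_env$codon_rev
}

random_protein <- function(len) {
  paste(c("M", sample(GS_AA20, len - 1L, replace = TRUE)), collapse = "")
}

# Encode a protein as DNA with uniformly random synonymous codons + stop.
encode_protein <- function(prot) {
  rev_tab <- gs_codons_for()
  ch <- strsplit(prot, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(a) {
    opts <- rev_tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stop_opts <- rev_tab[["*"]]
  paste(c(codons, stop_opts[sample.int(length(stop_opts), 1L)]), collapse = "")
}

#' Generate a planted-gene fixture
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `truth.gff3`, `queries.fa`, `orthologs.tsv`, `paralogs.tsv`.
#' @return List with `genome` (named character), `truth` (annotation tibble),
#'   `queries` (query tibble), `orthologs`, `paralogs`, `config`, and `files`
#'   (paths, if written).
#' @export
#' @examples
#' fx <- generate_fixture(sim_config(seed = 7, n_genes = 2, n_paralogs = 0,
#'                                   n_pseudogenes = 0, n_absent = 1,
#'                                   contig_length = 30000))
#' fx$truth
generate_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "gs_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # --- design the planted loci ------------------------------------------
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  gene_len <- sample(config$gene_len_range[1]:config$gene_len_range[2],
                     config$n_genes, replace = TRUE)
  proteins <- vapply(gene_len, random_protein, character(1))
  gene_nt <- vapply(proteins, encode_protein, character(1), USE.NAMES = FALSE)

  par_src <- if (config$n_paralogs > 0)
    gene_ids[rep(seq_len(config$n_genes), length.out = config$n_paralogs)]
    else character()
  par_ids <- if (config$n_paralogs > 0)
    sprintf("par%02d_%s", seq_len(config$n_paralogs), par_src) else character()
  par_nt <- vapply(seq_along(par_ids), function(i) {
    src <- match(par_src[i], gene_ids)
    mut <- mutate_protein(proteins[src], config$paralog_divergence,
                          seed = sample.int(2^31 - 1, 1))
    encode_protein(mut)
  }, character(1))

  pse_src <- if (config$n_pseudogenes > 0)
    gene_ids[rep(seq_len(config$n_genes), length.out = config$n_pseudogenes)]
    else character()
  pse_ids <- if (config$n_pseudogenes > 0)
    sprintf("pseu%02d_%s", seq_len(config$n_pseudogenes), pse_src) else character()
  pse_nt <- vapply(seq_along(pse_ids), function(i) {
    src_nt <- gene_nt[match(pse_src[i], gene_ids)]
    cut <- sample.int(nchar(src_nt) - 10L, 1L) + 5L   # internal frameshift
    paste0(substring(src_nt, 1L, cut - 1L), substring(src_nt, cut + 1L))
  }, character(1))

  loci <- tibble(
    locus_id = c(gene_ids, par_ids, pse_ids),
    kind = rep(c("gene", "paralog", "pseudogene"),
               c(length(gene_ids), length(par_ids), length(pse_ids))),
    nt = c(gene_nt, par_nt, pse_nt),
    strand = sample(c("+", "-"), length(c(gene_ids, par_ids, pse_ids)),
                    replace = TRUE))
  loci$contig <- rep_len(seq_len(config$n_contigs), nrow(loci))
  loci <- loci[sample.int(nrow(loci)), , drop = FALSE]   # shuffle order on contigs

  # --- build contigs ----------------------------------------------------
  base_prob <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
                 G = config$gc / 2, T = (1 - config$gc) / 2)
  rand_dna <- function(n) {
    if (n <= 0L) return("")
    paste(sample(names(base_prob), n, replace = TRUE, prob = base_prob),
          collapse = "")
  }
  genome <- character(config$n_contigs)
  names(genome) <- sprintf("contig%d", seq_len(config$n_contigs))
  placed <- list()
  for (ci in seq_len(config$n_contigs)) {
    mine <- loci[loci$contig == ci, , drop = FALSE]
    lens <- nchar(mine$nt)
    slack <- config$contig_length - sum(lens) -
      (nrow(mine) + 1L) * config$min_spacing
    if (slack < 0L) {
      abort("planted loci do not fit: reduce n_genes or raise contig_length")
    }
    extra <- if (nrow(mine) == 0L) slack else {
      cuts <- sort(sample.int(slack + 1L, nrow(mine), replace = TRUE) - 1L)
      diff(c(0L, cuts, slack))
    }
    gaps <- config$min_spacing + extra
    pieces <- character(0)
    pos <- 0L
    starts <- integer(nrow(mine))
    for (i in seq_len(nrow(mine))) {
      g <- rand_dna(gaps[i])
      pieces <- c(pieces, g)
      pos <- pos + nchar(g)
      starts[i] <- pos
      ins <- if (mine$strand[i] == "+") mine$nt[i] else revcomp(mine$nt[i])
      pieces <- c(pieces, ins)
      pos <- pos + nchar(ins)
    }
    pieces <- c(pieces, rand_dna(config$contig_length - pos))
    genome[ci] <- paste(pieces, collapse = "")
    if (nrow(mine)) {
      placed[[length(placed) + 1L]] <-
        mutate(mine, start = starts, end = starts + nchar(.data$nt),
               contig_name = names(genome)[ci])
    }
  }
  placed <- bind_rows(placed)

  truth <- placed |>
    mutate(gene_id = .data$locus_id,
           contig = .data$contig_name,
           biotype = ifelse(.data$kind == "pseudogene", "pseudogene",
                            "protein_coding"),
           cds = pmap(list(.data$kind, .data$start, .data$end),
                      function(k, s, e) {
                        if (k == "pseudogene") {
                          tibble(start = integer(), end = integer())
                        } else {
                          tibble(start = s, end = e)
                        }
                      })) |>
    select("gene_id", "contig", "strand", "start", "end", "biotype", "cds") |>
    arrange(.data$contig, .data$start)

  # --- queries ----------------------------------------------------------
  qrows <- list()
  for (i in seq_len(config$n_genes)) {
    for (j in seq_len(config$n_isoforms)) {
      qrows[[length(qrows) + 1L]] <- tibble(
        gene_id = gene_ids[i], isoform_id = sprintf("i%d", j),
        seq = mutate_protein(proteins[i], config$divergence,
                             seed = sample.int(2^31 - 1, 1)))
    }
  }
  absent_ids <- if (config$n_absent > 0)
    sprintf("absent%02d", seq_len(config$n_absent)) else character()
  for (id in absent_ids) {
    len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1L)
    qrows[[length(qrows) + 1L]] <- tibble(gene_id = id, isoform_id = "i1",
                                          seq = random_protein(len))
  }
  queries <- bind_rows(qrows)

  orthologs <- tibble(gene_id = c(gene_ids, absent_ids),
                      present = c(rep(TRUE, length(gene_ids)),
                                  rep(FALSE, length(absent_ids))))
  paralogs <- tibble(gene_id = par_src, paralog_id = par_ids)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(genome = file.path(dir, "genome.fa"),
                  truth = file.path(dir, "truth.gff3"),
                  queries = file.path(dir, "queries.fa"),
                  orthologs = file.path(dir, "orthologs.tsv"),
                  paralogs = file.path(dir, "paralogs.tsv"))
    write_genome(genome, files$genome)
    write_gff3_annotation(truth, files$truth, source = "gs_sim")
    write_queries(queries, files$queries)
    write_ortholog_table(orthologs, files$orthologs)
    write_paralog_table(paralogs, files$paralogs)
  }
  list(genome = genome, truth = truth, queries = queries,
       orthologs = orthologs, paralogs = paralogs, config = config,
       files = files)
}

#' Label candidates against the truth annotation
#'
#' Label 1 when the candidate's CDS span overlaps its own query gene's true
#' locus by at least 1 bp (same contig); 0 otherwise — in particular for
#' candidates of absent queries and for decoy loci.
#'
#' @param candidates Candidate tibble (`gene_id`, `contig`, `start`, `end`).
#' @param truth Annotation tibble.
#' @return `candidates` with an integer `label` column.
#' @export
label_candidates <- function(candidates, truth) {
  lab <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    tr <- truth[truth$gene_id == cand$gene_id &
                  truth$contig == cand$contig, , drop = FALSE]
    as.integer(nrow(tr) > 0L &&
                 any(span_overlaps(cand$start, cand$end, tr$start, tr$end)))
  }, integer(1))
  mutate(candidates, label = lab)
}
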