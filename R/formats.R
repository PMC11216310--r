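# File-format frontier of the pipeline. Internally every interval is 0-based
# half-open on the forward strand; GFF3 is converted to/from 1-based inclusive
# at this boundary and nowhere else.

#' Read query proteins from FASTA
#'
#' Headers encode the gene and isoform as `gene_id|isoform_id` in the first
#' whitespace-delimited token. A header without `|` yields
#' `isoform_id == gene_id`.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A tibble with columns `gene_id`, `isoform_id`, `seq`.
#' @export
read_queries <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  gene <- sub("\\|.*$", "", ids)
  iso <- ifelse(grepl("|", ids, fixed = TRUE), sub("^[^|]*\\|", "", ids), gene)
  tibble(gene_id = gene, isoform_id = iso,
         seq = toupper(as.character(ss, use.names = FALSE)))
}

#' Write query proteins to FASTA
#'
#' @param queries Tibble with `gene_id`, `isoform_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  lines <- as.vector(rbind(paste0(">", queries$gene_id, "|", queries$isoform_id),
                           queries$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Quality-control a query set
#'
#' Removes sequences containing ambiguous amino acids (B, J, O, U, Z) and
#' collapses exact duplicate sequences to their first occurrence. `X` is
#' retained. Input order is preserved.
#'
#' @param queries Tibble with `gene_id`, `isoform_id`, `seq`.
#' @return Filtered tibble; errors if nothing survives QC.
#' @export
#' @examples
#' qc_queries(tibble::tibble(gene_id = "g1", isoform_id = "i1", seq = "MKLV"))
qc_queries <- function(queries) {
  stopifnot(all(c("gene_id", "isoform_id", "seq") %in% names(queries)))
  if (anyDuplicated(paste(queries$gene_id, queries$isoform_id))) {
    abort("duplicated (gene_id, isoform_id) in query set")
  }
  keep <- !grepl("[BJOUZ]", queries$seq) & nchar(queries$seq) > 0L
  out <- queries[keep, , drop = FALSE]
  out <- out[!duplicated(out$seq), , drop = FALSE]
  if (nrow(out) == 0L) abort("no usable queries after quality control")
  as_tibble(out)
}

#' Read a genome assembly from FASTA
#'
#' @param path Nucleotide FASTA.
#' @return Named character vector of uppercase contig sequences; names are the
#'   first header tokens.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss, use.names = FALSE))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @param width Line-wrap width. Default 70.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(genome)) {
    writeLines(paste0(">", names(genome)[i]), con)
    s <- genome[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse BLAST tabular (12-column) HSP lines
#'
#' Accepts the standard `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore` dialect. Subject coordinates are 1-based
#' inclusive; `sstart > send` encodes the minus strand. Query ids are split on
#' the first `|` into gene and isoform.
#'
#' @param lines Character vector of data lines (no header).
#' @param query_lengths Optional named vector (`gene|isoform` -> length in aa)
#'   used to compute `query_cov`; otherwise `query_cov` is `NA`.
#' @return An HSP tibble: `gene_id`, `isoform_id`, `contig`, `strand`,
#'   `start`, `end` (0-based half-open, forward strand), `pident`, `aln_len`,
#'   `query_cov`, `evalue`, `bits`.
#' @export
parse_blast_tab <- function(lines, query_lengths = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hsps())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    abort(paste0("malformed BLAST tabular line ", which(nf != 12L)[1],
                 ": expected 12 columns, got ", nf[nf != 12L][1]))
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, c(3:10, 11:12), drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  bad <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    abort(paste0("malformed BLAST tabular line ", bad[1], ": non-numeric field"))
  }
  qid <- m[, 1]
  gene <- sub("\\|.*$", "", qid)
  iso <- ifelse(grepl("|", qid, fixed = TRUE), sub("^[^|]*\\|", "", qid), gene)
  sstart <- num[, 7]; send <- num[, 8]
  strand <- ifelse(sstart < send, "+", "-")
  start0 <- as.integer(pmin(sstart, send) - 1)
  end0 <- as.integer(pmax(sstart, send))
  aln_len <- as.integer(num[, 2])
  qcov <- rep(NA_real_, length(qid))
  if (!is.null(query_lengths)) {
    qcov <- pmin(1, aln_len / unname(query_lengths[qid]))
  }
  tibble(gene_id = gene, isoform_id = iso, contig = m[, 2], strand = strand,
         start = start0, end = end0, pident = num[, 1], aln_len = aln_len,
         query_cov = qcov, evalue = num[, 9], bits = num[, 10])
}

#' @rdname parse_blast_tab
#' @param path File containing BLAST tabular output.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  parse_blast_tab(readLines(path), query_lengths)
}

empty_hsps <- function() {
  tibble(gene_id = character(), isoform_id = character(), contig = character(),
         strand = character(), start = integer(), end = integer(),
         pident = double(), aln_len = integer(), query_cov = double(),
         evalue = double(), bits = double())
}

#' Read a gene annotation from GFF3
#'
#' Builds one record per gene. For protein-coding genes the evaluated gene
#' region spans the CDS extent (start codon through stop codon) of the
#' representative transcript, defined as the transcript with the largest total
#' CDS length (ties broken by lexicographic transcript id). CDS features whose
#' parent transcript has no parent gene are skipped with a warning.
#'
#' @param path GFF3 file with gene/mRNA/CDS (and optionally pseudogene) rows.
#' @return Tibble with `gene_id`, `contig`, `strand`, `start`, `end` (0-based
#'   half-open gene region), `biotype` (`protein_coding`, `pseudogene`, or
#'   `other`), and list-column `cds` of tibbles with `start`, `end`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(if (is.null(df$Parent)) rep(list(character()), nrow(df)) else df$Parent,
                      function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  is_gene <- df$type %in% c("gene", "pseudogene")
  genes <- df[is_gene, , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), model_id = character(),
                  contig = character(), strand = character(),
                  start = integer(), end = integer(), biotype = character(),
                  probability = double(), cds = list()))
  }
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]

  tx_gene <- setNames(tx$Parent, tx$ID)
  if (nrow(cds)) {
    cds$gene <- tx_gene[cds$Parent]
    orphan <- is.na(cds$gene)
    if (any(orphan)) {
      warn(paste(sum(orphan), "CDS feature(s) with no parent gene skipped"))
      cds <- cds[!orphan, , drop = FALSE]
    }
  }

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    # prediction GFF3 carries the query gene as a gene_id attribute; the
    # feature ID is then the model id
    owner <- if (!is.null(genes$gene_id) && !is.na(g$gene_id)) g$gene_id else gid
    biotype <- if (!is.null(genes$biotype) && !is.na(g$biotype)) g$biotype
               else if (g$type == "pseudogene") "pseudogene" else "protein_coding"
    if (!biotype %in% c("protein_coding", "pseudogene")) biotype <- "other"
    gcds <- if (nrow(cds)) cds[cds$gene == gid, , drop = FALSE] else cds
    if (nrow(gcds)) {
      tot <- tapply(gcds$end - gcds$start + 1L, gcds$Parent, sum)
      rep_tx <- names(tot)[order(-tot, names(tot))][1]
      gcds <- gcds[gcds$Parent == rep_tx, , drop = FALSE]
      gcds <- gcds[order(gcds$start), , drop = FALSE]
      ivs <- tibble(start = gcds$start - 1L, end = gcds$end)
      region <- c(min(ivs$start), max(ivs$end))
    } else {
      ivs <- tibble(start = integer(), end = integer())
      region <- c(g$start - 1L, g$end)
    }
    tibble(gene_id = owner, model_id = gid, contig = as.character(g$seqnames),
           strand = as.character(g$strand), start = region[1], end = region[2],
           biotype = biotype,
           probability = if (!is.null(genes$probability) && !is.na(g$probability))
             as.numeric(g$probability) else NA_real_,
           cds = list(ivs))
  })
  arrange(bind_rows(out), .data$contig, .data$start)
}

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write a gene annotation to GFF3
#'
#' Emits gene/mRNA/CDS rows (one transcript per gene, `<gene_id>.t1`) for
#' protein-coding genes and a single `pseudogene` row for pseudogenes.
#' Coordinates are converted from the internal 0-based half-open convention to
#' GFF3's 1-based inclusive.
#'
#' @param genes Tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @param source Value of GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3_annotation <- function(genes, path, source = "genescout") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- arrange(genes, .data$contig, .data$start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    a1 <- g$start + 1L
    if (g$biotype == "pseudogene") {
      writeLines(paste(g$contig, source, "pseudogene", a1, g$end, ".",
                       g$strand, ".",
                       paste0("ID=", gff3_escape(g$gene_id), ";biotype=pseudogene"),
                       sep = "\t"), con)
      next
    }
    writeLines(paste(g$contig, source, "gene", a1, g$end, ".", g$strand, ".",
                     paste0("ID=", gff3_escape(g$gene_id), ";biotype=", g$biotype),
                     sep = "\t"), con)
    txid <- paste0(g$gene_id, ".t1")
    writeLines(paste(g$contig, source, "mRNA", a1, g$end, ".", g$strand, ".",
                     paste0("ID=", gff3_escape(txid), ";Parent=", gff3_escape(g$gene_id)),
                     sep = "\t"), con)
    cds <- g$cds[[1]]
    for (j in seq_len(nrow(cds))) {
      writeLines(paste(g$contig, source, "CDS", cds$start[j] + 1L, cds$end[j],
                       ".", g$strand, "0",
                       paste0("ID=", gff3_escape(paste0(txid, ".cds")), ";Parent=",
                              gff3_escape(txid)),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write predicted gene models to GFF3
#'
#' @param models Gene-model tibble (see [predict_genes()]); optional columns
#'   `probability` and `hint_support` are emitted as attributes.
#' @param path Output path.
#' @param source Value of GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3_models <- function(models, path, source = "genescout") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(models) == 0L) return(invisible(path))
  models <- arrange(models, .data$contig, .data$start, .data$model_id)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    attrs <- paste0("ID=", gff3_escape(m$model_id), ";gene_id=", gff3_escape(m$gene_id))
    if (!is.null(models$hint_support)) {
      attrs <- paste0(attrs, ";hint_support=", format_num(m$hint_support))
    }
    if (!is.null(models$probability) && !is.na(m$probability %||% NA)) {
      attrs <- paste0(attrs, ";probability=", format_num(m$probability))
    }
    writeLines(paste(m$contig, source, "gene", m$start + 1L, m$end, ".",
                     m$strand, ".", attrs, sep = "\t"), con)
    txid <- paste0(m$model_id, ".t1")
    writeLines(paste(m$contig, source, "mRNA", m$start + 1L, m$end, ".",
                     m$strand, ".",
                     paste0("ID=", gff3_escape(txid), ";Parent=", gff3_escape(m$model_id)),
                     sep = "\t"), con)
    cds <- m$cds[[1]]
    for (j in seq_len(nrow(cds))) {
      writeLines(paste(m$contig, source, "CDS", cds$start[j] + 1L, cds$end[j],
                       ".", m$strand, "0",
                       paste0("Parent=", gff3_escape(txid)), sep = "\t"), con)
    }
  }
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(round(x, 6), scientific = FALSE, trim = TRUE))
}

#' Write protein hints in the CDSpart dialect
#'
#' GFF-style tab-separated rows with feature `CDSpart` and attribute `src=P`,
#' the dialect consumed by hint-aware gene predictors.
#'
#' @param hints Tibble with `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `score`, `grp` (grouping id, typically the query isoform).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hints <- function(hints, path) {
  if (nrow(hints) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- paste(hints$contig, "genescout", "CDSpart", hints$start + 1L,
                 hints$end, format_num(hints$score), hints$strand, ".",
                 paste0("src=P;grp=", gff3_escape(hints$grp)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export candidate regions as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param regions Candidate-region tibble (see [group_and_extend()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  lines <- paste(regions$contig, regions$start, regions$end,
                 paste0(regions$region_id, ";", regions$gene_id),
                 0, regions$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an ortholog-presence table
#'
#' Two-column TSV: `gene_id`, `present` (0/1).
#'
#' @param path TSV path.
#' @return Tibble with `gene_id` (character) and `present` (logical).
#' @export
read_ortholog_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(gene_id = "c", present = "i"))
  mutate(df, present = .data$present == 1L)
}

#' @rdname read_ortholog_table
#' @param orthologs Tibble with `gene_id`, `present` (logical or 0/1).
#' @export
write_ortholog_table <- function(orthologs, path) {
  readr::write_tsv(mutate(orthologs, present = as.integer(.data$present)), path)
  invisible(path)
}

#' Read / write a paralog map
#'
#' Two-column TSV: `gene_id` (query gene), `paralog_id` (annotated paralog).
#'
#' @param path TSV path.
#' @return Tibble with `gene_id`, `paralog_id`.
#' @export
read_paralog_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' @rdname read_paralog_table
#' @param paralogs Tibble with `gene_id`, `paralog_id`.
#' @export
write_paralog_table <- function(paralogs, path) {
  readr::write_tsv(paralogs, path)
  invisible(path)
}
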