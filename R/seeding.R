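# Translated similarity search: query proteins vs. six-frame translation of
# the genome. The builtin backend is a deterministic reference implementation
# (exact k-mer seeds, ungapped BLOSUM62 X-drop extension); the external
# backend shells out to any tool that emits 12-column BLAST tabular output.

# Karlin-Altschul parameters for ungapped BLOSUM62; used to express raw
# scores in bits. The builtin e-value is a bits-derived placeholder: nothing
# downstream filters on it.
GS_KA_LAMBDA <- 0.3176
GS_KA_K <- 0.134

gs_env <- new.env(parent = emptyenv())

gs_blosum62 <- function() {
  if (is.null(gs_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    gs_env$blosum62 <- e$BLOSUM62
  }
  gs_env$blosum62
}

# Integer-encode an amino-acid string against the rows of a scoring matrix.
aa_encode <- function(seq, mat) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], rownames(mat))
  if (anyNA(idx)) abort("sequence contains letters outside the scoring alphabet")
  idx
}

raw_to_bits <- function(raw) (GS_KA_LAMBDA * raw - log(GS_KA_K)) / log(2)

#' Translated similarity search
#'
#' Seeds candidate loci by aligning query proteins to the six-frame
#' translation of the genome. The `"builtin"` backend seeds on exact k-mers
#' (`config$seed_k`), extends each seed without gaps under BLOSUM62 with an
#' X-drop cutoff, converts raw scores to bits, and reports at most one HSP per
#' (query, frame, diagonal) with bits >= `config$min_bits`. The `"external"`
#' backend runs a user-supplied command template and parses its BLAST tabular
#' output.
#'
#' @param queries QC'd query tibble (`gene_id`, `isoform_id`, `seq`).
#' @param genome Named character vector of contig sequences.
#' @param backend `"builtin"` or `"external"`.
#' @param config A [gs_config()].
#' @param command Command template for the external backend, with placeholders
#'   `{queries}`, `{genome}`, `{out}` (and optionally `{tmp}`).
#' @param workdir Scratch directory for the external backend.
#' @return HSP tibble (see [parse_blast_tab()] for columns); builtin results
#'   are sorted by (gene_id, isoform_id, contig, start).
#' @export
search_translated <- function(queries, genome, backend = c("builtin", "external"),
                              config = gs_config(), command = NULL,
                              workdir = tempfile("gs_search_")) {
  backend <- match.arg(backend)
  if (backend == "external") {
    return(search_external(queries, genome, command, workdir))
  }
  short <- nchar(genome) < 3L
  if (any(short)) {
    warn(paste("skipping contig(s) shorter than 3 nt:",
               paste(names(genome)[short], collapse = ", ")))
    genome <- genome[!short]
  }
  mat <- gs_blosum62()
  k <- config$seed_k
  qlens <- nchar(queries$seq)
  qcodes <- lapply(queries$seq, aa_encode, mat = mat)

  # k-mer index over all queries: kmer string -> (query row, 0-based offset)
  qk <- lapply(seq_len(nrow(queries)), function(i) {
    L <- qlens[i]
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    data.frame(kmer = substring(queries$seq[i], st, st + k - 1L),
               qi = i, qpos = st - 1L)
  })
  qk <- do.call(rbind, qk)
  if (is.null(qk) || nrow(qk) == 0L) return(empty_hsps())
  uk <- unique(qk$kmer)
  qk_by_kmer <- split(seq_len(nrow(qk)), factor(qk$kmer, levels = uk))
  total_nt <- sum(nchar(genome))

  out <- list()
  for (ci in seq_along(genome)) {
    cname <- names(genome)[ci]
    cseq <- genome[[ci]]
    clen <- nchar(cseq)
    frames <- translate_six_frames(cseq)
    for (fr in names(frames)) {
      faa <- frames[[fr]]
      Lf <- nchar(faa)
      if (Lf < k) next
      st <- seq_len(Lf - k + 1L)
      ids <- match(substring(faa, st, st + k - 1L), uk)
      hitpos <- which(!is.na(ids))
      if (length(hitpos) == 0L) next
      rows <- qk_by_kmer[ids[hitpos]]
      nrep <- lengths(rows)
      ri <- unlist(rows, use.names = FALSE)
      seeds <- data.frame(qi = qk$qi[ri], qpos = qk$qpos[ri],
                          fpos = rep(hitpos - 1L, nrep))
      seeds$diag <- seeds$fpos - seeds$qpos
      seeds <- seeds[order(seeds$qi, seeds$diag, seeds$fpos), , drop = FALSE]
      seeds <- seeds[!duplicated(seeds[c("qi", "diag")]), , drop = FALSE]
      fcode <- aa_encode(faa, mat)
      for (s in seq_len(nrow(seeds))) {
        hsp <- extend_seed(qcodes[[seeds$qi[s]]], fcode, seeds$qpos[s],
                           seeds$diag[s], k, mat, config$xdrop)
        if (is.null(hsp)) next
        bits <- raw_to_bits(hsp$raw)
        if (bits < config$min_bits) next
        g <- frame_to_genome(fr, hsp$fs, hsp$fe, clen)
        qi <- seeds$qi[s]
        aln_len <- hsp$qe - hsp$qs
        out[[length(out) + 1L]] <- tibble(
          gene_id = queries$gene_id[qi], isoform_id = queries$isoform_id[qi],
          contig = cname, strand = g$strand,
          start = g$start, end = g$end,
          pident = 100 * hsp$matches / aln_len, aln_len = aln_len,
          query_cov = aln_len / qlens[qi],
          evalue = GS_KA_K * qlens[qi] * total_nt * exp(-GS_KA_LAMBDA * hsp$raw),
          bits = bits)
      }
    }
  }
  if (length(out) == 0L) return(empty_hsps())
  arrange(bind_rows(out), .data$gene_id, .data$isoform_id, .data$contig,
          .data$start, .data$strand)
}

# Ungapped X-drop extension of one seed along a diagonal. qcode/fcode are
# integer-encoded sequences, qpos the 0-based seed offset in the query, d the
# diagonal (frame offset - query offset). Returns query/frame extents
# (0-based half-open, amino acids) or NULL.
extend_seed <- function(qcode, fcode, qpos, d, k, mat, xdrop) {
  Lq <- length(qcode); Lf <- length(fcode)
  i0 <- max(0L, -d)                 # first query index of the diagonal overlap
  i1 <- min(Lq, Lf - d)             # one-past-last query index
  if (i1 - i0 < k) return(NULL)
  qv <- qcode[(i0 + 1L):i1]
  fv <- fcode[(i0 + d + 1L):(i1 + d)]
  sv <- mat[cbind(qv, fv)]
  srel <- qpos - i0 + 1L            # 1-based seed start within the overlap
  seed_score <- sum(sv[srel:(srel + k - 1L)])

  ext <- function(scores) {         # scores beyond the seed, in scan order
    if (length(scores) == 0L) return(0L)
    cs <- cumsum(scores)
    rm <- cummax(cs)
    stop_at <- which(cs < rm - xdrop)
    scan <- if (length(stop_at)) seq_len(stop_at[1] - 1L) else seq_along(cs)
    if (length(scan) == 0L || max(cs[scan]) <= 0) return(0L)
    which.max(cs[scan])
  }
  nr <- ext(sv[seq.int(srel + k, length.out = length(sv) - (srel + k - 1L))])
  nl <- ext(rev(sv[seq_len(srel - 1L)]))
  qs <- i0 + (srel - nl) - 1L       # back to 0-based query coordinates
  qe <- i0 + (srel + k - 1L + nr)
  rng <- (qs - i0 + 1L):(qe - i0)
  raw <- sum(sv[rng])
  matches <- sum(qv[rng] == fv[rng])
  list(qs = qs, qe = qe, fs = qs + d, fe = qe + d, raw = raw, matches = matches)
}

search_external <- function(queries, genome, command, workdir) {
  if (is.null(command)) {
    abort("external backend requires a command template (placeholders {queries}, {genome}, {out})")
  }
  tool <- strsplit(trimws(command), "\\s+")[[1]][1]
  if (Sys.which(tool) == "") {
    abort(paste0("external search tool '", tool, "' not found on PATH"))
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  qf <- file.path(workdir, "queries.fa")
  gf <- file.path(workdir, "genome.fa")
  of <- file.path(workdir, "hsps.tsv")
  write_queries(queries, qf)
  write_genome(genome, gf)
  cmd <- command
  cmd <- gsub("{queries}", qf, cmd, fixed = TRUE)
  cmd <- gsub("{genome}", gf, cmd, fixed = TRUE)
  cmd <- gsub("{out}", of, cmd, fixed = TRUE)
  cmd <- gsub("{tmp}", file.path(workdir, "tmp"), cmd, fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE)
  if (status != 0L || !file.exists(of)) {
    abort(paste0("external search command failed (exit ", status, "): ", tool))
  }
  qlen <- setNames(nchar(queries$seq),
                   paste0(queries$gene_id, "|", queries$isoform_id))
  read_blast_tab(of, query_lengths = qlen)
}
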