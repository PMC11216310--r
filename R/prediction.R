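# Gene prediction inside candidate regions. The builtin predictor is
# deliberately modest: complete single-exon ORFs (ATG..stop, both strands).
# The simulator plants intronless genes when this backend is in play, so the
# no-dependency test path stays honest. Hint-aware external predictors plug
# in through a command adapter.

#' Extract the sequence of a candidate region
#'
#' Always the forward-strand genome subsequence; strand handling happens in
#' the predictor and the lift.
#'
#' @param genome Named character vector of contigs.
#' @param region One row of a candidate-region tibble.
#' @return Character scalar.
#' @export
region_sequence <- function(genome, region) {
  substring(genome[[region$contig]], region$start + 1L, region$end)
}

#' Build protein hints for a region
#'
#' Aligns the region's retained query isoforms back to the region sequence
#' with the builtin translated-search aligner and converts every matched
#' block into a `CDSpart` hint in region-local coordinates.
#'
#' @param region One row of a candidate-region tibble (after
#'   [retain_top_queries()]).
#' @param region_seq Sequence from [region_sequence()].
#' @param queries Full QC'd query tibble.
#' @param config A [gs_config()].
#' @return Hint tibble: `start`, `end` (region-local, 0-based half-open),
#'   `strand`, `kind` (`"CDSpart"`), `src` (`"P"`), `score`, `grp`.
#' @export
build_hints <- function(region, region_seq, queries, config = gs_config()) {
  retained <- region$queries[[1]]
  qs <- queries[queries$gene_id == region$gene_id &
                  queries$isoform_id %in% retained$isoform_id, , drop = FALSE]
  if (nrow(qs) == 0L) return(empty_hints())
  mini <- setNames(region_seq, "region")
  hits <- search_translated(qs, mini, backend = "builtin", config = config)
  if (nrow(hits) == 0L) return(empty_hints())
  tibble(start = hits$start, end = hits$end, strand = hits$strand,
         kind = "CDSpart", src = "P", score = hits$bits,
         grp = hits$isoform_id)
}

empty_hints <- function() {
  tibble(start = integer(), end = integer(), strand = character(),
         kind = character(), src = character(), score = double(),
         grp = character())
}

#' Predict gene models within a candidate region
#'
#' The `"builtin"` backend reports every complete ORF (ATG through stop, at
#' least `config$min_codons` codons of protein) on both strands of the region
#' sequence, single-exon, taking the longest ORF per in-frame stop. The
#' `"external"` backend runs a hint-aware gene predictor through a command
#' template (`{region}`, `{hints}`, `{out}`, `{species}` placeholders) and
#' parses its GFF3 output. Models lacking either a start or a stop codon are
#' never reported. Each model's `hint_support` is the percentage of its CDS
#' bases covered by at least one same-strand hint.
#'
#' @param region One row of a candidate-region tibble.
#' @param region_seq Sequence from [region_sequence()].
#' @param hints Hint tibble from [build_hints()].
#' @param config A [gs_config()].
#' @param backend `"builtin"` or `"external"`.
#' @param species Archetype species parameter for the external predictor.
#' @param command Command template for the external predictor.
#' @return Gene-model tibble in genomic coordinates: `model_id`, `region_id`,
#'   `gene_id`, `contig`, `strand`, `start`, `end`, list-column `cds`,
#'   `protein`, `hint_support`, `has_start`, `has_stop`.
#' @export
predict_genes <- function(region, region_seq, hints, config = gs_config(),
                          backend = c("builtin", "external"),
                          species = NULL, command = NULL) {
  backend <- match.arg(backend)
  if (backend == "external") {
    local <- predict_external(region, region_seq, hints, species, command)
  } else {
    if (nchar(region_seq) < 180L) return(empty_models())
    local <- scan_orfs(region_seq, config$min_codons)
  }
  if (nrow(local) == 0L) return(empty_models())
  local$hint_support <- map2_dbl_local(local, hints)
  lift_to_genome(local, region)
}

empty_models <- function() {
  tibble(model_id = character(), region_id = character(), gene_id = character(),
         contig = character(), strand = character(), start = integer(),
         end = integer(), cds = list(), protein = character(),
         hint_support = double(), has_start = logical(), has_stop = logical())
}

# Complete ORFs (>= min_codons aa of protein, ATG..stop) on both strands of
# seq; per in-frame stop, the earliest ATG after the previous stop. Local
# 0-based half-open coordinates on the forward sequence; CDS includes the
# stop codon.
scan_orfs <- function(seq, min_codons) {
  L <- nchar(seq)
  one_strand <- function(s, strand) {
    res <- list()
    for (off in 0:2) {
      aa <- translate_dna(substring(s, off + 1L, nchar(s)))
      if (nchar(aa) == 0L) next
      ch <- strsplit(aa, "", fixed = TRUE)[[1]]
      stops <- which(ch == "*")
      starts <- which(ch == "M")
      prev <- 0L
      for (st in stops) {
        cand <- starts[starts > prev & starts < st]
        prev <- st
        if (length(cand) == 0L) next
        a <- cand[1]
        if (st - a < min_codons) next
        # codon positions a..st (1-based in frame) -> nt, stop codon included
        nt_start <- off + 3L * (a - 1L)
        nt_end <- off + 3L * st
        if (strand == "+") {
          res[[length(res) + 1L]] <- tibble(
            start = nt_start, end = nt_end, strand = "+",
            protein = paste(ch[a:(st - 1L)], collapse = ""))
        } else {
          res[[length(res) + 1L]] <- tibble(
            start = L - nt_end, end = L - nt_start, strand = "-",
            protein = paste(ch[a:(st - 1L)], collapse = ""))
        }
      }
    }
    res
  }
  out <- c(one_strand(seq, "+"), one_strand(revcomp(seq), "-"))
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  protein = character()))
  }
  arrange(bind_rows(out), .data$start, .data$end, .data$strand)
}

# hint_support: percent of CDS bases covered by >= 1 same-strand hint.
# Invariant under hint fragmentation because coverage is a set union.
map2_dbl_local <- function(local, hints) {
  vapply(seq_len(nrow(local)), function(i) {
    m <- local[i, ]
    h <- hints[hints$strand == m$strand, , drop = FALSE]
    if ("cds_local" %in% names(local)) {
      iv <- m$cds_local[[1]]
      cds_ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    } else {
      cds_ir <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    }
    cds_len <- sum(IRanges::width(cds_ir))
    if (cds_len == 0L) return(0)
    if (nrow(h) == 0L) return(0)
    hint_ir <- IRanges::reduce(IRanges::IRanges(start = h$start + 1L, end = h$end))
    covered <- sum(IRanges::width(IRanges::intersect(cds_ir, hint_ir)))
    100 * covered / cds_len
  }, numeric(1))
}

#' Lift region-local gene models to genomic coordinates
#'
#' Local coordinates are offsets into the forward-strand region sequence, so
#' the lift is `region$start + local`. Set `from_revcomp = TRUE` when the
#' local model was called on the reverse complement of the region sequence;
#' its coordinates are then mirrored through the region length first.
#'
#' @param local Tibble with `start`, `end`, `strand`, `protein`, optionally
#'   `hint_support`.
#' @param region One row of a candidate-region tibble.
#' @param from_revcomp Local coordinates refer to the reverse complement.
#' @return Gene-model tibble in genomic coordinates (see [predict_genes()]).
#' @export
lift_to_genome <- function(local, region, from_revcomp = FALSE) {
  rlen <- region$end - region$start
  if (any(local$start < 0L | local$end > rlen)) {
    abort("lifted interval escapes region bounds")
  }
  start <- local$start
  end <- local$end
  strand <- local$strand
  if (from_revcomp) {
    tmp <- rlen - end
    end <- rlen - start
    start <- tmp
    strand <- ifelse(strand == "+", "-", "+")
  }
  n <- nrow(local)
  cds <- if ("cds_local" %in% names(local)) {
    map(local$cds_local, function(iv) {
      tibble(start = region$start + iv$start, end = region$start + iv$end)
    })
  } else {
    map2(region$start + start, region$start + end,
         ~tibble(start = .x, end = .y))
  }
  tibble(
    model_id = sprintf("%s.m%02d", region$region_id, seq_len(n)),
    region_id = region$region_id,
    gene_id = region$gene_id,
    contig = region$contig,
    strand = strand,
    start = region$start + start,
    end = region$start + end,
    cds = cds,
    protein = local$protein,
    hint_support = if (!"hint_support" %in% names(local)) rep(NA_real_, n) else local$hint_support,
    has_start = if (!"has_start" %in% names(local)) rep(TRUE, n) else local$has_start,
    has_stop = if (!"has_stop" %in% names(local)) rep(TRUE, n) else local$has_stop
  )
}

predict_external <- function(region, region_seq, hints, species, command) {
  if (is.null(command)) {
    abort("external predictor requires a command template ({region}, {hints}, {out}, {species})")
  }
  tool <- strsplit(trimws(command), "\\s+")[[1]][1]
  if (Sys.which(tool) == "") {
    abort(paste0("external gene predictor '", tool, "' not found on PATH"))
  }
  wd <- tempfile("gs_predict_")
  dir.create(wd, recursive = TRUE)
  rf <- file.path(wd, "region.fa")
  hf <- file.path(wd, "hints.gff")
  of <- file.path(wd, "predictions.gff3")
  write_genome(setNames(region_seq, region$region_id), rf)
  write_hints(mutate(hints, contig = region$region_id), hf)
  cmd <- command
  cmd <- gsub("{region}", rf, cmd, fixed = TRUE)
  cmd <- gsub("{hints}", hf, cmd, fixed = TRUE)
  cmd <- gsub("{out}", of, cmd, fixed = TRUE)
  cmd <- gsub("{species}", species %||% "human", cmd, fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE)
  if (status != 0L || !file.exists(of)) {
    abort(paste0("external gene predictor failed (exit ", status, "): ", tool))
  }
  preds <- read_gff3_genes(of)
  out <- lapply(seq_len(nrow(preds)), function(i) {
    p <- preds[i, ]
    cds <- p$cds[[1]]
    if (nrow(cds) == 0L) return(NULL)
    prot <- translate_model_cds(region_seq, cds, p$strand)
    has_stop <- endsWith(prot, "*")
    prot <- sub("\\*$", "", prot)
    tibble(start = min(cds$start), end = max(cds$end), strand = p$strand,
           protein = prot, cds_local = list(cds),
           has_start = startsWith(prot, "M"), has_stop = has_stop)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) return(out)
  filter(out, .data$has_start & .data$has_stop)
}
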