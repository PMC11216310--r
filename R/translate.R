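# Nucleotide-level helpers shared by the seeding and prediction stages.
# All coordinates in this package are 0-based half-open on the forward strand.

GS_AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V")

gs_check_dna <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L) {
    abort("dna must be a single character string")
  }
  if (grepl("[^ACGTN]", dna)) {
    abort("dna contains characters outside {A,C,G,T,N}")
  }
  invisible(dna)
}

#' Reverse complement of a nucleotide string
#'
#' @param dna Character scalar over `{A,C,G,T,N}`.
#' @return The reverse complement, same alphabet.
#' @export
#' @examples
#' revcomp("ATGAAATAA")
revcomp <- function(dna) {
  gs_check_dna(dna)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Translate a nucleotide string in frame +1
#'
#' Standard genetic code; stop codons become `*`; any codon containing `N`
#' becomes `X`; a trailing partial codon is dropped.
#'
#' @param dna Character scalar over `{A,C,G,T,N}`.
#' @return Amino-acid string (possibly empty).
#' @export
#' @examples
#' translate_dna("ATGAAATAA")
translate_dna <- function(dna) {
  gs_check_dna(dna)
  n <- nchar(dna)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates the three forward frames of `dna` and the three frames of its
#' reverse complement.
#'
#' @param dna Character scalar over `{A,C,G,T,N}`.
#' @return Named character vector with elements `"+1","+2","+3","-1","-2","-3"`.
#'   Frame `+f` starts at forward position `f`; frame `-f` starts at position
#'   `f` of the reverse complement.
#' @export
#' @examples
#' translate_six_frames("ATGAAATAA")
translate_six_frames <- function(dna) {
  gs_check_dna(dna)
  rc <- revcomp(dna)
  fr <- function(s, off) translate_dna(substring(s, off, nchar(s)))
  c("+1" = fr(dna, 1L), "+2" = fr(dna, 2L), "+3" = fr(dna, 3L),
    "-1" = fr(rc, 1L), "-2" = fr(rc, 2L), "-3" = fr(rc, 3L))
}

# Map an amino-acid interval [aa_start, aa_end) (0-based, within a frame
# translation) back to the genomic nucleotide interval on the forward strand.
# frame is one of "+1".."+3","-1".."-3"; contig_len is the contig length in nt.
frame_to_genome <- function(frame, aa_start, aa_end, contig_len) {
  off <- as.integer(substring(frame, 2L)) - 1L
  nt_start <- off + 3L * aa_start
  nt_end <- off + 3L * aa_end
  if (startsWith(frame, "+")) {
    list(start = nt_start, end = nt_end, strand = "+")
  } else {
    list(start = contig_len - nt_end, end = contig_len - nt_start, strand = "-")
  }
}

# Spliced CDS translation of a gene model on the genome. cds is a tibble with
# 0-based half-open start/end columns; minus-strand models are translated on
# the reverse complement of the concatenated exons.
translate_model_cds <- function(contig_seq, cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  parts <- substring(contig_seq, cds$start + 1L, cds$end)
  spliced <- paste(parts, collapse = "")
  if (strand == "-") spliced <- revcomp(spliced)
  translate_dna(spliced)
}
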