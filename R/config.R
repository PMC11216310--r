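#' Pipeline configuration
#'
#' Collects every tunable constant of the search pipeline in one object.
#' Defaults are the method's published operating point: HSPs of one gene and
#' strand separated by less than `merge_gap` bp are merged into one candidate
#' region, each region is extended by `margin` bp on both sides, at most
#' `top_k` query isoforms are retained per identical alignment location,
#' near-tied predictions within `tie_ratio` of a gene's best probability are
#' all reported, and the filter threshold is calibrated to
#' `calibration_sensitivity` on the training set.
#'
#' @param merge_gap Maximum gap (bp, exclusive) between same-gene same-strand
#'   HSPs that still merge into one region. Default 100000.
#' @param margin Extension (bp) added to both sides of a merged region,
#'   clipped to contig bounds. Default 10000.
#' @param top_k Number of query isoforms retained per identical alignment
#'   location. Default 5.
#' @param tie_ratio Near-tie retention factor at gene-level deduplication:
#'   candidates with probability strictly greater than `tie_ratio` times the
#'   gene's best probability survive. Default 0.95.
#' @param calibration_sensitivity Sensitivity floor used when calibrating the
#'   filter's decision threshold. Default 0.95.
#' @param seed_k Exact k-mer seed length of the builtin translated search.
#' @param min_bits Minimum bit score for a reported HSP (builtin backend).
#' @param xdrop X-drop cutoff (raw score units) for ungapped extension.
#' @param min_codons Minimum ORF length (codons of protein, excluding the stop
#'   codon) for the builtin gene predictor.
#' @param nn_lr,nn_epochs,nn_batch,nn_seed Hyperparameters of the 4-2-1
#'   result-filtering network: Adam learning rate, training epochs, minibatch
#'   size, RNG seed.
#'
#' @return A list of class `gs_config`.
#' @export
#' @examples
#' cfg <- gs_config(margin = 5000)
#' cfg$merge_gap
gs_config <- function(merge_gap = 100000L,
                      margin = 10000L,
                      top_k = 5L,
                      tie_ratio = 0.95,
                      calibration_sensitivity = 0.95,
                      seed_k = 5L,
                      min_bits = 40,
                      xdrop = 20,
                      min_codons = 60L,
                      nn_lr = 1e-5,
                      nn_epochs = 10000L,
                      nn_batch = 32L,
                      nn_seed = 1L) {
  stopifnot(merge_gap > 0, margin >= 0, top_k >= 1,
            tie_ratio > 0, tie_ratio <= 1,
            calibration_sensitivity > 0, calibration_sensitivity <= 1)
  structure(list(
    merge_gap = as.integer(merge_gap),
    margin = as.integer(margin),
    top_k = as.integer(top_k),
    tie_ratio = tie_ratio,
    calibration_sensitivity = calibration_sensitivity,
    seed_k = as.integer(seed_k),
    min_bits = min_bits,
    xdrop = xdrop,
    min_codons = as.integer(min_codons),
    nn_lr = nn_lr,
    nn_epochs = as.integer(nn_epochs),
    nn_batch = as.integer(nn_batch),
    nn_seed = as.integer(nn_seed)
  ), class = "gs_config")
}

#' Archetype species per taxonomic class
#'
#' Maps the supported taxonomic classes to the well-annotated archetype
#' species whose parameters anchor external gene prediction.
#'
#' @param class_name One of `"mammals"`, `"fish"`, `"birds"`,
#'   `"eudicotyledons"`, `"liliopsida"`.
#' @return The archetype species identifier (character scalar).
#' @export
#' @examples
#' archetype_species("fish")
archetype_species <- function(class_name) {
  map <- c(mammals = "human", fish = "zebrafish", birds = "chicken",
           eudicotyledons = "arabidopsis", liliopsida = "wheat")
  class_name <- tolower(class_name)
  if (!class_name %in% names(map)) {
    abort(paste0("unknown taxonomic class '", class_name, "'; expected one of ",
                 paste(names(map), collapse = ", ")))
  }
  unname(map[[class_name]])
}
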