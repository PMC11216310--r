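# End-to-end orchestration: qc -> translated search -> region building ->
# hints -> gene prediction -> validation alignment -> feature assembly ->
# scoring -> selection. Every intermediate is persisted under the output
# directory; per-stage counts go to stderr and into a run manifest. Outputs
# contain no timestamps, so reruns with identical inputs are byte-identical.

stage_log <- function(stage, n_in, n_out, quiet) {
  if (!quiet) {
    inform(sprintf("[genescout] %-12s in=%d out=%d", stage, n_in, n_out))
  }
}

#' Run the gene-search pipeline
#'
#' @param genome Genome FASTA path or named character vector of contigs.
#' @param queries Query FASTA path or query tibble.
#' @param out_dir Output directory (created if needed). Intermediates
#'   (`hsps.tsv`, `regions.bed`, `hints.gff`, `candidates.tsv`) and results
#'   (`report.gff3`, `proteins.fa`, `summary.tsv`, `manifest.json`) are
#'   written there.
#' @param filter A calibrated `gs_filter`, a filter archive path, or `NULL`
#'   to skip filtering and report raw candidates with their features.
#' @param config A [gs_config()].
#' @param backend `"builtin"` or `"external"` for both pluggable stages.
#' @param class_name Taxonomic class for the external predictor's archetype
#'   species parameter (see [archetype_species()]); unused by the builtin
#'   backend.
#' @param search_command,predict_command Command templates for the external
#'   backends.
#' @param quiet Suppress stage logging.
#' @return List with `report` (final tibble), `candidates` (all scored
#'   candidates), `regions`, `hsps`, `status` (`"ok"` or `"no seeds"`), and
#'   `files`.
#' @export
gs_run <- function(genome, queries, out_dir, filter = NULL,
                   config = gs_config(), backend = c("builtin", "external"),
                   class_name = NULL, search_command = NULL,
                   predict_command = NULL, quiet = FALSE) {
  backend <- match.arg(backend)
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) abort(paste("genome file not found:", genome))
    genome <- read_genome(genome)
  }
  if (is.character(queries)) {
    if (!file.exists(queries)) abort(paste("query file not found:", queries))
    queries <- read_queries(queries)
  }
  if (is.character(filter)) filter <- read_filter(filter)
  if (!is.null(filter) && is.na(filter$threshold)) {
    abort("filter model is not calibrated (threshold missing)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  species <- if (!is.null(class_name)) archetype_species(class_name) else NULL

  n_raw <- nrow(queries)
  queries <- qc_queries(queries)
  stage_log("qc", n_raw, nrow(queries), quiet)

  hsps <- search_translated(queries, genome, backend = backend, config = config,
                            command = search_command)
  stage_log("search", nrow(queries), nrow(hsps), quiet)
  readr::write_tsv(select(hsps, -dplyr::any_of("frame")),
                   file.path(out_dir, "hsps.tsv"))

  contig_lengths <- setNames(nchar(genome), names(genome))
  if (nrow(hsps) == 0L) {
    report <- empty_report()
    write_outputs(report, report, empty_regions(), out_dir, config, backend,
                  status = "no seeds")
    if (!quiet) inform("[genescout] no seeds: empty report")
    return(list(report = report, candidates = report, regions = empty_regions(),
                hsps = hsps, status = "no seeds", files = output_paths(out_dir)))
  }

  regions <- group_and_extend(hsps, config, contig_lengths) |>
    retain_top_queries(top_k = config$top_k)
  stage_log("regions", nrow(hsps), nrow(regions), quiet)
  write_region_bed(regions, file.path(out_dir, "regions.bed"))

  all_hints <- list()
  models <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    rseq <- region_sequence(genome, region)
    hints <- build_hints(region, rseq, queries, config)
    if (nrow(hints)) {
      all_hints[[length(all_hints) + 1L]] <-
        mutate(hints, contig = region$region_id)
    }
    m <- predict_genes(region, rseq, hints, config, backend = backend,
                       species = species, command = predict_command)
    if (nrow(m)) models[[length(models) + 1L]] <- m
  }
  write_hints(bind_rows(all_hints), file.path(out_dir, "hints.gff"))
  models <- if (length(models)) bind_rows(models) else empty_models()
  stage_log("predict", nrow(regions), nrow(models), quiet)

  candidates <- build_candidates(models, regions, queries)
  stage_log("validate", nrow(models), nrow(candidates), quiet)

  if (!is.null(filter)) {
    candidates$probability <- predict_proba(filter, assemble_features(candidates))
    report <- select_candidates(candidates, threshold = filter$threshold,
                                tie_ratio = config$tie_ratio)
  } else {
    candidates$probability <- NA_real_
    report <- arrange(candidates, .data$contig, .data$start)
  }
  stage_log("select", nrow(candidates), nrow(report), quiet)

  write_outputs(report, candidates, regions, out_dir, config, backend,
                status = "ok", filter = filter)
  list(report = report, candidates = candidates, regions = regions,
       hsps = hsps, status = "ok", files = output_paths(out_dir))
}

empty_report <- function() {
  mutate(empty_models(), isoform_id = character(), sim_pident = double(),
         sim_gene_cov = double(), aln_pident = double(), aln_psim = double(),
         aln_gene_cov = double(), score = double(), probability = double())
}

# Join each predicted model to its region's similarity summary and to the
# best validating isoform of the region's retained queries.
build_candidates <- function(models, regions, queries) {
  if (nrow(models) == 0L) return(empty_report())
  out <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    region <- regions[regions$region_id == m$region_id, ]
    retained <- region$queries[[1]]
    qs <- queries[queries$gene_id == m$gene_id &
                    queries$isoform_id %in% retained$isoform_id, , drop = FALSE]
    if (nrow(qs) == 0L) next
    best <- best_query_for_model(m$protein, qs)
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      m,
      tibble(isoform_id = best$isoform_id,
             sim_pident = region$sim_pident, sim_gene_cov = region$sim_gene_cov,
             aln_pident = best$aln_pident, aln_psim = best$aln_psim,
             aln_gene_cov = best$aln_gene_cov, score = best$score))
  }
  if (length(out) == 0L) return(empty_report())
  bind_rows(out)
}

output_paths <- function(out_dir) {
  list(report = file.path(out_dir, "report.gff3"),
       proteins = file.path(out_dir, "proteins.fa"),
       summary = file.path(out_dir, "summary.tsv"),
       candidates = file.path(out_dir, "candidates.tsv"),
       manifest = file.path(out_dir, "manifest.json"))
}

flatten_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(select(candidates, -dplyr::any_of("cds")))
  }
  candidates |>
    mutate(cds = map_chr(.data$cds, ~paste(paste0(.x$start, "-", .x$end),
                                           collapse = ";")))
}

write_outputs <- function(report, candidates, regions, out_dir, config,
                          backend, status, filter = NULL) {
  paths <- output_paths(out_dir)
  write_gff3_models(report, paths$report)
  fa <- as.vector(rbind(paste0(">", report$model_id, " ", report$gene_id),
                        report$protein))
  writeLines(if (nrow(report)) fa else character(), paths$proteins)
  readr::write_tsv(flatten_candidates(candidates), paths$candidates)

  gene_ids <- sort(unique(candidates$gene_id))
  summary <- lapply(gene_ids, function(g) {
    mine <- report[report$gene_id == g, , drop = FALSE]
    if (nrow(mine) == 0L) {
      return(tibble(gene_id = g, found = 0L, contig = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, probability = NA_real_))
    }
    best <- mine[order(-replace(mine$probability, is.na(mine$probability), 1)), ][1, ]
    tibble(gene_id = g, found = 1L, contig = best$contig, start = best$start,
           end = best$end, strand = best$strand, probability = best$probability)
  })
  readr::write_tsv(bind_rows(summary), paths$summary)

  manifest <- list(
    tool = "genescout", status = status, backend = backend,
    config = unclass(config),
    filter_threshold = if (!is.null(filter)) filter$threshold else NA,
    counts = list(regions = nrow(regions), candidates = nrow(candidates),
                  reported = nrow(report)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Train and calibrate the result filter from labeled candidates
#'
#' Balances classes with [smote_balance()], trains the 4-2-1 network on the
#' balanced set, then calibrates the decision threshold on the original
#' (pre-balancing) candidates so the calibrated sensitivity refers to real,
#' not synthetic, positives.
#'
#' @param candidates Labeled candidate tibble (feature columns + `label`),
#'   e.g. a `--no-filter` pipeline run passed through [label_candidates()].
#' @param config A [gs_config()].
#' @return A calibrated `gs_filter`.
#' @export
gs_train_filter <- function(candidates, config = gs_config()) {
  if (!"label" %in% names(candidates)) abort("candidates carry no label column")
  labels <- as.integer(candidates$label)
  if (length(unique(labels)) < 2L) {
    abort("training requires both positive and negative labels")
  }
  x <- assemble_features(candidates)
  bal <- smote_balance(x, labels, seed = config$nn_seed)
  model <- train_filter(bal$x, bal$labels, config)
  calibrate_threshold(model, x, labels,
                      target_sensitivity = config$calibration_sensitivity)
}

#' Evaluate prediction files against truth files
#'
#' File-level wrapper around [gs_evaluate()].
#'
#' @param pred_gff3 Prediction GFF3 (from [gs_run()]).
#' @param truth_gff3 Truth annotation GFF3.
#' @param ortholog_tsv Ortholog-presence TSV.
#' @param paralog_tsv Optional paralog TSV.
#' @param mode `"overlap"` or `"presence"`.
#' @return A `gs_eval` object.
#' @export
gs_evaluate_files <- function(pred_gff3, truth_gff3, ortholog_tsv,
                              paralog_tsv = NULL,
                              mode = c("overlap", "presence")) {
  report <- read_gff3_genes(pred_gff3)
  truth <- read_gff3_genes(truth_gff3)
  orthologs <- read_ortholog_table(ortholog_tsv)
  paralogs <- if (!is.null(paralog_tsv)) read_paralog_table(paralog_tsv) else NULL
  gs_evaluate(report, truth, orthologs, paralogs, mode = match.arg(mode))
}
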