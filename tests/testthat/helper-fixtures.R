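# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

.gs_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.gs_test_cache[[name]])) .gs_test_cache[[name]] <- force(expr)
  .gs_test_cache[[name]]
}

# the study-conditions fixture: 5 genes, 10% divergence, 2 absent queries
fx_eval <- function() cached("fx_eval", generate_fixture(sim_config(seed = 7)))

# an independent fixture used only to train the result filter
fx_train <- function() cached("fx_train", generate_fixture(sim_config(seed = 11)))

# raw (unfiltered) pipeline run + labels on the training fixture
train_candidates <- function() {
  cached("train_candidates", {
    fx <- fx_train()
    run <- gs_run(fx$genome, fx$queries, file.path(tempdir(), "gs_train_run"),
                  filter = NULL, quiet = TRUE)
    label_candidates(run$candidates, fx$truth)
  })
}

# calibrated filter trained on the independent fixture
trained_filter <- function() {
  cached("trained_filter", gs_train_filter(train_candidates(), gs_config()))
}

# a tiny query tibble
tiny_queries <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], isoform_id = r[[2]], seq = r[[3]])
  }))
}

# brute-force ungapped alignment oracle: scalar loops, independent of the
# vectorised implementation in the package
oracle_ungapped <- function(query, predicted, mat) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  p <- strsplit(predicted, "", fixed = TRUE)[[1]]
  best <- NULL
  for (off in (-(length(q) - 1L)):(length(p) - 1L)) {
    sc <- 0; n <- 0L; id <- 0L; sim <- 0L
    for (i in seq_along(q)) {
      j <- i + off
      if (j < 1L || j > length(p)) next
      s <- mat[q[i], p[j]]
      sc <- sc + s
      n <- n + 1L
      if (q[i] == p[j]) id <- id + 1L
      if (s > 0 || q[i] == p[j]) sim <- sim + 1L
    }
    if (n == 0L) next
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, pident = 100 * id / n, psim = 100 * sim / n,
                   cov = n / length(q))
    }
  }
  best
}

# connected-components oracle for HSP grouping: explicit interval graph
oracle_regions <- function(hsps, merge_gap) {
  keys <- split(seq_len(nrow(hsps)),
                paste(hsps$gene_id, hsps$contig, hsps$strand))
  comp_spans <- list()
  for (idx in keys) {
    n <- length(idx)
    adj <- matrix(FALSE, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      ga <- hsps$start[idx[b]] - hsps$end[idx[a]]
      gb <- hsps$start[idx[a]] - hsps$end[idx[b]]
      if (max(ga, gb) < merge_gap || a == b) adj[a, b] <- TRUE
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (adj[a, b] && comp[b] != comp[a]) {
          comp[comp == comp[b]] <- comp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      sel <- idx[comp == cc]
      comp_spans[[length(comp_spans) + 1L]] <- data.frame(
        gene_id = hsps$gene_id[sel[1]], contig = hsps$contig[sel[1]],
        strand = hsps$strand[sel[1]],
        span_start = min(hsps$start[sel]), span_end = max(hsps$end[sel]),
        n_members = length(sel))
    }
  }
  out <- do.call(rbind, comp_spans)
  out[order(out$gene_id, out$contig, out$strand, out$span_start), , drop = FALSE]
}

# random HSP set generator for region-builder properties
random_hsps <- function(n, n_genes = 3, n_contigs = 2, max_pos = 500000) {
  tibble::tibble(
    gene_id = sample(sprintf("g%d", seq_len(n_genes)), n, replace = TRUE),
    isoform_id = "i1",
    contig = sample(sprintf("c%d", seq_len(n_contigs)), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = as.integer(sample.int(max_pos, n)),
    aln_len = as.integer(sample(30:500, n, replace = TRUE)),
    pident = runif(n, 30, 100),
    query_cov = runif(n),
    evalue = 0, bits = runif(n, 40, 300)
  ) |>
    dplyr::mutate(end = start + aln_len * 3L) |>
    dplyr::relocate(end, .after = start)
}
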