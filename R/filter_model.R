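# The result-filtering model: a 6 -> 4 -> 2 -> 1 dense network (leaky-ReLU
# hidden layers, sigmoid output) trained with Adam on binary cross-entropy, fed the
# six similarity/prediction/validation features, with its decision threshold
# calibrated to a sensitivity floor on the training set.

GS_FEATURES <- c("sim_pident", "sim_gene_cov", "hint_support",
                 "aln_pident", "aln_psim", "aln_gene_cov")

#' Assemble the six-feature matrix from a candidate tibble
#'
#' Fixed feature order: similarity-search percent identity and gene coverage,
#' hint support, then validation percent identity, percent similarity, and
#' gene coverage.
#'
#' @param candidates Tibble containing the columns in `GS_FEATURES`.
#' @return Numeric matrix, one row per candidate, columns in fixed order.
#' @export
assemble_features <- function(candidates) {
  missing <- setdiff(GS_FEATURES, names(candidates))
  if (length(missing)) {
    stage <- c(sim_pident = "similarity search", sim_gene_cov = "similarity search",
               hint_support = "prediction", aln_pident = "validation alignment",
               aln_psim = "validation alignment", aln_gene_cov = "validation alignment")
    abort(paste0("feature(s) missing: ", paste(missing, collapse = ", "),
                 " (", paste(unique(stage[missing]), collapse = ", "),
                 " stage incomplete)"))
  }
  x <- as.matrix(candidates[, GS_FEATURES])
  if (any(!is.finite(x)) ) {
    bad <- GS_FEATURES[apply(!is.finite(x), 2, any)]
    stage <- if ("hint_support" %in% bad) "prediction stage incomplete"
             else "pipeline stage incomplete"
    abort(paste0("non-finite feature value in ", paste(bad, collapse = ", "),
                 ": ", stage))
  }
  x
}

#' SMOTE class balancing
#'
#' Oversamples the minority class to an exact 1:1 ratio by interpolating
#' between minority examples and their k nearest minority neighbours
#' (synthetic minority oversampling). Majority examples pass through
#' unchanged. With fewer than 2 minority examples, falls back to duplication
#' with a warning.
#'
#' @param x Numeric feature matrix.
#' @param labels 0/1 vector, same length as `nrow(x)`.
#' @param seed RNG seed; results are deterministic given it.
#' @param k Number of nearest neighbours. Default 5.
#' @return List with balanced `x` and `labels` (originals first, synthetic
#'   rows appended).
#' @export
smote_balance <- function(x, labels, seed = 1L, k = 5L) {
  stopifnot(nrow(x) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  if (n1 == n0) return(list(x = x, labels = labels))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  xm <- x[labels == minority, , drop = FALSE]
  nm <- nrow(xm)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (nm < 2L) {
    warn("minority class has < 2 members; duplicating instead of interpolating")
    synth <- xm[rep(1L, need), , drop = FALSE]
  } else {
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    kk <- min(k, nm - 1L)
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(kk)]))
    base <- sample.int(nm, need, replace = TRUE)
    neigh <- vapply(base, function(b) nn[b, sample.int(kk, 1L)], integer(1))
    u <- runif(need)
    synth <- xm[base, , drop = FALSE] +
      u * (xm[neigh, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  list(x = rbind(x, synth),
       labels = c(labels, rep(minority, need)))
}

glorot_init <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), nrow = fout, ncol = fin)
}

new_filter <- function(seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  structure(list(
    W1 = glorot_init(6, 4), b1 = rep(0, 4),
    W2 = glorot_init(4, 2), b2 = rep(0, 2),
    W3 = glorot_init(2, 1), b3 = 0,
    threshold = NA_real_, seed = seed, epochs = 0L,
    loss = numeric(), features = GS_FEATURES,
    activation = c(hidden = "leaky_relu(0.01)", output = "sigmoid")
  ), class = "gs_filter")
}

# Hidden activation: leaky ReLU. With strictly non-negative features a plain
# ReLU network of this width dies readily (an unlucky init leaves every hidden
# unit inactive for the whole positive orthant, and no gradient ever flows);
# the small negative slope keeps the gradient path alive.
GS_LEAKY <- 0.01

leaky_relu <- function(z) ifelse(z > 0, z, GS_LEAKY * z)
leaky_grad <- function(z) ifelse(z > 0, 1, GS_LEAKY)

filter_forward <- function(model, x) {
  z1 <- sweep(x %*% t(model$W1), 2, model$b1, "+"); a1 <- leaky_relu(z1)
  z2 <- sweep(a1 %*% t(model$W2), 2, model$b2, "+"); a2 <- leaky_relu(z2)
  z3 <- a2 %*% t(model$W3) + model$b3
  p <- 1 / (1 + exp(-z3))
  list(z1 = z1, a1 = a1, z2 = z2, a2 = a2,
       p = pmin(pmax(as.vector(p), 1e-12), 1 - 1e-12))
}

#' Train the result-filtering network
#'
#' Trains the 4-2-1 network with minibatch Adam on binary cross-entropy.
#' Features are fed raw (their ranges are bounded by construction). Training
#' is deterministic given `config$nn_seed`.
#'
#' @param x Feature matrix from [assemble_features()] (typically after
#'   [smote_balance()]).
#' @param labels 0/1 vector.
#' @param config A [gs_config()]; uses `nn_lr`, `nn_epochs`, `nn_batch`,
#'   `nn_seed`.
#' @return A fitted `gs_filter` object (weights, per-epoch loss curve,
#'   metadata; threshold unset until [calibrate_threshold()]).
#' @export
train_filter <- function(x, labels, config = gs_config()) {
  if (nrow(x) != length(labels)) abort("feature/label length mismatch")
  if (any(!is.finite(x))) abort("non-finite feature values")
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) abort("labels must be 0/1")
  model <- new_filter(config$nn_seed)
  adam_m <- lapply(model[1:6], function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(x)
  loss <- numeric(config$nn_epochs)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$nn_seed)
  for (ep in seq_len(config$nn_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (s in seq.int(1L, n, by = config$nn_batch)) {
      ii <- idx[s:min(s + config$nn_batch - 1L, n)]
      xb <- x[ii, , drop = FALSE]; yb <- labels[ii]; nb <- length(ii)
      f <- filter_forward(model, xb)
      ep_loss <- ep_loss - sum(yb * log(f$p) + (1 - yb) * log(1 - f$p))
      d3 <- matrix((f$p - yb) / nb, ncol = 1)
      g <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
                W3 = t(d3) %*% f$a2, b3 = sum(d3))
      d2 <- (d3 %*% model$W3) * leaky_grad(f$z2)
      g$W2 <- t(d2) %*% f$a1; g$b2 <- colSums(d2)
      d1 <- (d2 %*% model$W2) * leaky_grad(f$z1)
      g$W1 <- t(d1) %*% xb; g$b1 <- colSums(d1)
      t <- t + 1L
      for (w in names(adam_m)) {
        adam_m[[w]] <- b1 * adam_m[[w]] + (1 - b1) * g[[w]]
        adam_v[[w]] <- b2 * adam_v[[w]] + (1 - b2) * g[[w]]^2
        mh <- adam_m[[w]] / (1 - b1^t)
        vh <- adam_v[[w]] / (1 - b2^t)
        model[[w]] <- model[[w]] - config$nn_lr * mh / (sqrt(vh) + eps)
      }
    }
    loss[ep] <- ep_loss / n
    if (!is.finite(loss[ep])) abort("training diverged: non-finite loss")
  }
  model$loss <- loss
  model$epochs <- config$nn_epochs
  model
}

#' Score candidates with the filter
#'
#' Forward pass of the network; strictly inside (0, 1) and deterministic.
#'
#' @param model A `gs_filter`.
#' @param x Feature matrix (or vector of length 6).
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "gs_filter"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 6L) abort("feature matrix must have 6 columns")
  if (any(!is.finite(x))) abort("non-finite feature values")
  filter_forward(model, x)$p
}

#' Calibrate the decision threshold to a sensitivity floor
#'
#' Candidate thresholds are the sorted unique predicted probabilities of the
#' training set. Sensitivity (recall of label-1 candidates at `p >=
#' threshold`) is non-increasing in the threshold, so the thresholds meeting
#' the floor form a prefix; the largest such threshold is returned — the most
#' specific operating point that still meets the sensitivity target.
#'
#' @param model A fitted `gs_filter`.
#' @param x Training feature matrix.
#' @param labels 0/1 vector.
#' @param target_sensitivity Sensitivity floor (default 0.95).
#' @return The model with `$threshold` set.
#' @export
calibrate_threshold <- function(model, x, labels, target_sensitivity = 0.95) {
  p <- predict_proba(model, x)
  model$threshold <- threshold_scan(p, labels, target_sensitivity)
  model$target_sensitivity <- target_sensitivity
  model
}

# The threshold search itself: candidate thresholds are the sorted unique
# probabilities; return the largest one whose sensitivity meets the floor.
threshold_scan <- function(probs, labels, target_sensitivity) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L) abort("calibration requires at least one positive")
  pos <- probs[labels == 1L]
  cand <- sort(unique(probs))
  ok <- vapply(cand, function(t) mean(pos >= t) >= target_sensitivity, logical(1))
  if (!any(ok)) abort("no threshold attains the target sensitivity")  # unreachable: min(pos) always qualifies
  max(cand[ok])
}

# Doubles are archived as C99 hexadecimal float literals so a restored model
# is bit-identical to the saved one (decimal JSON numbers round-trip only to
# ~16 significant digits).
num_to_hex <- function(x) sprintf("%a", as.vector(x))
hex_to_num <- function(x) as.numeric(x)

#' Serialize / restore a filter model
#'
#' The archive is JSON holding layer shapes and weights at full precision,
#' the calibrated threshold, the feature order, and training metadata, so a
#' restored model reproduces probabilities bit-identically.
#'
#' @param model A `gs_filter`.
#' @param path Output path.
#' @return `path` invisibly (`write_filter`); a `gs_filter` (`read_filter`).
#' @export
write_filter <- function(model, path) {
  stopifnot(inherits(model, "gs_filter"))
  obj <- list(
    format = "gs_filter/1",
    shapes = list(W1 = dim(model$W1), W2 = dim(model$W2), W3 = dim(model$W3)),
    weights = list(W1 = num_to_hex(model$W1), b1 = num_to_hex(model$b1),
                   W2 = num_to_hex(model$W2), b2 = num_to_hex(model$b2),
                   W3 = num_to_hex(model$W3), b3 = num_to_hex(model$b3)),
    threshold = num_to_hex(model$threshold),
    target_sensitivity = model$target_sensitivity %||% NA_real_,
    seed = model$seed, epochs = model$epochs,
    loss = model$loss, features = model$features,
    activation = as.list(model$activation)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gs_filter/1")) abort("not a gs_filter archive")
  model <- new_filter(as.integer(obj$seed))
  model$W1 <- matrix(hex_to_num(obj$weights$W1), obj$shapes$W1[1], obj$shapes$W1[2])
  model$b1 <- hex_to_num(obj$weights$b1)
  model$W2 <- matrix(hex_to_num(obj$weights$W2), obj$shapes$W2[1], obj$shapes$W2[2])
  model$b2 <- hex_to_num(obj$weights$b2)
  model$W3 <- matrix(hex_to_num(obj$weights$W3), obj$shapes$W3[1], obj$shapes$W3[2])
  model$b3 <- hex_to_num(obj$weights$b3)
  model$threshold <- hex_to_num(obj$threshold)
  model$target_sensitivity <- obj$target_sensitivity
  model$epochs <- obj$epochs
  model$loss <- obj$loss
  model
}

#' @export
print.gs_filter <- function(x, ...) {
  cat("<gs_filter> 6-4-2-1 dense network (leaky-ReLU hidden, sigmoid out)\n")
  cat("  epochs trained:", x$epochs,
      if (x$epochs > 0) paste0("(final loss ", signif(x$loss[x$epochs], 4), ")"), "\n")
  cat("  threshold:", if (is.na(x$threshold)) "uncalibrated" else signif(x$threshold, 4), "\n")
  invisible(x)
}

#' @describeIn train_filter Tidy the network weights: one row per parameter
#'   with `layer`, `parameter`, `row`, `col`, `value`.
#' @export
tidy.gs_filter <- function(x, ...) {
  one <- function(w, layer, parameter) {
    w <- as.matrix(w)
    tibble(layer = layer, parameter = parameter,
           row = as.vector(row(w)), col = as.vector(col(w)),
           value = as.vector(w))
  }
  bind_rows(one(x$W1, 1L, "weight"), one(x$b1, 1L, "bias"),
            one(x$W2, 2L, "weight"), one(x$b2, 2L, "bias"),
            one(x$W3, 3L, "weight"), one(x$b3, 3L, "bias"))
}

#' @describeIn train_filter One-row model summary (epochs, final loss,
#'   threshold, parameter count).
#' @export
glance.gs_filter <- function(x, ...) {
  tibble(epochs = x$epochs,
         final_loss = if (x$epochs > 0) x$loss[x$epochs] else NA_real_,
         threshold = x$threshold,
         n_parameters = length(x$W1) + length(x$b1) + length(x$W2) +
           length(x$b2) + length(x$W3) + 1L,
         seed = x$seed)
}

#' @describeIn train_filter Training-loss curve.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.gs_filter <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = "Result-filter training loss") +
    ggplot2::theme_minimal()
}
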