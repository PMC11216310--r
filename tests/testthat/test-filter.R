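sep_set <- function(npos = 40, nneg = 40, seed = 42) {
  set.seed(seed)
  pos <- matrix(rep(c(100, 1, 100, 100, 100, 1), each = npos), npos) +
    matrix(rnorm(npos * 6, 0, 2), npos)
  neg <- matrix(rep(c(20, 0.1, 0, 20, 25, 0.1), each = nneg), nneg) +
    matrix(rnorm(nneg * 6, 0, 2), nneg)
  x <- abs(rbind(pos, neg))
  colnames(x) <- genescout:::GS_FEATURES
  list(x = x, y = c(rep(1L, npos), rep(0L, nneg)))
}

test_that("feature assembly enforces the fixed order and completeness", {
  cand <- tibble::tibble(sim_pident = 92.5, sim_gene_cov = 0.8,
                         hint_support = 75, aln_pident = 90, aln_psim = 95,
                         aln_gene_cov = 0.85, extra = 1)
  x <- assemble_features(cand)
  expect_equal(as.numeric(x), c(92.5, 0.8, 75, 90, 95, 0.85))
  expect_equal(colnames(x), genescout:::GS_FEATURES)

  expect_error(assemble_features(dplyr::select(cand, -hint_support)),
               "prediction")
  cand$hint_support <- NA_real_
  expect_error(assemble_features(cand), "prediction stage incomplete")
})

test_that("SMOTE yields an exact 1:1 ratio with originals unchanged", {
  s <- sep_set(10, 40)
  bal <- smote_balance(s$x, s$y, seed = 3)
  expect_equal(sum(bal$labels == 1), sum(bal$labels == 0))
  expect_equal(bal$x[1:50, ], s$x)
  # synthetic rows are convex combinations: inside the minority bounding box
  synth <- bal$x[-(1:50), , drop = FALSE]
  xm <- s$x[s$y == 1, ]
  expect_true(all(t(synth) >= apply(xm, 2, min) - 1e-9))
  expect_true(all(t(synth) <= apply(xm, 2, max) + 1e-9))
  # determinism
  bal2 <- smote_balance(s$x, s$y, seed = 3)
  expect_identical(bal, bal2)

  # already balanced: untouched
  expect_identical(smote_balance(s$x[1:20, ], c(rep(1, 10), rep(0, 10)),
                                 seed = 1)$x,
                   s$x[1:20, ])

  one <- rbind(s$x[1, , drop = FALSE], s$x[11:50, ])
  expect_warning(b1 <- smote_balance(one, c(1, rep(0, 40)), seed = 1),
                 "duplicating")
  expect_equal(sum(b1$labels == 1), 40)
  expect_error(smote_balance(s$x[1:10, ], rep(1, 10), seed = 1), "both classes")
})

test_that("an untrained zero-weight network outputs probability one half", {
  m <- genescout:::new_filter(seed = 1)
  for (w in c("W1", "b1", "W2", "b2", "W3", "b3")) m[[w]] <- m[[w]] * 0
  expect_equal(predict_proba(m, c(50, 0.5, 50, 50, 50, 0.5)), 0.5)
  expect_error(predict_proba(m, c(NaN, 0.5, 50, 50, 50, 0.5)), "non-finite")
})

test_that("training separates a wide-margin synthetic set", {
  s <- sep_set()
  model <- train_filter(s$x, s$y, gs_config())
  p <- predict_proba(model, s$x)
  expect_gte(mean((p > 0.5) == (s$y == 1)), 0.9)
  expect_gt(predict_proba(model, s$x[1, ]), 0.5)
  # average loss decreases over checkpoints
  ck <- model$loss[seq(1, model$epochs, length.out = 10)]
  expect_lt(mean(diff(ck)), 0)
  # reproducibility under the same seed
  model2 <- train_filter(s$x, s$y, gs_config())
  expect_identical(model$W1, model2$W1)

  expect_error(train_filter(s$x, s$y[-1], gs_config()), "mismatch")
  bad <- s$x; bad[1, 1] <- NaN
  expect_error(train_filter(bad, s$y, gs_config()), "non-finite")
})

test_that("threshold calibration picks the largest admissible threshold", {
  scan <- genescout:::threshold_scan
  # 3 positives, sensitivity floor 0.95: dropping any positive gives 2/3
  expect_equal(scan(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 1, 0), 0.95), 0.2)
  # at 0.8 sensitivity is 1.0; at 0.9 it falls to 0.5
  expect_equal(scan(c(0.9, 0.8, 0.5), c(1, 1, 0), 0.95), 0.8)
  expect_equal(scan(c(0.3), c(1), 0.95), 0.3)
  expect_error(scan(c(0.4, 0.2), c(0, 0), 0.95), "positive")

  # end-to-end: the calibrated threshold of a real model meets the floor and
  # the next larger candidate threshold violates it
  s <- sep_set(12, 60, seed = 9)
  model <- train_filter(s$x, s$y, gs_config())
  model <- calibrate_threshold(model, s$x, s$y, target_sensitivity = 0.95)
  p <- predict_proba(model, s$x)
  pos <- p[s$y == 1]
  expect_gte(mean(pos >= model$threshold), 0.95)
  larger <- sort(unique(p))[sort(unique(p)) > model$threshold]
  if (length(larger)) expect_lt(mean(pos >= larger[1]), 0.95)
})

test_that("serialized models reproduce probabilities bit-identically", {
  s <- sep_set(15, 30, seed = 2)
  model <- calibrate_threshold(train_filter(s$x, s$y, gs_config()),
                               s$x, s$y, 0.95)
  path <- withr::local_tempfile(fileext = ".json")
  write_filter(model, path)
  back <- read_filter(path)
  expect_identical(predict_proba(back, s$x), predict_proba(model, s$x))
  expect_identical(back$threshold, model$threshold)
  # tidy/glance surface the architecture
  td <- tidy(model)
  expect_equal(sum(td$parameter == "weight"), 6 * 4 + 4 * 2 + 2)
  expect_equal(glance(model)$n_parameters, 34 + 7)  # 24+8+2 weights, 4+2+1 biases
})
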