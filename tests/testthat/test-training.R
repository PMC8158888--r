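# Tiny problem sizes keep these runs to seconds; the scaled-up miniature
# study lives in the acceptance suite.

tiny_cases <- function(n, seed = 1) {
  generate_dataset(n, phantom_spec(shape = c(24L, 24L, 16L), seed = seed))
}

tiny_tcfg <- function(...) {
  train_config(learning_rate = 1e-3, min_pancreas_pixels = 10L, ...)
}

test_that("fold assignment partitions cases evenly and deterministically", {
  f <- assign_folds(82, 4, seed = 3)
  expect_length(f, 82)
  expect_setequal(unique(f), 1:4)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_identical(f, assign_folds(82, 4, seed = 3))
  expect_false(identical(f, assign_folds(82, 4, seed = 4)))

  f8 <- assign_folds(8, 4, seed = 1)
  expect_equal(as.integer(table(f8)), rep(2L, 4))
  expect_error(assign_folds(3, 4), "more folds")
})

test_that("training is seeded, finite, and splits validation slices aside", {
  cases <- tiny_cases(3, seed = 400)
  cfg <- tiny_tcfg(epochs = 2, seed = 11)
  mcfg <- tiny_model_cfg()
  r1 <- train_stage(cases, "axial", cfg, mcfg, stage = "coarse")
  r2 <- train_stage(cases, "axial", cfg, mcfg, stage = "coarse")
  expect_identical(r1$history, r2$history)
  expect_true(all(is.finite(as.matrix(r1$history[, -1]))))

  # the validation split takes 10% of qualifying slices (rounded, >= 1)
  istacks <- lapply(cases, function(cs) extract_slices(cs$image, "axial"))
  mstacks <- lapply(cases, function(cs) extract_slices(cs$mask, "axial"))
  n_slices <- sum(mapply(function(i, m)
    length(filter_training_slices(i, m, cfg$min_pancreas_pixels)),
    istacks, mstacks))
  expect_equal(r1$n_val, max(1, round(0.10 * n_slices)))
  expect_equal(r1$n_train + r1$n_val, n_slices)

  expect_error(train_stage(cases, "axial",
                           train_config(epochs = 1, learning_rate = 1e-3,
                                        min_pancreas_pixels = 10000L),
                           mcfg),
               "no qualifying")
})

test_that("a short run on separable phantoms reduces validation loss", {
  cases <- tiny_cases(4, seed = 500)
  cfg <- tiny_tcfg(epochs = 3, seed = 2)
  r <- train_stage(cases, "axial", cfg, tiny_model_cfg(), stage = "coarse")
  expect_lt(r$history$val_loss[nrow(r$history)], r$history$val_loss[1])
})

test_that("cross-validation tests every case exactly once", {
  cases <- tiny_cases(4, seed = 600)
  cfg <- tiny_tcfg(epochs = 1, seed = 5, folds = 2)
  cv <- cross_validate(cases, cfg, tiny_model_cfg(), stage = "coarse")
  expect_length(cv$scores, 4)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_setequal(unique(cv$assignment), 1:2)
  expect_length(cv$fold_summaries, 2)
  expect_equal(sum(vapply(cv$fold_summaries, `[[`, numeric(1), "n_cases")), 4)
  expect_equal(cv$pooled$n_cases, 4)
  expect_error(cross_validate(cases, tiny_tcfg(folds = 5), tiny_model_cfg()),
               "more folds")
})

test_that("cascade training wires coarse and fine stages together", {
  cases <- tiny_cases(3, seed = 700)
  cfg <- tiny_tcfg(epochs = 1, seed = 9)
  tc <- train_cascade(cases, cfg, tiny_model_cfg(), margin = 3)
  expect_named(tc$coarse, c("sagittal", "coronal", "axial"))
  expect_named(tc$fine, c("sagittal", "coronal", "axial"))
  expect_length(tc$histories, 6)
  sc <- evaluate_pipeline(tc$coarse, tc$fine, cases[1], margin = 3)
  expect_true(sc >= 0 && sc <= 1)
})
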