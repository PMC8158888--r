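test_that("dsc matches direct counting and its symmetry properties", {
  a <- array(0, c(5, 4, 3))
  a[1:10] <- 1
  expect_equal(dsc(a, a), 1)

  b <- array(0, c(5, 4, 3))
  b[11:15] <- 1
  a2 <- array(0, c(5, 4, 3))
  a2[1:5] <- 1
  expect_equal(dsc(a2, b), 0)

  # |A|=4, |B|=6, |A intersect B|=3 -> 0.6
  x <- array(0, c(4, 3, 1)); x[c(1, 2, 3, 4)] <- 1
  y <- array(0, c(4, 3, 1)); y[c(2, 3, 4, 7, 8, 9)] <- 1
  expect_equal(dsc(x, y), 0.6)
  expect_equal(dsc(y, x), 0.6)

  expect_equal(dsc(array(0, c(3, 3, 3)), array(0, c(3, 3, 3))), 1)
  expect_error(dsc(array(0, c(3, 3, 3)), array(0, c(3, 3, 2))), "shape")
  expect_error(dsc(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 2))), "binary")

  for (seed in 1:20) {
    m1 <- rand_mask(c(6, 5, 4), p = runif(1, 0.1, 0.6), seed = seed)
    m2 <- rand_mask(c(6, 5, 4), p = runif(1, 0.1, 0.6), seed = seed + 1000)
    expect_equal(dsc(m1, m2), dsc_loop(m1$data, m2$data))
    expect_equal(dsc(m1, m2), dsc(m2, m1))
  }
})

test_that("dice loss is the soft complement of the overlap", {
  y <- array(0, c(6, 6)); y[2:4, 2:4] <- 1
  expect_lt(dice_loss(y, y), 1e-5)
  expect_gt(dice_loss(y, y * 0), 1 - 1e-5)

  # the hard-count example: soft loss on binary maps = 1 - dsc
  x <- array(0, c(4, 3, 1)); x[1:4] <- 1
  p <- array(0, c(4, 3, 1)); p[c(2, 3, 4, 7, 8, 9)] <- 1
  expect_equal(dice_loss(x, p), 1 - 0.6, tolerance = 1e-6)

  for (seed in 1:5) {
    m1 <- rand_mask(c(5, 5, 2), seed = seed)
    m2 <- rand_mask(c(5, 5, 2), seed = seed + 77)
    expect_equal(dice_loss(m1$data, m2$data), 1 - dsc(m1, m2),
                 tolerance = 1e-5)
  }
  expect_error(dice_loss(y, matrix(0.5, 3, 3)), "shape")
  expect_error(dice_loss(y, y * 2), "\\[0,1\\]")
})

test_that("score summaries report exact order-invariant statistics", {
  s <- summarize_scores(c(0.8, 0.9))
  expect_equal(s$mean, 0.85)
  expect_equal(s$max, 0.9)
  expect_equal(s$min, 0.8)
  expect_equal(s$std, 0.05)  # population sd
  expect_equal(s$n_cases, 2)

  one <- summarize_scores(0.73)
  expect_equal(one$mean, 0.73)
  expect_equal(one$std, 0)
  expect_equal(one$min, one$max)

  set.seed(4)
  sc <- runif(9)
  expect_equal(summarize_scores(sc), summarize_scores(sample(sc)))
  expect_equal(summarize_scores(c(0.4, 0.6), sd_type = "sample")$std,
               stats::sd(c(0.4, 0.6)))
  expect_error(summarize_scores(numeric(0)), "empty")
  expect_error(summarize_scores(c(0.5, 1.2)))
})

test_that("DSC histogram uses a closed first bin and half-open-left bins", {
  h <- dsc_histogram(c(0.5))
  expect_equal(unname(h$fractions[1]), 100)
  h2 <- dsc_histogram(c(0.55, 0.55))
  expect_equal(unname(h2$fractions[2]), 100)
  h3 <- dsc_histogram(c(1.0))
  expect_equal(unname(h3$fractions[6]), 100)
  h4 <- dsc_histogram(c(0))
  expect_equal(unname(h4$fractions[1]), 100)

  set.seed(10)
  h5 <- dsc_histogram(runif(123))
  expect_equal(sum(h5$fractions), 100, tolerance = 1e-9)
  expect_error(dsc_histogram(c(0.5, 1.1)), "\\[0,1\\]")
})

test_that("evaluation reports are written as CSV + JSON", {
  dir <- file.path(tempdir(), "evalrep")
  write_evaluation(c(case_a = 0.8, case_b = 0.92), dir)
  csv <- utils::read.csv(file.path(dir, "per_case_dsc.csv"))
  expect_equal(csv$dsc, c(0.8, 0.92))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$mean, 0.86, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "histogram.json")))
})
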