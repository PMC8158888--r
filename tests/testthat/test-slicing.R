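test_that("slice extraction follows the axis naming convention", {
  v <- rand_volume(c(10, 12, 14), seed = 7)
  ax <- extract_slices(v, "axial")
  expect_length(ax$slices, 14)
  expect_equal(dim(ax$slices[[1]]), c(10L, 12L))
  expect_length(extract_slices(v, "sagittal")$slices, 10)
  expect_length(extract_slices(v, "coronal")$slices, 12)
  expect_error(extract_slices(v, "oblique"))
})

test_that("extract/stack is an exact bijection on all three axes", {
  for (seed in 1:8) {
    set.seed(seed)
    shp <- sample(5:17, 3, replace = TRUE)
    v <- rand_volume(shp, seed = seed + 100)
    for (ax in c("sagittal", "coronal", "axial")) {
      back <- stack_to_volume(extract_slices(v, ax))
      expect_identical(back$data, v$data)
    }
  }
})

test_that("2.5D inputs replicate end slices and stack neighbours inside", {
  v <- rand_volume(c(8, 9, 10), seed = 3)
  st <- extract_slices(v, "axial")
  n <- length(st$slices)

  first <- make_input25d(st, 1)
  expect_equal(first[, , 1], st$slices[[1]])
  expect_equal(first[, , 2], st$slices[[1]])
  expect_equal(first[, , 3], st$slices[[1]])

  last <- make_input25d(st, n)
  for (ch in 1:3) expect_equal(last[, , ch], st$slices[[n]])

  mid <- make_input25d(st, 4)
  expect_equal(mid[, , 1], st$slices[[3]])
  expect_equal(mid[, , 2], st$slices[[4]])
  expect_equal(mid[, , 3], st$slices[[5]])

  for (i in seq_len(n)) {
    expect_equal(make_input25d(st, i)[, , 2], st$slices[[i]])
  }
  expect_error(make_input25d(st, 0), "out of range")
  expect_error(make_input25d(st, n + 1), "out of range")
})

test_that("stack_to_volume validates inputs and resizes predictions back", {
  v <- rand_volume(c(8, 8, 6), seed = 1)
  st <- extract_slices(v, "axial")
  expect_error(stack_to_volume(st$slices[1:3], "axial", c(8, 8, 6)),
               "slice count")

  ones <- replicate(6, matrix(1, 8, 8), simplify = FALSE)
  out <- stack_to_volume(ones, "axial", c(8, 8, 6))
  expect_equal(out$data, array(1, c(8, 8, 6)))

  # network-resolution binary maps come back binary at native resolution
  preds <- replicate(6, matrix((stats::runif(16) > 0.5) * 1, 4, 4),
                     simplify = FALSE)
  rec <- stack_to_volume(preds, "axial", c(8, 8, 6), is_mask = TRUE)
  expect_equal(dim(rec$data), c(8L, 8L, 6L))
  expect_true(all(rec$data %in% c(0, 1)))
})

test_that("slice filter applies a strict foreground threshold", {
  arr <- array(0, c(20, 20, 3))
  arr[, , 1][seq_len(100)] <- 1   # exactly 100 pixels: excluded
  arr[, , 2][seq_len(101)] <- 1   # 101 pixels: included
  mask <- volume(arr, is_mask = TRUE)
  img <- rand_volume(c(20, 20, 3), seed = 9)
  idx <- filter_training_slices(extract_slices(img, "axial"),
                                extract_slices(mask, "axial"),
                                min_pixels = 100)
  expect_identical(idx, 2L)

  empty <- volume(array(0, c(20, 20, 3)), is_mask = TRUE)
  expect_length(filter_training_slices(extract_slices(img, "axial"),
                                       extract_slices(empty, "axial"), 100),
                0)

  # brute-force recount oracle on random stacks
  for (seed in 1:5) {
    m <- rand_mask(c(12, 11, 9), p = 0.35, seed = seed)
    im <- rand_volume(c(12, 11, 9), seed = seed + 50)
    for (ax in c("sagittal", "coronal", "axial")) {
      ms <- extract_slices(m, ax)
      got <- filter_training_slices(extract_slices(im, ax), ms, 30)
      counts <- vapply(ms$slices, sum, numeric(1))
      expect_identical(got, which(counts > 30))
      expect_false(is.unsorted(got))
      expect_true(all(counts[setdiff(seq_along(counts), got)] <= 30))
    }
  }

  bad <- extract_slices(rand_volume(c(12, 11, 8)), "axial")
  good <- extract_slices(rand_volume(c(12, 11, 9)), "axial")
  expect_error(filter_training_slices(good, bad, 10), "misaligned")
})
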