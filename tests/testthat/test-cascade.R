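test_that("majority-vote fusion agrees with enumeration of all vote patterns", {
  # all 8 binary vote combinations, one voxel each
  combos <- expand.grid(s = 0:1, a = 0:1, c = 0:1)
  preds <- list(
    sagittal = array(combos$s, c(8, 1, 1)),
    axial    = array(combos$a, c(8, 1, 1)),
    coronal  = array(combos$c, c(8, 1, 1))
  )
  fused <- fuse_views(preds)
  oracle <- as.numeric(rowSums(combos) >= 2)
  expect_equal(as.numeric(fused$data), oracle)

  # probabilities binarize at 0.5 before voting; (1,1,0) -> 1, (1,0,0) -> 0
  p2 <- list(sagittal = array(0.9, c(1, 1, 1)),
             coronal = array(0.51, c(1, 1, 1)),
             axial = array(0.49, c(1, 1, 1)))
  expect_equal(as.numeric(fuse_views(p2)$data), 1)
  p3 <- list(sagittal = array(0.9, c(1, 1, 1)),
             coronal = array(0.2, c(1, 1, 1)),
             axial = array(0.1, c(1, 1, 1)))
  expect_equal(as.numeric(fuse_views(p3)$data), 0)
})

test_that("fusion is permutation-invariant and shape-checked", {
  set.seed(6)
  ps <- lapply(1:3, function(i) array(runif(6 * 5 * 4), c(6, 5, 4)))
  f1 <- fuse_views(list(sagittal = ps[[1]], coronal = ps[[2]], axial = ps[[3]]))
  f2 <- fuse_views(list(sagittal = ps[[3]], coronal = ps[[1]], axial = ps[[2]]))
  expect_identical(f1$data, f2$data)
  expect_error(fuse_views(list(sagittal = ps[[1]], coronal = ps[[2]],
                               axial = array(0, c(6, 5, 3)))), "shape")
  expect_error(fuse_views(list(a = ps[[1]])), "named list")
})

test_that("coarse bounding boxes frame the mask and clip to the volume", {
  m <- array(0, c(100, 100, 100))
  m[11, 21, 31] <- 1   # voxel (10, 20, 30) in 0-based coordinates
  box <- coarse_bbox(volume(m, is_mask = TRUE), margin = 5)
  expect_equal(box$lo, c(5L, 15L, 25L))
  expect_equal(box$hi, c(16L, 26L, 36L))

  m2 <- array(0, c(30, 30, 30))
  m2[1, 1, 1] <- 1
  box2 <- coarse_bbox(volume(m2, is_mask = TRUE), margin = 5)
  expect_equal(box2$lo, c(0L, 0L, 0L))
  expect_equal(box2$hi, c(6L, 6L, 6L))

  expect_error(coarse_bbox(volume(array(0, c(5, 5, 5)), is_mask = TRUE)),
               "empty")
})

test_that("crop and stitch are inverse around the box", {
  v <- rand_volume(c(100, 100, 100), seed = 31)
  m <- array(0, c(100, 100, 100))
  m[11, 21, 31] <- 1
  box <- coarse_bbox(volume(m, is_mask = TRUE), margin = 5)
  crop <- crop_volume(v, box)
  expect_equal(dim(crop$data), c(11L, 11L, 11L))
  expect_equal(crop$data[1, 1, 1], v$data[6, 16, 26])

  fine <- volume((crop$data > 0) * 1, is_mask = TRUE)
  full <- stitch_volume(fine, box, c(100, 100, 100))
  expect_equal(sum(full$data), sum(fine$data))
  expect_equal(full$data[6:16, 16:26, 26:36], fine$data)
  full$data[6:16, 16:26, 26:36] <- 0
  expect_equal(sum(full$data), 0)

  whole <- structure(list(lo = c(0L, 0L, 0L), hi = c(100L, 100L, 100L),
                          margin = 0L), class = "bounding_box")
  expect_identical(crop_volume(v, whole)$data, v$data)
  expect_error(stitch_volume(volume(array(1, c(3, 3, 3)), is_mask = TRUE),
                             box, c(100, 100, 100)), "shape")
  bad <- structure(list(lo = c(95L, 0L, 0L), hi = c(105L, 5L, 5L),
                        margin = 0L), class = "bounding_box")
  expect_error(crop_volume(v, bad), "bounds")
})

test_that("largest_component keeps the dominant blob", {
  m <- array(0, c(20, 20, 20))
  m[2:6, 2:6, 2:6] <- 1       # 125 voxels
  m[15:16, 15:16, 15:16] <- 1 # 8 voxels
  lc <- largest_component(volume(m, is_mask = TRUE))
  expect_equal(sum(lc$data), 125)
  expect_equal(sum(lc$data[2:6, 2:6, 2:6]), 125)
  expect_equal(count_components_loop(m), 2)
  expect_equal(count_components_loop(lc$data), 1)
})

test_that("the cascade reproduces ground truth with oracle models", {
  ph <- generate_phantom(small_phantom_spec(seed = 77))
  om <- oracle_model(ph$mask)
  models <- list(sagittal = om, coronal = om, axial = om)
  out <- run_pipeline(ph$image, models, models, margin = 4)
  expect_identical(out$data, ph$mask$data)
  expect_true(all(out$data %in% c(0, 1)))
  expect_equal(dim(out$data), dim(ph$image$data))

  # foreground is confined to the crop box
  box <- out$box
  expect_false(is.null(box))
  inside <- array(0, dim(out$data))
  inside[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
         (box$lo[3] + 1):box$hi[3]] <- 1
  expect_equal(sum(out$data * (1 - inside)), 0)
})

test_that("an empty coarse mask falls back to a whole-volume fine stage", {
  ph <- generate_phantom(small_phantom_spec(seed = 78))
  empty <- oracle_model(volume(array(0, dim(ph$mask$data)), is_mask = TRUE))
  truth <- oracle_model(ph$mask)
  none <- list(sagittal = empty, coronal = empty, axial = empty)
  good <- list(sagittal = truth, coronal = truth, axial = truth)
  expect_warning(out <- run_pipeline(ph$image, none, good, margin = 4),
                 "whole volume")
  expect_identical(out$data, ph$mask$data)
  expect_null(out$box)
})
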