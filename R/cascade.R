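# Coarse-to-fine orchestration: each stage runs one model per anatomical
# view, per-view probability volumes are binarized and fused by per-voxel
# majority vote, and the fused coarse mask defines a framed crop for the
# fine stage.

VIEW_NAMES <- c("sagittal", "coronal", "axial")

#' Predict a per-view probability volume
#'
#' Cuts the volume into slices along `axis`, resizes each slice to the
#' model's input size, builds the 3-adjacent-slice 2.5D input for every
#' index, and reassembles the per-slice probability maps at native in-plane
#' resolution (bilinear) into a probability volume.
#'
#' @param model A `seg_model` (or an [oracle_model] in tests).
#' @param v Image [volume] on the 0..255 preprocessing scale.
#' @param axis View name.
#' @return A [volume] of foreground probabilities (not a mask).
#' @export
predict_volume <- function(model, v, axis) UseMethod("predict_volume")

#' @export
predict_volume.seg_model <- function(model, v, axis) {
  v <- as_volume(v)
  stack <- extract_slices(v, axis)
  insz <- model$config$in_size
  rstack <- stack
  rstack$slices <- lapply(stack$slices, resize_slice, target = insz, is_mask = FALSE)
  probs <- vector("list", length(rstack$slices))
  for (i in seq_along(probs)) {
    probs[[i]] <- predict_slice(model, make_input25d(rstack, i))
  }
  out <- stack_to_volume(probs, axis, dim(v$data), is_mask = FALSE)
  out$data <- pmin(pmax(out$data, 0), 1)  # bilinear resize can overshoot ends
  out
}

#' Ground-truth oracle model
#'
#' A stand-in "model" that emits its stored ground-truth mask as the
#' prediction for any view — used to test pipeline plumbing independently of
#' training. When asked to predict on a cropped volume (one produced by
#' [crop_volume], which records its source box), the stored mask is cropped
#' the same way.
#'
#' @param mask Ground-truth mask [volume].
#' @return An object of class `oracle_model`.
#' @export
oracle_model <- function(mask) {
  mask <- as_volume(mask, is_mask = TRUE)
  structure(list(mask = mask), class = "oracle_model")
}

#' @export
predict_volume.oracle_model <- function(model, v, axis) {
  m <- model$mask
  v <- as_volume(v)
  if (!is.null(v$origin)) m <- crop_volume(m, v$origin)
  if (!all(dim(m$data) == dim(v$data))) stop("oracle mask shape mismatch")
  volume(m$data, is_mask = FALSE)
}

.check_views <- function(x, what = "models") {
  if (!is.list(x) || !all(VIEW_NAMES %in% names(x))) {
    stop(what, " must be a named list with elements sagittal, coronal, axial")
  }
  x[VIEW_NAMES]
}

#' Fuse three per-view predictions by majority vote
#'
#' Each view's probability volume is binarized at 0.5, the three binary
#' votes are averaged per voxel, and a voxel is foreground iff its mean vote
#' is `>= vote_threshold` (default 0.5, i.e. at least 2 of 3 views).
#'
#' @param preds Named list (`sagittal`, `coronal`, `axial`) of probability
#'   volumes/arrays of identical shape.
#' @param vote_threshold Fraction of views required.
#' @return Binary mask [volume].
#' @export
fuse_views <- function(preds, vote_threshold = 0.5) {
  preds <- .check_views(preds, "preds")
  arrs <- lapply(preds, function(p) if (inherits(p, "volume")) p$data else p)
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1)))) {
    stop("per-view predictions must share one shape")
  }
  votes <- (arrs[[1]] >= 0.5) + (arrs[[2]] >= 0.5) + (arrs[[3]] >= 0.5)
  volume((votes / 3 >= vote_threshold) * 1, is_mask = TRUE)
}

#' Framed bounding box of a coarse mask
#'
#' The tight foreground bounding box, expanded by `margin` voxels per side
#' (the safety frame filled with original image intensities once cropped)
#' and clipped to the volume bounds. Coordinates are 0-based, half-open:
#' `lo` inclusive, `hi` exclusive.
#'
#' @param mask Nonempty binary mask [volume].
#' @param margin Frame width in voxels per side.
#' @return An object of class `bounding_box` with `lo`, `hi`, `margin`.
#' @export
coarse_bbox <- function(mask, margin = 20L) {
  mask <- as_volume(mask, is_mask = TRUE)
  if (sum(mask$data) == 0) {
    stop("empty coarse mask: fall back to a whole-volume fine stage")
  }
  shp <- dim(mask$data)
  idx <- which(mask$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - 1L - margin, 0L)
  hi <- pmin(apply(idx, 2L, max) + margin, shp)  # max is 1-based -> exclusive 0-based is max
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 margin = as.integer(margin)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> lo (%s) hi (%s), margin %d\n",
              paste(x$lo, collapse = ","), paste(x$hi, collapse = ","), x$margin))
  invisible(x)
}

#' Crop a volume to a bounding box
#'
#' The crop records its source box in the result's `origin` field, so
#' downstream consumers (and [oracle_model]) know where it came from.
#'
#' @param v A [volume].
#' @param box A `bounding_box` within the volume's bounds.
#' @return The cropped [volume] of shape `hi - lo`.
#' @export
crop_volume <- function(v, box) {
  v <- as_volume(v)
  stopifnot(inherits(box, "bounding_box"))
  shp <- dim(v$data)
  if (any(box$lo < 0L) || any(box$hi > shp) || any(box$lo >= box$hi)) {
    stop("bounding box out of volume bounds")
  }
  out <- volume(v$data[(box$lo[1] + 1):box$hi[1],
                       (box$lo[2] + 1):box$hi[2],
                       (box$lo[3] + 1):box$hi[3], drop = FALSE],
                spacing = v$spacing, is_mask = v$is_mask)
  out$origin <- box
  out
}

#' Place a fine-stage mask back into the full volume
#'
#' @param fine_mask Mask [volume] with the box's shape.
#' @param box The `bounding_box` that produced the crop.
#' @param full_shape Length-3 shape of the full volume.
#' @return Full-shape mask [volume], zero outside the box.
#' @export
stitch_volume <- function(fine_mask, box, full_shape) {
  fine_mask <- as_volume(fine_mask, is_mask = TRUE)
  full_shape <- as.integer(full_shape)
  if (!all(dim(fine_mask$data) == (box$hi - box$lo))) {
    stop("fine mask shape does not match the bounding box")
  }
  out <- array(0, dim = full_shape)
  out[(box$lo[1] + 1):box$hi[1],
      (box$lo[2] + 1):box$hi[2],
      (box$lo[3] + 1):box$hi[3]] <- fine_mask$data
  volume(out, is_mask = TRUE)
}

#' Largest 6-connected foreground component of a mask
#'
#' Used to localize the organ robustly: stray false-positive voxels far from
#' the organ would otherwise inflate the coarse bounding box to most of the
#' volume.
#'
#' @param mask Binary mask [volume].
#' @return Mask [volume] keeping only the largest component (the input if it
#'   is empty).
#' @export
largest_component <- function(mask) {
  mask <- as_volume(mask, is_mask = TRUE)
  if (sum(mask$data) == 0) return(mask)
  lab <- .cpp_label6(mask$data, dim(mask$data))
  counts <- tabulate(lab[lab > 0])
  volume((lab == which.max(counts)) * 1, spacing = mask$spacing, is_mask = TRUE)
}

.predict_fused <- function(models, v, vote_threshold) {
  preds <- lapply(VIEW_NAMES, function(ax) predict_volume(models[[ax]], v, ax))
  names(preds) <- VIEW_NAMES
  fuse_views(preds, vote_threshold)
}

#' Run the full coarse-to-fine cascade on one volume
#'
#' Coarse per-view prediction and majority-vote fusion localize the organ;
#' the fused mask's framed bounding box crops the image; the fine models
#' segment the crop per view, are fused again, and the result is stitched
#' back to full shape. An empty coarse mask triggers a whole-volume fine
#' stage with a warning.
#'
#' @param v Image [volume] (0..255 scale).
#' @param coarse_models,fine_models Named lists (`sagittal`, `coronal`,
#'   `axial`) of models.
#' @param margin Safety frame width in voxels (default 20).
#' @param vote_threshold Majority-vote fraction (default 0.5).
#' @param localize `"largest_component"` (default) restricts the bounding
#'   box to the largest 6-connected component of the fused coarse mask, so
#'   isolated false positives cannot inflate the crop; `"full_mask"` boxes
#'   every coarse foreground voxel.
#' @return Binary mask [volume] of the input's shape, with the used
#'   `bounding_box` (or `NULL`) attached as field `box`.
#' @export
run_pipeline <- function(v, coarse_models, fine_models, margin = 20L,
                         vote_threshold = 0.5,
                         localize = c("largest_component", "full_mask")) {
  localize <- match.arg(localize)
  v <- as_volume(v)
  coarse_models <- .check_views(coarse_models, "coarse_models")
  fine_models <- .check_views(fine_models, "fine_models")
  coarse_mask <- .predict_fused(coarse_models, v, vote_threshold)
  shp <- dim(v$data)
  if (sum(coarse_mask$data) == 0) {
    warning("empty coarse mask; running the fine stage on the whole volume")
    box <- NULL
    crop <- v
  } else {
    loc_mask <- if (localize == "largest_component") {
      largest_component(coarse_mask)
    } else coarse_mask
    box <- coarse_bbox(loc_mask, margin = margin)
    crop <- crop_volume(v, box)
  }
  fine_mask <- .predict_fused(fine_models, crop, vote_threshold)
  out <- if (is.null(box)) fine_mask else stitch_volume(fine_mask, box, shp)
  out$box <- box
  out
}
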