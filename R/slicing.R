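#' @keywords internal
.axis_num <- function(axis) {
  switch(match.arg(axis, c("sagittal", "coronal", "axial")),
         sagittal = 1L,  # fix width index
         coronal  = 2L,  # fix height index
         axial    = 3L)  # fix depth index
}

#' Decompose a volume into slices along one anatomical axis
#'
#' Axis semantics over the `(width, height, depth)` array order: `axial`
#' fixes the depth index, `coronal` the height index, `sagittal` the width
#' index. The stack carries the recipe ([stack_to_volume]) to reassemble the
#' volume exactly.
#'
#' @param v A [volume] (or 3D array).
#' @param axis One of `"sagittal"`, `"coronal"`, `"axial"`.
#' @return An object of class `slice_stack`: list of 2D matrices `slices`,
#'   the `axis`, the original `source_shape`, and `is_mask`.
#' @export
extract_slices <- function(v, axis) {
  v <- as_volume(v)
  a <- .axis_num(axis)
  shp <- dim(v$data)
  n <- shp[a]
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    s <- switch(a, v$data[i, , ], v$data[, i, ], v$data[, , i])
    slices[[i]] <- as.matrix(s)
  }
  structure(list(slices = slices,
                 axis = match.arg(axis, c("sagittal", "coronal", "axial")),
                 source_shape = shp, is_mask = v$is_mask),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d %s slices of %s (source %s)\n",
              length(x$slices), x$axis,
              paste(dim(x$slices[[1]]), collapse = "x"),
              paste(x$source_shape, collapse = "x")))
  invisible(x)
}

#' Build a 3-channel 2.5D input from adjacent slices
#'
#' The input for slice `i` stacks its neighbours as channels in the order
#' (previous, current, next). At the stack boundaries (`i = 1` or `i = n`)
#' the end slice is replicated three times rather than zero-padded.
#'
#' @param stack A `slice_stack`.
#' @param i Slice index, `1 <= i <= n`.
#' @return An `(H, W, 3)` array of class `input25d`.
#' @export
make_input25d <- function(stack, i) {
  stopifnot(inherits(stack, "slice_stack"))
  n <- length(stack$slices)
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    stop("slice index out of range (1..", n, ")")
  }
  idx <- if (i == 1L || i == n) c(i, i, i) else c(i - 1L, i, i + 1L)
  d <- dim(stack$slices[[i]])
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3) out[, , ch] <- stack$slices[[idx[ch]]]
  structure(out, class = c("input25d", class(out)))
}

#' Reassemble per-slice 2D maps into a volume
#'
#' Inverse of [extract_slices]. If slice shapes differ from the source's
#' in-plane shape (e.g. network-resolution predictions), each map is resized
#' back to native resolution first — bilinear for continuous maps, nearest
#' for masks — because evaluation is defined on the full-resolution 3D
#' volume. If shapes already match, values pass through untouched, so
#' `stack_to_volume(extract_slices(v, a)$slices, a, dim(v))` is exact.
#'
#' @param maps List of 2D matrices, or a `slice_stack`.
#' @param axis Stacking axis (ignored when `maps` is a `slice_stack`).
#' @param source_shape Length-3 target volume shape (ditto).
#' @param is_mask Logical; affects resize interpolation and output flag.
#' @return A [volume].
#' @export
stack_to_volume <- function(maps, axis = NULL, source_shape = NULL,
                            is_mask = FALSE) {
  if (inherits(maps, "slice_stack")) {
    axis <- maps$axis
    source_shape <- maps$source_shape
    is_mask <- maps$is_mask
    maps <- maps$slices
  }
  if (is.null(axis) || is.null(source_shape)) {
    stop("`axis` and `source_shape` are required for plain slice lists")
  }
  a <- .axis_num(axis)
  shp <- as.integer(source_shape)
  if (length(maps) != shp[a]) {
    stop("slice count (", length(maps), ") does not match source shape along ",
         axis, " (", shp[a], ")")
  }
  plane <- shp[-a]
  out <- array(0, dim = shp)
  for (i in seq_along(maps)) {
    m <- as.matrix(maps[[i]])
    if (!all(dim(m) == plane)) m <- resize_slice(m, plane, is_mask = is_mask)
    switch(a,
           out[i, , ] <- m,
           out[, i, ] <- m,
           out[, , i] <- m)
  }
  volume(out, is_mask = is_mask)
}

#' Select training slices by foreground content
#'
#' Returns the indices of slices whose mask foreground count is strictly
#' greater than `min_pixels` — the slice filter used for coarse-stage
#' training (default threshold 100 pixels).
#'
#' @param image_stack,mask_stack Aligned `slice_stack`s (same axis/length).
#' @param min_pixels Strict lower bound on foreground pixel count.
#' @return Sorted integer vector of qualifying slice indices.
#' @export
filter_training_slices <- function(image_stack, mask_stack, min_pixels = 100) {
  stopifnot(inherits(image_stack, "slice_stack"), inherits(mask_stack, "slice_stack"))
  if (image_stack$axis != mask_stack$axis ||
      length(image_stack$slices) != length(mask_stack$slices) ||
      !all(image_stack$source_shape == mask_stack$source_shape)) {
    stop("image and mask stacks are misaligned")
  }
  counts <- vapply(mask_stack$slices, function(s) sum(s > 0), numeric(1))
  which(counts > min_pixels)
}
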