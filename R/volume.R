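#' 3D volume container
#'
#' A `volume` holds a 3D scalar array in `(width, height, depth)` order —
#' depth being the axial stacking direction — together with optional per-axis
#' voxel spacing in millimetres and a flag marking binary masks. Masks must
#' contain only 0/1 values.
#'
#' @param data 3D numeric array.
#' @param spacing Optional numeric length-3 vector of voxel sizes (mm), all
#'   positive.
#' @param is_mask Logical; if `TRUE`, `data` is validated as binary.
#' @return An object of class `volume` with elements `data`, `spacing`,
#'   `is_mask`.
#' @export
volume <- function(data, spacing = NULL, is_mask = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (non-3D payload)")
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  storage.mode(data) <- "double"
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop("`spacing` must be 3 positive values")
    }
  }
  if (isTRUE(is_mask) && !all(data %in% c(0, 1))) {
    stop("mask volumes must be binary {0,1}")
  }
  structure(list(data = data, spacing = spacing, is_mask = isTRUE(is_mask)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d (%s)%s\n", d[1], d[2], d[3],
              if (x$is_mask) "mask" else "image",
              if (is.null(x$spacing)) "" else
                sprintf(", spacing %s mm", paste(signif(x$spacing, 3), collapse = "x"))))
  invisible(x)
}

as_volume <- function(x, spacing = NULL, is_mask = FALSE) {
  if (inherits(x, "volume")) x else volume(x, spacing, is_mask)
}

#' Read a volume from disk
#'
#' Reads a NIfTI (`.nii` / `.nii.gz`) file. Mask files are binarized with a
#' strict `> 0` rule, so masks coded 0/255 load as 0/1.
#'
#' @param path Path to an existing NIfTI file.
#' @param is_mask Logical; treat the payload as a binary mask.
#' @return A [volume].
#' @export
read_volume <- function(path, is_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  data <- array(as.vector(data), dim = dim(data))  # drop NIfTI attributes
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim = dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stop("non-3D payload in ", path, " (", length(dim(data)), " dims)")
  }
  spacing <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) NULL)
  if (!is.null(spacing) && (length(spacing) != 3L || any(spacing <= 0))) spacing <- NULL
  if (isTRUE(is_mask)) data <- (data > 0) * 1
  volume(data, spacing = spacing, is_mask = is_mask)
}

#' Write a volume to disk
#'
#' Writes NIfTI. Masks are stored with an integer datatype; images as float.
#'
#' @param v A [volume].
#' @param path Output path ending in `.nii` or `.nii.gz`; parent directory
#'   must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  if (!is.null(v$spacing)) RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path,
                     datatype = if (v$is_mask) "uint8" else "double")
  invisible(path)
}

#' Intensity preprocessing specification
#'
#' Defaults implement the standard abdominal soft-tissue treatment for CT:
#' Hounsfield units clipped to `[-100, 240]`, affinely rescaled to
#' `[0, 255]`, slices resized to 224 x 224.
#'
#' @param window_lo,window_hi Clipping window (input units).
#' @param out_lo,out_hi Output intensity range.
#' @param target_size Length-2 integer in-plane size for [resize_slice].
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(window_lo = -100, window_hi = 240,
                            out_lo = 0, out_hi = 255,
                            target_size = c(224L, 224L)) {
  if (!(window_lo < window_hi)) stop("window_lo must be < window_hi")
  if (!(out_lo < out_hi)) stop("out_lo must be < out_hi")
  target_size <- as.integer(rep(target_size, length.out = 2L))
  if (any(target_size < 8L)) stop("target sizes must be >= 8")
  structure(list(window_lo = window_lo, window_hi = window_hi,
                 out_lo = out_lo, out_hi = out_hi, target_size = target_size),
            class = "preprocess_spec")
}

#' Clip and rescale intensities
#'
#' Clips voxel values to `[window_lo, window_hi]` and maps the clipped range
#' affinely onto `[out_lo, out_hi]`:
#' `out = (clip(x) - lo) / (hi - lo) * (out_hi - out_lo) + out_lo`.
#' The result stays floating point (no integer quantization). Monotone
#' non-decreasing in the input, and idempotent once the data already lie in a
#' window that maps onto itself.
#'
#' @param v An image [volume] (not a mask).
#' @param spec A [preprocess_spec].
#' @return The windowed [volume].
#' @export
window_and_rescale <- function(v, spec = preprocess_spec()) {
  v <- as_volume(v)
  if (v$is_mask) stop("window_and_rescale() is for image volumes, not masks")
  x <- pmin(pmax(v$data, spec$window_lo), spec$window_hi)
  out <- (x - spec$window_lo) / (spec$window_hi - spec$window_lo) *
    (spec$out_hi - spec$out_lo) + spec$out_lo
  volume(out, spacing = v$spacing, is_mask = FALSE)
}

#' Resize a 2D slice
#'
#' Image slices use bilinear interpolation (half-pixel centre convention);
#' mask slices use nearest-neighbour so the output stays binary.
#'
#' @param s 2D numeric matrix.
#' @param target Length-2 integer output size `(rows, cols)`.
#' @param is_mask Logical; use nearest-neighbour.
#' @return Matrix of dimension `target`.
#' @export
resize_slice <- function(s, target, is_mask = FALSE) {
  if (!is.matrix(s)) stop("`s` must be a 2D matrix")
  if (any(dim(s) < 2L)) stop("input slice dimensions must be >= 2")
  target <- as.integer(rep(target, length.out = 2L))
  if (any(target < 1L)) stop("degenerate target size")
  out <- if (isTRUE(is_mask)) {
    .cpp_resize_nearest(s, dim(s), target[1], target[2])
  } else {
    .cpp_resize_bilinear(s, dim(s), target[1], target[2])
  }
  matrix(out, target[1], target[2])
}
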