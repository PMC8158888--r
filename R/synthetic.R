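# Seeded phantom volumes with the statistical structure the method assumes:
# a small (<2% of voxels), irregular, low-contrast foreground "organ" with a
# location prior and blurred boundary, peripheral distractor blobs whose
# intensities overlap the organ's, a smooth background field, and additive
# Gaussian noise. Intensities live on the post-preprocessing 0..255 scale.

#' Phantom specification
#'
#' @param shape Length-3 voxel shape (all dims >= 16).
#' @param organ_fraction_max Upper bound on the organ's volume fraction
#'   (default 0.02, i.e. the organ occupies under 2% of the volume).
#' @param organ_contrast Mean intensity offset of organ and distractors over
#'   the background (default 60; comparable to the noise + background
#'   variation, so contrast alone does not solve the task).
#' @param boundary_blur_sigma Gaussian blur (voxels) applied to the clean
#'   intensity image, blurring organ boundaries (default 1.5).
#' @param n_distractors Number of similar-intensity distractor blobs
#'   (default 4; their total volume exceeds the organ's, so global
#'   thresholding cannot succeed).
#' @param noise_sigma Additive Gaussian noise standard deviation (default 8).
#' @param seed Integer seed; generation is fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 48L), organ_fraction_max = 0.02,
                         organ_contrast = 60, boundary_blur_sigma = 1.5,
                         n_distractors = 4L, noise_sigma = 8, seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 3L))
  stopifnot(all(shape >= 16L), organ_fraction_max > 0, organ_fraction_max < 0.1,
            noise_sigma >= 0, boundary_blur_sigma >= 0, n_distractors >= 0L)
  structure(list(shape = shape, organ_fraction_max = organ_fraction_max,
                 organ_contrast = organ_contrast,
                 boundary_blur_sigma = boundary_blur_sigma,
                 n_distractors = as.integer(n_distractors),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur along all three axes (band-matrix multiply).
.blur_mat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    K[i, j] <- w / sum(w)
  }
  K
}

.gauss_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  K1 <- .blur_mat(d[1], sigma)
  K2 <- .blur_mat(d[2], sigma)
  K3 <- .blur_mat(d[3], sigma)
  out <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), d)
  out <- aperm(array(K2 %*% matrix(aperm(out, c(2, 1, 3)), d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(K3 %*% matrix(aperm(out, c(3, 1, 2)), d[3], d[1] * d[2]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

# Normalized coordinate arrays (value - center) / radius along each axis.
.coord3 <- function(shape, center, radius) {
  ux <- (seq_len(shape[1]) - center[1]) / radius[1]
  vy <- (seq_len(shape[2]) - center[2]) / radius[2]
  wz <- (seq_len(shape[3]) - center[3]) / radius[3]
  list(U = array(ux, shape),
       V = aperm(array(vy, shape[c(2, 1, 3)]), c(2, 1, 3)),
       W = aperm(array(wz, shape[c(3, 1, 2)]), c(2, 3, 1)))
}

.ellipsoid_mask <- function(shape, center, radius, deform_amp = 0,
                            deform_freq = NULL, deform_phase = NULL) {
  cc <- .coord3(shape, center, radius)
  q <- cc$U^2 + cc$V^2 + cc$W^2
  thr <- if (deform_amp > 0) {
    p <- deform_amp * sin(deform_freq[1] * cc$U + deform_freq[2] * cc$V +
                            deform_phase[1]) *
      cos(deform_freq[3] * cc$W + deform_phase[2])
    (1 + p)^2
  } else 1
  (q <= thr) * 1
}

#' Generate one phantom volume with its ground-truth mask
#'
#' The image is a smooth random background plus a randomly posed, sinusoidally
#' deformed ellipsoid "organ" near the volume centre at `organ_contrast`
#' above background, plus `n_distractors` peripheral ellipsoid blobs at
#' overlapping intensities that do not touch the organ; the whole clean image
#' is Gaussian-blurred (vague boundaries) and Gaussian noise is added. The
#' mask is the pre-blur organ. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` and `mask` [volume]s and the organ volume
#'   `fraction`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shp <- spec$shape
  nvox <- prod(shp)

  # smooth background field
  bg <- array(90, shp)
  for (b in 1:3) {
    ctr <- stats::runif(3, 0.1, 0.9) * shp
    sig <- stats::runif(1, 0.25, 0.5) * shp
    cc <- .coord3(shp, ctr, sig)
    bg <- bg + stats::runif(1, -18, 18) * exp(-(cc$U^2 + cc$V^2 + cc$W^2) / 2)
  }

  # deformed ellipsoid organ with a central location prior
  center <- stats::runif(3, 0.42, 0.58) * shp
  radius <- c(0.195, 0.140, 0.145) * shp * stats::runif(3, 0.9, 1.1)
  freq <- stats::runif(3, 1.5, 3)
  phase <- stats::runif(2, 0, 2 * pi)
  organ <- NULL
  for (attempt in 1:5) {
    organ <- .ellipsoid_mask(shp, center, radius, deform_amp = 0.2,
                             deform_freq = freq, deform_phase = phase)
    frac <- sum(organ) / nvox
    if (frac <= spec$organ_fraction_max) break
    radius <- radius * (spec$organ_fraction_max / frac)^(1 / 3) * 0.98
  }
  if (sum(organ) == 0) stop("infeasible spec: organ does not fit the volume")
  if (sum(organ) / nvox > spec$organ_fraction_max) {
    stop("infeasible spec: organ fraction cannot satisfy organ_fraction_max")
  }

  # peripheral distractor blobs, never overlapping the organ
  img <- bg + spec$organ_contrast * organ
  placed <- 0L
  tries <- 0L
  while (placed < spec$n_distractors && tries < 200L) {
    tries <- tries + 1L
    dr <- radius * stats::runif(3, 0.65, 0.85)
    margin <- dr + 2
    lohi <- cbind(margin, shp - margin)
    if (any(lohi[, 1] >= lohi[, 2])) next
    dc <- stats::runif(3, lohi[, 1], lohi[, 2])
    # peripheral: keep distractor centres away from the organ's centre zone
    if (all(abs(dc - center) < radius + dr + 2)) next
    dmask <- .ellipsoid_mask(shp, dc, dr)
    if (sum(dmask * organ) > 0) next
    img <- img + spec$organ_contrast * stats::runif(1, 0.8, 1.2) * dmask
    placed <- placed + 1L
  }

  img <- .gauss_blur3d(img, spec$boundary_blur_sigma)
  if (spec$noise_sigma > 0) {
    img <- img + stats::rnorm(nvox, 0, spec$noise_sigma)
  }
  img <- pmin(pmax(img, 0), 255)
  dim(img) <- shp
  list(image = volume(img, is_mask = FALSE),
       mask = volume(organ, is_mask = TRUE),
       fraction = sum(organ) / nvox)
}

#' Generate a phantom dataset
#'
#' Case `i` uses seed `spec$seed + i - 1`. When `dir` is given, images and
#' masks are written as NIfTI with a JSON manifest listing every file and
#' its seed.
#'
#' @param n Number of cases (>= 1).
#' @param spec A [phantom_spec] (its `seed` is the base seed).
#' @param dir Optional output directory (created if missing).
#' @return List of cases `list(image=, mask=, seed=)`, invisibly when
#'   writing to `dir`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), dir = NULL) {
  stopifnot(n >= 1L)
  cases <- vector("list", n)
  manifest <- list()
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- spec$seed + i - 1L
    ph <- generate_phantom(si)
    cases[[i]] <- list(image = ph$image, mask = ph$mask, seed = si$seed)
    if (!is.null(dir)) {
      img_file <- sprintf("case%03d_image.nii.gz", i)
      msk_file <- sprintf("case%03d_mask.nii.gz", i)
      write_volume(ph$image, file.path(dir, img_file))
      write_volume(ph$mask, file.path(dir, msk_file))
      manifest[[i]] <- list(case = i, seed = si$seed,
                            image = img_file, mask = msk_file)
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(list(shape = spec$shape, base_seed = spec$seed,
                              cases = manifest),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(cases))
  }
  cases
}

#' Load a phantom dataset written by [generate_dataset]
#'
#' @param dir Directory containing `manifest.json`.
#' @return List of cases `list(image=, mask=, seed=)`.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  lapply(manifest$cases, function(cs) {
    list(image = read_volume(file.path(dir, cs$image)),
         mask = read_volume(file.path(dir, cs$mask), is_mask = TRUE),
         seed = cs$seed)
  })
}

#' Best-case global-threshold baseline
#'
#' Scans intensity thresholds and returns the best achievable volume DSC for
#' a segmenter that simply labels every voxel above a global threshold as
#' foreground. On default phantoms this stays well below a trained model
#' because the distractors share the organ's intensity range — separating
#' "the task is hard" from "the method works".
#'
#' @param image Image [volume].
#' @param mask Ground-truth mask [volume].
#' @param n_thresholds Number of thresholds scanned across the intensity
#'   range.
#' @return The maximum DSC over all scanned thresholds.
#' @export
threshold_baseline_dsc <- function(image, mask, n_thresholds = 64L) {
  image <- as_volume(image)
  mask <- as_volume(mask, is_mask = TRUE)
  ths <- seq(min(image$data), max(image$data), length.out = n_thresholds)
  best <- 0
  for (t in ths) {
    best <- max(best, dsc((image$data >= t) * 1, mask$data))
  }
  best
}
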