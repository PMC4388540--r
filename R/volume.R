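#' Voxel volume image
#'
#' A 3D (structural/mask) or 4D (dynamic) voxel grid with physical voxel
#' dimensions in mm and, for 4D data, an optional [frame_schedule()].
#'
#' @param data 3D or 4D numeric/logical array.
#' @param voxel_mm Voxel size per spatial axis (length 3, mm).
#' @param schedule Optional frame schedule (4D data).
#' @return Object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_mm, schedule = NULL) {
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stop("data must be a 3D or 4D array")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be 3 positive sizes")
  if (!is.null(schedule)) {
    stopifnot(is_frame_schedule(schedule))
    if (nd != 4L || dim(data)[4] != schedule$F)
      stop("schedule length must match the 4th dimension")
  }
  structure(list(data = data, voxel_mm = voxel_mm, schedule = schedule),
            class = "volume_image")
}

is_volume <- function(x) inherits(x, "volume_image")

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels @ %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_mm, 4), collapse = "x")))
  invisible(x)
}

# voxel volume in cc (1 cc = 1000 mm^3)
voxel_cc <- function(vol) prod(vol$voxel_mm) / 1000

is_binary <- function(a) {
  u <- unique(as.vector(a))
  all(u %in% c(0, 1, TRUE, FALSE))
}

# 1D Gaussian kernel integrated over voxel bins (exact for a boxcar voxel
# model), truncated at `trunc` sigma, normalized to sum 1
gauss_kernel_1d <- function(sigma_vox, trunc = 5) {
  m <- max(1L, ceiling(trunc * sigma_vox))
  j <- (-m):m
  w <- stats::pnorm(j + 0.5, sd = sigma_vox) - stats::pnorm(j - 0.5, sd = sigma_vox)
  w / sum(w)
}

# separable convolution of a 3D array along one axis with zero padding
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  m <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  mat <- matrix(ap, nrow = dp[1])
  padded <- rbind(matrix(0, m, ncol(mat)), mat, matrix(0, m, ncol(mat)))
  out <- stats::filter(padded, kernel, sides = 2)
  out <- out[(m + 1):(m + dp[1]), , drop = FALSE]
  res <- array(as.numeric(out), dim = dp)
  aperm(res, order(perm))
}

gaussian_smooth_3d <- function(a, sigma_vox, trunc = 5) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      a <- conv_axis(a, gauss_kernel_1d(sigma_vox[ax], trunc), ax)
  }
  a
}

#' Smooth a mask (or image) to PET resolution
#'
#' Gaussian filtering with `sigma = FWHM / (2 sqrt(2 ln 2))` per axis,
#' converted from mm to voxels; zero-padded boundaries (vessels are assumed
#' away from the volume edge).
#'
#' @param vol A [volume_image()] (3D).
#' @param fwhm_mm Point-spread FWHM in mm (scalar or length 3), default 8.
#' @return A float-valued [volume_image()].
#' @export
smooth_to_pet_resolution <- function(vol, fwhm_mm = 8) {
  stopifnot(is_volume(vol), length(dim(vol$data)) == 3L)
  fwhm_mm <- rep(as.numeric(fwhm_mm), length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_mm
  volume_image(gaussian_smooth_3d(vol$data * 1.0, sigma_vox), vol$voxel_mm)
}

# 6-connected component labelling (iterative flood fill)
label_components <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  idx <- which(as.vector(mask) != 0)
  inmask <- logical(n); inmask[idx] <- TRUE
  strides <- c(1L, d[1], d[1] * d[2])
  coord_ok <- function(i, axis, step) {
    # check the neighbour along `axis` stays in grid
    pos <- arrayInd(i, d)[, axis]
    pos + step >= 1 & pos + step <= d[axis]
  }
  current <- 0L
  stack <- integer(0)
  for (seed in idx) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    stack <- seed
    lab[seed] <- current
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- arrayInd(v, d)
      for (ax in 1:3) for (st in c(-1L, 1L)) {
        p <- pos[ax] + st
        if (p < 1L || p > d[ax]) next
        nb <- v + st * strides[ax]
        if (inmask[nb] && lab[nb] == 0L) {
          lab[nb] <- current
          stack <- c(stack, nb)
        }
      }
    }
  }
  array(lab, dim = d)
}

#' Simple intensity-threshold vessel segmentation
#'
#' Stand-in for adaptive MRA segmentation: voxels above an intensity
#' percentile, optionally intersected with a brain mask, keeping the largest
#' connected component(s).
#'
#' @param mra 3D intensity [volume_image()] (e.g. time-of-flight angiography).
#' @param percentile Intensity percentile threshold (default 99).
#' @param brain_mask Optional binary [volume_image()] to intersect with.
#' @param components Number of largest 6-connected components to keep
#'   (default 1).
#' @return Binary [volume_image()] vessel mask.
#' @export
segment_vessels_simple <- function(mra, percentile = 99, brain_mask = NULL,
                                   components = 1L) {
  stopifnot(is_volume(mra), length(dim(mra$data)) == 3L)
  vals <- as.vector(mra$data)
  if (!is.null(brain_mask)) vals <- vals[as.vector(brain_mask$data) != 0]
  thr <- stats::quantile(vals, percentile / 100, names = FALSE)
  mask <- mra$data >= thr
  if (!is.null(brain_mask)) mask <- mask & (brain_mask$data != 0)
  if (!any(mask)) stop("vessel segmentation produced an empty mask")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(components, length(sizes)))]
  out <- array(as.numeric(lab %in% keep), dim = dim(mask))
  volume_image(out, mra$voxel_mm)
}

box_index_array <- function(d, box) {
  if (is.null(box)) return(array(TRUE, dim = d))
  stopifnot(is.matrix(box) || is.list(box))
  if (is.list(box)) box <- do.call(rbind, box)
  ok <- array(FALSE, dim = d)
  ok[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]] <- TRUE
  ok
}

#' Threshold a smoothed mask to hit a target volume
#'
#' Finds the intensity threshold whose supra-threshold volume (voxel count
#' times voxel volume, within an optional rectangular box) is closest to the
#' target; succeeds only when that volume is within one voxel of the target
#' (flat intensity plateaus make some targets unattainable). Ties between
#' equally close thresholds resolve to the higher threshold.
#'
#' @param smoothed Float [volume_image()] (a PSF-smoothed mask).
#' @param target_cc Target volume in cc (1 cc = 1000 mm^3).
#' @param box Optional voxel-index bounds, a 3x2 matrix (or list of 3
#'   `c(lo, hi)` pairs), 1-based inclusive.
#' @return List: `mask` (binary [volume_image()], `smoothed >= threshold`
#'   within the box), `threshold`, `volume_cc`.
#' @export
threshold_to_volume <- function(smoothed, target_cc, box = NULL) {
  stopifnot(is_volume(smoothed))
  vcc <- voxel_cc(smoothed)
  inbox <- box_index_array(dim(smoothed$data), box)
  vals <- as.vector(smoothed$data)[as.vector(inbox)]
  pos <- sort(vals[vals > 0], decreasing = TRUE)
  if (length(pos) == 0L) stop("no positive voxels to threshold")
  # candidate thresholds: distinct positive values; count(>= v) is the
  # position of the last occurrence of v in the sorted vector
  uv <- unique(pos)
  counts <- cumsum(tabulate(match(pos, uv)))
  vols <- counts * vcc
  err <- abs(vols - target_cc)
  best <- which(err == min(err))[1]   # uv sorted desc -> first = higher thr
  if (err[best] > vcc + 1e-9)
    stop(sprintf(
      "target %.3g cc unattainable within one voxel; attainable volumes span [%.3g, %.3g] cc with gaps",
      target_cc, vols[1], vols[length(vols)]))
  thr <- uv[best]
  mask <- (smoothed$data >= thr) & inbox
  list(mask = volume_image(array(as.numeric(mask), dim = dim(mask)),
                           smoothed$voxel_mm),
       threshold = thr, volume_cc = sum(mask) * vcc)
}

#' Build the arterial ROI / background mask pair
#'
#' The arterial ROI (ROIa) is the smoothed vessel mask thresholded to
#' `cc_a` (default 16 cc) inside the carotid box; a larger envelope (ROIb)
#' is thresholded to `cc_b` (default 100 cc) over the whole volume; the
#' background mask is `ROIb AND NOT ROIa`.
#'
#' @param smoothed PSF-smoothed vessel mask ([volume_image()]).
#' @param box Voxel-index box for the ROIa search (see
#'   [threshold_to_volume()]).
#' @param cc_a,cc_b Target volumes (cc) for ROIa and ROIb.
#' @return List: `roia`, `bg` (binary [volume_image()]s), `roib`,
#'   thresholds, and `roia_in_roib` (containment check).
#' @export
build_roi_pair <- function(smoothed, box, cc_a = 16, cc_b = 100) {
  if (cc_b < cc_a) stop("cc_b must be >= cc_a")
  if (cc_b == cc_a) warning("cc_a == cc_b: background mask will be (nearly) empty")
  ra <- threshold_to_volume(smoothed, cc_a, box = box)
  rb <- threshold_to_volume(smoothed, cc_b, box = NULL)
  a <- ra$mask$data != 0
  b <- rb$mask$data != 0
  contained <- !any(a & !b)
  if (!contained) warning("ROIa is not fully contained in ROIb")
  bg <- b & !a
  list(roia = ra$mask,
       bg = volume_image(array(as.numeric(bg), dim = dim(bg)),
                         smoothed$voxel_mm),
       roib = rb$mask,
       threshold_a = ra$threshold, threshold_b = rb$threshold,
       roia_in_roib = contained)
}

#' Extract a regional time-activity curve from a 4D volume
#'
#' Per-frame unweighted mean over the mask voxels. The PET grid and the mask
#' grid must already be aligned (registration is out of scope).
#'
#' @param pet4d 4D [volume_image()] with a frame schedule.
#' @param mask Binary 3D [volume_image()] on the same grid.
#' @param role Role for the returned [tac()] (default `"tissue"`).
#' @return A [tac()].
#' @export
extract_tac <- function(pet4d, mask, role = "tissue") {
  stopifnot(is_volume(pet4d), is_volume(mask))
  if (length(dim(pet4d$data)) != 4L || is.null(pet4d$schedule))
    stop("pet4d must be 4D with a frame schedule")
  if (!all(dim(pet4d$data)[1:3] == dim(mask$data)) ||
      max(abs(pet4d$voxel_mm - mask$voxel_mm)) > 1e-6)
    stop("pet4d and mask grids are not aligned")
  m <- mask$data != 0
  if (!any(m)) stop("empty mask")
  vals <- apply(pet4d$data, 4, function(fr) mean(fr[m]))
  tac(pet4d$schedule, vals, role = role)
}

#' Recovery coefficient of an arterial ROI
#'
#' Fraction of true vessel signal recovered inside the ROI after blurring
#' with the scanner point-spread function: the vessel mask is convolved with
#' a Gaussian of the given FWHM and averaged over the ROIa voxels.
#'
#' @param vessel_mask Binary [volume_image()].
#' @param roia Binary [volume_image()] on the same grid.
#' @param fwhm_mm PSF FWHM in mm, default 8.
#' @return r in (0, 1].
#' @export
recovery_coefficient <- function(vessel_mask, roia, fwhm_mm = 8) {
  stopifnot(is_volume(vessel_mask), is_volume(roia))
  if (!all(dim(vessel_mask$data) == dim(roia$data)))
    stop("masks must share a grid")
  m <- roia$data != 0
  if (!any(m)) stop("empty ROIa")
  sm <- smooth_to_pet_resolution(vessel_mask, fwhm_mm)
  r <- mean(sm$data[m])
  min(max(r, .Machine$double.eps), 1)
}
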