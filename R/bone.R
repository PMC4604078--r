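#' Trabecular bone ROI
#'
#' A contiguous slice range of a micro-CT volume, e.g. "100 contiguous
#' slices starting 100 slices below the growth plate".
#'
#' @param start_slice first slice (1-based)
#' @param n_slices number of contiguous slices (>= 1)
#' @return object of class `bone_roi`
#' @export
bone_roi <- function(start_slice, n_slices) {
  stopifnot(start_slice >= 1, n_slices >= 1)
  structure(list(start_slice = as.integer(start_slice),
                 n_slices = as.integer(n_slices)), class = "bone_roi")
}

roi_slices <- function(roi, n3) {
  if (is.null(roi)) return(seq_len(n3))
  sl <- roi$start_slice:(roi$start_slice + roi$n_slices - 1L)
  if (any(sl > n3)) stop("ROI extends beyond the volume (", n3, " slices)")
  sl
}

#' Segment bone from background by seeded region growing
#'
#' Grows a region from seed voxels through 6-connected neighbours whose
#' intensity lies within `tolerance` of the running region mean (FIFO
#' order; deterministic for fixed seeds and tolerance). Seeds must lie in
#' foreground-intensity voxels; a tolerance wide enough to annex the
#' background triggers an overflow guard instead of silently flooding the
#' volume.
#'
#' @param volume numeric 3-D array of intensities
#' @param seeds matrix of seed voxel indices, one row per seed, columns
#'   (i, j, slice), 1-based
#' @param tolerance homogeneity criterion half-width on the intensity scale
#' @param max_fraction overflow guard: stop with an error if the region
#'   exceeds this fraction of the volume
#' @return logical 3-D array: TRUE = bone
#' @export
srg_segment <- function(volume, seeds, tolerance, max_fraction = 0.95) {
  stopifnot(length(dim(volume)) == 3, tolerance > 0)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(volume)
  if (any(seeds < 1L) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed voxel outside the volume")
  thr <- otsu_threshold(sample_voxels(volume))
  svals <- volume[seeds]
  if (any(svals < thr))
    stop("seed in background: seed intensity ", round(min(svals), 3),
         " below the foreground threshold ", round(thr, 3))
  flat <- (seeds[, 1] - 1L) + d[1] * ((seeds[, 2] - 1L) + d[2] * (seeds[, 3] - 1L))
  res <- cpp_srg(as.numeric(volume), as.integer(d), as.integer(flat),
                 tolerance, max_fraction)
  if (res$overflow)
    stop("overflow guard: tolerance ", tolerance, " spans the background ",
         "(region exceeded ", max_fraction * 100, "% of the volume)")
  array(res$mask, dim = d)
}

sample_voxels <- function(volume, n = 100000L) {
  v <- as.numeric(volume)
  if (length(v) <= n) return(v)
  v[as.integer(seq(1, length(v), length.out = n))]
}

#' Bone volume fraction (BV/TV)
#'
#' Bone voxels over total voxels within the ROI.
#'
#' @param mask logical 3-D bone mask
#' @param roi optional [bone_roi()]
#' @return fraction in [0, 1]
#' @export
bvtv <- function(mask, roi = NULL) {
  stopifnot(length(dim(mask)) == 3)
  sl <- roi_slices(roi, dim(mask)[3])
  sub <- mask[, , sl, drop = FALSE]
  if (length(sub) == 0) stop("empty ROI")
  mean(sub)
}

#' Mean local thickness of a binary structure
#'
#' Hildebrand-style model-independent thickness: the volume-weighted mean
#' diameter of the largest sphere fully inside the structure covering each
#' voxel (exact 3-D Euclidean distance transform, distance ridge, sphere
#' painting; a half-voxel boundary correction makes an n-voxel slab measure
#' n voxels). The thickness map is computed over the whole volume and then
#' averaged over the ROI voxels. The first and last slice are treated as
#' phase boundaries (the stack is cropped along the slice axis, so a
#' structure running through those faces would otherwise be measured
#' against voxels arbitrarily far away); in-plane the field of view is
#' assumed to contain the structure. Applied to the mask complement this
#' yields trabecular separation.
#'
#' @param mask logical 3-D array
#' @param um_per_vox voxel pitch, micrometres
#' @param roi optional [bone_roi()]; the mean is taken over ROI voxels
#' @return mean thickness in micrometres
#' @export
local_thickness <- function(mask, um_per_vox = 1, roi = NULL) {
  stopifnot(length(dim(mask)) == 3, um_per_vox > 0)
  d <- dim(mask)
  sl <- roi_slices(roi, d[3])
  if (!any(mask[, , sl])) stop("empty mask: local thickness undefined")
  pad <- array(0L, d + c(0L, 0L, 2L))
  pad[, , 2:(d[3] + 1L)] <- as.integer(mask != 0)
  map <- cpp_local_thickness(pad, dim(pad))
  map <- array(map, dim(pad))[, , 2:(d[3] + 1L), drop = FALSE]
  vals <- map[, , sl, drop = FALSE][mask[, , sl, drop = FALSE]]
  mean(vals) * um_per_vox
}

#' Trabecular separation (Tb.Sp)
#'
#' Mean local thickness of the non-bone phase within the ROI.
#'
#' @inheritParams local_thickness
#' @return mean separation in micrometres
#' @export
tb_spacing <- function(mask, um_per_vox = 1, roi = NULL) {
  local_thickness(!mask, um_per_vox, roi)
}

#' Trabecular number (Tb.N) under the plate model
#'
#' Number of plates per millimetre of length: BV/TV divided by the
#' trabecular thickness.
#'
#' @param bvtv bone volume fraction in [0, 1]
#' @param tb_th_um trabecular thickness, micrometres (> 0)
#' @return plates per millimetre
#' @export
tb_number <- function(bvtv, tb_th_um) {
  if (tb_th_um <= 0) stop("tb_th_um must be positive")
  bvtv / (tb_th_um / 1000)
}

#' Full trabecular morphometry of a bone mask
#'
#' BV/TV, Tb.Th, Tb.Sp (both by maximal-sphere local thickness) and Tb.N
#' (plate model BV/TV / Tb.Th, with the alternative 1 / (Tb.Th + Tb.Sp)
#' plate estimate reported alongside for comparison).
#'
#' @param mask logical 3-D bone mask (e.g. from [srg_segment()])
#' @param um_per_vox voxel pitch, micrometres
#' @param roi optional [bone_roi()]
#' @return list of class `bone_morphometry`: bvtv, tb_th_um, tb_sp_um,
#'   tb_n_per_mm, tb_n_plate_per_mm
#' @export
bone_morphometry <- function(mask, um_per_vox, roi = NULL) {
  bv <- bvtv(mask, roi)
  th <- local_thickness(mask, um_per_vox, roi)
  sp <- tb_spacing(mask, um_per_vox, roi)
  structure(list(bvtv = bv, tb_th_um = th, tb_sp_um = sp,
                 tb_n_per_mm = tb_number(bv, th),
                 tb_n_plate_per_mm = 1000 / (th + sp)),
            class = "bone_morphometry")
}
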