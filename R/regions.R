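#' Count immunopositive cells by threshold-and-label particle analysis
#'
#' The semi-automated counting macro: threshold the channel (Otsu unless a
#' threshold is given), label connected objects (8-connected by default),
#' drop objects outside the size window, and express the count per unit
#' area.
#'
#' @param image single-channel numeric matrix
#' @param um_per_px pixel pitch, micrometres
#' @param threshold intensity threshold; `NULL` for Otsu
#' @param min_area_um2,max_area_um2 object size window
#' @param connectivity 4 or 8
#' @return list of class `count_result`: n_objects, area_mm2,
#'   density_per_mm2, threshold_used, saturated (TRUE when the whole frame
#'   thresholds positive), um_per_px
#' @export
count_positive_cells <- function(image, um_per_px = 1, threshold = NULL,
                                 min_area_um2 = 20, max_area_um2 = 500,
                                 connectivity = 8L) {
  stopifnot(is.matrix(image), um_per_px > 0)
  thr <- threshold %||% otsu_threshold(image)
  bin <- image >= thr
  saturated <- all(bin)
  n <- 0L
  if (any(bin)) {
    lab <- cpp_label_components(as_int_mat(bin), as.integer(connectivity))
    sizes <- tabulate(lab[lab > 0L]) * um_per_px^2
    n <- sum(sizes >= min_area_um2 & sizes <= max_area_um2)
  }
  area_mm2 <- prod(dim(image)) * um_per_px^2 / 1e6
  structure(list(n_objects = n, area_mm2 = area_mm2,
                 density_per_mm2 = n / area_mm2, threshold_used = thr,
                 saturated = saturated, um_per_px = um_per_px),
            class = "count_result")
}

#' Average cell densities over fields of view
#'
#' Arithmetic mean of per-FOV densities, as used for diaphragm sections
#' where several fields of view sample one cross-section. All FOVs must
#' share the same pixel calibration.
#'
#' @param counts list of `count_result` objects
#' @return mean density per square millimetre (scalar)
#' @export
average_fov_density <- function(counts) {
  stopifnot(length(counts) >= 1)
  if (!all(vapply(counts, inherits, TRUE, "count_result")))
    stop("all elements must be count_result objects")
  cal <- vapply(counts, `[[`, 1, "um_per_px")
  if (length(unique(cal)) != 1)
    stop("mismatched pixel calibrations across fields of view")
  mean(vapply(counts, `[[`, 1, "density_per_mm2"))
}

#' Positive-area fraction of a section
#'
#' Percent of the section area that is positive, either by automatic
#' thresholding or by replaying manually delineated ROI polygons (the
#' historical workflow for IgG-positive areas). The `method` field of the
#' result records which mode produced the number.
#'
#' @param image single-channel numeric matrix
#' @param threshold intensity threshold (`NULL` = Otsu); ignored when ROIs
#'   are given
#' @param roi optional list of polygons (n x 2 matrices of x, y vertex
#'   coordinates in pixels) delineating positive areas
#' @param um_per_px pixel pitch, micrometres
#' @param section_mask optional logical matrix restricting the section
#'   (total) area; default: the full frame
#' @return list of class `area_fraction_result`: positive_area_um2,
#'   total_area_um2, percent_positive, method
#' @export
area_fraction <- function(image, threshold = NULL, roi = NULL,
                          um_per_px = 1, section_mask = NULL) {
  stopifnot(is.matrix(image), um_per_px > 0)
  total_px <- if (is.null(section_mask)) prod(dim(image)) else sum(section_mask)
  if (total_px == 0) stop("empty section mask")
  total_um2 <- total_px * um_per_px^2
  if (!is.null(roi)) {
    for (p in roi) {
      if (any(p[, 1] < 0 | p[, 1] > ncol(image) |
              p[, 2] < 0 | p[, 2] > nrow(image)))
        stop("ROI polygon extends outside the image")
    }
    pos_um2 <- sum(vapply(roi, polygon_area, 1)) * um_per_px^2
    method <- "manual_roi"
  } else {
    thr <- threshold %||% otsu_threshold(image)
    bin <- image >= thr
    if (!is.null(section_mask)) bin <- bin & section_mask
    pos_um2 <- sum(bin) * um_per_px^2
    method <- "auto_threshold"
  }
  pct <- 100 * pos_um2 / total_um2
  structure(list(positive_area_um2 = pos_um2, total_area_um2 = total_um2,
                 percent_positive = pct, method = method),
            class = "area_fraction_result")
}

#' Trichrome (collagen) positive-area fraction of an RGB section
#'
#' A pixel is collagen-positive when its blue channel dominates both red
#' and green by `margin`; near-white pixels (slide background) are excluded
#' from the tissue area by a luminance cutoff. Percent positive is taken
#' over the tissue (non-background) area.
#'
#' @param rgb numeric array rows x cols x 3, intensities in [0, 1]
#' @param margin blue-dominance margin on the [0, 1] scale (20/255
#'   reproduces the 8-bit default)
#' @param white_cutoff pixels with all channels above this are background
#' @param um_per_px pixel pitch, micrometres
#' @return an `area_fraction_result` (method "blue_dominance")
#' @export
trichrome_fraction <- function(rgb, margin = 20 / 255, white_cutoff = 0.92,
                               um_per_px = 1) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  background <- R > white_cutoff & G > white_cutoff & B > white_cutoff
  tissue <- !background
  if (!any(tissue)) stop("no tissue pixels below the white cutoff")
  pos <- tissue & (B > R + margin) & (B > G + margin)
  structure(list(positive_area_um2 = sum(pos) * um_per_px^2,
                 total_area_um2 = sum(tissue) * um_per_px^2,
                 percent_positive = 100 * sum(pos) / sum(tissue),
                 method = "blue_dominance"),
            class = "area_fraction_result")
}

#' Revertant-fiber density per square millimetre
#'
#' Counts connected components of a dystrophin-positive fiber mask and
#' divides by the section area. Clusters of adjacent positive fibers count
#' as their number of connected components under the declared connectivity
#' (the historical counting unit is ambiguous; components are the
#' reproducible choice).
#'
#' @param mask logical matrix of dystrophin-positive pixels
#' @param um_per_px pixel pitch, micrometres
#' @param connectivity 4 or 8
#' @return list with n_fibers, area_mm2, density_per_mm2
#' @export
revertant_density <- function(mask, um_per_px = 1, connectivity = 8L) {
  stopifnot(is.matrix(mask), um_per_px > 0)
  n <- if (any(mask != 0))
    max(cpp_label_components(as_int_mat(mask), as.integer(connectivity)))
  else 0L
  area_mm2 <- prod(dim(mask)) * um_per_px^2 / 1e6
  list(n_fibers = n, area_mm2 = area_mm2, density_per_mm2 = n / area_mm2)
}
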