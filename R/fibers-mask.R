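#' Configuration for the fiber morphometry macro
#'
#' Collects every tunable of the six-step border-mask macro. Thresholds
#' left `NULL` are derived per image by Otsu's method on the
#' background-subtracted channel.
#'
#' @param background_radius_px spatial scale (px) of the background
#'   estimate subtracted before thresholding
#' @param bandpass_low,bandpass_high intensity band kept by the border
#'   threshold; `NULL` low means automatic (Otsu), `NULL` high means no
#'   upper cut
#' @param dilation_radius_px border dilation radius; gaps up to twice this
#'   are bridged before skeletonisation
#' @param min_fiber_area_um2,max_fiber_area_um2 particle filter: fiber
#'   regions outside this window are treated as stray non-fiber signal
#' @param nucleus_threshold intensity threshold for the nuclei channel
#'   (`NULL` = Otsu)
#' @param central_margin_fraction a nucleus counts as central when its
#'   centroid lies deeper than this fraction of the fiber's
#'   equivalent-circle radius from the border
#' @param um_per_px pixel pitch in micrometres
#' @return object of class `morphometry_config`
#' @export
morphometry_config <- function(background_radius_px = 50L,
                               bandpass_low = NULL, bandpass_high = NULL,
                               dilation_radius_px = 2L,
                               min_fiber_area_um2 = 50,
                               max_fiber_area_um2 = 10000,
                               nucleus_threshold = NULL,
                               central_margin_fraction = 0.1,
                               um_per_px = 1) {
  stopifnot(min_fiber_area_um2 < max_fiber_area_um2,
            central_margin_fraction > 0, central_margin_fraction < 1,
            um_per_px > 0, dilation_radius_px >= 0)
  structure(list(background_radius_px = background_radius_px,
                 bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 dilation_radius_px = dilation_radius_px,
                 min_fiber_area_um2 = min_fiber_area_um2,
                 max_fiber_area_um2 = max_fiber_area_um2,
                 nucleus_threshold = nucleus_threshold,
                 central_margin_fraction = central_margin_fraction,
                 um_per_px = um_per_px),
            class = "morphometry_config")
}

#' Build the fiber border mask from a membrane channel
#'
#' Steps i-v of the morphometry macro: subtract the low-frequency
#' background, apply the band-pass threshold, dilate to close gaps in the
#' stained borders, and skeletonise to a 1-px closed border network.
#' Deterministic for a fixed input and configuration.
#'
#' @param membrane single-channel numeric matrix (intensities in [0, 1])
#' @param cfg a [morphometry_config()]
#' @return logical matrix: TRUE on the border skeleton
#' @export
build_border_mask <- function(membrane, cfg = morphometry_config()) {
  stopifnot(is.matrix(membrane))
  if (all(membrane == membrane[1])) {
    warning("uniform membrane channel: returning an empty border mask")
    return(matrix(FALSE, nrow(membrane), ncol(membrane)))
  }
  bg <- as.matrix(EBImage::gblur(EBImage::Image(membrane),
                                 sigma = cfg$background_radius_px / 2))
  sub <- pmax(membrane - bg, 0)
  lo <- cfg$bandpass_low %||% otsu_threshold(sub)
  hi <- cfg$bandpass_high %||% Inf
  bin <- sub >= lo & sub <= hi
  if (cfg$dilation_radius_px >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(cfg$dilation_radius_px) + 1L,
                                shape = "disc")
    bin <- as.matrix(EBImage::dilate(EBImage::Image(bin * 1), brush)) > 0.5
  }
  cpp_thin(as_int_mat(bin)) > 0L
}

#' Label fiber regions enclosed by a border mask
#'
#' Steps v-vi of the macro's particle analysis: connected non-border
#' regions (4-connected) become candidate fibers; regions touching the
#' image edge (censored geometry) and regions outside the configured area
#' window (stray non-border signal) are removed. Removal counts are
#' reported via `message()`.
#'
#' @param border_mask logical matrix from [build_border_mask()]
#' @param cfg a [morphometry_config()]
#' @return object of class `labeled_fiber_map`: list with `labels`
#'   (integer matrix, 0 = border/background, k > 0 = fiber k, labels
#'   contiguous), `um_per_px`, `tissue_area_um2`, and removal counts
#' @export
label_fibers <- function(border_mask, cfg = morphometry_config()) {
  lab <- cpp_label_components(as_int_mat(!border_mask), 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  edge_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  edge_labels <- edge_labels[edge_labels > 0L]
  counts <- tabulate(lab[lab > 0L])
  areas <- counts * cfg$um_per_px^2
  keep <- which(areas >= cfg$min_fiber_area_um2 &
                  areas <= cfg$max_fiber_area_um2)
  keep <- setdiff(keep, edge_labels)
  n_edge <- length(intersect(which(counts > 0), edge_labels))
  n_size <- sum(counts > 0) - n_edge - length(keep)
  message("label_fibers: kept ", length(keep), " fibers; removed ",
          n_edge, " edge-touching and ", n_size, " size-filtered regions")
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nr, nc)
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  structure(list(labels = out, um_per_px = cfg$um_per_px,
                 tissue_area_um2 = nr * nc * cfg$um_per_px^2,
                 n_fibers = length(keep),
                 n_removed_edge = n_edge, n_removed_size = n_size),
            class = "labeled_fiber_map")
}

#' Measure per-fiber morphometric variables
#'
#' For every labelled fiber: area, minimum Feret diameter (rotating
#' calipers on the pixel hull) and centroid.
#'
#' @param map a `labeled_fiber_map` from [label_fibers()]
#' @return data.frame with columns label, area_um2, min_feret_um,
#'   centroid_row, centroid_col
#' @export
measure_fibers <- function(map) {
  stopifnot(inherits(map, "labeled_fiber_map"))
  lab <- map$labels
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      min_feret_um = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  nr <- nrow(lab)
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  l <- lab[idx]
  by_lab <- split(seq_along(idx), l)
  res <- lapply(names(by_lab), function(k) {
    sel <- by_lab[[k]]
    px <- cbind(r[sel], c_[sel])
    data.frame(label = as.integer(k),
               area_um2 = nrow(px) * map$um_per_px^2,
               min_feret_um = min_feret(px, map$um_per_px),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  })
  out <- do.call(rbind, res)
  out[order(out$label), , drop = FALSE]
}
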