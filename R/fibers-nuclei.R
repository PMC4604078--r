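#' Classify centrally nucleated (C/N) fibers
#'
#' Step vi of the macro: nuclei are thresholded and labelled (8-connected)
#' in the nuclei channel, and a fiber is called centrally nucleated when at
#' least one nucleus centroid lies deeper inside the fiber than
#' `central_margin_fraction` times the fiber's equivalent-circle radius.
#' The per-fiber maximum centroid depth (as a fraction of the equivalent
#' radius) is returned so the sensitivity of the C/N call to the margin can
#' be inspected downstream.
#'
#' @param map a `labeled_fiber_map` from [label_fibers()]
#' @param nuclei single-channel numeric matrix, co-registered with the map
#' @param cfg a [morphometry_config()]
#' @return data.frame with columns label, n_central_nuclei,
#'   is_central_nucleated, max_nucleus_depth_frac
#' @export
classify_central_nucleation <- function(map, nuclei,
                                        cfg = morphometry_config()) {
  stopifnot(inherits(map, "labeled_fiber_map"),
            all(dim(nuclei) == dim(map$labels)))
  thr <- cfg$nucleus_threshold %||% otsu_threshold(nuclei)
  nucmask <- nuclei >= thr
  nuclab <- cpp_label_components(as_int_mat(nucmask), 8L)
  cents <- label_centroids(nuclab)
  lab <- map$labels
  labels <- sort(unique(lab[lab > 0L]))
  areas <- tabulate(lab[lab > 0L])
  r_eq <- sqrt(areas / pi)
  D <- as.matrix(EBImage::distmap(EBImage::Image((lab > 0L) * 1)))
  n_central <- integer(length(labels))
  depth <- numeric(length(labels))
  if (nrow(cents)) {
    rr <- pmin(pmax(round(cents[, "row"]), 1L), nrow(lab))
    cc <- pmin(pmax(round(cents[, "col"]), 1L), ncol(lab))
    for (i in seq_len(nrow(cents))) {
      k <- lab[rr[i], cc[i]]
      if (k == 0L) next
      frac <- D[rr[i], cc[i]] / r_eq[k]
      pos <- match(k, labels)
      depth[pos] <- max(depth[pos], frac)
      if (frac >= cfg$central_margin_fraction)
        n_central[pos] <- n_central[pos] + 1L
    }
  }
  data.frame(label = labels, n_central_nuclei = n_central,
             is_central_nucleated = n_central > 0L,
             max_nucleus_depth_frac = depth)
}

#' Summarise fiber morphometry records
#'
#' Produces the per-section summary reported alongside the figures: fiber
#' count, fibers per square millimetre of tissue, percent centrally
#' nucleated, mean minimum Feret diameter overall and split by C/N status,
#' and the minimum-Feret frequency histogram.
#'
#' @param records data.frame with at least `min_feret_um` and
#'   `is_central_nucleated` (e.g. merged output of [measure_fibers()] and
#'   [classify_central_nucleation()])
#' @param tissue_area_um2 analysed tissue area in square micrometres
#' @param bin_width_um histogram bin width, micrometres
#' @return list of class `morphometry_summary`: n_fibers, fibers_per_mm2,
#'   pct_central_nucleated, mean_min_feret_um, mean_min_feret_cn_um,
#'   mean_min_feret_non_cn_um, histogram (data.frame bin_low, bin_high,
#'   count)
#' @export
summarize_morphometry <- function(records, tissue_area_um2,
                                  bin_width_um = 5) {
  if (!nrow(records)) stop("no fiber records to summarise")
  stopifnot(tissue_area_um2 > 0, bin_width_um > 0)
  cn <- records$is_central_nucleated
  mf <- records$min_feret_um
  breaks <- seq(0, max(mf) + bin_width_um, by = bin_width_um)
  counts <- tabulate(findInterval(mf, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  structure(list(
    n_fibers = nrow(records),
    fibers_per_mm2 = nrow(records) / (tissue_area_um2 / 1e6),
    pct_central_nucleated = 100 * mean(cn),
    mean_min_feret_um = mean(mf),
    mean_min_feret_cn_um = if (any(cn)) mean(mf[cn]) else NA_real_,
    mean_min_feret_non_cn_um = if (any(!cn)) mean(mf[!cn]) else NA_real_,
    histogram = data.frame(bin_low = breaks[-length(breaks)],
                           bin_high = breaks[-1], count = counts)
  ), class = "morphometry_summary")
}

#' Run the full fiber morphometry macro on a membrane/nuclei image pair
#'
#' Convenience wrapper chaining [build_border_mask()], [label_fibers()],
#' [measure_fibers()], [classify_central_nucleation()] and
#' [summarize_morphometry()].
#'
#' @param membrane,nuclei co-registered single-channel matrices
#' @param cfg a [morphometry_config()]
#' @param bin_width_um histogram bin width
#' @return list with `records` (per-fiber data.frame), `summary`
#'   (`morphometry_summary`), and the intermediate `map`
#' @export
fiber_morphometry <- function(membrane, nuclei, cfg = morphometry_config(),
                              bin_width_um = 5) {
  mask <- build_border_mask(membrane, cfg)
  map <- label_fibers(mask, cfg)
  rec <- measure_fibers(map)
  if (nrow(rec)) {
    cn <- classify_central_nucleation(map, nuclei, cfg)
    rec <- merge(rec, cn, by = "label")
  }
  list(records = rec,
       summary = if (nrow(rec))
         summarize_morphometry(rec, map$tissue_area_um2, bin_width_um)
       else NULL,
       map = map)
}
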