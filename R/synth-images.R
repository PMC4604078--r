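#' Simulate an image with a known positive-area fraction
#'
#' Paints random disc-shaped patches until a target pixel count is reached,
#' then trims the final patch so the realized fraction equals the rounded
#' target exactly; the realized fraction is always recomputable by counting
#' painted pixels. Fixture for trichrome (blue-on-red) and IgG-influx
#' (bright-on-dark) area-fraction quantification.
#'
#' @param true_fraction target positive fraction in [0, 1]
#' @param size_px image size c(rows, cols)
#' @param mode `"rgb"` (blue patches on tissue-red background, near-white
#'   frame corners excluded as non-tissue do not occur: the whole frame is
#'   tissue) or `"gray"` (bright patches on dark background)
#' @param positive_color RGB triple in [0, 1] for positive pixels (rgb mode)
#' @param background_color RGB triple for the tissue background (rgb mode)
#' @param seed integer seed
#' @return list with `image` (matrix for gray, rows x cols x 3 array for
#'   rgb), `realized_fraction`, and the logical `positive_mask`
#' @export
generate_area_fraction_image <- function(true_fraction, size_px = c(256, 256),
                                         mode = c("rgb", "gray"),
                                         positive_color = c(0.15, 0.25, 0.75),
                                         background_color = c(0.80, 0.35, 0.30),
                                         seed) {
  stopifnot(true_fraction >= 0, true_fraction <= 1)
  mode <- match.arg(mode)
  ny <- as.integer(size_px[1]); nx <- as.integer(size_px[2])
  npx <- ny * nx
  target <- round(true_fraction * npx)
  mask <- with_seed(seed, {
    m <- matrix(FALSE, ny, nx)
    if (target >= npx) {
      m[] <- TRUE
    } else if (target > 0) {
      while (sum(m) < target) {
        r0 <- runif(1, 1, ny); c0 <- runif(1, 1, nx)
        rad <- runif(1, 3, 9)
        rs <- max(1L, floor(r0 - rad)):min(ny, ceiling(r0 + rad))
        cs <- max(1L, floor(c0 - rad)):min(nx, ceiling(c0 + rad))
        dy <- outer(rs - r0, rep(1, length(cs)))
        dx <- outer(rep(1, length(rs)), cs - c0)
        patch <- dy^2 + dx^2 <= rad^2
        new <- which(patch & !m[rs, cs], arr.ind = TRUE)
        if (!nrow(new)) next
        excess <- sum(m) + nrow(new) - target
        if (excess > 0) new <- new[seq_len(nrow(new) - excess), , drop = FALSE]
        m[cbind(rs[new[, 1]], cs[new[, 2]])] <- TRUE
      }
    }
    m
  })
  realized <- sum(mask) / npx
  img <- if (mode == "gray") {
    0.05 + 0.85 * mask
  } else {
    arr <- array(0, dim = c(ny, nx, 3))
    for (ch in 1:3)
      arr[, , ch] <- ifelse(mask, positive_color[ch], background_color[ch])
    arr
  }
  list(image = img, realized_fraction = realized, positive_mask = mask)
}

#' Simulate a field of disjoint bright cells
#'
#' Places exactly `n_cells` non-overlapping bright discs on a dark
#' background; fixture for thresholded cell counting.
#'
#' @param n_cells number of cells (>= 0)
#' @param size_px image size c(rows, cols)
#' @param radius_px disc radius in pixels
#' @param seed integer seed
#' @return list with `image` (numeric matrix in [0, 1]), `n_cells`, and
#'   `centers` (n x 2 matrix of row/col)
#' @export
generate_cell_field <- function(n_cells, size_px = c(256, 256), radius_px = 4,
                                seed) {
  stopifnot(n_cells >= 0, radius_px >= 1)
  ny <- as.integer(size_px[1]); nx <- as.integer(size_px[2])
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    min_sep <- 2 * radius_px + 3
    tries <- 0L
    while (nrow(centers) < n_cells) {
      if (tries > 200L * max(1L, n_cells))
        stop("cell density too high: cannot place ", n_cells,
             " disjoint cells of radius ", radius_px)
      tries <- tries + 1L
      p <- c(runif(1, radius_px + 1, ny - radius_px),
             runif(1, radius_px + 1, nx - radius_px))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >= min_sep^2))
        centers <- rbind(centers, p)
    }
    mask <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(centers))) {
      r0 <- centers[i, 1]; c0 <- centers[i, 2]
      rs <- max(1L, floor(r0 - radius_px)):min(ny, ceiling(r0 + radius_px))
      cs <- max(1L, floor(c0 - radius_px)):min(nx, ceiling(c0 + radius_px))
      dy <- outer(rs - r0, rep(1, length(cs)))
      dx <- outer(rep(1, length(rs)), cs - c0)
      mask[rs, cs] <- mask[rs, cs] | (dy^2 + dx^2 <= radius_px^2)
    }
    img <- 0.05 + 0.85 * mask
    list(image = img, n_cells = n_cells, centers = centers)
  })
}
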