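#' Simulate a trabecular bone micro-CT volume with exact ground truth
#'
#' Builds idealised trabecular geometry -- parallel plates, a square rod
#' lattice, or a sphere lattice -- on a voxel grid, then renders a grayscale
#' volume (bone vs marrow intensity plus Gaussian noise). All truth
#' quantities are fixed by construction before noise: for parallel plates
#' the bone volume fraction within complete plate/gap periods equals
#' tb_th / (tb_th + tb_sp) exactly.
#'
#' Plates and gaps are stacked along the third (slice) axis. `truth$roi`
#' gives the slice range covering complete periods, `truth$seeds` one seed
#' voxel per connected bone component (for seeded region growing).
#'
#' @param kind geometry: "parallel_plates", "rods" or "spheres"
#' @param tb_th_um trabecular thickness (plate/rod/sphere diameter), um;
#'   must be a whole number of voxels
#' @param tb_sp_um trabecular separation (gap), um; whole voxels; 0 gives a
#'   solid volume
#' @param size_vox volume size c(n1, n2, n_slices)
#' @param um_per_vox isotropic voxel pitch in micrometres
#' @param noise_sd Gaussian noise SD on the intensity scale
#' @param seed integer seed
#' @param bone_intensity,background_intensity mean intensities of the two
#'   phases
#' @return list with `volume` (numeric 3-D array), `mask` (true bone,
#'   logical), and `truth` (list: bvtv, tb_th_um, tb_sp_um, geometry_kind,
#'   roi = c(start_slice, n_slices), seeds = matrix of voxel indices)
#' @export
generate_trabecular_volume <- function(kind = c("parallel_plates", "rods",
                                                "spheres"),
                                       tb_th_um, tb_sp_um,
                                       size_vox = c(128, 128, 128),
                                       um_per_vox = 8, noise_sd = 0.05, seed,
                                       bone_intensity = 0.75,
                                       background_intensity = 0.15) {
  kind <- match.arg(kind)
  t_vox <- tb_th_um / um_per_vox
  s_vox <- tb_sp_um / um_per_vox
  if (abs(t_vox - round(t_vox)) > 1e-9 || abs(s_vox - round(s_vox)) > 1e-9)
    stop("tb_th_um and tb_sp_um must be whole numbers of voxels")
  t_vox <- as.integer(round(t_vox)); s_vox <- as.integer(round(s_vox))
  stopifnot(t_vox >= 1, s_vox >= 0)
  n1 <- size_vox[1]; n2 <- size_vox[2]; n3 <- size_vox[3]
  period <- t_vox + s_vox

  if (kind == "parallel_plates") {
    z <- seq_len(n3) - 1L
    plate <- (z %% period) < t_vox
    mask <- array(rep(plate, each = n1 * n2), dim = c(n1, n2, n3))
    n_periods <- n3 %/% period
    roi <- c(1L, if (n_periods >= 1) n_periods * period else n3)
    starts <- z[plate & (z %% period) == 0L]
    seeds <- cbind(ceiling(n1 / 2), ceiling(n2 / 2),
                   pmin(n3, starts + t_vox %/% 2 + 1L))
  } else if (kind == "rods") {
    x <- (seq_len(n1) - 1L) %% period
    y <- (seq_len(n2) - 1L) %% period
    r <- t_vox / 2
    cx <- (x + 0.5) - period / 2
    cy <- (y + 0.5) - period / 2
    sl <- outer(cx, cy, function(a, b) a^2 + b^2 <= r^2)
    mask <- array(rep(sl, n3), dim = c(n1, n2, n3))
    roi <- c(1L, n3)
    ctr <- period %/% 2
    seeds <- cbind(ctr + 1L, ctr + 1L, ceiling(n3 / 2))
  } else {
    g1 <- (seq_len(n1) - 0.5) %% period - period / 2
    g2 <- (seq_len(n2) - 0.5) %% period - period / 2
    g3 <- (seq_len(n3) - 0.5) %% period - period / 2
    r <- t_vox / 2
    mask <- outer(outer(g1^2, g2^2, `+`), g3^2, `+`) <= r^2
    roi <- c(1L, n3)
    ctr <- period %/% 2
    seeds <- cbind(ctr, ctr, ctr)
  }

  bv <- mask[, , roi[1]:(roi[1] + roi[2] - 1L), drop = FALSE]
  truth <- list(bvtv = mean(bv), tb_th_um = tb_th_um, tb_sp_um = tb_sp_um,
                geometry_kind = kind, roi = roi, seeds = seeds,
                um_per_vox = um_per_vox)
  vol <- with_seed(seed, {
    v <- ifelse(mask, bone_intensity, background_intensity)
    if (noise_sd > 0) v <- v + array(rnorm(length(v), 0, noise_sd), dim = dim(v))
    v
  })
  list(volume = vol, mask = mask, truth = truth)
}
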