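#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All randomness in the package flows through this helper: the global RNG
#' state is saved, the seed applied, and the state restored afterwards, so
#' generators are reproducible without clobbering the session RNG.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold of a numeric image or vector
#'
#' Maximises between-class variance on a 256-bin histogram of the data
#' range. Used wherever a configuration leaves a threshold to be derived
#' automatically from the image.
#'
#' @param x numeric vector, matrix or array of intensities
#' @param levels number of histogram bins
#' @return the threshold intensity (scalar)
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# shoelace polygon area; vertices as n x 2 matrix, any orientation
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# centroids of labelled pixels; returns matrix with columns (label, row, col)
label_centroids <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(matrix(numeric(0), ncol = 3,
                                  dimnames = list(NULL, c("label", "row", "col"))))
  nr <- nrow(lab)
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  l <- lab[idx]
  cbind(label = sort(unique(l)),
        row = as.numeric(tapply(r, l, mean)),
        col = as.numeric(tapply(c_, l, mean)))
}

# binary matrix to integer (for the compiled kernels)
as_int_mat <- function(x) {
  m <- matrix(as.integer(x != 0), nrow = nrow(x))
  m
}
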