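# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) label
# assignments (distribution of U is symmetric about n1*n2/2)
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# greedy Ward agglomeration: at each step merge the pair of clusters with
# the smallest increase in total within-cluster sum of squares; returns the
# sequence of merged leaf sets
oracle_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(X[a, , drop = FALSE])
        cb <- colMeans(X[b, , drop = FALSE])
        d <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# merged leaf sets from an hclust merge matrix, in merge order
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

# independent ddct arithmetic: explicit loops, no shared code path
oracle_ddct <- function(ct, refs, groups, calibrator) {
  targets <- setdiff(colnames(ct), refs)
  out <- list()
  for (g in targets) {
    dct <- numeric(nrow(ct))
    for (s in seq_len(nrow(ct)))
      dct[s] <- ct[s, g] - mean(ct[s, refs])
    cal_mean <- mean(dct[groups == calibrator])
    for (grp in unique(groups)) {
      dd <- mean(dct[groups == grp]) - cal_mean
      out[[paste(g, grp)]] <- data.frame(gene = g, group = grp,
                                         fold_change = 2^-dd)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random convex polygon via polar-sorted random vertices
random_convex_polygon <- function(n) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 5, 40)
  pts <- cbind(r * cos(ang), r * sin(ang))
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}
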