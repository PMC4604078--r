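test_that("geNorm M values behave on degenerate and planted tables", {
  # all genes identical across samples -> every M is 0
  ct0 <- matrix(rep(c(20, 22, 25, 21), 3), ncol = 3,
                dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  expect_true(all(genorm_stability(ct0)$M < 1e-12))

  # two genes differing by a constant offset have pairwise ratio SD 0
  set.seed(1)
  base <- rnorm(6, 22, 2)
  ct <- cbind(a = base, b = base + 3, c = base + rnorm(6, 0, 1))
  rownames(ct) <- paste0("s", 1:6)
  gs <- genorm_stability(ct)
  expect_equal(gs$exclusion_order[1], "c")
  # M of a and b comes only from the noisy partner, and is equal
  expect_equal(unname(gs$M["a"]), unname(gs$M["b"]))

  # 3 perfectly covarying + 1 noisy candidate: noisy gene excluded first
  ct4 <- cbind(r1 = base, r2 = base + 1, r3 = base - 2,
               noisy = base + rnorm(6, 0, 2))
  rownames(ct4) <- paste0("s", 1:6)
  expect_equal(genorm_stability(ct4)$exclusion_order[1], "noisy")
  expect_setequal(genorm_stability(ct4)$retained, c("r1", "r2", "r3")[
    c("r1", "r2", "r3") %in% genorm_stability(ct4)$retained])

  expect_error(genorm_stability(ct[, 1:2]), "at least 3")
})

test_that("geNorm ranking is invariant to per-gene constant Ct offsets", {
  ct <- generate_ct_table(8, paste0("g", 1:5), stable_refs = 2,
                          noise_sd = 0.6, seed = 13)
  shifted <- sweep(ct, 2, c(5, -3, 0, 1, 2), `+`)
  expect_equal(genorm_stability(ct)$exclusion_order,
               genorm_stability(shifted)$exclusion_order)
  expect_equal(genorm_stability(ct)$M, genorm_stability(shifted)$M)
})

test_that("ddct reproduces hand-computed fold changes", {
  # one cycle lower in treated with unchanged references -> fold 2
  ct <- cbind(ref = rep(20, 6), tgt = c(25, 25, 25, 24, 24, 24))
  rownames(ct) <- paste0("s", 1:6)
  groups <- rep(c("ctrl", "trt"), each = 3)
  r <- ddct(ct, "ref", groups, "ctrl")
  expect_equal(r$fold_change[r$group == "ctrl"], 1)
  expect_equal(r$fold_change[r$group == "trt"], 2)

  # ddCt = 0 -> fold 1
  ct_eq <- cbind(ref = rnorm(6, 20), tgt = rnorm(6, 25))
  ct_eq[4:6, "tgt"] <- ct_eq[1:3, "tgt"]
  ct_eq[4:6, "ref"] <- ct_eq[1:3, "ref"]
  rownames(ct_eq) <- paste0("s", 1:6)
  r2 <- ddct(ct_eq, "ref", groups, "ctrl")
  expect_equal(r2$fold_change, c(1, 1))

  expect_error(ddct(ct, "nope", groups, "ctrl"), "not in table")
  expect_error(ddct(ct, "ref", groups, "missing"), "not present")
})

test_that("ddct matches an independent arithmetic oracle on random tables", {
  set.seed(31)
  ct <- matrix(rnorm(8 * 5, 25, 3), 8, 5,
               dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  groups <- rep(c("wt", "mdx"), each = 4)
  mine <- ddct(ct, c("g1", "g2"), groups, "wt")
  orac <- oracle_ddct(ct, c("g1", "g2"), groups, "wt")
  m <- merge(mine, orac, by = c("gene", "group"))
  expect_equal(m$fold_change.x, m$fold_change.y, tolerance = 1e-9)
})

test_that("ddct is equivariant under per-sample constant Ct shifts", {
  set.seed(32)
  ct <- matrix(rnorm(8 * 4, 25, 2), 8, 4,
               dimnames = list(paste0("s", 1:8), paste0("g", 1:4)))
  groups <- rep(c("a", "b"), each = 4)
  shifted <- ct
  shifted[3, ] <- shifted[3, ] + 4  # one sample loaded differently
  expect_equal(ddct(ct, c("g1", "g2"), groups, "a")$fold_change,
               ddct(shifted, c("g1", "g2"), groups, "a")$fold_change,
               tolerance = 1e-12)
})

test_that("z-scoring removes bad rows and normalises the rest", {
  m <- rbind(a = c(10, 100), b = c(1, 1), c = c(5, 50), d = c(NA, 3))
  z <- zscore_log(m)
  expect_equal(z$removed_missing, "d")
  expect_equal(z$removed_constant, "b")
  expect_equal(unname(z$z["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_true(all(abs(rowMeans(z$z)) < 1e-9))
  expect_true(all(abs(apply(z$z, 1, sd) - 1) < 1e-9))
  expect_error(zscore_log(rbind(c(-1, 2))), "non-negative")
})

test_that("Ward clustering merges identical rows first at height zero", {
  x <- rbind(a = c(0, 0, 0), b = c(5, 5, 1), c = c(0, 0, 0))
  hc <- ward_cluster(x)
  expect_equal(sort(hc$merge[1, ]), c(-3, -1))
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("Ward merge sequence matches the brute-force oracle up to n = 12", {
  set.seed(23)
  for (n in c(6, 9, 12)) {
    X <- matrix(rnorm(n * 4), n, 4)
    hc <- ward_cluster(X)
    expect_identical(hclust_merge_sets(hc), oracle_ward_merges(X))
  }
})

test_that("Ward result is invariant to input row order up to leaf naming", {
  set.seed(29)
  X <- matrix(rnorm(10 * 3), 10, 3)
  rownames(X) <- paste0("r", 1:10)
  perm <- sample(10)
  h1 <- ward_cluster(X)
  h2 <- ward_cluster(X[perm, ])
  relabel <- function(sets, names) lapply(sets, function(s) sort(names[s]))
  expect_setequal(relabel(hclust_merge_sets(h1), rownames(X)),
                  relabel(hclust_merge_sets(h2), rownames(X)[perm]))
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
})

test_that("dendrograms export to Newick and read back with ape", {
  fx <- generate_fpkm_matrix(12, 6, seed = 4)
  hc <- ward_cluster(zscore_log(fx$fpkm)$z, "columns")
  nwk <- dendrogram_newick(hc)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, hc$labels)
})
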