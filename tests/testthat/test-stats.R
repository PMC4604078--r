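test_that("analytic p kernels reproduce published statistic-p pairs", {
  expect_equal(round(p_from_t(2.3, 26), 3), 0.030)
  expect_lt(p_from_t(6.99, 6), 0.001)
  expect_equal(round(p_from_t(4.73, 4), 3), 0.009)
  expect_equal(round(p_from_f(11.57, 2, 9), 3), 0.003)
  expect_equal(round(p_from_f(5.52, 2, 8), 3), 0.031)
  expect_equal(p_from_t(0, 17), 1)
  expect_equal(p_from_f(0, 2, 10), 1)
  expect_error(p_from_t(1, 0), "df")
  expect_error(p_from_f(-1, 2, 4), "non-negative")
})

test_that("p kernels are strictly decreasing in their statistic", {
  ts <- seq(0, 6, by = 0.5)
  expect_true(all(diff(p_from_t(ts, 9)) < 0))
  fs <- seq(0, 30, by = 2)
  expect_true(all(diff(vapply(fs, p_from_f, 1, 2, 9)) < 0))
  hs <- seq(0.5, 12, by = 0.5)
  expect_true(all(diff(exp(-hs / 2)) < 0))
})

test_that("two-group ANOVA equals the squared t test", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    tt <- t_test_groups(x, y)
    av <- one_way_anova(list(a = x, b = y))
    expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(av$p, tt$p, tolerance = 1e-10)
  }
})

test_that("ANOVA handles identical groups and degenerate input", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- one_way_anova(g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("Tukey HSD orders pairs by separation and handles equality", {
  g_eq <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  th <- tukey_hsd(g_eq)
  expect_true(all(th$p_adj > 0.999))
  set.seed(9)
  g <- list(a = rnorm(6), b = rnorm(6), far = rnorm(6, 10))
  th2 <- tukey_hsd(g)
  far_p <- th2$p_adj[grepl("far", th2$pair)]
  other_p <- th2$p_adj[!grepl("far", th2$pair)]
  expect_true(max(far_p) < min(other_p))
  expect_error(tukey_hsd(g_eq[1:2]), "at least 3")
})

test_that("Tukey HSD is consistent with a permutation-of-pairs oracle", {
  set.seed(77)
  g <- list(a = rnorm(8, 0), b = rnorm(8, 1.2), c = rnorm(8, 0.3))
  th <- tukey_hsd(g)
  # max-|t| permutation oracle for the family of pairwise comparisons
  v <- unlist(g); gi <- rep(1:3, each = 8)
  pair_t <- function(v, gi) {
    ms <- tapply(v, gi, mean); ns <- tabulate(gi)
    s2 <- sum((v - ms[gi])^2) / (length(v) - 3)
    combs <- utils::combn(3, 2)
    apply(combs, 2, function(pr)
      abs(ms[pr[1]] - ms[pr[2]]) / sqrt(s2 * (1 / ns[pr[1]] + 1 / ns[pr[2]])))
  }
  obs <- pair_t(v, gi)
  B <- 2000
  set.seed(78)
  exceed <- matrix(0L, B, 3)
  for (b in 1:B) exceed[b, ] <- max(pair_t(v, sample(gi))) >= obs - 1e-12
  p_perm <- colMeans(exceed)
  ord <- order(th$p_adj)
  expect_equal(order(p_perm), ord)
  expect_lt(max(abs(sort(p_perm) - sort(th$p_adj))), 0.12)
})

test_that("Mann-Whitney W is the first sample's rank sum", {
  mw <- mann_whitney(c(5, 7, 9), c(1, 2, 3))
  expect_equal(mw$statistic, sum(rank(c(5, 7, 9, 1, 2, 3))[1:3]))
})

test_that("Mann-Whitney reproduces the published large-sample case", {
  # reconstruct samples with rank sum 388 for n = 18 vs 16 (no ties)
  set.seed(1)
  repeat {
    x <- sample(1:34, 18)
    if (sum(x) == 388) break
  }
  y <- setdiff(1:34, x)
  mw <- mann_whitney(as.numeric(x), as.numeric(y))
  expect_equal(mw$statistic, 388)
  expect_equal(round(mw$p, 3), 0.012)
})

test_that("Mann-Whitney exact path equals full enumeration for n <= 6", {
  set.seed(6)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    mw <- mann_whitney(x, y)
    expect_equal(mw$p, oracle_mw_exact_p(x, y), tolerance = 1e-12,
                 label = paste("n1 =", n1, "n2 =", n2))
  }
  # complete separation, 4 vs 4: p = 2/70
  mw <- mann_whitney(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(mw$p, 2 / 70, tolerance = 1e-12)
  # perfectly interleaved samples are far from rejection
  mw_i <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_gt(mw_i$p, 0.6)
})

test_that("Kruskal-Wallis p follows the chi-square closed form at df = 2", {
  set.seed(12)
  for (i in 1:10) {
    g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
    kw <- kruskal_wallis(g)
    expect_equal(kw$p, exp(-kw$statistic / 2), tolerance = 1e-12)
  }
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw0 <- kruskal_wallis(g0)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
})

test_that("Anderson-Darling calibrates near its nominal level", {
  set.seed(41)
  rej <- mean(replicate(800, anderson_darling(rnorm(30))$p < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  rej_heavy <- mean(replicate(300, {
    x <- rnorm(50) * ifelse(runif(50) < 0.15, 6, 1)
    anderson_darling(x)$p < 0.05
  }))
  expect_gt(rej_heavy, 0.5)
  expect_error(anderson_darling(rep(1, 20)), "constant")
  expect_warning(small <- anderson_darling(rnorm(5)), "skipped")
  expect_null(small)
})

test_that("permutation ANOVA is seeded, bounded and consistent", {
  g_far <- list(a = rnorm(6), b = rnorm(6, 100))
  r <- permutation_anova(g_far, B = 199, seed = 2)
  expect_equal(r$p, 1 / 200)  # lower bound attained at huge separation
  r2 <- permutation_anova(g_far, B = 199, seed = 2)
  expect_identical(r$p, r2$p)
  expect_error(permutation_anova(g_far, B = 50, seed = 1), "B must be")
  # converges to the parametric p on large normal samples
  set.seed(19)
  g <- list(a = rnorm(60), b = rnorm(60, 0.4), c = rnorm(60))
  pa <- permutation_anova(g, B = 1999, seed = 3)
  av <- one_way_anova(g)
  mc_sd <- sqrt(av$p * (1 - av$p) / 1999)
  expect_lt(abs(pa$p - av$p), 2 * mc_sd + 0.005)
})

test_that("the decision pipeline routes by design", {
  cfg <- decision_config(seed = 8, permutation_B = 199)
  # two groups never produce Tukey output
  set.seed(2)
  r2g <- decision_pipeline(list(a = rnorm(10), b = rnorm(10, 3)), cfg)
  expect_null(r2g$posthoc)
  expect_equal(r2g$decision_path[1], "t_test")

  # significant + normal: permutation runs alongside
  expect_true("permutation_anova(label_shuffle)" %in% r2g$decision_path ||
                attr(r2g, "anderson_darling")$p < 0.05)

  # a clearly non-normal significant dataset walks ANOVA -> AD -> routed
  set.seed(5)
  g_ln <- list(a = exp(rnorm(12, 0, 1)), b = 6 + 2 * exp(rnorm(12, 0, 1)),
               c = 14 + 3 * exp(rnorm(12, 0, 1)))
  r3 <- decision_pipeline(g_ln, cfg)
  expect_true(all(c("one_way_anova", "anderson_darling_gate",
                    "routed_kruskal_wallis") %in% r3$decision_path))
  expect_equal(r3$statistic_kind, "H")
})

test_that("stars follow the {0.05, 0.005, 0.001} legend convention", {
  expect_equal(stars_for_p(0.2), "")
  expect_equal(stars_for_p(0.04), "*")
  expect_equal(stars_for_p(0.004), "**")
  expect_equal(stars_for_p(0.0005), "***")
  expect_error(stars_for_p(0.01, c(0.05, 0.05, 0.001)), "decrease")
  expect_error(decision_config(seed = 1,
                               star_thresholds = c(0.05, 0.1, 0.001)),
               "decrease")
})
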