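#' Construct a test result record
#'
#' Common container for every statistical kernel: the statistic kind and
#' value, degrees of freedom, p value, optional post-hoc table, the
#' ordered decision path that produced the number, and the significance
#' stars under the configured thresholds.
#'
#' @param statistic_kind one of "t", "F", "W_ranksum", "H", "A2", "F_perm"
#' @param statistic statistic value
#' @param df integer degrees of freedom (length 1 or 2)
#' @param p p value in (0, 1]
#' @param posthoc optional data.frame of pairwise comparisons
#' @param decision_path character vector of applied rules, in order
#' @param star_thresholds strictly decreasing significance thresholds
#' @return object of class `test_result`
#' @export
test_result <- function(statistic_kind, statistic, df, p, posthoc = NULL,
                        decision_path = character(0),
                        star_thresholds = c(0.05, 0.005, 0.001)) {
  stopifnot(p > 0, p <= 1 + 1e-12)
  structure(list(statistic_kind = statistic_kind, statistic = statistic,
                 df = df, p = min(p, 1), posthoc = posthoc,
                 decision_path = decision_path,
                 stars = stars_for_p(p, star_thresholds)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s = %.4g, df = %s, p = %.4g %s\n", x$statistic_kind,
              x$statistic, dfs, x$p, x$stars))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, ...)
  }
  if (length(x$decision_path))
    cat("decision path:", paste(x$decision_path, collapse = " -> "), "\n")
  invisible(x)
}

#' Significance stars for a p value
#'
#' Uses the figure-legend convention *p < 0.05, **p < 0.005, ***p < 0.001
#' (note the unusual middle threshold); thresholds are configurable but
#' must decrease strictly.
#'
#' @param p p value
#' @param thresholds strictly decreasing vector of thresholds
#' @return a string of 0 to `length(thresholds)` stars
#' @export
stars_for_p <- function(p, thresholds = c(0.05, 0.005, 0.001)) {
  if (any(diff(thresholds) >= 0)) stop("thresholds must strictly decrease")
  strrep("*", sum(p < thresholds))
}

#' Two-sided p value from a t statistic
#'
#' @param t t statistic
#' @param df degrees of freedom (>= 1)
#' @return 2 x upper-tail t probability at |t|
#' @export
p_from_t <- function(t, df) {
  if (df < 1) stop("df must be >= 1")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Upper-tail p value from an F statistic
#'
#' For df1 = 2 this equals the closed form (1 + 2F/df2)^(-df2/2), which is
#' used as a cross-check in the test-suite.
#'
#' @param f F statistic (>= 0)
#' @param df1,df2 numerator and denominator degrees of freedom (> 0)
#' @return upper-tail F probability
#' @export
p_from_f <- function(f, df1, df2) {
  if (df1 <= 0 || df2 <= 0) stop("degrees of freedom must be positive")
  if (f < 0) stop("F must be non-negative")
  pf(f, df1, df2, lower.tail = FALSE)
}

# normalise a groups argument: named list of numeric vectors
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, as.character(groups$group))
  }
  if (!is.list(groups)) stop("groups must be a named list or data.frame")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Unpaired Student's t test for two groups
#'
#' Classical pooled-variance (equal-variance) unpaired t test, the
#' convention consistent with the integer degrees of freedom printed in
#' the source figure legends.
#'
#' @param x,y numeric samples (each n >= 2)
#' @param star_thresholds passed to [test_result()]
#' @return a `test_result` with kind "t"
#' @export
t_test_groups <- function(x, y, star_thresholds = c(0.05, 0.005, 0.001)) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  tt <- t.test(x, y, var.equal = TRUE)
  test_result("t", unname(tt$statistic), as.integer(unname(tt$parameter)),
              tt$p.value, decision_path = "t_test",
              star_thresholds = star_thresholds)
}

#' One-way ANOVA
#'
#' Classical between-groups F test (df1 = k - 1, df2 = N - k) via
#' [stats::aov()].
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   columns `group` and `value`; each group needs n >= 2
#' @param star_thresholds passed to [test_result()]
#' @return a `test_result` with kind "F"; the fitted aov object is
#'   attached as attribute "fit"
#' @export
one_way_anova <- function(groups, star_thresholds = c(0.05, 0.005, 0.001)) {
  g <- as_group_list(groups)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2)) stop("each group needs n >= 2")
  dat <- data.frame(value = unlist(g, use.names = FALSE),
                    group = factor(rep(names(g), lengths(g))))
  fit <- aov(value ~ group, data = dat)
  tab <- anova(fit)
  res <- test_result("F", tab$`F value`[1],
                     as.integer(tab$Df), tab$`Pr(>F)`[1],
                     decision_path = "one_way_anova",
                     star_thresholds = star_thresholds)
  attr(res, "fit") <- fit
  res
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range-based all-pairs comparisons after one-way ANOVA;
#' unbalanced designs use the Tukey-Kramer standard error (as implemented
#' by [stats::TukeyHSD()]).
#'
#' @inheritParams one_way_anova
#' @return data.frame with columns pair, diff, p_adj
#' @export
tukey_hsd <- function(groups) {
  g <- as_group_list(groups)
  if (length(g) < 3) stop("Tukey post hoc needs at least 3 groups")
  res <- one_way_anova(g)
  th <- TukeyHSD(attr(res, "fit"))$group
  data.frame(pair = rownames(th), diff = th[, "diff"],
             p_adj = th[, "p adj"], row.names = NULL)
}

#' Mann-Whitney U test with W reported as the first sample's rank sum
#'
#' W is the sum of the ranks of the FIRST sample in the pooled ranking
#' (the only reading consistent with the printed W = 388 for group sizes
#' 18 and 16). The exact null distribution ([stats::pwilcox]) is used when
#' n1 + n2 <= 12 and there are no ties; otherwise the normal approximation
#' with tie correction and (by default) continuity correction.
#'
#' @param x,y numeric samples (n >= 1 each)
#' @param exact force (TRUE) or suppress (FALSE) the exact path; default
#'   NULL chooses automatically
#' @param correct apply the continuity correction in the normal
#'   approximation
#' @param star_thresholds passed to [test_result()]
#' @return a `test_result` with kind "W_ranksum"
#' @export
mann_whitney <- function(x, y, exact = NULL, correct = TRUE,
                         star_thresholds = c(0.05, 0.005, 0.001)) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (n1 + n2 <= 12 && !ties)
  if (use_exact && ties)
    stop("exact Mann-Whitney p undefined with ties")
  if (use_exact) {
    lower <- pwilcox(U, n1, n2)
    upper <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    path <- "mann_whitney(exact)"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    dev <- U - mu
    cc <- if (correct) 0.5 * sign(dev) else 0
    z <- if (sig2 > 0) (dev - cc) / sqrt(sig2) else 0
    p <- 2 * pnorm(-abs(z))
    path <- "mann_whitney(normal_approx)"
  }
  test_result("W_ranksum", W, NA_integer_, p, decision_path = path,
              star_thresholds = star_thresholds)
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with an upper-tail chi-square p on k - 1 degrees of
#' freedom (for df = 2 the p value is exactly exp(-H/2)).
#'
#' @inheritParams one_way_anova
#' @return a `test_result` with kind "H"
#' @export
kruskal_wallis <- function(groups, star_thresholds = c(0.05, 0.005, 0.001)) {
  g <- as_group_list(groups)
  if (length(g) < 3) stop("Kruskal-Wallis needs at least 3 groups")
  kt <- kruskal.test(g)
  test_result("H", unname(kt$statistic), as.integer(unname(kt$parameter)),
              kt$p.value, decision_path = "kruskal_wallis",
              star_thresholds = star_thresholds)
}

#' Anderson-Darling normality test
#'
#' A2 statistic with small-sample correction and the case-3 (estimated
#' mean and variance) p approximation, via nortest. Requires n >= 8; a
#' constant sample is an error.
#'
#' @param x numeric sample
#' @return a `test_result` with kind "A2", or NULL (with a warning) when
#'   n < 8 so callers can record a skipped gate
#' @export
anderson_darling <- function(x) {
  x <- x[is.finite(x)]
  if (sd(x) == 0) stop("constant sample: normality test undefined")
  if (length(x) < 8) {
    warning("Anderson-Darling test skipped: n < 8")
    return(NULL)
  }
  at <- nortest::ad.test(x)
  test_result("A2", unname(at$statistic), NA_integer_, at$p.value,
              decision_path = "anderson_darling")
}

# fast one-way F statistic on a value vector and integer group index
fstat_fast <- function(v, gi, ns, k, n, sum_v, sum_v2) {
  sums <- vapply(seq_len(k), function(j) sum(v[gi == j]), 1)
  ssb <- sum(sums^2 / ns) - sum_v^2 / n
  ssw <- sum_v2 - sum(sums^2 / ns)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation one-way ANOVA by raw label shuffling
#'
#' The observed F statistic is compared with F statistics from B random
#' reassignments of group labels (drawn from the seeded generator); the p
#' value is (1 + #{F* >= F_obs}) / (B + 1), so it is bounded below by
#' 1/(B + 1).
#'
#' @inheritParams one_way_anova
#' @param B number of permutations (>= 99)
#' @param seed integer seed (mandatory: permutation p values are otherwise
#'   irreproducible)
#' @return a `test_result` with kind "F_perm" (statistic = observed F)
#' @export
permutation_anova <- function(groups, B = 9999, seed,
                              star_thresholds = c(0.05, 0.005, 0.001)) {
  if (B < 99) stop("B must be >= 99")
  g <- as_group_list(groups)
  if (length(g) < 2) stop("need at least 2 groups")
  v <- unlist(g, use.names = FALSE)
  gi <- rep(seq_along(g), lengths(g))
  ns <- lengths(g); k <- length(g); n <- length(v)
  sv <- sum(v); sv2 <- sum(v^2)
  f_obs <- fstat_fast(v, gi, ns, k, n, sv, sv2)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(B)) {
      f_b <- fstat_fast(v, sample(gi), ns, k, n, sv, sv2)
      if (f_b >= f_obs - 1e-12) h <- h + 1L
    }
    h
  })
  test_result("F_perm", f_obs, c(k - 1L, n - k), (1 + hits) / (B + 1),
              decision_path = "permutation_anova(label_shuffle)",
              star_thresholds = star_thresholds)
}
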