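#' Configuration for the statistical decision pipeline
#'
#' @param alpha significance level for the primary test and the gates
#' @param permutation_B permutations for the confirmatory permutation
#'   ANOVA
#' @param seed integer seed for the permutation draws (mandatory)
#' @param star_thresholds strictly decreasing star thresholds; the default
#'   follows the figure-legend convention {0.05, 0.005, 0.001}
#' @param normality_alpha level of the Anderson-Darling gate
#' @return object of class `decision_config`
#' @export
decision_config <- function(alpha = 0.05, permutation_B = 9999, seed,
                            star_thresholds = c(0.05, 0.005, 0.001),
                            normality_alpha = 0.05) {
  if (any(diff(star_thresholds) >= 0))
    stop("star thresholds must strictly decrease")
  if (missing(seed)) stop("a seed is required (permutation reproducibility)")
  structure(list(alpha = alpha, permutation_B = permutation_B, seed = seed,
                 star_thresholds = star_thresholds,
                 normality_alpha = normality_alpha),
            class = "decision_config")
}

#' The full statistical decision procedure
#'
#' Routes grouped measurements the way the study's analysis plan does:
#' two groups get an unpaired Student's t test; three or more get one-way
#' ANOVA with Tukey's post hoc. When the primary parametric p falls below
#' alpha, the Anderson-Darling normality gate is applied to the pooled
#' group-centred residuals (to account for possible heteroscedasticity and
#' non-normality): data flagged non-normal are re-routed to the
#' Mann-Whitney U (two groups) or Kruskal-Wallis H (three or more) test,
#' which then provides the reported p; otherwise a label-shuffling
#' permutation ANOVA is run alongside as confirmation. Every applied rule
#' is recorded, in order, in the result's `decision_path`.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   columns `group` and `value`
#' @param cfg a [decision_config()]
#' @return a `test_result`; for >= 3 groups the Tukey table is in
#'   `$posthoc`, any confirmatory permutation test in
#'   `attr(res, "permutation")`, and the gate result in
#'   `attr(res, "anderson_darling")`
#' @export
decision_pipeline <- function(groups, cfg) {
  stopifnot(inherits(cfg, "decision_config"))
  g <- as_group_list(groups)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2)) stop("each group needs n >= 2")
  path <- character(0)
  ad <- NULL
  perm <- NULL

  if (length(g) == 2) {
    primary <- t_test_groups(g[[1]], g[[2]], cfg$star_thresholds)
    path <- c(path, "t_test")
  } else {
    primary <- one_way_anova(g, cfg$star_thresholds)
    path <- c(path, "one_way_anova")
    primary$posthoc <- tukey_hsd(g)
    path <- c(path, "tukey_hsd")
  }

  if (primary$p < cfg$alpha) {
    resid <- unlist(lapply(g, function(v) v - mean(v)), use.names = FALSE)
    ad <- tryCatch(anderson_darling(resid), warning = function(w) {
      path <<- c(path, "anderson_darling_gate(skipped: n too small)")
      NULL
    })
    if (!is.null(ad)) path <- c(path, "anderson_darling_gate")
    nonnormal <- !is.null(ad) && ad$p < cfg$normality_alpha
    if (nonnormal) {
      routed <- if (length(g) == 2) {
        path <- c(path, "routed_mann_whitney")
        mann_whitney(g[[1]], g[[2]], star_thresholds = cfg$star_thresholds)
      } else {
        path <- c(path, "routed_kruskal_wallis")
        kruskal_wallis(g, star_thresholds = cfg$star_thresholds)
      }
      routed$posthoc <- primary$posthoc
      primary <- routed
    } else {
      perm <- permutation_anova(g, B = cfg$permutation_B, seed = cfg$seed,
                                star_thresholds = cfg$star_thresholds)
      path <- c(path, "permutation_anova(label_shuffle)")
    }
  }

  primary$decision_path <- path
  primary$stars <- stars_for_p(primary$p, cfg$star_thresholds)
  attr(primary, "anderson_darling") <- ad
  attr(primary, "permutation") <- perm
  primary
}
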