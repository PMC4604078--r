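#' geNorm reference-gene stability values and exclusion ranking
#'
#' For each candidate reference gene the stability value M is the mean,
#' over all other candidates, of the standard deviation across samples of
#' the pairwise log2 expression ratio. On the Ct scale the log2 ratio of
#' genes j and k is simply Ct_k - Ct_j, so M is computed directly from Ct
#' differences and is invariant to constant per-gene Ct offsets. The least
#' stable gene (highest M) is excluded and M recomputed, iterating until
#' two genes remain; those two are the recommended reference set.
#'
#' @param ct numeric matrix, samples x genes (Ct cycle values); missing
#'   values must be explicit NA and are rejected
#' @param candidates character vector of candidate reference genes
#'   (default: all columns); at least 3
#' @return list with `M` (named vector of initial stability values),
#'   `exclusion_order` (genes in order of removal, least stable first) and
#'   `retained` (the final pair, most stable)
#' @export
genorm_stability <- function(ct, candidates = colnames(ct)) {
  stopifnot(is.matrix(ct), nrow(ct) >= 2)
  if (length(candidates) < 3)
    stop("need at least 3 candidate reference genes to rank stability")
  sub <- ct[, candidates, drop = FALSE]
  if (anyNA(sub)) stop("Ct table contains missing values; handle explicitly")
  m_of <- function(mat) {
    g <- colnames(mat)
    vapply(g, function(j) {
      others <- setdiff(g, j)
      mean(vapply(others, function(k) sd(mat[, k] - mat[, j]), 1))
    }, 1)
  }
  M0 <- m_of(sub)
  excl <- character(0)
  mat <- sub
  while (ncol(mat) > 2) {
    m <- m_of(mat)
    worst <- names(which.max(m))
    excl <- c(excl, worst)
    mat <- mat[, setdiff(colnames(mat), worst), drop = FALSE]
  }
  list(M = M0, exclusion_order = excl, retained = colnames(mat))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct_target - mean(Ct of the reference genes); per
#' group, ddCt = mean dCt(group) - mean dCt(calibrator group); fold change
#' = 2^-ddCt. The calibrator group's fold change is 1 by construction.
#' Including the references makes fold changes invariant to a constant Ct
#' shift of any sample (loading differences).
#'
#' @param ct numeric matrix, samples x genes
#' @param reference_genes character vector of reference gene columns
#' @param groups factor or character vector of group membership, one per
#'   sample (row)
#' @param calibrator name of the calibrator group
#' @param aggregate `"mean_dct"` (default: group mean of per-sample dCt,
#'   the conventional reading) or `"mean_fold"` (mean of per-sample fold
#'   changes)
#' @return data.frame with columns gene, group, fold_change
#' @export
ddct <- function(ct, reference_genes, groups, calibrator,
                 aggregate = c("mean_dct", "mean_fold")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(ct), length(groups) == nrow(ct))
  missing_refs <- setdiff(reference_genes, colnames(ct))
  if (length(missing_refs))
    stop("reference genes not in table: ", paste(missing_refs, collapse = ", "))
  groups <- as.character(groups)
  if (!calibrator %in% groups)
    stop("calibrator group '", calibrator, "' not present")
  if (anyNA(ct)) stop("Ct table contains missing values; handle explicitly")
  targets <- setdiff(colnames(ct), reference_genes)
  ref_mean <- rowMeans(ct[, reference_genes, drop = FALSE])
  out <- lapply(targets, function(g) {
    dct <- ct[, g] - ref_mean
    if (aggregate == "mean_dct") {
      gm <- tapply(dct, groups, mean)
      fold <- 2^-(gm - gm[[calibrator]])
    } else {
      f_s <- 2^-(dct - mean(dct[groups == calibrator]))
      fold <- tapply(f_s, groups, mean)
    }
    data.frame(gene = g, group = names(fold),
               fold_change = as.numeric(fold))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log-transform and row-wise z-score an FPKM matrix
#'
#' Rows (genes) containing missing values are removed, the matrix is
#' log-transformed with a pseudocount, and each remaining row is centred
#' and scaled to zero mean and unit SD. Rows with zero variance after the
#' log transform cannot be scaled and are removed (and reported).
#'
#' @param fpkm numeric matrix, genes x samples, values >= 0
#' @param base logarithm base
#' @param pseudocount added before the log
#' @return list with `z` (the z-scored matrix), `removed_missing` and
#'   `removed_constant` (row names)
#' @export
zscore_log <- function(fpkm, base = 2, pseudocount = 1) {
  stopifnot(is.matrix(fpkm))
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  miss <- apply(fpkm, 1, anyNA)
  m <- fpkm[!miss, , drop = FALSE]
  lm_ <- log(m + pseudocount) / log(base)
  sds <- apply(lm_, 1, sd)
  const <- sds == 0
  z <- t(scale(t(lm_[!const, , drop = FALSE])))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(z = z,
       removed_missing = rownames(fpkm)[miss] %||% character(0),
       removed_constant = rownames(lm_)[const] %||% character(0))
}

#' Ward hierarchical clustering of a z-scored matrix
#'
#' Agglomerative clustering minimising the within-cluster variance
#' increase (Ward linkage on Euclidean distances, the ward.D2 variant, in
#' which distances enter the criterion squared).
#'
#' @param z numeric matrix (typically from [zscore_log()])
#' @param axis cluster `"rows"` or `"columns"`
#' @return an [stats::hclust] object
#' @export
ward_cluster <- function(z, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- if (axis == "columns") t(z) else z
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  hclust(dist(x), method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an [stats::hclust] object
#' @param file optional path; when given the tree is written there
#' @return the Newick string, invisibly when written to file
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
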