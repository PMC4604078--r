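#' Simulate grouped measurements for the statistical decision pipeline
#'
#' Draws per-group samples from normal, lognormal (parameters on the log
#' scale) or contaminated-normal (10 percent of observations with 5x SD)
#' distributions. Each group carries its own seed so fixtures are
#' reproducible row for row.
#'
#' @param specs a data.frame (or list of lists) with columns/fields
#'   `group_name`, `n` (>= 2), `distribution` ("normal", "lognormal",
#'   "contaminated"), `mean`, `sd` (> 0), `seed`
#' @return data.frame with columns `group` and `value`; `sum(n)` rows
#' @export
generate_group_measurements <- function(specs) {
  if (is.data.frame(specs)) specs <- split(specs, seq_len(nrow(specs)))
  if (length(specs) < 2) stop("need at least 2 group specs")
  out <- lapply(specs, function(s) {
    s <- as.list(s)
    stopifnot(s$n >= 2, s$sd > 0)
    v <- with_seed(s$seed, switch(match.arg(s$distribution,
                                            c("normal", "lognormal",
                                              "contaminated")),
      normal = rnorm(s$n, s$mean, s$sd),
      lognormal = rlnorm(s$n, s$mean, s$sd),
      contaminated = {
        wide <- runif(s$n) < 0.1
        rnorm(s$n, s$mean, s$sd * ifelse(wide, 5, 1))
      }))
    data.frame(group = rep(as.character(s$group_name), s$n), value = v)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a qPCR Ct table with planted stable reference genes
#'
#' Every sample gets a random RNA-loading offset shared by all genes (this
#' is what reference normalisation removes). The first `stable_refs` genes
#' follow the loading offset with 5 percent of `noise_sd`; the remaining
#' genes add the full `noise_sd`, so the stable genes have the lowest
#' pairwise log-ratio SD by construction. With `noise_sd = 0` all genes
#' covary perfectly and every geNorm M value is 0.
#'
#' @param n_samples number of samples (rows)
#' @param genes character vector of gene names (columns)
#' @param stable_refs number of planted stable reference genes (>= 2),
#'   taken from the front of `genes`
#' @param noise_sd per-gene Ct noise SD in cycles
#' @param seed integer seed
#' @return numeric matrix samples x genes (dimnames set)
#' @export
generate_ct_table <- function(n_samples, genes, stable_refs = 3,
                              noise_sd = 0.5, seed) {
  stopifnot(stable_refs >= 2, stable_refs <= length(genes), n_samples >= 2)
  with_seed(seed, {
    loading <- rnorm(n_samples, 0, 1.5)
    base <- runif(length(genes), 18, 30)
    ct <- outer(loading, base, `+`)
    for (j in seq_along(genes)) {
      s <- if (j <= stable_refs) 0.05 * noise_sd else noise_sd
      if (s > 0) ct[, j] <- ct[, j] + rnorm(n_samples, 0, s)
    }
    dimnames(ct) <- list(paste0("sample_", seq_len(n_samples)), genes)
    ct
  })
}

#' Simulate an FPKM matrix with a planted sample-cluster structure
#'
#' Genes-by-samples abundance matrix in the cuffnorm layout (gene ids in
#' rows, samples in columns). Half the genes are up-regulated and half
#' down-regulated by `effect_fold` in the second sample cluster, so Ward
#' clustering of the z-scored matrix should recover the planted split.
#'
#' @param n_genes number of genes
#' @param n_samples number of samples
#' @param cluster_structure integer vector of planted cluster labels, one
#'   per sample (default: two equal halves)
#' @param effect_fold fold change separating the clusters
#' @param seed integer seed
#' @return list with `fpkm` (matrix, dimnames set) and `sample_cluster`
#' @export
generate_fpkm_matrix <- function(n_genes, n_samples,
                                 cluster_structure = NULL, effect_fold = 4,
                                 seed) {
  if (is.null(cluster_structure))
    cluster_structure <- rep(1:2, c(ceiling(n_samples / 2), floor(n_samples / 2)))
  stopifnot(length(cluster_structure) == n_samples)
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 2.5, sdlog = 1)
    dir <- rep(c(1, -1), length.out = n_genes)
    m <- matrix(0, n_genes, n_samples)
    for (s in seq_len(n_samples)) {
      fc <- ifelse(cluster_structure[s] == max(cluster_structure),
                   effect_fold^dir, 1)
      m[, s] <- base * fc * rlnorm(n_genes, 0, 0.2)
    }
    dimnames(m) <- list(paste0("gene_", seq_len(n_genes)),
                        paste0("sample_", seq_len(n_samples)))
    list(fpkm = m, sample_cluster = cluster_structure)
  })
}
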