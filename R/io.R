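#' Read a TIFF image or stack
#'
#' Single-page TIFFs return a matrix (or rows x cols x channels array for
#' RGB); multi-page stacks return a 3-D array with slices in the third
#' dimension. The pixel/voxel calibration is attached as attribute
#' `um_per_px` when supplied (TIFF files rarely carry a trustworthy
#' physical calibration, so it is passed explicitly and functions that
#' need it error when it is missing).
#'
#' @param path TIFF file
#' @param um_per_px optional calibration attached to the result
#' @return numeric matrix or array with intensities in [0, 1]
#' @export
read_image <- function(path, um_per_px = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- if (length(pages) == 1) pages[[1]] else simplify2array(pages)
  if (!is.null(um_per_px)) attr(img, "um_per_px") <- um_per_px
  img
}

#' Write a TIFF image or stack
#'
#' Matrices and RGB arrays are written as a single page; 3-D grayscale
#' arrays as multi-page stacks (one page per slice). Intensities are
#' clipped to [0, 1].
#'
#' @param img numeric matrix or array
#' @param path output file
#' @param bits_per_sample 8 or 16
#' @return the path, invisibly
#' @export
write_image <- function(img, path, bits_per_sample = 16L) {
  img <- pmin(pmax(img, 0), 1)
  what <- if (length(dim(img)) == 3 && dim(img)[3] > 4) {
    lapply(seq_len(dim(img)[3]), function(k) img[, , k])
  } else img
  tiff::writeTIFF(what, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Write records to CSV with a header row
#'
#' @param records data.frame
#' @param path output file
#' @return the path, invisibly
#' @export
write_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format measurement table (group, value)
#'
#' @param path CSV with columns `group` and `value`
#' @return data.frame
#' @export
read_measurements <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(d)))
    stop("expected columns 'group' and 'value' in ", path)
  d
}

#' Read a genes-in-rows CSV matrix (cuffnorm-style layout)
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path CSV file
#' @return numeric matrix with gene rownames
#' @export
read_gene_matrix <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

pipeline_config_schema <- list(
  seed = "numeric", out_dir = "character",
  um_per_px = "numeric", um_per_vox = "numeric",
  fibers = c("background_radius_px", "bandpass_low", "bandpass_high",
             "dilation_radius_px", "min_fiber_area_um2", "max_fiber_area_um2",
             "nucleus_threshold", "central_margin_fraction"),
  regions = c("threshold", "min_area_um2", "max_area_um2", "connectivity",
              "trichrome_margin", "white_cutoff"),
  bone = c("tolerance", "max_fraction", "roi_start", "roi_n"),
  stats = c("alpha", "permutation_B", "star_thresholds", "normality_alpha"),
  expression = c("log_base", "pseudocount")
)

#' Load and validate a pipeline configuration (YAML)
#'
#' Unknown keys are a hard error so misspelt options cannot silently fall
#' back to defaults.
#'
#' @param path YAML file
#' @return list of class `pipeline_config`
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(pipeline_config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(cfg),
                        c("fibers", "regions", "bone", "stats", "expression"))) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_config_schema[[sec]])
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$um_per_px) && cfg$um_per_px <= 0)
    stop("um_per_px must be positive")
  if (!is.null(cfg$um_per_vox) && cfg$um_per_vox <= 0)
    stop("um_per_vox must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Write a provenance record for a pipeline run
#'
#' Records the package version, the seed and the full configuration as
#' JSON next to the outputs, so the origin of every number is auditable.
#' Deliberately contains no timestamp: outputs of a seeded run are
#' bit-reproducible.
#'
#' @param cfg configuration list
#' @param seed the run seed
#' @param path output JSON file
#' @return the path, invisibly
#' @export
write_provenance <- function(cfg, seed, path) {
  rec <- list(package = "dystromorph",
              version = as.character(utils::packageVersion("dystromorph")),
              seed = seed, config = cfg)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
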