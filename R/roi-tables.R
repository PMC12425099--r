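#' @include utils.R
NULL

#' Construct a RoiTable
#'
#' @param label character vector of unique ROI labels.
#' @param x,y,z numeric MNI coordinates (mm).
#' @param locationGroup character, one of the 18 anatomical group names per
#'   ROI.
#' @param roiKind `"seed"` or `"atlas"`.
#' @param strict enforce the reference design sizes (76 seeds / 116 atlas
#'   regions). Set `FALSE` for reduced designs, e.g. toy examples.
#' @return a [RoiTable-class] object.
#' @export
roiTable <- function(label, x, y, z, locationGroup,
                     roiKind = c("seed", "atlas"), strict = TRUE) {
  roiKind <- match.arg(roiKind)
  n <- length(label)
  obj <- new("RoiTable", label = as.character(label),
             x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
             z = rep_len(as.numeric(z), n),
             locationGroup = rep_len(as.character(locationGroup), n),
             roiKind = roiKind)
  if (strict) {
    want <- if (roiKind == "seed") 76L else 116L
    if (length(label) != want)
      stop(sprintf("expected %d %s ROIs, got %d (use strict = FALSE to relax)",
                   want, roiKind, length(label)), call. = FALSE)
  }
  obj
}

#' Read a ROI table from a delimited file
#'
#' Reads a tab-separated table with mandatory header columns `label`, `x`,
#' `y`, `z`, `location_group` into a [RoiTable-class]. In strict mode the
#' row count must match the reference design: 76 seed coordinates or 116
#' atlas regions.
#'
#' @param path file path.
#' @param roiKind `"seed"` or `"atlas"`.
#' @param strict enforce 76/116 rows (default `TRUE`).
#' @return a [RoiTable-class].
#' @seealso [defaultSeedTable()], [defaultAtlasTable()]
#' @export
readRoiTable <- function(path, roiKind = c("seed", "atlas"), strict = TRUE) {
  roiKind <- match.arg(roiKind)
  df <- readTsv(path)
  need <- c("label", "x", "y", "z", "location_group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", "z"))
    if (!is.numeric(df[[col]]))
      stop("ROI table column '", col, "' is not numeric", call. = FALSE)
  roiTable(df$label, df$x, df$y, df$z, df$location_group,
           roiKind = roiKind, strict = strict)
}

#' Write a RoiTable to a tab-separated file
#'
#' @param roi a [RoiTable-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRoiTable <- function(roi, path) {
  writeTsv(data.frame(label = roi@label, x = roi@x, y = roi@y, z = roi@z,
                      location_group = roi@locationGroup,
                      stringsAsFactors = FALSE), path)
}

#' Packaged ROI tables
#'
#' The package ships synthetic reconstructions of the two ROI sets used by
#' the analysis design: 76 pain-related seed coordinates and a 116-region
#' AAL-style whole-brain parcellation, each ROI assigned to one of 18
#' anatomical location groups (thalamus, cingulate gyrus, insula, ...).
#' Group names and per-group seed multiplicities (12 insula, 10 thalamus,
#' 4 amygdala seeds) follow the published design; labels and coordinates
#' are synthetic stand-ins, not the original supplementary tables, and the
#' files are editable TSVs under `inst/extdata/`.
#'
#' @return a [RoiTable-class].
#' @examples
#' seeds <- defaultSeedTable()
#' atlas <- defaultAtlasTable()
#' nRois(seeds); nRois(atlas)
#' length(unique(c(roiGroups(seeds), roiGroups(atlas))))  # 18 groups
#' @export
defaultSeedTable <- function() {
  readRoiTable(system.file("extdata", "seed_rois_synthetic.tsv",
                           package = "painConn", mustWork = TRUE), "seed")
}

#' @rdname defaultSeedTable
#' @export
defaultAtlasTable <- function() {
  readRoiTable(system.file("extdata", "atlas_rois_synthetic.tsv",
                           package = "painConn", mustWork = TRUE), "atlas")
}
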