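#' @include roi-tables.R timeseries-io.R
NULL

#' Extract seed and atlas ROI time series from a 4D BOLD image
#'
#' Produces the 76 + 116 regional signals the connectivity stage consumes:
#' atlas ROI signals are the unweighted mean over that label's voxels per
#' timepoint; seed signals are the mean over in-brain voxels within
#' `sphereRadiusMm` of the seed's MNI coordinate (the brain mask is the set
#' of voxels with a nonzero atlas label). Both images must live in the same
#' space (matching dimensions and voxel-to-world affine, RAS+ assumed).
#'
#' @param bold 4D NIfTI image (path or `RNifti` image).
#' @param atlas 3D labeled NIfTI image; voxels of atlas ROI k (row k of
#'   `atlasTable`, 1-based in image values) carry label k.
#' @param seedTable [RoiTable-class] of seed coordinates (MNI mm).
#' @param atlasTable [RoiTable-class] of atlas regions.
#' @param sphereRadiusMm seed sphere radius in mm (default 6).
#' @param subjectId subject identifier for the output.
#' @return a [SubjectTimeSeries-class] with seed columns first, then atlas
#'   columns.
#' @export
extractRoiTimeSeries <- function(bold, atlas, seedTable, atlasTable,
                                 sphereRadiusMm = 6, subjectId = "subject") {
  img <- if (is.character(bold)) RNifti::readNifti(bold) else bold
  atl <- if (is.character(atlas)) RNifti::readNifti(atlas) else atlas
  dimg <- dim(img)
  datl <- dim(atl)
  if (length(dimg) != 4L)
    stop("BOLD image must be 4D", call. = FALSE)
  if (length(datl) != 3L)
    stop("atlas image must be 3D", call. = FALSE)
  if (!all(dimg[1:3] == datl))
    stop("space mismatch: BOLD and atlas grids differ", call. = FALSE)
  affB <- RNifti::xform(img)
  affA <- RNifti::xform(atl)
  if (max(abs(affB - affA)) > 1e-4)
    stop("space mismatch: BOLD and atlas affines differ", call. = FALSE)

  nvox <- prod(dimg[1:3])
  Tn <- dimg[4L]
  voxmat <- matrix(as.numeric(img), nvox, Tn)
  lab <- as.integer(round(as.numeric(atl)))

  nA <- nRois(atlasTable)
  atlSig <- matrix(NA_real_, Tn, nA)
  for (k in seq_len(nA)) {
    idx <- which(lab == k)
    if (!length(idx))
      stop("atlas label ", k, " (", roiLabels(atlasTable)[k],
           ") has no voxels", call. = FALSE)
    atlSig[, k] <- colMeans(voxmat[idx, , drop = FALSE])
  }

  # world coordinates of every voxel center (0-based voxel indices)
  gi <- arrayInd(seq_len(nvox), dimg[1:3]) - 1L
  world <- cbind(gi, 1) %*% t(affB)
  brain <- lab > 0L

  nS <- nRois(seedTable)
  seedSig <- matrix(NA_real_, Tn, nS)
  co <- roiCoordinates(seedTable)
  for (s in seq_len(nS)) {
    d2 <- (world[, 1L] - co[s, 1L])^2 + (world[, 2L] - co[s, 2L])^2 +
      (world[, 3L] - co[s, 3L])^2
    idx <- which(d2 <= sphereRadiusMm^2 & brain)
    if (!length(idx))
      stop("seed '", roiLabels(seedTable)[s],
           "' has no in-brain voxels within ", sphereRadiusMm,
           " mm (outside the field of view?)", call. = FALSE)
    seedSig[, s] <- colMeans(voxmat[idx, , drop = FALSE])
  }

  data <- cbind(seedSig, atlSig)
  colnames(data) <- c(roiLabels(seedTable), roiLabels(atlasTable))
  new("SubjectTimeSeries", subjectId = as.character(subjectId), data = data)
}
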