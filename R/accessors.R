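#' @include AllGenerics.R
NULL

#' Accessors for painConn S4 objects
#'
#' Small read-only accessors for the package's central objects; use these
#' rather than reaching into slots.
#'
#' @param object a painConn S4 object.
#' @param kind for `nodeCounts`, which node set to return.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectId", "SubjectTimeSeries", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "ConnectivityMatrix", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "EdgeTestResult", function(object) object@patientId)

#' @rdname accessors
setMethod("connValues", "ConnectivityMatrix", function(object) object@values)
#' @rdname accessors
setMethod("connScale", "ConnectivityMatrix", function(object) object@scale)
#' @rdname accessors
setMethod("connScale", "CohortStack", function(object) object@scale)

#' @rdname accessors
setMethod("roiLabels", "RoiTable", function(object) object@label)
#' @rdname accessors
setMethod("roiGroups", "RoiTable", function(object) {
  stats::setNames(object@locationGroup, object@label)
})
#' @rdname accessors
setMethod("roiKind", "RoiTable", function(object) object@roiKind)
#' @rdname accessors
setMethod("nRois", "RoiTable", function(object) length(object@label))
#' @rdname accessors
setMethod("roiCoordinates", "RoiTable", function(object) {
  cbind(x = object@x, y = object@y, z = object@z)
})

#' @rdname accessors
setMethod("tsData", "SubjectTimeSeries", function(object) object@data)

#' @rdname accessors
setMethod("stackValues", "CohortStack", function(object) object@values)
#' @rdname accessors
setMethod("stackSubjects", "CohortStack", function(object) object@subjectIds)

#' @rdname accessors
setMethod("observedDiff", "EdgeTestResult", function(object) object@observedDiff)
#' @rdname accessors
setMethod("pRaw", "EdgeTestResult", function(object) object@pRaw)
#' @rdname accessors
setMethod("pAdj", "EdgeTestResult", function(object) object@pAdj)
#' @rdname accessors
setMethod("isSignificant", "EdgeTestResult", function(object) object@significant)

#' @rdname accessors
setMethod("significantEdges", "EdgeTestResult", function(object) {
  idx <- which(object@significant, arr.ind = TRUE)
  sl <- rownames(object@significant)
  al <- colnames(object@significant)
  out <- data.frame(
    patient_id = rep(object@patientId, nrow(idx)),
    seed_index = idx[, 1L] - 1L, atlas_index = idx[, 2L] - 1L,
    seed_label = if (is.null(sl)) as.character(idx[, 1L] - 1L) else sl[idx[, 1L]],
    atlas_label = if (is.null(al)) as.character(idx[, 2L] - 1L) else al[idx[, 2L]],
    observed_diff = object@observedDiff[idx],
    p_raw = object@pRaw[idx], p_adj = object@pAdj[idx],
    stringsAsFactors = FALSE)
  out[order(out$p_adj, out$seed_index, out$atlas_index), , drop = FALSE]
})

#' @rdname accessors
setMethod("edgeCounts", "CohortSummary", function(object) object@edgeCounts)
#' @rdname accessors
setMethod("nodeCounts", "CohortSummary",
  function(object, kind = c("seed", "atlas")) {
    kind <- match.arg(kind)
    if (kind == "seed") object@seedNodeCounts else object@atlasNodeCounts
  })
#' @rdname accessors
setMethod("perPatientCounts", "CohortSummary",
          function(object) object@perPatientCounts)

#' @rdname accessors
setMethod("graphEdges", "GroupGraph", function(object) object@edges)
#' @rdname accessors
setMethod("graphNodes", "GroupGraph", function(object) object@nodes)

setMethod("show", "RoiTable", function(object) {
  cat(sprintf("RoiTable (%s): %d ROIs, %d location groups\n",
              object@roiKind, length(object@label),
              length(unique(object@locationGroup))))
})

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s': %d timepoints x %d regions\n",
              object@subjectId, nrow(object@data), ncol(object@data)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix '%s': %d x %d (%s)\n", object@subjectId,
              nrow(object@values), ncol(object@values), object@scale))
})

setMethod("show", "CohortStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("CohortStack: %d subjects x %d seeds x %d atlas ROIs (%s)\n",
              d[1L], d[2L], d[3L], object@scale))
})

setMethod("show", "EdgeTestResult", function(object) {
  cat(sprintf(
    "EdgeTestResult '%s': %d edges, %d significant at alpha=%g\n",
    object@patientId, length(object@pRaw), sum(object@significant),
    object@alpha))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf(
    "CohortSummary: %d patients, %d unique atypical edges, %d seed / %d atlas nodes involved\n",
    object@nPatients, nrow(object@edgeCounts),
    length(object@seedNodeCounts), length(object@atlasNodeCounts)))
})

setMethod("show", "GroupGraph", function(object) {
  cat(sprintf("GroupGraph: %d groups, %d edges (count > %g)\n",
              length(object@nodes), nrow(object@edges), object@minCount))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec (%s): %d controls, %d patients, %d x %d edges, delta=%g\n",
    object@mode, object@nControls, object@nPatients, object@nSeeds,
    object@nAtlas, object@delta))
})

setMethod("show", "PermutationConfig", function(object) {
  cat(sprintf(
    "PermutationConfig: method=%s, nPerm=%d, alpha=%g, pRule=%s, null=%s\n",
    object@method, object@nPerm, object@alpha, object@pRule,
    object@nullModel))
})
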