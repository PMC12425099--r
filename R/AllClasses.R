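#' @import methods
NULL

#' RoiTable: seed or atlas region metadata
#'
#' Holds one set of regions of interest: either the 76 pain-related seed
#' coordinates or the 116 AAL atlas regions. Each ROI carries a unique label,
#' an MNI coordinate (mm) and one of the 18 anatomical location groups used
#' for group-level network analysis.
#'
#' @slot label character vector of unique ROI labels.
#' @slot x,y,z numeric MNI coordinates in mm (RAS+).
#' @slot locationGroup character, anatomical group per ROI.
#' @slot roiKind `"seed"` or `"atlas"`.
#' @exportClass RoiTable
setClass("RoiTable",
  representation(label = "character", x = "numeric", y = "numeric",
                 z = "numeric", locationGroup = "character",
                 roiKind = "character"))

setValidity("RoiTable", function(object) {
  n <- length(object@label)
  if (n == 0L) return("RoiTable must contain at least one ROI")
  if (length(object@x) != n || length(object@y) != n ||
      length(object@z) != n || length(object@locationGroup) != n)
    return("all ROI columns must have the same length")
  if (anyDuplicated(object@label))
    return("ROI labels must be unique within a table")
  if (!object@roiKind %in% c("seed", "atlas"))
    return("roiKind must be 'seed' or 'atlas'")
  if (anyNA(object@x) || anyNA(object@y) || anyNA(object@z))
    return("MNI coordinates must not contain NA")
  if (any(!nzchar(object@locationGroup)) || anyNA(object@locationGroup))
    return("every ROI needs a non-empty location_group")
  TRUE
})

#' SubjectTimeSeries: one subject's regional BOLD signals
#'
#' A T-by-R numeric matrix of BOLD time series (timepoints by regions) with
#' region labels as column names.
#'
#' @slot subjectId character scalar.
#' @slot data numeric matrix, T rows (timepoints) by R labeled columns.
#' @exportClass SubjectTimeSeries
setClass("SubjectTimeSeries",
  representation(subjectId = "character", data = "matrix"))

setValidity("SubjectTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("time-series data must be numeric")
  if (nrow(d) < 2L) return("need at least 2 timepoints")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    return("columns must carry unique region labels")
  if (anyNA(d)) return("time-series data must not contain NA")
  sds <- apply(d, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(d)[sds == 0]
    return(paste0("constant (zero-variance) region column(s): ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' ConnectivityMatrix: one subject's seed-to-atlas connectivity
#'
#' The 76-by-116 matrix of seed-to-atlas functional connectivity values for
#' one subject, either raw Pearson correlations (`pearson_r`) or
#' variance-stabilized Fisher z values (`fisher_z`).
#'
#' @slot subjectId character scalar.
#' @slot values numeric matrix, seeds in rows, atlas regions in columns.
#' @slot scale `"pearson_r"` or `"fisher_z"`.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(subjectId = "character", values = "matrix",
                 scale = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("connectivity values must be numeric")
  if (anyNA(v)) return("connectivity values must not contain NA")
  if (!object@scale %in% c("pearson_r", "fisher_z"))
    return("scale must be 'pearson_r' or 'fisher_z'")
  if (object@scale == "pearson_r" && (any(v < -1) || any(v > 1)))
    return("pearson_r values must lie in [-1, 1]")
  TRUE
})

#' CohortStack: stacked control connectivity matrices
#'
#' The normative cohort as a 3D array: subjects by seeds by atlas regions
#' (20 x 76 x 116 in the reference design). All matrices share one scale.
#'
#' @slot values numeric 3D array, subject x seed x atlas.
#' @slot subjectIds character, one id per subject (first array dimension).
#' @slot scale `"pearson_r"` or `"fisher_z"`.
#' @exportClass CohortStack
setClass("CohortStack",
  representation(values = "array", subjectIds = "character",
                 scale = "character"))

setValidity("CohortStack", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (dim(v)[1L] != length(object@subjectIds))
    return("first dimension must equal the number of subjects")
  if (dim(v)[1L] < 2L) return("need at least 2 control subjects")
  if (anyNA(v)) return("stack must not contain NA")
  if (!object@scale %in% c("pearson_r", "fisher_z"))
    return("scale must be 'pearson_r' or 'fisher_z'")
  TRUE
})

#' SimulationSpec: parameters of the synthetic cohort generator
#'
#' Describes a synthetic study: cohort sizes, connectivity dimensions, the
#' baseline edge distribution (Fisher-z scale), the atypical edges injected
#' into each patient with effect size `delta`, and optional linear couplings
#' from chosen edges to clinical outcomes.
#'
#' @slot nControls,nPatients,nSeeds,nAtlas integer design sizes.
#' @slot mode `"edge_level"` or `"timeseries_level"`.
#' @slot nTimepoints integer, timepoints per subject (timeseries mode).
#' @slot mu,muSd numeric: per-edge baseline means are drawn once from
#'   Normal(mu, muSd) (Fisher-z units).
#' @slot sigmaBetween numeric, between-subject edge SD (Fisher-z units).
#' @slot injectedEdges list, one integer matrix (n x 2, 0-based seed/atlas
#'   indices) per patient.
#' @slot delta numeric >= 0, injected shift in Fisher-z units.
#' @slot clinicalCoupling data.frame with columns outcome, seed_index,
#'   atlas_index, slope, intercept, noise_sd.
#' @slot rngSeed integer seed for the generator.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(nControls = "integer", nPatients = "integer",
                 nSeeds = "integer", nAtlas = "integer", mode = "character",
                 nTimepoints = "integer", mu = "numeric", muSd = "numeric",
                 sigmaBetween = "numeric", injectedEdges = "list",
                 delta = "numeric", clinicalCoupling = "data.frame",
                 rngSeed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (object@nControls < 2L) return("nControls must be >= 2")
  if (object@nPatients < 0L) return("nPatients must be >= 0")
  if (object@delta < 0) return("delta must be >= 0")
  if (!object@mode %in% c("edge_level", "timeseries_level"))
    return("mode must be 'edge_level' or 'timeseries_level'")
  if (object@mode == "timeseries_level" && object@nTimepoints < 50L)
    return("timeseries mode needs nTimepoints >= 50")
  if (length(object@injectedEdges) != object@nPatients)
    return("injectedEdges must hold one matrix per patient")
  for (m in object@injectedEdges) {
    if (length(m) == 0L) next
    if (ncol(m) != 2L) return("each injectedEdges element must be an n x 2 matrix")
    if (any(m[, 1L] < 0L) || any(m[, 1L] >= object@nSeeds) ||
        any(m[, 2L] < 0L) || any(m[, 2L] >= object@nAtlas))
      return("injected edge indices out of bounds (0-based)")
  }
  cc <- object@clinicalCoupling
  if (nrow(cc)) {
    need <- c("outcome", "seed_index", "atlas_index", "slope", "intercept",
              "noise_sd")
    if (!all(need %in% names(cc)))
      return(paste("clinicalCoupling needs columns:",
                   paste(need, collapse = ", ")))
    if (any(cc$seed_index < 0L) || any(cc$seed_index >= object@nSeeds) ||
        any(cc$atlas_index < 0L) || any(cc$atlas_index >= object@nAtlas))
      return("clinicalCoupling edge indices out of bounds (0-based)")
  }
  TRUE
})

#' PermutationConfig: settings of the per-edge permutation test
#'
#' @slot nPerm integer, Monte-Carlo shuffles (default 10000).
#' @slot alpha numeric significance level in (0,1).
#' @slot method `"monte_carlo"` or `"exact"` (full enumeration of the n+1
#'   distinct relabelings of an n-vs-1 shuffle).
#' @slot rngSeed integer seed; per-edge sub-streams derive from it.
#' @slot pRule `"plus_one"` ((1+b)/(1+nPerm), Monte-Carlo default) or
#'   `"raw_proportion"`; exact mode always uses the true proportion.
#' @slot nullModel `"per_edge"` (the test as described: each edge judged
#'   against its own 21-point relabeling null) or `"pooled_edges"` (null
#'   statistics pooled across all edges; an explicitly flagged variant that
#'   can yield per-edge FDR discoveries despite the coarse n-vs-1 null).
#' @exportClass PermutationConfig
setClass("PermutationConfig",
  representation(nPerm = "integer", alpha = "numeric", method = "character",
                 rngSeed = "integer", pRule = "character",
                 nullModel = "character"))

setValidity("PermutationConfig", function(object) {
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  # alpha = 0 is allowed as a degenerate screen (flags nothing)
  if (object@alpha < 0 || object@alpha >= 1) return("alpha must be in [0, 1)")
  if (!object@method %in% c("monte_carlo", "exact"))
    return("method must be 'monte_carlo' or 'exact'")
  if (!object@pRule %in% c("plus_one", "raw_proportion"))
    return("pRule must be 'plus_one' or 'raw_proportion'")
  if (!object@nullModel %in% c("per_edge", "pooled_edges"))
    return("nullModel must be 'per_edge' or 'pooled_edges'")
  TRUE
})

#' EdgeTestResult: per-edge normative test results for one patient
#'
#' Matrices (seeds x atlas) of the observed absolute mean difference, raw
#' permutation p-values, BH-adjusted p-values, and the significance mask
#' (adjusted p <= alpha).
#'
#' @slot patientId character scalar.
#' @slot observedDiff,pRaw,pAdj numeric matrices, seeds x atlas.
#' @slot significant logical matrix.
#' @slot alpha numeric level used for the mask.
#' @slot config list recording the PermutationConfig used.
#' @exportClass EdgeTestResult
setClass("EdgeTestResult",
  representation(patientId = "character", observedDiff = "matrix",
                 pRaw = "matrix", pAdj = "matrix", significant = "matrix",
                 alpha = "numeric", config = "list"))

setValidity("EdgeTestResult", function(object) {
  dm <- dim(object@observedDiff)
  if (!identical(dm, dim(object@pRaw)) || !identical(dm, dim(object@pAdj)) ||
      !identical(dm, dim(object@significant)))
    return("all result matrices must share one shape")
  if (any(object@observedDiff < 0)) return("observedDiff must be >= 0")
  if (any(object@pRaw < 0 | object@pRaw > 1)) return("pRaw outside [0,1]")
  if (any(object@pAdj < object@pRaw - 1e-12))
    return("adjusted p must be >= raw p")
  if (!identical(as.vector(object@significant),
                 as.vector(object@pAdj <= object@alpha)))
    return("significant mask must equal (pAdj <= alpha)")
  TRUE
})

#' CohortSummary: recurrence of atypical edges and nodes across patients
#'
#' @slot edgeCounts data.frame: seed_index, atlas_index (0-based),
#'   seed_label, atlas_label, n_patients.
#' @slot seedNodeCounts,atlasNodeCounts named integer vectors; a node's count
#'   is the number of patients with at least one significant edge touching it.
#' @slot perPatientCounts named integer vector of atypical-edge counts.
#' @slot nPatients integer.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(edgeCounts = "data.frame", seedNodeCounts = "integer",
                 atlasNodeCounts = "integer", perPatientCounts = "integer",
                 nPatients = "integer"))

setValidity("CohortSummary", function(object) {
  ec <- object@edgeCounts
  need <- c("seed_index", "atlas_index", "seed_label", "atlas_label",
            "n_patients")
  if (!all(need %in% names(ec)))
    return(paste("edgeCounts needs columns:", paste(need, collapse = ", ")))
  if (nrow(ec) && any(ec$n_patients < 1L))
    return("edge patient counts must be >= 1")
  if (sum(ec$n_patients) != sum(object@perPatientCounts))
    return("sum of edge counts must equal total per-patient incidences")
  TRUE
})

#' GroupGraph: weighted graph over anatomical region groups
#'
#' Undirected weighted graph whose nodes are the (at most 18) location
#' groups and whose edge weights count (patient, edge) occurrences mapped
#' into each unordered group pair. Self-loops are legal (e.g. thalamus with
#' itself).
#'
#' @slot edges data.frame: group_a, group_b (group_a <= group_b
#'   lexicographically), weight (positive integer count).
#' @slot nodes character, groups present in the graph.
#' @slot minCount numeric, the strict recurrence threshold applied.
#' @exportClass GroupGraph
setClass("GroupGraph",
  representation(edges = "data.frame", nodes = "character",
                 minCount = "numeric"))

setValidity("GroupGraph", function(object) {
  e <- object@edges
  if (!all(c("group_a", "group_b", "weight") %in% names(e)))
    return("edges needs columns group_a, group_b, weight")
  if (nrow(e)) {
    if (any(e$weight <= 0)) return("edge weights must be positive")
    if (any(e$group_a > e$group_b))
      return("group pairs must be stored with group_a <= group_b")
    if (!all(c(e$group_a, e$group_b) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
  }
  TRUE
})
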