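#' @include permutation.R
NULL

#' Aggregate per-patient atypical edges into cohort recurrence counts
#'
#' Collects each patient's significant (atypical) edges and tallies, per
#' unique (seed, atlas) edge, the number of patients in which it is
#' atypical, plus per-node recurrence: a node's count is the number of
#' patients with at least one atypical edge touching it (a patient with
#' five thalamic edges contributes one to the thalamus seed's count).
#'
#' @param results list of [EdgeTestResult-class] objects, one per patient
#'   (duplicated patient ids are rejected — repeated assessments must be
#'   resolved upstream).
#' @return a [CohortSummary-class].
#' @export
aggregateResults <- function(results) {
  if (!length(results))
    stop("no results to aggregate", call. = FALSE)
  ids <- vapply(results, function(r) r@patientId, character(1L))
  if (anyDuplicated(ids))
    stop("duplicated patient_id in results: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(results, significantEdges)
  perPatient <- stats::setNames(vapply(sets, nrow, integer(1L)), ids)

  all <- do.call(rbind, sets)
  if (is.null(all) || nrow(all) == 0L) {
    ec <- data.frame(seed_index = integer(), atlas_index = integer(),
                     seed_label = character(), atlas_label = character(),
                     n_patients = integer(), stringsAsFactors = FALSE)
    return(new("CohortSummary", edgeCounts = ec,
               seedNodeCounts = integer(), atlasNodeCounts = integer(),
               perPatientCounts = perPatient,
               nPatients = length(results)))
  }
  key <- paste(all$seed_index, all$atlas_index)
  tab <- table(key)
  first <- all[!duplicated(key), , drop = FALSE]
  first <- first[order(first$seed_index, first$atlas_index), , drop = FALSE]
  ec <- data.frame(seed_index = first$seed_index,
                   atlas_index = first$atlas_index,
                   seed_label = first$seed_label,
                   atlas_label = first$atlas_label,
                   n_patients = as.integer(tab[paste(first$seed_index,
                                                     first$atlas_index)]),
                   stringsAsFactors = FALSE, row.names = NULL)
  nodeTally <- function(labels, patient) {
    u <- unique(data.frame(l = labels, p = patient))
    t <- table(u$l)
    stats::setNames(as.integer(t), names(t))
  }
  seedCounts <- nodeTally(all$seed_label, all$patient_id)
  atlasCounts <- nodeTally(all$atlas_label, all$patient_id)
  new("CohortSummary", edgeCounts = ec, seedNodeCounts = seedCounts,
      atlasNodeCounts = atlasCounts, perPatientCounts = perPatient,
      nPatients = length(results))
}

#' Recurrently atypical nodes
#'
#' Nodes (seed coordinates and atlas regions, reported separately) whose
#' patient count strictly exceeds `minPatients` — the "atypical in more
#' than 10 patients" screen. Sorted by count descending, ties broken by
#' label.
#'
#' @param summary a [CohortSummary-class].
#' @param minPatients strict lower threshold (default 10).
#' @return list of two data.frames (`seed`, `atlas`) with columns `label`,
#'   `n_patients`.
#' @export
recurrentNodes <- function(summary, minPatients = 10L) {
  pick <- function(counts) {
    keep <- counts[counts > minPatients]
    if (!length(keep))
      return(data.frame(label = character(), n_patients = integer(),
                        stringsAsFactors = FALSE))
    ord <- order(-keep, names(keep))
    data.frame(label = names(keep)[ord],
               n_patients = as.integer(keep[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(seed = pick(summary@seedNodeCounts),
       atlas = pick(summary@atlasNodeCounts))
}

#' Recurrently atypical edges
#'
#' Edges observed in strictly more than `minCount` patients — the "appear
#' in more than seven different patient assessments" subnetwork filter
#' (use 3 for the seed-level view).
#'
#' @param summary a [CohortSummary-class].
#' @param minCount strict lower threshold (default 7).
#' @return data.frame of edges with counts, sorted by count descending.
#' @export
recurrentEdges <- function(summary, minCount = 7L) {
  ec <- summary@edgeCounts
  keep <- ec[ec$n_patients > minCount, , drop = FALSE]
  keep[order(-keep$n_patients, keep$seed_label, keep$atlas_label), ,
       drop = FALSE]
}

#' Distribution of atypical-edge counts across patients
#'
#' @param summary a [CohortSummary-class].
#' @return list with `histogram` (data.frame `n_edges`, `n_patients`),
#'   `fractionWithEdge` (proportion of patients with at least one atypical
#'   edge), and `pctWithEdge` (the same as a percentage, one decimal,
#'   round-half-even).
#' @export
perPatientDistribution <- function(summary) {
  cnt <- summary@perPatientCounts
  tab <- table(cnt)
  frac <- if (length(cnt)) mean(cnt >= 1L) else 0
  list(histogram = data.frame(n_edges = as.integer(names(tab)),
                              n_patients = as.integer(tab),
                              row.names = NULL),
       fractionWithEdge = frac,
       pctWithEdge = round(100 * frac, 1))
}
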