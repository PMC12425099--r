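#' @include utils.R
NULL

#' Construct a SubjectTimeSeries
#'
#' @param subjectId character scalar.
#' @param data numeric matrix, timepoints in rows, labeled region columns.
#' @param dropInitialVolumes number of leading timepoints to discard before
#'   validation (default 0; signal-stabilization dropping is normally done
#'   upstream in preprocessing).
#' @return a [SubjectTimeSeries-class].
#' @export
subjectTimeSeries <- function(subjectId, data, dropInitialVolumes = 0L) {
  data <- as.matrix(data)
  if (dropInitialVolumes > 0L) {
    if (dropInitialVolumes >= nrow(data))
      stop("dropInitialVolumes leaves no timepoints", call. = FALSE)
    data <- data[-seq_len(dropInitialVolumes), , drop = FALSE]
  }
  new("SubjectTimeSeries", subjectId = as.character(subjectId), data = data)
}

#' Read a subject's ROI time series from a delimited file
#'
#' Expects a tab-separated numeric table, one row per timepoint, header row
#' of region labels. Non-numeric cells are a format error; a constant
#' (zero-variance) column is a validation error naming the region.
#'
#' @param path file path.
#' @param subjectId subject identifier; defaults to the file name without
#'   extension.
#' @param dropInitialVolumes leading timepoints to discard (default 0).
#' @return a [SubjectTimeSeries-class].
#' @export
readTimeSeries <- function(path, subjectId = NULL, dropInitialVolumes = 0L) {
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(readTsv(path, colClasses = "numeric"),
                 error = function(e)
                   stop("malformed time-series file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty time-series file: ", path, call. = FALSE)
  subjectTimeSeries(subjectId, as.matrix(df),
                    dropInitialVolumes = dropInitialVolumes)
}

#' Write a subject's time series to a tab-separated file
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  writeTsv(as.data.frame(ts@data, check.names = FALSE), path)
}

#' Read / write a connectivity matrix as TSV
#'
#' Matrices are stored with seed labels as the leading `seed` column and
#' atlas labels as the remaining column headers; values keep full double
#' precision so a write/read round trip is exact.
#'
#' @param path file path.
#' @param subjectId subject identifier (read); defaults to file name.
#' @param scale connectivity scale of the stored values.
#' @param cm a [ConnectivityMatrix-class] (write).
#' @return `readConnectivityMatrix`: a [ConnectivityMatrix-class];
#'   `writeConnectivityMatrix`: the path, invisibly.
#' @export
readConnectivityMatrix <- function(path, subjectId = NULL,
                                   scale = c("fisher_z", "pearson_r")) {
  scale <- match.arg(scale)
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  m <- readMatrixTsv(path)
  new("ConnectivityMatrix", subjectId = subjectId, values = m, scale = scale)
}

#' @rdname readConnectivityMatrix
#' @export
writeConnectivityMatrix <- function(cm, path) {
  writeMatrixTsv(cm@values, path, rowColName = "seed")
}

#' Stack control connectivity matrices into a cohort array
#'
#' @param matrices list of [ConnectivityMatrix-class] objects sharing shape
#'   and scale.
#' @return a [CohortStack-class] (subjects x seeds x atlas).
#' @export
cohortStack <- function(matrices) {
  if (length(matrices) < 2L)
    stop("need at least 2 control matrices", call. = FALSE)
  scales <- vapply(matrices, function(m) m@scale, character(1L))
  if (length(unique(scales)) != 1L)
    stop("all matrices in a stack must share one scale", call. = FALSE)
  dims <- vapply(matrices, function(m) dim(m@values), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all matrices in a stack must share one shape", call. = FALSE)
  arr <- array(NA_real_, dim = c(length(matrices), dims[1L, 1L], dims[2L, 1L]),
               dimnames = list(NULL, rownames(matrices[[1L]]@values),
                               colnames(matrices[[1L]]@values)))
  for (i in seq_along(matrices)) arr[i, , ] <- matrices[[i]]@values
  new("CohortStack", values = arr,
      subjectIds = vapply(matrices, function(m) m@subjectId, character(1L)),
      scale = scales[1L])
}
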