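#' @include timeseries-io.R
NULL

#' Pearson correlation between two region time series
#'
#' Sample Pearson correlation of two equal-length series; the elementary
#' statistic behind every edge of the seed-to-atlas connectivity matrix.
#'
#' @param x,y numeric vectors of equal length (T >= 3), non-constant.
#' @return correlation in `[-1, 1]`.
#' @examples
#' pearsonEdge(1:4, c(1, 2, 3, 5))
#' @export
pearsonEdge <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 timepoints", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are rejected, not imputed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y)
}

#' Seed-to-atlas connectivity matrix for one subject
#'
#' Correlates every seed region's time series with every atlas region's time
#' series, producing the subject's seeds-by-atlas connectivity matrix (76 x
#' 116 in the reference design). With `scale = "fisher_z"` each correlation
#' is variance-stabilized with [fisherZ()].
#'
#' @param ts a [SubjectTimeSeries-class] containing all seed and atlas
#'   columns.
#' @param seedLabels,atlasLabels character vectors naming the seed and atlas
#'   columns of `ts` (row/column order of the output).
#' @param scale `"fisher_z"` (default, used downstream for testing) or
#'   `"pearson_r"`.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(ts, seedLabels, atlasLabels,
                               scale = c("fisher_z", "pearson_r")) {
  scale <- match.arg(scale)
  d <- ts@data
  miss <- setdiff(c(seedLabels, atlasLabels), colnames(d))
  if (length(miss))
    stop("time series is missing region column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  r <- stats::cor(d[, seedLabels, drop = FALSE],
                  d[, atlasLabels, drop = FALSE])
  v <- if (scale == "fisher_z") fisherZ(r) else r
  dimnames(v) <- list(seedLabels, atlasLabels)
  new("ConnectivityMatrix", subjectId = ts@subjectId, values = v,
      scale = scale)
}
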