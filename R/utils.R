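#' @include AllClasses.R
NULL

# Deterministic 31-bit sub-stream seed: keeps per-subject / per-edge RNG
# independent of evaluation order. Knuth multiplicative hash on doubles;
# all intermediates stay below 2^53 so arithmetic is exact.
substreamSeed <- function(seed, index) {
  m <- 2147483647
  a <- 48271
  s <- (as.numeric(seed) %% m) + 1
  x <- (s * a + as.numeric(index) * 104729) %% m
  as.integer(x)
}

# Tab-separated, UTF-8, '.' decimal, mandatory header; >= 15 significant
# digits so write/read round-trips are exact at double precision.
writeTsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- formatC(df2[[j]], digits = 17, format = "g")
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8", ...)
}

# Write a labeled numeric matrix with a leading label column.
writeMatrixTsv <- function(m, path, rowColName = "row") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- rowColName
  writeTsv(df, path)
}

readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix file: ", path,
                           call. = FALSE)
  rownames(m) <- df[[1L]]
  m
}

#' Fisher z transform of a correlation coefficient
#'
#' `fisherZ()` applies `atanh` after clipping `r` to +/- (1 - 1e-7) so that
#' correlations of exactly +/- 1 map to large finite values;
#' `inverseFisherZ()` is `tanh`.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @param z Fisher-z value(s).
#' @return numeric vector of the same length.
#' @examples
#' fisherZ(0.5)            # atanh(0.5) = 0.5493...
#' inverseFisherZ(fisherZ(0.3))
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @rdname fisherZ
#' @export
inverseFisherZ <- function(z) tanh(z)
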