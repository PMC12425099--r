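# Shared in-code fixtures: tiny ROI tables, toy matrices and brute-force
# oracles used across test files.

tinySeedTable <- function(n = 3L, groups = c("Thalamus", "Insula", "Thalamus")) {
  roiTable(sprintf("seed%02d", seq_len(n)), x = seq_len(n), y = 0, z = 0,
           locationGroup = rep_len(groups, n), roiKind = "seed",
           strict = FALSE)
}

tinyAtlasTable <- function(n = 4L,
                           groups = c("BasalGanglia", "Thalamus",
                                      "OccipitalLobe", "Insula")) {
  roiTable(sprintf("atlas%02d", seq_len(n)), x = seq_len(n), y = 1, z = 1,
           locationGroup = rep_len(groups, n), roiKind = "atlas",
           strict = FALSE)
}

toyConnectivity <- function(values, subjectId = "s1", scale = "fisher_z",
                            seedLabels = NULL, atlasLabels = NULL) {
  m <- as.matrix(values)
  if (is.null(seedLabels)) seedLabels <- sprintf("seed%02d", seq_len(nrow(m)))
  if (is.null(atlasLabels)) atlasLabels <- sprintf("atlas%02d", seq_len(ncol(m)))
  dimnames(m) <- list(seedLabels, atlasLabels)
  new("ConnectivityMatrix", subjectId = subjectId, values = m, scale = scale)
}

toyStack <- function(arr, scale = "fisher_z") {
  dimnames(arr) <- list(NULL, sprintf("seed%02d", seq_len(dim(arr)[2])),
                        sprintf("atlas%02d", seq_len(dim(arr)[3])))
  new("CohortStack", values = arr,
      subjectIds = sprintf("c%02d", seq_len(dim(arr)[1])), scale = scale)
}

# Brute-force permutation oracle: enumerate every assignment of the n+1
# pooled values to the patient role and count exceedances directly.
oracleExactP <- function(controls, patient) {
  pooled <- c(controls, patient)
  n <- length(controls)
  stats <- vapply(seq_along(pooled), function(i)
    abs(mean(pooled[-i]) - pooled[i]), numeric(1))
  obs <- stats[length(pooled)]
  mean(stats >= obs)
}

# Brute-force BH step-up oracle straight from the definition.
oracleBH <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  list(pAdj = out, reject = out <= alpha)
}

# A fabricated EdgeTestResult whose significance mask is exactly `edges`
# (data.frame seed_index/atlas_index, 0-based) on an nS x nA grid.
resultWithEdges <- function(patientId, edges, nS = 3L, nA = 4L,
                            alpha = 0.05) {
  pRaw <- matrix(0.9, nS, nA,
                 dimnames = list(sprintf("seed%02d", seq_len(nS)),
                                 sprintf("atlas%02d", seq_len(nA))))
  if (NROW(edges))
    pRaw[cbind(edges$seed_index + 1L, edges$atlas_index + 1L)] <- 1e-6
  bh <- fdrBH(as.vector(pRaw), alpha)
  shape <- function(v) matrix(v, nS, nA, dimnames = dimnames(pRaw))
  new("EdgeTestResult", patientId = patientId, observedDiff = shape(1),
      pRaw = pRaw, pAdj = shape(bh$pAdj), significant = shape(bh$reject),
      alpha = alpha, config = list())
}
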