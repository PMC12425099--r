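#' @include aggregate.R
NULL

#' Map edge recurrence counts onto anatomical region-group pairs
#'
#' Each (seed, atlas) edge occurrence contributes its patient count to the
#' unordered pair of location groups of its endpoints; a seed and an atlas
#' region in the same group produce a self-pair (e.g. thalamus with
#' itself).
#'
#' @param edgeCounts data.frame with columns `seed_index`, `atlas_index`
#'   (0-based) and `n_patients`, as in [edgeCounts()] of a
#'   [CohortSummary-class].
#' @param seedTable,atlasTable [RoiTable-class] objects supplying the
#'   location groups.
#' @return data.frame `group_a`, `group_b` (sorted within pair), `weight`.
#' @export
mapEdgesToGroups <- function(edgeCounts, seedTable, atlasTable) {
  if (!nrow(edgeCounts))
    return(data.frame(group_a = character(), group_b = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  if (any(edgeCounts$seed_index < 0L) ||
      any(edgeCounts$seed_index >= nRois(seedTable)) ||
      any(edgeCounts$atlas_index < 0L) ||
      any(edgeCounts$atlas_index >= nRois(atlasTable)))
    stop("edge indices outside the ROI tables", call. = FALSE)
  gs <- seedTable@locationGroup[edgeCounts$seed_index + 1L]
  ga <- atlasTable@locationGroup[edgeCounts$atlas_index + 1L]
  a <- pmin(gs, ga)
  b <- pmax(gs, ga)
  agg <- stats::aggregate(list(weight = edgeCounts$n_patients),
                          by = list(group_a = a, group_b = b), FUN = sum)
  agg <- agg[order(agg$group_a, agg$group_b), , drop = FALSE]
  agg$weight <- as.integer(agg$weight)
  rownames(agg) <- NULL
  agg
}

#' Build the thresholded region-group graph
#'
#' Keeps group pairs whose occurrence count strictly exceeds `minCount`
#' (the "occurred more than four times between regions" filter) and wraps
#' them as a weighted undirected graph over the location groups; self-loops
#' are retained.
#'
#' @param groupPairCounts data.frame from [mapEdgesToGroups()].
#' @param minCount strict lower threshold (default 4).
#' @return a [GroupGraph-class].
#' @export
buildGroupGraph <- function(groupPairCounts, minCount = 4L) {
  keep <- groupPairCounts[groupPairCounts$weight > minCount, , drop = FALSE]
  rownames(keep) <- NULL
  nodes <- sort(unique(c(keep$group_a, keep$group_b)))
  new("GroupGraph", edges = keep, nodes = nodes, minCount = as.numeric(minCount))
}

#' Hub scores: max-normalized degree centrality
#'
#' For each group, the weighted degree is the sum of incident edge weights
#' with self-loops counted twice (standard graph convention); hub score is
#' the weighted degree divided by the maximum over groups, so the top hub
#' scores exactly 1. `weighted = FALSE` uses unweighted degree (each
#' retained edge counts 1, self-loops 2).
#'
#' @param graph a non-empty [GroupGraph-class].
#' @param weighted use edge weights (default) or plain edge counts.
#' @return data.frame `group`, `degree`, `hub_score`, sorted by score
#'   descending then group name.
#' @export
hubScores <- function(graph, weighted = TRUE) {
  e <- graph@edges
  if (!nrow(e))
    stop("hub scores are undefined on an empty graph", call. = FALSE)
  w <- if (weighted) e$weight else rep(1L, nrow(e))
  deg <- stats::setNames(numeric(length(graph@nodes)), graph@nodes)
  for (i in seq_len(nrow(e))) {
    deg[e$group_a[i]] <- deg[e$group_a[i]] + w[i]
    deg[e$group_b[i]] <- deg[e$group_b[i]] + w[i]  # self-loop adds twice
  }
  out <- data.frame(group = names(deg), degree = as.numeric(deg),
                    hub_score = as.numeric(deg) / max(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hub_score, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort prevalence of group-pair connections
#'
#' Expresses group-pair patient counts as percentages of the cohort (one
#' decimal, round-half-even) — the "thalamus with basal ganglia (18%)"
#' style summary.
#'
#' @param groupPairCounts data.frame from [mapEdgesToGroups()].
#' @param nPatients cohort size, > 0.
#' @return the input with an added `pct` column.
#' @export
edgePrevalencePct <- function(groupPairCounts, nPatients) {
  if (nPatients <= 0) stop("nPatients must be positive", call. = FALSE)
  groupPairCounts$pct <- round(100 * groupPairCounts$weight / nPatients, 1)
  groupPairCounts
}

#' Plot a region-group graph
#'
#' Circular layout with node size proportional to weighted degree and edge
#' width proportional to weight; a quick diagnostic, not a publication
#' figure.
#'
#' @param x a [GroupGraph-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, the node coordinates.
#' @export
setMethod("plot", signature(x = "GroupGraph", y = "missing"),
  function(x, y, ...) {
    nodes <- x@nodes
    if (!length(nodes)) stop("empty graph", call. = FALSE)
    th <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[-1L]
    xy <- cbind(cos(th), sin(th))
    rownames(xy) <- nodes
    hs <- hubScores(x)
    graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                   xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1, ...)
    e <- x@edges
    for (i in seq_len(nrow(e))) {
      a <- xy[e$group_a[i], ]; b <- xy[e$group_b[i], ]
      lw <- 0.5 + 3 * e$weight[i] / max(e$weight)
      if (e$group_a[i] == e$group_b[i]) {
        graphics::points(a[1] * 1.12, a[2] * 1.12, cex = lw, pch = 1)
      } else {
        graphics::segments(a[1], a[2], b[1], b[2], lwd = lw, col = "grey40")
      }
    }
    sz <- 1 + 2 * hs$hub_score[match(nodes, hs$group)]
    graphics::points(xy, pch = 21, bg = "steelblue", cex = sz)
    graphics::text(xy * 1.25, labels = nodes, cex = 0.7)
    invisible(xy)
  })
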