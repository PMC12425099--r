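test_that("edges map onto unordered group pairs including self-pairs", {
  st <- tinySeedTable()    # groups: Thalamus, Insula, Thalamus
  at <- tinyAtlasTable()   # groups: BasalGanglia, Thalamus, OccipitalLobe, Insula
  ec <- data.frame(seed_index = c(0L, 0L, 2L), atlas_index = c(0L, 1L, 0L),
                   n_patients = c(10L, 3L, 5L))
  pairs <- mapEdgesToGroups(ec, st, at)
  expect_identical(
    pairs$weight[pairs$group_a == "BasalGanglia" &
                 pairs$group_b == "Thalamus"], 15L)  # 10 + 5 pooled
  expect_identical(
    pairs$weight[pairs$group_a == "Thalamus" &
                 pairs$group_b == "Thalamus"], 3L)   # self-pair
  expect_identical(nrow(mapEdgesToGroups(ec[0, ], st, at)), 0L)
  expect_error(mapEdgesToGroups(data.frame(seed_index = 9L, atlas_index = 0L,
                                           n_patients = 1L), st, at),
               "outside")
})

test_that("group graph thresholding is strict", {
  pairs <- data.frame(group_a = c("A", "A"), group_b = c("B", "C"),
                      weight = c(5L, 4L))
  g <- buildGroupGraph(pairs, minCount = 4)
  expect_identical(graphEdges(g)$group_b, "B")
  expect_identical(graphNodes(g), c("A", "B"))
  g0 <- buildGroupGraph(pairs, minCount = 0)
  expect_identical(nrow(graphEdges(g0)), 2L)
  gEmpty <- buildGroupGraph(pairs, minCount = 10)
  expect_identical(nrow(graphEdges(gEmpty)), 0L)
  expect_error(hubScores(gEmpty), "empty")
})

test_that("hub scores are max-normalized weighted degree with self-loops doubled", {
  tri <- buildGroupGraph(data.frame(group_a = c("A", "A", "B"),
                                    group_b = c("B", "C", "C"),
                                    weight = c(1L, 1L, 1L)), minCount = 0)
  hs <- hubScores(tri)
  expect_equal(hs$hub_score, rep(1, 3))  # symmetric triangle

  star <- buildGroupGraph(data.frame(group_a = c("C", "C", "C", "C"),
                                     group_b = c("L1", "L2", "L3", "L4"),
                                     weight = rep(1L, 4)), minCount = 0)
  hsS <- hubScores(star)
  expect_equal(hsS$hub_score[hsS$group == "C"], 1.0)
  expect_equal(hsS$hub_score[hsS$group != "C"], rep(0.25, 4))

  loop <- buildGroupGraph(data.frame(group_a = c("A", "A"),
                                     group_b = c("A", "B"),
                                     weight = c(3L, 2L)), minCount = 0)
  hsL <- hubScores(loop)
  expect_equal(hsL$degree[hsL$group == "A"], 2 * 3 + 2)  # self counts twice
  expect_equal(max(hsL$hub_score), 1.0)
})

test_that("hub scores are invariant to relabeling and weight rescaling", {
  set.seed(71)
  nodes <- LETTERS[1:6]
  pairs <- expand.grid(group_a = nodes, group_b = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$group_a <= pairs$group_b, ]
  pairs <- pairs[sample(nrow(pairs), 9), ]
  pairs$weight <- sample(1:20, 9)
  g <- buildGroupGraph(pairs, minCount = 0)
  hs <- hubScores(g)

  # conservation: sum of degrees = 2 * sum of weights (self-loops double)
  expect_equal(sum(hs$degree), 2 * sum(pairs$weight))

  # weight rescaling leaves normalized scores unchanged
  pairs3 <- pairs; pairs3$weight <- pairs3$weight * 3L
  hs3 <- hubScores(buildGroupGraph(pairs3, minCount = 0))
  expect_equal(hs3$hub_score, hs$hub_score)

  # node relabeling permutes but does not change scores
  map <- setNames(paste0("N", sample(6)), nodes)
  pairsR <- data.frame(group_a = pmin(map[pairs$group_a], map[pairs$group_b]),
                       group_b = pmax(map[pairs$group_a], map[pairs$group_b]),
                       weight = pairs$weight, stringsAsFactors = FALSE)
  hsR <- hubScores(buildGroupGraph(pairsR, minCount = 0))
  expect_equal(sort(hsR$hub_score), sort(hs$hub_score))

  # independent check against igraph strength
  skip_if_not_installed("igraph")
  el <- as.matrix(pairs[, c("group_a", "group_b")])
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(ig)$weight <- pairs$weight
  strg <- igraph::strength(ig, loops = TRUE)
  expect_equal(hs$degree[match(names(strg), hs$group)], unname(strg))
})

test_that("group-pair prevalence percentages use one-decimal rounding", {
  pairs <- data.frame(group_a = "Thalamus", group_b = "BasalGanglia",
                      weight = 10L)
  out <- edgePrevalencePct(pairs, nPatients = 56)
  expect_equal(out$pct, 17.9)  # 10/56 cohort share
  expect_equal(edgePrevalencePct(data.frame(group_a = "A", group_b = "B",
                                            weight = 0L), 56)$pct, 0)
  expect_equal(edgePrevalencePct(data.frame(group_a = "A", group_b = "B",
                                            weight = 56L), 56)$pct, 100)
  expect_error(edgePrevalencePct(pairs, 0), "positive")
})

test_that("thalamus-heavy synthetic cohorts rank thalamus as the top hub", {
  st <- defaultSeedTable()
  focus <- which(unname(roiGroups(st)) == "Thalamus") - 1L
  spec <- simulationSpec(nControls = 20, nPatients = 12, delta = 0.5,
                         focusSeedIndices = focus, rngSeed = 11)
  sim <- simulateEdgeLevel(spec)
  cfg <- permutationConfig(method = "exact", nullModel = "pooled_edges")
  res <- lapply(sim$patients, function(p) testPatient(sim$stack, p, cfg))
  summ <- aggregateResults(res)
  pairs <- mapEdgesToGroups(edgeCounts(summ), st, defaultAtlasTable())
  g <- buildGroupGraph(pairs, minCount = 4)
  hs <- hubScores(g)
  expect_gt(nrow(hs), 1)
  expect_identical(hs$group[1], "Thalamus")
  expect_identical(hs$hub_score[1], 1.0)
})
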