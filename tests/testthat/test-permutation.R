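test_that("exact enumeration matches hand-computed relabeling p-values", {
  cfg <- permutationConfig(method = "exact")
  r <- edgePermTest(c(0, 0, 0, 0), 1, cfg)
  expect_equal(r$observedDiff, 1.0)
  expect_equal(r$pRaw, 1 / 5)  # only the true labeling attains diff 1

  # patient at the pooled mean minimizes the statistic -> p = 1
  r2 <- edgePermTest(c(1, 2, 3, 4, 5), 3, cfg)
  expect_equal(r2$pRaw, 1.0)

  # all values tied: observed diff 0, every relabeling ties
  r3 <- edgePermTest(rep(2.5, 6), 2.5, cfg)
  expect_equal(r3$observedDiff, 0)
  expect_equal(r3$pRaw, 1.0)

  expect_error(edgePermTest(1, 2, cfg), "at least 2")
})

test_that("exact p-values agree with the brute-force oracle on random edges", {
  cfg <- permutationConfig(method = "exact")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    ctrl <- rnorm(n)
    pat <- rnorm(1, sd = sample(c(0.5, 1, 3), 1))
    expect_equal(edgePermTest(ctrl, pat, cfg)$pRaw, oracleExactP(ctrl, pat))
  }
})

test_that("Monte-Carlo p converges to the exact p as nPerm grows", {
  set.seed(12)
  ctrl <- rnorm(5)
  pats <- rnorm(12, sd = 2)
  cfgE <- permutationConfig(method = "exact")
  for (i in seq_along(pats)) {
    pe <- edgePermTest(ctrl, pats[i], cfgE)$pRaw
    cfgM <- permutationConfig(nPerm = 100000, method = "monte_carlo",
                              rngSeed = 100 + i)
    pm <- edgePermTest(ctrl, pats[i], cfgM)$pRaw
    expect_lt(abs(pm - pe), 0.01)
  }
})

test_that("p-values are invariant to control order and location shifts", {
  set.seed(13)
  ctrl <- rnorm(8)
  pat <- 1.4
  cfg <- permutationConfig(method = "exact")
  p0 <- edgePermTest(ctrl, pat, cfg)$pRaw
  expect_equal(edgePermTest(sample(ctrl), pat, cfg)$pRaw, p0)
  expect_equal(edgePermTest(ctrl + 17.3, pat + 17.3, cfg)$pRaw, p0)
  # exact p lives on the grid {1/(n+1), ..., 1}
  grid <- seq_len(9) / 9
  for (pv in rnorm(20))
    expect_true(edgePermTest(ctrl, pv, cfg)$pRaw %in% grid)
})

test_that("plus-one Monte-Carlo p-values never reach zero", {
  cfg <- permutationConfig(nPerm = 200, rngSeed = 1, pRule = "plus_one")
  r <- edgePermTest(c(0, 0, 0, 0, 0), 50, cfg)
  expect_gte(r$pRaw, 1 / 201)
})

test_that("BH adjustment matches both the step-up oracle and p.adjust", {
  r <- fdrBH(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))  # p_(i) <= (i/4) * 0.05 for all i
  r2 <- fdrBH(c(0.5, 0.5, 0.5), alpha = 0.05)
  expect_false(any(r2$reject))
  expect_equal(r2$pAdj, rep(0.5, 3))
  r3 <- fdrBH(0.04, alpha = 0.05)
  expect_equal(r3$pAdj, 0.04)
  expect_true(r3$reject)
  expect_error(fdrBH(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(14)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(c(0.5, 1, 3), 1)
    mine <- fdrBH(p, alpha = 0.05)
    orc <- oracleBH(p, alpha = 0.05)
    expect_equal(mine$pAdj, orc$pAdj)
    expect_identical(mine$reject, orc$reject)
    expect_equal(mine$pAdj, p.adjust(p, method = "BH"))
    expect_true(all(mine$pAdj >= p - 1e-12))
  }
})

test_that("testPatient evaluates the full edge grid deterministically", {
  spec <- simulationSpec(nControls = 20, nPatients = 1, delta = 0.5,
                         rngSeed = 21)
  sim <- simulateEdgeLevel(spec)
  cfg <- permutationConfig(nPerm = 500, rngSeed = 21)
  r1 <- testPatient(sim$stack, sim$patients[[1]], cfg)
  expect_identical(length(pRaw(r1)), 8816L)
  expect_identical(dim(pRaw(r1)), c(76L, 116L))
  r2 <- testPatient(sim$stack, sim$patients[[1]], cfg)
  expect_identical(pRaw(r1), pRaw(r2))
  expect_identical(isSignificant(r1), isSignificant(r2))
  expect_true(all(pAdj(r1) >= pRaw(r1)))

  bad <- toyConnectivity(matrix(0.1, 3, 4), "p")
  expect_error(testPatient(sim$stack, bad, cfg), "shape")
})

test_that("a patient equal to the control mean has no significant edges", {
  set.seed(22)
  arr <- array(rnorm(10 * 3 * 4, 0.3, 0.1), c(10, 3, 4))
  st <- toyStack(arr)
  # same floating arithmetic as the statistic (sum then divide)
  mean_m <- apply(arr, c(2, 3), sum) / 10
  pat <- toyConnectivity(mean_m, "pmean")
  r <- testPatient(st, pat, permutationConfig(method = "exact"))
  expect_true(all(observedDiff(r) == 0))
  expect_true(all(pRaw(r) == 1))
  expect_false(any(isSignificant(r)))
})

test_that("testPatient agrees edge-wise with edgePermTest in exact mode", {
  set.seed(23)
  arr <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  st <- toyStack(arr)
  pat <- toyConnectivity(matrix(rnorm(6, sd = 2), 2, 3), "p")
  r <- testPatient(st, pat, permutationConfig(method = "exact"))
  cfg <- permutationConfig(method = "exact")
  for (i in 1:2) for (j in 1:3) {
    e <- edgePermTest(arr[, i, j], connValues(pat)[i, j], cfg)
    expect_equal(pRaw(r)[i, j], e$pRaw)
    expect_equal(observedDiff(r)[i, j], e$observedDiff)
  }
})

test_that("injected edges at five sigma match the oracle and are near-always minimal", {
  # In the n-vs-1 relabeling null the shifted patient value leaks into the
  # relabeled "control" means only through delta/n, so at delta = 5 sigma
  # an injected edge attains the minimum p of 1/21 with probability
  # ~99.25%, not with certainty; what must hold exactly is agreement with
  # the enumeration oracle on every edge.
  spec <- simulationSpec(nControls = 20, nPatients = 5, delta = 0.5,
                         sigmaBetween = 0.1, rngSeed = 31)
  sim <- simulateEdgeLevel(spec)
  cfg <- permutationConfig(method = "exact")
  nMin <- 0L; nTot <- 0L
  for (p in seq_along(sim$patients)) {
    r <- testPatient(sim$stack, sim$patients[[p]], cfg)
    inj <- spec@injectedEdges[[p]]
    for (q in seq_len(nrow(inj))) {
      i <- inj[q, 1] + 1; j <- inj[q, 2] + 1
      pOracle <- oracleExactP(stackValues(sim$stack)[, i, j],
                              connValues(sim$patients[[p]])[i, j])
      expect_equal(pRaw(r)[i, j], pOracle)
      nTot <- nTot + 1L
      nMin <- nMin + (pRaw(r)[i, j] == 1 / 21)
    }
  }
  expect_gte(nMin / nTot, 0.9)
})

test_that("pooled-edges null yields discoveries bounded by alpha", {
  spec <- simulationSpec(nControls = 20, nPatients = 2, delta = 0.5,
                         rngSeed = 41)
  sim <- simulateEdgeLevel(spec)
  cfg <- permutationConfig(method = "exact", nullModel = "pooled_edges")
  r <- testPatient(sim$stack, sim$patients[[1]], cfg)
  se <- significantEdges(r)
  expect_gt(nrow(se), 0)
  expect_lte(max(se$p_adj), 0.05)
  inj <- spec@injectedEdges[[1]]
  expect_true(all(paste(se$seed_index, se$atlas_index) %in%
                    paste(inj[, 1], inj[, 2])))
})

test_that("null calibration keeps the flagged proportion at or below alpha", {
  spec <- simulationSpec(nControls = 20, nPatients = 10, delta = 0,
                         rngSeed = 51)
  cal <- calibrationExperiment(spec, permutationConfig(nPerm = 500,
                                                       rngSeed = 51))
  expect_lte(cal$meanFlaggedProportion, 0.05)

  # alpha = 0 flags nothing, and flagged proportion is monotone in alpha
  cal0 <- calibrationExperiment(
    simulationSpec(nControls = 10, nPatients = 2, delta = 0, nSeeds = 6,
                   nAtlas = 8, rngSeed = 52),
    permutationConfig(nPerm = 200, alpha = 0, rngSeed = 52))
  expect_identical(cal0$meanFlaggedProportion, 0)

  specS <- simulationSpec(nControls = 10, nPatients = 3, delta = 0,
                          nSeeds = 6, nAtlas = 8, rngSeed = 53)
  props <- vapply(c(0.01, 0.05, 0.10), function(a) {
    calibrationExperiment(specS,
      permutationConfig(nPerm = 200, alpha = a, rngSeed = 53,
                        nullModel = "pooled_edges"))$meanFlaggedProportion
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
  expect_error(calibrationExperiment(
    simulationSpec(nControls = 5, nPatients = 1, delta = 0.5, rngSeed = 1),
    permutationConfig()), "delta = 0")
})
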