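mkClinical <- function(nPat = 20, nCtl = 10, seed = 81,
                       vas = NULL, age = NULL, sex = NULL) {
  set.seed(seed)
  n <- nPat + nCtl
  df <- data.frame(
    subject_id = c(sprintf("p%02d", seq_len(nPat)),
                   sprintf("c%02d", seq_len(nCtl))),
    group = rep(c("patient", "control"), c(nPat, nCtl)),
    age = if (is.null(age)) rnorm(n, 58, 7) else age,
    sex = if (is.null(sex)) sample(c("F", "M"), n, TRUE) else sex,
    vas_pct = NA_real_, womac_pct = NA_real_,
    mean_fd = abs(rnorm(n, 0.15, 0.05)), stringsAsFactors = FALSE)
  df$vas_pct[seq_len(nPat)] <- if (is.null(vas)) rnorm(nPat, 17, 30) else vas
  df$womac_pct[seq_len(nPat)] <- rnorm(nPat, 18, 30)
  df
}

test_that("olsFit matches hand normal equations and handles degenerate y", {
  f <- olsFit(0:9, 2 * (0:9) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  fc <- olsFit(0:9, rep(3, 10))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  # hand computation: x=(0,1,2), y=(0,1,4): Sxy=4, Sxx=2 -> slope 2,
  # intercept -1/3; SSE=6/9, SST=78/9 -> R^2 = 12/13
  f3 <- olsFit(c(0, 1, 2), c(0, 1, 4))
  expect_equal(f3$slope, 2)
  expect_equal(f3$intercept, -1 / 3)
  expect_equal(f3$r_squared, 12 / 13)

  expect_error(olsFit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(olsFit(1:2, 1:2), "at least 3")

  # oracle equivalence on random small inputs
  set.seed(82)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- olsFit(x, y)
    sx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sx
    expect_equal(f$slope, slope, tolerance = 1e-10)
    expect_equal(f$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
  }
})

test_that("R squared is scale-invariant while the slope rescales inversely", {
  set.seed(83)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  f <- olsFit(x, y)
  fs <- olsFit(10 * x + 5, y)
  expect_equal(fs$r_squared, f$r_squared, tolerance = 1e-12)
  expect_equal(fs$slope, f$slope / 10, tolerance = 1e-12)
})

test_that("edge-outcome screen recovers a planted noiseless coupling", {
  set.seed(84)
  patients <- lapply(1:20, function(i)
    toyConnectivity(matrix(rnorm(12, 0.3, 0.1), 3, 4), sprintf("p%02d", i)))
  x <- vapply(patients, function(m) connValues(m)[2, 3], numeric(1))
  clin <- mkClinical(nPat = 20, vas = 8.71 + 67.87 * x)
  edges <- data.frame(seed_index = c(1L, 0L), atlas_index = c(2L, 0L))
  fits <- correlateEdgesWithOutcome(patients, edges, clin, "vas_pct",
                                    r2Threshold = 0.10)
  expect_identical(fits$seed_index[1], 1L)  # sorted by R^2 descending
  expect_equal(fits$slope[1], 67.87, tolerance = 1e-8)
  expect_equal(fits$intercept[1], 8.71, tolerance = 1e-8)
  expect_equal(fits$r_squared[1], 1.0)
  expect_true(fits$flagged[1])
})

test_that("a noisy planted coupling is recovered within the fit's confidence interval", {
  coupling <- data.frame(outcome = "vas_pct", seed_index = 1L,
                         atlas_index = 2L, slope = 67.87, intercept = 8.71,
                         noise_sd = 5)
  spec <- simulationSpec(nControls = 5, nPatients = 56, nSeeds = 4,
                         nAtlas = 5, delta = 0, nInjectedPerPatient = 1,
                         clinicalCoupling = coupling, rngSeed = 95)
  sim <- simulateEdgeLevel(spec)
  clin <- simulateClinical(sim$groundTruth, sim$patients, spec)
  x <- vapply(sim$patients, function(m) connValues(m)[2, 3], numeric(1))
  y <- clin$vas_pct[clin$group == "patient"]
  ci <- confint(lm(y ~ x))["x", ]
  expect_gte(67.87, ci[1])
  expect_lte(67.87, ci[2])
  f <- olsFit(x, y)
  expect_equal(f$slope, unname(coef(lm(y ~ x))[2]))
})

test_that("a shuffled outcome rarely clears the R squared screen", {
  set.seed(85)
  patients <- lapply(1:56, function(i)
    toyConnectivity(matrix(rnorm(4, 0.3, 0.1), 2, 2), sprintf("p%02d", i)))
  hits <- 0L
  for (rep in 1:40) {
    clin <- mkClinical(nPat = 56, nCtl = 5, seed = 1000 + rep)
    fits <- correlateEdgesWithOutcome(
      patients, data.frame(seed_index = 0L, atlas_index = 0L), clin,
      "vas_pct", r2Threshold = 0.10)
    hits <- hits + fits$flagged[1]
  }
  expect_lt(hits / 40, 0.05 + 0.10)  # > 95% of replicates below 0.10
})

test_that("patients with missing outcomes are excluded with a warning", {
  set.seed(86)
  patients <- lapply(1:10, function(i)
    toyConnectivity(matrix(rnorm(4, 0.3, 0.1), 2, 2), sprintf("p%02d", i)))
  clin <- mkClinical(nPat = 10, nCtl = 4)
  clin$vas_pct[2] <- NA
  expect_warning(
    fits <- correlateEdgesWithOutcome(
      patients, data.frame(seed_index = 0L, atlas_index = 0L), clin),
    "1 patient")
  expect_identical(fits$n[1], 9L)
})

test_that("age-outcome correlation is stratified by sex with small strata skipped", {
  clin <- mkClinical(nPat = 30, seed = 87)
  pats <- clin$group == "patient"
  clin$vas_pct[pats] <- -clin$age[pats]  # exact negative dependence
  out <- ageOutcomeBySex(clin)
  expect_identical(sort(out$sex), c("F", "M"))
  expect_equal(out$r, rep(-1, 2), tolerance = 1e-12)

  clin2 <- mkClinical(nPat = 10, seed = 88,
                      sex = c(rep("F", 9), "M", rep("F", 10)))
  expect_warning(out2 <- ageOutcomeBySex(clin2), "fewer than 3")
  expect_identical(out2$sex, "F")

  # independence: |r| < 0.5 in the large majority of null replicates
  rs <- unlist(lapply(1:20, function(rep)
    ageOutcomeBySex(mkClinical(nPat = 60, seed = 3000 + rep))$r))
  expect_gte(mean(abs(rs) < 0.5), 0.95)
})

test_that("confounder screen behaves under null, identical and shifted groups", {
  clinNull <- mkClinical(nPat = 56, nCtl = 20, seed = 90)
  outNull <- confounderCheck(clinNull)
  expect_identical(outNull$variable, c("age", "mean_fd", "sex"))
  expect_true(all(outNull$p_value > 0 & outNull$p_value <= 1))

  # identical distributions: t = 0, p = 1
  clinSame <- mkClinical(nPat = 5, nCtl = 5, seed = 91,
                         age = rep(58, 10))
  clinSame$mean_fd <- rep(0.15, 10)
  outSame <- confounderCheck(clinSame)
  expect_equal(outSame$p_value[outSame$variable == "age"], 1)
  expect_equal(outSame$statistic[outSame$variable == "age"], 0)

  # a 20-year age shift is decisively detected
  clinShift <- mkClinical(nPat = 56, nCtl = 20, seed = 92)
  clinShift$age[clinShift$group == "patient"] <-
    clinShift$age[clinShift$group == "patient"] + 20
  outShift <- confounderCheck(clinShift)
  expect_lt(outShift$p_value[outShift$variable == "age"], 0.001)

  expect_error(confounderCheck(clinNull[clinNull$group == "patient", ]),
               "non-empty")
})

test_that("null confounder screen passes p > 0.1 most of the time", {
  passes <- vapply(1:30, function(rep) {
    clin <- mkClinical(nPat = 56, nCtl = 20, seed = 2000 + rep)
    all(confounderCheck(clin)$p_value > 0.1)
  }, logical(1))
  # three independent null tests each pass ~90% -> joint ~0.73
  expect_gt(mean(passes), 0.5)
})
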