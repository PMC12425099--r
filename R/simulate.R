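#' @include roi-tables.R connectivity.R
NULL

#' Build a SimulationSpec
#'
#' Describes a synthetic study design mirroring the reference cohort: a
#' normative control group plus patients whose connectivity deviates from
#' the control distribution on a known set of injected edges. Defaults
#' reproduce the study conditions: 20 controls, 56 patients, 76 x 116
#' edges, per-edge baseline means drawn once from Normal(0.3, 0.1) on the
#' Fisher-z scale with between-subject SD 0.1, and a shift of
#' `delta = 0.5` (five between-subject SDs) on each patient's injected
#' edges.
#'
#' @param nControls,nPatients cohort sizes (defaults 20 and 56).
#' @param nSeeds,nAtlas connectivity dimensions (defaults 76 and 116).
#' @param mode `"edge_level"` (draw connectivity values directly) or
#'   `"timeseries_level"` (draw BOLD-like signals and correlate them).
#' @param nTimepoints timepoints per subject in timeseries mode
#'   (default 200).
#' @param mu,muSd mean and SD of the per-edge baseline connectivity
#'   (Fisher-z units).
#' @param sigmaBetween between-subject edge SD (Fisher-z units).
#' @param delta injected atypicality effect size (Fisher-z units), >= 0.
#' @param injectedEdges either a list with one n x 2 integer matrix of
#'   0-based (seed, atlas) indices per patient, or `NULL` to sample
#'   `nInjectedPerPatient` distinct edges per patient from `rngSeed`.
#' @param nInjectedPerPatient edges sampled per patient when
#'   `injectedEdges` is `NULL` (default 10).
#' @param focusSeedIndices optional 0-based seed indices to which sampled
#'   injected edges are restricted (e.g. all thalamus seeds, to emulate a
#'   thalamus-centred atypical network).
#' @param clinicalCoupling `NULL` or a data.frame with columns `outcome`
#'   (`"vas_pct"`/`"womac_pct"`), `seed_index`, `atlas_index`, `slope`,
#'   `intercept`, `noise_sd`: the named outcome is generated as
#'   `intercept + slope * edge + Normal(0, noise_sd)`.
#' @param rngSeed integer seed controlling every random draw.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nControls = 20L, nPatients = 56L, nSeeds = 76L,
                           nAtlas = 116L,
                           mode = c("edge_level", "timeseries_level"),
                           nTimepoints = 200L, mu = 0.3, muSd = 0.1,
                           sigmaBetween = 0.1, delta = 0.5,
                           injectedEdges = NULL, nInjectedPerPatient = 10L,
                           focusSeedIndices = NULL, clinicalCoupling = NULL,
                           rngSeed = 1L) {
  mode <- match.arg(mode)
  nControls <- as.integer(nControls); nPatients <- as.integer(nPatients)
  nSeeds <- as.integer(nSeeds); nAtlas <- as.integer(nAtlas)
  if (is.null(injectedEdges)) {
    injectedEdges <- sampleInjectedEdges(
      nPatients, nSeeds, nAtlas, nEdges = nInjectedPerPatient,
      focusSeedIndices = focusSeedIndices, rngSeed = rngSeed)
  }
  injectedEdges <- lapply(injectedEdges, function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    colnames(m) <- c("seed_index", "atlas_index")
    m
  })
  if (is.null(clinicalCoupling))
    clinicalCoupling <- data.frame(outcome = character(),
                                   seed_index = integer(),
                                   atlas_index = integer(), slope = numeric(),
                                   intercept = numeric(), noise_sd = numeric(),
                                   stringsAsFactors = FALSE)
  new("SimulationSpec", nControls = nControls, nPatients = nPatients,
      nSeeds = nSeeds, nAtlas = nAtlas, mode = mode,
      nTimepoints = as.integer(nTimepoints), mu = mu, muSd = muSd,
      sigmaBetween = sigmaBetween, injectedEdges = injectedEdges,
      delta = delta, clinicalCoupling = clinicalCoupling,
      rngSeed = as.integer(rngSeed))
}

#' Sample injected atypical edges for each synthetic patient
#'
#' Draws `nEdges` distinct (seed, atlas) pairs per patient, uniformly over
#' the full edge grid or restricted to `focusSeedIndices` (used to build
#' e.g. thalamus-heavy cohorts).
#'
#' @inheritParams simulationSpec
#' @param nSeeds,nAtlas grid dimensions.
#' @param nEdges edges per patient.
#' @return list of n x 2 integer matrices of 0-based indices.
#' @export
sampleInjectedEdges <- function(nPatients, nSeeds = 76L, nAtlas = 116L,
                                nEdges = 10L, focusSeedIndices = NULL,
                                rngSeed = 1L) {
  seedPool <- if (is.null(focusSeedIndices)) seq_len(nSeeds) - 1L
              else as.integer(focusSeedIndices)
  if (any(seedPool < 0L) || any(seedPool >= nSeeds))
    stop("focusSeedIndices out of range", call. = FALSE)
  nCells <- length(seedPool) * nAtlas
  if (nEdges > nCells)
    stop("more injected edges requested than available cells", call. = FALSE)
  lapply(seq_len(max(nPatients, 0L)), function(p) {
    set.seed(substreamSeed(rngSeed, 900000 + p))
    flat <- sample.int(nCells, nEdges) - 1L
    cbind(seed_index = seedPool[flat %% length(seedPool) + 1L],
          atlas_index = flat %/% length(seedPool))
  })
}

edgeLabels <- function(spec) {
  if (spec@nSeeds == 76L && spec@nAtlas == 116L) {
    list(seed = roiLabels(defaultSeedTable()),
         atlas = roiLabels(defaultAtlasTable()))
  } else {
    list(seed = sprintf("seed_%03d", seq_len(spec@nSeeds) - 1L),
         atlas = sprintf("atlas_%03d", seq_len(spec@nAtlas) - 1L))
  }
}

#' Simulate a cohort at the connectivity-edge level
#'
#' Draws each control subject's edge values from Normal(mu_e, sigmaBetween),
#' where the per-edge baseline mu_e is itself drawn once from
#' Normal(mu, muSd); patients receive the same draw plus `delta` on their
#' injected edges only. Values are on the Fisher-z scale. Everything is
#' reproducible from `rngSeed` via deterministic per-subject sub-streams.
#'
#' @param spec a [SimulationSpec-class] with `mode = "edge_level"`.
#' @return a list with elements `stack` ([CohortStack-class] of controls),
#'   `patients` (list of [ConnectivityMatrix-class]), and `groundTruth`
#'   (list: `muEdge` matrix, `injectedEdges`, `delta`, `sigmaBetween`,
#'   `clinicalCoupling`).
#' @export
simulateEdgeLevel <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  if (spec@mode != "edge_level")
    stop("spec mode must be 'edge_level'", call. = FALSE)
  lab <- edgeLabels(spec)
  S <- spec@nSeeds; A <- spec@nAtlas
  set.seed(substreamSeed(spec@rngSeed, 0L))
  muEdge <- matrix(stats::rnorm(S * A, spec@mu, spec@muSd), S, A,
                   dimnames = list(lab$seed, lab$atlas))
  ctrl <- array(NA_real_, c(spec@nControls, S, A),
                dimnames = list(NULL, lab$seed, lab$atlas))
  for (s in seq_len(spec@nControls)) {
    set.seed(substreamSeed(spec@rngSeed, s))
    ctrl[s, , ] <- muEdge + stats::rnorm(S * A, 0, spec@sigmaBetween)
  }
  stack <- new("CohortStack", values = ctrl,
               subjectIds = sprintf("control_%02d", seq_len(spec@nControls)),
               scale = "fisher_z")
  patients <- vector("list", spec@nPatients)
  for (p in seq_len(spec@nPatients)) {
    set.seed(substreamSeed(spec@rngSeed, spec@nControls + p))
    v <- muEdge + matrix(stats::rnorm(S * A, 0, spec@sigmaBetween), S, A)
    inj <- spec@injectedEdges[[p]]
    if (nrow(inj))
      v[inj[, 1L] + (inj[, 2L]) * S + 1L] <- v[inj[, 1L] + inj[, 2L] * S + 1L] +
        spec@delta
    dimnames(v) <- list(lab$seed, lab$atlas)
    patients[[p]] <- new("ConnectivityMatrix",
                         subjectId = sprintf("patient_%02d", p),
                         values = v, scale = "fisher_z")
  }
  list(stack = stack, patients = patients,
       groundTruth = list(muEdge = muEdge,
                          injectedEdges = spec@injectedEdges,
                          delta = spec@delta,
                          sigmaBetween = spec@sigmaBetween,
                          clinicalCoupling = spec@clinicalCoupling))
}

# Target correlation matrix over (seed, atlas) columns from a sparse edge
# list; identity elsewhere. edges: data.frame/matrix with 0-based
# seed_index, atlas_index and a correlation column r.
buildTargetCorrelation <- function(nSeeds, nAtlas, edges) {
  R <- diag(nSeeds + nAtlas)
  if (NROW(edges)) {
    i <- edges[, 1L] + 1L
    j <- nSeeds + edges[, 2L] + 1L
    r <- edges[, 3L]
    if (any(abs(r) >= 1)) stop("target correlations must be in (-1, 1)",
                               call. = FALSE)
    R[cbind(i, j)] <- r
    R[cbind(j, i)] <- r
  }
  R
}

#' Simulate a cohort at the BOLD time-series level
#'
#' Draws each subject's T x (nSeeds + nAtlas) signals from a zero-mean,
#' unit-variance multivariate normal. The target correlation is sparse:
#' each designated base edge (by default, seed k paired with atlas region
#' k) gets correlation tanh(mu_e); injected patient edges get
#' tanh(mu_e + delta); all other region pairs are uncorrelated. Positive
#' definiteness of the target is verified by Cholesky factorization.
#'
#' @param spec a [SimulationSpec-class] with `mode = "timeseries_level"`.
#' @param baseEdges `NULL` (default diagonal matching) or an n x 2 matrix of
#'   0-based (seed, atlas) pairs carrying baseline correlation.
#' @return list with `subjects` (list of [SubjectTimeSeries-class], controls
#'   first), `groundTruth` (per-subject target correlation entries), and
#'   `labels`.
#' @export
simulateTimeseriesLevel <- function(spec, baseEdges = NULL) {
  stopifnot(is(spec, "SimulationSpec"))
  if (spec@mode != "timeseries_level")
    stop("spec mode must be 'timeseries_level'", call. = FALSE)
  lab <- edgeLabels(spec)
  S <- spec@nSeeds; A <- spec@nAtlas
  if (is.null(baseEdges)) {
    k <- seq_len(min(S, A)) - 1L
    baseEdges <- cbind(seed_index = k, atlas_index = k)
  }
  set.seed(substreamSeed(spec@rngSeed, 0L))
  muBase <- stats::rnorm(nrow(baseEdges), spec@mu, spec@muSd)
  colLabels <- c(lab$seed, lab$atlas)

  cholFor <- function(edges) {
    R <- buildTargetCorrelation(S, A, edges)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch))
      stop("requested correlation structure is not positive definite; ",
           "use smaller couplings or fewer overlapping edges",
           call. = FALSE)
    ch
  }
  drawSubject <- function(id, streamIndex, edges) {
    ch <- cholFor(edges)
    set.seed(substreamSeed(spec@rngSeed, streamIndex))
    Z <- matrix(stats::rnorm(spec@nTimepoints * (S + A)),
                spec@nTimepoints, S + A)
    X <- Z %*% ch
    colnames(X) <- colLabels
    new("SubjectTimeSeries", subjectId = id, data = X)
  }

  baseTriplet <- cbind(baseEdges[, 1L], baseEdges[, 2L], tanh(muBase))
  subjects <- list()
  truth <- list()
  for (s in seq_len(spec@nControls)) {
    id <- sprintf("control_%02d", s)
    subjects[[id]] <- drawSubject(id, s, baseTriplet)
    truth[[id]] <- baseTriplet
  }
  for (p in seq_len(spec@nPatients)) {
    id <- sprintf("patient_%02d", p)
    ed <- baseTriplet
    inj <- spec@injectedEdges[[p]]
    if (nrow(inj)) {
      # injected pairs overriding a base edge get the shifted correlation;
      # new pairs get tanh(mu + delta)
      key <- paste(ed[, 1L], ed[, 2L])
      for (q in seq_len(nrow(inj))) {
        hit <- match(paste(inj[q, 1L], inj[q, 2L]), key)
        if (!is.na(hit)) {
          ed[hit, 3L] <- tanh(atanh(ed[hit, 3L]) + spec@delta)
        } else {
          ed <- rbind(ed, c(inj[q, 1L], inj[q, 2L],
                            tanh(spec@mu + spec@delta)))
        }
      }
    }
    subjects[[id]] <- drawSubject(id, spec@nControls + p, ed)
    truth[[id]] <- ed
  }
  list(subjects = subjects, groundTruth = truth, labels = colLabels)
}

#' Simulate clinical outcomes coupled to connectivity edges
#'
#' Builds a clinical table for the synthetic cohort. Ages are drawn from
#' Normal(58, 7) (matching the reference demographics), sex is sampled with
#' the reference cohort proportions (30/56 female patients, 10/20 female
#' controls), and mean framewise displacement from a truncated
#' Normal(0.15, 0.05). Patient outcomes named in the spec's
#' `clinicalCoupling` are generated as
#' `intercept + slope * edge_value + Normal(0, noise_sd)` from that
#' patient's connectivity matrix; uncoupled outcomes are drawn around the
#' reference cohort moments.
#'
#' @param groundTruth the `groundTruth` element returned by
#'   [simulateEdgeLevel()].
#' @param patients list of patient [ConnectivityMatrix-class] objects.
#' @param spec the [SimulationSpec-class] used to generate them.
#' @return a clinical `data.frame` with columns `subject_id`, `group`,
#'   `age`, `sex`, `vas_pct`, `womac_pct`, `mean_fd` (outcomes `NA` for
#'   controls).
#' @export
simulateClinical <- function(groundTruth, patients, spec) {
  nP <- length(patients); nC <- spec@nControls
  set.seed(substreamSeed(spec@rngSeed, 500000L))
  age <- stats::rnorm(nP + nC, 58, 7)
  sex <- c(ifelse(stats::runif(nP) < 30 / 56, "F", "M"),
           ifelse(stats::runif(nC) < 0.5, "F", "M"))
  fd <- abs(stats::rnorm(nP + nC, 0.15, 0.05))
  out <- data.frame(
    subject_id = c(vapply(patients, subjectId, character(1L)),
                   sprintf("control_%02d", seq_len(nC))),
    group = rep(c("patient", "control"), c(nP, nC)),
    age = age, sex = sex,
    vas_pct = NA_real_, womac_pct = NA_real_, mean_fd = fd,
    stringsAsFactors = FALSE)
  cc <- groundTruth$clinicalCoupling
  pat <- seq_len(nP)
  for (oc in c("vas_pct", "womac_pct")) {
    rows <- which(cc$outcome == oc)
    set.seed(substreamSeed(spec@rngSeed, 500001L + match(oc, c("vas_pct", "womac_pct"))))
    if (length(rows)) {
      r1 <- rows[1L]  # one generating edge per outcome
      ev <- vapply(patients, function(m)
        connValues(m)[cc$seed_index[r1] + 1L, cc$atlas_index[r1] + 1L],
        numeric(1L))
      out[[oc]][pat] <- cc$intercept[r1] + cc$slope[r1] * ev +
        stats::rnorm(nP, 0, cc$noise_sd[r1])
    } else {
      moments <- if (oc == "vas_pct") c(17, 32) else c(18, 30)
      out[[oc]][pat] <- stats::rnorm(nP, moments[1L], moments[2L])
    }
  }
  out
}

#' Validate a clinical table
#'
#' Checks the contract of the clinical table consumed by the statistics
#' stage: unique subject ids, a `group` column of patients and controls,
#' and pain outcomes present only for patients.
#'
#' @param clinical a data.frame.
#' @return the data.frame, invisibly, or an error.
#' @export
validateClinicalTable <- function(clinical) {
  need <- c("subject_id", "group", "age", "sex", "vas_pct", "womac_pct",
            "mean_fd")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(clinical$subject_id))
    stop("duplicated subject_id in clinical table", call. = FALSE)
  if (!all(clinical$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'", call. = FALSE)
  ctl <- clinical$group == "control"
  if (any(!is.na(clinical$vas_pct[ctl])) ||
      any(!is.na(clinical$womac_pct[ctl])))
    stop("pain outcomes must be present only for patients", call. = FALSE)
  invisible(clinical)
}
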