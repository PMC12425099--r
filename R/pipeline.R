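#' @include clinical.R nifti.R
NULL

pipelineDefaults <- function() {
  list(mode = "synthetic", seed = 1L, n_perm = 10000L, alpha = 0.05,
       method = "monte_carlo", p_rule = NULL, null_model = "per_edge",
       scale = "fisher_z", drop_initial_volumes = 0L, sphere_radius_mm = 6,
       node_min_patients = 10L, edge_min_count = 7L, seed_edge_min_count = 3L,
       group_min_count = 4L, r2_threshold = 0.10,
       n_controls = 20L, n_patients = 56L, delta = 0.5, n_injected = 10L,
       focus_group = NULL, mu = 0.3, mu_sd = 0.1, sigma_between = 0.1,
       vas_slope = 67.87, vas_intercept = 8.71, vas_noise_sd = 15,
       write_patient_tables = TRUE, strict_roi = TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [runPipeline()].
#' @return named list merged over the defaults.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  utils::modifyList(pipelineDefaults(), yaml::read_yaml(path))
}

cfgGet <- function(config, key) {
  if (is.null(config[[key]]))
    stop("configuration error: missing key '", key, "'", call. = FALSE)
  config[[key]]
}

loadSubjectMatrices <- function(paths, seedTab, atlasTab, scale,
                                dropInitialVolumes) {
  lapply(paths, function(p) {
    ts <- readTimeSeries(p, dropInitialVolumes = dropInitialVolumes)
    connectivityMatrix(ts, roiLabels(seedTab), roiLabels(atlasTab),
                       scale = scale)
  })
}

#' Run the full atypical-connectivity pipeline
#'
#' Orchestrates every stage: obtain per-subject connectivity (synthetic
#' generator, ROI time-series files, or 4D images plus an atlas), test each
#' patient edge-wise against the control cohort, aggregate recurrence
#' across patients, build the region-group hub graph, run the clinical
#' screens, and write all result tables plus a JSON run manifest recording
#' the parameters and random seed to `out_dir`. With a fixed `seed` the
#' run is bit-reproducible (the manifest carries no timestamp).
#'
#' @param config named list (or path to a YAML file, see
#'   [readPipelineConfig()]). Common keys: `mode`
#'   (`"synthetic"`/`"timeseries"`/`"images"`), `out_dir`, `seed`,
#'   `n_perm`, `alpha`, `method`, `null_model`, `scale`, recurrence
#'   thresholds (`node_min_patients`, `edge_min_count`,
#'   `group_min_count`), and per-mode inputs: synthetic generator
#'   parameters (`n_controls`, `n_patients`, `delta`, `n_injected`,
#'   `focus_group`, `vas_slope`, `vas_intercept`, `vas_noise_sd`) or file
#'   lists (`control_timeseries`, `patient_timeseries`, `seed_table`,
#'   `atlas_table`, `clinical_table`; in images mode `control_images`,
#'   `patient_images`, `atlas_image`).
#' @return invisibly, a list with all in-memory stage outputs (`stack`,
#'   `patients`, `results`, `summary`, `graph`, `hubs`, `clinical`, ...).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- utils::modifyList(pipelineDefaults(), config)
  outDir <- cfgGet(config, "out_dir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  mode <- cfgGet(config, "mode")

  if (mode == "synthetic") {
    seedTab <- defaultSeedTable(); atlasTab <- defaultAtlasTable()
    focusIdx <- NULL
    if (!is.null(config$focus_group)) {
      focusIdx <- which(seedTab@locationGroup == config$focus_group) - 1L
      if (!length(focusIdx))
        stop("configuration error: no seeds in focus_group '",
             config$focus_group, "'", call. = FALSE)
    }
    spec <- simulationSpec(
      nControls = config$n_controls, nPatients = config$n_patients,
      mu = config$mu, muSd = config$mu_sd,
      sigmaBetween = config$sigma_between, delta = config$delta,
      nInjectedPerPatient = config$n_injected,
      focusSeedIndices = focusIdx, rngSeed = config$seed)
    # couple VAS to the first injected edge of patient 1 so the clinical
    # screen has a known planted signal
    if (config$n_patients > 0L && nrow(spec@injectedEdges[[1L]])) {
      spec@clinicalCoupling <- data.frame(
        outcome = "vas_pct",
        seed_index = spec@injectedEdges[[1L]][1L, 1L],
        atlas_index = spec@injectedEdges[[1L]][1L, 2L],
        slope = config$vas_slope, intercept = config$vas_intercept,
        noise_sd = config$vas_noise_sd, stringsAsFactors = FALSE)
    }
    sim <- simulateEdgeLevel(spec)
    stack <- sim$stack; patients <- sim$patients
    clinical <- simulateClinical(sim$groundTruth, patients, spec)
    gt <- sim$groundTruth
    gtOut <- list(delta = gt$delta, sigmaBetween = gt$sigmaBetween,
                  injectedEdges = lapply(gt$injectedEdges, function(m)
                    as.data.frame(m)),
                  clinicalCoupling = gt$clinicalCoupling)
    jsonlite::write_json(gtOut, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (mode %in% c("timeseries", "images")) {
    seedTab <- readRoiTable(cfgGet(config, "seed_table"), "seed",
                            strict = config$strict_roi)
    atlasTab <- readRoiTable(cfgGet(config, "atlas_table"), "atlas",
                             strict = config$strict_roi)
    if (mode == "timeseries") {
      ctrlPaths <- cfgGet(config, "control_timeseries")
      patPaths <- cfgGet(config, "patient_timeseries")
      ctrlMats <- loadSubjectMatrices(ctrlPaths, seedTab, atlasTab,
                                      config$scale,
                                      config$drop_initial_volumes)
      patients <- loadSubjectMatrices(patPaths, seedTab, atlasTab,
                                      config$scale,
                                      config$drop_initial_volumes)
    } else {
      atlasImg <- cfgGet(config, "atlas_image")
      mk <- function(p) {
        ts <- extractRoiTimeSeries(p, atlasImg, seedTab, atlasTab,
                                   sphereRadiusMm = config$sphere_radius_mm,
                                   subjectId = sub("\\.nii(\\.gz)?$", "",
                                                   basename(p)))
        connectivityMatrix(ts, roiLabels(seedTab), roiLabels(atlasTab),
                           scale = config$scale)
      }
      ctrlMats <- lapply(cfgGet(config, "control_images"), mk)
      patients <- lapply(cfgGet(config, "patient_images"), mk)
    }
    stack <- cohortStack(ctrlMats)
    clinical <- if (!is.null(config$clinical_table))
      validateClinicalTable(readTsv(config$clinical_table)) else NULL
  } else {
    stop("configuration error: unknown mode '", mode, "'", call. = FALSE)
  }

  pcfg <- permutationConfig(nPerm = config$n_perm, alpha = config$alpha,
                            method = config$method, rngSeed = config$seed,
                            pRule = config$p_rule,
                            nullModel = config$null_model)
  results <- lapply(patients, function(p) testPatient(stack, p, pcfg))

  if (isTRUE(config$write_patient_tables)) {
    resDir <- file.path(outDir, "patient_results")
    dir.create(resDir, showWarnings = FALSE)
    for (r in results) {
      df <- data.frame(
        seed_label = rep(rownames(r@pRaw), ncol(r@pRaw)),
        atlas_label = rep(colnames(r@pRaw), each = nrow(r@pRaw)),
        observed_diff = as.vector(r@observedDiff),
        p_raw = as.vector(r@pRaw), p_adj = as.vector(r@pAdj),
        significant = as.vector(r@significant), stringsAsFactors = FALSE)
      writeTsv(df, file.path(resDir, paste0(r@patientId, "_edges.tsv")))
    }
  }

  summary <- aggregateResults(results)
  dist <- perPatientDistribution(summary)
  writeTsv(summary@edgeCounts, file.path(outDir, "edge_counts.tsv"))
  nodeDf <- rbind(
    data.frame(kind = rep("seed", length(summary@seedNodeCounts)),
               label = names(summary@seedNodeCounts),
               n_patients = as.integer(summary@seedNodeCounts),
               stringsAsFactors = FALSE),
    data.frame(kind = rep("atlas", length(summary@atlasNodeCounts)),
               label = names(summary@atlasNodeCounts),
               n_patients = as.integer(summary@atlasNodeCounts),
               stringsAsFactors = FALSE))
  writeTsv(nodeDf, file.path(outDir, "node_counts.tsv"))
  writeTsv(dist$histogram, file.path(outDir, "histogram.tsv"))
  recN <- recurrentNodes(summary, config$node_min_patients)
  tagKind <- function(df, kind)
    data.frame(kind = rep(kind, nrow(df)), df, stringsAsFactors = FALSE)
  writeTsv(rbind(tagKind(recN$seed, "seed"), tagKind(recN$atlas, "atlas")),
           file.path(outDir, "recurrent_nodes.tsv"))
  writeTsv(recurrentEdges(summary, config$edge_min_count),
           file.path(outDir, "recurrent_edges.tsv"))

  pairs <- mapEdgesToGroups(summary@edgeCounts, seedTab, atlasTab)
  graph <- buildGroupGraph(pairs, config$group_min_count)
  hubs <- if (nrow(graph@edges)) hubScores(graph) else
    data.frame(group = character(), degree = numeric(),
               hub_score = numeric(), stringsAsFactors = FALSE)
  writeTsv(edgePrevalencePct(pairs, summary@nPatients),
           file.path(outDir, "group_pairs.tsv"))
  writeTsv(graph@edges, file.path(outDir, "group_graph.tsv"))
  writeTsv(hubs, file.path(outDir, "hub_scores.tsv"))

  fits <- NULL; confounders <- NULL; ageCor <- NULL
  if (!is.null(clinical)) {
    writeTsv(clinical, file.path(outDir, "clinical.tsv"))
    confounders <- confounderCheck(clinical)
    writeTsv(confounders, file.path(outDir, "confounders.tsv"))
    if (nrow(summary@edgeCounts)) {
      fits <- correlateEdgesWithOutcome(patients, summary@edgeCounts,
                                        clinical, "vas_pct",
                                        config$r2_threshold)
      writeTsv(fits, file.path(outDir, "clinical_fits.tsv"))
    }
    ageCor <- suppressWarnings(ageOutcomeBySex(clinical, "vas_pct"))
    writeTsv(ageCor, file.path(outDir, "age_outcome_by_sex.tsv"))
  }

  manifest <- list(
    package = "painConn",
    version = as.character(utils::packageVersion("painConn")),
    mode = mode, seed = config$seed, n_perm = config$n_perm,
    alpha = config$alpha, method = config$method,
    p_rule = pcfg@pRule, null_model = config$null_model,
    scale = config$scale, n_controls = dim(stack@values)[1L],
    n_patients = length(patients),
    thresholds = list(node_min_patients = config$node_min_patients,
                      edge_min_count = config$edge_min_count,
                      seed_edge_min_count = config$seed_edge_min_count,
                      group_min_count = config$group_min_count,
                      r2_threshold = config$r2_threshold),
    pct_patients_with_atypical_edge = dist$pctWithEdge,
    n_unique_atypical_edges = nrow(summary@edgeCounts))
  if (mode == "synthetic")
    manifest$simulation <- list(delta = config$delta,
                                n_injected = config$n_injected,
                                mu = config$mu, mu_sd = config$mu_sd,
                                sigma_between = config$sigma_between)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(stack = stack, patients = patients, results = results,
                 summary = summary, distribution = dist, pairs = pairs,
                 graph = graph, hubs = hubs, clinical = clinical,
                 clinicalFits = fits, confounders = confounders,
                 ageOutcome = ageCor, seedTable = seedTab,
                 atlasTable = atlasTab, manifest = manifest))
}
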