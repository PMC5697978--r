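## End-to-end orchestration: simulate -> preprocess -> extract -> connect ->
## normative -> morphometry -> FA, with a machine-readable report bundle.

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Generates the configured cohort, preprocesses every BOLD run
#' (physiological regression then zero-phase low-pass), extracts network
#' signals and correlation matrices, fits the control normative band, flags
#' each patient's abnormal links, aggregates frequency-of-occurrence maps,
#' runs the per-network deficit t-tests and inter-network correlations,
#' computes volumetry with group comparisons (GM, WM, thalamus asymmetry
#' index), and runs the voxelwise single-case FA comparison per patient.
#' Writes a report bundle to \code{outDir}:
#' \itemize{
#'   \item \code{summary.json} — machine-readable study summary: per-network
#'     deficit mean (sd), t and p; the network-by-network correlation
#'     matrix; volumetry comparisons; per-patient FA summaries; seed.
#'   \item \code{normative_links.tsv}, \code{patient_links.tsv},
#'     \code{frequency_maps.tsv}, \code{morphometry.tsv} — long-format
#'     tables.
#'   \item \code{config.json} — the scalar configuration and seed.
#'   \item with \code{writeImages = TRUE}, per-subject NIfTI/TSV inputs and
#'     per-patient FA statistic overlays under \code{images/}.
#' }
#' Identical config and seed reproduce every output byte for byte.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param outDir output directory (created if needed).
#' @param stratifyBySex fit sex-stratified normative bands when both sexes
#'   have at least two controls (default TRUE).
#' @param reducedOnly aggregate frequency maps over reduced links only
#'   (default TRUE; FALSE counts any abnormal link).
#' @param null,nullMean null specification for \code{\link{deficitTTest}}.
#' @param fisherZ analyse Fisher-transformed correlations (default FALSE).
#' @param signedAI report the signed thalamus asymmetry index instead of its
#'   magnitude in \code{morphometry.tsv} (group comparison always uses the
#'   magnitude).
#' @param faMethod \code{"single_case"} or \code{"naive"}, see
#'   \code{\link{singleCaseMap}}.
#' @param cutoffHz low-pass cutoff (default 0.08 Hz).
#' @param pThreshold FA overlay/report threshold on p (default 0.01).
#' @param writeImages also write NIfTI/TSV inputs and FA overlays.
#' @param verbose log stage progress to stderr.
#' @return invisibly, the in-memory bundle: connectivity matrices, normative
#'   models, patient reports, frequency maps, group statistics, morphometry
#'   records and FA maps.
#' @export
runPipeline <- function(config = simulationConfig(), outDir,
                        stratifyBySex = TRUE, reducedOnly = TRUE,
                        null = "value", nullMean = 0, fisherZ = FALSE,
                        signedAI = FALSE,
                        faMethod = c("single_case", "naive"),
                        cutoffHz = 0.08, pThreshold = 0.01,
                        writeImages = FALSE, verbose = TRUE) {
  faMethod <- match.arg(faMethod)
  stopifnot(is(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (writeImages)
    dir.create(file.path(outDir, "images"), showWarnings = FALSE)
  log <- function(...) if (verbose) message("[cognet] ", sprintf(...))

  subjects <- config@subjects
  networks <- config@networks
  netNames <- names(networks)
  isPatient <- subjects$kind == "patient"

  log("simulate + preprocess + connect: %d subjects, %d networks",
      nrow(subjects), length(networks))
  cms <- stats::setNames(
    lapply(netNames, function(nn) vector("list", nrow(subjects))), netNames)
  morphs <- vector("list", nrow(subjects))
  for (k in seq_len(nrow(subjects))) {
    id <- subjects$id[k]
    stageTry("simulate", {
      labels <- generateLabelMap(config, k)
      gen <- generateBold(config, labels, k)
    })
    clean <- stageTry("preprocess",
                      lowpass(regressPhysio(gen$bold, gen$physio),
                              cutoffHz = cutoffHz))
    stageTry("connect", for (nn in netNames) {
      ts <- extractRoiSignals(clean, labels, networks[[nn]],
                              subjectId = id)
      cms[[nn]][[k]] <- correlationMatrix(ts, networkName = nn,
                                          fisherZ = fisherZ)
    })
    morphs[[k]] <- stageTry("volumes",
                            computeVolumes(labels, subjectId = id))
    if (writeImages) {
      writeBold(gen$bold, file.path(outDir, "images",
                                    paste0(id, "_bold.nii.gz")))
      writePhysio(gen$physio, file.path(outDir, "images",
                                        paste0(id, "_physio.tsv")))
      writeLabelMap(labels, file.path(outDir, "images",
                                      paste0(id, "_labels.nii.gz")))
    }
  }

  log("normative band + abnormal-link flagging")
  ctrlSex <- subjects$sex[!isPatient]
  strat <- stratifyBySex && length(unique(ctrlSex)) > 1L &&
    min(table(ctrlSex)) >= 2L
  if (stratifyBySex && !strat)
    log("sex stratification requested but not usable; pooling controls")
  models <- stats::setNames(lapply(netNames, function(nn) stageTry(
    "normative",
    fitNormative(cms[[nn]][!isPatient],
                 sex = if (strat) ctrlSex else NULL,
                 stratifyBySex = strat))), netNames)

  patIdx <- which(isPatient)
  reports <- freq <- deficits <- NULL
  netCor <- NULL
  if (length(patIdx)) {
    reports <- stats::setNames(lapply(netNames, function(nn) stageTry(
      "normative",
      lapply(patIdx, function(k)
        flagAbnormal(cms[[nn]][[k]], models[[nn]],
                     sex = if (strat) subjects$sex[k] else NULL)))),
      netNames)
    freq <- lapply(reports, frequencyMap, reducedOnly = reducedOnly)
    if (length(patIdx) >= 2L)
      deficits <- lapply(reports, deficitTTest, nullMean = nullMean,
                         null = null)
    if (length(patIdx) >= 3L && length(netNames) >= 2L)
      netCor <- networkCorrelations(reports)
  } else {
    warning("no patients configured: normative model built, ",
            "patient analyses skipped")
  }

  log("volumetry group comparison")
  volStats <- NULL
  if (sum(isPatient) >= 2L && sum(!isPatient) >= 2L) {
    measures <- c("GM", "WM")
    if ("thalamus" %in% morphs[[1]]@asymmetry$structure)
      measures <- c(measures, "thalamus_AI")
    volStats <- lapply(measures, function(m)
      stageTry("volumes", groupCompare(morphs[isPatient], morphs[!isPatient],
                                       measure = m)))
    names(volStats) <- measures
  }

  log("FA single-case comparison")
  faMaps <- stageTry("fa", lapply(seq_len(nrow(subjects)), function(k)
    generateFaSkeleton(config, k)))
  faStats <- NULL
  if (length(patIdx) && sum(!isPatient) >= 3L) {
    faStats <- lapply(patIdx, function(k) {
      sm <- stageTry("fa", singleCaseMap(faMaps[[k]], faMaps[!isPatient],
                                         method = faMethod))
      nSig <- sum(sm@p < pThreshold, na.rm = TRUE)
      if (writeImages)
        overlayReport(sm, faMaps[[k]], pThreshold = pThreshold,
                      outNifti = file.path(outDir, "images",
                        paste0(subjects$id[k], "_fa_tmap.nii.gz")),
                      outPng = file.path(outDir, "images",
                        paste0(subjects$id[k], "_fa_tmap.png")))
      list(subject = subjects$id[k], analysedVoxels = sum(sm@mask),
           significantVoxels = nSig,
           significantFraction = nSig / max(1L, sum(sm@mask)))
    })
  }

  log("write report bundle")
  writeBundle(outDir, config, subjects, models, reports, freq, deficits,
              netCor, morphs, volStats, faStats, signedAI, reducedOnly)
  invisible(list(connectivity = cms, models = models, reports = reports,
                 frequency = freq, deficits = deficits,
                 networkCorrelations = netCor, morphometry = morphs,
                 volumeStats = volStats, faStats = faStats,
                 faMaps = faMaps, outDir = outDir))
}

writeBundle <- function(outDir, config, subjects, models, reports, freq,
                        deficits, netCor, morphs, volStats, faStats,
                        signedAI, reducedOnly) {
  # normative bands, long format
  normTab <- do.call(rbind, unlist(lapply(names(models), function(nn) {
    ms <- models[[nn]]
    if (!is.list(ms)) ms <- list(ms)
    lapply(ms, function(m) {
      df <- m@links
      df <- data.frame(network = nn, stratum = m@stratum, df)
      df
    })
  }), recursive = FALSE))
  writeTsv(normTab, file.path(outDir, "normative_links.tsv"))

  if (!is.null(reports)) {
    patTab <- do.call(rbind, unlist(lapply(names(reports), function(nn)
      lapply(reports[[nn]], function(rep)
        data.frame(subject = rep@subjectId, network = nn,
                   rep@links[, c("node_i", "node_j", "r", "status")]))),
      recursive = FALSE))
    writeTsv(patTab, file.path(outDir, "patient_links.tsv"))

    freqTab <- do.call(rbind, lapply(names(freq), function(nn)
      data.frame(network = nn, measure = if (reducedOnly) "reduced"
                 else "abnormal",
                 freq[[nn]][, c("node_i", "node_j", "count")])))
    writeTsv(freqTab, file.path(outDir, "frequency_maps.tsv"))
  }

  morphTab <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(k) {
    m <- morphs[[k]]
    thal <- match("thalamus", m@asymmetry$structure)
    data.frame(subject = subjects$id[k], kind = subjects$kind[k],
               sex = subjects$sex[k],
               GM = m@tissueFractions[["GM"]],
               WM = m@tissueFractions[["WM"]],
               CSF = m@tissueFractions[["CSF"]],
               thalamus_AI = if (is.na(thal)) NA
                 else if (signedAI) m@asymmetry$aiSigned[thal]
                 else m@asymmetry$ai[thal])
  }))
  writeTsv(morphTab, file.path(outDir, "morphometry.tsv"))

  summary <- list(
    seed = config@seed,
    nControls = config@nControls, nPatients = config@nPatients,
    nTimepoints = config@nTimepoints, trSeconds = config@trSeconds,
    deficits = if (!is.null(deficits)) lapply(deficits, function(d)
      list(mean = d$mean, sd = d$sd, t = d$t, df = d$df, p = d$p,
           nullMean = d$nullMean, counts = d$counts)),
    networkCorrelations = if (!is.null(netCor)) list(
      networks = colnames(netCor$r),
      r = apply(netCor$r, 1L, as.numeric, simplify = FALSE),
      p = apply(netCor$p, 1L, as.numeric, simplify = FALSE)),
    volumetry = volStats,
    fa = faStats)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  cfg <- list(seed = config@seed, nControls = config@nControls,
              nPatients = config@nPatients,
              nTimepoints = config@nTimepoints,
              trSeconds = config@trSeconds,
              gridShape = config@gridShape, voxelDims = config@voxelDims,
              cardiacHz = config@cardiacHz,
              respiratoryHz = config@respiratoryHz,
              confoundAmplitude = config@confoundAmplitude,
              noiseSd = config@noiseSd,
              networks = names(config@networks))
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
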