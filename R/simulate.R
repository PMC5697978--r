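## Synthetic study generator: label maps, 4D BOLD with planted covariance and
## physiological confounds, and FA skeletons with planted lesions. All
## randomness flows from one master seed; each subject owns derived streams so
## cohorts are extensible without perturbing earlier subjects.

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stream seed for subject k (1-based global index); `sub` separates the
# attribute / BOLD / FA draws within a subject. Kept below 2^31.
subjectSeed <- function(masterSeed, k, sub = 0L) {
  (((masterSeed %% 2147483647) * 48271 + k * 1299721 + sub * 7919) %%
     2147483629) + 1
}

#' Split a paired structure's voxel budget to realize an asymmetry index
#'
#' Solves AI = (V_L - V_R) / ((V_L + V_R) / 2) for integer left/right voxel
#' counts given their total, so the generated label map realizes a planted
#' (signed) asymmetry index up to one-voxel rounding.
#'
#' @param total combined voxel count of the left and right structure.
#' @param ai signed asymmetry index in (-2, 2); positive means left larger.
#' @return integer vector \code{c(left, right)}.
#' @examples
#' splitPairedVoxels(250, 0.4)   # 150, 100
#' @export
splitPairedVoxels <- function(total, ai) {
  stopifnot(total >= 2, abs(ai) < 2)
  left <- as.integer(round(total * (2 + ai) / 4))
  left <- max(1L, min(as.integer(total) - 1L, left))
  c(left = left, right = as.integer(total) - left)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Planted link targets specified pairwise need not form a valid joint
#' correlation matrix. Negative eigenvalues are clipped at zero and the
#' result is renormalized to unit diagonal. The largest entrywise adjustment
#' is recorded in attribute \code{"maxAdjust"}; an adjustment beyond
#' \code{tol} aborts, flagging an unusable link configuration.
#'
#' @param C square symmetric matrix of correlation targets.
#' @param tol maximum admissible entrywise change (default 0.2).
#' @return the repaired correlation matrix with attribute \code{maxAdjust}.
#' @export
psdRepair <- function(C, tol = 0.2) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -1e-10) {
    attr(C, "maxAdjust") <- 0
    return(C)
  }
  lam <- pmax(e$values, 0)
  S <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(S), .Machine$double.eps))
  R <- S / outer(d, d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  adj <- max(abs(R - C))
  if (adj > tol)
    stop(sprintf(paste0("planted correlation targets are not realizable: ",
                        "PSD repair moved an entry by %.3f (> tolerance %.3f)"),
                 adj, tol))
  attr(R, "maxAdjust") <- adj
  R
}

# Largest-remainder apportionment of `total` items by positive weights.
apportion <- function(total, weights) {
  stopifnot(all(weights > 0))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# The default region table: every node of the five packaged networks plus
# deep white matter, ventricles and subarachnoid CSF so that GM/WM/CSF
# volumetry is meaningful. Weights set relative anatomical size.
defaultRegionTable <- function() {
  doc <- jsonlite::read_json(system.file("extdata", "networks.json",
                                         package = "cognet"),
                             simplifyVector = TRUE)
  parc <- unlist(doc$parcellation)
  name <- names(parc)
  region <- sub("_[LR]$", "", name)
  hemisphere <- sub("^.*_([LR])$", "\\1", name)
  tissue <- ifelse(region %in% c("fornix", "deep_white_matter"), "WM",
                   ifelse(region %in% c("lateral_ventricles",
                                        "subarachnoid_csf"), "CSF", "GM"))
  weight <- rep(1, length(name))
  weight[region == "thalamus"] <- 4
  weight[region == "deep_white_matter"] <- 12
  weight[region == "fornix"] <- 0.5
  weight[region == "subarachnoid_csf"] <- 2
  data.frame(name = name, label = as.integer(parc), tissue = tissue,
             hemisphere = hemisphere, weight = weight,
             stringsAsFactors = FALSE)
}

#' Specify a synthetic resting-state study
#'
#' Builds a \code{\linkS4class{SimulationConfig}} describing a full synthetic
#' study: cohort sizes and sex layout, acquisition parameters, the planted
#' inter-node correlation structure (with per-patient weakened links), the
#' planted per-subject tissue composition and thalamus asymmetry, the
#' physiological confound model, and the FA lesion model. All per-subject
#' quantities are drawn at construction time from per-subject random streams
#' derived from the master seed, so the same seed and arguments always yield
#' the same study and appending subjects never changes earlier ones.
#'
#' Defaults emulate the emulated study's conditions: 20 controls (10 male,
#' 10 female) and 10 patients (9 female, 1 male); 150 volumes at TR = 2 s;
#' group-specific normal distributions for GM/WM fractions (controls
#' 0.453/0.281, patients 0.435/0.297) and thalamus asymmetry magnitude
#' (controls 0.089 +/- 0.057, patients 0.188 +/- 0.172); within-network link
#' correlations of 0.35 with 3 links per network weakened to 0 in each
#' patient. The default within-network level is the largest round value at
#' which the union of the five overlapping networks stays close to a jointly
#' realizable correlation matrix (PSD repair then moves entries by < 0.11);
#' higher levels are accepted but are increasingly reshaped by the repair.
#'
#' @param nControls,nPatients cohort sizes.
#' @param nTimepoints number of BOLD volumes (default 150).
#' @param trSeconds repetition time in seconds (default 2).
#' @param gridShape integer 3-vector of voxel counts.
#' @param voxelDims voxel size in mm (used for the affine).
#' @param regions region table (columns name, label, tissue, hemisphere,
#'   weight); defaults to the packaged parcellation.
#' @param networks list of \code{\linkS4class{NetworkDefinition}} used to
#'   derive the default connectivity structure; default the packaged five.
#' @param withinNetworkR baseline correlation target for every within-network
#'   link (ignored when \code{baseConnectivity} is given).
#' @param baseConnectivity data.frame (node_a, node_b, r) of explicit planted
#'   targets; overrides \code{withinNetworkR}.
#' @param weakenedPerNetwork number of links per network weakened in each
#'   patient (ignored when \code{weakenedLinks} is given).
#' @param weakenedR correlation target weakened links are set to.
#' @param weakenedLinks explicit list (one data.frame per patient, columns
#'   node_a, node_b, r) of per-patient overrides.
#' @param cardiacHz,respiratoryHz confound fundamentals in Hz.
#' @param physioHz physiological recording sample rate in Hz.
#' @param confoundAmplitude amplitude of each sinusoidal confound in signal
#'   units (latent regional signals have unit SD).
#' @param noiseSd independent voxel noise SD in signal units.
#' @param brainFraction fraction of grid voxels occupied by brain labels.
#' @param gmFractionMean,gmFractionSd,wmFractionMean,wmFractionSd named
#'   vectors (\code{control}, \code{patient}): group distributions of the
#'   normalized GM/WM volume fractions.
#' @param aiMean,aiSd group distributions of the thalamus asymmetry-index
#'   magnitude; the affected side is random per subject.
#' @param thalamusAsymmetry optional numeric vector (length
#'   \code{nControls + nPatients}) of signed per-subject asymmetry indices,
#'   overriding the draws.
#' @param sex optional character vector ("M"/"F") per subject; default 10/10
#'   split in controls, 9 female / 1 male in patients (recycled
#'   proportionally for other cohort sizes).
#' @param faMean,faSd control FA skeleton value distribution.
#' @param lesionDepth FA reduction inside a patient's lesional patch.
#' @param lesionRadius Chebyshev radius (voxels) of the lesional patch.
#' @param psdTolerance see \code{\link{psdRepair}}.
#' @param seed master integer seed.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(nControls = 20L, nPatients = 10L,
    nTimepoints = 150L, trSeconds = 2, gridShape = c(20L, 20L, 10L),
    voxelDims = c(3.4375, 3.4375, 3.5),
    regions = defaultRegionTable(), networks = defaultNetworks(),
    withinNetworkR = 0.35, baseConnectivity = NULL,
    weakenedPerNetwork = 3L, weakenedR = 0, weakenedLinks = NULL,
    cardiacHz = 1.1, respiratoryHz = 0.3, physioHz = 25,
    confoundAmplitude = 1, noiseSd = 1, brainFraction = 0.65,
    gmFractionMean = c(control = 0.453, patient = 0.435),
    gmFractionSd = c(control = 0.011, patient = 0.021),
    wmFractionMean = c(control = 0.281, patient = 0.297),
    wmFractionSd = c(control = 0.0168, patient = 0.048),
    aiMean = c(control = 0.089, patient = 0.188),
    aiSd = c(control = 0.057, patient = 0.172),
    thalamusAsymmetry = NULL, sex = NULL,
    faMean = 0.5, faSd = 0.03, lesionDepth = 0.15, lesionRadius = 2L,
    psdTolerance = 0.5, seed = 1L) {

  nControls <- as.integer(nControls); nPatients <- as.integer(nPatients)
  nTotal <- nControls + nPatients
  seed <- as.integer(seed)

  if (is.null(sex)) {
    sexC <- rep(c("M", "F"), length.out = nControls)
    sexP <- rep(c(rep("F", 9), "M"), length.out = max(nPatients, 0L))[
      seq_len(nPatients)]
    sex <- c(sexC, sexP)
  }
  stopifnot(length(sex) == nTotal)

  kind <- c(rep("control", nControls), rep("patient", nPatients))
  id <- c(sprintf("control_%02d", seq_len(nControls)),
          sprintf("patient_%02d", seq_len(nPatients)))

  # Per-subject planted attributes, each from the subject's own stream.
  grp <- ifelse(kind == "patient", "patient", "control")
  draw <- function(k) {
    withSeed(subjectSeed(seed, k, 1L), {
      g <- grp[k]
      gm <- min(max(rnorm(1, gmFractionMean[[g]], gmFractionSd[[g]]), 0.05),
                0.9)
      wm <- min(max(rnorm(1, wmFractionMean[[g]], wmFractionSd[[g]]), 0.05),
                0.9 - gm + 0.05)
      if (gm + wm > 0.95) wm <- 0.95 - gm
      aiMag <- abs(rnorm(1, aiMean[[g]], aiSd[[g]]))
      aiMag <- min(aiMag, 1.5)
      side <- sample(c(-1, 1), 1)
      c(gm = gm, wm = wm, ai = side * aiMag)
    })
  }
  att <- t(vapply(seq_len(nTotal), draw, numeric(3)))
  subjects <- data.frame(id = id, kind = kind, index = seq_len(nTotal),
                         sex = sex, gmFraction = att[, "gm"],
                         wmFraction = att[, "wm"],
                         thalamusAsymmetry = att[, "ai"],
                         streamSeed = vapply(seq_len(nTotal), function(k)
                           subjectSeed(seed, k), numeric(1)),
                         stringsAsFactors = FALSE)
  if (!is.null(thalamusAsymmetry)) {
    stopifnot(length(thalamusAsymmetry) %in% c(1L, nTotal))
    subjects$thalamusAsymmetry <- rep(thalamusAsymmetry,
                                      length.out = nTotal)
  }

  if (is.null(baseConnectivity)) {
    baseConnectivity <- if (length(networks) && withinNetworkR != 0) {
      pairs <- do.call(rbind, lapply(networks, function(net) {
        lt <- linkTable(enumerateLinks(net))
        data.frame(node_a = lt$node_i, node_b = lt$node_j,
                   stringsAsFactors = FALSE)
      }))
      pairs <- pairs[!duplicated(linkKey(pairs$node_a, pairs$node_b)), ,
                     drop = FALSE]
      rownames(pairs) <- NULL
      pairs$r <- withinNetworkR
      pairs
    } else data.frame(node_a = character(), node_b = character(),
                      r = numeric())
  }

  if (is.null(weakenedLinks)) {
    weakenedLinks <- lapply(seq_len(nPatients), function(p) {
      k <- nControls + p
      withSeed(subjectSeed(seed, k, 4L), {
        picks <- do.call(rbind, lapply(networks, function(net) {
          lt <- linkTable(enumerateLinks(net))
          take <- sample(nrow(lt), min(weakenedPerNetwork, nrow(lt)))
          data.frame(node_a = lt$node_i[take], node_b = lt$node_j[take],
                     stringsAsFactors = FALSE)
        }))
        if (is.null(picks))
          picks <- data.frame(node_a = character(), node_b = character())
        picks <- picks[!duplicated(linkKey(picks$node_a, picks$node_b)), ,
                       drop = FALSE]
        rownames(picks) <- NULL
        picks$r <- weakenedR
        picks
      })
    })
  }

  new("SimulationConfig", nControls = nControls, nPatients = nPatients,
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      gridShape = as.integer(gridShape), voxelDims = as.numeric(voxelDims),
      regions = regions, networks = networks,
      baseConnectivity = baseConnectivity, weakenedLinks = weakenedLinks,
      subjects = subjects, cardiacHz = cardiacHz,
      respiratoryHz = respiratoryHz, physioHz = physioHz,
      confoundAmplitude = confoundAmplitude, noiseSd = noiseSd,
      brainFraction = brainFraction, faMean = faMean, faSd = faSd,
      lesionDepth = lesionDepth, lesionRadius = as.integer(lesionRadius),
      psdTolerance = psdTolerance, seed = seed)
}

# Resolve a subject argument (index or id) to its row in the subjects table.
resolveSubject <- function(config, subject) {
  s <- config@subjects
  if (is.character(subject)) {
    row <- match(subject, s$id)
    if (is.na(row)) stop("unknown subject id: ", subject)
  } else {
    row <- as.integer(subject)
    if (row < 1L || row > nrow(s)) stop("subject index out of range")
  }
  s[row, , drop = FALSE]
}

#' Generate a subject's parcellation label map
#'
#' Lays the configured regions out as contiguous voxel blocks inside the
#' grid (label 0 is background), apportioning the brain voxel budget to the
#' subject's planted GM/WM/CSF fractions and splitting the thalamus pair so
#' its voxel counts realize the subject's planted asymmetry index
#' (\code{\link{splitPairedVoxels}}).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param subject subject index (1-based, controls first) or subject id.
#' @return a \code{\linkS4class{LabelVolume}}.
#' @export
generateLabelMap <- function(config, subject = 1L) {
  sub <- resolveSubject(config, subject)
  reg <- config@regions
  nTotalVox <- prod(config@gridShape)
  brainVox <- as.integer(round(config@brainFraction * nTotalVox))
  if (brainVox < nrow(reg))
    stop(sprintf("grid too small: %d brain voxels cannot host %d regions",
                 brainVox, nrow(reg)))

  g <- sub$gmFraction; w <- sub$wmFraction
  tissueCounts <- c(GM = round(g * brainVox), WM = round(w * brainVox))
  tissueCounts <- c(tissueCounts,
                    CSF = brainVox - sum(tissueCounts))
  if (any(tissueCounts < 1))
    stop("grid too small for the requested tissue composition")

  counts <- integer(nrow(reg))
  for (tis in c("GM", "WM", "CSF")) {
    rows <- which(reg$tissue == tis)
    if (!length(rows)) next
    counts[rows] <- apportion(tissueCounts[[tis]], reg$weight[rows])
  }

  thal <- which(reg$name %in% c("thalamus_L", "thalamus_R"))
  if (length(thal) == 2L) {
    pairTotal <- sum(counts[thal])
    lr <- splitPairedVoxels(pairTotal, sub$thalamusAsymmetry)
    counts[thal[reg$hemisphere[thal] == "L"]] <- lr[["left"]]
    counts[thal[reg$hemisphere[thal] == "R"]] <- lr[["right"]]
  }
  if (any(counts < 1))
    stop("grid too small: a region received no voxels")

  lab <- integer(nTotalVox)
  start <- (nTotalVox - brainVox) %/% 2L
  pos <- start
  for (r in seq_len(nrow(reg))) {
    lab[(pos + 1L):(pos + counts[r])] <- reg$label[r]
    pos <- pos + counts[r]
  }
  regOut <- reg[, c("name", "label", "tissue", "hemisphere")]
  regOut$voxels <- counts
  new("LabelVolume", data = array(lab, dim = config@gridShape),
      affine = diag(c(config@voxelDims, 1)), regions = regOut)
}

# Target correlation matrix over the label map's regions for one subject:
# identity plus planted base links, with the patient's weakened-link
# overrides applied, PSD-repaired.
targetCorrelation <- function(config, regionNames, sub) {
  R <- length(regionNames)
  C <- diag(R)
  setLinks <- function(C, df) {
    for (r in seq_len(nrow(df))) {
      ia <- match(df$node_a[r], regionNames)
      ib <- match(df$node_b[r], regionNames)
      if (is.na(ia) || is.na(ib)) next
      C[ia, ib] <- C[ib, ia] <- df$r[r]
    }
    C
  }
  C <- setLinks(C, config@baseConnectivity)
  if (sub$kind == "patient") {
    p <- sub$index - config@nControls
    C <- setLinks(C, config@weakenedLinks[[p]])
  }
  psdRepair(C, config@psdTolerance)
}

# Symmetric PSD square root used to draw latents (tolerates singular targets
# such as a planted r of exactly 1).
corrSqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a subject's 4D BOLD run and physiological recording
#'
#' Every voxel of a region carries that region's latent signal — the regions'
#' latents are drawn i.i.d. over time from a multivariate Gaussian with the
#' planted correlation structure (the subject's weakened links applied for
#' patients) — plus independent Gaussian voxel noise and sinusoidal cardiac
#' and respiratory confounds with subject-specific random phases. The
#' returned \code{\linkS4class{PhysioTrace}} holds the exact confound time
#' courses sampled at \code{physioHz}. Background voxels are zero.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param labels the subject's \code{\linkS4class{LabelVolume}}.
#' @param subject subject index or id.
#' @return list with elements \code{bold} (\code{\linkS4class{Bold4D}}) and
#'   \code{physio} (\code{\linkS4class{PhysioTrace}}).
#' @export
generateBold <- function(config, labels, subject = 1L) {
  sub <- resolveSubject(config, subject)
  if (!identical(dim(labels@data), as.integer(config@gridShape)))
    stop("label map grid does not match config gridShape")
  reg <- labels@regions
  nT <- config@nTimepoints
  tr <- config@trSeconds
  C <- targetCorrelation(config, reg$name, sub)

  frameTimes <- (seq_len(nT) - 1) * tr
  physioTimes <- seq(0, by = 1 / config@physioHz,
                     length.out = ceiling(frameTimes[nT] * config@physioHz) +
                       1L)

  labFlat <- as.integer(labels@data)
  brain <- which(labFlat > 0L)
  regIdx <- match(labFlat[brain], reg$label)

  out <- withSeed(subjectSeed(config@seed, sub$index, 2L), {
    phases <- stats::runif(2, 0, 2 * pi)
    latent <- matrix(stats::rnorm(nT * nrow(reg)), nT) %*% corrSqrt(C)
    confound <- config@confoundAmplitude *
      (sin(2 * pi * config@cardiacHz * frameTimes + phases[1]) +
         sin(2 * pi * config@respiratoryHz * frameTimes + phases[2]))
    M <- matrix(0, prod(config@gridShape), nT)
    noise <- if (config@noiseSd > 0)
      matrix(stats::rnorm(length(brain) * nT, sd = config@noiseSd),
             length(brain)) else 0
    M[brain, ] <- t(latent)[regIdx, , drop = FALSE] + noise +
      rep(confound, each = length(brain))
    list(M = M, phases = phases)
  })

  physio <- new("PhysioTrace", time = physioTimes,
                cardiac = sin(2 * pi * config@cardiacHz * physioTimes +
                                out$phases[1]),
                respiratory = sin(2 * pi * config@respiratoryHz *
                                    physioTimes + out$phases[2]))
  bold <- new("Bold4D", data = array(out$M, c(config@gridShape, nT)),
              trSeconds = tr, affine = labels@affine)
  list(bold = bold, physio = physio)
}

# Fixed skeleton geometry: two orthogonal one-voxel-thick sheets through the
# grid centre, inset from the faces. Identical for every subject of a grid.
skeletonGeometry <- function(gridShape) {
  d <- gridShape
  m <- pmax(2L, d %/% 8L)
  mask <- array(FALSE, d)
  zmid <- max(1L, d[3] %/% 2L)
  ymid <- max(1L, d[2] %/% 2L)
  mask[(m[1] + 1):(d[1] - m[1]), (m[2] + 1):(d[2] - m[2]), zmid] <- TRUE
  mask[(m[1] + 1):(d[1] - m[1]), ymid,
       max(1L, m[3]):(d[3] - m[3] + 1L)] <- TRUE
  mask
}

.faDraw <- function(config, subject) {
  sub <- resolveSubject(config, subject)
  mask <- skeletonGeometry(config@gridShape)
  vox <- which(mask)
  withSeed(subjectSeed(config@seed, sub$index, 3L), {
    lesion <- array(FALSE, dim(mask))
    if (sub$kind == "patient") {
      centre <- arrayInd(vox[sample(length(vox), 1L)], dim(mask))
      idx <- arrayInd(vox, dim(mask))
      cheb <- pmax(abs(idx[, 1] - centre[1]), abs(idx[, 2] - centre[2]),
                   abs(idx[, 3] - centre[3]))
      lesion[vox[cheb <= config@lesionRadius]] <- TRUE
    }
    fa <- array(0, dim(mask))
    fa[vox] <- pmin(pmax(stats::rnorm(length(vox), config@faMean,
                                      config@faSd), 0.2), 1)
    fa[lesion] <- pmin(pmax(fa[lesion] - config@lesionDepth, 0), 1)
    list(map = new("FASkeletonMap", fa = fa, skeletonMask = mask,
                   affine = diag(c(config@voxelDims, 1))),
         lesion = lesion)
  })
}

#' Generate a subject's skeletonized FA map
#'
#' Control subjects carry FA values drawn around the control mean (clamped to
#' the white-matter range [0.2, 1]) on a fixed skeleton; patients additionally
#' carry a contiguous lesional patch in which FA is reduced by
#' \code{lesionDepth}. Off-skeleton voxels are zero.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param subject subject index or id.
#' @return a \code{\linkS4class{FASkeletonMap}}.
#' @seealso \code{\link{faLesionMask}} for the planted patch.
#' @export
generateFaSkeleton <- function(config, subject = 1L) {
  .faDraw(config, subject)$map
}

#' Planted lesional patch of a synthetic patient's FA map
#'
#' Recomputes (deterministically, from the subject's stream) the voxel set in
#' which \code{\link{generateFaSkeleton}} reduced FA for this subject. All
#' FALSE for controls.
#'
#' @inheritParams generateFaSkeleton
#' @return logical 3D array.
#' @export
faLesionMask <- function(config, subject = 1L) {
  .faDraw(config, subject)$lesion
}
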