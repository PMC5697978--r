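#' @import methods
NULL

.isAffine <- function(x) is.matrix(x) && all(dim(x) == c(4L, 4L)) && is.numeric(x)

#' Bold4D: a 4D BOLD time series volume
#'
#' Container for a blood-oxygen-level-dependent (BOLD) fMRI run: a 4D array
#' indexed (x, y, z, t), the repetition time in seconds, and the voxel-to-world
#' affine of the spatial grid.
#'
#' @slot data numeric 4D array, dimensions (x, y, z, t).
#' @slot trSeconds repetition time (sampling interval) in seconds.
#' @slot affine 4x4 voxel-to-world matrix.
#' @exportClass Bold4D
setClass("Bold4D",
  representation(data = "array", trSeconds = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4-D array (x, y, z, t)")
    else if (dim(object@data)[4L] < 2L)
      msg <- c(msg, "need at least 2 timepoints")
    if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
        object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a single positive number")
    if (!.isAffine(object@affine))
      msg <- c(msg, "affine must be a 4x4 numeric matrix")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: an integer-labelled parcellation
#'
#' A 3D volume assigning each voxel an integer anatomical region label
#' (0 = background), together with a region table giving each label's name,
#' tissue class (GM, WM or CSF) and hemisphere.
#'
#' @slot data integer 3D array of region labels; 0 is background.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot regions data.frame with columns \code{name}, \code{label},
#'   \code{tissue} (\code{"GM"}, \code{"WM"} or \code{"CSF"}) and
#'   \code{hemisphere} (\code{"L"}, \code{"R"} or \code{NA}).
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", affine = "matrix", regions = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (!.isAffine(object@affine))
      msg <- c(msg, "affine must be a 4x4 numeric matrix")
    need <- c("name", "label", "tissue")
    if (!all(need %in% names(object@regions)))
      msg <- c(msg, "regions must have columns name, label, tissue")
    else {
      if (anyDuplicated(object@regions$label))
        msg <- c(msg, "region labels must be distinct")
      if (any(object@regions$label == 0L))
        msg <- c(msg, "label 0 is reserved for background")
      if (!all(object@regions$tissue %in% c("GM", "WM", "CSF")))
        msg <- c(msg, "tissue must be GM, WM or CSF")
    }
    if (length(msg)) msg else TRUE
  })

#' PhysioTrace: recorded physiological confound traces
#'
#' Cardiac and respiratory recordings covering a BOLD run, sampled on a
#' strictly increasing time grid (seconds from run onset).
#'
#' @slot time numeric vector of sample times in seconds, strictly increasing.
#' @slot cardiac unitless cardiac trace, same length as \code{time}.
#' @slot respiratory unitless respiratory trace, same length as \code{time}.
#' @exportClass PhysioTrace
setClass("PhysioTrace",
  representation(time = "numeric", cardiac = "numeric",
                 respiratory = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (n < 2L) msg <- c(msg, "need at least 2 samples")
    if (any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (length(object@cardiac) != n || length(object@respiratory) != n)
      msg <- c(msg, "cardiac and respiratory must match time in length")
    if (length(msg)) msg else TRUE
  })

#' NetworkDefinition: a cognitive network as bilateral region sets
#'
#' A named cognitive network defined by a list of bilateral region names, each
#' expanded to a left and a right node, with every node mapped to an integer
#' parcellation label.
#'
#' @slot name network identifier.
#' @slot regions character vector of bilateral region names.
#' @slot nodes data.frame with columns \code{region}, \code{hemisphere}
#'   (\code{"L"}/\code{"R"}), \code{node} (e.g. \code{"precuneus_L"}) and
#'   \code{label} (integer parcellation label).
#' @exportClass NetworkDefinition
setClass("NetworkDefinition",
  representation(name = "character", regions = "character",
                 nodes = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@regions) < 1L)
      msg <- c(msg, "network must contain at least one region")
    if (nrow(object@nodes) != 2L * length(object@regions))
      msg <- c(msg, "every region must expand to exactly one L and one R node")
    if (anyDuplicated(object@nodes$label))
      msg <- c(msg, "node labels must be distinct")
    if (length(msg)) msg else TRUE
  })

#' LinkSet: the within-network link enumeration
#'
#' All unordered node pairs of a network in canonical order (ascending node
#' index), satisfying L = n(n-1)/2.
#'
#' @slot networkName network identifier.
#' @slot nodeOrder character vector of node identities (row/column order).
#' @slot links data.frame with integer columns \code{i}, \code{j} (i < j) and
#'   character columns \code{node_i}, \code{node_j}.
#' @exportClass LinkSet
setClass("LinkSet",
  representation(networkName = "character", nodeOrder = "character",
                 links = "data.frame"),
  validity = function(object) {
    n <- length(object@nodeOrder)
    L <- nrow(object@links)
    msg <- character()
    if (L != n * (n - 1L) / 2L)
      msg <- c(msg, "link count must equal n(n-1)/2")
    if (L > 0L && any(object@links$i >= object@links$j))
      msg <- c(msg, "links must be canonical (i < j): no self links")
    if (anyDuplicated(object@links[, c("i", "j")]))
      msg <- c(msg, "duplicate links")
    if (length(msg)) msg else TRUE
  })

#' RoiTimeSeries: region-averaged BOLD signals
#'
#' Matrix of node-mean BOLD time courses for one subject and one network.
#'
#' @slot subjectId subject identifier.
#' @slot signals numeric matrix, nodes x timepoints.
#' @slot trSeconds sampling interval in seconds.
#' @slot nodeOrder node identities in row order.
#' @slot degenerate logical per node: TRUE where the node had no voxels (row
#'   is NaN) or constant signal.
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(subjectId = "character", signals = "matrix",
                 trSeconds = "numeric", nodeOrder = "character",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@signals) != length(object@nodeOrder))
      msg <- c(msg, "signals rows must match nodeOrder")
    if (length(object@degenerate) != length(object@nodeOrder))
      msg <- c(msg, "degenerate flags must match nodeOrder")
    if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
    if (length(msg)) msg else TRUE
  })

#' ConnectivityMatrix: per-subject network correlation matrix
#'
#' Symmetric matrix of zero-lag Pearson correlations between node-mean signals
#' of one network, unit diagonal; entries for degenerate nodes are NaN.
#'
#' @slot subjectId subject identifier.
#' @slot networkName network identifier.
#' @slot r node x node correlation matrix.
#' @slot nodeOrder node identities in matrix order.
#' @slot scale \code{"r"} for raw correlations (entries bounded by 1) or
#'   \code{"z"} for Fisher-transformed values.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(subjectId = "character", networkName = "character",
                 r = "matrix", nodeOrder = "character", scale = "character"),
  prototype(scale = "r"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@r) != ncol(object@r))
      msg <- c(msg, "r must be square")
    if (nrow(object@r) != length(object@nodeOrder))
      msg <- c(msg, "r dimension must match nodeOrder")
    if (!object@scale %in% c("r", "z"))
      msg <- c(msg, "scale must be 'r' or 'z'")
    ok <- is.finite(object@r)
    if (object@scale == "r" && any(abs(object@r[ok]) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (any(ok) && max(abs(object@r - t(object@r)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "r must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' NormativeLinkModel: control-cohort per-link normative band
#'
#' Per-link sample mean and SD of control correlations, defining the
#' mean +/- 2 SD normality band. Links with fewer than two usable controls are
#' unmodelable (NA mean/sd).
#'
#' @slot networkName network identifier.
#' @slot nodeOrder node identities.
#' @slot links data.frame with columns \code{i}, \code{j}, \code{node_i},
#'   \code{node_j}, \code{mean_r}, \code{sd_r}, \code{n} (per-link usable
#'   control count).
#' @slot nControls number of controls in the stratum.
#' @slot stratum optional sex label ("" when unstratified).
#' @exportClass NormativeLinkModel
setClass("NormativeLinkModel",
  representation(networkName = "character", nodeOrder = "character",
                 links = "data.frame", nControls = "integer",
                 stratum = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("i", "j", "node_i", "node_j", "mean_r", "sd_r", "n")
    if (!all(need %in% names(object@links)))
      msg <- c(msg, paste("links must have columns",
                          paste(need, collapse = ", ")))
    else if (any(object@links$sd_r < 0, na.rm = TRUE))
      msg <- c(msg, "sd_r must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' AbnormalLinkReport: per-patient abnormal-link classification
#'
#' Each within-network link of one patient classified against the normative
#' band: \code{reduced} (below mean - 2 SD), \code{elevated} (above
#' mean + 2 SD), \code{normal}, or \code{undefined} (unmodelable link or NaN
#' correlation). Counts are over defined links only.
#'
#' @slot subjectId patient identifier.
#' @slot networkName network identifier.
#' @slot links data.frame with columns \code{i}, \code{j}, \code{node_i},
#'   \code{node_j}, \code{r}, \code{status}.
#' @slot reducedCount number of reduced links.
#' @slot elevatedCount number of elevated links.
#' @slot abnormalCount reduced + elevated.
#' @slot definedCount number of links with defined status.
#' @exportClass AbnormalLinkReport
setClass("AbnormalLinkReport",
  representation(subjectId = "character", networkName = "character",
                 links = "data.frame", reducedCount = "integer",
                 elevatedCount = "integer", abnormalCount = "integer",
                 definedCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@abnormalCount != object@reducedCount + object@elevatedCount)
      msg <- c(msg, "abnormalCount must equal reduced + elevated")
    if (object@abnormalCount > object@definedCount)
      msg <- c(msg, "abnormalCount cannot exceed definedCount")
    if (!all(object@links$status %in%
             c("normal", "reduced", "elevated", "undefined")))
      msg <- c(msg, "invalid link status")
    if (length(msg)) msg else TRUE
  })

#' MorphometryRecord: normalized regional volumetry for one subject
#'
#' Raw and total-brain-normalized region volumes, tissue-group fractions
#' (GM/WM/CSF summing to 1), and asymmetry indices for every bilateral
#' structure pair.
#'
#' @slot subjectId subject identifier.
#' @slot regions data.frame with columns \code{name}, \code{label},
#'   \code{tissue}, \code{voxels}, \code{rawVolume} (mm^3),
#'   \code{normVolume} (fraction of total brain volume).
#' @slot tissueFractions named numeric: GM, WM and CSF fractions.
#' @slot asymmetry data.frame with columns \code{structure}, \code{ai}
#'   (absolute) and \code{aiSigned} (left minus right).
#' @exportClass MorphometryRecord
setClass("MorphometryRecord",
  representation(subjectId = "character", regions = "data.frame",
                 tissueFractions = "numeric", asymmetry = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!all(c("GM", "WM", "CSF") %in% names(object@tissueFractions)))
      msg <- c(msg, "tissueFractions must contain GM, WM, CSF")
    else if (abs(sum(object@tissueFractions) - 1) > 1e-9)
      msg <- c(msg, "tissue fractions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' FASkeletonMap: skeletonized fractional-anisotropy map
#'
#' FA values on a fixed white-matter skeleton; voxels off the skeleton are
#' zero and ignored by all statistics.
#'
#' @slot fa numeric 3D array of fractional anisotropy in [0, 1].
#' @slot skeletonMask logical 3D array marking skeleton voxels.
#' @slot affine 4x4 voxel-to-world matrix.
#' @exportClass FASkeletonMap
setClass("FASkeletonMap",
  representation(fa = "array", skeletonMask = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@fa)) != 3L)
      msg <- c(msg, "fa must be a 3-D array")
    if (!identical(dim(object@fa), dim(object@skeletonMask)))
      msg <- c(msg, "fa and skeletonMask dimensions must agree")
    if (!is.logical(object@skeletonMask))
      msg <- c(msg, "skeletonMask must be logical")
    inm <- object@fa[object@skeletonMask]
    if (length(inm) && (min(inm) < 0 || max(inm) > 1))
      msg <- c(msg, "in-mask FA must lie in [0, 1]")
    if (!.isAffine(object@affine))
      msg <- c(msg, "affine must be a 4x4 numeric matrix")
    if (length(msg)) msg else TRUE
  })

#' FAStatMap: voxelwise single-case statistic map
#'
#' Per-voxel t and two-sided p values comparing one patient's skeletonized FA
#' against a control cohort; NaN outside the analysis mask (skeleton voxels
#' with control mean FA at or above the white-matter threshold).
#'
#' @slot t numeric 3D array of t statistics (NaN outside mask).
#' @slot p numeric 3D array of two-sided p values.
#' @slot mask logical 3D array of analysed voxels.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot nControls control cohort size.
#' @slot df degrees of freedom (nControls - 1).
#' @slot sdZeroVoxels number of in-mask voxels dropped for zero control SD.
#' @slot method "single_case" (Crawford-Howell) or "naive".
#' @exportClass FAStatMap
setClass("FAStatMap",
  representation(t = "array", p = "array", mask = "array", affine = "matrix",
                 nControls = "integer", df = "numeric",
                 sdZeroVoxels = "integer", method = "character"))

#' SimulationConfig: full specification of a synthetic study
#'
#' Holds the cohort layout, acquisition parameters, planted connectivity
#' structure, planted volumetric asymmetry and tissue composition, confound
#' and noise levels, FA lesion model and master seed from which every
#' synthetic input is generated deterministically. Construct with
#' \code{\link{simulationConfig}}.
#'
#' @slot nControls,nPatients cohort sizes.
#' @slot nTimepoints number of BOLD volumes.
#' @slot trSeconds repetition time, seconds.
#' @slot gridShape integer 3-vector of voxel counts.
#' @slot voxelDims voxel dimensions in mm.
#' @slot regions region table (name, label, tissue, hemisphere, weight).
#' @slot networks list of \code{NetworkDefinition}.
#' @slot baseConnectivity data.frame (node_a, node_b, r) of planted link
#'   correlation targets.
#' @slot weakenedLinks list (one per patient) of data.frames
#'   (node_a, node_b, r) overriding targets for that patient.
#' @slot subjects per-subject table: id, kind, index, sex, gmFraction,
#'   wmFraction, thalamusAsymmetry (signed), streamSeed.
#' @slot cardiacHz,respiratoryHz confound fundamentals, Hz.
#' @slot physioHz physiological recording sample rate, Hz.
#' @slot confoundAmplitude,noiseSd signal-unit amplitudes.
#' @slot brainFraction fraction of grid voxels occupied by brain labels.
#' @slot faMean,faSd,lesionDepth,lesionRadius FA skeleton model parameters.
#' @slot psdTolerance maximum admissible entrywise adjustment when repairing a
#'   non-positive-semi-definite planted correlation matrix.
#' @slot seed master integer seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nControls = "integer", nPatients = "integer",
                 nTimepoints = "integer", trSeconds = "numeric",
                 gridShape = "integer", voxelDims = "numeric",
                 regions = "data.frame", networks = "list",
                 baseConnectivity = "data.frame", weakenedLinks = "list",
                 subjects = "data.frame",
                 cardiacHz = "numeric", respiratoryHz = "numeric",
                 physioHz = "numeric", confoundAmplitude = "numeric",
                 noiseSd = "numeric", brainFraction = "numeric",
                 faMean = "numeric", faSd = "numeric",
                 lesionDepth = "numeric", lesionRadius = "integer",
                 psdTolerance = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
    if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive voxel counts")
    if (anyDuplicated(object@regions$label) ||
        any(object@regions$label == 0L))
      msg <- c(msg, "region labels must be distinct and nonzero")
    if (nrow(object@baseConnectivity) &&
        any(abs(object@baseConnectivity$r) > 1))
      msg <- c(msg, "planted correlation targets must lie in [-1, 1]")
    if (length(object@weakenedLinks) != object@nPatients)
      msg <- c(msg, "weakenedLinks must have one entry per patient")
    if (nrow(object@subjects) != object@nControls + object@nPatients)
      msg <- c(msg, "subjects table must cover all controls and patients")
    if (length(msg)) msg else TRUE
  })
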