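## Normalized regional volumetry, tissue-group fractions and the paired
## structure asymmetry index; Welch group comparison.

#' Compute normalized regional volumes and asymmetry indices
#'
#' Raw region volume is voxel count times the voxel volume (the absolute
#' determinant of the affine's 3x3 spatial block, mm^3). Volumes are
#' normalized to the total brain volume — the sum over all labelled regions,
#' GM, WM and CSF alike — so GM + WM + CSF fractions sum to 1 by
#' construction. For every bilateral structure pair the asymmetry index is
#' computed from the normalized volumes (see \code{\link{asymmetryIndex}}).
#'
#' @param labels a \code{\linkS4class{LabelVolume}} whose region table
#'   assigns every label a tissue group.
#' @param tissueGroups optional named character vector (region name ->
#'   "GM"/"WM"/"CSF") overriding the region table's tissue column.
#' @param subjectId subject identifier carried through.
#' @return a \code{\linkS4class{MorphometryRecord}}.
#' @export
computeVolumes <- function(labels, tissueGroups = NULL,
                           subjectId = "subject") {
  stopifnot(is(labels, "LabelVolume"))
  reg <- labels@regions
  if (!is.null(tissueGroups)) {
    miss <- setdiff(reg$name, names(tissueGroups))
    if (length(miss))
      stop("no tissue-group assignment for region(s): ",
           paste(miss, collapse = ", "))
    reg$tissue <- unname(tissueGroups[reg$name])
    if (!all(reg$tissue %in% c("GM", "WM", "CSF")))
      stop("tissue groups must be GM, WM or CSF")
  }
  voxVol <- abs(det(labels@affine[1:3, 1:3]))
  labFlat <- as.integer(labels@data)
  present <- labFlat[labFlat > 0L]
  unknown <- setdiff(unique(present), reg$label)
  if (length(unknown))
    stop("label(s) in volume without region entry: ",
         paste(sort(unknown), collapse = ", "))
  counts <- vapply(reg$label, function(l) sum(present == l), integer(1))
  reg$voxels <- counts
  reg$rawVolume <- counts * voxVol
  total <- sum(reg$rawVolume)
  if (total <= 0) stop("empty label volume")
  reg$normVolume <- reg$rawVolume / total

  fr <- vapply(c("GM", "WM", "CSF"), function(tis)
    sum(reg$normVolume[reg$tissue == tis]), numeric(1))

  base <- sub("_[LR]$", "", reg$name)
  paired <- unique(base[duplicated(base)])
  ai <- do.call(rbind, lapply(paired, function(b) {
    vl <- reg$normVolume[reg$name == paste0(b, "_L")]
    vr <- reg$normVolume[reg$name == paste0(b, "_R")]
    if (!length(vl) || !length(vr) || vl + vr <= 0) return(NULL)
    data.frame(structure = b,
               ai = asymmetryIndex(vl, vr),
               aiSigned = asymmetryIndex(vl, vr, signed = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ai))
    ai <- data.frame(structure = character(), ai = numeric(),
                     aiSigned = numeric())
  new("MorphometryRecord", subjectId = subjectId,
      regions = reg[, c("name", "label", "tissue", "voxels", "rawVolume",
                        "normVolume")],
      tissueFractions = fr, asymmetry = ai)
}

#' Asymmetry index of a paired structure
#'
#' AI = |V_L - V_R| / ((V_L + V_R) / 2), ranging from 0 (perfect symmetry)
#' to 2 (one side absent). The defining formula is signed (left minus
#' right); the magnitude is returned by default because group summaries of
#' asymmetry pool subjects whose smaller side differs, and the signed value
#' is available via \code{signed = TRUE}.
#'
#' @param vLeft,vRight volumes of the left and right structure (any common
#'   unit; the index is scale-free).
#' @param signed return the signed index (left minus right) instead of the
#'   magnitude.
#' @return the asymmetry index.
#' @examples
#' asymmetryIndex(3, 2)   # 0.4
#' asymmetryIndex(1, 0)   # 2, maximal
#' @export
asymmetryIndex <- function(vLeft, vRight, signed = FALSE) {
  stopifnot(vLeft >= 0, vRight >= 0)
  if (vLeft + vRight <= 0)
    stop("asymmetry index undefined: both volumes are zero")
  ai <- (vLeft - vRight) / ((vLeft + vRight) / 2)
  if (signed) ai else abs(ai)
}

# Pull one scalar measure out of a MorphometryRecord.
morphMeasure <- function(record, measure) {
  if (measure %in% c("GM", "WM", "CSF"))
    return(record@tissueFractions[[measure]])
  if (grepl("_AI$", measure)) {
    structure <- sub("_AI$", "", measure)
    row <- match(structure, record@asymmetry$structure)
    if (is.na(row)) stop("no asymmetry entry for structure: ", structure)
    return(record@asymmetry$ai[row])
  }
  row <- match(measure, record@regions$name)
  if (is.na(row)) stop("unknown measure: ", measure)
  record@regions$normVolume[row]
}

#' Compare a volumetric measure between patients and controls
#'
#' Welch two-sample two-sided t-test on a volumetric measure: a tissue
#' fraction (\code{"GM"}, \code{"WM"}, \code{"CSF"}), a paired-structure
#' asymmetry index (\code{"<structure>_AI"}, e.g. \code{"thalamus_AI"}), or
#' a single region's normalized volume by name. Reported as per-group
#' mean (sd) with t, df and p.
#'
#' @param patients,controls lists of \code{\linkS4class{MorphometryRecord}}
#'   (>= 2 subjects each).
#' @param measure measure name as above.
#' @return list with \code{measure}, \code{patientMean}, \code{patientSd},
#'   \code{controlMean}, \code{controlSd}, \code{t}, \code{df}, \code{p},
#'   \code{nPatients}, \code{nControls}.
#' @export
groupCompare <- function(patients, controls, measure = "GM") {
  if (length(patients) < 2L || length(controls) < 2L)
    stop("need at least 2 subjects per group")
  xp <- vapply(patients, morphMeasure, numeric(1), measure = measure)
  xc <- vapply(controls, morphMeasure, numeric(1), measure = measure)
  if (stats::sd(xp) == 0 && stats::sd(xc) == 0) {
    same <- mean(xp) == mean(xc)
    return(list(measure = measure, patientMean = mean(xp),
                patientSd = 0, controlMean = mean(xc), controlSd = 0,
                t = 0, df = NA, p = if (same) 1 else NA,
                nPatients = length(xp), nControls = length(xc)))
  }
  tt <- stats::t.test(xp, xc)   # Welch by default
  list(measure = measure, patientMean = mean(xp), patientSd = stats::sd(xp),
       controlMean = mean(xc), controlSd = stats::sd(xc),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       nPatients = length(xp), nControls = length(xc))
}
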