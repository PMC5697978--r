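#' Accessors for cognet data containers
#'
#' Small accessor generics exposing the slots of the package's S4 containers:
#' the voxel-to-world affine, the repetition time, node/link structure, and
#' the per-link table of a normative model or patient report.
#'
#' @param object a cognet S4 object.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("affine", function(object) standardGeneric("affine"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("nodeOrder", function(object) standardGeneric("nodeOrder"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("networkName", function(object) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("linkCount", function(object) standardGeneric("linkCount"))
#' @rdname accessors
#' @export
setGeneric("linkTable", function(object) standardGeneric("linkTable"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))
#' @rdname accessors
#' @export
setGeneric("tissueFractions", function(object)
  standardGeneric("tissueFractions"))

#' @rdname accessors
setMethod("affine", "Bold4D", function(object) object@affine)
#' @rdname accessors
setMethod("affine", "LabelVolume", function(object) object@affine)
#' @rdname accessors
setMethod("affine", "FASkeletonMap", function(object) object@affine)
#' @rdname accessors
setMethod("affine", "FAStatMap", function(object) object@affine)

#' @rdname accessors
setMethod("trSeconds", "Bold4D", function(object) object@trSeconds)
#' @rdname accessors
setMethod("trSeconds", "RoiTimeSeries", function(object) object@trSeconds)

#' @rdname accessors
setMethod("nodeOrder", "NetworkDefinition",
          function(object) object@nodes$node)
#' @rdname accessors
setMethod("nodeOrder", "LinkSet", function(object) object@nodeOrder)
#' @rdname accessors
setMethod("nodeOrder", "RoiTimeSeries", function(object) object@nodeOrder)
#' @rdname accessors
setMethod("nodeOrder", "ConnectivityMatrix", function(object)
  object@nodeOrder)
#' @rdname accessors
setMethod("nodeOrder", "NormativeLinkModel", function(object)
  object@nodeOrder)

#' @rdname accessors
setMethod("subjectId", "RoiTimeSeries", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "ConnectivityMatrix", function(object)
  object@subjectId)
#' @rdname accessors
setMethod("subjectId", "AbnormalLinkReport", function(object)
  object@subjectId)
#' @rdname accessors
setMethod("subjectId", "MorphometryRecord", function(object)
  object@subjectId)

#' @rdname accessors
setMethod("networkName", "NetworkDefinition", function(object) object@name)
#' @rdname accessors
setMethod("networkName", "LinkSet", function(object) object@networkName)
#' @rdname accessors
setMethod("networkName", "ConnectivityMatrix", function(object)
  object@networkName)
#' @rdname accessors
setMethod("networkName", "NormativeLinkModel", function(object)
  object@networkName)
#' @rdname accessors
setMethod("networkName", "AbnormalLinkReport", function(object)
  object@networkName)

#' @rdname accessors
setMethod("nNodes", "NetworkDefinition", function(object)
  nrow(object@nodes))
#' @rdname accessors
setMethod("nNodes", "LinkSet", function(object) length(object@nodeOrder))

#' @rdname accessors
setMethod("linkCount", "LinkSet", function(object) nrow(object@links))
#' @rdname accessors
setMethod("linkCount", "NetworkDefinition", function(object) {
  n <- nrow(object@nodes)
  n * (n - 1L) / 2L
})

#' @rdname accessors
setMethod("linkTable", "LinkSet", function(object) object@links)
#' @rdname accessors
setMethod("linkTable", "NormativeLinkModel", function(object) object@links)
#' @rdname accessors
setMethod("linkTable", "AbnormalLinkReport", function(object) object@links)

#' @rdname accessors
setMethod("regionTable", "LabelVolume", function(object) object@regions)
#' @rdname accessors
setMethod("regionTable", "SimulationConfig", function(object) object@regions)
#' @rdname accessors
setMethod("regionTable", "MorphometryRecord", function(object)
  object@regions)

#' @rdname accessors
setMethod("corValues", "ConnectivityMatrix", function(object) object@r)

#' @rdname accessors
setMethod("tissueFractions", "MorphometryRecord", function(object)
  object@tissueFractions)

setMethod("show", "Bold4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Bold4D: %d x %d x %d grid, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume: %d x %d x %d grid, %d regions (%s)\n",
              d[1], d[2], d[3], nrow(object@regions),
              paste(sprintf("%s: %d", names(table(object@regions$tissue)),
                            as.integer(table(object@regions$tissue))),
                    collapse = ", ")))
})

setMethod("show", "PhysioTrace", function(object) {
  cat(sprintf("PhysioTrace: %d samples over %.1f s\n",
              length(object@time), diff(range(object@time))))
})

setMethod("show", "NetworkDefinition", function(object) {
  n <- nrow(object@nodes)
  cat(sprintf("NetworkDefinition '%s': %d bilateral regions, %d nodes, %d links\n",
              object@name, length(object@regions), n, n * (n - 1L) / 2L))
})

setMethod("show", "LinkSet", function(object) {
  cat(sprintf("LinkSet '%s': %d nodes, %d links\n", object@networkName,
              length(object@nodeOrder), nrow(object@links)))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d nodes x %d timepoints (TR = %g s)%s\n",
              object@subjectId, nrow(object@signals), ncol(object@signals),
              object@trSeconds,
              if (any(object@degenerate)) sprintf(", %d degenerate node(s)",
                                                  sum(object@degenerate))
              else ""))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix '%s' / '%s': %d x %d\n", object@subjectId,
              object@networkName, nrow(object@r), ncol(object@r)))
})

setMethod("show", "NormativeLinkModel", function(object) {
  cat(sprintf(
    "NormativeLinkModel '%s'%s: %d links, %d controls, %d unmodelable\n",
    object@networkName,
    if (nzchar(object@stratum)) sprintf(" [%s]", object@stratum) else "",
    nrow(object@links), object@nControls, sum(object@links$n < 2L)))
})

setMethod("show", "AbnormalLinkReport", function(object) {
  cat(sprintf(
    "AbnormalLinkReport '%s' / '%s': %d reduced, %d elevated of %d defined links\n",
    object@subjectId, object@networkName, object@reducedCount,
    object@elevatedCount, object@definedCount))
})

setMethod("show", "MorphometryRecord", function(object) {
  f <- object@tissueFractions
  cat(sprintf(
    "MorphometryRecord '%s': GM %.3f, WM %.3f, CSF %.3f of total brain volume\n",
    object@subjectId, f[["GM"]], f[["WM"]], f[["CSF"]]))
})

setMethod("show", "FASkeletonMap", function(object) {
  cat(sprintf("FASkeletonMap: %s grid, %d skeleton voxels\n",
              paste(dim(object@fa), collapse = " x "),
              sum(object@skeletonMask)))
})

setMethod("show", "FAStatMap", function(object) {
  cat(sprintf(
    "FAStatMap (%s): %d analysed voxels, %d controls (df = %g), %d zero-SD voxels\n",
    object@method, sum(object@mask), object@nControls, object@df,
    object@sdZeroVoxels))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d controls + %d patients, %d volumes @ TR %g s, grid %s, seed %d\n",
    object@nControls, object@nPatients, object@nTimepoints, object@trSeconds,
    paste(object@gridShape, collapse = " x "), object@seed))
})
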