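## ROI signal extraction and per-network cross-correlation matrices.

#' Extract region-averaged signals for a network
#'
#' Each node's signal is the unweighted mean, per timepoint, over the voxels
#' carrying the node's parcellation label. The label map must share the BOLD
#' grid and affine (no implicit resampling). A node whose label is absent
#' from the volume yields a NaN row and is flagged degenerate.
#'
#' @param bold a (preprocessed) \code{\linkS4class{Bold4D}}.
#' @param labels a \code{\linkS4class{LabelVolume}} on the same grid.
#' @param net a \code{\linkS4class{NetworkDefinition}}.
#' @param subjectId subject identifier carried through to the result.
#' @return a \code{\linkS4class{RoiTimeSeries}} (nodes x timepoints).
#' @export
extractRoiSignals <- function(bold, labels, net, subjectId = "subject") {
  stopifnot(is(bold, "Bold4D"), is(labels, "LabelVolume"),
            is(net, "NetworkDefinition"))
  d <- dim(bold@data)
  if (!identical(d[1:3], dim(labels@data)))
    stop("BOLD and label volumes are on different grids")
  if (max(abs(bold@affine - labels@affine)) > 1e-4)
    stop("BOLD and label affines disagree beyond tolerance 1e-4; ",
         "inputs must be pre-aligned")

  nT <- d[4]
  labFlat <- as.integer(labels@data)
  wanted <- net@nodes$label
  sel <- labFlat %in% wanted
  sig <- matrix(NaN, length(wanted), nT,
                dimnames = list(net@nodes$node, NULL))
  if (any(sel)) {
    Y <- matrix(bold@data, length(labFlat), nT)[sel, , drop = FALSE]
    grp <- factor(labFlat[sel], levels = wanted)
    sums <- rowsum(Y, grp)   # only levels present in the volume
    counts <- as.integer(table(grp))
    rows <- match(as.character(wanted), rownames(sums))
    nz <- counts > 0L & !is.na(rows)
    sig[nz, ] <- sums[rows[nz], , drop = FALSE] / counts[nz]
  }
  degenerate <- !(wanted %in% labFlat)
  if (any(degenerate))
    warning("label(s) absent from volume for node(s): ",
            paste(net@nodes$node[degenerate], collapse = ", "))
  new("RoiTimeSeries", subjectId = subjectId, signals = sig,
      trSeconds = bold@trSeconds, nodeOrder = net@nodes$node,
      degenerate = degenerate)
}

#' Per-subject network cross-correlation matrix
#'
#' Entry (i, j) is the zero-lag Pearson correlation between node signals i
#' and j; the matrix is symmetric with unit diagonal. Links touching a
#' degenerate node (missing label or zero-variance signal) are NaN and a
#' warning is raised for zero-variance rows.
#'
#' @param ts a \code{\linkS4class{RoiTimeSeries}} with at least 3 timepoints.
#' @param networkName network identifier carried through to the result
#'   (default: inferred, see Details).
#' @param fisherZ if TRUE, return Fisher z-transformed values
#'   (atanh of r) instead of raw correlations; off by default since the
#'   abnormality rule thresholds raw correlations.
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @export
correlationMatrix <- function(ts, networkName = "network",
                              fisherZ = FALSE) {
  stopifnot(is(ts, "RoiTimeSeries"))
  S <- ts@signals
  if (ncol(S) < 3L) stop("need at least 3 timepoints")
  sds <- apply(S, 1L, stats::sd)
  zeroVar <- is.finite(sds) & sds == 0
  bad <- ts@degenerate | zeroVar | !is.finite(sds)
  if (any(zeroVar))
    warning("zero-variance signal for node(s): ",
            paste(ts@nodeOrder[zeroVar], collapse = ", "),
            "; their links are NaN")
  r <- suppressWarnings(stats::cor(t(S)))
  r[bad, ] <- NaN
  r[, bad] <- NaN
  r[is.na(r)] <- NaN
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  if (fisherZ) {
    r <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    diag(r) <- 1   # diagonal kept at 1 as a marker, not a z value
  }
  dimnames(r) <- list(ts@nodeOrder, ts@nodeOrder)
  new("ConnectivityMatrix", subjectId = ts@subjectId,
      networkName = networkName, r = r, nodeOrder = ts@nodeOrder,
      scale = if (fisherZ) "z" else "r")
}

# Link-value vector of a connectivity matrix for a canonical LinkSet order.
linkValues <- function(cm, links) {
  cm@r[cbind(links$i, links$j)]
}
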