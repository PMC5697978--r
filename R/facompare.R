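## Voxelwise single-case comparison of a skeletonized FA map against a
## control cohort, masked at the white-matter FA threshold.

#' Voxelwise single-case comparison of skeletonized FA maps
#'
#' Compares one patient's FA skeleton against a control cohort voxel by
#' voxel. The default statistic is the Crawford-Howell single-case t,
#' t = (x - mean_c) / (sd_c * sqrt(1 + 1/n_c)) with n_c - 1 degrees of
#' freedom, which treats the patient as a sample of one from the control
#' population; the naive form t = (x - mean_c) / (sd_c / sqrt(n_c)), which
#' tests the patient's value as if it were a group mean and is
#' anti-conservative, is available via \code{method = "naive"}. Voxels off
#' the skeleton, or whose control mean FA falls below \code{faThreshold}
#' (non white matter), are excluded (NaN); in-mask voxels with zero control
#' SD are NaN and counted.
#'
#' @param patient the patient's \code{\linkS4class{FASkeletonMap}}.
#' @param controls list of >= 3 control \code{\linkS4class{FASkeletonMap}}
#'   on the same grid, affine and skeleton.
#' @param faThreshold white-matter threshold on the control mean FA
#'   (default 0.2).
#' @param method \code{"single_case"} (default) or \code{"naive"}.
#' @return an \code{\linkS4class{FAStatMap}} of voxelwise t and two-sided p.
#' @export
singleCaseMap <- function(patient, controls, faThreshold = 0.2,
                          method = c("single_case", "naive")) {
  method <- match.arg(method)
  stopifnot(is(patient, "FASkeletonMap"))
  if (length(controls) < 3L) stop("need at least 3 controls")
  for (ctrl in controls) {
    if (!identical(dim(ctrl@fa), dim(patient@fa)))
      stop("control grid does not match the patient's")
    if (max(abs(ctrl@affine - patient@affine)) > 1e-4)
      stop("control affine does not match the patient's")
    if (!identical(ctrl@skeletonMask, patient@skeletonMask))
      stop("skeleton masks differ; maps must share the skeleton")
  }
  mask <- patient@skeletonMask
  vox <- which(mask)
  n <- length(controls)
  vals <- vapply(controls, function(c) c@fa[vox], numeric(length(vox)))
  meanC <- rowMeans(vals)
  sdC <- apply(vals, 1L, stats::sd)

  include <- meanC >= faThreshold
  sdZero <- include & sdC == 0
  x <- patient@fa[vox]
  denom <- if (method == "single_case") sdC * sqrt(1 + 1 / n)
           else sdC / sqrt(n)
  tval <- (x - meanC) / denom
  tval[!include | sdZero] <- NaN
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)

  tArr <- array(NaN, dim(mask)); pArr <- array(NaN, dim(mask))
  mArr <- array(FALSE, dim(mask))
  tArr[vox] <- tval
  pArr[vox] <- pval
  mArr[vox[include & !sdZero]] <- TRUE
  new("FAStatMap", t = tArr, p = pArr, mask = mArr,
      affine = patient@affine, nControls = as.integer(n), df = n - 1,
      sdZeroVoxels = as.integer(sum(sdZero)), method = method)
}

#' Write a thresholded statistic overlay
#'
#' Writes the t statistic thresholded at a p value as a NIfTI overlay on the
#' reference grid (zeros outside the surviving voxel set), and optionally a
#' PNG rendering of axial slices with the overlay in colour on the reference
#' image. Purely presentational.
#'
#' @param statmap an \code{\linkS4class{FAStatMap}}.
#' @param reference a 3D anatomical array (or \code{\linkS4class{FASkeletonMap}})
#'   on the same grid, used as background.
#' @param pThreshold overlay threshold on the two-sided p value
#'   (default 0.01).
#' @param outNifti path of the NIfTI overlay to write.
#' @param outPng optional path of a PNG slice rendering.
#' @return invisibly, the logical array of overlay voxels.
#' @export
overlayReport <- function(statmap, reference, pThreshold = 0.01,
                          outNifti, outPng = NULL) {
  stopifnot(is(statmap, "FAStatMap"))
  ref <- if (is(reference, "FASkeletonMap")) reference@fa else reference
  if (!identical(dim(ref), dim(statmap@t)))
    stop("reference grid does not match the statistic map")
  sel <- is.finite(statmap@p) & statmap@p < pThreshold
  overlay <- array(0, dim(statmap@t))
  overlay[sel] <- statmap@t[sel]
  writeNiftiVolume(overlay, statmap@affine, outNifti)
  if (!is.null(outPng)) {
    nz <- dim(ref)[3]
    slices <- unique(pmax(1L, pmin(nz, round(seq(1, nz, length.out = 4)))))
    grDevices::png(outPng, width = 250 * length(slices), height = 250)
    op <- graphics::par(mfrow = c(1, length(slices)), mar = rep(0.5, 4))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    for (z in slices) {
      graphics::image(ref[, , z], col = grDevices::gray.colors(64),
                      axes = FALSE, useRaster = TRUE)
      ov <- overlay[, , z]
      ov[ov == 0] <- NA
      graphics::image(ov, col = grDevices::hcl.colors(64, "YlOrRd"),
                      add = TRUE, useRaster = TRUE)
    }
  }
  invisible(sel)
}
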