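## File interfaces: NIfTI volumes (via RNifti), physiological TSV, tabular
## TSV reports and JSON sidecars.

writeNiftiVolume <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

plainArray <- function(img) {
  array(as.vector(img), dim = dim(img))
}

readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = plainArray(img),
       affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Read and write cognet volumes as NIfTI
#'
#' \code{writeBold}/\code{readBold} store a \code{\linkS4class{Bold4D}} with
#' its TR in the NIfTI header's temporal pixdim; \code{writeLabelMap}/
#' \code{readLabelMap} store a \code{\linkS4class{LabelVolume}} alongside a
#' JSON region-table sidecar (\code{<path>.regions.json});
#' \code{writeFaSkeleton}/\code{readFaSkeleton} store an
#' \code{\linkS4class{FASkeletonMap}} (off-skeleton voxels are zero; the
#' mask is recovered as the nonzero voxel set).
#'
#' @param bold,labels,map the object to write.
#' @param path file path (conventionally \code{.nii.gz}).
#' @param trSeconds repetition time used by \code{readBold} when the header
#'   carries none.
#' @return the read object, or (writers) the path invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
writeBold <- function(bold, path) {
  stopifnot(is(bold, "Bold4D"))
  img <- RNifti::asNifti(bold@data)
  RNifti::`sform<-`(img, structure(bold@affine, code = 2L))
  RNifti::pixdim(img) <- c(abs(diag(bold@affine)[1:3]), bold@trSeconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readBold <- function(path, trSeconds = NULL) {
  img <- RNifti::readNifti(path)
  tr <- RNifti::pixdim(img)[4]
  if (!is.null(trSeconds)) tr <- trSeconds
  if (!isTRUE(tr > 0))
    stop("no usable TR in header; supply trSeconds")
  new("Bold4D", data = plainArray(img), trSeconds = as.numeric(tr),
      affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' @rdname nifti-io
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  writeNiftiVolume(labels@data, labels@affine, path)
  jsonlite::write_json(labels@regions, paste0(path, ".regions.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readLabelMap <- function(path) {
  v <- readNiftiVolume(path)
  sidecar <- paste0(path, ".regions.json")
  if (!file.exists(sidecar))
    stop("missing region-table sidecar: ", sidecar)
  reg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  reg$label <- as.integer(reg$label)
  new("LabelVolume", data = array(as.integer(round(v$data)), dim(v$data)),
      affine = v$affine, regions = reg)
}

#' @rdname nifti-io
#' @export
writeFaSkeleton <- function(map, path) {
  stopifnot(is(map, "FASkeletonMap"))
  writeNiftiVolume(map@fa * map@skeletonMask, map@affine, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readFaSkeleton <- function(path) {
  v <- readNiftiVolume(path)
  new("FASkeletonMap", fa = v$data, skeletonMask = v$data != 0,
      affine = v$affine)
}

#' Read and write physiological recordings as TSV
#'
#' Columns \code{time_s}, \code{cardiac}, \code{respiratory}.
#'
#' @param physio a \code{\linkS4class{PhysioTrace}}.
#' @param path TSV file path.
#' @return the trace, or (writer) the path invisibly.
#' @export
writePhysio <- function(physio, path) {
  stopifnot(is(physio, "PhysioTrace"))
  utils::write.table(
    data.frame(time_s = physio@time, cardiac = physio@cardiac,
               respiratory = physio@respiratory),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhysio
#' @export
readPhysio <- function(path) {
  df <- utils::read.delim(path)
  need <- c("time_s", "cardiac", "respiratory")
  if (!all(need %in% names(df)))
    stop("physio TSV must have columns ", paste(need, collapse = ", "))
  new("PhysioTrace", time = df$time_s, cardiac = df$cardiac,
      respiratory = df$respiratory)
}

#' Write a connectivity matrix as TSV
#'
#' Square tab-separated matrix with the node order as header row and first
#' column.
#'
#' @param cm a \code{\linkS4class{ConnectivityMatrix}}.
#' @param path TSV file path.
#' @export
writeConnectivityMatrix <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  m <- cm@r
  dimnames(m) <- list(NULL, cm@nodeOrder)
  df <- data.frame(node = cm@nodeOrder, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
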