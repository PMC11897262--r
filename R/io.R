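#' Write a 3D/4D array as NIfTI-1
#'
#' @param arr Numeric array (3D map or 4D series).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_mm Isotropic voxel size, mm.
#' @param tr_s Volume repetition interval for 4D series, s.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(arr, path, voxel_mm = 1.2, tr_s = NULL) {
  nd <- length(dim(arr))
  pd <- c(rep(voxel_mm, 3), if (nd == 4L) (tr_s %||% 1))
  img <- RNifti::asNifti(arr, pixdim = pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path NIfTI file path.
#' @return Numeric array with attributes stripped to plain `dim`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  array(as.numeric(arr), dim(arr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
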