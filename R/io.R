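#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti preserving lattice values bit-exactly
#' through a round trip: continuous volumes are stored as float64,
#' integer label maps as int32 (and come back with integer storage).
#' Gzipped files (`.nii.gz`) are handled transparently.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol 3D array (numeric or integer/logical for label maps).
#' @param voxel_size Isotropic voxel size in mm written to the header.
#' @param datatype NIfTI datatype; default `"auto"` picks `"int32"` for
#'   integer/logical input and `"double"` otherwise.
#' @return `read_volume()` returns the array (integer storage for
#'   integer-typed files) with attribute `voxel_size`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("failed to read '", path,
                         "' as NIfTI: ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  out <- as.array(img)
  attributes(out) <- list(dim = dim(out))
  if (hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L))
    storage.mode(out) <- "integer"
  attr(out, "voxel_size") <- hdr$pixdim[2]
  out
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_size = 1, datatype = "auto") {
  if (is.logical(vol)) storage.mode(vol) <- "integer"
  if (identical(datatype, "auto"))
    datatype <- if (is.integer(vol)) "int32" else "double"
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write TSV tables
#'
#' Tab-separated tables with a header row; column names and order are
#' preserved. A `.gz` suffix compresses/decompresses transparently.
#'
#' @param x data.frame to write.
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return `read_table()` returns a data.frame; `write_table()` returns
#'   `path` invisibly.
#' @export
write_table <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
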