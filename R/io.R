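#' Read a 2-D scalar image
#'
#' Dispatches on file extension: NIfTI (`.nii`, `.nii.gz`) via RNifti, PNG
#' via the png package (converted to greyscale on the 0-255 scale), TIFF via
#' the tiff package when available. 3-D NIfTI volumes are returned as arrays
#' and can be processed slice by slice.
#'
#' @param path Input file.
#' @return A numeric matrix (or array for 3-D NIfTI).
#' @export
read_image <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    return(img[])
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img * 255)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("read_image: the 'tiff' package is required for TIFF input",
           call. = FALSE)
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img * 255)
  }
  stop("read_image: unsupported file type: ", path, call. = FALSE)
}

#' Write a 2-D scalar image or mask
#'
#' NIfTI output stores the values as given (masks as unsigned 8-bit,
#' responses as 32-bit float); PNG output rescales `[0, 255]` to `[0, 1]`.
#'
#' @param x Numeric or logical matrix. `NA` entries are written as 0.
#' @param path Output file (`.nii`, `.nii.gz` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (is.logical(x)) {
      RNifti::writeNifti(RNifti::asNifti(x * 1L, datatype = "uint8"), path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(x, datatype = "float"), path)
    }
    return(invisible(path))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- if (is.logical(x)) x * 1 else pmin(pmax(x / 255, 0), 1)
    png::writePNG(v, path)
    return(invisible(path))
  }
  stop("write_image: unsupported file type: ", path, call. = FALSE)
}
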