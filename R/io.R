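# Image file I/O: PNG for 2D images, NIfTI-1 for 3D volumes. Readers return
# the package's channel-first tensor plus whatever is needed to write the
# result back in the source format with metadata intact.

#' Read a PNG or NIfTI image as a data tensor
#'
#' 2D PNGs become channel-first tensors (`C x H x W`, or `H x W` for
#' grayscale) with the channel axis non-eligible for shifting by default.
#' NIfTI volumes keep their native voxel grid with all axes spatial; the
#' original header/affine are retained for write-back.
#'
#' @param path Path to a `.png`, `.nii` or `.nii.gz` file.
#' @return A list with `tensor` (a `data_tensor`), `format` (`"png"` or
#'   `"nifti"`), and `reference` (format-specific write-back metadata).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    sulba_stop(paste("cannot read:", path), "io_error")
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L || is.null(dim(a))) {
      tensor <- data_tensor(a)
    } else {
      tensor <- data_tensor(aperm(a, c(3, 1, 2)),
                            c("channel", "spatial", "spatial"))
    }
    list(tensor = tensor, format = "png", reference = NULL)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim(img))
    list(tensor = data_tensor(v), format = "nifti", reference = img)
  } else {
    sulba_stop(paste("unsupported image format:", path), "io_error")
  }
}

#' Write a data tensor back to PNG or NIfTI
#'
#' The inverse of [read_image()]: channel-first PNG tensors are returned to
#' channel-last layout; NIfTI volumes are written against the original
#' header so the affine and datatype survive unchanged.
#'
#' @param tensor A `data_tensor`.
#' @param path Output file path (extension decides the format).
#' @param format `"png"` or `"nifti"`; inferred from `path` when `NULL`.
#' @param reference Write-back metadata from [read_image()] (NIfTI only).
#' @return `path`, invisibly.
#' @export
write_image <- function(tensor, path, format = NULL, reference = NULL) {
  tensor <- as_data_tensor(tensor)
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "png") "png" else "nifti"
  }
  if (format == "png") {
    v <- tensor$values
    if (length(dim(v)) == 3L) {
      v <- aperm(v, c(2, 3, 1))
    }
    png::writePNG(pmin(pmax(v, 0), 1), path)
  } else {
    out <- if (is.null(reference)) {
      RNifti::asNifti(tensor$values)
    } else {
      RNifti::asNifti(tensor$values, reference = reference)
    }
    RNifti::writeNifti(out, path)
  }
  invisible(path)
}
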