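#' Scalar image volume
#'
#' Container for a 2-D grayscale image or 3-D volume together with its pixel
#' size and a brain mask. All downstream field computations
#' ([structure_tensor()], [classify_tissue()]) start from this object.
#'
#' @param data numeric matrix (2-D) or 3-D array of intensities.
#' @param pixel_size edge length of one pixel/voxel in micrometres (um).
#' @param brain_mask logical array of the same shape as `data`; `TRUE` marks
#'   voxels inside the tissue. Defaults to all `TRUE`.
#' @return An object of class `image_volume` with elements `data`,
#'   `pixel_size` and `brain_mask`.
#' @examples
#' img <- image_volume(matrix(runif(64), 8, 8), pixel_size = 1.444)
#' @export
image_volume <- function(data, pixel_size, brain_mask = NULL) {
  if (!is.array(data) && !is.matrix(data)) stop("data must be a matrix or array")
  nd <- length(dim(data))
  if (!nd %in% 2:3) stop("data must be 2-D or 3-D")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (um per pixel)")
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim(data))
  }
  if (!identical(dim(brain_mask), dim(data))) {
    stop("brain_mask and data must have identical shapes")
  }
  storage.mode(brain_mask) <- "logical"
  structure(
    list(data = data, pixel_size = pixel_size, brain_mask = brain_mask),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s px, %.4g um/px, %.1f%% in brain mask\n",
    paste(dim(x$data), collapse = " x "), x$pixel_size, 100 * mean(x$brain_mask)
  ))
  invisible(x)
}

#' Read a scalar volume from disk
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) volumes or TIFF / PNG 2-D images into an
#' [image_volume()]. For NIfTI the pixel size defaults to the header `pixdim`.
#'
#' @param path file to read.
#' @param pixel_size um per pixel; required for TIFF/PNG, optional for NIfTI.
#' @param brain_mask optional logical array, or a path to a volume of the same
#'   geometry whose non-zero voxels define the mask.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, pixel_size = NULL, brain_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    data <- array(as.numeric(vol), dim(vol))
    if (is.null(pixel_size)) {
      pd <- RNifti::pixdim(vol)
      pixel_size <- pd[1]
    }
  } else if (grepl("\\.tiff?$", lower)) {
    data <- tiff::readTIFF(path)
    if (length(dim(data)) == 3L) data <- data[, , 1L]  # first channel
    if (is.null(pixel_size)) stop("pixel_size must be given for TIFF input")
  } else {
    stop("unsupported volume format: ", path)
  }
  if (is.character(brain_mask)) {
    brain_mask <- read_volume(brain_mask, pixel_size = pixel_size)$data > 0
  }
  image_volume(data, pixel_size = pixel_size, brain_mask = brain_mask)
}

#' Write a scalar volume or field map to disk
#'
#' Writes NIfTI for 2-D or 3-D arrays and TIFF for 2-D arrays; the format is
#' chosen from the file extension. TIFF output is rescaled to `[0, 1]` when
#' values fall outside that range (TIFF stores normalised intensities).
#'
#' @param x an [image_volume()], or a numeric/logical array.
#' @param path destination file (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param pixel_size um per pixel, stored in the NIfTI header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, pixel_size = NULL) {
  if (inherits(x, "image_volume")) {
    pixel_size <- pixel_size %||% x$pixel_size
    x <- x$data
  }
  pixel_size <- pixel_size %||% 1
  if (is.logical(x)) {
    x <- array(as.numeric(x), dim(x))
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- rep(pixel_size, length(dim(x)))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (length(dim(x)) != 2L) stop("TIFF output supports 2-D arrays only")
    rng <- range(x)
    if (rng[1] < 0 || rng[2] > 1) {
      span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
      x <- (x - rng[1]) / span
    }
    tiff::writeTIFF(x, path, bits.per.sample = 16L)
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}
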