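# Greyscale image and label-map I/O. Images: 8-bit grey PNG (intensities in
# [0,1]) or NIfTI via RNifti; label maps: grey PNG storing the raw label
# index per pixel (indexed-style), or NIfTI.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read / write a greyscale image
#'
#' PNG images are stored 8-bit (intensities quantized to 1/255); NIfTI images
#' keep float precision. Multi-channel PNGs are averaged to grey on read.
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param image `(H, W)` matrix with values in `[0, 1]`.
#' @return `read_image`: an `(H, W)` matrix; `write_image`: `path` invisibly.
#' @export
read_image <- function(path) {
  if (is_nifti_path(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    arr <- as.array(RNifti::readNifti(path))
    return(matrix(arr, nrow = dim(arr)[1]))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  if (is_nifti_path(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI output requires the RNifti package")
    RNifti::writeNifti(RNifti::asNifti(image, datatype = "float"), path)
  } else {
    png::writePNG(image, path)
  }
  invisible(path)
}

#' Read / write an integer label map
#'
#' PNG label maps store the raw label index in the 8-bit grey channel
#' (supports up to 256 labels).
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param labels `(H, W)` integer matrix of label indices.
#' @return `read_labels`: an integer matrix; `write_labels`: `path`
#'   invisibly.
#' @export
read_labels <- function(path) {
  if (is_nifti_path(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    arr <- as.array(RNifti::readNifti(path))
    lab <- matrix(as.integer(round(arr)), nrow = dim(arr)[1])
    return(lab)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 255L) stop("more than 256 labels not supported by PNG")
  if (is_nifti_path(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI output requires the RNifti package")
    RNifti::writeNifti(RNifti::asNifti(labels + 0, datatype = "int16"), path)
  } else {
    png::writePNG(labels / 255, path)
  }
  invisible(path)
}
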