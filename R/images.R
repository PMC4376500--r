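#' Read a grayscale image
#'
#' Loads a PNG or TIFF image as a numeric matrix of intensities. RGB(A) inputs
#' are converted to luminance (Rec. 601 weights); bit depth is mapped to
#' \[0, 1\] by the readers.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` file.
#' @return A numeric matrix (rows x cols) of finite intensities.
#' @export
read_gray_image <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '.", ext, "' (use PNG or TIFF)")
  )
  as_gray(img)
}

#' Coerce an image array to a grayscale matrix
#'
#' @param img Numeric matrix, or array with a trailing channel dimension
#'   (RGB or RGBA; alpha ignored).
#' @return Numeric matrix.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) {
    m <- img
  } else if (is.array(img) && length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 1L) {
      m <- img[, , 1L]
    } else {
      # luminance; ignore alpha channel if present
      m <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    }
  } else {
    stop("expected a matrix or a rows x cols x channels array")
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("image contains non-finite values")
  m
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' Values are clipped to \[0, 1\] and quantized to 8 bits.
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  m <- pmin(pmax(img, 0), 1)
  png::writePNG(m, target = path)
  invisible(path)
}

# Min-max normalize to [0, 1]; constant images map to all zeros.
# Applied before phase-congruency filtering so the descriptor is exactly
# invariant under any affine gray-scale map of the input.
normalize_unit <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

check_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix")
  }
  if (!all(is.finite(img))) stop("image contains non-finite values")
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop("image must be at least ", min_dim, "x", min_dim)
  }
  invisible(img)
}
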