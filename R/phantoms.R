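# Synthetic breast-ultrasound-like speckle phantoms. Two classes mirror the
# sonographic morphology the descriptor is meant to separate:
#   benign    - centered ellipse, smooth sharply-defined border,
#               homogeneous hypoechoic interior;
#   malignant - sinusoidally lobed ("spiculated") boundary, blurred border,
#               heterogeneous interior.
# Both are multiplied by correlated Rayleigh speckle. Everything is
# deterministic given the seed.

# periodic Gaussian blur via the frequency domain; sigma in pixels
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  u <- ifftshift_mat(matrix(freq_coords(ncol(m)), nrow(m), ncol(m), byrow = TRUE))
  v <- ifftshift_mat(matrix(freq_coords(nrow(m)), nrow(m), ncol(m)))
  h <- exp(-2 * pi^2 * sigma^2 * (u^2 + v^2))
  Re(fft(fft(m) * h, inverse = TRUE)) / length(m)
}

# correlated Rayleigh field with unit mean, drawn from the current RNG
speckle_core <- function(rows, cols, corr_length) {
  sigma <- (corr_length - 1) / 2  # corr_length = 1: uncorrelated speckle
  re <- matrix(rnorm(rows * cols), rows, cols)
  im <- matrix(rnorm(rows * cols), rows, cols)
  if (sigma > 0) {
    u <- ifftshift_mat(matrix(freq_coords(cols), rows, cols, byrow = TRUE))
    v <- ifftshift_mat(matrix(freq_coords(rows), rows, cols))
    h <- exp(-2 * pi^2 * sigma^2 * (u^2 + v^2))
    re <- Re(fft(fft(re) * h, inverse = TRUE)) / (rows * cols)
    im <- Re(fft(fft(im) * h, inverse = TRUE)) / (rows * cols)
    comp_sd <- sqrt(mean(h^2))  # Parseval: sd of each smoothed component
  } else {
    comp_sd <- 1
  }
  mag <- sqrt(re^2 + im^2)
  mag / (comp_sd * sqrt(pi / 2))  # Rayleigh mean = sigma * sqrt(pi/2)
}

#' Correlated multiplicative speckle field
#'
#' Magnitude of a smoothed complex Gaussian field: Rayleigh-distributed,
#' normalized to unit mean analytically (not empirically). `corr_length`
#' is the approximate correlation footprint in pixels; 1 gives uncorrelated
#' pixel-level speckle.
#'
#' @param rows,cols Field size in pixels.
#' @param corr_length Correlation length in pixels (>= 1).
#' @param seed Integer seed; the field is a pure function of it.
#' @return Numeric `rows` x `cols` matrix with expected value 1.
#' @export
speckle_field <- function(rows, cols, corr_length = 1.5, seed = 1L) {
  if (corr_length < 1) stop("corr_length must be >= 1")
  withr::with_seed(as.integer(seed), speckle_core(rows, cols, corr_length))
}

#' Phantom specification
#'
#' All tunables of one synthetic tumor image. Defaults encode the class
#' morphology: benign phantoms have zero boundary irregularity and interior
#' heterogeneity and a sharp border; malignant phantoms get a lobed radius,
#' a blurrier border and a smooth interior heterogeneity field.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param rows,cols Image size in pixels (ROI-scale).
#' @param seed Integer seed; fully determines the image.
#' @param bg_level,tumor_level Background / tumor mean echogenicity in
#'   \[0, 1\] (tumor hypoechoic).
#' @param edge_sigma Boundary blur sigma, pixels; `NULL` picks the class
#'   default (1.5 benign, 4 malignant).
#' @param irregularity Relative amplitude of the sinusoidal radius lobes;
#'   `NULL` picks 0 (benign) or 0.25 (malignant).
#' @param n_lobes Range of angular lobe frequencies sampled for malignant
#'   boundaries.
#' @param heterogeneity Interior heterogeneity amplitude; `NULL` picks 0
#'   (benign) or 0.15 (malignant).
#' @param het_corr Correlation length of the heterogeneity field, pixels.
#' @param speckle_corr Speckle correlation length, pixels.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(label = c("benign", "malignant"), rows = 160L,
                         cols = 220L, seed = 1L, bg_level = 0.62,
                         tumor_level = 0.32, edge_sigma = NULL,
                         irregularity = NULL, n_lobes = 3:8,
                         heterogeneity = NULL, het_corr = 8,
                         speckle_corr = 1.5) {
  label <- match.arg(label)
  malignant <- label == "malignant"
  if (is.null(edge_sigma)) edge_sigma <- if (malignant) 4 else 1.5
  if (is.null(irregularity)) irregularity <- if (malignant) 0.25 else 0
  if (is.null(heterogeneity)) heterogeneity <- if (malignant) 0.15 else 0
  if (!malignant && (irregularity != 0 || heterogeneity != 0)) {
    stop("benign phantoms must have zero irregularity and heterogeneity")
  }
  if (rows < 16 || cols < 16) stop("phantom must be at least 16x16")
  if (bg_level <= 0 || bg_level > 1 || tumor_level <= 0 || tumor_level > 1) {
    stop("echogenicity levels must lie in (0, 1]")
  }
  structure(list(label = label, rows = as.integer(rows),
                 cols = as.integer(cols), seed = as.integer(seed),
                 bg_level = bg_level, tumor_level = tumor_level,
                 edge_sigma = edge_sigma, irregularity = irregularity,
                 n_lobes = n_lobes, heterogeneity = heterogeneity,
                 het_corr = het_corr, speckle_corr = speckle_corr),
            class = "phantom_spec")
}

#' Generate one speckle phantom
#'
#' Renders the specification: a centered (possibly lobed) ellipse of
#' hypoechoic tissue inside a brighter background, border blurred by
#' `edge_sigma`, malignant interiors modulated by a smooth heterogeneity
#' field, everything multiplied by correlated Rayleigh speckle. Values are
#' not clipped (speckle highlights may exceed 1); quantization and clipping
#' happen only at 8-bit export.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix), `mask` (logical interior
#'   mask before blurring/speckle) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- spec$rows; cols <- spec$cols
  withr::with_seed(spec$seed, {
    dy <- matrix(seq_len(rows) - (rows + 1) / 2, rows, cols)
    dx <- matrix(seq_len(cols) - (cols + 1) / 2, rows, cols, byrow = TRUE)

    psi <- runif(1, 0, pi)
    a <- runif(1, 0.26, 0.34) * cols   # semi-axes, pixels
    b <- runif(1, 0.26, 0.34) * rows
    xr <- dx * cos(psi) + dy * sin(psi)
    yr <- -dx * sin(psi) + dy * cos(psi)
    rho <- sqrt((xr / a)^2 + (yr / b)^2)

    if (spec$irregularity > 0) {
      theta <- atan2(dy, dx)
      m <- sample(spec$n_lobes, 3)
      w <- runif(3); w <- w / sum(w)
      phase <- runif(3, 0, 2 * pi)
      pert <- 1 + spec$irregularity *
        (w[1] * sin(m[1] * theta + phase[1]) +
         w[2] * sin(m[2] * theta + phase[2]) +
         w[3] * sin(m[3] * theta + phase[3]))
      rho <- rho / pert
    }
    mask <- rho <= 1

    soft <- blur_gaussian(mask * 1, spec$edge_sigma)
    echo <- spec$bg_level + (spec$tumor_level - spec$bg_level) * soft

    if (spec$heterogeneity > 0) {
      h <- blur_gaussian(matrix(rnorm(rows * cols), rows, cols),
                         (spec$het_corr - 1) / 2)
      h <- h / max(sd(h), 1e-12)
      echo <- echo + spec$heterogeneity * h * soft
    }

    # no upper clip here: speckle highlights keep their tail; 8-bit
    # clipping happens only at PNG export
    spk <- speckle_core(rows, cols, spec$speckle_corr)
    img <- pmax(echo, 0.02) * spk
  })
  list(image = img, mask = mask, spec = spec)
}

#' Band of pixels around a mask boundary
#'
#' Pixels within `width` of the interior/exterior transition, found by
#' comparing dilation and erosion shifts of the mask.
#'
#' @param mask Logical matrix.
#' @param width Half-width of the band in pixels.
#' @return Logical matrix.
#' @export
boundary_band <- function(mask, width = 3L) {
  stopifnot(is.logical(mask), width >= 1)
  up <- function(m) rbind(m[-1, , drop = FALSE], m[nrow(m), ])
  dn <- function(m) rbind(m[1, ], m[-nrow(m), , drop = FALSE])
  lf <- function(m) cbind(m[, -1, drop = FALSE], m[, ncol(m)])
  rt <- function(m) cbind(m[, 1], m[, -ncol(m), drop = FALSE])
  dil <- ero <- mask
  for (k in seq_len(width)) {
    dil <- dil | up(dil) | dn(dil) | lf(dil) | rt(dil)
    ero <- ero & up(ero) & dn(ero) & lf(ero) & rt(ero)
  }
  dil & !ero
}

#' Generate a labeled phantom dataset
#'
#' Emulates a two-class ROI database: image sizes are sampled uniformly in
#' the ROI-size range, per-image seeds are derived deterministically from
#' the master seed, and each image is rendered by [make_phantom()].
#'
#' @param n_benign,n_malignant Cases per class (>= 1).
#' @param seed Master seed; the whole dataset is a pure function of it.
#' @param rows_range,cols_range Sampling ranges for the image size, pixels.
#' @param ... Further fields passed to [phantom_spec()] (same for every
#'   image, e.g. `speckle_corr`).
#' @return Tibble: `id`, `label`, `rows`, `cols`, `seed`, list columns
#'   `image` and `mask`.
#' @examples
#' ds <- phantom_dataset(3, 3, seed = 7, rows_range = c(64, 80),
#'                       cols_range = c(64, 80))
#' table(ds$label)
#' @export
phantom_dataset <- function(n_benign = 69L, n_malignant = 69L, seed = 1L,
                            rows_range = c(82L, 330L),
                            cols_range = c(104L, 473L), ...) {
  if (n_benign < 1 || n_malignant < 1) stop("need at least one case per class")
  n <- n_benign + n_malignant
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  withr::with_seed(as.integer(seed), {
    img_seeds <- sample.int(.Machine$integer.max - 1L, n)
    rows <- sample(seq(rows_range[1], rows_range[2]), n, replace = TRUE)
    cols <- sample(seq(cols_range[1], cols_range[2]), n, replace = TRUE)
  })
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- phantom_spec(label = labels[k], rows = rows[k], cols = cols[k],
                       seed = img_seeds[k], ...)
    out[[k]] <- make_phantom(sp)
  }
  tibble::tibble(
    id = sprintf("%s_%03d", substr(labels, 1, 3), seq_len(n)),
    label = labels, rows = as.integer(rows), cols = as.integer(cols),
    seed = img_seeds,
    image = lapply(out, `[[`, "image"),
    mask = lapply(out, `[[`, "mask")
  )
}

#' Write a phantom dataset to disk
#'
#' 8-bit PNGs plus a `manifest.csv` (`id,label,rows,cols,seed`) that
#' [read_image_dataset()] can load back.
#'
#' @param dataset Tibble from [phantom_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  stopifnot(is.data.frame(dataset), all(c("id", "label", "image") %in% names(dataset)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_len(nrow(dataset))) {
    write_gray_png(dataset$image[[k]], file.path(dir, paste0(dataset$id[k], ".png")))
  }
  manifest <- dataset[, intersect(c("id", "label", "rows", "cols", "seed"),
                                  names(dataset))]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load an image dataset from a manifest
#'
#' Reads `manifest.csv` (columns `id,label,...`) and the images
#' `<id>.png`/`.tif` next to it.
#'
#' @param dir Directory containing the manifest and images.
#' @return Tibble with the manifest columns plus list column `image`.
#' @export
read_image_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir)
  manifest <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  manifest$image <- lapply(manifest$id, function(id) {
    for (ext in c(".png", ".tif", ".tiff")) {
      f <- file.path(dir, paste0(id, ext))
      if (file.exists(f)) return(read_gray_image(f))
    }
    stop("image file for id '", id, "' not found in ", dir)
  })
  manifest
}
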