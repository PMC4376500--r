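# Monotone gray-scale transforms used by the robustness protocol:
# contrast improvement (linear), gamma correction and histogram
# equalization (nonlinear). All operate on [0,1]-normalized floats.

#' Contrast improvement (linear remapping)
#'
#' Affinely maps the image's value range onto `[lo, hi]`: input minimum to
#' `lo`, maximum to `hi`. Strictly monotone, so pixel ordering is preserved.
#'
#' @param image Numeric matrix; must not be constant.
#' @param lo,hi Target range (default full `[0, 1]`).
#' @return Numeric matrix.
#' @export
contrast_improve <- function(image, lo = 0, hi = 1) {
  check_gray_image(image)
  if (lo >= hi) stop("need lo < hi")
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) stop("constant image: contrast mapping undefined")
  (image - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

#' Gamma correction (power-law remapping)
#'
#' `out = in^gamma` on intensities in `[0, 1]`. `gamma < 1` brightens,
#' `gamma > 1` darkens; monotone for any `gamma > 0`.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param gamma Exponent (> 0); default 0.5.
#' @return Numeric matrix.
#' @export
gamma_correct <- function(image, gamma = 0.5) {
  check_gray_image(image)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (min(image) < 0 || max(image) > 1) {
    stop("gamma correction expects intensities in [0, 1]")
  }
  image^gamma
}

#' Histogram equalization
#'
#' Spreads the intensity distribution over the full `[0, 1]` range via the
#' empirical CDF on `bins` quantization levels; monotone non-decreasing in
#' the input value, idempotent up to quantization.
#'
#' @param image Numeric matrix with finite values.
#' @param bins Number of quantization levels (>= 2, default 256).
#' @return Numeric matrix in `[0, 1]`.
#' @export
hist_equalize <- function(image, bins = 256L) {
  check_gray_image(image)
  if (bins < 2) stop("bins must be >= 2")
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) return(image)  # single CDF step: unchanged
  q <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1)
  counts <- tabulate(q + 1L, nbins = bins)
  cdf <- cumsum(counts) / length(image)
  cdf_min <- cdf[which(counts > 0)[1]]
  lut <- (cdf - cdf_min) / (1 - cdf_min)
  if (!all(is.finite(lut))) lut <- rep(0, bins)  # all mass in one level
  matrix(lut[q + 1L], nrow(image), ncol(image))
}

#' Gray-scale transform specification
#'
#' @param kind `"identity"`, `"contrast_improve"`, `"gamma_correct"` or
#'   `"hist_equalize"`.
#' @param ... Parameters of the transform (`lo`/`hi`, `gamma`, or `bins`).
#' @return A function of one image, carrying class `transform_spec` and a
#'   `kind` attribute.
#' @export
transform_spec <- function(kind = c("identity", "contrast_improve",
                                    "gamma_correct", "hist_equalize"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  f <- switch(kind,
    identity = function(image) image,
    contrast_improve = function(image) do.call(contrast_improve, c(list(image), args)),
    # the power law acts on the display range [0, 1]: float inputs whose
    # values stray outside (speckle highlights) are clipped, exactly as
    # 8-bit storage would saturate them; no offset is subtracted, since
    # gamma correction has no black-level shift
    gamma_correct = function(image) {
      image <- pmin(pmax(image, 0), 1)
      do.call(gamma_correct, c(list(image), args))
    },
    hist_equalize = function(image) do.call(hist_equalize, c(list(image), args))
  )
  structure(f, kind = kind, params = args, class = c("transform_spec", "function"))
}

#' Apply a gray-scale transform to an image table
#'
#' @param images Data frame with list column `image` (as produced by
#'   [phantom_dataset()]), or a list of matrices.
#' @param spec A [transform_spec()].
#' @return Same shape as the input with every image transformed.
#' @export
transform_images <- function(images, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (is.data.frame(images)) {
    images$image <- lapply(images$image, spec)
    images
  } else {
    lapply(images, spec)
  }
}

#' Cross-contrast train/test evaluation
#'
#' Robustness protocol: the feature scaler and SVM are fitted only on
#' descriptors of the original images; testing uses descriptors of
#' gray-scale-transformed versions of the held-out images. Under
#' leave-one-out, iteration `i` trains on the original images minus case
#' `i` and scores case `i` from each transformed database, so the `Origin`
#' report of the identity transform is the ordinary LOO result.
#'
#' @param images Image tibble (needs `image`, `id`, `label` columns).
#' @param transforms Named list of [transform_spec()] objects; an `Origin`
#'   identity entry is prepended automatically.
#' @param params [pcbp_params()] for the descriptor.
#' @param config [svm_config()]; when `NULL` a grid search (see
#'   [grid_search_svm()]) is run once on the original-image features.
#' @param descriptor Passed to [extract_features()].
#' @param seed Seed for the grid-search fold assignment.
#' @param origin_features Optional precomputed feature table of the original
#'   images (must match `images` row for row); skips re-extraction.
#' @return An object of class `cross_contrast_eval`: list of `pcbp_eval`
#'   reports (one per database, `Origin` first), the shared `config`, and a
#'   `summary` tibble of the seven metrics per database.
#' @export
cross_contrast_experiment <- function(images, transforms = default_transforms(),
                                      params = pcbp_params(), config = NULL,
                                      descriptor = "pcbp", seed = 1L,
                                      origin_features = NULL) {
  stopifnot(is.data.frame(images), all(c("image", "label") %in% names(images)))
  if (is.null(names(transforms)) || any(!nzchar(names(transforms)))) {
    stop("`transforms` must be a named list")
  }
  origin_feats <- if (is.null(origin_features)) {
    extract_features(images, params, descriptor = descriptor)
  } else {
    stopifnot(nrow(origin_features) == nrow(images))
    origin_features
  }
  test_feats <- lapply(transforms, function(sp) {
    extract_features(transform_images(images, sp), params,
                     descriptor = descriptor)
  })
  if (is.null(config)) {
    config <- grid_search_svm(origin_feats, seed = seed)
  }
  reports <- vector("list", length(transforms) + 1L)
  names(reports) <- c("Origin", names(transforms))
  reports[["Origin"]] <- loo_cv(origin_feats, config)
  for (nm in names(transforms)) {
    reports[[nm]] <- loo_cv(origin_feats, config, test_features = test_feats[[nm]])
  }
  summary <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    dplyr::bind_cols(tibble::tibble(database = nm), glance(reports[[nm]]))
  }))
  structure(list(reports = reports, config = config, summary = summary),
            class = "cross_contrast_eval")
}

#' Default gray-scale robustness transforms
#'
#' The three databases of the robustness protocol: full-range contrast
#' improvement (CI), gamma correction with gamma 0.5 (GC) and 256-bin
#' histogram equalization (HE).
#'
#' @return Named list of [transform_spec()] objects.
#' @export
default_transforms <- function() {
  list(CI = transform_spec("contrast_improve", lo = 0, hi = 1),
       GC = transform_spec("gamma_correct", gamma = 0.5),
       HE = transform_spec("hist_equalize", bins = 256L))
}

#' @export
print.cross_contrast_eval <- function(x, ...) {
  cat("cross-contrast evaluation (train on Origin, test per database)\n")
  print(x$summary)
  invisible(x)
}
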