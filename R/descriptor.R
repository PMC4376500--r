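# The PCBP descriptor: per-orientation LBPV histograms of the oriented
# phase-congruency maps, L1-normalized per orientation block and
# concatenated. Defaults (S = 6, O = 8, P = 8, R = 1) give 10 bins x 8
# orientations = 80 features per image.

#' PCBP descriptor parameters
#'
#' Bundles every tunable of the descriptor with its default configuration:
#' six log-Gabor scales, eight orientations, and an 8-neighbor radius-1 LBP
#' on each oriented phase-congruency map.
#'
#' @param scales,orientations Log-Gabor bank size (defaults 6 and 8).
#' @param P,R LBP neighborhood (defaults 8 and 1).
#' @param lambda_min,mult,sigma_onf,theta_spread Filter geometry, see
#'   [log_gabor_bank()].
#' @param cutoff,gain,eta,epsilon Phase-congruency constants, see
#'   [oriented_pc()].
#' @param k_noise Noise-compensation strength; 0 gives exact affine
#'   gray-scale invariance.
#' @return A list of class `pcbp_params`.
#' @export
pcbp_params <- function(scales = 6L, orientations = 8L, P = 8L, R = 1,
                        lambda_min = 3, mult = 2.1, sigma_onf = 0.55,
                        theta_spread = 1.2, cutoff = 0.4, gain = 10,
                        eta = 1e-4, epsilon = 1e-4, k_noise = 2) {
  check_neighborhood(P, R)
  structure(list(scales = as.integer(scales),
                 orientations = as.integer(orientations),
                 P = as.integer(P), R = R,
                 lambda_min = lambda_min, mult = mult, sigma_onf = sigma_onf,
                 theta_spread = theta_spread, cutoff = cutoff, gain = gain,
                 eta = eta, epsilon = epsilon, k_noise = k_noise),
            class = "pcbp_params")
}

#' @export
print.pcbp_params <- function(x, ...) {
  cat("PCBP parameters: S = ", x$scales, ", O = ", x$orientations,
      ", P = ", x$P, ", R = ", x$R, ", k_noise = ", x$k_noise,
      " (", (x$P + 2) * x$orientations, " features)\n", sep = "")
  invisible(x)
}

#' Compute the PCBP descriptor of one image
#'
#' Pipeline: oriented phase congruency, then one variance-weighted riu2
#' histogram per orientation map, each L1-normalized, concatenated in
#' orientation order.
#'
#' @param image Numeric matrix (a grayscale ROI).
#' @param params A [pcbp_params()] object.
#' @param bank Optional precomputed [log_gabor_bank()] matching the image
#'   size (avoids rebuilding when many same-sized images are processed).
#' @return Numeric vector of length `(P + 2) * orientations`, names
#'   `pcbp_0 ...`; attribute `params`.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' length(compute_pcbp(img))  # 80 under defaults
#' @export
compute_pcbp <- function(image, params = pcbp_params(), bank = NULL) {
  stopifnot(inherits(params, "pcbp_params"))
  margin <- 2 * ceiling(params$R) + 1
  check_gray_image(image, min_dim = max(8L, margin))
  if (is.null(bank)) {
    bank <- log_gabor_bank(nrow(image), ncol(image),
                           scales = params$scales,
                           orientations = params$orientations,
                           lambda_min = params$lambda_min, mult = params$mult,
                           sigma_onf = params$sigma_onf,
                           theta_spread = params$theta_spread)
  }
  stack <- oriented_pc(image, bank, cutoff = params$cutoff, gain = params$gain,
                       eta = params$eta, epsilon = params$epsilon,
                       k_noise = params$k_noise)
  blocks <- lapply(stack$pc, function(map) {
    as.numeric(lbpv_histogram(map, P = params$P, R = params$R,
                              normalize = TRUE, weight = "variance"))
  })
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- paste0("pcbp_", seq_along(v) - 1)
  attr(v, "params") <- params
  v
}

#' Plain-LBP baseline descriptor
#'
#' The comparison descriptor: a count-based (not variance-weighted) riu2
#' occurrence histogram computed directly on the raw gray image with 24
#' neighbors at radius 3, normalized to sum 1 — 26 features.
#'
#' @param image Numeric matrix, at least 7x7.
#' @param P,R Neighborhood (defaults 24 and 3).
#' @return Numeric vector of length `P + 2`, names `lbp_0 ...`.
#' @export
compute_lbp_baseline <- function(image, P = 24L, R = 3) {
  check_gray_image(image, min_dim = 2L * ceiling(R) + 1L)
  h <- lbpv_histogram(image, P = P, R = R, normalize = TRUE, weight = "count")
  v <- as.numeric(h)
  names(v) <- paste0("lbp_", seq_along(v) - 1)
  v
}

#' Extract a feature table from a set of images
#'
#' Maps the descriptor over a list of images (or an image tibble from
#' [phantom_dataset()]) and returns one row per image. Any image that fails
#' aborts the extraction with its identifier; no partial table is returned.
#'
#' @param images A list of numeric matrices, or a data frame with list
#'   column `image` plus `id`/`label` columns.
#' @param params A [pcbp_params()] for `descriptor = "pcbp"`.
#' @param descriptor `"pcbp"` (default, 80 features) or `"lbp24"` (the
#'   26-feature baseline).
#' @param id,label Optional vectors overriding the identifier and class
#'   label columns.
#' @return A tibble: `id`, `label`, then `pcbp_0 ...` or `lbp_0 ...`.
#' @export
extract_features <- function(images, params = pcbp_params(),
                             descriptor = c("pcbp", "lbp24"),
                             id = NULL, label = NULL) {
  descriptor <- match.arg(descriptor)
  if (is.data.frame(images)) {
    stopifnot("image" %in% names(images))
    if (is.null(id) && "id" %in% names(images)) id <- images$id
    if (is.null(label) && "label" %in% names(images)) label <- images$label
    images <- images$image
  }
  if (!is.list(images) || length(images) == 0) {
    stop("`images` must be a non-empty list of matrices")
  }
  n <- length(images)
  if (is.null(id)) id <- sprintf("img_%03d", seq_len(n))
  if (is.null(label)) label <- rep(NA_character_, n)
  stopifnot(length(id) == n, length(label) == n)

  rows <- vector("list", n)
  for (k in seq_len(n)) {
    rows[[k]] <- tryCatch(
      switch(descriptor,
             pcbp = compute_pcbp(images[[k]], params),
             lbp24 = compute_lbp_baseline(images[[k]])),
      error = function(e) {
        stop("feature extraction failed for image '", id[k], "': ",
             conditionMessage(e), call. = FALSE)
      })
  }
  feat <- do.call(rbind, lapply(rows, as.numeric))
  colnames(feat) <- names(rows[[1]])
  dplyr::bind_cols(tibble::tibble(id = id, label = label),
                   tibble::as_tibble(feat))
}

# feature-column helper used across the evaluation functions
feature_matrix <- function(tbl) {
  cols <- setdiff(names(tbl), c("id", "label"))
  as.matrix(tbl[, cols, drop = FALSE])
}
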