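# Frequency-domain log-Gabor quadrature filter bank.
#
# Each (scale, orientation) filter is a real, non-negative transfer function:
# a Gaussian on the log-frequency axis (zero DC response by construction)
# times a Gaussian angular window around the orientation axis. Because the
# angular window covers only one half-plane, inverse-transforming the
# filtered spectrum yields a complex analytic response whose real and
# imaginary parts are the even- and odd-symmetric filter outputs.

# centered frequency coordinates in (-0.5, 0.5], Kovesi convention
freq_coords <- function(n) {
  if (n %% 2L) seq(-(n - 1) / 2, (n - 1) / 2) / (n - 1)
  else seq(-n / 2, n / 2 - 1) / n
}

# move the DC sample from the grid center to index [1,1]
ifftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((floor(nr / 2) + 1):nr, seq_len(floor(nr / 2)))
  ci <- c((floor(nc / 2) + 1):nc, seq_len(floor(nc / 2)))
  m[ri, ci]
}

#' Build a log-Gabor quadrature filter bank
#'
#' Constructs the `scales` x `orientations` frequency-domain transfer
#' functions used by [oriented_pc()]. The radial profile of scale `s` is a
#' log-Gaussian centered on frequency `1 / (lambda_min * mult^(s-1))` with
#' bandwidth set by `sigma_onf` (the ratio of the Gaussian sigma to the
#' center frequency on the log axis); a low-pass taper removes corner
#' frequencies beyond 0.45 cycles/pixel. The angular profile of orientation
#' `o` is a Gaussian in angle centered on `(o-1) * pi / orientations`, so the
#' bank spans a half-turn of directions uniformly; its sigma is the
#' orientation spacing divided by `theta_spread`.
#'
#' @param rows,cols Image dimensions in pixels (>= 8).
#' @param scales Number of wavelet scales `S` (default 6).
#' @param orientations Number of orientations `O` (default 8).
#' @param lambda_min Wavelength of the smallest-scale filter, pixels (>= 2).
#' @param mult Scaling factor between successive filter wavelengths (> 1).
#' @param sigma_onf Ratio defining the radial (log-frequency) bandwidth;
#'   0.55 gives roughly two octaves.
#' @param theta_spread Ratio of the angular filter spacing to the angular
#'   Gaussian sigma.
#' @return An object of class `log_gabor_bank`: a list with the geometry
#'   parameters and `transfer[[o]][[s]]`, each a `rows` x `cols` real
#'   non-negative matrix (DC at element \[1,1\], which is always 0).
#' @examples
#' bank <- log_gabor_bank(64, 64, scales = 4, orientations = 6)
#' bank$transfer[[1]][[1]][1, 1]  # no DC response
#' @export
log_gabor_bank <- function(rows, cols, scales = 6L, orientations = 8L,
                           lambda_min = 3, mult = 2.1, sigma_onf = 0.55,
                           theta_spread = 1.2) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 8 || cols < 8) {
    stop("rows and cols must be >= 8")
  }
  if (scales < 1 || orientations < 1) stop("scales and orientations must be >= 1")
  if (lambda_min < 2) stop("lambda_min must be >= 2 pixels")
  if (mult <= 1) stop("mult must be > 1")
  if (sigma_onf <= 0 || sigma_onf >= 1) stop("sigma_onf must be in (0, 1)")
  rows <- as.integer(rows); cols <- as.integer(cols)
  S <- as.integer(scales); O <- as.integer(orientations)

  x <- matrix(freq_coords(cols), rows, cols, byrow = TRUE)
  y <- matrix(freq_coords(rows), rows, cols)
  radius <- ifftshift_mat(sqrt(x^2 + y^2))
  radius[1, 1] <- 1  # avoid log(0); radial profile forced to 0 at DC below
  theta <- ifftshift_mat(atan2(-y, x))
  sintheta <- sin(theta)
  costheta <- cos(theta)

  lowpass <- 1 / (1 + (radius / 0.45)^(2 * 15))

  radial <- vector("list", S)
  for (s in seq_len(S)) {
    f0 <- 1 / (lambda_min * mult^(s - 1))
    lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lowpass
    lg[1, 1] <- 0
    radial[[s]] <- lg
  }

  theta_sigma <- (pi / O) / theta_spread
  transfer <- vector("list", O)
  for (o in seq_len(O)) {
    angl <- (o - 1) * pi / O
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    transfer[[o]] <- lapply(radial, function(r) r * spread)
  }

  structure(
    list(rows = rows, cols = cols, scales = S, orientations = O,
         lambda_min = lambda_min, mult = mult, sigma_onf = sigma_onf,
         theta_spread = theta_spread, transfer = transfer),
    class = "log_gabor_bank"
  )
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat("log-Gabor filter bank: ", x$scales, " scales x ", x$orientations,
      " orientations for ", x$rows, "x", x$cols, " images\n",
      "  lambda_min = ", x$lambda_min, " px, mult = ", x$mult,
      ", sigma_onf = ", x$sigma_onf, ", theta_spread = ", x$theta_spread,
      "\n", sep = "")
  invisible(x)
}

# complex analytic response for one (orientation, scale): even = Re, odd = Im
analytic_response <- function(image_fft, transfer) {
  n <- length(transfer)
  fft(image_fft * transfer, inverse = TRUE) / n
}

#' Quadrature filter responses of an image
#'
#' Filters the image with every (scale, orientation) analytic filter of the
#' bank and returns the even/odd responses, their amplitude and phase, and
#' the per-orientation maximum amplitude across scales.
#'
#' @param image Numeric matrix with dimensions matching `bank`.
#' @param bank A [log_gabor_bank()].
#' @return An object of class `quadrature_response`: lists indexed
#'   `[[orientation]][[scale]]` of matrices `even`, `odd`, `amplitude`,
#'   `phase` (in `(-pi, pi]`), plus `a_max[[orientation]]`.
#' @export
quadrature_responses <- function(image, bank) {
  check_gray_image(image)
  stopifnot(inherits(bank, "log_gabor_bank"))
  if (nrow(image) != bank$rows || ncol(image) != bank$cols) {
    stop("image is ", nrow(image), "x", ncol(image),
         " but bank was built for ", bank$rows, "x", bank$cols)
  }
  O <- bank$orientations; S <- bank$scales
  imfft <- fft(image)
  even <- odd <- amplitude <- phase <- vector("list", O)
  a_max <- vector("list", O)
  for (o in seq_len(O)) {
    even[[o]] <- odd[[o]] <- amplitude[[o]] <- phase[[o]] <- vector("list", S)
    for (s in seq_len(S)) {
      eo <- analytic_response(imfft, bank$transfer[[o]][[s]])
      e <- Re(eo); od <- Im(eo)
      even[[o]][[s]] <- e
      odd[[o]][[s]] <- od
      amplitude[[o]][[s]] <- sqrt(e^2 + od^2)
      phase[[o]][[s]] <- atan2(od, e)
    }
    a_max[[o]] <- Reduce(pmax, amplitude[[o]])
  }
  structure(
    list(even = even, odd = odd, amplitude = amplitude, phase = phase,
         a_max = a_max, scales = S, orientations = O),
    class = "quadrature_response"
  )
}
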