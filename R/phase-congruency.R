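# Oriented phase congruency from log-Gabor quadrature responses.
#
# Per orientation o the congruency at pixel (i,j) is
#
#   PC_o = W_o * max(sum_s A_{s,o} * dphi_{s,o} - T_o, 0) / (sum_s A_{s,o} + eps)
#
# where dphi = cos(phi_s - phibar) - |sin(phi_s - phibar)| is the phase
# deviation from the amplitude-weighted mean phase, W_o a sigmoid weight on
# the spread of filter responses across scales, and T_o a Rayleigh-derived
# noise floor subtracted from the orientation's total energy before the
# zeroing of negative values. PC_o is dimensionless and lies in [0, 1].

#' Filter-response spread weighting
#'
#' Computes the sigmoid weight that down-weights phase congruency where the
#' response is concentrated in few scales. The spread fraction is
#' `s_o = (sum_s A_s / (A_max + eta)) / S`, near `1/S` for a single active
#' scale and near 1 when all scales respond equally; the weight is
#' `1 / (1 + exp(gain * (cutoff - s_o)))`.
#'
#' @param amplitudes List of `S` amplitude matrices for one orientation
#'   (or a list of scalars for a single point).
#' @param cutoff Spread cut-off `c` below which congruency is penalized
#'   (default 0.4).
#' @param gain Sharpness `alpha` of the sigmoid cut-off (default 10).
#' @param eta Small positive constant guarding the division (default 1e-4).
#' @return List with `spread` (matrix in \[0, ~1\]) and `weight`
#'   (matrix in (0, 1)).
#' @export
spread_weight <- function(amplitudes, cutoff = 0.4, gain = 10, eta = 1e-4) {
  stopifnot(is.list(amplitudes), length(amplitudes) >= 1, eta > 0)
  S <- length(amplitudes)
  sum_a <- Reduce(`+`, amplitudes)
  a_max <- Reduce(pmax, amplitudes)
  spread <- (sum_a / (a_max + eta)) / S
  weight <- 1 / (1 + exp(gain * (cutoff - spread)))
  list(spread = spread, weight = weight)
}

#' Orientation-specific noise threshold
#'
#' Estimates the noise floor of the phase-congruency energy for one
#' orientation. The amplitude response of the smallest-scale filter to
#' additive Gaussian noise is Rayleigh distributed, so its median estimates
#' the noise sigma (`median / sqrt(log(4))`); the sigma is extrapolated over
#' scales by the filter bandwidth ratio and converted to the mean and
#' standard deviation of the implied Rayleigh energy distribution. The
#' threshold is `mean + k_noise * sd`, subtracted from the orientation's
#' total (scale-summed) energy before zeroing.
#'
#' @param responses A [quadrature_responses()] object, or a list with an
#'   `amplitude[[o]][[s]]` component.
#' @param o Orientation index.
#' @param k_noise Number of noise standard deviations above the mean
#'   (default 2); 0 disables compensation entirely (returns 0).
#' @param mult Wavelength scaling factor of the bank (used to extrapolate
#'   the noise amplitude across scales).
#' @return Scalar threshold `T_o >= 0` applied to the total energy.
#' @export
noise_threshold <- function(responses, o, k_noise = 2, mult = 2.1) {
  if (k_noise == 0) return(0)
  if (k_noise < 0) stop("k_noise must be >= 0")
  a1 <- responses$amplitude[[o]][[1]]
  S <- length(responses$amplitude[[o]])
  tau <- median(a1) / sqrt(log(4))
  total_tau <- tau * (1 - (1 / mult)^S) / (1 - 1 / mult)
  noise_mean <- total_tau * sqrt(pi / 2)
  noise_sd <- total_tau * sqrt((4 - pi) / 2)
  noise_mean + k_noise * noise_sd
}

#' Oriented phase-congruency maps
#'
#' Computes one phase-congruency map per orientation of the filter bank.
#' The image is min-max normalized to \[0, 1\] first, which makes the output
#' exactly invariant under any affine gray-scale map of the input. The phase
#' deviation term `A * dphi` is evaluated in the numerically stable
#' dot/cross-product form against the unit mean-phase vector, avoiding
#' arctangents where the amplitude vanishes; negative energy contributions
#' (after subtracting the noise floor) are zeroed.
#'
#' @param image Numeric matrix of finite intensities.
#' @param bank A [log_gabor_bank()] matching the image size; built on the
#'   fly from `...` defaults when `NULL`.
#' @param cutoff,gain,eta Spread-weighting parameters, see [spread_weight()].
#' @param epsilon Small positive constant guarding the energy normalization
#'   (default 1e-4).
#' @param k_noise Noise compensation strength, see [noise_threshold()];
#'   `k_noise = 0` gives the exactly contrast-invariant regime.
#' @param ... Passed to [log_gabor_bank()] when `bank` is `NULL`.
#' @return An object of class `pc_stack`: `pc` (list of `O` matrices in
#'   \[0, 1\]), `weights` (list of `O` matrices), `noise_t` (numeric `O`),
#'   and `params`.
#' @examples
#' img <- matrix(0.2, 64, 64); img[, 33:64] <- 0.8
#' stack <- oriented_pc(img, scales = 4, orientations = 6, k_noise = 0)
#' range(stack$pc[[1]])
#' @export
oriented_pc <- function(image, bank = NULL, cutoff = 0.4, gain = 10,
                        eta = 1e-4, epsilon = 1e-4, k_noise = 2, ...) {
  check_gray_image(image, min_dim = 8L)
  if (is.null(bank)) bank <- log_gabor_bank(nrow(image), ncol(image), ...)
  stopifnot(inherits(bank, "log_gabor_bank"))
  if (nrow(image) != bank$rows || ncol(image) != bank$cols) {
    stop("image is ", nrow(image), "x", ncol(image),
         " but bank was built for ", bank$rows, "x", bank$cols)
  }
  if (eta <= 0 || epsilon <= 0) stop("eta and epsilon must be > 0")

  img <- normalize_unit(image)
  imfft <- fft(img)
  O <- bank$orientations; S <- bank$scales
  pc <- weights <- vector("list", O)
  noise_t <- numeric(O)

  for (o in seq_len(O)) {
    e_list <- od_list <- a_list <- vector("list", S)
    for (s in seq_len(S)) {
      eo <- analytic_response(imfft, bank$transfer[[o]][[s]])
      e_list[[s]] <- Re(eo)
      od_list[[s]] <- Im(eo)
      a_list[[s]] <- Mod(eo)
    }
    sum_e <- Reduce(`+`, e_list)
    sum_o <- Reduce(`+`, od_list)
    sum_a <- Reduce(`+`, a_list)

    # unit mean-phase vector (phibar_o); epsilon guards zero total energy
    x_energy <- sqrt(sum_e^2 + sum_o^2) + epsilon
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy

    sw <- spread_weight(a_list, cutoff = cutoff, gain = gain, eta = eta)
    w <- sw$weight

    if (k_noise > 0) {
      resp <- list(amplitude = list(), scales = S)
      resp$amplitude[[1]] <- a_list  # only orientation slot consulted
      t_o <- noise_threshold(resp, 1L, k_noise = k_noise, mult = bank$mult)
    } else {
      t_o <- 0
    }
    noise_t[o] <- t_o

    energy <- 0
    for (s in seq_len(S)) {
      # A_s * dphi_s = e_s*cos(phibar) + o_s*sin(phibar) - |cross product|
      energy <- energy + e_list[[s]] * mean_e + od_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - od_list[[s]] * mean_e)
    }
    pc[[o]] <- w * pmax(energy - t_o, 0) / (sum_a + epsilon)
    weights[[o]] <- w
  }

  structure(
    list(pc = pc, weights = weights, noise_t = noise_t,
         params = list(cutoff = cutoff, gain = gain, eta = eta,
                       epsilon = epsilon, k_noise = k_noise,
                       scales = S, orientations = O,
                       lambda_min = bank$lambda_min, mult = bank$mult,
                       sigma_onf = bank$sigma_onf,
                       theta_spread = bank$theta_spread)),
    class = "pc_stack"
  )
}

#' Overall phase congruency
#'
#' Pointwise sum of the oriented phase-congruency maps; values lie in
#' \[0, O\]. High values mark in-phase structure (edges, ridges) at any
#' orientation.
#'
#' @param stack A `pc_stack` from [oriented_pc()].
#' @return Numeric matrix.
#' @export
overall_pc <- function(stack) {
  stopifnot(inherits(stack, "pc_stack"))
  Reduce(`+`, stack$pc)
}

#' @export
print.pc_stack <- function(x, ...) {
  d <- dim(x$pc[[1]])
  cat("oriented phase-congruency stack: ", length(x$pc), " orientations, ",
      d[1], "x", d[2], " pixels\n", sep = "")
  cat("  S = ", x$params$scales, ", k_noise = ", x$params$k_noise,
      ", max PC = ", format(max(unlist(lapply(x$pc, max))), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Write a PC stack as per-orientation PNG images
#'
#' Each map is scaled by 255, rounded, and written as an 8-bit PNG named
#' `<prefix>_o<k>.png` for inspection.
#'
#' @param stack A `pc_stack`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_pc_stack <- function(stack, dir, prefix = "pc") {
  stopifnot(inherits(stack, "pc_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(stack$pc))
  for (o in seq_along(stack$pc)) {
    paths[o] <- file.path(dir, sprintf("%s_o%d.png", prefix, o))
    write_gray_png(round(stack$pc[[o]] * 255) / 255, paths[o])
  }
  invisible(paths)
}
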