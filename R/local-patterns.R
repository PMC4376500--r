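# Rotation-invariant uniform LBP codes, local variance, and
# variance-weighted (LBPV) histograms on arbitrary 2-D maps.
#
# Neighbor p of P sits at angle 2*pi*p/P on the circle of radius R around
# the center; off-grid positions are bilinearly interpolated. The sign
# convention is s(x) = 1 for x >= 0 (ties count as "not below center").

.snap_tol <- 1e-9

snap_offset <- function(d) {
  r <- round(d)
  if (abs(d - r) < .snap_tol) r else d
}

check_neighborhood <- function(P, R) {
  if (!is.numeric(P) || P < 4 || P != round(P)) stop("P must be an integer >= 4")
  if (!is.numeric(R) || R < 1) stop("R must be >= 1")
  invisible(NULL)
}

#' Sample the circular neighborhood of one pixel
#'
#' @param map Numeric matrix.
#' @param i,j Center row/column (1-based); must be at least `R` pixels from
#'   every border.
#' @param P Number of neighbors (integer >= 4).
#' @param R Circle radius in pixels (>= 1).
#' @return Numeric vector of `P` samples; sample `p` (1-based index `p+1`)
#'   is the map at `(i - R*sin(2*pi*p/P), j + R*cos(2*pi*p/P))`, bilinearly
#'   interpolated off-grid.
#' @export
sample_neighbors <- function(map, i, j, P = 8L, R = 1) {
  check_neighborhood(P, R)
  stopifnot(is.matrix(map))
  if (i - R < 1 || i + R > nrow(map) || j - R < 1 || j + R > ncol(map)) {
    stop("center (", i, ",", j, ") lies closer than R to the border")
  }
  vapply(0:(P - 1), function(p) {
    ang <- 2 * pi * p / P
    y <- i + snap_offset(-R * sin(ang))
    x <- j + snap_offset(R * cos(ang))
    fy <- floor(y); fx <- floor(x)
    wy <- y - fy; wx <- x - fx
    if (wy == 0 && wx == 0) return(map[fy, fx])
    (1 - wy) * (1 - wx) * map[fy, fx] +
      (1 - wy) * wx * map[fy, fx + 1] +
      wy * (1 - wx) * map[fy + 1, fx] +
      wy * wx * map[fy + 1, fx + 1]
  }, numeric(1))
}

#' Initial LBP code
#'
#' Thresholds the neighbors at the center value and reads the results as a
#' binary number: `sum_p s(g_p - g_c) * 2^p` with `s(x) = 1` iff `x >= 0`.
#'
#' @param g_c Center value.
#' @param neighbors Numeric vector of `P` neighbor values.
#' @return Integer code in `[0, 2^P - 1]` (double for large `P`).
#' @export
initial_code <- function(g_c, neighbors) {
  bits <- as.numeric(neighbors >= g_c)
  sum(bits * 2^(seq_along(bits) - 1))
}

#' Uniformity of a circular bit pattern
#'
#' Counts 0/1 transitions traversing the bit sequence circularly (the
#' wrap-around pair included).
#'
#' @param bits Vector of `P` binary values (0/1 or logical).
#' @return Integer transition count `U` (always even).
#' @export
uniformity <- function(bits) {
  b <- as.numeric(bits)
  sum(abs(b - b[c(length(b), seq_len(length(b) - 1))]))
}

#' Rotation-invariant uniform (riu2) code
#'
#' Uniform patterns (`U <= 2`) map to their count of set bits; all others
#' collapse into the non-uniform bucket `P + 1`, reducing the code set from
#' `2^P` to `P + 2` values.
#'
#' @inheritParams initial_code
#' @return Integer code in `{0, ..., P + 1}`.
#' @export
riu2_code <- function(g_c, neighbors) {
  bits <- as.numeric(neighbors >= g_c)
  if (uniformity(bits) <= 2) sum(bits) else length(bits) + 1
}

#' Local variance of a neighborhood
#'
#' Population variance (1/P normalization) of the `P` neighbor samples about
#' their mean: the contrast measure complementing the riu2 code.
#'
#' @param neighbors Numeric vector of `P` values.
#' @return Non-negative scalar.
#' @export
local_variance <- function(neighbors) {
  u <- mean(neighbors)
  mean((neighbors - u)^2)
}

#' Per-pixel riu2 code and local-variance maps
#'
#' Computes the riu2 code and the local variance at every pixel with a
#' complete circular neighborhood (no padding: border pixels within
#' `ceiling(R)` of an edge are excluded via `valid_mask`).
#'
#' @param map Numeric matrix, at least `(2*ceiling(R)+1)` on each side.
#' @inheritParams sample_neighbors
#' @return An object of class `pattern_maps`: full-size matrices `riu2`
#'   (codes, `NA` outside the valid region), `var` (local variances), and
#'   logical `valid_mask`; plus `P` and `R`.
#' @export
pattern_maps <- function(map, P = 8L, R = 1) {
  check_neighborhood(P, R)
  check_gray_image(map)
  m <- as.integer(ceiling(R))
  nr <- nrow(map); nc <- ncol(map)
  if (nr < 2 * m + 1 || nc < 2 * m + 1) {
    stop("map must be at least ", 2 * m + 1, "x", 2 * m + 1, " for R = ", R)
  }
  vi <- (m + 1):(nr - m)
  vj <- (m + 1):(nc - m)
  center <- map[vi, vj]
  npx <- length(center)

  bits <- matrix(0, npx, P)
  nb_sum <- nb_sum2 <- 0
  for (p in 0:(P - 1)) {
    ang <- 2 * pi * p / P
    dy <- snap_offset(-R * sin(ang))
    dx <- snap_offset(R * cos(ang))
    fy <- floor(dy); fx <- floor(dx)
    wy <- dy - fy; wx <- dx - fx
    if (wy == 0 && wx == 0) {
      nbp <- map[vi + fy, vj + fx]
    } else {
      nbp <- (1 - wy) * (1 - wx) * map[vi + fy, vj + fx] +
        (1 - wy) * wx * map[vi + fy, vj + fx + 1] +
        wy * (1 - wx) * map[vi + fy + 1, vj + fx] +
        wy * wx * map[vi + fy + 1, vj + fx + 1]
    }
    bits[, p + 1] <- as.numeric(nbp >= center)
    nb_sum <- nb_sum + nbp
    nb_sum2 <- nb_sum2 + nbp^2
  }

  trans <- abs(bits - bits[, c(P, seq_len(P - 1)), drop = FALSE])
  u_count <- rowSums(trans)
  set_bits <- rowSums(bits)
  codes <- ifelse(u_count <= 2, set_bits, P + 1)

  u_mean <- nb_sum / P
  variance <- pmax(nb_sum2 / P - u_mean^2, 0)

  riu2 <- var_m <- matrix(NA_real_, nr, nc)
  riu2[vi, vj] <- codes
  var_m[vi, vj] <- variance
  valid <- matrix(FALSE, nr, nc)
  valid[vi, vj] <- TRUE

  structure(list(riu2 = riu2, var = var_m, valid_mask = valid,
                 P = as.integer(P), R = R),
            class = "pattern_maps")
}

#' @export
print.pattern_maps <- function(x, ...) {
  cat("pattern maps: P = ", x$P, ", R = ", x$R, ", ",
      sum(x$valid_mask), " valid pixels of ", length(x$valid_mask), "\n",
      sep = "")
  invisible(x)
}

#' Variance-weighted (LBPV) pattern histogram
#'
#' Accumulates each valid pixel's local variance (or a unit count) into the
#' bin of its riu2 code, giving a `P + 2`-bin histogram. With
#' `weight = "variance"` this is the LBPV histogram: high-contrast texture
#' contributes more mass.
#'
#' @inheritParams pattern_maps
#' @param normalize Divide by the total mass (L1); an all-zero histogram is
#'   left untouched.
#' @param weight `"variance"` (LBPV) or `"count"` (plain occurrence
#'   histogram).
#' @return Numeric vector of length `P + 2`, names `k0 ... k<P+1>`, with
#'   attributes `P`, `R`, `normalized`, `weight`.
#' @export
lbpv_histogram <- function(map, P = 8L, R = 1, normalize = TRUE,
                           weight = c("variance", "count")) {
  weight <- match.arg(weight)
  pm <- pattern_maps(map, P = P, R = R)
  codes <- pm$riu2[pm$valid_mask]
  w <- if (weight == "variance") pm$var[pm$valid_mask] else rep(1, length(codes))
  bins <- vapply(0:(P + 1), function(k) sum(w[codes == k]), numeric(1))
  if (normalize) {
    total <- sum(bins)
    if (total > 0) bins <- bins / total
  }
  names(bins) <- paste0("k", 0:(P + 1))
  structure(bins, P = as.integer(P), R = R, normalized = normalize,
            weight = weight)
}
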