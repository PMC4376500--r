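# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# riu2 coding oracle: minimum over all circular rotations, then the
# uniform/non-uniform bucketing, from first principles on a bit vector.
oracle_riu2 <- function(bits) {
  P <- length(bits)
  rotations <- vapply(0:(P - 1), function(r) {
    b <- bits[((seq_len(P) - 1 + r) %% P) + 1]
    sum(b * 2^(seq_len(P) - 1))
  }, numeric(1))
  min_rot <- min(rotations)
  b <- as.integer(intToBits(min_rot))[seq_len(P)]
  transitions <- sum(b != b[c(P, seq_len(P - 1))])
  if (transitions <= 2) sum(b) else P + 1
}

# integer -> P-bit vector (bit p = weight 2^p)
int_to_bits <- function(x, P) as.integer(intToBits(x))[seq_len(P)]

# pairwise concordance AUC with ties counted one half, O(n^2)
oracle_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# direct circular (periodic) convolution of an image with a complex kernel
oracle_circ_conv <- function(img, h) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0 + 0i, n1, n2)
  for (i in seq_len(n1)) {
    ridx <- ((i - seq_len(n1)) %% n1) + 1
    for (j in seq_len(n2)) {
      cidx <- ((j - seq_len(n2)) %% n2) + 1
      out[i, j] <- sum(img * h[ridx, cidx])
    }
  }
  out
}

# closed-form log-Gabor radial profile (the formula, independent of the
# bank construction code)
oracle_log_gabor_radial <- function(f, f0, sigma_onf) {
  ifelse(f > 0, exp(-(log(f / f0))^2 / (2 * log(sigma_onf)^2)), 0)
}
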