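test_that("spread weighting matches hand-evaluated sigmoid values", {
  zero <- matrix(0, 4, 4)
  one <- matrix(1, 4, 4)
  # all response in a single scale of six: s_o ~ 1/6, W ~ 0.088
  sw <- spread_weight(c(list(one), rep(list(zero), 5)))
  expect_equal(sw$weight[1, 1], 1 / (1 + exp(10 * (0.4 - 1 / 6))),
               tolerance = 1e-3)
  # equal response at all six scales: s_o ~ 1, W ~ 0.998
  sw <- spread_weight(rep(list(one), 6))
  expect_equal(sw$weight[1, 1], 1 / (1 + exp(-6)), tolerance = 1e-3)
  # zero amplitude: s_o = 0, W = 1/(1 + e^(alpha c))
  sw <- spread_weight(rep(list(zero), 6))
  expect_equal(sw$weight[1, 1], 1 / (1 + exp(10 * 0.4)), tolerance = 1e-12)
  expect_equal(sw$spread[1, 1], 0)
})

test_that("noise threshold: disabled at k = 0, homogeneous of degree one", {
  set.seed(21)
  img <- matrix(rnorm(64 * 64), 64, 64)
  bank <- log_gabor_bank(64, 64, scales = 4, orientations = 4)
  resp <- quadrature_responses(img, bank)
  expect_identical(noise_threshold(resp, 1, k_noise = 0), 0)
  t1 <- noise_threshold(resp, 2, k_noise = 2, mult = bank$mult)
  resp3 <- quadrature_responses(3 * img, bank)
  t3 <- noise_threshold(resp3, 2, k_noise = 2, mult = bank$mult)
  expect_gt(t1, 0)
  expect_equal(t3, 3 * t1, tolerance = 1e-10)
})

test_that("noise compensation silences pure white-noise images", {
  set.seed(31)
  for (rep in 1:2) {
    img <- matrix(rnorm(96 * 96), 96, 96)
    stack <- oriented_pc(img, k_noise = 2)
    expect_gt(mean(unlist(stack$pc) <= 0.01), 0.95)
  }
})

test_that("oriented PC is zero on constant images and bounded in [0, 1]", {
  stack <- oriented_pc(matrix(0.4, 48, 48), scales = 3, orientations = 4)
  expect_true(all(unlist(stack$pc) == 0))
  expect_equal(length(stack$pc), 4)

  set.seed(8)
  imgs <- list(matrix(runif(64 * 80), 64, 80),
               small_phantom("benign", seed = 12)$image,
               small_phantom("malignant", seed = 13)$image)
  for (img in imgs) {
    stack <- oriented_pc(img)
    v <- unlist(stack$pc)
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
  }
})

test_that("a vertical step edge localizes at the edge column", {
  img <- matrix(0.2, 64, 64); img[, 33:64] <- 0.8
  stack <- oriented_pc(img, scales = 4, orientations = 6, k_noise = 0)
  # channel 1 is tuned to horizontal spatial frequency (vertical structure);
  # ignore the periodic wrap-around edge at the image border
  pc <- stack$pc[[1]][, 8:56]
  argmax <- apply(pc, 1, which.max) + 7
  expect_true(all(abs(argmax - 32.5) <= 1))
})

test_that("PC maps are invariant to affine gray-scale changes", {
  img <- small_phantom("malignant", seed = 14)$image
  ref <- oriented_pc(img, k_noise = 0)
  set.seed(9)
  for (k in 1:3) {
    a <- runif(1, 0.2, 3); b <- runif(1, -0.5, 0.5)
    alt <- oriented_pc(a * img + b, k_noise = 0)
    expect_lt(max(abs(unlist(ref$pc) - unlist(alt$pc))), 1e-6)
  }
})

test_that("rotating a stripe pattern by pi/O permutes the dominant channel", {
  n <- 96; O <- 6
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  bank <- log_gabor_bank(n, n, scales = 3, orientations = O)
  dominant <- function(phi) {
    img <- sin(2 * pi * (cos(phi) * xs + sin(phi) * ys) / 8)
    resp <- quadrature_responses(img, bank)
    which.max(vapply(seq_len(O), function(o) {
      sum(unlist(lapply(resp$amplitude[[o]], sum)))
    }, numeric(1)))
  }
  base <- vapply((0:(O - 1)) * pi / O, dominant, integer(1))
  rotated <- vapply((0:(O - 1)) * pi / O + pi / O, dominant, integer(1))
  expect_equal(sort(base), 1:O)          # each stripe angle owns one channel
  expect_equal(rotated, base[c(2:O, 1)]) # quarter-step rotation permutes them
})

test_that("overall PC sums orientations and highlights the phantom boundary", {
  ph <- small_phantom("benign", seed = 16, rows = 128, cols = 160)
  stack <- oriented_pc(ph$image)
  total <- overall_pc(stack)
  expect_equal(total, Reduce(`+`, stack$pc))
  expect_lte(max(total), length(stack$pc))
  band <- boundary_band(ph$mask, 4)
  expect_gt(mean(total[band]), mean(total[!band]))
})
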