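test_that("circular sampling: exact on-grid values, bilinear off-grid", {
  const <- matrix(3.7, 9, 9)
  expect_equal(sample_neighbors(const, 5, 5, P = 8, R = 1), rep(3.7, 8))

  set.seed(2)
  m <- matrix(rnorm(81), 9, 9)
  # P = 4, R = 1: the four axial pixels, no interpolation
  expect_identical(sample_neighbors(m, 5, 5, P = 4, R = 1),
                   c(m[5, 6], m[4, 5], m[5, 4], m[6, 5]))
  # bilinear interpolation reproduces a plane exactly (diagonal samples)
  plane <- outer(1:9, 1:9, function(i, j) 2 * i - 3 * j + 1)
  got <- sample_neighbors(plane, 5, 5, P = 8, R = 1)
  ang <- 2 * pi * (0:7) / 8
  expect_equal(got, 2 * (5 - sin(ang)) - 3 * (5 + cos(ang)) + 1,
               tolerance = 1e-12)
  expect_error(sample_neighbors(m, 1, 5, P = 8, R = 1), "border")
})

test_that("initial code packs threshold bits as powers of two", {
  expect_equal(initial_code(1, rep(2, 8)), 255)
  expect_equal(initial_code(5, rep(4, 8)), 0)
  expect_equal(initial_code(5, c(6, 4, 4, 4, 6, 4, 4, 4)), 17)
  expect_equal(initial_code(5, rep(5, 4)), 15)  # ties count as >= center
})

test_that("uniformity counts circular transitions including the wrap", {
  expect_equal(uniformity(rep(0, 8)), 0)
  expect_equal(uniformity(c(0, 0, 0, 0, 1, 1, 1, 1)), 2)
  expect_equal(uniformity(c(0, 1, 0, 1, 0, 1, 0, 1)), 8)
  expect_equal(uniformity(c(1, 0, 0, 0, 0, 0, 0, 1)), 2)  # wrap joins the run
})

test_that("riu2 coding matches the exhaustive min-rotation oracle (P = 8)", {
  codes <- integer(256)
  for (pattern in 0:255) {
    bits <- int_to_bits(pattern, 8)
    neighbors <- ifelse(bits == 1, 2, 0)  # center 1: bit = (neighbor >= 1)
    codes[pattern + 1] <- riu2_code(1, neighbors)
    expect_equal(codes[pattern + 1], oracle_riu2(bits))
    # rotation invariance: every circular rotation gives the same code
    rot <- bits[c(4:8, 1:3)]
    expect_equal(riu2_code(1, ifelse(rot == 1, 2, 0)), codes[pattern + 1])
  }
  expect_equal(sort(unique(codes)), 0:9)  # exactly P + 2 = 10 distinct codes
})

test_that("riu2 code set has P + 2 members for P = 24", {
  # uniform patterns: one circular run of c ones (any rotation shares a code)
  codes <- vapply(0:24, function(c) {
    bits <- c(rep(1, c), rep(0, 24 - c))
    riu2_code(1, ifelse(bits == 1, 2, 0))
  }, numeric(1))
  expect_equal(codes, 0:24)
  alternating <- rep(c(1, 0), 12)
  expect_equal(riu2_code(1, ifelse(alternating == 1, 2, 0)), 25)
})

test_that("riu2 maps are invariant under monotone intensity transforms", {
  set.seed(5)
  m <- matrix(runif(30 * 40), 30, 40)
  # integer-offset neighborhoods: exact under any strictly increasing map
  base4 <- pattern_maps(m, P = 4, R = 1)
  for (f in list(function(x) x^3, function(x) exp(2 * x), function(x) 5 * x - 1)) {
    expect_identical(pattern_maps(f(m), P = 4, R = 1)$riu2, base4$riu2)
  }
  # interpolated neighborhoods commute exactly with affine maps only
  # (interpolation is linear); nonlinear maps perturb few borderline codes
  base8 <- pattern_maps(m, P = 8, R = 1)
  expect_identical(pattern_maps(5 * m - 1, P = 8, R = 1)$riu2, base8$riu2)
  # cubing pure uniform noise is close to a worst case: many interpolated
  # comparisons sit near the center value, yet most codes survive
  cube <- pattern_maps(m^3, P = 8, R = 1)
  agree <- mean(cube$riu2[cube$valid_mask] == base8$riu2[base8$valid_mask])
  expect_gt(agree, 0.75)
})

test_that("local variance is the population variance and scales quadratically", {
  expect_equal(local_variance(rep(2, 8)), 0)
  expect_equal(local_variance(c(0, 0, 0, 0, 1, 1, 1, 1)), 0.25)
  x <- c(0.1, 0.9, 0.4, 0.2, 0.7, 0.3, 0.5, 0.6)
  expect_equal(local_variance(3 * x), 9 * local_variance(x))
  expect_equal(local_variance(x), mean((x - mean(x))^2))
})

test_that("pattern maps agree with per-pixel scalar evaluation", {
  set.seed(13)
  m <- matrix(runif(15 * 17), 15, 17)
  pm <- pattern_maps(m, P = 8, R = 1)
  expect_equal(dim(pm$riu2), dim(m))
  expect_false(any(pm$valid_mask[1, ]) || any(pm$valid_mask[, 1]))
  for (i in c(2, 7, 14)) {
    for (j in c(2, 9, 16)) {
      nb <- sample_neighbors(m, i, j, P = 8, R = 1)
      expect_equal(pm$riu2[i, j], riu2_code(m[i, j], nb))
      expect_equal(pm$var[i, j], local_variance(nb), tolerance = 1e-12)
    }
  }
  expect_true(all(pm$riu2[pm$valid_mask] <= 9))
  expect_true(all(pm$var[pm$valid_mask] >= 0))
})

test_that("LBPV histograms conserve variance mass and normalize to one", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 24), 20, 24)
    h <- lbpv_histogram(m, P = 8, R = 1, normalize = FALSE)
    expect_length(h, 10)
    pm <- pattern_maps(m, P = 8, R = 1)
    expect_equal(sum(h), sum(pm$var[pm$valid_mask]), tolerance = 1e-10)
    hn <- lbpv_histogram(m, P = 8, R = 1, normalize = TRUE)
    expect_equal(sum(hn), 1)
  }
  expect_true(all(lbpv_histogram(matrix(1, 10, 10), P = 8, R = 1) == 0))
  expect_error(lbpv_histogram(matrix(0, 2, 2), P = 8, R = 1), "at least")
})
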