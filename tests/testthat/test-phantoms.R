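test_that("phantoms are bit-reproducible from their seed", {
  sp <- phantom_spec("malignant", rows = 90, cols = 110, seed = 12345)
  a <- make_phantom(sp); b <- make_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- make_phantom(phantom_spec("malignant", rows = 90, cols = 110, seed = 12346))
  expect_false(identical(a$image, c$image))
})

test_that("phantom interior carries the specified hypoechoic contrast", {
  diffs <- vapply(1:4, function(k) {
    ph <- make_phantom(phantom_spec("benign", rows = 160, cols = 200, seed = 600 + k))
    core <- ph$mask & !boundary_band(ph$mask, 6)   # away from the blurred rim
    outside <- !ph$mask & !boundary_band(ph$mask, 6)
    mean(ph$image[outside]) - mean(ph$image[core])
  }, numeric(1))
  expected <- 0.62 - 0.32
  expect_true(all(abs(diffs - expected) / expected < 0.1))
})

test_that("malignant borders are blurrier than benign at equal contrast", {
  # average speckle out with a 5x5 box mean before measuring edge slope
  box5 <- function(g) {
    cs <- function(m) {
      out <- m
      for (k in 1:2) out <- out + rbind(m[-(1:k), , drop = FALSE],
                                        m[rep(nrow(m), k), ]) +
          rbind(m[rep(1, k), ], m[seq_len(nrow(m) - k), , drop = FALSE])
      out
    }
    t(cs(t(cs(g)))) / 25
  }
  grad_energy <- function(ph) {
    g <- box5(ph$image)
    gx <- g[, -1] - g[, -ncol(g)]
    gy <- g[-1, ] - g[-nrow(g), ]
    gm <- sqrt(gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2)
    band <- boundary_band(ph$mask, 2)[-nrow(g), -ncol(g)]
    mean(gm[band])
  }
  res <- vapply(1:3, function(k) {
    ben <- make_phantom(phantom_spec("benign", 140, 170, seed = 700 + k))
    mal <- make_phantom(phantom_spec("malignant", 140, 170, seed = 700 + k))
    grad_energy(mal) < grad_energy(ben)
  }, logical(1))
  expect_true(all(res))
})

test_that("malignant phantoms disperse phase-congruency mass off the boundary", {
  off_boundary_mass <- function(ph) {
    total <- overall_pc(oriented_pc(ph$image))
    band <- boundary_band(ph$mask, 5)
    1 - sum(total[band]) / sum(total)
  }
  pairs <- vapply(1:3, function(k) {
    ben <- make_phantom(phantom_spec("benign", 128, 150, seed = 800 + k))
    mal <- make_phantom(phantom_spec("malignant", 128, 150, seed = 800 + k))
    off_boundary_mass(mal) - off_boundary_mass(ben)
  }, numeric(1))
  expect_gt(mean(pairs), 0)
})

test_that("speckle field: unit mean, Rayleigh shape, short-range correlation", {
  sp <- speckle_field(320, 320, corr_length = 1.5, seed = 31)
  expect_lt(abs(mean(sp) - 1), 0.02)

  raw <- speckle_field(320, 320, corr_length = 1, seed = 37)  # unsmoothed
  # Rayleigh coefficient of variation: sqrt((4 - pi) / pi) ~ 0.5227
  expect_lt(abs(sd(raw) / mean(raw) - sqrt((4 - pi) / pi)), 0.02)
  adj <- cor(as.vector(raw[, -1]), as.vector(raw[, -ncol(raw)]))
  expect_lt(abs(adj), 0.1)
  expect_error(speckle_field(50, 50, corr_length = 0.5), "corr_length")
})

test_that("dataset generation is deterministic with labeled, sized manifest rows", {
  ds <- phantom_dataset(4, 5, seed = 77, rows_range = c(82, 120),
                        cols_range = c(104, 140))
  expect_equal(nrow(ds), 9)
  expect_equal(sum(ds$label == "benign"), 4)
  expect_true(all(ds$rows >= 82 & ds$rows <= 120))
  ds2 <- phantom_dataset(4, 5, seed = 77, rows_range = c(82, 120),
                         cols_range = c(104, 140))
  expect_identical(ds$image, ds2$image)
  ds3 <- phantom_dataset(4, 5, seed = 78, rows_range = c(82, 120),
                         cols_range = c(104, 140))
  expect_false(identical(ds$image, ds3$image))
})

test_that("datasets round-trip through PNG files and a manifest", {
  dir <- withr::local_tempdir()
  ds <- phantom_dataset(2, 2, seed = 88, rows_range = c(82, 90),
                        cols_range = c(104, 110))
  write_image_dataset(ds, dir)
  back <- read_image_dataset(dir)
  expect_equal(back$id, ds$id)
  expect_equal(back$label, ds$label)
  # 8-bit export clips speckle highlights to 1 and quantizes to 256 levels
  for (k in 1:4) {
    clipped <- pmin(pmax(ds$image[[k]], 0), 1)
    expect_lt(max(abs(back$image[[k]] - clipped)), 0.5 / 255 + 1e-9)
  }
})
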