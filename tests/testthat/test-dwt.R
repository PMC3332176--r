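test_that("a constant image under orthonormal Haar scales by 2 with zero details", {
  d <- dwt2(matrix(100, 8, 8), "haar", 1)
  sc <- d$scales[[1]]
  expect_equal(sc$A, matrix(200, 4, 4))
  expect_equal(sc$Dh, matrix(0, 4, 4))
  expect_equal(sc$Dv, matrix(0, 4, 4))
  expect_equal(sc$Dd, matrix(0, 4, 4))
})

test_that("round trips reconstruct the input for every built-in family", {
  set.seed(11)
  x16 <- matrix(runif(16 * 16, 0, 255), 16, 16)
  expect_lt(max(abs(idwt2(dwt2(x16, "db4", 1)) - x16)), 1e-8)
  ramp <- matrix(seq(0, 255, length.out = 32 * 32), 32, 32)
  expect_lt(max(abs(idwt2(dwt2(ramp, "bior6.8", 1)) - ramp)), 1e-6)
  bin <- matrix(sample(c(0, 1), 16 * 16, TRUE) * 255, 16, 16)
  expect_lt(max(abs(idwt2(dwt2(bin, "haar", 1)) - bin)), 1e-10)
  x32 <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_lt(max(abs(idwt2(dwt2(x32, "coif3", 1)) - x32)), 1e-8)
  # deeper pyramid and periodic boundary
  expect_lt(max(abs(idwt2(dwt2(x32, "db4", 2)) - x32)), 1e-8)
  expect_lt(max(abs(idwt2(dwt2(x32, "db4", 2, "periodic")) - x32)), 1e-8)
})

test_that("all-zero subbands invert to an all-zero image", {
  d <- dwt2(matrix(0, 8, 8), "db4", 1)
  expect_equal(idwt2(d), matrix(0, 8, 8))
})

test_that("orthonormal analysis conserves energy under periodization", {
  set.seed(12)
  x <- matrix(runif(16 * 16, 0, 255), 16, 16)
  for (fam in c("haar", "db4")) {
    sc <- dwt2(x, fam, 1, "periodic")$scales[[1]]
    e <- sum(sc$A^2 + sc$Dh^2 + sc$Dv^2 + sc$Dd^2)
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
})

test_that("an inadmissible scale count errors naming the maximal J", {
  expect_error(dwt2(matrix(0, 16, 16), "bior6.8", 1), "maximal admissible J is 0")
  expect_error(dwt2(matrix(0, 8, 8), "haar", 9), "maximal admissible J is 3")
  # periodization halves exactly, so an 18-tap bank admits one scale at 32
  expect_identical(dwt_max_levels(c(32, 32), "bior6.8", "periodic"), 1L)
  expect_gte(dwt_max_levels(c(32, 32), "bior6.8", "symmetric"), 1L)
})

test_that("shape-inconsistent subbands are rejected on reconstruction", {
  d <- dwt2(matrix(runif(64), 8, 8), "haar", 1)
  d$scales[[1]]$Dh <- matrix(0, 3, 4)
  expect_error(idwt2(d), "shape-inconsistent")
})

test_that("magnitude and phase follow the printed form and its sign branches", {
  mp <- magnitude_phase(matrix(3), matrix(4), matrix(0))
  expect_equal(mp$magnitude[1, 1], 25)          # sum of squares, no sqrt
  expect_equal(mp$phase[1, 1], atan(4 / 3))
  expect_equal(magnitude_phase(matrix(1), matrix(1), matrix(0))$phase[1, 1],
               pi / 4)
  # Dh < 0 branch: theta = pi - alpha
  expect_equal(magnitude_phase(matrix(-1), matrix(1), matrix(0))$phase[1, 1],
               5 * pi / 4)
  # optional Euclidean-norm magnitude
  expect_equal(magnitude_phase(matrix(3), matrix(4), matrix(0),
                               sqrt_magnitude = TRUE)$magnitude[1, 1], 5)
  expect_error(magnitude_phase(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 2)),
               "share one shape")
})

test_that("magnitude ignores the diagonal detail's sign and phase handles Dh = 0", {
  set.seed(13)
  Dh <- matrix(rnorm(16), 4); Dv <- matrix(rnorm(16), 4); Dd <- matrix(rnorm(16), 4)
  expect_equal(magnitude_phase(Dh, Dv, Dd)$magnitude,
               magnitude_phase(Dh, Dv, -Dd)$magnitude)
  mp <- magnitude_phase(matrix(0), matrix(2), matrix(1))
  expect_equal(mp$phase[1, 1], pi / 2)
  expect_equal(magnitude_phase(matrix(0), matrix(-2), matrix(1))$phase[1, 1],
               3 * pi / 2)
  expect_equal(magnitude_phase(matrix(0), matrix(0), matrix(1))$phase[1, 1], 0)
  th <- magnitude_phase(Dh, Dv, Dd)$phase
  expect_true(all(th >= 0 & th < 2 * pi))
})

test_that("feature images keep shape, range, and known closed forms", {
  cst <- matrix(100, 8, 8)
  expect_equal(feature_image(cst, "haar", 1, "approximation"), matrix(200, 8, 8))
  expect_equal(feature_image(cst, "haar", 1, "magnitude"), matrix(0, 8, 8))
  # 2x2-block-constant image under Haar: blocks of the block means, rescaled
  blk <- matrix(0, 4, 4)
  blk[1:2, 1:2] <- 10; blk[1:2, 3:4] <- 60; blk[3:4, 1:2] <- 110; blk[3:4, 3:4] <- 200
  got <- feature_image(blk, "haar", 1, "approximation")
  expect_equal(got, (blk - 10) * 255 / 190, tolerance = 1e-10)
  set.seed(14)
  x <- matrix(runif(32 * 32, 0, 255), 32, 32)
  f <- feature_image(x, "db4", 1)
  expect_identical(dim(f), dim(x))
  expect_true(all(f >= 0 & f <= 255))
})

test_that("two-region structure survives the approximation feature", {
  img <- two_level_image()$image[, , 1]
  gt <- two_level_image()$gt
  f <- feature_image(img, "db4", 1)
  wvar <- stats::var(f[gt == 1]) + stats::var(f[gt == 0])
  bvar <- (mean(f[gt == 1]) - mean(f[gt == 0]))^2
  expect_lt(wvar, bvar)
})

test_that("nearest-neighbor resampling replicates, is identity at scale 1, and adds no values", {
  m <- matrix(1:4, 2, 2)
  up <- nni_resample(m, c(4, 4))
  expect_equal(up, m[c(1, 1, 2, 2), c(1, 1, 2, 2)])
  expect_equal(nni_resample(m, c(2, 2)), m)
  set.seed(15)
  lab <- matrix(sample(1:3, 25, TRUE), 5, 5)
  expect_true(all(nni_resample(lab, c(9, 7)) %in% lab))
})
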