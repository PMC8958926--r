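test_that("structure tensor of trivial images is analytic", {
  # constant image: zero gradients, zero tensors, zero eigenvalues
  img <- image_volume(matrix(3.7, 12, 12), pixel_size = 1)
  tf <- structure_tensor(img, smoothing_sigma = 0)
  expect_true(all(tf$eigenvalues == 0))

  # pure ramp I(x, y) = x: gradient (1, 0), tensor [[1,0],[0,0]] away from
  # the replicated edges, principal eigenvector (1, 0), lambda2 = 0
  ramp <- image_volume(matrix(seq_len(16), 16, 16), pixel_size = 1)
  tf <- structure_tensor(ramp, smoothing_sigma = 0)
  interior <- 2:15
  expect_equal(max(abs(tf$eigenvalues[interior, interior, 1] - 1)), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(tf$eigenvalues[interior, interior, 2])), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(abs(tf$principal_evec[interior, interior, 1]) - 1)), 0,
               tolerance = 1e-12)
})

test_that("2-D eigen-system matches base eigen() on a random image", {
  set.seed(42)
  img <- image_volume(matrix(runif(64), 8, 8), pixel_size = 1)
  tf <- structure_tensor(img, smoothing_sigma = 0)
  for (i in 1:8) for (j in 1:8) {
    m <- matrix(c(tf$tensors[i, j, 1], tf$tensors[i, j, 2],
                  tf$tensors[i, j, 2], tf$tensors[i, j, 3]), 2, 2)
    ref <- eigen(m, symmetric = TRUE)
    expect_lt(max(abs(tf$eigenvalues[i, j, ] - ref$values)), 1e-10)
    if (ref$values[1] - ref$values[2] > 1e-8) {
      agree <- abs(sum(tf$principal_evec[i, j, ] * ref$vectors[, 1]))
      expect_gt(agree, 1 - 1e-10)
    }
  }
})

test_that("3-D eigen-system matches base eigen() on a random volume", {
  set.seed(7)
  img <- image_volume(array(runif(6 * 6 * 5), c(6, 6, 5)), pixel_size = 1)
  tf <- structure_tensor(img, smoothing_sigma = 1)
  comp <- tf$tensors
  worst <- 0
  for (i in 1:6) for (j in 1:6) for (k in 1:5) {
    v <- comp[i, j, k, ]
    m <- matrix(c(v[1], v[2], v[3],
                  v[2], v[4], v[5],
                  v[3], v[5], v[6]), 3, 3)
    ref <- eigen(m, symmetric = TRUE)
    worst <- max(worst, max(abs(tf$eigenvalues[i, j, k, ] - ref$values)))
    if (ref$values[1] - ref$values[2] > 1e-6 * max(abs(ref$values), 1)) {
      agree <- abs(sum(tf$principal_evec[i, j, k, ] * ref$vectors[, 1]))
      expect_gt(agree, 1 - 1e-6)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("principal eigenvector follows a rotated ramp gradient", {
  n <- 24
  for (theta in c(0.3, 1.1, 2.4)) {
    x <- matrix(seq_len(n), n, n)
    y <- matrix(seq_len(n), n, n, byrow = TRUE)
    img <- image_volume(cos(theta) * x + sin(theta) * y, pixel_size = 1)
    tf <- structure_tensor(img, smoothing_sigma = 0)
    ev <- tf$principal_evec[n / 2, n / 2, ]
    expect_gt(abs(sum(ev * c(cos(theta), sin(theta)))), 1 - 1e-6)
  }
})

test_that("coherence and fractional anisotropy match hand evaluations", {
  expect_equal(coherence_2d(1, 1), 0)
  expect_equal(coherence_2d(1, 0), 1)
  expect_equal(coherence_2d(3, 1), 0.25)
  expect_message(z <- coherence_2d(0, 0), "zero")
  expect_equal(z, 0)

  expect_equal(fractional_anisotropy(1, 1, 1), 0)
  expect_equal(fractional_anisotropy(1, 0, 0), 1)
  expect_equal(fractional_anisotropy(2, 1, 1), sqrt(1 / 6), tolerance = 1e-12)
  expect_message(z <- fractional_anisotropy(0, 0, 0), "zero")
  expect_equal(z, 0)

  expect_error(coherence_2d(1, 2), "eigenvalues")
  expect_error(fractional_anisotropy(1, 2, 0), "eigenvalues")
})

test_that("anisotropy measures stay in [0, 1] and FA is scale-invariant", {
  set.seed(11)
  for (rep in 1:200) {
    lam <- sort(runif(3, 0, 10), decreasing = TRUE)
    co <- coherence_2d(lam[1], lam[2])
    fa <- fractional_anisotropy(lam[1], lam[2], lam[3])
    expect_true(co >= 0 && co <= 1)
    expect_true(fa >= 0 && fa <= 1)
    expect_equal(fa, fractional_anisotropy(7.3 * lam[1], 7.3 * lam[2],
                                           7.3 * lam[3]), tolerance = 1e-12)
  }
})

test_that("orientation angle follows the stated convention", {
  expect_equal(angle_2d(c(1, 0)), 0)
  expect_equal(angle_2d(c(0, 1)), pi)   # e_x = 0 maps to pi
  expect_equal(angle_2d(c(1, 1) / sqrt(2)), pi / 4)
  expect_error(angle_2d(c(0, 0)), "zero")
})

test_that("tissue classification thresholds anisotropy inclusively", {
  # coherence of (3, 1) is exactly 0.25; threshold 0.25 must classify white
  tens <- array(0, c(2, 2, 3))
  tens[, , 1] <- 3   # xx
  tens[, , 3] <- 1   # yy: eigenvalues (3, 1) everywhere
  tis <- classify_tissue(tensor_field(tens), epsilon_M = 0.25)
  expect_true(all(tis$wm_mask))
  tis2 <- classify_tissue(tensor_field(tens), epsilon_M = 0.251)
  expect_false(any(tis2$wm_mask))
  expect_equal(tis$direction[1, 1, ], c(1, 0))

  # tissue_field applies the same inclusive rule to raw anisotropy values
  tf <- tissue_field(array(c(0.4, 0.39), c(2, 1)),
                     array(rep(c(1, 0), each = 2), c(2, 1, 2)),
                     epsilon_M = 0.4)
  expect_identical(as.vector(tf$wm_mask), c(TRUE, FALSE))
})

test_that("a uniform-intensity phantom has an empty white-matter mask", {
  spec <- phantom_spec(c(48, 48), "uniform_grey")
  img <- make_phantom(spec)
  tis <- classify_tissue(structure_tensor(img, 2), epsilon_M = 0.4)
  expect_false(any(tis$wm_mask))
  expect_equal(max(tis$anisotropy), 0)
})

test_that("field sampling uses nearest-voxel lookup with half-up rounding", {
  tis <- strip_tissue(c(20, 20), y0 = 10, y1 = 10)
  # exact voxel centre
  s <- sample_field_at(tis, c(5, 10))
  expect_true(s$is_white && s$in_brain)
  expect_equal(s$direction[1, ], c(1, 0))
  # (i + 0.4, j) rounds to voxel i
  expect_true(sample_field_at(tis, c(5.4, 10))$is_white)
  expect_false(sample_field_at(tis, c(5.6, 10.6))$is_white)  # rounds to y=11
  # outside the grid
  s <- sample_field_at(tis, c(-3, 10))
  expect_false(s$in_brain)
  # outside the brain mask
  anis <- array(0, c(4, 4))
  mask <- array(TRUE, c(4, 4)); mask[1, 1] <- FALSE
  tf <- tissue_field(anis, array(rep(c(1, 0), each = 16), c(4, 4, 2)),
                     brain_mask = mask)
  expect_false(sample_field_at(tf, c(1, 1))$in_brain)
  expect_true(sample_field_at(tf, c(2, 2))$in_brain)
})

test_that("precomputed tensor fields bypass structure-tensor analysis", {
  spec <- phantom_spec(c(64, 48), "straight_tract")
  tf <- make_tensor_phantom(spec)
  tis <- classify_tissue(tf, epsilon_M = 0.4)
  cl <- nscmigrate:::phantom_centerline(spec)
  s <- sample_field_at(tis, cl$points)
  expect_true(all(s$is_white))
  expect_true(all(abs(rowSums(s$direction * cl$tangent)) > 0.999))
})
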