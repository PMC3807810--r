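test_that("resampling honours the pull-back convention", {
  set.seed(1)
  v <- scalar_volume(array(rnorm(12^3), c(12, 12, 12)))
  # identity on the same grid is exact
  r <- resample_volume(v, affine_identity(), v$grid, "linear")
  expect_identical(r$values, v$values)
  # translation by one voxel spacing, nearest: index shift, border zero
  t <- affine_from_params(translation = c(1, 0, 0))
  r2 <- resample_volume(v, t, v$grid, "nearest")
  expect_equal(r2$values[1:11, , ], v$values[2:12, , ])
  expect_true(all(r2$values[12, , ] == 0))
  # constant volume stays constant inside the support
  cv <- scalar_volume(array(3.5, c(12, 12, 12)))
  t3 <- affine_from_params(translation = c(0.4, -0.3, 0.2),
                           angles_deg = c(5, 0, 0), center = c(5.5, 5.5, 5.5))
  out_grid <- volume_grid(c(6, 6, 6), c(1, 1, 1), c(3, 3, 3))
  r3 <- resample_volume(cv, t3, out_grid, "linear")
  expect_equal(max(abs(r3$values - 3.5)), 0, tolerance = 1e-12)
  # errors
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(resample_volume(v, bad), "singular")
})

test_that("round-trip resampling of a smooth volume is near-lossless", {
  set.seed(2)
  raw <- scalar_volume(array(rnorm(24^3), c(24, 24, 24)))
  v <- gaussian_smooth(raw, 2.5)
  t <- affine_from_params(translation = c(1.3, -0.7, 0.4),
                          angles_deg = c(7, -4, 3), center = c(11.5, 11.5, 11.5))
  f <- resample_volume(v, t, v$grid, "linear")
  b <- resample_volume(f, affine_invert(t), v$grid, "linear")
  interior <- 7:18
  err <- abs(b$values[interior, interior, interior] -
               v$values[interior, interior, interior])
  # bounded by interpolation error of a smooth field
  grad_scale <- max(abs(diff(v$values)))
  expect_lt(max(err), 2 * grad_scale)
})

test_that("gaussian smoothing acts in physical units and conserves mass", {
  cv <- scalar_volume(array(2, c(10, 10, 10)), spacing = c(0.5, 1, 2))
  s <- gaussian_smooth(cv, 1.5)
  expect_equal(s$values, cv$values, tolerance = 1e-12)
  # impulse response: separable sampled Gaussian, sigma 2 voxels on a
  # 0.5 mm grid for sigma_mm = 1
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  v <- scalar_volume(imp, spacing = c(0.5, 0.5, 0.5))
  s2 <- gaussian_smooth(v, 1)
  g <- exp(-0.5 * ((-8:8) / 2)^2); g <- g / sum(exp(-0.5 * ((-8:8) / 2)^2))
  r <- max(1, ceiling(4 * 2))
  k <- exp(-0.5 * ((-r:r) / 2)^2); k <- k / sum(k)
  expected_centre <- k[r + 1]^3
  expect_equal(s2$values[11, 11, 11], expected_centre, tolerance = 1e-10)
  expect_equal(sum(s2$values), 1, tolerance = 1e-9)  # reflective boundary
  expect_error(gaussian_smooth(v, -1), "positive")
})

test_that("distance maps are exact Euclidean distances in mm", {
  g <- volume_grid(c(9, 8, 7), c(0.5, 1, 2))
  m <- array(FALSE, c(9, 8, 7)); m[3, 4, 2] <- TRUE
  d <- distance_map(m, grid = g)
  expect_equal(d$values[3, 4, 2], 0)
  expect_equal(d$values[4, 4, 2], 0.5)   # one voxel along x = spacing
  expect_equal(d$values[3, 4, 3], 2)     # one voxel along z
  # full mask -> all zeros
  expect_true(all(distance_map(array(TRUE, c(4, 4, 4)),
                               grid = volume_grid(c(4, 4, 4), c(1, 1, 1)))$values == 0))
  # two-voxel anisotropic case against brute force
  m2 <- array(FALSE, c(9, 8, 7)); m2[2, 2, 2] <- TRUE; m2[8, 7, 6] <- TRUE
  d2 <- distance_map(m2, grid = g)$values
  pts <- rbind(c(1, 1, 1), c(7, 6, 5)) * rep(g$spacing, each = 2)
  for (k in 1:7) for (j in 1:8) for (i in 1:9) {
    p <- c(i - 1, j - 1, k - 1) * g$spacing
    expect_equal(d2[i, j, k], sqrt(min(rowSums(sweep(pts, 2, p)^2))),
                 tolerance = 1e-9)
  }
  expect_error(distance_map(array(FALSE, c(3, 3, 3)),
                            grid = volume_grid(c(3, 3, 3), c(1, 1, 1))),
               "empty")
})

test_that("distance map agrees with brute force on random small grids", {
  for (seed in 1:3) {
    set.seed(seed)
    sh <- c(11, 9, 10)
    g <- volume_grid(sh, c(0.7, 1.1, 0.9))
    m <- array(runif(prod(sh)) < 0.05, sh)
    m[1, 1, 1] <- TRUE
    d <- distance_map(m, grid = g)$values
    idx <- which(m, arr.ind = TRUE) - 1
    pw <- sweep(idx, 2, g$spacing, "*")
    for (s in sample(prod(sh), 40)) {
      ijk <- arrayInd(s, sh) - 1
      p <- ijk * g$spacing
      expect_equal(d[s], sqrt(min(rowSums(sweep(pw, 2, as.numeric(p))^2))),
                   tolerance = 1e-9)
    }
  }
})

test_that("maximum Euler rotation uses the rotation factor only", {
  expect_equal(max_euler_rotation(affine_identity()), 0)
  expect_equal(max_euler_rotation(affine_from_params(angles_deg = c(0, 0, 30))),
               30, tolerance = 1e-9)
  # scale must not change the answer (polar decomposition)
  t <- affine_from_params(angles_deg = c(20, 0, 0), scales = rep(1.1, 3))
  expect_equal(max_euler_rotation(t), 20, tolerance = 1e-9)
  t2 <- affine_from_params(angles_deg = c(11, -7, 3), scales = c(0.8, 1.3, 1.1))
  expect_equal(max_euler_rotation(t2), 11, tolerance = 1e-6)
  bad <- diag(4); bad[2, 2] <- 0
  expect_error(max_euler_rotation(bad), "singular")
})

test_that("rigid parameters report angles in (-180, 180]", {
  t <- affine_from_params(translation = c(1, 2, 3),
                          angles_deg = c(170, -10, -170))
  rp <- rigid_params(t)
  expect_true(all(rp$euler_deg > -180 & rp$euler_deg <= 180))
  expect_equal(rp$translation, c(1, 2, 3))
})

test_that("transforms and volumes survive file round-trips", {
  tdir <- withr::local_tempdir()
  t <- affine_from_params(translation = c(1.5, -2, 3),
                          angles_deg = c(10, 5, -3), scales = c(1, 1.05, 0.98))
  f <- file.path(tdir, "t.mat")
  write_transform(t, f)
  expect_equal(read_transform(f), t, tolerance = 1e-10)
  set.seed(3)
  v <- scalar_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                     spacing = c(0.5, 1, 2), origin = c(-3, 4, 5))
  nf <- file.path(tdir, "v.nii.gz")
  write_volume(v, nf)
  v2 <- read_volume(nf)
  expect_equal(v2$values, v$values, tolerance = 1e-6)
  expect_equal(v2$grid$spacing, v$grid$spacing, tolerance = 1e-6)
  expect_equal(v2$grid$origin, v$grid$origin, tolerance = 1e-5)
})
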