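test_that("NCC and CR behave as correlation measures", {
  a <- array(rnorm(27), c(3, 3, 3))
  expect_equal(ncc_similarity(a, a), 1)
  expect_equal(ncc_similarity(a, 2 * a + 5), 1, tolerance = 1e-12)
  expect_equal(ncc_similarity(a, -a), -1, tolerance = 1e-12)
  expect_equal(ncc_similarity(a, -a, similarity = "cr"), 1,
               tolerance = 1e-12)
  expect_error(ncc_similarity(a, array(1, c(3, 3, 3))), "variance")
})

test_that("block selection applies the variance rules", {
  cv <- scalar_volume(array(1, c(10, 10, 10)))
  expect_error(select_source_blocks(cv, match_settings(), "source"),
               "variance")
  # threshold arithmetic: range 100, factor 0.04 -> variance < 4 excluded
  set.seed(10)
  sh <- c(20, 20, 20)
  img <- array(0, sh)
  img[1:10, , ] <- rnorm(prod(c(10, 20, 20)), 50, 10)   # high variance half
  img[11:20, , ] <- rnorm(prod(c(10, 20, 20)), 50, 0.5) # low variance half
  img[1, 1, 1] <- 0; img[2, 1, 1] <- 100                # force range 100
  v <- scalar_volume(img)
  s <- match_settings(block_step = 1)
  sel <- select_source_blocks(v, s, "target_threshold")
  expect_equal(sel$threshold, 0.04 * 100)
  # brute-force count of surviving blocks
  cnt <- 0
  for (k in 1:18) for (j in 1:18) for (i in 1:18) {
    b <- img[i:(i + 2), j:(j + 2), k:(k + 2)]
    if (mean((b - mean(b))^2) >= 4) cnt <- cnt + 1
  }
  expect_equal(nrow(sel$centres), cnt)
  expect_true(all(sel$variance >= 4))
})

test_that("matching recovers exact integer translations (search oracle)", {
  tex <- get_texture()
  n <- tex$grid$shape[1]
  tv <- array(0, tex$grid$shape)
  tv[4:n, , ] <- tex$values[1:(n - 3), , ]
  tgt <- scalar_volume(tv, grid = tex$grid)
  s <- match_settings(search_radius = 5)
  fld <- match_blocks(tex, tgt, affine_identity(), s)
  # interior blocks (away from the zero-filled border) all agree with the
  # exhaustive-search oracle displacement (3, 0, 0) voxels
  interior <- fld$cx >= 8 & fld$cx <= n - 9 & fld$cy >= 5 &
    fld$cy <= n - 6 & fld$cz >= 5 & fld$cz <= n - 6
  # keep blocks whose true target candidate passes the variance rule
  thr <- s$variance_threshold_factor * diff(range(tgt$values))
  cand_ok <- vapply(seq_len(nrow(fld)), function(r) {
    c0 <- round(as.numeric(fld[r, 1:3])) + c(3, 0, 0)
    if (any(c0 < 1) || any(c0 + 2 > dim(tgt$values))) return(FALSE)
    b <- tgt$values[(c0[1]):(c0[1] + 2), (c0[2]):(c0[2] + 2),
                    (c0[3]):(c0[3] + 2)]
    mean((b - mean(b))^2) >= thr
  }, logical(1))
  sel <- interior & cand_ok
  expect_gt(sum(sel), 500)
  expect_true(all(abs(fld$dx[sel] - 3) < 1e-9))
  expect_true(all(abs(fld$dy[sel]) < 1e-9))
  expect_true(all(abs(fld$dz[sel]) < 1e-9))
  # search radius 0: all displacements vanish
  fld0 <- match_blocks(tex, tex, affine_identity(),
                       match_settings(search_radius = 0))
  expect_true(all(abs(c(fld0$dx, fld0$dy, fld0$dz)) < 1e-9))
})

test_that("matching equals an R brute-force search block by block", {
  tex <- get_texture()
  t_true <- affine_from_params(translation = c(2, -1, 1),
                               angles_deg = c(4, 0, 0),
                               center = c(23.5, 23.5, 23.5))
  tgt <- resample_volume(tex, affine_invert(t_true), tex$grid, "linear")
  s <- match_settings(search_radius = 3, block_step = 7)
  fld <- match_blocks(tex, tgt, affine_identity(), s)
  warped <- resample_volume(tex, affine_identity(), tgt$grid, "linear")
  thr <- s$variance_threshold_factor * diff(range(tgt$values))
  blk <- function(vol, c0) vol$values[c0[1]:(c0[1] + 2), c0[2]:(c0[2] + 2),
                                      c0[3]:(c0[3] + 2)]
  set.seed(11)
  for (r in sample(nrow(fld), 8)) {
    c0 <- round(as.numeric(fld[r, 1:3])) + 1  # 1-based corner of 3^3 block
    a <- blk(warped, c0 - 1)
    best <- -2; bo <- NULL
    for (oz in -3:3) for (oy in -3:3) for (ox in -3:3) {
      cc <- c0 - 1 + c(ox, oy, oz)
      if (any(cc < 1) || any(cc + 2 > tgt$grid$shape)) next
      b <- blk(tgt, cc)
      if (mean((b - mean(b))^2) < thr) next
      r2 <- suppressWarnings(cor(as.numeric(a), as.numeric(b)))
      if (!is.na(r2) && r2 > best + 1e-12) { best <- r2; bo <- c(ox, oy, oz) }
    }
    expect_equal(as.numeric(fld[r, 4:6]), bo, tolerance = 1e-9)
  }
})

test_that("LTS recovers transforms exactly and resists gross outliers", {
  set.seed(12)
  p <- matrix(runif(3 * 120, 0, 80), ncol = 3)
  t_true <- affine_from_params(translation = c(4, -3, 2),
                               angles_deg = c(9, -6, 12),
                               scales = c(1.04, 0.97, 1.01),
                               center = c(40, 40, 40))
  d <- affine_apply(t_true, p) - p
  fld <- data.frame(cx = p[, 1], cy = p[, 2], cz = p[, 3],
                    dx = d[, 1], dy = d[, 2], dz = d[, 3], similarity = 1)
  fit <- lts_estimate(fld, "affine", 0.75)
  expect_lt(max(abs(fit - t_true)), 1e-6)
  # 20% gross outliers (>= 20 mm) leave the estimate untouched
  fld_out <- fld
  out <- 1:24
  fld_out[out, c("dx", "dy", "dz")] <-
    fld_out[out, c("dx", "dy", "dz")] + 25 + matrix(runif(72, 0, 10), 24)
  fit2 <- lts_estimate(fld_out, "affine", 0.75)
  expect_lt(max(abs(fit2 - t_true)), 1e-6)
  expect_false(any(attr(fit2, "inliers")[out]))
  # h = 1 reduces to the closed-form least squares fit
  fld_noisy <- fld
  fld_noisy[, c("dx", "dy", "dz")] <-
    fld_noisy[, c("dx", "dy", "dz")] + rnorm(360, 0, 0.5)
  fit3 <- lts_estimate(fld_noisy, "affine", 1)
  q <- p + as.matrix(fld_noisy[, c("dx", "dy", "dz")])
  X <- cbind(p, 1)
  B <- solve(crossprod(X), crossprod(X, q))
  ls_fit <- rbind(cbind(t(B[1:3, ]), B[4, ]), c(0, 0, 0, 1))
  expect_equal(unclass(fit3), ls_fit, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rigid LTS uses a proper rotation and flags degeneracy", {
  set.seed(13)
  p <- matrix(runif(3 * 60, 0, 50), ncol = 3)
  t_true <- affine_from_params(translation = c(1, 2, -3),
                               angles_deg = c(15, 8, -11),
                               center = c(25, 25, 25))
  d <- affine_apply(t_true, p) - p
  fld <- data.frame(cx = p[, 1], cy = p[, 2], cz = p[, 3],
                    dx = d[, 1], dy = d[, 2], dz = d[, 3], similarity = 1)
  fit <- lts_estimate(fld, "rigid", 0.75)
  expect_lt(max(abs(fit - t_true)), 1e-6)
  expect_equal(det(fit[1:3, 1:3]), 1, tolerance = 1e-9)
  # collinear points are rejected with a rank message
  pc <- cbind(seq_len(10), seq_len(10), seq_len(10))
  fldc <- data.frame(cx = pc[, 1], cy = pc[, 2], cz = pc[, 3],
                     dx = 1, dy = 0, dz = 0, similarity = 1)
  expect_error(lts_estimate(fldc, "affine", 1), "degenerate|coplanar")
})

test_that("registering a volume to itself is a fixed point", {
  pseudo <- get_pseudo()
  # target rendered at the conventional byte scale (the variance
  # threshold is a fraction of the target intensity range); NCC itself is
  # scale-invariant, so this is the same registration problem
  target <- scalar_volume(pseudo$values * 255, grid = pseudo$grid)
  reg <- register_us(pseudo, target,
                     settings = match_settings(levels = 2, max_iter = 5))
  expect_false(reg$failed)
  expect_lt(fetalreg:::corner_displacement(reg$transform, diag(4),
                                           pseudo$grid), 0.1)
})

test_that("registration is equivariant under a pre-rotation of the target", {
  ph <- get_phantom()
  pseudo <- get_pseudo()
  t_true <- affine_from_params(angles_deg = c(6, -4, 5),
                               translation = c(2, -1, 2),
                               center = ph$centre)
  art <- us_artifact_spec(transform = t_true, speckle_sigma = 0,
                          attenuation_per_mm = 0, noise_sd = 0, seed = 3)
  us <- preprocess_us(simulate_us(pseudo, art)$us)$us
  reg1 <- register_us(pseudo, us)
  # pre-rotate the target and compose the init accordingly
  r_extra <- affine_from_params(angles_deg = c(0, 0, 8), center = ph$centre)
  grid_r <- us$grid
  us_rot <- resample_volume(us, affine_invert(r_extra), grid_r, "linear")
  reg2 <- register_us(pseudo, us_rot, init = r_extra)
  # recovered transforms differ by r_extra up to the per-registration
  # noise floor of integer-voxel matching (about one voxel at the
  # bounding-box corners; the 8-degree pre-rotation itself moves the
  # corners by roughly 10 mm)
  expect_lt(fetalreg:::corner_displacement(reg2$transform,
                                           r_extra %*% reg1$transform,
                                           pseudo$grid), 2)
})
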