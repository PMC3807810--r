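test_that("phantom generation is deterministic and complete", {
  a <- make_label_phantom(phantom_spec(seed = 5))
  b <- make_label_phantom(phantom_spec(seed = 5))
  expect_identical(a$smap$values, b$smap$values)
  c <- make_label_phantom(phantom_spec(seed = 6))
  expect_false(identical(a$smap$values, c$smap$values))
  # every structure of the scheme is present
  sch <- structure_scheme()
  expect_setequal(setdiff(unique(as.vector(a$smap$values)), 0L),
                  unname(sch))
})

test_that("mirrored phantoms swap left and right labels", {
  a <- make_label_phantom(phantom_spec(seed = 2))
  m <- make_label_phantom(phantom_spec(seed = 2, mirror = TRUE))
  flip <- function(x) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  # mirroring the spec flips the voxel grid exactly
  expect_identical(m$smap$values, flip(a$smap$values))
  # for the bilaterally symmetric anatomy this is the original phantom
  # with the left/right hemisphere labels swapped
  sch <- structure_scheme()
  swap <- a$smap$values
  l <- a$smap$values == sch[["cortical_hemisphere_L"]]
  r <- a$smap$values == sch[["cortical_hemisphere_R"]]
  swap[l] <- sch[["cortical_hemisphere_R"]]
  swap[r] <- sch[["cortical_hemisphere_L"]]
  expect_gt(mean(swap == m$smap$values), 0.95)
})

test_that("skull voxel count matches the analytic ellipsoidal shell", {
  spec <- phantom_spec(surface_irregularity_mm = 0)   # exact ellipsoids
  ph <- make_label_phantom(spec)
  sch <- structure_scheme()
  n_skull <- sum(ph$smap$values == sch[["skull"]])
  h <- spec$head
  # shells are eroded in normalised units: q <= 1 - d / mean(h)
  f <- 1 - spec$skull / mean(h)
  vol_mm3 <- 4 / 3 * pi * (prod(h) - prod(h) * f^3)
  expect_lt(abs(n_skull - vol_mm3) / vol_mm3, 0.02)
})

test_that("MR simulation produces the requested class statistics", {
  ph <- get_phantom()
  mu <- setNames(seq(100, 100 + 20 * 11, by = 20),
                 names(structure_scheme()))
  sd0 <- setNames(rep(0, 12), names(structure_scheme()))
  sim0 <- simulate_mr(ph$smap, mu, sd0, bias_amplitude = 0, seed = 1)
  sch <- structure_scheme()
  for (nm in c("skull", "dgm", "csf"))
    expect_equal(unique(sim0$volume$values[ph$smap$values == sch[[nm]]]),
                 unname(mu[nm]))
  # empirical means within 3 sd / sqrt(n)
  sdv <- setNames(rep(10, 12), names(structure_scheme()))
  sim <- simulate_mr(ph$smap, mu, sdv, bias_amplitude = 0, seed = 2)
  for (nm in c("cerebellum", "brainstem")) {
    sel <- ph$smap$values == sch[[nm]]
    expect_lt(abs(mean(sim$volume$values[sel]) - mu[nm]),
              3 * 10 / sqrt(sum(sel)))
  }
  # known bias field is reproduced by construction
  simb <- simulate_mr(ph$smap, mu, sd0, bias_amplitude = 0.2, seed = 3)
  sel <- ph$smap$values > 0
  ratio <- log(simb$volume$values[sel] / sim0$volume$values[sel])
  expect_equal(ratio, simb$bias[sel], tolerance = 1e-9)
  expect_equal(max(abs(simb$bias[sel])), 0.2, tolerance = 1e-9)
  expect_equal(mean(simb$bias[sel]), 0, tolerance = 1e-9)
})

test_that("ultrasound simulation composes artefacts deterministically", {
  pseudo <- get_pseudo()
  # no artefacts, identity transform: output equals the (padded) pseudo
  art0 <- us_artifact_spec(speckle_sigma = 0, attenuation_per_mm = 0,
                           noise_sd = 0, output_scale = 1, pad_voxels = 0L)
  sim0 <- simulate_us(pseudo, art0)
  expect_equal(sim0$us$values, pseudo$values, tolerance = 1e-9)
  # shadow factor 0: zeroed voxels equal the analytic cone membership
  probe <- c(47.5, 160, 47.5)
  art_sh <- us_artifact_spec(speckle_sigma = 0, attenuation_per_mm = 0,
                             noise_sd = 0, probe_pos = probe,
                             shadow_halfangle_deg = 12,
                             shadow_axis = c(0, -1, 0), shadow_factor = 0,
                             pad_voxels = 0L, output_scale = 1)
  sim_sh <- simulate_us(pseudo, art_sh)
  grid <- sim_sh$us$grid
  idx <- which(array(TRUE, grid$shape), arr.ind = TRUE) - 1
  w <- grid_world(grid, idx)
  v <- sweep(w, 2, probe)
  cosang <- (-v[, 2]) / sqrt(rowSums(v^2))
  cone <- array(cosang >= cos(12 * pi / 180), grid$shape)
  expect_identical(sim_sh$shadow_mask, cone)
  expect_true(all(sim_sh$us$values[cone] == 0))
  # determinism per seed
  art <- us_artifact_spec(speckle_sigma = 0.2, seed = 4)
  expect_identical(simulate_us(pseudo, art)$us$values,
                   simulate_us(pseudo, art)$us$values)
})

test_that("speckle keeps most feature blocks correlated with the pseudo image", {
  pseudo <- get_pseudo()
  art <- us_artifact_spec(speckle_sigma = 0.2, attenuation_per_mm = 0,
                          noise_sd = 0, pad_voxels = 0L, seed = 5)
  sim <- simulate_us(pseudo, art)
  s <- match_settings(block_step = 4)
  sel <- select_source_blocks(pseudo, s, "source")
  nccs <- vapply(seq_len(nrow(sel$centres)), function(t) {
    c0 <- sel$centres[t, ] + 1
    a <- pseudo$values[(c0[1] - 1):(c0[1] + 1), (c0[2] - 1):(c0[2] + 1),
                       (c0[3] - 1):(c0[3] + 1)]
    b <- sim$us$values[(c0[1] - 1):(c0[1] + 1), (c0[2] - 1):(c0[2] + 1),
                       (c0[3] - 1):(c0[3] + 1)]
    if (sd(b) == 0) return(NA_real_)
    suppressWarnings(cor(as.numeric(a), as.numeric(b)))
  }, numeric(1))
  expect_gt(mean(nccs > 0.5, na.rm = TRUE), 0.9)
})

test_that("stack simulation applies the exact corruption count per seed", {
  lab <- make_tissue_phantom(c(24, 24, 24))
  vol <- simulate_mr(lab, c(class_1 = 100, class_2 = 200, class_3 = 300),
                     seed = 1)$volume
  psf <- make_psf(2.5, 1, 1)
  st0 <- simulate_stacks(vol, psf, 2, 0, seed = 3)
  # corrupt_fraction 0: stacks equal the clean forward simulation
  expect_identical(st0$stacks[[1]]$values, st0$clean[[1]])
  st <- simulate_stacks(vol, psf, 2, 0.2, seed = 3)
  for (q in 1:2) {
    ns <- dim(st$stacks[[q]]$values)[3]
    expect_equal(sum(st$corrupted[[q]]), round(0.2 * ns))
  }
  st2 <- simulate_stacks(vol, psf, 2, 0.2, seed = 4)
  expect_false(identical(st$corrupted, st2$corrupted))
  expect_error(simulate_stacks(vol, psf, 2, 1.2), "corrupt_fraction")
})

test_that("the shadow half-angle solver hits the requested occlusion", {
  ph <- get_phantom()
  grid <- ph$smap$grid
  probe <- ph$centre + c(0, 120, 0)
  half <- shadow_halfangle_for_fraction(ph$brain_mask, grid, probe,
                                        c(0, -1, 0), 0.2)
  co <- fetalreg:::coord_arrays(grid, probe)
  depth <- sqrt(co$x^2 + co$y^2 + co$z^2)
  cone <- (-co$y / pmax(depth, 1e-9)) >= cos(half * pi / 180)
  frac <- sum(cone & ph$brain_mask) / sum(ph$brain_mask)
  expect_equal(frac, 0.2, tolerance = 0.02)
})
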