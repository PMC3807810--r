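make_flat_priors <- function(n, probs) {
  grid <- volume_grid(c(n, 1, 1), c(1, 1, 1))
  pl <- lapply(probs, function(p) array(p, c(n, 1, 1)))
  atlas_priors(pl, grid)
}

test_that("posteriors follow the Bayes combination of likelihoods and priors", {
  # two classes, equal priors, x midway between equal-sd Gaussians
  pr <- make_flat_priors(1, list(a = 0.45, b = 0.45, background = 0.1))
  params <- class_params(c(a = 0, b = 10), c(a = 2, b = 2),
                         list(mean = c(-50, -40), sd = c(1, 1), w = c(.5, .5)))
  x <- scalar_volume(array(5, c(1, 1, 1)))
  post <- em_posteriors(x, params, pr)
  expect_equal(post$p[1, 1], post$p[1, 2], tolerance = 1e-12)
  # prior 1 for one class forces its posterior to 1
  pr2 <- make_flat_priors(1, list(a = 1, b = 0, background = 0))
  post2 <- em_posteriors(x, params, pr2)
  expect_equal(post2$p[1, 1], 1)
  # three-class hand case evaluated against the scalar formula
  pr3 <- make_flat_priors(1, list(a = 0.2, b = 0.3, c = 0.5,
                                  background = 0))
  params3 <- class_params(c(a = 0, b = 10, c = 20), c(a = 2, b = 2, c = 2),
                          list(mean = c(-50, -40), sd = c(1, 1),
                               w = c(.5, .5)))
  x3 <- scalar_volume(array(9, c(1, 1, 1)))
  post3 <- em_posteriors(x3, params3, pr3)
  lik <- dnorm(9, c(0, 10, 20), 2) * c(0.2, 0.3, 0.5)
  expect_equal(post3$p[1, 1:3], lik / sum(lik), tolerance = 1e-12)
  # rows sum to one
  expect_equal(rowSums(post3$p), 1, tolerance = 1e-12)
  expect_error(class_params(c(a = 0), c(a = 0),
                            list(mean = c(0, 1), sd = c(1, 1), w = c(.5, .5))),
               "positive")
})

test_that("class parameter updates are the posterior-weighted moments", {
  grid <- volume_grid(c(2, 1, 1), c(1, 1, 1))
  x <- scalar_volume(array(c(0, 10), c(2, 1, 1)))
  prev <- class_params(c(a = 5), c(a = 5),
                       list(mean = c(0, 1), sd = c(1, 1), w = c(.5, .5)))
  post <- structure(list(p = cbind(c(0.25, 0.75), c(0.75, 0.25)),
                         classes = c("a", "background"),
                         background = "background", grid = grid),
                    class = "posterior_field")
  up <- update_class_params(x, post, prev)
  expect_equal(up$mean[["a"]], 7.5)
  expect_equal(up$sd[["a"]]^2, 18.75)
  # one-hot posteriors give the sample mean / population variance
  post2 <- structure(list(p = cbind(c(1, 1), c(0, 0)),
                          classes = c("a", "background"),
                          background = "background", grid = grid),
                     class = "posterior_field")
  up2 <- update_class_params(x, post2, prev)
  expect_equal(up2$mean[["a"]], 5)
  expect_equal(up2$sd[["a"]]^2, 25)
  # empty class stays frozen with a warning
  post3 <- structure(list(p = cbind(c(0, 0), c(1, 1)),
                          classes = c("a", "background"),
                          background = "background", grid = grid),
                     class = "posterior_field")
  expect_warning(up3 <- update_class_params(x, post3, prev), "frozen")
  expect_equal(up3$mean[["a"]], prev$mean[["a"]])
})

test_that("uniform posteriors make all class means equal the global mean", {
  set.seed(4)
  grid <- volume_grid(c(50, 1, 1), c(1, 1, 1))
  x <- scalar_volume(array(rnorm(50, 100, 10), c(50, 1, 1)))
  prev <- class_params(c(a = 0, b = 1), c(a = 1, b = 1),
                       list(mean = c(0, 1), sd = c(1, 1), w = c(.5, .5)))
  post <- structure(list(p = matrix(1 / 3, 50, 3),
                         classes = c("a", "b", "background"),
                         background = "background", grid = grid),
                    class = "posterior_field")
  up <- update_class_params(x, post, prev)
  expect_equal(up$mean[["a"]], mean(x$values))
  expect_equal(up$mean[["b"]], mean(x$values))
})

test_that("bias estimation recovers closed-form cases", {
  # uniform one-class image of value v with mu = v/2: residual log 2
  # everywhere, smoothing leaves it flat, re-centring returns b == 0
  grid <- volume_grid(c(8, 8, 8), c(1, 1, 1))
  x <- scalar_volume(array(10, c(8, 8, 8)), grid = grid)
  params <- class_params(c(a = 5), c(a = 1),
                         list(mean = c(0, 1), sd = c(1, 1), w = c(.5, .5)))
  post <- structure(list(p = cbind(rep(1, 512), rep(0, 512)),
                         classes = c("a", "background"),
                         background = "background", grid = grid),
                    class = "posterior_field")
  bs <- estimate_bias(x, post, params, sigma_bias_mm = 5)
  expect_lt(max(abs(bs$b$values)), 1e-9)
  expect_equal(unique(round(as.numeric(bs$r), 9)), round(log(2), 9))
  # bias-free image with correct params: negligible bias
  set.seed(5)
  x2 <- scalar_volume(array(rnorm(512, 10, 0.01), c(8, 8, 8)), grid = grid)
  params2 <- class_params(c(a = 10), c(a = 0.01),
                          list(mean = c(0, 1), sd = c(1, 1), w = c(.5, .5)))
  bs2 <- estimate_bias(x2, post, params2, sigma_bias_mm = 5)
  expect_lt(max(abs(bs2$b$values)), 0.1 * diff(range(bs2$r)))
  # non-positive intensities inside the mask are an error
  x3 <- scalar_volume(array(c(-1, rep(10, 511)), c(8, 8, 8)), grid = grid)
  expect_error(estimate_bias(x3, post, params, 5), "non-positive")
})

test_that("EM segmentation recovers a known phantom with bias", {
  lab <- make_tissue_phantom(c(40, 40, 40))
  mu <- c(class_1 = 100, class_2 = 200, class_3 = 300)
  sdv <- c(class_1 = 20, class_2 = 20, class_3 = 20)   # SNR 10 per class
  sim <- simulate_mr(lab, mu, sdv, bias_amplitude = 0.2, seed = 3)
  pr <- priors_from_labels(lab, sigma_mm = 2)
  seg <- segment_em(sim$volume, pr, list(sigma_bias_mm = 20))
  # off-boundary voxelwise accuracy
  v <- lab$values; sh <- dim(v)
  nb <- array(TRUE, sh)
  nb[-1, , ] <- nb[-1, , ] & (v[-1, , ] == v[-sh[1], , ])
  nb[-sh[1], , ] <- nb[-sh[1], , ] & (v[-1, , ] == v[-sh[1], , ])
  nb[, -1, ] <- nb[, -1, ] & (v[, -1, ] == v[, -sh[2], ])
  nb[, -sh[2], ] <- nb[, -sh[2], ] & (v[, -1, ] == v[, -sh[2], ])
  nb[, , -1] <- nb[, , -1] & (v[, , -1] == v[, , -sh[3]])
  nb[, , -sh[3]] <- nb[, , -sh[3]] & (v[, , -1] == v[, , -sh[3]])
  sel <- nb & v > 0
  expect_gt(mean(seg$labels$values[sel] == v[sel]), 0.99)
  rng <- diff(range(sim$volume$values))
  expect_lt(max(abs(unlist(seg$params$mean) - mu)), 0.02 * rng)
  expect_lt(max(abs(unlist(seg$params$sd) - sdv) / sdv), 0.10)
  expect_lt(sqrt(mean((seg$bias$values[v > 0] - sim$bias[v > 0])^2)), 0.05)
})

test_that("EM from ground-truth parameters is a fixed point", {
  lab <- make_tissue_phantom(c(24, 24, 24))
  mu <- c(class_1 = 100, class_2 = 200, class_3 = 300)
  sim <- simulate_mr(lab, mu, 0 * mu, bias_amplitude = 0, seed = 1)
  # avoid exactly zero sds in the model
  init <- class_params(mu, c(class_1 = 1, class_2 = 1, class_3 = 1),
                       list(mean = c(0, 5), sd = c(1, 1), w = c(.5, .5)))
  pr <- priors_from_labels(lab, sigma_mm = 1)
  seg <- segment_em(sim$volume, pr,
                    list(init = init, bias = FALSE, max_iter = 10))
  expect_lte(seg$iterations, 2)
  expect_true(seg$converged)
  v <- lab$values
  expect_equal(mean(seg$labels$values[v > 0] == v[v > 0]), 1)
})

test_that("permuting prior classes permutes output labels identically", {
  lab <- make_tissue_phantom(c(20, 20, 20))
  mu <- c(class_1 = 100, class_2 = 200, class_3 = 300)
  sim <- simulate_mr(lab, mu, mu * 0 + 10, bias_amplitude = 0, seed = 2)
  pr <- priors_from_labels(lab, sigma_mm = 1)
  seg <- segment_em(sim$volume, pr, list(bias = FALSE))
  # permute tissue classes 1<->3 in the priors
  perm_list <- setNames(
    lapply(c("class_3", "class_2", "class_1", "background"), function(nm)
      array(pr$p[, match(nm, pr$classes)], lab$grid$shape)),
    c("class_3", "class_2", "class_1", "background"))
  pr2 <- atlas_priors(perm_list, lab$grid)
  seg2 <- segment_em(sim$volume, pr2, list(bias = FALSE))
  remap <- c(`1` = 3L, `2` = 2L, `3` = 1L, `0` = 0L)
  expect_equal(as.vector(remap[as.character(seg$labels$values)]),
               as.vector(seg2$labels$values),
               ignore_attr = TRUE)
})
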