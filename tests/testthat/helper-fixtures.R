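# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# standard young-preset phantom and its pseudo-US image
get_phantom <- function() fixture("phantom", function() make_label_phantom())
get_pseudo <- function() fixture("pseudo", function()
  assign_pseudo_intensities(get_phantom()$smap))

# smooth random texture volume: every block informative
get_texture <- function() fixture("texture", function() {
  set.seed(42)
  raw <- scalar_volume(array(runif(48^3), c(48, 48, 48)))
  v <- gaussian_smooth(raw, 1)   # feature-rich: every block has variance
  scalar_volume(v$values * 255, grid = v$grid)
})

# mean displacement error of a recovered transform over a voxel mask
mean_displacement_error <- function(t_est, t_true, mask, grid, n = 4000,
                                    seed = 7) {
  idx <- which(mask, arr.ind = TRUE) - 1
  set.seed(seed)
  if (nrow(idx) > n) idx <- idx[sample(nrow(idx), n), ]
  pw <- grid_world(grid, idx)
  mean(sqrt(rowSums((affine_apply(t_est, pw) - affine_apply(t_true, pw))^2)))
}

# rotation by `angle_deg` about a random axis, about `centre`
random_rigid <- function(angle_deg, centre, trans_range = 5, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- runif(3, -trans_range, trans_range)
  t <- diag(4)
  t[1:3, 1:3] <- R
  t[1:3, 4] <- centre - R %*% centre + tr
  t
}
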