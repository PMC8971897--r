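# a uniform direction field on a grid, pointing along `dir`
uniform_field <- function(grid, dir = c(1, 0, 0)) {
  mk <- function(v) { out <- grid; out$data[] <- v; out }
  list(dx = mk(dir[1]), dy = mk(dir[2]), dz = mk(dir[3]), support = mk(1))
}

test_that("tracking a uniform field yields straight capped streamlines", {
  g <- small_grid(41, vs = 1)
  field <- uniform_field(g, c(1, 0, 0))
  seed_mask <- g
  ij <- round(world_to_voxel(g, c(0, 0, 0))) + 1
  seed_mask$data[ij[1], ij[2], ij[3]] <- 1
  prm <- tracking_params(n_seeds = 5, step_size = 0.5, min_length = 5,
                         max_length = 30, seed = 2)
  tr <- track_from_seeds(field, seed_mask, prm)
  expect_gt(length(tr), 0)
  for (pts in tr$streamlines) {
    steps <- diff(pts)
    expect_equal(max(abs(steps[, 2:3])), 0, tolerance = 1e-9) # straight in x
    expect_equal(unique(round(abs(steps[, 1]), 9)), 0.5)      # step size
    len <- (nrow(pts) - 1) * 0.5
    expect_gte(len, 5); expect_lte(len, 30)
  }
})

test_that("tracking stops at a sharp bend exceeding the angular threshold", {
  g <- small_grid(41, vs = 1)
  field <- uniform_field(g, c(1, 0, 0))
  # 90 degree instantaneous bend at world x >= 5
  xs <- grid_coordinates(g)[, 1]
  bend <- array(xs >= 5, dim(g$data))
  field$dx$data[bend] <- 0
  field$dy$data[bend] <- 1
  seed_mask <- g
  ij <- round(world_to_voxel(g, c(0, 0, 0))) + 1
  seed_mask$data[ij[1], ij[2], ij[3]] <- 1
  tr <- track_from_seeds(field, seed_mask,
                         tracking_params(n_seeds = 5, step_size = 0.5,
                                         max_angle = 45, min_length = 2,
                                         max_length = 100, seed = 4))
  for (pts in tr$streamlines) {
    expect_lt(max(pts[, 1]), 6)       # terminated at the bend
    expect_lt(diff(range(pts[, 2])), 1e-9)
  }
})

test_that("tracking a circular field recovers the curvature radius", {
  g <- small_grid(49, vs = 1)
  xyz <- grid_coordinates(g)
  r_true <- 12
  theta <- atan2(xyz[, 2], xyz[, 1])
  field <- list(
    dx = g, dy = g, dz = g, support = g)
  field$dx$data <- array(-sin(theta), dim(g$data))
  field$dy$data <- array(cos(theta), dim(g$data))
  field$dz$data <- array(0, dim(g$data))
  field$support$data <- array(1, dim(g$data))
  seed_mask <- g
  ij <- round(world_to_voxel(g, c(r_true, 0, 0))) + 1
  seed_mask$data[ij[1], ij[2], ij[3]] <- 1
  tr <- track_from_seeds(field, seed_mask,
                         tracking_params(n_seeds = 10, step_size = 0.25,
                                         min_length = 10, max_length = 40,
                                         seed = 6))
  expect_gt(length(tr), 0)
  # fit radius from point distances to the rotation axis
  for (pts in tr$streamlines) {
    r_emp <- mean(sqrt(pts[, 1]^2 + pts[, 2]^2))
    expect_equal(r_emp, r_true, tolerance = 0.05 * r_true)
  }
})

test_that("streamline selection honors sub-voxel crossings and is idempotent", {
  g <- small_grid(11)
  region <- g
  ij <- round(world_to_voxel(g, c(0, 0, 0))) + 1
  region$data[ij[1], ij[2], ij[3]] <- 1   # single voxel about the origin

  outside <- tractogram(list(cbind(c(-4, -4), c(4, 4.5), c(0, 1))))
  expect_length(select_streamlines(outside, region), 0)

  # stored vertices lie outside the voxel; only the half-voxel sub-sampling
  # of the crossing segment lands inside
  crossing <- tractogram(list(rbind(c(-0.8, 0.01, 0), c(0.8, 0.01, 0))))
  expect_length(select_streamlines(crossing, region), 1)

  whole <- g; whole$data[] <- 1
  set.seed(12)
  rnd <- tractogram(lapply(1:20, function(i) matrix(runif(9, -4, 4), 3, 3)))
  sel <- select_streamlines(rnd, whole)
  expect_equal(length(sel), 20)
  twice <- select_streamlines(select_streamlines(rnd, region), region)
  expect_equal(twice$ids, select_streamlines(rnd, region)$ids)
})

test_that("connectivity fractions match hand counts and ignore ordering", {
  g <- small_grid(20)
  roi_a <- g; roi_a$data[1:2, , ] <- 1       # world x in [-9.5, -8.5]
  roi_b <- g; roi_b$data[19:20, , ] <- 1     # world x in [8.5, 9.5]
  rois <- list(PMC = roi_a, SMA = roi_b)

  line_to <- function(x_end) cbind(seq(0, x_end, length.out = 10), 0, 0)
  tract <- tractogram(c(lapply(1:4, function(i) line_to(-9.4)),
                        lapply(1:6, function(i) line_to(9.4))))
  prof <- connectivity_fractions(tract, rois, total = 10)
  expect_equal(unname(prof$fractions["PMC"]), 0.4)
  expect_equal(unname(prof$fractions["SMA"]), 0.6)

  shuffled <- subset_tractogram(tract, c(7, 2, 10, 1, 3, 9, 4, 5, 8, 6))
  expect_equal(connectivity_fractions(shuffled, rois, 10)$fractions,
               prof$fractions)

  empty <- connectivity_fractions(empty_tractogram(), rois, total = 5)
  expect_equal(unname(empty$fractions), c(0, 0))

  ends_only <- connectivity_fractions(tract, rois, 10, mode = "end")
  expect_equal(unname(ends_only$fractions["SMA"]), 0.6)
})

test_that("ROIs with zero connectivity everywhere are discarded, others kept", {
  prof <- rbind(c(PVC = 0, PMC = 0.2, SMA = 0.5),
                c(PVC = 0, PMC = 0.0, SMA = 0.4),
                c(PVC = 0, PMC = 0.1, SMA = 0.6))
  expect_equal(drop_zero_rois(prof), c("PMC", "SMA"))
  all_pos <- prof; all_pos[, "PVC"] <- 0.01
  expect_equal(drop_zero_rois(all_pos), c("PVC", "PMC", "SMA"))
})

test_that("regression reproduces exact lines and independent formula oracles", {
  prof <- cbind(SMA = c(1, 2, 3))
  fits <- regress_connectivity(prof, c(10, 20, 30))
  expect_equal(fits$slope, 10, tolerance = 1e-12)
  expect_equal(fits$intercept, 0, tolerance = 1e-12)
  expect_equal(fits$spearman_rho, 1)

  fits_rev <- regress_connectivity(prof, c(30, 20, 10))
  expect_equal(fits_rev$spearman_rho, -1)

  set.seed(23)
  for (rep in 1:5) {
    x <- round(runif(11), 2)        # rounding forces occasional rank ties
    y <- round(rnorm(11, 5 * x, 2), 1)
    fits <- regress_connectivity(cbind(ROI = x), y)
    o <- ols_oracle(x, y)
    expect_equal(fits$slope, unname(o["slope"]), tolerance = 1e-9)
    expect_equal(fits$intercept, unname(o["intercept"]), tolerance = 1e-9)
    expect_equal(fits$spearman_rho, spearman_oracle(x, y), tolerance = 1e-9)
  }

  bands <- attr(regress_connectivity(cbind(ROI = rnorm(11)), rnorm(11)),
                "bands")
  b <- bands$ROI
  expect_true(all(b$lwr <= b$fit & b$fit <= b$upr))
  expect_error(regress_connectivity(cbind(A = 1:2), c(1, 2)), ">= 3 subjects")
})

test_that("direction fields rasterized from bundles support round-trip tracking", {
  g <- small_grid(30)
  straight <- tractogram(lapply(seq(-3, 3, by = 0.75), function(y0)
    cbind(seq(-12, 12, by = 1), y0, 0)))
  field <- bundle_direction_field(straight, g)
  expect_equal(max(field$support$data), 1)
  mid <- round(world_to_voxel(g, c(0, 0, 0))) + 1
  expect_gt(abs(field$dx$data[mid[1], mid[2], mid[3]]), 0.99)

  seed_mask <- g; seed_mask$data[mid[1], mid[2], mid[3]] <- 1
  tr <- track_from_seeds(field, seed_mask,
                         tracking_params(n_seeds = 20, step_size = 0.5,
                                         min_length = 4, max_length = 40,
                                         mask_threshold = 1e-6, seed = 8))
  expect_gt(length(tr), 0)
  spans <- vapply(tr$streamlines, function(p) diff(range(p[, 1])), 0)
  expect_gt(median(spans), 8)   # tracks follow the bundle axis
})

test_that("empty seed masks are a seeding error", {
  g <- small_grid(10)
  expect_error(track_from_seeds(uniform_field(g), g, tracking_params()),
               "seeding error")
})
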