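test_that("improvement weighting is an exact product, negatives preserved", {
  g <- small_grid(6)
  vta <- g; vta$data[2:4, 2:4, 2:4] <- 1
  st <- weight_vtas(list(vta, vta, vta), c(78, -50, 0))
  expect_equal(sort(unique(as.numeric(st$volumes[[1]]$data))), c(0, 78))
  expect_equal(sort(unique(as.numeric(st$volumes[[2]]$data))), c(-50, 0))
  expect_true(all(st$volumes[[3]]$data == 0))
  expect_equal(sum(st$volumes[[1]]$data != 0), sum(vta$data))
})

test_that("mean effect divides by N everywhere and matches a naive loop", {
  g <- small_grid(5)
  a <- array(0, c(5, 5, 5)); a[1, 1, 1] <- 10
  b <- array(0, c(5, 5, 5))
  st <- toy_stack(list(a, b), g)
  expect_equal(mean_effect(st)$data[1, 1, 1], 5)

  set.seed(3)
  arrs <- lapply(1:4, function(i) array(rnorm(125) *
                                          rbinom(125, 1, 0.4), c(5, 5, 5)))
  st2 <- toy_stack(arrs, g)
  me <- mean_effect(st2)$data
  brute <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    brute[i, j, k] <- mean(vapply(arrs, function(x) x[i, j, k], 0))
  expect_equal(me, brute)

  same <- toy_stack(list(arrs[[1]], arrs[[1]]), g)
  expect_equal(mean_effect(same)$data, arrs[[1]])
})

test_that("one-sample t matches hand computation and is scale invariant", {
  g <- small_grid(4)
  mk <- function(v) { a <- array(0, c(4, 4, 4)); a[2, 2, 2] <- v; a }
  st <- toy_stack(list(mk(2), mk(4), mk(6)), g)
  p0 <- tfce_params(variance_smoothing_sigma = 0)
  t_img <- onesample_t(st, p0)
  expect_equal(t_img$data[2, 2, 2], 4 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(t_img$data[2, 2, 2], 3.4641, tolerance = 1e-4)

  st_k <- toy_stack(list(mk(2 * 7), mk(4 * 7), mk(6 * 7)), g)
  expect_equal(onesample_t(st_k, p0)$data, t_img$data, tolerance = 1e-12)

  # degenerate variance: equal values at an isolated voxel stay finite
  st_c <- toy_stack(list(mk(3), mk(3), mk(3)), g)
  t_c <- onesample_t(st_c, p0)$data
  expect_true(all(is.finite(t_c)))
  expect_equal(t_c[2, 2, 2], 0) # zero smoothed variance path

  # smoothing borrows variance from a neighbour, regularising the
  # zero-variance voxel to a finite positive t
  mk2 <- function(v, w) { a <- mk(v); a[3, 2, 2] <- w; a }
  st_n <- toy_stack(list(mk2(3, 1), mk2(3, 2), mk2(3, 6)), g)
  t_s <- onesample_t(st_n, tfce_params(variance_smoothing_sigma = 2))$data
  expect_true(all(is.finite(t_s)))
  expect_gt(t_s[2, 2, 2], 0)
})

test_that("TFCE matches the closed-form single-voxel integral and brute force", {
  g <- small_grid(9, vs = 1)
  single <- g; single$data[5, 5, 5] <- 1.5
  tf <- tfce(single, tfce_params(n_steps = 200))
  expect_equal(tf$data[5, 5, 5], 1.5^3 / 3, tolerance = 0.02)

  expect_true(all(tfce(empty_like(g), tfce_params())$data == 0))

  # two disjoint cubes of equal height: the larger wins
  cubes <- g
  cubes$data[1:2, 1:2, 1:2] <- 1        # 8 voxels
  cubes$data[6:9, 6:9, 6:9] <- 1        # 64 voxels
  tfc <- tfce(cubes, tfce_params())$data
  expect_gt(tfc[7, 7, 7], tfc[1, 1, 1])

  # random maps (positive and signed) against the brute-force oracle
  set.seed(21)
  for (rep in 1:3) {
    arr <- array(stats::rnorm(1000), c(10, 10, 10))
    arr[abs(arr) < 0.8] <- 0
    m <- image_volume(arr, diag(4))
    prm <- tfce_params(n_steps = 60, connectivity = c(6, 18, 26)[rep])
    got <- tfce(m, prm)$data
    want <- tfce_oracle(pmax(arr, 0), prm$E, prm$H, prm$n_steps,
                        prm$connectivity) -
      tfce_oracle(pmax(-arr, 0), prm$E, prm$H, prm$n_steps, prm$connectivity)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("TFCE is monotone under pointwise domination", {
  set.seed(5)
  arr <- array(pmax(stats::rnorm(512), 0), c(8, 8, 8))
  lo <- image_volume(arr, diag(4))
  hi <- image_volume(arr + 0.3 * (arr > 0), diag(4))
  prm <- tfce_params(n_steps = 50)
  expect_true(all(tfce(hi, prm)$data - tfce(lo, prm)$data >= -1e-9))
})

test_that("sign-flip inference: all-zero stacks give p = 1 everywhere", {
  st <- toy_stack(list(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))))
  res <- permutation_fwe(st, tfce_params(n_permutations = 128))
  expect_true(all(res$fwe_p$data == 1))
})

test_that("exact enumeration at N = 3 equals the brute-force oracle", {
  set.seed(17)
  arrs <- lapply(1:3, function(i)
    array(stats::rnorm(64) * rbinom(64, 1, 0.5), c(4, 4, 4)))
  st <- toy_stack(arrs)
  prm <- tfce_params(variance_smoothing_sigma = 0, n_steps = 40,
                     n_permutations = 5000)
  res <- permutation_fwe(st, prm)
  expect_true(res$exact)

  mat <- vapply(arrs, as.numeric, numeric(64))
  p_oracle <- perm_fwe_oracle(mat, c(4, 4, 4), prm$E, prm$H, prm$n_steps,
                              prm$connectivity)
  expect_equal(res$fwe_p$data, p_oracle, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values agree with exact enumeration within binomial error", {
  set.seed(31)
  N <- 12
  arrs <- lapply(seq_len(N), function(i)
    array(stats::rnorm(64) * rbinom(64, 1, 0.6), c(4, 4, 4)))
  st <- toy_stack(arrs)
  base <- list(variance_smoothing_sigma = 0, n_steps = 30)
  exact <- permutation_fwe(st, do.call(tfce_params,
                                       c(base, n_permutations = 5000)))
  expect_true(exact$exact)   # 2^12 = 4096 <= 5000
  P <- 1000
  mc <- permutation_fwe(st, do.call(tfce_params,
                                    c(base, n_permutations = P, seed = 77)))
  expect_false(mc$exact)
  pe <- as.numeric(exact$fwe_p$data)
  pm <- as.numeric(mc$fwe_p$data)
  tol <- 3 * sqrt(pe * (1 - pe) / P) + 2 / P
  expect_true(all(abs(pm - pe) <= tol))
})

test_that("coverage mask thresholds by ceiling of the cohort fraction", {
  g <- small_grid(6)
  vtas <- lapply(1:11, function(i) {
    v <- g; v$data[seq_len(min(i, 6)), , ] <- 1; v
  })
  cov <- coverage_mask(vtas, 0.4)      # ceil(4.4) = 5 subjects required
  counts <- Reduce(`+`, lapply(vtas, `[[`, "data"))
  expect_equal(cov$data, array(as.numeric(counts >= 5), dim(counts)))

  expect_equal(coverage_mask(vtas, 0)$data,
               array(as.numeric(counts >= 1), dim(counts)))
  expect_equal(coverage_mask(vtas, 1)$data,
               array(as.numeric(counts >= 11), dim(counts)))
  # exact-integer product: 2 of 5 is exactly 40%
  expect_equal(sum(coverage_mask(vtas[1:5], 0.4)$data),
               sum(Reduce(`+`, lapply(vtas[1:5], `[[`, "data")) >= 2))
})

test_that("centre of gravity matches hand and brute-force computation", {
  aff <- diag(c(2, 2, 1.5, 1)); aff[1:3, 4] <- c(-20, -20, 0)
  v <- image_volume(array(0, c(8, 8, 8)), aff)
  v$data[4, 3, 4] <- 2          # voxel (3,2,3) -> world (-14, -16, 4.5)
  expect_equal(centre_of_gravity(v), c(-14, -16, 4.5))

  g <- small_grid(9)
  two <- g
  ij0 <- round(world_to_voxel(g, c(0, 0, 0))) + 1
  ij2 <- round(world_to_voxel(g, c(2, 0, 0))) + 1
  two$data[ij0[1], ij0[2], ij0[3]] <- 1
  two$data[ij2[1], ij2[2], ij2[3]] <- 1
  expect_equal(centre_of_gravity(two), c(1, 0, 0))

  set.seed(9)
  nv <- length(g$data)
  blob <- g; blob$data[] <- stats::runif(nv) * (stats::runif(nv) < 0.2)
  w <- as.numeric(blob$data)
  xyz <- grid_coordinates(blob)
  expect_equal(centre_of_gravity(blob),
               c(sum(w * xyz[, 1]), sum(w * xyz[, 2]), sum(w * xyz[, 3])) / sum(w))

  expect_error(centre_of_gravity(empty_like(g)), "empty-mask")
  neg <- g; neg$data[1, 1, 1] <- -1
  expect_error(centre_of_gravity(neg), "domain error")
})

test_that("finalize combines significance and coverage; masks nest correctly", {
  g <- small_grid(6)
  me <- g; me$data[] <- 10
  p <- g; p$data[] <- 1; p$data[2:5, 2:5, 2:5] <- 0.01
  cov <- g; cov$data[1:4, 1:4, 1:4] <- 1
  res <- finalize_sweetspot(me, p, cov, tfce_params())
  expect_true(all(res$final_mask$data <= res$sig_mask$data))
  expect_true(all(res$final_mask$data <= res$coverage_mask$data))
  expect_equal(res$weighted_map$data, me$data * res$final_mask$data)
  # COG inside the bounding box of the final mask
  idx <- which(res$final_mask$data != 0, arr.ind = TRUE) - 1
  w <- voxel_to_world(g, idx)
  expect_true(all(res$cog >= apply(w, 2, min) & res$cog <= apply(w, 2, max)))
  expect_equal(unname(res$fwe_p$data[1, 1, 1]), 1)
})

test_that("p-values respect the (1+b)/(P+1) floor", {
  sim <- planted_cohort()
  vtas <- lapply(sim$vtas, `[[`, "vta_6m")
  st <- weight_vtas(vtas, sim$cohort$improvement_6m)
  res <- permutation_fwe(st, tfce_params(n_permutations = 256, seed = 3))
  P <- length(res$null_max)
  expect_gte(min(res$fwe_p$data), 1 / (P + 1))
  expect_lte(max(res$fwe_p$data), 1)
})
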