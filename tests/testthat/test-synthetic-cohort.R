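test_that("phantom nuclei are disjoint, nonempty, bilaterally symmetric", {
  ph <- build_phantom()
  expect_gt(sum(ph$vim_mask$data), 0)
  expect_gt(sum(ph$vop_mask$data), 0)
  expect_equal(sum(ph$vim_mask$data * ph$vop_mask$data), 0)
  rois <- ph$cortical_rois
  expect_named(rois, c("SMA", "PMC", "PSC", "SSC", "PVC", "TL"))
  for (i in seq_along(rois)) {
    expect_gt(sum(rois[[i]]$data), 0)
    for (j in seq_along(rois))
      if (i < j) expect_equal(sum(rois[[i]]$data * rois[[j]]$data), 0)
  }
  # mirror symmetry of every mask
  for (m in c(list(ph$vim_mask, ph$vop_mask), rois))
    expect_equal(mirror_flip_volume(m)$data, m$data)
})

test_that("coarser voxels keep world extents and scale voxel counts by ~1/8", {
  ph1 <- build_phantom(voxel_size_mm = 1)
  ph2 <- build_phantom(voxel_size_mm = 2)
  b1 <- voxel_to_world(ph1$grid, rbind(c(0, 0, 0), dim(ph1$grid$data) - 1))
  b2 <- voxel_to_world(ph2$grid, rbind(c(0, 0, 0), dim(ph2$grid$data) - 1))
  expect_equal(b2[2, ] - b2[1, ], b1[2, ] - b1[1, ], tolerance = 0.05)
  ratio <- sum(ph2$vim_mask$data) / sum(ph1$vim_mask$data)
  expect_equal(ratio, 1 / 8, tolerance = 0.2)
})

test_that("lead placement honors jitter, determinism and grid bounds", {
  ph <- build_phantom()
  pl0 <- place_leads(ph, 4, jitter_sd_mm = 0, seed = 1)
  for (s in pl0) {
    target <- ph$centroids[[paste0("vim_", s$side)]]
    expect_equal(s$leads$VIM$tip_position, target, tolerance = 1e-9)
  }

  pl_a <- place_leads(ph, 6, jitter_sd_mm = 1, seed = 5)
  pl_b <- place_leads(ph, 6, jitter_sd_mm = 1, seed = 5)
  expect_identical(leads_to_table(pl_a), leads_to_table(pl_b))

  expect_error(place_leads(ph, 4, jitter_sd_mm = 40, seed = 3),
               "placement error")
  expect_error(place_leads(ph, 1), "n_subjects")
})

test_that("per-axis deepest-contact offsets follow the folded-normal mean", {
  ph <- build_phantom()
  pl <- place_leads(ph, 100, jitter_sd_mm = 1, frac_right = 0, seed = 11)
  offs <- t(vapply(pl, function(s)
    s$leads$VIM$tip_position - ph$centroids$vim_left, numeric(3)))
  absoff <- abs(as.numeric(offs))           # 300 folded-normal draws, sd 1
  mu <- sqrt(2 / pi)
  se <- sqrt(1 - 2 / pi) / sqrt(length(absoff))
  expect_lt(abs(mean(absoff) - mu), 3 * se)
})

test_that("side assignment matches the requested right-sided fraction", {
  ph <- build_phantom()
  pl <- place_leads(ph, 11, frac_right = 2 / 11, seed = 2)
  expect_equal(sum(vapply(pl, `[[`, "", "side") == "right"), 2)
})

test_that("bundles obey their waypoint construction", {
  ph <- build_phantom()
  tr0 <- synthetic_truth(bundle_specs = data.frame(
    name = c("favorable", "unfavorable", "background"),
    waypoint = c("vop", "vim", "none"), cortex = c("SMA", "PMC", "none"),
    n_streamlines = c(40L, 40L, 40L), jitter_sd_mm = c(0, 0, 0.5)))
  b <- generate_bundles(ph, tr0, seed = 3)
  expect_equal(table(b$labels)[["favorable"]], 40)

  hits <- function(sel, mask) vapply(b$streamlines[sel],
                                     streamline_hits_mask, TRUE, mask = mask)
  fav <- b$labels == "favorable"
  unf <- b$labels == "unfavorable"
  bg <- b$labels == "background"
  # zero-jitter bundles pass through their waypoint nucleus, reach their ROI
  expect_true(all(hits(fav, ph$vop_mask)))
  expect_true(all(hits(fav, ph$cortical_rois$SMA)))
  expect_true(all(hits(unf, ph$vim_mask)))
  expect_true(all(hits(unf, ph$cortical_rois$PMC)))
  # background avoids both nuclei entirely
  both <- aggregate_vta(ph$vim_mask, ph$vop_mask)
  expect_false(any(hits(bg, both)))

  # a bundle with zero streamlines is absent
  tr1 <- synthetic_truth(bundle_specs = data.frame(
    name = "favorable", waypoint = "vop", cortex = "SMA",
    n_streamlines = 0L, jitter_sd_mm = 0))
  expect_length(generate_bundles(ph, tr1, seed = 3), 0)
})

test_that("outcome model is exact in its noiseless part", {
  tr <- synthetic_truth(outcome_coeffs = c(b0 = 5, b_g = 50, b_sma = 0,
                                           b_pmc = 0))
  out <- simulate_outcomes(tr, overlaps = 1, conn_sma = 0, conn_pmc = 0,
                           noise_sd = 0, seed = 1)
  expect_equal(out$improvement, 55)

  tr0 <- synthetic_truth(outcome_coeffs = c(b0 = 12, b_g = 0, b_sma = 0,
                                            b_pmc = 0))
  out0 <- simulate_outcomes(tr0, overlaps = runif(5), conn_sma = runif(5),
                            conn_pmc = runif(5), noise_sd = 0)
  expect_equal(out0$improvement, rep(12, 5))

  # CLT check: noisy mean within 3 standard errors of the noiseless value
  trc <- synthetic_truth(outcome_coeffs = c(b0 = 0, b_g = 50, b_sma = 0,
                                            b_pmc = 0))
  n <- 200
  out_n <- simulate_outcomes(trc, overlaps = rep(0.5, n),
                             conn_sma = rep(0, n), conn_pmc = rep(0, n),
                             noise_sd = 10, seed = 8)
  expect_lt(abs(mean(out_n$improvement) - 25), 3 * 10 / sqrt(n))
})

test_that("cohort simulation is deterministic and its truth record replays exactly", {
  sim <- planted_cohort()
  expect_equal(nrow(sim$cohort), 11)
  expect_equal(sum(sim$cohort$side == "right"), 2)

  # noiseless outcomes recompute exactly from the stored terms
  b <- sim$truth$outcome_coeffs
  recomputed <- b[["b0"]] + b[["b_g"]] * sim$overlaps[, "6m"] +
    b[["b_sma"]] * sim$connectivity[["6m"]][, "SMA"] -
    b[["b_pmc"]] * sim$connectivity[["6m"]][, "PMC"]
  expect_equal(unname(recomputed), sim$noiseless[["6m"]])

  # the JSON truth file carries the same information
  path <- tempfile(fileext = ".json")
  write_truth(sim, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$subjects$noiseless_6m, sim$noiseless[["6m"]])
  replay <- js$outcome_coeffs$b0 + js$outcome_coeffs$b_g * js$subjects$overlap_6m +
    js$outcome_coeffs$b_sma * js$subjects$conn_6m$SMA -
    js$outcome_coeffs$b_pmc * js$subjects$conn_6m$PMC
  expect_equal(replay, sim$noiseless[["6m"]])

  # bit-identical regeneration on a reduced cohort
  a <- simulate_cohort(n_subjects = 3, seed = 9)
  bb <- simulate_cohort(n_subjects = 3, seed = 9)
  expect_identical(a$cohort, bb$cohort)
  expect_identical(a$vtas[[1]]$vta_6m$data, bb$vtas[[1]]$vta_6m$data)
})

test_that("a planted sweet spot outside the nuclei is rejected", {
  expect_error(
    simulate_cohort(truth = synthetic_truth(sweetspot_center = c(0, 20, 0)),
                    n_subjects = 2, seed = 1),
    "not contained")
})
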