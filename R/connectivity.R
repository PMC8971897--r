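#' Deterministic tractography parameters
#'
#' @param n_seeds Number of seed attempts (default 200000; retained
#'   streamline totals are normalised separately).
#' @param step_size Integration step, mm (default 0.5; must not exceed one
#'   voxel of the tracked field).
#' @param max_angle Maximum turning angle between consecutive steps,
#'   degrees (default 45).
#' @param min_length,max_length Retained streamline length bounds, mm
#'   (defaults 10 and 200).
#' @param mask_threshold Stopping threshold on the tracking-support image
#'   (default 0.5).
#' @param seed RNG seed for seed placement.
#' @return A `tracking_params`.
#' @export
tracking_params <- function(n_seeds = 200000L, step_size = 0.5,
                            max_angle = 45, min_length = 10,
                            max_length = 200, mask_threshold = 0.5,
                            seed = 1L) {
  stopifnot(n_seeds > 0, step_size > 0, max_angle > 0, max_angle < 90,
            min_length >= 0, max_length > min_length)
  structure(list(n_seeds = as.integer(n_seeds), step_size = step_size,
                 max_angle = max_angle, min_length = min_length,
                 max_length = max_length, mask_threshold = mask_threshold,
                 seed = as.integer(seed)),
            class = "tracking_params")
}

#' Rasterize a tractogram into a direction field
#'
#' Segment directions (sign-aligned along each segment's dominant axis) are
#' averaged per voxel; the support image counts traversing segments,
#' normalised to [0, 1] by its maximum. Supplies the direction-field
#' tracking path with an in-universe field derived from the planted
#' bundles.
#'
#' @param tract A `tractogram`.
#' @param grid Template `image_volume`.
#' @return List with `dx`, `dy`, `dz` (unit direction components) and
#'   `support` `image_volume`s.
#' @export
bundle_direction_field <- function(tract, grid) {
  d <- dim(grid$data)
  acc <- matrix(0, prod(d), 3)
  cnt <- numeric(prod(d))
  h <- min(voxel_sizes(grid)) / 2
  for (pts in tract$streamlines) {
    pts <- densify_points(pts, h)
    mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
    dir <- diff(pts)
    nrm <- sqrt(rowSums(dir^2))
    dir <- dir / nrm
    # antipodal segments must not cancel: align along the dominant axis
    dom <- max.col(abs(dir))
    flip <- dir[cbind(seq_len(nrow(dir)), dom)] < 0
    dir[flip, ] <- -dir[flip, , drop = FALSE]
    ijk <- round(world_to_voxel(grid, mid))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
          ijk[, 3] >= 0 & ijk[, 3] < d[3]
    if (!any(ok)) next
    lin <- 1 + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
    rs <- rowsum(dir[ok, , drop = FALSE], lin)
    rows <- as.integer(rownames(rs))
    acc[rows, ] <- acc[rows, , drop = FALSE] + rs
    cnt[rows] <- cnt[rows] + as.numeric(rowsum(rep(1, sum(ok)), lin))
  }
  nrm <- sqrt(rowSums(acc^2))
  unit <- acc / pmax(nrm, 1e-12)
  unit[nrm == 0, ] <- 0
  support <- cnt / max(cnt, 1)
  as_vol <- function(v) image_volume(array(v, d), grid$affine, grid$space)
  list(dx = as_vol(unit[, 1]), dy = as_vol(unit[, 2]),
       dz = as_vol(unit[, 3]), support = as_vol(support))
}

#' Deterministic streamline tracking through a direction field
#'
#' Bidirectional fixed-step integration along the local (nearest-voxel)
#' principal direction: from each seed the tracker steps both ways,
#' choosing the direction sign continuous with the previous step, and stops
#' when the turning angle exceeds `max_angle`, the support image falls
#' below `mask_threshold`, the point leaves the grid, or the length cap is
#' reached. Streamlines shorter than `min_length` are discarded. Seeds are
#' drawn uniformly within the nonzero voxels of `seed_mask`.
#'
#' @param field List with `dx`, `dy`, `dz`, `support` `image_volume`s (as
#'   from [bundle_direction_field()]).
#' @param seed_mask Binary `image_volume` of seed voxels (nonempty).
#' @param params A `tracking_params`.
#' @return A `tractogram`; every retained streamline has length in
#'   `[min_length, max_length]` and starts inside the seed mask.
#' @export
track_from_seeds <- function(field, seed_mask, params = tracking_params()) {
  if (sum(seed_mask$data != 0) == 0)
    stop("seeding error: empty seed mask", call. = FALSE)
  if (params$step_size > min(voxel_sizes(field$support)) + 1e-9)
    stop("step_size must not exceed one voxel", call. = FALSE)
  set.seed(params$seed)
  d <- dim(field$support$data)
  cos_max <- cos(params$max_angle * pi / 180)
  max_steps <- ceiling(params$max_length / params$step_size)

  sample_dir <- function(pts) {
    ijk <- round(world_to_voxel(field$support, pts))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
          ijk[, 3] >= 0 & ijk[, 3] < d[3]
    out <- matrix(0, nrow(pts), 4) # dx dy dz support
    if (any(ok)) {
      idx <- cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3]) + 1
      out[ok, 1] <- field$dx$data[idx]
      out[ok, 2] <- field$dy$data[idx]
      out[ok, 3] <- field$dz$data[idx]
      out[ok, 4] <- field$support$data[idx]
    }
    out
  }

  vox <- which(seed_mask$data != 0, arr.ind = TRUE) - 1
  pick <- vox[sample.int(nrow(vox), params$n_seeds, replace = TRUE), ,
              drop = FALSE]
  seeds <- voxel_to_world(seed_mask,
                          pick + matrix(stats::runif(3 * params$n_seeds,
                                                     -0.5, 0.5),
                                        ncol = 3))

  half_steps <- ceiling(max_steps / 2)
  # vectorised half-tracking: a chunk of seeds steps together
  half_track <- function(seeds, sign0) {
    n <- nrow(seeds)
    traj <- array(NA_real_, c(n, 3, half_steps))
    taken <- integer(n)
    pos <- seeds
    s0 <- sample_dir(seeds)
    prev <- s0[, 1:3, drop = FALSE] * sign0
    nrm <- sqrt(rowSums(prev^2))
    active <- s0[, 4] >= params$mask_threshold & nrm > 1e-12
    prev <- prev / pmax(nrm, 1e-12)
    for (step in seq_len(half_steps)) {
      if (!any(active)) break
      act <- which(active)
      pos[act, ] <- pos[act, , drop = FALSE] +
        params$step_size * prev[act, , drop = FALSE]
      traj[act, , step] <- pos[act, , drop = FALSE]
      taken[act] <- step
      smp <- sample_dir(pos[act, , drop = FALSE])
      dir <- smp[, 1:3, drop = FALSE]
      nrm <- sqrt(rowSums(dir^2))
      alive <- smp[, 4] >= params$mask_threshold & nrm > 1e-12
      dir <- dir / pmax(nrm, 1e-12)
      dots <- rowSums(dir * prev[act, , drop = FALSE])
      dir[dots < 0, ] <- -dir[dots < 0, , drop = FALSE]
      alive <- alive & abs(dots) >= cos_max
      prev[act, ] <- dir
      active[act] <- alive
    }
    list(traj = traj, taken = taken)
  }

  streamlines <- list(); ids <- integer(0)
  chunk_size <- 5000L
  for (start in seq(1L, nrow(seeds), by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, nrow(seeds))
    sd_chunk <- seeds[sel, , drop = FALSE]
    fwd <- half_track(sd_chunk, +1)
    bwd <- half_track(sd_chunk, -1)
    slice_traj <- function(traj, j, idx) {
      m <- traj[j, , idx]
      if (is.null(dim(m))) matrix(m, 1, 3) else t(m)
    }
    for (j in seq_along(sel)) {
      nb <- bwd$taken[j]; nf <- fwd$taken[j]
      pts <- rbind(
        if (nb > 0) slice_traj(bwd$traj, j, nb:1),
        sd_chunk[j, , drop = FALSE],
        if (nf > 0) slice_traj(fwd$traj, j, seq_len(nf)))
      if (nrow(pts) < 2) next
      len <- (nrow(pts) - 1) * params$step_size
      if (len < params$min_length || len > params$max_length) next
      streamlines[[length(streamlines) + 1L]] <- pts
      ids <- c(ids, sel[j])
    }
  }
  if (length(streamlines) == 0) return(empty_tractogram())
  tractogram(streamlines, ids)
}

#' Select streamlines intersecting a seed region
#'
#' Realises VTA "seeding" against a precomputed shared tractogram: a
#' streamline is retained iff at least one of its points, after segment
#' sub-sampling at half-voxel spacing, falls inside a nonzero voxel of the
#' region. Idempotent.
#'
#' @param tract A `tractogram`.
#' @param region Binary `image_volume`.
#' @return The selected `tractogram` (ids and labels preserved).
#' @export
select_streamlines <- function(tract, region) {
  if (length(tract) == 0) return(tract)
  keep <- vapply(tract$streamlines, streamline_hits_mask, TRUE, mask = region)
  subset_tractogram(tract, keep)
}

#' Per-ROI connectivity fractions
#'
#' `fraction_ROI = #\{streamlines intersecting ROI\} / total`, with the same
#' half-voxel sub-sampled intersection test as [select_streamlines()]. With
#' `mode = "end"` only streamline endpoints count.
#'
#' @param tract A `tractogram` (e.g. the VTA-selected set).
#' @param rois Named list of binary `image_volume`s.
#' @param total Normalising total streamline count (e.g. the number of
#'   streamlines seeded/selected for the subject).
#' @param mode "pass" (default: traversal or termination) or "end".
#' @return A `connectivity_profile` with `fractions` (named, in [0, 1]) and
#'   `total_streamlines`.
#' @export
connectivity_fractions <- function(tract, rois, total,
                                   mode = c("pass", "end")) {
  mode <- match.arg(mode)
  stopifnot(total >= 0)
  counts <- vapply(rois, function(roi) {
    if (length(tract) == 0) return(0L)
    sum(vapply(tract$streamlines, function(pts) {
      if (mode == "end") pts <- pts[c(1L, nrow(pts)), , drop = FALSE]
      streamline_hits_mask(pts, roi, densify = mode == "pass")
    }, TRUE))
  }, 0L)
  fractions <- if (total > 0) counts / total else counts * 0
  structure(list(fractions = fractions, counts = counts,
                 total_streamlines = as.integer(total)),
            class = "connectivity_profile")
}

#' Discard ROIs with zero connectivity in every subject
#'
#' @param profiles Subject x ROI matrix of connectivity fractions.
#' @return Character vector of retained ROI names.
#' @export
drop_zero_rois <- function(profiles) {
  colnames(profiles)[colSums(profiles != 0) > 0]
}

#' Regress tremor improvement on per-ROI connectivity
#'
#' Ordinary least squares of percent improvement on connectivity fraction
#' for each retained ROI, with Spearman's rank correlation (average ranks
#' for ties) and the pointwise 95% confidence band of the best-fit line.
#' ROIs with zero connectivity in all subjects are discarded first.
#'
#' @param profiles Subject x ROI matrix of connectivity fractions.
#' @param improvements Percent improvement per subject.
#' @return A `regression_fits` data frame (roi, slope, intercept,
#'   spearman_rho, spearman_p, n) with the per-ROI confidence bands in
#'   attribute `"bands"`.
#' @export
regress_connectivity <- function(profiles, improvements) {
  stopifnot(nrow(profiles) == length(improvements))
  keep <- is.finite(improvements)
  if (sum(keep) < 3) stop("need >= 3 subjects with finite improvement",
                          call. = FALSE)
  profiles <- profiles[keep, , drop = FALSE]
  improvements <- improvements[keep]
  rois <- drop_zero_rois(profiles)
  bands <- list()
  rows <- lapply(rois, function(roi) {
    x <- profiles[, roi]
    fit <- stats::lm(improvements ~ x)
    xg <- seq(min(x), max(x), length.out = 50)
    ci <- stats::predict(fit, newdata = data.frame(x = xg),
                         interval = "confidence", level = 0.95)
    bands[[roi]] <<- data.frame(x = xg, fit = ci[, "fit"],
                                lwr = ci[, "lwr"], upr = ci[, "upr"])
    rho <- stats::cor(x, improvements, method = "spearman")
    rho_p <- tryCatch(
      suppressWarnings(stats::cor.test(x, improvements,
                                       method = "spearman")$p.value),
      error = function(e) NA_real_)
    data.frame(roi = roi, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               spearman_rho = rho, spearman_p = rho_p,
               n = length(x))
  })
  out <- do.call(rbind, rows)
  attr(out, "bands") <- bands
  class(out) <- c("regression_fits", "data.frame")
  out
}
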