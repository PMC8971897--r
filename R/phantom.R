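#' Build the synthetic phantom space
#'
#' A bilaterally symmetric cubic phantom (default 48 mm extent, 1 mm
#' isotropic voxels, world origin at the cube center so the grid is
#' symmetric about x = 0). A thalamus-like ellipsoid in each hemisphere is
#' split by a coronal plane into an anterior VOp-like nucleus and a
#' posterior VIM-like nucleus. Six disjoint cortical ROI boxes stand in for
#' the cortical parcellation: SMA, PMC, PSC and SSC along the superior
#' convexity (anterior to posterior), PVC at the posterior pole and TL
#' inferiorly.
#'
#' @param extent_mm World edge length of the cubic grid (mm); fixed phantom
#'   anatomy assumes the default 48.
#' @param voxel_size_mm Isotropic voxel size (mm). Halving the extent is not
#'   supported; coarser voxels on the same extent are (e.g. 2.0 for a
#'   downsampled grid).
#' @param thal_center Center of the left thalamus ellipsoid (mirrored for
#'   the right), world mm.
#' @param thal_semiaxes Ellipsoid semi-axes (mm).
#' @param border_y Coronal plane (world y, mm) splitting VIM (y <= border)
#'   from VOp (y > border).
#' @return A `phantom_space` with fields `grid` (zero template
#'   `image_volume`), `vim_mask`, `vop_mask`, `cortical_rois` (named list of
#'   six binary volumes), `centroids` (left/right VIM and VOp centroids) and
#'   the construction parameters.
#' @export
build_phantom <- function(extent_mm = 48, voxel_size_mm = 1.0,
                          thal_center = c(-10, 0, 0),
                          thal_semiaxes = c(5, 9, 6), border_y = -1) {
  n <- round(extent_mm / voxel_size_mm)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -(n - 1) / 2 * voxel_size_mm
  grid <- image_volume(array(0, c(n, n, n)), affine)
  xyz <- grid_coordinates(grid)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]

  in_thal <- function(cx) {
    ((x - cx) / thal_semiaxes[1])^2 + ((y - thal_center[2]) / thal_semiaxes[2])^2 +
      ((z - thal_center[3]) / thal_semiaxes[3])^2 <= 1
  }
  thal <- in_thal(thal_center[1]) | in_thal(-thal_center[1])
  as_vol <- function(v) image_volume(array(as.numeric(v), dim(grid$data)),
                                     affine)
  vim <- as_vol(thal & y <= border_y)
  vop <- as_vol(thal & y > border_y)

  lat <- abs(x) >= 2 & abs(x) <= 16
  rois <- list(
    SMA = as_vol(z >= 18 & z <= 22 & y >= 8 & y <= 15 & lat),
    PMC = as_vol(z >= 18 & z <= 22 & y >= 1 & y <= 7 & lat),
    PSC = as_vol(z >= 18 & z <= 22 & y >= -6 & y <= 0 & lat),
    SSC = as_vol(z >= 18 & z <= 22 & y >= -13 & y <= -7 & lat),
    PVC = as_vol(y >= -22 & y <= -18 & abs(z) <= 8 & lat),
    TL  = as_vol(z >= -22 & z <= -18 & abs(y) <= 8 & lat)
  )

  centroid_of <- function(mask, hemisphere) {
    sel <- mask$data != 0 &
      array(if (hemisphere == "left") x < 0 else x > 0, dim(mask$data))
    w <- which(sel, arr.ind = TRUE) - 1
    colMeans(voxel_to_world(mask, w))
  }
  centroids <- list(
    vim_left = centroid_of(vim, "left"), vim_right = centroid_of(vim, "right"),
    vop_left = centroid_of(vop, "left"), vop_right = centroid_of(vop, "right")
  )

  structure(list(grid = grid, vim_mask = vim, vop_mask = vop,
                 cortical_rois = rois, centroids = centroids,
                 extent_mm = extent_mm, voxel_size_mm = voxel_size_mm,
                 thal_center = thal_center, thal_semiaxes = thal_semiaxes,
                 border_y = border_y),
            class = "phantom_space")
}

#' @export
print.phantom_space <- function(x, ...) {
  cat(sprintf("<phantom_space> %s grid, %.3g mm voxels\n",
              paste(dim(x$grid$data), collapse = "x"), x$voxel_size_mm))
  cat(sprintf("  VIM %d voxels, VOp %d voxels, ROIs: %s\n",
              sum(x$vim_mask$data), sum(x$vop_mask$data),
              paste(names(x$cortical_rois), collapse = " ")))
  invisible(x)
}

#' Planted ground truth for the synthetic cohort
#'
#' Encodes everything the downstream stages are expected to recover: a
#' spherical sweet spot at the VOp/VIM border, favorable (VOp to SMA) and
#' unfavorable (VIM to PMC) bundles plus background fibers, and a linear
#' outcome model
#' `improvement = b0 + b_g * overlap + b_sma * C_SMA - b_pmc * C_PMC + noise`
#' where `overlap` is |VTA intersect sweet spot| / |sweet spot| and C_* are
#' connectivity fractions.
#'
#' @param sweetspot_center World mm center of the planted sweet spot.
#' @param sweetspot_radius Radius, mm.
#' @param bundle_specs Data frame with columns `name`, `waypoint`
#'   ("vim"/"vop"/"none"), `cortex` (ROI name or "none"), `n_streamlines`,
#'   `jitter_sd_mm` (per-streamline rigid Gaussian offset).
#' @param outcome_coeffs Named vector `b0`, `b_g`, `b_sma`, `b_pmc`
#'   (percent; `b_pmc` enters negatively).
#' @param noise_sd Outcome noise SD, percent (>= 0).
#' @param seed RNG seed for all generation.
#' @return A `synthetic_truth`.
#' @export
synthetic_truth <- function(sweetspot_center = c(-10, 1.5, 0),
                            sweetspot_radius = 2.5,
                            bundle_specs = default_bundle_specs(),
                            outcome_coeffs = c(b0 = -100, b_g = 150,
                                               b_sma = 120, b_pmc = 145),
                            noise_sd = 10, seed = 42L) {
  stopifnot(noise_sd >= 0, sweetspot_radius > 0,
            all(c("b0", "b_g", "b_sma", "b_pmc") %in% names(outcome_coeffs)))
  structure(list(sweetspot_center = as.numeric(sweetspot_center),
                 sweetspot_radius = sweetspot_radius,
                 bundle_specs = as.data.frame(bundle_specs),
                 outcome_coeffs = outcome_coeffs[c("b0", "b_g", "b_sma", "b_pmc")],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @export
default_bundle_specs <- function() {
  data.frame(
    name = c("favorable", "unfavorable", "background"),
    waypoint = c("vop", "vim", "none"),
    cortex = c("SMA", "PMC", "none"),
    n_streamlines = c(300L, 300L, 400L),
    jitter_sd_mm = c(1.0, 1.0, 0.5)
  )
}

#' Binary sphere mask on a grid
#' @param grid Template `image_volume`.
#' @param center World mm center.
#' @param radius mm.
#' @return Binary `image_volume`.
#' @export
sphere_mask <- function(grid, center, radius) {
  xyz <- grid_coordinates(grid)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2
  out <- empty_like(grid)
  out$data <- array(as.numeric(d2 <= radius^2), dim(grid$data))
  out
}

world_bounds <- function(vol) {
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- voxel_to_world(vol, corners)
  list(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Place per-subject dual leads
#'
#' Each subject receives one lead targeting the VIM centroid and one
#' targeting the VOp centroid of the operated hemisphere, implanted
#' vertically. The deepest contact lands on the nucleus centroid plus
#' isotropic Gaussian placement jitter; contact 0 is the active cathode
#' (monopolar) with a per-lead current drawn uniformly from
#' `current_range_ma`.
#'
#' @param space A `phantom_space`.
#' @param n_subjects Cohort size (>= 2).
#' @param jitter_sd_mm Placement jitter SD (mm).
#' @param frac_right Fraction of right-sided surgeries (default 2/11).
#' @param current_range_ma Range for the cathodal current magnitude (mA);
#'   either a single `c(lo, hi)` shared by both leads or a named list
#'   `list(VIM = c(lo, hi), VOp = c(lo, hi))`.
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return A `lead_placements` list, one element per subject with fields
#'   `id`, `side`, `leads` (VIM/VOp `lead_model`s) and `stim` (VIM/VOp
#'   `stim_setting`s).
#' @export
place_leads <- function(space, n_subjects, jitter_sd_mm = 0.4,
                        frac_right = 2 / 11,
                        current_range_ma = default_current_ranges(),
                        seed = NULL) {
  stopifnot(n_subjects >= 2)
  if (!is.list(current_range_ma))
    current_range_ma <- list(VIM = current_range_ma, VOp = current_range_ma)
  if (!is.null(seed)) set.seed(seed)
  n_right <- round(frac_right * n_subjects)
  sides <- rep("left", n_subjects)
  sides[sample.int(n_subjects, n_right)] <- "right"
  bounds <- world_bounds(space$grid)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    leads <- list(); stims <- list()
    for (nucleus in c("VIM", "VOp")) {
      target <- space$centroids[[paste0(tolower(nucleus), "_", sides[i])]]
      tip <- target + stats::rnorm(3, 0, jitter_sd_mm)
      lead <- lead_model(tip, label = nucleus)
      cc <- lead$contact_centers
      if (any(cc < matrix(bounds$lo, nrow(cc), 3, byrow = TRUE)) ||
          any(cc > matrix(bounds$hi, nrow(cc), 3, byrow = TRUE)))
        stop("placement error: lead contacts exit the grid for subject ", i,
             call. = FALSE)
      rng_ma <- current_range_ma[[nucleus]]
      amp <- -stats::runif(1, rng_ma[1], rng_ma[2])
      leads[[nucleus]] <- lead
      stims[[nucleus]] <- stim_setting(
        data.frame(contact = 0L, amplitude = amp))
    }
    subjects[[i]] <- list(id = as.character(i), side = sides[i],
                          leads = leads, stim = stims)
  }
  structure(subjects, class = "lead_placements")
}

#' @rdname place_leads
#' @export
default_current_ranges <- function() {
  list(VIM = c(0.5, 4.5), VOp = c(3.4, 3.6))
}

#' Flatten lead placements to a table (one row per active contact)
#' @param placements A `lead_placements`.
#' @return Data frame suitable for [write_table()].
#' @export
leads_to_table <- function(placements) {
  do.call(rbind, lapply(placements, function(s) {
    do.call(rbind, lapply(names(s$leads), function(nm) {
      ld <- s$leads[[nm]]; st <- s$stim[[nm]]
      data.frame(subject = s$id, side = s$side, lead = nm,
                 tip_x = ld$tip_position[1], tip_y = ld$tip_position[2],
                 tip_z = ld$tip_position[3], dir_x = ld$direction[1],
                 dir_y = ld$direction[2], dir_z = ld$direction[3],
                 contact = st$active$contact, amplitude = st$active$amplitude,
                 mode = st$mode)
    }))
  }))
}

#' Rebuild lead placements from a table
#' @param tab Data frame as produced by [leads_to_table()].
#' @return A `lead_placements`.
#' @export
table_to_leads <- function(tab) {
  subjects <- lapply(split(tab, factor(tab$subject, unique(tab$subject))),
    function(rows) {
      leads <- list(); stims <- list()
      for (nm in unique(rows$lead)) {
        r <- rows[rows$lead == nm, ]
        leads[[nm]] <- lead_model(c(r$tip_x[1], r$tip_y[1], r$tip_z[1]),
                                  c(r$dir_x[1], r$dir_y[1], r$dir_z[1]),
                                  label = nm)
        stims[[nm]] <- stim_setting(
          data.frame(contact = r$contact, amplitude = r$amplitude),
          mode = r$mode[1])
      }
      list(id = as.character(rows$subject[1]), side = rows$side[1],
           leads = leads, stim = stims)
    })
  structure(unname(subjects), class = "lead_placements")
}

sample_points_in_mask <- function(mask, n, hemisphere = "left") {
  x <- grid_coordinates(mask)[, 1]
  sel <- which(mask$data != 0 &
                 array(if (hemisphere == "left") x < 0 else x > 0,
                       dim(mask$data)))
  if (length(sel) == 0) stop("empty mask for point sampling", call. = FALSE)
  idx <- sel[sample.int(length(sel), n, replace = TRUE)]
  ijk <- cbind((idx - 1) %% dim(mask$data)[1],
               ((idx - 1) %/% dim(mask$data)[1]) %% dim(mask$data)[2],
               (idx - 1) %/% (dim(mask$data)[1] * dim(mask$data)[2]))
  jit <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
  voxel_to_world(mask, ijk + jit)
}

bezier_points <- function(p0, p1, p2, spacing = 0.8) {
  chord <- sqrt(sum((p2 - p0)^2))
  n <- max(8L, ceiling(1.2 * chord / spacing))
  tt <- seq(0, 1, length.out = n)
  b0 <- (1 - tt)^2; b1 <- 2 * tt * (1 - tt); b2 <- tt^2
  cbind(b0 * p0[1] + b1 * p1[1] + b2 * p2[1],
        b0 * p0[2] + b1 * p1[2] + b2 * p2[2],
        b0 * p0[3] + b1 * p1[3] + b2 * p2[3])
}

#' Generate the shared synthetic tractogram
#'
#' One cohort-level tractogram (the normative-connectome analogue) in the
#' left hemisphere: favorable streamlines run from inside VOp to the SMA
#' ROI, unfavorable from inside VIM to the PMC ROI, background fibers run
#' anterior-posteriorly clear of both nuclei. Each streamline is a smooth
#' quadratic arc displaced by one rigid Gaussian offset (the bundle's jitter
#' SD); with zero jitter every bundle streamline passes through its waypoint
#' nucleus by construction.
#'
#' @param space A `phantom_space`.
#' @param truth A `synthetic_truth` (supplies `bundle_specs`).
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return A labelled `tractogram`.
#' @export
generate_bundles <- function(space, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- truth$bundle_specs
  streamlines <- list(); labels <- character(0)
  for (k in seq_len(nrow(specs))) {
    n <- specs$n_streamlines[k]
    if (n == 0) next
    jit_sd <- specs$jitter_sd_mm[k]
    if (specs$waypoint[k] != "none") {
      wp_mask <- if (specs$waypoint[k] == "vim") space$vim_mask else space$vop_mask
      roi <- space$cortical_rois[[specs$cortex[k]]]
      p0s <- sample_points_in_mask(wp_mask, n, "left")
      p2s <- sample_points_in_mask(roi, n, "left")
      for (i in seq_len(n)) {
        p0 <- p0s[i, ]; p2 <- p2s[i, ]
        # extend below the nucleus so fibers traverse, not merely touch
        pstart <- p0 + c(0, 0, -4)
        mid <- (p0 + p2) / 2 + stats::rnorm(3, 0, 1.5)
        pts <- rbind(pstart, bezier_points(p0, mid, p2))
        off <- stats::rnorm(3, 0, jit_sd)
        streamlines[[length(streamlines) + 1L]] <- sweep(pts, 2, -off)
      }
    } else {
      # background: straight x-traversing lines clear of the thalamus
      for (i in seq_len(n)) {
        ysign <- if (i %% 2 == 0) 1 else -1
        y0 <- ysign * stats::runif(1, 13, 18)
        z0 <- stats::runif(1, -8, 8)
        pts <- cbind(seq(-20, 20, by = 1), y0, z0)
        off <- stats::rnorm(3, 0, jit_sd)
        streamlines[[length(streamlines) + 1L]] <- sweep(pts, 2, -off)
      }
    }
    labels <- c(labels, rep(specs$name[k], n))
  }
  if (length(streamlines) == 0) return(empty_tractogram())
  tractogram(streamlines, seq_along(streamlines), labels)
}
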