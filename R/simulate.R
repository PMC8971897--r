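#' Sweet-spot overlap fraction of a VTA
#'
#' |VTA intersect sweet-spot sphere| / |sphere|, in voxel counts on the
#' VTA's grid.
#'
#' @param vta Binary `image_volume`.
#' @param truth A `synthetic_truth` (or list with `sweetspot_center`,
#'   `sweetspot_radius`).
#' @return Overlap fraction in [0, 1].
#' @export
sweetspot_overlap <- function(vta, truth) {
  sph <- sphere_mask(vta, truth$sweetspot_center, truth$sweetspot_radius)
  n_sph <- sum(sph$data)
  if (n_sph == 0) return(0)
  sum(sph$data != 0 & vta$data != 0) / n_sph
}

#' Simulate clinical outcomes from planted truth
#'
#' The generative outcome model:
#' `improvement_i = b0 + b_g * O_i + b_sma * C_i(SMA) - b_pmc * C_i(PMC) + e_i`
#' with `O_i` the sweet-spot overlap of subject i's VTA, `C_i(.)` the
#' connectivity fractions, and `e_i ~ Normal(0, noise_sd^2)`. Improvements
#' are percent and may be negative (worsening).
#'
#' @param truth A `synthetic_truth` (supplies coefficients).
#' @param overlaps Numeric vector `O_i`.
#' @param conn_sma,conn_pmc Connectivity fractions per subject.
#' @param noise_sd Noise SD (percent); defaults to `truth$noise_sd`.
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return List with `improvement` (noisy) and `noiseless` vectors.
#' @export
simulate_outcomes <- function(truth, overlaps, conn_sma, conn_pmc,
                              noise_sd = truth$noise_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd >= 0,
            length(conn_sma) == length(overlaps),
            length(conn_pmc) == length(overlaps))
  b <- truth$outcome_coeffs
  noiseless <- b[["b0"]] + b[["b_g"]] * overlaps + b[["b_sma"]] * conn_sma -
    b[["b_pmc"]] * conn_pmc
  list(improvement = noiseless + stats::rnorm(length(overlaps), 0, noise_sd),
       noiseless = noiseless)
}

subject_lead_vta <- function(space, subject, cond, which_leads) {
  vtas <- lapply(which_leads, function(nm) {
    ef <- efield_magnitude(subject$leads[[nm]], subject$stim[[nm]], cond,
                           space$grid)
    threshold_vta(ef, cond)
  })
  v <- Reduce(aggregate_vta, vtas)
  if (subject$side == "right") v <- mirror_flip_volume(v)
  v
}

subject_connectivity <- function(bundles, vta, rois) {
  sel <- select_streamlines(bundles, vta)
  connectivity_fractions(sel, rois, total = length(sel))
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Runs the complete generative model: phantom anatomy, jittered dual-lead
#' placements, shared bundles, per-subject electric fields and VTAs
#' (right-sided subjects mirrored to the left hemisphere), sweet-spot
#' overlaps, connectivity fractions, and outcomes at 3 months (single-lead
#' stimulation of the initial target) and 6 months (dual-lead stimulation,
#' aggregate VTA). Everything is deterministic given `seed`.
#'
#' @param truth A `synthetic_truth`.
#' @param n_subjects Cohort size (default 11).
#' @param frac_right Fraction right-sided (default 2/11).
#' @param jitter_sd_mm Lead placement jitter SD, mm.
#' @param current_range_ma Cathodal current magnitude range, mA.
#' @param noise_sd Outcome noise SD (percent); defaults to `truth$noise_sd`.
#' @param cond A `conductivity_params`.
#' @param space_args List of arguments for [build_phantom()].
#' @param seed Master seed (default `truth$seed`).
#' @return A `synthetic_cohort` list: `space`, `truth`, `placements`,
#'   `bundles`, `cohort` (a `cohort_table`), `vtas` (per subject: `vta_3m`,
#'   `vta_6m`, both left-hemisphere), `overlaps`, `connectivity` (per-
#'   timepoint subject x ROI matrices) and `noiseless` improvements.
#' @export
simulate_cohort <- function(truth = synthetic_truth(), n_subjects = 11,
                            frac_right = 2 / 11, jitter_sd_mm = 0.4,
                            current_range_ma = default_current_ranges(),
                            noise_sd = truth$noise_sd,
                            cond = conductivity_params(),
                            space_args = list(), seed = truth$seed) {
  set.seed(seed)
  space <- do.call(build_phantom, space_args)
  check_sweetspot_inside(space, truth)
  placements <- place_leads(space, n_subjects, jitter_sd_mm, frac_right,
                            current_range_ma)
  bundles <- generate_bundles(space, truth)

  roi_names <- names(space$cortical_rois)
  vtas <- vector("list", n_subjects)
  overlaps <- matrix(NA_real_, n_subjects, 2,
                     dimnames = list(NULL, c("3m", "6m")))
  conn <- list("3m" = matrix(0, n_subjects, length(roi_names),
                             dimnames = list(NULL, roi_names)),
               "6m" = matrix(0, n_subjects, length(roi_names),
                             dimnames = list(NULL, roi_names)))
  initial_target <- ifelse(seq_len(n_subjects) %% 2 == 1, "VIM", "VOp")
  for (i in seq_len(n_subjects)) {
    s <- placements[[i]]
    v3 <- subject_lead_vta(space, s, cond, initial_target[i])
    v6 <- subject_lead_vta(space, s, cond, c("VIM", "VOp"))
    vtas[[i]] <- list(vta_3m = v3, vta_6m = v6)
    overlaps[i, ] <- c(sweetspot_overlap(v3, truth),
                       sweetspot_overlap(v6, truth))
    conn[["3m"]][i, ] <- subject_connectivity(bundles, v3,
                                              space$cortical_rois)$fractions
    conn[["6m"]][i, ] <- subject_connectivity(bundles, v6,
                                              space$cortical_rois)$fractions
  }

  out3 <- simulate_outcomes(truth, overlaps[, "3m"], conn[["3m"]][, "SMA"],
                            conn[["3m"]][, "PMC"], noise_sd)
  out6 <- simulate_outcomes(truth, overlaps[, "6m"], conn[["6m"]][, "SMA"],
                            conn[["6m"]][, "PMC"], noise_sd)

  n_rr <- max(0L, n_subjects - round(0.27 * n_subjects) - 1L)
  subtypes <- sample(c(rep("relapsing-remitting", n_rr),
                       rep("primary-progressive",
                           max(1L, round(0.27 * n_subjects))),
                       rep("secondary-progressive",
                           n_subjects - n_rr -
                             max(1L, round(0.27 * n_subjects)))))
  cohort <- as_cohort_table(data.frame(
    id = as.character(seq_len(n_subjects)),
    age = pmin(80, pmax(18, round(stats::rnorm(n_subjects, 44, 14)))),
    sex = sample(c("F", "M"), n_subjects, TRUE, prob = c(0.9, 0.1)),
    ms_subtype = subtypes,
    initial_target = initial_target,
    side = vapply(placements, `[[`, "", "side"),
    baseline_trs_motor = pmax(5, round(stats::rnorm(n_subjects, 40.4, 9))),
    improvement_3m = round(out3$improvement, 1),
    improvement_6m = round(out6$improvement, 1)
  ))

  structure(list(space = space, truth = truth, placements = placements,
                 bundles = bundles, cohort = cohort, vtas = vtas,
                 overlaps = overlaps, connectivity = conn,
                 noiseless = list("3m" = out3$noiseless,
                                  "6m" = out6$noiseless),
                 seed = seed),
            class = "synthetic_cohort")
}

check_sweetspot_inside <- function(space, truth) {
  sph <- sphere_mask(space$grid, truth$sweetspot_center,
                     truth$sweetspot_radius)
  inside <- space$vim_mask$data != 0 | space$vop_mask$data != 0
  if (any(sph$data != 0 & !inside))
    stop("planted sweet spot is not contained in VIM union VOp",
         call. = FALSE)
  invisible(TRUE)
}

#' Serialize planted truth to JSON
#'
#' The written record (coefficients, sweet spot, bundle specs, per-subject
#' overlap and connectivity terms) is sufficient to recompute every
#' noiseless outcome exactly.
#'
#' @param sim A `synthetic_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  truth <- sim$truth
  obj <- list(
    sweetspot_center = truth$sweetspot_center,
    sweetspot_radius = truth$sweetspot_radius,
    bundle_specs = truth$bundle_specs,
    outcome_coeffs = as.list(truth$outcome_coeffs),
    noise_sd = truth$noise_sd,
    seed = sim$seed,
    subjects = lapply(seq_len(nrow(sim$cohort)), function(i) list(
      id = sim$cohort$id[i],
      overlap_3m = sim$overlaps[i, "3m"], overlap_6m = sim$overlaps[i, "6m"],
      conn_3m = as.list(sim$connectivity[["3m"]][i, ]),
      conn_6m = as.list(sim$connectivity[["6m"]][i, ]),
      noiseless_3m = sim$noiseless[["3m"]][i],
      noiseless_6m = sim$noiseless[["6m"]][i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
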