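#' Default run configuration
#'
#' Nested parameter blocks mirroring each stage, serializable to/from JSON.
#' Unknown keys are rejected on validation.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 42L,
    stages = list(simulate = TRUE, vta = TRUE, sweetspot = TRUE,
                  connectivity = TRUE, fiberfilter = TRUE, summarize = TRUE),
    simulate = list(n_subjects = 11L, frac_right = 2 / 11,
                    jitter_sd_mm = 0.4, current_range_ma = list(VIM = c(0.5, 4.5),
                                            VOp = c(3.4, 3.6)),
                    noise_sd = 10, voxel_size_mm = 1.0),
    vta = list(sigma_s_per_m = 0.14, efield_threshold_v_per_mm = 0.2,
               impedance_ohm = 1000),
    sweetspot = list(E = 0.5, H = 2.0, n_steps = 100L, connectivity = 26L,
                     variance_smoothing_sigma = 2.5, n_permutations = 5000L,
                     alpha = 0.05, coverage_fraction = 0.4,
                     timepoint = "6m"),
    connectivity = list(timepoint = "6m"),
    fiberfilter = list(lower_fraction = 0.2, upper_fraction = 0.8,
                       var_type = "pooled", timepoint = "6m")
  ), class = "run_config")
}

#' Read / write / validate a run configuration
#'
#' @param path JSON path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_keys <- function(cfg, ref, prefix = "") {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown) > 0)
      stop("validation error: unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    for (k in names(cfg))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        check_keys(as.list(cfg[[k]]), ref[[k]], paste0(prefix, k, "."))
  }
  check_keys(as.list(config), ref)
  merged <- utils::modifyList(unclass(ref), as.list(config))
  structure(merged, class = "run_config")
}

write_provenance <- function(dir, stage, params, seed, inputs, outputs) {
  rec <- list(stage = stage, params = params, seed = seed,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = outputs)
  path <- file.path(dir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> vta -> sweetspot -> connectivity -> fiberfilter
#' -> summarize, writing each stage's outputs plus a JSON provenance record
#' (input hashes, parameters, seed) under `out_dir`. Deterministic stages
#' are bit-identical on rerun with the same config.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (named list of per-stage output files), also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  cond <- conductivity_params(config$vta$sigma_s_per_m,
                              config$vta$efield_threshold_v_per_mm,
                              config$vta$impedance_ohm)

  if (isTRUE(config$stages$simulate)) {
    sc <- config$simulate
    sim <- simulate_cohort(
      truth = synthetic_truth(seed = config$seed),
      n_subjects = sc$n_subjects, frac_right = sc$frac_right,
      jitter_sd_mm = sc$jitter_sd_mm,
      current_range_ma = sc$current_range_ma, noise_sd = sc$noise_sd,
      cond = cond, space_args = list(voxel_size_mm = sc$voxel_size_mm),
      seed = config$seed)
    files <- c(
      vim_mask = write_volume(sim$space$vim_mask,
                              file.path(out_dir, "vim_mask.nii.gz")),
      vop_mask = write_volume(sim$space$vop_mask,
                              file.path(out_dir, "vop_mask.nii.gz")),
      bundles = write_tractogram(sim$bundles,
                                 file.path(out_dir, "bundles.trk"),
                                 sim$space$grid),
      leads = write_table(leads_to_table(sim$placements),
                          file.path(out_dir, "leads.csv")),
      cohort = write_table(sim$cohort, file.path(out_dir, "cohort.csv")),
      truth = write_truth(sim, file.path(out_dir, "truth.json")))
    for (nm in names(sim$space$cortical_rois))
      files[paste0("roi_", nm)] <- write_volume(
        sim$space$cortical_rois[[nm]],
        file.path(out_dir, paste0("roi_", nm, ".nii.gz")))
    write_provenance(out_dir, "simulate", config$simulate, config$seed,
                     character(0), as.list(files))
    manifest$simulate <- as.list(files)
    bundle_labels <- data.frame(id = sim$bundles$ids,
                                label = sim$bundles$labels)
    manifest$simulate$bundle_labels <-
      write_table(bundle_labels, file.path(out_dir, "bundle_labels.csv"))
  }

  need <- function(key, stage) {
    path <- file.path(out_dir, key)
    if (!file.exists(path))
      stop("dependency error: stage '", stage, "' requires ", key,
           " produced by an upstream stage", call. = FALSE)
    path
  }

  if (isTRUE(config$stages$vta)) {
    leads_csv <- need("leads.csv", "vta")
    grid <- read_volume(need("vim_mask.nii.gz", "vta"))
    grid$data[] <- 0
    placements <- table_to_leads(utils::read.csv(leads_csv))
    rows <- list(); files <- character(0)
    for (s in placements) {
      per_lead <- list()
      for (nm in names(s$leads)) {
        ef <- efield_magnitude(s$leads[[nm]], s$stim[[nm]], cond, grid)
        vta <- threshold_vta(ef, cond)
        if (s$side == "right") {
          ef <- mirror_flip_volume(ef)
          vta <- mirror_flip_volume(vta)
        }
        base <- sprintf("sub-%s_%s", s$id, nm)
        f_ef <- write_volume(ef, file.path(out_dir,
                                           paste0(base, "_efield.nii.gz")))
        f_vta <- write_volume(vta, file.path(out_dir,
                                             paste0(base, "_vta.nii.gz")))
        files <- c(files, f_ef, f_vta)
        per_lead[[nm]] <- vta
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s$id, lead = nm, side = s$side,
                     efield = basename(f_ef), vta = basename(f_vta))
      }
      agg <- aggregate_vta(per_lead$VIM, per_lead$VOp)
      f_agg <- write_volume(agg, file.path(out_dir,
                                           sprintf("sub-%s_aggregate_vta.nii.gz",
                                                   s$id)))
      files <- c(files, f_agg)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s$id, lead = "aggregate", side = s$side,
                   efield = NA, vta = basename(f_agg))
    }
    manifest_csv <- write_table(do.call(rbind, rows),
                                file.path(out_dir, "vta_manifest.csv"))
    write_provenance(out_dir, "vta", config$vta, config$seed, leads_csv,
                     as.list(c(files, manifest_csv)))
    manifest$vta <- list(manifest = manifest_csv, files = files)
  }

  read_vta_set <- function(stage) {
    man <- utils::read.csv(need("vta_manifest.csv", stage))
    agg <- man[man$lead == "aggregate", ]
    vtas <- lapply(agg$vta, function(f) read_volume(file.path(out_dir, f)))
    names(vtas) <- agg$subject
    vtas
  }
  read_improvements <- function(stage, timepoint) {
    cohort <- read_cohort(need("cohort.csv", stage))
    cohort[[paste0("improvement_", timepoint)]]
  }

  if (isTRUE(config$stages$sweetspot)) {
    sp <- config$sweetspot
    vtas <- read_vta_set("sweetspot")
    improvements <- read_improvements("sweetspot", sp$timepoint)
    params <- tfce_params(sp$E, sp$H, sp$n_steps, sp$connectivity,
                          sp$variance_smoothing_sigma, sp$n_permutations,
                          sp$alpha, seed = config$seed)
    res <- sweetspot_analysis(vtas, improvements, params,
                              sp$coverage_fraction)
    files <- c(
      mean_effect = write_volume(res$mean_effect,
                                 file.path(out_dir, "mean_effect.nii.gz")),
      t_map = write_volume(res$t_map, file.path(out_dir, "t_map.nii.gz")),
      tfce_map = write_volume(res$tfce_map,
                              file.path(out_dir, "tfce_map.nii.gz")),
      fwe_p = write_volume(res$fwe_p, file.path(out_dir, "fwe_p.nii.gz")),
      final_mask = write_volume(res$final_mask,
                                file.path(out_dir, "final_mask.nii.gz")),
      cog = write_table(data.frame(analysis = "aggregate",
                                   timepoint = sp$timepoint,
                                   x = res$cog[1], y = res$cog[2],
                                   z = res$cog[3],
                                   n_voxels = sum(res$final_mask$data)),
                        file.path(out_dir, "cog.csv")))
    write_provenance(out_dir, "sweetspot", sp, config$seed,
                     file.path(out_dir, c("vta_manifest.csv", "cohort.csv")),
                     as.list(files))
    manifest$sweetspot <- as.list(files)
  }

  if (isTRUE(config$stages$connectivity)) {
    vtas <- read_vta_set("connectivity")
    improvements <- read_improvements("connectivity",
                                      config$connectivity$timepoint)
    bundles <- read_tractogram(need("bundles.trk", "connectivity"))
    rois <- stats::setNames(
      lapply(c("SMA", "PMC", "PSC", "SSC", "PVC", "TL"), function(nm)
        read_volume(need(paste0("roi_", nm, ".nii.gz"), "connectivity"))),
      c("SMA", "PMC", "PSC", "SSC", "PVC", "TL"))
    prof <- t(vapply(vtas, function(v)
      subject_connectivity(bundles, v, rois)$fractions,
      numeric(length(rois))))
    fits <- regress_connectivity(prof, improvements)
    files <- c(
      profiles = write_table(data.frame(subject = rownames(prof), prof),
                             file.path(out_dir, "connectivity_profiles.csv")),
      regression = write_table(as.data.frame(fits),
                               file.path(out_dir,
                                         "connectivity_regression.csv")))
    write_provenance(out_dir, "connectivity", config$connectivity,
                     config$seed,
                     file.path(out_dir, c("vta_manifest.csv", "cohort.csv",
                                          "bundles.trk")),
                     as.list(files))
    manifest$connectivity <- as.list(files)
  }

  if (isTRUE(config$stages$fiberfilter)) {
    ff <- config$fiberfilter
    vtas <- read_vta_set("fiberfilter")
    improvements <- read_improvements("fiberfilter", ff$timepoint)
    bundles <- read_tractogram(need("bundles.trk", "fiberfilter"))
    res <- fiber_filter_analysis(bundles, vtas, improvements,
                                 filter_params(ff$lower_fraction,
                                               ff$upper_fraction),
                                 ff$var_type)
    grid <- read_volume(need("vim_mask.nii.gz", "fiberfilter"))
    files <- c(stats = write_table(res$stats,
                                   file.path(out_dir, "fiber_stats.csv")))
    if (length(res$favorable) > 0)
      files["favorable"] <- write_tractogram(
        res$favorable, file.path(out_dir, "favorable.trk"), grid)
    if (length(res$unfavorable) > 0)
      files["unfavorable"] <- write_tractogram(
        res$unfavorable, file.path(out_dir, "unfavorable.trk"), grid)
    write_provenance(out_dir, "fiberfilter", ff, config$seed,
                     file.path(out_dir, c("vta_manifest.csv", "cohort.csv",
                                          "bundles.trk")),
                     as.list(files))
    manifest$fiberfilter <- as.list(files)
  }

  if (isTRUE(config$stages$summarize)) {
    cohort <- read_cohort(need("cohort.csv", "summarize"))
    s <- summarize_cohort(cohort)
    summary_df <- data.frame(
      n = s$n, mean_age = s$mean_age, sd_age = s$sd_age,
      mean_baseline_trs = s$mean_baseline_trs,
      sd_baseline_trs = s$sd_baseline_trs,
      mean_improvement_6m = s$mean_improvement_6m,
      sd_improvement_6m = s$sd_improvement_6m)
    files <- c(summary = write_table(summary_df,
                                     file.path(out_dir,
                                               "cohort_summary.csv")))
    write_provenance(out_dir, "summarize", list(), config$seed,
                     file.path(out_dir, "cohort.csv"), as.list(files))
    manifest$summarize <- as.list(files)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
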