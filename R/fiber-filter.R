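#' Traversal-window parameters for fiber filtering
#'
#' Fibers entering the discriminative analysis must traverse at least
#' `lower_fraction` and at most `upper_fraction` of the cohort's VTAs
#' (defaults 0.2 and 0.8).
#'
#' @param lower_fraction,upper_fraction Bounds in [0, 1], lower < upper.
#' @return A `filter_params`.
#' @export
filter_params <- function(lower_fraction = 0.2, upper_fraction = 0.8) {
  stopifnot(lower_fraction >= 0, upper_fraction <= 1,
            lower_fraction < upper_fraction)
  structure(list(lower_fraction = lower_fraction,
                 upper_fraction = upper_fraction),
            class = "filter_params")
}

#' Fiber x subject traversal matrix
#'
#' Entry (f, i) is 1 iff fiber f has at least one point inside subject i's
#' VTA after segment sub-sampling at half-voxel spacing (the same
#' intersection test as [select_streamlines()]).
#'
#' @param tract A `tractogram`.
#' @param vtas List of per-subject binary `image_volume`s.
#' @return Binary matrix, rownames = fiber ids.
#' @export
traversal_matrix <- function(tract, vtas) {
  h <- if (length(vtas) > 0) min(voxel_sizes(vtas[[1]])) / 2 else Inf
  dense <- lapply(tract$streamlines, densify_points, hmax = h)
  mat <- vapply(vtas, function(vta)
    vapply(dense, function(pts)
      as.numeric(streamline_hits_mask(pts, vta, densify = FALSE)), 0),
    numeric(length(dense)))
  mat <- matrix(mat, nrow = length(dense),
                dimnames = list(tract$ids, names(vtas)))
  mat
}

#' Apply the traversal-count window
#'
#' A fiber is retained iff `lower*N <= n_traversed <= upper*N`, with
#' inclusive bounds compared exactly as fractions (no rounding of the
#' products): at N = 11 the retained counts are 3..8.
#'
#' @param mat Traversal matrix from [traversal_matrix()].
#' @param params A `filter_params`.
#' @param n_subjects Cohort size N (default `ncol(mat)`).
#' @return Integer indices (rows of `mat`) of retained fibers.
#' @export
filter_by_traversal <- function(mat, params = filter_params(),
                                n_subjects = ncol(mat)) {
  n_trav <- rowSums(mat != 0)
  which(n_trav >= params$lower_fraction * n_subjects &
        n_trav <= params$upper_fraction * n_subjects)
}

two_sample_t <- function(x1, x0, var_type = "pooled") {
  n1 <- length(x1); n0 <- length(x0)
  m1 <- mean(x1); m0 <- mean(x0)
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  if (var_type == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  } else {
    (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  }
}

#' Per-fiber two-sample t-scores against clinical improvement
#'
#' For each fiber, compares percent improvement between the subjects whose
#' VTA the fiber traverses and those it does not (traversed minus
#' non-traversed; pooled-variance Student t by default, Welch via
#' `var_type = "welch"`). A positive t labels the fiber favorable. Fibers
#' with fewer than two subjects in either group get `t = 0` and a flag
#' rather than being dropped, keeping fiber counts stable.
#'
#' @param mat Traversal matrix (fibers x subjects).
#' @param improvements Percent improvement per subject.
#' @param var_type "pooled" (default) or "welch".
#' @return A `fiber_stat_table` data frame: id, n_traversed, t_score,
#'   favorable, flagged.
#' @export
fiber_t_scores <- function(mat, improvements, var_type = c("pooled", "welch")) {
  var_type <- match.arg(var_type)
  stopifnot(ncol(mat) == length(improvements))
  n_trav <- rowSums(mat != 0)
  t_score <- numeric(nrow(mat))
  flagged <- logical(nrow(mat))
  for (f in seq_len(nrow(mat))) {
    g1 <- improvements[mat[f, ] != 0]
    g0 <- improvements[mat[f, ] == 0]
    if (length(g1) < 2 || length(g0) < 2) {
      flagged[f] <- TRUE
      next
    }
    t_score[f] <- two_sample_t(g1, g0, var_type)
  }
  if (any(flagged))
    message(sum(flagged), " fiber(s) with a group of size < 2 set to t = 0")
  ids <- rownames(mat)
  ids_int <- if (is.null(ids)) seq_len(nrow(mat))
             else suppressWarnings(as.integer(ids))
  if (anyNA(ids_int)) ids_int <- seq_len(nrow(mat))
  out <- data.frame(
    id = ids_int,
    n_traversed = as.integer(n_trav), t_score = t_score,
    favorable = t_score > 0, flagged = flagged)
  class(out) <- c("fiber_stat_table", "data.frame")
  out
}

#' Extract the favorable-fiber tractogram
#'
#' Fibers with a strictly positive t-score, geometry and ids preserved.
#'
#' @param table A `fiber_stat_table`.
#' @param tract The `tractogram` the table was computed from (matched by
#'   id).
#' @return A `tractogram`.
#' @export
favorable_fibers <- function(table, tract) {
  keep_ids <- table$id[table$t_score > 0]
  subset_tractogram(tract, tract$ids %in% keep_ids)
}

#' Full discriminative fiber-filtering analysis
#'
#' Traversal matrix -> 20-80% window -> per-fiber t-scores ->
#' favorable/unfavorable split.
#'
#' @param tract Shared `tractogram`.
#' @param vtas Per-subject binary `image_volume`s.
#' @param improvements Percent improvement per subject.
#' @param params A `filter_params`.
#' @param var_type Passed to [fiber_t_scores()].
#' @return List with `stats` (`fiber_stat_table` restricted to the
#'   traversal window), `favorable` and `unfavorable` `tractogram`s, and
#'   the full `matrix`.
#' @export
fiber_filter_analysis <- function(tract, vtas, improvements,
                                  params = filter_params(),
                                  var_type = "pooled") {
  mat <- traversal_matrix(tract, vtas)
  keep <- filter_by_traversal(mat, params)
  windowed <- subset_tractogram(tract, keep)
  stats <- fiber_t_scores(mat[keep, , drop = FALSE], improvements, var_type)
  fav <- favorable_fibers(stats, windowed)
  unfav <- subset_tractogram(windowed,
                             windowed$ids %in% stats$id[stats$t_score <= 0])
  list(stats = stats, favorable = fav, unfavorable = unfav, matrix = mat)
}

#' Compare favorable-fiber networks of two cohorts
#'
#' Per-ROI endpoint-termination fractions of each cohort's favorable fibers
#' (a fiber terminates in an ROI if either endpoint lies inside it) and
#' whether both cohorts reach the ROI.
#'
#' @param fav_a,fav_b Favorable `tractogram`s of cohorts A and B.
#' @param rois Named list of binary `image_volume`s.
#' @return Data frame: roi, frac_a, frac_b, in_both.
#' @export
compare_networks <- function(fav_a, fav_b, rois) {
  frac <- function(tract) {
    if (length(tract) == 0) return(stats::setNames(numeric(length(rois)),
                                                   names(rois)))
    connectivity_fractions(tract, rois, total = length(tract),
                           mode = "end")$fractions
  }
  fa <- frac(fav_a); fb <- frac(fav_b)
  data.frame(roi = names(rois), frac_a = as.numeric(fa),
             frac_b = as.numeric(fb), in_both = fa > 0 & fb > 0)
}
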