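#' Improvement-weighted VTA stack
#'
#' Multiplies each subject's binary VTA by that subject's percent TRS
#' improvement, producing the weighted heat maps that enter the voxel-wise
#' analysis. Negative improvements (worsening) yield negative-valued maps.
#'
#' @param vtas List of binary `image_volume`s on a shared grid.
#' @param improvements Percent improvement per subject.
#' @param ids Optional subject ids.
#' @return A `weighted_vta_stack` with fields `volumes` (list of
#'   `image_volume`), `ids`, `grid`.
#' @export
weight_vtas <- function(vtas, improvements, ids = NULL) {
  stopifnot(length(vtas) == length(improvements), length(vtas) >= 1)
  for (v in vtas[-1])
    if (!same_grid(vtas[[1]], v))
      stop("all VTAs must share grid and affine", call. = FALSE)
  if (any(!is.finite(improvements)))
    stop("improvements must be finite", call. = FALSE)
  volumes <- Map(function(v, w) {
    out <- v
    out$data <- array(as.numeric(v$data != 0) * w, dim(v$data))
    out
  }, vtas, improvements)
  structure(list(volumes = volumes,
                 ids = if (is.null(ids)) as.character(seq_along(vtas)) else ids,
                 grid = empty_like(vtas[[1]])),
            class = "weighted_vta_stack")
}

stack_matrix <- function(stack) {
  vapply(stack$volumes, function(v) as.numeric(v$data),
         numeric(length(stack$grid$data)))
}

#' Voxel-wise mean effect image
#'
#' Arithmetic mean over all N subjects at every voxel; the divisor is N
#' everywhere (subjects whose VTA does not cover a voxel contribute a zero),
#' matching a mean taken across the whole cohort rather than across
#' covering subjects only. Set `per_coverage = TRUE` to divide by the
#' per-voxel coverage count instead.
#'
#' @param stack A `weighted_vta_stack`.
#' @param per_coverage Divide by per-voxel coverage instead of N.
#' @return An `image_volume` (percent units).
#' @export
mean_effect <- function(stack, per_coverage = FALSE) {
  m <- stack_matrix(stack)
  out <- stack$grid
  if (per_coverage) {
    cov <- rowSums(m != 0)
    mu <- ifelse(cov > 0, rowSums(m) / pmax(cov, 1), 0)
  } else {
    mu <- rowMeans(m)
  }
  out$data <- array(mu, dim(out$data))
  out
}

#' TFCE and permutation-inference parameters
#'
#' @param E,H TFCE extent and height exponents (defaults 0.5 and 2, the
#'   de-facto standard).
#' @param n_steps Number of equal threshold steps (default 100).
#' @param connectivity Neighbourhood: 6, 18 or 26 (default 26).
#' @param variance_smoothing_sigma Gaussian sigma (mm) applied to the
#'   sample-variance image before forming t (default 2.5, for small
#'   samples).
#' @param n_permutations Sign-flip permutations (default 5000). When
#'   2^N <= n_permutations all sign patterns are enumerated exactly.
#' @param alpha Family-wise error level (default 0.05).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return A `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100L,
                        connectivity = 26L, variance_smoothing_sigma = 2.5,
                        n_permutations = 5000L, alpha = 0.05, seed = 1L) {
  stopifnot(E >= 0, H >= 0, n_steps >= 10, connectivity %in% c(6L, 18L, 26L),
            variance_smoothing_sigma >= 0, alpha > 0, alpha < 1)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-values will be very coarse")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity),
                 variance_smoothing_sigma = variance_smoothing_sigma,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "tfce_params")
}

#' Gaussian-smooth an image volume
#' @param vol An `image_volume`.
#' @param sigma_mm Isotropic smoothing sigma in mm (converted to voxels via
#'   the affine); 0 is a no-op.
#' @return Smoothed `image_volume`.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  if (sigma_mm <= 0) return(vol)
  out <- vol
  out$data <- array(gauss_smooth3d_cpp(as.numeric(vol$data), dim(vol$data),
                                       sigma_mm / voxel_sizes(vol)),
                    dim(vol$data))
  out
}

#' One-sample t map with variance smoothing
#'
#' `t(v) = mean(v) / sqrt(smoothed_var(v) / N)` where the per-voxel sample
#' variance image is Gaussian-smoothed (sigma in mm) before forming t, the
#' standard small-sample regularisation. Evaluated on voxels covered by at
#' least one subject; t is 0 where the smoothed variance is still zero and
#' outside the evaluation domain.
#'
#' @param stack A `weighted_vta_stack` (N >= 2).
#' @param params A `tfce_params`.
#' @return An `image_volume` t map.
#' @export
onesample_t <- function(stack, params = tfce_params()) {
  m <- stack_matrix(stack)
  if (ncol(m) < 2) stop("need at least 2 subjects", call. = FALSE)
  domain <- rowSums(m != 0) > 0
  mu <- rowMeans(m)
  va <- apply(m, 1, stats::var)
  out <- stack$grid
  va_img <- out; va_img$data <- array(va, dim(out$data))
  va_s <- as.numeric(gaussian_smooth(va_img,
                                     params$variance_smoothing_sigma)$data)
  t <- ifelse(domain & va_s > 1e-12, mu / sqrt(va_s / ncol(m)), 0)
  out$data <- array(t, dim(out$data))
  out
}

#' Threshold-free cluster enhancement of a statistical map
#'
#' `TFCE(v) = sum_h e_h(v)^E * h^H * dh` over `n_steps` equal thresholds h
#' in (0, max], where `e_h(v)` is the voxel count of the suprathreshold
#' connected component containing v at height h. Negative values are
#' processed symmetrically on the negated map and subtracted.
#'
#' @param map An `image_volume` (e.g. a t map).
#' @param params A `tfce_params`.
#' @return An `image_volume` of TFCE scores.
#' @export
tfce <- function(map, params = tfce_params()) {
  d <- dim(map$data)
  v <- as.numeric(map$data)
  pos <- tfce_pos_cpp(pmax(v, 0), d, params$E, params$H, params$n_steps,
                      params$connectivity)
  neg <- tfce_pos_cpp(pmax(-v, 0), d, params$E, params$H, params$n_steps,
                      params$connectivity)
  out <- map
  out$data <- array(pos - neg, d)
  out
}

sign_matrix <- function(n_subjects, params) {
  n_exact <- 2^n_subjects
  if (n_subjects <= 30 && n_exact <= params$n_permutations) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_subjects)))
    list(signs = t(signs), exact = TRUE)
  } else {
    set.seed(params$seed)
    list(signs = matrix(sample(c(-1, 1), n_subjects * params$n_permutations,
                               replace = TRUE),
                        n_subjects, params$n_permutations),
         exact = FALSE)
  }
}

bbox_crop <- function(domain_arr, margin, d) {
  idx <- which(domain_arr, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

#' Sign-flip permutation FWE inference on a weighted VTA stack
#'
#' The one-sample non-parametric test: each permutation multiplies every
#' subject's volume by an independent sign, recomputes the variance-smoothed
#' t map and its TFCE, and records the maximum TFCE over the analysis
#' domain (the union of subject coverage). Inference is one-sided on the
#' positive (improvement) tail. When `2^N <= n_permutations` all sign
#' patterns are enumerated exactly (the study-scale cohort of N = 11 gives
#' 2048 < 5000, hence exact inference); otherwise a seeded Monte-Carlo
#' sample is drawn. The corrected p-value is
#' `p(v) = (1 + #\{perms: max >= TFCE_obs(v)\}) / (P + 1)`, so p is at
#' least `1/(P+1)` and equals 1 outside the domain.
#'
#' @param stack A `weighted_vta_stack` (N >= 2).
#' @param params A `tfce_params`.
#' @return List with `fwe_p`, `tfce_obs`, `t_obs` (`image_volume`s),
#'   `null_max` (numeric vector) and `exact` (logical).
#' @export
permutation_fwe <- function(stack, params = tfce_params()) {
  m <- stack_matrix(stack)
  N <- ncol(m)
  if (N < 2) stop("need at least 2 subjects", call. = FALSE)
  d <- dim(stack$grid$data)
  domain <- array(rowSums(m != 0) > 0, d)

  p_img <- stack$grid; p_img$data <- array(1, d)
  tf_img <- stack$grid; tf_img$data <- array(0, d)
  t_img <- stack$grid; t_img$data <- array(0, d)
  sg <- sign_matrix(N, params)
  if (!any(domain)) {
    return(list(fwe_p = p_img, tfce_obs = tf_img, t_obs = t_img,
                null_max = rep(0, ncol(sg$signs)), exact = sg$exact))
  }

  sig_vox <- params$variance_smoothing_sigma / voxel_sizes(stack$grid)
  margin <- ceiling(3 * max(sig_vox)) + 1
  bb <- bbox_crop(domain, margin, d)
  sub <- function(a) a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                       bb$lo[3]:bb$hi[3], drop = FALSE]
  dc <- bb$hi - bb$lo + 1L
  mc <- apply(m, 2, function(col) as.numeric(sub(array(col, d))))

  res <- perm_maxtfce_cpp(mc, dc, sg$signs, sig_vox, params$E, params$H,
                          params$n_steps, params$connectivity,
                          as.logical(sub(domain)))
  P <- ncol(sg$signs)
  null_sorted <- sort(res$max_null)
  # #{null >= o} = P - #{null < o}
  pvals <- (1 + P - findInterval(res$tfce_obs, null_sorted,
                                 left.open = TRUE)) / (P + 1)
  pvals[!as.logical(sub(domain))] <- 1

  fill <- function(img, vals) {
    img$data[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <-
      array(vals, dc)
    img
  }
  list(fwe_p = fill(p_img, pvals), tfce_obs = fill(tf_img, res$tfce_obs),
       t_obs = fill(t_img, res$t_obs), null_max = as.numeric(res$max_null),
       exact = sg$exact)
}

#' Cohort coverage mask
#'
#' Keeps voxels covered by at least `fraction` of the N subjects' VTAs:
#' count >= max(1, ceiling(fraction * N)). With the default 0.4 and N = 11
#' the threshold count is 5.
#'
#' @param vtas List of binary `image_volume`s.
#' @param fraction Required coverage fraction (default 0.4).
#' @return Binary `image_volume`.
#' @export
coverage_mask <- function(vtas, fraction = 0.4) {
  stopifnot(fraction >= 0, fraction <= 1)
  counts <- Reduce(`+`, lapply(vtas, function(v) (v$data != 0) * 1))
  thr <- max(1, ceiling(fraction * length(vtas) - 1e-9))
  out <- empty_like(vtas[[1]])
  out$data <- array(as.numeric(counts >= thr), dim(out$data))
  out
}

#' Intensity-weighted centre of gravity, world mm
#'
#' @param map An `image_volume` with at least one nonzero voxel and no
#'   negative values (binarize or shift first otherwise).
#' @return Length-3 world mm coordinate.
#' @export
centre_of_gravity <- function(map) {
  w <- as.numeric(map$data)
  if (any(w < 0))
    stop("domain error: negative values present; binarize or shift first",
         call. = FALSE)
  if (all(w == 0)) stop("empty-mask error: all-zero map", call. = FALSE)
  xyz <- grid_coordinates(map)
  colSums(xyz * w) / sum(w)
}

#' Assemble the final sweet-spot result
#'
#' `sig_mask = (fwe_p < alpha)`, `final_mask = sig_mask AND coverage`,
#' `weighted_map = mean_effect * final_mask`; the centre of gravity is taken
#' over the weighted map (over the binary final mask if the weighted map has
#' negative values; NA if the final mask is empty).
#'
#' @param mean_effect_img Mean effect `image_volume`.
#' @param fwe_p FWE-corrected p `image_volume`.
#' @param coverage Binary coverage `image_volume`.
#' @param params A `tfce_params` (supplies alpha).
#' @return A `sweetspot_result`.
#' @export
finalize_sweetspot <- function(mean_effect_img, fwe_p, coverage,
                               params = tfce_params()) {
  sig <- fwe_p; sig$data <- array(as.numeric(fwe_p$data < params$alpha),
                                  dim(fwe_p$data))
  final <- sig
  final$data <- array(as.numeric(sig$data != 0 & coverage$data != 0),
                      dim(sig$data))
  weighted <- mean_effect_img
  weighted$data <- mean_effect_img$data * final$data
  cog <- if (sum(final$data) == 0) {
    warning("final significance mask is empty; COG undefined")
    c(NA_real_, NA_real_, NA_real_)
  } else if (any(weighted$data < 0)) centre_of_gravity(final)
  else centre_of_gravity(weighted)
  structure(list(mean_effect = mean_effect_img, fwe_p = fwe_p,
                 sig_mask = sig, coverage_mask = coverage,
                 final_mask = final, weighted_map = weighted, cog = cog,
                 alpha = params$alpha),
            class = "sweetspot_result")
}

#' @export
print.sweetspot_result <- function(x, ...) {
  cat(sprintf("<sweetspot_result> %d significant voxels, %d in final mask\n",
              sum(x$sig_mask$data), sum(x$final_mask$data)))
  if (all(is.finite(x$cog)))
    cat(sprintf("  COG (mm): (%.1f, %.1f, %.1f)\n", x$cog[1], x$cog[2],
                x$cog[3]))
  invisible(x)
}

#' Full improvement-weighted sweet-spot analysis
#'
#' Weighted VTAs -> mean effect -> sign-flip TFCE permutation inference ->
#' FWE threshold -> coverage masking -> centre of gravity.
#'
#' @param vtas List of binary `image_volume`s (one per subject).
#' @param improvements Percent improvement per subject.
#' @param params A `tfce_params`.
#' @param coverage_fraction Cohort mask fraction (default 0.4).
#' @return A `sweetspot_result`; the permutation record is attached as
#'   attribute `"permutation"`.
#' @export
sweetspot_analysis <- function(vtas, improvements, params = tfce_params(),
                               coverage_fraction = 0.4) {
  stack <- weight_vtas(vtas, improvements)
  me <- mean_effect(stack)
  perm <- permutation_fwe(stack, params)
  cov <- coverage_mask(vtas, coverage_fraction)
  res <- finalize_sweetspot(me, perm$fwe_p, cov, params)
  res$t_map <- perm$t_obs
  res$tfce_map <- perm$tfce_obs
  attr(res, "permutation") <- perm[c("null_max", "exact")]
  res
}
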