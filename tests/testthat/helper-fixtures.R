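# Shared fixtures, built in code at test time.

# small centered grid: n^3 voxels, vs mm isotropic, symmetric about the origin
small_grid <- function(n = 8, vs = 1) {
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- -(n - 1) / 2 * vs
  image_volume(array(0, c(n, n, n)), aff)
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  out <- grid
  out$data <- array(as.numeric(stats::runif(length(grid$data)) < p),
                    dim(grid$data))
  out
}

# The planted study cohort (fixed generator seed, criterion noise level),
# simulated once per test run and shared across test files.
planted_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(noise_sd = 5)
    cache
  }
})

# toy weighted stack from per-subject value arrays on a shared small grid
toy_stack <- function(value_arrays, grid = small_grid(dim(value_arrays[[1]])[1])) {
  vols <- lapply(value_arrays, function(a) {
    v <- grid
    v$data <- array(as.numeric(a), dim(grid$data))
    v
  })
  structure(list(volumes = vols, ids = as.character(seq_along(vols)),
                 grid = grid),
            class = "weighted_vta_stack")
}
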