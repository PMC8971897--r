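#' Image volume: 3D scalar grid with a voxel-to-world affine
#'
#' The carrier type for every mask, electric-field image and statistical map
#' in the pipeline. Conventions: world coordinates are RAS+ millimetres,
#' voxel indices are 0-based, and the affine maps voxel *centers* to world
#' points, `world = affine %*% c(i, j, k, 1)`. All analysis happens in world
#' mm; voxel/world conversion occurs only at file and grid boundaries.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix (mm).
#' @param space Free-text label for the coordinate space.
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `space`.
#' @export
image_volume <- function(data, affine, space = "phantom-RAS") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("`affine` must be invertible", call. = FALSE)
  structure(list(data = data, affine = affine, space = as.character(space)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d, space '%s'\n", d[1], d[2], d[3], x$space))
  cat(sprintf("  voxel size (mm): %s\n", paste(signif(voxel_sizes(x), 4), collapse = " x ")))
  cat(sprintf("  value range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel sizes (mm) of an image volume
#' @param vol An `image_volume`.
#' @return Length-3 numeric vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Convert 0-based voxel indices to world mm coordinates
#'
#' @param vol An `image_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   may be fractional.
#' @return n x 3 matrix of world mm coordinates (voxel centers).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_coords(ijk)
  xyz <- cbind(ijk, 1) %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Convert world mm coordinates to (continuous) 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world mm points.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_coords(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(vol$affine))
  ijk[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

#' World coordinates of every voxel center
#' @param vol An `image_volume`.
#' @return (prod(dim)) x 3 matrix, rows in array (column-major) order.
#' @export
grid_coordinates <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  voxel_to_world(vol, ijk)
}

#' Do two volumes share grid shape and affine?
#' @param a,b `image_volume` objects.
#' @param tol Absolute tolerance on affine entries.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$affine - b$affine) < tol)
}

#' A zero-filled volume on the same grid
#' @param vol Template `image_volume`.
#' @param fill Fill value.
#' @export
empty_like <- function(vol, fill = 0) {
  image_volume(array(fill, dim(vol$data)), vol$affine, vol$space)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param space Space label to attach.
#' @return An `image_volume`.
#' @export
read_volume <- function(path, space = "phantom-RAS") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) < 3L) stop("NIfTI field 'dim': expected a 3D image, got ",
                           length(d), "D", call. = FALSE)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("NIfTI field 'dim': expected a single 3D frame", call. = FALSE)
    d <- d[1:3]
  }
  # prefer the sform, which stores a general affine exactly
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  image_volume(array(as.numeric(img), d), aff, space)
}

#' Write a NIfTI-1 volume
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_sizes(vol)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mirror a volume across the mid-sagittal plane (x = 0)
#'
#' Right-hemisphere stimulation volumes are folded onto the left hemisphere
#' before group analysis. On the bilaterally symmetric phantom grid this is
#' an exact rigid reflection: the value at world (x, y, z) moves to
#' (-x, y, z). Applying the flip twice returns the original volume.
#'
#' @param vol An `image_volume` whose grid is symmetric about x = 0 and whose
#'   x world axis is aligned with the first array axis.
#' @return The reflected `image_volume`.
#' @export
mirror_flip_volume <- function(vol) {
  aff <- vol$affine
  if (any(abs(aff[1, 2:3]) > 1e-9) || any(abs(aff[2:3, 1]) > 1e-9))
    stop("geometry error: x axis is not aligned with the first voxel axis",
         call. = FALSE)
  n <- dim(vol$data)[1]
  # world x of voxel i is a*i + b; need x(n-1-i) == -x(i), i.e. a*(n-1) + 2b == 0
  if (abs(aff[1, 1] * (n - 1) + 2 * aff[1, 4]) > 1e-6)
    stop("geometry error: grid is not symmetric about x = 0", call. = FALSE)
  out <- vol
  out$data <- vol$data[n:1, , , drop = FALSE]
  out
}
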