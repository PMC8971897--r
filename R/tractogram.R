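#' Tractogram: a bundle of streamlines in world mm
#'
#' Each streamline is an n x 3 matrix (n >= 2) of RAS+ world-mm points with
#' distinct consecutive points and finite coordinates. Streamlines carry an
#' integer `id`; the synthetic generator additionally attaches a per-
#' streamline `label` ("favorable", "unfavorable", "background").
#'
#' @param streamlines List of n x 3 numeric matrices.
#' @param ids Integer ids, one per streamline.
#' @param labels Optional character labels, one per streamline.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, ids = seq_along(streamlines), labels = NULL) {
  stopifnot(is.list(streamlines))
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be an n x 3 matrix with n >= 2", call. = FALSE)
    if (!all(is.finite(s)))
      stop("streamline coordinates must be finite", call. = FALSE)
    if (any(rowSums(abs(diff(s))) == 0))
      stop("consecutive streamline points must be distinct", call. = FALSE)
  }
  if (length(ids) != length(streamlines))
    stop("`ids` must match the number of streamlines", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(streamlines))
    stop("`labels` must match the number of streamlines", call. = FALSE)
  structure(list(streamlines = streamlines, ids = as.integer(ids),
                 labels = labels),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf("<tractogram> %d streamlines, %d points total\n",
              length(np), sum(np)))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Subset a tractogram
#' @param tract A `tractogram`.
#' @param keep Logical or integer index over streamlines.
#' @export
subset_tractogram <- function(tract, keep) {
  tractogram(tract$streamlines[keep], tract$ids[keep],
             if (!is.null(tract$labels)) tract$labels[keep])
}

# ---- TrackVis TRK v2 binary I/O -------------------------------------------
# 1000-byte header; points are stored in "voxmm" coordinates:
#   voxmm = (voxel_index_0based + 0.5) * voxel_size
# with the reference geometry carried in the header's vox_to_ras matrix.
# The streamline id is stored as a single per-track property ("fiber_id").

trk_string <- function(s, width) {
  raw <- charToRaw(s)
  c(raw[seq_len(min(length(raw), width))], raw(width - min(length(raw), width)))
}

#' Write a tractogram to a TrackVis TRK file
#'
#' Coordinates are converted from world mm to the TRK voxel-mm convention
#' using the reference volume's affine; streamline ids are stored as a track
#' property so they survive the round trip.
#'
#' @param tract A `tractogram`.
#' @param path Output `.trk` path.
#' @param reference An `image_volume` supplying grid shape, voxel size and
#'   the voxel-to-world affine embedded in the header.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tract, path, reference) {
  stopifnot(inherits(tract, "tractogram"), inherits(reference, "image_volume"))
  vs <- voxel_sizes(reference)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trk_string("TRACK", 6L), con)
  writeBin(as.integer(dim(reference$data)), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")         # origin
  writeBin(0L, con, size = 2L, endian = "little")                 # n_scalars
  writeBin(raw(10L * 20L), con)                                   # scalar names
  writeBin(1L, con, size = 2L, endian = "little")                 # n_properties
  writeBin(c(trk_string("fiber_id", 20L), raw(9L * 20L)), con)    # property names
  writeBin(as.numeric(t(reference$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                        # reserved
  writeBin(trk_string("RAS", 4L), con)                            # voxel_order
  writeBin(raw(4L), con)                                          # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")         # img orientation
  writeBin(raw(2L), con)                                          # pad1
  writeBin(raw(6L), con)                                          # invert/swap flags
  writeBin(length(tract), con, size = 4L, endian = "little")      # n_count
  writeBin(2L, con, size = 4L, endian = "little")                 # version
  writeBin(1000L, con, size = 4L, endian = "little")              # hdr_size
  for (i in seq_along(tract$streamlines)) {
    pts <- tract$streamlines[[i]]
    vox <- world_to_voxel(reference, pts)
    voxmm <- sweep(vox + 0.5, 2, vs, `*`)
    writeBin(nrow(pts), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
    writeBin(as.numeric(tract$ids[i]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' @param path Path to a `.trk` file.
#' @return A `tractogram` with world-mm coordinates reconstructed from the
#'   header's vox_to_ras matrix and voxel sizes.
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (!identical(magic, "TRACK"))
    stop("format error: TRK field 'id_string' is not 'TRACK'", call. = FALSE)
  invisible(readBin(con, "integer", 3L, size = 2L, endian = "little")) # dim
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  if (any(vs <= 0))
    stop("format error: TRK field 'voxel_size' must be positive", call. = FALSE)
  invisible(readBin(con, "numeric", 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L))
    stop("format error: TRK field 'hdr_size' is ", hdr_size, ", expected 1000",
         call. = FALSE)
  if (version >= 2L && abs(det(aff)) < 1e-12)
    stop("format error: TRK field 'vox_to_ras' is singular", call. = FALSE)
  ref <- image_volume(array(0, c(2, 2, 2)), aff)

  streamlines <- vector("list", 0L)
  ids <- integer(0)
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    if (npts < 0L)
      stop("format error: negative point count in track ", i + 1L, call. = FALSE)
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) < npts * (3L + n_scalars))
      stop("format error: truncated track ", i + 1L,
           " (point count exceeds file size)", call. = FALSE)
    props <- readBin(con, "numeric", n_props, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, vs, `/`) - 0.5
    i <- i + 1L
    streamlines[[i]] <- voxel_to_world(ref, vox)
    ids[i] <- if (n_props >= 1L) as.integer(round(props[1])) else i
  }
  if (n_count > 0L && i != n_count)
    stop("format error: header n_count is ", n_count, " but file contains ",
         i, " tracks", call. = FALSE)
  if (i == 0L) return(empty_tractogram())
  tractogram(streamlines, ids)
}

#' An empty tractogram
#' @export
empty_tractogram <- function() {
  structure(list(streamlines = list(), ids = integer(0), labels = NULL),
            class = "tractogram")
}

# Densify a polyline so consecutive samples are at most `hmax` mm apart.
densify_points <- function(pts, hmax) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  if (all(seg <= hmax)) return(pts)
  out <- vector("list", nrow(pts) - 1L)
  for (k in seq_len(nrow(pts) - 1L)) {
    n_sub <- max(1L, ceiling(seg[k] / hmax))
    tt <- seq(0, 1, length.out = n_sub + 1L)[-(n_sub + 1L)]
    out[[k]] <- cbind(pts[k, 1] + tt * (pts[k + 1, 1] - pts[k, 1]),
                      pts[k, 2] + tt * (pts[k + 1, 2] - pts[k, 2]),
                      pts[k, 3] + tt * (pts[k + 1, 3] - pts[k, 3]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

# Does a polyline (densified at half-voxel spacing) touch a nonzero voxel of
# `mask`? The shared point-in-mask primitive of the connectivity and fiber
# filtering stages.
streamline_hits_mask <- function(pts, mask, densify = TRUE) {
  if (densify) pts <- densify_points(pts, min(voxel_sizes(mask)) / 2)
  ijk <- round(world_to_voxel(mask, pts))
  d <- dim(mask$data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  if (!any(ok)) return(FALSE)
  ijk <- ijk[ok, , drop = FALSE] + 1
  any(mask$data[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] != 0)
}
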