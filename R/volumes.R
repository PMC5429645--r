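#' Construct a 3D scalar volume
#'
#' A `volume3d` is the package's container for regularly gridded 3D data:
#' CT intensities in Hounsfield units, or integer tissue label maps. The
#' grid uses the voxel-centre convention: the world position (mm) of the
#' 0-based voxel index `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param values A 3D numeric (or integer/logical) array.
#' @param spacing Per-axis voxel size in mm; strictly positive, length 3.
#' @param origin World position (mm) of voxel `(0, 0, 0)`; length 3.
#'
#' @return An object of class `volume3d`: a list with elements `values`,
#'   `spacing` and `origin`.
#' @examples
#' vol <- volume3d(array(0L, c(4, 4, 4)), spacing = c(0.9, 0.9, 0.9))
#' vol_dim(vol)
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) {
    abort("expected 3D volume", class = "punctforce_format_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite values (mm)")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    d[1], d[2], d[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(signif(x$origin, 4), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname volume3d
#' @param vol A `volume3d`.
#' @export
vol_dim <- function(vol) dim(vol$values)

is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_volume <- function(vol) {
  if (!is_volume3d(vol)) abort("expected a `volume3d` object")
  invisible(vol)
}

#' Convert between world coordinates and voxel indices
#'
#' Voxel indices are 0-based and refer to voxel centres, so
#' `voxel_to_world()` is the exact inverse of `world_to_voxel()` up to the
#' nearest-voxel rounding. Points are "inside" the volume as long as their
#' nearest voxel exists, i.e. within half a voxel of the outermost centres.
#'
#' @param p World point(s) in mm: a length-3 vector or an `n x 3` matrix.
#' @param vol A [volume3d()].
#' @return `world_to_voxel()`: integer 0-based indices (vector or matrix);
#'   `voxel_to_world()`: world coordinates in mm.
#' @examples
#' vol <- volume3d(array(0, c(8, 8, 8)), spacing = c(0.9, 0.9, 0.9))
#' world_to_voxel(c(1.4, 0, 0), vol)  # 1.4/0.9 = 1.56 -> voxel 2
#' @export
world_to_voxel <- function(p, vol) {
  stopifnot_volume(vol)
  p <- to_point_matrix(p)
  d <- vol_dim(vol)
  idx <- round(sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/"))
  bad <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
    idx[, 1] > d[1] - 1 | idx[, 2] > d[2] - 1 | idx[, 3] > d[3] - 1
  if (any(bad)) {
    abort(sprintf("point outside volume (first offender: %s mm)",
                  paste(signif(p[which(bad)[1], ], 5), collapse = ", ")),
          class = "punctforce_outside_volume")
  }
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1L) idx[1, ] else idx
}

#' @rdname world_to_voxel
#' @param idx 0-based voxel index (length-3 vector or `n x 3` matrix).
#' @export
voxel_to_world <- function(idx, vol) {
  stopifnot_volume(vol)
  idx <- to_point_matrix(idx)
  w <- sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
  if (nrow(w) == 1L) w[1, ] else w
}

to_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) abort("points must have 3 coordinates")
    matrix(as.numeric(p), nrow = 1L)
  } else {
    if (ncol(p) != 3L) abort("point matrices must have 3 columns")
    matrix(as.numeric(p), ncol = 3L)
  }
}

# Linear (1-based) array index for an n x 3 matrix of 0-based voxel indices.
voxel_linear_index <- function(idx, vol) {
  d <- vol_dim(vol)
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  1L + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
}

#' Define a straight needle trajectory
#'
#' A trajectory is a straight insertion path: an entry point on (or above)
#' the skin, a unit direction, an insertion length and a sample count.
#' Depth along the path is measured in mm from the entry point. The
#' default 1,000 samples per path gives a worst-case sample spacing of
#' 90/999 = 0.09 mm at the 90 mm insertion-length limit, i.e. at least
#' 10-fold oversampling of sub-millimetre voxel grids.
#'
#' @param entry World entry point, mm.
#' @param direction Direction of insertion; normalised to unit length
#'   (must be non-zero).
#' @param length Insertion length in mm; must not exceed `max_length`.
#' @param n_samples Number of uniformly spaced samples (>= 2).
#' @param max_length Maximum permitted insertion length, mm.
#' @return An object of class `trajectory`.
#' @examples
#' tr <- trajectory(c(0, 0, 0), c(0, 0, 1), length = 90)
#' traj_spacing(tr)  # 0.09009... mm
#' @export
trajectory <- function(entry, direction, length, n_samples = 1000L,
                       max_length = 90) {
  entry <- as.numeric(entry)
  direction <- as.numeric(direction)
  if (length(entry) != 3L || length(direction) != 3L) {
    abort("`entry` and `direction` must have 3 coordinates")
  }
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) abort("`direction` must be non-zero")
  direction <- direction / nrm
  length <- as.numeric(length)
  if (!is.finite(length) || length < 0) abort("`length` must be >= 0 mm")
  if (length > max_length) {
    abort(sprintf("trajectory length %.3f mm exceeds the %.0f mm limit",
                  length, max_length))
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) abort("`n_samples` must be at least 2")
  structure(list(entry = entry, direction = direction, length = length,
                 n_samples = n_samples),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> entry (%s) mm, direction (%s), length %.2f mm, %d samples\n",
    paste(signif(x$entry, 4), collapse = ", "),
    paste(signif(x$direction, 4), collapse = ", "),
    x$length, x$n_samples
  ))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
traj_depths <- function(traj) {
  seq(0, traj$length, length.out = traj$n_samples)
}

#' @rdname trajectory
#' @export
traj_spacing <- function(traj) traj$length / (traj$n_samples - 1)

#' @rdname trajectory
#' @export
traj_points <- function(traj) {
  d <- traj_depths(traj)
  cbind(traj$entry[1] + d * traj$direction[1],
        traj$entry[2] + d * traj$direction[2],
        traj$entry[3] + d * traj$direction[3])
}

check_oversampling <- function(traj, vol) {
  # 1% headroom: the canonical 1,000-sample / 90 mm path on a 0.9 mm grid
  # (spacing 90/999 = 0.09009 mm) counts as 10-fold oversampling
  if (traj_spacing(traj) > min(vol$spacing) / 10 * 1.01) {
    warn(sprintf(
      "sample spacing %.4f mm exceeds min(voxel spacing)/10 = %.4f mm; oversampling < 10x",
      traj_spacing(traj), min(vol$spacing) / 10
    ))
  }
  invisible(NULL)
}

#' Sample a label volume along a trajectory
#'
#' Labels are looked up at the nearest voxel centre of each of the
#' trajectory's uniformly spaced samples (labels are categorical, so no
#' interpolation is meaningful). A warning is raised when the sample
#' spacing does not oversample the voxel grid at least 10-fold.
#'
#' @param traj A [trajectory()] fully inside the volume.
#' @param labels A [volume3d()] of integer labels.
#' @return A tibble with columns `depth_mm` and `label`.
#' @examples
#' lab <- volume3d(array(2L, c(8, 8, 8)), spacing = c(1, 1, 1))
#' tr <- trajectory(c(3, 3, 0), c(0, 0, 1), length = 7, n_samples = 71)
#' table(sample_labels_along(tr, lab)$label)
#' @export
sample_labels_along <- function(traj, labels) {
  stopifnot_volume(labels)
  check_oversampling(traj, labels)
  v <- sample_values_along(traj, labels)
  tibble::tibble(depth_mm = traj_depths(traj), label = as.integer(v))
}

# Nearest-voxel lookup of a volume along a trajectory; errors with the valid
# depth range when the path leaves the volume.
sample_values_along <- function(traj, vol) {
  pts <- traj_points(traj)
  d <- vol_dim(vol)
  idx <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/"))
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] <= d[1] - 1 & idx[, 2] <= d[2] - 1 & idx[, 3] <= d[3] - 1
  if (!all(inside)) {
    depths <- traj_depths(traj)
    valid <- range(depths[inside])
    if (!any(inside)) valid <- c(NA_real_, NA_real_)
    abort(
      sprintf("trajectory exits the volume; valid depth range [%.3f, %.3f] mm",
              valid[1], valid[2]),
      class = "punctforce_truncation",
      valid_range = valid
    )
  }
  storage.mode(idx) <- "integer"
  vol$values[voxel_linear_index(idx, vol)]
}
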