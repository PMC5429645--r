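#' Path planner configuration
#'
#' @param max_length Hard insertion-length limit in mm (criterion C2).
#' @param quality_threshold Paths scoring below this quality `Q` are
#'   removed from the accepted set.
#' @param d_cap Normalisation cap in mm for the risk-clearance soft
#'   criterion C3: clearances at or beyond `d_cap` saturate at 1.
#' @param n_cap Normalisation cap (voxel count) for the target-hit soft
#'   criterion C4.
#' @param step_frac Ray-walk step as a fraction of the smallest voxel
#'   spacing (<= 0.5 guarantees no voxel is skipped diagonally).
#' @return A list of class `planner_config`.
#' @export
planner_config <- function(max_length = 90, quality_threshold = 0.4,
                           d_cap = 10, n_cap = 10, step_frac = 0.5) {
  if (d_cap <= 0 || n_cap <= 0) abort("normalisation caps must be positive")
  if (step_frac <= 0 || step_frac > 0.5) {
    abort("`step_frac` must be in (0, 0.5]")
  }
  structure(list(max_length = max_length,
                 quality_threshold = quality_threshold,
                 d_cap = d_cap, n_cap = n_cap, step_frac = step_frac),
            class = "planner_config")
}

#' Extract the centerline of a tubular target structure
#'
#' Deterministic one-voxel-wide skeletonisation tailored to elongated
#' targets such as dilated bile ducts: each 6-connected component is
#' projected onto its principal axis, voxels are binned at one-voxel
#' resolution along that axis and each bin is collapsed to the voxel
#' nearest its centroid. Compact (non-elongated) components collapse to a
#' single centroid voxel. An already one-voxel-wide straight tube maps to
#' itself.
#'
#' @param mask A [volume3d()] whose non-zero voxels form the target.
#' @return An integer matrix of 0-based voxel indices (columns x, y, z),
#'   ordered by component then by position along the component axis.
#' @export
extract_centerline <- function(mask) {
  stopifnot_volume(mask)
  m <- as.integer(mask$values != 0)
  if (!any(m == 1L)) abort("target mask is empty")
  comp <- .flood_components(m, vol_dim(mask))
  coords <- which(array(comp, vol_dim(mask)) > 0L, arr.ind = TRUE) - 1L
  ids <- comp[comp > 0L]
  out <- lapply(sort(unique(ids)), function(id) {
    vox <- coords[ids == id, , drop = FALSE]
    world <- sweep(sweep(vox, 2, mask$spacing, "*"), 2, mask$origin, "+")
    if (nrow(vox) == 1L) return(vox)
    ctr <- colMeans(world)
    centred <- sweep(world, 2, ctr, "-")
    pc <- prcomp(centred, center = FALSE)
    axis <- pc$rotation[, 1]
    # deterministic sign: largest-magnitude axis component positive
    s <- sign(axis[which.max(abs(axis))])
    if (s < 0) axis <- -axis
    ev <- pc$sdev^2
    if (length(ev) < 2L || ev[1] < 4 * ev[2]) {
      # compact blob: collapse to the voxel nearest the centroid
      d2 <- rowSums(centred^2)
      return(vox[which.min(d2), , drop = FALSE])
    }
    proj <- drop(centred %*% axis)
    bin <- floor(proj / min(mask$spacing))
    centroids <- vapply(sort(unique(bin)), function(b) {
      colMeans(world[bin == b, , drop = FALSE])
    }, numeric(3))
    idx <- round(sweep(sweep(t(centroids), 2, mask$origin, "-"),
                       2, mask$spacing, "/"))
    storage.mode(idx) <- "integer"
    idx[!duplicated(idx), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y", "z")
  res
}

#' Cast a ray between two voxels and report tissue crossings
#'
#' Walks the straight segment between the voxel centres at sub-voxel
#' steps (nearest-voxel lookup) and reports the ordered sequence of
#' tissue crossings with their entry depths.
#'
#' @param from,to 0-based voxel indices (length-3).
#' @param labels A [volume3d()] of integer labels.
#' @param cfg A [planner_config()] (controls the walk step).
#' @return A list with `crossings` (tibble of `label` and entry
#'   `depth_mm`) and `length_mm` (Euclidean distance between the voxel
#'   centres).
#' @export
cast_ray <- function(from, to, labels, cfg = planner_config()) {
  stopifnot_volume(labels)
  p0 <- voxel_to_world(from, labels)
  p1 <- voxel_to_world(to, labels)
  step <- min(labels$spacing) * cfg$step_frac
  seq_labels <- .trace_ray(as.integer(labels$values), vol_dim(labels),
                           labels$spacing, labels$origin, p0, p1, step)
  len <- sqrt(sum((p1 - p0)^2))
  depths <- seq(0, len, length.out = length(seq_labels))
  keep <- c(TRUE, seq_labels[-1] != seq_labels[-length(seq_labels)])
  keep[is.na(keep)] <- FALSE
  keep[1] <- TRUE
  list(crossings = tibble::tibble(label = seq_labels[keep],
                                  depth_mm = depths[keep]),
       length_mm = len)
}

#' Score a candidate trajectory
#'
#' Combines the two hard constraints and two soft criteria into the path
#' quality `Q = sum(alpha_i C_i)` with equal weights `alpha_i = 1/2`:
#' `C1` is 0 if no risk-role tissue is crossed before the target and
#' `Inf` otherwise; `C2` is 0 if the path length is within the limit and
#' `Inf` otherwise; `C3` is the smallest distance to a risk structure
#' along the path, clipped at `d_cap` and normalised to `[0, 1]`; `C4` is
#' the number of target voxels along the shaft, capped at `n_cap` and
#' normalised to `[0, 1]`. Higher `Q` is better; `Q = Inf` flags an
#' infeasible path.
#'
#' @param crossings Crossing tibble from [cast_ray()] (used for C1).
#' @param length Path length, mm.
#' @param cfg A [planner_config()].
#' @param table Haptic tissue table (provides tissue roles).
#' @param min_risk_dist Smallest distance (mm) to a risk structure along
#'   the path.
#' @param n_target_voxels Number of target voxels along the shaft.
#' @return A one-row tibble with columns `C1`, `C2`, `C3`, `C4`, `Q`.
#' @export
score_path <- function(crossings, length, cfg = planner_config(),
                       table = default_tissue_table(),
                       min_risk_dist = Inf, n_target_voxels = 0) {
  risk_codes <- table$code[table$role == "risk"]
  target_codes <- table$code[table$role == "target"]
  first_target <- match(TRUE, crossings$label %in% target_codes)
  before <- if (is.na(first_target)) crossings$label else
    crossings$label[seq_len(first_target - 1L)]
  C1 <- if (any(before %in% risk_codes)) Inf else 0
  C2 <- if (length > cfg$max_length) Inf else 0
  C3 <- min(min_risk_dist, cfg$d_cap) / cfg$d_cap
  C4 <- min(n_target_voxels, cfg$n_cap) / cfg$n_cap
  Q <- if (is.infinite(C1) || is.infinite(C2)) Inf else
    0.5 * (C1 + C2 + C3 + C4)
  tibble::tibble(C1 = C1, C2 = C2, C3 = C3, C4 = C4, Q = Q)
}

#' Skin voxels eligible as needle entry points
#'
#' The outermost skin-labelled voxels: those with at least one 6-connected
#' air neighbour (or a face on the volume boundary).
#'
#' @param labels A fully labelled [volume3d()].
#' @param table Haptic tissue table.
#' @return Integer matrix of 0-based voxel indices (columns x, y, z).
#' @export
skin_entry_voxels <- function(labels, table = default_tissue_table()) {
  stopifnot_volume(labels)
  skin_code <- table$code[table$tissue == "skin"]
  air_code <- table$code[table$tissue == "air"]
  if (length(skin_code) != 1L || length(air_code) != 1L) {
    abort("tissue table must contain exactly one 'skin' and one 'air' row")
  }
  arr <- labels$values
  d <- dim(arr)
  skin <- arr == skin_code
  air <- arr == air_code
  pad <- function(a, shift, axis) {
    # neighbour-is-air (or outside) along one direction
    out <- array(TRUE, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (shift > 0) {
      idx_dst[[axis]] <- seq_len(d[axis] - 1L)
      idx_src[[axis]] <- 2:d[axis]
    } else {
      idx_dst[[axis]] <- 2:d[axis]
      idx_src[[axis]] <- seq_len(d[axis] - 1L)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      air[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  exposed <- pad(air, 1, 1) | pad(air, -1, 1) | pad(air, 1, 2) |
    pad(air, -1, 2) | pad(air, 1, 3) | pad(air, -1, 3)
  which(skin & exposed, arr.ind = TRUE) - 1L
}

#' Plan all accepted skin-to-target trajectories
#'
#' For every eligible skin voxel, straight candidates to every voxel of
#' the target centerline are measured by CPU ray casting, scored with
#' [score_path()], and the best-scoring candidate is kept. Candidates
#' failing a hard constraint (`Q = Inf`) or falling below the quality
#' threshold are removed. Ties in quality are broken towards the
#' smallest `(z, y, x)` target voxel, making the output deterministic.
#'
#' @param model A [patient_model()] whose label volume contains skin and
#'   the target structure.
#' @param cfg A [planner_config()].
#' @param n_samples Sample count recorded on the planned trajectories.
#' @return A tibble of class `puncture_plan`: one row per accepted path
#'   with entry point, unit direction, length, soft-criterion scores and
#'   quality `Q`.
#' @export
plan_all <- function(model, cfg = planner_config(), n_samples = 1000L) {
  stopifnot(inherits(model, "patient_model"))
  labels <- model$labels
  if (is.null(labels)) abort("planning requires a label volume")
  table <- model$table
  tc <- tissue_codes()
  target_code <- table$code[table$role == "target"]
  if (length(target_code) != 1L) {
    abort("planning requires exactly one target-role tissue in the table")
  }
  target_mask <- volume3d(array(as.integer(labels$values == target_code),
                                vol_dim(labels)),
                          labels$spacing, labels$origin)
  centerline <- extract_centerline(target_mask)
  skin <- skin_entry_voxels(labels, table)
  if (nrow(skin) == 0L) abort("no skin entry voxels found")

  risk_codes <- table$code[table$role == "risk"]
  risk_mask <- array(as.integer(labels$values %in% risk_codes),
                     vol_dim(labels))
  risk_dist <- .edt3d(as.integer(risk_mask), vol_dim(labels), labels$spacing)
  risk_lut <- logical(max(table$code) + 1L)
  risk_lut[risk_codes + 1L] <- TRUE

  step <- min(labels$spacing) * cfg$step_frac
  meas <- .measure_candidates(as.integer(labels$values), vol_dim(labels),
                              labels$spacing, labels$origin,
                              skin, centerline, risk_lut, target_code,
                              risk_dist, step, cfg$max_length)

  nt <- nrow(centerline)
  cand <- tibble::tibble(
    skin_i = rep(seq_len(nrow(skin)), each = nt),
    target_j = rep(seq_len(nt), times = nrow(skin)),
    blocked = meas[, 1] > 0,
    length_mm = meas[, 2],
    min_risk_dist = meas[, 3],
    n_target = meas[, 4]
  )
  cand <- dplyr::mutate(cand,
    C1 = ifelse(.data$blocked, Inf, 0),
    C2 = ifelse(.data$length_mm > cfg$max_length, Inf, 0),
    C3 = pmin(dplyr::coalesce(.data$min_risk_dist, 0), cfg$d_cap) / cfg$d_cap,
    C4 = pmin(.data$n_target, cfg$n_cap) / cfg$n_cap,
    Q = ifelse(is.infinite(.data$C1) | is.infinite(.data$C2), Inf,
               0.5 * (.data$C1 + .data$C2 + .data$C3 + .data$C4))
  )
  feasible <- dplyr::filter(cand, is.finite(.data$Q))
  if (nrow(feasible) == 0L) {
    warn("no feasible path from any skin voxel to the target")
    return(empty_plan(n_samples, cfg))
  }
  # deterministic best per skin voxel: highest Q, ties to smallest (z,y,x)
  feasible$tz <- centerline[feasible$target_j, 3]
  feasible$ty <- centerline[feasible$target_j, 2]
  feasible$tx <- centerline[feasible$target_j, 1]
  best <- feasible |>
    dplyr::arrange(.data$skin_i, dplyr::desc(.data$Q), .data$tz, .data$ty,
                   .data$tx) |>
    dplyr::distinct(.data$skin_i, .keep_all = TRUE) |>
    dplyr::filter(.data$Q >= cfg$quality_threshold)
  if (nrow(best) == 0L) {
    warn("all candidate paths fall below the quality threshold")
    return(empty_plan(n_samples, cfg))
  }
  entry <- voxel_to_world(skin[best$skin_i, , drop = FALSE], labels)
  target <- voxel_to_world(as.matrix(best[, c("tx", "ty", "tz")]), labels)
  entry <- matrix(entry, ncol = 3)
  target <- matrix(target, ncol = 3)
  dir <- (target - entry) / best$length_mm
  plan <- tibble::tibble(
    path_id = seq_len(nrow(best)),
    entry_x_mm = entry[, 1], entry_y_mm = entry[, 2], entry_z_mm = entry[, 3],
    dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3],
    length_mm = best$length_mm,
    C3 = best$C3, C4 = best$C4, Q = best$Q,
    target_x = best$tx, target_y = best$ty, target_z = best$tz
  )
  structure(plan, class = c("puncture_plan", class(plan)),
            n_samples = as.integer(n_samples), cfg = cfg)
}

empty_plan <- function(n_samples, cfg) {
  plan <- tibble::tibble(
    path_id = integer(), entry_x_mm = numeric(), entry_y_mm = numeric(),
    entry_z_mm = numeric(), dir_x = numeric(), dir_y = numeric(),
    dir_z = numeric(), length_mm = numeric(), C3 = numeric(),
    C4 = numeric(), Q = numeric(), target_x = integer(),
    target_y = integer(), target_z = integer()
  )
  structure(plan, class = c("puncture_plan", class(plan)),
            n_samples = as.integer(n_samples), cfg = cfg)
}

#' Materialise trajectories from a plan
#'
#' @param plan A `puncture_plan` from [plan_all()].
#' @param n_samples Samples per trajectory (defaults to the plan's).
#' @return A list of [trajectory()] objects.
#' @export
plan_trajectories <- function(plan, n_samples = NULL) {
  n_samples <- n_samples %||% attr(plan, "n_samples") %||% 1000L
  cfg <- attr(plan, "cfg") %||% planner_config()
  purrr::pmap(
    list(plan$entry_x_mm, plan$entry_y_mm, plan$entry_z_mm,
         plan$dir_x, plan$dir_y, plan$dir_z, plan$length_mm),
    function(ex, ey, ez, dx, dy, dz, len) {
      trajectory(c(ex, ey, ez), c(dx, dy, dz), len, n_samples,
                 max_length = cfg$max_length)
    }
  )
}

#' Write an accepted plan as CSV
#'
#' @param plan A `puncture_plan`.
#' @param path Output CSV path.
#' @export
write_plan_csv <- function(plan, path) {
  readr::write_csv(tibble::as_tibble(plan), path)
  invisible(path)
}
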