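#' Force engine configuration
#'
#' @param a1_fraction Pre-puncture design slope `a1` as a fraction of the
#'   tissue stiffness `k` (in `[0, 1]`). Any value preserves the puncture
#'   displacement (see [spring_coeffs()]), so rendered peak positions do
#'   not depend on it; it only shapes the ramp between start level and
#'   peak.
#' @param device_max Haptic device force ceiling, N (22 N for the
#'   high-force device the renderer targets).
#' @param n_samples Force samples per rendered path.
#' @param identical_tol Tolerance in N under which two forces count as
#'   "exactly identical" for the percent-identical-forces metric; the
#'   default admits bit-level float noise only.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(a1_fraction = 0.5, device_max = 22,
                          n_samples = 1000L, identical_tol = 1e-9) {
  if (a1_fraction < 0 || a1_fraction > 1) abort("`a1_fraction` must be in [0, 1]")
  if (device_max <= 0) abort("`device_max` must be positive")
  structure(list(a1_fraction = a1_fraction, device_max = device_max,
                 n_samples = as.integer(n_samples),
                 identical_tol = identical_tol),
            class = "engine_config")
}

#' Initial needle state for stepwise rendering
#'
#' @param cfg An [engine_config()].
#' @return A list of class `needle_state` holding the rendering phase,
#'   tip and proxy depths, the pinned surface depth (phase 1), the
#'   current sustained force level and the classifier flags.
#' @seealso [needle_step()]
#' @export
needle_state <- function(cfg = engine_config()) {
  structure(list(
    phase = 3L, tip_depth = 0, proxy_depth = 0, surface_depth = NA_real_,
    sustain = 0, coeffs = NULL, surf_T_N = NA_real_, code = NA_integer_,
    params = list(T_N = 0, R = 0, k = 0),
    inside_body = FALSE, passed_fascia = FALSE, blocked = FALSE,
    cfg = cfg
  ), class = "needle_state")
}

# Core phase-cycle transition. `code`/`params` describe the tissue at the
# new tip depth; returns the updated state plus the force emitted there.
#
# Phase cycle:
#   1 pre-puncture  proxy pinned at the surface, non-linear spring ramp
#   2 post-puncture the cut sample; emits the trigger force T_N, then the
#                   proxy is released to tip - R/k so the next sample is
#                   already at the sustain level R
#   3 pass          proxy dragged at l_max = R/k behind the tip, force R
#   4 transition    the surface-detection sample of a softer tissue
#                   (T_N <= sustained force): cut immediately, force drops
#                   to the new tissue's phase-2 level R
engine_transition <- function(st, depth, code, params) {
  cfg <- st$cfg
  force <- 0
  phase <- 3L
  event <- character()

  if (st$blocked) {
    # bone refused further advance; the handle stays at the device ceiling
    st$tip_depth <- depth
    return(list(state = st, force = cfg$device_max, phase = 1L,
                event = "bone_block"))
  }

  # While the proxy is pinned (phase 1) the cut condition is governed by the
  # pinned surface's threshold; tissue changes at the tip do not interrupt
  # the ramp (they determine the sustain level once the cut fires).
  tissue_changed <- !identical(code, st$code) && st$phase != 1L
  if (tissue_changed) {
    if (params$T_N > st$sustain) {
      # harder tissue: new pre-puncture cycle starting from the sustained level
      st$phase <- 1L
      st$surface_depth <- depth
      st$surf_T_N <- params$T_N
      st$coeffs <- spring_coeffs(params$T_N, st$sustain, params$k,
                                 cfg$a1_fraction * params$k)
      event <- c(event, "surface")
    } else {
      # softer tissue: cut immediately, drop to the new phase-2 force R
      st$phase <- if (is.na(st$code)) 3L else 4L
      st$sustain <- params$R
      if (!is.na(st$code)) event <- c(event, "surface", "cut")
    }
  }

  if (st$phase == 1L) {
    d <- depth - st$surface_depth
    f <- spring_force(d, st$coeffs)
    if (is.finite(st$surf_T_N) && f >= st$surf_T_N - 1e-12) {
      # cut: the sample emits the trigger force T_N (phase 2); the proxy is
      # released and the next sample sits at the sustain level of the
      # tissue now at the tip
      force <- st$surf_T_N
      phase <- 2L
      event <- c(event, "cut")
      st$phase <- 3L
      st$sustain <- params$R
      st$proxy_depth <- depth - params$R / max(params$k, .Machine$double.eps)
    } else {
      force <- min(f, cfg$device_max)
      phase <- 1L
      st$proxy_depth <- st$surface_depth
      if (!is.finite(st$surf_T_N) && f >= cfg$device_max) {
        st$blocked <- TRUE
        event <- c(event, "bone_block")
      }
    }
  } else {
    force <- st$sustain
    phase <- st$phase
    st$phase <- 3L
    st$proxy_depth <- depth -
      params$R / max(params$k, .Machine$double.eps) * (st$sustain > 0)
  }

  st$tip_depth <- depth
  st$code <- code
  st$params <- params
  list(state = st, force = force, phase = phase,
       event = paste(event, collapse = ";"))
}

#' Advance the needle one step
#'
#' Stateful single-step interface to the four-phase proxy/spring cycle:
#' looks up the tissue at the new tip depth through the patient model
#' (segmentation mask first, transfer function otherwise), updates the
#' classifier flags and returns the axial force emitted at that depth.
#' [render_insertion()] is the batch equivalent over a whole trajectory.
#'
#' @param state A [needle_state()].
#' @param new_tip_depth New tip depth along the path, mm (monotone
#'   non-decreasing across calls).
#' @param traj The [trajectory()] being followed.
#' @param model A [patient_model()].
#' @return A list with elements `state` (updated), `force` (N), `phase`
#'   and `event`.
#' @export
needle_step <- function(state, new_tip_depth, traj, model) {
  if (new_tip_depth < state$tip_depth) {
    abort("tip must not move backwards during insertion rendering")
  }
  pos <- traj$entry + new_tip_depth * traj$direction
  cls <- classifier_state(state$inside_body, state$passed_fascia)
  at <- haptic_params_at(pos, model, cls)
  tc <- tissue_codes()
  if (at$code != tc[["air"]]) state$inside_body <- TRUE
  if (at$code == tc[["fascia"]]) state$passed_fascia <- TRUE
  if (state$passed_fascia) state$inside_body <- TRUE
  out <- engine_transition(state, new_tip_depth, at$code, at$params)
  if (at$event == "risk") {
    out$event <- paste(c(out$event[nzchar(out$event)], "risk"), collapse = ";")
  }
  out
}

# Resolve the effective tissue code at every sample of a path: segmented
# voxels win; unsegmented voxels go through the transfer function with the
# classifier flags evolving along the path (fascia crossing switches the
# bone threshold, skin crossing arms the air-cavity risk flag).
resolve_path_tissues <- function(traj, model) {
  tc <- tissue_codes()
  grid <- model_grid(model)
  check_oversampling(traj, grid)
  n <- traj$n_samples
  labels <- if (!is.null(model$labels)) {
    as.integer(sample_values_along(traj, model$labels))
  } else {
    integer(n)
  }
  codes <- labels
  unseg <- which(labels == 0L)
  if (length(unseg)) {
    hu <- sample_values_along(traj, model$intensity)
    # fascia is an explicitly segmented key structure, so passed_fascia is
    # known from the labels; classify unsegmented voxels in the two regimes
    first_fascia <- match(tc[["fascia"]], labels)
    pre <- classify_intensity(hu[unseg], classifier_state(), model$thresholds)
    if (!is.na(first_fascia)) {
      post_idx <- unseg >= first_fascia
      if (any(post_idx)) {
        post <- classify_intensity(hu[unseg[post_idx]],
                                   classifier_state(TRUE, TRUE),
                                   model$thresholds)
        pre[post_idx] <- post
      }
    }
    codes[unseg] <- pre
  }
  unknown <- setdiff(unique(codes), model$table$code)
  if (length(unknown)) {
    abort(sprintf("label code %d is not registered in the tissue table",
                  unknown[1]),
          class = "punctforce_config_error")
  }
  inside_body <- cumsum(codes != tc[["air"]]) > 0L
  list(codes = codes, inside_body = inside_body)
}

#' Render the axial force signal of a needle insertion
#'
#' Runs the four-phase proxy/spring cycle along a straight trajectory and
#' returns one force sample per trajectory sample. Surface events are
#' detected where the sampled tissue changes between consecutive samples
#' (the surface position is the first sample of the new tissue); cut
#' events mark punctures, `risk` events mark contact with risk-role
#' tissue or an air cavity inside the body, and `bone_block` marks the
#' depth at which impenetrable bone clamps the device at its force
#' ceiling — the tip is refused beyond that depth and the remaining
#' samples hold the ceiling force.
#'
#' @param traj A [trajectory()]; its sample count is overridden by
#'   `cfg$n_samples` if they differ.
#' @param model A [patient_model()].
#' @param cfg An [engine_config()].
#' @return A `force_signal`: a tibble with columns `depth_mm`, `force_N`,
#'   `tissue`, `code`, `phase`, `event`, ordered by strictly increasing
#'   depth.
#' @examples
#' lab <- volume3d(array(tissue_codes()[["air"]], c(6, 6, 40)),
#'                 spacing = c(1, 1, 1))
#' tr <- trajectory(c(2, 2, 0), c(0, 0, 1), 30, n_samples = 400)
#' sig <- render_insertion(tr, patient_model(labels = lab))
#' all(sig$force_N == 0)
#' @export
render_insertion <- function(traj, model, cfg = engine_config()) {
  stopifnot(inherits(model, "patient_model"))
  if (traj$n_samples != cfg$n_samples) traj$n_samples <- cfg$n_samples
  res <- resolve_path_tissues(traj, model)
  codes <- res$codes
  inside <- res$inside_body
  tc <- tissue_codes()
  tbl <- model$table
  rows <- match(codes, tbl$code)
  T_N <- tbl$T_N[rows]; R <- tbl$R[rows]; k <- tbl$k[rows]
  role <- tbl$role[rows]
  depths <- traj_depths(traj)
  n <- length(depths)

  # tight scalar-state loop; mirrors engine_transition() (the stepwise
  # reference implementation) without per-sample allocations
  force <- numeric(n)
  phase <- integer(n)
  ev_surface <- logical(n)
  ev_cut <- logical(n)
  ev_block <- logical(n)
  in_ph1 <- FALSE
  blocked <- FALSE
  sustain <- 0
  surface <- 0
  a0 <- 0; a1 <- 0; a2 <- 0
  surf_T_N <- NA_real_
  prev_code <- NA_integer_
  a1f <- cfg$a1_fraction
  dmax <- cfg$device_max
  for (i in seq_len(n)) {
    if (blocked) {
      force[i] <- dmax
      phase[i] <- 1L
      ev_block[i] <- TRUE
      next
    }
    code_i <- codes[i]
    ph_i <- 3L
    if (!in_ph1 && !identical(code_i, prev_code)) {
      if (T_N[i] > sustain) {
        in_ph1 <- TRUE
        surface <- depths[i]
        surf_T_N <- T_N[i]
        a0 <- sustain
        a1 <- if (is.finite(T_N[i])) a1f * k[i] else k[i]
        a2 <- if (is.finite(T_N[i]) && T_N[i] != a0)
          k[i] * (k[i] - a1) / abs(T_N[i] - a0) else 0
        ev_surface[i] <- TRUE
      } else {
        sustain <- R[i]
        if (!is.na(prev_code)) {
          ph_i <- 4L
          ev_surface[i] <- TRUE
          ev_cut[i] <- TRUE
        }
      }
    }
    if (in_ph1) {
      d <- depths[i] - surface
      f <- a2 * d * d + a1 * d + a0
      if (is.finite(surf_T_N) && f >= surf_T_N - 1e-12) {
        force[i] <- surf_T_N
        ph_i <- 2L
        ev_cut[i] <- TRUE
        in_ph1 <- FALSE
        sustain <- R[i]
      } else {
        ph_i <- 1L
        if (f >= dmax) {
          force[i] <- dmax
          if (!is.finite(surf_T_N)) {
            blocked <- TRUE
            ev_block[i] <- TRUE
          }
        } else {
          force[i] <- f
        }
      }
    } else if (ph_i != 2L) {
      force[i] <- sustain
    }
    phase[i] <- ph_i
    prev_code <- code_i
  }
  ev_risk <- role == "risk" | (codes == tc[["air"]] & inside)
  event <- character(n)
  for (i in which(ev_surface | ev_cut | ev_block | ev_risk)) {
    event[i] <- paste(c(
      if (ev_surface[i]) "surface",
      if (ev_cut[i]) "cut",
      if (ev_block[i]) "bone_block",
      if (ev_risk[i]) "risk"
    ), collapse = ";")
  }

  new_force_signal(tibble::tibble(
    depth_mm = depths,
    force_N = pmin(pmax(force, 0), cfg$device_max),
    tissue = tbl$tissue[rows],
    code = codes,
    phase = phase,
    event = event
  ), traj = traj, direction = "insertion")
}

#' Render the force signal of a needle retraction
#'
#' Retraction reuses only the pass phase with inverted direction: every
#' membrane along the path has already been cut, so no puncture peaks
#' occur and the shaft friction alone is felt — the sustained force `R`
#' of the local tissue, zero in air. Samples are emitted in motion order,
#' i.e. depth decreasing from `from_depth` back to the entry point.
#'
#' @inheritParams render_insertion
#' @param from_depth Depth at which retraction starts, mm; defaults to
#'   the full trajectory length. A zero-length retraction yields an empty
#'   signal.
#' @return A `force_signal` tibble (depths decreasing).
#' @export
render_retraction <- function(traj, model, cfg = engine_config(),
                              from_depth = NULL) {
  stopifnot(inherits(model, "patient_model"))
  if (traj$n_samples != cfg$n_samples) traj$n_samples <- cfg$n_samples
  from_depth <- from_depth %||% traj$length
  if (from_depth <= 0) {
    return(new_force_signal(tibble::tibble(
      depth_mm = numeric(), force_N = numeric(), tissue = character(),
      code = integer(), phase = integer(), event = character()
    ), traj = traj, direction = "retraction"))
  }
  res <- resolve_path_tissues(traj, model)
  keep <- which(traj_depths(traj) <= from_depth + 1e-12)
  idx <- rev(keep)
  codes <- res$codes[idx]
  rows <- match(codes, model$table$code)
  tc <- tissue_codes()
  force <- model$table$R[rows]
  force[codes == tc[["air"]]] <- 0
  new_force_signal(tibble::tibble(
    depth_mm = traj_depths(traj)[idx],
    force_N = pmin(force, cfg$device_max),
    tissue = model$table$tissue[rows],
    code = codes,
    phase = 3L,
    event = ""
  ), traj = traj, direction = "retraction")
}

new_force_signal <- function(df, traj = NULL, direction = "insertion") {
  structure(df, class = c("force_signal", class(df)),
            traj = traj, direction = direction)
}

#' Write or read a force signal as CSV
#'
#' @param signal A `force_signal` from [render_insertion()].
#' @param path Output CSV path.
#' @return `path` (write) or a `force_signal` tibble (read), invisibly
#'   for the writer.
#' @export
write_signal_csv <- function(signal, path) {
  readr::write_csv(tibble::as_tibble(signal), path)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          depth_mm = "d", force_N = "d", tissue = "c",
                          code = "i", phase = "i", event = "c"
                        ))
  df$event[is.na(df$event)] <- ""
  new_force_signal(df)
}
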