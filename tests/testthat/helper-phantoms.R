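# Shared fixtures: all volumes are generated in code at test time.

# Small lateral footprint keeps renders fast; depth extent matches the
# default phantom so the layer stack is unchanged. Lateral features
# (vessels, intercostal window) are scaled into the 21.6 mm footprint.
small_spec <- function(...) {
  phantom_spec(dims = c(24L, 24L, 160L),
               vessel_ys = c(5.4, 16.2),
               rib_window_y = c(7.2, 14.4), ...)
}

small_two_fascia_spec <- function(...) {
  phantom_spec(dims = c(24L, 24L, 160L), second_fascia_depth = 40,
               liver_range = c(44.5, 110),
               vessel_ys = c(5.4, 16.2),
               rib_window_y = c(7.2, 14.4), ...)
}

# perpendicular insertion path through the middle of the (x, y) footprint
centre_path <- function(length = 80, n_samples = 1000L) {
  trajectory(c(10.8, 10.8, 0), c(0, 0, 1), length, n_samples)
}

# A single-column layer stack volume: labels change along z only.
# `layers` is a tibble/data.frame with columns code and thickness_mm.
stack_volume <- function(layers, spacing = 0.9, nx = 6L) {
  nz <- sum(round(layers$thickness_mm / spacing))
  z_codes <- unlist(mapply(function(code, th) {
    rep.int(code, round(th / spacing))
  }, layers$code, layers$thickness_mm, SIMPLIFY = FALSE))
  arr <- array(rep(as.integer(z_codes), each = nx * nx), c(nx, nx, nz))
  volume3d(arr, spacing = rep(spacing, 3))
}

# Random layered stack starting with air and skin, then a random sequence
# of penetrable tissues; used for engine-vs-oracle property tests.
random_stack <- function(seed, allow_bone = FALSE) {
  withr::with_seed(seed, {
    tc <- tissue_codes()
    pool <- tc[c("soft", "fascia", "liver", "bile", "vessel")]
    if (allow_bone) pool <- c(pool, tc[["bone_sensitive"]])
    n_mid <- sample(2:5, 1)
    codes <- c(tc[["air"]], tc[["skin"]],
               sample(pool, n_mid, replace = TRUE), tc[["soft"]])
    th <- c(runif(1, 2, 5), runif(1, 1.8, 3.6),
            runif(n_mid, 3, 12), 40)
    stack_volume(data.frame(code = as.integer(codes), thickness_mm = th))
  })
}

stack_path <- function(vol, n_samples = 1000L) {
  len <- min(90, (vol_dim(vol)[3] - 1) * vol$spacing[3] * 0.95)
  trajectory(c(2.25, 2.25, 0), c(0, 0, 1), len, n_samples)
}

# ---------------------------------------------------------------------------
# Independent brute-force force oracle: a literal proxy simulation on a fine
# depth grid. The proxy is a depth coordinate; forces come straight from the
# spring polynomial between proxy and tip (pinned) or from the Hooke spring
# dragged at l_max = R/k behind the tip (free). Written independently of the
# engine's run-length state machine.
oracle_render <- function(traj, model, n = 20000L, cfg = engine_config()) {
  traj$n_samples <- as.integer(n)
  depths <- traj_depths(traj)
  labs <- suppressWarnings(sample_labels_along(traj, model$labels))$label
  tbl <- model$table
  rows <- match(labs, tbl$code)
  T_N <- tbl$T_N[rows]; R <- tbl$R[rows]; k <- tbl$k[rows]

  force <- numeric(n)
  events <- numeric(0)           # depths of cut events
  pinned <- FALSE
  blocked <- FALSE
  proxy <- 0
  cs <- NULL
  pin_T_N <- NA_real_
  f_prev <- 0
  for (i in seq_len(n)) {
    x <- depths[i]
    if (blocked) {
      force[i] <- cfg$device_max
      next
    }
    if (!pinned && i > 1 && labs[i] != labs[i - 1]) {
      if (T_N[i] > f_prev + 1e-12) {
        pinned <- TRUE
        proxy <- x
        pin_T_N <- T_N[i]
        cs <- spring_coeffs(T_N[i], f_prev, k[i], cfg$a1_fraction * k[i])
      } else {
        # cut immediately: proxy jumps to x - R/k
        proxy <- x - ifelse(k[i] > 0, R[i] / k[i], 0)
        events <- c(events, x)
      }
    }
    if (pinned) {
      f <- spring_force(x - proxy, cs)
      if (is.finite(pin_T_N) && f >= pin_T_N - 1e-12) {
        force[i] <- pin_T_N
        events <- c(events, x)
        pinned <- FALSE
        proxy <- x - ifelse(k[i] > 0, R[i] / k[i], 0)
      } else if (f >= cfg$device_max) {
        force[i] <- cfg$device_max
        if (!is.finite(pin_T_N)) blocked <- TRUE
      } else {
        force[i] <- f
      }
    } else {
      # pass: drag the proxy so the spring never stretches past l_max
      lmax <- ifelse(k[i] > 0, R[i] / k[i], 0)
      if (x - proxy > lmax) proxy <- x - lmax
      force[i] <- k[i] * (x - proxy)
    }
    f_prev <- force[i]
  }
  list(depth = depths, force = force, cut_depths = events)
}
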