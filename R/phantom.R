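#' Specify a layered synthetic phantom
#'
#' The phantom emulates a desk-scale lower-thorax/upper-abdomen stack
#' along the insertion (z) axis: air, skin, fat/soft tissue, a fascia
#' sheet (optionally two), the liver with an embedded bile-duct tube
#' (target) and hepatic vessel tubes (risk), and two rib-like bone slabs
#' flanking an intercostal window in the soft-tissue region. Class
#' intensities are drawn per voxel from seeded Gaussians whose means lie
#' strictly inside the configured threshold intervals; the default
#' standard deviation keeps the probability of a noise-induced
#' misclassification below 1e-6, so segmentation discrepancies come only
#' from the controlled perturbations: per-structure entry-surface offsets
#' (the test model detects the surface deeper) and misclassified voxel
#' bands.
#'
#' @param dims Volume dimensions (x, y, z voxels).
#' @param spacing_mm Isotropic voxel spacing, mm.
#' @param seed Seed for the intensity noise.
#' @param air_depth,skin_thickness,fascia_depth,fascia_thickness Layer
#'   geometry along z, mm.
#' @param second_fascia_depth Entry depth of an optional second fascia
#'   sheet, mm (`NULL` = single sheet).
#' @param liver_range Liver extent along z, mm.
#' @param bile_depth,bile_y,bile_radius Bile-duct tube (along x), mm;
#'   `bile_y = NULL` centres it.
#' @param vessel_depths,vessel_ys,vessel_radius Hepatic vessel tubes
#'   (along x), mm.
#' @param rib_z_range,rib_window_y Rib slabs: z extent and the y interval
#'   of the intercostal window between them, mm.
#' @param intensity_means Named per-class mean intensities, HU.
#' @param intensity_sd Per-class intensity standard deviation, HU.
#' @param offsets Named entry-surface offsets (mm, applied to the test
#'   model), e.g. `c(skin = 2)` or `c(fascia = 1)`.
#' @param misclassify Optional list `(structure, thickness_mm,
#'   as_tissue)`: a band of that thickness proximal to the structure's
#'   entry surface is relabelled in the test (partial) segmentation.
#' @param thresholds The [threshold_set()] the intensities are generated
#'   against.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128L, 128L, 160L), spacing_mm = 0.9,
                         seed = 1L,
                         air_depth = 5, skin_thickness = 2.7,
                         fascia_depth = 25, fascia_thickness = 4.5,
                         second_fascia_depth = NULL,
                         liver_range = c(29.5, 110),
                         bile_depth = 60, bile_y = NULL, bile_radius = 3,
                         vessel_depths = c(50, 80),
                         vessel_ys = NULL, vessel_radius = 2.25,
                         rib_z_range = c(9, 18),
                         rib_window_y = NULL,
                         intensity_means = c(air = -1000, skin = -200,
                                             soft = 100, bone_sensitive = 700,
                                             fascia = 100, liver = 90,
                                             vessel = 110, bile = 80),
                         intensity_sd = 10,
                         offsets = c(skin = 0, fascia = 0),
                         misclassify = NULL,
                         thresholds = threshold_set()) {
  extent <- dims * spacing_mm
  bile_y <- bile_y %||% (extent[2] / 2)
  vessel_ys <- vessel_ys %||% (extent[2] / 2 + c(-18, 18))
  rib_window_y <- rib_window_y %||% (extent[2] / 2 + c(-10, 10))
  if (!is.null(second_fascia_depth)) {
    if (second_fascia_depth < fascia_depth + fascia_thickness) {
      abort("fascia sheets overlap")
    }
    if (liver_range[1] < second_fascia_depth + fascia_thickness) {
      abort("liver must start below the second fascia sheet")
    }
  }
  if (liver_range[1] < fascia_depth + fascia_thickness) {
    abort("liver must start below the fascia")
  }
  if (liver_range[2] > extent[3]) abort("liver exceeds the volume extent")
  if (bile_depth < liver_range[1] || bile_depth > liver_range[2]) {
    abort("bile duct must lie inside the liver")
  }
  # intensity means must lie strictly inside their class intervals so the
  # transfer function reproduces the generating class
  thr <- thresholds
  iv <- list(air = c(-Inf, thr$t0), skin = c(thr$t0, thr$t1),
             soft = c(thr$t1, thr$t2_minus),
             bone_sensitive = c(thr$t2_minus, Inf))
  for (cls in names(iv)) {
    m <- intensity_means[[cls]]
    if (!(m > iv[[cls]][1] && m < iv[[cls]][2])) {
      abort(sprintf("intensity mean for '%s' (%g HU) lies outside its threshold interval",
                    cls, m))
    }
  }
  structure(list(
    dims = as.integer(dims), spacing_mm = spacing_mm, seed = as.integer(seed),
    air_depth = air_depth, skin_thickness = skin_thickness,
    fascia_depth = fascia_depth, fascia_thickness = fascia_thickness,
    second_fascia_depth = second_fascia_depth,
    liver_range = liver_range,
    bile_depth = bile_depth, bile_y = bile_y, bile_radius = bile_radius,
    vessel_depths = vessel_depths, vessel_ys = vessel_ys,
    vessel_radius = vessel_radius,
    rib_z_range = rib_z_range, rib_window_y = rib_window_y,
    intensity_means = intensity_means, intensity_sd = intensity_sd,
    offsets = offsets, misclassify = misclassify, thresholds = thresholds
  ), class = "phantom_spec")
}

# Label geometry for a given set of entry-surface offsets. Offsets delay
# the *entry* (proximal) surface of a structure; distal surfaces stay put,
# so everything outside the offset band is unchanged.
build_geometry <- function(spec, offsets = c(skin = 0, fascia = 0)) {
  tc <- tissue_codes()
  d <- spec$dims
  sp <- spec$spacing_mm
  z <- (seq_len(d[3]) - 1L) * sp  # voxel-centre depths
  off <- function(nm) if (nm %in% names(offsets)) offsets[[nm]] else 0
  skin_start <- spec$air_depth + off("skin")
  skin_end <- spec$air_depth + spec$skin_thickness
  fascia_start <- spec$fascia_depth + off("fascia")
  fascia_end <- spec$fascia_depth + spec$fascia_thickness
  layer <- rep.int(tc[["air"]], d[3])
  layer[z >= skin_end] <- tc[["soft"]]
  layer[z >= skin_start & z < skin_end] <- tc[["skin"]]
  layer[z >= fascia_start & z < fascia_end] <- tc[["fascia"]]
  if (!is.null(spec$second_fascia_depth)) {
    f2 <- spec$second_fascia_depth
    layer[z >= f2 & z < f2 + spec$fascia_thickness] <- tc[["fascia"]]
  }
  layer[z >= spec$liver_range[1] & z < spec$liver_range[2]] <- tc[["liver"]]
  arr <- array(rep(layer, each = d[1] * d[2]), d)

  y <- (seq_len(d[2]) - 1L) * sp
  # rib slabs: bone wherever soft tissue sits in the rib z-range outside
  # the intercostal window
  rib_z <- z >= spec$rib_z_range[1] & z < spec$rib_z_range[2]
  rib_y <- y < spec$rib_window_y[1] | y >= spec$rib_window_y[2]
  if (any(rib_z) && any(rib_y)) {
    sub <- arr[, rib_y, rib_z, drop = FALSE]
    sub[sub == tc[["soft"]]] <- tc[["bone_sensitive"]]
    arr[, rib_y, rib_z] <- sub
  }
  # tubes along x inside the liver
  yz <- expand.grid(y = y, z = z)
  carve_tube <- function(arr, yc, zc, radius, code) {
    inside <- (yz$y - yc)^2 + (yz$z - zc)^2 <= radius^2
    if (!any(inside)) return(arr)
    m <- matrix(inside, d[2], d[3])
    sel <- which(m, arr.ind = TRUE)
    liver_ok <- arr[cbind(1L, sel[, 1], sel[, 2])] == tc[["liver"]]
    sel <- sel[liver_ok, , drop = FALSE]
    if (nrow(sel)) {
      for (x in seq_len(d[1])) arr[cbind(x, sel[, 1], sel[, 2])] <- code
    }
    arr
  }
  for (i in seq_along(spec$vessel_depths)) {
    arr <- carve_tube(arr, spec$vessel_ys[i], spec$vessel_depths[i],
                      spec$vessel_radius, tc[["vessel"]])
  }
  arr <- carve_tube(arr, spec$bile_y, spec$bile_depth, spec$bile_radius,
                    tc[["bile"]])
  volume3d(arr, spacing = rep(sp, 3), origin = c(0, 0, 0))
}

#' Generate a layered phantom
#'
#' Produces the gold-standard fully labelled volume, the partial
#' segmentation of key structures only (fascia, liver, vessels, bile
#' ducts; skin, fat, bone and air are left to the transfer function) and
#' a CT intensity volume. The configured perturbations (entry-surface
#' offsets, misclassified bands) are applied to the partial labels and
#' intensities only — the gold standard is the unperturbed truth.
#' Identical specs (including seed) yield bit-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `gold`, `partial`,
#'   `intensity` (all [volume3d()]) and the resolved `spec`.
#' @export
layered_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  tc <- tissue_codes()
  gold <- build_geometry(spec, offsets = c(skin = 0, fascia = 0))
  test_geom <- build_geometry(spec, offsets = spec$offsets)
  key <- tc[c("fascia", "liver", "vessel", "bile")]
  partial_arr <- test_geom$values
  partial_arr[!(partial_arr %in% key)] <- 0L
  partial <- volume3d(partial_arr, gold$spacing, gold$origin)
  if (!is.null(spec$misclassify)) {
    mc <- spec$misclassify
    partial <- misclassify_band(partial, mc$structure, mc$thickness_mm,
                                mc$as_tissue)
  }
  means <- spec$intensity_means
  mean_of <- numeric(max(tc) + 1L)
  mean_of[tc[names(tc)] ] <- NA_real_
  for (nm in names(means)) mean_of[tc[[nm]]] <- means[[nm]]
  # bone_specific shares the bone intensity model
  if (is.na(mean_of[tc[["bone_specific"]]])) {
    mean_of[tc[["bone_specific"]]] <- means[["bone_sensitive"]]
  }
  mu <- mean_of[test_geom$values]
  if (anyNA(mu)) abort("missing intensity mean for a generated class")
  noise <- with_preserved_seed(spec$seed, {
    rnorm(length(mu), mean = 0, sd = spec$intensity_sd)
  })
  intensity <- volume3d(array(mu + noise, spec$dims), gold$spacing,
                        gold$origin)
  structure(list(gold = gold, partial = partial, intensity = intensity,
                 spec = spec),
            class = "phantom")
}

#' Generate the two-fascial-layer phantom
#'
#' Convenience wrapper around [layered_phantom()] with a second fascia
#' sheet: two parallel sheets separated by soft tissue, reproducing the
#' double puncture-peak force pattern. Overlapping sheets are rejected.
#'
#' @param spec A [phantom_spec()]; its `second_fascia_depth` defaults to
#'   40 mm and `liver_range` to start below the second sheet.
#' @return A `phantom` list, as [layered_phantom()].
#' @export
two_fascia_phantom <- function(spec = phantom_spec(second_fascia_depth = 40,
                                                   liver_range = c(44.5, 110))) {
  if (is.null(spec$second_fascia_depth)) {
    abort("two_fascia_phantom() requires `second_fascia_depth`")
  }
  layered_phantom(spec)
}

#' Relabel a band proximal to a structure's surface
#'
#' In every (x, y) column where the structure occurs, the band of the
#' given thickness immediately above (proximal to, i.e. at smaller depth
#' than) its first voxel is set to the substitute tissue — emulating a
#' segmentation that misclassifies the tissue just before a membrane.
#' Zero thickness is the identity.
#'
#' @param labels A label [volume3d()].
#' @param structure Tissue name or code whose surface the band abuts.
#' @param thickness_mm Band thickness, mm (rounded to whole voxels).
#' @param as_tissue Tissue name or code to write into the band.
#' @return The modified label [volume3d()].
#' @export
misclassify_band <- function(labels, structure, thickness_mm, as_tissue) {
  stopifnot_volume(labels)
  code <- resolve_code(structure)
  as_code <- resolve_code(as_tissue)
  nb <- round(thickness_mm / labels$spacing[3])
  if (nb == 0) return(labels)
  arr <- labels$values
  d <- dim(arr)
  mask <- arr == code
  if (!any(mask)) {
    abort(sprintf("structure '%s' not present in the label volume", structure))
  }
  zfirst <- matrix(NA_integer_, d[1], d[2])
  for (k in seq_len(d[3])) {
    new <- mask[, , k] & is.na(zfirst)
    if (any(new)) zfirst[new] <- k
  }
  cols <- which(!is.na(zfirst), arr.ind = TRUE)
  z0 <- zfirst[cols]
  if (any(z0 - nb < 1L)) {
    abort("misclassification band extends beyond the volume bounds")
  }
  for (off in seq_len(nb)) {
    arr[cbind(cols, z0 - off)] <- as_code
  }
  volume3d(arr, labels$spacing, labels$origin)
}

resolve_code <- function(x) {
  tc <- tissue_codes()
  if (is.character(x)) {
    if (!x %in% names(tc)) abort(sprintf("unknown tissue '%s'", x))
    return(unname(tc[x]))
  }
  as.integer(x)
}

#' Patient models from a phantom
#'
#' @param ph A `phantom` from [layered_phantom()].
#' @param table Haptic tissue table.
#' @return A list with `ref` (gold-standard full segmentation) and
#'   `test` (partial segmentation plus intensities) [patient_model()]s.
#' @export
phantom_models <- function(ph, table = default_tissue_table()) {
  stopifnot(inherits(ph, "phantom"))
  list(
    ref = patient_model(labels = ph$gold, table = table,
                        thresholds = ph$spec$thresholds),
    test = patient_model(labels = ph$partial, intensity = ph$intensity,
                         table = table, thresholds = ph$spec$thresholds)
  )
}

#' Write phantom volumes to a directory
#'
#' Writes `gold.mhd`, `partial.mhd`, `intensity.mhd` and the resolved
#' spec as `spec.yaml`.
#'
#' @param ph A `phantom`.
#' @param dir Output directory.
#' @export
write_phantom <- function(ph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(ph$gold, file.path(dir, "gold.mhd"))
  write_volume(ph$partial, file.path(dir, "partial.mhd"))
  write_volume(ph$intensity, file.path(dir, "intensity.mhd"))
  sp <- ph$spec
  sp$thresholds <- unclass(sp$thresholds)
  yaml::write_yaml(lapply(unclass(sp), function(x) if (is.null(x)) NULL else x),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
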