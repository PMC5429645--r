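#' Tissue codes used by the default haptic table
#'
#' Integer label codes for the tissues of the default virtual patient.
#' Code 0 is reserved for "unsegmented" voxels, whose tissue is estimated
#' from CT intensity by the transfer function ([classify_intensity()]).
#'
#' @return A named integer vector.
#' @export
tissue_codes <- function() {
  c(air = 1L, skin = 2L, soft = 3L, bone_sensitive = 4L, bone_specific = 5L,
    fascia = 6L, vessel = 7L, liver = 8L, bile = 9L)
}

#' Per-tissue haptic parameters
#'
#' Each tissue carries the tuple `(T_N, R, k)`: the cut-force threshold
#' `T_N` in N that the pre-puncture spring must reach before the tissue
#' surface is pierced (infinite for impenetrable bone), the sustained
#' friction force `R` in N while advancing inside the tissue, and the
#' stiffness `k` in N/mm of the spring connecting needle tip and proxy.
#' Most tissues satisfy `R <= T_N` (the sustained level does not exceed
#' the force that cut the surface), but the liver deliberately does not:
#' its membrane is easy to pierce (`T_N = 0.3` N) while dragging the
#' shaft through the parenchyma costs more (`R = 0.9` N), so the
#' condition is not enforced.
#'
#' @param T_N Cut-force threshold, N (may be `Inf`).
#' @param R Friction/sustain force, N.
#' @param k Stiffness, N/mm (> 0 for penetrable tissues).
#' @return A named list with elements `T_N`, `R`, `k`.
#' @examples
#' haptic_params(2.5, 1.0, 1.0)  # fascia
#' @export
haptic_params <- function(T_N, R, k) {
  if (is.na(T_N) || is.na(R) || is.na(k) || T_N < 0 || R < 0 || k < 0) {
    abort("haptic parameters must be non-negative (T_N may be Inf)")
  }
  list(T_N = as.numeric(T_N), R = as.numeric(R), k = as.numeric(k))
}

#' The default haptic tissue table
#'
#' One row per tissue of the layered thorax/abdomen model: label `code`,
#' tissue name, its planning `role` (`pass` tissues may be traversed,
#' `risk` tissues must not be touched, `target` is the structure to hit),
#' and the haptic tuple `(T_N, R, k)` from the expert-tuned parameter
#' table. Skin has `R == T_N` (the needle enters through a small incision,
#' so no force drop follows the skin cut); both bone rows are impenetrable
#' (`T_N = Inf`) and share one tuple, differing only by the intensity
#' threshold that detects them; the liver has the lowest finite cut
#' threshold of all tissues.
#'
#' @return A tibble with columns `code`, `tissue`, `role`, `T_N`, `R`, `k`.
#' @examples
#' default_tissue_table()
#' @export
default_tissue_table <- function() {
  tc <- tissue_codes()
  tbl <- tibble::tribble(
    ~tissue,          ~role,    ~T_N, ~R,   ~k,
    "air",            "pass",   0,    0,    0,
    "skin",           "pass",   0.7,  0.7,  0.8,
    "soft",           "pass",   0.7,  0.7,  1.0,
    "bone_sensitive", "risk",   Inf,  3.0,  2.0,
    "bone_specific",  "risk",   Inf,  3.0,  2.0,
    "fascia",         "pass",   2.5,  1.0,  1.0,
    "vessel",         "risk",   1.05, 0.75, 1.1,
    "liver",          "pass",   0.3,  0.9,  1.2,
    "bile",           "target", 1.2,  0.5,  1.0
  )
  tbl$code <- unname(tc[tbl$tissue])
  validate_tissue_table(tbl[, c("code", "tissue", "role", "T_N", "R", "k")])
}

validate_tissue_table <- function(tbl) {
  stopifnot(all(c("code", "tissue", "role", "T_N", "R", "k") %in% names(tbl)))
  if (anyDuplicated(tbl$code)) abort("duplicate tissue codes in table")
  if (any(tbl$code == 0L)) abort("code 0 is reserved for unsegmented voxels")
  if (!all(tbl$role %in% c("pass", "risk", "target"))) {
    abort("tissue roles must be one of 'pass', 'risk', 'target'")
  }
  ok <- tbl$T_N >= 0 & tbl$R >= 0 & tbl$k >= 0
  if (!all(ok)) {
    abort(sprintf("invalid haptic parameters for tissue '%s' (need T_N, R, k >= 0)",
                  tbl$tissue[!ok][1]))
  }
  tibble::as_tibble(tbl)
}

#' Intensity interval thresholds of the transfer function
#'
#' Lower interval bounds, in Hounsfield units, of the half-open intensity
#' intervals that classify unsegmented voxels: air `(-Inf, t0)`, skin
#' `[t0, t1)`, fat/soft tissue `[t1, bone threshold)` and bone above.
#' The bone threshold is position-state dependent: `t2_minus` (sensitive)
#' applies while the needle tip is outside the fascia, the higher
#' `t2_plus` (specific) once the fascia has been passed, where dense
#' tissue close to bone intensity is common and a stricter bone call
#' avoids false impenetrable voxels. Thresholds are patient-specific in
#' practice; the defaults here only anchor the synthetic phantoms.
#'
#' @param t0,t1,t2_minus,t2_plus Lower interval bounds in HU, ordered
#'   `t0 < t1 < t2_minus <= t2_plus`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(t0 = -500, t1 = 50, t2_minus = 200, t2_plus = 400) {
  if (!(t0 < t1 && t1 < t2_minus && t2_minus <= t2_plus)) {
    abort("thresholds must satisfy t0 < t1 < t2_minus <= t2_plus")
  }
  structure(list(t0 = as.numeric(t0), t1 = as.numeric(t1),
                 t2_minus = as.numeric(t2_minus), t2_plus = as.numeric(t2_plus)),
            class = "threshold_set")
}

#' Needle-tip classifier state
#'
#' The transfer function depends on where the needle tip has been:
#' `inside_body` is set once the tip has crossed the skin (first non-air
#' tissue on the path) and turns an air classification into a risk event
#' (an air cavity inside the body must not be punctured); `passed_fascia`
#' is set once the fascia has been crossed and switches the bone
#' threshold from sensitive to specific.
#'
#' @param inside_body Has the tip passed the skin?
#' @param passed_fascia Has the tip passed the fascia (implies
#'   `inside_body`)?
#' @return An object of class `classifier_state`.
#' @export
classifier_state <- function(inside_body = FALSE, passed_fascia = FALSE) {
  if (passed_fascia && !inside_body) {
    abort("`passed_fascia` implies `inside_body`")
  }
  structure(list(inside_body = isTRUE(inside_body),
                 passed_fascia = isTRUE(passed_fascia)),
            class = "classifier_state")
}

#' Classify a CT intensity into a tissue code
#'
#' The threshold transfer function for unsegmented voxels. Intervals are
#' half-open `[lower, next)`: intensities below `t0` are air, `[t0, t1)`
#' skin, `[t1, bone threshold)` fat/soft tissue, and anything above the
#' bone threshold is bone. Outside the fascia the sensitive bone
#' threshold `t2_minus` applies (bone code `bone_sensitive`); once the
#' fascia has been passed the specific threshold `t2_plus` applies
#' (`bone_specific`), so an intensity between the two thresholds is bone
#' before the fascia but fat/soft tissue after it.
#'
#' @param hu Intensity value(s), HU (vectorised).
#' @param state A [classifier_state()].
#' @param thr A [threshold_set()].
#' @return Integer tissue code(s) from [tissue_codes()].
#' @examples
#' thr <- threshold_set()
#' classify_intensity(300, classifier_state(), thr)                  # bone
#' classify_intensity(300, classifier_state(TRUE, TRUE), thr)        # soft
#' @export
classify_intensity <- function(hu, state = classifier_state(),
                               thr = threshold_set()) {
  tc <- tissue_codes()
  bone_thr <- if (state$passed_fascia) thr$t2_plus else thr$t2_minus
  bone_code <- if (state$passed_fascia) tc[["bone_specific"]] else tc[["bone_sensitive"]]
  out <- rep.int(tc[["air"]], length(hu))
  out[hu >= thr$t0] <- tc[["skin"]]
  out[hu >= thr$t1] <- tc[["soft"]]
  out[hu >= bone_thr] <- bone_code
  out
}

#' Assemble a virtual patient model
#'
#' A patient model bundles what the force engine needs at every position:
#' an optional integer label volume (full gold-standard segmentation, or
#' a partial segmentation of key structures with 0 elsewhere), an
#' optional CT intensity volume for the transfer function, the haptic
#' tissue table and the intensity thresholds. At least one volume must be
#' present; a model without intensities must be fully labelled, and a
#' model with unsegmented voxels must carry intensities.
#'
#' @param labels Optional [volume3d()] of integer label codes (0 =
#'   unsegmented).
#' @param intensity Optional [volume3d()] of HU intensities.
#' @param table Haptic tissue table, see [default_tissue_table()].
#' @param thresholds A [threshold_set()].
#' @return An object of class `patient_model`.
#' @export
patient_model <- function(labels = NULL, intensity = NULL,
                          table = default_tissue_table(),
                          thresholds = threshold_set()) {
  table <- validate_tissue_table(table)
  if (is.null(labels) && is.null(intensity)) {
    abort("a patient model needs a label volume, an intensity volume, or both")
  }
  if (!is.null(labels)) {
    stopifnot_volume(labels)
    codes <- unique(as.integer(labels$values))
    unknown <- setdiff(codes, c(0L, table$code))
    if (length(unknown)) {
      abort(sprintf("label volume contains code(s) %s not registered in the tissue table",
                    paste(sort(unknown), collapse = ", ")),
            class = "punctforce_config_error")
    }
  }
  if (!is.null(intensity)) stopifnot_volume(intensity)
  if (!is.null(labels) && !is.null(intensity)) {
    if (!identical(vol_dim(labels), vol_dim(intensity)) ||
        max(abs(labels$spacing - intensity$spacing)) > 1e-9 ||
        max(abs(labels$origin - intensity$origin)) > 1e-9) {
      abort("label and intensity volumes must share grid, spacing and origin")
    }
  }
  if (is.null(intensity) && any(labels$values == 0L)) {
    abort("model has unsegmented voxels but no intensity volume for the transfer function")
  }
  structure(list(labels = labels, intensity = intensity, table = table,
                 thresholds = thresholds),
            class = "patient_model")
}

#' @export
print.patient_model <- function(x, ...) {
  vol <- x$labels %||% x$intensity
  seg <- if (is.null(x$labels)) {
    "unlabelled"
  } else if (any(x$labels$values == 0L)) "partially segmented" else "fully segmented"
  cat(sprintf("<patient_model> %s, %s; %d tissues in table\n",
              paste(vol_dim(vol), collapse = " x "), seg, nrow(x$table)))
  invisible(x)
}

model_grid <- function(model) model$labels %||% model$intensity

#' Haptic parameters at a world position
#'
#' The case distinction of the partially segmented patient: a segmented
#' (non-zero) voxel at the needle tip wins and its table entry is used
#' directly; otherwise the CT intensity at the tip is classified by the
#' transfer function under the current classifier state. An air result
#' while the tip is inside the body signals a risk structure (air
#' cavity), as does hitting a risk-role tissue (bone, blood vessel).
#'
#' @param pos World position, mm.
#' @param model A [patient_model()].
#' @param state A [classifier_state()].
#' @return A list with elements `params` (list `T_N`, `R`, `k`), `code`
#'   (integer tissue code) and `event` (`"none"` or `"risk"`).
#' @export
haptic_params_at <- function(pos, model, state = classifier_state()) {
  stopifnot(inherits(model, "patient_model"))
  code <- 0L
  if (!is.null(model$labels)) {
    idx <- world_to_voxel(pos, model$labels)
    code <- as.integer(model$labels$values[voxel_linear_index(idx, model$labels)])
  }
  if (code == 0L) {
    if (is.null(model$intensity)) {
      abort("unsegmented voxel but model has no intensity volume")
    }
    idx <- world_to_voxel(pos, model$intensity)
    hu <- model$intensity$values[voxel_linear_index(idx, model$intensity)]
    code <- classify_intensity(hu, state, model$thresholds)
  }
  row <- match(code, model$table$code)
  if (is.na(row)) {
    abort(sprintf("label code %d is not registered in the tissue table", code),
          class = "punctforce_config_error")
  }
  tc <- tissue_codes()
  event <- "none"
  if (model$table$role[row] == "risk") event <- "risk"
  if (code == tc[["air"]] && state$inside_body) event <- "risk"
  list(params = haptic_params(model$table$T_N[row], model$table$R[row],
                              model$table$k[row]),
       code = code, event = event)
}

#' Read or write a haptic configuration file
#'
#' The tissue table and intensity thresholds travel together as a
#' YAML or JSON file with one record per tissue (`tissue`, `code`,
#' `role`, `T_N`, `R`, `k`, `lower_threshold`); the string `"inf"`
#' (or `.inf`) is accepted for an infinite cut threshold. The interval
#' thresholds are carried on the `skin`, `soft`, `bone_sensitive` and
#' `bone_specific` rows.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_tissue_config()`: a list with elements `table` and
#'   `thresholds`; `write_tissue_config()`: `path`, invisibly.
#' @export
read_tissue_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- purrr::map_dfr(raw$tissues, function(r) {
    tibble::tibble(
      code = as.integer(r$code), tissue = r$tissue, role = r$role,
      T_N = parse_force(r$T_N), R = parse_force(r$R), k = parse_force(r$k),
      lower_threshold = if (length(r$lower_threshold) != 1L) NA_real_ else
        as.numeric(r$lower_threshold)
    )
  })
  table <- validate_tissue_table(rows[, c("code", "tissue", "role", "T_N", "R", "k")])
  thr_of <- function(name) rows$lower_threshold[match(name, rows$tissue)]
  thresholds <- threshold_set(thr_of("skin"), thr_of("soft"),
                              thr_of("bone_sensitive"), thr_of("bone_specific"))
  list(table = table, thresholds = thresholds)
}

parse_force <- function(x) {
  if (is.character(x) && tolower(x) %in% c("inf", ".inf", "infinity")) return(Inf)
  as.numeric(x)
}

#' @rdname read_tissue_config
#' @param table Haptic tissue table.
#' @param thresholds A [threshold_set()].
#' @export
write_tissue_config <- function(table, thresholds, path) {
  table <- validate_tissue_table(table)
  lower <- c(air = -1024, skin = thresholds$t0, soft = thresholds$t1,
             bone_sensitive = thresholds$t2_minus,
             bone_specific = thresholds$t2_plus)
  tissues <- purrr::pmap(table, function(code, tissue, role, T_N, R, k) {
    Filter(Negate(is.null), list(
      tissue = tissue, code = code, role = role,
      T_N = if (is.finite(T_N)) T_N else "inf", R = R, k = k,
      lower_threshold = if (tissue %in% names(lower))
        unname(lower[tissue]) else NULL
    ))
  })
  payload <- list(tissues = tissues)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}
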