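#' Read and write 3D volumes (MetaImage and NIfTI)
#'
#' `read_volume()` and `write_volume()` move [volume3d()] objects to and
#' from the two interchange formats used by medical image pipelines:
#' MetaImage (`.mhd` header plus `.raw` data block) and NIfTI-1
#' (`.nii`/`.nii.gz`, via the RNifti package). Round trips preserve
#' values, spacing and origin; integer label volumes round-trip
#' bit-exactly.
#'
#' @param path File path. The format is inferred from the extension
#'   unless `format` is given.
#' @param format `"metaimage"` or `"nifti"`.
#' @return `read_volume()` returns a [volume3d()]; `write_volume()`
#'   returns `path` invisibly.
#' @examples
#' vol <- volume3d(array(sample.int(5L, 64, TRUE), c(4, 4, 4)),
#'                 spacing = c(0.775, 0.925, 1))
#' f <- tempfile(fileext = ".mhd")
#' write_volume(vol, f)
#' identical(read_volume(f)$values, vol$values)
#' @export
read_volume <- function(path, format = NULL) {
  format <- format %||% guess_volume_format(path)
  switch(format,
    metaimage = read_metaimage(path),
    nifti = read_nifti_volume(path),
    abort(sprintf("unknown volume format '%s'", format),
          class = "punctforce_format_error")
  )
}

#' @rdname read_volume
#' @param vol A [volume3d()].
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot_volume(vol)
  format <- format %||% guess_volume_format(path)
  switch(format,
    metaimage = write_metaimage(vol, path),
    nifti = write_nifti_volume(vol, path),
    abort(sprintf("unknown volume format '%s'", format),
          class = "punctforce_format_error")
  )
  invisible(path)
}

guess_volume_format <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return("metaimage")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  abort(sprintf("cannot infer volume format from '%s'", basename(path)),
        class = "punctforce_format_error")
}

# -- MetaImage -----------------------------------------------------------
# The .mhd header is a plain-text "Key = Value" list; the voxel block is a
# little-endian raw file referenced by ElementDataFile.

mhd_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("malformed MetaImage header line: '%s'", lines[bad][1]),
          class = "punctforce_format_error")
  }
  hdr <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  need <- function(field) {
    if (is.na(hdr[field])) {
      abort(sprintf("MetaImage header missing field '%s'", field),
            class = "punctforce_format_error")
    }
    hdr[[field]]
  }
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L)) {
    abort("expected 3D volume", class = "punctforce_format_error")
  }
  dims <- as.integer(strsplit(trimws(need("DimSize")), "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    abort("malformed MetaImage header field 'DimSize'",
          class = "punctforce_format_error")
  }
  spacing <- as.numeric(strsplit(trimws(hdr["ElementSpacing"] %|na|%
                                          "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr["Offset"] %|na|%
                                         "0 0 0"), "\\s+")[[1]])
  type <- need("ElementType")
  spec <- mhd_types[[type]]
  if (is.null(spec)) {
    abort(sprintf("unsupported MetaImage field ElementType = '%s'", type),
          class = "punctforce_format_error")
  }
  msb <- toupper(hdr["ElementByteOrderMSB"] %|na|%
                   (hdr["BinaryDataByteOrderMSB"] %|na|% "FALSE"))
  endian <- if (identical(msb, "TRUE")) "big" else "little"
  datafile <- need("ElementDataFile")
  raw_path <- if (identical(datafile, "LOCAL")) path else {
    file.path(dirname(path), datafile)
  }
  if (!file.exists(raw_path)) {
    abort(sprintf("MetaImage data file not found: %s", raw_path),
          class = "punctforce_format_error")
  }
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n) {
    abort(sprintf("MetaImage data file too short: got %d of %d voxels",
                  length(vals), n),
          class = "punctforce_format_error")
  }
  volume3d(array(vals, dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path) {
  vals <- vol$values
  integral <- is.integer(vals) || is.logical(vals) ||
    (is.numeric(vals) && all(vals == round(vals)) &&
       all(abs(vals) <= .Machine$integer.max))
  if (integral) {
    vals <- as.integer(vals)
    rng <- range(vals)
    type <- if (rng[1] >= -32768 && rng[2] <= 32767) "MET_SHORT" else "MET_INT"
  } else {
    vals <- as.numeric(vals)
    type <- "MET_DOUBLE"
  }
  spec <- mhd_types[[type]]
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste("DimSize =", paste(vol_dim(vol), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                    collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste("ElementType =", type),
    "ElementByteOrderMSB = False",
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}

`%|na|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

# -- NIfTI ---------------------------------------------------------------

read_nifti_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort("expected 3D volume", class = "punctforce_format_error")
  }
  xf <- RNifti::xform(img)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img))
  volume3d(vals,
           spacing = abs(RNifti::pixdim(img))[1:3],
           origin = as.numeric(xf[1:3, 4]))
}

write_nifti_volume <- function(vol, path) {
  vals <- vol$values
  if (is.numeric(vals) && !is.integer(vals) && all(vals == round(vals)) &&
      all(abs(vals) <= .Machine$integer.max)) {
    vals <- array(as.integer(vals), dim(vals))
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
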