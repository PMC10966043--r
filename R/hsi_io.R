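#' Hyperspectral cube
#'
#' In-memory container for a single-camera hyperspectral raster. The layout
#' contract is rows x cols x bands (band-last): the row index is the
#' push-broom scan direction, the column index the sensor width, so the
#' column-wise calibration operates on the second margin. The band axis is
#' always in ascending wavelength order regardless of how the cube was
#' stored on disk.
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelengths numeric vector of per-band center wavelengths (nm),
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param range_tag `"VNIR"` or `"SWIR"`; which camera the cube came from.
#' @param value_kind `"dn"` for raw digital numbers (non-negative counts) or
#'   `"reflectance"` for calibrated data.
#' @param interleave storage interleave the cube was read from (or will be
#'   written with): `"bsq"`, `"bil"` or `"bip"`. Purely metadata in memory.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths,
                       range_tag = c("VNIR", "SWIR"),
                       value_kind = c("dn", "reflectance"),
                       interleave = c("bsq", "bil", "bip")) {
  range_tag <- match.arg(range_tag)
  value_kind <- match.arg(value_kind)
  interleave <- match.arg(interleave)
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_domain("`data` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    abort_consistency(sprintf(
      "wavelength count (%d) does not match band count (%d)",
      length(wavelengths), dim(data)[3L]))
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    abort_domain("wavelengths must be strictly increasing within a cube")
  if (value_kind == "dn" && any(data < 0, na.rm = TRUE))
    abort_domain("DN cubes must be non-negative")
  structure(
    list(data = data, wavelengths = wavelengths, range_tag = range_tag,
         value_kind = value_kind, interleave = interleave),
    class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %s %s  %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              x$range_tag, x$value_kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3L]

#' Index of the band nearest a target wavelength
#'
#' @param cube a [hyper_cube()].
#' @param wavelength_nm target wavelength in nm; must lie within the cube's
#'   spectral range.
#' @return integer band index.
#' @export
band_index_at <- function(cube, wavelength_nm) {
  wl <- cube$wavelengths
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    abort_domain(sprintf(
      "wavelength %.1f nm outside cube range [%.1f, %.1f] nm",
      wavelength_nm, min(wl), max(wl)))
  which.min(abs(wl - wavelength_nm))
}

#' Per-sample record: paired VNIR and SWIR cubes plus labels
#'
#' The binary use label is derived from the growth year: years 1-5 are the
#' food class, years 6-7 the medicinal class.
#'
#' @param sample_id character scalar.
#' @param vnir,swir [hyper_cube()] objects with matching range tags.
#' @param label_year integer growth year in 1..7.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, vnir, swir, label_year) {
  stopifnot(inherits(vnir, "hyper_cube"), inherits(swir, "hyper_cube"))
  if (vnir$range_tag != "VNIR" || swir$range_tag != "SWIR")
    abort_domain("`vnir`/`swir` cubes must carry matching range tags")
  label_year <- as.integer(label_year)
  if (is.na(label_year) || label_year < 1L || label_year > 7L)
    abort_domain("label_year must be an integer in 1..7")
  structure(
    list(sample_id = as.character(sample_id), vnir = vnir, swir = swir,
         label_year = label_year,
         label_use = if (label_year <= 5L) "food" else "medicinal"),
    class = "sample_record")
}

# ---- ENVI-style header + flat binary -------------------------------------

# data type codes we support (subset of the ENVI dialect)
.envi_types <- data.frame(
  code = c(2L, 3L, 4L, 5L, 12L),
  what = c("integer", "integer", "double", "double", "integer"),
  size = c(2L, 4L, 4L, 8L, 2L),
  signed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
  name = c("int16", "int32", "float32", "float64", "uint16"),
  stringsAsFactors = FALSE)

.envi_known_keys <- c("samples", "lines", "bands", "header offset",
                      "file type", "data type", "interleave", "byte order",
                      "wavelength", "wavelength units", "range_tag",
                      "value_kind", "description")

.parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^\\s*ENVI\\s*$", txt[1], ignore.case = TRUE))
    abort_format(sprintf("'%s' is not an ENVI header (missing ENVI magic line)", hdr_path))
  body <- paste(txt[-1], collapse = "\n")
  # match `key = value` where value may be a {...} block spanning lines
  keys <- list()
  pat <- "(?m)^\\s*([a-zA-Z_][a-zA-Z_ 0-9]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] == -1L) abort_format(sprintf("'%s' contains no key = value entries", hdr_path))
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    entry <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", entry, fixed = TRUE)
    key <- tolower(trimws(substr(entry, 1L, eq - 1L)))
    val <- trimws(substr(entry, eq + 1L, nchar(entry)))
    keys[[key]] <- val
  }
  unknown <- setdiff(names(keys), .envi_known_keys)
  if (length(unknown))
    warning(sprintf("ignoring unknown ENVI header key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  keys
}

.envi_int <- function(keys, key, hdr_path) {
  if (is.null(keys[[key]]))
    abort_format(sprintf("ENVI header '%s' is missing required field '%s'", hdr_path, key))
  v <- suppressWarnings(as.integer(keys[[key]]))
  if (is.na(v))
    abort_format(sprintf("ENVI header field '%s' is not an integer: '%s'", key, keys[[key]]))
  v
}

.envi_paths <- function(path) {
  # accept the header path, the binary path, or the common basename
  if (grepl("\\.hdr$", path)) {
    hdr <- path
    base <- sub("\\.hdr$", "", path)
  } else {
    base <- sub("\\.(img|raw|dat)$", "", path)
    hdr <- paste0(base, ".hdr")
  }
  bin <- NULL
  for (ext in c(".img", ".raw", ".dat", "")) {
    cand <- paste0(base, ext)
    if (file.exists(cand) && !grepl("\\.hdr$", cand)) { bin <- cand; break }
  }
  list(hdr = hdr, bin = bin, base = base)
}

#' Read an ENVI-style hyperspectral cube
#'
#' Accepts BSQ, BIL and BIP interleaves; the returned cube is always laid
#' out rows x cols x bands in ascending wavelength order. Unknown header
#' keys are ignored with a warning; missing or inconsistent required keys
#' raise classed format/consistency errors.
#'
#' @param path path to the `.hdr` file, the binary file, or their common
#'   basename.
#' @param range_tag optional override of the header's `range_tag` key.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, range_tag = NULL) {
  p <- .envi_paths(path)
  if (!file.exists(p$hdr)) abort_io(sprintf("header file '%s' not found", p$hdr))
  if (is.null(p$bin)) abort_io(sprintf("no binary file found for '%s'", p$base))
  keys <- .parse_envi_header(p$hdr)

  ns <- .envi_int(keys, "samples", p$hdr)   # columns
  nl <- .envi_int(keys, "lines", p$hdr)     # rows
  nb <- .envi_int(keys, "bands", p$hdr)
  dtcode <- .envi_int(keys, "data type", p$hdr)
  ti <- match(dtcode, .envi_types$code)
  if (is.na(ti)) abort_format(sprintf("unsupported ENVI data type code %d", dtcode))
  byte_order <- if (is.null(keys[["byte order"]])) 0L else .envi_int(keys, "byte order", p$hdr)
  endian <- if (byte_order == 0L) "little" else "big"
  interleave <- tolower(if (is.null(keys[["interleave"]])) "bsq" else keys[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip"))
    abort_format(sprintf("unsupported interleave '%s'", interleave))

  if (is.null(keys[["wavelength"]]))
    abort_format(sprintf("ENVI header '%s' is missing required field 'wavelength'", p$hdr))
  wl_txt <- gsub("[{}]", "", keys[["wavelength"]])
  wl <- suppressWarnings(as.numeric(strsplit(wl_txt, ",")[[1]]))
  if (anyNA(wl)) abort_format("could not parse wavelength list in header")
  if (length(wl) != nb)
    abort_consistency(sprintf(
      "header declares %d wavelengths but %d bands", length(wl), nb))

  n <- ns * nl * nb
  con <- file(p$bin, "rb"); on.exit(close(con))
  v <- readBin(con, what = .envi_types$what[ti], n = n,
               size = .envi_types$size[ti], signed = .envi_types$signed[ti],
               endian = endian)
  if (length(v) != n)
    abort_format(sprintf("binary file '%s' holds %d values, expected %d",
                         p$bin, length(v), n))
  v <- as.numeric(v)
  x <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L)))

  # enforce ascending wavelength order in memory
  if (is.unsorted(wl, strictly = TRUE)) {
    o <- order(wl)
    x <- x[, , o, drop = FALSE]
    wl <- wl[o]
  }
  vk <- if (is.null(keys[["value_kind"]])) "dn" else tolower(keys[["value_kind"]])
  rt <- if (!is.null(range_tag)) range_tag
        else if (!is.null(keys[["range_tag"]])) toupper(keys[["range_tag"]])
        else "VNIR"
  hyper_cube(x, wl, range_tag = rt, value_kind = vk, interleave = interleave)
}

#' Write a cube as an ENVI-style header + flat binary pair
#'
#' `read_cube(write_cube(cube, path))` is the identity on data and
#' wavelengths for the `float64` and (integer-valued) `uint16` data types.
#'
#' @param cube a [hyper_cube()].
#' @param path output basename; `.hdr` and `.img` are appended.
#' @param interleave storage order on disk; BSQ by default.
#' @param data_type one of `"float64"`, `"float32"`, `"uint16"`, `"int16"`,
#'   `"int32"`. The default preserves doubles exactly.
#' @return the basename `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = c("float64", "float32", "uint16",
                                     "int16", "int32")) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  data_type <- match.arg(data_type)
  ti <- match(data_type, .envi_types$name)
  x <- cube$data
  d <- dim(x)
  if (.envi_types$what[ti] == "integer") {
    if (any(x != round(x), na.rm = TRUE))
      abort_domain(sprintf("cube has non-integer values; cannot store as %s", data_type))
    if (data_type == "uint16" && any(x < 0 | x > 65535, na.rm = TRUE))
      abort_domain("values outside [0, 65535]; cannot store as uint16")
  }
  v <- switch(interleave,
    bsq = as.vector(aperm(x, c(2L, 1L, 3L))),
    bil = as.vector(aperm(x, c(2L, 3L, 1L))),
    bip = as.vector(aperm(x, c(3L, 2L, 1L))))
  base <- sub("\\.(hdr|img|raw|dat)$", "", path)
  hdr <- paste0(base, ".hdr"); bin <- paste0(base, ".img")
  ok <- tryCatch({
    con <- file(bin, "wb")
    if (.envi_types$what[ti] == "integer") {
      vi <- as.integer(v)
      if (data_type == "uint16") {
        # writeBin size=2 takes signed shorts; wrap the unsigned upper range
        vi[vi > 32767L] <- vi[vi > 32767L] - 65536L
      }
      writeBin(vi, con, size = .envi_types$size[ti], endian = "little")
    } else {
      writeBin(as.double(v), con, size = .envi_types$size[ti], endian = "little")
    }
    close(con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(sprintf("cannot write '%s': %s", bin, conditionMessage(ok)))
  lines <- c(
    "ENVI",
    "description = { specfuse hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", .envi_types$code[ti]),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("range_tag = %s", cube$range_tag),
    sprintf("value_kind = %s", cube$value_kind),
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(lines, hdr)
  invisible(base)
}
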