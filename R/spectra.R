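#' Mean reflectance of the sample region at one band
#'
#' Sum of the reflectance of all sample pixels divided by the number of
#' sample pixels, for a single band of a calibrated cube.
#'
#' @param refl a reflectance [hyper_cube()].
#' @param mask a [roi_mask()] with a non-empty sample region.
#' @param band_index integer band index.
#' @return scalar mean reflectance.
#' @export
band_mean <- function(refl, mask, band_index) {
  stopifnot(inherits(refl, "hyper_cube"), inherits(mask, "roi_mask"))
  if (!any(mask$groi)) abort_domain("sample region is empty")
  band_index <- as.integer(band_index)
  if (band_index < 1L || band_index > n_bands(refl))
    abort_domain(sprintf("band_index %d outside 1..%d", band_index, n_bands(refl)))
  v <- refl$data[, , band_index][mask$groi]
  sum(v) / length(v)
}

#' Mean reflectance spectral curve of one sample
#'
#' Applies [band_mean()] to every VNIR band and then every SWIR band of a
#' calibrated sample, concatenating into one curve (default length
#' 288 + 108 = 396, VNIR ascending then SWIR ascending). The two camera
#' ranges overlap near 1000 nm and are both retained, so a level
#' discontinuity between the segments is expected and permitted.
#'
#' @param sample a [sample_record()] whose cubes are calibrated
#'   (`value_kind = "reflectance"`).
#' @param masks list with elements `vnir` and `swir`, each a [roi_mask()].
#' @return An object of class `spectral_curve`: `values`, `wavelengths`,
#'   `range` (per-element `"VNIR"`/`"SWIR"`), `sample_id`, `label_year`,
#'   `label_use`, `n_groi`.
#' @export
extract_curve <- function(sample, masks) {
  stopifnot(inherits(sample, "sample_record"))
  if (sample$vnir$value_kind != "reflectance" ||
      sample$swir$value_kind != "reflectance")
    abort_calibration("extract_curve requires calibrated (reflectance) cubes")
  mv <- masks$vnir; ms <- masks$swir
  stopifnot(inherits(mv, "roi_mask"), inherits(ms, "roi_mask"))
  vn <- vapply(seq_len(n_bands(sample$vnir)),
               function(b) band_mean(sample$vnir, mv, b), numeric(1))
  sw <- vapply(seq_len(n_bands(sample$swir)),
               function(b) band_mean(sample$swir, ms, b), numeric(1))
  structure(
    list(values = c(vn, sw),
         wavelengths = c(sample$vnir$wavelengths, sample$swir$wavelengths),
         range = c(rep("VNIR", length(vn)), rep("SWIR", length(sw))),
         sample_id = sample$sample_id,
         label_year = sample$label_year,
         label_use = sample$label_use,
         n_groi = c(vnir = sum(mv$groi), swir = sum(ms$groi))),
    class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %s (year %d, %s): %d bands, range [%.3f, %.3f]\n",
              x$sample_id, x$label_year, x$label_use, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Assemble spectral curves into a feature matrix with aligned labels
#'
#' @param curves list of [extract_curve()] results with identical band
#'   grids.
#' @return An object of class `spectral_dataset`: `x` (samples x bands
#'   matrix), `wavelengths`, `range`, `sample_id`, `year`, `use`.
#' @export
curve_matrix <- function(curves) {
  if (length(curves) < 1L) abort_domain("need at least one curve")
  lens <- vapply(curves, function(cv) length(cv$values), integer(1))
  if (length(unique(lens)) != 1L)
    abort_consistency(sprintf(
      "curves have inconsistent lengths: %s",
      paste(unique(lens), collapse = ", ")))
  wl <- curves[[1]]$wavelengths
  for (cv in curves)
    if (!isTRUE(all.equal(cv$wavelengths, wl)))
      abort_consistency("curves are on different wavelength grids")
  x <- do.call(rbind, lapply(curves, function(cv) cv$values))
  colnames(x) <- paste0(curves[[1]]$range, "_",
                        format(wl, trim = TRUE, digits = 6))
  rownames(x) <- vapply(curves, function(cv) cv$sample_id, character(1))
  structure(
    list(x = x,
         wavelengths = wl,
         range = curves[[1]]$range,
         sample_id = rownames(x),
         year = vapply(curves, function(cv) cv$label_year, integer(1)),
         use = vapply(curves, function(cv) cv$label_use, character(1))),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands; years: %s\n",
              nrow(x$x), ncol(x$x),
              paste(names(table(x$year)), table(x$year), sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Write a spectral dataset as CSV
#'
#' One row per sample: `sample_id`, `label_year`, `label_use`, then one
#' column per band named `<RANGE>_<wavelength>`.
#'
#' @param ds a [curve_matrix()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(sample_id = ds$sample_id, label_year = ds$year,
                   label_use = ds$use, check.names = FALSE)
  df <- cbind(df, as.data.frame(ds$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral dataset from CSV written by [write_curves_csv()]
#' @param path CSV path.
#' @return A `spectral_dataset`.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "label_year", "label_use")
  if (!all(meta %in% names(df)))
    abort_format("curves CSV must contain sample_id, label_year, label_use")
  bandcols <- setdiff(names(df), meta)
  rng <- sub("_.*$", "", bandcols)
  wl <- as.numeric(sub("^[A-Z]+_", "", bandcols))
  x <- as.matrix(df[, bandcols, drop = FALSE])
  rownames(x) <- df$sample_id
  structure(
    list(x = x, wavelengths = wl, range = rng, sample_id = df$sample_id,
         year = as.integer(df$label_year), use = df$label_use),
    class = "spectral_dataset")
}
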