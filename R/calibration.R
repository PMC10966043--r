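#' Column-wise white-reference statistics
#'
#' For each band and each image column that intersects the white-reference
#' region, computes the mean DN of the whiteboard pixels in that column:
#' the denominator of the reflectance ratio. Columns with no whiteboard
#' pixels are flagged invalid (NA), never zero-filled. The reference is kept
#' per band because the whiteboard DN varies with the source spectrum.
#'
#' @param cube a DN [hyper_cube()].
#' @param mask a [roi_mask()] whose `wroi` is non-empty.
#' @return An object of class `column_reference`: list with `ref`
#'   (bands x cols matrix, NA on invalid columns), `valid` (logical per
#'   column), and `wavelengths`.
#' @export
column_reference <- function(cube, mask) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "roi_mask"))
  if (cube$value_kind != "dn")
    abort_calibration("column_reference expects a DN cube")
  w <- mask$wroi
  if (!any(w)) abort_calibration("white-reference region is empty")
  d <- dim(cube$data)
  if (!identical(dim(w), d[1:2]))
    abort_consistency("mask dimensions do not match cube")
  counts <- colSums(w)
  valid <- counts > 0L
  nb <- d[3]
  ref <- matrix(NA_real_, nb, d[2])
  wnum <- w * 1
  for (b in seq_len(nb)) {
    s <- colSums(cube$data[, , b] * wnum)
    ref[b, valid] <- s[valid] / counts[valid]
  }
  if (any(ref[, valid] <= 0, na.rm = TRUE))
    abort_calibration("white-reference mean DN is non-positive in a valid column")
  structure(list(ref = ref, valid = valid, wavelengths = cube$wavelengths),
            class = "column_reference")
}

#' Convert a DN cube to reflectance by column-wise white-reference ratio
#'
#' Every sample pixel (i, j) at band b becomes
#' `DN(i, j, b) / ref(b, j)`, where `ref(b, j)` is the mean whiteboard DN of
#' column j at band b. Because illumination and lens falloff act
#' multiplicatively per column, the ratio cancels them exactly. Pixels
#' outside the sample region are set to `NA`. No dark-current term is
#' subtracted.
#'
#' @param cube a DN [hyper_cube()].
#' @param mask a [roi_mask()]; calibration is applied on `mask$groi`.
#' @param ref optional precomputed [column_reference()]; computed from
#'   `cube` and `mask` when omitted.
#' @param missing_ref what to do when a sample column has no valid
#'   reference: `"error"` (default) or `"nearest"` (borrow the nearest valid
#'   column's reference).
#' @return A reflectance [hyper_cube()] (`value_kind = "reflectance"`).
#' @export
calibrate <- function(cube, mask, ref = NULL,
                      missing_ref = c("error", "nearest")) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "roi_mask"))
  missing_ref <- match.arg(missing_ref)
  if (cube$value_kind != "dn")
    abort_calibration("calibrate expects a DN cube")
  if (is.null(ref)) ref <- column_reference(cube, mask)
  stopifnot(inherits(ref, "column_reference"))
  d <- dim(cube$data)
  if (ncol(ref$ref) != d[2] || nrow(ref$ref) != d[3])
    abort_consistency("column reference dimensions do not match cube")

  groi_cols <- which(colSums(mask$groi) > 0L)
  need <- groi_cols[!ref$valid[groi_cols]]
  use_col <- seq_len(d[2])
  if (length(need)) {
    if (missing_ref == "error")
      abort_calibration(sprintf(
        "sample column(s) %s have no valid white-reference column",
        paste(utils::head(need, 5L), collapse = ", ")))
    vc <- which(ref$valid)
    if (!length(vc)) abort_calibration("no valid reference columns at all")
    for (j in need) use_col[j] <- vc[which.min(abs(vc - j))]
  }

  out <- array(NA_real_, d)
  not_groi <- !mask$groi
  for (b in seq_len(d[3])) {
    sl <- sweep(cube$data[, , b], 2L, ref$ref[b, use_col], "/")
    sl[not_groi] <- NA_real_
    out[, , b] <- sl
  }
  hyper_cube(out, cube$wavelengths, range_tag = cube$range_tag,
             value_kind = "reflectance", interleave = cube$interleave)
}
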