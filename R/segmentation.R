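#' Scene layout configuration
#'
#' The sample and the white-reference strip sit at fixed relative positions
#' in every acquisition, so the whiteboard position is declared up front
#' rather than auto-detected. The whiteboard is scanned before or after the
#' sample in the push-broom scan direction, so it spans the full sensor
#' width over a fixed range of image rows: that is what makes a per-column
#' white reference available for every sample column.
#'
#' @param whiteboard_rows integer vector of row indices covered by the
#'   white-reference strip (e.g. `106:128`), or a length-2 `c(first, last)`
#'   range.
#' @param flare_margin pixels eroded from the whiteboard region to exclude
#'   the stray-light flare at its edges. Default 5.
#' @param min_component_px connected components of the sample mask smaller
#'   than this are discarded as speckle. Default 50.
#' @param ref_wavelength_vnir,ref_wavelength_swir wavelengths (nm) of the
#'   gray-scale band used for binarization in each range; defaults 622 and
#'   1597 nm.
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(whiteboard_rows, flare_margin = 5L,
                         min_component_px = 50L,
                         ref_wavelength_vnir = 622,
                         ref_wavelength_swir = 1597) {
  whiteboard_rows <- as.integer(whiteboard_rows)
  if (length(whiteboard_rows) == 2L)
    whiteboard_rows <- seq.int(whiteboard_rows[1], whiteboard_rows[2])
  if (length(whiteboard_rows) < 1L || any(whiteboard_rows < 1L))
    abort_domain("whiteboard_rows must be positive row indices")
  structure(
    list(whiteboard_rows = whiteboard_rows,
         flare_margin = as.integer(flare_margin),
         min_component_px = as.integer(min_component_px),
         ref_wavelength_vnir = ref_wavelength_vnir,
         ref_wavelength_swir = ref_wavelength_swir),
    class = "scene_layout")
}

#' Region-of-interest mask pair
#'
#' @param groi,wroi logical matrices (rows x cols) marking the sample region
#'   and the white-reference region; must be disjoint.
#' @param reference_wavelength wavelength (nm) of the band the binarization
#'   ran on.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(groi, wroi, reference_wavelength = NA_real_) {
  stopifnot(is.logical(groi), is.logical(wroi), identical(dim(groi), dim(wroi)))
  if (any(groi & wroi))
    abort_domain("sample and white-reference regions must be disjoint")
  structure(list(groi = groi, wroi = wroi,
                 reference_wavelength = reference_wavelength),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, sample px %d, reference px %d (ref %.0f nm)\n",
              nrow(x$groi), ncol(x$groi), sum(x$groi), sum(x$wroi),
              x$reference_wavelength))
  invisible(x)
}

#' Segment a scene into sample, white-reference and background
#'
#' Selects the band nearest `reference_wavelength` (622 nm for VNIR, 1597 nm
#' for SWIR by default), thresholds its gray-scale image with Otsu's method
#' (the threshold is estimated from the pixels outside the whiteboard span,
#' where the histogram is cleanly bimodal background-vs-sample, and applied
#' globally), and splits the bright pixels by the declared whiteboard row
#' span: bright pixels inside the span become the white-reference region
#' (then eroded by the flare margin to drop flare-contaminated edge
#' pixels), bright pixels outside it the sample region. Sample-mask
#' speckle below `layout$min_component_px` is removed.
#'
#' @param cube a DN [hyper_cube()].
#' @param layout a [scene_layout()].
#' @param reference_wavelength optional override (nm) of the layout default
#'   for the cube's range.
#' @return A [roi_mask()].
#' @export
build_mask <- function(cube, layout, reference_wavelength = NULL) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(layout, "scene_layout"))
  if (is.null(reference_wavelength))
    reference_wavelength <- if (cube$range_tag == "VNIR")
      layout$ref_wavelength_vnir else layout$ref_wavelength_swir
  bi <- band_index_at(cube, reference_wavelength)   # domain error if outside
  g <- cube$data[, , bi]
  rng <- range(g)
  if (rng[2] <= rng[1])
    abort_segmentation("reference band is constant; cannot binarize")
  g01 <- (g - rng[1]) / (rng[2] - rng[1])

  wb_rows <- layout$whiteboard_rows
  if (max(wb_rows) > nrow(g))
    abort_domain("whiteboard row span exceeds scene height")
  in_span <- matrix(FALSE, nrow(g), ncol(g))
  in_span[wb_rows, ] <- TRUE

  # Otsu on the pixels outside the whiteboard span: there the histogram is
  # bimodal (background vs sample), so the threshold lands between them;
  # the whiteboard is far brighter and clears it as well.
  outside <- g01[!in_span]
  if (length(outside) < 2L || diff(range(outside)) == 0)
    abort_segmentation("no contrast outside the whiteboard span; cannot binarize")
  thr <- EBImage::otsu(EBImage::Image(matrix(outside)), range = c(0, 1))
  bright <- g01 > thr

  wroi <- bright & in_span
  if (layout$flare_margin > 0L && any(wroi)) {
    # erode on a zero-padded frame so image borders count as background
    m <- layout$flare_margin
    pad <- matrix(FALSE, nrow(g) + 2L * m, ncol(g) + 2L * m)
    pad[m + seq_len(nrow(g)), m + seq_len(ncol(g))] <- wroi
    brush <- EBImage::makeBrush(2L * m + 1L, shape = "box")
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(pad * 1), brush)) > 0.5
    wroi <- matrix(er[m + seq_len(nrow(g)), m + seq_len(ncol(g))],
                   nrow(g), ncol(g))
  }
  groi <- bright & !in_span
  if (any(groi) && layout$min_component_px > 1L) {
    lbl <- EBImage::bwlabel(EBImage::Image(groi * 1))
    sizes <- tabulate(as.integer(lbl))
    keep <- which(sizes >= layout$min_component_px)
    groi <- matrix(as.integer(lbl) %in% keep, nrow(g), ncol(g))
  }
  if (!any(groi))
    abort_segmentation("segmentation produced an empty sample region")
  if (!any(wroi))
    abort_segmentation("segmentation produced an empty white-reference region")
  roi_mask(groi, wroi, cube$wavelengths[bi])
}

#' Drop noisy head and tail bands
#'
#' Push-broom cameras produce elevated random noise in the first and last
#' bands; this removes `n_head` leading and `n_tail` trailing bands. The
#' defaults keep every band, matching a 288 + 108 = 396 band total.
#'
#' @param cube a [hyper_cube()].
#' @param n_head,n_tail non-negative counts of bands to drop at either end.
#' @return The trimmed [hyper_cube()].
#' @export
trim_noisy_bands <- function(cube, n_head = 0L, n_tail = 0L) {
  stopifnot(inherits(cube, "hyper_cube"))
  n_head <- as.integer(n_head); n_tail <- as.integer(n_tail)
  if (n_head < 0L || n_tail < 0L)
    abort_domain("n_head and n_tail must be non-negative")
  nb <- n_bands(cube)
  if (n_head + n_tail >= nb)
    abort_domain(sprintf(
      "removing %d + %d bands would leave no bands (cube has %d)",
      n_head, n_tail, nb))
  keep <- seq.int(n_head + 1L, nb - n_tail)
  hyper_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
             range_tag = cube$range_tag, value_kind = cube$value_kind,
             interleave = cube$interleave)
}
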