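#' Run segmentation, calibration and curve extraction on one sample
#'
#' The standard per-sample preprocessing chain: build masks on both cubes
#' (622 nm / 1597 nm reference bands), compute the column-wise white
#' references, calibrate DN to reflectance, and extract the mean
#' reflectance curve.
#'
#' @param record a DN [sample_record()].
#' @param layout a [scene_layout()].
#' @param masks optional precomputed mask pair (list `vnir`, `swir`), e.g.
#'   ground-truth masks from the generator.
#' @return list with `sample` (the calibrated record), `masks`, `curve`.
#' @export
process_sample <- function(record, layout = NULL, masks = NULL) {
  stopifnot(inherits(record, "sample_record"))
  if (is.null(masks)) {
    if (is.null(layout)) abort_domain("either layout or masks must be given")
    masks <- list(vnir = build_mask(record$vnir, layout),
                  swir = build_mask(record$swir, layout))
  }
  cal <- sample_record(
    record$sample_id,
    calibrate(record$vnir, masks$vnir),
    calibrate(record$swir, masks$swir),
    record$label_year)
  list(sample = cal, masks = masks, curve = extract_curve(cal, masks))
}

#' Generate a synthetic dataset and reduce it to model-ready features
#'
#' Streams samples from the generator one at a time (cubes are dropped
#' after processing, so memory stays flat): each sample is segmented,
#' calibrated, reduced to its mean reflectance curve, and optionally to a
#' stack of selected band images. Returns the spectral feature matrix and
#' the per-sample image stacks.
#'
#' @param cfg a [generator_config()].
#' @param bands optional band set (data.frame with `wavelength`, `range`)
#'   whose images to stack per sample; NULL for curves only.
#' @param out_rows,out_cols spatial size of the stacked images.
#' @param layout optional [scene_layout()]; defaults to the generator's
#'   geometry.
#' @param use_truth_masks use the generator's ground-truth masks instead of
#'   running segmentation (default FALSE).
#' @return list with `curves` (a `spectral_dataset`), `x_img`
#'   (n x rows x cols x k array or NULL), `year`, `use`.
#' @export
prepare_synthetic_dataset <- function(cfg, bands = NULL,
                                      out_rows = 64L, out_cols = 256L,
                                      layout = NULL,
                                      use_truth_masks = FALSE) {
  if (is.null(layout)) layout <- layout_from_config(cfg)
  n <- sum(cfg$n_per_year)
  curves <- vector("list", n)
  x_img <- if (!is.null(bands))
    array(0, c(n, out_rows, out_cols, NROW(bands)))
  collect <- function(record, truth, i) {
    masks <- if (use_truth_masks)
      list(vnir = roi_mask(truth$groi, truth$wroi),
           swir = roi_mask(truth$groi, truth$wroi))
    else NULL
    pr <- process_sample(record, layout, masks = masks)
    curves[[i]] <<- pr$curve
    if (!is.null(bands))
      x_img[i, , , ] <<- stack_selected(pr$sample, bands, out_rows, out_cols)
    invisible(NULL)
  }
  ds <- make_dataset(cfg, callback = collect)
  cm <- curve_matrix(curves)
  list(curves = cm, x_img = x_img, year = cm$year, use = cm$use,
       labels = ds$labels)
}

#' Stack images for a set of samples
#'
#' @param processed list of [process_sample()] results.
#' @param bands band set as in [stack_selected()].
#' @param out_rows,out_cols output spatial size.
#' @return array n x out_rows x out_cols x k.
#' @export
stack_images <- function(processed, bands, out_rows = 64L, out_cols = 256L) {
  n <- length(processed)
  out <- array(0, c(n, out_rows, out_cols, NROW(bands)))
  for (i in seq_len(n))
    out[i, , , ] <- stack_selected(processed[[i]]$sample, bands,
                                   out_rows, out_cols)
  out
}
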