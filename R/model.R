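#' Architecture configuration for the dual-branch fusion classifier
#'
#' Defaults reproduce the reference architecture exactly: a fully-connected
#' spectral branch (396 -> 512 -> 1024 -> 512 -> 128, ReLU, dropout between
#' layers), a convolutional image branch of five blocks
#' (3x3 conv, stride 1, same padding; batch-norm; ReLU; 2x2 max-pool) with
#' filters 64/128/128/64/32 on a 256 x 1024 x C input (C in 0..6), a
#' post-flatten dense(512), and a concatenate -> dropout -> dense(n_classes)
#' -> softmax head. The 3x3/stride-1/same-padding choice is forced by the
#' reference per-layer weight counts (e.g. 3*3*6*64 + 64 = 3520), and
#' batch-norm is accounted at 4 parameters per channel (scale, shift and
#' the two moving statistics).
#'
#' @param spectral_input_len length of the spectral input vector (default
#'   396); 0 disables the spectral branch (pure-CNN ablation).
#' @param image_rows,image_cols spatial input size, each divisible by 32.
#' @param image_channels number of stacked band images C (default 6); 0
#'   disables the image branch (pure-FCNN ablation).
#' @param spectral_units dense widths of the spectral branch.
#' @param conv_filters filters of the five conv blocks.
#' @param n_classes output classes (7 for year-by-year, 2 for
#'   food/medicinal).
#' @param dropout_spectral,dropout_head dropout rates (defaults 0.25 and
#'   0.25; heavier spectral dropout prevents convergence under the
#'   bounded-gradient MAE loss at the 84-sample scale).
#' @param bn_momentum batch-norm moving-statistics momentum.
#' @return An object of class `fccnn_spec`.
#' @export
fccnn_spec <- function(spectral_input_len = 396L,
                       image_rows = 256L, image_cols = 1024L,
                       image_channels = 6L,
                       spectral_units = c(512L, 1024L, 512L, 128L),
                       conv_filters = c(64L, 128L, 128L, 64L, 32L),
                       n_classes = 7L,
                       dropout_spectral = 0.25, dropout_head = 0.25,
                       bn_momentum = 0.9) {
  spectral_input_len <- as.integer(spectral_input_len)
  image_channels <- as.integer(image_channels)
  if (spectral_input_len < 0L) abort_spec("spectral_input_len must be >= 0")
  if (image_channels < 0L) abort_spec("image_channels must be >= 0")
  if (spectral_input_len == 0L && image_channels == 0L)
    abort_spec("at least one branch (spectral or image) must be enabled")
  if (image_channels > 0L &&
      (image_rows %% 32L != 0L || image_cols %% 32L != 0L))
    abort_spec("image_rows and image_cols must be divisible by 2^5 = 32")
  if (n_classes < 2L) abort_spec("n_classes must be >= 2")
  structure(
    list(spectral_input_len = spectral_input_len,
         image_rows = as.integer(image_rows),
         image_cols = as.integer(image_cols),
         image_channels = image_channels,
         spectral_units = as.integer(spectral_units),
         conv_filters = as.integer(conv_filters),
         n_classes = as.integer(n_classes),
         dropout_spectral = dropout_spectral,
         dropout_head = dropout_head,
         bn_momentum = bn_momentum),
    class = "fccnn_spec")
}

.summary_row <- function(layer, shape, params)
  data.frame(layer = layer, output_shape = shape, params = params,
             stringsAsFactors = FALSE)

.shape1 <- function(n) sprintf("(None, %d)", n)
.shape3 <- function(h, w, c) sprintf("(None, %d, %d, %d)", h, w, c)

#' Build the fully-connected spectral branch
#'
#' Dense(512) -> dropout -> dense(1024) -> dropout -> dense(512) -> dropout
#' -> dense(128), every dense with bias and ReLU.
#'
#' @param spec an [fccnn_spec()].
#' @return An object of class `nn_branch`: `layers`, `summary`
#'   (data.frame: layer, output_shape, params), `out_len`.
#' @export
build_spectral_branch <- function(spec) {
  stopifnot(inherits(spec, "fccnn_spec"))
  L <- spec$spectral_input_len
  if (L < 1L) abort_spec("spectral branch requires spectral_input_len >= 1")
  units <- spec$spectral_units
  layers <- list()
  rows <- .summary_row("Input", .shape1(L), 0)
  n_in <- L
  for (i in seq_along(units)) {
    layers <- c(layers, list(new_dense(n_in, units[i], act = TRUE)))
    rows <- rbind(rows, .summary_row("Dense", .shape1(units[i]),
                                     n_in * units[i] + units[i]))
    if (i < length(units)) {
      layers <- c(layers, list(new_dropout(spec$dropout_spectral)))
      rows <- rbind(rows, .summary_row("Dropout", .shape1(units[i]), 0))
    }
    n_in <- units[i]
  }
  structure(list(layers = layers, summary = rows, out_len = n_in),
            class = "nn_branch")
}

#' Build the convolutional image branch
#'
#' Five blocks of 3x3 same-padding convolution, batch normalization, ReLU
#' and 2x2 max-pooling, then flatten -> dropout -> dense(512) with ReLU.
#'
#' @param spec an [fccnn_spec()].
#' @return An `nn_branch`.
#' @export
build_image_branch <- function(spec) {
  stopifnot(inherits(spec, "fccnn_spec"))
  C <- spec$image_channels
  if (C < 1L) abort_spec("image branch requires image_channels >= 1")
  H <- spec$image_rows; W <- spec$image_cols
  if (H %% 32L != 0L || W %% 32L != 0L)
    abort_spec("image dims must be divisible by 2^5 (pooling would truncate)")
  filters <- spec$conv_filters
  layers <- list()
  rows <- .summary_row("Input", .shape3(H, W, C), 0)
  c_in <- C; h <- H; w <- W
  for (f in filters) {
    layers <- c(layers, list(new_conv(c_in, f),
                             new_bn(f, momentum = spec$bn_momentum),
                             new_relu(), new_pool()))
    rows <- rbind(rows,
      .summary_row("Conv", .shape3(h, w, f), 9 * c_in * f + f),
      .summary_row("BatchNorm", .shape3(h, w, f), 4 * f))
    h <- h %/% 2L; w <- w %/% 2L
    rows <- rbind(rows, .summary_row("MaxPooling", .shape3(h, w, f), 0))
    c_in <- f
  }
  flat <- h * w * c_in
  layers <- c(layers, list(new_flatten(), new_dropout(spec$dropout_head),
                           new_dense(flat, 512L, act = TRUE)))
  rows <- rbind(rows,
    .summary_row("Flatten", .shape1(flat), 0),
    .summary_row("Dropout", .shape1(flat), 0),
    .summary_row("Dense", .shape1(512L), flat * 512 + 512))
  structure(list(layers = layers, summary = rows, out_len = 512L),
            class = "nn_branch")
}

#' Build the full fusion network (or an ablation branch of it)
#'
#' Concatenates the enabled branch outputs (128 + 512 = 640 with both
#' branches), applies dropout, and maps to `n_classes` softmax logits.
#' With `image_channels = 0` the result is the pure spectral (FCNN-only)
#' model; with `spectral_input_len = 0` the pure image (CNN-only) model.
#'
#' @param spec an [fccnn_spec()].
#' @return An object of class `fccnn`: `spec`, `spectral`/`image`
#'   (`nn_branch` or NULL), `head` (`nn_branch`), `n_classes`.
#' @export
build_fccnn <- function(spec) {
  stopifnot(inherits(spec, "fccnn_spec"))
  spectral <- if (spec$spectral_input_len > 0L) build_spectral_branch(spec) else NULL
  image <- if (spec$image_channels > 0L) build_image_branch(spec) else NULL
  width <- sum(c(if (!is.null(spectral)) spectral$out_len,
                 if (!is.null(image)) image$out_len))
  head_dense <- new_dense(width, spec$n_classes, act = FALSE)
  # zero-initialized classifier: training starts from the uniform softmax,
  # which keeps the bounded MAE gradient alive instead of letting random
  # initial logits saturate toward one class
  head_dense$W[] <- 0
  head_layers <- list(new_dropout(spec$dropout_head), head_dense)
  head_rows <- rbind(
    .summary_row("Concatenate", .shape1(width), 0),
    .summary_row("Dropout", .shape1(width), 0),
    .summary_row("Dense", .shape1(spec$n_classes),
                 width * spec$n_classes + spec$n_classes))
  head <- structure(list(layers = head_layers, summary = head_rows,
                         out_len = spec$n_classes), class = "nn_branch")
  structure(list(spec = spec, spectral = spectral, image = image,
                 head = head, n_classes = spec$n_classes),
            class = "fccnn")
}

#' Per-layer parameter accounting of a network or branch
#'
#' Recounts parameters from the actual weight arrays (batch-norm moving
#' statistics included at 2 per channel alongside scale and shift) and
#' cross-checks them against the architecture summary built at
#' construction time.
#'
#' @param network an `fccnn` or `nn_branch`.
#' @return An object of class `model_summary`: data.frame with columns
#'   `block`, `layer`, `output_shape`, `params`, and attribute `total`.
#' @export
count_parameters <- function(network) {
  if (inherits(network, "nn_branch")) {
    df <- cbind(block = "branch", network$summary)
    actual <- branch_param_count(network$layers)
  } else if (inherits(network, "fccnn")) {
    parts <- list(spectral = network$spectral, image = network$image,
                  head = network$head)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    df <- do.call(rbind, lapply(names(parts), function(nm)
      cbind(block = nm, parts[[nm]]$summary)))
    actual <- sum(vapply(parts, function(p) branch_param_count(p$layers),
                         numeric(1)))
  } else abort_spec("count_parameters expects an fccnn or nn_branch")
  if (sum(df$params) != actual)
    abort_consistency(sprintf(
      "summary parameter total (%d) disagrees with weight arrays (%d)",
      sum(df$params), actual))
  rownames(df) <- NULL
  structure(df, class = c("model_summary", "data.frame"), total = actual)
}

#' @export
print.model_summary <- function(x, ...) {
  for (blk in unique(x$block)) {
    cat(sprintf("-- %s --\n", blk))
    sub <- x[x$block == blk, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("%-12s %-24s %s\n", sub$layer[i], sub$output_shape[i],
                  format(sub$params[i], big.mark = ",")))
  }
  cat(sprintf("Total parameters: %s\n", format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' @export
print.fccnn <- function(x, ...) {
  branches <- c(if (!is.null(x$spectral)) "spectral (FCNN)",
                if (!is.null(x$image)) "image (CNN)")
  cat(sprintf("<fccnn> %s -> %d classes, %s parameters\n",
              paste(branches, collapse = " + "), x$n_classes,
              format(attr(count_parameters(x), "total"), big.mark = ",")))
  invisible(x)
}
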