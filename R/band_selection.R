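# Stratified holdout split shared by band ranking and the experiment
# harness. Allocates per-class test quotas proportionally (largest-remainder
# rounding), guaranteeing every class at least one test member when
# test_size >= number of classes.
stratified_holdout <- function(y, test_size) {
  y <- as.integer(factor(y))
  n <- length(y)
  test_size <- as.integer(test_size)
  if (test_size < 1L || test_size >= n)
    abort_split("test_size must be in 1..(n-1)")
  classes <- sort(unique(y))
  nk <- vapply(classes, function(k) sum(y == k), integer(1))
  exact <- test_size * nk / n
  quota <- floor(exact)
  if (test_size >= length(classes)) quota <- pmax(quota, 1L)
  # largest-remainder adjustment to hit test_size exactly
  while (sum(quota) < test_size) {
    room <- which(quota < nk - 1L)
    i <- room[which.max((exact - quota)[room])]
    quota[i] <- quota[i] + 1L
  }
  while (sum(quota) > test_size) {
    i <- which.max(quota - exact)
    quota[i] <- quota[i] - 1L
  }
  test <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    if (quota[i] > 0L)
      test <- c(test, sample(idx, quota[i]))
  }
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

#' Rank band importance with a random forest over repeated random splits
#'
#' For each of `n_splits` seeded rounds, draws a stratified train/test
#' split, fits a random-forest classifier on the training portion of the
#' spectral feature matrix, and records the impurity-based feature
#' importances normalized to sum to one across all bands. Importances are
#' aggregated across rounds (mean by default) and ranked; the VNIR and SWIR
#' shares of total importance are reported alongside.
#'
#' @param ds a `spectral_dataset` from [curve_matrix()], or a plain matrix
#'   (then `wavelengths` and `range` must be given).
#' @param labels class labels, one per sample; defaults to the dataset's
#'   growth year.
#' @param n_splits number of random splits (default 10).
#' @param seed integer seed controlling splits and forests.
#' @param n_trees trees per forest (default 500).
#' @param test_size held-out samples per split; default 17 when the dataset
#'   has 84 samples, else ~20%.
#' @param aggregate `"mean"` (default) or `"median"` across splits.
#' @param wavelengths,range per-band metadata when `ds` is a plain matrix.
#' @return An object of class `band_importance`: a data.frame with columns
#'   `band`, `wavelength`, `range`, `imp_split_1..n`, `imp_agg`, `rank`,
#'   plus attributes `range_share` (named numeric, sums to 1) and
#'   `aggregate`.
#' @export
rank_bands <- function(ds, labels = NULL, n_splits = 10L, seed = 1L,
                       n_trees = 500L, test_size = NULL,
                       aggregate = c("mean", "median"),
                       wavelengths = NULL, range = NULL) {
  aggregate <- match.arg(aggregate)
  if (inherits(ds, "spectral_dataset")) {
    x <- ds$x
    if (is.null(labels)) labels <- ds$year
    wavelengths <- ds$wavelengths
    range <- ds$range
  } else {
    x <- as.matrix(ds)
    if (is.null(labels) || is.null(wavelengths) || is.null(range))
      abort_domain("matrix input requires labels, wavelengths and range")
  }
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("band_", seq_len(p))
  if (length(unique(labels)) < 2L)
    abort_domain("band ranking requires at least two classes")
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) abort_domain("n_splits must be >= 1")
  if (is.null(test_size)) test_size <- if (n == 84L) 17L else max(1L, round(0.2 * n))

  y <- factor(labels)
  imp <- matrix(0, p, n_splits)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  split_seeds <- sample.int(.Machine$integer.max %/% 2L, n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    sp <- stratified_holdout(y, test_size)
    fit <- ranger::ranger(
      x = x[sp$train, , drop = FALSE], y = y[sp$train],
      num.trees = n_trees, importance = "impurity",
      mtry = floor(sqrt(p)), seed = split_seeds[s],
      num.threads = 1L, verbose = FALSE)
    v <- fit$variable.importance
    v[v < 0] <- 0
    tot <- sum(v)
    imp[, s] <- if (tot > 0) v / tot else rep(1 / p, p)
  }
  agg <- if (aggregate == "mean") rowMeans(imp) else apply(imp, 1L, stats::median)
  # rank 1 = most important; ties broken toward lower wavelength
  o <- order(-agg, wavelengths)
  rk <- integer(p); rk[o] <- seq_len(p)
  tbl <- data.frame(band = seq_len(p), wavelength = wavelengths,
                    range = range, stringsAsFactors = FALSE)
  for (s in seq_len(n_splits)) tbl[[paste0("imp_split_", s)]] <- imp[, s]
  tbl$imp_agg <- agg
  tbl$rank <- rk
  share <- vapply(c(VNIR = "VNIR", SWIR = "SWIR"),
                  function(r) sum(agg[range == r]) / sum(agg), numeric(1))
  structure(tbl, class = c("band_importance", "data.frame"),
            range_share = share, aggregate = aggregate)
}

#' Select the most important bands per spectral range
#'
#' Takes the `k` highest aggregate-importance bands within each range
#' (default five VNIR and five SWIR), ties broken toward the lower
#' wavelength, and returns them wavelength-sorted within range (VNIR block
#' first).
#'
#' @param table a [rank_bands()] result.
#' @param k_vnir,k_swir how many bands to keep per range.
#' @return A data.frame of class `band_set` with columns `band`,
#'   `wavelength`, `range`, `imp_agg`.
#' @export
select_top <- function(table, k_vnir = 5L, k_swir = 5L) {
  stopifnot(inherits(table, "band_importance"))
  pick <- function(rng, k) {
    sub <- table[table$range == rng, , drop = FALSE]
    if (k > nrow(sub))
      abort_domain(sprintf("k_%s = %d exceeds the %d %s bands",
                           tolower(rng), k, nrow(sub), rng))
    if (k == 0L) return(sub[0L, ])
    sub <- sub[order(-sub$imp_agg, sub$wavelength), , drop = FALSE]
    sel <- sub[seq_len(k), , drop = FALSE]
    sel[order(sel$wavelength), , drop = FALSE]
  }
  out <- rbind(pick("VNIR", as.integer(k_vnir)),
               pick("SWIR", as.integer(k_swir)))
  if (nrow(out) == 0L) abort_domain("selected band set is empty")
  out <- out[, c("band", "wavelength", "range", "imp_agg")]
  rownames(out) <- NULL
  class(out) <- c("band_set", "data.frame")
  out
}

# Nearest-neighbor resize of a matrix onto r2 x c2, preserving aspect ratio
# by scaling to fit and padding with `fill` (centered).
resize_pad <- function(m, r2, c2, fill = 0) {
  r <- nrow(m); cc <- ncol(m)
  s <- min(r2 / r, c2 / cc)
  rr <- max(1L, round(r * s)); rc <- max(1L, round(cc * s))
  ri <- pmin(r, floor((seq_len(rr) - 0.5) * r / rr) + 1L)
  ci <- pmin(cc, floor((seq_len(rc) - 0.5) * cc / rc) + 1L)
  core <- m[ri, ci, drop = FALSE]
  out <- matrix(fill, r2, c2)
  r0 <- (r2 - rr) %/% 2L; c0 <- (c2 - rc) %/% 2L
  out[r0 + seq_len(rr), c0 + seq_len(rc)] <- core
  out
}

#' Stack selected band images into a model-ready channel array
#'
#' Extracts the chosen band images from a calibrated sample's cubes (band
#' matched by wavelength), sets non-sample pixels to zero, rescales each
#' image onto the common model grid (aspect-preserving nearest-neighbor
#' resample with zero padding; this is also how SWIR images are
#' co-registered onto the VNIR grid), and stacks channels in the order the
#' bands appear in `bands`.
#'
#' @param sample a calibrated [sample_record()].
#' @param bands a [select_top()] result (or data.frame with `wavelength`
#'   and `range`).
#' @param out_rows,out_cols output spatial size; defaults 256 x 1024, the
#'   fusion model's native input.
#' @return numeric array `out_rows x out_cols x n_bands`.
#' @export
stack_selected <- function(sample, bands, out_rows = 256L, out_cols = 1024L) {
  stopifnot(inherits(sample, "sample_record"))
  if (NROW(bands) < 1L) abort_domain("band set is empty")
  out <- array(0, c(out_rows, out_cols, NROW(bands)))
  for (k in seq_len(NROW(bands))) {
    cube <- if (bands$range[k] == "VNIR") sample$vnir else sample$swir
    wl <- cube$wavelengths
    bi <- which.min(abs(wl - bands$wavelength[k]))
    spacing <- if (length(wl) > 1L) stats::median(diff(wl)) else Inf
    if (abs(wl[bi] - bands$wavelength[k]) > spacing / 2 + 1e-9)
      abort_domain(sprintf("band at %.1f nm not found in %s cube",
                           bands$wavelength[k], bands$range[k]))
    img <- cube$data[, , bi]
    img[is.na(img)] <- 0
    out[, , k] <- resize_pad(img, out_rows, out_cols)
  }
  out
}

#' Band indices nearest a set of target wavelengths
#'
#' Convenience for assembling an RGB-like stack (e.g. 622/546/443 nm) from
#' a VNIR cube.
#'
#' @param wavelengths numeric vector of band centers, or a [hyper_cube()].
#' @param targets target wavelengths (nm).
#' @return integer indices, one per target.
#' @export
bands_nearest <- function(wavelengths, targets) {
  if (inherits(wavelengths, "hyper_cube")) wavelengths <- wavelengths$wavelengths
  vapply(targets, function(t) which.min(abs(wavelengths - t)), integer(1))
}

# Save/restore .Random.seed so seeded helpers do not clobber the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
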