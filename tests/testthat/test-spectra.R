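# reflectance cube + mask with arbitrary values for oracle comparisons
random_refl <- function(rows = 9, cols = 11, nb = 6, seed = 5) {
  set.seed(seed)
  x <- array(runif(rows * cols * nb, 0.1, 0.9), c(rows, cols, nb))
  groi <- matrix(runif(rows * cols) < 0.4, rows, cols)
  groi[1, 1] <- TRUE   # never empty
  x_na <- x
  for (b in seq_len(nb)) { sl <- x_na[, , b]; sl[!groi] <- NA; x_na[, , b] <- sl }
  list(cube = hyper_cube(x_na, seq(400, by = 40, length.out = nb), "VNIR",
                         value_kind = "reflectance"),
       mask = roi_mask(groi, matrix(FALSE, rows, cols)),
       raw = x, groi = groi)
}

test_that("band_mean is the arithmetic mean over the sample region", {
  x <- array(NA_real_, c(2, 2, 1))
  x[, , 1] <- c(0.2, 0.6, 0.4, 0.8)
  cube <- hyper_cube(x, 500, "VNIR", value_kind = "reflectance")
  mask <- roi_mask(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2))
  expect_equal(band_mean(cube, mask, 1), 0.5)

  const <- hyper_cube(array(0.5, c(3, 3, 1)), 500, "VNIR", "reflectance")
  m3 <- roi_mask(matrix(TRUE, 3, 3), matrix(FALSE, 3, 3))
  expect_equal(band_mean(const, m3, 1), 0.5)

  checker <- array(rep_len(c(0, 1), 16), c(4, 4, 1))
  cc <- hyper_cube(checker, 500, "VNIR", "reflectance")
  m4 <- roi_mask(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(band_mean(cc, m4, 1), 0.5)

  empty <- roi_mask(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2))
  expect_error(band_mean(cube, empty, 1), class = "specfuse_domain_error")
  expect_error(band_mean(cube, mask, 9), class = "specfuse_domain_error")
})

test_that("band_mean equals a brute-force pixel loop and stays bounded", {
  rr <- random_refl()
  for (b in c(1, 3, 6)) {
    acc <- 0; n <- 0
    for (i in seq_len(nrow(rr$groi))) for (j in seq_len(ncol(rr$groi))) {
      if (rr$groi[i, j]) { acc <- acc + rr$raw[i, j, b]; n <- n + 1 }
    }
    bm <- band_mean(rr$cube, rr$mask, b)
    expect_equal(bm, acc / n, tolerance = 1e-14)
    vals <- rr$raw[, , b][rr$groi]
    expect_gte(bm, min(vals)); expect_lte(bm, max(vals))
  }
})

test_that("mean of per-pixel spectra equals the spectrum of band means", {
  rr <- random_refl()
  # oracle: average the full spectral vector of every sample pixel
  px <- which(rr$groi, arr.ind = TRUE)
  spectra <- t(apply(px, 1, function(ij) rr$raw[ij[1], ij[2], ]))
  oracle <- colMeans(spectra)
  measured <- vapply(seq_len(6), function(b) band_mean(rr$cube, rr$mask, b),
                     numeric(1))
  expect_equal(measured, oracle)
})

test_that("extract_curve concatenates VNIR then SWIR at full default length", {
  # default 288 + 108 bands on a small scene
  cfg <- generator_config(seed = 31L, scene_rows = 32L, scene_cols = 64L,
                          n_per_year = rep(1L, 7), snr = Inf, sample_sigma = 0)
  sim <- simulate_sample(1L, cfg, "full")
  pr <- process_sample(sim$record, layout_from_config(cfg))
  cv <- pr$curve
  expect_length(cv$values, 396L)
  expect_length(cv$wavelengths, 396L)
  expect_identical(cv$range, c(rep("VNIR", 288L), rep("SWIR", 108L)))
  expect_true(all(diff(cv$wavelengths[1:288]) > 0))
  expect_true(all(diff(cv$wavelengths[289:396]) > 0))
  expect_true(all(is.finite(cv$values)) && all(cv$values >= 0))
  # the VNIR/SWIR overlap near 1000 nm is retained twice
  expect_gt(cv$wavelengths[289], cv$wavelengths[288] - 100)
})

test_that("extract_curve is invariant to a consistent pixel permutation", {
  rr <- random_refl(rows = 8, cols = 8, nb = 4, seed = 6)
  perm <- sample(8)
  permuted <- hyper_cube(rr$cube$data[perm, , , drop = FALSE],
                         rr$cube$wavelengths, "VNIR", "reflectance")
  pmask <- roi_mask(rr$mask$groi[perm, , drop = FALSE],
                    rr$mask$wroi[perm, , drop = FALSE])
  for (b in 1:4)
    expect_equal(band_mean(permuted, pmask, b), band_mean(rr$cube, rr$mask, b))
})

test_that("measured VNIR-SWIR gap tracks the planted year-dependent gap", {
  gap_stat <- function(v) {
    nv <- sum(attr(v, "rng") == "VNIR")
    mean(v[(nv - 4):nv]) - mean(v[nv + (1:5)])
  }
  for (yr in c(1L, 4L, 7L)) {
    cfg <- tiny_cfg(seed = 40L + yr, snr = Inf, sample_sigma = 0)
    sim <- simulate_sample(yr, cfg, "gap")
    pr <- process_sample(sim$record, layout_from_config(cfg))
    measured <- pr$curve$values; attr(measured, "rng") <- pr$curve$range
    truth <- sim$truth$curve$values; attr(truth, "rng") <- pr$curve$range
    # oracle recomputes the same statistic from the true reflectance
    expect_equal(gap_stat(measured), gap_stat(truth), tolerance = 0.02)
  }
})

test_that("curve_matrix aligns features and labels and checks consistency", {
  cfg <- tiny_cfg(snr = 100)
  ds <- make_dataset(cfg)
  prs <- lapply(ds$records, process_sample, layout = layout_from_config(cfg))
  cm <- curve_matrix(lapply(prs, `[[`, "curve"))
  expect_identical(dim(cm$x), c(7L, 30L))
  expect_identical(cm$year, 1:7)
  expect_identical(cm$use, c(rep("food", 5), rep("medicinal", 2)))

  single <- curve_matrix(list(prs[[1]]$curve))
  expect_identical(dim(single$x), c(1L, 30L))

  short <- prs[[1]]$curve; short$values <- short$values[1:10]
  expect_error(curve_matrix(list(short, prs[[2]]$curve)),
               class = "specfuse_consistency_error")
  expect_error(curve_matrix(list()), class = "specfuse_domain_error")
})

test_that("curves CSV round-trips through write/read", {
  cfg <- tiny_cfg(snr = 100)
  ds <- make_dataset(cfg)
  prs <- lapply(ds$records[1:3], process_sample,
                layout = layout_from_config(cfg))
  cm <- curve_matrix(lapply(prs, `[[`, "curve"))
  path <- file.path(tempdir(), "curves.csv")
  write_curves_csv(cm, path)
  back <- read_curves_csv(path)
  expect_equal(back$x, cm$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$year, cm$year)
  expect_identical(back$range, cm$range)
})
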