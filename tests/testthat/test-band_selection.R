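# Curve-level synthetic data where ONLY the planted bands carry year
# signal: flat level across years, no range gap, no scene rendering needed.
planted_curves <- function(seed, n_each = 9L, shuffle_labels = FALSE) {
  cfg <- tiny_cfg(level_step = 0, gap0 = 0,
                  planted_vnir = c(520, 650, 900), planted_swir = numeric(0),
                  effect_size = 0.05, sample_sigma = 0.03)
  years <- rep(1:7, each = n_each)
  set.seed(seed)
  x <- t(vapply(years, function(y) make_reflectance_curve(y, cfg)$values,
                numeric(cfg$n_vnir + cfg$n_swir)))
  x <- x + matrix(rnorm(length(x), 0, 0.004), nrow(x))
  ac <- analytic_curve(1, cfg)
  if (shuffle_labels) years <- sample(years)
  list(x = x, years = years, wavelengths = ac$wavelengths, range = ac$range,
       planted = bands_nearest(ac$wavelengths[ac$range == "VNIR"],
                               cfg$planted_vnir))
}

fake_table <- function(imp, wavelengths, range) {
  tbl <- data.frame(band = seq_along(imp), wavelength = wavelengths,
                    range = range, imp_split_1 = imp, imp_agg = imp)
  o <- order(-imp, wavelengths)
  tbl$rank <- integer(length(imp)); tbl$rank[o] <- seq_along(imp)
  structure(tbl, class = c("band_importance", "data.frame"),
            range_share = c(VNIR = sum(imp[range == "VNIR"]) / sum(imp),
                            SWIR = sum(imp[range == "SWIR"]) / sum(imp)),
            aggregate = "mean")
}

test_that("planted discriminative bands take the top aggregate ranks", {
  hits <- 0L
  for (seed in 1:10) {
    pc <- planted_curves(seed)
    tbl <- rank_bands(pc$x, labels = pc$years, wavelengths = pc$wavelengths,
                      range = pc$range, n_splits = 10, seed = seed,
                      n_trees = 300)
    top3 <- tbl$band[order(tbl$rank)][1:3]
    if (setequal(top3, pc$planted)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("shuffled labels show no spurious importance concentration", {
  p <- 30L
  for (seed in 1:10) {
    pc <- planted_curves(100L + seed, shuffle_labels = TRUE)
    tbl <- rank_bands(pc$x, labels = pc$years, wavelengths = pc$wavelengths,
                      range = pc$range, n_splits = 5, seed = seed,
                      n_trees = 300)
    expect_lt(max(tbl$imp_agg), 3 / p)
  }
})

test_that("importance table satisfies its normalization invariants", {
  pc <- planted_curves(7)
  tbl <- rank_bands(pc$x, labels = pc$years, wavelengths = pc$wavelengths,
                    range = pc$range, n_splits = 3, seed = 1, n_trees = 200)
  for (s in 1:3) {
    imp <- tbl[[paste0("imp_split_", s)]]
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1)
  }
  expect_equal(sum(attr(tbl, "range_share")), 1, tolerance = 1e-9)
  expect_setequal(tbl$rank, seq_len(nrow(tbl)))

  # single split: degenerate but well-defined
  t1 <- rank_bands(pc$x, labels = pc$years, wavelengths = pc$wavelengths,
                   range = pc$range, n_splits = 1, seed = 1, n_trees = 200)
  expect_true("imp_split_1" %in% names(t1))
  expect_false("imp_split_2" %in% names(t1))
  expect_setequal(t1$rank, seq_len(nrow(t1)))

  # sample order only permutes split membership, not the science:
  # aggregate importance concentrates on the same top band either way
  perm <- sample(nrow(pc$x))
  t2 <- rank_bands(pc$x[perm, ], labels = pc$years[perm],
                   wavelengths = pc$wavelengths, range = pc$range,
                   n_splits = 10, seed = 1, n_trees = 300)
  expect_true(t2$band[which.min(t2$rank)] %in% pc$planted)

  expect_error(rank_bands(pc$x, labels = rep(1, nrow(pc$x)),
                          wavelengths = pc$wavelengths, range = pc$range),
               class = "specfuse_domain_error")
})

test_that("select_top picks the k best per range with deterministic ties", {
  wl <- c(400, 500, 600, 700, 800, 1000, 1500, 2000)
  rng <- c(rep("VNIR", 5), rep("SWIR", 3))
  tbl <- fake_table(c(.5, .3, .1, .05, .03, .01, .005, .005), wl, rng)

  sel3 <- select_top(tbl, 3, 0)
  expect_equal(sel3$wavelength, c(400, 500, 600))

  sel <- select_top(tbl, 2, 2)
  expect_equal(nrow(sel), 4)
  expect_equal(sel$range, c("VNIR", "VNIR", "SWIR", "SWIR"))
  # SWIR tie at .005 broken toward the lower wavelength
  expect_equal(sel$wavelength[3:4], c(1000, 1500))

  # all-equal importances: lowest wavelengths win
  teq <- fake_table(rep(1 / 8, 8), wl, rng)
  expect_equal(select_top(teq, 2, 0)$wavelength, c(400, 500))

  # nesting: select_top(k) is a subset of select_top(k+1)
  for (k in 1:4)
    expect_true(all(select_top(tbl, k, 0)$band %in%
                    select_top(tbl, k + 1, 0)$band))

  expect_error(select_top(tbl, 6, 0), class = "specfuse_domain_error")
})

test_that("stack_selected extracts, rescales and stacks in selection order", {
  vn <- hyper_cube(array(rep(1:4, each = 80), c(8, 10, 4)),
                   c(500, 600, 700, 800), "VNIR", "reflectance")
  sw <- hyper_cube(array(rep(10 * (1:3), each = 80), c(8, 10, 3)),
                   c(1100, 1400, 2000), "SWIR", "reflectance")
  rec <- sample_record("s", vn, sw, 3)

  bands <- data.frame(wavelength = c(800, 600), range = "VNIR")
  st <- stack_selected(rec, bands, out_rows = 16, out_cols = 20)
  expect_identical(dim(st), c(16L, 20L, 2L))
  expect_true(all(st[, , 1] == 4))   # selection order preserved
  expect_true(all(st[, , 2] == 2))

  mixed <- data.frame(wavelength = c(500, 600, 700, 1100, 1400),
                      range = c(rep("VNIR", 3), rep("SWIR", 2)))
  stm <- stack_selected(rec, mixed, out_rows = 16, out_cols = 20)
  expect_identical(dim(stm), c(16L, 20L, 5L))
  expect_true(all(stm[, , 4] == 10))  # SWIR co-registered onto the grid

  # background NA pixels become zeros
  vn2 <- vn; vn2$data[1, 1, ] <- NA
  rec2 <- sample_record("s2", vn2, sw, 3)
  st2 <- stack_selected(rec2, bands, out_rows = 8, out_cols = 10)
  expect_equal(st2[1, 1, 1], 0)

  expect_error(stack_selected(rec, bands[0, ]), class = "specfuse_domain_error")
  expect_error(stack_selected(rec, data.frame(wavelength = 999, range = "VNIR")),
               class = "specfuse_domain_error")
})

test_that("aspect-preserving resize pads asymmetric targets with zeros", {
  m <- matrix(1, 10, 10)
  out <- specfuse:::resize_pad(m, 16, 32)   # scale 1.6, pad columns
  expect_identical(dim(out), c(16L, 32L))
  expect_true(all(out[, 9:24] == 1))        # centered 16-wide core
  expect_true(all(out[, 1:8] == 0) && all(out[, 25:32] == 0))
})

test_that("bands_nearest resolves RGB-like targets", {
  wl <- seq(400, 1000, by = 2)
  idx <- bands_nearest(wl, c(622, 546, 443))
  expect_equal(wl[idx], c(622, 546, 442))   # equidistant tie -> first band
})
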