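#' Configuration of the synthetic scene generator
#'
#' The generator emulates the statistical structure the pipeline assumes in
#' real acquisitions: DN cubes containing an elliptical textured sample and
#' a Lambertian whiteboard strip at a fixed column span; a column-wise
#' illumination profile (bright center, dark edges); stray-light flare at
#' the whiteboard edges; smooth per-year reflectance signatures with a
#' peak near 800 nm, a year-dependent VNIR-SWIR level gap at the 1000 nm
#' range boundary that shrinks linearly with age
#' (`gap(year) = gap0 * (1 - (year - 1)/6)`), planted discriminative bands,
#' multiplicative log-normal between-sample variability, and multiplicative
#' sensor noise of standard deviation `1/snr`.
#'
#' `effect_scale` scales every year-dependent term about its year-4 value:
#' 1 keeps the standard contrasts, 0 yields a null dataset in which all
#' years share one reflectance distribution (for calibration of chance
#' performance).
#'
#' @param seed master seed; all generated data are reproducible from it.
#' @param n_per_year samples per growth year 1..7 (default
#'   `c(17, 11, 12, 12, 8, 12, 12)`, 84 total).
#' @param scene_rows,scene_cols scene size in pixels per camera.
#' @param n_vnir,n_swir band counts (defaults 288 and 108).
#' @param vnir_range,swir_range wavelength spans in nm.
#' @param whiteboard_rows row span of the whiteboard strip (the whiteboard
#'   is scanned after the sample, so it crosses the full sensor width);
#'   default the last 18% of the scan rows.
#' @param flare_width,flare_boost width (px) and DN multiplier of the flare
#'   at the whiteboard edges.
#' @param illum_a quadratic illumination falloff: column j is lit
#'   proportionally to `1 - illum_a * u(j)^2` with `u` in [-1, 1].
#' @param gain DN per unit reflectance at full illumination.
#' @param snr signal-to-noise ratio of the multiplicative sensor noise;
#'   `Inf` disables noise.
#' @param level0,level_step base VNIR reflectance level of year 1 and its
#'   per-year increment.
#' @param peak_center,peak_sigma,peak_height Gaussian reflectance peak
#'   (defaults: 800 nm, width 90 nm, height 0.26).
#' @param gap0 VNIR-SWIR reflectance gap of year 1 at the range boundary.
#' @param swir_slope linear reflectance slope over the SWIR range (per nm).
#' @param planted_vnir,planted_swir wavelengths (nm) of bands carrying
#'   planted year-discriminative signal.
#' @param effect_size reflectance offset of a planted band per unit of the
#'   standardized year contrast `(year - 4)/3`.
#' @param effect_scale global scale of year effects (see above).
#' @param sample_sigma log-normal sigma of per-sample multiplicative
#'   variability.
#' @param texture_roughness relative amplitude of the smooth spatial
#'   texture on the sample.
#' @param background_rho background reflectance.
#' @param rho_limits curves are clamped to this range (default 0.15-0.7).
#' @param ellipse_frac semi-axes of the sample ellipse as fractions of the
#'   scan rows above the whiteboard and of the scene width.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_per_year = c(17L, 11L, 12L, 12L, 8L, 12L, 12L),
                             scene_rows = 128L, scene_cols = 512L,
                             n_vnir = 288L, n_swir = 108L,
                             vnir_range = c(400, 1000),
                             swir_range = c(930, 2500),
                             whiteboard_rows = NULL,
                             flare_width = 3L, flare_boost = 1.6,
                             illum_a = 0.3, gain = 3000, snr = 100,
                             level0 = 0.25, level_step = 0.018,
                             peak_center = 800, peak_sigma = 90,
                             peak_height = 0.26,
                             gap0 = 0.08, swir_slope = -2e-5,
                             planted_vnir = c(520, 560, 650, 770, 900),
                             planted_swir = c(1150, 1400),
                             effect_size = 0.05, effect_scale = 1,
                             sample_sigma = 0.04,
                             texture_roughness = 0.08,
                             background_rho = 0.02,
                             rho_limits = c(0.15, 0.7),
                             ellipse_frac = c(0.38, 0.30)) {
  if (length(n_per_year) != 7L || any(n_per_year < 0L))
    abort_domain("n_per_year must be 7 non-negative counts")
  if (is.null(whiteboard_rows))
    whiteboard_rows <- seq.int(ceiling(0.82 * scene_rows) + 1L, scene_rows)
  whiteboard_rows <- as.integer(whiteboard_rows)
  if (length(whiteboard_rows) == 2L)
    whiteboard_rows <- seq.int(whiteboard_rows[1], whiteboard_rows[2])
  if (max(whiteboard_rows) > scene_rows)
    abort_domain("whiteboard span exceeds the scene's scan length")
  if (min(whiteboard_rows) < 16L)
    abort_domain("scene too small to hold both whiteboard strip and sample")
  structure(
    list(seed = as.integer(seed), n_per_year = as.integer(n_per_year),
         scene_rows = as.integer(scene_rows),
         scene_cols = as.integer(scene_cols),
         n_vnir = as.integer(n_vnir), n_swir = as.integer(n_swir),
         vnir_range = vnir_range, swir_range = swir_range,
         whiteboard_rows = whiteboard_rows,
         flare_width = as.integer(flare_width), flare_boost = flare_boost,
         illum_a = illum_a, gain = gain, snr = snr,
         level0 = level0, level_step = level_step,
         peak_center = peak_center, peak_sigma = peak_sigma,
         peak_height = peak_height, gap0 = gap0, swir_slope = swir_slope,
         planted_vnir = planted_vnir, planted_swir = planted_swir,
         effect_size = effect_size, effect_scale = effect_scale,
         sample_sigma = sample_sigma,
         texture_roughness = texture_roughness,
         background_rho = background_rho, rho_limits = rho_limits,
         ellipse_frac = ellipse_frac),
    class = "generator_config")
}

.gen_wavelengths <- function(cfg) {
  list(vnir = seq(cfg$vnir_range[1], cfg$vnir_range[2], length.out = cfg$n_vnir),
       swir = seq(cfg$swir_range[1], cfg$swir_range[2], length.out = cfg$n_swir))
}

# year-dependent parameter, scaled about its year-4 value by effect_scale
.year_scaled <- function(val_year, val_mid, scale) val_mid + scale * (val_year - val_mid)

#' Analytic (noise-free) reflectance curve of a growth year
#'
#' The deterministic base curve before per-sample variability: VNIR level
#' rising with year, Gaussian peak near 800 nm, SWIR segment starting one
#' gap `gap(year)` below the VNIR endpoint with a gentle linear slope, and
#' planted band offsets proportional to the standardized year contrast.
#'
#' @param year growth year in 1..7.
#' @param cfg a [generator_config()].
#' @return list with `vnir`, `swir`, `values` (their concatenation),
#'   `wavelengths`, `range` and `gap`.
#' @export
analytic_curve <- function(year, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (year < 1 || year > 7) abort_domain("year must be in 1..7")
  wl <- .gen_wavelengths(cfg)
  es <- cfg$effect_scale
  level <- .year_scaled(cfg$level0 + cfg$level_step * (year - 1),
                        cfg$level0 + cfg$level_step * 3, es)
  gap <- .year_scaled(cfg$gap0 * (1 - (year - 1) / 6), cfg$gap0 / 2, es)
  z <- es * (year - 4) / 3

  vnir <- level + cfg$peak_height *
    exp(-(wl$vnir - cfg$peak_center)^2 / (2 * cfg$peak_sigma^2))
  swir_start <- vnir[length(vnir)] - gap
  swir <- swir_start + cfg$swir_slope * (wl$swir - wl$swir[1])
  iv <- bands_nearest(wl$vnir, cfg$planted_vnir)
  vnir[iv] <- vnir[iv] + cfg$effect_size * z
  is_ <- bands_nearest(wl$swir, cfg$planted_swir)
  swir[is_] <- swir[is_] + cfg$effect_size * z
  vnir <- pmin(pmax(vnir, cfg$rho_limits[1]), cfg$rho_limits[2])
  swir <- pmin(pmax(swir, cfg$rho_limits[1]), cfg$rho_limits[2])
  list(vnir = vnir, swir = swir, values = c(vnir, swir),
       wavelengths = c(wl$vnir, wl$swir),
       range = c(rep("VNIR", cfg$n_vnir), rep("SWIR", cfg$n_swir)),
       gap = gap)
}

#' Draw one sample's true reflectance curve
#'
#' The analytic year curve times a per-sample log-normal factor
#' (`exp(N(0, sample_sigma))`), clamped to the configured reflectance
#' range. Uses the current RNG state.
#'
#' @inheritParams analytic_curve
#' @return as [analytic_curve()], plus `factor` and `year`.
#' @export
make_reflectance_curve <- function(year, cfg) {
  base <- analytic_curve(year, cfg)
  f <- exp(stats::rnorm(1, 0, cfg$sample_sigma))
  base$vnir <- pmin(pmax(base$vnir * f, cfg$rho_limits[1]), cfg$rho_limits[2])
  base$swir <- pmin(pmax(base$swir * f, cfg$rho_limits[1]), cfg$rho_limits[2])
  base$values <- c(base$vnir, base$swir)
  base$factor <- f
  base$year <- as.integer(year)
  base
}

# smooth multiplicative texture field with mean exactly 1 over the ellipse
.texture_field <- function(r, c, ell, roughness) {
  if (roughness <= 0) return(matrix(1, r, c))
  k <- max(3L, 2L * (round(min(r, c) / 16) %/% 2L) + 3L)  # odd width
  z <- matrix(stats::rnorm(r * c), r, c)
  z <- t(apply(z, 1L, function(v) stats::filter(v, rep(1 / k, k), circular = TRUE)))
  z <- apply(z, 2L, function(v) stats::filter(v, rep(1 / k, k), circular = TRUE))
  z <- z / max(stats::sd(z), 1e-12)
  t_f <- pmax(1 + roughness * z, 0.1)
  t_f / mean(t_f[ell])
}

.scene_geometry <- function(cfg) {
  r <- cfg$scene_rows; cc <- cfg$scene_cols
  wb <- cfg$whiteboard_rows
  avail <- min(wb) - max(4L, round(0.02 * r))   # scan rows left for the sample
  ctr_i <- (avail + 1) / 2; ctr_j <- (cc + 1) / 2
  a <- cfg$ellipse_frac[1] * avail; b <- cfg$ellipse_frac[2] * cc
  ii <- matrix(seq_len(r), r, cc)
  jj <- matrix(seq_len(cc), r, cc, byrow = TRUE)
  ell <- ((ii - ctr_i) / a)^2 + ((jj - ctr_j) / b)^2 <= 1
  if (!any(ell)) abort_domain("scene too small: sample ellipse is empty")
  wb_mask <- matrix(FALSE, r, cc); wb_mask[wb, ] <- TRUE
  fw <- cfg$flare_width
  flare <- matrix(FALSE, r, cc)
  if (fw > 0L) {
    edge_rows <- c(utils::head(wb, fw), utils::tail(wb, fw))
    flare[edge_rows, ] <- TRUE
    flare[wb, c(seq_len(fw), cc - seq_len(fw) + 1L)] <- TRUE
    flare <- flare & wb_mask
  }
  list(ell = ell, wb_mask = wb_mask, flare = flare,
       wroi_true = wb_mask & !flare)
}

.render_cube <- function(curve_vals, wl, range_tag, geom, t_field, cfg) {
  r <- cfg$scene_rows; cc <- cfg$scene_cols
  nb <- length(curve_vals)
  u <- (seq_len(cc) - (cc + 1) / 2) / ((cc - 1) / 2)
  illum <- 1 - cfg$illum_a * u^2
  illum_mat <- matrix(illum, r, cc, byrow = TRUE)
  base_wb <- matrix(0, r, cc)
  base_wb[geom$wb_mask] <- 1
  base_wb[geom$flare] <- cfg$flare_boost
  x <- array(0, c(r, cc, nb))
  bg <- cfg$background_rho
  for (b in seq_len(nb)) {
    rho <- matrix(bg, r, cc)
    rho[geom$ell] <- curve_vals[b] * t_field[geom$ell]
    rho[geom$wb_mask] <- base_wb[geom$wb_mask]
    x[, , b] <- cfg$gain * illum_mat * rho
  }
  if (is.finite(cfg$snr)) {
    noise <- 1 + stats::rnorm(length(x), 0, 1 / cfg$snr)
    x <- pmax(x * array(noise, dim(x)), 0)
  }
  hyper_cube(x, wl, range_tag = range_tag, value_kind = "dn",
             interleave = "bsq")
}

#' Render one sample's DN scene cubes from a true reflectance curve
#'
#' Builds the VNIR and SWIR DN cubes
#' `DN(i, j, b) = gain * illum(j) * rho_scene(i, j, b) * (1 + noise)` where
#' the scene reflectance is the whiteboard (1, flare-boosted at the strip
#' edges), the textured sample ellipse (`curve(b)` times a smooth
#' multiplicative texture with unit mean over the ellipse), or dark
#' background. Uses the current RNG state.
#'
#' @param curve a [make_reflectance_curve()] result.
#' @param cfg a [generator_config()].
#' @param sample_id id for the resulting record.
#' @return list with `record` (a DN [sample_record()]) and `truth` (true
#'   curve, true masks `groi`/`wroi`, illumination profile, `label_year`).
#' @export
render_scene <- function(curve, cfg, sample_id = "S001") {
  stopifnot(inherits(cfg, "generator_config"))
  geom <- .scene_geometry(cfg)
  t_field <- .texture_field(cfg$scene_rows, cfg$scene_cols, geom$ell,
                            cfg$texture_roughness)
  wl <- .gen_wavelengths(cfg)
  vnir <- .render_cube(curve$vnir, wl$vnir, "VNIR", geom, t_field, cfg)
  swir <- .render_cube(curve$swir, wl$swir, "SWIR", geom, t_field, cfg)
  u <- (seq_len(cfg$scene_cols) - (cfg$scene_cols + 1) / 2) /
    ((cfg$scene_cols - 1) / 2)
  list(record = sample_record(sample_id, vnir, swir, curve$year),
       truth = list(curve = curve, groi = geom$ell, wroi = geom$wroi_true,
                    flare = geom$flare, illum = 1 - cfg$illum_a * u^2,
                    texture = t_field, label_year = curve$year))
}

#' Generate one fully seeded sample
#'
#' @inheritParams render_scene
#' @param year growth year.
#' @export
simulate_sample <- function(year, cfg, sample_id = "S001") {
  render_scene(make_reflectance_curve(year, cfg), cfg, sample_id)
}

#' Scene layout matching the generator's geometry
#'
#' @param cfg a [generator_config()].
#' @param flare_margin erosion margin for segmentation; defaults to cover
#'   the generated flare width, capped so a thin whiteboard strip is not
#'   eroded away entirely.
#' @return a [scene_layout()].
#' @export
layout_from_config <- function(cfg, flare_margin = NULL) {
  if (is.null(flare_margin))
    flare_margin <- min(cfg$flare_width + 2L,
                        (length(cfg$whiteboard_rows) - 1L) %/% 2L)
  scene_layout(whiteboard_rows = cfg$whiteboard_rows,
               flare_margin = flare_margin,
               min_component_px = min(50L, max(1L, sum(.scene_geometry(cfg)$ell) %/% 4L)))
}

#' Generate a labeled synthetic dataset
#'
#' Draws `sum(n_per_year)` samples (default 84 with per-year counts
#' 17/11/12/12/8/12/12). Each sample gets its own seed derived from the
#' master seed, so individual samples can be re-rendered identically and
#' the whole dataset is byte-reproducible. Optionally writes ENVI cube
#' pairs, a labels CSV and a JSON manifest to `dir`, or streams records
#' through `callback(record, truth, index)` without keeping them.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory for ENVI cubes + labels.csv +
#'   manifest.json.
#' @param callback optional function called per sample; when given,
#'   records are not accumulated in memory.
#' @return list with `records` and `truths` (NULL under `callback`),
#'   `labels` (data.frame sample_id/label_year/label_use/seed), and
#'   `manifest`.
#' @export
make_dataset <- function(cfg, dir = NULL, callback = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  years <- rep(1:7, cfg$n_per_year)
  n <- length(years)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  sample_seeds <- sample.int(2^30, n)
  ids <- sprintf("S%03d_Y%d", seq_len(n), years)
  keep <- is.null(callback)
  records <- if (keep) vector("list", n)
  truths <- if (keep) vector("list", n)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(n)) {
    set.seed(sample_seeds[s])
    sim <- simulate_sample(years[s], cfg, ids[s])
    if (!is.null(dir)) {
      write_cube(sim$record$vnir, file.path(dir, paste0(ids[s], "_vnir")))
      write_cube(sim$record$swir, file.path(dir, paste0(ids[s], "_swir")))
    }
    if (!is.null(callback)) callback(sim$record, sim$truth, s)
    if (keep) { records[[s]] <- sim$record; truths[[s]] <- sim$truth }
  }
  labels <- data.frame(sample_id = ids, label_year = years,
                       label_use = ifelse(years <= 5L, "food", "medicinal"),
                       seed = sample_seeds)
  manifest <- list(config = unclass(cfg), n_samples = n,
                   sample_ids = ids, years = years)
  if (!is.null(dir)) {
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = records, truths = truths, labels = labels,
       manifest = manifest)
}
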