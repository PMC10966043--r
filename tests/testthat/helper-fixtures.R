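# Shared fixtures: small generator configurations and hand-built scenes.

# tiny generator config for fast unit tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(seed = 11L, scene_rows = 48L, scene_cols = 96L,
                   n_vnir = 20L, n_swir = 10L,
                   n_per_year = c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  do.call(generator_config, utils::modifyList(defaults, args))
}

# trimodal test scene: background / sample blob / whiteboard strip at known
# DN levels, one band
trimodal_scene <- function(rows = 40L, cols = 60L, wb_rows = 33:40,
                           bg = 50, blob = 400, strip = 900,
                           wavelength = 622) {
  g <- matrix(bg, rows, cols)
  blob_mask <- matrix(FALSE, rows, cols)
  blob_mask[10:22, 15:40] <- TRUE
  g[blob_mask] <- blob
  g[wb_rows, ] <- strip
  cube <- hyper_cube(array(g, c(rows, cols, 1L)), wavelength, "VNIR")
  list(cube = cube, blob = blob_mask, wb_rows = wb_rows)
}

# expected whiteboard mask after zero-padded box erosion by m on a solid
# full-width strip
eroded_strip <- function(rows, cols, wb_rows, m) {
  out <- matrix(FALSE, rows, cols)
  rr <- (min(wb_rows) + m):(max(wb_rows) - m)
  cc <- (1 + m):(cols - m)
  if (length(rr) > 0 && min(rr) <= max(wb_rows) - m && length(cc) > 0)
    out[rr, cc] <- TRUE
  out
}
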