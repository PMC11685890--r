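# Small builders used across the suite.

make_grid <- function(values, pixel_size = 100) {
  raster_grid(values, origin = c(0, nrow(values) * pixel_size),
              pixel_size = pixel_size)
}

random_grid <- function(nr, nc, pixel_size = 100, nodata_frac = 0) {
  v <- matrix(stats::runif(nr * nc, -1, 1), nr, nc)
  if (nodata_frac > 0) {
    v[sample.int(nr * nc, round(nodata_frac * nr * nc))] <- NA_real_
  }
  make_grid(v, pixel_size)
}

random_stack <- function(nr, nc, nlayers, pixel_size = 100, nodata_frac = 0) {
  raster_stack(lapply(seq_len(nlayers), function(i) {
    random_grid(nr, nc, pixel_size, nodata_frac)
  }), timestamps = seq_len(nlayers))
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Four rectangular quadrant regions covering an nr x nc grid.
quadrant_regions <- function(nr, nc, pixel_size = 100) {
  W <- nc * pixel_size; H <- nr * pixel_size
  region_set(
    ids = c("NW", "NE", "SW", "SE"),
    countries = c("MNG", "MNG", "IMNG", "IMNG"),
    polygons = list(rect_poly(0, H / 2, W / 2, H),
                    rect_poly(W / 2, H / 2, W, H),
                    rect_poly(0, 0, W / 2, H / 2),
                    rect_poly(W / 2, 0, W, H / 2)))
}
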