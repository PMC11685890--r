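#' Set of administrative region polygons
#'
#' @param ids character vector of unique region identifiers.
#' @param names character vector of display names.
#' @param countries character vector, each \code{"MNG"} or \code{"IMNG"}.
#' @param polygons list of closed polygon rings: two-column matrices of
#'   (x, y) vertices. The ring need not repeat the first vertex.
#' @param crs equal-area CRS tag shared with the rasters the set is used
#'   against.
#' @return An object of class \code{region_set}.
#' @export
region_set <- function(ids, names = ids, countries, polygons,
                       crs = "local-equal-area") {
  n <- length(ids)
  stopifnot(length(names) == n, length(countries) == n, length(polygons) == n)
  if (anyDuplicated(ids)) stop("region ids must be unique", call. = FALSE)
  if (!all(countries %in% c("MNG", "IMNG"))) {
    stop("country must be 'MNG' or 'IMNG'", call. = FALSE)
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop("each polygon needs >= 3 (x, y) vertices", call. = FALSE)
    }
    # drop an explicitly closed last vertex; the ring is implicit
    if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (abs(polygon_area(p)) <= 0) stop("polygon area must be positive",
                                        call. = FALSE)
    p
  })
  structure(list(ids = as.character(ids), names = as.character(names),
                 countries = countries, polygons = polygons, crs = crs),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions (%d MNG, %d IMNG), crs '%s'\n",
              length(x$ids), sum(x$countries == "MNG"),
              sum(x$countries == "IMNG"), x$crs))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$ids)

# Shoelace signed area of a ring given as an open vertex matrix.
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Vectorized even-odd (ray casting) point-in-polygon test. Points exactly on
# an edge may fall either side; pixel centers generated on a regular grid
# against axis-aligned region rectangles never sit on shared edges in the
# synthetic scenarios, and ties are resolved deterministically.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize regions onto a template grid
#'
#' Assigns each pixel to the region whose polygon contains the pixel center
#' (first matching region wins where polygons overlap). Pixels outside every
#' region are nodata.
#'
#' @param regions a \code{region_set}.
#' @param template a \code{raster_grid} defining the output geometry.
#' @return a \code{raster_grid} of integer region indices (1-based into
#'   \code{regions$ids}).
#' @export
rasterize_regions <- function(regions, template) {
  stopifnot(inherits(regions, "region_set"), is_raster_grid(template))
  ctr <- pixel_centers(template)
  lab <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (k in rev(seq_along(regions$polygons))) {
    hit <- points_in_polygon(as.vector(ctr$x), as.vector(ctr$y),
                             regions$polygons[[k]])
    lab[matrix(hit, nrow(lab), ncol(lab))] <- k
  }
  if (all(is.na(lab))) {
    warning("no pixel center falls inside any region; result is all nodata",
            call. = FALSE)
  }
  grid_like(template, lab, nodata = NA_real_)
}

#' Per-region mean of a raster
#'
#' Mean of \code{value} over the pixels inside each region (pixel-center
#' rule), optionally restricted to pixels where \code{mask} is true. Regions
#' with no eligible pixel are reported with \code{undefined = TRUE} and
#' \code{mean = NA}, never dropped.
#'
#' @param value a \code{raster_grid} of the quantity to average.
#' @param regions a \code{region_set}.
#' @param mask optional \code{raster_grid}; cells with value 0 or nodata are
#'   excluded.
#' @param region_raster optional precomputed \code{rasterize_regions} result
#'   (saves rework in pipelines).
#' @return data.frame with columns \code{region}, \code{mean}, \code{n_pixels},
#'   \code{undefined}.
#' @export
zonal_mean <- function(value, regions, mask = NULL, region_raster = NULL) {
  stopifnot(is_raster_grid(value))
  if (is.null(region_raster)) region_raster <- rasterize_regions(regions, value)
  check_aligned(c(list(value, region_raster),
                  if (!is.null(mask)) list(mask)))
  eligible <- grid_valid_mask(value)
  if (!is.null(mask)) {
    eligible <- eligible & grid_valid_mask(mask) & mask$values != 0
  }
  lab <- region_raster$values
  out <- data.frame(region = regions$ids, mean = NA_real_, n_pixels = 0L,
                    undefined = TRUE, stringsAsFactors = FALSE)
  for (k in seq_along(regions$ids)) {
    sel <- !is.na(lab) & lab == k & eligible
    n <- sum(sel)
    out$n_pixels[k] <- n
    if (n > 0L) {
      out$mean[k] <- mean(value$values[sel])
      out$undefined[k] <- FALSE
    }
  }
  out
}

#' Per-region masked area
#'
#' Counts masked pixels inside each region and converts to area using the
#' template's pixel size. Returned in both m\eqn{^2} (for the carrying-capacity
#' formula) and hectares (for per-ha reporting).
#'
#' @param regions a \code{region_set}.
#' @param mask \code{raster_grid}; pixels with nonzero, non-nodata value count.
#' @param template \code{raster_grid} defining geometry (defaults to the mask).
#' @param region_raster optional precomputed label raster.
#' @param pixel_area_m2 override for geographic-degrees grids
#'   (see \code{\link{pixel_area}}).
#' @return data.frame with columns \code{region}, \code{n_pixels},
#'   \code{area_m2}, \code{area_ha}.
#' @export
zonal_area <- function(regions, mask, template = mask, region_raster = NULL,
                       pixel_area_m2 = NULL) {
  stopifnot(is_raster_grid(mask))
  if (is.null(region_raster)) {
    region_raster <- rasterize_regions(regions, template)
  }
  check_aligned(list(mask, region_raster, template))
  px_m2 <- pixel_area(template, pixel_area_m2)
  eligible <- grid_valid_mask(mask) & mask$values != 0
  lab <- region_raster$values
  n <- vapply(seq_along(regions$ids), function(k) {
    sum(!is.na(lab) & lab == k & eligible)
  }, integer(1L))
  data.frame(region = regions$ids, n_pixels = n,
             area_m2 = n * px_m2, area_ha = n * px_m2 / 1e4,
             stringsAsFactors = FALSE)
}

#' Write a region set as GeoJSON
#'
#' Each region becomes a Polygon feature with properties \code{id},
#' \code{name} and \code{country}; the CRS tag goes into a top-level
#' \code{crs_tag} member.
#'
#' @param regions a \code{region_set}.
#' @param path output file.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- lapply(seq_along(regions$ids), function(k) {
    ring <- regions$polygons[[k]]
    ring <- rbind(ring, ring[1L, ])  # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(id = regions$ids[k], name = regions$names[k],
                           country = regions$countries[k]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1L, as.list,
                                                         simplify = FALSE)))))
  })
  doc <- list(type = "FeatureCollection", crs_tag = regions$crs,
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region set from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features carrying
#'   properties \code{id}, \code{name}, \code{country}.
#' @return a \code{region_set}.
#' @export
read_regions_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  feats <- doc$features
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  })
  region_set(
    ids = vapply(feats, function(f) f$properties$id, character(1L)),
    names = vapply(feats, function(f) f$properties$name, character(1L)),
    countries = vapply(feats, function(f) f$properties$country, character(1L)),
    polygons = polys,
    crs = if (!is.null(doc$crs_tag)) doc$crs_tag else "local-equal-area")
}
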