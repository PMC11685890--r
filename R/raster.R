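#' Georeferenced raster grid
#'
#' Lightweight container for a single-band raster: a numeric matrix plus an
#' affine geotransform, a CRS tag and a nodata sentinel. Row 1 is the
#' northernmost row (map orientation), matching the usual raster layout.
#'
#' The geotransform is the 6-tuple \code{(x_origin, pixel_width, 0,
#' y_origin, 0, -pixel_height)}: \code{x_origin, y_origin} are the
#' coordinates of the outer corner of the top-left pixel, pixel width is
#' positive and the y step negative (north-up).
#'
#' @param values numeric (or integer/logical) matrix of cell values.
#' @param origin numeric length-2, (x, y) of the top-left corner.
#' @param pixel_size numeric length-1 or 2, cell size in CRS units
#'   (positive; a single value means square pixels).
#' @param crs character CRS tag. Use an equal-area tag (anything other than
#'   \code{"EPSG:4326"}-style geographic degrees) for area computations.
#' @param nodata sentinel marking missing cells. \code{NA} by default.
#'
#' @return An object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, origin = c(0, 0), pixel_size = 1,
                        crs = "local-equal-area", nodata = NA_real_) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (any(!is.finite(pixel_size)) || any(pixel_size <= 0)) {
    stop("pixel sizes must be strictly positive", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values,
         transform = c(x_origin = origin[[1L]], px = pixel_size[[1L]], rx = 0,
                       y_origin = origin[[2L]], ry = 0, py = -pixel_size[[2L]]),
         crs = crs,
         nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- grid_valid_values(x)
  cat(sprintf("<raster_grid> %d x %d, pixel %g x %g, crs '%s'\n",
              nrow(x$values), ncol(x$values),
              x$transform[["px"]], -x$transform[["py"]], x$crs))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d valid / %d cells\n",
                min(v), max(v), length(v), length(x$values)))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Pixel area of a raster grid
#'
#' @param grid a \code{raster_grid}.
#' @param pixel_area_m2 override used (with a warning) when the grid's CRS is
#'   geographic degrees and cell area cannot be taken from the transform.
#' @return Pixel area in square metres (strictly positive).
#' @export
pixel_area <- function(grid, pixel_area_m2 = NULL) {
  stopifnot(is_raster_grid(grid))
  if (grid_is_geographic(grid)) {
    if (is.null(pixel_area_m2)) {
      stop("grid CRS is geographic degrees; supply `pixel_area_m2` explicitly",
           call. = FALSE)
    }
    warning("geographic-degrees grid: using user-supplied pixel area",
            call. = FALSE)
    return(pixel_area_m2)
  }
  area <- grid$transform[["px"]] * -grid$transform[["py"]]
  stopifnot(area > 0)
  unname(area)
}

grid_is_geographic <- function(grid) {
  grepl("4326|WGS84|longlat|degrees", grid$crs, ignore.case = TRUE)
}

#' Mask of valid (non-nodata) cells
#' @param grid a \code{raster_grid}.
#' @return logical matrix, TRUE where the cell holds data.
#' @export
grid_valid_mask <- function(grid) {
  v <- grid$values
  if (is.na(grid$nodata)) !is.na(v) else !is.na(v) & v != grid$nodata
}

grid_valid_values <- function(grid) grid$values[grid_valid_mask(grid)]

#' Coordinates of all pixel centers
#' @param grid a \code{raster_grid}.
#' @return list with matrices \code{x} and \code{y} of pixel-center coordinates.
#' @export
pixel_centers <- function(grid) {
  tr <- grid$transform
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- tr[["x_origin"]] + (seq_len(nc) - 0.5) * tr[["px"]]
  ys <- tr[["y_origin"]] + (seq_len(nr) - 0.5) * tr[["py"]]
  list(x = matrix(xs, nr, nc, byrow = TRUE),
       y = matrix(ys, nr, nc, byrow = FALSE))
}

#' Replace the value matrix of a grid, keeping georeferencing
#' @param grid template \code{raster_grid}.
#' @param values new matrix with the template's shape.
#' @param nodata nodata sentinel for the result.
#' @return a \code{raster_grid}.
#' @export
grid_like <- function(grid, values, nodata = grid$nodata) {
  stopifnot(is_raster_grid(grid), identical(dim(values), dim(grid$values)))
  out <- grid
  storage.mode(values) <- "double"
  out$values <- values
  out$nodata <- nodata
  out
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$transform - b$transform) < tol) &&
    identical(a$crs, b$crs)
}

check_aligned <- function(grids) {
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!same_geometry(ref, g)) {
      stop("rasters are not aligned: shape, transform and crs must match",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Temporal stack of aligned raster grids
#'
#' @param layers list of \code{raster_grid} objects sharing shape, transform
#'   and CRS.
#' @param timestamps vector of date labels (coercible to \code{Date} or
#'   already ordered labels), strictly increasing, one per layer.
#' @return An object of class \code{raster_stack}.
#' @export
raster_stack <- function(layers, timestamps = seq_along(layers)) {
  if (length(layers) == 0L) stop("empty stack", call. = FALSE)
  stopifnot(all(vapply(layers, is_raster_grid, logical(1L))))
  if (length(timestamps) != length(layers)) {
    stop("layer count must equal timestamp count", call. = FALSE)
  }
  ord <- if (inherits(timestamps, "Date")) as.numeric(timestamps)
         else if (is.numeric(timestamps)) timestamps
         else as.numeric(as.Date(timestamps))
  if (any(diff(ord) <= 0)) stop("timestamps must be strictly increasing",
                                call. = FALSE)
  check_aligned(layers)
  structure(list(layers = layers, timestamps = timestamps),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers of %d x %d\n", length(x$layers),
              nrow(x$layers[[1L]]$values), ncol(x$layers[[1L]]$values)))
  invisible(x)
}

#' @export
length.raster_stack <- function(x) length(x$layers)

# Nodata-aware per-pixel reduction over a stack. `fun` must accept a vector
# of valid values; cells valid in no layer become nodata.
stack_reduce <- function(stack, fun) {
  if (!inherits(stack, "raster_stack")) stop("not a raster_stack", call. = FALSE)
  layers <- stack$layers
  ref <- layers[[1L]]
  arr <- vapply(layers, function(g) {
    v <- g$values
    v[!grid_valid_mask(g)] <- NA_real_
    v
  }, ref$values)
  dim(arr) <- c(dim(ref$values), length(layers))
  out <- apply(arr, c(1L, 2L), function(series) {
    ok <- !is.na(series)
    if (!any(ok)) NA_real_ else fun(series[ok])
  })
  grid_like(ref, out, nodata = NA_real_)
}

#' Maximum value composite of a raster stack
#'
#' Per-pixel maximum across the temporal layers, ignoring nodata cells; a
#' pixel is nodata in the result only when it is nodata in every layer. The
#' standard compositing step for vegetation-index time series: taking the
#' maximum suppresses cloud- and aerosol-induced dips.
#'
#' @param stack a \code{raster_stack}.
#' @return a \code{raster_grid} composite.
#' @export
max_value_composite <- function(stack) stack_reduce(stack, max)

#' Temporal mean of a raster stack
#'
#' Per-pixel arithmetic mean over the layers, nodata-aware. Used for the
#' seasonal mean of land-surface temperature.
#'
#' @inheritParams max_value_composite
#' @return a \code{raster_grid}.
#' @export
temporal_mean <- function(stack) stack_reduce(stack, mean)

#' Temporal sum of a raster stack
#'
#' Per-pixel sum over the layers, nodata-aware. Used for seasonal total
#' precipitation.
#'
#' @inheritParams max_value_composite
#' @return a \code{raster_grid}.
#' @export
temporal_sum <- function(stack) stack_reduce(stack, sum)

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#' The CRS tag is stored in a sidecar \code{<path>.crs} single-line file.
#'
#' @param grid a \code{raster_grid} with square pixels.
#' @param path output file path.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(is_raster_grid(grid))
  tr <- grid$transform
  if (abs(tr[["px"]] - -tr[["py"]]) > 1e-9) {
    stop("ASCII grid requires square pixels", call. = FALSE)
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nodata_out <- -9999
  v <- grid$values
  v[!grid_valid_mask(grid)] <- nodata_out
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", tr[["x_origin"]]),
    sprintf("yllcorner %.10g", tr[["y_origin"]] + nr * tr[["py"]]),
    sprintf("cellsize %.10g", tr[["px"]]),
    sprintf("NODATA_value %d", nodata_out)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  writeLines(grid$crs, paste0(path, ".crs"))
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file written by \code{\link{write_ascii_grid}} (or any
#'   conforming ASCII grid).
#' @return a \code{raster_grid}; cells equal to the file's NODATA value
#'   become \code{NA}.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  vals <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(vals) <- NULL
  vals[vals == h[["nodata_value"]]] <- NA_real_
  crs_path <- paste0(path, ".crs")
  crs <- if (file.exists(crs_path)) readLines(crs_path, n = 1L)
         else "local-equal-area"
  raster_grid(vals,
              origin = c(h[["xllcorner"]],
                         h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]]),
              pixel_size = h[["cellsize"]], crs = crs)
}

#' Write a raster stack as dated ASCII grids with an index CSV
#'
#' @param stack a \code{raster_stack}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the per-date layers.
#' @return path of the index CSV (columns \code{date}, \code{path}).
#' @export
write_stack <- function(stack, dir, prefix = "layer") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$layers))
  for (i in seq_along(stack$layers)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.asc", prefix, i))
    write_ascii_grid(stack$layers[[i]], paths[i])
  }
  idx <- data.frame(date = as.character(stack$timestamps), path = paths)
  idx_path <- file.path(dir, paste0(prefix, "_index.csv"))
  utils::write.csv(idx, idx_path, row.names = FALSE)
  idx_path
}

#' Read a raster stack from an index CSV of dated ASCII grids
#'
#' @param index_csv path to a CSV with columns \code{date} and \code{path}
#'   (paths relative to the CSV's directory or absolute).
#' @return a \code{raster_stack}.
#' @export
read_stack <- function(index_csv) {
  idx <- utils::read.csv(index_csv, stringsAsFactors = FALSE)
  base <- dirname(index_csv)
  paths <- ifelse(file.exists(idx$path), idx$path, file.path(base, idx$path))
  layers <- lapply(paths, read_ascii_grid)
  ts <- suppressWarnings(as.numeric(idx$date))
  if (anyNA(ts)) ts <- idx$date
  raster_stack(layers, timestamps = ts)
}
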