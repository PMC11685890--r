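#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators: grid geometry, the
#' southwest-to-northeast biomass gradient, the latent linear link between
#' above-ground biomass (AGB) and the three seasonal predictors, land-cover
#' class fractions and separability, field-sampling noise, and per-region
#' livestock inventories. One seed determines every output; each generator
#' consumes its own derived stream (seed * 1000 + a fixed per-generator
#' offset), so adding a generator never shifts the outputs of another.
#'
#' Defaults emulate the eastern-steppe study conditions: a 128 x 128 grid of
#' 1 km pixels, biomass rising from 100 g/m2 in the southwest to 350 g/m2 in
#' the northeast, 327 field samples, land cover dominated by grassland
#' (~47%), bare land (~35%) and forest (~15%), and livestock inventories
#' compounding at ~4.2% per year over 2018-2022 (~18% over the period).
#'
#' @param seed integer master seed.
#' @param nrows,ncols grid shape in pixels.
#' @param pixel_size pixel edge length in metres (equal-area grid).
#' @param n_regions number of rectangular provinces partitioning the extent.
#' @param agb_gradient length-2: AGB at the southwest and northeast corners,
#'   g/m2.
#' @param agb_noise_sd spatial noise on the AGB truth field, g/m2.
#' @param predictor_coefs named numeric \code{(intercept, ndvi, precip, lst)}
#'   of the latent link AGB = b0 + b1 NDVI + b2 P + b3 LST + eps.
#' @param model_noise_sd sd of the link residual eps, g/m2.
#' @param ndvi_noise_sd,lst_noise_sd field noise on the NDVI and LST
#'   composites (NDVI dimensionless, LST degrees C).
#' @param n_ndvi_dates,n_lst_dates,n_precip_dates temporal layers per stack
#'   (16-day NDVI, 8-day LST, daily precipitation over June-August).
#' @param n_samples number of field biomass samples.
#' @param sample_noise_sd measurement noise on field samples, g/m2.
#' @param class_fractions named land-cover fractions summing to 1; must
#'   include \code{grassland}.
#' @param class_sep per-band gap between adjacent class feature means.
#' @param feature_noise_sd per-band feature noise sd.
#' @param n_features number of classification feature bands.
#' @param livestock_base named list \code{MNG} and \code{IMNG} of per-species
#'   base headcounts for a reference region.
#' @param livestock_growth annual compound growth fraction of headcounts
#'   (scalar or one value per region); must exceed -1.
#' @param livestock_region_scale per-region multiplier on base headcounts
#'   (recycled); defaults to an even spread around 1.
#' @param target_gcsi optional per-region target carrying-state index. When
#'   set, \code{\link{gen_livestock}} ignores the base inventories and
#'   instead issues sheep-only inventories sized so that actual SU equals
#'   target_gcsi times the region's analytic carrying capacity.
#' @param years inventory years.
#'
#' @return An object of class \code{scenario} (a validated list).
#' @export
scenario <- function(seed = 1L,
                     nrows = 128L, ncols = 128L, pixel_size = 1000,
                     n_regions = 8L,
                     agb_gradient = c(sw = 100, ne = 350),
                     agb_noise_sd = 30,
                     predictor_coefs = c(intercept = -150, ndvi = 300,
                                         precip = 1.2, lst = -5),
                     model_noise_sd = 0,
                     ndvi_noise_sd = 0.10, lst_noise_sd = 5,
                     n_ndvi_dates = 6L, n_lst_dates = 12L,
                     n_precip_dates = 92L,
                     n_samples = 327L, sample_noise_sd = 5,
                     class_fractions = c(grassland = 0.4709, bare = 0.346,
                                         forest = 0.1498, water = 0.0333),
                     class_sep = 10, feature_noise_sd = 9,
                     n_features = 10L,
                     livestock_base = list(
                       MNG = c(sheep = 45000, goat = 25000, horse = 3000,
                               cattle = 5000, camel = 400),
                       IMNG = c(cattle = 10000, horse = 2000,
                                sheep_goat = 45000, donkey = 800,
                                mule = 200, camel = 100)),
                     livestock_growth = 0.042,
                     livestock_region_scale = NULL,
                     target_gcsi = NULL,
                     years = 2018:2022) {
  stopifnot(nrows >= 1L, ncols >= 1L, pixel_size > 0, n_regions >= 1L,
            length(agb_gradient) == 2L, all(agb_gradient >= 0),
            agb_noise_sd >= 0, model_noise_sd >= 0, ndvi_noise_sd >= 0,
            lst_noise_sd >= 0, sample_noise_sd >= 0, feature_noise_sd >= 0,
            n_samples >= 2L, length(years) >= 1L)
  if (n_regions > nrows * ncols) {
    stop("n_regions exceeds pixel count", call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class fractions must sum to 1", call. = FALSE)
  }
  if (!"grassland" %in% names(class_fractions)) {
    stop("class fractions must include 'grassland'", call. = FALSE)
  }
  if (any(livestock_growth <= -1)) {
    stop("annual growth below -100% is invalid", call. = FALSE)
  }
  if (is.null(livestock_region_scale)) {
    livestock_region_scale <- if (n_regions == 1L) 1
                              else seq(0.7, 1.3, length.out = n_regions)
  }
  structure(list(
    seed = as.integer(seed), nrows = as.integer(nrows),
    ncols = as.integer(ncols), pixel_size = pixel_size,
    n_regions = as.integer(n_regions), agb_gradient = agb_gradient,
    agb_noise_sd = agb_noise_sd, predictor_coefs = predictor_coefs,
    model_noise_sd = model_noise_sd, ndvi_noise_sd = ndvi_noise_sd,
    lst_noise_sd = lst_noise_sd, n_ndvi_dates = as.integer(n_ndvi_dates),
    n_lst_dates = as.integer(n_lst_dates),
    n_precip_dates = as.integer(n_precip_dates),
    n_samples = as.integer(n_samples), sample_noise_sd = sample_noise_sd,
    class_fractions = class_fractions, class_sep = class_sep,
    feature_noise_sd = feature_noise_sd, n_features = as.integer(n_features),
    livestock_base = livestock_base, livestock_growth = livestock_growth,
    livestock_region_scale = livestock_region_scale,
    target_gcsi = target_gcsi, years = as.integer(years)),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("<scenario> seed %d: %dx%d grid @ %g m, %d regions, ",
                     "AGB %g-%g g/m2, %d samples\n"),
              x$seed, x$nrows, x$ncols, x$pixel_size, x$n_regions,
              x$agb_gradient[[1L]], x$agb_gradient[[2L]], x$n_samples))
  invisible(x)
}

#' Read/write a scenario as a YAML config file
#' @param path file path.
#' @return \code{read_scenario} returns a \code{scenario}.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("agb_gradient", "predictor_coefs", "class_fractions")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$livestock_base)) {
    cfg$livestock_base <- lapply(cfg$livestock_base, unlist)
  }
  do.call(scenario, cfg)
}

#' @rdname read_scenario
#' @param scn a \code{scenario}.
#' @export
write_scenario <- function(scn, path) {
  out <- unclass(scn)
  # keep names of named vectors (YAML maps, not sequences)
  for (nm in c("agb_gradient", "predictor_coefs", "class_fractions")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  out$livestock_base <- lapply(out$livestock_base, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Seed discipline: each generator draws from its own stream derived from the
# master seed, and the caller's RNG state is restored on exit.
with_gen_seed <- function(scn, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scn$seed * 1000L + offset)
  expr
}

# Normalized SW->NE position of each pixel center: 0 at the southwest corner
# pixel, 1 at the northeast corner pixel.
ramp_position <- function(nrows, ncols) {
  xn <- if (ncols == 1L) rep(0, ncols) else (seq_len(ncols) - 1) / (ncols - 1)
  yn <- if (nrows == 1L) rep(0, nrows) else (nrows - seq_len(nrows)) / (nrows - 1)
  (matrix(xn, nrows, ncols, byrow = TRUE) + matrix(yn, nrows, ncols)) / 2
}

template_grid <- function(scn) {
  raster_grid(matrix(0, scn$nrows, scn$ncols),
              origin = c(0, scn$nrows * scn$pixel_size),
              pixel_size = scn$pixel_size)
}

#' Generate rectangular region polygons partitioning the grid extent
#'
#' The extent is tiled into \code{n_regions} equal rectangles (as close to a
#' square tiling as the count allows); the first half of the regions is
#' tagged MNG, the rest IMNG.
#'
#' @param scn a \code{\link{scenario}}.
#' @return a \code{\link{region_set}}.
#' @export
gen_regions <- function(scn) {
  n <- scn$n_regions
  d <- max(which(n %% seq_len(floor(sqrt(n))) == 0L))  # tile rows
  m <- n %/% d                                          # tile cols
  W <- scn$ncols * scn$pixel_size
  H <- scn$nrows * scn$pixel_size
  polys <- vector("list", n)
  k <- 0L
  for (i in seq_len(d)) for (j in seq_len(m)) {
    k <- k + 1L
    x0 <- (j - 1) * W / m; x1 <- j * W / m
    y1 <- H - (i - 1) * H / d; y0 <- H - i * H / d
    polys[[k]] <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  ids <- sprintf("R%02d", seq_len(n))
  n_mng <- ceiling(n / 2)
  region_set(ids = ids, names = paste("Province", seq_len(n)),
             countries = c(rep("MNG", n_mng), rep("IMNG", n - n_mng)),
             polygons = polys)
}

#' Generate the AGB truth field
#'
#' A bilinear ramp from the southwest gradient endpoint to the northeast
#' endpoint plus Gaussian spatial noise, clipped below at 0 g/m2.
#'
#' @param scn a \code{\link{scenario}}.
#' @return a \code{raster_grid} of AGB in g/m2.
#' @export
gen_agb_truth <- function(scn) {
  t <- ramp_position(scn$nrows, scn$ncols)
  sw <- scn$agb_gradient[[1L]]; ne <- scn$agb_gradient[[2L]]
  vals <- sw + (ne - sw) * t
  if (scn$agb_noise_sd > 0) {
    vals <- vals + with_gen_seed(scn, 2L, {
      matrix(stats::rnorm(length(vals), 0, scn$agb_noise_sd),
             scn$nrows, scn$ncols)
    })
  }
  grid_like(template_grid(scn), pmax(vals, 0))
}

#' Generate predictor stacks consistent with the latent AGB link
#'
#' Builds seasonal NDVI, LST and precipitation composites satisfying
#' \code{AGB = b0 + b1 NDVI + b2 P + b3 LST + eps} by construction (NDVI and
#' LST fields are drawn, eps ~ N(0, model_noise_sd), and precipitation is
#' solved from the link), then expands each composite into dated layers whose
#' recomposition returns it exactly: NDVI layers never exceed the composite
#' and touch it on one date per pixel (maximum-value compositing inverts
#' them), LST date perturbations average to zero, and daily precipitation
#' weights sum to one.
#'
#' @param scn a \code{\link{scenario}}.
#' @param agb_truth the grid from \code{\link{gen_agb_truth}}.
#' @return list of \code{raster_stack}s: \code{ndvi}, \code{lst},
#'   \code{precip}.
#' @export
gen_predictor_stacks <- function(scn, agb_truth) {
  stopifnot(is_raster_grid(agb_truth))
  nr <- scn$nrows; nc <- scn$ncols; np <- nr * nc
  b <- scn$predictor_coefs
  t <- ramp_position(nr, nc)
  with_gen_seed(scn, 3L, {
    ndvi <- 0.15 + 0.0018 * agb_truth$values +
      matrix(stats::rnorm(np, 0, scn$ndvi_noise_sd), nr, nc)
    ndvi <- pmin(pmax(ndvi, -1), 1)
    lst <- 30 - 12 * t + matrix(stats::rnorm(np, 0, scn$lst_noise_sd), nr, nc)
    eps <- matrix(stats::rnorm(np, 0, scn$model_noise_sd), nr, nc)
    precip <- (agb_truth$values - b[["intercept"]] - b[["ndvi"]] * ndvi -
                 b[["lst"]] * lst - eps) / b[["precip"]]

    tmpl <- template_grid(scn)
    # NDVI: composite minus non-negative dips, zero dip on one date per pixel
    nd <- scn$n_ndvi_dates
    peak <- matrix(sample.int(nd, np, replace = TRUE), nr, nc)
    ndvi_layers <- lapply(seq_len(nd), function(d) {
      dip <- matrix(stats::runif(np, 0.02, 0.2), nr, nc)
      dip[peak == d] <- 0
      grid_like(tmpl, ndvi - dip)
    })
    # LST: date perturbations centred per pixel so the mean is exact
    nl <- scn$n_lst_dates
    pert <- array(stats::rnorm(np * nl, 0, 2), c(nr, nc, nl))
    pert <- sweep(pert, c(1L, 2L), apply(pert, c(1L, 2L), mean))
    lst_layers <- lapply(seq_len(nl), function(d) {
      grid_like(tmpl, lst + pert[, , d])
    })
    # Precipitation: random daily shares of the seasonal total
    nq <- scn$n_precip_dates
    w <- array(stats::rgamma(np * nq, shape = 0.8), c(nr, nc, nq))
    w <- sweep(w, c(1L, 2L), apply(w, c(1L, 2L), sum), "/")
    precip_layers <- lapply(seq_len(nq), function(d) {
      grid_like(tmpl, precip * w[, , d])
    })
    list(
      ndvi = raster_stack(ndvi_layers,
                          timestamps = as.Date("2020-06-01") +
                            16 * (seq_len(nd) - 1)),
      lst = raster_stack(lst_layers,
                         timestamps = as.Date("2020-06-01") +
                           8 * (seq_len(nl) - 1)),
      precip = raster_stack(precip_layers,
                            timestamps = as.Date("2020-06-01") +
                              seq_len(nq) - 1))
  })
}

#' Generate field biomass samples
#'
#' Draws sample locations uniformly over grassland pixels (from the
#' scenario's land-cover truth unless a label raster is supplied) and
#' perturbs the truth value with Gaussian measurement noise.
#'
#' @param scn a \code{\link{scenario}}.
#' @param agb_truth grid from \code{\link{gen_agb_truth}}.
#' @param labels optional land-cover label raster; defaults to the
#'   scenario's own \code{\link{gen_landcover}} truth.
#' @return data.frame with columns \code{x}, \code{y},
#'   \code{agb_g_m2}.
#' @export
gen_field_samples <- function(scn, agb_truth, labels = NULL) {
  stopifnot(scn$n_samples >= 2L)
  if (is.null(labels)) labels <- gen_landcover(scn)$labels
  grass_code <- landcover_codebook()[["grassland"]]
  candidates <- which(grid_valid_mask(labels) & labels$values == grass_code)
  if (length(candidates) == 0L) stop("no grassland pixels to sample",
                                     call. = FALSE)
  with_gen_seed(scn, 4L, {
    idx <- sample(candidates, scn$n_samples, replace = TRUE)
    rc <- arrayInd(idx, dim(agb_truth$values))
    px <- scn$pixel_size
    jx <- stats::runif(scn$n_samples, -0.45, 0.45)
    jy <- stats::runif(scn$n_samples, -0.45, 0.45)
    x <- (rc[, 2L] - 0.5 + jx) * px
    y <- (scn$nrows - rc[, 1L] + 0.5 + jy) * px
    measured <- agb_truth$values[idx] +
      stats::rnorm(scn$n_samples, 0, scn$sample_noise_sd)
    data.frame(x = x, y = y, agb_g_m2 = pmax(measured, 0))
  })
}

#' Land-cover class codebook
#'
#' Integer codes for the cover classes used throughout the package.
#' @return named integer vector.
#' @export
landcover_codebook <- function() {
  c(grassland = 1L, bare = 2L, forest = 3L, water = 4L,
    cropland = 5L, built = 6L, other = 7L)
}

#' Generate land-cover truth and classification features
#'
#' Labels come from a smooth random field thresholded at the quantiles of
#' the configured class fractions, giving spatially coherent blobs whose
#' areal shares match the fractions to within rounding. Each of the feature
#' bands is the class-dependent mean plus Gaussian noise, so classes are
#' separable to a degree set by \code{class_sep / feature_noise_sd}.
#'
#' @param scn a \code{\link{scenario}}.
#' @return list with \code{labels} (a \code{raster_grid} of class codes) and
#'   \code{features} (a \code{raster_stack} of feature bands).
#' @export
gen_landcover <- function(scn) {
  nr <- scn$nrows; nc <- scn$ncols; np <- nr * nc
  fr <- scn$class_fractions
  codes <- landcover_codebook()[names(fr)]
  if (anyNA(codes)) stop("unknown land-cover class in fractions", call. = FALSE)
  with_gen_seed(scn, 5L, {
    field <- smooth_field(nr, nc, coarse = 8L)
    labels <- matrix(codes[[1L]], nr, nc)
    if (length(fr) > 1L) {
      qs <- stats::quantile(field, cumsum(fr)[-length(fr)])
      cls <- findInterval(field, qs, left.open = TRUE) + 1L
      labels <- matrix(codes[cls], nr, nc)
    }
    tmpl <- template_grid(scn)
    means <- outer(seq_along(landcover_codebook()),
                   seq_len(scn$n_features),
                   function(k, j) scn$class_sep * k + 2 * j)
    feats <- lapply(seq_len(scn$n_features), function(j) {
      grid_like(tmpl, matrix(means[labels, j] +
                               stats::rnorm(np, 0, scn$feature_noise_sd),
                             nr, nc))
    })
    list(labels = grid_like(tmpl, labels),
         features = raster_stack(feats, timestamps = seq_len(scn$n_features)))
  })
}

# Smooth unit-variance field: coarse white noise, bilinearly upsampled.
smooth_field <- function(nr, nc, coarse = 8L) {
  cr <- min(coarse, nr); cc <- min(coarse, nc)
  z <- matrix(stats::rnorm(cr * cc), cr, cc)
  ri <- if (nr == 1L) rep(1, nr) else seq(1, cr, length.out = nr)
  ci <- if (nc == 1L) rep(1, nc) else seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1L); c0 <- pmin(floor(ci), cc - 1L)
  fr <- ri - r0; fc <- ci - c0
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    out[i, ] <- (1 - fr[i]) * ((1 - fc) * z[r0[i], cbind(c0)] +
                                 fc * z[r0[i], c0 + 1L]) +
      fr[i] * ((1 - fc) * z[r0[i] + 1L, c0] + fc * z[r0[i] + 1L, c0 + 1L])
  }
  out + matrix(stats::rnorm(nr * nc, 0, 0.15), nr, nc)
}

#' Generate per-region livestock inventories
#'
#' Headcounts compound annually:
#' \code{headcount(region, species, year) = base * scale_region *
#' (1 + growth)^(year - year0)}, rounded to integers. MNG regions carry
#' sheep, goats, horses, cattle and camels; IMNG regions carry cattle,
#' horses, merged sheep/goats, donkeys, mules and camels.
#'
#' When the scenario sets \code{target_gcsi}, inventories are instead
#' sheep-only with headcount equal to the target index times the region's
#' analytic carrying capacity (see \code{\link{analytic_capacity}}), constant
#' across years — the configuration used for end-to-end recovery checks.
#'
#' @param scn a \code{\link{scenario}}.
#' @param params \code{\link{carrying_params}} used only for the
#'   \code{target_gcsi} mode.
#' @return an inventory data.frame (region, country, year, species,
#'   headcount).
#' @export
gen_livestock <- function(scn, params = carrying_params()) {
  regions <- gen_regions(scn)
  years <- scn$years
  y0 <- years[[1L]]
  if (!is.null(scn$target_gcsi)) {
    stopifnot(length(scn$target_gcsi) == scn$n_regions)
    cap <- analytic_capacity(scn, params)
    recs <- do.call(rbind, lapply(seq_along(regions$ids), function(k) {
      country <- regions$countries[k]
      sp <- if (country == "MNG") "sheep" else "sheep_goat"
      coef <- default_coefficients(country)[[sp]]
      data.frame(region = regions$ids[k], country = country,
                 year = years, species = sp,
                 headcount = round(scn$target_gcsi[[k]] *
                                     cap$gcc_total_su[k] / coef))
    }))
    rownames(recs) <- NULL
    return(recs)
  }
  growth <- rep_len(scn$livestock_growth, scn$n_regions)
  scale <- rep_len(scn$livestock_region_scale, scn$n_regions)
  recs <- do.call(rbind, lapply(seq_along(regions$ids), function(k) {
    base <- scn$livestock_base[[regions$countries[k]]]
    do.call(rbind, lapply(seq_along(years), function(iy) {
      data.frame(region = regions$ids[k], country = regions$countries[k],
                 year = years[iy], species = names(base),
                 headcount = round(base * scale[k] *
                                     (1 + growth[k])^(years[iy] - y0)))
    }))
  }))
  rownames(recs) <- NULL
  recs
}

#' Analytic carrying capacity of the noise-free scenario
#'
#' Closed-form regional carrying capacity implied by the scenario's exact
#' bilinear AGB ramp and rectangular regions: the ground truth against which
#' pipeline estimates are judged. Grassland area is taken as the region area
#' times the scenario's overall grassland class fraction (cover blobs are
#' generated independently of the biomass ramp, so this is the expected
#' grassland area; regional cover shares fluctuate around it).
#'
#' @param scn a \code{\link{scenario}}.
#' @param params \code{\link{carrying_params}}.
#' @return data.frame with \code{region}, \code{mean_agb_g_m2},
#'   \code{area_ha}, \code{gcc_total_su}, \code{gcc_su_per_ha}.
#' @export
analytic_capacity <- function(scn, params = carrying_params()) {
  regions <- gen_regions(scn)
  tmpl <- template_grid(scn)
  lab <- rasterize_regions(regions, tmpl)
  t <- ramp_position(scn$nrows, scn$ncols)
  sw <- scn$agb_gradient[[1L]]; ne <- scn$agb_gradient[[2L]]
  px_m2 <- scn$pixel_size^2
  grass_frac <- scn$class_fractions[["grassland"]]
  out <- do.call(rbind, lapply(seq_along(regions$ids), function(k) {
    sel <- !is.na(lab$values) & lab$values == k
    mean_agb <- sw + (ne - sw) * mean(t[sel])
    area_m2 <- sum(sel) * px_m2 * grass_frac
    cap <- carrying_capacity(mean_agb, area_m2, params)
    data.frame(region = regions$ids[k], mean_agb_g_m2 = mean_agb,
               area_ha = area_m2 / 1e4, gcc_total_su = cap$gcc_total_su,
               gcc_su_per_ha = cap$gcc_su_per_ha)
  }))
  rownames(out) <- NULL
  out
}

#' Packaged region-by-year standard-livestock-unit table, 2018-2022
#'
#' The published end-of-year standard livestock units (thousands of SU) for
#' the 16 eastern-plateau provinces and leagues, 2018-2022, shipped with the
#' package as a CSV.
#'
#' @return an \code{\link{su_table}} with units \code{"thousands"}.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_su.csv", package = "rangebalance")
  if (path == "" || !file.exists(path)) {
    stop("packaged SU table is missing; reinstall the package", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "country", "year", "su_thousands")
  if (!all(need %in% names(df)) || nrow(df) == 0L) {
    stop("packaged SU table is corrupt", call. = FALSE)
  }
  su_table(data.frame(region = df$region, country = df$country,
                      year = df$year, su = df$su_thousands),
           units = "thousands")
}
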