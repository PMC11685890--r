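#' Run the full grazing-balance pipeline on a synthetic scenario
#'
#' Chains every stage: synthetic input generation, land-cover classification
#' and accuracy assessment, temporal compositing, AGB model fitting and
#' validation, productivity classification, regional carrying capacity, SU
#' conversion and the final balance table.
#'
#' @param scn a \code{\link{scenario}}.
#' @param params \code{\link{carrying_params}}.
#' @param agb_method \code{"linear"} or \code{"random_forest"}.
#' @param lc_method \code{"random_forest"} or \code{"nearest_centroid"}.
#' @param n_train,n_validate land-cover training and validation sample sizes.
#' @return list of stage artifacts: \code{scenario}, \code{regions},
#'   \code{landcover} (classifier, map, accuracy), \code{composites},
#'   \code{agb} (model, validation, map, productivity), \code{capacity},
#'   \code{su}, \code{balance}, \code{growth}.
#' @export
run_pipeline <- function(scn = scenario(), params = carrying_params(),
                         agb_method = "linear", lc_method = "random_forest",
                         n_train = 2500L, n_validate = 1500L) {
  regions <- gen_regions(scn)
  agb_truth <- gen_agb_truth(scn)
  stacks <- gen_predictor_stacks(scn, agb_truth)
  lc <- gen_landcover(scn)

  # --- land cover: sample truth, train, map, assess ---
  np <- length(lc$labels$values)
  if (n_train + n_validate > np) {
    stop("training + validation samples exceed pixel count", call. = FALSE)
  }
  samp_idx <- with_gen_seed(scn, 7L, sample.int(np, n_train + n_validate))
  train_idx <- samp_idx[seq_len(n_train)]
  val_idx <- samp_idx[n_train + seq_len(n_validate)]
  feat_mat <- vapply(lc$features$layers, function(g) as.vector(g$values),
                     numeric(np))
  lab_vec <- as.vector(lc$labels$values)
  classifier <- train_classifier(feat_mat[train_idx, , drop = FALSE],
                                 lab_vec[train_idx], method = lc_method,
                                 seed = scn$seed * 1000L + 8L)
  lc_map <- predict_landcover(classifier, lc$features)
  cm <- confusion_matrix(lab_vec[val_idx],
                         as.vector(lc_map$values)[val_idx])
  accuracy <- accuracy_metrics(cm)

  # --- composites ---
  composites <- list(ndvi = max_value_composite(stacks$ndvi),
                     lst = temporal_mean(stacks$lst),
                     precip = temporal_sum(stacks$precip))

  # --- AGB model ---
  samples <- gen_field_samples(scn, agb_truth, labels = lc$labels)
  X <- sample_predictors(composites, samples)
  keep <- match(paste(X$x, X$y), paste(samples$x, samples$y))
  y <- samples$agb_g_m2[keep]
  model <- fit_agb_model(X, y, method = agb_method,
                         seed = scn$seed * 1000L + 9L)
  validation <- validate_agb(stats::predict(model, X), y)
  agb_map <- predict_agb(model, composites)
  productivity <- classify_productivity(agb_map)

  # --- regional capacity over the classified grassland ---
  mask <- grassland_mask(lc_map)
  region_raster <- rasterize_regions(regions, agb_map)
  zm <- zonal_mean(agb_map, regions, mask = mask,
                   region_raster = region_raster)
  za <- zonal_area(regions, mask, template = agb_map,
                   region_raster = region_raster)
  cap <- carrying_capacity(ifelse(zm$undefined, 0, zm$mean), za$area_m2,
                           params)
  capacity <- data.frame(region = regions$ids,
                         mean_agb_g_m2 = zm$mean, area_ha = za$area_ha,
                         gcc_total_su = cap$gcc_total_su,
                         gcc_su_per_ha = cap$gcc_su_per_ha,
                         stringsAsFactors = FALSE)

  # --- livestock and balance ---
  inventory <- gen_livestock(scn, params)
  su <- convert_to_su(inventory)
  balance <- balance_table(capacity, su)
  y0 <- min(scn$years); y1 <- max(scn$years)
  growth <- list(
    per_region = data.frame(
      region = regions$ids,
      growth_pct = vapply(regions$ids, function(r) {
        growth_rate(su, r, y0, y1)
      }, numeric(1L))),
    mean_pct = mean_growth_rate(su, y0, y1),
    annual_head_increase = annual_average_increase(inventory, y0, y1))

  list(scenario = scn, params = params, regions = regions,
       landcover = list(classifier = classifier, map = lc_map,
                        truth = lc$labels, confusion = cm,
                        accuracy = accuracy),
       composites = composites,
       agb = list(truth = agb_truth, samples = samples, model = model,
                  validation = validation, map = agb_map,
                  productivity = productivity),
       capacity = capacity, inventory = inventory, su = su,
       balance = balance, growth = growth)
}

#' Write pipeline outputs to a directory
#'
#' Serializes the main artifacts in standard plain formats (CSV, GeoJSON,
#' ASCII grid, JSON) plus a run log carrying the seed, a config hash and
#' per-stage record counts, so two runs with the same scenario can be
#' compared byte for byte.
#'
#' @param result value of \code{\link{run_pipeline}}.
#' @param outdir output directory (created if needed).
#' @param rasters also write the AGB/land-cover/productivity rasters
#'   (ASCII grid; off by default to keep output small).
#' @return \code{outdir}, invisibly.
#' @export
write_outputs <- function(result, outdir, rasters = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  bal <- as.data.frame(result$balance)
  bal$load_class <- as.character(bal$load_class)
  utils::write.csv(bal, p("balance.csv"), row.names = FALSE)
  utils::write.csv(result$capacity, p("capacity.csv"), row.names = FALSE)
  write_su_csv(result$su, p("su.csv"))
  utils::write.csv(result$inventory, p("inventory.csv"), row.names = FALSE)
  utils::write.csv(result$growth$per_region, p("growth.csv"),
                   row.names = FALSE)
  acc <- result$landcover$accuracy
  jsonlite::write_json(
    list(overall_accuracy = acc$overall_accuracy, kappa = acc$kappa,
         per_class = acc$per_class,
         class_fractions = class_fractions(result$landcover$map),
         agb_validation = result$agb$validation),
    p("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  write_regions_geojson(result$regions, p("regions.geojson"))
  if (rasters) {
    write_ascii_grid(result$agb$map, p("agb.asc"))
    write_ascii_grid(result$landcover$map, p("landcover.asc"))
    write_ascii_grid(result$agb$productivity, p("productivity.asc"))
  }
  cfg <- tempfile(fileext = ".yml")
  write_scenario(result$scenario, cfg)
  log_lines <- c(
    sprintf("seed: %d", result$scenario$seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg))),
    sprintf("regions: %d", length(result$regions)),
    sprintf("field_samples: %d", nrow(result$agb$samples)),
    sprintf("samples_excluded: %d",
            attr(result$agb$samples, "n_excluded") %||% 0L),
    sprintf("balance_records: %d", nrow(result$balance)),
    sprintf("carrying_params: usable_fraction=%g intake=%g days=%g",
            result$params$usable_fraction, result$params$intake_kg_per_day,
            result$params$grazing_days))
  writeLines(log_lines, p("run_log.txt"))
  unlink(cfg)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Growth-rate report for an SU table
#'
#' Per-region growth between the table's first and last year, plus the
#' unweighted mean — the regional trend summary for a published or generated
#' SU table.
#'
#' @param su an \code{\link{su_table}}.
#' @param year0,year1 endpoints (default: the table's min and max year).
#' @return list with \code{per_region} data.frame and \code{mean_pct}.
#' @export
growth_report <- function(su, year0 = min(su$year), year1 = max(su$year)) {
  regs <- unique(su$region)
  per_region <- data.frame(
    region = regs,
    growth_pct = vapply(regs, function(r) growth_rate(su, r, year0, year1),
                        numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(per_region) <- NULL
  list(per_region = per_region,
       mean_pct = mean_growth_rate(su, year0, year1),
       year0 = year0, year1 = year1)
}
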